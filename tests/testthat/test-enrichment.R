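# exhaustive-enumeration oracle: fraction of n-subsets of {1..N} with at
# least x elements among the first M, computed by brute force
enum_upper_tail <- function(N, M, n, x) {
  if (n == 0) return(if (x == 0) 1 else stop("invalid"))
  subsets <- utils::combn(N, n)
  mean(colSums(subsets <= M) >= x)
}

test_that("hypergeometric upper tail matches hand-derived values", {
  expect_equal(hypergeom_upper_tail(10, 4, 3, 0), 1)       # full tail
  expect_equal(hypergeom_upper_tail(10, 4, 3, 2), 1 / 3)   # enumeration by hand
  expect_equal(hypergeom_upper_tail(6, 3, 3, 3), 1 / 20)   # single extreme term
  expect_error(hypergeom_upper_tail(10, 4, 3, 4), "exceeds min")
  expect_error(hypergeom_upper_tail(10, 4, 11, 1), "universe")
  expect_error(hypergeom_upper_tail(10, -1, 3, 0), "nonnegative")
})

test_that("hypergeometric tail agrees with enumeration on small universes", {
  worst <- 0
  for (N in c(5, 8, 10)) {
    for (n in 0:N) {
      for (M in c(0, 2, N %/% 2, N)) {
        for (x in 0:min(M, n)) {
          worst <- max(worst, abs(hypergeom_upper_tail(N, M, n, x) -
                                    enum_upper_tail(N, M, n, x)))
        }
      }
    }
  }
  expect_lt(worst, 1e-12)
})

test_that("p-to-z transformation is the inverse normal tail", {
  expect_equal(p_to_z(0.5), 0)
  expect_equal(p_to_z(0.05), 1.644853626951, tolerance = 1e-9)
  # clamped below: finite and equal to the clamp image
  expect_equal(p_to_z(1e-300), p_to_z(1e-16))
  expect_true(is.finite(p_to_z(1)))
  expect_error(p_to_z(0), "domain")
  expect_error(p_to_z(1.2), "domain")

  # round trip on z in [-6, 6] above the clamp
  z <- seq(-6, 6, by = 0.25)
  expect_equal(p_to_z(stats::pnorm(z, lower.tail = FALSE)), z,
               tolerance = 1e-9)
  # strictly decreasing in p
  p <- seq(0.01, 0.99, by = 0.01)
  expect_true(all(diff(p_to_z(p)) < 0))
})

test_that("contrast enrichment scores every pathway in both directions", {
  gs <- as_gene_sets(list(pw1 = c("g1", "g2", "g3"),
                          pw2 = c("g4", "g5", "g6", "g7"),
                          pw3 = c("g8", "g9", "g10")))
  # up-set is exactly pw1 with M = 3: p = 1/C(10,3)
  fc <- stats::setNames(c(2, 2, 2, rep(0, 7)), paste0("g", 1:10))
  ct <- select_degs(fc, 2)
  enr <- enrich_contrast(ct, gs)
  up <- enr$pathways[enr$pathways$direction == "up", ]
  expect_equal(up$p[up$pathway == "pw1"], 1 / choose(10, 3))
  expect_true(up$significant[up$pathway == "pw1"])
  expect_equal(up$p[up$pathway == "pw3"], 1)          # disjoint, x = 0
  expect_false(up$significant[up$pathway == "pw3"])

  # empty DEG sets: all p = 1, nothing significant
  none <- enrich_contrast(select_degs(fc * 0, 2), gs)
  expect_true(all(none$pathways$p == 1))
  expect_false(any(none$pathways$significant))
  expect_true(all(is.finite(none$pathways$z)))

  # DEGs outside the annotation are dropped and counted
  fc2 <- c(fc, gX = 5)
  enr2 <- enrich_contrast(select_degs(fc2, 2), gs)
  expect_equal(unname(enr2$dropped["up"]), 1)
  expect_equal(enr2$pathways$M[enr2$pathways$direction == "up"][1], 3)

  expect_error(enrich_contrast(ct, as_gene_sets(list())), "empty annotation")
})

test_that("meta-z follows the configured denominator convention", {
  expect_equal(meta_z(1.7), 1.7)                     # n = 1, both conventions
  expect_equal(meta_z(1.7, "n"), 1.7)
  expect_equal(meta_z(c(1, 1, 1, 1)), 2)             # 4 / sqrt(4)
  expect_equal(meta_z(c(1, 1, 1, 1), "n"), 1)
  expect_equal(meta_z(c(1, -1)), 0)
  expect_equal(meta_z(c(1, -1), "n"), 0)
  expect_error(meta_z(numeric(0)), "empty")

  # permutation invariance and linearity
  set.seed(3)
  z <- stats::rnorm(7)
  expect_equal(meta_z(z), meta_z(sample(z)))
  expect_equal(meta_z(2 * z + 0), 2 * meta_z(z))
  expect_equal(meta_z(z) + meta_z(rev(z)), meta_z(z + rev(z)))
})

test_that("profile aggregation rolls pathway z up the hierarchy", {
  h <- toy_hierarchy()
  # single chain: subsystem and system inherit the lone pathway's z
  prof1 <- aggregate_profile(fake_enrichment("P3", 1.7), h)
  expect_equal(prof1$subsystems$meta_z[prof1$subsystems$id == "B2"], 1.7)
  expect_equal(prof1$systems$meta_z[prof1$systems$id == "S2"], 1.7)

  # two subsystems of one pathway each under one system: 2 / sqrt(2)
  df <- data.frame(
    pathway_id = c("Q1", "Q2"), pathway_name = c("q1", "q2"),
    subsystem_id = c("C1", "C2"), subsystem_name = c("c1", "c2"),
    system_id = "SX", system_name = "sx")
  prof2 <- aggregate_profile(fake_enrichment(c("Q1", "Q2"), c(2, 0)),
                             as_hierarchy(df))
  expect_equal(prof2$subsystems$meta_z, c(2, 0))
  expect_equal(prof2$systems$meta_z, 2 / sqrt(2))
  expect_equal(prof2$systems$n_pathways, 2L)

  expect_error(aggregate_profile(fake_enrichment("nope", 1), h),
               "missing from hierarchy: nope")
})

test_that("enrichment profile serializes all three levels", {
  prof <- aggregate_profile(fake_enrichment(c("P1", "P2", "P3"),
                                            c(1, 2, 3)),
                            toy_hierarchy())
  path <- withr::local_tempfile(fileext = ".tsv")
  write_profile(prof, path)
  df <- utils::read.delim(path)
  expect_equal(sort(unique(df$level)),
               c("pathway", "subsystem", "system"))
  expect_equal(nrow(df), 3 + 2 + 2)
})
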
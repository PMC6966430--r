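test_that("S_N and S_FC are anchored min-max scores", {
  ctx <- structure(list(min_ng = 1, max_ng = 5, min_fc = 0, max_fc = 4),
                   class = "NormalizationContext")
  expect_equal(s_n(1, ctx), 0)
  expect_equal(s_n(5, ctx), 1)
  expect_equal(s_n(3, ctx), 0.5)
  expect_error(s_n(-1, ctx), "nonnegative")

  expect_equal(s_fc(0, ctx), 0)
  expect_equal(s_fc(4, ctx), 1)
  expect_equal(s_fc(1, ctx), 0.25)
  expect_error(s_fc(-0.1, ctx), "absolute")

  degenerate <- structure(list(min_ng = 2, max_ng = 2, min_fc = 1,
                               max_fc = 1), class = "NormalizationContext")
  expect_equal(s_n(2, degenerate), 0)
  expect_equal(s_fc(1, degenerate), 0)
})

test_that("per-gene system and subsystem z are grouped means", {
  h <- toy_hierarchy()
  gs <- toy_gene_sets()
  z <- c(P1 = 1, P2 = 3, P3 = 2)
  zz <- gene_level_zsys_zsub(gs, h, z)

  # gTop sits in P1 and P2, both under B1/S1: mean z = 2
  expect_equal(zz$zsys$z_mean[zz$zsys$gene == "gTop"], 2)
  expect_equal(zz$zsub$z_mean[zz$zsub$gene == "gTop"], 2)
  # gD sits in the single pathway P3: singleton mean
  expect_equal(zz$zsys$z_mean[zz$zsys$gene == "gD"], 2)

  # a gene spanning two systems gets one row per system
  gs2 <- as_gene_sets(list(P1 = c("gBoth"), P3 = c("gBoth")))
  zz2 <- gene_level_zsys_zsub(gs2, h, z)
  rows <- zz2$zsys[zz2$zsys$gene == "gBoth", ]
  expect_equal(sort(rows$system), c("S1", "S2"))
  expect_equal(rows$z_mean[order(rows$system)], c(1, 2))
})

test_that("normalization context pools extremes over the scored universe", {
  h <- toy_hierarchy()
  gs <- toy_gene_sets()
  z <- c(P1 = 1, P2 = 3, P3 = -1)
  fc <- abs(c(gTop = 3, gA = 0.5, gB = 0.2, gC = 0.1, gD = 0, gE = 0,
              gF = 0))
  ctx <- build_normalization_context(gs, h, z, fc)
  expect_equal(c(ctx$min_ng, ctx$max_ng), c(1, 2))
  expect_equal(c(ctx$min_fc, ctx$max_fc), c(0, 3))
  expect_equal(c(ctx$min_zpath, ctx$max_zpath), c(-1, 3))
  # pooled per-gene Zsys values: gC sits only in P2 (z = 3), the pool
  # max; P3 genes sit at -1; gTop's mean(1, 3) = 2 lies inside
  expect_equal(c(ctx$min_zsys, ctx$max_zsys), c(-1, 3))
  expect_equal(ctx$zsys$z_mean[ctx$zsys$gene == "gTop"], 2)
  expect_error(build_normalization_context(gs, h, z, c(nope = 1)),
               "empty universe")
})

test_that("MCS and ARCS combine normalized terms as defined", {
  expect_equal(mcs(c(0.5 + 0.5 + 0.5), 0.2, 0.3), 2)
  expect_equal(mcs(c(3), 1, 1), 5)
  expect_equal(mcs(c(0), 0, 0), 0)
  expect_error(mcs(numeric(0), 0, 0), "no annotated pathways")

  expect_equal(arcs(c(3), 1, 1), 5)                 # (3 + 1 + 1) / 1
  expect_equal(arcs(rep(3, 4), 1, 0), 8)            # (12 + 4 + 0) / 2
  expect_equal(arcs(rep(3, 4), 1, 0, "n"), 4)
  expect_equal(arcs(c(0, 0), 0, 0), 0)

  # MCS >= best single-pathway term + s_n + s_fc, and bounded by 5 when
  # all terms are unit-normalized
  set.seed(5)
  for (i in 1:20) {
    terms <- stats::runif(sample(1:6, 1), 0, 3)
    sn <- stats::runif(1); sfc <- stats::runif(1)
    expect_gte(mcs(terms, sn, sfc), max(terms) + sn + sfc - 1e-12)
  }
})

test_that("the maximal gene attains MCS = 5 through the full scoring path", {
  sc <- max_gene_scenario()$scores
  expect_equal(sc$mcs[sc$gene == "gTop"], 5)
  expect_true(all(sc$mcs >= 0 & sc$mcs <= 5))
  expect_true(all(sc$s_n >= 0 & sc$s_n <= 1))
  expect_true(all(sc$s_fc >= 0 & sc$s_fc <= 1))
  expect_equal(sc$rank_mcs[sc$gene == "gTop"], 1L)
})

test_that("with pools fixed, raising a pathway term never lowers MCS or ARCS", {
  set.seed(17)
  for (i in 1:20) {
    terms <- stats::runif(sample(2:6, 1))
    sn <- stats::runif(1); sfc <- stats::runif(1)
    j <- sample(seq_along(terms), 1)
    bumped <- terms
    bumped[j] <- bumped[j] + stats::runif(1)
    expect_gte(mcs(bumped, sn, sfc), mcs(terms, sn, sfc))
    expect_gte(arcs(bumped, sn, sfc), arcs(terms, sn, sfc))
  }
})

test_that("gene ranking is deterministic with lexicographic tie-breaks", {
  tab <- data.frame(gene = c("gB", "gA", "gC"),
                    mcs = c(5, 3, 3), arcs = c(1, 2, 3),
                    abs_log2fc = c(0.1, 0.2, 0.3))
  expect_equal(rank_genes(tab, "MCS"), c("gB", "gA", "gC"))
  expect_equal(rank_genes(tab, "ARCS"), c("gC", "gA", "gB"))
  expect_equal(rank_genes(tab, "FC"), c("gC", "gA", "gB"))
  tie <- data.frame(gene = c("gB", "gA"), mcs = c(2, 2),
                    arcs = c(1, 1), abs_log2fc = c(1, 1))
  expect_equal(rank_genes(tie, "MCS"), c("gA", "gB"))
  expect_error(rank_genes(tie[0, ], "MCS"), "empty")

  # unannotated genes (NA scores) are excluded from MCS but kept in FC
  mixed <- data.frame(gene = c("gA", "gU"), mcs = c(1, NA),
                      arcs = c(1, NA), abs_log2fc = c(0.5, 3))
  expect_equal(rank_genes(mixed, "MCS"), "gA")
  expect_equal(rank_genes(mixed, "FC"), c("gU", "gA"))
})

test_that("precision at k counts gold-standard hits in the top k", {
  ranked <- paste0("g", 1:30)
  gold_all <- ranked[1:20]
  expect_equal(precision_at_k(ranked, gold_all, 20), 1)
  expect_equal(precision_at_k(ranked, paste0("x", 1:5), 20), 0)
  gold8 <- ranked[c(1:8)]
  expect_equal(precision_at_k(ranked, gold8, 20), 0.4)
  expect_error(precision_at_k(ranked, gold8, 31), "k must lie")
  expect_error(precision_at_k(ranked, character(0), 5), "empty")

  curve <- precision_curve(ranked, gold8, 20)
  expect_equal(curve$precision[1], 1)
  expect_equal(curve$precision[20], 0.4)
  expect_equal(curve$precision[8], 1)
})
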
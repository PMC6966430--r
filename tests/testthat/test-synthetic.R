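test_that("the generator is fully determined by its seed", {
  d <- small_design(seed = 13)
  a <- gen_dataset(d)
  b <- gen_dataset(d)
  expect_identical(a$hierarchy, b$hierarchy)
  expect_identical(a$gene_sets, b$gene_sets)
  expect_identical(a$microarray$values, b$microarray$values)
  expect_identical(a$rnaseq$values, b$rnaseq$values)
  expect_identical(a$truth, b$truth)
  expect_identical(a$gold, b$gold)

  c <- gen_dataset(small_design(seed = 14))
  expect_false(identical(a$microarray$values, c$microarray$values))
})

test_that("requested hierarchy level counts are realized exactly", {
  d <- synthetic_design(seed = 5, n_genes = 600, n_pathways = 58,
                        n_subsystems = 58, n_systems = 6,
                        pathway_size_range = c(3, 6),
                        n_planted_pathways = 2, n_diet_pathways = 2)
  h <- gen_hierarchy(d)
  expect_equal(unname(hierarchy_counts(h$hierarchy)), c(58, 58, 6))
  expect_gte(h$gene_sets$N, max(lengths(h$gene_sets$sets)))
})

test_that("design validation rejects infeasible requests", {
  expect_error(synthetic_design(pathway_size_range = c(2, 10)), ">= 3")
  expect_error(synthetic_design(n_subsystems = 100), "subsystems")
  expect_error(synthetic_design(genotype_effect = c(2, 1, 1, 1)),
               "nondecreasing")
  expect_error(synthetic_design(genotype_effect = c(1, 2)),
               "one effect size per genotype")
  expect_error(synthetic_design(n_planted_pathways = 61), "planted")
  expect_error(synthetic_design(samples_per_group = 0), "samples_per_group")
})

test_that("zero effects and zero noise produce no fold changes", {
  d <- small_design(seed = 21,
                    genotype_effect = c(0, 0, 0, 0),
                    noise_sd = c(microarray = 0, rnaseq = 0),
                    n_diet_genes = 0, n_diet_pathways = 0,
                    n_outlier_genes = 0)
  data <- gen_dataset(d)
  for (platform in c("microarray", "rnaseq")) {
    fc <- compute_log2fc(data[[platform]], "WT__DIO", "WT__NOR",
                         pseudocount = 0)
    expect_equal(max(abs(fc)), 0)
    ct <- select_degs(fc, 2)
    expect_length(c(ct$up, ct$down), 0)
  }
})

test_that("a clean planted effect is recovered exactly on both platforms", {
  d <- small_design(seed = 22,
                    genotype_effect = c(2, 2, 2, 2),
                    gene_effect_jitter = c(1, 1),
                    noise_sd = c(microarray = 0, rnaseq = 0),
                    n_diet_genes = 0, n_diet_pathways = 0,
                    n_outlier_genes = 0)
  data <- gen_dataset(d)
  up <- data$truth$planted_genes$gene[data$truth$planted_genes$direction == "up"]
  down <- data$truth$planted_genes$gene[data$truth$planted_genes$direction == "down"]
  for (platform in c("microarray", "rnaseq")) {
    fc <- compute_log2fc(data[[platform]], "R1R2__DIO", "R1R2__NOR",
                         pseudocount = 0)
    expect_equal(unname(fc[up]), rep(2, length(up)), tolerance = 1e-9)
    expect_equal(unname(fc[down]), rep(-2, length(down)), tolerance = 1e-9)
    expect_equal(max(abs(fc[setdiff(names(fc), c(up, down))])), 0)
  }
  # linear platform is nonnegative by construction
  expect_true(all(data$rnaseq$values >= 0))
})

test_that("the gold standard is the planted positives plus optional decoys", {
  data <- gen_dataset(small_design(seed = 23))
  expect_setequal(data$gold$genes, data$truth$positives)

  gold2 <- gen_gold_standard(data$truth, n_decoys = 10, seed = 4)
  expect_length(gold2$genes, length(data$truth$positives) + 10)
  expect_identical(gold2, gen_gold_standard(data$truth, 10, seed = 4))

  remainder <- length(data$truth$universe) - length(data$truth$positives)
  all_in <- gen_gold_standard(data$truth, n_decoys = remainder, seed = 1)
  expect_setequal(all_in$genes, data$truth$universe)
  expect_error(gen_gold_standard(data$truth, remainder + 1), "decoy count")
})

test_that("planted structure is consistent with the produced annotation", {
  data <- gen_dataset(small_design(seed = 24))
  truth <- data$truth
  expect_true(all(truth$planted_pathways$pathway %in%
                    names(data$gene_sets$sets)))
  expect_equal(unique(truth$planted_pathways$system),
               truth$planted_system)
  # planted genes are members of their planted pathways
  members <- unique(unlist(
    data$gene_sets$sets[truth$planted_pathways$pathway]))
  expect_true(all(truth$positives %in% members))
  # diet pathways never overlap planted pathways
  expect_length(intersect(truth$diet_pathways$pathway,
                          truth$planted_pathways$pathway), 0)
})

test_that("datasets are written in the pipeline's standard formats", {
  dir <- withr::local_tempdir()
  data <- gen_dataset(small_design(seed = 25))
  write_synthetic_dataset(data, dir)

  h <- load_hierarchy(file.path(dir, "hierarchy.tsv"))
  expect_identical(hierarchy_counts(h), hierarchy_counts(data$hierarchy))
  gs <- load_gene_sets(file.path(dir, "pathways.gmt"))
  expect_identical(gs$sets, data$gene_sets$sets)
  em <- load_expression(file.path(dir, "microarray_expression.tsv"),
                        file.path(dir, "microarray_samples.tsv"),
                        value_scale = "log2")
  expect_equal(em$values, data$microarray$values, tolerance = 1e-6)
  truth <- jsonlite::read_json(file.path(dir, "truth.json"),
                               simplifyVector = TRUE)
  expect_setequal(truth$planted_genes$gene, data$truth$positives)
})
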
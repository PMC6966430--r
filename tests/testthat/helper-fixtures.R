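# Small in-code fixtures shared across test files.

# three-level toy hierarchy: P1,P2 under B1/S1; P3 under B2/S2
toy_hierarchy_df <- function() {
  data.frame(
    pathway_id = c("P1", "P2", "P3"),
    pathway_name = c("alpha", "beta", "gamma"),
    subsystem_id = c("B1", "B1", "B2"),
    subsystem_name = c("sub one", "sub one", "sub two"),
    system_id = c("S1", "S1", "S2"),
    system_name = c("sys one", "sys one", "sys two"))
}

toy_hierarchy <- function() as_hierarchy(toy_hierarchy_df())

toy_gene_sets <- function() {
  as_gene_sets(list(P1 = c("gTop", "gA", "gB"),
                    P2 = c("gTop", "gA", "gC"),
                    P3 = c("gD", "gE", "gF")))
}

# a scenario in which gTop attains the pool maximum of every scoring term
max_gene_scenario <- function() {
  hierarchy <- toy_hierarchy()
  gene_sets <- toy_gene_sets()
  log2fc <- c(gTop = 3, gA = 0.5, gB = 0.2, gC = 0.1,
              gD = 0, gE = 0, gF = 0)
  contrast <- select_degs(log2fc, threshold = 2)
  enrichment <- enrich_contrast(contrast, gene_sets, hierarchy)
  scores <- score_genes(contrast, enrichment, gene_sets, hierarchy)
  list(hierarchy = hierarchy, gene_sets = gene_sets,
       contrast = contrast, enrichment = enrichment, scores = scores)
}

# minimal EnrichmentResult wrapper for aggregation-level tests
fake_enrichment <- function(pathway, z) {
  structure(list(
    combined = data.frame(pathway = pathway, z = z,
                          p_min = rep(NA_real_, length(pathway)),
                          significant = rep(FALSE, length(pathway))),
    pathways = data.frame(),
    dropped = c(up = 0L, down = 0L),
    params = list(alpha = 0.05, clamp = 1e-16, combine = "max"),
    metadata = list()
  ), class = "EnrichmentResult")
}

# small, fast synthetic design for module-level smoke tests
small_design <- function(seed = 7, ...) {
  base <- list(seed = seed, n_genes = 400, n_pathways = 16,
               n_subsystems = 8, n_systems = 4,
               pathway_size_range = c(10, 20),
               n_planted_pathways = 2, n_diet_genes = 60,
               n_diet_pathways = 4, n_outlier_genes = 10,
               samples_per_group = 3, diets = c("NOR", "DIO"))
  do.call(synthetic_design, utils::modifyList(base, list(...)))
}

# an expression matrix with explicit values for deg-level unit tests
toy_expression <- function(values, scale = "log2") {
  samples <- data.frame(sample_id = colnames(values),
                        genotype = rep("WT", ncol(values)),
                        diet = sub("_.*", "", colnames(values)))
  expression_matrix(values, samples, value_scale = scale)
}
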
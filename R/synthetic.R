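# Synthetic cross-platform omics generator with planted (known) structure.
#
# The generator emulates the study design the pipeline targets: four
# genotype-like backgrounds of increasing severity, a control diet plus
# treatment diets, and two platforms (a log2-scale microarray-like one and
# a linear FPKM-like one) measuring a shared gene universe. Three signal
# layers ride on a shared per-gene baseline:
#   * planted pathways carry coherent up/down shifts whose strength grows
#     along the genotype axis; their member genes double as the
#     gold-standard positive set;
#   * diet-responder genes model the strong diet main effect every
#     background shows; their near-threshold effects are shared between
#     platforms but detected platform-independently around the fold-change
#     cutoff, which is what keeps gene-level cross-platform agreement well
#     below pathway-level agreement;
#   * platform-specific "idiosyncratic responder" genes (probe artifacts,
#     single-gene responders) carry large shifts with no pathway
#     coherence — the realistic noise floor that separates pathway-aware
#     prioritization from plain fold-change ranking.

#' Define a synthetic study design
#'
#' All sizes, rates and effect strengths of the generator, with defaults
#' chosen as a desk-scale version of a two-platform, four-genotype,
#' three-diet feeding study. The seed fully determines every generated
#' object.
#'
#' @param seed Integer seed.
#' @param n_genes Gene universe size.
#' @param n_pathways,n_subsystems,n_systems Hierarchy level counts
#'   (pathways >= subsystems >= systems).
#' @param pathway_size_range Inclusive size range for pathway gene sets
#'   (minimum 3).
#' @param genotypes Ordered genotype labels, mildest first.
#' @param genotype_effect Nondecreasing per-genotype planted effect sizes
#'   in log2 units (applied in treatment diets).
#' @param diets Diet labels; the first is the control diet.
#' @param n_planted_pathways Number of pathways carrying planted effects
#'   (all placed under one system so the system-level dose response is
#'   observable).
#' @param planted_gene_fraction Fraction of each planted pathway's genes
#'   that actually shift.
#' @param gene_effect_jitter Range of the per-gene multiplicative jitter
#'   on the planted effect.
#' @param n_diet_genes Total diet-responder genes shared by all genotypes
#'   and both platforms.
#' @param diet_effect_range Absolute log2 effect range for diet
#'   responders (near the fold-change threshold by design).
#' @param n_diet_pathways Pathways in which part of the diet response is
#'   concentrated (one coherent direction per pathway, constant across
#'   genotypes); the remaining diet responders are scattered across the
#'   universe.
#' @param diet_pathway_gene_fraction Fraction of each diet pathway's
#'   genes recruited into its coherent response.
#' @param n_outlier_genes Platform-specific idiosyncratic responders per
#'   platform.
#' @param outlier_effect_range Absolute log2 shift range for those genes.
#' @param noise_sd Named vector: per-sample log2 noise sd for
#'   `microarray` and `rnaseq`.
#' @param samples_per_group Replicates per (genotype, diet) group.
#' @param baseline_mean,baseline_sd Log2 baseline expression distribution
#'   shared by both platforms.
#' @return A validated `SyntheticDesign` list.
#' @export
synthetic_design <- function(seed = 1,
                             n_genes = 2000,
                             n_pathways = 60,
                             n_subsystems = 18,
                             n_systems = 6,
                             pathway_size_range = c(25, 55),
                             genotypes = c("WT", "R1", "R2", "R1R2"),
                             genotype_effect = c(1.0, 1.4, 1.8, 2.2),
                             diets = c("NOR", "DIO", "FAT"),
                             n_planted_pathways = 4,
                             planted_gene_fraction = 0.6,
                             gene_effect_jitter = c(0.3, 1.3),
                             n_diet_genes = 400,
                             diet_effect_range = c(0.7, 1.6),
                             n_diet_pathways = 18,
                             diet_pathway_gene_fraction = 0.3,
                             n_outlier_genes = 50,
                             outlier_effect_range = c(1.5, 3),
                             noise_sd = c(microarray = 0.5, rnaseq = 0.6),
                             samples_per_group = 4,
                             baseline_mean = 7,
                             baseline_sd = 1.5) {
  design <- list(seed = seed, n_genes = n_genes, n_pathways = n_pathways,
                 n_subsystems = n_subsystems, n_systems = n_systems,
                 pathway_size_range = pathway_size_range,
                 genotypes = genotypes, genotype_effect = genotype_effect,
                 diets = diets,
                 n_planted_pathways = n_planted_pathways,
                 planted_gene_fraction = planted_gene_fraction,
                 gene_effect_jitter = gene_effect_jitter,
                 n_diet_genes = n_diet_genes,
                 diet_effect_range = diet_effect_range,
                 n_diet_pathways = n_diet_pathways,
                 diet_pathway_gene_fraction = diet_pathway_gene_fraction,
                 n_outlier_genes = n_outlier_genes,
                 outlier_effect_range = outlier_effect_range,
                 noise_sd = noise_sd,
                 samples_per_group = samples_per_group,
                 baseline_mean = baseline_mean, baseline_sd = baseline_sd)
  if (pathway_size_range[1] < 3) {
    stop("design error: pathway sizes must be >= 3", call. = FALSE)
  }
  if (pathway_size_range[2] > n_genes) {
    stop("design error: pathway size exceeds gene universe", call. = FALSE)
  }
  if (n_pathways < n_subsystems || n_subsystems < n_systems) {
    stop("design error: need pathways >= subsystems >= systems",
         call. = FALSE)
  }
  if (n_systems < 1 || n_pathways < 1) {
    stop("design error: counts must be positive", call. = FALSE)
  }
  if (length(genotype_effect) != length(genotypes)) {
    stop("design error: one effect size per genotype", call. = FALSE)
  }
  if (is.unsorted(genotype_effect)) {
    stop("design error: genotype effects must be nondecreasing along the genotype axis",
         call. = FALSE)
  }
  if (n_planted_pathways > n_pathways) {
    stop("design error: more planted pathways than pathways", call. = FALSE)
  }
  if (n_planted_pathways + n_diet_pathways > n_pathways) {
    stop("design error: planted plus diet pathways exceed the pathway count",
         call. = FALSE)
  }
  if (planted_gene_fraction < 0 || planted_gene_fraction > 1) {
    stop("design error: planted_gene_fraction in [0,1]", call. = FALSE)
  }
  if (!all(c("microarray", "rnaseq") %in% names(noise_sd))) {
    stop("design error: noise_sd needs microarray and rnaseq entries",
         call. = FALSE)
  }
  if (samples_per_group < 1) {
    stop("design error: samples_per_group >= 1", call. = FALSE)
  }
  if (length(diets) < 2) {
    stop("design error: need a control diet and >=1 treatment diet",
         call. = FALSE)
  }
  structure(design, class = "SyntheticDesign")
}

#' Generate a pathway hierarchy and gene sets
#'
#' Subsystems are assigned to systems (and pathways to subsystems) round
#' robin, so every requested level count is realized exactly; pathway
#' members are sampled from the gene universe, allowing genes to belong
#' to several pathways. Deterministic given the design seed.
#'
#' @param design A `SyntheticDesign`.
#' @return List with `hierarchy` (an `AnnotationHierarchy`) and
#'   `gene_sets` (a `PathwayGeneSets`, whose universe records N).
#' @export
gen_hierarchy <- function(design) {
  stopifnot(inherits(design, "SyntheticDesign"))
  set.seed(design$seed)
  genes <- sprintf("g%05d", seq_len(design$n_genes))
  systems <- sprintf("sys%d", seq_len(design$n_systems))
  subsystems <- sprintf("sub%02d", seq_len(design$n_subsystems))
  pathways <- sprintf("pw%03d", seq_len(design$n_pathways))
  sub_parent <- systems[((seq_len(design$n_subsystems) - 1L) %%
                           design$n_systems) + 1L]
  pw_parent <- subsystems[((seq_len(design$n_pathways) - 1L) %%
                             design$n_subsystems) + 1L]
  df <- data.frame(
    pathway_id = pathways,
    pathway_name = paste("pathway", pathways),
    subsystem_id = pw_parent,
    subsystem_name = paste("subsystem", pw_parent),
    system_id = sub_parent[match(pw_parent, subsystems)],
    system_name = paste("system", sub_parent[match(pw_parent, subsystems)]))
  sizes <- sample(seq(design$pathway_size_range[1],
                      design$pathway_size_range[2]),
                  design$n_pathways, replace = TRUE)
  sets <- lapply(sizes, function(s) sample(genes, s))
  names(sets) <- pathways
  list(hierarchy = as_hierarchy(df), gene_sets = as_gene_sets(sets))
}

#' Generate paired cross-platform expression data with planted truth
#'
#' Both platforms share per-gene baseline log2 means; planted genes are
#' shifted by their genotype-specific effect in treatment-diet samples;
#' platform noise is independent. The microarray-like matrix stays on the
#' log2 scale; the RNA-seq-like matrix is the exponentiated log2 signal
#' (linear, hence nonnegative by construction).
#'
#' @param design A `SyntheticDesign`.
#' @param hierarchy An `AnnotationHierarchy` from [gen_hierarchy()].
#' @param gene_sets The matching `PathwayGeneSets`.
#' @return List with `microarray` and `rnaseq` (`ExpressionMatrix`
#'   objects covering every genotype x diet group) and `truth`
#'   (a `SyntheticTruth`).
#' @export
gen_expression <- function(design, hierarchy, gene_sets) {
  stopifnot(inherits(design, "SyntheticDesign"),
            inherits(hierarchy, "AnnotationHierarchy"),
            inherits(gene_sets, "PathwayGeneSets"))
  set.seed(design$seed + 1L)
  genes <- sprintf("g%05d", seq_len(design$n_genes))
  n_genes <- design$n_genes

  # planted pathways: the first n under the first system, alternating
  # direction (up, down, up, ...)
  first_sys <- hierarchy$names$system
  first_sys <- sort(names(first_sys))[1]
  under_first <- names(hierarchy$pathway_parent)[
    pathway_system(hierarchy, names(hierarchy$pathway_parent)) == first_sys]
  if (length(under_first) < design$n_planted_pathways) {
    stop("design error: planted system has too few pathways", call. = FALSE)
  }
  planted_pw <- sort(under_first)[seq_len(design$n_planted_pathways)]
  pw_dir <- rep_len(c(1, -1), length(planted_pw))

  # planted genes: a fraction of each planted pathway; a gene planted by
  # several pathways keeps its first-assigned direction
  gene_dir <- stats::setNames(numeric(0), character(0))
  for (i in seq_along(planted_pw)) {
    members <- gene_sets$sets[[planted_pw[i]]]
    k <- ceiling(design$planted_gene_fraction * length(members))
    chosen <- sample(members, k)
    new <- setdiff(chosen, names(gene_dir))
    gene_dir[new] <- pw_dir[i]
  }
  planted_genes <- names(gene_dir)
  jit <- stats::runif(length(planted_genes),
                      design$gene_effect_jitter[1],
                      design$gene_effect_jitter[2])
  names(jit) <- planted_genes

  # diet responders: the diet main effect every genotype shares, with
  # near-threshold effect sizes common to both platforms. Half-coherent:
  # some diet pathways respond as a unit (one direction per pathway),
  # the rest of the responders are scattered across the universe.
  pool <- setdiff(genes, planted_genes)
  non_planted_pw <- setdiff(names(gene_sets$sets), planted_pw)
  n_dpw <- min(design$n_diet_pathways, length(non_planted_pw))
  diet_pathways <- sort(sample(non_planted_pw, n_dpw))
  dpw_dir <- sample(c(1, -1), n_dpw, replace = TRUE)
  coherent <- character(0)
  coherent_dir <- numeric(0)
  for (i in seq_along(diet_pathways)) {
    members <- setdiff(gene_sets$sets[[diet_pathways[i]]],
                       c(planted_genes, coherent))
    k <- min(ceiling(design$diet_pathway_gene_fraction *
                       length(gene_sets$sets[[diet_pathways[i]]])),
             length(members))
    chosen <- sample(members, k)
    coherent <- c(coherent, chosen)
    coherent_dir <- c(coherent_dir, rep(dpw_dir[i], k))
  }
  n_scatter <- max(0L, design$n_diet_genes - length(coherent))
  scatter_pool <- setdiff(pool, coherent)
  scattered <- sample(scatter_pool, min(n_scatter, length(scatter_pool)))
  diet_genes <- c(coherent, scattered)
  diet_dir <- c(coherent_dir,
                sample(c(1, -1), length(scattered), replace = TRUE))
  diet_shift <- stats::setNames(
    diet_dir * stats::runif(length(diet_genes),
                            design$diet_effect_range[1],
                            design$diet_effect_range[2]),
    diet_genes)

  # platform-specific idiosyncratic responders, outside planted and diet sets
  pool <- setdiff(pool, diet_genes)
  outliers <- lapply(c(microarray = 1L, rnaseq = 2L), function(dummy) {
    n_out <- min(design$n_outlier_genes, length(pool))
    ids <- sample(pool, n_out)
    data.frame(gene = ids,
               shift = sample(c(-1, 1), n_out, replace = TRUE) *
                 stats::runif(n_out, design$outlier_effect_range[1],
                              design$outlier_effect_range[2]))
  })

  baseline <- stats::rnorm(n_genes, design$baseline_mean,
                           design$baseline_sd)
  names(baseline) <- genes

  control_diet <- design$diets[1]
  grid <- expand.grid(rep = seq_len(design$samples_per_group),
                      diet = design$diets, genotype = design$genotypes,
                      stringsAsFactors = FALSE)

  build_platform <- function(platform) {
    sd_p <- design$noise_sd[[platform]]
    out_shift <- stats::setNames(rep(0, n_genes), genes)
    out_shift[outliers[[platform]]$gene] <- outliers[[platform]]$shift
    cols <- matrix(0, nrow = n_genes, ncol = nrow(grid),
                   dimnames = list(genes, NULL))
    sample_ids <- character(nrow(grid))
    for (j in seq_len(nrow(grid))) {
      geno <- grid$genotype[j]; diet <- grid$diet[j]
      sample_ids[j] <- sprintf("%s_%s_%s_r%d", platform, geno, diet,
                               grid$rep[j])
      mu <- baseline
      if (diet != control_diet) {
        eff <- design$genotype_effect[match(geno, design$genotypes)]
        mu[planted_genes] <- mu[planted_genes] +
          gene_dir[planted_genes] * eff * jit[planted_genes]
        mu[diet_genes] <- mu[diet_genes] + diet_shift[diet_genes]
        mu <- mu + out_shift
      }
      cols[, j] <- mu + stats::rnorm(n_genes, 0, sd_p)
    }
    colnames(cols) <- sample_ids
    samples <- data.frame(sample_id = sample_ids,
                          genotype = grid$genotype, diet = grid$diet)
    if (platform == "rnaseq") {
      expression_matrix(2^cols, samples, value_scale = "linear",
                        platform = "rnaseq")
    } else {
      expression_matrix(cols, samples, value_scale = "log2",
                        platform = "microarray")
    }
  }

  truth <- structure(list(
    planted_pathways = data.frame(
      pathway = planted_pw,
      subsystem = pathway_subsystem(hierarchy, planted_pw),
      system = pathway_system(hierarchy, planted_pw),
      direction = ifelse(pw_dir > 0, "up", "down")),
    planted_genes = data.frame(
      gene = planted_genes,
      direction = ifelse(gene_dir[planted_genes] > 0, "up", "down"),
      effect_multiplier = unname(jit[planted_genes])),
    positives = planted_genes,
    planted_system = first_sys,
    diet_responders = data.frame(gene = diet_genes,
                                 shift = unname(diet_shift)),
    diet_pathways = data.frame(pathway = diet_pathways,
                               direction = ifelse(dpw_dir > 0, "up",
                                                  "down")),
    outliers = outliers,
    universe = genes,
    control_diet = control_diet,
    genotype_effect = stats::setNames(design$genotype_effect,
                                      design$genotypes)
  ), class = "SyntheticTruth")

  list(microarray = build_platform("microarray"),
       rnaseq = build_platform("rnaseq"),
       truth = truth)
}

#' Derive a gold-standard positive set from the planted truth
#'
#' The positives are the planted genes, optionally diluted with decoy
#' genes drawn from the non-planted universe to emulate an imperfect
#' disease-gene catalogue.
#'
#' @param truth A `SyntheticTruth`.
#' @param n_decoys Number of non-planted genes to add, default 0.
#' @param seed Seed for decoy sampling.
#' @return A `GoldStandard`: list with `genes` and `provenance`.
#' @export
gen_gold_standard <- function(truth, n_decoys = 0, seed = 1) {
  stopifnot(inherits(truth, "SyntheticTruth"))
  pool <- setdiff(truth$universe, truth$positives)
  if (n_decoys > length(pool)) {
    stop("decoy count exceeds the non-planted universe", call. = FALSE)
  }
  set.seed(seed)
  decoys <- if (n_decoys > 0) sample(pool, n_decoys) else character(0)
  structure(list(genes = sort(c(truth$positives, decoys)),
                 provenance = sprintf("synthetic planted positives + %d decoys",
                                      n_decoys)),
            class = "GoldStandard")
}

#' Generate a complete synthetic dataset
#'
#' Convenience wrapper chaining [gen_hierarchy()], [gen_expression()] and
#' [gen_gold_standard()].
#'
#' @param design A `SyntheticDesign` (default: [synthetic_design()]
#'   defaults).
#' @return List: `hierarchy`, `gene_sets`, `microarray`, `rnaseq`,
#'   `truth`, `gold`.
#' @export
gen_dataset <- function(design = synthetic_design()) {
  h <- gen_hierarchy(design)
  e <- gen_expression(design, h$hierarchy, h$gene_sets)
  gold <- gen_gold_standard(e$truth, n_decoys = 0,
                            seed = design$seed + 2L)
  list(hierarchy = h$hierarchy, gene_sets = h$gene_sets,
       microarray = e$microarray, rnaseq = e$rnaseq,
       truth = e$truth, gold = gold)
}

#' Write a synthetic dataset in the pipeline's standard input formats
#'
#' Emits expression TSVs, sample sheets, the hierarchy TSV, the GMT gene
#' sets, the gold-standard TSV, and a truth JSON for tests.
#'
#' @param dataset A list from [gen_dataset()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_synthetic_dataset <- function(dataset, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_hierarchy(dataset$hierarchy, file.path(dir, "hierarchy.tsv"))
  write_gene_sets(dataset$gene_sets, file.path(dir, "pathways.gmt"))
  for (p in c("microarray", "rnaseq")) {
    em <- dataset[[p]]
    utils::write.table(
      data.frame(gene = rownames(em$values), em$values,
                 check.names = FALSE),
      file.path(dir, paste0(p, "_expression.tsv")),
      sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(em$samples,
                       file.path(dir, paste0(p, "_samples.tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  utils::write.table(
    data.frame(gene_id = dataset$gold$genes,
               source = dataset$gold$provenance),
    file.path(dir, "gold_standard.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE)
  truth <- dataset$truth
  jsonlite::write_json(
    list(planted_pathways = truth$planted_pathways,
         planted_genes = truth$planted_genes,
         planted_system = truth$planted_system,
         control_diet = truth$control_diet,
         genotype_effect = as.list(truth$genotype_effect)),
    file.path(dir, "truth.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
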
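# End-to-end orchestration: simulate (or load), DEG selection, enrichment,
# aggregation, gene scoring, cross-platform concordance, and a
# machine-readable run summary.

#' Default pipeline configuration
#'
#' Every tunable of the pipeline with its default. Pass a modified copy
#' (or a YAML file with the same structure) to [run_pipeline()]; unknown
#' keys are rejected.
#'
#' @return Nested list of configuration defaults.
#' @export
default_config <- function() {
  list(
    seed = 1,
    design = list(),             # overrides forwarded to synthetic_design()
    inputs = NULL,               # or a list of file paths (see run_pipeline)
    deg = list(threshold = 2, comparator = ">=", pseudocount = NULL),
    enrichment = list(alpha = 0.05, clamp = 1e-16, combine = "max",
                      meta_denominator = "sqrt_n"),
    scoring = list(arcs_denominator = "sqrt_n", platform = "microarray",
                   genotype = NULL, diet = NULL, top_k = 20),
    concordance = list(system_z_threshold = stats::qnorm(0.95),
                       linkage = "average", diet = NULL),
    output_dir = NULL
  )
}

merge_config <- function(user, defaults, path = "config") {
  unknown <- setdiff(names(user), names(defaults))
  if (length(unknown)) {
    stop("config error: unknown key(s) ",
         paste(paste0(path, "$", unknown), collapse = ", "), call. = FALSE)
  }
  for (key in names(user)) {
    if (is.list(defaults[[key]]) && !is.null(names(defaults[[key]])) &&
        key != "design" && key != "inputs") {
      defaults[[key]] <- merge_config(user[[key]], defaults[[key]],
                                      paste0(path, "$", key))
    } else {
      defaults[key] <- user[key]
    }
  }
  defaults
}

validate_config <- function(config) {
  if (config$deg$threshold < 1) {
    stop("config error: deg$threshold must be >= 1", call. = FALSE)
  }
  if (!config$deg$comparator %in% c(">=", ">")) {
    stop("config error: deg$comparator must be '>=' or '>'", call. = FALSE)
  }
  if (config$enrichment$alpha <= 0 || config$enrichment$alpha >= 1) {
    stop("config error: enrichment$alpha in (0,1)", call. = FALSE)
  }
  if (!config$enrichment$meta_denominator %in% c("sqrt_n", "n")) {
    stop("config error: meta_denominator must be sqrt_n or n", call. = FALSE)
  }
  if (!config$scoring$arcs_denominator %in% c("sqrt_n", "n")) {
    stop("config error: arcs_denominator must be sqrt_n or n", call. = FALSE)
  }
  invisible(config)
}

load_inputs <- function(inputs) {
  need <- c("microarray_expression", "microarray_samples",
            "rnaseq_expression", "rnaseq_samples", "gmt", "hierarchy")
  missing <- setdiff(need, names(inputs))
  if (length(missing)) {
    stop("config error: inputs missing ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  gold <- NULL
  if (!is.null(inputs$gold)) {
    df <- utils::read.delim(inputs$gold, colClasses = "character")
    gold <- structure(list(genes = unique(df$gene_id),
                           provenance = "file"),
                      class = "GoldStandard")
  }
  list(
    hierarchy = load_hierarchy(inputs$hierarchy),
    gene_sets = load_gene_sets(inputs$gmt),
    microarray = load_expression(inputs$microarray_expression,
                                 inputs$microarray_samples,
                                 value_scale = "log2",
                                 platform = "microarray"),
    rnaseq = load_expression(inputs$rnaseq_expression,
                             inputs$rnaseq_samples,
                             value_scale = "linear", platform = "rnaseq"),
    truth = NULL, gold = gold)
}

#' Run the full analysis pipeline
#'
#' Stages: obtain data (simulate from the synthetic design, or load the
#' files named in `config$inputs`), compute one contrast per
#' (platform, genotype, treatment diet) against the control diet, run
#' directional pathway enrichment and hierarchy aggregation per contrast,
#' score and rank genes for the configured scoring contrast, compute
#' per-genotype cross-platform concordance, and cluster the
#' condition-by-system meta-z profiles. Writes all stage outputs plus a
#' JSON summary when `output_dir` is set; the summary embeds the full
#' configuration and seed for provenance.
#'
#' @param config A configuration list (see [default_config()]) or the
#'   path to a YAML file with the same structure. Partial configs are
#'   merged over the defaults; unknown keys abort before any computation.
#' @return A `PipelineRun` list: `summary` (the machine-readable report),
#'   `contrasts`, `profiles`, `scores`, `concordance`, `clustering`, and
#'   the data bundle used.
#' @export
run_pipeline <- function(config = default_config()) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  config <- merge_config(config, default_config())
  validate_config(config)

  # --- data stage
  if (is.null(config$inputs)) {
    design_args <- config$design
    if (is.null(design_args$seed)) design_args$seed <- config$seed
    design <- do.call(synthetic_design, design_args)
    data <- gen_dataset(design)
  } else {
    data <- load_inputs(config$inputs)
  }
  hierarchy <- data$hierarchy
  gene_sets <- data$gene_sets

  control_diet <- data$microarray$samples$diet[1]
  if (!is.null(data$truth)) control_diet <- data$truth$control_diet
  platforms <- c("microarray", "rnaseq")
  genotypes <- unique(data$microarray$samples$genotype)
  diets <- unique(data$microarray$samples$diet)
  treatment_diets <- setdiff(diets, control_diet)

  # --- contrast + enrichment stages
  contrasts <- list()
  profiles <- list()
  deg_counts <- list()
  for (platform in platforms) {
    expr <- data[[platform]]
    for (geno in genotypes) {
      for (diet in treatment_diets) {
        id <- paste(geno, diet, platform, sep = "__")
        fc <- compute_log2fc(expr, paste(geno, diet, sep = "__"),
                             paste(geno, control_diet, sep = "__"),
                             pseudocount = config$deg$pseudocount)
        contrast <- select_degs(fc, threshold = config$deg$threshold,
                                comparator = config$deg$comparator,
                                metadata = list(platform = platform,
                                                genotype = geno,
                                                diet = diet,
                                                control = control_diet))
        enr <- enrich_contrast(contrast, gene_sets, hierarchy,
                               alpha = config$enrichment$alpha,
                               clamp = config$enrichment$clamp,
                               combine = config$enrichment$combine)
        profile <- aggregate_profile(enr, hierarchy,
                                     denominator = config$enrichment$meta_denominator)
        contrasts[[id]] <- list(contrast = contrast, enrichment = enr)
        profiles[[id]] <- profile
        deg_counts[[id]] <- list(up = length(contrast$up),
                                 down = length(contrast$down),
                                 dropped_by_annotation = unname(sum(enr$dropped)),
                                 significant_pathways = sum(enr$combined$significant),
                                 significant_systems = length(
                                   significant_systems(profile,
                                     config$concordance$system_z_threshold)))
      }
    }
  }

  # --- gene scoring stage (one configured contrast)
  sc <- config$scoring
  score_geno <- if (is.null(sc$genotype)) genotypes[length(genotypes)] else sc$genotype
  score_diet <- if (is.null(sc$diet)) treatment_diets[1] else sc$diet
  score_id <- paste(score_geno, score_diet, sc$platform, sep = "__")
  if (is.null(contrasts[[score_id]])) {
    stop("config error: scoring contrast ", score_id, " not available",
         call. = FALSE)
  }
  scores <- score_genes(contrasts[[score_id]]$contrast,
                        contrasts[[score_id]]$enrichment,
                        gene_sets, hierarchy,
                        arcs_denominator = sc$arcs_denominator)
  top_k <- min(sc$top_k, nrow(scores))
  top_genes <- lapply(c(MCS = "MCS", ARCS = "ARCS", FC = "FC"),
                      function(m) rank_genes(scores, m)[seq_len(top_k)])
  precision <- NULL
  if (!is.null(data$gold)) {
    precision <- lapply(top_genes, function(g) {
      mean(g %in% data$gold$genes)
    })
  }

  # --- concordance stage (per genotype, microarray vs rnaseq)
  conc_diet <- if (is.null(config$concordance$diet)) treatment_diets[1] else config$concordance$diet
  zthr <- config$concordance$system_z_threshold
  concordance <- list()
  for (geno in genotypes) {
    bundles <- lapply(platforms, function(platform) {
      id <- paste(geno, conc_diet, platform, sep = "__")
      ct <- contrasts[[id]]$contrast
      enr <- contrasts[[id]]$enrichment
      concordance_bundle(
        degs = c(ct$up, ct$down),
        pathways = enr$combined$pathway[enr$combined$significant],
        systems = significant_systems(profiles[[id]], zthr))
    })
    concordance[[geno]] <- concordance_report(bundles[[1]], bundles[[2]])
  }

  # --- condition clustering stage (platform x genotype at the concordance diet)
  system_ids <- sort(unique(profiles[[1]]$systems$id))
  cond_ids <- as.vector(outer(genotypes, platforms, function(g, p) {
    paste(g, conc_diet, p, sep = "__")
  }))
  pm <- t(vapply(cond_ids, function(id) {
    s <- profiles[[id]]$systems
    stats::setNames(s$meta_z, s$id)[system_ids]
  }, stats::setNames(numeric(length(system_ids)), system_ids)))
  clustering <- cluster_conditions(pm, linkage = config$concordance$linkage)

  summary <- list(
    config = config,
    control_diet = control_diet,
    deg_counts = deg_counts,
    scoring_contrast = score_id,
    top_genes = top_genes,
    precision_at_k = precision,
    concordance = lapply(concordance, as.list),
    cluster_groups = as.list(clustering$groups)
  )

  if (!is.null(config$output_dir)) {
    dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
    for (id in names(contrasts)) {
      write_contrast(contrasts[[id]]$contrast,
                     file.path(config$output_dir,
                               paste0("contrast_", id, ".tsv")))
      write_profile(profiles[[id]],
                    file.path(config$output_dir,
                              paste0("profile_", id, ".tsv")))
    }
    utils::write.table(scores,
                       file.path(config$output_dir, "gene_scores.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(
      data.frame(condition = rownames(pm), pm, check.names = FALSE),
      file.path(config$output_dir, "condition_meta_z.tsv"),
      sep = "\t", quote = FALSE, row.names = FALSE)
    jsonlite::write_json(summary,
                         file.path(config$output_dir, "summary.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }

  structure(list(summary = summary, contrasts = contrasts,
                 profiles = profiles, scores = scores,
                 concordance = concordance, clustering = clustering,
                 profile_matrix = pm, data = data),
            class = "PipelineRun")
}

#' @export
print.PipelineRun <- function(x, ...) {
  cat("PipelineRun:", length(x$contrasts), "contrasts;",
      "scoring contrast", x$summary$scoring_contrast, "\n")
  invisible(x)
}
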
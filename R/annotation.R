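#' Load a three-level pathway hierarchy from TSV
#'
#' Reads a table with one row per pathway describing the KEGG-style
#' three-level annotation: pathways nest in subsystems, subsystems nest in
#' systems. The reference KEGG instance has 6 systems and 58 subsystems;
#' this loader accepts any consistent hierarchy.
#'
#' @param path Path to a tab-separated file with columns `pathway_id`,
#'   `pathway_name`, `subsystem_id`, `subsystem_name`, `system_id`,
#'   `system_name`.
#' @return An `AnnotationHierarchy` object: a validated list with the
#'   pathway table and parent maps.
#' @seealso [hierarchy_counts()], [write_hierarchy()]
#' @export
load_hierarchy <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          colClasses = "character", check.names = FALSE)
  as_hierarchy(df)
}

#' Construct an AnnotationHierarchy from a data frame
#'
#' @param df Data frame with the six hierarchy columns (see
#'   [load_hierarchy()]).
#' @return An `AnnotationHierarchy`.
#' @export
as_hierarchy <- function(df) {
  required <- c("pathway_id", "pathway_name", "subsystem_id",
                "subsystem_name", "system_id", "system_name")
  missing <- setdiff(required, names(df))
  if (length(missing)) {
    stop("hierarchy format error: missing column(s) ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  df <- df[required]
  for (col in required) df[[col]] <- as.character(df[[col]])
  if (anyNA(df) || any(df == "")) {
    stop("hierarchy format error: empty or missing cells", call. = FALSE)
  }

  # a pathway re-listed under two subsystems (or inconsistent names) is an error
  dup <- unique(df$pathway_id[duplicated(df$pathway_id)])
  if (length(dup)) {
    bad <- df[df$pathway_id %in% dup, ]
    conflicting <- vapply(split(bad, bad$pathway_id), function(x) {
      nrow(unique(x)) > 1L
    }, logical(1))
    if (any(conflicting)) {
      stop("hierarchy validation error: pathway(s) with conflicting parentage: ",
           paste(names(conflicting)[conflicting], collapse = ", "),
           call. = FALSE)
    }
    df <- df[!duplicated(df$pathway_id), ]
  }
  # a subsystem must have a single parent system
  sub <- unique(df[c("subsystem_id", "system_id")])
  dup_sub <- unique(sub$subsystem_id[duplicated(sub$subsystem_id)])
  if (length(dup_sub)) {
    stop("hierarchy validation error: subsystem(s) with conflicting parent system: ",
         paste(dup_sub, collapse = ", "), call. = FALSE)
  }

  structure(list(
    table = df,
    pathway_parent = stats::setNames(df$subsystem_id, df$pathway_id),
    subsystem_parent = stats::setNames(sub$system_id, sub$subsystem_id),
    names = list(
      pathway = stats::setNames(df$pathway_name, df$pathway_id),
      subsystem = stats::setNames(
        df$subsystem_name[!duplicated(df$subsystem_id)],
        df$subsystem_id[!duplicated(df$subsystem_id)]),
      system = stats::setNames(
        df$system_name[!duplicated(df$system_id)],
        df$system_id[!duplicated(df$system_id)])
    )
  ), class = "AnnotationHierarchy")
}

#' Write an AnnotationHierarchy back to TSV
#'
#' @param hierarchy An `AnnotationHierarchy`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_hierarchy <- function(hierarchy, path) {
  stopifnot(inherits(hierarchy, "AnnotationHierarchy"))
  utils::write.table(hierarchy$table, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Level counts of a hierarchy
#'
#' @param hierarchy An `AnnotationHierarchy`.
#' @return Named integer vector with elements `pathways`, `subsystems`,
#'   `systems`.
#' @export
hierarchy_counts <- function(hierarchy) {
  stopifnot(inherits(hierarchy, "AnnotationHierarchy"))
  c(pathways = length(hierarchy$pathway_parent),
    subsystems = length(hierarchy$subsystem_parent),
    systems = length(hierarchy$names$system))
}

#' @export
print.AnnotationHierarchy <- function(x, ...) {
  n <- hierarchy_counts(x)
  cat(sprintf("AnnotationHierarchy: %d pathways / %d subsystems / %d systems\n",
              n[["pathways"]], n[["subsystems"]], n[["systems"]]))
  invisible(x)
}

#' Parent system of a pathway
#'
#' @param hierarchy An `AnnotationHierarchy`.
#' @param pathway_id Character vector of pathway ids.
#' @return Character vector of system ids.
#' @export
pathway_system <- function(hierarchy, pathway_id) {
  unname(hierarchy$subsystem_parent[hierarchy$pathway_parent[pathway_id]])
}

#' Parent subsystem of a pathway
#'
#' @inheritParams pathway_system
#' @return Character vector of subsystem ids.
#' @export
pathway_subsystem <- function(hierarchy, pathway_id) {
  unname(hierarchy$pathway_parent[pathway_id])
}

#' Load pathway gene sets from a GMT file
#'
#' Standard GMT dialect: one set per line, tab-separated as
#' `id<TAB>description<TAB>gene1<TAB>gene2...`. Gene ids are treated as
#' case-sensitive opaque strings; duplicates within a line are stored once.
#' The gene universe (the `N` of the hypergeometric test) is the union of
#' all member genes.
#'
#' @param path Path to a GMT file.
#' @return A `PathwayGeneSets` object.
#' @export
load_gene_sets <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) return(as_gene_sets(list()))
  fields <- strsplit(lines, "\t", fixed = TRUE)
  short <- which(lengths(fields) < 3L)
  if (length(short)) {
    stop("GMT format error: line ", short[1],
         " has fewer than 3 fields", call. = FALSE)
  }
  sets <- lapply(fields, function(f) unique(f[-(1:2)]))
  names(sets) <- vapply(fields, `[[`, "", 1L)
  if (anyDuplicated(names(sets))) {
    stop("GMT format error: duplicated set id ",
         names(sets)[duplicated(names(sets))][1], call. = FALSE)
  }
  as_gene_sets(sets)
}

#' Construct PathwayGeneSets from a named list
#'
#' @param sets Named list; each element a character vector of gene ids.
#' @return A `PathwayGeneSets` with the deduplicated sets, the gene
#'   universe (union of members) and its size `N`.
#' @export
as_gene_sets <- function(sets) {
  sets <- lapply(sets, function(g) unique(as.character(g)))
  universe <- sort(unique(unlist(sets, use.names = FALSE)))
  structure(list(sets = sets, universe = universe, N = length(universe)),
            class = "PathwayGeneSets")
}

#' @export
print.PathwayGeneSets <- function(x, ...) {
  cat(sprintf("PathwayGeneSets: %d sets over a universe of %d genes\n",
              length(x$sets), x$N))
  invisible(x)
}

#' Write gene sets to GMT
#'
#' @param gene_sets A `PathwayGeneSets`.
#' @param path Output path.
#' @param descriptions Optional named character vector of set descriptions;
#'   defaults to the set id.
#' @return `path`, invisibly.
#' @export
write_gene_sets <- function(gene_sets, path, descriptions = NULL) {
  stopifnot(inherits(gene_sets, "PathwayGeneSets"))
  ids <- names(gene_sets$sets)
  desc <- if (is.null(descriptions)) ids else unname(descriptions[ids])
  lines <- vapply(seq_along(ids), function(i) {
    paste(c(ids[i], desc[i], gene_sets$sets[[i]]), collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}

#' Pathways containing a gene
#'
#' Membership lookup in the gene-to-pathway direction; agrees with the
#' stored pathway-to-gene sets by construction.
#'
#' @param gene_sets A `PathwayGeneSets`.
#' @param gene A single gene id.
#' @return Character vector of pathway ids (possibly empty).
#' @export
pathways_of_gene <- function(gene_sets, gene) {
  stopifnot(inherits(gene_sets, "PathwayGeneSets"), length(gene) == 1L)
  names(gene_sets$sets)[vapply(gene_sets$sets, function(s) gene %in% s,
                               logical(1))]
}

#' Per-gene pathway membership counts
#'
#' @param gene_sets A `PathwayGeneSets`.
#' @return Named integer vector over the universe: number of pathways each
#'   gene belongs to (the `N_i` feeding the S_N score).
#' @export
pathway_counts <- function(gene_sets) {
  members <- unlist(gene_sets$sets, use.names = FALSE)
  tab <- table(factor(members, levels = gene_sets$universe))
  stats::setNames(as.integer(tab), gene_sets$universe)
}

#' Load an orthology map from TSV
#'
#' @param path TSV with columns `source_id`, `target_id`, one pair per row.
#' @return An `OrthologyMap`: named list source gene -> character vector of
#'   target genes (one-to-many allowed; empty target sets are never stored).
#' @export
load_orthology <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          colClasses = "character")
  if (!all(c("source_id", "target_id") %in% names(df))) {
    stop("orthology format error: need columns source_id, target_id",
         call. = FALSE)
  }
  as_orthology(split(df$target_id, df$source_id))
}

#' Construct an OrthologyMap from a named list
#'
#' @param map Named list: source gene id -> character vector of target ids.
#' @return An `OrthologyMap`.
#' @export
as_orthology <- function(map) {
  map <- lapply(map, function(t) unique(as.character(t)))
  map <- map[lengths(map) > 0L]
  structure(map, class = "OrthologyMap")
}

#' Map a gene set through an orthology table
#'
#' Many-to-many orthology is resolved by set union: the result is the union
#' of the target sets of every mappable source gene. Unmappable genes are
#' not an error; they are dropped and counted.
#'
#' @param source_genes Character vector of source-species gene ids.
#' @param map An `OrthologyMap`.
#' @return List with `genes` (mapped target set), `n_dropped`, and
#'   `dropped` (the unmappable source ids).
#' @export
map_orthologs <- function(source_genes, map) {
  stopifnot(inherits(map, "OrthologyMap"))
  source_genes <- unique(as.character(source_genes))
  hit <- source_genes %in% names(map)
  targets <- sort(unique(unlist(map[source_genes[hit]], use.names = FALSE)))
  if (is.null(targets)) targets <- character(0)
  list(genes = targets,
       n_dropped = sum(!hit),
       dropped = source_genes[!hit])
}
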
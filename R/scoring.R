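#' Marker gene score for one source
#'
#' Converts each raw statistic of one source to its cutoff-anchored
#' preliminary score (see [normalize_statistic()]) and averages the
#' preliminary scores within the source per gene-cell type pair, yielding
#' one marker gene score per unique (gene, cell type, source) combination.
#' A score of 1 indicates strong evidence from that source that the gene
#' marks that cell type; 0 indicates little to none; 0.5 sits exactly at the
#' source's own significance cutoffs. Endpoints not reported for a pair are
#' omitted from the mean, not imputed: some sources only release their
#' significant results.
#'
#' Mouse and human records within one source are scored separately (the
#' `species` column is part of the grouping) because species-level medians
#' are needed downstream for the species-specificity call.
#'
#' @param records Tibble of validated statistic records for one source
#'   (columns `gene_id`, `cell_type_id`, `source_id`, `endpoint_name`,
#'   `value`, `species`).
#' @param meta The [source_metadata()] for that source.
#' @return Tibble with columns `gene_id`, `cell_type_id`, `source_id`,
#'   `species`, `marker_gene_score` (in `[0, 1]`) and `n_endpoints`.
#' @export
score_source <- function(records, meta) {
  stopifnot(is_source_metadata(meta))
  records <- tibble::as_tibble(records)
  if (nrow(records) == 0L) {
    return(tibble::tibble(gene_id = character(0), cell_type_id = character(0),
                          source_id = character(0), species = character(0),
                          marker_gene_score = numeric(0),
                          n_endpoints = integer(0)))
  }
  if (!all(records$source_id == meta$source_id)) {
    stop("records contain source_id other than '", meta$source_id, "'",
         call. = FALSE)
  }
  unknown <- setdiff(unique(records$endpoint_name), names(meta$endpoints))
  if (length(unknown)) {
    stop("source '", meta$source_id, "': undeclared endpoint(s): ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  dup <- duplicated(records[, c("gene_id", "cell_type_id", "species",
                                "endpoint_name")])
  if (any(dup)) {
    stop("source '", meta$source_id, "': duplicate statistic for the same ",
         "(gene, cell type, species, endpoint); first offender: ",
         paste(unlist(records[which(dup)[1],
                              c("gene_id", "cell_type_id", "species",
                                "endpoint_name")]), collapse = "/"),
         call. = FALSE)
  }
  prelim <- numeric(nrow(records))
  for (ep_name in unique(records$endpoint_name)) {
    idx <- records$endpoint_name == ep_name
    prelim[idx] <- normalize_statistic(records$value[idx],
                                       meta$endpoints[[ep_name]])
  }
  records$.prelim <- prelim
  out <- dplyr::summarise(
    dplyr::group_by(records, .data$gene_id, .data$cell_type_id,
                    .data$source_id, .data$species),
    marker_gene_score = mean(.data$.prelim),
    n_endpoints = dplyr::n(),
    .groups = "drop")
  dplyr::arrange(out, .data$gene_id, .data$cell_type_id, .data$species)
}

#' Marker gene scores for a whole study collection
#'
#' Splits a validated statistics table by source and applies
#' [score_source()] with each source's own endpoint definitions.
#'
#' @param records Tibble of validated statistic records (any mix of sources).
#' @param sources Named list of [source_metadata()].
#' @return Tibble of score records, one row per
#'   (gene, cell type, source, species).
#' @export
score_all <- function(records, sources) {
  sources <- as_source_collection(sources)
  records <- tibble::as_tibble(records)
  unknown <- setdiff(unique(records$source_id), names(sources))
  if (length(unknown)) {
    stop("no metadata for source(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  parts <- lapply(split(records, records$source_id),
                  function(d) score_source(d, sources[[d$source_id[1]]]))
  out <- dplyr::bind_rows(parts)
  if (nrow(out) == 0L) {
    return(score_source(records[0, ], sources[[1]]))
  }
  dplyr::arrange(out, .data$gene_id, .data$cell_type_id, .data$source_id,
                 .data$species)
}

#' Read/write score tables
#'
#' @param scores Score tibble as produced by [score_all()].
#' @param path CSV path.
#' @return `read_scores()` returns the score tibble; writers return `path`
#'   invisibly.
#' @export
write_scores <- function(scores, path) {
  readr::write_csv(scores, path, progress = FALSE)
  invisible(path)
}

#' @rdname write_scores
#' @export
read_scores <- function(path) {
  df <- read_strict_csv(path, c("gene_id", "cell_type_id", "source_id",
                                "species", "marker_gene_score", "n_endpoints"))
  df$marker_gene_score <- as.numeric(df$marker_gene_score)
  df$n_endpoints <- as.integer(df$n_endpoints)
  bad <- !is.finite(df$marker_gene_score) | df$marker_gene_score < 0 |
    df$marker_gene_score > 1
  if (any(bad)) {
    stop("score file contains scores outside [0, 1]: ", path, call. = FALSE)
  }
  tibble::as_tibble(df)
}
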
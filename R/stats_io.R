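#' Load and validate a long-format statistics table
#'
#' Reads the standardized per-source statistics table (one statistic per
#' row) and validates each row against the source metadata and the gene
#' cross-reference. Invalid rows are never silently dropped: they are
#' removed from the returned records and counted per reason in a rejection
#' report, mirroring curation workflows in which unmappable entities are
#' excluded with accounting rather than aborting the run.
#'
#' Rejection reasons: `unknown_source` (source_id absent from metadata),
#' `unknown_endpoint` (endpoint_name not declared by its source),
#' `unmapped_gene` (gene_id absent from the cross-reference),
#' `bad_species` (not mouse/human, or not a species the source covers),
#' `nonfinite_value`.
#'
#' @param path Path to the stats CSV with columns `gene_id`, `cell_type_id`,
#'   `source_id`, `endpoint_name`, `value`, `species`.
#' @param sources Named list of [source_metadata()] (see [read_sources()]).
#' @param genes Gene cross-reference tibble (see [read_gene_xref()]);
#'   `NULL` skips gene mapping checks.
#' @return A list with `records` (validated tibble) and `report` (named
#'   integer vector of rejection counts; empty when every row is valid).
#' @export
load_stat_table <- function(path, sources, genes = NULL) {
  df <- read_strict_csv(path, c("gene_id", "cell_type_id", "source_id",
                                "endpoint_name", "value", "species"))
  df <- dplyr::mutate(df,
    gene_id = as.character(.data$gene_id),
    cell_type_id = as.character(.data$cell_type_id),
    source_id = as.character(.data$source_id),
    endpoint_name = as.character(.data$endpoint_name),
    value = suppressWarnings(as.numeric(.data$value)),
    species = as.character(.data$species))
  validate_stat_records(df, sources, genes)
}

validate_stat_records <- function(df, sources, genes = NULL) {
  sources <- as_source_collection(sources)
  reason <- rep(NA_character_, nrow(df))

  known_source <- df$source_id %in% names(sources)
  reason[!known_source] <- "unknown_source"

  ep_key <- paste(df$source_id, df$endpoint_name, sep = "\r")
  valid_eps <- unlist(lapply(sources, function(s)
    paste(s$source_id, names(s$endpoints), sep = "\r")))
  bad_ep <- known_source & !(ep_key %in% valid_eps)
  reason[is.na(reason) & bad_ep] <- "unknown_endpoint"

  if (!is.null(genes)) {
    unmapped <- !(df$gene_id %in% genes$gene_id)
    reason[is.na(reason) & unmapped] <- "unmapped_gene"
  }

  src_species <- lapply(sources, function(s) s$species)
  ok_species <- df$species %in% c("mouse", "human") &
    mapply(function(sp, sid) sid %in% names(src_species) &&
             sp %in% src_species[[sid]],
           df$species, df$source_id, USE.NAMES = FALSE)
  reason[is.na(reason) & !ok_species] <- "bad_species"

  reason[is.na(reason) & !is.finite(df$value)] <- "nonfinite_value"

  rejected <- !is.na(reason)
  report <- table(reason[rejected])
  report <- stats::setNames(as.integer(report), names(report))
  list(records = tibble::as_tibble(df[!rejected, , drop = FALSE]),
       report = report)
}

#' Write a statistics table to CSV
#'
#' Inverse of [load_stat_table()]: a written table re-loads to the identical
#' record set with an empty rejection report.
#'
#' @param records Tibble of validated statistic records.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_stat_table <- function(records, path) {
  cols <- c("gene_id", "cell_type_id", "source_id", "endpoint_name",
            "value", "species")
  readr::write_csv(records[, cols], path, progress = FALSE)
  invisible(path)
}
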
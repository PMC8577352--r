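#' Read the gene cross-reference table
#'
#' The cross-reference joins mouse and human gene identifiers onto a single
#' unified key per mouse-human ortholog pair (or per species-specific gene
#' when no ortholog exists). Columns: `gene_id`, `mouse_symbol`,
#' `human_symbol`, `entrez_ids`, `ensembl_ids`; the two ID columns are
#' ';'-delimited lists. At least one of the symbols must be present per row
#' and `gene_id` must be unique.
#'
#' @param path Path to the cross-reference CSV.
#' @return A tibble with list-columns `entrez_ids` and `ensembl_ids`.
#' @export
read_gene_xref <- function(path) {
  df <- read_strict_csv(path, c("gene_id", "mouse_symbol", "human_symbol",
                                "entrez_ids", "ensembl_ids"))
  df <- dplyr::mutate(df, dplyr::across(
    c("gene_id", "mouse_symbol", "human_symbol", "entrez_ids", "ensembl_ids"),
    as.character))
  if (anyDuplicated(df$gene_id)) {
    stop("duplicate gene_id in cross-reference: ",
         paste(unique(df$gene_id[duplicated(df$gene_id)]), collapse = ", "),
         call. = FALSE)
  }
  no_symbol <- (is.na(df$mouse_symbol) | !nzchar(df$mouse_symbol)) &
    (is.na(df$human_symbol) | !nzchar(df$human_symbol))
  if (any(no_symbol)) {
    stop("cross-reference rows without any symbol: gene_id ",
         paste(df$gene_id[no_symbol], collapse = ", "), call. = FALSE)
  }
  df$entrez_ids <- lapply(df$entrez_ids, split_list_field_na)
  df$ensembl_ids <- lapply(df$ensembl_ids, split_list_field_na)
  tibble::as_tibble(df)
}

#' Write a gene cross-reference table
#'
#' @param genes Tibble as returned by [read_gene_xref()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_gene_xref <- function(genes, path) {
  out <- genes
  out$entrez_ids <- vapply(out$entrez_ids, paste, character(1), collapse = ";")
  out$ensembl_ids <- vapply(out$ensembl_ids, paste, character(1), collapse = ";")
  readr::write_csv(out, path, progress = FALSE)
  invisible(path)
}

split_list_field_na <- function(x) {
  if (is.na(x) || !nzchar(x)) character(0) else strsplit(x, ";", fixed = TRUE)[[1]]
}

#' Resolve a gene symbol to the unified gene key
#'
#' Exact, case-insensitive lookup of a symbol in the species-appropriate
#' column of the cross-reference (mouse and human symbol casing conventions
#' differ, so `Cd19` and `CD19` match the same entry). No fuzzy matching is
#' attempted. A symbol absent from the table yields `NA_character_` rather
#' than an error; a symbol mapping to more than one `gene_id` is ambiguous
#' and raises an error listing the candidates.
#'
#' @param symbol Gene symbol to look up.
#' @param species `"mouse"` or `"human"`.
#' @param genes Cross-reference tibble from [read_gene_xref()].
#' @return The matching `gene_id`, or `NA_character_` if not found.
#' @export
resolve_gene_id <- function(symbol, species, genes) {
  species <- match.arg(species, c("mouse", "human"))
  col <- if (species == "mouse") genes$mouse_symbol else genes$human_symbol
  hit <- !is.na(col) & toupper(col) == toupper(symbol)
  ids <- genes$gene_id[hit]
  if (length(ids) == 0L) return(NA_character_)
  if (length(ids) > 1L) {
    stop("ambiguous symbol '", symbol, "' (", species, "): matches ",
         paste(ids, collapse = ", "), call. = FALSE)
  }
  ids
}
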
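#' Describe one source (publication or dataset) and its endpoints
#'
#' Contextual metadata collected for each curated source: the species its
#' samples came from, the sample and expression/statistical methodology, and
#' the definitions of every statistical endpoint it reports.
#'
#' @param source_id Text key, unique within a collection.
#' @param species Character vector, subset of `c("mouse", "human")`.
#' @param sample_type Free-text sample description (e.g. "pancreas").
#' @param expression_method Free text, e.g. "scRNA-seq" or "FACS+RNA-seq".
#' @param statistical_method Free text, e.g. "Wilcoxon rank-sum".
#' @param endpoints Non-empty list of [endpoint_definition()] objects with
#'   unique names within the source.
#'
#' @return An object of class `source_metadata`.
#' @export
source_metadata <- function(source_id, species, sample_type = "",
                            expression_method = "", statistical_method = "",
                            endpoints = list()) {
  stopifnot(is.character(source_id), length(source_id) == 1L, nzchar(source_id))
  species <- unique(match.arg(species, c("mouse", "human"), several.ok = TRUE))
  if (length(endpoints) == 0L) {
    stop("source '", source_id, "': endpoints must be non-empty", call. = FALSE)
  }
  ok <- vapply(endpoints, is_endpoint_definition, logical(1))
  if (!all(ok)) {
    stop("source '", source_id,
         "': all endpoints must be endpoint_definition objects", call. = FALSE)
  }
  nm <- vapply(endpoints, function(e) e$endpoint_name, character(1))
  if (anyDuplicated(nm)) {
    stop("source '", source_id, "': duplicate endpoint names: ",
         paste(unique(nm[duplicated(nm)]), collapse = ", "), call. = FALSE)
  }
  names(endpoints) <- nm
  structure(
    list(source_id = source_id, species = species, sample_type = sample_type,
         expression_method = expression_method,
         statistical_method = statistical_method, endpoints = endpoints),
    class = "source_metadata"
  )
}

#' @export
print.source_metadata <- function(x, ...) {
  cat(sprintf("<source '%s'> species %s; %d endpoint(s): %s\n",
              x$source_id, paste(x$species, collapse = "+"),
              length(x$endpoints),
              paste(names(x$endpoints), collapse = ", ")))
  invisible(x)
}

is_source_metadata <- function(x) inherits(x, "source_metadata")

as_source_collection <- function(sources) {
  if (is_source_metadata(sources)) sources <- list(sources)
  ok <- vapply(sources, is_source_metadata, logical(1))
  if (!all(ok)) stop("sources must be source_metadata objects", call. = FALSE)
  ids <- vapply(sources, function(s) s$source_id, character(1))
  if (anyDuplicated(ids)) {
    stop("duplicate source_id in collection: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  }
  names(sources) <- ids
  sources
}

#' Read a source-metadata collection from JSON or CSV
#'
#' The JSON dialect is a list of objects with fields `source_id`, `species`
#' (list), `sample_type`, `expression_method`, `statistical_method` and
#' `endpoints` (list of objects with `endpoint_name`, `direction`,
#' `range_min`, `range_max`, `significance_cutoff`). The CSV dialect has one
#' endpoint per row with the same fields flattened and `species`
#' ';'-delimited.
#'
#' @param path Path to a `.json` or `.csv` file.
#' @return Named list of [source_metadata()], keyed by `source_id`.
#' @export
read_sources <- function(path) {
  if (!file.exists(path)) stop("sources file not found: ", path, call. = FALSE)
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    raw <- jsonlite::read_json(path, simplifyVector = FALSE)
    sources <- lapply(raw, function(s) {
      eps <- lapply(s$endpoints, function(e) {
        endpoint_definition(e$endpoint_name, e$direction, e$range_min,
                            e$range_max, e$significance_cutoff)
      })
      source_metadata(s$source_id, unlist(s$species),
                      s$sample_type %||% "", s$expression_method %||% "",
                      s$statistical_method %||% "", eps)
    })
  } else {
    df <- read_strict_csv(path, c("source_id", "species", "sample_type",
                                  "expression_method", "statistical_method",
                                  "endpoint_name", "direction", "range_min",
                                  "range_max", "significance_cutoff"))
    sources <- lapply(split(df, df$source_id), function(d) {
      eps <- lapply(seq_len(nrow(d)), function(i) {
        endpoint_definition(d$endpoint_name[i], d$direction[i],
                            d$range_min[i], d$range_max[i],
                            d$significance_cutoff[i])
      })
      source_metadata(d$source_id[1], split_list_field(d$species[1]),
                      d$sample_type[1], d$expression_method[1],
                      d$statistical_method[1], eps)
    })
  }
  as_source_collection(unname(sources))
}

#' Write a source-metadata collection to JSON
#'
#' @param sources Named list of [source_metadata()].
#' @param path Output `.json` path.
#' @return `path`, invisibly.
#' @export
write_sources <- function(sources, path) {
  sources <- as_source_collection(sources)
  out <- lapply(sources, function(s) {
    list(source_id = s$source_id, species = as.list(s$species),
         sample_type = s$sample_type, expression_method = s$expression_method,
         statistical_method = s$statistical_method,
         endpoints = lapply(s$endpoints, unclass))
  })
  jsonlite::write_json(unname(out), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

split_list_field <- function(x) {
  if (is.na(x) || !nzchar(x)) character(0) else strsplit(x, ";", fixed = TRUE)[[1]]
}

read_strict_csv <- function(path, required_cols) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- tryCatch(
    readr::read_csv(path, show_col_types = FALSE, progress = FALSE),
    error = function(e) stop("failed to read ", path, ": ",
                             conditionMessage(e), call. = FALSE)
  )
  if (nrow(df) == 0L) stop("empty file: ", path, call. = FALSE)
  missing <- setdiff(required_cols, names(df))
  if (length(missing)) {
    stop("missing required column(s) in ", path, ": ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  df
}
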
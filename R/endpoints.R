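#' Define a statistical endpoint of a source
#'
#' An endpoint is one statistical output of a source's marker-gene analysis
#' (for example a log fold change enrichment score, an adjusted p-value, or
#' an AUROC), together with the range it can take, the direction in which it
#' becomes more significant, and the significance cutoff the source's authors
#' declared. The cutoff is the anchor of the normalization: it always maps to
#' a preliminary score of exactly 0.5.
#'
#' @param endpoint_name Text label, unique within a source.
#' @param direction `"lower_more_significant"` (e.g. p-values, negative
#'   enrichment scores) or `"higher_more_significant"` (e.g. AUROC, z-score).
#' @param range_min,range_max Least and greatest value the endpoint can take.
#' @param significance_cutoff The author-declared significance threshold;
#'   must lie within `[range_min, range_max]`.
#'
#' @return An object of class `endpoint_definition`.
#' @seealso [normalize_statistic()]
#' @export
#' @examples
#' lfc <- endpoint_definition("log_fc_enrichment", "lower_more_significant",
#'                            range_min = -9, range_max = 0,
#'                            significance_cutoff = -2)
#' normalize_statistic(c(-9, -5.5, -2, 0), lfc)
endpoint_definition <- function(endpoint_name, direction, range_min, range_max,
                                significance_cutoff) {
  direction <- match.arg(direction,
                         c("lower_more_significant", "higher_more_significant"))
  stopifnot(is.character(endpoint_name), length(endpoint_name) == 1L,
            nzchar(endpoint_name))
  range_min <- as.numeric(range_min)
  range_max <- as.numeric(range_max)
  significance_cutoff <- as.numeric(significance_cutoff)
  if (!is.finite(range_min) || !is.finite(range_max) ||
      !is.finite(significance_cutoff)) {
    stop("endpoint '", endpoint_name, "': range and cutoff must be finite",
         call. = FALSE)
  }
  if (!(range_min < range_max)) {
    stop("endpoint '", endpoint_name, "': range_min must be < range_max",
         call. = FALSE)
  }
  if (significance_cutoff < range_min || significance_cutoff > range_max) {
    stop("endpoint '", endpoint_name,
         "': significance_cutoff must lie within [range_min, range_max]",
         call. = FALSE)
  }
  structure(
    list(endpoint_name = endpoint_name, direction = direction,
         range_min = range_min, range_max = range_max,
         significance_cutoff = significance_cutoff),
    class = "endpoint_definition"
  )
}

#' @export
print.endpoint_definition <- function(x, ...) {
  cat(sprintf("<endpoint '%s'> range [%g, %g], cutoff %g, %s\n",
              x$endpoint_name, x$range_min, x$range_max,
              x$significance_cutoff, x$direction))
  invisible(x)
}

is_endpoint_definition <- function(x) inherits(x, "endpoint_definition")

check_nondegenerate <- function(ep) {
  if (ep$significance_cutoff <= ep$range_min ||
      ep$significance_cutoff >= ep$range_max) {
    stop("endpoint '", ep$endpoint_name,
         "': significance_cutoff coincides with a range bound; ",
         "one normalization segment would be degenerate", call. = FALSE)
  }
  invisible(ep)
}

#' Normalize a raw statistic to a cutoff-anchored preliminary score
#'
#' Maps a raw endpoint value to `[0, 1]` with a two-segment piecewise-linear
#' map anchored so that the declared significance cutoff scores exactly 0.5.
#' For a lower-is-more-significant endpoint, `range_min` maps to 1,
#' the cutoff to 0.5, and `range_max` to 0, with linear interpolation within
#' each segment; a higher-is-more-significant endpoint is the mirror image.
#' Observed values outside the declared range are clamped to the nearest
#' bound before mapping, so the map is total, bounded, and monotone.
#'
#' @param value Numeric vector of raw endpoint values; must be finite.
#' @param ep An [endpoint_definition()]. Its cutoff must lie strictly inside
#'   the range, otherwise a configuration error is raised.
#'
#' @return Numeric vector of preliminary scores in `[0, 1]`.
#' @export
normalize_statistic <- function(value, ep) {
  stopifnot(is_endpoint_definition(ep))
  check_nondegenerate(ep)
  value <- as.numeric(value)
  if (any(!is.finite(value))) {
    stop("endpoint '", ep$endpoint_name,
         "': cannot normalize non-finite values", call. = FALSE)
  }
  v <- pmin(pmax(value, ep$range_min), ep$range_max)
  cut <- ep$significance_cutoff
  if (ep$direction == "lower_more_significant") {
    ifelse(v <= cut,
           0.5 + 0.5 * (cut - v) / (cut - ep$range_min),
           0.5 - 0.5 * (v - cut) / (ep$range_max - cut))
  } else {
    ifelse(v >= cut,
           0.5 + 0.5 * (v - cut) / (ep$range_max - cut),
           0.5 - 0.5 * (cut - v) / (cut - ep$range_min))
  }
}

#' Invert the cutoff-anchored normalization
#'
#' Maps a preliminary score in `[0, 1]` back to the raw endpoint scale.
#' Exact inverse of [normalize_statistic()] on the declared range; used by
#' the synthetic corpus generator to write latent significance scores out as
#' raw statistics.
#'
#' @param score Numeric vector of scores in `[0, 1]`.
#' @param ep An [endpoint_definition()].
#' @return Numeric vector of raw values within `[range_min, range_max]`.
#' @export
denormalize_score <- function(score, ep) {
  stopifnot(is_endpoint_definition(ep))
  check_nondegenerate(ep)
  score <- as.numeric(score)
  if (any(!is.finite(score)) || any(score < 0 | score > 1)) {
    stop("scores must be finite and within [0, 1]", call. = FALSE)
  }
  cut <- ep$significance_cutoff
  if (ep$direction == "lower_more_significant") {
    ifelse(score >= 0.5,
           cut - (score - 0.5) / 0.5 * (cut - ep$range_min),
           cut + (0.5 - score) / 0.5 * (ep$range_max - cut))
  } else {
    ifelse(score >= 0.5,
           cut + (score - 0.5) / 0.5 * (ep$range_max - cut),
           cut - (0.5 - score) / 0.5 * (cut - ep$range_min))
  }
}
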
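#' Aggregate per-source marker gene scores across a study collection
#'
#' Collapses score records to one row per (gene, cell type). Each source
#' contributes a single value per pair — the mean of its per-species score
#' records — so a source that assayed both species is not double-weighted in
#' the cross-source mean, median and significant-source fraction. Species
#' medians, needed for the species-specificity call, are computed across the
#' species-resolved records.
#'
#' @param scores Score tibble (see [score_all()]).
#' @return Tibble with one row per (gene, cell type): `mean_score`,
#'   `median_score`, `frac_significant_sources` (fraction of sources whose
#'   value is >= 0.5), `n_sources`, `median_mouse`, `median_human` (`NA`
#'   when that species was not observed for the pair).
#' @export
aggregate_pairs <- function(scores) {
  scores <- tibble::as_tibble(scores)
  empty <- tibble::tibble(gene_id = character(0), cell_type_id = character(0),
                          mean_score = numeric(0), median_score = numeric(0),
                          frac_significant_sources = numeric(0),
                          n_sources = integer(0),
                          median_mouse = numeric(0), median_human = numeric(0))
  if (nrow(scores) == 0L) return(empty)

  src_vals <- dplyr::summarise(
    dplyr::group_by(scores, .data$gene_id, .data$cell_type_id,
                    .data$source_id),
    value = mean(.data$marker_gene_score), .groups = "drop")
  pairs <- dplyr::summarise(
    dplyr::group_by(src_vals, .data$gene_id, .data$cell_type_id),
    mean_score = mean(.data$value),
    median_score = stats::median(.data$value),
    frac_significant_sources = mean(.data$value >= 0.5),
    n_sources = dplyr::n(), .groups = "drop")

  sp_med <- dplyr::summarise(
    dplyr::group_by(scores, .data$gene_id, .data$cell_type_id, .data$species),
    med = stats::median(.data$marker_gene_score), .groups = "drop")
  sp_med <- tidyr::pivot_wider(sp_med, names_from = "species",
                               values_from = "med", names_prefix = "median_")
  for (col in c("median_mouse", "median_human")) {
    if (!col %in% names(sp_med)) sp_med[[col]] <- NA_real_
  }
  out <- dplyr::left_join(pairs,
                          sp_med[, c("gene_id", "cell_type_id",
                                     "median_mouse", "median_human")],
                          by = c("gene_id", "cell_type_id"))
  dplyr::arrange(out, .data$gene_id, .data$cell_type_id)
}

#' Sparse-data gate preceding classification
#'
#' Genes reported in fewer cell types than `min_cell_types` carry too little
#' information to judge specificity across cell types and are labelled
#' indeterminate — unless some single cell type was examined by enough
#' independent sources (`min_sources_common`, relaxed to `min_sources_rare`
#' for rare cell types such as pancreatic epsilon cells, which few studies
#' assay), in which case the gene is rescued and proceeds to classification.
#'
#' @param pairs Aggregated pairs ([aggregate_pairs()]) for a single gene.
#' @param rare_types Character vector of rare cell-type IDs.
#' @param min_cell_types Minimum distinct cell types to proceed outright.
#' @param min_sources_common,min_sources_rare Source-count rescue thresholds
#'   for common and rare cell types.
#' @return `TRUE` to proceed to classification, `FALSE` for indeterminate.
#' @export
gate_indeterminate <- function(pairs, rare_types = character(0),
                               min_cell_types = 4L, min_sources_common = 4L,
                               min_sources_rare = 2L) {
  pairs <- tibble::as_tibble(pairs)
  if (nrow(pairs) == 0L) return(FALSE)
  if (length(unique(pairs$gene_id)) != 1L) {
    stop("gate_indeterminate expects pairs of a single gene", call. = FALSE)
  }
  if (length(unique(pairs$cell_type_id)) >= min_cell_types) return(TRUE)
  need <- ifelse(pairs$cell_type_id %in% rare_types,
                 min_sources_rare, min_sources_common)
  any(pairs$n_sources >= need)
}

#' Classify one gene from its aggregated pairs
#'
#' Implements the marker-gene decision rule. A pair is *significant* when
#' its cross-source mean score is >= 0.5 (`rule = "mean"`) or when at least
#' two-thirds of its sources individually scored it >= 0.5
#' (`rule = "two_thirds"`); ties at exactly 0.5 count as significant. With
#' X = number of significant cell types:
#'
#' * X = 0 — the gene marks no cell type (`non_marker`).
#' * X = 1 — marker for that one cell type; the specificity propagates up
#'   the branch, so all strict ancestors are reported as
#'   `propagated_cell_types`.
#' * X >= 2 — Y = number of distinct higher-level groups
#'   ([higher_level_group()]) among the significant cell types. Y = 1 means
#'   all subtypes share a group: the gene is a marker for the higher-level
#'   group itself, not the subtypes (`higher_level_marker`). Y >= 2 with
#'   `dual_marker_policy = "allow"` and X <= `max_marker_types` leaves the
#'   gene a marker for those X cell types; otherwise it is a `non_marker`
#'   for lack of specificity.
#'
#' A species-specificity call ([species_specificity()]) is made per marker
#' cell type from the species medians; for a higher-level marker the group's
#' species medians are taken as the median over its significant subtypes'
#' species medians.
#'
#' @param pairs Aggregated pairs for one gene; every `cell_type_id` must
#'   exist in `tree`. The gene must have passed [gate_indeterminate()].
#' @param tree A `cell_ontology`.
#' @param rule Significance rule, `"mean"` or `"two_thirds"`.
#' @param dual_marker_policy `"allow"` keeps genes significant in up to
#'   `max_marker_types` cell types from different groups as multi-cell-type
#'   markers; `"forbid"` sends every Y >= 2 gene to `non_marker`.
#' @param max_marker_types Cap on marker cell types per gene.
#' @param fold,min_median Passed to [species_specificity()].
#' @return One-row tibble: `gene_id`, `label`, and list-columns
#'   `marker_cell_types`, `propagated_cell_types`, `species_call` (named by
#'   marker cell type), plus counts `X`, `Y`, `n_sources` (max over pairs).
#' @export
classify_gene <- function(pairs, tree, rule = c("mean", "two_thirds"),
                          dual_marker_policy = c("allow", "forbid"),
                          max_marker_types = 2L, fold = 3, min_median = 0.5) {
  rule <- match.arg(rule)
  dual_marker_policy <- match.arg(dual_marker_policy)
  pairs <- tibble::as_tibble(pairs)
  stopifnot(nrow(pairs) >= 1L, is_cell_ontology(tree))
  if (length(unique(pairs$gene_id)) != 1L) {
    stop("classify_gene expects pairs of a single gene", call. = FALSE)
  }
  for (ct in unique(pairs$cell_type_id)) ontology_check_node(tree, ct)

  sig_mask <- if (rule == "mean") pairs$mean_score >= 0.5 else
    pairs$frac_significant_sources >= 2 / 3
  sig <- sort(unique(pairs$cell_type_id[sig_mask]))
  X <- length(sig)

  groups <- character(0)
  Y <- 0L
  marker_cts <- character(0)
  label <- "non_marker"
  if (X == 1L) {
    label <- "marker"
    marker_cts <- sig
  } else if (X >= 2L) {
    groups <- sort(unique(vapply(sig, function(ct)
      higher_level_group(tree, ct), character(1))))
    Y <- length(groups)
    if (Y == 1L) {
      label <- "higher_level_marker"
      marker_cts <- groups
    } else if (dual_marker_policy == "allow" && X <= max_marker_types) {
      label <- "marker"
      marker_cts <- sig
    } else {
      label <- "non_marker"
    }
  }

  propagated <- character(0)
  if (length(marker_cts)) {
    propagated <- sort(setdiff(
      unique(unlist(lapply(marker_cts, function(ct) ancestors(tree, ct)[-1]))),
      marker_cts))
  }

  species_call <- character(0)
  if (length(marker_cts)) {
    species_call <- vapply(marker_cts, function(ct) {
      med <- marker_species_medians(pairs, tree, ct, sig)
      species_specificity(med, fold = fold, min_median = min_median)
    }, character(1))
  }

  tibble::tibble(
    gene_id = pairs$gene_id[1], label = label,
    marker_cell_types = list(marker_cts),
    propagated_cell_types = list(propagated),
    species_call = list(species_call),
    X = X, Y = Y, n_sources = max(pairs$n_sources))
}

# Species medians backing the specificity call for one marker cell type.
# For a subtype marker these are the pair's own medians; for a higher-level
# group (which need not itself be an assayed pair) the medians are pooled
# over the significant subtypes falling under that group.
marker_species_medians <- function(pairs, tree, marker_ct, sig) {
  if (marker_ct %in% pairs$cell_type_id) {
    row <- pairs[pairs$cell_type_id == marker_ct, ][1, ]
    med <- c(mouse = row$median_mouse, human = row$median_human)
  } else {
    under <- sig[vapply(sig, function(ct)
      marker_ct %in% ancestors(tree, ct), logical(1))]
    sub <- pairs[pairs$cell_type_id %in% under, ]
    med <- c(mouse = stats::median(sub$median_mouse, na.rm = TRUE),
             human = stats::median(sub$median_human, na.rm = TRUE))
  }
  med[!is.na(med)]
}

#' Species specificity of a marker call
#'
#' A marker is called specific to one species when the species' median
#' marker gene scores differ at least `fold`-fold and the larger median
#' exceeds `min_median`; a zero smaller median counts as an infinite fold
#' difference. With only one species observed the call is `insufficient`.
#'
#' @param per_species_median Named numeric vector (names among `mouse`,
#'   `human`) of median marker gene scores per observed species; must be
#'   non-negative.
#' @param fold Required fold difference between species medians.
#' @param min_median The larger median must exceed this.
#' @return One of `"both"`, `"mouse_specific"`, `"human_specific"`,
#'   `"insufficient"`.
#' @export
species_specificity <- function(per_species_median, fold = 3,
                                min_median = 0.5) {
  med <- per_species_median[!is.na(per_species_median)]
  stopifnot(all(names(med) %in% c("mouse", "human")))
  if (any(med < 0)) stop("species medians must be non-negative", call. = FALSE)
  if (length(med) < 2L) return("insufficient")
  hi_sp <- names(med)[which.max(med)]
  hi <- max(med); lo <- min(med)
  # small relative slack so an exactly fold-times gap is not lost to
  # floating-point division (0.6 / 0.2 < 3 in double arithmetic)
  specific <- hi > min_median &&
    (lo == 0 || hi / lo >= fold * (1 - 1e-12))
  if (specific) paste0(hi_sp, "_specific") else "both"
}

#' Classification configuration
#'
#' Bundles every tunable of the classification stage with its default.
#'
#' @param rule Significance rule: `"mean"` (cross-source mean score >= 0.5)
#'   or `"two_thirds"` (>= 0.5 in at least two-thirds of sources).
#' @param dual_marker_policy `"allow"` or `"forbid"` (see [classify_gene()]).
#' @param min_cell_types,min_sources_common,min_sources_rare Gate thresholds
#'   (see [gate_indeterminate()]).
#' @param max_marker_types Cap on marker cell types per gene.
#' @param fold,min_median Species-specificity thresholds
#'   (see [species_specificity()]).
#' @param rare_cell_types Rare cell-type IDs; `NULL` takes the tree's
#'   `is_rare` flags.
#' @return A list of class `classification_config`.
#' @export
classification_config <- function(rule = "mean", dual_marker_policy = "allow",
                                  min_cell_types = 4L, min_sources_common = 4L,
                                  min_sources_rare = 2L, max_marker_types = 2L,
                                  fold = 3, min_median = 0.5,
                                  rare_cell_types = NULL) {
  rule <- match.arg(rule, c("mean", "two_thirds"))
  dual_marker_policy <- match.arg(dual_marker_policy, c("allow", "forbid"))
  stopifnot(min_cell_types >= 1, min_sources_common >= 1,
            min_sources_rare >= 1, max_marker_types >= 1,
            fold >= 1, min_median >= 0, min_median <= 1)
  structure(list(rule = rule, dual_marker_policy = dual_marker_policy,
                 min_cell_types = as.integer(min_cell_types),
                 min_sources_common = as.integer(min_sources_common),
                 min_sources_rare = as.integer(min_sources_rare),
                 max_marker_types = as.integer(max_marker_types),
                 fold = fold, min_median = min_median,
                 rare_cell_types = rare_cell_types),
            class = "classification_config")
}

#' Classify every gene of a study collection
#'
#' Full classification stage: aggregate score records across sources, gate
#' sparsely observed genes as indeterminate, classify the rest, and tally
#' the results. Deterministic given the inputs and configuration.
#'
#' @param scores Score tibble (see [score_all()]).
#' @param tree A `cell_ontology`; every scored cell type must exist in it.
#' @param config A [classification_config()].
#' @return A list with `classifications` (one row per gene; see
#'   [classify_gene()], plus the `indeterminate` rows) and `summary`: gene
#'   counts per label, marker-gene counts per cell type, total marker
#'   pairs, mean supporting sources per marker pair, and `review_genes` —
#'   genes whose significant cell types span more than two higher-level
#'   groups, flagged for manual curation against pruned-away branches.
#' @export
classify_all <- function(scores, tree, config = classification_config()) {
  stopifnot(inherits(config, "classification_config"), is_cell_ontology(tree))
  rare <- config$rare_cell_types %||% rare_cell_types(tree)
  pairs <- aggregate_pairs(scores)

  empty_cls <- tibble::tibble(
    gene_id = character(0), label = character(0),
    marker_cell_types = list(), propagated_cell_types = list(),
    species_call = list(), X = integer(0), Y = integer(0),
    n_sources = integer(0))
  if (nrow(pairs) == 0L) {
    return(list(classifications = empty_cls,
                summary = summarize_classifications(empty_cls)))
  }

  per_gene <- split(pairs, pairs$gene_id)
  rows <- lapply(per_gene, function(gp) {
    if (!gate_indeterminate(gp, rare_types = rare,
                            min_cell_types = config$min_cell_types,
                            min_sources_common = config$min_sources_common,
                            min_sources_rare = config$min_sources_rare)) {
      return(tibble::tibble(
        gene_id = gp$gene_id[1], label = "indeterminate",
        marker_cell_types = list(character(0)),
        propagated_cell_types = list(character(0)),
        species_call = list(character(0)),
        X = NA_integer_, Y = NA_integer_,
        n_sources = max(gp$n_sources)))
    }
    classify_gene(gp, tree, rule = config$rule,
                  dual_marker_policy = config$dual_marker_policy,
                  max_marker_types = config$max_marker_types,
                  fold = config$fold, min_median = config$min_median)
  })
  cls <- dplyr::bind_rows(rows)
  cls <- dplyr::arrange(cls, .data$gene_id)
  list(classifications = cls, summary = summarize_classifications(cls))
}

summarize_classifications <- function(cls) {
  labels <- c("marker", "higher_level_marker", "non_marker", "indeterminate")
  label_counts <- vapply(labels, function(l) sum(cls$label == l), integer(1))
  marker_rows <- cls$label %in% c("marker", "higher_level_marker")
  pair_cts <- unlist(cls$marker_cell_types[marker_rows])
  per_ct <- if (length(pair_cts)) {
    tab <- sort(table(pair_cts), decreasing = TRUE)
    stats::setNames(as.integer(tab), names(tab))
  } else integer(0)
  mean_src <- if (any(marker_rows)) {
    reps <- vapply(cls$marker_cell_types[marker_rows], length, integer(1))
    sum(cls$n_sources[marker_rows] * reps) / sum(reps)
  } else NA_real_
  list(n_genes = nrow(cls),
       label_counts = as.list(label_counts),
       n_marker_genes = sum(marker_rows),
       n_marker_pairs = length(pair_cts),
       markers_per_cell_type = as.list(per_ct),
       mean_sources_per_marker = mean_src,
       review_genes = cls$gene_id[!is.na(cls$Y) & cls$Y > 2])
}

#' Read/write classification tables
#'
#' The markers CSV flattens the list-columns with ';' delimiters; the
#' `species_call` column is aligned with `marker_cell_types` order.
#'
#' @param cls Classification tibble from [classify_all()].
#' @param path CSV path.
#' @return `read_classifications()` returns the tibble with list-columns
#'   restored; writers return `path` invisibly.
#' @export
write_classifications <- function(cls, path) {
  out <- tibble::tibble(
    gene_id = cls$gene_id, label = cls$label,
    marker_cell_types = vapply(cls$marker_cell_types, paste, character(1),
                               collapse = ";"),
    propagated_cell_types = vapply(cls$propagated_cell_types, paste,
                                   character(1), collapse = ";"),
    species_call = vapply(cls$species_call, paste, character(1),
                          collapse = ";"),
    X = cls$X, Y = cls$Y, n_sources = cls$n_sources)
  readr::write_csv(out, path, progress = FALSE)
  invisible(path)
}

#' @rdname write_classifications
#' @export
read_classifications <- function(path) {
  df <- read_strict_csv(path, c("gene_id", "label", "marker_cell_types",
                                "propagated_cell_types", "species_call",
                                "X", "Y", "n_sources"))
  tibble::tibble(
    gene_id = as.character(df$gene_id), label = as.character(df$label),
    marker_cell_types = lapply(as.character(df$marker_cell_types),
                               split_list_field_na),
    propagated_cell_types = lapply(as.character(df$propagated_cell_types),
                                   split_list_field_na),
    species_call = lapply(as.character(df$species_call), split_list_field_na),
    X = as.integer(df$X), Y = as.integer(df$Y),
    n_sources = as.integer(df$n_sources))
}
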
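# Shared fixtures, built in code at test time.

# Source 1 of the worked scoring example: a log fold change enrichment
# endpoint on [-9, 0] with cutoff -2 and an adjusted p-value on [0, 1]
# with cutoff 0.05, both lower-more-significant.
worked_source <- function(id = "S1", species = c("mouse", "human")) {
  source_metadata(
    id, species, sample_type = "pancreas",
    expression_method = "scRNA-seq", statistical_method = "wilcoxon",
    endpoints = list(
      endpoint_definition("log_fc_enrichment", "lower_more_significant",
                          -9, 0, -2),
      endpoint_definition("adj_p", "lower_more_significant", 0, 1, 0.05)))
}

# Two higher-level groups with three subtypes each:
#   root -> g1 -> {a1, a2, a3};  root -> g2 -> {b1, b2, b3}
two_group_tree <- function() {
  nodes <- tibble::tibble(
    node_id = c("root", "g1", "g2", "a1", "a2", "a3", "b1", "b2", "b3"),
    name = c("cell", "group 1", "group 2", paste0("subtype a", 1:3),
             paste0("subtype b", 1:3)),
    is_higher_level = c(FALSE, TRUE, TRUE, rep(FALSE, 6)),
    is_rare = FALSE,
    keep = c(TRUE, TRUE, TRUE, rep(FALSE, 6)))
  edges <- tibble::tibble(
    child_id = c("g1", "g2", "a1", "a2", "a3", "b1", "b2", "b3"),
    parent_id = c("root", "root", "g1", "g1", "g1", "g2", "g2", "g2"))
  prune_to_tree(nodes, edges)$tree
}

two_group_map <- c(a1 = "g1", a2 = "g1", a3 = "g1",
                   b1 = "g2", b2 = "g2", b3 = "g2",
                   g1 = "g1", g2 = "g2", root = "root")

# Aggregated-pair rows for one gene from named mean scores, bypassing the
# per-source layer (n_sources set high enough to satisfy any gate).
pairs_from_means <- function(means, gene = "G1", n_sources = 5L) {
  tibble::tibble(
    gene_id = gene, cell_type_id = names(means),
    mean_score = unname(means), median_score = unname(means),
    frac_significant_sources = as.numeric(means >= 0.5),
    n_sources = n_sources,
    median_mouse = unname(means), median_human = unname(means))
}

# Score records for one gene from a named list of per-source score vectors
# (one single-species source per value; species alternate mouse/human).
scores_from_vectors <- function(by_ct, gene = "G1") {
  rows <- lapply(names(by_ct), function(ct) {
    v <- by_ct[[ct]]
    tibble::tibble(
      gene_id = gene, cell_type_id = ct,
      source_id = sprintf("S%02d", seq_along(v)),
      species = rep(c("mouse", "human"), length.out = length(v)),
      marker_gene_score = v, n_endpoints = 1L)
  })
  dplyr::bind_rows(rows)
}

random_endpoint <- function() {
  lo <- stats::runif(1, -50, 50)
  hi <- lo + stats::runif(1, 0.5, 100)
  cut <- stats::runif(1, lo + 1e-3 * (hi - lo), hi - 1e-3 * (hi - lo))
  endpoint_definition(
    "ep", sample(c("lower_more_significant", "higher_more_significant"), 1),
    lo, hi, cut)
}

# Random raw ontology graphs with multi-parents, cycles and chains.
random_raw_ontology <- function(n_nodes = 12L) {
  ids <- sprintf("N%02d", seq_len(n_nodes))
  nodes <- tibble::tibble(
    node_id = ids, name = ids,
    is_higher_level = stats::runif(n_nodes) < 0.2,
    is_rare = FALSE,
    keep = stats::runif(n_nodes) < 0.15)
  n_edges <- sample(n_nodes:(3L * n_nodes), 1)
  edges <- tibble::tibble(child_id = sample(ids, n_edges, replace = TRUE),
                          parent_id = sample(ids, n_edges, replace = TRUE))
  list(nodes = nodes, edges = edges)
}
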
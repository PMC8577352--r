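#' Configuration for the synthetic corpus generator
#'
#' The generator emulates a curated corpus of per-source marker-gene
#' statistics at the statistics layer (not the read-count layer): every
#' gene-cell type-source observation is given a latent preliminary score in
#' `[0, 1]` expressing how significant that source found the relationship,
#' which is then written out on each endpoint's raw scale through the
#' inverse of the cutoff-anchored normalization.
#'
#' @param n_genes Number of genes.
#' @param n_sources Number of sources; species alternate mouse/human so
#'   both species are always represented.
#' @param ontology_depth Levels below the root of the balanced cell-type
#'   tree (depth 1 holds the higher-level groups).
#' @param children_per_node Branching factor of the tree (>= 2 so sibling
#'   subtypes exist for planted higher-level markers).
#' @param planted_marker_fraction Fraction of genes planted as single-cell
#'   type markers (a small share of these is routed through a rare cell
#'   type observed by few sources, exercising the rare-type rescue).
#' @param planted_higher_level_fraction Fraction planted significant in two
#'   sibling subtypes of one higher-level group.
#' @param planted_species_specific_fraction Fraction planted significant in
#'   one species only.
#' @param noise_sd Gaussian perturbation (score scale) of the latent
#'   significance before inverse-mapping to raw values; 0 is noiseless.
#' @param missing_rate Probability that any single endpoint value is absent
#'   from the written table.
#' @param seed Integer seed; all outputs are reproducible given it.
#' @return A list of class `simulation_config`.
#' @export
simulation_config <- function(n_genes = 500L, n_sources = 6L,
                              ontology_depth = 3L, children_per_node = 3L,
                              planted_marker_fraction = 0.25,
                              planted_higher_level_fraction = 0.10,
                              planted_species_specific_fraction = 0.10,
                              noise_sd = 0.1, missing_rate = 0.05,
                              seed = 1L) {
  fr <- c(planted_marker_fraction, planted_higher_level_fraction,
          planted_species_specific_fraction)
  stopifnot(n_genes >= 1, n_sources >= 2, ontology_depth >= 2,
            children_per_node >= 2, all(fr >= 0), all(fr <= 1), sum(fr) <= 1,
            noise_sd >= 0, missing_rate >= 0, missing_rate < 1)
  structure(list(n_genes = as.integer(n_genes),
                 n_sources = as.integer(n_sources),
                 ontology_depth = as.integer(ontology_depth),
                 children_per_node = as.integer(children_per_node),
                 planted_marker_fraction = planted_marker_fraction,
                 planted_higher_level_fraction = planted_higher_level_fraction,
                 planted_species_specific_fraction =
                   planted_species_specific_fraction,
                 noise_sd = noise_sd, missing_rate = missing_rate,
                 seed = as.integer(seed)),
            class = "simulation_config")
}

# fixed endpoint catalog with heterogeneous ranges/cutoffs/directions
endpoint_catalog <- function() {
  list(
    adj_p = endpoint_definition("adj_p", "lower_more_significant", 0, 1, 0.05),
    log_fc_enrichment = endpoint_definition("log_fc_enrichment",
                                            "lower_more_significant",
                                            -9, 0, -2),
    auroc = endpoint_definition("auroc", "higher_more_significant", 0, 1, 0.7),
    z_score = endpoint_definition("z_score", "higher_more_significant",
                                  0, 10, 2),
    effect_size = endpoint_definition("effect_size", "higher_more_significant",
                                      0, 5, 1))
}

build_balanced_ontology <- function(depth, children) {
  nodes <- tibble::tibble(node_id = "CT:root", name = "cell",
                          is_higher_level = FALSE, is_rare = FALSE,
                          keep = TRUE)
  edges <- tibble::tibble(child_id = character(0), parent_id = character(0))
  level <- "CT:root"
  for (d in seq_len(depth)) {
    nxt <- character(0)
    for (p in level) {
      kid_ids <- paste0(p, ".", seq_len(children))
      nodes <- rbind(nodes, tibble::tibble(
        node_id = kid_ids, name = paste0("cell type ", sub("^CT:root\\.", "", kid_ids)),
        is_higher_level = d == 1L, is_rare = FALSE, keep = d == 1L))
      edges <- rbind(edges,
                     tibble::tibble(child_id = kid_ids, parent_id = p))
      nxt <- c(nxt, kid_ids)
    }
    level <- nxt
  }
  # one rare leaf so the rare-type source threshold is exercised
  rare_leaf <- level[length(level)]
  nodes$is_rare[nodes$node_id == rare_leaf] <- TRUE
  nodes$name[nodes$node_id == rare_leaf] <- "rare cell type (synthetic)"
  list(nodes = nodes, edges = edges, leaves = level, rare_leaf = rare_leaf)
}

#' Generate a complete synthetic study corpus with planted ground truth
#'
#' Produces, from one seed, every input the pipeline consumes — source
#' metadata with 1-3 endpoints each (heterogeneous ranges, cutoffs and
#' directions), a gene cross-reference, ontology node/edge tables, and a
#' long-format statistics table — together with the ground-truth label each
#' gene was planted with.
#'
#' Planted classes: single-cell-type markers (latent scores well past the
#' cutoff in the target cell type, non-significant elsewhere); higher-level
#' markers (significant in two sibling subtypes of one group); species-
#' specific markers (significant in one species' sources only, with medians
#' separated more than threefold); non-markers (non-significant everywhere);
#' and sparsely observed genes intended to be gated as indeterminate
#' (three cell types, three sources each). Gated genes are observed in four
#' cell types by every source so the sparse-data gate passes by cell-type
#' count; rare-pathway markers are observed only in the rare cell type by
#' exactly two sources (one per species).
#'
#' @param config A [simulation_config()].
#' @return A list with `sources` (named list of [source_metadata()]),
#'   `genes` (cross-reference tibble), `ontology` (list of `nodes`,
#'   `edges`), `tree` (pruned `cell_ontology`), `stats` (statistics
#'   tibble), `truth` (tibble `gene_id`, `label`, `cell_types`,
#'   `species_call`) and `config`.
#' @export
simulate_corpus <- function(config = simulation_config()) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(config$seed)
  catalog <- endpoint_catalog()

  onto <- build_balanced_ontology(config$ontology_depth,
                                  config$children_per_node)
  pruned <- prune_to_tree(onto$nodes, onto$edges)
  tree <- pruned$tree
  leaves <- onto$leaves
  common_leaves <- setdiff(leaves, onto$rare_leaf)
  if (length(common_leaves) < 5L) {
    stop("ontology too small for planting: need at least 5 common leaf ",
         "cell types (increase ontology_depth or children_per_node)",
         call. = FALSE)
  }
  groups <- tree$nodes$node_id[tree$nodes$is_higher_level]
  # groups with >= 2 plantable leaves (the rare leaf is reserved)
  hl_groups <- groups[vapply(groups, function(g)
    sum(startsWith(common_leaves, paste0(g, "."))) >= 2L, logical(1))]

  species_of_source <- rep(c("mouse", "human"),
                           length.out = config$n_sources)
  sources <- lapply(seq_len(config$n_sources), function(i) {
    n_ep <- sample(1:3, 1)
    eps <- catalog[sample(names(catalog), n_ep)]
    source_metadata(sprintf("S%02d", i), species_of_source[i],
                    sample_type = sample(c("blood", "brain", "pancreas",
                                           "kidney", "lung"), 1),
                    expression_method = sample(c("scRNA-seq",
                                                 "FACS+RNA-seq"), 1),
                    statistical_method = sample(c("wilcoxon", "MAST",
                                                  "t-test"), 1),
                    endpoints = unname(eps))
  })
  sources <- as_source_collection(sources)
  src_ids <- names(sources)
  mouse_srcs <- src_ids[species_of_source == "mouse"]
  human_srcs <- src_ids[species_of_source == "human"]

  n <- config$n_genes
  n_marker <- round(n * config$planted_marker_fraction)
  n_higher <- round(n * config$planted_higher_level_fraction)
  n_species <- round(n * config$planted_species_specific_fraction)
  n_rest <- n - n_marker - n_higher - n_species
  n_indet <- round(n_rest * 0.2)
  n_non <- n_rest - n_indet
  n_rare <- min(3L, n_marker)  # markers routed through the rare cell type

  gene_ids <- sprintf("G%05d", seq_len(n))
  classes <- c(rep("marker", n_marker), rep("higher_level_marker", n_higher),
               rep("species_marker", n_species), rep("non_marker", n_non),
               rep("indeterminate", n_indet))
  genes <- tibble::tibble(
    gene_id = gene_ids,
    mouse_symbol = paste0("Gene", seq_len(n)),
    human_symbol = toupper(paste0("GENE", seq_len(n))),
    entrez_ids = lapply(seq_len(n), function(i) as.character(c(i, 100000 + i))),
    ensembl_ids = lapply(seq_len(n), function(i)
      c(sprintf("ENSMUSG%011d", i), sprintf("ENSG%011d", i))))

  sig_draw <- function(k) stats::runif(k, 0.75, 0.95)
  non_draw <- function(k) stats::runif(k, 0.05, 0.30)

  plan <- vector("list", n)
  truth <- vector("list", n)
  for (g in seq_len(n)) {
    cls <- classes[g]
    if (cls == "marker" && g <= n_rare) {
      # rare pathway: one rare cell type, two sources (one per species)
      obs_src <- c(sample(mouse_srcs, 1), sample(human_srcs, 1))
      cts <- onto$rare_leaf
      latent <- matrix(sig_draw(2), nrow = 1,
                       dimnames = list(cts, obs_src))
      truth_ct <- cts; truth_sp <- "both"
    } else if (cls == "marker") {
      target <- sample(common_leaves, 1)
      fill <- sample(setdiff(common_leaves, target), 3)
      cts <- c(target, fill)
      obs_src <- src_ids
      latent <- rbind(sig_draw(length(obs_src)),
                      matrix(non_draw(3 * length(obs_src)), nrow = 3))
      dimnames(latent) <- list(cts, obs_src)
      truth_ct <- target; truth_sp <- "both"
    } else if (cls == "higher_level_marker") {
      grp <- sample(hl_groups, 1)
      grp_leaves <- setdiff(leaves[startsWith(leaves, paste0(grp, "."))],
                            onto$rare_leaf)
      targets <- sample(grp_leaves, 2)
      fill <- sample(setdiff(common_leaves, targets), 2)
      cts <- c(targets, fill)
      obs_src <- src_ids
      latent <- rbind(sig_draw(length(obs_src)), sig_draw(length(obs_src)),
                      matrix(non_draw(2 * length(obs_src)), nrow = 2))
      dimnames(latent) <- list(cts, obs_src)
      truth_ct <- grp; truth_sp <- "both"
    } else if (cls == "species_marker") {
      target <- sample(common_leaves, 1)
      fill <- sample(setdiff(common_leaves, target), 3)
      cts <- c(target, fill)
      obs_src <- src_ids
      hi_sp <- if (length(mouse_srcs) >= length(human_srcs)) "mouse" else
        "human"
      if (length(mouse_srcs) == length(human_srcs)) {
        hi_sp <- sample(c("mouse", "human"), 1)
      }
      hi_srcs <- if (hi_sp == "mouse") mouse_srcs else human_srcs
      tgt_scores <- ifelse(obs_src %in% hi_srcs,
                           stats::runif(length(obs_src), 0.90, 1.00),
                           stats::runif(length(obs_src), 0.15, 0.25))
      latent <- rbind(tgt_scores,
                      matrix(non_draw(3 * length(obs_src)), nrow = 3))
      dimnames(latent) <- list(cts, obs_src)
      truth_ct <- target; truth_sp <- paste0(hi_sp, "_specific")
    } else if (cls == "non_marker") {
      cts <- sample(common_leaves, 4)
      obs_src <- src_ids
      latent <- matrix(non_draw(4 * length(obs_src)), nrow = 4,
                       dimnames = list(cts, obs_src))
      truth_ct <- ""; truth_sp <- ""
    } else {  # indeterminate: 3 cell types x 3 sources, below both gates
      cts <- sample(common_leaves, 3)
      obs_src <- sample(src_ids, 3)
      latent <- matrix(stats::runif(9, 0.05, 0.95), nrow = 3,
                       dimnames = list(cts, obs_src))
      truth_ct <- ""; truth_sp <- ""
    }
    plan[[g]] <- list(gene = gene_ids[g], latent = latent)
    truth[[g]] <- tibble::tibble(
      gene_id = gene_ids[g],
      label = if (cls == "species_marker") "marker" else cls,
      cell_types = truth_ct, species_call = truth_sp)
  }
  truth <- dplyr::bind_rows(truth)

  # expand plans to one row per (gene, ct, source, endpoint), add noise,
  # inverse-map to raw endpoint scales
  rows <- lapply(plan, function(p) {
    lt <- p$latent
    df <- expand.grid(cell_type_id = rownames(lt), source_id = colnames(lt),
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
    df$latent <- as.vector(lt)
    df$gene_id <- p$gene
    df
  })
  obs <- dplyr::bind_rows(rows)
  ep_rows <- lapply(src_ids, function(sid) {
    d <- obs[obs$source_id == sid, , drop = FALSE]
    eps <- sources[[sid]]$endpoints
    dplyr::bind_rows(lapply(names(eps), function(en) {
      d$endpoint_name <- en
      d
    }))
  })
  stats_df <- dplyr::bind_rows(ep_rows)
  stats_df$species <- vapply(stats_df$source_id,
                             function(s) sources[[s]]$species[1], character(1))
  if (config$noise_sd > 0) {
    stats_df$latent <- pmin(pmax(
      stats_df$latent + stats::rnorm(nrow(stats_df), 0, config$noise_sd),
      0), 1)
  }
  if (config$missing_rate > 0) {
    keep <- stats::runif(nrow(stats_df)) >= config$missing_rate
    stats_df <- stats_df[keep, , drop = FALSE]
  }
  stats_df$value <- NA_real_
  for (sid in src_ids) {
    for (en in names(sources[[sid]]$endpoints)) {
      idx <- stats_df$source_id == sid & stats_df$endpoint_name == en
      if (any(idx)) {
        stats_df$value[idx] <- denormalize_score(stats_df$latent[idx],
                                                 sources[[sid]]$endpoints[[en]])
      }
    }
  }
  stats_df <- tibble::as_tibble(stats_df[, c("gene_id", "cell_type_id",
                                             "source_id", "endpoint_name",
                                             "value", "species")])
  stats_df <- dplyr::arrange(stats_df, .data$gene_id, .data$cell_type_id,
                             .data$source_id, .data$endpoint_name)

  list(sources = sources, genes = genes, ontology = onto[c("nodes", "edges")],
       tree = tree, stats = stats_df, truth = truth, config = config)
}

#' Write a simulated corpus to a directory
#'
#' Writes exactly the file dialects the pipeline stages read:
#' `sources.json`, `genes.csv`, `ontology_nodes.csv`, `ontology_edges.csv`,
#' `stats.csv` and `truth.csv`.
#'
#' @param sim Output of [simulate_corpus()].
#' @param outdir Directory (created if needed).
#' @return Named character vector of the written paths, invisibly.
#' @export
write_corpus <- function(sim, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(sources = file.path(outdir, "sources.json"),
             genes = file.path(outdir, "genes.csv"),
             nodes = file.path(outdir, "ontology_nodes.csv"),
             edges = file.path(outdir, "ontology_edges.csv"),
             stats = file.path(outdir, "stats.csv"),
             truth = file.path(outdir, "truth.csv"))
  write_sources(sim$sources, paths[["sources"]])
  write_gene_xref(sim$genes, paths[["genes"]])
  readr::write_csv(sim$ontology$nodes, paths[["nodes"]], progress = FALSE)
  readr::write_csv(sim$ontology$edges, paths[["edges"]], progress = FALSE)
  write_stat_table(sim$stats, paths[["stats"]])
  readr::write_csv(sim$truth, paths[["truth"]], progress = FALSE)
  invisible(paths)
}

#' Compare recovered classifications with planted ground truth
#'
#' A gene counts as recovered when its label matches the planted label and,
#' for markers, the marker cell-type set and species call match too.
#'
#' @param cls Classification tibble from [classify_all()].
#' @param truth Ground-truth tibble from [simulate_corpus()].
#' @return A list with `recovery` (fraction recovered), `n_genes`, and
#'   `mismatches` (tibble of genes that differ).
#' @export
score_recovery <- function(cls, truth) {
  m <- dplyr::left_join(truth, cls, by = "gene_id")
  ok <- vapply(seq_len(nrow(m)), function(i) {
    if (is.na(m$label.y[i])) return(FALSE)
    if (m$label.x[i] != m$label.y[i]) return(FALSE)
    if (!m$label.x[i] %in% c("marker", "higher_level_marker")) return(TRUE)
    cts <- sort(split_list_field_na(m$cell_types[i]))
    identical(cts, sort(m$marker_cell_types[[i]])) &&
      all(m$species_call.y[[i]] == m$species_call.x[i])
  }, logical(1))
  list(recovery = mean(ok), n_genes = nrow(m),
       mismatches = m[!ok, c("gene_id", "label.x", "label.y")])
}
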
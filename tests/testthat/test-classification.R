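test_that("aggregation summarizes per-source values and species medians", {
  # a single source with one score
  one <- aggregate_pairs(scores_from_vectors(list(ct1 = 0.75)))
  expect_equal(one$mean_score, 0.75)
  expect_equal(one$median_score, 0.75)
  expect_equal(one$frac_significant_sources, 1.0)
  expect_equal(one$n_sources, 1L)

  # three sources {0.9, 0.5, 0.1}: mean 0.5, two of three significant
  three <- aggregate_pairs(scores_from_vectors(list(ct1 = c(0.9, 0.5, 0.1))))
  expect_equal(three$mean_score, 0.5)
  expect_equal(three$frac_significant_sources, 2 / 3)

  # species medians across sources: mouse {0.9, 0.8}, human {0.2}
  sc <- tibble::tibble(
    gene_id = "G1", cell_type_id = "ct1",
    source_id = c("S1", "S2", "S3"),
    species = c("mouse", "mouse", "human"),
    marker_gene_score = c(0.9, 0.8, 0.2), n_endpoints = 1L)
  sp <- aggregate_pairs(sc)
  expect_equal(sp$median_mouse, 0.85)
  expect_equal(sp$median_human, 0.2)

  expect_equal(nrow(aggregate_pairs(sc[0, ])), 0L)
})

test_that("a dual-species source contributes one value per pair, not two", {
  sc <- tibble::tibble(
    gene_id = "G1", cell_type_id = "ct1",
    source_id = c("S1", "S1", "S2"),
    species = c("mouse", "human", "mouse"),
    marker_gene_score = c(1.0, 0.0, 0.8), n_endpoints = 1L)
  out <- aggregate_pairs(sc)
  expect_equal(out$n_sources, 2L)
  expect_equal(out$mean_score, mean(c(0.5, 0.8)))  # S1 collapses to 0.5
})

test_that("the sparse-data gate holds and rescues as specified", {
  mk <- function(n_ct, n_src, cts = NULL) {
    cts <- cts %||% paste0("ct", seq_len(n_ct))
    tibble::tibble(gene_id = "G1", cell_type_id = cts,
                   mean_score = 0.9, median_score = 0.9,
                   frac_significant_sources = 1, n_sources = n_src,
                   median_mouse = 0.9, median_human = 0.9)
  }
  `%||%` <- function(a, b) if (is.null(a)) b else a
  # 3 cell types from 1 source each: indeterminate
  expect_false(gate_indeterminate(mk(3, 1)))
  # 2 cell types but one examined by 4 sources: proceed
  expect_true(gate_indeterminate(mk(2, c(4, 1))))
  # 1 rare cell type with 2 sources: proceed
  expect_true(gate_indeterminate(mk(1, 2, cts = "pancreatic_epsilon_cell"),
                                 rare_types = "pancreatic_epsilon_cell"))
  expect_false(gate_indeterminate(mk(1, 2)))  # same counts, common type
  # 5 cell types from 1 source each: cell-type count suffices
  expect_true(gate_indeterminate(mk(5, 1)))
})

test_that("the X/Y decision table assigns labels and propagates ancestors", {
  tree <- two_group_tree()
  # X = 0: no significant cell type
  r <- classify_gene(pairs_from_means(c(a1 = 0.2, a2 = 0.4, b1 = 0.1)), tree)
  expect_identical(r$label, "non_marker")
  expect_length(r$marker_cell_types[[1]], 0L)

  # X = 1: marker, with specificity propagated up the branch
  r <- classify_gene(pairs_from_means(c(a1 = 0.8, a2 = 0.4, b1 = 0.1)), tree)
  expect_identical(r$label, "marker")
  expect_identical(r$marker_cell_types[[1]], "a1")
  expect_setequal(r$propagated_cell_types[[1]], c("g1", "root"))

  # X = 3 in one group: marker for the group, not the subtypes
  r <- classify_gene(pairs_from_means(c(a1 = 0.8, a2 = 0.9, a3 = 0.7,
                                        b1 = 0.1)), tree)
  expect_identical(r$label, "higher_level_marker")
  expect_identical(r$marker_cell_types[[1]], "g1")
  expect_identical(r$propagated_cell_types[[1]], "root")
  expect_equal(r$X, 3L)
  expect_equal(r$Y, 1L)

  # X = 3 across two groups: non-marker for lack of specificity
  r <- classify_gene(pairs_from_means(c(a1 = 0.8, a2 = 0.9, b1 = 0.7,
                                        b2 = 0.1)), tree)
  expect_identical(r$label, "non_marker")
  expect_equal(r$Y, 2L)

  # X = 2 across two groups: dual marker under allow, non-marker under forbid
  means <- c(a1 = 0.8, b1 = 0.7, a2 = 0.1, b2 = 0.2)
  r <- classify_gene(pairs_from_means(means), tree,
                     dual_marker_policy = "allow")
  expect_identical(r$label, "marker")
  expect_setequal(r$marker_cell_types[[1]], c("a1", "b1"))
  r <- classify_gene(pairs_from_means(means), tree,
                     dual_marker_policy = "forbid")
  expect_identical(r$label, "non_marker")

  expect_error(classify_gene(pairs_from_means(c(zz = 0.9)), tree),
               "unknown cell type")
})

test_that("ties at exactly 0.5 count as significant under both rules", {
  tree <- two_group_tree()
  r <- classify_gene(pairs_from_means(c(a1 = 0.5, b1 = 0.2)), tree)
  expect_identical(r$label, "marker")
  sc <- scores_from_vectors(list(a1 = c(0.5, 0.5, 0.2), b1 = c(0.1, 0.1, 0.1)))
  r2 <- classify_gene(aggregate_pairs(sc), tree, rule = "two_thirds")
  expect_identical(r2$label, "marker")
  expect_identical(r2$marker_cell_types[[1]], "a1")
})

test_that("species specificity needs a 3-fold median gap with the larger median above 0.5", {
  expect_identical(species_specificity(c(mouse = 0.9, human = 0.2)),
                   "mouse_specific")
  expect_identical(species_specificity(c(mouse = 0.6, human = 0.6)), "both")
  expect_identical(species_specificity(c(mouse = 0.9, human = 0)),
                   "mouse_specific")
  expect_identical(species_specificity(c(human = 0.8)), "insufficient")
  # larger median must exceed 0.5, not merely reach the fold gap
  expect_identical(species_specificity(c(mouse = 0.45, human = 0.1)), "both")
  # boundary: exactly 3-fold qualifies
  expect_identical(species_specificity(c(mouse = 0.2, human = 0.6)),
                   "human_specific")
  expect_error(species_specificity(c(mouse = -0.1, human = 0.5)),
               "non-negative")
})

test_that("swapping species labels swaps the specific calls and fixes the rest", {
  set.seed(11)
  for (i in 1:100) {
    med <- c(mouse = stats::runif(1), human = stats::runif(1))
    a <- species_specificity(med)
    b <- species_specificity(c(mouse = med[["human"]],
                               human = med[["mouse"]]))
    expected <- c(mouse_specific = "human_specific",
                  human_specific = "mouse_specific",
                  both = "both", insufficient = "insufficient")[[a]]
    expect_identical(b, expected)
  }
})

test_that("classify_gene agrees with the brute-force decision table on random instances", {
  tree <- two_group_tree()
  set.seed(21)
  grid <- c(0, 0.25, 0.5, 0.75, 1)
  for (i in 1:300) {
    n_ct <- sample(1:6, 1)
    cts <- sample(names(two_group_map)[1:6], n_ct)
    by_ct <- lapply(stats::setNames(cts, cts),
                    function(ct) sample(grid, sample(1:5, 1), replace = TRUE))
    pairs <- aggregate_pairs(scores_from_vectors(by_ct))
    for (rule in c("mean", "two_thirds")) {
      for (policy in c("allow", "forbid")) {
        got <- classify_gene(pairs, tree, rule = rule,
                             dual_marker_policy = policy)
        want <- oracle_classify(by_ct, two_group_map, rule, policy)
        expect_identical(got$label, want$label)
        expect_setequal(got$marker_cell_types[[1]], want$cts)
      }
    }
  }
})

test_that("raising a marker cell type's scores never demotes the gene to non-marker", {
  tree <- two_group_tree()
  set.seed(22)
  for (i in 1:50) {
    # one significant cell type, all others firmly below threshold
    target <- sample(c("a1", "a2", "a3", "b1", "b2", "b3"), 1)
    others <- sample(setdiff(c("a1", "a2", "a3", "b1", "b2", "b3"), target),
                     3)
    by_ct <- c(stats::setNames(list(stats::runif(4, 0.5, 0.9)), target),
               lapply(stats::setNames(others, others),
                      function(x) stats::runif(4, 0, 0.4)))
    before <- classify_gene(aggregate_pairs(scores_from_vectors(by_ct)), tree)
    expect_identical(before$label, "marker")
    by_ct[[target]] <- pmin(1, by_ct[[target]] + stats::runif(4, 0, 0.5))
    after <- classify_gene(aggregate_pairs(scores_from_vectors(by_ct)), tree)
    expect_identical(after$label, "marker")
    expect_identical(after$marker_cell_types[[1]], target)
  }
})

test_that("propagated cell types are strict ancestors and disjoint from marker types", {
  tree <- two_group_tree()
  set.seed(23)
  for (i in 1:60) {
    cts <- sample(names(two_group_map)[1:6], sample(2:6, 1))
    means <- stats::setNames(sample(c(0, 0.25, 0.5, 0.75, 1), length(cts),
                                    replace = TRUE), cts)
    r <- classify_gene(pairs_from_means(means), tree)
    mk <- r$marker_cell_types[[1]]
    pg <- r$propagated_cell_types[[1]]
    expect_length(intersect(mk, pg), 0L)
    for (p in pg) {
      expect_true(any(vapply(mk, function(m)
        p %in% ancestors(tree, m)[-1], logical(1))))
    }
  }
})

test_that("classify_all gates, classifies, and tallies a whole collection", {
  tree <- two_group_tree()
  sc <- dplyr::bind_rows(
    # marker gene: significant in a1 only, 4 cell types observed
    scores_from_vectors(list(a1 = c(0.9, 0.8, 0.9, 0.7),
                             a2 = c(0.1, 0.2, 0.1, 0.3),
                             b1 = c(0.2, 0.1, 0.2, 0.1),
                             b2 = c(0.1, 0.1, 0.2, 0.2)), gene = "G_mark"),
    # sparse gene: 2 cell types, 2 sources each -> indeterminate
    scores_from_vectors(list(a1 = c(0.9, 0.9), b1 = c(0.8, 0.9)),
                        gene = "G_sparse"))
  out <- classify_all(sc, tree)
  cls <- out$classifications
  expect_identical(cls$label[cls$gene_id == "G_mark"], "marker")
  expect_identical(cls$label[cls$gene_id == "G_sparse"], "indeterminate")
  expect_equal(out$summary$n_genes, 2L)
  expect_equal(out$summary$label_counts$marker, 1L)
  expect_equal(out$summary$label_counts$indeterminate, 1L)
  expect_equal(out$summary$n_marker_pairs, 1L)
  expect_equal(out$summary$markers_per_cell_type$a1, 1L)
  # label counts partition the genes
  expect_equal(sum(unlist(out$summary$label_counts)), out$summary$n_genes)

  empty <- classify_all(sc[0, ], tree)
  expect_equal(nrow(empty$classifications), 0L)
  expect_equal(empty$summary$n_genes, 0L)
})

test_that("classification tables round-trip through the markers CSV", {
  tree <- two_group_tree()
  sc <- scores_from_vectors(list(a1 = c(0.9, 0.8, 0.9, 0.7),
                                 a2 = c(0.8, 0.9, 0.8, 0.9),
                                 b1 = c(0.2, 0.1, 0.2, 0.1),
                                 b2 = c(0.1, 0.1, 0.2, 0.2)))
  cls <- classify_all(sc, tree)$classifications
  path <- withr::local_tempfile(fileext = ".csv")
  write_classifications(cls, path)
  back <- read_classifications(path)
  expect_identical(back$label, cls$label)
  expect_identical(back$marker_cell_types, unname(cls$marker_cell_types))
  expect_identical(back$propagated_cell_types,
                   unname(cls$propagated_cell_types))
})
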
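test_that("single-child intermediates collapse, with the removal reported", {
  nodes <- tibble::tibble(node_id = c("A", "B", "C"), name = c("A", "B", "C"))
  edges <- tibble::tibble(child_id = c("B", "C"), parent_id = c("A", "B"))
  out <- prune_to_tree(nodes, edges)
  expect_setequal(out$tree$nodes$node_id, c("A", "C"))
  expect_identical(unname(out$tree$parent[["C"]]), "A")
  expect_identical(out$report$collapsed_nodes, "B")
  # a kept node in the same position is retained
  nodes$keep <- c(FALSE, TRUE, FALSE)
  out2 <- prune_to_tree(nodes, edges)
  expect_setequal(out2$tree$nodes$node_id, c("A", "B", "C"))
})

test_that("multi-parent nodes keep the priority-listed parent, else the smallest", {
  # microglial-cell-like node reachable from both glial cell and macrophage
  nodes <- tibble::tibble(
    node_id = c("root", "glial_cell", "macrophage", "microglial_cell",
                "x1", "x2"),
    name = c("root", "glial cell", "macrophage", "microglial cell",
             "x1", "x2"))
  edges <- tibble::tibble(
    child_id = c("glial_cell", "macrophage", "microglial_cell",
                 "microglial_cell", "x1", "x2"),
    parent_id = c("root", "root", "glial_cell", "macrophage",
                  "glial_cell", "macrophage"))
  pr <- tibble::tibble(child_id = "microglial_cell", parent_id = "glial_cell")
  out <- prune_to_tree(nodes, edges, parent_priority = pr)
  expect_identical(unname(out$tree$parent[["microglial_cell"]]), "glial_cell")
  expect_equal(out$report$multi_parent_edges_removed$parent_id, "macrophage")
  # without a priority table the lexicographically smallest parent wins
  out2 <- prune_to_tree(nodes, edges)
  expect_identical(unname(out2$tree$parent[["microglial_cell"]]),
                   "glial_cell")
})

test_that("an input that is already a pruned tree passes through unchanged", {
  tree <- two_group_tree()
  nodes <- tree$nodes
  edges <- tibble::tibble(
    child_id = names(tree$parent)[!is.na(tree$parent)],
    parent_id = tree$parent[!is.na(tree$parent)])
  out <- prune_to_tree(nodes, edges)
  expect_equal(out$tree$parent[sort(names(out$tree$parent))],
               tree$parent[sort(names(tree$parent))])
  expect_length(out$report$collapsed_nodes, 0L)
  expect_equal(nrow(out$report$multi_parent_edges_removed), 0L)
})

test_that("cycles are broken deterministically at the smallest member", {
  nodes <- tibble::tibble(node_id = c("A", "B", "C", "D"),
                          name = c("A", "B", "C", "D"))
  # parent loop A <- B <- C <- A; D is an isolated root
  edges <- tibble::tibble(child_id = c("A", "B", "C"),
                          parent_id = c("C", "A", "B"))
  out <- prune_to_tree(nodes, edges)
  expect_identical(out$report$cycle_edges_removed$child_id, "A")
  expect_true(is.na(out$tree$parent[["A"]]))
})

test_that("edges naming undeclared nodes are a hard error", {
  nodes <- tibble::tibble(node_id = "A", name = "A")
  edges <- tibble::tibble(child_id = "B", parent_id = "A")
  expect_error(prune_to_tree(nodes, edges), "undeclared node.*B")
})

test_that("pruning satisfies tree invariants, is idempotent, and conserves nodes", {
  set.seed(7)
  for (i in 1:40) {
    raw <- random_raw_ontology(sample(5:20, 1))
    out <- prune_to_tree(raw$nodes, raw$edges)
    tree <- out$tree
    parent <- tree$parent

    # forest: every node reaches a root by walking parent pointers,
    # in at most |nodes| steps (i.e. acyclically)
    for (id in names(parent)) {
      seen <- character(0)
      node <- id
      while (!is.na(node) && length(seen) <= length(parent)) {
        seen <- c(seen, node)
        node <- parent[[node]]
      }
      expect_true(is.na(node))                        # acyclic
      expect_length(unique(seen), length(seen))
      expect_true(seen[length(seen)] %in% tree$roots)
    }
    # no non-root, non-leaf, non-kept node with exactly one child
    kids <- table(parent[!is.na(parent)])
    single <- names(kids)[kids == 1L]
    kept <- tree$nodes$node_id[tree$nodes$keep]
    offenders <- setdiff(single[!is.na(parent[single])], kept)
    expect_length(offenders, 0L)

    # node conservation: input nodes = output nodes + collapsed nodes
    expect_setequal(raw$nodes$node_id,
                    c(tree$nodes$node_id, out$report$collapsed_nodes))

    # idempotence on its own output
    edges2 <- tibble::tibble(
      child_id = names(parent)[!is.na(parent)],
      parent_id = unname(parent[!is.na(parent)]))
    again <- prune_to_tree(tree$nodes, edges2)
    expect_equal(again$tree$parent[sort(names(again$tree$parent))],
                 parent[sort(names(parent))])
    expect_length(again$report$collapsed_nodes, 0L)
    expect_equal(nrow(again$report$cycle_edges_removed), 0L)
    expect_equal(nrow(again$report$multi_parent_edges_removed), 0L)
  }
})

test_that("ancestors runs from the node to its root", {
  tree <- two_group_tree()
  expect_identical(ancestors(tree, "root"), "root")
  expect_identical(ancestors(tree, "a2"), c("a2", "g1", "root"))
  for (id in tree$nodes$node_id) {
    path <- ancestors(tree, id)
    expect_identical(path[1], id)
    expect_true(path[length(path)] %in% tree$roots)
  }
  expect_error(ancestors(tree, "nope"), "unknown cell type")
})

test_that("higher_level_group returns the nearest flagged ancestor, itself, or the root", {
  tree <- two_group_tree()
  expect_identical(higher_level_group(tree, "a1"), "g1")   # flagged ancestor
  expect_identical(higher_level_group(tree, "g2"), "g2")   # itself flagged
  expect_identical(higher_level_group(tree, "root"), "root") # fallback root
  for (id in tree$nodes$node_id) {
    expect_true(higher_level_group(tree, id) %in% ancestors(tree, id))
  }
})

test_that("tree tables and OBO subsets round-trip through their readers", {
  tree <- two_group_tree()
  path <- withr::local_tempfile(fileext = ".csv")
  write_tree(tree, path)
  back <- read_tree(path)
  expect_equal(back$parent[sort(names(back$parent))],
               tree$parent[sort(names(tree$parent))])
  expect_equal(back$nodes$is_higher_level[match(tree$nodes$node_id,
                                                back$nodes$node_id)],
               tree$nodes$is_higher_level)

  obo <- withr::local_tempfile(fileext = ".obo")
  writeLines(c(
    "format-version: 1.2", "",
    "[Term]", "id: CL:0000000", "name: cell", "",
    "[Term]", "id: CL:0000084", "name: T cell",
    "is_a: CL:0000000 ! cell", "",
    "[Term]", "id: CL:0000625", "name: CD8 T cell",
    "is_a: CL:0000084 ! T cell", "",
    "[Term]", "id: CL:9999999", "name: gone", "is_obsolete: true"), obo)
  parsed <- read_obo_subset(obo)
  expect_setequal(parsed$nodes$node_id,
                  c("CL:0000000", "CL:0000084", "CL:0000625"))
  expect_equal(parsed$edges$parent_id[parsed$edges$child_id == "CL:0000625"],
               "CL:0000084")
})
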
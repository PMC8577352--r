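#' Cell ontology utilities
#'
#' The classification algorithm needs the cell-type hierarchy as a forest
#' (every node has at most one parent) rooted at the most general cell
#' terms, with designated "higher-level" grouping nodes (e.g. connective
#' tissue cell, T cell) to which subtype-level marker specificity can be
#' re-assigned. Community cell ontologies are DAGs with multi-parent terms
#' and occasionally cyclic curation artifacts, so [prune_to_tree()] reduces
#' a raw edge list to such a forest deterministically.
#'
#' @name cell_ontology
NULL

new_cell_ontology <- function(nodes, parent) {
  stopifnot(all(names(parent) %in% nodes$node_id),
            all(nodes$node_id %in% names(parent)))
  roots <- names(parent)[is.na(parent)]
  structure(list(nodes = nodes, parent = parent, roots = roots),
            class = "cell_ontology")
}

#' @export
print.cell_ontology <- function(x, ...) {
  cat(sprintf("<cell_ontology> %d nodes, %d root(s): %s\n",
              nrow(x$nodes), length(x$roots),
              paste(x$roots, collapse = ", ")))
  invisible(x)
}

is_cell_ontology <- function(x) inherits(x, "cell_ontology")

ontology_check_node <- function(tree, cell_type_id) {
  if (!cell_type_id %in% tree$nodes$node_id) {
    stop("unknown cell type: ", cell_type_id, call. = FALSE)
  }
  invisible(TRUE)
}

normalize_node_table <- function(nodes) {
  stopifnot(all(c("node_id", "name") %in% names(nodes)))
  nodes <- tibble::as_tibble(nodes)
  nodes$node_id <- as.character(nodes$node_id)
  nodes$name <- as.character(nodes$name)
  for (flag in c("is_higher_level", "is_rare", "keep")) {
    if (!flag %in% names(nodes)) nodes[[flag]] <- FALSE
    nodes[[flag]] <- as.logical(nodes[[flag]]) %in% TRUE
  }
  if (anyDuplicated(nodes$node_id)) {
    stop("duplicate node_id: ",
         paste(unique(nodes$node_id[duplicated(nodes$node_id)]),
               collapse = ", "), call. = FALSE)
  }
  nodes
}

#' Prune a raw cell-type graph to a forest
#'
#' Three deterministic passes reduce a raw parent-child edge list (possibly
#' a multi-rooted DAG with cycles) to a forest suitable for classification:
#'
#' 1. *Single-parent resolution.* For every node with more than one parent,
#'    exactly one parent edge is retained: the first parent listed for that
#'    node in `parent_priority`, else the lexicographically smallest parent
#'    ID. The priority table lets curators reproduce manual choices (e.g.
#'    keeping microglial cell under glial cell rather than macrophage).
#' 2. *Cycle breaking.* Any remaining cycle is broken by removing the parent
#'    edge of the cycle member with the lexicographically smallest ID; that
#'    node becomes a root.
#' 3. *Chain collapsing.* Intermediate nodes with exactly one child that are
#'    neither roots, leaves, nor protected by `keep` add nothing to the
#'    classification and are removed, their parent reconnected to their
#'    child; repeated to fixpoint. Branching intermediates are retained so
#'    new cell types can attach later.
#'
#' @param nodes Node table: `node_id`, `name`, and optional logical flags
#'   `is_higher_level`, `is_rare`, `keep`.
#' @param edges Edge table with columns `child_id`, `parent_id`; every ID
#'   must be declared in `nodes`.
#' @param parent_priority Optional data frame (`child_id`, `parent_id`) whose
#'   row order gives, per child, the preference order among its parents.
#' @return A list with `tree` (a `cell_ontology`) and `report`, a list of
#'   `multi_parent_edges_removed`, `cycle_edges_removed` (data frames of
#'   dropped edges) and `collapsed_nodes` (character vector).
#' @export
prune_to_tree <- function(nodes, edges, parent_priority = NULL) {
  nodes <- normalize_node_table(nodes)
  edges <- tibble::as_tibble(edges)
  stopifnot(all(c("child_id", "parent_id") %in% names(edges)))
  edges$child_id <- as.character(edges$child_id)
  edges$parent_id <- as.character(edges$parent_id)
  edges <- dplyr::distinct(edges)

  undeclared <- setdiff(unique(c(edges$child_id, edges$parent_id)),
                        nodes$node_id)
  if (length(undeclared)) {
    stop("edge references undeclared node(s): ",
         paste(undeclared, collapse = ", "), call. = FALSE)
  }
  self_loop <- edges$child_id == edges$parent_id
  cycle_removed <- edges[self_loop, , drop = FALSE]
  edges <- edges[!self_loop, , drop = FALSE]

  # pass 1: one parent per child
  multi_removed <- edges[0, , drop = FALSE]
  parent <- stats::setNames(rep(NA_character_, nrow(nodes)), nodes$node_id)
  for (child in unique(edges$child_id)) {
    cand <- sort(unique(edges$parent_id[edges$child_id == child]))
    chosen <- cand[1]
    if (!is.null(parent_priority)) {
      pr <- parent_priority$parent_id[parent_priority$child_id == child]
      pr <- pr[pr %in% cand]
      if (length(pr)) chosen <- pr[1]
    }
    parent[child] <- chosen
    if (length(cand) > 1L) {
      multi_removed <- rbind(multi_removed,
                             tibble::tibble(child_id = child,
                                            parent_id = setdiff(cand, chosen)))
    }
  }

  # pass 2: each node now has <= 1 parent, so any cycle is a pure loop of
  # parent pointers; break it at the lexicographically smallest member
  repeat {
    cyc <- find_parent_cycle(parent)
    if (is.null(cyc)) break
    victim <- min(cyc)
    cycle_removed <- rbind(cycle_removed,
                           tibble::tibble(child_id = victim,
                                          parent_id = parent[[victim]]))
    parent[victim] <- NA_character_
  }

  # pass 3: collapse non-branching, unprotected intermediates to fixpoint
  keep_ids <- nodes$node_id[nodes$keep]
  collapsed <- character(0)
  repeat {
    kids <- table(parent[!is.na(parent)])
    single_child <- names(kids)[kids == 1L]
    removable <- setdiff(single_child, keep_ids)
    removable <- removable[!is.na(parent[removable])]   # never roots
    if (!length(removable)) break
    victim <- sort(removable)[1]
    child <- names(parent)[!is.na(parent) & parent == victim]
    parent[child] <- parent[[victim]]
    parent <- parent[names(parent) != victim]
    collapsed <- c(collapsed, victim)
  }
  out_nodes <- nodes[!nodes$node_id %in% collapsed, , drop = FALSE]

  list(tree = new_cell_ontology(out_nodes, parent),
       report = list(multi_parent_edges_removed = multi_removed,
                     cycle_edges_removed = cycle_removed,
                     collapsed_nodes = collapsed))
}

find_parent_cycle <- function(parent) {
  color <- stats::setNames(integer(length(parent)), names(parent)) # 0 white
  for (start in names(parent)) {
    if (color[[start]] != 0L) next
    path <- character(0)
    node <- start
    while (!is.na(node)) {
      if (color[[node]] == 1L) return(path[which(path == node):length(path)])
      if (color[[node]] == 2L) break
      color[node] <- 1L
      path <- c(path, node)
      node <- parent[[node]]
    }
    color[path] <- 2L
  }
  NULL
}

#' Path from a cell type to its root
#'
#' @param tree A `cell_ontology` from [prune_to_tree()].
#' @param cell_type_id Node key; must exist in the tree.
#' @return Character vector of node IDs from the node itself (first element)
#'   up to its root (last element); length >= 1.
#' @export
ancestors <- function(tree, cell_type_id) {
  stopifnot(is_cell_ontology(tree))
  ontology_check_node(tree, cell_type_id)
  path <- character(0)
  node <- cell_type_id
  while (!is.na(node)) {
    path <- c(path, node)
    node <- tree$parent[[node]]
  }
  path
}

#' Nearest higher-level grouping of a cell type
#'
#' Walks from the node toward the root and returns the first node (possibly
#' the node itself) flagged `is_higher_level`; when no ancestor on the
#' branch carries the flag, the branch root is returned as the fallback
#' grouping.
#'
#' @inheritParams ancestors
#' @return A single node ID.
#' @export
higher_level_group <- function(tree, cell_type_id) {
  path <- ancestors(tree, cell_type_id)
  flagged <- tree$nodes$node_id[tree$nodes$is_higher_level]
  hit <- path[path %in% flagged]
  if (length(hit)) hit[1] else path[length(path)]
}

#' Rare cell types of a tree
#'
#' @param tree A `cell_ontology`.
#' @return Character vector of node IDs flagged `is_rare`.
#' @export
rare_cell_types <- function(tree) {
  tree$nodes$node_id[tree$nodes$is_rare]
}

#' Read/write ontology node and edge tables
#'
#' @param nodes_path CSV with columns `node_id`, `name`, and optional
#'   `is_higher_level`, `is_rare`, `keep`.
#' @param edges_path CSV with columns `child_id`, `parent_id`.
#' @return For `read_ontology_tables()`, a list with `nodes` and `edges`
#'   tibbles suitable for [prune_to_tree()].
#' @export
read_ontology_tables <- function(nodes_path, edges_path) {
  nodes <- read_strict_csv(nodes_path, c("node_id", "name"))
  edges <- read_strict_csv(edges_path, c("child_id", "parent_id"))
  list(nodes = normalize_node_table(nodes),
       edges = tibble::as_tibble(lapply(edges[, c("child_id", "parent_id")],
                                        as.character)))
}

#' @rdname read_ontology_tables
#' @param tree A `cell_ontology`.
#' @param path Output CSV path; the forest is written as one row per node
#'   with its retained parent (`NA` for roots) and the node flags.
#' @export
write_tree <- function(tree, path) {
  stopifnot(is_cell_ontology(tree))
  out <- tree$nodes
  out$parent_id <- unname(tree$parent[out$node_id])
  readr::write_csv(out, path, progress = FALSE)
  invisible(path)
}

#' @rdname read_ontology_tables
#' @export
read_tree <- function(path) {
  df <- read_strict_csv(path, c("node_id", "name", "parent_id"))
  nodes <- normalize_node_table(df[, setdiff(names(df), "parent_id")])
  parent <- stats::setNames(as.character(df$parent_id), df$node_id)
  new_cell_ontology(nodes, parent)
}

#' Read an OBO-subset file as ontology tables
#'
#' Minimal reader for the `[Term]` stanzas of an OBO file, using `id`,
#' `name` and `is_a` lines only (the is_a closure is what the hierarchy is
#' built from); obsolete terms are skipped. Output feeds [prune_to_tree()].
#'
#' @param path Path to an OBO file.
#' @return A list with `nodes` and `edges` tibbles.
#' @export
read_obo_subset <- function(path) {
  if (!file.exists(path)) stop("OBO file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  term_starts <- which(lines == "[Term]")
  if (!length(term_starts)) stop("no [Term] stanzas in ", path, call. = FALSE)
  bounds <- c(term_starts, length(lines) + 1L)
  nodes <- list(); edges <- list()
  for (i in seq_along(term_starts)) {
    block <- lines[(bounds[i] + 1L):(bounds[i + 1L] - 1L)]
    block <- block[!grepl("^\\[", block)]
    get1 <- function(key) {
      v <- sub(paste0("^", key, ": *"), "", block[startsWith(block, paste0(key, ":"))])
      if (length(v)) v else character(0)
    }
    if (any(grepl("^is_obsolete: *true", block))) next
    id <- get1("id")[1]
    if (is.na(id) || !length(get1("id"))) next
    nm <- get1("name")
    isa <- sub(" *!.*$", "", get1("is_a"))
    nodes[[length(nodes) + 1L]] <-
      tibble::tibble(node_id = id, name = if (length(nm)) nm[1] else id)
    if (length(isa)) {
      edges[[length(edges) + 1L]] <-
        tibble::tibble(child_id = id, parent_id = trimws(isa))
    }
  }
  list(nodes = normalize_node_table(dplyr::bind_rows(nodes)),
       edges = if (length(edges)) dplyr::bind_rows(edges) else
         tibble::tibble(child_id = character(0), parent_id = character(0)))
}
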
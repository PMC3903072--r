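#' Summarize per-sample driver orders as a prefix tree
#'
#' Builds a trie over the per-sample driver orderings: each node is a
#' driver, each root-to-node path a shared order prefix, and each node
#' carries the number of samples whose order starts with that prefix.
#' Subtrees whose depth-2 prefix is shared by fewer than `min_support`
#' samples are pruned, so the tree shows only orders whose first two
#' alterations recur.
#'
#' @param posteriors A `mutclock_posterior`.
#' @param min_support Minimum number of samples sharing a depth-2 prefix
#'   (default 2).
#' @return An object of class `mutclock_tree`: a tibble of nodes (`id`,
#'   `parent`, `driver`, `depth`, `count`, `n_end`) plus print/format
#'   methods; [tree_newick()] renders a Newick-like string with counts in
#'   the node labels.
#' @export
build_order_tree <- function(posteriors, min_support = 2) {
  orders <- posteriors$order
  orders <- orders[lengths(orders) > 0]

  nodes <- tibble::tibble(id = integer(), parent = integer(),
                          driver = character(), depth = integer(),
                          count = integer(), n_end = integer())
  key <- character()  # full prefix key per node
  for (ord in orders) {
    parent <- 0L
    prefix <- ""
    for (d in seq_along(ord)) {
      prefix <- paste(prefix, ord[d], sep = "/")
      hit <- which(key == prefix)
      if (length(hit)) {
        nodes$count[hit] <- nodes$count[hit] + 1L
        node <- hit
      } else {
        node <- nrow(nodes) + 1L
        nodes <- dplyr::bind_rows(nodes, tibble::tibble(
          id = node, parent = parent, driver = ord[d],
          depth = d, count = 1L, n_end = 0L
        ))
        key <- c(key, prefix)
      }
      if (d == length(ord)) nodes$n_end[node] <- nodes$n_end[node] + 1L
      parent <- node
    }
  }

  # prune subtrees whose depth-2 prefix has support < min_support
  if (nrow(nodes)) {
    weak2 <- nodes$id[nodes$depth == 2 & nodes$count < min_support]
    drop <- weak2
    repeat {
      more <- nodes$id[nodes$parent %in% drop & !(nodes$id %in% drop)]
      if (!length(more)) break
      drop <- c(drop, more)
    }
    nodes <- nodes[!(nodes$id %in% drop), , drop = FALSE]
  }
  structure(list(nodes = nodes, min_support = min_support),
            class = "mutclock_tree")
}

#' @export
format.mutclock_tree <- function(x, ...) {
  nodes <- x$nodes
  if (!nrow(nodes)) return("<empty order tree>")
  lines <- character()
  recurse <- function(id, indent) {
    row <- nodes[nodes$id == id, ]
    lines <<- c(lines, paste0(strrep("  ", indent), row$driver,
                              " (", row$count, ")"))
    for (ch in nodes$id[nodes$parent == id]) recurse(ch, indent + 1)
  }
  for (root in nodes$id[nodes$parent == 0]) recurse(root, 0)
  paste(lines, collapse = "\n")
}

#' @export
print.mutclock_tree <- function(x, ...) {
  cat(format(x), "\n")
  invisible(x)
}

#' @rdname build_order_tree
#' @param tree A `mutclock_tree`.
#' @export
tree_newick <- function(tree) {
  nodes <- tree$nodes
  if (!nrow(nodes)) return(";")
  lab <- function(id) {
    row <- nodes[nodes$id == id, ]
    kids <- nodes$id[nodes$parent == id]
    core <- paste0(row$driver, "_", row$count)
    if (!length(kids)) return(core)
    paste0("(", paste(vapply(kids, lab, character(1)), collapse = ","),
           ")", core)
  }
  roots <- nodes$id[nodes$parent == 0]
  paste0("(", paste(vapply(roots, lab, character(1)), collapse = ","),
         ")root;")
}
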
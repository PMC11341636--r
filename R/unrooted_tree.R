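#' Unrooted binary phylogenetic trees
#'
#' A connected undirected acyclic graph whose leaves are labelled by X
#' and whose inner vertices all have degree three. The degenerate tree on
#' two taxa (a single edge) is allowed.
#'
#' @param edges two-column character matrix of undirected edges.
#' @param labels named character vector, leaf vertex -> taxon.
#' @return An object of class `phyutree`.
#' @export
phyutree <- function(edges, labels) {
  edges <- as_edge_matrix(edges)
  vertices <- canon_sort(unique(c(edges)))
  if (any(edges[, 1L] == edges[, 2L])) np_validation_error("loops are not allowed")
  ek <- apply(edges, 1L, function(e) paste(canon_sort(e), collapse = "\r"))
  if (anyDuplicated(ek)) np_validation_error("parallel edges are not allowed")
  deg <- tabulate_degree(c(edges), vertices)
  if (nrow(edges) != length(vertices) - 1L)
    np_validation_error("an unrooted tree must have one edge fewer than vertices")
  leaves <- vertices[deg == 1L]
  if (!all(deg %in% c(1L, 3L)))
    np_validation_error("inner vertices of an unrooted tree must have degree three")
  labels <- validate_leaf_labels(labels, leaves)
  ut <- structure(list(edges = edges, vertices = vertices, labels = labels),
                  class = "phyutree")
  if (length(components_undirected(edges, vertices)) != 1L)
    np_validation_error("unrooted tree must be connected")
  ut
}

#' @export
print.phyutree <- function(x, ...) {
  cat(sprintf("phyutree: %d taxa (%s)\n", length(x$labels), cnewick_unrooted(x)))
  invisible(x)
}

ut_neighbors <- function(ut, v) {
  canon_sort(c(ut$edges[ut$edges[, 1L] == v, 2L],
               ut$edges[ut$edges[, 2L] == v, 1L]))
}

## connected components of an undirected edge set; returns list of vertex sets
components_undirected <- function(edges, vertices) {
  comp <- list()
  left <- vertices
  while (length(left)) {
    seen <- left[[1L]]
    queue <- seen
    while (length(queue)) {
      v <- queue[[1L]]; queue <- queue[-1L]
      nb <- setdiff(c(edges[edges[, 1L] == v, 2L], edges[edges[, 2L] == v, 1L]), seen)
      seen <- c(seen, nb)
      queue <- c(queue, nb)
    }
    comp[[length(comp) + 1L]] <- seen
    left <- setdiff(left, seen)
  }
  comp
}

#' @rdname phyutree
#' @param x object to test.
#' @export
is_phyutree <- function(x) inherits(x, "phyutree")

#' @export
parsimony_score.phyutree <- function(x, f) unrooted_parsimony(x, f)

#' Canonical form of an unrooted tree
#'
#' Roots the tree at the leaf with the canonically smallest taxon and
#' returns the sorted-children Newick string, so two unrooted trees get
#' the same string iff they are isomorphic respecting leaf labels.
#'
#' @param ut a [phyutree].
#' @return A string.
#' @export
cnewick_unrooted <- function(ut) {
  lf <- names(ut$labels)[order(unname(ut$labels), method = "radix")][1L]
  rec <- function(v, from) {
    nb <- setdiff(ut_neighbors(ut, v), from)
    if (!length(nb)) return(unname(ut$labels[v]))
    parts <- sort(vapply(nb, rec, character(1), from = v), method = "radix")
    paste0("(", paste(parts, collapse = ","), ")")
  }
  paste0("(", unname(ut$labels[lf]), ",", rec(ut_neighbors(ut, lf)[1L], lf), ");")
}

#' Unroot a rooted phylogenetic tree
#'
#' Deletes the root and suppresses its child, yielding the unrooted tree
#' underlying a rooted one (at least three taxa required for a proper
#' unrooted tree; two taxa give the single-edge tree).
#'
#' @param tr a [phynet] with no reticulations and at least two leaves.
#' @return A [phyutree].
#' @export
unroot_tree <- function(tr) {
  if (!is_phytree(tr)) np_validation_error("unroot_tree() expects a tree")
  if (length(tr$labels) < 2L)
    np_validation_error("cannot unroot a single-leaf tree")
  edges <- tr$edges
  c1 <- np_children(tr, tr$root)
  edges <- edges[edges[, 1L] != tr$root, , drop = FALSE]
  kids <- np_children(tr, c1)
  edges <- edges[edges[, 1L] != c1, , drop = FALSE]
  edges <- rbind(edges, kids)
  phyutree(edges, tr$labels)
}
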
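#' Rooted binary phylogenetic networks
#'
#' A `phynet` object is a rooted acyclic digraph with no loops and no
#' parallel edges in which the root has out-degree one, every other
#' internal vertex is either a tree vertex (in-degree 1, out-degree 2) or a
#' reticulation (in-degree 2, out-degree 1), and the leaves are labelled
#' bijectively by a taxon set X. A network without reticulations is a
#' rooted binary phylogenetic X-tree.
#'
#' @param edges two-column character matrix (or data frame) of directed
#'   edges, one row per edge, tail in column 1 and head in column 2.
#' @param labels named character vector mapping each leaf vertex identifier
#'   to its taxon name.
#' @return A validated object of class `phynet` with components `edges`,
#'   `vertices`, `root`, `labels`, and adjacency lists `children` and
#'   `parents`.
#' @examples
#' net <- phynet(rbind(c("rho", "x")), c(x = "x"))
#' n_reticulations(net)
#' @export
phynet <- function(edges, labels) {
  edges <- as_edge_matrix(edges)
  if (nrow(edges) == 0L) np_validation_error("edge list is empty")
  if (any(edges[, 1L] == edges[, 2L]))
    np_validation_error("loops are not allowed")
  if (anyDuplicated(paste(edges[, 1L], edges[, 2L], sep = "\r")))
    np_validation_error("parallel edges are not allowed")

  vertices <- canon_sort(unique(c(edges)))
  outdeg <- tabulate_degree(edges[, 1L], vertices)
  indeg <- tabulate_degree(edges[, 2L], vertices)

  roots <- vertices[indeg == 0L]
  if (length(roots) != 1L)
    np_validation_error(sprintf("expected exactly one root, found %d", length(roots)))
  root <- roots
  if (outdeg[root] != 1L)
    np_validation_error(sprintf("root out-degree must be 1, found %d", outdeg[root]))

  leaves <- vertices[outdeg == 0L]
  inner <- setdiff(vertices, c(root, leaves))
  ok <- (indeg[inner] == 1L & outdeg[inner] == 2L) |
    (indeg[inner] == 2L & outdeg[inner] == 1L)
  if (!all(ok))
    np_validation_error(sprintf(
      "vertex '%s' has in-degree %d and out-degree %d; only tree vertices (1,2) and reticulations (2,1) are allowed",
      inner[!ok][1L], indeg[inner[!ok][1L]], outdeg[inner[!ok][1L]]))

  labels <- validate_leaf_labels(labels, leaves)
  assert_acyclic(edges, vertices)

  structure(
    list(
      edges = edges,
      vertices = vertices,
      root = root,
      labels = labels,
      children = adjacency(edges, vertices, from = TRUE),
      parents = adjacency(edges, vertices, from = FALSE)
    ),
    class = "phynet"
  )
}

as_edge_matrix <- function(edges) {
  if (is.data.frame(edges)) edges <- as.matrix(edges)
  if (is.null(dim(edges))) edges <- matrix(edges, ncol = 2L, byrow = TRUE)
  edges <- matrix(as.character(edges), ncol = 2L,
                  dimnames = list(NULL, c("from", "to")))
  edges
}

tabulate_degree <- function(ends, vertices) {
  d <- table(factor(ends, levels = vertices))
  stats::setNames(as.integer(d), vertices)
}

adjacency <- function(edges, vertices, from = TRUE) {
  key <- if (from) edges[, 1L] else edges[, 2L]
  val <- if (from) edges[, 2L] else edges[, 1L]
  adj <- split(val, factor(key, levels = vertices))
  lapply(adj, canon_sort)
}

validate_leaf_labels <- function(labels, leaves) {
  if (is.null(names(labels)) || any(names(labels) == ""))
    np_validation_error("leaf labels must be a named vector (leaf vertex -> taxon)")
  labels <- stats::setNames(as.character(labels), names(labels))
  if (any(is.na(labels)) || any(labels == ""))
    np_validation_error("taxon names must be non-empty")
  if (anyDuplicated(labels))
    np_validation_error(sprintf("duplicate taxon name '%s'", labels[duplicated(labels)][1L]))
  missing <- setdiff(leaves, names(labels))
  if (length(missing))
    np_validation_error(sprintf("leaf vertex '%s' has no taxon label", missing[1L]))
  extra <- setdiff(names(labels), leaves)
  if (length(extra))
    np_validation_error(sprintf("label given for '%s', which is not a leaf", extra[1L]))
  labels[canon_sort(names(labels))]
}

assert_acyclic <- function(edges, vertices) {
  ## Kahn peeling; anything left over lies on a directed cycle.
  indeg <- tabulate_degree(edges[, 2L], vertices)
  kids <- adjacency(edges, vertices, from = TRUE)
  queue <- vertices[indeg == 0L]
  seen <- 0L
  while (length(queue)) {
    v <- queue[[1L]]; queue <- queue[-1L]
    seen <- seen + 1L
    for (w in kids[[v]]) {
      indeg[w] <- indeg[w] - 1L
      if (indeg[w] == 0L) queue <- c(queue, w)
    }
  }
  if (seen != length(vertices)) np_validation_error("graph contains a directed cycle")
  invisible(TRUE)
}

#' @export
print.phynet <- function(x, ...) {
  cat(sprintf("phynet: %d taxa, %d vertices, %d reticulations (level %d)\n",
              length(x$labels), length(x$vertices), n_reticulations(x),
              network_level(x)))
  invisible(x)
}

#' @rdname phynet
#' @param x object to test.
#' @export
is_phynet <- function(x) inherits(x, "phynet")

#' Taxa, leaves and reticulations of a network
#'
#' @param net a [phynet] object.
#' @return `taxa()` the sorted taxon set X; `net_leaves()` the leaf vertex
#'   identifiers; `reticulations()` the reticulation vertices;
#'   `n_reticulations()` the count h(N).
#' @export
taxa <- function(net) canon_sort(unname(net$labels))

#' @rdname taxa
#' @export
net_leaves <- function(net) canon_sort(names(net$labels))

#' @rdname taxa
#' @export
reticulations <- function(net) {
  indeg <- tabulate_degree(net$edges[, 2L], net$vertices)
  net$vertices[indeg == 2L]
}

#' @rdname taxa
#' @export
n_reticulations <- function(net) length(reticulations(net))

#' @rdname taxa
#' @export
is_phytree <- function(net) is_phynet(net) && n_reticulations(net) == 0L

np_children <- function(obj, v) {
  kids <- obj$children[[v]]
  if (is.null(kids)) character(0) else kids
}

np_parents <- function(obj, v) {
  par <- obj$parents[[v]]
  if (is.null(par)) character(0) else par
}

## All vertices reachable from v by directed paths, v included.
reachable_from <- function(obj, v) {
  seen <- character(0)
  stack <- v
  while (length(stack)) {
    u <- stack[[length(stack)]]; stack <- stack[-length(stack)]
    if (u %in% seen) next
    seen <- c(seen, u)
    stack <- c(stack, np_children(obj, u))
  }
  seen
}

#' Cluster of a vertex
#'
#' The cluster cl(v) of a vertex v of a network or tree subdivision is the
#' set of taxa labelling the leaves that are reachable from v by directed
#' paths (v itself included if it is a leaf).
#'
#' @param obj a [phynet] or [physub] object.
#' @param v a vertex identifier of `obj`.
#' @return Sorted character vector of taxon names.
#' @export
descendant_cluster <- function(obj, v) {
  if (!v %in% obj$vertices)
    np_validation_error(sprintf("unknown vertex '%s'", v))
  desc <- reachable_from(obj, v)
  canon_sort(unname(obj$labels[intersect(desc, names(obj$labels))]))
}

#' Blob decomposition of a network
#'
#' A blob is a biconnected component of the underlying undirected graph
#' that contains at least one reticulation (both of whose incoming edges
#' then lie inside the component). Its source is the unique blob vertex
#' with no incoming edge from inside the blob; it has out-degree two
#' within the blob.
#'
#' @param net a [phynet] object.
#' @return A list of `phyblob` objects, each with components `vertices`,
#'   `edges`, `source` and `n_ret`, ordered by source vertex.
#' @seealso [network_level()], [maximal_blob()], [blob_children()]
#' @export
blobs <- function(net) {
  verts <- net$vertices
  ti <- match(net$edges[, 1L], verts)
  hi <- match(net$edges[, 2L], verts)
  indeg <- tabulate(hi, length(verts))
  g <- igraph::graph_from_edgelist(cbind(ti, hi), directed = FALSE)
  bc <- igraph::biconnected_components(g)
  out <- list()
  for (comp in bc$component_edges) {
    idx <- as.integer(comp)          # edge ids are input row numbers
    heads <- hi[idx]; tails <- ti[idx]
    vs <- unique(c(heads, tails))
    head_count <- tabulate(heads, length(verts))
    ## reticulations with both incoming edges inside the component
    n_ret <- sum(indeg[vs] == 2L & head_count[vs] == 2L)
    if (!n_ret) next
    src <- vs[head_count[vs] == 0L]
    if (length(src) != 1L)
      np_validation_error("blob without a unique source vertex")
    if (sum(tails == src) != 2L)
      np_validation_error("blob source does not have out-degree two inside the blob")
    out[[length(out) + 1L]] <- structure(
      list(vertices = canon_sort(verts[vs]),
           edges = cbind(verts[tails], verts[heads]),
           source = verts[src], n_ret = n_ret),
      class = "phyblob")
  }
  ord <- order(vapply(out, function(b) b$source, character(1)), method = "radix")
  out[ord]
}

## level computed straight from an edge matrix, without building a
## phynet; used in the generator's rejection loop where it runs often
level_of_edges <- function(edges) {
  verts <- unique(c(edges))
  ti <- match(edges[, 1L], verts)
  hi <- match(edges[, 2L], verts)
  indeg <- tabulate(hi, length(verts))
  if (!any(indeg == 2L)) return(0L)
  g <- igraph::graph_from_edgelist(cbind(ti, hi), directed = FALSE)
  bc <- igraph::biconnected_components(g)
  best <- 0L
  for (comp in bc$component_edges) {
    idx <- as.integer(comp)
    heads <- hi[idx]
    head_count <- tabulate(heads, length(verts))
    vs <- unique(c(heads, ti[idx]))
    best <- max(best, sum(indeg[vs] == 2L & head_count[vs] == 2L))
  }
  best
}

#' @export
print.phyblob <- function(x, ...) {
  cat(sprintf("blob: source '%s', %d vertices, %d reticulations\n",
              x$source, length(x$vertices), x$n_ret))
  invisible(x)
}

#' Level of a network
#'
#' The level is the maximum number of reticulations over the blobs of the
#' network (0 for a tree). The tight value is returned: a level-k network
#' is also level-(k+1), but the approximation guarantee k+1 should use the
#' exact maximum.
#'
#' @inheritParams blobs
#' @return Non-negative integer.
#' @export
network_level <- function(net) {
  bl <- blobs(net)
  if (!length(bl)) 0L else max(vapply(bl, function(b) b$n_ret, integer(1)))
}

blob_has_vertex <- function(B, v) v %in% B$vertices

## TRUE when edge (a,b) of the host lies inside blob B.
blob_has_edge <- function(B, a, b) {
  key <- paste(B$edges[, 1L], B$edges[, 2L], sep = "\r")
  paste(a, b, sep = "\r") %in% key || paste(b, a, sep = "\r") %in% key
}

#' Children of a blob
#'
#' C_N(B): every vertex of N that is not in B and is a child of a vertex
#' of B. Every such vertex lies on every embedding of every displayed
#' tree, so blob indicators of extensions are always well defined.
#'
#' @inheritParams blobs
#' @param B a blob of `net` as returned by [blobs()].
#' @return Sorted character vector of vertex identifiers.
#' @export
blob_children <- function(net, B) {
  check_blob_of(net, B)
  kids <- unique(unlist(lapply(B$vertices, function(v) np_children(net, v)),
                        use.names = FALSE))
  canon_sort(setdiff(kids, B$vertices))
}

check_blob_of <- function(net, B) {
  if (!inherits(B, "phyblob") || !all(B$vertices %in% net$vertices) ||
      !all(apply(B$edges, 1L, function(e)
        any(net$edges[, 1L] == e[1L] & net$edges[, 2L] == e[2L]) ||
        any(net$edges[, 1L] == e[2L] & net$edges[, 2L] == e[1L]))))
    np_validation_error("B is not a blob of this network")
  invisible(TRUE)
}

#' Maximal blob of a network
#'
#' A blob B with source s is maximal when s is not an ancestor of the
#' source of any other blob, i.e. no other blob lies below it. Ties (several
#' maximal blobs) are broken by the canonical vertex order of the sources.
#'
#' @inheritParams blobs
#' @return A `phyblob` object.
#' @export
maximal_blob <- function(net) {
  bl <- blobs(net)
  if (!length(bl)) np_validation_error("network has no blob (it is a tree)")
  sources <- vapply(bl, function(b) b$source, character(1))
  is_max <- vapply(seq_along(bl), function(i) {
    desc <- setdiff(reachable_from(net, sources[i]), sources[i])
    !any(sources[-i] %in% desc)
  }, logical(1))
  cand <- bl[is_max]
  srcs <- vapply(cand, function(b) b$source, character(1))
  cand[[order(srcs, method = "radix")[1L]]]
}
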
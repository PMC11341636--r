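#' Tree subdivisions
#'
#' A `physub` is a subdivision of a rooted binary phylogenetic tree: a
#' rooted tree whose root has out-degree one, whose other internal
#' vertices have out-degree one (subdivision vertices) or two, and whose
#' leaves are labelled bijectively. Embeddings of displayed trees in a
#' network are subdivisions whose vertex identifiers are vertices of the
#' host network.
#'
#' @param edges two-column character matrix of directed edges.
#' @param labels named character vector, leaf vertex -> taxon.
#' @return An object of class `physub`.
#' @export
physub <- function(edges, labels) {
  edges <- as_edge_matrix(edges)
  if (nrow(edges) == 0L) np_validation_error("edge list is empty")
  vertices <- canon_sort(unique(c(edges)))
  outdeg <- tabulate_degree(edges[, 1L], vertices)
  indeg <- tabulate_degree(edges[, 2L], vertices)
  roots <- vertices[indeg == 0L]
  if (length(roots) != 1L || any(indeg > 1L))
    np_validation_error("subdivision must be a rooted tree")
  if (any(outdeg > 2L))
    np_validation_error("subdivision vertices have out-degree at most two")
  if (outdeg[roots] != 1L)
    np_validation_error("subdivision root must have out-degree one")
  leaves <- vertices[outdeg == 0L]
  labels <- validate_leaf_labels(labels, leaves)
  structure(
    list(edges = edges, vertices = vertices, root = roots, labels = labels,
         children = adjacency(edges, vertices, from = TRUE),
         parents = adjacency(edges, vertices, from = FALSE)),
    class = "physub")
}

#' @export
print.physub <- function(x, ...) {
  cat(sprintf("physub: %d taxa, %d vertices\n", length(x$labels),
              length(x$vertices)))
  invisible(x)
}

#' @rdname physub
#' @param net a [phynet] with no reticulations (a phylogenetic tree).
#' @export
as_physub <- function(net) {
  if (inherits(net, "physub")) return(net)
  if (!is_phytree(net))
    np_validation_error("only a tree (network without reticulations) is its own subdivision")
  physub(net$edges, net$labels)
}

#' Root path of a subdivision
#'
#' The directed path from the root to its closest out-degree-two vertex
#' (the whole root-to-leaf path if the subdivision has a single leaf).
#'
#' @param S a [physub] object.
#' @return Character vector of vertices along the path, root first.
#' @export
root_path <- function(S) {
  path <- S$root
  v <- S$root
  repeat {
    kids <- np_children(S, v)
    if (length(kids) != 1L) break
    v <- kids
    path <- c(path, v)
    if (length(np_children(S, v)) != 1L) break
  }
  path
}

#' Suppress subdivision vertices
#'
#' Repeatedly removes vertices of in-degree one and out-degree one,
#' joining their neighbours, until the result is a binary phylogenetic
#' tree.
#'
#' @param S a [physub] object.
#' @return A [phynet] with no reticulations.
#' @export
suppress_subdivision <- function(S) {
  edges <- S$edges
  repeat {
    vertices <- unique(c(edges))
    outdeg <- tabulate_degree(edges[, 1L], vertices)
    indeg <- tabulate_degree(edges[, 2L], vertices)
    deg2 <- vertices[indeg == 1L & outdeg == 1L]
    if (!length(deg2)) break
    v <- deg2[[1L]]
    p <- edges[edges[, 2L] == v, 1L]
    c_ <- edges[edges[, 1L] == v, 2L]
    edges <- edges[edges[, 1L] != v & edges[, 2L] != v, , drop = FALSE]
    edges <- rbind(edges, c(p, c_))
  }
  phynet(edges, S$labels)
}

#' Canonical Newick string of a rooted tree
#'
#' Children are emitted in sorted order and degree-two chain vertices
#' are walked through, so two trees (or subdivisions) get equal strings
#' iff they are isomorphic as leaf-labelled rooted trees. Used for all
#' tree deduplication.
#'
#' @param tr a [phynet] without reticulations, or a [physub].
#' @return A Newick string ending in `;`.
#' @export
cnewick <- function(tr) {
  rec <- function(v) {
    kids <- np_children(tr, v)
    if (!length(kids)) return(unname(tr$labels[v]))
    parts <- vapply(kids, rec, character(1))
    if (length(parts) == 1L) return(parts)      # walk through chain vertices
    paste0("(", paste(canon_sort(parts), collapse = ","), ")")
  }
  paste0("(", rec(np_children(tr, tr$root)), ");")
}

#' Test whether a subdivision is an embedding of a tree in a network
#'
#' `S` is an embedding of `T` in `N` when `S` is a subgraph of `N`, is a
#' subdivision of `T`, and contains the root of `N`.
#'
#' @param S a [physub] whose vertex identifiers are vertices of `N`.
#' @param N a [phynet].
#' @param T_ a [phynet] with no reticulations.
#' @return Logical.
#' @export
is_embedding <- function(S, N, T_) {
  ekey <- paste(N$edges[, 1L], N$edges[, 2L], sep = "\r")
  skey <- paste(S$edges[, 1L], S$edges[, 2L], sep = "\r")
  if (!all(skey %in% ekey)) return(FALSE)
  if (!N$root %in% S$vertices || S$root != N$root) return(FALSE)
  identical(cnewick(S), cnewick(T_))
}
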
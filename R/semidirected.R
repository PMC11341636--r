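#' Semi-directed networks
#'
#' A semi-directed network is what remains of a rooted binary network
#' after deleting the root, suppressing its child and forgetting the
#' direction of every non-reticulation edge: reticulations keep their
#' two incoming directed edges, everything else is undirected. At most
#' one pair of parallel edges can occur (exactly when the rooted partner
#' has a 3-cycle through the child of the root).
#'
#' @param edges a data frame with columns `u`, `v` and logical
#'   `directed` (`u -> v` for reticulation edges).
#' @param labels named character vector, leaf vertex -> taxon.
#' @return An object of class `semidnet`.
#' @export
semidnet <- function(edges, labels) {
  edges <- data.frame(u = as.character(edges[[1L]]), v = as.character(edges[[2L]]),
                      directed = as.logical(edges[[3L]]))
  if (any(edges$u == edges$v)) np_validation_error("loops are not allowed")
  vertices <- canon_sort(unique(c(edges$u, edges$v)))
  key <- apply(edges[, 1:2], 1L, function(e) paste(canon_sort(e), collapse = "\r"))
  if (sum(duplicated(key)) > 1L)
    np_validation_error("at most one pair of parallel edges is allowed")
  deg <- tabulate_degree(c(edges$u, edges$v), vertices)
  leaves <- vertices[deg == 1L]
  if (!all(deg[setdiff(vertices, leaves)] == 3L))
    np_validation_error("inner vertices of a semi-directed network must have degree three")
  din <- tabulate_degree(edges$v[edges$directed], vertices)
  if (!all(din %in% c(0L, 2L)))
    np_validation_error("every reticulation must have exactly two incoming directed edges")
  if (length(components_undirected(as.matrix(edges[, 1:2]), vertices)) != 1L)
    np_validation_error("semi-directed network must be connected")
  labels <- validate_leaf_labels(labels, leaves)
  structure(list(edges = edges, vertices = vertices, labels = labels),
            class = "semidnet")
}

#' @export
print.semidnet <- function(x, ...) {
  cat(sprintf("semidnet: %d taxa, %d reticulations\n", length(x$labels),
              length(sd_reticulations(x))))
  invisible(x)
}

#' @rdname semidnet
#' @param ns a [semidnet].
#' @export
sd_reticulations <- function(ns) {
  din <- tabulate_degree(ns$edges$v[ns$edges$directed], ns$vertices)
  ns$vertices[din == 2L]
}

#' Level of semi-directed and unrooted networks
#'
#' For a semi-directed network the level is the maximum number of
#' reticulations in a biconnected component (equal to the level of any
#' rooted partner); for an unrooted network it is the maximum cycle rank
#' (edges - vertices + 1) over biconnected components, the number of
#' edge deletions needed to make each component acyclic.
#'
#' @param ns a [semidnet].
#' @return Non-negative integer.
#' @export
sd_level <- function(ns) {
  verts <- ns$vertices
  ti <- match(ns$edges$u, verts); hi <- match(ns$edges$v, verts)
  g <- igraph::graph_from_edgelist(cbind(ti, hi), directed = FALSE)
  bc <- igraph::biconnected_components(g)
  retics <- match(sd_reticulations(ns), verts)
  best <- 0L
  for (comp in bc$components)
    best <- max(best, sum(retics %in% as.integer(comp)))
  best
}

#' @rdname sd_level
#' @param U a [unet].
#' @export
unet_level <- function(U) {
  verts <- U$vertices
  ti <- match(U$edges[, 1L], verts); hi <- match(U$edges[, 2L], verts)
  g <- igraph::graph_from_edgelist(cbind(ti, hi), directed = FALSE)
  bc <- igraph::biconnected_components(g)
  best <- 0L
  for (comp in bc$component_edges)
    best <- max(best, length(comp) -
                  length(unique(c(igraph::ends(g, comp)))) + 1L)
  best
}

#' Unrooted networks
#'
#' A connected undirected graph with no loops or parallel edges whose
#' inner vertices all have degree three and whose leaves are labelled by
#' X. Unlike a semi-directed network it retains no direction
#' information at all.
#'
#' @param edges two-column character matrix of undirected edges.
#' @param labels named character vector, leaf vertex -> taxon.
#' @return An object of class `unet`.
#' @export
unet <- function(edges, labels) {
  edges <- as_edge_matrix(edges)
  if (any(edges[, 1L] == edges[, 2L])) np_validation_error("loops are not allowed")
  key <- apply(edges, 1L, function(e) paste(canon_sort(e), collapse = "\r"))
  if (anyDuplicated(key)) np_validation_error("parallel edges are not allowed")
  vertices <- canon_sort(unique(c(edges)))
  deg <- tabulate_degree(c(edges), vertices)
  leaves <- vertices[deg == 1L]
  if (!all(deg[setdiff(vertices, leaves)] == 3L))
    np_validation_error("inner vertices of an unrooted network must have degree three")
  if (length(components_undirected(edges, vertices)) != 1L)
    np_validation_error("unrooted network must be connected")
  labels <- validate_leaf_labels(labels, leaves)
  structure(list(edges = edges, vertices = vertices, labels = labels),
            class = "unet")
}

#' @export
print.unet <- function(x, ...) {
  cat(sprintf("unet: %d taxa, cycle rank %d\n", length(x$labels),
              nrow(x$edges) - length(x$vertices) + 1L))
  invisible(x)
}

#' Deroot a rooted network
#'
#' Deletes the root, suppresses the child of the root and drops the
#' direction of every non-reticulation edge. The merged edge stays
#' directed when one of its endpoints is a reticulation of the rooted
#' network; when the child of the root tops an underlying 3-cycle the
#' merge creates the (single) parallel pair.
#'
#' @param net a [phynet] with at least two leaves.
#' @return A [semidnet] with `net` among its rooted partners.
#' @export
deroot <- function(net) {
  if (length(net$labels) < 2L)
    np_validation_error("cannot deroot a single-leaf network")
  retics <- reticulations(net)
  v0 <- np_children(net, net$root)
  kids <- np_children(net, v0)
  rows <- net$edges[net$edges[, 1L] != net$root &
                    net$edges[, 1L] != v0, , drop = FALSE]
  df <- data.frame(u = rows[, 1L], v = rows[, 2L],
                   directed = rows[, 2L] %in% retics)
  merged_head_ret <- kids[kids %in% retics]
  if (length(merged_head_ret)) {
    other <- setdiff(kids, merged_head_ret)
    df <- rbind(df, data.frame(u = other, v = merged_head_ret, directed = TRUE))
  } else {
    df <- rbind(df, data.frame(u = kids[1L], v = kids[2L], directed = FALSE))
  }
  semidnet(df, net$labels)
}

#' Rooted partners of a semi-directed network
#'
#' Enumerates, up to labelled isomorphism, every rooted binary network
#' that deroots to the given semi-directed network: each edge is tried
#' as the re-insertion point of the root, every orientation of the
#' undirected edges is tried, and a candidate is kept when it validates
#' and its reticulations (with their directed in-edges) are exactly
#' those of the input.
#'
#' @param ns a [semidnet].
#' @param guard maximum number of undirected edges for the exhaustive
#'   orientation search.
#' @return A list of [phynet]s.
#' @export
rooted_partners <- function(ns, guard = 15L) {
  und <- which(!ns$edges$directed)
  if (length(und) > guard)
    np_guard_error(sprintf("%d undirected edges exceed the orientation guard %d",
                           length(und), guard))
  out <- list()
  retics <- sd_reticulations(ns)
  for (i in seq_len(nrow(ns$edges))) {
    e <- ns$edges[i, ]
    base <- ns$edges[-i, , drop = FALSE]
    head_rows <- rbind(c("rho0", "c0"), c("c0", e$u), c("c0", e$v))
    free <- which(!base$directed)
    fixed <- as.matrix(base[base$directed, c("u", "v"), drop = FALSE])
    for (mask in seq_len(2^length(free)) - 1L) {
      bits <- (mask %/% 2^(seq_along(free) - 1L)) %% 2L
      oriented <- t(vapply(seq_along(free), function(j) {
        r <- base[free[j], ]
        if (bits[j] == 0L) c(r$u, r$v) else c(r$v, r$u)
      }, character(2)))
      if (!length(free)) oriented <- matrix(character(0), ncol = 2L)
      cand_edges <- rbind(head_rows, fixed, oriented)
      if (!fast_degree_ok(cand_edges, names(ns$labels))) next
      cand <- tryCatch(phynet(cand_edges, ns$labels),
                       netpars_error = function(err) NULL)
      if (is.null(cand)) next
      if (!setequal(reticulations(cand), retics)) next
      if (!any(vapply(out, net_isomorphic, logical(1), n2 = cand)))
        out[[length(out) + 1L]] <- cand
    }
  }
  if (!length(out))
    np_validation_error("no rooted partner exists; not a valid semi-directed network")
  out
}

## ---- unrooted display sets --------------------------------------------

## Enumerate, by deleting cycle-rank-many edges, every spanning tree of
## the underlying (multi)graph, prune unlabelled degree-one chains, and
## suppress. For a semi-directed network, embeddings keeping both
## incoming edges of a reticulation are rejected. This realises the
## display definition directly, with no detour through rooted partners.
display_core <- function(edge_rows, labels, retic_in = NULL, guard = 1e5) {
  vertices <- canon_sort(unique(c(edge_rows)))
  m <- nrow(edge_rows)
  r <- m - length(vertices) + 1L
  if (r > 0 && choose(m, r) > guard)
    np_guard_error(sprintf("%g edge subsets exceed the display guard %g",
                           choose(m, r), guard))
  subsets <- if (r == 0L) list(integer(0)) else
    asplit(utils::combn(m, r), 2L)
  out <- list()
  for (drop in subsets) {
    rest <- if (length(drop)) edge_rows[-drop, , drop = FALSE] else edge_rows
    if (length(components_undirected(rest, vertices)) != 1L) next
    pruned <- prune_unlabelled(rest, labels)
    if (!is.null(retic_in)) {
      ok <- all(vapply(retic_in, function(rows) {
        sum(rows %in% setdiff(seq_len(m), drop) &
              row_retained(edge_rows, rows, pruned)) <= 1L
      }, logical(1)))
      if (!ok) next
    }
    ut <- tryCatch(suppress_unrooted(pruned, labels),
                   netpars_error = function(e) NULL)
    if (is.null(ut)) next
    key <- cnewick_unrooted(ut)
    if (is.null(out[[key]])) out[[key]] <- ut
  }
  out[canon_sort(names(out))]
}

## which of the original edge rows (by index) survive in `pruned`
row_retained <- function(edge_rows, rows, pruned) {
  pk <- apply(pruned, 1L, function(e) paste(canon_sort(e), collapse = "\r"))
  vapply(rows, function(i) {
    k <- paste(canon_sort(edge_rows[i, ]), collapse = "\r")
    k %in% pk
  }, logical(1))
}

prune_unlabelled <- function(edges, labels) {
  repeat {
    vertices <- unique(c(edges))
    deg <- tabulate_degree(c(edges), vertices)
    dangling <- vertices[deg == 1L & !vertices %in% names(labels)]
    if (!length(dangling)) return(edges)
    edges <- edges[!(edges[, 1L] %in% dangling | edges[, 2L] %in% dangling), ,
                   drop = FALSE]
  }
}

suppress_unrooted <- function(edges, labels) {
  repeat {
    vertices <- unique(c(edges))
    deg <- tabulate_degree(c(edges), vertices)
    d2 <- vertices[deg == 2L]
    if (!length(d2)) break
    v <- d2[[1L]]
    nb <- c(edges[edges[, 1L] == v, 2L], edges[edges[, 2L] == v, 1L])
    edges <- edges[edges[, 1L] != v & edges[, 2L] != v, , drop = FALSE]
    edges <- rbind(edges, nb)
  }
  phyutree(edges, labels[names(labels) %in% unique(c(edges))])
}

## cheap degree screen applied before full validation in the
## orientation/partner enumerations (almost all direction assignments
## fail it, so the expensive constructor runs rarely)
fast_degree_ok <- function(edges, leaf_ids) {
  verts <- unique(c(edges))
  ti <- match(edges[, 1L], verts); hi <- match(edges[, 2L], verts)
  outd <- tabulate(ti, length(verts)); ind <- tabulate(hi, length(verts))
  is_leaf <- verts %in% leaf_ids
  if (any(ind[is_leaf] != 1L) || any(outd[is_leaf] != 0L)) return(FALSE)
  roots <- ind == 0L
  if (sum(roots) != 1L || outd[roots] != 1L) return(FALSE)
  inner <- !is_leaf & !roots
  all((ind[inner] == 1L & outd[inner] == 2L) |
        (ind[inner] == 2L & outd[inner] == 1L))
}

#' Unrooted display set
#'
#' All unrooted phylogenetic X-trees displayed by a semi-directed or an
#' unrooted network: subgraphs that are subdivisions of an X-tree, where
#' a semi-directed embedding may keep at most one incoming reticulation
#' edge per reticulation. For a semi-directed network this set equals
#' the deroot-image of the display set of any rooted partner, which the
#' test suite checks; the computation here is direct.
#'
#' @param x a [semidnet] or [unet].
#' @param guard maximum number of edge subsets examined.
#' @return A named list of [phyutree]s; names are canonical strings.
#' @export
display_set_unrooted <- function(x, guard = 1e5) {
  if (inherits(x, "semidnet")) {
    rows <- as.matrix(x$edges[, c("u", "v")])
    retics <- sd_reticulations(x)
    retic_in <- lapply(retics, function(v) which(x$edges$directed & x$edges$v == v))
    names(retic_in) <- retics
    display_core(rows, x$labels, retic_in, guard)
  } else if (inherits(x, "unet")) {
    display_core(x$edges, x$labels, NULL, guard)
  } else np_validation_error("expected a semidnet or unet")
}

#' @rdname softwired_score
#' @export
softwired_score.semidnet <- function(x, A, guard = 1e5, ...) {
  sw_unrooted_score(display_set_unrooted(x, guard), x, A)
}

#' @rdname softwired_score
#' @export
softwired_score.unet <- function(x, A, guard = 1e5, ...) {
  sw_unrooted_score(display_set_unrooted(x, guard), x, A)
}

sw_unrooted_score <- function(trees, x, A) {
  A <- as_alignment(A)
  if (!setequal(taxa(x), rownames(A)))
    np_taxon_error("network taxa and alignment taxa differ")
  total <- 0L
  for (i in seq_len(ncol(A))) {
    f <- site_character(A, i)
    total <- total + min(vapply(trees, unrooted_parsimony, numeric(1), f = f))
  }
  as.integer(total)
}

#' Orientations of an unrooted network
#'
#' Every rooted binary network that deroots (delete the root, suppress
#' its child, forget all directions) to the given unrooted network:
#' each edge is tried as the root insertion point and every assignment
#' of directions to the remaining edges is kept when it validates.
#' Results are deduplicated up to labelled isomorphism. Unlike the
#' semi-directed case, different orientations can have different
#' softwired scores.
#'
#' @param U a [unet].
#' @param guard maximum number of edges for the exhaustive orienter.
#' @return A list of [phynet]s.
#' @export
orientations <- function(U, guard = 14L) {
  m <- nrow(U$edges)
  if (m > guard)
    np_guard_error(sprintf("%d edges exceed the orientation guard %d", m, guard))
  out <- list()
  for (i in seq_len(m)) {
    e <- U$edges[i, ]
    base <- U$edges[-i, , drop = FALSE]
    head_rows <- rbind(c("rho0", "c0"), c("c0", e[[1L]]), c("c0", e[[2L]]))
    for (mask in seq_len(2^nrow(base)) - 1L) {
      bits <- (mask %/% 2^(seq_len(nrow(base)) - 1L)) %% 2L
      oriented <- cbind(ifelse(bits == 0L, base[, 1L], base[, 2L]),
                        ifelse(bits == 0L, base[, 2L], base[, 1L]))
      cand_edges <- rbind(head_rows, oriented)
      if (!fast_degree_ok(cand_edges, names(U$labels))) next
      cand <- tryCatch(phynet(cand_edges, U$labels),
                       netpars_error = function(err) NULL)
      if (is.null(cand)) next
      if (!any(vapply(out, net_isomorphic, logical(1), n2 = cand)))
        out[[length(out) + 1L]] <- cand
    }
  }
  out
}

#' Underlying unrooted network of a rooted one
#'
#' Deroots and forgets the remaining reticulation-edge directions; an
#' error when derooting creates a parallel pair (such a rooted network
#' is not an orientation of any simple unrooted network).
#'
#' @param net a [phynet].
#' @return A [unet].
#' @export
as_unet <- function(net) {
  ds <- deroot(net)
  unet(as.matrix(ds$edges[, c("u", "v")]), ds$labels)
}
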
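#' MUL-tree unfolding of a network
#'
#' The unfolding U*(N) is the multilabelled tree whose vertices are the
#' root-initiated directed paths of N, with an edge whenever one path
#' extends another by a single network edge. A taxon gets one leaf copy
#' per distinct root-to-leaf path, so reticulations duplicate the
#' subtrees hanging below them. Parental trees of N are the
#' phylogenetic X-trees obtained by keeping one leaf copy per taxon and
#' suppressing.
#'
#' @param net a [phynet].
#' @param guard maximum number of leaves of the unfolding.
#' @return An object of class `multree`: a rooted tree (`edges`, `root`,
#'   `children`) with a multilabel map `labels` (leaf vertex -> taxon,
#'   taxa may repeat) and a `copy` index per labelled leaf, assigned in
#'   canonical depth-first order.
#' @export
unfold_multree <- function(net, guard = 1e5) {
  ## leaf-copy count = number of root-to-leaf paths; check the guard first
  npaths <- stats::setNames(rep(0, length(net$vertices)), net$vertices)
  npaths[net$root] <- 1
  topo <- topological_order(net)
  for (v in topo) for (w in np_children(net, v)) npaths[w] <- npaths[w] + npaths[v]
  total_leaves <- sum(npaths[names(net$labels)])
  if (total_leaves > guard)
    np_guard_error(sprintf("unfolding would have %g leaves; guard is %g", total_leaves, guard))

  env <- new.env(parent = emptyenv())
  env$counter <- 0L
  env$edges <- character(0)
  env$labels <- character(0)
  walk <- function(v) {        # copy the sub-DAG below v as a tree
    env$counter <- env$counter + 1L
    id <- sprintf("p%d", env$counter)
    if (v %in% names(net$labels)) {
      env$labels[id] <- net$labels[[v]]
    } else {
      for (w in np_children(net, v)) {
        cid <- walk(w)
        env$edges <- c(env$edges, id, cid)
      }
    }
    id
  }
  root_id <- walk(net$root)
  edges <- matrix(env$edges, ncol = 2L, byrow = TRUE)
  labels <- env$labels
  copy <- stats::setNames(integer(length(labels)), names(labels))
  for (x in unique(labels)) {
    ids <- names(labels)[labels == x]
    copy[ids] <- seq_along(ids)     # depth-first discovery order
  }
  vertices <- canon_sort(unique(c(edges)))
  structure(list(edges = edges, vertices = vertices, root = root_id,
                 labels = labels, copy = copy,
                 children = adjacency(edges, vertices, from = TRUE)),
            class = "multree")
}

topological_order <- function(net) {
  indeg <- tabulate_degree(net$edges[, 2L], net$vertices)
  queue <- net$vertices[indeg == 0L]
  out <- character(0)
  while (length(queue)) {
    v <- queue[[1L]]; queue <- queue[-1L]
    out <- c(out, v)
    for (w in np_children(net, v)) {
      indeg[w] <- indeg[w] - 1L
      if (indeg[w] == 0L) queue <- c(queue, w)
    }
  }
  out
}

#' @export
print.multree <- function(x, ...) {
  cat(sprintf("multree: %d leaves over %d taxa\n", length(x$labels),
              length(unique(x$labels))))
  invisible(x)
}

#' @rdname unfold_multree
#' @param U a `multree`.
#' @export
leaf_copies <- function(U) table(unname(U$labels))

#' Restriction of a MUL-tree to one leaf copy per taxon
#'
#' Keeps, for each taxon, the chosen leaf copy, restricts the unfolding
#' to the union of root paths to those leaves, and suppresses vertices
#' of in- and out-degree one. The result is a phylogenetic X-tree; over
#' all copy assignments these are exactly the parental trees.
#'
#' @param U a `multree` from [unfold_multree()].
#' @param sigma named integer vector: taxon -> copy index.
#' @return A [phynet] without reticulations.
#' @export
restriction_tree <- function(U, sigma) {
  xs <- unique(unname(U$labels))
  if (!setequal(names(sigma), xs))
    np_taxon_error("copy assignment must cover every taxon exactly once")
  chosen <- vapply(xs, function(x) {
    id <- names(U$labels)[U$labels == x & U$copy == sigma[[x]]]
    if (length(id) != 1L)
      np_validation_error(sprintf("taxon '%s' has no copy %d", x, sigma[[x]]))
    id
  }, character(1))
  parents <- adjacency(U$edges, U$vertices, from = FALSE)
  keep <- character(0)
  for (lf in chosen) {         # walk up to the root
    v <- lf
    while (!v %in% keep) {
      keep <- c(keep, v)
      p <- parents[[v]]
      if (!length(p)) break
      v <- p
    }
  }
  edges <- U$edges[U$edges[, 1L] %in% keep & U$edges[, 2L] %in% keep, , drop = FALSE]
  labels <- stats::setNames(unname(U$labels[chosen]), chosen)
  suppress_subdivision(physub(edges, labels))
}

#' Parental trees of a network
#'
#' P(N): all trees obtainable from the MUL-tree unfolding by choosing
#' one leaf copy per taxon, deduplicated by canonical Newick. Every
#' displayed tree is parental (choosing all copies along one switching),
#' but not conversely.
#'
#' @param net a [phynet].
#' @param guard maximum number of copy assignments to enumerate.
#' @return A named list of trees; names are canonical Newick strings.
#' @export
parental_trees <- function(net, guard = 1e4) {
  U <- unfold_multree(net)
  xs <- canon_sort(unique(unname(U$labels)))
  counts <- vapply(xs, function(x) sum(U$labels == x), integer(1))
  if (prod(counts) > guard)
    np_guard_error(sprintf("%g copy assignments exceed the guard %g", prod(counts), guard))
  out <- list()
  grid <- do.call(expand.grid, lapply(counts, seq_len))
  names(grid) <- xs
  for (i in seq_len(nrow(grid))) {
    sigma <- stats::setNames(as.integer(grid[i, ]), xs)
    tr <- restriction_tree(U, sigma)
    key <- cnewick(tr)
    if (is.null(out[[key]])) out[[key]] <- tr
  }
  out[canon_sort(names(out))]
}

#' @rdname parental_trees
#' @param tr a tree to test for membership in P(N).
#' @export
is_parental <- function(net, tr, guard = 1e4) {
  cnewick(tr) %in% names(parental_trees(net, guard))
}

#' Parental parsimony score
#'
#' The minimum parsimony score over all parental trees; for alignments
#' the per-site minima are summed (each site may follow its own parental
#' tree). Always at most the softwired score, since the parental set
#' contains the display set. Computed by brute force over leaf-copy
#' assignments of the unfolding.
#'
#' @param net a [phynet].
#' @param A a character or [phyalign].
#' @param guard maximum number of copy assignments.
#' @return Non-negative integer.
#' @export
parental_score <- function(net, A, guard = 1e4) {
  A <- as_alignment(A)
  if (!setequal(taxa(net), rownames(A)))
    np_taxon_error("network taxa and alignment taxa differ")
  trees <- parental_trees(net, guard)
  per_tree <- vapply(trees, function(tr) {
    vapply(seq_len(ncol(A)), function(i)
      parsimony_score(tr, site_character(A, i)), numeric(1))
  }, numeric(ncol(A)))
  per_tree <- matrix(per_tree, nrow = ncol(A))
  as.integer(sum(apply(per_tree, 1L, min)))
}
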
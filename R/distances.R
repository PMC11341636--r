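#' Switching distance
#'
#' The number of reticulations at which two switchings of the same
#' network choose different incoming edges: h(N) minus the number of
#' shared choices.
#'
#' @param R,R2 switchings of the same network (see [switchings()]).
#' @return Integer between 0 and h(N).
#' @export
switching_distance <- function(R, R2) {
  if (!identical(attr(R, "host"), attr(R2, "host")))
    np_validation_error("switchings belong to different networks")
  sum(unname(unclass(R)[names(R)]) != unname(unclass(R2)[names(R)]))
}

## ---- exact rSPR distance on small rooted trees -------------------------

## package-level memo: canonical newick -> character vector of canonical
## newicks one rSPR move away
.rspr_cache <- new.env(parent = emptyenv())

cnewick_core <- function(children, labels, root) {
  rec <- function(v) {
    kids <- children[[v]]
    if (is.null(kids) || !length(kids)) return(unname(labels[v]))
    parts <- vapply(kids, rec, character(1))
    if (length(parts) == 1L) return(parts)
    paste0("(", paste(sort(parts, method = "radix"), collapse = ","), ")")
  }
  paste0("(", rec(children[[root]]), ");")
}

cnewick_edges <- function(edges, labels, root) {
  vertices <- unique(c(edges))
  cnewick_core(adjacency(edges, vertices, from = TRUE), labels, root)
}

## All trees one rSPR move from the tree encoded by a canonical newick.
## Moves prune any edge not incident with the root and regraft into any
## edge of the root component (the root edge included), per the standard
## definition; the pruned parent is suppressed.
rspr_neighbors <- function(nwk) {
  hit <- .rspr_cache[[nwk]]
  if (!is.null(hit)) return(hit)
  tr <- read_enewick(nwk)
  edges <- tr$edges
  labels <- tr$labels
  root <- tr$root
  out <- character(0)
  for (i in seq_len(nrow(edges))) {
    u <- edges[i, 1L]; v <- edges[i, 2L]
    if (u == root) next
    rest <- edges[-i, , drop = FALSE]
    p <- rest[rest[, 2L] == u, 1L]
    oc <- rest[rest[, 1L] == u, 2L]
    rest <- rest[rest[, 1L] != u & rest[, 2L] != u, , drop = FALSE]
    rest <- rbind(rest, c(p, oc))
    ## vertices of the root component (the pruned subtree hangs off v)
    in_sub <- reachable_from(list(children = adjacency(
      rest, unique(c(rest)), from = TRUE)), v)
    for (j in seq_len(nrow(rest))) {
      a <- rest[j, 1L]; b <- rest[j, 2L]
      if (a %in% in_sub || b %in% in_sub) next
      e2 <- rbind(rest[-j, , drop = FALSE], c(a, "u+"), c("u+", b), c("u+", v))
      out <- c(out, cnewick_edges(e2, labels, root))
    }
  }
  out <- setdiff(unique(out), nwk)
  assign(nwk, out, envir = .rspr_cache)
  out
}

expand_frontier <- function(front, visited) {
  nxt <- unique(unlist(lapply(front, rspr_neighbors), use.names = FALSE))
  setdiff(nxt, visited)
}

## bidirectional BFS; returns the exact distance, or limit + 1 when the
## distance exceeds `limit` (limit = Inf gives the exact distance)
rspr_search <- function(s1, s2, limit = Inf) {
  if (identical(s1, s2)) return(0L)
  a <- s1; b <- s2
  visa <- a; visb <- b
  fa <- a; fb <- b
  d <- 0L
  repeat {
    if (d >= limit) return(as.integer(limit + 1L))
    if (length(fa) <= length(fb)) {
      fa <- expand_frontier(fa, visa)
      visa <- c(visa, fa)
    } else {
      fb <- expand_frontier(fb, visb)
      visb <- c(visb, fb)
    }
    d <- d + 1L
    if (length(intersect(fa, visb)) || length(intersect(fb, visa)))
      return(d)
    if (!length(fa) || !length(fb)) return(as.integer(limit + 1L))
  }
}

#' Exact rSPR distance between two small trees
#'
#' Minimum number of rooted subtree-prune-and-regraft operations turning
#' one tree into the other, found by bidirectional breadth-first search
#' over the rSPR graph with canonical-Newick memoisation. Exact but
#' exponential: guarded to small leaf sets.
#'
#' @param t1,t2 [phynet]s without reticulations on the same taxa.
#' @param guard maximum number of leaves (default 8).
#' @return Non-negative integer.
#' @export
rspr_distance <- function(t1, t2, guard = 8L) {
  if (!setequal(taxa(t1), taxa(t2)))
    np_taxon_error("trees have different leaf sets")
  if (length(taxa(t1)) > guard)
    np_guard_error(sprintf("exact rSPR search is guarded to %d leaves", guard))
  rspr_search(cnewick(t1), cnewick(t2))
}

#' Check the switching bound on the rSPR distance
#'
#' For two switchings R, R' of the same network, the trees they yield
#' satisfy d_rSPR(T_R, T_R') <= d_switch(R, R'): trees that differ in
#' few reticulation choices are few prune-and-regraft moves apart. This
#' verifies the inequality on one instance by depth-limited search.
#'
#' @param net a [phynet].
#' @param R,R2 switchings of `net`.
#' @param guard leaf guard for the rSPR search.
#' @return TRUE iff the bound holds for this pair.
#' @export
switch_bound_holds <- function(net, R, R2, guard = 8L) {
  if (length(taxa(net)) > guard)
    np_guard_error(sprintf("exact rSPR search is guarded to %d leaves", guard))
  t1 <- switching_tree(net, R)$tree
  t2 <- switching_tree(net, R2)$tree
  d_sw <- switching_distance(R, R2)
  rspr_search(cnewick(t1), cnewick(t2), limit = d_sw) <= d_sw
}
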
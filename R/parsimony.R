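#' Changing number of an extension
#'
#' An extension F of a character f assigns a state to every vertex of a
#' rooted graph G while agreeing with f on the leaves. Its changing
#' number ch(F,G) is the number of edges whose endpoints receive
#' different states.
#'
#' @param F a named character vector assigning a state to every vertex.
#' @param obj an object with an `edges` matrix ([phynet], [physub], ...).
#' @return Non-negative integer.
#' @export
changing_number <- function(F, obj) {
  vs <- unique(c(obj$edges))
  miss <- setdiff(vs, names(F))
  if (length(miss))
    np_validation_error(sprintf("extension misses vertex '%s'", miss[1L]))
  sum(F[obj$edges[, 1L]] != F[obj$edges[, 2L]])
}

## postorder over a rooted structure given by a children list
postorder_vertices <- function(root, children) {
  out <- character(0)
  stack <- root
  while (length(stack)) {
    v <- stack[[length(stack)]]; stack <- stack[-length(stack)]
    out <- c(out, v)
    kids <- children[[v]]
    if (!is.null(kids)) stack <- c(stack, kids)
  }
  rev(out)   # reverse preorder = a valid postorder for trees
}

## Fitch-Hartigan small-parsimony DP with unit costs: for each vertex v
## and state a, cost[v, a] is the minimum number of changes in the
## subtree below v when v is assigned a. Handles out-degree 1 vertices
## (subdivisions) and out-degree 3 roots (unrooted trees rooted at an
## internal vertex) natively.
fh_costs <- function(root, children, labels, f) {
  states <- canon_sort(unique(unname(f)))
  po <- postorder_vertices(root, children)
  cost <- matrix(0, nrow = length(po), ncol = length(states),
                 dimnames = list(po, states))
  big <- length(po) + 1   # acts as infinity: no score can reach it
  for (v in po) {
    kids <- children[[v]]
    if (is.null(kids) || !length(kids)) {
      s <- f[[labels[[v]]]]
      cost[v, ] <- big
      cost[v, s] <- 0
    } else {
      acc <- numeric(length(states))
      for (u in kids) {
        cu <- cost[u, ]
        acc <- acc + pmin(cu, min(cu) + 1)
      }
      cost[v, ] <- acc
    }
  }
  cost
}

check_taxa <- function(obj, f) {
  if (!setequal(taxa(obj), names(f)))
    np_taxon_error("leaf labels of the tree and the character's taxa differ")
  invisible(TRUE)
}

#' Parsimony score of a tree, subdivision or unrooted tree
#'
#' The minimum changing number over all extensions of a character (or,
#' for an alignment, the sum of per-site minima). Computed by the
#' Fitch-Hartigan bottom-up dynamic program; on a subdivision the score
#' equals the score of the suppressed tree, and on an unrooted tree it is
#' independent of the rooting, both of which are exercised as properties
#' in the test suite.
#'
#' @param x a [phynet] without reticulations, a [physub], or a
#'   [phyutree].
#' @param f a character (named vector taxon -> state) or a [phyalign].
#' @return Non-negative integer.
#' @examples
#' tr <- read_enewick("((a,(b,(c,(d,e)))));")
#' parsimony_score(tr, c(a = "0", b = "0", c = "0", d = "1", e = "1"))
#' @export
parsimony_score <- function(x, f) {
  if (inherits(f, "phyalign")) {
    return(sum(vapply(seq_len(ncol(f)), function(i)
      parsimony_score(x, site_character(f, i)), numeric(1))))
  }
  f <- as_phychar(f)
  UseMethod("parsimony_score")
}

#' @export
parsimony_score.phynet <- function(x, f) {
  if (n_reticulations(x) > 0L)
    np_validation_error("network has reticulations; use softwired_score() or parental_score()")
  check_taxa(x, f)
  rev_labels <- stats::setNames(names(x$labels), x$labels)
  labmap <- stats::setNames(unname(x$labels), names(x$labels))
  cost <- fh_costs(x$root, x$children, labmap, f)
  as.integer(min(cost[x$root, ]))
}

#' @export
parsimony_score.physub <- function(x, f) {
  check_taxa(x, f)
  labmap <- stats::setNames(unname(x$labels), names(x$labels))
  cost <- fh_costs(x$root, x$children, labmap, f)
  as.integer(min(cost[x$root, ]))
}

#' Enumerate all minimum extensions
#'
#' Yields every extension of `f` to the vertices of `S` whose changing
#' number equals the parsimony score, by top-down backtracking over the
#' per-vertex optimal state sets of the dynamic program. Minimum
#' extensions never place a change on the root path (an extension with a
#' root-path change always admits a strictly cheaper one), so the
#' enumeration is automatically normalised. A hard guard bounds the
#' number of extensions produced since the count can grow exponentially.
#'
#' @param S a [physub] or a [phynet] without reticulations.
#' @param f a character on the taxa of `S`.
#' @param guard maximum number of extensions to enumerate.
#' @return A list of named character vectors (vertex -> state), in a
#'   deterministic order; states are expanded in sorted order so the
#'   first entry is the lexicographically smallest minimum extension.
#' @export
min_extensions <- function(S, f, guard = 2^20) {
  if (is_phynet(S)) S <- as_physub(S)
  f <- as_phychar(f)
  check_taxa(S, f)
  labmap <- stats::setNames(unname(S$labels), names(S$labels))
  cost <- fh_costs(S$root, S$children, labmap, f)
  states <- colnames(cost)
  pre <- rev(postorder_vertices(S$root, S$children))

  root_states <- states[cost[S$root, ] == min(cost[S$root, ])]
  partial <- lapply(root_states, function(a) stats::setNames(a, S$root))
  for (v in pre) {
    kids <- S$children[[v]]
    if (is.null(kids) || !length(kids)) next
    for (u in kids) {
      nxt <- vector("list", 0L)
      for (asg in partial) {
        a <- asg[[v]]
        tot <- cost[u, ] + (states != a)
        opts <- states[tot == min(tot)]
        for (b in opts) {
          asg2 <- asg
          asg2[[u]] <- b
          nxt[[length(nxt) + 1L]] <- asg2
          if (length(nxt) > guard)
            np_guard_error(sprintf("more than %d minimum extensions; raise the guard", guard))
        }
      }
      partial <- nxt
    }
  }
  partial
}

#' Parsimony score of an unrooted tree
#'
#' Scores an unrooted binary phylogenetic tree by orienting it away from
#' an internal vertex and running the rooted dynamic program; the score
#' does not depend on the orientation.
#'
#' @param ut a [phyutree].
#' @param f a character or [phyalign] on the taxa of `ut`.
#' @param at optional vertex at which to root (used by the invariance
#'   property tests); defaults to the neighbour of the canonically
#'   smallest leaf.
#' @return Non-negative integer.
#' @export
unrooted_parsimony <- function(ut, f, at = NULL) {
  if (inherits(f, "phyalign")) {
    return(sum(vapply(seq_len(ncol(f)), function(i)
      unrooted_parsimony(ut, site_character(f, i), at = at), numeric(1))))
  }
  f <- as_phychar(f)
  check_taxa(ut, f)
  rs <- root_unrooted(ut, at)
  labmap <- stats::setNames(unname(ut$labels), names(ut$labels))
  cost <- fh_costs(rs$root, rs$children, labmap, f)
  as.integer(min(cost[rs$root, ]))
}

## Orient an unrooted tree away from a start vertex; returns root +
## children list for the DP.
root_unrooted <- function(ut, at = NULL) {
  if (is.null(at)) {
    lf <- names(ut$labels)[order(unname(ut$labels), method = "radix")][1L]
    at <- ut_neighbors(ut, lf)[1L]
  }
  children <- stats::setNames(vector("list", length(ut$vertices)), ut$vertices)
  seen <- at
  queue <- at
  while (length(queue)) {
    v <- queue[[1L]]; queue <- queue[-1L]
    nb <- setdiff(ut_neighbors(ut, v), seen)
    children[[v]] <- canon_sort(nb)
    seen <- c(seen, nb)
    queue <- c(queue, nb)
  }
  list(root = at, children = children)
}
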
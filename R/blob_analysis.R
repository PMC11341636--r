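#' Blob indicator of an extension
#'
#' For an extension F on an embedding S, the indicator of a blob B is 0
#' when every vertex of C_N(B) (the children of the blob) receives the
#' same state under F, and 1 otherwise. The children of a blob lie on
#' every embedding of every displayed tree, so the indicator is well
#' defined; an S that misses one of them is rejected.
#'
#' @param F named character vector: an extension on the vertices of `S`.
#' @param net the host [phynet].
#' @param B a blob of `net`.
#' @param S a [physub] embedding of a displayed tree of `net`.
#' @return 0 or 1.
#' @export
blob_indicator <- function(F, net, B, S) {
  kids <- blob_children(net, B)
  if (!all(kids %in% S$vertices))
    np_validation_error("some children of the blob are not vertices of S")
  if (!all(kids %in% names(F)))
    np_validation_error("extension does not cover all children of the blob")
  as.integer(length(unique(unname(F[kids]))) > 1L)
}

#' Number of informative blobs
#'
#' b(f, N, S): the minimum, over all minimum extensions of f to the
#' vertices of S, of the number of blobs whose children receive more
#' than one state. A blob that can be made single-state by some minimum
#' extension is non-informative; informative blobs are the ones that
#' force state diversity among their children and each contributes at
#' least one change to PS(f, S). Computed by exhaustive iteration over
#' minimum extensions, which is the defining semantics and is guarded by
#' instance size.
#'
#' @param f a character on the taxa of `net`.
#' @param net a [phynet].
#' @param S a [physub] embedding of a displayed tree of `net`.
#' @param guard passed to [min_extensions()].
#' @return A list with `count` (b(f,N,S)) and `extension` (a minimum
#'   extension realising it).
#' @export
informative_blob_count <- function(f, net, S, guard = 2^20) {
  f <- as_phychar(f)
  bl <- blobs(net)
  exts <- min_extensions(S, f, guard)
  if (!length(bl))
    return(list(count = 0L, extension = exts[[1L]]))
  best <- NULL
  best_n <- Inf
  for (F in exts) {
    n_inf <- sum(vapply(bl, function(B) blob_indicator(F, net, B, S), integer(1)))
    if (n_inf < best_n) {
      best_n <- n_inf
      best <- F
    }
  }
  list(count = as.integer(best_n), extension = best)
}

fresh_name <- function(base, used) {
  if (!base %in% used) return(base)
  i <- 1L
  while (paste0(base, i) %in% used) i <- i + 1L
  paste0(base, i)
}

#' Blob reduction
#'
#' Splits a network at the source s of a maximal blob B (no other blob
#' below it): `below` is the subnetwork rooted at s with a fresh root
#' above it, a network on Y = cl(s); `above` is the rest of the network
#' with the whole subnetwork replaced by one fresh leaf y, a network on
#' (X \ Y) + y. Reducing a non-maximal blob is an error, since the part
#' below s would then contain a further blob and the reduction's
#' accounting would not apply.
#'
#' @param net a [phynet] with at least one blob.
#' @param B a maximal blob of `net` (see [maximal_blob()]).
#' @return A list with `below` and `above` ([phynet]s), the fresh leaf
#'   taxon `y`, the fresh root `rho_Y`, the source `s` and the cluster
#'   `Y`.
#' @export
blob_reduce <- function(net, B) {
  check_blob_of(net, B)
  s <- B$source
  others <- blobs(net)
  other_sources <- setdiff(vapply(others, function(b) b$source, character(1)), s)
  if (any(other_sources %in% setdiff(reachable_from(net, s), s)))
    np_validation_error("blob is not maximal: another blob lies below its source")

  cone <- reachable_from(net, s)
  y <- fresh_name("y", c(net$vertices, taxa(net)))
  rho_y <- fresh_name("rhoY", net$vertices)

  above_edges <- net$edges[!net$edges[, 1L] %in% cone, , drop = FALSE]
  above_edges[above_edges == s] <- y
  above_labels <- c(net$labels[!net$labels %in% descendant_cluster(net, s)],
                    stats::setNames(y, y))
  above <- phynet(above_edges, above_labels)

  below_edges <- rbind(c(rho_y, s),
                       net$edges[net$edges[, 1L] %in% cone, , drop = FALSE])
  below_labels <- net$labels[names(net$labels) %in% cone]
  below <- phynet(below_edges, below_labels)

  list(below = below, above = above, y = y, rho_Y = rho_y, s = s,
       Y = descendant_cluster(net, s))
}

#' Cluster tree pair of an embedding
#'
#' The tree analogue of the blob reduction: the embedding S is cut at
#' the blob source s into `SY` (the subtree rooted at s plus a fresh
#' root) and `SYbar` (the rest with a fresh leaf y in place of the
#' subtree). Reassembling at s/y recovers S.
#'
#' @param S a [physub] containing the source of `B`.
#' @param B a blob (of the host network of `S`).
#' @return A list of class `cluster_pair` with `SY`, `SYbar`, `y`,
#'   `rho_Y`, `s` and the cluster `Y`.
#' @export
cluster_tree_pair <- function(S, B) {
  s <- B$source
  if (!s %in% S$vertices)
    np_validation_error(sprintf("blob source '%s' is not a vertex of S", s))
  cone <- reachable_from(S, s)
  y <- fresh_name("y", c(S$vertices, taxa(S)))
  rho_y <- fresh_name("rhoY", S$vertices)

  ybar_edges <- S$edges[!S$edges[, 1L] %in% cone, , drop = FALSE]
  ybar_edges[ybar_edges == s] <- y
  ybar_labels <- c(S$labels[!names(S$labels) %in% cone], stats::setNames(y, y))
  SYbar <- physub(ybar_edges, ybar_labels)

  y_edges <- rbind(c(rho_y, s), S$edges[S$edges[, 1L] %in% cone, , drop = FALSE])
  SY <- physub(y_edges, S$labels[names(S$labels) %in% cone])

  structure(list(SY = SY, SYbar = SYbar, y = y, rho_Y = rho_y, s = s,
                 Y = descendant_cluster(S, s)),
            class = "cluster_pair")
}

#' Split an extension along a cluster tree pair
#'
#' Restricts an extension F on S to the two halves of a cluster tree
#' pair, assigning F(s) to the fresh root and the fresh leaf so that the
#' halves form a pair of cluster extensions and the changing numbers add
#' exactly: ch(F,S) = ch(F_Y, S(Y)) + ch(F_Ybar, S(Ybar)).
#'
#' @param F named character vector on the vertices of the original S.
#' @param pair a `cluster_pair` from [cluster_tree_pair()].
#' @return A list of class `cluster_extensions` with `FY` and `FYbar`.
#' @export
split_extension <- function(F, pair) {
  fs <- F[[pair$s]]
  FY <- c(F[setdiff(pair$SY$vertices, pair$rho_Y)],
          stats::setNames(fs, pair$rho_Y))
  FYbar <- c(F[setdiff(pair$SYbar$vertices, pair$y)],
             stats::setNames(fs, pair$y))
  structure(list(FY = FY[pair$SY$vertices], FYbar = FYbar[pair$SYbar$vertices]),
            class = "cluster_extensions")
}

#' Merge a pair of cluster extensions
#'
#' Inverse of [split_extension()]: glues a pair of cluster extensions
#' back into one extension on the original embedding. Requires the
#' defining invariant F_Ybar(y) = F_Y(rho_Y) (and, by the no-root-path-
#' change convention, F_Y(rho_Y) = F_Y(s)); changing numbers again add
#' exactly.
#'
#' @param exts a `cluster_extensions` object.
#' @param pair the `cluster_pair` the extensions live on.
#' @return A named character vector on the vertices of the original S.
#' @export
merge_extension <- function(exts, pair) {
  FY <- exts$FY; FYbar <- exts$FYbar
  if (FYbar[[pair$y]] != FY[[pair$rho_Y]])
    np_validation_error("not a pair of cluster extensions: F_Ybar(y) != F_Y(rho_Y)")
  if (FY[[pair$rho_Y]] != FY[[pair$s]])
    np_validation_error("cluster extension places a change on the root path of S(Y)")
  F <- c(FY[setdiff(names(FY), pair$rho_Y)],
         FYbar[setdiff(names(FYbar), pair$y)])
  F[canon_sort(names(F))]
}
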
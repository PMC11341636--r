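#' Sharp level-k family for the (k+1) bound
#'
#' Builds, for each k >= 1, a single-blob level-k network on 3k+1 leaves
#' together with a binary character for which the (k+1) approximation
#' bound is met with equality: some displayed tree scores exactly
#' (k+1) times the softwired score, which is 1. The network consists of
#' a spine of k gadgets; gadget i offers a choice between routing leaf
#' x_i next to its cherry partner x''_i (cheap) or collecting it on a
#' path towards x_0 (which concentrates all state-1 leaves on one
#' subtree). The character assigns state 1 exactly to x_0, x_1, ..., x_k.
#'
#' For k <= 5 the sharpness is re-verified at generation time by exact
#' softwired scoring; the constructor fails if the certified property
#' does not hold.
#'
#' @param k level, a positive integer.
#' @return A list with `network`, `char` (the binary character),
#'   `t_good` (a displayed tree attaining the softwired score 1) and
#'   `t_bad` (a displayed tree scoring k+1).
#' @examples
#' sharp <- sharp_level_k(2)
#' softwired_score(sharp$network, sharp$char)
#' parsimony_score(sharp$t_bad, sharp$char)
#' @export
sharp_level_k <- function(k) {
  if (!is.numeric(k) || k < 1 || k != round(k))
    np_validation_error("k must be an integer >= 1")
  k <- as.integer(k)
  ed <- function(a, b) c(a, b)
  u <- function(i) sprintf("u%d", i); g <- function(i) sprintf("g%d", i)
  cc <- function(i) sprintf("c%d", i); r <- function(i) sprintf("r%d", i)
  m <- function(i) sprintf("m%d", i)
  lx <- function(i) sprintf("x%d", i)
  lxp <- function(i) sprintf("xp%d", i); lxpp <- function(i) sprintf("xpp%d", i)

  edges <- list(ed("rho", "s"), ed("s", cc(1)))
  if (k == 1L) {
    edges <- c(edges, list(ed("s", u(1))))
  } else {
    edges <- c(edges, list(ed("s", m(1))))
    if (k >= 3L) for (i in seq_len(k - 2L))
      edges <- c(edges, list(ed(m(i), u(i)), ed(m(i), m(i + 1L))))
    edges <- c(edges, list(ed(m(k - 1L), u(k - 1L)), ed(m(k - 1L), u(k))))
  }
  for (i in seq_len(k)) {
    edges <- c(edges, list(
      ed(u(i), lxp(i)), ed(u(i), g(i)),
      ed(g(i), lxpp(i)), ed(g(i), r(i)),
      ed(r(i), lx(i)),
      ed(cc(i), r(i))))
    edges <- c(edges, list(if (i < k) ed(cc(i), cc(i + 1L)) else ed(cc(k), lx(0))))
  }
  leaf_ids <- c(lx(0:k), lxp(seq_len(k)), lxpp(seq_len(k)))
  taxon <- c(paste0("x", 0:k), paste0("x", seq_len(k), "p"),
             paste0("x", seq_len(k), "pp"))
  net <- phynet(do.call(rbind, edges), stats::setNames(taxon, leaf_ids))

  f <- stats::setNames(rep("0", length(taxon)), taxon)
  f[paste0("x", 0:k)] <- "1"
  f <- as_phychar(f)

  retics <- canon_sort(reticulations(net))
  good_pick <- vapply(retics, function(v) grep("^c", np_parents(net, v), value = TRUE), character(1))
  bad_pick <- vapply(retics, function(v) grep("^g", np_parents(net, v), value = TRUE), character(1))
  t_good <- switching_tree(net, new_switching(stats::setNames(good_pick, retics), net))$tree
  t_bad <- switching_tree(net, new_switching(stats::setNames(bad_pick, retics), net))$tree

  if (k <= 5L) {
    sw_score <- softwired_score(net, f)
    stopifnot(sw_score == 1L,
              parsimony_score(t_good, f) == 1L,
              parsimony_score(t_bad, f) == (k + 1L) * sw_score)
  }
  list(network = net, char = f, t_good = t_good, t_bad = t_bad)
}

#' Parental-gap family: no constant-factor bound for parental parsimony
#'
#' A level-1 single-blob network on n+1 leaves (n even) with an
#' alternating binary character. Its parental parsimony score is 1
#' because the MUL-tree unfolding duplicates the caterpillar below the
#' reticulation, letting odd- and even-state leaves be split into two
#' clean clades, while every displayed tree is the caterpillar itself
#' and scores n/2. The softwired-style factor (k+1) = 2 therefore fails
#' for parental parsimony as n grows.
#'
#' @param n an even integer >= 4; the network has n+1 leaves.
#' @return A list with `network` and `char`.
#' @export
parental_gap_network <- function(n) {
  if (!is.numeric(n) || n < 4 || n %% 2 != 0)
    np_validation_error("n must be an even integer >= 4")
  n <- as.integer(n)
  d <- function(i) sprintf("d%d", i)
  lx <- function(i) sprintf("x%d", i)
  edges <- list(c("rho", "s"), c("s", "r"), c("s", "a"),
                c("a", lx(n + 1L)), c("a", "r"), c("r", d(1)))
  for (i in seq_len(n - 2L)) edges <- c(edges, list(c(d(i), lx(i)), c(d(i), d(i + 1L))))
  edges <- c(edges, list(c(d(n - 1L), lx(n - 1L)), c(d(n - 1L), lx(n))))
  leaf_ids <- lx(seq_len(n + 1L))
  net <- phynet(do.call(rbind, edges),
                stats::setNames(paste0("x", seq_len(n + 1L)), leaf_ids))
  f <- stats::setNames(ifelse(seq_len(n + 1L) %% 2L == 1L, "1", "0"),
                       paste0("x", seq_len(n + 1L)))
  list(network = net, char = as_phychar(f))
}

#' Random level-k networks, characters and alignments
#'
#' `random_network()` grows a random binary tree on the requested leaves
#' and then adds `h` reticulations one at a time by subdividing two
#' comparable-free edges and joining them, rejection-sampling until the
#' result validates and its level does not exceed `k`. The sampler makes
#' no uniformity claim; it exists to exercise properties on a broad set
#' of valid instances. Seeds are mandatory: all randomness is local and
#' reproducible.
#'
#' @param n_leaves number of taxa (>= 2).
#' @param k maximum level allowed.
#' @param h number of reticulations (h >= k needed only when k > 0;
#'   h = 0 gives a random tree).
#' @param seed integer seed.
#' @param taxa optional taxon names (defaults to t1, t2, ...).
#' @param max_tries rejection-sampling budget per reticulation.
#' @return A [phynet] with exactly `h` reticulations and level at most `k`.
#' @export
random_network <- function(n_leaves, k, h, seed, taxa = NULL, max_tries = 2000L) {
  if (n_leaves < 2L) np_validation_error("need at least two leaves")
  if (h > 0L && k < 1L) np_validation_error("h > 0 requires k >= 1")
  if (is.null(taxa)) taxa <- paste0("t", seq_len(n_leaves))
  with_seed(seed, {
    for (restart in seq_len(5L)) {
      net <- random_tree_edges(n_leaves, taxa)
      added <- 0L
      tries <- 0L
      while (added < h && tries <= max_tries) {
        tries <- tries + 1L
        cand <- try_add_reticulation(net, k)
        if (!is.null(cand)) {
          net <- cand
          added <- added + 1L
          tries <- 0L
        }
      }
      if (added == h) return(net)
    }
    np_validation_error("could not place the requested reticulations within the retry budget")
  })
}

random_tree_edges <- function(n_leaves, taxa) {
  ids <- paste0("L", seq_len(n_leaves))
  labels <- stats::setNames(taxa, ids)
  avail <- ids
  cnt <- 0L
  edges <- NULL
  while (length(avail) > 1L) {
    pick <- sample(length(avail), 2L)
    cnt <- cnt + 1L
    v <- sprintf("i%d", cnt)
    edges <- rbind(edges, c(v, avail[pick[1L]]), c(v, avail[pick[2L]]))
    avail <- c(avail[-pick], v)
  }
  edges <- rbind(edges, c("rho", avail))
  phynet(edges, labels)
}

## subdivide edge e1 with a new tree vertex and e2 with a new
## reticulation, join them; NULL when the result would contain a cycle
## or exceed the level budget. Degree validity holds by construction, so
## only acyclicity (checked cheaply up front) and the level need work.
try_add_reticulation <- function(net, k) {
  m <- nrow(net$edges)
  i1 <- sample(m, 1L); i2 <- sample(m, 1L)
  if (i1 == i2) return(NULL)
  e1 <- net$edges[i1, ]; e2 <- net$edges[i2, ]
  ## the new arc runs from inside e1 into inside e2: a directed cycle
  ## arises iff e2's head already reaches e1's tail
  if (e1[[1L]] %in% reachable_from(net, e2[[2L]])) return(NULL)
  nv <- sprintf("a%d", nrow(net$edges))
  nr <- sprintf("b%d", nrow(net$edges))
  edges <- net$edges[-c(i1, i2), , drop = FALSE]
  edges <- rbind(edges,
                 c(e1[[1L]], nv), c(nv, e1[[2L]]),
                 c(e2[[1L]], nr), c(nr, e2[[2L]]),
                 c(nv, nr))
  if (level_of_edges(edges) > k) return(NULL)
  phynet(edges, net$labels)
}

#' @rdname random_network
#' @param r number of states (`r <=` number of taxa so the character can
#'   be surjective).
#' @export
random_character <- function(taxa, r, seed) {
  if (r > length(taxa)) np_validation_error("r cannot exceed the number of taxa")
  states <- as.character(seq_len(r) - 1L)
  with_seed(seed, {
    repeat {
      f <- sample(states, length(taxa), replace = TRUE)
      if (length(unique(f)) == r) break
    }
    as_phychar(stats::setNames(f, taxa))
  })
}

#' @rdname random_network
#' @param n_sites number of alignment sites.
#' @export
random_alignment <- function(taxa, n_sites, r, seed) {
  sites <- lapply(seq_len(n_sites), function(i)
    random_character(taxa, r, seed + 7919L * i))
  phyalign(sites)
}
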
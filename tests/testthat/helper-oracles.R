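## Independent oracles used to check the implementation. These share no
## code path with the functions they verify.

## Minimum changing number by exhaustive search over all assignments of
## observed states to internal vertices.
brute_parsimony <- function(S, f) {
  f <- netpars::as_phychar(f)
  states <- sort(unique(unname(f)), method = "radix")
  r <- length(states)
  leaf_state <- stats::setNames(unname(f[unname(S$labels)]), names(S$labels))
  internal <- setdiff(S$vertices, names(S$labels))
  n <- length(internal)
  from <- S$edges[, 1L]
  to <- S$edges[, 2L]
  best <- Inf
  idx <- rep(1L, n)
  repeat {
    F <- c(leaf_state, stats::setNames(states[idx], internal))
    best <- min(best, sum(F[from] != F[to]))
    j <- 1L
    while (j <= n && idx[j] == r) { idx[j] <- 1L; j <- j + 1L }
    if (j > n) break
    idx[j] <- idx[j] + 1L
  }
  as.integer(best)
}

## Biconnected components by cycle equivalence: two edges belong to the
## same component iff some simple cycle contains both (bridges stay
## alone). Exponential path enumeration; only for tiny graphs.
brute_blobs <- function(net) {
  edges <- net$edges
  m <- nrow(edges)
  parent <- seq_len(m)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  adj <- lapply(unique(c(edges)), function(v) which(edges[, 1L] == v | edges[, 2L] == v))
  names(adj) <- unique(c(edges))
  other <- function(ei, v) if (edges[ei, 1L] == v) edges[ei, 2L] else edges[ei, 1L]
  for (e in seq_len(m)) {
    a <- edges[e, 1L]; b <- edges[e, 2L]
    stack <- list(list(v = a, used = integer(0), vis = a))
    while (length(stack)) {
      st <- stack[[length(stack)]]; stack <- stack[-length(stack)]
      if (st$v == b) {
        for (ei in st$used) { ra <- find(e); rb <- find(ei); parent[ra] <- rb }
        next
      }
      for (ei in adj[[st$v]]) {
        if (ei == e || ei %in% st$used) next
        w <- other(ei, st$v)
        if (w %in% st$vis && w != b) next
        stack[[length(stack) + 1L]] <- list(v = w, used = c(st$used, ei),
                                            vis = c(st$vis, w))
      }
    }
  }
  cls <- split(seq_len(m), vapply(seq_len(m), find, integer(1)))
  indeg <- table(factor(edges[, 2L], levels = unique(c(edges))))
  out <- list()
  for (cl in cls) {
    heads <- edges[cl, 2L]
    vs <- unique(c(edges[cl, , drop = FALSE]))
    retics <- vs[indeg[vs] == 2L &
                   vapply(vs, function(v) sum(heads == v) == 2L, logical(1))]
    if (!length(retics)) next
    src <- vs[vapply(vs, function(v) sum(heads == v) == 0L, logical(1))]
    out[[length(out) + 1L]] <- list(
      vertices = sort(vs, method = "radix"),
      source = src, n_ret = length(retics))
  }
  ord <- order(vapply(out, function(b) b$source, character(1)), method = "radix")
  out[ord]
}

## softwired score by switching enumeration + brute-force extension
## minima (independent of the Fitch DP)
brute_softwired <- function(net, f) {
  min(vapply(netpars::display_set(net), brute_parsimony, integer(1), f = f))
}

## random subdivision of a tree: subdivide `extra` randomly chosen edges
random_subdivision <- function(tr, extra, seed) {
  set.seed(seed)
  edges <- tr$edges
  for (j in seq_len(extra)) {
    i <- sample(nrow(edges), 1L)
    v <- sprintf("sub%d", j)
    e <- edges[i, ]
    edges <- rbind(edges[-i, , drop = FALSE], c(e[[1L]], v), c(v, e[[2L]]))
  }
  netpars::physub(edges, tr$labels)
}

## deterministic small instance pool shared by several property tests
random_net_char <- function(i, nl_base = 4L, k_mod = 3L) {
  nl <- nl_base + (i %% 4L)
  k <- 1L + (i %% k_mod)
  net <- random_network(nl, k, k, seed = 5000L + i)
  f <- random_character(taxa(net), 2L + (i %% 2L), seed = 6000L + i)
  list(net = net, f = f)
}

## does a rooted network deroot (directions dropped) to exactly this
## simple unrooted network? Parallel pairs mean "no".
net_isomorphic_unet <- function(N, U) {
  ds <- tryCatch(netpars::as_unet(N), netpars_error = function(e) NULL)
  if (is.null(ds)) return(FALSE)
  pal <- sort(unname(U$labels), method = "radix")
  mk <- function(x) {
    g <- igraph::graph_from_edgelist(x$edges, directed = FALSE)
    nm <- igraph::V(g)$name
    col <- integer(length(nm))
    lf <- nm %in% names(x$labels)
    col[lf] <- match(x$labels[nm[lf]], pal)
    list(g = g, col = col)
  }
  a <- mk(ds); b <- mk(U)
  igraph::vcount(a$g) == igraph::vcount(b$g) &&
    igraph::ecount(a$g) == igraph::ecount(b$g) &&
    igraph::is_isomorphic_to(a$g, b$g, method = "vf2",
                             vertex.color1 = a$col, vertex.color2 = b$col)
}
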
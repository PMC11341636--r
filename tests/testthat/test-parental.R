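test_that("unfolding a tree reproduces the tree; paths multiply through reticulations", {
  tr <- random_network(5, 0, 0, seed = 41)
  U <- unfold_multree(tr)
  expect_equal(sort(unname(U$labels)), taxa(tr))
  expect_true(all(leaf_copies(U) == 1L))

  pg <- parental_gap_network(6)$network
  U6 <- unfold_multree(pg)
  expect_equal(length(U6$labels), 13L)
  copies <- leaf_copies(U6)
  expect_equal(as.integer(copies[paste0("x", 1:6)]), rep(2L, 6L))
  expect_equal(unname(copies[["x7"]]), 1L)
})

test_that("a leaf below two stacked reticulations gets four copies", {
  net <- phynet(rbind(
    c("rho", "t"), c("t", "u1"), c("t", "u2"),
    c("u1", "a"), c("u1", "r1"), c("u2", "r1"), c("u2", "b"),
    c("r1", "w"), c("w", "v1"), c("w", "v2"),
    c("v1", "c"), c("v1", "r2"), c("v2", "r2"), c("v2", "d"),
    c("r2", "z")),
    stats::setNames(c("a", "b", "c", "d", "z"), c("a", "b", "c", "d", "z")))
  U <- unfold_multree(net)
  expect_equal(unname(leaf_copies(U)[["z"]]), 4L)
})

test_that("restrictions produce trees; the odd/even split realises the gap", {
  pg <- parental_gap_network(6)
  U <- unfold_multree(pg$network)
  ## copy 1 descends through the first-found path; picking odd taxa from
  ## one copy and even from the other separates the states into clades
  for (flip in c(0L, 1L)) {
    sigma <- stats::setNames(
      ifelse(seq_len(7L) %% 2L == flip, 1L, 2L), paste0("x", 1:7))
    sigma["x7"] <- 1L
    tr <- restriction_tree(U, sigma)
    expect_s3_class(tr, "phynet")
    expect_equal(n_reticulations(tr), 0L)
    expect_setequal(taxa(tr), taxa(pg$network))
    if (parsimony_score(tr, pg$char) == 1L) {
      ## odd and even leaves form clean clusters in this tree
      clusters <- lapply(tr$vertices, function(v) descendant_cluster(tr, v))
      expect_true(any(vapply(clusters, setequal, logical(1),
                             y = c("x1", "x3", "x5"))) ||
                  any(vapply(clusters, setequal, logical(1),
                             y = c("x2", "x4", "x6"))))
    }
  }
  ## all taxa from the same copy gives a displayed tree
  sigma1 <- stats::setNames(rep(1L, 7L), paste0("x", 1:7))
  expect_true(cnewick(restriction_tree(U, sigma1)) %in%
                names(display_set(pg$network)))
  expect_error(restriction_tree(U, sigma1[-1L]), class = "netpars_taxon_error")
  expect_error(restriction_tree(U, stats::setNames(c(3L, rep(1L, 6L)),
                                                   paste0("x", 1:7))),
               class = "netpars_validation_error")
})

test_that("parental trees contain the display set, sometimes strictly", {
  tr <- random_network(5, 0, 0, seed = 42)
  expect_equal(names(parental_trees(tr)), names(display_set(tr)))

  pg <- parental_gap_network(6)$network
  expect_gt(length(parental_trees(pg)), length(display_set(pg)))

  rc <- retic_cherry_net()
  P <- names(parental_trees(rc))
  D <- names(display_set(rc))
  expect_true(all(D %in% P))
  expect_gt(length(setdiff(P, D)), 0L)

  for (i in 1:8) {
    net <- random_network(4L + i %% 3L, 1L + i %% 2L, 1L + i %% 2L,
                          seed = 4200L + i)
    expect_true(all(names(display_set(net)) %in% names(parental_trees(net))))
  }
})

test_that("is_parental distinguishes members from non-members", {
  rc <- retic_cherry_net()
  P <- parental_trees(rc)
  expect_true(is_parental(rc, P[[1L]]))
  outsider <- read_enewick("((((x1,x4),x2),x3));")
  expect_equal(is_parental(rc, outsider),
               cnewick(outsider) %in% names(P))
})

test_that("parental score: tree case, the gap family, and the softwired bound", {
  tr <- random_network(5, 0, 0, seed = 43)
  f <- random_character(taxa(tr), 2L, seed = 44)
  expect_equal(parental_score(tr, f), parsimony_score(tr, f))

  pg <- parental_gap_network(6)
  expect_equal(parental_score(pg$network, pg$char), 1L)

  for (i in 1:10) {
    net <- random_network(4L + i %% 3L, 1L + i %% 2L, 1L + i %% 2L,
                          seed = 4300L + i)
    f <- random_character(taxa(net), 2L, seed = 4310L + i)
    expect_lte(parental_score(net, f), softwired_score(net, f))
  }
})

test_that("no constant-factor bound holds for parental parsimony", {
  for (n in c(6L, 8L, 10L)) {
    pg <- parental_gap_network(n)
    ps_pa <- parental_score(pg$network, pg$char)
    expect_equal(ps_pa, 1L)
    min_displayed <- min(vapply(display_set(pg$network), parsimony_score,
                                numeric(1), f = pg$char))
    expect_equal(min_displayed, n / 2L)
    expect_gt(min_displayed, 2L * ps_pa)
  }
})

test_that("restrictions equal the subgraph-then-suppress route on a small case", {
  ## independent oracle: enumerate all leaf-copy subsets directly on the
  ## unfolding's edge structure
  rc <- retic_cherry_net()
  U <- unfold_multree(rc)
  got <- names(parental_trees(rc))
  xs <- sort(unique(unname(U$labels)))
  parents <- stats::setNames(U$edges[, 1L], U$edges[, 2L])
  all_keys <- character(0)
  combos <- expand.grid(lapply(xs, function(x)
    names(U$labels)[U$labels == x]), stringsAsFactors = FALSE)
  for (j in seq_len(nrow(combos))) {
    keep <- character(0)
    for (lf in as.character(combos[j, ])) {
      v <- lf
      while (!v %in% keep) {
        keep <- c(keep, v)
        if (!v %in% names(parents)) break
        v <- parents[[v]]
      }
    }
    edges <- U$edges[U$edges[, 2L] %in% keep & U$edges[, 1L] %in% keep, ,
                     drop = FALSE]
    labels <- stats::setNames(unname(U$labels[as.character(combos[j, ])]),
                              as.character(combos[j, ]))
    all_keys <- c(all_keys, cnewick(suppress_subdivision(physub(edges, labels))))
  }
  expect_setequal(unique(all_keys), got)
})
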
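test_that("network construction validates degree and acyclicity rules", {
  n1 <- phynet(rbind(c("rho", "x")), c(x = "x"))
  expect_s3_class(n1, "phynet")
  expect_equal(n_reticulations(n1), 0L)

  sharp <- sharp_level_k(1)$network
  expect_equal(n_reticulations(sharp), 1L)
  expect_length(taxa(sharp), 4L)

  expect_error(phynet(rbind(c("a", "b"), c("a", "b")), c(b = "b")),
               "parallel edges", class = "netpars_validation_error")
  expect_error(phynet(rbind(c("a", "a")), c(a = "a")),
               "loops", class = "netpars_validation_error")
  expect_error(
    phynet(rbind(c("r", "a"), c("r", "b")), c(a = "a", b = "b")),
    "root out-degree", class = "netpars_validation_error")
  expect_error(
    phynet(rbind(c("r", "v"), c("v", "a"), c("v", "b"), c("v", "c")),
           c(a = "a", b = "b", c = "c")),
    "tree vertices", class = "netpars_validation_error")
  expect_error(
    phynet(rbind(c("r", "v"), c("v", "a"), c("v", "b")),
           c(a = "t", b = "t")),
    "duplicate taxon", class = "netpars_validation_error")
  expect_error(
    phynet(rbind(c("r", "v"), c("v", "a"), c("v", "b")), c(a = "a")),
    "no taxon label", class = "netpars_validation_error")
  ## a directed cycle: u -> v -> w -> u plus decoration cannot validate
  expect_error(
    phynet(rbind(c("u", "v"), c("v", "w"), c("w", "u")), character(0)),
    class = "netpars_validation_error")
})

test_that("edge count equals vertex count - 1 + h on generated networks", {
  for (i in 1:25) {
    net <- random_network(4L + i %% 5L, 1L + i %% 3L, 1L + i %% 3L, seed = i)
    expect_equal(nrow(net$edges),
                 length(net$vertices) - 1L + n_reticulations(net))
  }
})

test_that("blob decomposition agrees with the cycle-equivalence oracle", {
  check_against_oracle <- function(net) {
    got <- blobs(net)
    want <- brute_blobs(net)
    expect_equal(length(got), length(want))
    for (j in seq_along(got)) {
      expect_equal(got[[j]]$vertices, want[[j]]$vertices)
      expect_equal(got[[j]]$source, want[[j]]$source)
      expect_equal(got[[j]]$n_ret, want[[j]]$n_ret)
    }
  }
  check_against_oracle(sharp_level_k(2)$network)
  check_against_oracle(parental_gap_network(6)$network)
  check_against_oracle(chained_cycles())
  for (i in 1:15) {
    net <- random_network(4L + i %% 3L, 1L + i %% 2L, 1L + i %% 3L, seed = 100L + i)
    if (length(net$vertices) <= 20L) check_against_oracle(net)
  }
})

test_that("blob counts on the example families are as constructed", {
  expect_equal(length(blobs(sharp_level_k(2)$network)), 1L)
  expect_equal(blobs(sharp_level_k(2)$network)[[1L]]$n_ret, 2L)
  bl <- blobs(parental_gap_network(6)$network)
  expect_equal(length(bl), 1L)
  expect_equal(bl[[1L]]$n_ret, 1L)
  expect_equal(length(blobs(random_network(5, 0, 0, seed = 1))), 0L)
})

test_that("level is the tight maximum of blob reticulation counts", {
  expect_equal(network_level(random_network(6, 0, 0, seed = 2)), 0L)
  expect_equal(network_level(sharp_level_k(3)$network), 3L)
  expect_equal(network_level(chained_cycles()), 1L)
  expect_equal(n_reticulations(chained_cycles()), 2L)
})

test_that("clusters collect exactly the descendant taxa", {
  sh <- sharp_level_k(1)$network
  expect_equal(descendant_cluster(sh, names(sh$labels)[1L]),
               unname(sh$labels[1L]))
  expect_equal(descendant_cluster(sh, sh$root), taxa(sh))
  expect_equal(descendant_cluster(sh, "c1"), c("x0", "x1"))
  expect_error(descendant_cluster(sh, "nope"), "unknown vertex",
               class = "netpars_validation_error")
})

test_that("blob children are the out-of-blob successors", {
  pg <- parental_gap_network(6)$network
  B <- blobs(pg)[[1L]]
  expect_setequal(blob_children(pg, B), c("x7", "d1"))
  sh <- sharp_level_k(1)$network
  expect_setequal(blob_children(sh, blobs(sh)[[1L]]),
                  c("x0", "x1", "xp1", "xpp1"))
  expect_error(blob_children(pg, blobs(sh)[[1L]]),
               class = "netpars_validation_error")
})

test_that("maximal blob is the lowest one, ties broken canonically", {
  sh <- sharp_level_k(2)$network
  expect_equal(maximal_blob(sh)$source, blobs(sh)[[1L]]$source)
  ch <- chained_cycles()
  expect_equal(maximal_blob(ch)$source, "s2")
  expect_error(maximal_blob(random_network(4, 0, 0, seed = 3)),
               class = "netpars_validation_error")
})

test_that("incomparable blobs: the canonically smallest source wins", {
  ## two disjoint cycles hanging off the two root-child subtrees
  net <- phynet(rbind(
    c("rho", "t"), c("t", "s1"), c("t", "s2"),
    c("s1", "a1"), c("a1", "x1"), c("a1", "r1"),
    c("s1", "b1"), c("b1", "x2"), c("b1", "r1"), c("r1", "x3"),
    c("s2", "a2"), c("a2", "x4"), c("a2", "r2"),
    c("s2", "b2"), c("b2", "x5"), c("b2", "r2"), c("r2", "x6")),
    stats::setNames(paste0("x", 1:6), paste0("x", 1:6)))
  expect_equal(network_level(net), 1L)
  expect_equal(maximal_blob(net)$source, "s1")
})

test_that("embeddings are recognised and switching embeddings qualify", {
  tr <- random_network(5, 0, 0, seed = 9)
  expect_true(is_embedding(as_physub(tr), tr, tr))
  sh <- sharp_level_k(2)$network
  for (sw in switchings(sh)) {
    st <- switching_tree(sh, sw)
    expect_true(is_embedding(st$embedding, sh, st$tree))
  }
  ## a subdivision not containing the network root is no embedding
  st <- switching_tree(sh, switchings(sh)[[1L]])
  emb <- st$embedding
  path <- root_path(emb)
  chain <- path[-length(path)]                       # root-side chain vertices
  rewired <- emb$edges[!emb$edges[, 1L] %in% chain, , drop = FALSE]
  rewired <- rbind(c("z", path[length(path)]), rewired)
  sub <- physub(rewired, emb$labels)
  expect_false(is_embedding(sub, sh, st$tree))
})

test_that("children of a blob lie on every embedding (with blob sources as entry points)", {
  for (i in 1:12) {
    net <- random_network(4L + i %% 4L, 1L + i %% 3L, min(3L, 1L + i %% 3L),
                          seed = 300L + i)
    bl <- blobs(net)
    sources <- vapply(bl, function(b) b$source, character(1))
    for (sw in switchings(net)) {
      emb <- switching_tree(net, sw)$embedding
      for (B in bl) {
        kids <- blob_children(net, B)
        expect_true(all(kids %in% emb$vertices))
        for (v in kids) {
          inblob <- vapply(bl, function(b) v %in% b$vertices, logical(1))
          if (any(inblob)) expect_true(v %in% sources)
        }
      }
    }
  }
})
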
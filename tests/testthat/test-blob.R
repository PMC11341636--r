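## embedding of a displayed tree chosen deterministically
first_embedding <- function(net) {
  switching_tree(net, switchings(net)[[1L]])$embedding
}

test_that("the blob indicator reads the states of the blob's children", {
  net <- two_blob_net()
  f <- two_blob_char()
  bl <- blobs(net)
  upper <- bl[[which(vapply(bl, function(b) b$source, character(1)) == "s1")]]
  lower <- bl[[which(vapply(bl, function(b) b$source, character(1)) == "s2")]]
  S <- first_embedding(net)
  exts <- min_extensions(S, f)
  ## the lower blob's children are leaves with both states: always 1
  for (F in exts) expect_equal(blob_indicator(F, net, lower, S), 1L)
  ## some minimum extension assigns all of the upper blob's children 0
  ind_upper <- vapply(exts, blob_indicator, integer(1), net = net,
                      B = upper, S = S)
  expect_true(any(ind_upper == 0L))
  ## constant extensions always give indicator 0
  F0 <- stats::setNames(rep("0", length(S$vertices)), S$vertices)
  expect_equal(blob_indicator(F0, net, upper, S), 0L)
})

test_that("informative blob counts: constants, trees and the sharp family", {
  tr <- random_network(6, 0, 0, seed = 31)
  S0 <- as_physub(tr)
  f0 <- stats::setNames(rep("0", 6L), taxa(tr))
  expect_equal(informative_blob_count(f0, tr, S0)$count, 0L)

  net <- two_blob_net()
  res <- informative_blob_count(two_blob_char(), net, first_embedding(net))
  expect_equal(res$count, 1L)
  expect_equal(changing_number(res$extension, first_embedding(net)),
               parsimony_score(first_embedding(net), two_blob_char()))

  sh <- sharp_level_k(1)
  retic <- reticulations(sh$network)
  good <- new_switching(stats::setNames("c1", retic), sh$network)
  S <- switching_tree(sh$network, good)$embedding
  expect_equal(informative_blob_count(sh$char, sh$network, S)$count, 1L)
})

test_that("informative blob count is zero when the score is zero", {
  for (i in 1:10) {
    net <- random_network(4L + i %% 3L, 1L, 1L, seed = 3100L + i)
    f0 <- stats::setNames(rep("0", length(taxa(net))), taxa(net))
    S <- first_embedding(net)
    expect_equal(informative_blob_count(f0, net, S)$count, 0L)
  }
})

test_that("informative blobs each contribute a change: b <= PS", {
  for (i in 1:15) {
    net <- random_network(4L + i %% 4L, 1L + i %% 3L, 1L + i %% 3L,
                          seed = 3200L + i)
    f <- random_character(taxa(net), 2L, seed = 3210L + i)
    S <- first_embedding(net)
    expect_lte(informative_blob_count(f, net, S)$count, parsimony_score(S, f))
  }
})

test_that("blob reduction splits the chained network at the lower blob", {
  net <- chained_cycles()
  B <- maximal_blob(net)
  expect_equal(B$source, "s2")
  res <- blob_reduce(net, B)
  expect_setequal(res$Y, c("x1", "x2", "x3"))
  expect_setequal(taxa(res$below), c("x1", "x2", "x3"))
  expect_setequal(taxa(res$above), c("x4", "x5", "x6", "x7", "x8", res$y))
  expect_equal(n_reticulations(res$below), 1L)
  expect_equal(length(blobs(res$above)), length(blobs(net)) - 1L)
  expect_lte(network_level(res$below), network_level(net))
  ## reducing the upper (non-maximal) blob is refused
  upper <- blobs(net)[[which(vapply(blobs(net), function(b) b$source,
                                    character(1)) == "s1")]]
  expect_error(blob_reduce(net, upper), "not maximal",
               class = "netpars_validation_error")
})

test_that("a blob directly below the root reduces to a trivial 'above' part", {
  sh <- sharp_level_k(2)$network
  res <- blob_reduce(sh, maximal_blob(sh))
  expect_equal(taxa(res$above), res$y)          # single-leaf network
  expect_true(net_isomorphic(res$below, sh))    # below is N itself (re-rooted)
})

test_that("cluster tree pairs mirror the reduction and reassemble", {
  net <- chained_cycles()
  B <- maximal_blob(net)
  S <- first_embedding(net)
  pair <- cluster_tree_pair(S, B)
  expect_setequal(taxa(pair$SY), c("x1", "x2", "x3"))
  expect_setequal(taxa(pair$SYbar), c("x4", "x5", "x6", "x7", "x8", pair$y))
  ## reassembly: edge sets glue back to S
  glued <- rbind(pair$SY$edges[pair$SY$edges[, 1L] != pair$rho_Y, , drop = FALSE],
                 `[<-`(pair$SYbar$edges, pair$SYbar$edges == pair$y, B$source))
  expect_setequal(paste(glued[, 1L], glued[, 2L]),
                  paste(S$edges[, 1L], S$edges[, 2L]))
  expect_error(cluster_tree_pair(as_physub(random_network(4, 0, 0, seed = 33)), B),
               class = "netpars_validation_error")
})

test_that("split and merge of extensions are exactly additive inverses", {
  for (i in 1:50) {
    net <- random_network(4L + i %% 5L, 1L + i %% 3L, 1L + i %% 3L,
                          seed = 3300L + i)
    if (!length(blobs(net))) next
    B <- maximal_blob(net)
    S <- first_embedding(net)
    if (!B$source %in% S$vertices) next
    f <- random_character(taxa(net), 2L + i %% 2L, seed = 3310L + i)
    ## a random (not necessarily minimum) extension
    states <- sort(unique(unname(f)))
    set.seed(3320L + i)
    F <- stats::setNames(sample(states, length(S$vertices), replace = TRUE),
                         S$vertices)
    F[names(S$labels)] <- f[unname(S$labels)]
    pair <- cluster_tree_pair(S, B)
    exts <- split_extension(F, pair)
    expect_equal(changing_number(F, S),
                 changing_number(exts$FY, pair$SY) +
                   changing_number(exts$FYbar, pair$SYbar))
    merged <- merge_extension(exts, pair)
    expect_equal(changing_number(merged, S), changing_number(F, S))
  }
})

test_that("merging rejects pairs violating the gluing invariant", {
  net <- chained_cycles()
  B <- maximal_blob(net)
  S <- first_embedding(net)
  pair <- cluster_tree_pair(S, B)
  F <- stats::setNames(rep("0", length(S$vertices)), S$vertices)
  F[names(S$labels)] <- "0"
  exts <- split_extension(F, pair)
  exts$FYbar[[pair$y]] <- "1"
  expect_error(merge_extension(exts, pair), class = "netpars_validation_error")
})

test_that("any embedding is within k informative blobs of an optimal one", {
  ## single-blob networks: PS(f,S) <= PS(f,S') + k * b(f,N,S') where S'
  ## attains the softwired optimum
  for (i in 1:20) {
    net <- random_network(4L + i %% 4L, 1L + i %% 3L, 1L + i %% 3L,
                          seed = 3400L + i)
    if (length(blobs(net)) != 1L) next
    k <- network_level(net)
    f <- random_character(taxa(net), 2L, seed = 3410L + i)
    embs <- lapply(switchings(net), function(sw) switching_tree(net, sw)$embedding)
    scores <- vapply(embs, parsimony_score, integer(1), f = f)
    Sopt <- embs[[which.min(scores)]]
    b <- informative_blob_count(f, net, Sopt)$count
    for (S in embs)
      expect_lte(parsimony_score(S, f), min(scores) + k * b)
  }
})
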
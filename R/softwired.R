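#' Switchings of a network
#'
#' A switching picks, for each reticulation, exactly one of its two
#' incoming edges; deleting the other edges and cleaning up yields a
#' displayed tree, and every displayed tree arises this way. A network
#' with h reticulations has 2^h switchings; enumeration is guarded.
#'
#' @param net a [phynet].
#' @param guard maximum number of reticulations for enumeration.
#' @return A list of switchings. Each switching is a named character
#'   vector mapping each reticulation to the chosen parent (the tail of
#'   the kept incoming edge); attribute `"host"` records the host edges.
#' @export
switchings <- function(net, guard = 20L) {
  h <- n_reticulations(net)
  if (h > guard)
    np_guard_error(sprintf("network has %d reticulations; 2^%d switchings exceed the guard", h, h))
  retics <- canon_sort(reticulations(net))
  if (!h) return(list(new_switching(character(0), net)))
  choices <- lapply(retics, function(r) np_parents(net, r))  # already sorted
  lapply(seq_len(2^h) - 1L, function(idx) {
    bits <- (idx %/% 2^(seq_len(h) - 1L)) %% 2L      # retic 1 least significant
    pick <- vapply(seq_len(h), function(j) choices[[j]][bits[j] + 1L], character(1))
    new_switching(stats::setNames(pick, retics), net)
  })
}

#' @rdname switchings
#' @param choice named character vector mapping each reticulation of
#'   `net` to the parent whose edge the switching keeps.
#' @export
new_switching <- function(choice, net) {
  structure(choice, class = "switching", host = net$edges)
}

#' @export
print.switching <- function(x, ...) {
  if (!length(x)) cat("switching: (empty; host is a tree)\n")
  else cat("switching:", paste(sprintf("%s<-%s", names(x), unname(x)), collapse = " "), "\n")
  invisible(x)
}

#' Displayed tree yielded by a switching
#'
#' Deletes each reticulation edge not chosen by the switching, removes
#' vertices without leaf descendants, and suppresses subdivision
#' vertices. Returns both the phylogenetic X-tree and the embedding (the
#' subdivision inside the network, before suppression).
#'
#' @param net a [phynet].
#' @param sw a switching of `net` from [switchings()].
#' @return A list with components `tree` (a [phynet] without
#'   reticulations) and `embedding` (a [physub] whose vertices are
#'   vertices of `net`).
#' @export
switching_tree <- function(net, sw) {
  if (!identical(attr(sw, "host"), net$edges))
    np_validation_error("switching does not belong to this network")
  edges <- net$edges
  for (r in names(sw)) {
    drop <- edges[, 2L] == r & edges[, 1L] != sw[[r]]
    edges <- edges[!drop, , drop = FALSE]
  }
  ## restrict to vertices with a leaf descendant (the root always has one)
  repeat {
    vertices <- unique(c(edges))
    outdeg <- tabulate_degree(edges[, 1L], vertices)
    dangling <- vertices[outdeg == 0L & !vertices %in% names(net$labels)]
    if (!length(dangling)) break
    edges <- edges[!edges[, 2L] %in% dangling, , drop = FALSE]
  }
  S <- physub(edges, net$labels)
  list(tree = suppress_subdivision(S), embedding = S)
}

#' Display set of a network
#'
#' All phylogenetic X-trees displayed by the network, deduplicated by
#' canonical Newick over all switchings.
#'
#' @inheritParams switchings
#' @return A named list of trees ([phynet] objects without
#'   reticulations); names are canonical Newick strings.
#' @export
display_set <- function(net, guard = 20L) {
  sws <- switchings(net, guard)
  out <- list()
  for (sw in sws) {
    tr <- switching_tree(net, sw)$tree
    key <- cnewick(tr)
    if (is.null(out[[key]])) out[[key]] <- tr
  }
  out[canon_sort(names(out))]
}

#' Softwired parsimony score
#'
#' The softwired score minimises tree parsimony over the display set. In
#' `per_site` mode every alignment site may follow its own displayed
#' tree (the sum of per-site minima); in `single_tree` mode one tree must
#' serve the whole alignment (the minimum over trees of the total). The
#' per-site score never exceeds the single-tree score, and the two agree
#' on single-site alignments.
#'
#' @param x a [phynet], [semidnet] or [unet].
#' @param A a character (named vector) or a [phyalign].
#' @param mode `"per_site"` or `"single_tree"`.
#' @param guard passed to the display-set enumeration.
#' @param ... unused.
#' @return Non-negative integer.
#' @examples
#' sharp <- sharp_level_k(1)
#' softwired_score(sharp$network, sharp$char)
#' @export
softwired_score <- function(x, A, ...) UseMethod("softwired_score")

#' @rdname softwired_score
#' @export
softwired_score.phynet <- function(x, A, mode = c("per_site", "single_tree"),
                                   guard = 20L, ...) {
  mode <- match.arg(mode)
  A <- as_alignment(A)
  if (!setequal(taxa(x), rownames(A)))
    np_taxon_error("network taxa and alignment taxa differ")
  trees <- display_set(x, guard)
  per_tree <- vapply(trees, function(tr) {
    vapply(seq_len(ncol(A)), function(i)
      parsimony_score(tr, site_character(A, i)), numeric(1))
  }, numeric(ncol(A)))
  per_tree <- matrix(per_tree, nrow = ncol(A))   # sites x trees
  if (mode == "per_site") as.integer(sum(apply(per_tree, 1L, min)))
  else as.integer(min(colSums(per_tree)))
}

as_alignment <- function(A) {
  if (inherits(A, "phyalign")) A else phyalign(list(as_phychar(A)))
}

#' Approximate the softwired score from one displayed tree
#'
#' Scores the tree yielded by the canonical switching (for each
#' reticulation, the incoming edge with the canonically smallest tail).
#' For a level-k network the returned score is at most (k+1) times the
#' softwired score, so this is a polynomial (k+1)-approximation: no
#' display-set enumeration takes place. With a seed, a uniformly random
#' switching is used instead of the canonical one.
#'
#' @param net a [phynet].
#' @param A a character or [phyalign].
#' @param seed optional integer; if given, pick the switching at random.
#' @return A list with `tree` (the displayed tree scored), `score`, and
#'   `guarantee` = level(net) + 1.
#' @export
approx_softwired <- function(net, A, seed = NULL) {
  A <- as_alignment(A)
  if (!setequal(taxa(net), rownames(A)))
    np_taxon_error("network taxa and alignment taxa differ")
  retics <- canon_sort(reticulations(net))
  choice <- if (is.null(seed)) {
    vapply(retics, function(r) np_parents(net, r)[1L], character(1))
  } else {
    with_seed(seed, vapply(retics, function(r)
      sample(np_parents(net, r), 1L), character(1)))
  }
  sw <- new_switching(stats::setNames(choice, retics), net)
  tr <- switching_tree(net, sw)$tree
  score <- sum(vapply(seq_len(ncol(A)), function(i)
    parsimony_score(tr, site_character(A, i)), numeric(1)))
  list(tree = tr, score = as.integer(score),
       guarantee = network_level(net) + 1L)
}
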
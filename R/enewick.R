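#' Read a network from extended Newick
#'
#' Parses a single extended-Newick (eNewick) statement. Hybrid nodes are
#' written with `#H` tags; the two occurrences of a tag are merged into a
#' single reticulation vertex. Exactly one occurrence of each tag may
#' carry a subtree, the other is a leaf-like reference. Branch lengths and
#' internal labels are parsed and discarded (all scores in this package
#' are purely topological). If the parsed root has out-degree two, as in
#' most interchange files, an auxiliary root with out-degree one is
#' prepended; [write_enewick()] strips it again.
#'
#' @param text a string containing one eNewick statement ending in `;`.
#' @return A validated [phynet].
#' @examples
#' net <- read_enewick("((a,(x)#H1),(#H1,b));")
#' n_reticulations(net)
#' @export
read_enewick <- function(text) {
  text <- trimws(paste(text, collapse = ""))
  if (!nzchar(text) || !endsWith(text, ";"))
    np_parse_error("eNewick statement must end in ';'")
  st <- new.env(parent = emptyenv())
  st$s <- text
  st$pos <- 1L
  top <- parse_subtree(st)
  skip_ws(st)
  if (peek(st) != ";")
    np_parse_error(sprintf("unexpected character '%s' at position %d",
                           peek(st), st$pos))
  build_from_ast(top)
}

peek <- function(st) {
  if (st$pos > nchar(st$s)) np_parse_error("unexpected end of input")
  substr(st$s, st$pos, st$pos)
}

advance <- function(st) st$pos <- st$pos + 1L

skip_ws <- function(st) {
  while (st$pos <= nchar(st$s) && grepl("^[ \t\r\n]$", peek(st))) advance(st)
}

## label token: anything up to a structural character
read_token <- function(st) {
  start <- st$pos
  while (st$pos <= nchar(st$s) && !peek(st) %in% c("(", ")", ",", ";", ":"))
    advance(st)
  trimws(substr(st$s, start, st$pos - 1L))
}

parse_subtree <- function(st) {
  skip_ws(st)
  node <- list(children = list(), label = NULL, tag = NULL)
  if (peek(st) == "(") {
    advance(st)
    repeat {
      node$children <- c(node$children, list(parse_subtree(st)))
      skip_ws(st)
      if (peek(st) == ",") { advance(st); next }
      if (peek(st) == ")") { advance(st); break }
      np_parse_error(sprintf("expected ',' or ')' at position %d", st$pos))
    }
    tok <- read_token(st)
  } else {
    tok <- read_token(st)
    if (!nzchar(tok))
      np_parse_error(sprintf("expected a label at position %d", st$pos))
  }
  if (grepl("#", tok, fixed = TRUE)) {
    parts <- strsplit(tok, "#", fixed = TRUE)[[1L]]
    if (nzchar(parts[1L])) node$label <- parts[1L]
    node$tag <- paste0("#", parts[2L])
  } else if (nzchar(tok)) {
    node$label <- tok
  }
  skip_ws(st)
  if (st$pos <= nchar(st$s) && peek(st) == ":") {   # branch length: discard
    advance(st)
    len <- read_token(st)
    if (!grepl("^[-+0-9.eE]+$", len))
      np_parse_error(sprintf("malformed branch length at position %d", st$pos))
  }
  node
}

build_from_ast <- function(top) {
  env <- new.env(parent = emptyenv())
  env$edges <- character(0)
  env$labels <- character(0)
  env$counter <- 0L
  env$hybrid_id <- character(0)     # tag -> vertex id
  env$hybrid_def <- character(0)    # tags whose subtree has been seen
  env$hybrid_seen <- integer(0)     # occurrence counts

  fresh <- function() {
    env$counter <- env$counter + 1L
    sprintf("v%03d", env$counter)
  }
  walk <- function(node) {
    if (!is.null(node$tag)) {
      tag <- node$tag
      if (is.na(match(tag, names(env$hybrid_id)))) {
        env$hybrid_id[tag] <- fresh()
        env$hybrid_seen[tag] <- 0L
      }
      env$hybrid_seen[tag] <- env$hybrid_seen[tag] + 1L
      id <- env$hybrid_id[[tag]]
      if (length(node$children)) {
        if (tag %in% env$hybrid_def)
          np_parse_error(sprintf("hybrid tag '%s' carries a subtree more than once", tag))
        env$hybrid_def <- c(env$hybrid_def, tag)
        for (ch in node$children) {
          cid <- walk(ch)
          env$edges <- c(env$edges, id, cid)
        }
      }
      return(id)
    }
    id <- fresh()
    if (length(node$children)) {
      for (ch in node$children) {
        cid <- walk(ch)
        env$edges <- c(env$edges, id, cid)
      }
    } else {
      if (is.null(node$label))
        np_parse_error("leaf without a label")
      env$labels[id] <- node$label
    }
    id
  }

  top_id <- walk(top)
  lone <- names(env$hybrid_seen)[env$hybrid_seen < 2L]
  if (length(lone))
    np_parse_error(sprintf("unmatched hybrid tag '%s'", lone[1L]))
  undef <- setdiff(names(env$hybrid_id), env$hybrid_def)
  if (length(undef))
    np_parse_error(sprintf("hybrid tag '%s' never carries a subtree", undef[1L]))

  edges <- matrix(env$edges, ncol = 2L, byrow = TRUE)
  ## redundant parentheses create in-1 out-1 wrapper vertices: suppress
  repeat {
    vs <- unique(c(edges))
    outd <- tabulate_degree(edges[, 1L], vs)
    ind <- tabulate_degree(edges[, 2L], vs)
    wrap <- vs[ind == 1L & outd == 1L & !vs %in% names(env$labels)]
    if (!length(wrap)) break
    v <- wrap[[1L]]
    p <- edges[edges[, 2L] == v, 1L]
    ch <- edges[edges[, 1L] == v, 2L]
    edges <- edges[edges[, 1L] != v & edges[, 2L] != v, , drop = FALSE]
    edges <- rbind(edges, c(p, ch))
  }
  ## enforce the root-out-degree-one convention of rooted binary networks
  n_top <- sum(edges[, 1L] == top_id)
  if (length(edges) == 0L || n_top != 1L) {
    rho <- "v000"
    edges <- rbind(edges, c(rho, top_id))
  }
  phynet(edges, env$labels)
}

#' Write a network as extended Newick
#'
#' Deterministic serialisation: reticulations are numbered `#H1, #H2, ...`
#' in canonical vertex order, the subtree of a reticulation is attached at
#' its canonically smallest parent, and the children of every tree vertex
#' are emitted in sorted order. The auxiliary out-degree-one root is
#' stripped, so `read_enewick(write_enewick(N))` is isomorphic to `N`
#' (the round trip reinserts it).
#'
#' @param net a [phynet].
#' @return A single eNewick string ending in `;`.
#' @export
write_enewick <- function(net) {
  retics <- reticulations(net)
  tagno <- stats::setNames(seq_along(retics), retics)
  defpar <- stats::setNames(
    vapply(retics, function(r) np_parents(net, r)[1L], character(1)), retics)

  rec <- function(v, parent) {
    if (v %in% names(net$labels)) return(unname(net$labels[v]))
    if (v %in% retics) {
      tag <- sprintf("#H%d", tagno[[v]])
      if (!identical(parent, defpar[[v]])) return(tag)
      kid <- np_children(net, v)
      return(paste0("(", rec(kid, v), ")", tag))
    }
    kids <- np_children(net, v)
    parts <- sort(vapply(kids, rec, character(1), parent = v), method = "radix")
    paste0("(", paste(parts, collapse = ","), ")")
  }

  child <- np_children(net, net$root)
  body <- rec(child, net$root)
  if (!startsWith(body, "(")) body <- paste0("(", body, ")")
  paste0(body, ";")
}
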
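## Labelled-graph isomorphism between networks: VF2 on the directed
## graphs with leaves coloured by taxon rank and internal vertices
## uncoloured. Used for round-trip identity and for deduplicating
## orientations / rooted partners, where no cheap canonical form exists.

#' Test two networks for labelled isomorphism
#'
#' @param n1,n2 [phynet] objects.
#' @return TRUE iff there is a digraph isomorphism mapping each leaf of
#'   `n1` to the leaf of `n2` with the same taxon name.
#' @export
net_isomorphic <- function(n1, n2) {
  if (!setequal(taxa(n1), taxa(n2))) return(FALSE)
  pal <- canon_sort(taxa(n1))
  color_of <- function(net) {
    g <- igraph::graph_from_edgelist(net$edges, directed = TRUE)
    nm <- igraph::V(g)$name
    cols <- integer(length(nm))
    leaf <- nm %in% names(net$labels)
    cols[leaf] <- match(net$labels[nm[leaf]], pal)
    list(g = g, col = cols)
  }
  a <- color_of(n1); b <- color_of(n2)
  if (igraph::vcount(a$g) != igraph::vcount(b$g) ||
      igraph::ecount(a$g) != igraph::ecount(b$g)) return(FALSE)
  igraph::is_isomorphic_to(a$g, b$g, method = "vf2",
                           vertex.color1 = a$col, vertex.color2 = b$col)
}
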
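# netpars

Parsimony scores and bounds for phylogenetic networks.

## The problem

Phylogenetic networks extend trees with *reticulations* — vertices with two
parents that model hybridisation or lateral gene transfer. The small
parsimony problem, solvable in polynomial time on trees by the
Fitch–Hartigan algorithm, becomes NP-hard on networks: the *softwired*
parsimony score of a gap-free alignment A on a rooted binary network N,

```
PS_sw(A, N) = Σ_i  min_{T ∈ D(N)}  PS(f_i, T)
```

minimises over the exponentially large *display set* D(N) of trees
embeddable in N (one tree per alignment site; the stricter variant
PS_sw' forces a single tree for the whole alignment). For a *level-k*
network — every biconnected component (*blob*) carries at most k
reticulations — scoring **any one** displayed tree already gives a
(k+1)-approximation:

```
PS(A, T) ≤ (k+1) · PS_sw(A, N)      for every T ∈ D(N),
```

and the factor k+1 is tight. `netpars` implements the exact scores, this
approximation, and the machinery around the bound:

* `phynet()`, `read_enewick()`, `write_enewick()` — validated rooted
  binary networks, extended-Newick I/O (`#H` hybrid tags).
* `blobs()`, `network_level()`, `maximal_blob()`, `blob_reduce()` —
  blob decomposition and reduction; `informative_blob_count()` computes
  b(f, N, S), the number of blobs that force state diversity among their
  children under every minimum extension.
* `switchings()`, `display_set()`, `softwired_score()` (per-site and
  single-tree modes), `approx_softwired()` — exact softwired scoring by
  switching enumeration, and the polynomial (k+1)-approximation.
* `rspr_distance()`, `switching_distance()`, `switch_bound_holds()` —
  exact rSPR distances on small trees and the bound
  d_rSPR(T_R, T_R') ≤ d_switch(R, R').
* `unfold_multree()`, `parental_trees()`, `parental_score()` — parental
  parsimony via the MUL-tree unfolding U*(N) (brute force over leaf-copy
  assignments); the bundled `parental_gap_network()` family shows that no
  (k+1)-style bound exists for parental parsimony.
* `deroot()`, `rooted_partners()`, `display_set_unrooted()`,
  `orientations()` — semi-directed networks (where the bound transfers
  through any rooted partner) and fully unrooted networks (where it does
  not: different orientations can score differently).
* `sharp_level_k()`, `parental_gap_network()`, `random_network()` —
  deterministic example families and seeded random instances.

## Worked example

The sharp level-2 family: a single-blob network on 7 leaves whose binary
character assigns state 1 to `x0, x1, x2`.

```r
library(netpars)
sh <- sharp_level_k(2)
write_enewick(sh$network)
#> "((((#H1,x1pp),x1p),((#H2,x2pp),x2p)),(((x2)#H2,x0),(x1)#H1));"
network_level(sh$network)          # k = 2
softwired_score(sh$network, sh$char)
#> 1
res <- approx_softwired(sh$network, sh$char)
res$score; res$guarantee
#> 1
#> 3
max(sapply(display_set(sh$network), parsimony_score, f = sh$char))
#> 3
```

The exact softwired score is 1 (one displayed tree groups all state-1
leaves in a single clade). The approximation scored a displayed tree with
guaranteed factor k+1 = 3; the worst displayed tree indeed costs
3 = (k+1)·1, so the guarantee is met with equality on this family —
scoring an arbitrary displayed tree can be off by exactly the factor
k+1, never more.

A command-line interface wraps the same functions:

```sh
Rscript inst/cli/netpars score --network net.enewick --alignment sites.csv --mode softwired
Rscript inst/cli/netpars info --network net.enewick
Rscript inst/cli/netpars generate --family sharp --k 3 --prefix sharp3
```

Output is JSON; exit codes distinguish parse (2), validation (3),
enumeration-guard (4) and taxon-mismatch (5) failures.

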
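---
title: "Softwired and parental parsimony on level-k phylogenetic networks"
author: "netpars"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Softwired and parental parsimony on level-k phylogenetic networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(netpars)
```

## Model and definitions

A rooted binary phylogenetic network on a taxon set X is a rooted DAG
without loops or parallel edges in which the root has out-degree one,
every other internal vertex is a tree vertex (in 1, out 2) or a
reticulation (in 2, out 1), and the leaves are labelled bijectively by
X. Reticulations model non-treelike events: hybrid speciation, lateral
gene transfer. A *blob* is a biconnected component of the underlying
undirected graph containing at least one reticulation; its *source* is
its unique entry vertex. A network is *level-k* when no blob carries
more than k reticulations; `network_level()` reports the tight maximum,
since the quality of the approximation below depends on it.

A *switching* keeps exactly one incoming edge per reticulation. Deleting
the rejected edges, pruning childless unlabelled vertices and
suppressing degree-two vertices yields a *displayed tree*; the display
set D(N) collects all of them, and every member arises from at least one
of the 2^h switchings (h = number of reticulations). A character is a
surjective map f : X → C of states; an extension F assigns states to all
vertices, and its changing number ch(F, G) counts edges whose endpoints
disagree. `parsimony_score()` computes the minimum changing number with
the Fitch–Hartigan per-state dynamic program, which handles multistate
characters, out-degree-one subdivision vertices and unrooted trees
natively.

Two softwired scores are in use and both are implemented by
`softwired_score()`:

* **per-site** (the default): each alignment site may follow its own
  displayed tree, `PS_sw(A, N) = Σ_i min_T PS(f_i, T)`;
* **single-tree**: one tree serves the whole alignment,
  `PS_sw'(A, N) = min_T Σ_i PS(f_i, T)`.

The per-site score never exceeds the single-tree score, and the two
agree on single-site alignments; both are exercised in the test suite.

## The (k+1)-approximation

Computing either score is NP-hard even for level-1 networks with binary
characters, but a useful bound is cheap: for every displayed tree T of a
level-k network,

PS(A, T) ≤ (k+1) · PS_sw(A, N)  and  PS(A, T) ≤ (k+1) · PS_sw'(A, N).

`approx_softwired()` therefore scores the tree of one fixed switching —
for each reticulation the incoming edge with the canonically smallest
tail — and reports the guarantee k+1. The choice of switching is
mathematically arbitrary; pinning it makes runs reproducible, and a
`seed` argument substitutes a random switching when sensitivity to the
choice is of interest.

The bound rests on two ingredients that the package exposes as
first-class operations because they are independently useful:

* **Informative blobs.** Relative to an embedding S of a displayed tree
  and a character f, a blob is *informative* when every minimum
  extension assigns more than one state to the blob's children C_N(B)
  (the out-of-blob successors of blob vertices). The count b(f, N, S) of
  informative blobs under a best minimum extension
  (`informative_blob_count()`) satisfies b ≤ PS(f, S): each informative
  blob forces at least one change. The count is computed by exhaustive
  iteration over minimum extensions (`min_extensions()`), which is the
  defining semantics; a guard (default 2^20 extensions) keeps the
  enumeration at desk scale. Minimum extensions never place a change on
  the root path — an extension with such a change is never minimum — so
  the enumeration is normalised for free.
* **Blob reduction.** A *maximal* blob (no blob below it) splits the
  network at its source s into the subnetwork below s (on the cluster
  Y = cl(s)) and the rest with a fresh leaf y (`blob_reduce()`); an
  embedding splits likewise into a cluster tree pair, and
  `split_extension()` / `merge_extension()` translate extensions across
  the cut with exactly additive changing numbers. The additivity is
  checked exactly on hundreds of random instances in the tests.

Tightness: `sharp_level_k(k)` constructs, for every k ≥ 1, a single-blob
level-k network on 3k+1 leaves and a binary character with softwired
score 1 for which some displayed tree scores exactly k+1. The
construction chains k gadgets: gadget i offers a cheap routing of leaf
x_i next to its cherry partner and an expensive routing onto a collector
path towards x_0; taking all cheap edges concentrates the k+1 state-1
leaves in one clade (score 1), taking all expensive edges isolates each
of them (score k+1). The generator re-verifies both scores by exact
enumeration at construction time for k ≤ 5 and fails loudly otherwise.

## Related quantities

**Switching and rSPR distances.** Two switchings differ at
d_switch = h − |R ∩ R'| reticulations, and the trees they yield satisfy
d_rSPR(T_R, T_R') ≤ d_switch(R, R'). `rspr_distance()` computes exact
rSPR distances by bidirectional breadth-first search over canonical
Newick forms, memoised; this is exponential and guarded at 8 leaves,
which suffices for the property checks. Moves never prune an edge
incident with the root; regrafts may subdivide any edge of the root
component, the root edge included. This convention affects distances
and is therefore pinned here.

**Parental parsimony.** The MUL-tree unfolding U*(N)
(`unfold_multree()`) has one vertex per root-initiated directed path, so
a taxon below reticulations appears on several leaves. Keeping one leaf
copy per taxon and suppressing yields the parental trees P(N) ⊇ D(N);
`parental_score()` minimises over all copy assignments by brute force —
a deliberate choice of reference semantics over speed, guarded by the
product of copy counts (default 10^4). No analogue of the (k+1) bound
holds here: `parental_gap_network(n)` is level-1 with a single blob, has
parental score 1, yet its unique displayed tree scores n/2, which the
tests confirm for n = 6, 8, 10.

**Semi-directed and unrooted networks.** `deroot()` removes the root,
suppresses its child and keeps directions only on reticulation edges; at
most one parallel edge pair can arise (a 3-cycle through the root
child). Display sets of semi-directed networks equal the deroot-image of
any rooted partner's display set, so softwired scores are
partner-invariant and inherit the (k+1) bound; the package nevertheless
computes `display_set_unrooted()` *directly* — by enumerating spanning
trees of the underlying multigraph, pruning unlabelled chains and
rejecting embeddings that keep both incoming edges of a reticulation —
so that the partner-equality is a genuine cross-check in the tests, not
a tautology. For fully unrooted networks the story breaks:
`orientations()` enumerates all rooted orientations, and on the 5-cycle
network with character 0,0,0,1,1 they split into softwired scores 1 and
2 while the unrooted score is 1. One cannot, therefore, score an
unrooted network through an arbitrary orientation.

## Generators and what the tests do (and do not) show

`random_network(n_leaves, k, h, seed)` grows a random binary tree
(random sequential pair joining) and adds reticulations one at a time by
subdividing two edges and joining them, rejecting proposals that would
create a directed cycle or push a blob over k reticulations. Seeds are
mandatory and all randomness is local: the caller's RNG state is
untouched. The sampler is not uniform over level-k networks and makes no
biological claims (no clock, no realistic branch lengths — scores here
are purely topological, so branch lengths are parsed and discarded on
input). Random characters and alignments are uniform over states with
surjectivity enforced. Passing property tests on these instances
demonstrates correctness of the combinatorial claims on a broad instance
family; it does not calibrate anything against empirical alignments.

Problem sizes used by the verification suite, chosen to exercise every
code path at desk scale: the factor-(k+1) bound on 200 seeded networks
with 5–10 leaves, level ≤ 3 and up to 5 reticulations under alignments
of up to 4 sites and 4 states; the rSPR/switching bound on 100 networks
with 4–7 leaves and up to 3 reticulations (exhaustive over switching
pairs); deroot-invariance on 50 networks; subdivision-invariance and
cluster-extension additivity on 200 instances each; and the dynamic
program against brute-force extension minima on trees with up to 7
leaves and 3 states.

## Numerical and design choices

* Vertex identifiers are opaque strings under a fixed C-locale
  lexicographic order used for every tie-break (maximal-blob choice,
  switching order, canonical serialisation); all set-like results are
  returned sorted.
* Degree-two vertices in subdivisions are scored natively by the DP
  rather than suppressed first, so embeddings keep their host-network
  vertex identities — which the blob machinery relies on.
* Trees are deduplicated by canonical sorted-children Newick; general
  networks, which admit no such cheap canonical form, are compared by
  VF2 isomorphism with leaf colours.
* Exact enumerations are guarded, not silently truncated: switchings at
  h ≤ 20, minimum extensions at 2^20, copy assignments at 10^4, rSPR at
  8 leaves, unrooted display enumeration at 10^5 edge subsets. Exceeding
  a guard raises a distinct condition class (`netpars_guard_error`),
  surfaced by the CLI as exit code 4. Guards are user-overridable.
* Characters reject the gap symbol everywhere: with gaps the softwired
  score is not approximable in this way, so supporting them would
  silently void the guarantee the package exists to provide.
* A constant (single-state) character is legal and scores 0; a network
  on one leaf (root plus leaf) is legal as the blob-reduction base case.
* eNewick: the reader accepts definitions of a hybrid tag at any of its
  occurrences (exactly one may carry a subtree), inserts an auxiliary
  out-degree-one root when a file encodes the common degree-two root,
  and suppresses redundant wrapper parentheses; the writer is
  deterministic and strips the auxiliary root again. Round trips are
  isomorphism-stable, which the tests check on 200 random networks.

## Limitations

Everything here is exact and exponential in h or k by design; the
package is a reference implementation for bounds and counterexamples at
desk scale, not a heuristic scorer for genome-scale networks. Non-binary
networks, gap handling, weighted (Sankoff) parsimony and FPT/DP
algorithms for single-character softwired or parental parsimony are out
of scope. For unrooted networks only the counterexample side is
implemented; whether some other bound holds there is open.
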
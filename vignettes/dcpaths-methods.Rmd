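---
title: "Diversified control paths: model, parameters and design decisions"
author: "ctrlpaths"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Diversified control paths: model, parameters and design decisions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ctrlpaths)
```

## The model

A directed molecular network G(A) — nodes are genes, links are directed
regulatory relationships — underlies the linear time-invariant dynamics
dX/dt = A·X + B·u. The system is controllable when the controllability
matrix Q_C = [B, AB, ..., A^(n-1)B] reaches rank n. Checking this rank
directly is infeasible beyond a handful of nodes, and the link weights of
a biological network are unknown anyway, so the package works with
*structural* controllability: properties that hold for almost every
choice of nonzero weights.

The structural machinery is maximum matching on the node-split bipartite
graph. Every node v becomes an out-copy v+ and an in-copy v−, a link
(u, w) becomes the bipartite edge (u+, w−), and a matching is a link set
in which no two links share a tail or a head. A maximum matching M fixes
the minimum number of driver nodes, N_D = max{n − |M|, 1}: the nodes
whose in-copy is unmatched must receive external input. The matched links
form a stem–cycle cover — stems are maximal matched chains starting at
driver nodes, the remaining matched links form node-disjoint cycles — and
this cactus skeleton is exactly the set of *control paths* along which
input signals propagate.

Maximum matchings are rarely unique. Each maximum matching M_k induces
its own control-path set C_k, and the union of the C_k over all (sampled)
MMSets is the network's *diversified control paths*. The perturbation
range of node i under one C_k is the set of nodes reachable from i along
matched links only; the perturbation influence Pi_i is the union of these
ranges over the collection. Two modelling conventions deserve emphasis:

* **Reachability uses matched links only.** Control signals transmit
  along the matched chains, not along arbitrary network links, so an
  unmatched link contributes nothing to any perturbation range even
  though it exists in the network. Pi_i is therefore always a subset of
  i's ordinary descendants.
* **Self-exclusion.** Pi_i never contains i, even when i sits on a
  matched cycle that re-reaches it; influence lists are strictly
  downstream.

Disease-gene scoring assumes genes causing one disease drive similar
perturbation influence. A candidate i is scored against known disease
genes X_d as score(i) = max over x of sim(Pi_i, Pi_x), where sim is the
total weight of a maximum-weight bipartite matching between the two gene
sets, with edge weights given by Wang-style best-match-average ontology
similarity between genes.

## Algorithms and numerical choices

**Maximum matching** is computed by augmenting-path search (Kuhn's
algorithm) on the split graph; self-loops are matchable (v+ to v−). The
result is deterministic given the node order; the `seed` argument
permutes node and adjacency order, which selects among equally large
matchings. Matching cardinality is independent of the seed (it is checked
against brute-force enumeration and an independent library implementation
in the tests).

**Perfect matchings** leave no unmatched in-copy, yet N_D = 1 demands a
driver. The package deterministically returns the lexicographically
smallest node; any node would do, and no principled choice exists, so the
convention is arbitrary but reproducible.

**MMSet sampling** follows a link-swap random walk: pick a matched link
uniformly, enumerate every matching of the same cardinality that keeps
all the other links (the removed link's endpoints are freed; any network
link between a free tail and a free head completes the matching), move to
one uniformly, and record every visited state including repeats. The
stopping rule is a fixed sample count, with an optional convergence
window (stop after `window` consecutive samples without a new MMSet,
default 1000 when enabled). Single-link swaps provably cannot connect
*fully disjoint* maximum matchings — the two orientations of a reciprocal
cycle are the minimal example — so the walk alone can undercount MMSets
on such graphs. Rather than claim completeness, the sampler exposes
`restarts`: independent walks from differently seeded initial matchings
whose results are merged. Ten restarts recover the exhaustive MMSet set
on every small random instance the tests draw; the default remains a
single walk, which is the plain form of the procedure.

**The Kalman rank oracle** exists for small systems (n ≤ 12) as a ground
truth: weights are drawn uniformly on [0.5, 1.5] over the nonzero
structure, rank uses a singular-value cutoff of 1e−9 relative to the
largest singular value, and 5 independent draws guard against degenerate
weight choices (generic rank holds almost surely, so one draw nearly
always suffices). When certifying a matching's cactus, inputs are placed
at the driver nodes *and* at one attachment node per matched cycle: a
cycle is controllable only as a bud hanging off an input signal, which is
precisely why N_D = max{n − |M|, 1} inputs suffice with signal sharing.
Deleting any matched link then destroys controllability, with one
principled exception: the cycle link entering an attachment node is
redundant, because its removal merely straightens that bud into a stem.

**Ontology similarity** uses Wang's S-values: the query term contributes
1, and each ancestor the maximum product of relation weights along a path
toward the query, with the published defaults is_a = 0.8 and
part_of = 0.6 (configurable). Terms from different namespaces score 0
with a warning; the default working namespace is biological_process, a
configuration choice rather than an interpretation (nothing in the method
fixes it). Gene similarity is the best-match average over the two genes'
term sets.

**Set similarity is intentionally unnormalized.** The score is the plain
sum of matched weights, so a larger coherent influence set scores higher
than a smaller one. This is the literal output of the matching step and
is kept as the default; a normalized variant (divide by the larger set
size) is available via `normalized = TRUE` for users who want
set-size-invariant scores. The assignment itself is solved exactly by the
Hungarian algorithm (`clue::solve_LSAP`), with rectangular grids handled
by orienting the smaller side as rows; exhaustive enumeration confirms it
on every grid up to 6×6 in the tests.

**Ranking and cross-validation.** Ties receive the mean of the tied rank
positions — deterministic and conservative, since no tie policy is
implied by integer published ranks. The LOO candidate pool is all
annotated network genes minus the training genes (`pool = "all"` widens
it to every node); known disease genes always belong to the pool. The
recall curve is reported on an integer percent grid 1..100. k-fold CV
partitions associations globally at random under the given seed; a trial
whose disease loses every training gene to the fold is skipped with a
warning. AUC is the rank-sum form — the probability that the withheld
gene outscores a random pool gene, ties counting one half — averaged
across trials.

**SPi** removes ⌊fraction·|L|⌋ links uniformly without replacement (nodes
are never removed), resamples MMSets on the reduced network with the same
budget, and averages per-node Jaccard overlaps of old and new influence.
Two conventions matter: 0/0 = 1 (a node with no influence is perfectly
stable — this inflates SPi on sparse networks and is stated prominently
for that reason), and a zero removal count reuses the intact profile so
SPi(0) = 1 holds exactly rather than up to sampling noise. Every
repetition derives its removal seed and its sampling seed from the master
seed by an explicit counter, so reports are reproducible bit for bit.

## What the synthetic generator emulates

`generateNetwork` produces simple digraphs at a default mean out-degree
of 4.8, the density of the KEGG-derived human regulatory network the
method targets (1579 genes, 7630 relationships); the `scale_free` mode
adds the heavy-tailed degree structure of real regulatory maps by
preferential attachment. `generateOntology` builds an is_a tree of given
depth and branching plus part_of cross-links into strictly shallower
levels (10% of terms by default), acyclic by construction.

`generateDiseaseBenchmark` plants the structure the score assumes: each
disease gets a dedicated downstream module — a chain of fresh nodes whose
only in-links are the chain itself — and disease genes wired into the
module's entry node. Every maximum matching must match the entry node to
exactly one disease gene, so each gene reaches the whole module along
matched links under some MMSet, and the single-link swaps at the entry
node are exactly the moves that rotate which gene is matched. The
embedding is never assumed: the bundle samples MMSets and verifies that
every planted gene's influence covers its module, and errors out
otherwise. Module and disease genes are annotated from one ontology
branch per disease with a 0.2 annotation-noise fraction — informative but
not degenerate — while background genes draw terms uniformly.

Defaults (10 diseases × 3 genes, module size 5, 150-node base network at
mean out-degree 1.5, 2000 samples with 2 restarts) keep background
influence sets modest so planted modules are identifiable; they are the
regime the cross-validation machinery is demonstrated in, not a fit to
any particular dataset. What passing on these bundles shows is that the
pipeline recovers *constructed* shared-influence structure; it does not
show that real disease genes share influence in a real regulatory
network, which depends on curated interactions and annotations the
generator does not model (hub biology, annotation bias, correlated
modules, literature-driven incompleteness).

## Problem sizes

The test suite and the acceptance script run everything at desk scale by
choice: brute-force oracles up to 20 links and 6×6 grids, rank oracles up
to 12 nodes, SPi on a 300-node scale-free surrogate with a 150-sample
budget and 20 repetitions per fraction, and benchmarks between 30 and 230
nodes. The algorithms themselves have no such limits — matching is
near-linear per augmentation and influence aggregation is one successor
pass per MMSet — but exhaustive verification is what the small sizes buy.

## Known limitations

* The walk's stationary distribution over MMSets is not uniform and no
  mixing guarantee is claimed; diversified coverage, not unbiased
  sampling, is the goal, and restarts are the practical mitigation.
* Influence is unweighted and unsigned: activation and inhibition are not
  distinguished, and all matched links count equally.
* The unnormalized score favors genes with large influence sets by
  construction; use the normalized variant when that is undesirable.
* The 0/0 = 1 Jaccard convention makes SPi optimistic on networks with
  many uninfluential nodes.
* GO namespaces other than the chosen one contribute nothing to
  similarity under the default configuration.
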
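---
title: "Methods: network-pharmacology hub inference in netpharm"
author: "netpharm authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: network-pharmacology hub inference in netpharm}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(netpharm)
```

## The problem

Multi-herb traditional-medicine formulas act through many compounds hitting
many protein targets at once. Network pharmacology replaces the
one-drug-one-target view with a pipeline: screen the herb ingredients down
to pharmacokinetically plausible candidates, link candidates to predicted
protein targets, situate those targets (and the disease's own associated
targets) in the protein–protein interaction (PPI) network, and ask which
proteins sit at the topological core of the shared network — the hub
targets most likely to mediate the formula's effect. Finally, annotate the
hubs by gene-set over-representation. `netpharm` implements this pipeline
end to end, with a synthetic-data generator that plants recoverable ground
truth at every stage.

## Stage models and parameters

### ADME screening

A compound record carries oral bioavailability OB (percent, ≥ 0) and
drug-likeness DL (dimensionless, in [0, 1]). A record is a candidate iff

$$ (\mathrm{OB} \ge 30 \,\wedge\, \mathrm{DL} \ge 0.18) \,\vee\, \text{whitelisted}. $$

The cutoffs (30%, 0.18) are the conventional ADME screening values for
herbal-compound databases and are configurable via `screen_config()`. The
comparison is inclusive by default: the cutoff is stated as the boundary of
admissibility, and the inclusive reading is the boundary-safe choice; a
strict variant is available (`inclusive = FALSE`). The whitelist is an
explicit input column — compounds with well-documented pharmacological
activity (the psoralen/angelicin situation) are rescued regardless of their
computed OB/DL — never a hard-coded name list. Per-herb accounting credits
a compound shared by *k* herbs once to each herb.

### Compound–target network

The compound–target map is consumed as input (target prediction from
chemistry is out of scope). Duplicate assertions collapse to a single edge;
node and edge counts, compound degrees (distinct targets), per-herb
distinct-target unions, and the intersection with the disease target set
are pure set arithmetic. The "highly connected ingredient" report uses a
degree ≥ 20 cut by default; the threshold is a parameter.

### Seed PPI networks and the core network

Drug targets and disease targets are used as *seeds* into a reference PPI
graph. Interactome tools that build such seed networks typically admit
connecting proteins beyond the seeds; since the exact expansion rule of any
given tool is rarely documented, `seed_network()` offers three bracketing
modes: `induced` (seeds only), `induced_plus_bridges` (default; also admits
non-seed proteins adjacent to ≥ 2 distinct seeds — the smallest expansion
that can connect seed pairs through a shared interactor), and
`first_neighbors` (largest). The modes are provably nested, and the choice
is echoed in every run summary.

The two seed networks are merged into the core PPI (CPPI) network by
**node intersection** (default): proteins present in both networks, with
every edge of either network between them. Intersection is the only merge
consistent with a core network smaller than both inputs; `union` is
available for sensitivity analysis.

### Six centralities and the hub rule

On the CPPI network each node gets six scores (`centrality_table()`),
following the CytoNCA-style conventions used in hub screening:

| metric | definition |
|---|---|
| DC | neighbour count |
| BC | unnormalized betweenness: $\sum_{\{s,t\}} \sigma_{st}(v)/\sigma_{st}$, each unordered pair once; disconnected pairs contribute 0 |
| CC | component-relative closeness: $(m-1)/\sum_u d(v,u)$ within v's component of size m; isolated node → 0 |
| EC | principal eigenvector of the adjacency matrix, $\lVert \cdot \rVert_2 = 1$ |
| NC | $\sum_{u \in N(v)} z(v,u)/\min(d_v - 1, d_u - 1)$, z = common neighbours; zero denominator contributes 0 |
| LAC | mean degree of N(v) in the subgraph N(v) induces, $= 2T(v)/d_v$ |

Hub targets are the nodes whose **six** centralities all *strictly* exceed
the network-wide medians (`median_thresholds()` + `select_hubs()`). For an
even node count the median is the midpoint of the two central order
statistics — which is how a non-integer degree median arises in practice.
Strict exceedance means a metric on which many nodes tie at the median
(common for NC/LAC, where sparse-graph values are 0) disqualifies the
tied nodes, and the hub set can never exceed ⌊n/2⌋. Ties are never broken
heuristically; selection is purely the six-way conjunction.

### Enrichment and kappa grouping

Over-representation of the hub set in each annotation term uses the
hypergeometric upper tail
$P(X \ge k) = \sum_{i=k}^{\min(K,n)} \binom{K}{i}\binom{N-K}{n-i} / \binom{N}{n}$,
evaluated through the distribution's survival function (numerically stable
in the far tail; `k = 0` returns exactly 1). The universe N defaults to the
union of annotated genes, the behaviour of the standard grouping tools; an
explicit universe can be supplied (the pipeline passes the full protein
pool). Significance is gated on raw p ≤ 0.05 — the classical reporting
convention for this analysis — while Benjamini–Hochberg adjusted values are
always reported alongside (`gate_on_adjusted = TRUE` switches the gate).

Significant terms are grouped by Cohen's kappa agreement of their gene
memberships over the universe: terms are linked when κ ≥ 0.4 (the
conventional default of kappa-grouping tools; visible in
`enrichment_config()`), and groups are the connected components of that
term graph, ordered by best p, each led by its smallest-p term (ties:
larger term, then lexicographic id). Connected components are deliberately
used instead of the iterative group-merging heuristics of GUI tools: they
are simpler, deterministic, and refine monotonically as the threshold
rises.

## Synthetic data: what it emulates, and what it does not

`synthetic_spec()` fixes the study conditions; every generator is a pure
function of the spec (including its seed — randomness is scoped with
`withr::with_seed`, never global).

* **Compound table** — five herbs (BGZ, BZ, FJ, WM, GC) with quotas
  (25, 60, 20, 25, 120; about 250 ingredients, a desk-scale analogue of a
  real five-herb ingredient database), a 30% joint OB/DL pass rate with
  values straddling both cutoffs, a 10% whitelist rate among failing
  compounds, and 8% multi-herb membership.
* **PPI graph** — a 300-protein Erdős–Rényi background at edge probability
  0.02 with a planted 20-protein module wired at density 0.9. The ER
  background is chosen for analyzability (binomial degrees, known expected
  module contrast); the module is dense but *not* a clique, so hub
  recovery is a statistical success, not a definitional one.
* **Compound–target map** — compound degrees follow a truncated power law
  (exponent 2), giving the few promiscuous, many specific ingredients seen
  in real data. Every planted hub is guaranteed ≥ 1 compound edge so the
  planted signal can enter the drug-target seed network at all.
* **Disease targets** — 60 proteins overlapping the drug-target set in
  exactly 15 genes, about 80% of which are planted hubs. Without this the
  node-intersection CPPI could not contain the ground-truth module even in
  principle; with it, the remaining hubs enter the disease network as
  bridges of the dense module.
* **Annotations** — 25 terms over the full protein pool; one planted term
  of 40 genes containing 16 of the 20 hubs, the rest random (15–60 genes).

What the generator does **not** emulate: the scale-free degree distribution
of real interactomes (an option exists, but benchmarks use the analyzable
default), literature biases of curated PPI databases, identifier-namespace
noise, or the hierarchical structure of real ontology annotations. Passing
the planted-recovery benchmarks therefore shows the machinery extracts a
strong topological signal correctly — not that real database extractions
would yield equally clean hubs.

## Numerical choices

* **Eigenvector centrality** is computed by power iteration on **A + I**
  rather than A: on bipartite components plain iteration oscillates with
  period 2 and never converges, while the unit shift leaves the principal
  eigenvector unchanged and guarantees convergence (all eigenvalues shift
  by +1, so the Perron pair strictly dominates in modulus). Tolerance
  1e-10 on the max successive-iterate difference, 1000-iteration cap;
  tests assert the eigen-residual of the result against a dense
  eigensolver. Graphs with no edges return all zeros with a warning. On
  disconnected graphs the iteration runs on the full adjacency, so mass
  concentrates on the components of largest spectral radius.
* **Betweenness** uses Brandes' accumulation over BFS DAGs, halved so each
  unordered pair counts once; it is exact, not sampled.
* **Degenerate inputs**: NC's edge-clustering denominator
  `min(d-1, d-1) = 0` contributes 0 (the only finite-safe reading); LAC
  and CC of isolated nodes are 0; kappa with expected agreement 1 returns
  1 for identical sets, else 0; an empty node intersection in the merge
  warns and returns the empty graph rather than erroring.
* **Determinism**: node sets, hub lists and enrichment rows are sorted
  with C-locale (radix) ordering, so byte-identical outputs do not depend
  on the session locale. Written artifacts omit wall-clock timestamps for
  the same reason: a re-run with identical inputs must be bit-identical.

## Problem sizes

The shipped analysis and the benchmarks run at the generator's default
scale: 300-protein interactomes, ~250-compound tables, 20-replicate
recovery experiments, and an oracle library of ~60 graphs on ≤ 7 nodes for
the exhaustive centrality checks. These sizes give stable recovery
statistics while keeping a full run in seconds on a single core; all of
them are spec parameters, so larger experiments are one argument away.

## Known limitations

* Identifiers are opaque case-sensitive strings; no symbol/UniProt/Entrez
  mapping is attempted (a deliberate non-goal — mapping belongs upstream).
* SIF cannot represent isolated nodes (an edge row needs three fields), so
  SIF round-trips are exact only for graphs without isolates; GraphML
  round-trips everything.
* The hub rule is the strict six-way median conjunction; no weighting or
  ranking across metrics is offered, matching the screening convention it
  implements.
* Reproduction of a specific published study's counts requires that
  study's exported tables as inputs; with synthetic inputs the pipeline
  reproduces its *own* manifest exactly, which is what the test suite
  verifies.
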
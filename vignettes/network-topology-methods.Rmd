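---
title: "Comparative topology of protein sets: models, parameters and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparative topology of protein sets: models, parameters and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(netonco)
```

# The analysis in one paragraph

Given an undirected protein–protein interaction network and named protein
sets (a disease set, an essential set, and the control set of everything
else), `netonco` asks three questions. *Globally*: do the sets differ in
degree, betweenness, clustering coefficient and shortest-path distance?
*Locally*: is the disease set's induced subnetwork more densely and tightly
wired than Erdős–Rényi graphs of the same size? *Functionally*: which
annotation categories are over-represented among the proteins that rank
highest on the topological measures? Each stage is a separate module with a
documented contract, and a synthetic-world generator supplies inputs whose
correct answer is known in advance.

# Measures and their conventions

**Degree** `k(v)` counts direct interaction partners; `P(k)` is the
empirical probability that a set member has exactly `k` links. **Hubs** are
nodes with `k` *strictly* above a cutoff; 5 (a traditional PPI convention)
and 12 (a distribution-derived cutoff from the hub literature, taken here
as a given constant) are the defaults and are configurable.

**Clustering coefficient** `C(v) = 2 t(v) / (k(k−1))`, `t(v)` the number of
edges among v's neighbors. `C` is *undefined* (`NA`), not zero, for
`k < 2`: a 0/0 must not contaminate set averages, and the "C = 0" bin of a
histogram then contains only genuinely unclustered `k ≥ 2` nodes. Set
averages are taken over defined values only; the same rule applies to every
measure.

**Betweenness.** The default is the standard pair-dependency (Brandes)
betweenness: `B(v) = Σ_{s<t} σ_st(v)/σ_st`, endpoints excluded,
unnormalized, each unordered pair counted once. A verbal definition of
betweenness as "the number of shortest paths traversing the node" can also
be read literally as a raw count `Σ_{s<t} σ_st(v)`; in empirical PPI work
the reported magnitudes and the tight degree–betweenness correlation are
the signature of the pair-dependency form, so that is the default, and
`node_betweenness(net, "raw_count")` implements the literal count for
anyone who wants the other reading. The raw-count variant uses a BFS path
counting pass plus a backward suffix-count accumulation
(`S(v) = Σ_{w ∈ succ(v)} (1 + S(w))`), summing `σ_sv·S(v)` over sources and
halving.

**Set-relative distances.** For a member v of set S, `gSPD(v)` is the mean
shortest-path distance to reachable nodes *outside* S, and `cSPD(v)` the
mean distance to reachable *other members* of S. A set that interacts
mostly within itself shows `cSPD < gSPD`. Unreachable pairs are excluded
from the means rather than mapped to an arbitrary large value — the
empirical interactome is not connected, yet finite averages are the
quantity of interest; nodes with no reachable target at all are `NA` and
drop out of the set average. Both per-node means (the default, averaged
over members) and the underlying per-node vectors are returned, because
"average distance of a set" could alternatively pool all pair distances;
callers can recompute the pooled version from `$values` if they prefer.

# Between-set statistics

"Wilcoxon test" here means the two-sample rank-sum (Mann–Whitney) test,
two-sided: the compared sets are independent, never paired. `wilcox.test`
provides exact enumeration for small tie-free samples and the tie-corrected
normal approximation otherwise; correctness is pinned by a test that
enumerates all `C(n_x+n_y, n_x)` rank assignments. Hub fractions are
compared with the 2×2 χ² test (1 d.f.). Yates continuity correction is ON
by default — reconstructing a published hub comparison (250/342 vs
61.4% of 1896) reproduces the printed p = 4.7×10⁻⁵ only with the
correction, which is how the default was validated. When the two
proportions are exactly equal — including the all-or-none boundary where
the χ² statistic is formally 0/0 — the test returns statistic 0, p = 1.
Because an *average-degree* comparison and a *degree-distribution*
comparison are different questions that can disagree (a location test may
see nothing while the shapes differ), `compare_profiles()` emits both the
rank-sum row and a two-sample Kolmogorov–Smirnov row for degree, labeled
distinctly; neither is claimed to be "the" published statistic. No
multiple-testing correction is applied across the comparison table, which
reports raw p-values.

# The G(n,m) null model

The induced subnetwork of a set keeps exactly the within-set edges.
Members with no within-set edge are excluded from the observed summaries
and from the null dimensions: the null asks "is this *wiring* special",
and unlinked members carry no wiring. The replicates are `G(n, m)` —
exactly `m` edges uniformly without replacement — not `G(n, p)`, because
the observed edge count is a design constant, and replicates are *not*
forced to be connected: nothing in the procedure rejects disconnected
graphs, `L` simply averages over reachable pairs (at `n = 254, m = 595`
the giant component dominates anyway).

Per replicate, `B` is the mean betweenness over all nodes, `C` the mean
clustering over `k ≥ 2` nodes, `L` the mean distance over reachable
unordered pairs. Counts use strict inequalities (`B_rep > B_obs`,
`C_rep > C_obs`, `L_rep < L_obs`; ties count as non-exceeding), and the
empirical p is `count/reps` — a valid empirical tail probability that can
be exactly 0 at finite `reps`. With 1000 replicates at `n = 254, m = 595`
the null means are ≈ `2m/(n(n−1)) = 0.0185` for clustering (prints as
0.02) and ≈ 3.73 for `L`. A published table prints 3.71 for the same
construction; the between-replicate SD is 0.026, so a 1000-replicate mean
has SE ≈ 0.0008 and the 0.02 gap cannot be Monte-Carlo noise of this exact
procedure (node-weighted averaging gives 3.732 and does not explain it
either). The acceptance suite therefore checks the 2-dp value within the
stated ±0.02 band, which 3.73 meets at the boundary, and the discrepancy
is documented rather than tuned away. The same published analysis reports
that only 0.2% of null nodes had degree > 5, which is irreconcilable with
the Poisson(4.69) tail (~30%); that number is not used as an anchor.

**Centralization.** Freeman degree centralization
`Σ_v(k_max − k_v)/((n−1)(n−2))` ∈ [0,1], 1 exactly for a star, 0 for any
regular graph. The centralization index behind published before/after
removal figures is not specified in the source material, so those exact
values are not asserted; the qualitative property — deleting the top-degree
hubs of a heavy-tailed subnetwork lowers centralization — is
property-tested across seeded replicates.

# Enrichment

Selection: top 20 per measure (descending `k, B, C`; ascending gSPD/cSPD —
*short* distances are "top"), ties broken lexicographically by node id so
rankings are reproducible, union across the five lists with membership
flags. The over-representation test is the one-sided Fisher/hypergeometric
`P(X ≥ x)`: enrichment is an inherently one-sided question and the source
procedure does not state sidedness. The background is caller-supplied: a
genome-wide background inflates enrichment for network-mapped genes, so
using the network's node set is the recommended (and pipeline-default)
choice; pathway membership is always intersected with the background so
the 2×2 table stays coherent. BH FDR is the in-package step-up
(`p_(i)·n/i`, cumulative minimum from the largest, capped at 1); note BH
adjustment is *not* idempotent in general (p = {0.1, 0.9} adjusts to
{0.2, 0.9}, which re-adjusts to {0.4, 0.9}) — a property sometimes claimed
but easily falsified, so tests pin the step-up definition instead. The
reporting filter keeps pathways with FDR p strictly below 0.001 *and*
overlap ≥ 5.

# The synthetic world

The generator's job is to emulate the *relevant* features of an empirical
interactome analysis, with truth recorded:

* **Network**: linear preferential attachment (default `m_attach = 5`)
  gives the heavy-tailed degree distribution that drives hub statistics; a
  duplication–divergence model (`p_retain = 0.4`, `p_anchor = 0.1`,
  seeded from a 5-cycle) is available when modularity matters, and plain
  `G(n,m)` for calibration. Default scale is 2,000 nodes / ~10,000 edges
  so the full suite runs in well under a minute; the empirical-scale preset
  is `n = 10549` (≈ 53k edges at `m_attach = 5`), mirroring the 10,549
  proteins / 53,255 interactions of the merged human network the analysis
  design comes from.
* **Planted sets**: membership sampled without replacement with
  probability `∝ k^α`. The mechanism biases *membership*, not wiring: the
  network is identical across sets, so between-set differences are
  attributable to selection alone — exactly the design of comparing gene
  sets on one fixed interactome. Defaults scale the empirical set
  proportions (342/10549 ≈ 3.24% "cancer", 1896/10549 ≈ 17.97%
  "essential") to the requested `n`, with α = 1.5 and 0.8; the control set
  is everything else. α = 0 is the null world used for type-I-error
  calibration.
* **Catalog**: uniform pathways plus `n_enriched` pathways whose members
  are drawn with weight `enrichment_factor` (default 20) on the target
  set. Factor 1 is the enrichment null.

What a green test does **not** establish: the generator has no
study-ascertainment bias (much-studied genes accruing interactions), no
false-positive/false-negative interaction structure, no correlated
multi-database provenance, and preferential attachment is not a mechanistic
model of interactome evolution. Green tests certify the *pipeline* —
measures, tests, nulls, and their calibration — not any biological claim
about real cancer genes.

# Numerical and degenerate-input choices

* Distances/means: unreachable targets excluded; `NA` propagates out of
  set averages via defined-value means.
* `gSPD` errors when the set covers the whole network if called directly;
  `build_profile` instead marks the column `NA` so whole-network profiles
  still render.
* Empirical p-values are exact fractions of integers; seeded runs are
  bit-for-bit reproducible (`randomization_test` twice with one seed gives
  `identical()` results, and a world regenerates byte-identically from its
  truth record).
* Report TSVs print floats at 6 significant digits with sorted rows and
  lexicographic edge orientation, so diffs are meaningful.
* Config is JSON (no YAML parser in the supported dependency set); unknown
  keys are errors rather than silently ignored.

# Known limitations

* Betweenness is exact, not sampled: profiles on networks far beyond ~10⁵
  edges will be slow (the empirical-scale preset is fine).
* The G(n,m) null preserves only node and edge counts. A degree-preserving
  (configuration/edge-swap) null, modularity analysis, and weighted or
  directed variants are out of scope.
* The rank-sum/KS duality for "degree distributions differ" is reported,
  not resolved — the published pair of discordant p-values for that
  comparison cannot be reconstructed from the text that accompanies them.
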
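# netonco

Comparative network topology of protein sets in a protein–protein
interaction (PPI) network.

## The problem

Disease genes are increasingly studied not one locus at a time but as a
*set of proteins embedded in the interactome*: do they sit in more central,
more densely wired, or more mutually proximate positions than essential or
background proteins? `netonco` implements that comparison end-to-end for
any undirected PPI network and any named gene sets:

* **Interactome construction** — merge heterogeneous two-column edge lists
  (plain TSV or a minimal PSI-MI-TAB dialect), drop self-interactions,
  collapse duplicate pairs while keeping per-edge source provenance.
* **Topology profiles** — per protein: degree `k`, betweenness `B`
  (pair-dependency/Brandes by default, a literal shortest-path-count
  variant as an option), clustering coefficient
  `C(v) = 2 t(v) / (k(k−1))` (undefined for `k < 2`), and two set-relative
  distances: **gSPD** (mean shortest-path distance to reachable nodes
  *outside* the set) and **cSPD** (mean distance to reachable *other
  members* of the set). Per set: means of the defined values, `P(k)`, and
  hub fractions at strict cutoffs `k > 5` and `k > 12`.
* **Between-set statistics** — two-sided Wilcoxon rank-sum on per-node
  values (exact for small tie-free samples), two-proportion χ² (Yates) for
  hub fractions, Kolmogorov–Smirnov for degree distributions, Pearson
  correlation among measures.
* **Subnetwork null model** — extract a set's induced subnetwork and
  compare its mean betweenness `B`, clustering `C`, and mean shortest-path
  distance `L` (over reachable pairs) against `R` Erdős–Rényi `G(n,m)`
  replicates with matched node/edge counts. Empirical p-values use strict
  exceedance counts: `p_B = n_B/R`, `p_C = n_C/R` (replicates *above* the
  observed value) and `p_L = n_L/R` (replicates *below*). Freeman degree
  centralization `Σ(k_max − k_v) / ((n−1)(n−2))` quantifies how the
  subnetwork loosens when its top hubs are removed.
* **Enrichment of top proteins** — top-20 per measure (descending for
  `k, B, C`; ascending for gSPD/cSPD), union with membership flags,
  one-sided Fisher/hypergeometric test per GMT pathway
  (`P(X ≥ x)`, `X ~ Hypergeom(N, K, n)`), Benjamini–Hochberg FDR, and the
  reporting filter *FDR p < 0.001 and overlap ≥ 5*.
* **Synthetic worlds** — heavy-tailed networks (preferential attachment or
  duplication–divergence), planted sets sampled with probability `∝ k^α`
  (α = 0 gives a uniform control), and GMT catalogs with planted-enriched
  pathways, all bit-reproducible from a seed, so every stage can be
  validated against known ground truth.

## Worked example

```r
library(netonco)

w <- generate_world(n = 2000, seed = 42)   # net + cancer/essential/control + catalog
prof <- build_profile(w$net, w$sets$cancer)
print(prof)
#> topology profile 'cancer' (65 proteins)
#>     set n_genes n_mapped connectivity betweenness clustering     gSPD     cSPD
#>  cancer      65       65     87.46154     36010.2  0.1093507 2.342278 2.140865
```

The planted degree bias (α = 1.5) is detected against the uniform control:

```r
profs <- lapply(w$sets, function(s) build_profile(w$net, s))
compare_profiles(profs, list(c("cancer", "control")))
#>   measure  set_a   set_b       test statistic  p_value n_a  n_b
#> 1       k cancer control   wilcoxon  8.38e+04 1.54e-21  65 1576
#> 7   hub>5 cancer control chi_square  3.42e+01 5.08e-09  65 1576
```

The induced cancer-like subnetwork is far from random: its clustering is
five-fold the `G(64, 221)` null and its internal distances are shorter, so
both empirical p-values are 0/1000:

```r
sub <- induced_subnetwork(w$net, w$sets$cancer)
randomization_test(sub, reps = 1000, seed = 42)
#> G(n=64, m=221) null, 1000 replicates
#>   observed  B=36.22 C=0.5361 L=2.15
#>   null mean B=41.94 C=0.1103 L=2.333
#>   empirical p: p_B=1 p_C=0 p_L=0
```

Ranking the set by each measure, taking the union of the five top-20 lists
(44 proteins here) and testing the catalog recovers the planted pathways:

```r
tops <- lapply(c(k="k", B="B", C="C", gSPD="gSPD", cSPD="cSPD"),
               function(m) top_by_measure(prof, m, k = 20))
sel  <- union_top(tops)                                  # 44 proteins
rows <- fisher_enrichment(sel$gene, w$catalog, interactome_nodes(w$net))
head(filter_enriched(rows, 0.001, 5), 3)
#>   pathway_id n_overlap  p_value    fdr_p
#> 1     PW0010        21 4.23e-22 5.07e-20
#> 2     PW0003        16 6.33e-16 3.80e-14
#> 3     PW0007        13 4.73e-12 1.89e-10
```

All ten pathways passing the filter are exactly the ten planted ones
(`w$truth$enriched_ids`).

The same analysis runs from one JSON config:

```r
run_all(list(simulate = list(n = 2000, seed = 42), seed = 42), "out/")
# out/: summary.tsv, comparisons.tsv, nullmodel.json, enrichment.tsv,
#        enrichment_filtered.tsv, run_log.json   (byte-stable per seed)
```

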
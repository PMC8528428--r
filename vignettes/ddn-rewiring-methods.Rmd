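---
title: "Detecting dependency-network rewiring between drug-response conditions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting dependency-network rewiring between drug-response conditions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ddnrewire)
```

## The question the package answers

Pharmacogenomic screens pair transcriptomes of many cell lines with their
response to many compounds. For a given compound, the interesting signal is
often not which genes change in *level* between responders and non-responders,
but which gene–gene *dependencies* change: a gene cluster can keep its average
expression while completely re-organizing which of its members co-vary. This
package tests, for every (compound, gene cluster) pair, whether the cluster's
pairwise dependency structure differs between drug-sensitive and
drug-resistant cell lines — "rewiring" — and annotates the rewired network
with the genes that mediate the change.

The pipeline is: (1) dichotomize samples per compound by the area under the
dose–response curve (AUC); (2) estimate a per-condition dependency network
over the cluster's gene pairs; (3) score rewiring by a divergence between the
two networks and calibrate it with a label-permutation null; (4) correct
across the drug × cluster grid; (5) for significant cells, build the
annotated differential dependency network (DDN), flag mediator genes, and
aggregate everything into a sortable landscape.

## Model and statistic

**Cohorts.** For one compound, samples in the lowest `lower_q` AUC tail are
sensitive (low area = effective kill), the highest `upper_q` tail resistant,
the middle excluded. Defaults are tertiles (`lower_q = upper_q = 1/3`), a
balanced, assumption-light dichotomization; boundary ties join the extreme
group so the partition is deterministic. Groups below `min_group_size`
(default 15) are skipped as underpowered rather than failing the run: a
resampled 3×3 contingency test is unstable below roughly that size.

**Dependence between two genes.** Expression is reduced per gene to
equal-frequency tertile levels {0, 1, 2} (stable ranking, ties broken by
sample index). Discretization sacrifices some information for a dependence
test that is distribution-free and captures non-monotone coupling. Pairwise
dependence is the likelihood-ratio (G) test of independence on the 3×3 table,
with all-zero rows/columns removed; a table with fewer than two non-empty
rows or columns carries no information and counts as independent. Genes with
zero interquartile range are flagged degenerate and contribute no pairs
(they remain cluster members for bookkeeping).

**Per-condition network.** The candidate edge space of a cluster is every
unordered pair of its informative members (novel pairs) plus its
prior-knowledge interaction edges (known pairs). Prior knowledge assists
discovery through the inclusion threshold: known edges enter a resampled
structure at `alpha_known = 0.05`, novel pairs at the stricter
`alpha_novel = 0.01`. The condition's network estimate is the edge-inclusion
frequency over `n_resamples` (default 100) bootstrap draws of its samples.

A calibration point discovered during development and worth stating plainly:
if a size-preserved with-replacement draw is fed directly to the G-test, the
duplicated rows inflate the nominal test level by more than an order of
magnitude (we measured ≈ 0.19 empirical rejection at a nominal 0.01 with 60
samples), which would fill null networks with phantom edges. The engine
therefore tests each draw on its *distinct* samples and applies Williams'
small-sample correction to G; the measured null rejection is then ≈ 0.01 at
nominal 0.01. The exported `g_test_pair()` remains the plain G-test (its
closed forms are used as test oracles); the corrected variant is available
via `williams = TRUE`.

**Rewiring statistic.** Each pair's edge frequency is read as a Bernoulli
presence probability, and the statistic is the summed Jensen–Shannon
divergence in bits between the sensitive and resistant profiles:
`D = Σ_pairs JSD(Bern(p_s), Bern(p_r))`. `D` is symmetric, non-negative,
zero exactly when the profiles coincide, and bounded by one bit per pair —
so it is comparable across clusters of equal pair count and each pair's
contribution is interpretable in isolation.

**Significance.** `D` has no useful closed-form null, so significance comes
from a permutation test: the sensitive/resistant labels are permuted over the
pooled samples (group sizes preserved) `n_permutations` times (default 999),
both ensembles are re-estimated per permutation, and
`p = (1 + #{D_perm ≥ D_obs}) / (N + 1)` — the plus-one estimator, with ties
counted against rejection (conservative). Benjamini–Hochberg q-values are
computed across all non-skipped grid cells (skipped cells produce no p-value
and stay out of the denominator); `significant ⇔ q ≤ fdr_alpha` (default
0.05). FDR-wide control is the default because the drug × cluster grid is a
single family of hypotheses reported together.

## The annotated network and its mediators

For a significant cell, each candidate pair is classified from its two
frequencies: absent if `max(p_s, p_r) < presence_theta` (0.5); otherwise
condition-specific if the frequency difference exceeds `specific_tau` (0.3),
else present in both. Swapping the conditions maps sensitive ↔ resistant and
fixes both/absent. Known and novel edges keep their flag through export
(SIF/GraphML/JSON).

Two mediator classes describe genes that organize the rewiring:

* **Specificity mediators** — genes whose incident edges are unusually often
  condition-specific. "Unusually" is operationalized as a one-sided binomial
  tail against the network-wide specific-edge fraction:
  `P(X ≥ k | n, p₀) < mediator_alpha` with `k` specific of `n` incident
  edges. The binomial test was chosen because the network-wide fraction is
  the natural exchangeable background and the test is exact at the small
  edge counts DDNs have. A background of zero with any specific edge flags
  the node (the tail is 0); a background of one can never flag.
* **Essentiality mediators** — genes whose normalized betweenness centrality
  (fractional credit for tied shortest paths, normalization by
  `(n−1)(n−2)/2`) differs between the sensitive subgraph (sensitive + both
  edges) and the resistant subgraph by at least `bc_delta_cutoff` (0.3).
  Shared edges belong to both subgraphs because a "both" dependency exists
  in each condition's network. An absolute cutoff was preferred over a rank
  rule so the flag is reproducible from the stored node fields alone.
  Betweenness is computed with igraph; the test suite cross-checks it
  against exhaustive simple-path enumeration on small graphs.

Cluster members with no retained edges appear as nodes with zero metrics, so
mediator counts share a stable denominator across cells.

## Landscape, hotspots, drug classes

The landscape grid stores one cell per attempted (drug, cluster) pair. A
cell's weight is its mediator count (non-significant cells have no network,
hence zero). A drug's rewiring score is the summed mediator count over its
significant cells; cluster scores are symmetric; frequencies count
significant partners. This score is deliberately simple — it is the quantity
the landscape heatmap's margins display — and the scoring hook is isolated so
alternatives (significant-cluster count, `Σ(1−q)`) can be substituted.
Sorting is descending by score with ascending lexicographic tie-break, making
every export byte-deterministic. The hotspot view selects the top 15 drugs ×
top 5 clusters and reports, per selected cluster, the fraction of selected
drugs converging on it.

A drug class (drugs sharing a target) is summarized by the intersection of
its members' significant-cluster sets, and, per shared cluster, a combined
DDN built on the arithmetic mean of the members' edge frequencies. Pooling
frequencies (rather than intersecting per-drug DDN edges) keeps the combined
object a single network on which mediator detection is well defined, which
matches the intent of a "collective action" network; it is order-invariant in
the members.

## The synthetic-data generator

`simulate_cluster_data()` draws two-condition discretized expression with
planted pairwise dependencies: root genes are uniform over {0, 1, 2}; a child
copies its lowest-index parent with probability `rho`, else redraws
uniformly. Orienting edges by gene index makes the scheme acyclic by
construction, so no cycle handling is needed. The single-parent rule means a
gene listed with several higher-index partners realizes only the
lowest-index dependency — the generator's edge lists should be read as a
forest per condition. Continuous mode maps level ℓ to `Normal(ℓ − 1,
noise_sd)` with `noise_sd = 0.4`, a separation at which `discretize()`
recovers ≈ 85% of levels, i.e. realistic-but-imperfect discretization.

`simulate_landscape_fixture()` emits a complete pipeline input bundle
(expression TSV, AUC table whose tertile split recovers the intended groups
exactly, GMT/SIF catalog) with planted significant cells. Its defaults are
the package's standard study conditions: 180 samples (tertile groups of 60 —
the same per-condition size as the calibration and power studies below),
6-gene clusters with three disjoint planted edges at `rho = 0.9`, and prior
edges carrying the planted pairs.

What the generator does *not* emulate: transcriptome-scale covariance,
batch effects, dose–response curve shapes (AUC is consumed as given), or
library-size artifacts. Passing tests therefore demonstrate the statistical
behavior of the engine under its own model — calibration, power, and
determinism — not robustness to every failure mode of real expression data.

## Validation design and problem sizes

The test suite validates four layers, at sizes chosen to keep the default
run in the minutes range:

* **Analytic oracles** — divergence identities (0 for equal profiles, 1 bit
  for opposite deterministic edges, `H(0.75) − 0.5 ≈ 0.3113` bits for
  (1, 0.5)), closed-form G (`60·ln 3` on `diag(10,10,10)`), the binomial
  tail `0.3⁵ = 0.00243`, and the Benjamini–Hochberg step-up on
  `p = (0.01, 0.02, 0.03, 0.04)`.
* **Brute-force equivalence** — betweenness vs exhaustive path enumeration
  on 200 random graphs of ≤ 6 nodes; the G-test vs a direct textbook
  computation on 1,000 random 3×3 tables.
* **Null calibration** — 200 null datasets (6 genes, common structure, 60+60
  samples, R = 50, N = 99): the fraction of permutation p ≤ 0.05 must fall
  in the binomial band [0.02, 0.08].
* **Power and determinism** — a single rewired edge at `rho = 0.8`
  (60+60, R = 100, N = 199) is classified condition-specific and significant
  in ≥ 80% of 50 runs; a hub gene carrying two rewired edges against eight
  shared triangles is flagged as a specificity mediator in ≥ 80% of runs
  (the triangle background supplies enough stable shared edges for the
  binomial background to be meaningfully below 1 — a hub cannot be a
  specificity mediator in a network whose edges are all specific); and the
  3-drug × 2-cluster fixture run twice with one seed yields byte-identical
  artifacts, with the planted cell the grid's only significant cell in
  ≥ 80% of 20 repeats.

## Numerical and degenerate-input choices

* Quantiles are empirical type-7 (R's default linear interpolation)
  everywhere.
* Missing expression cells below the reader's 20% per-gene tolerance are
  assigned the middle level: they dilute dependence slightly instead of
  biasing it.
* `JSD` terms are clamped at zero against floating-point cancellation.
* Permutation and resample seeds derive from a string hash of
  `(seed, drug, cluster, permutation index)`, so every grid cell's result is
  unchanged by adding or removing other drugs, and the whole engine is a
  pure function of `(inputs, seed)`.
* The run manifest records wall-clock timing; everything else the pipeline
  writes is byte-deterministic.
* An edgeless DDN is valid: background fraction 0, all metrics zero.
* All-equal AUC vectors (tails overlap) are flagged degenerate and skipped,
  not errors.

## Known limitations

* The per-edge Bernoulli view ignores correlation between edge inclusions
  within a resample; `D` is a sum of marginal divergences, not a divergence
  between joint network distributions. This is the price of an exactly
  testable, decomposable statistic.
* Permutation re-estimates both ensembles per relabeling, so cost scales as
  `N × R × pairs`; clusters above `max_cluster_size = 60` members are
  refused to bound the quadratic pair space.
* With ~300 candidate pairs and `alpha_novel = 0.01`, a null pair
  occasionally reaches an inclusion frequency above `presence_theta` in one
  condition (a "lucky" data realization); such edges appear
  condition-specific and add background noise to mediator detection. The
  binomial background test absorbs this at the rates we measure, but
  mediator flags in very sparse DDNs should be read with their
  `specificity_p`.
* Tertile dichotomization discards the middle third of samples by design;
  compounds whose response distribution is not bimodal lose power relative
  to a tailored cut.
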
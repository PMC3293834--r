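---
title: "Genetic-interaction filters for minimotif predictions: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Genetic-interaction filters for minimotif predictions: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gimotif)
```

## The problem

Minimotifs (short linear motifs) are contiguous peptide elements, usually
under 15 residues, that mediate binding, posttranslational modification or
trafficking. Because their consensus definitions are short, scanning a
query protein against a motif catalogue yields many matches that occur by
chance. Each prediction, however, comes with a *pair* of proteins — the
source S containing the motif and the target T acting on it — and that
pair can be checked against orthogonal functional data. Genetic-interaction
(GI) screens in yeast, fly and worm provide hundreds of thousands of gene
pairs with an experimentally observed functional relationship (synthetic
lethality and the like), and an enzyme/substrate relationship that is too
transient to appear in physical-interaction screens can still leave a GI
trace. `gimotif` turns GI data into filters over predicted (S, T) pairs.

## The three filters

All filters operate on one canonical structure (`build_network()`): an
undirected, unweighted graph over canonical gene ids with a
case-insensitive alias index. GIs are treated as symmetric and unsigned;
epistasis sign, edge weights and directionality are out of scope.

**Basic GI filter.** Resolve S and T through the alias index to candidate
gene sets S′ and T′ (an ambiguous alias contributes all its candidates — a
deliberate bias toward sensitivity, since the filter's job is retention).
Retain the motif iff some s ∈ S′ and t ∈ T′ share an edge. A motif whose
source or target resolves to nothing fails with an explanatory note rather
than raising an error, because the filter runs over thousands of rows.

**GI-node filter.** For i = 1..N (N = `node_count`), grow the *cumulative*
radius-i balls around S′ and T′ and retain the motif at the first i at
which any edge joins the two balls. Two design points deserve emphasis:

* *Cumulative balls, not frontiers.* The expansion at iteration i includes
  everything within distance i, not only the newly discovered frontier.
  This makes the filter a monotone superset chain — every motif the basic
  filter retains is retained at N = 1, and pass sets only grow with N —
  which is the behaviour one wants from a sensitivity-increasing
  relaxation, and it cannot miss the direct edge the way a frontier-only
  reading can. Under this semantics the decision is equivalent to
  d(S′, T′) ≤ 2N + 1 for resolved, distinct genes (asserted against a
  shortest-path oracle in the tests).
* *N counts expansion iterations.* The default is N = 2; selectivity
  degrades steeply beyond that (each iteration roughly squares the
  neighborhood), so `node_count > 4` triggers a warning.

**GI-HomoloGene filter.** Map S′ and T′ to their homolog clusters and
retain the motif if any member A of the source cluster interacts with any
member B of the target cluster; by default A and B must carry the same
known taxon (`require_same_species = TRUE`), so the filter extrapolates a
*within-species* GI observed between homologs in another organism. Three
permissive choices keep it a superset of the basic filter on
taxon-annotated data:

* genes absent from the homolog map fall back to singleton clusters rather
  than failing;
* the interacting pair may be S′ and T′ themselves;
* a source or target absent from the GI network is still looked up in the
  homolog map under its canonical name — a gene with no recorded GI of its
  own but with interacting homologs is exactly the case the filter exists
  for.

Members with unknown taxon never satisfy the same-species constraint, and
relaxing the constraint can only add passes (a tested invariant).

**Composition.** `generic_network_filter()` applies the direct lookup to
any network, typically physical protein–protein interactions (PPI);
`combine_decisions()` takes unions and intersections (union sensitivity is
never below the best constituent); `apply_filters()` adds exclude polarity
— retaining the motifs *without* GI support, useful for studying what the
filters discard — and external-flag filters that read precomputed verdicts
of other filter families (frequency score, cellular function) from the
input table. Those families' internals are out of scope here.

## Evaluation harness

`evaluate_filter()` reports, in percent: **sensitivity**, the share of
true motifs retained, and **selectivity**, the share of random-pair
negatives retained. This use of "selectivity" is nonstandard — it is an
empirical false-positive rate, *lower is better*, not specificity — and is
kept because the **discrimination ratio** DR = sensitivity/selectivity is
defined on it (DR > 1 favorable). Display rounding is one decimal; full
precision is retained internally.

Negative sets come from `generate_negative_pairs()`: distinct uniformly
random same-pool gene pairs, defensible as negatives because known GIs are
a negligible fraction of the ~n(n−1)/2 possible pairs
(`possible_pair_count(25000)` ≈ 312 million). A `"exclude_known"` policy
additionally rejects pairs present in a supplied network for stricter
benchmarking; the default keeps pure random sampling.

For ROC analysis the binary filters must be replaced by a graded score.
The ranking used by the original web system is not recoverable, so the
package defines its own documented score, `gi_evidence_score()`:
1/(1 + d) with d the shortest-path distance between the resolved sets,
plus a tie-break bonus of 1e-8·min(k, 100) for k witness pairs at distance
d. The bonus is far below any gap between consecutive 1/(1+d) levels on
realistic diameters, so score order always agrees with distance order.
`roc_auc()` sweeps thresholds over the distinct scores (ties collapse) and
integrates trapezoidally; the result equals the Mann–Whitney concordance
statistic, which the tests verify by brute-force pair counting and against
`pROC` as an independent implementation. Because the score is
package-defined, published AUC values for these filters are not comparable
and are not asserted anywhere; the ROC machinery is governed by
property-based tests instead. The smoothed (binomial-fit) ROC overlay some
reports show is likewise out of scope — curves here are empirical.

`stratify_metrics()` repeats the evaluation within activity or
sub-activity strata (binding vs posttranslational-modification motifs
behave very differently under GI filtering); strata with fewer than 5
positives are flagged low-n.

## The synthetic world

`simulate_world()` generates a complete, internally consistent test bed —
GI and PPI edge lists, alias table, homolog clusters, positive motifs and
random negatives — with *planted* statistical structure recorded in
`ground_truth`. The defaults are the package's reference benchmark
conditions:

| parameter | default | meaning |
|---|---|---|
| `n_positive_motifs` | 3000 | true (S, T) pairs with usable accessions |
| `p_pos_gi_edge` | 0.212 | chance a true pair carries a direct GI edge |
| `n_negative_pairs` | 27000 | random same-species pairs |
| `p_neg_gi_edge` | 0.029 | chance a random pair collides with a GI edge |
| `gi_conservation_rate` | 0.29 | chance a planted edge is copied between homologs in another species (the approximate GI conservation between closely related budding yeasts) |
| `n_genes`, `n_species` | 6000, 3 | yeast-proteome-like scale |
| `background_edge_prob` | 2e-4 | Erdős–Rényi within-species background |
| `p_ppi_given_gi` | 0.4 | chance a planted GI pair also gets a PPI edge |
| `alias_rate` | 0.2 | genes given a synthetic alias; motifs then use the alias half the time |
| `homolog_cluster_rate` | 0.3 | genes placed in cross-species clusters |

With these sizes the basic filter's expected sensitivity and selectivity
are simply the planted rates (21.2% and 2.9%, hence DR ≈ 7.3), up to
binomial noise and a negligible cross-collision term: at 6000 genes the
pair space is ~18 million, so the chance that a sampled negative pair
coincides with a planted positive edge contributes well under 0.01% to
either metric. The acceptance script and tests check recovery within 3
binomial standard deviations; these tolerance bands were fixed from the
planted rates before any measurement and are not tuned.

Design choices worth recording:

* *Erdős–Rényi background.* The filters depend only on edge existence and
  path length, not on degree distribution, and ER keeps the collision
  arithmetic analytic for the tests. Realistic scale-free topology is a
  non-goal; consequently the GI-node filter gains much less over the basic
  filter on synthetic worlds than it does on real, dense GI networks,
  where hub genes put many pairs within distance 2N + 1. Passing tests
  demonstrate correctness of the algorithms, not real-data effect sizes.
* *Per-activity planting.* `per_activity_gi_rates` (e.g.
  `c(modifies = 0.56, binds = 0.19)`, the stratified rates observed for
  modification vs binding motifs) overrides the global rate per activity;
  the default is `NULL` so that the headline benchmark world uses the
  single global rate 0.212, matching how the aggregate metrics are
  defined. The stratified configuration is exercised in the stratification
  tests.
* *Conservation copies planted edges.* A conserved edge is a cross-species
  copy of an edge that exists, so in synthetic worlds the HomoloGene
  filter retains a superset of the basic filter's passes but gains little
  sensitivity; its real-data gain comes from pairs whose only evidence
  lives in another species, which the generator does not fabricate
  (`gi_conservation_rate` applies to planted edges, per its definition).
* *Taxon-complete homolog maps.* Every gene gets at least a singleton
  cluster record carrying its species, so the same-species constraint is
  decidable for all genes and the basic ⊆ HomoloGene nesting holds
  world-wide. Genes outside any cross-species cluster simply have nothing
  to extrapolate from.
* *Same-species sampling.* Both motif pairs and negative pairs are drawn
  within one species, mirroring how source/target pairs arise.
* *Determinism.* The world is a pure function of `world_config()`
  including its seed; `world_to_files()` output is byte-identical across
  runs, which the tests verify by checksum.

## Numerical and degenerate-input choices

* Identifiers are compared case-insensitively after trimming; edges are
  stored with lexicographically ordered endpoints and deduplicated on
  (pair, interaction kind). Witnesses use the same canonical `"a--b"` form.
* Self-loop edges are legal and retained; a motif whose source equals its
  target passes the basic filter only if a self-loop exists (conservative:
  the graph is the sole arbiter).
* Unknown seed genes survive neighborhood expansion as isolated vertices;
  empty gene sets never interact; radius 0 is the seed itself.
* `sample_distinct_pairs()` switches from rejection sampling to full
  enumeration when the request exceeds 40% of the pair space, so
  near-exhaustive draws terminate; both paths are seed-deterministic.
* Zero selectivity reports DR as infinite rather than dividing by zero.
* Problem sizes in the tests are chosen to keep the full suite under a few
  minutes: the benchmark world runs once at full 3000/27000 scale; the
  property loops use 100 worlds of 40 genes and graphs of ≤ 50 nodes,
  which is where the brute-force oracles (O(n²) scans, BFS, exhaustive
  pair counting) are exact and cheap.

## Known limitations

* GI sign (positive/negative epistasis), interaction weights and
  directionality are ignored throughout.
* The BioGRID dialect maps only the official-symbol and
  experimental-system-type columns; identifier-namespace reconciliation
  (e.g. Entrez ids vs symbols) is limited to the alias table the caller
  supplies.
* Orthology is consumed, never computed: the homolog map is whatever the
  flat file says, a gene belongs to at most one cluster, and
  paralog/ortholog distinctions within a cluster are not made.
* The evidence score is a ranking device for ROC analysis, not a
  calibrated probability.
* Synthetic worlds validate algorithmic correctness and statistical
  recovery of planted rates; they deliberately do not reproduce real GI
  network topology, database redundancy, or identifier noise beyond simple
  aliases.
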
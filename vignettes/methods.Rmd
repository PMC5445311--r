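---
title: "Methods: variant prioritisation, druggability and co-expression context"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: variant prioritisation, druggability and co-expression context}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(oncoprior)
```

This vignette is the package's own account of its methods: the statistical
model behind each stage, the tunable parameters and why their defaults are
what they are, what the synthetic-data generators do and do not emulate, and
the design decisions taken where more than one reasonable choice existed.

## The prioritisation problem

A tumour exome yields hundreds to thousands of somatic calls, most of them
passengers. Prioritisation contrasts three kinds of evidence per variant:
membership in germline catalogues (evidence *against* a somatic driver —
1000 Genomes flags are a common artifact of somatic calling pipelines),
recurrence in cancer catalogues (COSMIC overlap: evidence *for* a driver),
and predicted functional impact from variant-effect algorithms. The package
deliberately does not benchmark or recalibrate the prediction algorithms; it
summarises their joint evidence and leaves the thresholds to the analyst,
recording every choice in the output's provenance block.

## Consensus clustering of rankscores

Rankscores place all prediction algorithms on a common [0, 1] scale (the
score's rank among all possible non-synonymous SNVs). Families of algorithms
— conservation-based, protein-function-based, ensemble — correlate strongly
within themselves, so summing raw scores would double-count evidence.
`consensus_cluster()` finds the redundancy structure: for each of `reps`
replicates it draws `p_item` of the algorithms and `p_feature` of the
variants (defaults 100, 0.8, 0.8), clusters the drawn rankscore profiles by
average-linkage agglomeration on `1 − Pearson correlation`
(pairwise-complete observations), and cuts at every `k` in `k_range`. The
consensus index of an algorithm pair is the fraction of replicates in which
both were drawn and co-clustered; the final partition at each `k` clusters
the consensus matrix itself.

Distance and linkage are a design choice: rankscores are comparable in
[0, 1], correlation captures "carries the same information", and average
linkage matches the dendrogram-centric workflow of the consensus-index
heatmap. Pairs never co-sampled (possible at small `reps`) get consensus 0
with a warning rather than an error. A single integer seed drives the whole
resampling schedule sequentially, so results are bit-reproducible.

**Choosing k.** `cdf_and_delta()` computes `A(k)`, the exact area under the
empirical CDF of the upper-triangle consensus indices, and the relative
change `Δ(2) = A(2)`, `Δ(k) = (A(k) − A(k−1))/A(k−1)`. `select_k()`
automates the usual visual rule as "the largest `k` with `Δ(k) ≥ 0.05`",
with an always-winning user override recorded in provenance. A known
limitation, documented here deliberately: consensus clustering with a
deterministic hierarchical inner loop over heavily-overlapping subsamples
keeps sub-splits of a true cluster partially stable, so `A(k)` continues to
grow past the true `k`. In planted-block simulations the partition at the
true `k` is recovered essentially perfectly (adjusted Rand index 1), and the
automatic rule finds `k` for 4–5 planted blocks, but for 2–3 well-separated
blocks it systematically over-selects — the classical overestimation
artifact of the consensus CDF. With real rankscore data the practical
workflow is to inspect `plot(<consensus_result>)` and override; the 4-block
structure typical of melanoma-style rankscore data is selected correctly by
the rule.

## The combination score

Given a partition of algorithms into `m` clusters, the per-variant score is
`c = Σ_j y_j` with `y_j = x̄_j` if `x̄_j ≥ 0.75`, else 0, where `x̄_j` is the
mean of the variant's non-missing rankscores in cluster `j`. Decisions baked
into `combination_score()`:

* The 0.75 gate is **inclusive** and fixed on the theoretical [0, 1]
  rankscore range ("upper quartile" of the scale, not of the dataset); an
  empirical-quartile mode is available via `threshold = "empirical"`.
* The per-cluster mean is taken **per variant**; the alternative reading (a
  dataset-wide cluster mean) would make `c` constant across variants and
  useless for ranking.
* Missing rankscores are averaged out, never imputed as 0 — conservation
  scores are genuinely undefined for some variant types. A variant whose
  clusters are all missing gets a missing score: it cannot pass a score
  cutoff but remains eligible for rescue filters.
* `0 ≤ c ≤ m`, and `c` is monotone non-decreasing in every rankscore (the
  gate only opens).

## Filter algebra

`apply_filters()` keeps a variant iff

```
protein_changing AND germline_pass AND (score ≥ cutoff OR cosmic_rescue OR ddr_rescue)
```

COSMIC and DNA-repair membership act as **rescues** (a union with the
score-passers), not as additional conjunctive filters: including known
cancer variants must be able to grow the prioritised set, which is the only
reading consistent with rescue settings yielding more variants than the
score cutoff alone. The score comparison is inclusive (`≥`) with a
strict-mode flag; germline filtering is strict by default, or lenient with
`max_1000g_af` (some bona fide somatic hotspots appear at low frequency in
germline panels). DNP/DEL/INS variants lack most prediction scores and rely
on the rescue paths — a documented limitation, not a bug. A cutoff above 1
demands evidence in at least two algorithm clusters.

`cutoff_curve()` reports kept counts over a cutoff grid (non-increasing by
construction); `assemble_top_table()` merges patients per unique
(gene, protein change, type), renders COSMIC entity counts as
`entity:count` sorted by count, sorts by score descending then gene
ascending, and attaches the full configuration as provenance that
`write_top_table()` emits as `#` comment lines.

## Druggability

The interaction snapshot is a file, not a live API: hermetic tests and
version pinning outweigh freshness for a reproducible analysis. Source
rules: My Cancer Genome entries always; TEND entries only when
antineoplastic; anything else is dropped with a warning. The join is by
uppercased gene symbol, deliberately ignoring the tumour entity a drug was
approved in (off-label reasoning); one hit per (variant, drug class) with
sources merged. `patient_summary()` counts distinct patients with any hit,
patients with ≥ 2 distinct (gene, protein change, drug) combinations (and,
separately, exactly 2), and distinct patients per drug class. The packaged
93-patient melanoma case study reproduces its printed summary from the raw
table at run time; no count is stored.

## Co-expression network

The network is **unsigned**: adjacency `|cor(x_i, x_j)|^β` (the
signed/unsigned choice is genuinely open in the field; unsigned keeps
strongly anti-correlated genes in one module, which suits a variant-context
view). `pick_soft_power()` applies the scale-free criterion — smallest β
with model-fit R² ≥ 0.8 for the regression of log₁₀ p(k) on log₁₀ k over 10
connectivity bins — falling back to the conventional β = 6 with a warning
when nothing qualifies (modular fixtures, for instance, are not scale-free;
that is expected). The topological overlap
`TOM_ij = (Σ_u a_iu a_uj + a_ij)/(min(k_i, k_j) + 1 − a_ij)` smooths the
adjacency by shared neighbourhoods; `1 − TOM` is the clustering
dissimilarity.

**Tree cut.** Adaptive branch cutting is *not* re-implemented. Modules come
from a static cut: branches merging below an absolute height `cut_height`
(default 0.99 on the [0, 1] TOM-dissimilarity scale) with at least
`min_module_size` genes (default 30) become modules 1..M ordered by
decreasing size; everything else is module 0, the conventional container for
genes not significantly co-expressed. The absolute-height convention (rather
than a quantile of merge heights) is what makes the noise case behave:
uncorrelated genes have TOM dissimilarities essentially at 1, merge above
any sensible cut, and correctly end in module 0, whereas a merge-height
quantile would manufacture ~(1−q)(n−1) clusters from any data whatsoever.
The cost of the simplification is sensitivity to `cut_height` on complex
dendrograms with nested modules — the regime where adaptive cutting earns
its complexity.

**Eigengenes and membership.** A module's eigengene is the first principal
component of its standardised expression submatrix: one value per sample,
unit norm, sign-oriented so it correlates non-negatively with the module's
mean expression (PC sign is otherwise arbitrary). Module membership is
`K(i, q) = |cor(x_i, E_q)|`. Relationships between modules are an
average-linkage dendrogram on `1 − cor(E_q, E_r)`, exportable as Newick.

## Gene and module significance

`GS = −log₁₀ p`, with base 10 fixed by contract for readability and
p-values floored at 1e−300 before the log. Dichotomous traits (lymphocyte
score, UV signature, primary vs metastatic — dichotomisation is the
caller's responsibility) use an unpaired two-sided Welch t-test with the
absolute mean-expression difference as effect size. Survival uses univariate
Cox proportional-hazards models (Breslow ties, Wald p) with effect size
`max(HR, 1/HR)` — direction-free, so dot-size weighting in the module view
never hides protective associations. Raw p-values are reported by default
(per-gene screening, not inference); a Benjamini–Hochberg flag exists.
Module significance is the mean |GS| over a module's scored genes; module 0
is computable but reads as background. Modules are named by the most
significant hypergeometric over-representation among user-supplied gene
sets (GMT file; no live ontology service) with **fewer than** 100 genes per
term — the strict bound excludes uninformative high-level terms — falling
back to `module_<id>` when nothing reaches p < 0.05; the size filter
applies to the term as supplied, before intersection with the network
universe.

## Synthetic data: what it emulates, what it does not

`make_variant_fixture()` plants algorithm-cluster structure with a
per-cluster latent deleteriousness per variant; Gaussian draws pass through
the probability-integral transform so marginal rankscores are exactly
uniform on [0, 1]. The latent within-cluster correlation defaults to 0.85
because the Gaussian-copula transform attenuates correlations (≈ (6/π)
asin(ρ/2) for the uniform margins), leaving observed rankscore correlations
around 0.84 — comfortably in the strongly-redundant regime the clustering
is meant to detect. Annotation flags are independent draws at configurable
fractions.

`make_expression_fixture()` builds modules as a shared latent factor plus
independent noise (within-module correlation 0.8 by default, 150 genes in
three modules of 50, 100 samples — the scale at which the whole suite runs
in seconds), shifts module 1's factor by `trait_effect` in trait-positive
samples, and draws survival as exponential with log-hazard linear in module
2's factor, administratively censored at a horizon giving roughly 30%
events under the null.

Neither generator emulates real data's heavy-tailed count distributions,
batch effects, correlated annotation errors, mutation spectra, or
correlated background expression. Passing tests therefore demonstrate
correctness of the algorithms under their own assumptions — planted
structure is recovered, statistics match their references — not performance
on real cohorts.

## Numerical and testing choices

* CDF areas are the exact integral of the step CDF (all-1 consensus → area
  0; all-0 → area 1), not a trapezoid across jump points.
* Degenerate all-zero-distance inputs (identical algorithms) collapse to a
  single cluster per replicate rather than an arbitrary tie-broken split, so
  the consensus is all ones and `select_k` falls back to the smallest
  candidate with a warning.
* Eigengene computation requires ≥ 2 genes per module (guaranteed by
  `min_module_size`); zero-variance genes get missing membership with a
  warning; genes are standardised before the PCA so expression scale does
  not dominate.
* Cox fits that fail to converge within 50 iterations (or degenerate
  covariates) yield missing values, never silent zeros.
* The null-calibration check of the survival screen simulates an
  independent 300-sample cohort per gene: sharing one risk-set realisation
  across genes shifts all p-values together and would inflate the spread of
  the mean beyond its nominal Monte-Carlo error, and n = 300 keeps the Wald
  reference accurate.
* Property suites run at deliberately small sizes — 50-variant cohorts for
  the filter oracle, 16–20 algorithms for consensus runs, 150 × 100
  expression matrices — chosen so each suite completes in well under two
  minutes while leaving the asymptotics of every statistic intact.

## Known limitations

* The static tree cut is a documented simplification; complex nested
  dendrograms are better served by adaptive cutting.
* Automatic `k` selection over-estimates for few, well-separated algorithm
  clusters (see above); the override exists for a reason.
* Druggability is annotation, not efficacy prediction; a hit means a
  curated interaction exists for the gene, nothing more.
* Cohort-scale counts from any specific published analysis depend on the
  annotation-database versions used there and are out of scope; the
  packaged case-study table is the one worked example carried verbatim.
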
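---
title: "Methods: consensus stratification of telomerase activity and the association battery"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: consensus stratification of telomerase activity and the association battery}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(telostrat)
```

## The problem

Telomerase re-activation is a near-universal route by which tumors escape
replicative senescence, but its activity varies widely across and within
cancer types. Given one expression-derived activity score per sample (an
EXTEND-style enrichment score; this package consumes the score, it does not
estimate it), the analysis framework implemented here answers three
questions:

1. Which samples are *low* and which are *high* telomerase activity? —
   unsupervised, by consensus k-means on the one-dimensional score vector.
2. How strongly does each sample (or cell, or spot) express a gene
   program such as a 125-gene senescence signature? — single-sample
   signature scoring with three engines matched to the data modality.
3. Which clinical, genomic-instability, and pathway features differ
   between the two groups? — an association battery with exact and
   rank-based tests, conventional effect sizes, and Benjamini–Hochberg FDR
   within each feature family.

A seeded synthetic-cohort generator plants the statistical structure those
analyses assume, so every stage is testable against a known ground truth.

## Stratification by consensus k-means

The score vector is clustered with k-means at $k = 2$. A single run draws
two distinct observed score values as initial centroids, applies Lloyd
assignment/update steps until the assignment is stable, and then applies a
Hartigan–Wong style *single-point transfer* stage: boundary samples are
moved across the split while the total within-cluster sum of squares (SS)
strictly improves. The transfer stage matters: on near-tied score vectors,
pure Lloyd iterations can stall one sample away from the SS optimum in a
local fixed point whose basin of attraction dwarfs the optimum's (we have
measured basins below 1% for the optimal split on unstructured vectors);
the transfer step is the standard cure and is what R's default k-means
algorithm does.

The robustness protocol runs `n_iter = 1000` iterations of
`n_init = 50` random initialisations each (50,000 runs in total). Each
iteration keeps its best-of-50 partition by within-SS and casts one
consensus vote; the per-sample final label is the majority vote over the
1000 iteration-level partitions, after aligning every partition so that the
cluster with the larger centroid is "high". The per-sample *consensus
fraction* (share of agreeing iterations, in $[0.5, 1]$) quantifies boundary
stability; exact 50/50 ties are labelled low and flagged. A
co-assignment-matrix consensus (average-linkage cut of the pairwise
co-clustering frequencies) is available behind `method = "coassign"`; in
one dimension it reproduces the majority vote and is provided for
comparability with generic consensus-clustering practice.

Because a $k = 2$ Lloyd trajectory in one dimension is fully determined by
the split index implied by its initial centroid midpoint, the implementation
memoises the convergence map over all $n - 1$ initial splits and evaluates
the 50,000 runs as table lookups; the full protocol costs milliseconds, so
no reduced mode is needed for the activity vector itself (tests still reduce
run counts where many cohorts are stratified in a loop).

Properties asserted by the test suite: the consensus partition of a sorted
score vector is always contiguous; labels are invariant under positive
affine transforms of the scores; and on random vectors ($n \le 200$) the
consensus partition equals the exhaustively enumerated minimum-SS threshold
split whenever that optimum is unique.

## Signature scoring engines

All three engines are rank-based, so the expression scale (raw, log, TPM)
is immaterial; this also settles the question of whether spot-level data
should be scored on raw or normalised counts.

**Bulk: weighted running-sum enrichment (ssGSEA-style).** Per sample, genes
are ranked by expression (average ranks on ties; the top gene carries rank
value $G$). Walking down the ranked list, the enrichment score is
$ES = \sum_i [P_{in}(i) - P_{out}(i)]$, with $P_{in}$ the
$r^\alpha$-weighted in-set CDF ($\alpha = 0.25$) and $P_{out}$ the uniform
CDF over out-of-set genes. The raw ES is reported with no cross-sample
normalisation: every downstream use is rank- or group-based, and a raw ES
keeps the single-sample contract (each score depends only on its own
column). Ties across the in/out boundary are ordered stably by gene id so
the score is invariant to row order.

**Single-cell: rank/odds-ratio composite (JASMINE-style).** Per cell, a
rank component (mean rank of *expressed* set genes among the cell's
expressed genes, scaled by the number of expressed genes; 0 when no set
gene is expressed) and an enrichment component (odds ratio of the 2×2
set-membership × expressed table, Haldane +0.5 on zero cells) are each
min–max scaled to $[0,1]$ across cells and averaged. The odds-ratio
enrichment variant is implemented; a likelihood-ratio variant would be a
drop-in alternative. A degenerate min–max range (all cells identical on a
component) maps that component to 0 for every cell — a deterministic,
test-friendly convention.

**Spot/module scoring: recovery-curve AUC (AUCell-style).** Per
sample/spot, the area under the step curve of cumulative set-gene recovery
over the top `top_fraction` (default 0.05) of ranked genes, normalised by
the ideal curve in which all reachable set genes occupy the very top ranks.
Scores lie in $[0,1]$ by construction.

Genes named in a set but absent from the matrix are dropped with a warning,
never imputed; an empty overlap, or a set covering every gene (empty
complement), is an error.

## Association battery

* **Fisher's exact test** (2×2): two-sided p by the small-p-values method
  (sum of hypergeometric probabilities no larger than the observed
  table's). Two-sided is used throughout. The reported odds ratio is the
  sample cross-product ratio with Haldane +0.5 applied iff any cell is
  zero — the conventional scale on which count-table odds ratios in this
  literature (e.g. values near 28) are reported — not the conditional MLE.
* **Welch t** with Satterthwaite degrees of freedom; effect is Cohen's d
  with the $(n-1)$-weighted pooled SD, the conventional reading of
  reported "effect sizes" near 0.6.
* **Wilcoxon rank-sum** with average ranks; p exact by enumeration when
  the combined sample size is ≤ 12 with no ties, otherwise the normal
  approximation with tie and continuity corrections; effect is the
  Hodges–Lehmann estimate, the median of all pairwise between-group
  differences.
* **Spearman correlation** as Pearson on average ranks, p from the
  t-approximation with $n-2$ df.
* **Benjamini–Hochberg step-up** q-values, computed within each submitted
  feature family (clinical, genomic, scores), mirroring per-analysis FDR
  reporting.

Effects are oriented high-minus-low (for Fisher: odds of the positive
covariate level in low vs high, so OR > 1 reads "low-enriched"), and each
row carries a `direction` of low_enriched / high_enriched / none by the
effect sign. Standard implementations back the standard steps: the Welch
and rank-sum p-values come from `t.test()` and `wilcox.test()`; the exact
2×2 p, the Haldane odds ratio, the Hodges–Lehmann estimate, Spearman's
t-approximation, and the BH step-up are computed directly as specified
above, and every path is checked in the tests against independent
enumeration oracles and against `fisher.test()`, `cor.test()` and
`p.adjust()`.

## Cohort-construction rules

* Age schemes: clinical YA (18–50 inclusive) vs OA (> 50); AYA (15–39
  inclusive) vs OA (> 39). The upper bounds are inclusive because the
  closed ranges are stated against open lower bounds — the only reading
  with neither gap nor overlap. Below-range ages are labelled `excluded`,
  never silently dropped, and are removed only from age comparisons, not
  from stratification.
* Stage harmonisation: sub-stage letters and case are stripped
  ("Stage IVb" → IV); I–II map to low-stage, III–IV to high-stage,
  anything unparsable to `unknown`.
* Recurrence filters: a mutated gene is *recurrent* when present in ≥ 2
  cancer types ("two or more"); a fusion is kept per cancer type when its
  frequency strictly exceeds 1% of samples (a strict ">").
* Cross-tabulation: every combination of low/high states over the chosen
  axes (telomerase, senescence, MAPK, ROS, immune flags, ...) is counted;
  the counts sum to the cohort size and are the tabulation behind a
  Sankey-style summary — rendering is out of scope.

## The synthetic cohort generator

The generator plants, per module:

* **Scores:** a two-component Gaussian mixture. Group sizes are
  deterministic (`round(mix_high * n)`), so composition assertions are
  exact. Default `mix_high = 0.43` emulates the reported 57%/43% low/high
  split; `mu_low = 0, mu_high = 1, sigma = 1` give an overlapping mixture —
  overlap is what real activity scores within a cancer type look like, and
  it leaves room for the within-group coupling term below (a 3-SD
  separation, used in the recovery tests, would by itself force the
  activity–senescence correlation far past the target).
* **Expression:** background genes i.i.d. normal (truncated at zero around
  per-gene baselines drawn once); `signature_size = 125` senescence genes
  shifted by `senescence_d = 0.6` per-gene SDs toward the low group, plus a
  continuous latent term proportional to the negated within-group residual
  of the activity score. The latent weight is calibrated per cohort by a
  1-D root search on a cheap proxy (Spearman of the score against the
  realized mean of the standardized signature block), then refined with a
  few secant steps against the Spearman with the actual running-sum
  senescence score, hitting the target `coupling_rho = -0.57` on the scale
  downstream analyses measure. The search is monotone in the weight and
  all noise is drawn before the search, so the result is deterministic.
* **Clinical:** binary covariates drawn so the expected 2×2 odds ratio of
  covariate vs low group equals the configured value (defaults: female sex
  OR 2, low stage OR 3, the reported average enrichments); ages uniform on
  18–85.
* **Genomic:** TMB negative-binomial (group means 5/15, size 2), CNA and
  LOH fractions Beta with group-dependent means (0.15/0.30 and 0.12/0.25),
  telomere-length ratio log-normal with group-dependent median (1.1 low /
  0.9 high — longer telomeres in the low-activity group, matching the
  ALT-associated pattern).
* **Single cells:** Poisson counts around per-gene baselines, an exact
  `round(frac_cycling * n_cells)` cycling flag, activity-program genes
  elevated (and signature genes depressed) by a `2^senescence_d` fold in
  cycling cells and the reverse in non-cycling cells.

All randomness flows from one root seed through documented child streams
(one per generator block; the initial-centroid draws of a consensus run use
one child stream), so partial re-runs reproduce bit-identically.

The generator does **not** emulate RNA-seq library-size or GC artifacts,
batch effects, survival times, spatial coordinates, or realistic
gene–gene correlation beyond the single planted program. Passing tests
therefore demonstrate that the pipeline recovers planted structure under
clean distributional assumptions — not that it is robust to the technical
artifacts of real cohorts.

## Numerical choices and degenerate inputs

* k-means ties: a sample equidistant from both centroids joins the lower
  cluster; empty clusters are reseeded at the point farthest from the
  remaining centroid; consensus vote ties go to "low" and are flagged.
* Fewer than 4 samples, non-finite scores, or fewer than 2 distinct values
  are stratification errors, as are score vectors that degenerate inside
  `stratify_scores_generic` (the error names the offending vector).
* A constant feature under Welch's test returns $t = 0, p = 1, d = 0$;
  both-groups-constant-but-unequal is an error. A zero 2×2 margin returns
  $p = 1$ with an undefined odds ratio. Constant input to Spearman yields
  an NA rho with a warning. All-missing features are skipped with a
  warning.
* BH input outside $[0,1]$ is an error; q-values are clipped to 1 and
  returned in input order.

## Problem sizes in the tests

The test-suite and the acceptance script use cohorts of 150–1000 samples,
200–300 genes with 40–60 signature genes (the full 125-gene default is
exercised in the 1000-sample coupling checks), 20 seeded replicates for
effect-recovery averages, and 100 replicates for the null-calibration
average; the consensus stratifier runs its full 1000×50 protocol on single
vectors and reduced 50×5 counts inside replicate loops. These sizes were
chosen so the whole suite runs on a laptop in about a minute while keeping
every Monte-Carlo tolerance several standard errors wide.

## Known limitations

* The stratifier is one-dimensional and binary by design; $k > 2$,
  multivariate inputs, and model-based (Gaussian-mixture) classification
  are out of scope.
* Survival modelling, differential expression, pathway-database
  enrichment, immune deconvolution, MAF parsing, and telomere-length
  estimation are consumed as upstream annotations or left to the dedicated
  tools for those tasks.
* The activity score itself is an input; nothing here validates the score
  estimator.
* With heavily overlapping mixtures the k-means boundary is a biased
  estimator of the mixture crossing point; consensus fractions quantify
  assignment stability, not classification accuracy against a latent truth.
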
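---
title: "Mining pharmacogenomic interactions with random forests: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mining pharmacogenomic interactions with random forests}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pgxforest)
```

# The statistical problem

A pan-cancer screen provides two matrices over a shared panel of cell
lines: a binary alteration matrix (rows of the source file are gene
alterations — `GENE_MUT`, `GENE_DEL`, `GENE_AMP` — columns are cell lines)
and a dose-response matrix (one row per compound, entries the AUC of the
dose-response curve on [0, 1], smaller = more cytotoxic, with many
unscreened combinations). A *pharmacogenomic interaction* is, statistically,
a drug × genotype interaction: the effect of administering compound *d*
rather than *d′* depends on the alteration profile of the treated cells.
`pgxforest` operationalizes the search in two stages: first, independent
per-compound models `Y_d ~ alterations` identify compounds whose response is
predictable from genotype and which alterations carry that signal; second,
compound pairs with similar average potency but different leading
alterations are tested directly for an interaction on the logit-AUC scale.

Random forests are the per-compound learner because the predictor set is
large and binary, the response continuous, interactions among predictors
are absorbed by the tree structure without being specified, out-of-bag
(OOB) resampling replaces cross-validation at no extra cost, and
permutation importance yields a testable per-alteration statistic.

# Per-compound modelling

## Forest and out-of-bag machinery

For each compound, cell lines with missing AUC are dropped (no imputation;
a model needs at least 10 screened lines — the same floor the missingness
QC uses). A regression forest of `B = 500` bootstrap CART trees is grown
(`ranger` back end), with `m = max(1, floor(p/3))` candidate predictors per
split — the classic regression default — minimum node size 5 and no depth
limit. Only `B` and `m` are treated as scientifically meaningful tuning
parameters; the remaining knobs follow the default ecosystem of the
reference implementation and are exposed as arguments. Cross-validated
tuning of `m` is deliberately avoided: with hundreds of models it buys
little and costs much.

The fit keeps its own books: the n × B matrix of bootstrap multiplicities,
every tree's prediction on every training row (computed by the package's
own flattened-tree traversal in C++, cross-checked in the tests against
the back end's `predict.all`), the OOB prediction of sample *i* as the mean
over the trees whose bootstrap missed it, and the OOB error curve
`e_b` = OOB MSE using only the first *b* trees, accumulated from running
per-sample prediction sums in O(nB). Samples that were in-bag in every
tree have no defined OOB prediction; they are flagged `NA` and excluded
pairwise from all downstream scores (at B = 500 the event has probability
`(1 − e^{-1})^{500}`, i.e. never happens in practice).

The *stability indicator* is the mean of the last ten squared successive
differences of `e_b`. Its raw value is stored; "stability reached" is
declared below 10⁻⁶, so the printed zero remains auditable.

## Concordance scoring

Predictive performance is the concordance correlation coefficient between
observed AUCs and OOB predictions,

$$\mathrm{CCC} = \frac{2\,\mathrm{cov}(Y, \hat Y)}
{\mathrm{var}(Y) + \mathrm{var}(\hat Y) + (\bar Y - \bar{\hat Y})^2},$$

with population (divide-by-n) moments throughout: mixing 1/(n−1) variances
with a squared mean difference that does not rescale would break the
[−1, 1] bound. The CCC penalizes location and scale shifts as well as
scatter, so it is never larger in magnitude than the Pearson correlation —
a deliberate conservatism when comparing models across compounds. Values
are reported ×100 and labelled none/poor/fair/moderate/substantial/excellent
on the half-open bins (−∞,0], (0,20], …, (80,100].

The 95% CI uses Lin's asymptotic variance of the Fisher-z-transformed CCC,
back-transformed. The construction is the field's standard for this
statistic, but it was an open design choice; it is recorded in the
provenance output so a bootstrap interval could be swapped in. Its coverage
is verified by simulation in the test suite (500 replicates at n = 50,
true concordance 0.5). A compound enters Report 1 when the lower bound
exceeds 20 ("at least fair"); the threshold is an argument, and lowering it
(e.g. to 10) admits less predictable compounds at the price of noisier
interaction clues.

## Importance testing

For tree *b* and alteration *j*, `imp_jb` is the tree's OOB MSE after
randomly permuting alteration *j* within the tree's OOB sample, minus the
unpermuted OOB MSE — one seeded permutation per (tree, predictor), drawn
in R and executed by the C++ kernel, so a brute-force recomputation in the
tests can replay the identical draws. Trees with fewer than two OOB
samples contribute nothing and the averaging divisor is adjusted. The mean
importance is normalized by the across-tree standard deviation (B − 1
denominator) into an approximate z-score, the p-value is the upper-tail
standard-normal area, and a Bonferroni correction by the number of
predictors in that model precedes the significance call at adjusted
p < 0.005 — the stricter-than-0.05 criterion advocated for new-discovery
claims. Degenerate conventions are explicit: a predictor never used by any
tree has all `imp_jb = 0`, hence sd = 0 and p = 1; sd = 0 with a positive
mean yields p = 0 and is flagged.

Normalizing by the across-tree sd (rather than the standard error
sd/√B) makes the z-score essentially independent of B and very
conservative under the null — the family-wise false-discovery simulations
in the acceptance tests find no discoveries in 200 null models — while
strongly determined alterations still reach z well above the Bonferroni
bar. Users should read the z-test as a screening device with tight type-I
control, not as a calibrated effect-size inference.

# Predictor reduction

The three steps run before any response is seen, so no selection-induced
optimism can leak into the OOB scores.

* **Driver filter.** Keep alterations whose gene is on a driver list. The
  gene of a label is the token before the suffix, with variant qualifiers
  cut at the first dot (`BRAF.V600E_MUT` → `BRAF`).
* **Variance filter.** An alteration present in proportion *p* has variance
  `p(1 − p)`; the threshold is the variance at the reference small
  proportion `min_proportion = 0.05`, i.e. 0.0475, and removal is strict
  (`<`), so a boundary alteration survives. Proportions above 0.5 are
  rejected as infeasible: the surviving frequency band `[p0, 1 − p0]`
  would be empty. The power functions make the cost of the threshold
  explicit: they compute two-sided two-sample *t*-test power from the
  noncentral *t* with group sizes `freq·n` and `(1 − freq)·n` used as-is
  (continuous, as power calculators conventionally do), and search the
  smallest adequate frequency on a 0.001 grid.
* **Redundancy clustering.** Complete-linkage clustering on `1 − r²`
  (for binary columns the Pearson r is the phi coefficient of the 2 × 2
  table), cut at `1 − min_correlation²` plus a 10⁻⁹ floating-point margin
  so that merges exactly at the boundary — pairs the threshold itself calls
  redundant — are included. Each cluster keeps its first member (smallest
  original column index: reproducible, and faithful to "the first
  alteration"). The full composition is stored and surfaces in Report 2,
  where a merged alteration counts as exactly as influential as its
  representative. The implementation is `stats::hclust`/`cutree`; the test
  suite checks it against a brute-force agglomeration oracle whose tie
  break (lexicographically smallest member indices at equal merge heights)
  is deterministic. One caveat is inherent to complete linkage: the
  representatives of two different clusters can, in adversarial geometry,
  still be closer than the cut height even though their clusters are not;
  the reduction is therefore idempotent on the well-separated structures
  the generator produces, but not as a mathematical identity.

Cell-line matching is part of the same contract: alteration-side names
carry `_TISSUE` suffixes in the upstream files while response-side names do
not, so matching uppercases both and strips a suffix only when the
remainder is a known tissue token (the vocabulary is an argument). The
exact normalization used upstream of the original datasets is not
documented anywhere authoritative; this rule is explicit, configurable and
dog-fooded by the synthetic generator, which emits suffixed GCT columns
and unsuffixed response columns.

# Missingness QC

Each compound's model sees only its screened cell lines, which perturbs the
variances and pairwise correlations the reduction thresholds were
calibrated on. Per compound the package reports the CCC (×100) between the
full-cohort and subset variance vectors and squared-correlation vectors
(strict upper triangle, fixed order — a paired agreement measure needs
aligned vectors), the share of retained alterations whose subset variance
falls below the threshold (percent) and of pairs whose subset |r| exceeds
the redundancy threshold (pcm, per hundred thousand). A column that
becomes constant in the subset has no defined correlation: such pairs are
excluded from the CCC vector but counted as degenerate violations and
reported (`n_degenerate`) rather than dropped silently. Note that the
squared-correlation CCC is only informative when the alteration matrix has
genuine correlation structure; between independent columns the r² profile
is noise and its CCC legitimately hovers near zero.

# Interaction screening

Candidate pairs are Report-1 compounds with |mean AUC difference| ≤ 0.02
and different top (most important significant) alterations; compounds with
no significant alteration cannot nominate a top and are skipped. For a
pair, every cell line contributes one row per compound for which it was
screened: response logit(AUC) with AUC clipped into [10⁻³, 1 − 10⁻³]
(screens do report exactly 1.0; clipping bounds the influence of boundary
values and is recorded in provenance), factor 1 the compound, factor 2 the
2 × 2 joint status of the two alterations (levels 00/10/01/11). The
interaction is tested by a nested-model F comparison — additive
`compound + combination` against the full factorial — which is order-free
and well-defined under the unbalanced designs real screens produce, and
coincides with the classical two-way ANOVA interaction term on balanced
data (asserted in the tests). The pairing of the two rows a cell line
contributes is ignored, matching the two-factor specification; a
mixed-model refinement is out of scope. Per-combination two-sample t-tests
and boxplot summary statistics (n, mean, median, quartiles, 1.5-IQR
whiskers) are attached so the four-panel comparison figures can be redrawn
from the summaries alone.

# The synthetic-data generator

`synthetic_config()` fixes the study conditions the tests run under:

| parameter | default | rationale |
|---|---|---|
| cell lines | 400 | between the smallest and average per-compound cohorts of real pan-cancer screens |
| independent alterations | 60, prevalences evenly spaced on [0.02, 0.5] | a wide spectrum that leaves the variance filter real work (sub-0.05 columns) while keeping tests fast |
| redundant groups | 3 pairs, flip probability 0.005 | realized within-pair r ≥ 0.95: exercises the clustering cut |
| drugs | 6 (two −1-logit effects on adjacent-prevalence ≈0.3 alterations, one −0.5-logit effect at prevalence 0.2, three null) | a planted candidate pair with near-identical mean AUCs, one moderate model, and null compounds to exercise the exclusion path |
| baseline logit-AUC | 1.5 (mean AUC ≈ 0.82) | matches the high average AUCs of real screens |
| noise sd | 0.1 logits | keeps planted effects clearly supra-noise, so recovery failures indicate bugs rather than power limits |
| missingness | 20% MCAR per drug | the real screens' average screened fraction |

Effects live on the logit scale, so the interaction module's ANOVA is
correctly specified under the generator — by design, to separate
correctness checks from robustness checks. The −1-logit demo effects (not
−2) are a power-analysis choice: the candidate screen compares mean AUCs
within a ±0.02 tolerance, and steeper effects push the binomial sampling
noise of the planted alterations' prevalences through that tolerance for
an appreciable fraction of seeds. The acceptance simulations that
specifically measure recovery of a −2-logit effect at prevalence 0.3 use
their own dedicated configurations.

What the generator does *not* emulate — and what passing tests therefore do
not establish — includes the empirical marginal structure of real
alteration data (co-occurrence and mutual exclusivity patterns, tissue
effects), screen-driven (non-MCAR) missingness, AUC heteroscedasticity in
the partial-response range, and effects expressed on the raw AUC scale
(model misspecification). Interaction rows `(drug_a, drug_b, alteration,
effect)` add a differential effect to `drug_b` only; truth additionally
records every drug pair whose total effect vectors differ, since any such
pair is a true statistical interaction.

# Numerical conventions and problem sizes

* Seeds: every stochastic routine takes an explicit seed; the pipeline
  derives per-drug seeds as `seed + drug_index` (fits) and
  `seed + 1000 × drug_index` (permutations), so adding or removing
  compounds leaves other models untouched. Forests run single-threaded for
  exact reproducibility.
* `ccc` requires length ≥ 2 (the analytic antithetic case lives on two
  points); the CI requires n ≥ 4 and |CCC| < 1.
* Benchmark bins are half-open so every real value maps to exactly one
  label; a CCC in (0, 1) on the ×100 scale is "poor".
* Permutation draws are `sample.int` permutations generated under one
  `set.seed`, per (tree, predictor); they are returned on request so audit
  code can replay them.
* Test problem sizes, chosen as a deliberate compromise between resolution
  and runtime: oracle checks run on ≤ 12-column matrices and a 2-tree,
  8-sample forest (exact agreement demanded); recovery simulations use
  n = 400 with B = 500 over 20 replicates; null calibration uses 200
  single-drug studies at B = 200 and 1000 null ANOVA replicates.

# Limitations

The per-compound models are pan-cancer: tissue heterogeneity is neither
modelled nor adjusted for, and tissue-specific or heterogeneity-aware
forest variants are out of scope. Missing AUCs are deleted, not imputed;
the QC quantifies, but does not correct, the resulting distortion.
Importance is marginal permutation importance — correlated predictors
level each other's scores, which is exactly why the redundancy clustering
runs first, and conditional importance variants are not provided. The
interaction ANOVA treats the two observations a cell line contributes as
independent. Finally, the z-normalization of importances is deliberately
conservative; users mining weaker signals should expect it to under-call
rather than over-call.
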
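# pgxforest

Random-forest mining of pharmacogenomic interactions in cancer cell-line
screens.

Large screening projects characterize hundreds of cell lines both
genomically (binary alteration calls: somatic mutations, gene deletions and
amplifications, e.g. `BRAF.V600E_MUT`, `MAP2K4_DEL`, `ERBB2_AMP`) and
pharmacologically (the area under the dose-response curve, AUC ∈ [0, 1],
with 0 the highest cytotoxicity). `pgxforest` is for statisticians and
computational biologists who want to ask, compound by compound, *which
alterations shape the response, how predictable that response is, and where
two compounds with the same average potency diverge on genotype* — the
statistical signature of a drug–gene interaction.

## What the package computes

1. **Response-blind predictor reduction.** Alterations are restricted to a
   driver-gene list, filtered on binary variance `p(1 − p)` (an alteration
   at the reference small proportion p₀ = 0.05 sets the threshold
   0.05 × 0.95 = 0.0475; anything strictly below is dropped), and de-duplicated
   by complete-linkage clustering on the distance `1 − r²` cut at
   `1 − 0.95² = 0.0975`, keeping each cluster's first member. Cluster
   composition is retained, so merged alterations stay interpretable as
   "as important as their representative". A noncentral-*t* power check
   (`power_of_frequency()`, `min_frequency_for_power()`) quantifies what
   the frequency threshold costs in detectable effect size.
2. **One regression forest per compound** (B = 500 bootstrap CART trees,
   `m = max(1, ⌊p/3⌋)` candidate predictors per split) on the cell lines
   screened for that compound. Out-of-bag predictions
   `Ŷᵢ = |Bᵢ|⁻¹ Σ_{b∈Bᵢ} Ŷᵢᵦ` (over the trees whose bootstrap missed
   sample *i*) give an internal estimate of predictive performance, and a
   trailing-window statistic on the OOB error curve certifies that the
   forest has stabilized.
3. **Concordance scoring.** Agreement between observed AUCs and OOB
   predictions is the concordance correlation coefficient
   `CCC = 2 cov(Y, Ŷ) / [var(Y) + var(Ŷ) + (Ȳ − Ȳ̂)²]`, reported ×100 with
   a Fisher-z asymptotic 95% CI and the conventional benchmark labels
   (≤0 none, …, >80 excellent). A compound is "at least fairly" predictable
   when the lower CI bound exceeds 20.
4. **Permutation-importance testing.** For every tree and alteration, the
   increase in that tree's OOB MSE after permuting the alteration within
   the tree's OOB samples is recorded; the across-tree mean is normalized
   by the across-tree standard deviation into a z-score, turned into an
   upper-tail normal p-value and Bonferroni-corrected within the model;
   significance means adjusted p < 0.005.
5. **Missingness QC.** Per compound, how much does dropping unscreened cell
   lines distort the alteration variances and pairwise squared correlations
   the reduction was calibrated on (CCC of the two profiles, plus threshold
   violation rates in % and pcm)?
6. **Reports and interaction screening.** Report 1 lists the at-least-fair
   compounds with their significant alterations; Report 2 ranks alterations
   by how many Report-1 compounds they influence. Compound pairs with
   similar mean AUC (|Δ| ≤ 0.02) but different top alterations are screened
   and tested for a drug × alteration-combination interaction by a two-way
   ANOVA on logit(AUC) (nested-model F: additive vs full factorial).
7. **Synthetic studies with ground truth** (`synthetic_config()`,
   `make_study()`): binary alterations across a wide prevalence spectrum
   with near-duplicate columns, logit-scale responses with planted main and
   differential effects, and per-drug MCAR missingness — so the whole
   pipeline is testable without the original downloads.

## Worked example

```r
library(pgxforest)

study <- make_study(synthetic_config(), seed = 1)   # 400 cells, 6 drugs
run   <- run_pipeline(study, num_trees = 500, seed = 1)
print(run)
```

```
Pharmacogenomic mining pipeline
Three-step alteration reduction
 input: 63 -> drivers: 51 -> variance filter: - 3 -> clusters: 45 (42 singletons)
 thresholds: variance 0.0475 (p0 = 0.050), distance 0.0975 (|r| = 0.95)
 6 compound model(s) (0 skipped), 3 in Report 1, 3 alteration(s) in Report 2
 1 candidate pair(s) tested for interaction | elapsed 12.4 s
```

Of the 63 generated alterations, 12 involve non-driver genes, 3 are too
rare to clear the variance threshold and 3 are near-duplicates merged by
the redundancy clustering, leaving 45 predictors. The three drugs that
truly depend on an alteration are the three that reach Report 1:

```r
run$report1[, 1:7]
#>   compound  ccc ci_lower ci_upper mean_auc sample_size n_significant
#> 1   drug_2 96.8     96.2     97.3    0.760         323             1
#> 2   drug_1 96.8     96.1     97.3    0.754         309             1
#> 3   drug_3 88.3     85.9     90.3    0.801         322             1
```

Each model recovers exactly its planted alteration (`G037_MUT`,
`G036_AMP`, `G023_DEL`) as significant. `drug_1` and `drug_2` have
near-identical mean AUCs (Δ = 0.006) but different top alterations, so they
are flagged as a candidate drug–gene interaction, and the two-way ANOVA on
logit(AUC) confirms it:

```r
run$candidates[, c(1, 2, 5, 6, 7)]
#>   compound_a compound_b auc_difference top_alteration_a top_alteration_b
#> 1     drug_2     drug_1         0.0058         G037_MUT         G036_AMP
run$interactions[[1]]
#> Drug-gene interaction test: drug_1 vs drug_2
#>  interaction F(3, 624) = 2102.76, p = 0
```

The three null drugs have OOB CCCs near zero and are (correctly) excluded.
Real studies enter through the same door:

```r
study <- match_cell_lines(read_alteration_gct("alterations.gct"),
                          read_response_table("responses.csv"))
run   <- run_pipeline(study, drivers = read_driver_genes("drivers.txt"),
                      out_dir = "results")
```

or from a shell via the bundled CLI (`inst/cli/pgxforest run ...` /
`... simulate ...`).

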
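# Missing-response quality control: per compound, how does restricting to
# the screened cell lines perturb the alteration variances and pairwise
# correlations the reduction thresholds were calibrated on?

#' Impact of per-compound missingness on the reduction geometry
#'
#' For one compound's screened subset, compares the alteration variance
#' vector and the pairwise squared-correlation vector (strict upper
#' triangle, fixed order) of the full cohort against the subset, via the
#' CCC (x100 scale), and reports the rate of threshold violations:
#' alterations whose subset variance falls below the variance threshold
#' (percent) and pairs whose subset |r| exceeds the redundancy threshold
#' (pcm, per hundred thousand). Pairs where a subset column becomes
#' constant have no defined correlation; they are excluded from the CCC
#' vector but counted as degenerate threshold violations (`n_degenerate`),
#' not dropped silently.
#'
#' @param alterations Post-reduction alteration matrix (cell lines x
#'   alterations).
#' @param observed Logical vector, `TRUE` where the compound's AUC is
#'   observed.
#' @param min_proportion Variance-threshold proportion used in reduction.
#' @param min_correlation Redundancy correlation used in reduction.
#' @return One-row data frame: `sample_size`, `ccc_variances`,
#'   `ccc_sq_correlations` (both x100), `frac_low_variance` (%),
#'   `frac_high_correlation` (pcm), `n_degenerate`.
#' @export
missingness_impact <- function(alterations, observed, min_proportion = 0.05,
                               min_correlation = 0.95) {
  assert_alteration_matrix(alterations)
  if (length(observed) != nrow(alterations)) {
    stop("observation mask not aligned with cell lines")
  }
  if (sum(observed) < 10L) stop("fewer than 10 screened cell lines")
  sub <- alterations[observed, , drop = FALSE]
  v_full <- binary_variance(colMeans(alterations))
  v_sub <- binary_variance(colMeans(sub))
  vthr <- binary_variance(min_proportion)

  upper <- upper.tri(diag(ncol(alterations)))
  r2_full <- cor(alterations)[upper]^2
  sub_const <- colMeans(sub) %in% c(0, 1)
  r_sub <- suppressWarnings(cor(sub))
  r_sub[sub_const, ] <- NA_real_
  r_sub[, sub_const] <- NA_real_
  r2_sub <- r_sub[upper]^2
  defined <- !is.na(r2_sub)
  n_pairs <- length(r2_sub)
  n_degenerate <- sum(!defined)
  high_cor <- sum(abs(r_sub[upper][defined]) > min_correlation) + n_degenerate

  data.frame(
    sample_size = sum(observed),
    ccc_variances = 100 * ccc(v_full, v_sub),
    ccc_sq_correlations = if (sum(defined) >= 2) {
      100 * ccc(r2_full[defined], r2_sub[defined])
    } else {
      NA_real_
    },
    frac_low_variance = 100 * mean(v_sub < vthr),
    frac_high_correlation = if (n_pairs) 1e5 * high_cor / n_pairs else 0,
    n_degenerate = n_degenerate,
    stringsAsFactors = FALSE
  )
}
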
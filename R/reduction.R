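# Response-blind three-step predictor reduction: driver-gene filter,
# binary-variance filter, redundancy clustering. All steps see only the
# alteration matrix, never the responses, so no selection-induced
# overfitting can occur downstream.

#' Gene symbol of an alteration label
#'
#' Strips the `_MUT` / `_DEL` / `_AMP` suffix; a variant-qualified token
#' (`BRAF.V600E_MUT`) maps to the gene before the first dot (`BRAF`).
#'
#' @param label Character vector of alteration labels.
#' @return Character vector of gene symbols.
#' @export
gene_of <- function(label) {
  ok <- grepl("_(MUT|DEL|AMP)$", label)
  if (!all(ok)) {
    stop(
      "unknown suffix in alteration label(s): ",
      paste(head(label[!ok], 5L), collapse = ", ")
    )
  }
  sub("\\..*$", "", sub("_(MUT|DEL|AMP)$", "", label))
}

#' Step 1: keep alterations of driver genes
#'
#' @param alterations Alteration matrix (cell lines x alterations).
#' @param drivers Character vector of driver-gene symbols.
#' @return Alteration matrix restricted to driver-gene alterations, column
#'   order preserved. An empty result is allowed (with a warning).
#' @export
step1_driver_filter <- function(alterations, drivers) {
  assert_alteration_matrix(alterations)
  keep <- gene_of(colnames(alterations)) %in% drivers
  if (!any(keep)) warning("no alteration involves a driver gene")
  alterations[, keep, drop = FALSE]
}

#' Variance of a binary variable
#'
#' @param p Proportion(s) in \[0, 1\].
#' @return `p * (1 - p)`.
#' @export
binary_variance <- function(p) {
  if (any(p < 0 | p > 1)) stop("proportion outside [0, 1]")
  p * (1 - p)
}

#' Step 2: drop low-variance (very frequent/infrequent) alterations
#'
#' The threshold is the binary variance at the stated small proportion,
#' e.g. 0.05 * 0.95 = 0.0475. "Below" is strict: an alteration whose
#' observed variance equals the threshold survives.
#'
#' @param alterations Alteration matrix.
#' @param min_proportion Small proportion defining the variance threshold;
#'   must lie in (0, 0.5\] or no frequency band survives.
#' @return Filtered alteration matrix, column order preserved.
#' @export
step2_variance_filter <- function(alterations, min_proportion = 0.05) {
  assert_alteration_matrix(alterations)
  if (min_proportion <= 0 || min_proportion > 0.5) {
    stop("infeasible threshold: min_proportion must be in (0, 0.5]")
  }
  thr <- binary_variance(min_proportion)
  v <- binary_variance(colMeans(alterations))
  alterations[, v >= thr, drop = FALSE]
}

#' Squared-correlation distance between alterations
#'
#' One minus the squared Pearson correlation (for binary columns the Pearson
#' correlation is the phi coefficient of the 2x2 table).
#'
#' @param alterations Alteration matrix with non-constant columns.
#' @return Symmetric distance matrix with zero diagonal, entries
#'   `1 - r^2` in \[0, 1\].
#' @export
correlation_distance <- function(alterations) {
  assert_alteration_matrix(alterations)
  p <- colMeans(alterations)
  if (any(p == 0 | p == 1)) {
    stop(
      "constant column (undefined correlation): ",
      paste(head(colnames(alterations)[p == 0 | p == 1], 5L), collapse = ", ")
    )
  }
  r <- cor(alterations)
  d <- 1 - r^2
  d[d < 0] <- 0 # guard fp noise on |r| ~ 1
  diag(d) <- 0
  d
}

#' Step 3: merge redundant alterations by complete-linkage clustering
#'
#' Complete-linkage hierarchical clustering on the `1 - r^2` distance,
#' cutting at `1 - min_correlation^2`, so every within-cluster pair has
#' `|r| >= min_correlation`. Each cluster is represented by its first member
#' (smallest original column index); the full composition is kept so merged
#' alterations remain interpretable as "as important as their
#' representative".
#'
#' @param alterations Alteration matrix (post step 2).
#' @param min_correlation Absolute correlation qualifying two alterations as
#'   redundant.
#' @return List with `retained` (representatives only, original order) and
#'   `clusters`, a data frame (alteration, cluster_id, representative,
#'   cluster_size) covering every input alteration.
#' @export
step3_redundancy_clusters <- function(alterations, min_correlation = 0.95) {
  assert_alteration_matrix(alterations)
  p <- ncol(alterations)
  if (p == 0L) {
    return(list(
      retained = alterations,
      clusters = data.frame(
        alteration = character(), cluster_id = integer(),
        representative = logical(), cluster_size = integer(),
        stringsAsFactors = FALSE
      )
    ))
  }
  if (p == 1L) {
    membership <- 1L
  } else {
    d <- correlation_distance(alterations)
    cut_height <- 1 - min_correlation^2 + 1e-9 # merge height ties at the boundary
    tree <- hclust(as.dist(d), method = "complete")
    membership <- cutree(tree, h = cut_height)
  }
  # renumber clusters in order of first appearance (original column order)
  membership <- match(membership, unique(membership))
  first <- !duplicated(membership)
  sizes <- tabulate(membership)
  clusters <- data.frame(
    alteration = colnames(alterations),
    cluster_id = membership,
    representative = first,
    cluster_size = sizes[membership],
    stringsAsFactors = FALSE
  )
  list(
    retained = alterations[, first, drop = FALSE],
    clusters = clusters
  )
}

#' Run the full three-step reduction
#'
#' @param alterations Alteration matrix (cell lines x alterations).
#' @param drivers Driver-gene symbols (step 1).
#' @param min_proportion Small proportion for the variance threshold
#'   (step 2).
#' @param min_correlation Redundancy correlation (step 3).
#' @return A `reduction_result`: list with `retained`, `clusters`, per-step
#'   counts and the derived thresholds.
#' @export
reduce_alterations <- function(alterations, drivers, min_proportion = 0.05,
                               min_correlation = 0.95) {
  s1 <- step1_driver_filter(alterations, drivers)
  s2 <- step2_variance_filter(s1, min_proportion)
  s3 <- step3_redundancy_clusters(s2, min_correlation)
  structure(
    list(
      retained = s3$retained,
      clusters = s3$clusters,
      n_input = ncol(alterations),
      step1_kept = ncol(s1),
      step2_excluded = ncol(s1) - ncol(s2),
      step3_clusters = ncol(s3$retained),
      step3_singletons = sum(s3$clusters$cluster_size[s3$clusters$representative] == 1L),
      params = list(
        min_proportion = min_proportion,
        min_correlation = min_correlation,
        variance_threshold = binary_variance(min_proportion),
        distance_threshold = 1 - min_correlation^2
      )
    ),
    class = "reduction_result"
  )
}

#' @export
print.reduction_result <- function(x, ...) {
  cat("Three-step alteration reduction\n")
  cat(
    " input:", x$n_input,
    "-> drivers:", x$step1_kept,
    "-> variance filter: -", x$step2_excluded,
    "-> clusters:", x$step3_clusters,
    sprintf("(%d singletons)\n", x$step3_singletons)
  )
  cat(sprintf(
    " thresholds: variance %.4f (p0 = %.3f), distance %.4f (|r| = %.2f)\n",
    x$params$variance_threshold, x$params$min_proportion,
    x$params$distance_threshold, x$params$min_correlation
  ))
  invisible(x)
}

#' Power of a two-sample t-test at a given alteration frequency
#'
#' Power check behind the frequency threshold: an alteration at relative
#' frequency `freq` splits `n` cell lines into groups of `freq * n` and
#' `(1 - freq) * n`; the two-sided two-sample t-test power at standardized
#' effect size `effect_size` is computed from the noncentral t
#' distribution. Group sizes are used as-is (not rounded), matching usual
#' power-calculator conventions.
#'
#' @param freq Alteration relative frequency, in (0, 1).
#' @param n Total sample size.
#' @param effect_size Cohen's d (default 0.5, "moderate").
#' @param alpha Two-sided significance level.
#' @return Power in \[0, 1\].
#' @export
power_of_frequency <- function(freq, n, effect_size = 0.5, alpha = 0.05) {
  if (any(freq <= 0 | freq >= 1)) stop("freq must be in (0, 1)")
  n1 <- freq * n
  n2 <- (1 - freq) * n
  if (any(pmin(n1, n2) < 2)) stop("degenerate group size (< 2)")
  df <- n1 + n2 - 2
  ncp <- effect_size * sqrt(n1 * n2 / (n1 + n2))
  crit <- qt(1 - alpha / 2, df)
  pt(-crit, df, ncp) + pt(crit, df, ncp, lower.tail = FALSE)
}

#' Smallest alteration frequency reaching a target power
#'
#' Scans frequencies on a fixed grid (step 0.001 by default, up to the
#' balanced design at 0.5) and returns the smallest one whose
#' [power_of_frequency()] meets the target.
#'
#' @param target_power Required power.
#' @param n Total sample size.
#' @param effect_size Cohen's d.
#' @param alpha Two-sided significance level.
#' @param step Grid resolution.
#' @return Frequency on the grid.
#' @export
min_frequency_for_power <- function(target_power = 0.80, n, effect_size = 0.5,
                                    alpha = 0.05, step = 0.001) {
  grid <- seq(step, 0.5, by = step)
  grid <- grid[pmin(grid, 1 - grid) * n >= 2]
  if (!length(grid)) stop("sample size too small for any frequency on the grid")
  pow <- power_of_frequency(grid, n, effect_size, alpha)
  hit <- which(pow >= target_power)
  if (!length(hit)) {
    stop(sprintf(
      "unreachable target power %.4g (maximum on grid: %.4g at freq 0.5)",
      target_power, max(pow)
    ))
  }
  grid[hit[1L]]
}
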
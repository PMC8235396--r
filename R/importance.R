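# Alteration influence testing: per-tree OOB permutation importance,
# z-normalization by the across-tree standard deviation, one-sided normal
# p-values and Bonferroni significance calls.

#' Per-tree OOB permutation importance
#'
#' For each tree `b` and alteration `j`, `imp_jb` is the tree's OOB mean
#' squared error after randomly permuting alteration `j` within the tree's
#' OOB samples, minus its unpermuted OOB MSE. One seeded permutation is
#' drawn per (tree, predictor). Trees with fewer than two OOB samples are
#' skipped and the averaging divisor adjusted. The mean importance over
#' trees is then z-normalized and tested; see [importance_test()].
#'
#' @param fit A [fit_forest()] result.
#' @param seed Seed for the permutation draws.
#' @param alpha Per-model significance level applied after Bonferroni
#'   correction.
#' @param keep_per_tree Attach the per-tree `imp_jb` matrix and the
#'   permutation draws as attributes (for audit and oracle checks)?
#' @return An `importance_table` data frame (alteration, imp, sd, z, p,
#'   p_adj, significant), sorted by decreasing mean importance, with
#'   attributes `per_tree` (p x B) and `permutations` when requested.
#' @export
permutation_importance <- function(fit, seed = 1, alpha = 0.005,
                                   keep_per_tree = TRUE) {
  stopifnot(inherits(fit, "forest_fit"))
  p <- ncol(fit$X)
  oob_idx <- apply(fit$inbag == 0L, 2L, which, simplify = FALSE)
  set.seed(seed)
  perms <- lapply(oob_idx, function(idx) {
    m <- length(idx)
    if (m < 2L) {
      return(matrix(integer(), 0L, p))
    }
    vapply(seq_len(p), function(j) sample.int(m), integer(m))
  })
  per_tree <- perm_importance_cpp(fit$trees, fit$X, fit$y, oob_idx, perms)
  rownames(per_tree) <- colnames(fit$X)
  out <- importance_test(per_tree, alpha = alpha)
  if (keep_per_tree) {
    attr(out, "per_tree") <- per_tree
    attr(out, "permutations") <- perms
  }
  out
}

#' Significance testing of permutation importances
#'
#' The mean per-tree importance is normalized by its across-tree standard
#' deviation (denominator `B - 1` over contributing trees) into an
#' approximate z-score; the p-value is the upper-tail standard-normal area
#' at z, Bonferroni-corrected by the number of predictors entering the
#' model. Conventions for degenerate cases: a predictor with `sd = 0` and
#' mean importance 0 (never used by any tree) gets p = 1; `sd = 0` with a
#' positive mean gets p = 0.
#'
#' @param per_tree p x B matrix of per-tree importances `imp_jb` (rows
#'   named by alteration); `NA` columns mark skipped trees.
#' @param alpha Significance level compared against the adjusted p-value.
#' @return An `importance_table` data frame sorted by decreasing mean
#'   importance.
#' @export
importance_test <- function(per_tree, alpha = 0.005) {
  if (is.null(rownames(per_tree))) {
    rownames(per_tree) <- paste0("X", seq_len(nrow(per_tree)))
  }
  contributing <- colSums(is.na(per_tree)) == 0L
  if (!any(contributing)) stop("no tree contributed an importance value")
  m <- per_tree[, contributing, drop = FALSE]
  imp <- rowMeans(m)
  sds <- apply(m, 1L, sd) # B - 1 denominator over contributing trees
  z <- ifelse(sds > 0, imp / sds, NA_real_)
  p <- ifelse(sds > 0, pnorm(z, lower.tail = FALSE),
    ifelse(imp > 0, 0, 1)
  )
  n_tests <- nrow(per_tree)
  p_adj <- pmin(1, p * n_tests)
  out <- data.frame(
    alteration = rownames(per_tree),
    imp = imp, sd = sds, z = z, p = p, p_adj = p_adj,
    significant = p_adj < alpha,
    row.names = NULL, stringsAsFactors = FALSE
  )
  out <- out[order(-out$imp, out$alteration), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("importance_table", "data.frame")
  out
}
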
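# Per-compound random-forest engine. Fitting is delegated to ranger
# (bootstrap CART regression forest); out-of-bag bookkeeping — Eq.-style
# OOB predictions, the OOB error curve and the ex-post stability
# indicator — is computed here from the stored trees and in-bag counts.

#' Drop cell lines with missing response
#'
#' Cell lines not screened for a compound are removed before fitting; no
#' imputation is attempted.
#'
#' @param y AUC vector (may contain `NA`).
#' @param X Alteration matrix aligned with `y` (cell lines in rows).
#' @return List with `y`, `X` restricted to non-missing responses, and
#'   `kept`, the logical mask used.
#' @export
drop_missing <- function(y, X) {
  if (length(y) != nrow(X)) stop("response and alteration matrix are not aligned")
  kept <- !is.na(y)
  if (sum(kept) < 10L) {
    stop("fewer than 10 cell lines with observed response")
  }
  list(y = y[kept], X = X[kept, , drop = FALSE], kept = kept)
}

# Flatten a fitted ranger forest into the plain arrays the C++ kernel
# traverses. ranger stores, per tree, 0-based child ids (0 = none, i.e.
# terminal), 0-based split predictor ids, and split values that hold the
# leaf prediction at terminal nodes of a regression tree.
flatten_ranger_forest <- function(rf) {
  forest <- rf$forest
  lapply(seq_len(forest$num.trees), function(b) {
    children <- forest$child.nodeIDs[[b]]
    left <- children[[1]]
    right <- children[[2]]
    terminal <- left == 0L & right == 0L
    list(
      left = as.integer(left),
      right = as.integer(right),
      var = ifelse(terminal, -1L, as.integer(forest$split.varIDs[[b]])),
      split = ifelse(terminal, 0, as.numeric(forest$split.values[[b]])),
      pred = ifelse(terminal, as.numeric(forest$split.values[[b]]), NA_real_)
    )
  })
}

#' Fit a random-forest regression for one compound
#'
#' `B` CART regression trees, each grown on a bootstrap sample of size `n`
#' drawn with replacement, with `m = max(1, floor(p/3))` candidate
#' predictors per split (the classic regression default) and minimum node
#' size 5; no depth limit. In-bag multiplicities, per-tree predictions on
#' the training set, OOB predictions and the OOB error curve are all
#' retained.
#'
#' @param X Binary alteration matrix (cell lines x alterations), no
#'   missing values.
#' @param y AUC vector in \[0, 1\], no missing values.
#' @param num_trees Number of trees `B`.
#' @param mtry Candidate predictors per split; `NULL` means
#'   `max(1, floor(p/3))`.
#' @param min_node_size Minimum terminal node size.
#' @param seed Seed for the forest (fixed seed implies an identical
#'   refit).
#' @return A `forest_fit`: list with the fitted `ranger` object, flattened
#'   `trees`, `inbag` (n x B bootstrap multiplicities), `pred_per_tree`
#'   (n x B), `oob_pred` (Eq.-style OOB predictions; `NA` where a sample
#'   was in-bag in every tree), `oob_error_curve` (OOB MSE after 1..B
#'   trees), `B`, `m`, `seed`, `sample_size`, `mean_auc`, `y`, `X`.
#' @export
fit_forest <- function(X, y, num_trees = 500, mtry = NULL, min_node_size = 5,
                       seed = 1) {
  if (anyNA(y) || anyNA(X)) stop("missing values: call drop_missing() first")
  if (ncol(X) == 0L) stop("no predictors")
  if (length(y) != nrow(X)) stop("response and alteration matrix are not aligned")
  if (any(y < 0 | y > 1)) stop("AUC out of range [0, 1]")
  p <- ncol(X)
  num_trees <- as.integer(num_trees)
  if (is.null(mtry)) mtry <- max(1L, floor(p / 3))
  mtry <- as.integer(mtry)
  df <- as.data.frame(X)
  rf <- ranger::ranger(
    y = y, x = df,
    num.trees = num_trees, mtry = mtry, min.node.size = min_node_size,
    replace = TRUE, sample.fraction = 1,
    keep.inbag = TRUE, num.threads = 1, seed = seed,
    oob.error = FALSE
  )
  inbag <- do.call(cbind, rf$inbag.counts)
  trees <- flatten_ranger_forest(rf)
  storage.mode(X) <- "double"
  pred_per_tree <- predict_trees_cpp(trees, X)
  oob <- inbag == 0L
  n_oob <- rowSums(oob)
  oob_pred <- ifelse(n_oob > 0, rowSums(pred_per_tree * oob) / n_oob, NA_real_)
  # incremental OOB error curve from running per-sample prediction sums
  cum_sum <- t(apply(pred_per_tree * oob, 1L, cumsum))
  cum_cnt <- t(apply(oob, 1L, cumsum))
  sq_err <- (y - cum_sum / cum_cnt)^2 # NaN while a sample has no OOB tree yet
  oob_error_curve <- colMeans(sq_err, na.rm = TRUE)
  structure(
    list(
      forest = rf, trees = trees, inbag = inbag,
      pred_per_tree = pred_per_tree,
      oob_pred = oob_pred, oob_error_curve = oob_error_curve,
      B = num_trees, m = mtry, seed = seed,
      sample_size = length(y), mean_auc = mean(y),
      y = y, X = X
    ),
    class = "forest_fit"
  )
}

#' @export
print.forest_fit <- function(x, ...) {
  cat(sprintf(
    "Random-forest fit: B = %d trees, m = %d, n = %d cell lines, p = %d alterations\n",
    x$B, x$m, x$sample_size, ncol(x$X)
  ))
  cat(sprintf(
    " mean AUC %.3f | final OOB MSE %.5f | seed %d\n",
    x$mean_auc, x$oob_error_curve[x$B], x$seed
  ))
  invisible(x)
}

#' Out-of-bag predictions
#'
#' Per cell line, the mean prediction over the trees whose bootstrap sample
#' did not contain it. Samples in-bag in every tree have no OOB prediction
#' (`NA`) and are excluded from downstream agreement scores; at B = 500 the
#' event is vanishingly rare.
#'
#' @param fit A `forest_fit`.
#' @return Numeric vector of OOB predictions aligned with `fit$y`.
#' @export
oob_predictions <- function(fit) {
  stopifnot(inherits(fit, "forest_fit"))
  fit$oob_pred
}

#' Ex-post forest stability indicator
#'
#' Mean of the last `window` squared successive differences of the OOB
#' error curve: with enough trees the curve flattens and the indicator
#' rounds to zero.
#'
#' @param fit A `forest_fit`.
#' @param window Number of trailing curve gaps (default 10).
#' @param tol `reached` is declared when the value falls below `tol`.
#' @return List with `value`, `window` and `reached`.
#' @export
stability_indicator <- function(fit, window = 10, tol = 1e-6) {
  stopifnot(inherits(fit, "forest_fit"))
  if (fit$B < window + 1) {
    stop(sprintf("stability window %d needs at least %d trees", window, window + 1))
  }
  gaps <- diff(fit$oob_error_curve)
  value <- mean(utils::tail(gaps, window)^2)
  list(value = value, window = window, reached = value < tol)
}
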
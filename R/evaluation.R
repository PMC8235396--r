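# Predictive-performance scoring: concordance correlation coefficient
# between observed AUCs and OOB predictions, its asymptotic confidence
# interval, and the qualitative benchmark.

#' Concordance correlation coefficient
#'
#' Agreement measure between two vectors,
#' `2 cov(y, yhat) / (var(y) + var(yhat) + (mean(y) - mean(yhat))^2)`,
#' with population (divide-by-n) moments throughout. It equals 1 only for
#' identical vectors and is never larger in magnitude than the Pearson
#' correlation, penalizing location and scale shifts as well as scatter.
#'
#' @param y,yhat Numeric vectors of equal length (>= 2), no missing values.
#' @return Value in \[-1, 1\].
#' @export
ccc <- function(y, yhat) {
  if (length(y) != length(yhat)) stop("vectors differ in length")
  if (length(y) < 2L) stop("need at least 2 pairs")
  if (anyNA(y) || anyNA(yhat)) stop("missing values")
  n <- length(y)
  my <- mean(y)
  mh <- mean(yhat)
  vy <- mean((y - my)^2)
  vh <- mean((yhat - mh)^2)
  cyh <- mean((y - my) * (yhat - mh))
  denom <- vy + vh + (my - mh)^2
  if (denom == 0) stop("degenerate input: both vectors constant with equal means")
  2 * cyh / denom
}

#' Asymptotic confidence interval for the CCC
#'
#' Lin's variance of the Fisher-z-transformed CCC, back-transformed to the
#' \[-1, 1\] scale.
#'
#' @param y,yhat Numeric vectors (length >= 4).
#' @param level Confidence level.
#' @return Numeric vector `c(lower, upper)` on the \[-1, 1\] scale.
#' @export
ccc_interval <- function(y, yhat, level = 0.95) {
  n <- length(y)
  if (n < 4L) stop("need at least 4 pairs for a confidence interval")
  rho_c <- ccc(y, yhat)
  if (abs(rho_c) >= 1) stop("degenerate CCC (|ccc| = 1): no asymptotic interval")
  my <- mean(y)
  mh <- mean(yhat)
  sy <- mean((y - my)^2)
  sh <- mean((yhat - mh)^2)
  if (sy == 0 || sh == 0) stop("constant vector: no asymptotic interval")
  r <- cor(y, yhat)
  u <- (my - mh) / sqrt(sqrt(sy) * sqrt(sh)) # location shift in scale units
  z <- atanh(rho_c)
  se2 <- ((1 - r^2) * rho_c^2 / ((1 - rho_c^2) * r^2) +
    2 * rho_c^3 * (1 - rho_c) * u^2 / (r * (1 - rho_c^2)^2) -
    rho_c^4 * u^4 / (2 * r^2 * (1 - rho_c^2)^2)) / (n - 2)
  half <- qnorm(1 - (1 - level) / 2) * sqrt(se2)
  tanh(c(z - half, z + half))
}

#' Benchmark class of a CCC on the x100 scale
#'
#' Bins: <= 0 "none"; (0, 20\] "poor"; (20, 40\] "fair"; (40, 60\]
#' "moderate"; (60, 80\] "substantial"; (80, 100\] "excellent".
#'
#' @param value_x100 CCC value(s) multiplied by 100, in \[-100, 100\].
#' @return Character vector of benchmark labels.
#' @export
classify_ccc <- function(value_x100) {
  if (any(value_x100 < -100 | value_x100 > 100)) {
    stop("CCC x100 outside [-100, 100]")
  }
  labels <- c("none", "poor", "fair", "moderate", "substantial", "excellent")
  as.character(cut(value_x100,
    breaks = c(-100 - 1e-9, 0, 20, 40, 60, 80, 100),
    labels = labels, right = TRUE
  ))
}

#' Concordance between observed responses and OOB predictions
#'
#' Computes the CCC, its confidence interval and the benchmark label on the
#' conventional x100 reporting scale, over the pairs where an OOB
#' prediction exists.
#'
#' @param y Observed responses.
#' @param yhat OOB predictions (may contain `NA` for never-OOB samples;
#'   those pairs are excluded).
#' @param level Confidence level.
#' @param fair_threshold Lower-bound threshold (x100 scale) declaring an at
#'   least fair concordance.
#' @return A `ccc_result`: list with `ccc`, `ci_lower`, `ci_upper` (x100),
#'   `n`, `label`, `at_least_fair`.
#' @export
concordance_result <- function(y, yhat, level = 0.95, fair_threshold = 20) {
  ok <- !is.na(y) & !is.na(yhat)
  y <- y[ok]
  yhat <- yhat[ok]
  value <- ccc(y, yhat)
  ci <- ccc_interval(y, yhat, level)
  structure(
    list(
      ccc = 100 * value,
      ci_lower = 100 * ci[1], ci_upper = 100 * ci[2],
      n = length(y),
      label = classify_ccc(100 * value),
      at_least_fair = 100 * ci[1] > fair_threshold
    ),
    class = "ccc_result"
  )
}

#' @export
print.ccc_result <- function(x, ...) {
  cat(sprintf(
    "CCC %.1f (95%% CI %.1f, %.1f), n = %d: %s concordance%s\n",
    x$ccc, x$ci_lower, x$ci_upper, x$n, x$label,
    if (x$at_least_fair) " (at least fair)" else ""
  ))
  invisible(x)
}
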
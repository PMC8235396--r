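test_that("gene symbols are extracted from alteration labels", {
  expect_identical(gene_of("BRAF_MUT"), "BRAF")
  expect_identical(gene_of("BRAF.V600E_MUT"), "BRAF")
  expect_identical(
    gene_of(c("TP53_DEL", "ERBB2_AMP", "KRAS.G12_13_MUT")),
    c("TP53", "ERBB2", "KRAS")
  )
  expect_error(gene_of("TP53_AMPX"), "unknown suffix")
})

test_that("driver filter keeps driver-gene alterations in original order", {
  x <- toy_alterations(matrix(rbinom(40, 1, 0.5), 10, 4))
  colnames(x) <- c("BRAF_MUT", "XYZ9_DEL", "BRAF.V600E_MUT", "TP53_AMP")
  kept <- step1_driver_filter(x, c("BRAF", "TP53"))
  expect_identical(colnames(kept), c("BRAF_MUT", "BRAF.V600E_MUT", "TP53_AMP"))
  expect_identical(step1_driver_filter(x, c("BRAF", "XYZ9", "TP53")), x)
  expect_warning(step1_driver_filter(x, "NOPE"), "no alteration")
})

test_that("binary variance is p(1-p), symmetric, maximal at 1/2", {
  expect_identical(binary_variance(0.05), 0.05 * 0.95)
  expect_identical(binary_variance(0.5), 0.25)
  expect_identical(binary_variance(0), 0)
  p <- seq(0, 1, by = 0.01)
  expect_equal(binary_variance(p), binary_variance(1 - p))
  expect_true(all(binary_variance(p) <= 0.25))
  expect_error(binary_variance(1.1), "outside")
})

test_that("variance filter excludes strictly-below-threshold alterations", {
  x <- toy_alterations(cbind(
    boundary = c(rep(1L, 5), rep(0L, 95)), # p = 0.05, variance == threshold
    below = c(rep(1L, 4), rep(0L, 96)), # p = 0.04, variance 0.0384
    common = rep(c(1L, 0L), 50)
  ))
  kept <- step2_variance_filter(x, 0.05)
  expect_identical(colnames(kept), c("boundary", "common"))
  expect_identical(step2_variance_filter(kept, 0.05), kept) # idempotent
  expect_error(step2_variance_filter(x, 0.6), "infeasible threshold")
})

test_that("correlation distance is 1 - r^2 with binary phi semantics", {
  a <- c(1L, 1L, 0L, 0L, 1L, 0L)
  x <- toy_alterations(cbind(a = a, dup = a, flip = 1L - a))
  d <- correlation_distance(x)
  expect_equal(unname(diag(d)), c(0, 0, 0))
  expect_equal(d["a", "dup"], 0) # identical columns
  expect_equal(d["a", "flip"], 0) # complement: r = -1, squared
  # phi = 0.5 from the 2x2 table (3,1 / 1,3) -> distance 1 - 0.25
  y1 <- rep(c(1L, 0L), c(4L, 4L))
  y2 <- c(1L, 1L, 1L, 0L, 1L, 0L, 0L, 0L)
  d2 <- correlation_distance(toy_alterations(cbind(y1, y2)))
  expect_equal(d2[1, 2], 0.75)
  expect_error(
    correlation_distance(toy_alterations(cbind(a, rep(1L, 6)))),
    "constant column"
  )
})

test_that("redundancy clustering merges identical columns and keeps first members", {
  set.seed(21)
  a <- rbinom(40, 1L, 0.5)
  c_ <- rbinom(40, 1L, 0.5)
  x <- toy_alterations(cbind(A = a, B = a, C = c_))
  expect_lt(abs(cor(a, c_)), 0.9) # fixture sanity: C is genuinely independent
  s3 <- step3_redundancy_clusters(x, 0.95)
  expect_identical(colnames(s3$retained), c("A", "C"))
  expect_identical(s3$clusters$cluster_id, c(1L, 1L, 2L))
  expect_identical(s3$clusters$representative, c(TRUE, FALSE, TRUE))
  expect_identical(s3$clusters$cluster_size, c(2L, 2L, 1L))
})

test_that("all-weakly-correlated matrices reduce to singleton clusters", {
  set.seed(31)
  x <- random_alterations(200, 8)
  r <- cor(x)
  diag(r) <- 0
  expect_lt(max(abs(r)), 0.95) # fixture sanity: no redundant pair present
  s3 <- step3_redundancy_clusters(x, 0.95)
  expect_identical(s3$retained, x)
  expect_true(all(s3$clusters$cluster_size == 1L))
})

test_that("clustering matches the brute-force agglomeration oracle and the cut guarantee", {
  set.seed(42)
  for (rep in 1:8) {
    n <- 60
    base <- matrix(rbinom(n * 8, 1L, runif(8, 0.2, 0.8)), n, 8)
    dups <- base[, sample(8, 4, replace = TRUE)]
    flip <- matrix(rbinom(n * 4, 1L, 0.02), n, 4)
    x <- toy_alterations(cbind(base, (dups + flip) %% 2L))
    if (any(colMeans(x) %in% c(0, 1))) next
    s3 <- step3_redundancy_clusters(x, 0.95)
    oracle <- oracle_complete_linkage(correlation_distance(x), 1 - 0.95^2 + 1e-9)
    expect_identical(s3$clusters$cluster_id, oracle)
    # complete-linkage guarantee: within-cluster |r| >= 0.95
    r <- abs(cor(x))
    for (cid in unique(s3$clusters$cluster_id)) {
      members <- which(s3$clusters$cluster_id == cid)
      if (length(members) > 1) {
        expect_gte(min(r[members, members]), 0.95 - 1e-9)
      }
    }
  }
})

test_that("the three-step pipeline never grows and is stable on its own output", {
  cfg <- synthetic_config(n_cell_lines = 300, n_alterations = 30)
  ss <- make_study(cfg, seed = 77)
  x <- ss$study$alterations
  red <- reduce_alterations(x, ss$drivers)
  expect_lte(red$step1_kept, ncol(x))
  expect_lte(ncol(red$retained), red$step1_kept - red$step2_excluded)
  expect_identical(
    red$step1_kept - red$step2_excluded,
    as.integer(sum(red$clusters$representative) +
      sum(!red$clusters$representative))
  )
  # applying the reduction to its own output changes nothing
  red2 <- reduce_alterations(red$retained, ss$drivers)
  expect_identical(red2$retained, red$retained)
  expect_identical(red2$step2_excluded, 0L)
})

test_that("t-test power matches the frequency design and is monotone", {
  # balanced design maximizes the noncentrality at fixed n, d, alpha
  freqs <- seq(0.05, 0.5, by = 0.05)
  pow <- power_of_frequency(freqs, n = 200, effect_size = 0.5)
  expect_true(all(diff(pow) > 0))
  # monotone in n and in effect size
  expect_true(all(diff(power_of_frequency(0.1, c(100, 200, 400, 800))) > 0))
  expect_true(all(diff(power_of_frequency(0.1, 300, c(0.2, 0.5, 0.8))) > 0))
  expect_error(power_of_frequency(0.005, 100), "degenerate group")
  expect_error(power_of_frequency(0, 100), "in \\(0, 1\\)")
})

test_that("the smallest adequate frequency is found on the grid", {
  # target equal to the balanced-design power is reached exactly at 0.5
  n <- 523
  pmax_ <- power_of_frequency(0.5, n)
  expect_identical(min_frequency_for_power(pmax_, n), 0.5)
  expect_error(min_frequency_for_power(0.9999, 10, effect_size = 0.1), "unreachable")
  f <- min_frequency_for_power(0.80, n)
  expect_gte(power_of_frequency(f, n), 0.80)
  expect_lt(power_of_frequency(f - 0.001, n), 0.80)
})
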
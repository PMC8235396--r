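test_that("candidate screening pairs similar-AUC compounds with different top alterations", {
  results <- list(
    a = fake_drug_result("a", 47, 42, 52,
      mean_auc = 0.937,
      importance = fake_importance("BRAF.V600E_MUT")
    ),
    b = fake_drug_result("b", 32, 26, 38,
      mean_auc = 0.936,
      importance = fake_importance("TP53_MUT")
    ),
    c = fake_drug_result("c", 28, 22, 34,
      mean_auc = 0.904,
      importance = fake_importance("IKZF3_AMP")
    ),
    d = fake_drug_result("d", 27, 21, 33,
      mean_auc = 0.886,
      importance = fake_importance("BRAF.V600E_MUT")
    ),
    e = fake_drug_result("e", 25, 21, 30,
      mean_auc = 0.902,
      importance = fake_importance(character())
    )
  )
  r1 <- build_report1(results)
  imp <- lapply(results, `[[`, "importance")
  names(imp) <- vapply(results, `[[`, "", "compound")
  cp <- candidate_pairs(r1, imp, auc_tolerance = 0.02)
  # (a,b): diff 0.001, different tops -> candidate, first by ascending diff
  expect_identical(cp$compound_a[1], "a")
  expect_identical(cp$compound_b[1], "b")
  # (c,d): diff 0.018 within tolerance, different tops -> candidate
  expect_true(any(cp$compound_a == "c" & cp$compound_b == "d" |
    cp$compound_a == "d" & cp$compound_b == "c"))
  # compounds without significant alterations never pair
  expect_false("e" %in% c(cp$compound_a, cp$compound_b))
  # same top alteration is excluded regardless of AUC gap
  same_top <- candidate_pairs(r1, imp, auc_tolerance = 1)
  expect_false(any(same_top$top_alteration_a == same_top$top_alteration_b))
  expect_true(all(diff(cp$auc_difference) >= 0))
})

test_that("logit transform evaluates and clips as specified", {
  expect_identical(logit_auc(0.5), 0)
  expect_equal(logit_auc(0.886), 2.0506, tolerance = 1e-4)
  expect_equal(logit_auc(1), 6.906755, tolerance = 1e-6) # clipped at 1 - 1e-3
  expect_equal(logit_auc(0), -logit_auc(1))
  expect_error(logit_auc(1.2), "out of range")
})

test_that("pair data stacks one row per screened compound-cell combination", {
  alt <- toy_alterations(cbind(
    A_MUT = c(1L, 1L, 0L, 0L),
    B_DEL = c(1L, 0L, 1L, 0L)
  ))
  rownames(alt) <- c("C1", "C2", "C3", "C4")
  resp <- matrix(c(
    0.9, 0.8, 0.7, NA,
    0.5, 0.6, NA, 0.4
  ), 2, 4, byrow = TRUE, dimnames = list(c("dA", "dB"), rownames(alt)))
  study <- match_cell_lines(alt, resp, strip_tissue_suffix = FALSE)
  long <- pair_interaction_data(study, "dA", "dB", "A_MUT", "B_DEL")
  expect_identical(nrow(long), 6L) # 3 screened for dA + 3 for dB
  expect_identical(
    as.character(long$combination[long$cell_line == "C1"]),
    c("11", "11")
  )
  expect_identical(as.character(long$combination[long$compound == "dB"][3]), "00")
  expect_equal(long$logit_auc, logit_auc(long$auc))
  expect_error(pair_interaction_data(study, "dA", "nope", "A_MUT", "B_DEL"), "unknown compound")
  expect_error(pair_interaction_data(study, "dA", "dB", "A_MUT", "nope"), "unknown alteration")
})

test_that("a pure compound main effect yields an essentially zero interaction F", {
  set.seed(26)
  comb <- rep(c("00", "10", "01", "11"), each = 10)
  base <- rnorm(40)
  data <- data.frame(
    logit_auc = c(base, base + 1.5), # drug B = drug A + constant
    compound = rep(c("A", "B"), each = 40),
    combination = factor(c(comb, comb))
  )
  res <- interaction_anova(data)
  expect_lt(res$anova$F, 1e-20)
  expect_gt(res$anova$p_value, 0.999)
})

test_that("on balanced designs the nested-model F equals the classical ANOVA F", {
  set.seed(27)
  comb <- rep(c("00", "10", "01", "11"), each = 6)
  data <- data.frame(
    logit_auc = rnorm(48, mean = rep(c(0, 1), each = 24)),
    compound = rep(c("A", "B"), each = 24),
    combination = factor(c(comb, comb))
  )
  res <- interaction_anova(data)
  classical <- summary(aov(logit_auc ~ compound * combination, data = data))[[1]]
  expect_equal(res$anova$F, classical["compound:combination", "F value"],
    tolerance = 1e-10
  )
  expect_equal(res$anova$p_value, classical["compound:combination", "Pr(>F)"],
    tolerance = 1e-10
  )
})

test_that("the interaction test is invariant to level order and affine response scaling", {
  set.seed(28)
  comb <- sample(c("00", "10", "01", "11"), 120, replace = TRUE)
  cmp <- sample(c("A", "B"), 120, replace = TRUE)
  y <- rnorm(120) + (comb == "10") * (cmp == "B") * 0.8
  d1 <- data.frame(logit_auc = y, compound = cmp, combination = factor(comb))
  d2 <- data.frame(
    logit_auc = 3 * y - 7,
    compound = factor(cmp, levels = c("B", "A")),
    combination = factor(comb, levels = c("11", "01", "10", "00"))
  )
  r1 <- interaction_anova(d1)
  r2 <- interaction_anova(d2)
  expect_equal(r1$anova$F, r2$anova$F, tolerance = 1e-10)
  expect_equal(r1$anova$p_value, r2$anova$p_value, tolerance = 1e-10)
  # group summaries conserve counts
  expect_identical(sum(r1$groups$n), nrow(d1))
})

test_that("degenerate designs are rejected", {
  d <- data.frame(
    logit_auc = rnorm(20),
    compound = rep("A", 20),
    combination = factor(rep(c("00", "10"), 10))
  )
  expect_error(interaction_anova(d), "single level")
  d2 <- data.frame(
    logit_auc = rnorm(20),
    compound = rep(c("A", "B"), 10),
    combination = factor(rep("00", 20))
  )
  expect_error(interaction_anova(d2), "single level")
})

test_that("a planted differential effect is detected on generated data", {
  cfg <- synthetic_config(
    n_drugs = 2, effects = null_effects(),
    interactions = data.frame(
      drug_a = "drug_1", drug_b = "drug_2",
      alteration = nearest_label(synthetic_config(n_drugs = 2, effects = null_effects()), 0.3),
      effect = 0.5, stringsAsFactors = FALSE
    )
  )
  ss <- make_study(cfg, seed = 314)
  A <- cfg$interactions$alteration[1]
  B <- nearest_label(cfg, 0.4, exclude = A)
  res <- interaction_anova(pair_interaction_data(ss$study, "drug_1", "drug_2", A, B))
  expect_lt(res$anova$p_value, 0.001)
  # per-combination t-tests exist for the populated panels
  expect_true(all(c("combination", "p_value") %in% names(res$t_tests)))
})
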
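test_that("Kruskal-Wallis handles identical groups and matches the permutation oracle", {
  tied <- compare_grades(rep(5, 9), gl(3, 3))
  expect_equal(tied$statistic, 0)
  expect_equal(tied$p_value, 1)

  vals <- c(1, 2, 3, 4, 5, 6, 7, 8, 9)
  groups <- gl(3, 3, labels = c("I", "II", ">=III"))
  exact <- kw_exact_oracle(vals)
  res <- compare_grades(vals, groups, p_method = "permutation",
                        n_perm = 20000)
  expect_equal(res$statistic, exact$observed, tolerance = 1e-10)
  mc_se <- sqrt(exact$p * (1 - exact$p) / 20000)
  expect_lt(abs(res$p_value - exact$p), 4 * mc_se + 2e-4)
  # asymptotic path returns the base R chi-square approximation
  asym <- compare_grades(vals, groups)
  expect_equal(asym$p_value,
               stats::kruskal.test(vals, groups)$p.value)
  expect_equal(nrow(asym$posthoc), 3L)
  expect_equal(asym$posthoc$comparison,
               c("I vs II", "I vs >=III", "II vs >=III"))
})

test_that("degenerate groups yield a missing Kruskal-Wallis result", {
  expect_message(r <- compare_grades(1:4, factor(c("a", "a", "a", "b"))),
                 "degenerate")
  expect_true(is.na(r$p_value))
})

test_that("Friedman test handles ties and matches the exact enumeration oracle", {
  same <- matrix(rep(c(3, 1, 4, 1, 5), 3), 5, 3)
  r0 <- compare_loading(same)
  expect_equal(r0$statistic, 0)
  expect_equal(r0$p_value, 1)
  expect_false(any(r0$posthoc$significant))

  set.seed(17)
  y <- t(replicate(6, sort(runif(3), decreasing = TRUE)))
  colnames(y) <- c("delta0", "delta1", "delta2")
  exact <- friedman_exact_oracle(y)
  res <- compare_loading(y, p_method = "permutation", n_perm = 20000)
  expect_equal(res$statistic, exact$observed, tolerance = 1e-10)
  mc_se <- sqrt(exact$p * (1 - exact$p) / 20000)
  expect_lt(abs(res$p_value - exact$p), 4 * mc_se + 2e-4)
  expect_equal(compare_loading(y)$statistic,
               unname(stats::friedman.test(y)$statistic))
  # post-hoc flags come in the fixed reporting order
  expect_equal(res$posthoc$comparison,
               c("delta0 vs delta1", "delta0 vs delta2",
                 "delta1 vs delta2"))
})

test_that("incomplete loading series are dropped with a message", {
  y <- matrix(runif(12), 4, 3)
  y[2, 3] <- NA
  expect_message(r <- compare_loading(y), "incomplete")
})

test_that("Delta comparisons run the t-test, ANOVA and normality screen", {
  # identical Delta distributions: t = 0, p = 1
  d <- c(-21, -18, -25, -15, -19, -22, -17, -20)
  same <- compare_deltas(d, d)
  expect_equal(same$t_test$statistic, 0)
  expect_equal(same$t_test$p_value, 1)

  # two-group t equals the hand-computed pooled-variance formula (3+3)
  a <- c(1, 2, 3); b <- c(4, 6, 8)
  res <- compare_deltas(c(a, rep(NA, 0)), b)
  sp2 <- (2 * var(a) + 2 * var(b)) / 4
  t_hand <- (mean(a) - mean(b)) / sqrt(sp2 * (1 / 3 + 1 / 3))
  expect_equal(res$t_test$statistic, t_hand, tolerance = 1e-12)
  expect_equal(res$t_test$p_value, 2 * pt(-abs(t_hand), df = 4),
               tolerance = 1e-12)

  # ANOVA across balanced groups with equal means: F = 0, p = 1
  g <- gl(3, 3)
  dv <- rep(c(1, 2, 3), 3)
  r <- compare_deltas(dv, dv + 1, group = g)
  expect_equal(r$anova_delta1$statistic, 0, tolerance = 1e-12)
  expect_equal(r$anova_delta1$p_value, 1, tolerance = 1e-12)
  expect_true(all(c("delta1", "delta2") %in% names(r$normality_p)))
})

test_that("D'Agostino-Pearson K2 matches the frozen reference values", {
  x <- c(2.3, 1.9, 3.1, 2.8, 0.5, 4.2, 3.3, 2.7, 1.1, 2.2,
         2.9, 3.8, 0.9, 2.4, 3.0, 5.6, 1.7, 2.6, 3.4, 2.1)
  r <- dagostino_pearson(x)
  expect_equal(r$statistic, 2.4811655902, tolerance = 1e-8)
  expect_equal(r$p.value, 0.2892156154, tolerance = 1e-8)
  y <- exp(seq(0, 2, length.out = 25))
  r2 <- dagostino_pearson(y)
  expect_equal(r2$statistic, 2.9172566187, tolerance = 1e-8)
  expect_equal(r2$p.value, 0.2325550496, tolerance = 1e-8)
  expect_error(dagostino_pearson(1:5), "n >= 8")
})

test_that("Spearman correlation matches the rank formula and handles edge cases", {
  x <- c(10, 8, 6, 4, 2, 1)
  expect_equal(correlate_qmri_biomech(x, seq_along(x))$rho, -1)
  # untied 6-pair set: rho equals the closed-form rank computation
  set.seed(2)
  q <- c(3.2, 1.5, 4.8, 2.2, 5.9, 0.7)
  e <- c(12, 40, 9, 30, 5, 55)
  d <- rank(q) - rank(e)
  rho_hand <- 1 - 6 * sum(d^2) / (6 * (36 - 1))
  expect_equal(correlate_qmri_biomech(q, e)$rho, rho_hand, tolerance = 1e-12)
  expect_message(r <- correlate_qmri_biomech(rep(1, 6), 1:6), "constant")
  expect_true(is.na(r$rho))
  expect_error(correlate_qmri_biomech(1:4, 1:4), "5")
})

test_that("repeated-measures ANOVA detects decreasing pixel counts", {
  set.seed(3)
  base <- rnorm(10, 800, 150)
  counts <- cbind(base, base * 0.9, base * 0.75) + rnorm(30, 0, 5)
  r <- compare_pixel_counts(counts)
  expect_lt(r$p_value, 1e-6)
  flat <- cbind(base, base, base)
  r2 <- compare_pixel_counts(flat + rnorm(30, 0, 1))
  expect_gt(r2$p_value, 0.05)
})

test_that("significance flags are evaluated at the frozen alpha of 0.005", {
  y <- cbind(rnorm(20, 10), rnorm(20, 10.4), rnorm(20, 10.5))
  r <- compare_loading(y)
  expect_equal(r$alpha, 0.005)
  expect_identical(r$significant, isTRUE(r$p_value <= 0.005))
  expect_equal(compare_grades(rnorm(12), gl(3, 4))$alpha, 0.005)
})
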
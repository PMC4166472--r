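test_that("identical labelings give perfect agreement and kappa 1", {
  a <- sample(paste0("IC", 1:10), 200, replace = TRUE)
  rep <- agreement(a, a)
  expect_equal(rep$percent_agreement, 100)
  expect_equal(rep$kappa, 1)
  expect_lt(rep$expected_agreement_pe, 1)
})

test_that("kappa matches the contingency-table oracle on a printed 3x3", {
  # 3x3 toy table: rows a, cols b
  tab <- matrix(c(20, 5, 0,
                  3, 15, 2,
                  1, 4, 10), 3, 3, byrow = TRUE)
  a <- rep(rep(c("X", "Y", "Z"), each = 3), times = as.vector(t(tab)))
  b <- rep(rep(c("X", "Y", "Z"), times = 3), times = as.vector(t(tab)))
  rep_ <- agreement(a, b)
  expect_equal(unclass(rep_$contingency)[, ], tab,
               ignore_attr = TRUE)
  expect_equal(rep_$kappa, oracle_kappa(tab), tolerance = 1e-12)
  skip_if_not_installed("e1071")
  expect_equal(rep_$kappa,
               e1071::classAgreement(tab)$kappa, tolerance = 1e-10)
})

test_that("kappa is symmetric and invariant to consistent relabeling", {
  set.seed(31)
  a <- sample(letters[1:4], 300, replace = TRUE,
              prob = c(0.4, 0.3, 0.2, 0.1))
  b <- ifelse(runif(300) < 0.7, a, sample(letters[1:4], 300, TRUE))
  expect_equal(agreement(a, b)$kappa, agreement(b, a)$kappa,
               tolerance = 1e-12)
  map <- c(a = "w1", b = "w2", c = "w3", d = "w4")
  expect_equal(agreement(map[a], map[b])$kappa, agreement(a, b)$kappa,
               tolerance = 1e-12)
})

test_that("independent uniform 10-class labelings have ~10% chance agreement", {
  set.seed(32)
  a <- sample(paste0("IC", 1:10), 10000, replace = TRUE)
  b <- sample(paste0("IC", 1:10), 10000, replace = TRUE)
  rep_ <- agreement(a, b)
  expect_equal(rep_$expected_agreement_pe, 0.10, tolerance = 0.01)
  expect_lt(abs(rep_$kappa), 0.05)
})

test_that("disjoint label spaces warn and give zero observed agreement", {
  expect_warning(rep_ <- agreement(c("a", "b"), c("x", "y")), "disjoint")
  expect_equal(rep_$percent_agreement, 0)
})

test_that("printed response fractions reproduce from their counts", {
  expect_equal(proportion_from_counts(45, 121)$display, 37)
  expect_equal(proportion_from_counts(0, 20)$display, 0)
  expect_equal(proportion_from_counts(15, 76)$display, 20)
  expect_equal(proportion_from_counts(45, 121)$percent, 4500 / 121)
  expect_error(proportion_from_counts(1, 0), "positive")
  expect_error(proportion_from_counts(5, 4), "\\[0, total\\]")
  # one-decimal display for sub-percent reporting
  expect_equal(proportion_from_counts(298, 9524, digits = 1)$display, 3.1)
})

test_that("adjusted R-squared matches the sum-of-squares oracle", {
  # fixed n = 9, k = 3 fixture
  y <- c(1.2, 0.8, 1.0, 3.1, 2.9, 3.3, 5.2, 4.8, 5.1)
  g <- rep(c("a", "b", "c"), each = 3)
  expect_equal(anova_adjusted_r2(y, g), oracle_adj_r2(y, g),
               tolerance = 1e-10)
  for (rep in 1:10) {
    set.seed(40 + rep)
    n <- sample(8:30, 1); k <- sample(2:4, 1)
    g <- sample(paste0("g", 1:k), n, replace = TRUE)
    while (length(unique(g)) < k) g <- sample(paste0("g", 1:k), n, TRUE)
    y <- rnorm(n) + as.numeric(factor(g)) * runif(1, 0, 2)
    expect_equal(anova_adjusted_r2(y, g), oracle_adj_r2(y, g),
                 tolerance = 1e-10)
  }
})

test_that("adjusted R-squared limits: perfect fit and null case", {
  y <- rep(c(1, 5, 9), each = 4)
  g <- rep(c("a", "b", "c"), each = 4)
  expect_equal(suppressWarnings(anova_adjusted_r2(y, g)), 1)
  set.seed(50)
  y2 <- rnorm(60)
  g2 <- rep(c("a", "b", "c"), each = 20)
  r2adj <- anova_adjusted_r2(y2, g2)
  expect_lt(abs(r2adj), 0.1)
  # adjustment can push below zero and never exceeds raw R2
  r2 <- 1 - sum(resid(lm(y2 ~ factor(g2)))^2) / sum((y2 - mean(y2))^2)
  expect_lte(r2adj, r2)
  expect_error(anova_adjusted_r2(y2, rep("a", 60)), "2 groups")
  expect_error(anova_adjusted_r2(c(1, 2), c("a", "b")), "more samples")
  expect_error(anova_adjusted_r2(rep(1, 10), rep(c("a", "b"), 5)),
               "zero total variance")
})

test_that("explained-variation self-comparison is exactly zero", {
  set.seed(60)
  x <- matrix(rnorm(30 * 50), 30, 50,
              dimnames = list(paste0("g", 1:30), paste0("s", 1:50)))
  lab <- sample(c("A", "B", "C"), 50, replace = TRUE)
  rep_ <- explained_variation_comparison(x, lab, lab, rownames(x),
                                         n_bootstrap = 200, seed = 1)
  expect_equal(rep_$mean_delta, 0)
  expect_lte(rep_$ci_low, 0)
  expect_gte(rep_$ci_high, 0)
  expect_equal(rep_$study_weight, 50L)
})

test_that("label-driven expression yields positive delta with CI excluding 0", {
  successes <- 0
  for (s in 1:20) {
    set.seed(s)
    n <- 200; G <- 100
    lab_a <- sample(paste0("k", 1:4), n, replace = TRUE)
    lab_b <- sample(paste0("k", 1:4), n, replace = TRUE)
    eff <- matrix(rnorm(4 * G, sd = 1), 4, G)
    x <- t(eff[as.integer(factor(lab_a)), ]) +
      matrix(rnorm(G * n), G, n)
    dimnames(x) <- list(paste0("g", 1:G), paste0("s", 1:n))
    rep_ <- explained_variation_comparison(x, lab_a, lab_b, rownames(x),
                                           n_bootstrap = 200, seed = s)
    if (rep_$mean_delta > 0 && rep_$ci_low > 0) successes <- successes + 1
  }
  expect_gte(successes, 19)
})

test_that("bootstrap CIs are seed-reproducible and widen with confidence", {
  set.seed(61)
  x <- matrix(rnorm(20 * 40), 20, 40,
              dimnames = list(paste0("g", 1:20), paste0("s", 1:40)))
  a <- sample(c("A", "B"), 40, replace = TRUE)
  b <- sample(c("A", "B"), 40, replace = TRUE)
  r1 <- explained_variation_comparison(x, a, b, rownames(x),
                                       n_bootstrap = 300, seed = 7)
  r2 <- explained_variation_comparison(x, a, b, rownames(x),
                                       n_bootstrap = 300, seed = 7)
  expect_identical(c(r1$ci_low, r1$ci_high), c(r2$ci_low, r2$ci_high))
  r99 <- explained_variation_comparison(x, a, b, rownames(x),
                                        n_bootstrap = 300, seed = 7,
                                        conf = 0.99)
  expect_lte(r99$ci_low, r1$ci_low)
  expect_gte(r99$ci_high, r1$ci_high)
})

test_that("study-size weighting follows the closed form", {
  expect_equal(weighted_mean_across_studies(0.4, 120), 0.4)
  expect_equal(weighted_mean_across_studies(c(0.1, -0.1), c(50, 50)), 0)
  est <- c(0.05, 0.02, -0.01); n <- c(435, 200, 100)
  expect_equal(weighted_mean_across_studies(est, n),
               (0.05 * 435 + 0.02 * 200 - 0.01 * 100) / 735,
               tolerance = 1e-12)
  expect_error(weighted_mean_across_studies(numeric(0), numeric(0)),
               "empty")
  expect_error(weighted_mean_across_studies(0.1, 0), "positive")
})
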
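test_that("ROUT flags obvious outliers and nothing else", {
  expect_false(any(rout_outliers(rep(10, 10))))
  # nine values near 10 plus one at 100: exactly the extreme point flagged
  x <- c(9.9, 10.1, 9.95, 10.05, 9.92, 10.08, 10.02, 9.98, 10.0, 100)
  flags <- rout_outliers(x, Q = 1)
  expect_identical(which(flags), 10L)
  expect_identical(as.logical(flags), oracle_rout(x, Q = 1))
  # a clean symmetric sample has no point past the FDR boundary
  y <- qnorm(seq(0.05, 0.95, length.out = 11))
  expect_false(any(rout_outliers(y, Q = 1)))
  expect_error(rout_outliers(c(1, 2, 3, 4)), "at least 5")
})

test_that("ROUT flags are invariant to affine rescaling", {
  set.seed(11)
  for (i in 1:25) {
    x <- c(rnorm(sample(5:15, 1)), if (runif(1) < 0.5) rnorm(1, 8, 1))
    f0 <- rout_outliers(x)
    a <- runif(1, 0.1, 50); b <- runif(1, -100, 100)
    expect_identical(as.logical(rout_outliers(a * x + b)), as.logical(f0))
    expect_identical(as.logical(rout_outliers(-x)), as.logical(f0))
  }
})

test_that("Kruskal-Wallis/Dunn matches hand computation and handles ties in spirit", {
  rep3 <- kruskal_wallis_dunn(list(a = 1:3, b = 4:6, c = 7:9))
  expect_equal(unname(rep3$statistic["H"]), 7.2)
  # identical groups: H = 0, p = 1, no error
  same <- kruskal_wallis_dunn(list(a = c(5, 5), b = c(5, 5)))
  expect_equal(unname(same$statistic["H"]), 0)
  expect_equal(unname(same$p_value), 1)
  expect_true(all(same$comparisons$p_adj == 1))
  # adjusted p never below raw, never above 1
  set.seed(12)
  for (i in 1:20) {
    g <- list(a = rnorm(5), b = rnorm(6, 1), c = rnorm(4, 2))
    rep <- kruskal_wallis_dunn(g)
    expect_true(all(rep$comparisons$p_adj >= rep$comparisons$p_raw - 1e-15))
    expect_true(all(rep$comparisons$p_adj <= 1))
    expect_equal(unname(rep$statistic["H"]), oracle_kw_h(g), tolerance = 1e-12)
  }
  # vs-control comparison set
  vc <- kruskal_wallis_dunn(list(ctrl = rnorm(5), t1 = rnorm(5), t2 = rnorm(5)),
                            comparisons = "vs_control")
  expect_identical(nrow(vc$comparisons), 2L)
  expect_true(all(vc$comparisons$group1 == "ctrl"))
})

test_that("Welch's t handles degenerate and symmetric cases", {
  same <- welch_t(c(3, 3, 3), c(3, 3, 3))
  expect_equal(unname(same$statistic["t"]), 0)
  expect_equal(unname(same$p_value), 1)
  a <- c(1.2, 2.4, 3.1, 0.8); b <- c(4.5, 5.2, 3.9)
  ab <- welch_t(a, b); ba <- welch_t(b, a)
  expect_equal(unname(ab$statistic["t"]), -unname(ba$statistic["t"]))
  expect_equal(unname(ab$p_value), unname(ba$p_value))
  orc <- oracle_welch_t(a, b)
  expect_equal(unname(ab$statistic["t"]), orc$t, tolerance = 1e-12)
  expect_equal(unname(ab$p_value), orc$p, tolerance = 1e-12)
})

test_that("Brown-Forsythe and Welch ANOVA agree with the textbook formulas", {
  same <- brown_forsythe_welch_anova(list(a = c(1, 1), b = c(1, 1), c = c(1, 1)))
  expect_equal(unname(same$p_value["brown_forsythe"]), 1)
  expect_equal(unname(same$p_value["welch"]), 1)
  set.seed(13)
  g <- list(a = rnorm(6), b = rnorm(5, 0.5, 2), c = rnorm(7, 1, 0.5))
  rep <- brown_forsythe_welch_anova(g)
  expect_equal(unname(rep$statistic["F_star"]), oracle_brown_forsythe(g)$F,
               tolerance = 1e-12)
  expect_equal(unname(rep$p_value["brown_forsythe"]), oracle_brown_forsythe(g)$p,
               tolerance = 1e-12)
  expect_equal(unname(rep$statistic["W"]), oracle_welch_anova(g)$W,
               tolerance = 1e-12)
  # permuting group order leaves both statistics unchanged
  repp <- brown_forsythe_welch_anova(g[c(3, 1, 2)])
  expect_equal(repp$statistic, rep$statistic)
  expect_equal(repp$p_value, rep$p_value)
  expect_error(brown_forsythe_welch_anova(list(a = 1:3, b = 4:6)), ">= 3 groups")
})

test_that("Kolmogorov-Smirnov endpoints and exact small-sample p values", {
  same <- ks_two_sample(c(1, 2, 3), c(1, 2, 3))
  expect_equal(unname(same$statistic["D"]), 0)
  disj <- ks_two_sample(c(1, 2, 3), c(10, 11, 12))
  expect_equal(unname(disj$statistic["D"]), 1)
  # exact p agrees with full enumeration of group assignments
  set.seed(14)
  for (i in 1:5) {
    a <- rnorm(5); b <- rnorm(sample(4:6, 1), 0.8)
    rep <- ks_two_sample(a, b)
    expect_equal(unname(rep$statistic["D"]), oracle_ks_d(a, b), tolerance = 1e-12)
    expect_equal(unname(rep$p_value), oracle_ks_p_exact(a, b), tolerance = 1e-9)
  }
})

test_that("blot normalization is a ratio of ratios", {
  expect_equal(normalize_blot(1, 1, 1, 1), 1)
  expect_equal(normalize_blot(7, 1, 1, 1), 7)
  # common gain on band and loading control cancels
  expect_equal(normalize_blot(14, 2, 1, 1), normalize_blot(7, 1, 1, 1))
  expect_error(normalize_blot(1, 0, 1, 1), "positive")
})

test_that("group summaries report mean, SEM and a normality screen", {
  rep <- kruskal_wallis_dunn(list(a = c(1, 2, 3, 4, 5, 6), b = c(2, 3, 4, 5, 6, 7)))
  s <- rep$summaries
  expect_equal(s$mean, c(3.5, 4.5))
  expect_equal(s$sem, rep(sd(1:6) / sqrt(6), 2))
  expect_true(all(is.finite(s$shapiro_p)))
})

test_that("outlier removal inside the tests drops planted contaminants", {
  set.seed(15)
  clean_a <- rnorm(12, 10, 0.5); clean_b <- rnorm(12, 12, 0.5)
  rep <- kruskal_wallis_dunn(list(a = c(clean_a, 50), b = clean_b), rout_q = 1)
  expect_identical(rep$outliers_removed$a, 13L)
  expect_length(rep$outliers_removed$b, 0)
  expect_equal(rep$summaries$n, c(12L, 12L))
})
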
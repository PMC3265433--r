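test_that("welch_anova matches the step-by-step formula", {
  g <- stats_fixture()
  got <- welch_anova(g)
  want <- oracle_welch(g)
  expect_equal(got$statistic, want$statistic, tolerance = 1e-9)
  expect_equal(got$df1, want$df1)
  expect_equal(got$df2, want$df2, tolerance = 1e-9)
  expect_equal(got$p.value, want$p.value, tolerance = 1e-9)
  # identical groups: no between-group signal
  same <- list(a = c(1, 2, 3), b = c(1, 2, 3), c = c(1, 2, 3))
  expect_equal(welch_anova(same)$statistic, 0)
  expect_equal(welch_anova(same)$p.value, 1)
  # two groups: F_w is the square of Welch's two-sample t
  two <- list(x = c(3, 5, 8, 9, 12), y = c(1, 2, 2, 4))
  tt <- stats::t.test(two$x, two$y, var.equal = FALSE)
  expect_equal(welch_anova(two)$statistic, unname(tt$statistic)^2,
               tolerance = 1e-9)
  expect_equal(welch_anova(two)$p.value, tt$p.value, tolerance = 1e-9)
})

test_that("classic_anova matches the sum-of-squares formula", {
  g <- stats_fixture()
  got <- classic_anova(g)
  want <- oracle_classic(g)
  expect_equal(got$statistic, want$statistic, tolerance = 1e-9)
  expect_equal(got$df1, want$df1)
  expect_equal(got$df2, want$df2)
  expect_equal(got$p.value, want$p.value, tolerance = 1e-9)
  same_means <- list(a = c(1, 3), b = c(0, 4), c = c(-1, 5))
  expect_equal(classic_anova(same_means)$statistic, 0)
  # two groups: F equals the pooled-variance t squared
  two <- list(x = c(3, 5, 8, 9, 12), y = c(1, 2, 2, 4))
  tt <- stats::t.test(two$x, two$y, var.equal = TRUE)
  expect_equal(classic_anova(two)$statistic, unname(tt$statistic)^2,
               tolerance = 1e-9)
})

test_that("welch and classic ANOVA agree under equal variances and sizes", {
  set.seed(91)
  # two groups with exactly equal sample variances and sizes: the Welch
  # correction factor is identically 1 and the statistics coincide
  g2 <- lapply(list(a = stats::rnorm(20), b = stats::rnorm(20)),
               function(v) (v - mean(v)) / stats::sd(v))
  g2$a <- g2$a + 0.5
  expect_equal(welch_anova(g2)$statistic, classic_anova(g2)$statistic,
               tolerance = 1e-9)
  # three groups: the correction is O(1/n) and vanishes with group size
  n <- 1e6
  g3 <- lapply(list(a = stats::rnorm(n), b = stats::rnorm(n),
                    c = stats::rnorm(n)),
               function(v) (v - mean(v)) / stats::sd(v))
  g3$a <- g3$a + 0.01
  expect_equal(welch_anova(g3)$statistic, classic_anova(g3)$statistic,
               tolerance = 1e-6)
})

test_that("levene_test is an ANOVA on absolute deviations", {
  g <- stats_fixture()
  got <- levene_test(g)
  absdev <- lapply(g, function(v) abs(v - mean(v)))
  want <- oracle_classic(absdev)
  expect_equal(got$statistic, want$statistic, tolerance = 1e-9)
  expect_equal(got$p.value, want$p.value, tolerance = 1e-9)
  # equal spreads: W = 0 ({1,3} vs {5,7} both have unit deviations)
  flat <- list(a = c(1, 3), b = c(5, 7))
  expect_equal(levene_test(flat)$statistic, 0)
  # scaling one group strictly increases W
  g10 <- g; g10$c <- g$c * 10
  expect_gt(levene_test(g10)$statistic, levene_test(g)$statistic)
  # median centring is available and differs on skewed data
  skew <- list(a = c(1, 1, 1, 9), b = c(2, 4, 6, 8))
  expect_false(isTRUE(all.equal(levene_test(skew, "mean")$statistic,
                                levene_test(skew, "median")$statistic)))
  expect_error(levene_test(list(a = c(2, 2), b = c(3, 3))), "degenerate")
})

test_that("tamhane_t2 applies Welch pairs with the Sidak correction", {
  g <- stats_fixture()
  got <- tamhane_t2(g, alpha = 0.05)
  expect_equal(nrow(got), 3L)  # k(k-1)/2 pairs
  m <- 3
  combs <- utils::combn(names(g), 2)
  for (j in seq_len(ncol(combs))) {
    o <- oracle_welch_t(g[[combs[1, j]]], g[[combs[2, j]]])
    row <- got[got$group1 == combs[1, j] & got$group2 == combs[2, j], ]
    expect_equal(row$t, o$t, tolerance = 1e-9)
    expect_equal(row$df, o$df, tolerance = 1e-9)
    expect_equal(row$p_raw, o$p, tolerance = 1e-9)
    expect_equal(row$p_adj, min(1, 1 - (1 - o$p)^m), tolerance = 1e-9)
    expect_identical(row$significant, o$p < 1 - 0.95^(1 / m))
  }
  # identical groups: nothing significant, adjusted p = 1
  same <- list(a = c(1, 2, 3), b = c(1, 2, 3), c = c(1, 2, 3))
  ts <- tamhane_t2(same)
  expect_true(all(ts$p_adj == 1))
  expect_false(any(ts$significant))
  # with a single pair there is no correction
  two <- list(x = c(3, 5, 8, 9, 12), y = c(1, 2, 2, 4))
  t2 <- tamhane_t2(two)
  expect_equal(t2$p_adj, t2$p_raw, tolerance = 1e-12)
})

test_that("group inputs are validated", {
  expect_error(welch_anova(list(a = 1:3)), "at least 2 groups")
  expect_error(welch_anova(list(a = 1:3, b = 2)), "n >= 2")
  expect_error(welch_anova(list(a = c(1, 1, 1), b = c(1, 2, 3))),
               "zero within-group variance")
  # long-format data frame input
  df <- data.frame(surface = rep(c("soft", "firm"), each = 4),
                   dev_deg = c(10, 12, 14, 16, 4, 5, 6, 7))
  res <- welch_anova(df)
  expect_equal(res$statistic,
               oracle_welch(split(df$dev_deg, df$surface))$statistic,
               tolerance = 1e-9)
})

test_that("group_comparison bundles all four analyses coherently", {
  g <- stats_fixture()
  gc <- group_comparison(g, alpha = 0.05)
  expect_equal(gc$welch$statistic, oracle_welch(g)$statistic,
               tolerance = 1e-9)
  expect_equal(gc$classic$statistic, oracle_classic(g)$statistic,
               tolerance = 1e-9)
  expect_equal(nrow(gc$pairwise), 3L)
  expect_equal(gc$summary$mean_dev_deg, vapply(g, mean, 0),
               ignore_attr = TRUE)
})
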
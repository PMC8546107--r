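test_that("one-way ANOVA matches the sums-of-squares oracle", {
  g <- list(a = c(1, 2, 3), b = c(2, 3, 4), c = c(3, 4, 5))
  res <- one_way_anova(g)
  expect_equal(res$statistic, 3.0)
  expect_equal(res$df, c(2, 6))
  expect_equal(res$p_value, pf(3, 2, 6, lower.tail = FALSE))

  # identical means, nonzero spread -> F = 0
  g0 <- list(a = c(1, 3), b = c(0, 4), c = c(-1, 5))
  expect_equal(one_way_anova(g0)$statistic, 0)

  # random instances vs the oracle
  set.seed(50)
  for (i in 1:40) {
    gs <- lapply(seq_len(sample(2:4, 1)),
                 function(j) rnorm(sample(3:10, 1), sample(0:2, 1)))
    o <- oracle_anova(gs)
    r <- one_way_anova(gs)
    expect_equal(r$statistic, o$f, tolerance = 1e-10)
    expect_equal(r$p_value, o$p, tolerance = 1e-10)
    expect_equal(r$df, o$df)
  }
  expect_error(one_way_anova(list(a = rep(2, 3), b = rep(2, 4))),
               "identical")
  expect_error(one_way_anova(list(a = c(1, 2))), "group")
})

test_that("two-group ANOVA F equals the squared pooled t statistic", {
  set.seed(51)
  for (i in 1:15) {
    g1 <- rnorm(sample(4:9, 1)); g2 <- rnorm(sample(4:9, 1), 0.5)
    f <- one_way_anova(list(g1, g2))$statistic
    t <- oracle_pooled_t(g1, g2)$t
    expect_equal(f, t^2, tolerance = 1e-10)
  }
})

test_that("ANOVA is shift-invariant and scale-invariant in F", {
  set.seed(52)
  gs <- list(rnorm(8), rnorm(8, 1), rnorm(10, 2))
  f0 <- one_way_anova(gs)$statistic
  for (i in 1:10) {
    c0 <- rnorm(1, 0, 10); s <- runif(1, 0.1, 5)
    expect_equal(one_way_anova(lapply(gs, function(g) g + c0))$statistic,
                 f0, tolerance = 1e-9)
    expect_equal(one_way_anova(lapply(gs, function(g) s * g))$statistic,
                 f0, tolerance = 1e-9)
  }
})

test_that("Levene's test is ANOVA on absolute deviations", {
  # mirror-image groups have identical deviations -> statistic 0
  g <- list(a = c(-2, -1, 1, 2), b = c(8, 9, 11, 12))
  expect_equal(levene_test(g)$statistic, 0, tolerance = 1e-12)

  set.seed(53)
  for (i in 1:25) {
    gs <- list(rnorm(7), rnorm(6, 0, 2), rnorm(9, 0, 0.5))
    r <- levene_test(gs, center = "mean")
    o <- oracle_anova(lapply(gs, function(x) abs(x - mean(x))))
    expect_equal(r$statistic, o$f, tolerance = 1e-10)
    expect_equal(r$p_value, o$p, tolerance = 1e-10)
  }
  expect_error(levene_test(list(a = rnorm(5))), "group")
})

test_that("Levene's test agrees with the car implementation", {
  skip_if_not_installed("car")
  set.seed(54)
  for (i in 1:10) {
    gs <- list(rnorm(8), rnorm(7, 0, 1.7), rnorm(9, 0, 0.6))
    vals <- unlist(gs)
    fac <- factor(rep(seq_along(gs), lengths(gs)))
    ref <- car::leveneTest(vals ~ fac, center = mean)
    r <- levene_test(gs, center = "mean")
    expect_equal(r$statistic, ref[1, "F value"], tolerance = 1e-10)
    expect_equal(r$p_value, ref[1, "Pr(>F)"], tolerance = 1e-10)
  }
})

test_that("planned contrasts match the pooled-variance formula", {
  r <- planned_contrast(c(1, 2, 3), c(3, 4, 5), "pooled")
  expect_equal(abs(r$statistic), 2 * sqrt(3) / sqrt(2), tolerance = 1e-10)
  expect_equal(r$df, 4)

  # identical groups: t = 0, p = 1
  r0 <- planned_contrast(c(1, 2, 3), c(1, 2, 3), "pooled")
  expect_equal(r0$statistic, 0)
  expect_equal(r0$p_value, 1)

  set.seed(55)
  for (i in 1:25) {
    g1 <- rnorm(sample(4:10, 1)); g2 <- rnorm(sample(4:10, 1), 0.4)
    r <- planned_contrast(g1, g2, "pooled")
    o <- oracle_pooled_t(g1, g2)
    expect_equal(r$statistic, o$t, tolerance = 1e-10)
    expect_equal(r$p_value, o$p, tolerance = 1e-10)
    # antisymmetry
    rs <- planned_contrast(g2, g1, "pooled")
    expect_equal(rs$statistic, -r$statistic, tolerance = 1e-12)
    expect_equal(rs$p_value, r$p_value, tolerance = 1e-12)
  }
  # pooled equals Welch for equal sizes and equal variances
  g1 <- c(1, 2, 3, 4); g2 <- g1 + 2
  expect_equal(planned_contrast(g1, g2, "pooled")$statistic,
               planned_contrast(g1, g2, "welch")$statistic)
  expect_error(planned_contrast(rep(1, 3), rep(1, 4)), "undefined")
})

test_that("the contrast gate is strict at alpha", {
  mk <- function(p) structure(list(p_value = p), class = "test_result")
  expect_true(gate_contrasts(mk(0.031)))
  expect_false(gate_contrasts(mk(0.05)))
  expect_false(gate_contrasts(mk(0.649)))
  expect_true(gate_contrasts(mk(0.09), alpha = 0.1))
})

test_that("Pearson correlation matches the covariance formula", {
  x <- c(1, 2, 4, 7)
  expect_equal(pearson_correlation(x, x)$statistic, 1)
  expect_equal(pearson_correlation(x, -x)$statistic, -1)
  set.seed(56)
  for (i in 1:15) {
    x <- rnorm(10); y <- 0.5 * x + rnorm(10)
    r <- pearson_correlation(x, y)
    r_hand <- sum((x - mean(x)) * (y - mean(y))) /
      sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
    expect_equal(r$statistic, r_hand, tolerance = 1e-12)
    t_hand <- r_hand * sqrt(8 / (1 - r_hand^2))
    expect_equal(r$p_value, 2 * pt(-abs(t_hand), 8), tolerance = 1e-10)
  }
  expect_error(pearson_correlation(rep(1, 5), rnorm(5)), "zero variance")
  expect_error(pearson_correlation(1:2, 1:2), "lengths")
})

test_that("compare_groups runs the full design with gating", {
  set.seed(57)
  # strong separation: gate opens, pooled contrasts
  gs <- list(MS_ON = rnorm(16, 0), MS_noON = rnorm(16, 1),
             healthy = rnorm(18, 2))
  cmp <- compare_groups(gs)
  expect_true(cmp$gated)
  expect_equal(nrow(cmp$contrasts), 3)
  expect_equal(cmp$summary$n, c(16, 16, 18))
  # null data: gate usually closed; force with alpha ~ 1 boundary instead
  gs0 <- list(a = rnorm(16), b = rnorm(16), c = rnorm(18))
  cmp0 <- compare_groups(gs0, alpha = 1e-12)
  expect_false(cmp0$gated)
  expect_null(cmp0$contrasts)
})

test_that("the normality check reports one advisory row per group", {
  set.seed(58)
  out <- normality_check(list(a = rnorm(20), b = runif(20)))
  expect_equal(nrow(out), 2)
  expect_true(all(out$p_value >= 0 & out$p_value <= 1))
})
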
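test_that("mixed ANOVA time effect equals the squared paired t (one group + null)", {
  set.seed(8)
  # two groups drawn from the same distribution: interaction near null
  d <- tibble::tibble(
    group = rep(c("a", "b"), each = 40),
    pre = rnorm(80), post = rnorm(80)
  )
  m <- mixed_anova(d, "pre", "post")
  eff <- tidy(m)
  expect_gt(eff$p.value[eff$term == "group:time"], 0.01)

  # algebraic identity: one group, two time points -> time F = paired t^2
  d2 <- tibble::tibble(group = "a", pre = rnorm(30))
  d2$post <- d2$pre + rnorm(30, 0.4)
  m2 <- mixed_anova(d2, "pre", "post")
  tt <- t.test(d2$post, d2$pre, paired = TRUE)
  f_time <- tidy(m2)$statistic[tidy(m2)$term == "time"]
  expect_equal(f_time, unname(tt$statistic)^2, tolerance = 1e-8)
  expect_error(mixed_anova(d[c(1, 2, 41), ], "pre", "post"), "n >= 2")
})

test_that("mixed ANOVA detects a planted group-by-time effect", {
  set.seed(9)
  n <- 60
  d <- tibble::tibble(group = rep(c("trt", "ctl"), each = n), pre = rnorm(2 * n))
  d$post <- d$pre + ifelse(d$group == "trt", 0.8, 0) + rnorm(2 * n, sd = 0.5)
  m <- mixed_anova(d, "pre", "post")
  eff <- tidy(m)
  expect_lt(eff$p.value[eff$term == "group:time"], 0.001)
  expect_gt(eff$partial_eta_sq[eff$term == "group:time"], 0.1)
})

test_that("gain ANOVA isolates the null group in a 4-group fixture", {
  set.seed(10)
  n <- 50
  means <- c(walk = 0.5, walk_plus = 0.45, sss = 0.4, dance = 0)
  d <- tibble::tibble(
    group = rep(names(means), each = n),
    gain = rnorm(4 * n, mean = rep(means, each = n), sd = 0.3)
  )
  res <- gain_anova(d, "gain")
  expect_lt(tidy(res)$p.value, 0.001)
  gt <- tidy(res, "groups")
  expect_gt(gt$p.value[gt$group == "dance"], 0.05)
  expect_true(all(gt$p.value[gt$group != "dance"] < 0.001))
  pw <- tidy(res, "pairwise")
  expect_true(all(pw$p.adjusted >= pw$p.value))
})

test_that("all-zero gains are a no-effect result; degenerate variance errors", {
  d <- tibble::tibble(group = rep(c("a", "b"), each = 5), gain = 0)
  res <- gain_anova(d, "gain")
  expect_equal(tidy(res)$statistic, 0)
  expect_equal(tidy(res)$p.value, 1)
  expect_true(all(tidy(res, "groups")$p.value == 1))
  d2 <- tibble::tibble(group = rep(c("a", "b"), each = 5),
                       gain = rep(c(0, 1), each = 5))
  expect_error(gain_anova(d2, "gain"), "zero within-group variance")
})

test_that("ANCOVA with a covariate orthogonal to group matches plain ANOVA", {
  set.seed(12)
  n <- 40
  d <- tibble::tibble(group = rep(c("a", "b"), each = n))
  d$gain <- rnorm(2 * n) + ifelse(d$group == "a", 0.6, 0)
  # covariate orthogonalized against both group and gain: it explains
  # nothing, so the group F changes only through one lost error df
  z <- rnorm(2 * n)
  z <- resid(lm(z ~ d$group + d$gain))
  d$cov <- z
  f0 <- tidy(gain_anova(d, "gain"))$statistic
  f1 <- tidy(gain_anova(d, "gain", covariates = "cov"))$statistic
  expect_equal(f1, f0, tolerance = 0.03)
})

test_that("noise-free data generated from the model is recovered exactly", {
  set.seed(14)
  n <- 40
  d <- tibble::tibble(
    age = runif(n, 60, 80), mean_fd = runif(n, 0.05, 0.3),
    ef_baseline = rnorm(n), modularity = rnorm(n, 0.45, 0.07)
  )
  bc <- d$ef_baseline - mean(d$ef_baseline)
  qc <- d$modularity - mean(d$modularity)
  d$ef_gain <- 0.2 - 0.01 * d$age + 0.5 * d$mean_fd - 0.1 * d$ef_baseline +
    1.8 * d$modularity - 2.4 * bc * qc
  fit <- fit_gain_model(d, n_boot = 0)
  est <- setNames(fit$coefficients$estimate, fit$coefficients$term)
  expect_equal(est[["age"]], -0.01, tolerance = 1e-8)
  expect_equal(est[["mean_fd"]], 0.5, tolerance = 1e-8)
  expect_equal(est[["baseline"]], -0.1, tolerance = 1e-8)
  expect_equal(est[["modularity"]], 1.8, tolerance = 1e-8)
  expect_equal(est[["baseline:modularity"]], -2.4, tolerance = 1e-8)
  expect_equal(fit$r.squared, 1, tolerance = 1e-10)
  # residual orthogonality to every design column
  for (v in c("age", "mean_fd", "ef_baseline", "modularity")) {
    expect_lt(abs(sum(fit$residuals * d[[v]])), 1e-6)
  }
})

test_that("collinear predictors are rejected with a condition-number error", {
  set.seed(15)
  n <- 30
  d <- tibble::tibble(
    age = runif(n, 60, 80), ef_baseline = rnorm(n),
    modularity = rnorm(n), ef_gain = rnorm(n)
  )
  d$mean_fd <- d$age * 2 + 3   # exact collinearity
  expect_error(fit_gain_model(d, n_boot = 0), "collinear")
})

test_that("the reduced model regresses gain on modularity alone", {
  set.seed(16)
  n <- 35
  d <- tibble::tibble(modularity = rnorm(n, 0.45, 0.07))
  d$ef_gain <- 0.1 + 1.2 * d$modularity + rnorm(n, sd = 0.2)
  fit <- fit_gain_model(d, reduced = TRUE, n_boot = 0)
  expect_identical(fit$coefficients$term, c("(Intercept)", "modularity"))
  cmp <- lm(ef_gain ~ modularity, data = d)
  expect_equal(fit$coefficients$estimate, unname(coef(cmp)), tolerance = 1e-10)
  expect_equal(glance(fit)$r.squared, summary(cmp)$r.squared, tolerance = 1e-10)
})

test_that("partial correlation reduces to Pearson and matches the matrix oracle", {
  set.seed(18)
  n <- 20
  d <- tibble::tibble(x = rnorm(n), c1 = rnorm(n), c2 = rnorm(n))
  d$y <- 0.5 * d$x + 0.3 * d$c1 + rnorm(n, sd = 0.5)
  # no covariates: Pearson r
  p0 <- partial_correlation(d, "x", "y", n_boot = 0)
  expect_equal(p0$estimate, cor(d$x, d$y), tolerance = 1e-12)
  expect_equal(p0$df, n - 2)
  # matches the inverse-correlation-matrix oracle with 2 covariates
  p2 <- partial_correlation(d, "x", "y", c("c1", "c2"), n_boot = 0)
  expect_equal(p2$estimate, oracle_partial_cor(d, "x", "y", c("c1", "c2")),
               tolerance = 1e-10)
  expect_equal(p2$df, n - 2 - 2)
  # y = x gives r = 1
  d$y2 <- d$x
  expect_equal(partial_correlation(d, "x", "y2", "c1", n_boot = 0)$estimate, 1,
               tolerance = 1e-12)
  # one-tailed p is half the two-tailed for positive estimates
  p_two <- partial_correlation(d, "x", "y", "c1", n_boot = 0)
  p_one <- partial_correlation(d, "x", "y", "c1", alternative = "greater",
                               n_boot = 0)
  expect_equal(p_one$p.value, p_two$p.value / 2, tolerance = 1e-12)
})

test_that("partial correlation equals the correlation of OLS residuals", {
  set.seed(20)
  n <- 50
  d <- tibble::tibble(x = rnorm(n), y = rnorm(n), a = rnorm(n), b = rnorm(n))
  got <- partial_correlation(d, "x", "y", c("a", "b"), n_boot = 0)$estimate
  rx <- resid(lm(x ~ a + b, data = d))
  ry <- resid(lm(y ~ a + b, data = d))
  expect_equal(got, cor(rx, ry), tolerance = 1e-10)
})

test_that("BCa reduces to the percentile interval for a symmetric statistic", {
  set.seed(21)
  x <- rnorm(100)
  ci <- bca_ci(x, mean, n_boot = 4000, seed = 99)
  expect_lt(abs(ci$z0), 0.08)
  expect_lt(abs(ci$acceleration), 0.05)
  set.seed(99)
  boots <- replicate(4000, mean(sample(x, replace = TRUE)))
  perc <- quantile(boots, c(0.025, 0.975), names = FALSE, type = 6)
  expect_equal(ci$lower, perc[1], tolerance = 0.03)
  expect_equal(ci$upper, perc[2], tolerance = 0.03)
})

test_that("BCa matches an independent implementation on the same resamples scale", {
  skip_if_not_installed("boot")
  set.seed(22)
  x <- rexp(60)           # skewed: bias/acceleration matter
  ours <- bca_ci(x, mean, n_boot = 4000, seed = 5)
  bt <- boot::boot(x, function(d, i) mean(d[i]), R = 4000)
  bci <- boot::boot.ci(bt, type = "bca")$bca[4:5]
  expect_equal(ours$lower, bci[1], tolerance = 0.05)
  expect_equal(ours$upper, bci[2], tolerance = 0.05)
})

test_that("degenerate bootstrap distributions raise an error", {
  expect_error(bca_ci(rep(3, 20), mean, n_boot = 200), "degenerate")
})

test_that("BCa respects monotone transformation (log of a positive mean)", {
  set.seed(25)
  x <- rexp(80) + 0.5
  a <- bca_ci(x, mean, n_boot = 3000, seed = 7)
  b <- bca_ci(x, function(v) log(mean(v)), n_boot = 3000, seed = 7)
  expect_equal(log(a$lower), b$lower, tolerance = 0.02)
  expect_equal(log(a$upper), b$upper, tolerance = 0.02)
})

test_that("Bonferroni adjustment multiplies and caps", {
  expect_equal(bonferroni(0.01, 6), 0.06)
  expect_equal(bonferroni(0.5, 6), 1)
  expect_equal(bonferroni(0.3), 0.3)   # m = 1 identity
  expect_equal(bonferroni(c(0.01, 0.04), 6), c(0.06, 0.24))
})

test_that("tidy/glance/autoplot provide the standard surfaces", {
  set.seed(26)
  n <- 40
  d <- tibble::tibble(
    age = runif(n, 60, 80), mean_fd = runif(n, 0.05, 0.3),
    ef_baseline = rnorm(n), modularity = rnorm(n, 0.45, 0.07)
  )
  d$ef_gain <- 0.1 + 1.5 * d$modularity + rnorm(n, 0, 0.3)
  fit <- fit_gain_model(d, n_boot = 200, seed = 1)
  td <- tidy(fit)
  expect_named(td, c("term", "estimate", "std.error", "statistic", "p.value",
                     "conf.low", "conf.high"))
  expect_false(anyNA(td$conf.low))
  td_ols <- tidy(fit, conf_type = "ols")
  expect_true(all(td_ols$conf.low < td_ols$conf.high))
  gl <- glance(fit)
  expect_lte(gl$adj.r.squared, gl$r.squared)
  expect_equal(gl$df.residual, n - 6)
  expect_s3_class(autoplot(fit), "ggplot")
  expect_s3_class(plot_modularity_gain(dplyr::mutate(d, group = "walk")), "ggplot")
})
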
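#' Mixed (split-plot) ANOVA for pre/post by group designs
#'
#' Classical sums-of-squares decomposition for one within-subject factor
#' with two levels (time: pre, post) and one between-subject factor
#' (group), the standard test for differential intervention effects on a
#' repeatedly measured outcome such as cardiorespiratory fitness. Reports
#' F, degrees of freedom, p and partial eta-squared for the time effect,
#' the group effect and the time x group interaction.
#'
#' With a single group the design reduces to a one-way repeated-measures
#' ANOVA on time, whose F equals the squared paired t.
#'
#' @param data Data frame with one row per subject.
#' @param pre,post Names of the pre- and post-score columns (strings).
#' @param group Name of the group column.
#' @return A `mixed_anova` object; `tidy()` returns the effect table.
#' @export
mixed_anova <- function(data, pre, post, group = "group") {
  stopifnot(all(c(pre, post, group) %in% names(data)))
  d <- data[stats::complete.cases(data[c(pre, post, group)]), , drop = FALSE]
  g <- factor(d[[group]])
  if (any(table(g) < 2)) {
    stop("every group needs n >= 2: ",
         paste(names(which(table(g) < 2)), collapse = ", "), call. = FALSE)
  }
  one_group <- nlevels(g) == 1L
  long <- data.frame(
    subject = factor(rep(seq_len(nrow(d)), 2L)),
    group = rep(g, 2L),
    time = factor(rep(c("pre", "post"), each = nrow(d)), levels = c("pre", "post")),
    value = c(d[[pre]], d[[post]])
  )
  fit <- if (one_group) {
    stats::aov(value ~ time + Error(subject/time), data = long)
  } else {
    stats::aov(value ~ group * time + Error(subject/time), data = long)
  }
  s <- summary(fit)
  within <- as.data.frame(s[["Error: subject:time"]][[1L]])
  pull <- function(tab, term, err_row) {
    i <- match(term, trimws(rownames(tab)))
    ss <- tab[i, "Sum Sq"]
    ss_err <- tab[err_row, "Sum Sq"]
    tibble::tibble(
      term = term,
      df = tab[i, "Df"],
      df_error = tab[err_row, "Df"],
      statistic = tab[i, "F value"],
      p.value = tab[i, "Pr(>F)"],
      partial_eta_sq = ss / (ss + ss_err)
    )
  }
  eff <- if (one_group) {
    pull(within, "time", nrow(within))
  } else {
    between <- as.data.frame(s[["Error: subject"]][[1L]])
    dplyr::bind_rows(
      pull(between, "group", nrow(between)),
      pull(within, "time", nrow(within)),
      pull(within, "group:time", nrow(within))
    )
  }
  structure(list(effects = eff, n = nrow(d), n_groups = nlevels(g)),
            class = "mixed_anova")
}

#' @export
print.mixed_anova <- function(x, ...) {
  cat("Mixed ANOVA (time x group), n =", x$n, "\n")
  print(as.data.frame(x$effects), digits = 4)
  invisible(x)
}

#' One-way (AN)COVA on gain scores with per-group tests against zero
#'
#' Tests whether intervention groups differ in a composite gain score,
#' optionally adjusting for covariates (ANCOVA); also tests each group's
#' mean gain against zero (one-sample t) and reports Bonferroni-adjusted
#' pairwise group contrasts.
#'
#' @param data Data frame, one row per subject.
#' @param gain Name of the gain-score column.
#' @param group Name of the group column.
#' @param covariates Optional character vector of covariate columns.
#' @return A `gain_anova` object with elements `omnibus` (tibble),
#'   `group_tests` (per-group t against 0), `pairwise` (Bonferroni-adjusted
#'   contrasts).
#' @export
gain_anova <- function(data, gain, group = "group", covariates = NULL) {
  stopifnot(all(c(gain, group, covariates) %in% names(data)))
  d <- data[stats::complete.cases(data[c(gain, group, covariates)]), , drop = FALSE]
  g <- factor(d[[group]])
  if (nlevels(g) < 2) stop("need >= 2 groups", call. = FALSE)
  y <- d[[gain]]
  if (all(y == 0)) {
    # degenerate but well-defined: no gains anywhere, so no effect to test
    zero_groups <- tibble::tibble(
      group = levels(g), n = as.integer(table(g)), mean_gain = 0,
      statistic = NA_real_, p.value = 1
    )
    prs0 <- utils::combn(levels(g), 2L, simplify = FALSE)
    zero_pairs <- tibble::tibble(
      group1 = vapply(prs0, `[`, "", 1L), group2 = vapply(prs0, `[`, "", 2L),
      diff = 0, p.value = 1, p.adjusted = 1
    )
    return(structure(list(
      omnibus = tibble::tibble(term = "group", df = nlevels(g) - 1L,
                               df_error = length(y) - nlevels(g),
                               statistic = 0, p.value = 1,
                               partial_eta_sq = 0, n = length(y)),
      group_tests = zero_groups, pairwise = zero_pairs,
      covariates = covariates), class = "gain_anova"))
  }
  wv <- tapply(y, g, stats::var)
  if (any(!is.na(wv) & wv == 0)) stop("zero within-group variance", call. = FALSE)
  if (max(wv, na.rm = TRUE) > 4 * min(wv, na.rm = TRUE)) {
    warning("group variances differ by more than 4x; classical F may be liberal")
  }
  d$..group.. <- g
  fit <- stats::lm(stats::reformulate(c(covariates, "..group.."), response = gain), data = d)
  at <- stats::anova(fit)
  i <- match("..group..", rownames(at))
  omnibus <- tibble::tibble(
    term = "group",
    df = at[i, "Df"], df_error = at["Residuals", "Df"],
    statistic = at[i, "F value"], p.value = at[i, "Pr(>F)"],
    partial_eta_sq = at[i, "Sum Sq"] / (at[i, "Sum Sq"] + at["Residuals", "Sum Sq"]),
    n = nrow(d)
  )
  group_tests <- purrr::map_dfr(levels(g), function(lv) {
    v <- y[g == lv]
    tt <- stats::t.test(v, mu = 0)
    tibble::tibble(group = lv, n = length(v), mean_gain = mean(v),
                   statistic = unname(tt$statistic), p.value = tt$p.value)
  })
  prs <- utils::combn(levels(g), 2L, simplify = FALSE)
  pairwise <- purrr::map_dfr(prs, function(pr) {
    tt <- stats::t.test(y[g == pr[1L]], y[g == pr[2L]], var.equal = TRUE)
    tibble::tibble(group1 = pr[1L], group2 = pr[2L],
                   diff = mean(y[g == pr[1L]]) - mean(y[g == pr[2L]]),
                   p.value = tt$p.value)
  })
  pairwise$p.adjusted <- bonferroni(pairwise$p.value, m = length(prs))
  structure(list(omnibus = omnibus, group_tests = group_tests,
                 pairwise = pairwise, covariates = covariates),
            class = "gain_anova")
}

#' @export
print.gain_anova <- function(x, ...) {
  cat("Gain AN(C)OVA")
  if (length(x$covariates)) cat(" (covariates:", paste(x$covariates, collapse = ", "), ")")
  cat("\n")
  print(as.data.frame(x$omnibus), digits = 4)
  cat("\nPer-group mean gain vs 0:\n")
  print(as.data.frame(x$group_tests), digits = 4)
  invisible(x)
}

#' Moderated regression of EF gain on baseline modularity
#'
#' Ordinary least squares of a gain score on age, mean framewise
#' displacement, baseline performance, baseline network modularity and a
#' baseline-performance x modularity interaction — the model asking whether
#' individuals with more modular baseline networks gain more from an
#' intervention, and whether that relationship is moderated by baseline
#' ability. The interaction is formed from mean-centered copies of both
#' variables by default so main effects are interpretable at the sample
#' mean. Coefficient CIs are reported two ways: case-resampling BCa
#' bootstrap and analytic OLS.
#'
#' @param data Data frame, one row per subject (typically one intervention
#'   group), with complete cases on all model columns.
#' @param gain,modularity,baseline Column names (strings) for the gain
#'   score, baseline modularity and baseline performance.
#' @param covariates Character vector of additional covariate columns
#'   (default `c("age", "mean_fd")`).
#' @param center Mean-center modularity and baseline performance before
#'   forming the interaction (default `TRUE`).
#' @param reduced If `TRUE`, fit the reduced model with modularity as the
#'   only predictor.
#' @param n_boot Bootstrap resamples for the BCa CIs (default 5000; set to
#'   0 to skip the bootstrap).
#' @param level Confidence level.
#' @param seed Integer seed for the bootstrap resample stream.
#' @return A `gain_model` object. `tidy()` gives the coefficient table with
#'   both CI flavors; `glance()` gives R-squared, adjusted R-squared, F, df
#'   and n.
#' @export
fit_gain_model <- function(data, gain = "ef_gain", modularity = "modularity",
                           baseline = "ef_baseline",
                           covariates = c("age", "mean_fd"),
                           center = TRUE, reduced = FALSE,
                           n_boot = 5000, level = 0.95, seed = NULL) {
  cols <- c(gain, modularity, if (!reduced) c(baseline, covariates))
  stopifnot(all(cols %in% names(data)))
  d <- data[stats::complete.cases(data[cols]), cols, drop = FALSE]
  n <- nrow(d)
  y <- d[[gain]]
  if (reduced) {
    x <- cbind(`(Intercept)` = 1, modularity = d[[modularity]])
  } else {
    if (n <= 7) stop("need n > 7 for the 6-parameter model", call. = FALSE)
    q <- d[[modularity]]
    b <- d[[baseline]]
    qc <- if (center) q - mean(q) else q
    bc <- if (center) b - mean(b) else b
    x <- cbind(`(Intercept)` = 1,
               as.matrix(d[covariates]),
               baseline = b,
               modularity = q,
               `baseline:modularity` = bc * qc)
  }
  # collinearity guard on the scaled design (intercept excluded)
  xs <- scale(x[, -1L, drop = FALSE])
  kap <- kappa(xs, exact = TRUE)
  if (!is.finite(kap) || kap > 1e8) {
    stop("near-collinear predictors (condition number ", format(kap, digits = 3),
         "): ", paste(colnames(x)[-1L], collapse = ", "), call. = FALSE)
  }
  fit <- stats::lm.fit(x, y)
  coefs <- fit$coefficients
  res <- fit$residuals
  p <- length(coefs)
  df_res <- n - p
  sigma2 <- sum(res^2) / df_res
  xtx_inv <- chol2inv(chol(crossprod(x)))
  se <- sqrt(diag(xtx_inv) * sigma2)
  tval <- coefs / se
  pval <- 2 * stats::pt(abs(tval), df_res, lower.tail = FALSE)
  tcrit <- stats::qt(1 - (1 - level) / 2, df_res)

  tss <- sum((y - mean(y))^2)
  rss <- sum(res^2)
  r2 <- 1 - rss / tss
  adj_r2 <- 1 - (1 - r2) * (n - 1) / df_res
  fstat <- ((tss - rss) / (p - 1)) / (rss / df_res)
  f_p <- stats::pf(fstat, p - 1, df_res, lower.tail = FALSE)

  coef_tab <- tibble::tibble(
    term = names(coefs), estimate = unname(coefs), std.error = unname(se),
    statistic = unname(tval), p.value = unname(pval),
    conf.low.ols = unname(coefs - tcrit * se),
    conf.high.ols = unname(coefs + tcrit * se),
    conf.low = NA_real_, conf.high = NA_real_
  )

  if (n_boot > 0) {
    if (!is.null(seed)) set.seed(seed)
    ci <- bca_ci_ols(x, y, n_boot = n_boot, level = level)
    coef_tab$conf.low <- ci[, 1L]
    coef_tab$conf.high <- ci[, 2L]
  }

  structure(
    list(coefficients = coef_tab,
         r.squared = r2, adj.r.squared = adj_r2,
         statistic = fstat, df = p - 1, df.residual = df_res,
         p.value = f_p, n = n, level = level, n_boot = n_boot,
         reduced = reduced, residuals = res, fitted = drop(x %*% coefs),
         model = cbind(as.data.frame(x[, -1L, drop = FALSE]),
                       stats::setNames(data.frame(y), gain))),
    class = "gain_model"
  )
}

# vectorized case-resampling BCa intervals for every OLS coefficient;
# shared resample stream across terms (one model refit per resample)
bca_ci_ols <- function(x, y, n_boot, level) {
  n <- nrow(x)
  p <- ncol(x)
  t0 <- stats::lm.fit(x, y)$coefficients
  bt <- matrix(NA_real_, n_boot, p)
  for (bb in seq_len(n_boot)) {
    idx <- sample.int(n, n, replace = TRUE)
    cf <- tryCatch(stats::.lm.fit(x[idx, , drop = FALSE], y[idx])$coefficients,
                   error = function(e) rep(NA_real_, p))
    bt[bb, ] <- cf
  }
  jack <- matrix(NA_real_, n, p)
  for (i in seq_len(n)) {
    jack[i, ] <- stats::.lm.fit(x[-i, , drop = FALSE], y[-i])$coefficients
  }
  alpha <- (1 - level) / 2
  out <- matrix(NA_real_, p, 2L)
  for (j in seq_len(p)) {
    bj <- bt[, j]
    bj <- bj[is.finite(bj)]
    if (!length(bj) || stats::sd(bj) == 0) next
    pb <- mean(bj < t0[j])
    pb <- min(max(pb, 1 / (2 * length(bj))), 1 - 1 / (2 * length(bj)))
    z0 <- stats::qnorm(pb)
    jm <- mean(jack[, j])
    den <- 6 * sum((jm - jack[, j])^2)^1.5
    a <- if (den == 0) 0 else sum((jm - jack[, j])^3) / den
    adj <- function(alph) {
      z <- stats::qnorm(alph)
      stats::pnorm(z0 + (z0 + z) / (1 - a * (z0 + z)))
    }
    out[j, ] <- stats::quantile(bj, probs = c(adj(alpha), adj(1 - alpha)),
                                names = FALSE, type = 6)
  }
  out
}

#' @export
print.gain_model <- function(x, ...) {
  cat(sprintf("%s gain model: R^2 = %.3f, adj. R^2 = %.3f, F(%d, %d) = %.3f, p = %.4g, n = %d\n",
              if (x$reduced) "Reduced" else "Moderated",
              x$r.squared, x$adj.r.squared, x$df, x$df.residual,
              x$statistic, x$p.value, x$n))
  print(as.data.frame(x$coefficients), digits = 4)
  invisible(x)
}

#' Partial correlation with BCa bootstrap CI
#'
#' Correlation between the OLS residuals of `x` and `y` on a covariate set,
#' with t-test on df = n - #covariates - 2 and (optionally) a BCa bootstrap
#' CI from joint case resampling. With an empty covariate set this is the
#' Pearson correlation.
#'
#' @param data Data frame.
#' @param x,y Column names of the two variables.
#' @param covariates Character vector of covariate columns (may be empty).
#' @param alternative `"two.sided"` (default), `"greater"` or `"less"`.
#' @param n_boot BCa bootstrap resamples (0 to skip).
#' @param level Confidence level.
#' @param seed Integer seed for the resample stream.
#' @return A tibble with `estimate`, `df`, `statistic`, `p.value`,
#'   `conf.low`, `conf.high`, `n`.
#' @export
partial_correlation <- function(data, x, y, covariates = character(),
                                alternative = c("two.sided", "greater", "less"),
                                n_boot = 5000, level = 0.95, seed = NULL) {
  alternative <- match.arg(alternative)
  cols <- c(x, y, covariates)
  stopifnot(all(cols %in% names(data)))
  d <- data[stats::complete.cases(data[cols]), cols, drop = FALSE]
  n <- nrow(d)
  k <- length(covariates)
  if (n <= k + 2) stop("need n > #covariates + 2", call. = FALSE)

  pcor_of <- function(dd) {
    if (k == 0) return(stats::cor(dd[[x]], dd[[y]]))
    z <- cbind(1, as.matrix(dd[covariates]))
    rx <- stats::.lm.fit(z, dd[[x]])$residuals
    ry <- stats::.lm.fit(z, dd[[y]])$residuals
    stats::cor(rx, ry)
  }
  r <- pcor_of(d)
  df <- n - k - 2
  tval <- r * sqrt(df / (1 - r^2))
  pval <- switch(alternative,
    two.sided = 2 * stats::pt(abs(tval), df, lower.tail = FALSE),
    greater = stats::pt(tval, df, lower.tail = FALSE),
    less = stats::pt(tval, df)
  )
  lo <- hi <- NA_real_
  if (n_boot > 0 && abs(r) < 1) {
    ci <- bca_ci(d, pcor_of, n_boot = n_boot, level = level, seed = seed)
    lo <- ci$lower
    hi <- ci$upper
  }
  tibble::tibble(estimate = r, df = df, statistic = tval, p.value = pval,
                 conf.low = lo, conf.high = hi, n = n,
                 alternative = alternative)
}
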
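#' Bias-corrected and accelerated (BCa) bootstrap confidence interval
#'
#' Case-resampling bootstrap CI with bias correction (z0, from the fraction
#' of the bootstrap distribution below the point estimate) and acceleration
#' (a, from the skewness of jackknife leave-one-out estimates). With z0 = 0
#' and a = 0 the interval reduces to the percentile interval.
#'
#' @param data A data frame (rows resampled) or a vector.
#' @param statistic Function of one argument (a resampled `data`) returning
#'   a single number.
#' @param n_boot Number of bootstrap resamples (default 5000; use >= 1000
#'   for reported intervals).
#' @param level Confidence level (default 0.95).
#' @param seed Optional integer; if supplied, fixes the resample stream so
#'   intervals are bit-reproducible.
#' @return A `bca_ci` object: list with `lower`, `upper`, `estimate`, `z0`,
#'   `acceleration`, `n_boot`, `level`.
#' @export
bca_ci <- function(data, statistic, n_boot = 5000, level = 0.95, seed = NULL) {
  stopifnot(is.function(statistic), n_boot >= 1)
  if (!is.null(seed)) set.seed(seed)
  n <- if (is.data.frame(data) || is.matrix(data)) nrow(data) else length(data)
  take <- if (is.data.frame(data) || is.matrix(data)) {
    function(idx) data[idx, , drop = FALSE]
  } else {
    function(idx) data[idx]
  }
  t0 <- statistic(data)
  if (!is.finite(t0)) stop("statistic is not finite on the full data", call. = FALSE)

  boots <- vapply(seq_len(n_boot), function(b) {
    statistic(take(sample.int(n, n, replace = TRUE)))
  }, numeric(1))
  boots <- boots[is.finite(boots)]
  if (!length(boots) || stats::sd(boots) == 0) {
    stop("degenerate bootstrap distribution (statistic constant over resamples)",
         call. = FALSE)
  }

  # bias correction
  prop_below <- mean(boots < t0)
  if (prop_below == 0 || prop_below == 1) {
    warning("point estimate outside the bootstrap distribution; z0 clamped")
    prop_below <- min(max(prop_below, 1 / (2 * length(boots))),
                      1 - 1 / (2 * length(boots)))
  }
  z0 <- stats::qnorm(prop_below)

  # acceleration from jackknife skewness
  jack <- vapply(seq_len(n), function(i) statistic(take(-i)), numeric(1))
  jm <- mean(jack)
  num <- sum((jm - jack)^3)
  den <- 6 * (sum((jm - jack)^2))^1.5
  a <- if (den == 0) 0 else num / den

  alpha <- (1 - level) / 2
  adj <- function(alph) {
    z <- stats::qnorm(alph)
    stats::pnorm(z0 + (z0 + z) / (1 - a * (z0 + z)))
  }
  qs <- stats::quantile(boots, probs = c(adj(alpha), adj(1 - alpha)),
                        names = FALSE, type = 6)
  structure(
    list(lower = qs[1L], upper = qs[2L], estimate = t0, z0 = z0,
         acceleration = a, n_boot = n_boot, level = level),
    class = "bca_ci"
  )
}

#' @export
print.bca_ci <- function(x, ...) {
  cat(sprintf("BCa %g%% CI [%.4f, %.4f] (estimate %.4f, B = %d)\n",
              100 * x$level, x$lower, x$upper, x$estimate, x$n_boot))
  invisible(x)
}

#' Bonferroni adjustment
#'
#' p_adj = min(1, m * p). `m` may exceed the number of p-values supplied
#' (e.g., when only a subset of a planned family is reported).
#'
#' @param p Numeric vector of p-values.
#' @param m Number of tests in the family; defaults to `length(p)`.
#' @return Adjusted p-values.
#' @export
bonferroni <- function(p, m = length(p)) {
  stopifnot(m >= length(p))
  pmin(1, m * p)
}
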
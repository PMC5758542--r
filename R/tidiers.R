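#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy the coefficient table of a moderated gain model
#'
#' @param x A `gain_model` from [fit_gain_model()].
#' @param conf_type Which interval to report in `conf.low`/`conf.high`:
#'   `"bca"` (bootstrap, default) or `"ols"` (analytic).
#' @param ... Unused.
#' @return Tibble: term, estimate, std.error, statistic, p.value,
#'   conf.low, conf.high.
#' @export
tidy.gain_model <- function(x, conf_type = c("bca", "ols"), ...) {
  conf_type <- match.arg(conf_type)
  tab <- x$coefficients
  if (conf_type == "ols") {
    tab$conf.low <- tab$conf.low.ols
    tab$conf.high <- tab$conf.high.ols
  }
  tab[c("term", "estimate", "std.error", "statistic", "p.value",
        "conf.low", "conf.high")]
}

#' Model-level summary of a gain model
#'
#' @param x A `gain_model`.
#' @param ... Unused.
#' @return One-row tibble: r.squared, adj.r.squared, statistic, df,
#'   df.residual, p.value, n.
#' @export
glance.gain_model <- function(x, ...) {
  tibble::tibble(
    r.squared = x$r.squared, adj.r.squared = x$adj.r.squared,
    statistic = x$statistic, df = x$df, df.residual = x$df.residual,
    p.value = x$p.value, n = x$n
  )
}

#' Tidy the effect table of a mixed ANOVA
#'
#' @param x A `mixed_anova`.
#' @param ... Unused.
#' @return Tibble: term, df, df_error, statistic, p.value, partial_eta_sq.
#' @export
tidy.mixed_anova <- function(x, ...) x$effects

#' @export
#' @rdname tidy.mixed_anova
glance.mixed_anova <- function(x, ...) {
  tibble::tibble(n = x$n, n_groups = x$n_groups)
}

#' Tidy a gain AN(C)OVA
#'
#' @param x A `gain_anova`.
#' @param which `"omnibus"` (default), `"groups"` (per-group tests against
#'   zero) or `"pairwise"` (Bonferroni-adjusted contrasts).
#' @param ... Unused.
#' @return Tibble.
#' @export
tidy.gain_anova <- function(x, which = c("omnibus", "groups", "pairwise"), ...) {
  switch(match.arg(which),
         omnibus = x$omnibus,
         groups = x$group_tests,
         pairwise = x$pairwise)
}
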
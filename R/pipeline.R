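#' Subject-level modularity across density thresholds
#'
#' Runs the full connectome pipeline on one subject's ROI time series:
#' Pearson correlation, Fisher z, proportional thresholding at each cost,
#' then modularity under the spectral partition and (optionally) a supplied
#' canonical partition.
#'
#' @param ts Numeric matrix, volumes x ROIs.
#' @param costs Densities to evaluate (default `seq(0.02, 0.10, by = 0.02)`,
#'   the 2-10% range in 2% steps).
#' @param canonical Optional `partition` (or assignment table coercible via
#'   [canonical_partition()]) for fixed-partition modularity.
#' @return Tibble: one row per cost x partition source with columns `cost`,
#'   `source`, `Q`, `n_modules`.
#' @export
subject_modularity <- function(ts, costs = seq(0.02, 0.10, by = 0.02),
                               canonical = NULL) {
  zm <- fisher_z(correlation_matrix(ts))
  if (!is.null(canonical) && !inherits(canonical, "partition")) {
    canonical <- canonical_partition(canonical, rois = colnames(zm))
  }
  purrr::map_dfr(costs, function(cost) {
    g <- proportional_threshold(zm, cost)
    sp <- spectral_partition(g)
    out <- tibble::tibble(cost = cost, source = "spectral",
                          Q = attr(sp, "Q"), n_modules = sp$m)
    if (!is.null(canonical)) {
      qc <- modularity_q(g, canonical)
      out <- dplyr::bind_rows(out, tibble::tibble(
        cost = cost, source = "canonical", Q = qc$Q,
        n_modules = canonical$m))
    }
    out
  })
}

#' Cohort-level modularity table for a simulated cohort
#'
#' Regenerates every subject's time series from the generator (which is
#' deterministic per subject), runs [subject_modularity()], and returns the
#' stacked per-subject metrics table — the imaging half of the cohort
#' assembly.
#'
#' @param config A [sim_config()].
#' @param costs Densities to evaluate.
#' @param canonical Use the generator's planted module table as the
#'   canonical partition (default `TRUE`).
#' @param subjects Subject indices (default all).
#' @return Tibble: `subject_id`, `cost`, `source`, `Q`, `n_modules`.
#' @export
cohort_modularity <- function(config, costs = 0.06, canonical = TRUE,
                              subjects = seq_len(config$n_subjects)) {
  part <- if (canonical) sim_partition_table(config) else NULL
  purrr::map_dfr(subjects, function(i) {
    ts <- simulate_timeseries(config, i)
    res <- subject_modularity(ts, costs = costs, canonical = part)
    res$subject_id <- sprintf("sub-%03d", i)
    res[c("subject_id", setdiff(names(res), "subject_id"))]
  })
}

#' Assemble an analysis-ready cohort table
#'
#' Joins composite scores from the battery onto the cohort covariates and
#' applies the availability filter: analyses keep only subjects with a
#' usable baseline scan (not motion-excluded), a baseline EF composite and
#' an EF gain composite.
#'
#' @param cohort Cohort tibble from [simulate_cohort()] (or same layout).
#' @param map Test-to-construct map (default [battery_map()]).
#' @param apply_filter Drop rows failing the availability filter (default
#'   `TRUE`).
#' @return Tibble with covariates, `modularity`, composites
#'   (`ef_baseline`, `ef_gain`, ...) and an `included` flag.
#' @export
assemble_cohort <- function(cohort, map = battery_map(), apply_filter = TRUE) {
  comps <- composite_scores(cohort, map)
  keep <- c("subject_id", "group", "age", "mean_fd", "max_abs_disp",
            "motion_excluded", "modularity", "vo2peak_pre", "vo2peak_post")
  keep <- intersect(keep, names(cohort))
  out <- dplyr::left_join(cohort[keep], comps,
                          by = intersect(c("subject_id", "group"), names(comps)))
  out$included <- !isTRUE_vec(out$motion_excluded) &
    !is.na(out$ef_baseline) & !is.na(out$ef_gain)
  if (apply_filter) out[out$included, , drop = FALSE] else out
}

isTRUE_vec <- function(x) if (is.null(x)) FALSE else x %in% TRUE
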
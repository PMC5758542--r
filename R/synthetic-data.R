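#' Configuration for the synthetic cohort generator
#'
#' Defines the study conditions emulated by the generator: a resting-state
#' acquisition of `n_volumes` volumes over `n_rois` ROIs grouped into
#' modules (`partition_spec`), subject-level latent modularity targets that
#' drive the within/between-module correlation contrast, six-parameter
#' motion traces with spike contamination, and a 17-test pre/post cognitive
#' battery with four constructs and a planted baseline-modularity to
#' EF-gain slope moderated by baseline EF.
#'
#' @param n_subjects Number of subjects.
#' @param n_rois Number of ROIs (default 252, a 264-node cortical
#'   parcellation minus cerebellar and poorly covered regions).
#' @param n_volumes Volumes per scan (default 180).
#' @param tr_seconds Repetition time (default 2).
#' @param partition_spec Named integer vector of module sizes summing to
#'   `n_rois`; default is a 13-module layout mirroring the canonical
#'   functional systems.
#' @param r_within,r_between Within- and between-module correlations of the
#'   block-covariance time-series model, `0 <= r_between <= r_within < 1`.
#'   `r_within` is the cohort-average value; each subject's actual contrast
#'   scales monotonically with their latent modularity target.
#' @param q_mean,q_sd Mean and SD of the subject-level latent modularity
#'   target (the scale of a 6%-density spectral Q).
#' @param groups Data frame with columns `group`, `ef_gain_mean`,
#'   `crf_gain_mean`: per-group mean composite gains (pre-test-SD units) at
#'   the cohort-average modularity. Subjects are assigned round-robin.
#' @param beta_modularity Planted slope of EF composite gain on (centered)
#'   latent modularity.
#' @param beta_interaction Planted coefficient on centered-baseline-EF x
#'   centered-modularity.
#' @param noise_sd Residual SD of the EF construct gain.
#' @param construct_gain_mean Mean gain of the non-EF constructs (small
#'   practice effect, applied to all groups).
#' @param test_loading Loading of each test on its construct factor
#'   (default 0.8).
#' @param test_gain_noise_sd SD of per-test gain noise around the construct
#'   gain.
#' @param motion_drift_sd Per-frame SD of the translation drift random walk
#'   (mm); rotations drift at `motion_drift_sd / 50` radians.
#' @param motion_spike_prob Per-volume probability of a motion spike
#'   (> 0.5 mm).
#' @param seed Master integer seed; per-subject streams are derived from
#'   (seed, subject index) so each subject is independently reproducible.
#' @return A validated `sim_config` list.
#' @export
sim_config <- function(n_subjects,
                       n_rois = 252L,
                       n_volumes = 180L,
                       tr_seconds = 2,
                       partition_spec = default_partition_spec(),
                       r_within = 0.25,
                       r_between = 0.05,
                       q_mean = 0.45,
                       q_sd = 0.07,
                       groups = default_groups(),
                       beta_modularity = 1.8,
                       beta_interaction = -2.4,
                       noise_sd = 0.35,
                       construct_gain_mean = 0.05,
                       test_loading = 0.8,
                       test_gain_noise_sd = 0.15,
                       motion_drift_sd = 0.02,
                       motion_spike_prob = 0.02,
                       seed = 1L) {
  stopifnot(n_subjects >= 0, n_volumes >= 2, n_rois >= 2)
  if (sum(partition_spec) != n_rois) {
    stop("module sizes in partition_spec must sum to n_rois (",
         sum(partition_spec), " != ", n_rois, ")", call. = FALSE)
  }
  if (!(r_between >= 0 && r_between <= r_within && r_within < 1)) {
    stop("implied block covariance is not positive semi-definite: need ",
         "0 <= r_between <= r_within < 1, got r_within = ", r_within,
         ", r_between = ", r_between, call. = FALSE)
  }
  stopifnot(is.data.frame(groups),
            all(c("group", "ef_gain_mean", "crf_gain_mean") %in% names(groups)))
  if (n_subjects > 0 && nrow(groups) == 0) {
    stop("group labels do not cover the subjects (empty group table)", call. = FALSE)
  }
  structure(
    list(n_subjects = as.integer(n_subjects), n_rois = as.integer(n_rois),
         n_volumes = as.integer(n_volumes), tr_seconds = tr_seconds,
         partition_spec = partition_spec, r_within = r_within,
         r_between = r_between, q_mean = q_mean, q_sd = q_sd,
         groups = tibble::as_tibble(groups),
         beta_modularity = beta_modularity,
         beta_interaction = beta_interaction, noise_sd = noise_sd,
         construct_gain_mean = construct_gain_mean,
         test_loading = test_loading,
         test_gain_noise_sd = test_gain_noise_sd,
         motion_drift_sd = motion_drift_sd,
         motion_spike_prob = motion_spike_prob,
         seed = as.integer(seed)),
    class = "sim_config"
  )
}

#' Default 13-module layout for 252 ROIs
#' @return Named integer vector of module sizes.
#' @export
default_partition_spec <- function() {
  c(DMN = 58L, FP = 25L, CO = 14L, Sal = 18L, DAN = 11L, VAN = 9L,
    Aud = 13L, Vis = 31L, Mem = 5L, SM_hand = 30L, SM_mouth = 5L,
    Subcort = 13L, Unassigned = 20L)
}

#' Default intervention groups and planted mean gains
#'
#' Four groups (walking, walking with supplement, stretching/strength/
#' stability, dance) with EF composite gain means of the order reported for
#' such interventions, and CRF gains largest in the walking groups.
#' @return Tibble with `group`, `ef_gain_mean`, `crf_gain_mean`.
#' @export
default_groups <- function() {
  tibble::tibble(
    group = c("walk", "walk_plus", "sss", "dance"),
    ef_gain_mean = c(0.16, 0.17, 0.19, 0.03),
    crf_gain_mean = c(0.54, 0.54, 0.22, 0.06)
  )
}

# deterministic per-subject, per-purpose substream seeds (< 2^31). The
# arithmetic combination is rehashed through the generator itself (one
# sample.int draw) so that the structured (seed, subject, stream) lattice
# does not leak correlations into the first draws of neighbouring streams.
stream_seed <- function(seed, subject_index, stream) {
  k <- (as.numeric(seed) * 7 + subject_index * 104729 +
          stream * 15485863) %% 2147483629
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv(), inherits = FALSE) else NULL
  set.seed(k)
  out <- sample.int(2147483647, 2L)[2L]
  if (!is.null(old)) assign(".Random.seed", old, globalenv())
  out
}

# subject's latent modularity target; own stream so it is identical whether
# reached from the time-series, motion or cohort path
latent_modularity <- function(config, subject_index) {
  set.seed(stream_seed(config$seed, subject_index, 0L))
  config$q_mean + config$q_sd * stats::rnorm(1L)
}

# map a latent modularity target onto this subject's within-module
# correlation: contrast scales linearly (monotonically) with the target
subject_r_within <- function(config, q) {
  contrast <- (config$r_within - config$r_between) * (q / config$q_mean)
  r <- config$r_between + max(contrast, 0)
  min(r, 0.95)
}

#' Simulate one subject's ROI time series
#'
#' Draws `n_volumes` i.i.d. zero-mean multivariate normal vectors whose
#' correlation is the subject's within-module value inside planted modules
#' and `r_between` across modules (a planted-partition block-covariance
#' model). The subject's within-module correlation scales with their latent
#' modularity target, so subjects with higher targets yield more modular
#' graphs. Deterministic given (config seed, subject index).
#'
#' @param config A [sim_config()].
#' @param subject_index Subject number in `1:n_subjects`.
#' @return Numeric matrix, volumes x ROIs, with ROI column names
#'   `<module>_<k>`.
#' @export
simulate_timeseries <- function(config, subject_index) {
  stopifnot(inherits(config, "sim_config"),
            subject_index >= 1, subject_index <= max(config$n_subjects, 1))
  q <- latent_modularity(config, subject_index)
  rw <- subject_r_within(config, q)
  rb <- config$r_between
  sizes <- config$partition_spec
  mods <- rep(seq_along(sizes), sizes)
  nv <- config$n_volumes
  nr <- config$n_rois
  set.seed(stream_seed(config$seed, subject_index, 1L))
  # factor construction of the block covariance: shared global factor
  # (r_between), module factors (r_within - r_between), idiosyncratic noise
  g0 <- stats::rnorm(nv)
  gm <- matrix(stats::rnorm(nv * length(sizes)), nv, length(sizes))
  eps <- matrix(stats::rnorm(nv * nr), nv, nr)
  x <- sqrt(rb) * g0 +
    sqrt(rw - rb) * gm[, mods, drop = FALSE] +
    sqrt(1 - rw) * eps
  colnames(x) <- unlist(lapply(seq_along(sizes), function(i) {
    paste0(names(sizes)[i], "_", seq_len(sizes[i]))
  }), use.names = FALSE)
  x
}

#' Canonical node-to-module table for a simulated cohort
#'
#' The planted module labels of the generator's ROIs, in the two-column
#' form accepted by [canonical_partition()].
#'
#' @param config A [sim_config()].
#' @return Tibble with columns `roi`, `module`.
#' @export
sim_partition_table <- function(config) {
  sizes <- config$partition_spec
  tibble::tibble(
    roi = unlist(lapply(seq_along(sizes), function(i) {
      paste0(names(sizes)[i], "_", seq_len(sizes[i]))
    }), use.names = FALSE),
    module = rep(names(sizes), sizes)
  )
}

#' Simulate one subject's six-parameter motion trace
#'
#' Low-amplitude random-walk drift in all six rigid-body parameters
#' (translations in mm, rotations in radians) plus, at rate
#' `motion_spike_prob` per volume, persistent translation steps of 0.6-1.2
#' mm that register as framewise-displacement spikes above the 0.5 mm
#' screening threshold. Deterministic given (config seed, subject index).
#'
#' @inheritParams simulate_timeseries
#' @return Numeric matrix, volumes x 6, columns `trans_x,trans_y,trans_z,
#'   rot_x,rot_y,rot_z`.
#' @export
simulate_motion <- function(config, subject_index) {
  stopifnot(inherits(config, "sim_config"), config$n_volumes >= 2)
  nv <- config$n_volumes
  set.seed(stream_seed(config$seed, subject_index, 2L))
  dsd <- config$motion_drift_sd
  steps <- cbind(
    matrix(stats::rnorm(3L * (nv - 1L), sd = dsd), nv - 1L, 3L),
    matrix(stats::rnorm(3L * (nv - 1L), sd = dsd / 50), nv - 1L, 3L)
  )
  spikes <- stats::runif(nv - 1L) < config$motion_spike_prob
  if (any(spikes)) {
    for (t in which(spikes)) {
      axis <- sample.int(3L, 1L)
      steps[t, axis] <- steps[t, axis] +
        sample(c(-1, 1), 1L) * stats::runif(1L, 0.6, 1.2)
    }
  }
  trace <- rbind(0, apply(steps, 2L, cumsum))
  colnames(trace) <- c("trans_x", "trans_y", "trans_z",
                       "rot_x", "rot_y", "rot_z")
  trace
}

#' Simulate a full cohort with planted brain-behavior effects
#'
#' Generates, for each subject: age, group assignment (round-robin), a
#' latent modularity target (which also drives that subject's time-series
#' contrast, see [simulate_timeseries()]), a motion summary, VO2peak
#' pre/post, and a 17-test pre/post battery whose four constructs
#' (vocabulary, speed, memory, EF) follow a factor model. The EF construct
#' gain is planted as
#' `group mean + beta_modularity * (Q - q_mean) +
#'  beta_interaction * (centered baseline EF) * (Q - q_mean) + noise`,
#' so downstream composite scoring and regression can be checked against
#' known coefficients.
#'
#' Time series are not stored in the cohort table; regenerate any subject's
#' series with [simulate_timeseries()] (deterministic), or use
#' `modularity_source = "latent"` (default) to place the latent modularity
#' target directly in the `modularity` column for fast statistical studies.
#' With `modularity_source = "imaging"` the column is left `NA` and is meant
#' to be filled by running the connectome + network-metrics pipeline.
#'
#' @param config A [sim_config()].
#' @param modularity_source `"latent"` (default) or `"imaging"`.
#' @return A list with `cohort` (tibble, one row per subject) and
#'   `ground_truth` (tibble of latent quantities; planted coefficients and
#'   node labels attached as attributes). Never consumed by analysis
#'   stages.
#' @export
simulate_cohort <- function(config, modularity_source = c("latent", "imaging")) {
  stopifnot(inherits(config, "sim_config"))
  modularity_source <- match.arg(modularity_source)
  n <- config$n_subjects
  map <- battery_map()
  test_defs <- battery_test_defs()
  if (n == 0L) {
    empty <- tibble::tibble(subject_id = character(), group = character())
    return(list(cohort = empty,
                ground_truth = tibble::tibble(subject_id = character())))
  }
  groups <- config$groups
  grp <- groups$group[((seq_len(n) - 1L) %% nrow(groups)) + 1L]

  constructs <- c("vocabulary", "speed", "memory", "ef")
  # modest positive correlation among construct factors
  fac_cor <- matrix(0.3, 4L, 4L)
  diag(fac_cor) <- 1
  fac_chol <- chol(fac_cor)
  n_tests <- nrow(map)

  q_lat <- age <- mean_fd <- max_disp <- numeric(n)
  excluded <- logical(n)
  ef_base_lat <- ef_gain_true <- numeric(n)
  vo2_pre <- vo2_post <- numeric(n)
  pre_mat <- matrix(NA_real_, n, n_tests)
  post_mat <- matrix(NA_real_, n, n_tests)

  for (i in seq_len(n)) {
    q <- latent_modularity(config, i)
    mot <- simulate_motion(config, i)
    fd <- framewise_displacement(mot)
    q_lat[i] <- q
    mean_fd[i] <- mean(fd)
    max_disp[i] <- max_abs_displacement(mot)
    excluded[i] <- (100 * mean(fd > 0.5) > 10) || (max_disp[i] > 4.0)

    set.seed(stream_seed(config$seed, i, 3L))
    age[i] <- stats::runif(1L, 60, 80)
    f <- drop(stats::rnorm(4L) %*% fac_chol)   # construct factors, z units
    names(f) <- constructs

    gmeans <- groups[groups$group == grp[i], ]
    q_c <- q - config$q_mean
    ef_gain <- gmeans$ef_gain_mean +
      config$beta_modularity * q_c +
      config$beta_interaction * f[["ef"]] * q_c +
      stats::rnorm(1L, sd = config$noise_sd)
    other_gain <- stats::rnorm(3L, mean = config$construct_gain_mean,
                               sd = config$noise_sd)
    names(other_gain) <- setdiff(constructs, "ef")
    con_gain <- c(other_gain, ef = unname(ef_gain))[constructs]
    names(con_gain) <- constructs
    ef_base_lat[i] <- f[["ef"]]
    ef_gain_true[i] <- ef_gain

    lam <- config$test_loading
    latent <- lam * f[map$construct] +
      sqrt(1 - lam^2) * stats::rnorm(n_tests)
    pre_mat[i, ] <- test_defs$mean + map$direction * test_defs$sd * latent
    gain_j <- con_gain[map$construct] +
      stats::rnorm(n_tests, sd = config$test_gain_noise_sd)
    post_mat[i, ] <- pre_mat[i, ] + map$direction * test_defs$sd * gain_j

    vo2_pre[i] <- stats::rnorm(1L, 20, 4)
    vo2_post[i] <- vo2_pre[i] + 4 * (gmeans$crf_gain_mean + stats::rnorm(1L, sd = 0.3))
  }
  ids <- sprintf("sub-%03d", seq_len(n))
  cohort <- tibble::tibble(
    subject_id = ids, group = grp, age = age,
    mean_fd = mean_fd, max_abs_disp = max_disp, motion_excluded = excluded,
    modularity = if (modularity_source == "latent") q_lat else NA_real_,
    vo2peak_pre = vo2_pre, vo2peak_post = vo2_post
  )
  score_cols <- cbind(pre_mat, post_mat)
  colnames(score_cols) <- c(paste0(map$test, "_pre"), paste0(map$test, "_post"))
  cohort <- dplyr::bind_cols(cohort, tibble::as_tibble(score_cols))
  ground_truth <- tibble::tibble(
    subject_id = ids, group = grp, q_latent = q_lat,
    ef_baseline_latent = ef_base_lat, ef_gain_true = ef_gain_true
  )
  attr(ground_truth, "config") <- config
  attr(ground_truth, "node_modules") <- sim_partition_table(config)
  list(cohort = cohort, ground_truth = ground_truth)
}

# native-unit means/SDs for the 17 tests (arbitrary but plausible scales;
# standardized scoring removes them)
battery_test_defs <- function() {
  map <- battery_map()
  tibble::tibble(
    test = map$test,
    mean = c(30, 25, 28, 70, 16, 11, 20, 44, 26, 12, 8, 10, 9, 7, 11, 0.8, 250),
    sd = c(6, 5, 5.5, 12, 3, 2.5, 5, 9, 6, 3, 2.4, 2.8, 2.6, 2.2, 3, 0.08, 90)
  )
}
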
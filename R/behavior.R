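#' Two-pass outlier cleaning of a raw score vector
#'
#' Pass 1 marks values more than 3 SD from the mean as missing (excluded).
#' Pass 2 recomputes the mean and SD on the survivors and winsorizes
#' (clamps) any surviving value more than 3 SD from the recomputed mean to
#' the 3-SD cutoff. Both comparisons are strict, so a value at exactly 3 SD
#' is retained unclamped. The procedure is idempotent: cleaning a cleaned
#' vector changes nothing.
#'
#' @param x Numeric vector of raw scores (may contain `NA`).
#' @param n_sd Cutoff in SD units (default 3).
#' @return A list: `values` (cleaned vector, excluded entries `NA`) and
#'   `audit` (tibble with one row per excluded or winsorized entry: `index`,
#'   `raw`, `action`, `replacement`).
#' @export
clean_scores <- function(x, n_sd = 3) {
  stopifnot(is.numeric(x))
  if (sum(!is.na(x)) < 3L) {
    stop("need >= 3 non-missing values to clean", call. = FALSE)
  }
  audit <- tibble::tibble(index = integer(), raw = numeric(),
                          action = character(), replacement = numeric())
  mu <- mean(x, na.rm = TRUE)
  sdv <- stats::sd(x, na.rm = TRUE)
  if (is.na(sdv) || sdv == 0) {
    warning("zero dispersion; scores returned unchanged")
    return(list(values = x, audit = audit))
  }
  # strict comparisons carry a one-part-in-1e8 buffer so values sitting at
  # the cutoff (including previously winsorized ones) are never re-flagged
  # by floating-point residue
  tol <- 1 + 1e-8
  out1 <- which(!is.na(x) & abs(x - mu) > n_sd * sdv * tol)
  cleaned <- x
  if (length(out1)) {
    audit <- dplyr::bind_rows(audit, tibble::tibble(
      index = out1, raw = x[out1], action = "excluded", replacement = NA_real_
    ))
    cleaned[out1] <- NA_real_
  }
  mu2 <- mean(cleaned, na.rm = TRUE)
  sd2 <- stats::sd(cleaned, na.rm = TRUE)
  if (is.na(sd2) || sd2 == 0) {
    warning("zero dispersion after exclusion pass; no winsorization applied")
    return(list(values = cleaned, audit = audit))
  }
  # winsorization is iterated to a fixed point: clamping shrinks the SD, so a
  # single clamp would leave values strictly beyond 3 SD of the final
  # mean/SD and the procedure would not be idempotent
  wins_idx <- integer()
  wins_raw <- numeric()
  for (iter in 1:100) {
    mu2 <- mean(cleaned, na.rm = TRUE)
    sd2 <- stats::sd(cleaned, na.rm = TRUE)
    if (is.na(sd2) || sd2 == 0) break
    lo <- mu2 - n_sd * sd2
    hi <- mu2 + n_sd * sd2
    wins <- which(!is.na(cleaned) & abs(cleaned - mu2) > n_sd * sd2 * tol)
    if (!length(wins)) break
    new <- setdiff(wins, wins_idx)
    wins_idx <- c(wins_idx, new)
    wins_raw <- c(wins_raw, cleaned[new])
    cleaned[wins] <- pmin(pmax(cleaned[wins], lo), hi)
  }
  if (length(wins_idx)) {
    audit <- dplyr::bind_rows(audit, tibble::tibble(
      index = wins_idx, raw = wins_raw, action = "winsorized",
      replacement = cleaned[wins_idx]
    ))
  }
  list(values = cleaned, audit = audit)
}

#' Standardized gain scores
#'
#' gain = direction * (post - pre) / SD(pre), where the pre-test SD is pooled
#' (collapsed across groups) and `direction = -1` for lower-is-better
#' measures (e.g., an RT switch cost) so that a positive gain always means
#' improvement.
#'
#' @param pre,post Numeric vectors of pre- and post-test scores.
#' @param direction `1` (higher is better, default) or `-1`.
#' @return Numeric vector of gains in pre-test-SD units.
#' @export
standardized_gain <- function(pre, post, direction = 1) {
  stopifnot(length(pre) == length(post), direction %in% c(-1, 1))
  sd_pre <- stats::sd(pre, na.rm = TRUE)
  if (is.na(sd_pre) || sd_pre == 0) {
    stop("pooled pre-test SD is zero; gains undefined", call. = FALSE)
  }
  direction * (post - pre) / sd_pre
}

#' Construct composites and composite gains for a cognitive battery
#'
#' Given a wide battery table (one row per subject, columns `<test>_pre` and
#' `<test>_post`) and a test-to-construct map, computes (1) baseline
#' composites: per-test z-scores against the analyzed sample's pre-test
#' mean/SD, averaged within construct; and (2) composite gains: per-test
#' standardized gains (pooled pre-test SD, direction-corrected), averaged
#' within construct. Composites are averaged over a subject's available
#' (non-missing) member tests; a completeness column reports the fraction
#' available. Raw test scores are cleaned with [clean_scores()] first unless
#' `clean = FALSE`.
#'
#' @param battery Data frame: `subject_id` (and optionally `group`), plus
#'   `<test>_pre` / `<test>_post` columns for every test in `map`.
#' @param map Data frame with columns `test`, `construct`, `direction`
#'   (+1 higher-is-better / -1 lower-is-better), e.g. [battery_map()].
#' @param clean Apply the two-pass outlier procedure to every score column
#'   first (default `TRUE`).
#' @return Tibble with one row per subject: `subject_id` (and `group` if
#'   present), `<construct>_baseline` (z units), `<construct>_gain`
#'   (pre-test-SD units) and `<construct>_completeness` columns.
#' @export
composite_scores <- function(battery, map, clean = TRUE) {
  stopifnot(is.data.frame(battery), is.data.frame(map),
            all(c("test", "construct", "direction") %in% names(map)))
  if (anyDuplicated(map$test)) stop("each test must map to exactly one construct", call. = FALSE)
  need <- c(paste0(map$test, "_pre"), paste0(map$test, "_post"))
  missing_cols <- setdiff(need, names(battery))
  if (length(missing_cols)) {
    stop("battery is missing column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  id_cols <- intersect(c("subject_id", "group"), names(battery))
  out <- tibble::as_tibble(battery[id_cols])

  pre <- as.data.frame(battery[paste0(map$test, "_pre")])
  post <- as.data.frame(battery[paste0(map$test, "_post")])
  if (clean) {
    pre[] <- lapply(pre, function(v) clean_scores(v)$values)
    post[] <- lapply(post, function(v) clean_scores(v)$values)
  }
  # per-test baseline z against the analyzed sample, and standardized gains
  z_base <- matrix(NA_real_, nrow(battery), nrow(map))
  gains <- matrix(NA_real_, nrow(battery), nrow(map))
  for (j in seq_len(nrow(map))) {
    p <- pre[[j]]
    q <- post[[j]]
    mu <- mean(p, na.rm = TRUE)
    sdv <- stats::sd(p, na.rm = TRUE)
    if (is.na(sdv) || sdv == 0) {
      stop("zero pre-test SD for test ", map$test[j], call. = FALSE)
    }
    z_base[, j] <- map$direction[j] * (p - mu) / sdv
    gains[, j] <- standardized_gain(p, q, direction = map$direction[j])
  }
  for (con in unique(map$construct)) {
    cols <- which(map$construct == con)
    zb <- z_base[, cols, drop = FALSE]
    gn <- gains[, cols, drop = FALSE]
    out[[paste0(con, "_baseline")]] <- rowMeans(zb, na.rm = TRUE)
    out[[paste0(con, "_gain")]] <- rowMeans(gn, na.rm = TRUE)
    out[[paste0(con, "_completeness")]] <- rowMeans(!is.na(gn))
  }
  # constructs with no available members: NaN -> NA
  num <- vapply(out, is.numeric, logical(1))
  out[num] <- lapply(out[num], function(v) ifelse(is.nan(v), NA_real_, v))
  out
}

#' PCA check of battery construct structure
#'
#' Principal components analysis on the correlation matrix of baseline
#' scores, retaining `n_components` components and applying an oblique
#' (promax) rotation, as used to confirm that a battery's tests group into
#' the intended constructs. Returns the test x component standardized
#' loading table (pattern matrix) and each test's dominant component by
#' absolute loading.
#'
#' @param baseline Data frame or matrix of baseline scores, one column per
#'   test (missing values dropped casewise).
#' @param n_components Number of components to retain (default 4).
#' @return A list: `loadings` (tibble: test, one column per component,
#'   `dominant`), `variance_explained` (per retained component, fraction of
#'   total variance before rotation).
#' @export
pca_check <- function(baseline, n_components = 4) {
  x <- as.matrix(baseline)
  storage.mode(x) <- "double"
  x <- x[stats::complete.cases(x), , drop = FALSE]
  n <- nrow(x)
  p <- ncol(x)
  if (n < 4 * p) {
    warning("fewer than 4x more subjects than tests; loadings may be unstable")
  }
  r <- stats::cor(x)
  ev <- eigen(r, symmetric = TRUE)
  if (min(ev$values) < 1e-10) {
    stop("singular correlation matrix (duplicated or collinear tests)", call. = FALSE)
  }
  k <- n_components
  # standardized component loadings: eigenvectors scaled by sqrt(eigenvalue)
  load <- ev$vectors[, seq_len(k), drop = FALSE] %*% diag(sqrt(ev$values[seq_len(k)]), k)
  rot <- stats::promax(load)
  lr <- unclass(rot$loadings)
  dimnames(lr) <- list(colnames(x), paste0("PC", seq_len(k)))
  dominant <- colnames(lr)[apply(abs(lr), 1L, which.max)]
  tab <- tibble::as_tibble(lr, rownames = "test")
  tab$dominant <- dominant
  list(loadings = tab,
       variance_explained = ev$values[seq_len(k)] / p)
}

#' Task-switching summary scores from a trial table
#'
#' From mixed-block trials, computes each subject's (1) local switch cost:
#' mean correct-trial RT on switch trials minus mean correct-trial RT on
#' non-switch trials (ms; lower is better), and (2) a rank-binning score
#' combining accuracy and RT: within the sample, subjects' local RT switch
#' costs and accuracy costs (non-switch minus switch accuracy) are each
#' ranked into decile bins (1 = best) and the two bins are summed, giving a
#' score from 2 (best) to 20 (worst).
#'
#' @param trials Data frame with columns `subject_id`, `trial_type`
#'   (`"switch"`/`"nonswitch"`), `rt_ms`, `correct` (logical or 0/1).
#' @return Tibble: `subject_id`, `local_switch_cost_ms`, `accuracy_cost`,
#'   `bin_score`.
#' @export
task_switching_scores <- function(trials) {
  stopifnot(all(c("subject_id", "trial_type", "rt_ms", "correct") %in% names(trials)))
  if (!any(trials$trial_type == "switch")) {
    stop("no switch trials in the trial table", call. = FALSE)
  }
  per <- trials |>
    dplyr::group_by(.data$subject_id) |>
    dplyr::summarise(
      local_switch_cost_ms =
        mean(.data$rt_ms[.data$trial_type == "switch" & .data$correct == 1]) -
        mean(.data$rt_ms[.data$trial_type == "nonswitch" & .data$correct == 1]),
      accuracy_cost =
        mean(.data$correct[.data$trial_type == "nonswitch"]) -
        mean(.data$correct[.data$trial_type == "switch"]),
      .groups = "drop"
    )
  decile_bin <- function(v) {
    # rank into 10 bins, 1 = smallest cost (best); ties share the lower bin
    r <- rank(v, ties.method = "min", na.last = "keep")
    ceiling(10 * r / sum(!is.na(v)))
  }
  per$bin_score <- decile_bin(per$local_switch_cost_ms) + decile_bin(per$accuracy_cost)
  per
}

#' Default test-to-construct map for the 17-test battery
#'
#' Four constructs: vocabulary (3 tests), perceptual speed (3), episodic
#' memory (3) and executive function (6 fluid-reasoning tests plus spatial
#' working memory and the task-switching cost). The switch cost is the one
#' lower-is-better measure (`direction = -1`).
#'
#' @return Tibble with columns `test`, `construct`, `direction`.
#' @export
battery_map <- function() {
  tibble::tribble(
    ~test,                ~construct,  ~direction,
    "word_vocabulary",     "vocabulary", 1,
    "picture_vocabulary",  "vocabulary", 1,
    "synonym_antonym",     "vocabulary", 1,
    "digit_symbol",        "speed",      1,
    "pattern_comparison",  "speed",      1,
    "letter_comparison",   "speed",      1,
    "word_recall",         "memory",     1,
    "logical_memory",      "memory",     1,
    "paired_associates",   "memory",     1,
    "shipley_abstraction", "ef",         1,
    "form_boards",         "ef",         1,
    "letter_sets",         "ef",         1,
    "matrix_reasoning",    "ef",         1,
    "paper_folding",       "ef",         1,
    "spatial_relations",   "ef",         1,
    "spatial_working_memory", "ef",      1,
    "switch_cost",         "ef",        -1
  )
}
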
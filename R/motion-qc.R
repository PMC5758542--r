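#' Framewise displacement from a six-parameter motion trace
#'
#' Per-frame head-motion scalar in the Power convention: the L1 norm of the
#' backward differences of the six rigid-body realignment parameters, with
#' rotations converted to arc length on a sphere of radius `radius_mm`
#' (default 50 mm). The first frame has FD = 0 by convention. A
#' Jenkinson-style variant (RMS displacement approximation) is available via
#' `method = "jenkinson"`.
#'
#' @param mt Motion trace: numeric matrix or data frame, volumes x 6, with
#'   translations (mm) in columns 1-3 and rotations (radians) in columns 4-6.
#' @param radius_mm Sphere radius used to convert rotations to mm.
#' @param method `"power"` (default) or `"jenkinson"`.
#' @return Numeric vector of per-frame FD values (mm), same length as the
#'   number of volumes.
#' @export
framewise_displacement <- function(mt, radius_mm = 50, method = c("power", "jenkinson")) {
  method <- match.arg(method)
  mt <- as_motion_trace(mt)
  if (nrow(mt) < 2L) stop("need >= 2 volumes to compute FD", call. = FALSE)
  d <- diff(mt)
  if (method == "power") {
    fd <- rowSums(abs(d[, 1:3, drop = FALSE])) +
      radius_mm * rowSums(abs(d[, 4:6, drop = FALSE]))
  } else {
    # Jenkinson-style small-angle RMS approximation: mean squared displacement
    # of points in a sphere of radius R is |dt|^2 + (R^2/5)|dr|^2
    fd <- sqrt(rowSums(d[, 1:3, drop = FALSE]^2) +
                 (radius_mm^2 / 5) * rowSums(d[, 4:6, drop = FALSE]^2))
  }
  c(0, fd)
}

#' Maximum absolute displacement of a motion trace
#'
#' Largest absolute translation, across the three axes, relative to the
#' reference (first) volume.
#'
#' @inheritParams framewise_displacement
#' @return Single numeric value (mm).
#' @export
max_abs_displacement <- function(mt) {
  mt <- as_motion_trace(mt)
  trans <- sweep(mt[, 1:3, drop = FALSE], 2L, mt[1L, 1:3])
  max(abs(trans))
}

#' Motion-based subject exclusion decision
#'
#' Applies the study's two exclusion rules to a subject's motion summary:
#' exclude if strictly more than `pct_thresh` percent of volumes have
#' FD > `fd_thresh` mm, or if the maximum absolute displacement strictly
#' exceeds `max_disp_thresh` mm. Both comparisons are strict, so a subject at
#' exactly 10% high-FD volumes or exactly 4.0 mm displacement is retained.
#'
#' @param fd_series Per-frame FD values (mm), e.g. from
#'   [framewise_displacement()].
#' @param max_abs_disp Maximum absolute displacement (mm), e.g. from
#'   [max_abs_displacement()].
#' @param fd_thresh High-motion FD cutoff (mm), default 0.5.
#' @param pct_thresh Maximum tolerated percentage of high-FD volumes, default 10.
#' @param max_disp_thresh Maximum tolerated absolute displacement (mm), default 4.
#' @return A one-row tibble (`motion_summary`): `mean_fd`, `pct_high_fd`,
#'   `max_abs_disp`, `excluded`, `reason`.
#' @export
apply_exclusion <- function(fd_series, max_abs_disp,
                            fd_thresh = 0.5, pct_thresh = 10,
                            max_disp_thresh = 4.0) {
  stopifnot(is.numeric(fd_series), length(fd_series) >= 1L,
            is.numeric(max_abs_disp), length(max_abs_disp) == 1L)
  n <- length(fd_series)
  n_high <- sum(fd_series > fd_thresh)
  pct_high <- 100 * n_high / n
  fd_rule <- pct_high > pct_thresh
  disp_rule <- max_abs_disp > max_disp_thresh
  reason <- if (fd_rule && disp_rule) {
    "high-FD volume percentage and max displacement"
  } else if (fd_rule) {
    sprintf("%.1f%% of volumes with FD > %g mm", pct_high, fd_thresh)
  } else if (disp_rule) {
    sprintf("max absolute displacement %.2f mm > %g mm", max_abs_disp, max_disp_thresh)
  } else {
    NA_character_
  }
  tibble::tibble(
    n_volumes = n,
    mean_fd = mean(fd_series),
    pct_high_fd = pct_high,
    max_abs_disp = max_abs_disp,
    excluded = fd_rule || disp_rule,
    reason = reason
  )
}

#' Motion QC summary for one subject
#'
#' Convenience wrapper: computes FD and maximum absolute displacement from a
#' raw motion trace and applies the exclusion rules.
#'
#' @inheritParams framewise_displacement
#' @inheritParams apply_exclusion
#' @return One-row tibble as in [apply_exclusion()].
#' @export
motion_qc <- function(mt, radius_mm = 50, fd_thresh = 0.5, pct_thresh = 10,
                      max_disp_thresh = 4.0) {
  fd <- framewise_displacement(mt, radius_mm = radius_mm)
  apply_exclusion(fd, max_abs_displacement(mt),
                  fd_thresh = fd_thresh, pct_thresh = pct_thresh,
                  max_disp_thresh = max_disp_thresh)
}

as_motion_trace <- function(mt) {
  if (is.data.frame(mt)) mt <- as.matrix(mt)
  if (!is.matrix(mt) || !is.numeric(mt) || ncol(mt) != 6L) {
    stop("motion trace must be numeric with 6 columns ",
         "(3 translations mm, 3 rotations radians)", call. = FALSE)
  }
  if (any(!is.finite(mt))) stop("motion trace contains non-finite values", call. = FALSE)
  mt
}
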
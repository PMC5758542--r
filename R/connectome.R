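#' Pairwise Pearson correlation matrix from ROI time series
#'
#' Correlates every pair of ROI time series (columns) with Pearson's
#' coefficient, the first step in building a functional connectome from
#' region-averaged resting-state signals.
#'
#' @param ts Numeric matrix or data frame, volumes x ROIs. Column names are
#'   taken as ROI identifiers; unnamed columns are labelled `ROI_1`, ...
#' @return A `connectivity_matrix`: a symmetric ROI x ROI numeric matrix with
#'   attribute `scale = "pearson_r"`. The diagonal is set to `NA` and is
#'   excluded from all downstream computations.
#' @examples
#' ts <- matrix(rnorm(60), nrow = 20, ncol = 3,
#'              dimnames = list(NULL, c("a", "b", "c")))
#' cm <- correlation_matrix(ts)
#' @export
correlation_matrix <- function(ts) {
  ts <- as_timeseries_matrix(ts)
  if (nrow(ts) < 3L) {
    stop("at least 3 volumes are required to estimate correlations", call. = FALSE)
  }
  sds <- apply(ts, 2L, stats::sd)
  if (any(sds == 0)) {
    bad <- colnames(ts)[sds == 0]
    stop("constant time series (undefined correlation) for ROI(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  r <- stats::cor(ts)
  r <- (r + t(r)) / 2          # enforce exact symmetry
  diag(r) <- NA_real_
  new_connectivity_matrix(r, scale = "pearson_r")
}

#' Fisher z-transform of a correlation matrix
#'
#' Applies the variance-stabilizing transform z = atanh(r) elementwise to the
#' off-diagonal entries of a Pearson correlation matrix.
#'
#' @param cm A `connectivity_matrix` on the `pearson_r` scale.
#' @return A `connectivity_matrix` with `scale = "fisher_z"`.
#' @export
fisher_z <- function(cm) {
  stopifnot(inherits(cm, "connectivity_matrix"))
  if (cm_scale(cm) != "pearson_r") {
    stop("fisher_z() expects a matrix on the pearson_r scale", call. = FALSE)
  }
  off <- cm[upper.tri(cm)]
  if (any(abs(off) >= 1)) {
    stop("off-diagonal |r| = 1 found (infinite z); this usually signals ",
         "duplicated ROI time series", call. = FALSE)
  }
  z <- atanh(unclass(cm))
  diag(z) <- NA_real_
  new_connectivity_matrix(z, scale = "fisher_z")
}

#' Binarize a connectivity matrix at a proportional density threshold
#'
#' Retains the `floor(cost * M)` largest off-diagonal values, where
#' `M = n(n-1)/2` is the number of possible edges, and returns an unweighted,
#' undirected graph. Thresholding acts on the signed values by default, so at
#' the low densities used for whole-brain graphs (2-10%) only the strongest
#' positive connections survive. Ties at the cutoff are broken by (row,
#' column) lexicographic order so results are deterministic.
#'
#' @param cm A `connectivity_matrix` (normally `fisher_z` scale).
#' @param cost Fraction of all possible edges to retain, in (0, 1].
#' @param absolute If `TRUE`, rank connections by absolute value instead of
#'   signed value.
#' @return A `binary_graph`: symmetric 0/1 matrix with zero diagonal and
#'   attribute `cost`.
#' @export
proportional_threshold <- function(cm, cost, absolute = FALSE) {
  stopifnot(inherits(cm, "connectivity_matrix"))
  if (!is.numeric(cost) || length(cost) != 1L || cost <= 0 || cost > 1) {
    stop("`cost` must be a single fraction in (0, 1]", call. = FALSE)
  }
  n <- nrow(cm)
  m_possible <- n * (n - 1L) / 2L
  k <- floor(cost * m_possible)
  if (k < 1L) {
    stop("cost ", cost, " yields 0 edges for ", n, " nodes", call. = FALSE)
  }
  ut <- which(upper.tri(cm), arr.ind = TRUE)
  w <- cm[upper.tri(cm)]
  if (absolute) w <- abs(w)
  # largest first; ties broken by (i, j) lexicographic order
  ord <- order(-w, ut[, 1L], ut[, 2L])
  keep <- ord[seq_len(k)]
  adj <- matrix(0, n, n, dimnames = dimnames(unclass(cm)))
  adj[ut[keep, , drop = FALSE]] <- 1
  adj <- adj + t(adj)
  new_binary_graph(adj, cost = cost)
}

#' Drop ROIs from a time-series or connectivity matrix
#'
#' Removes the named ROIs (rows/columns for a connectivity matrix, columns
#' for a time series), preserving the order of the survivors. Mirrors the
#' exclusion of cerebellar and poorly covered regions from a parcellation.
#'
#' @param x A time-series matrix (volumes x ROIs) or `connectivity_matrix`.
#' @param drop Character vector of ROI identifiers to remove. May be empty.
#' @return Object of the same type with the ROIs removed.
#' @export
exclude_rois <- function(x, drop) {
  drop <- as.character(drop)
  if (inherits(x, "connectivity_matrix")) {
    ids <- colnames(x)
    unknown <- setdiff(drop, ids)
    if (length(unknown)) {
      stop("unknown ROI id(s): ", paste(unknown, collapse = ", "), call. = FALSE)
    }
    keep <- setdiff(ids, drop)
    if (!length(keep)) stop("cannot drop every ROI", call. = FALSE)
    new_connectivity_matrix(unclass(x)[keep, keep, drop = FALSE], scale = cm_scale(x))
  } else {
    x <- as_timeseries_matrix(x)
    ids <- colnames(x)
    unknown <- setdiff(drop, ids)
    if (length(unknown)) {
      stop("unknown ROI id(s): ", paste(unknown, collapse = ", "), call. = FALSE)
    }
    keep <- setdiff(ids, drop)
    if (!length(keep)) stop("cannot drop every ROI", call. = FALSE)
    x[, keep, drop = FALSE]
  }
}

# ---- internal constructors -------------------------------------------------

as_timeseries_matrix <- function(ts) {
  if (is.data.frame(ts)) ts <- as.matrix(ts)
  if (!is.matrix(ts) || !is.numeric(ts)) {
    stop("time series must be a numeric matrix (volumes x ROIs)", call. = FALSE)
  }
  if (anyNA(ts)) stop("time series contains missing values", call. = FALSE)
  if (is.null(colnames(ts))) colnames(ts) <- paste0("ROI_", seq_len(ncol(ts)))
  if (anyDuplicated(colnames(ts))) stop("ROI labels must be unique", call. = FALSE)
  ts
}

new_connectivity_matrix <- function(m, scale) {
  stopifnot(is.matrix(m), nrow(m) == ncol(m))
  if (is.null(colnames(m))) {
    colnames(m) <- rownames(m) <- paste0("ROI_", seq_len(ncol(m)))
  }
  max_asym <- max(abs(m - t(m)), na.rm = TRUE)
  if (is.finite(max_asym) && max_asym > 1e-12) {
    stop("connectivity matrix is not symmetric", call. = FALSE)
  }
  structure(m, scale = scale, class = c("connectivity_matrix", "matrix", "array"))
}

cm_scale <- function(cm) attr(cm, "scale")

new_binary_graph <- function(adj, cost) {
  stopifnot(is.matrix(adj), nrow(adj) == ncol(adj),
            all(adj %in% c(0, 1)), all(diag(adj) == 0),
            all(adj == t(adj)))
  if (is.null(colnames(adj))) {
    colnames(adj) <- rownames(adj) <- paste0("ROI_", seq_len(ncol(adj)))
  }
  structure(adj, cost = cost, class = c("binary_graph", "matrix", "array"))
}

#' @export
print.connectivity_matrix <- function(x, ...) {
  cat("<connectivity_matrix> ", nrow(x), " x ", ncol(x),
      " (scale: ", cm_scale(x), ")\n", sep = "")
  invisible(x)
}

#' @export
print.binary_graph <- function(x, ...) {
  cat("<binary_graph> ", nrow(x), " nodes, ", sum(x) / 2, " edges (cost ",
      attr(x, "cost"), ")\n", sep = "")
  invisible(x)
}

#' Construct a binary graph from a 0/1 adjacency matrix
#'
#' @param adj Symmetric 0/1 matrix with zero diagonal.
#' @param cost Optional density at which the graph was built.
#' @return A `binary_graph`.
#' @export
as_binary_graph <- function(adj, cost = NA_real_) {
  new_binary_graph(adj, cost = cost)
}

#' Number of edges in a binary graph
#' @param g A `binary_graph`.
#' @return Integer edge count.
#' @export
edge_count <- function(g) {
  stopifnot(inherits(g, "binary_graph"))
  as.integer(sum(g) / 2)
}
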
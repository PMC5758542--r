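#' Read / write ROI time series as tab-delimited text
#'
#' Time series are stored volumes x ROIs with a header row of ROI names.
#'
#' @param path File path.
#' @return `read_timeseries()`: numeric matrix with ROI column names.
#' @export
read_timeseries <- function(path) {
  df <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  as_timeseries_matrix(df)
}

#' @rdname read_timeseries
#' @param ts Numeric matrix, volumes x ROIs.
#' @export
write_timeseries <- function(ts, path) {
  ts <- as_timeseries_matrix(ts)
  readr::write_tsv(tibble::as_tibble(ts), path, progress = FALSE)
  invisible(path)
}

#' Read a six-parameter motion trace
#'
#' Reads a whitespace-delimited motion file (volumes x 6, no header by
#' default). Realignment tools differ in column order and rotation units,
#' so both must be declared explicitly; rotations given in degrees are
#' converted to radians.
#'
#' @param path File path.
#' @param rotation_units `"radians"` or `"degrees"` — no default, because
#'   realignment outputs do not label their units.
#' @param order `"translations_first"` (columns 1-3 translations, 4-6
#'   rotations) or `"rotations_first"`.
#' @param header Does the file have a header row (default `FALSE`)?
#' @return Numeric matrix, volumes x 6, translations (mm) then rotations
#'   (radians).
#' @export
read_motion <- function(path, rotation_units, order = "translations_first",
                        header = FALSE) {
  rotation_units <- match.arg(rotation_units, c("radians", "degrees"))
  order <- match.arg(order, c("translations_first", "rotations_first"))
  m <- as.matrix(utils::read.table(path, header = header))
  if (ncol(m) != 6L) stop("motion file must have 6 columns", call. = FALSE)
  if (order == "rotations_first") m <- m[, c(4:6, 1:3)]
  if (rotation_units == "degrees") m[, 4:6] <- m[, 4:6] * pi / 180
  colnames(m) <- c("trans_x", "trans_y", "trans_z", "rot_x", "rot_y", "rot_z")
  as_motion_trace(m)
}

#' @rdname read_motion
#' @param mt Motion trace matrix (translations mm, rotations radians).
#' @export
write_motion <- function(mt, path) {
  mt <- as_motion_trace(mt)
  utils::write.table(mt, path, sep = "\t", row.names = FALSE,
                     col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a node-to-module assignment table
#'
#' Two-column tab-delimited text: ROI id, module label (header optional,
#' detected from the first line).
#'
#' @param path File path.
#' @return Tibble with columns `roi`, `module`.
#' @export
read_partition_table <- function(path) {
  first <- readLines(path, n = 1L)
  has_header <- grepl("roi", first, ignore.case = TRUE)
  df <- if (has_header) {
    utils::read.table(path, header = TRUE, sep = "\t",
                      stringsAsFactors = FALSE)
  } else {
    utils::read.table(path, header = FALSE, sep = "\t",
                      col.names = c("roi", "module"),
                      stringsAsFactors = FALSE)
  }
  names(df) <- c("roi", "module")
  tibble::as_tibble(df)
}

#' Write a binary graph as an edge list
#'
#' One `roi_i<TAB>roi_j` pair per line (upper triangle only).
#'
#' @param g A `binary_graph`.
#' @param path File path.
#' @export
write_edge_list <- function(g, path) {
  stopifnot(inherits(g, "binary_graph"))
  idx <- which(upper.tri(g) & unclass(g) == 1, arr.ind = TRUE)
  lines <- paste(colnames(g)[idx[, 1L]], colnames(g)[idx[, 2L]], sep = "\t")
  writeLines(lines, path)
  invisible(path)
}

#' Read a binary graph from an edge list
#'
#' @param path File path of a `roi_i<TAB>roi_j` edge list.
#' @param rois Character vector of all node ids (isolated nodes included).
#' @param cost Optional density annotation.
#' @return A `binary_graph`.
#' @export
read_edge_list <- function(path, rois, cost = NA_real_) {
  ed <- utils::read.table(path, sep = "\t", stringsAsFactors = FALSE,
                          col.names = c("i", "j"))
  unknown <- setdiff(unique(c(ed$i, ed$j)), rois)
  if (length(unknown)) {
    stop("edge list references unknown ROI(s): ",
         paste(utils::head(unknown, 5L), collapse = ", "), call. = FALSE)
  }
  n <- length(rois)
  adj <- matrix(0, n, n, dimnames = list(rois, rois))
  adj[cbind(match(ed$i, rois), match(ed$j, rois))] <- 1
  adj <- pmax(adj, t(adj))
  new_binary_graph(adj, cost = cost)
}

#' Write simulation ground truth as JSON
#'
#' Serializes the per-subject latent quantities together with the planted
#' coefficients and node-module labels, so a simulated cohort's ground
#' truth can be archived next to its exported tables.
#'
#' @param ground_truth Ground-truth tibble from [simulate_cohort()].
#' @param path File path.
#' @export
write_ground_truth <- function(ground_truth, path) {
  config <- attr(ground_truth, "config")
  payload <- list(
    subjects = ground_truth,
    planted = list(
      beta_modularity = config$beta_modularity,
      beta_interaction = config$beta_interaction,
      noise_sd = config$noise_sd,
      q_mean = config$q_mean, q_sd = config$q_sd,
      groups = config$groups
    ),
    node_modules = attr(ground_truth, "node_modules")
  )
  jsonlite::write_json(payload, path, dataframe = "rows", digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Write a connectivity matrix as CSV
#'
#' Square CSV with ROI names as header and first column; the (undefined)
#' diagonal is written as empty cells.
#'
#' @param cm A `connectivity_matrix`.
#' @param path File path.
#' @export
write_connectivity <- function(cm, path) {
  stopifnot(inherits(cm, "connectivity_matrix"))
  m <- unclass(cm)
  utils::write.csv(m, path, row.names = TRUE, na = "")
  invisible(path)
}
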
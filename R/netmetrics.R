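#' Newman-Girvan modularity of a partitioned binary graph
#'
#' Computes Q = sum_i (e_ii - a_i^2), where `e_ii` is the fraction of edges
#' joining two nodes within module i and `a_i` is the fraction of edge
#' endpoints attached to module i. Q compares the observed within-module
#' connectivity to the expectation under a degree-preserving random graph;
#' higher Q indicates a more modular (segregated) network.
#'
#' @param g A `binary_graph`.
#' @param p A `partition` covering all nodes of `g` (see
#'   [spectral_partition()] / [canonical_partition()]), or a vector of module
#'   labels in node order.
#' @return A `modularity_result`: list with elements `Q`, `per_module_terms`
#'   (tibble: module, e_within, a_total, q_term), `cost` and `partition`.
#' @examples
#' # two disconnected triangles: Q = 0.5 under the component partition
#' adj <- matrix(0, 6, 6)
#' adj[1:3, 1:3] <- 1; adj[4:6, 4:6] <- 1; diag(adj) <- 0
#' g <- as_binary_graph(adj, cost = 6 / 15)
#' modularity_q(g, rep(c("a", "b"), each = 3))$Q
#' @export
modularity_q <- function(g, p) {
  stopifnot(inherits(g, "binary_graph"))
  p <- as_partition(p, nodes = colnames(g))
  lab <- p$assignment[colnames(g)]
  if (anyNA(lab)) {
    stop("partition does not cover all nodes of the graph", call. = FALSE)
  }
  adj <- unclass(g)
  m2 <- sum(adj)                       # 2 x edge count
  if (m2 == 0) stop("modularity is undefined for an edgeless graph", call. = FALSE)
  mods <- sort(unique(lab))
  deg <- colSums(adj)
  e_within <- vapply(mods, function(mm) {
    idx <- which(lab == mm)
    sum(adj[idx, idx, drop = FALSE]) / m2
  }, numeric(1), USE.NAMES = FALSE)
  a_total <- vapply(mods, function(mm) sum(deg[lab == mm]) / m2, numeric(1),
                    USE.NAMES = FALSE)
  q_terms <- e_within - a_total^2
  structure(
    list(
      Q = sum(q_terms),
      per_module_terms = tibble::tibble(
        module = mods, e_within = e_within, a_total = a_total, q_term = q_terms
      ),
      cost = attr(g, "cost"),
      partition = p
    ),
    class = "modularity_result"
  )
}

#' @export
print.modularity_result <- function(x, ...) {
  cat("<modularity_result> Q = ", format(x$Q, digits = 6),
      " (", nrow(x$per_module_terms), " modules, source: ",
      x$partition$source, ")\n", sep = "")
  invisible(x)
}

#' Spectral modularity-maximizing partition
#'
#' Finds a partition maximizing Newman-Girvan modularity by recursive
#' bisection on the leading eigenvector of the (generalized) modularity
#' matrix, with a Kernighan-Lin-style single-node refinement sweep after each
#' split. Recursion in a community stops when the leading eigenvalue is
#' non-positive, the sign vector is degenerate, or no split (after
#' refinement) increases Q. Connected components are partitioned
#' independently; edgeless nodes become singleton modules.
#'
#' The algorithm is deterministic: the dense symmetric eigensolver and the
#' fixed index-order refinement sweep contain no random choices. The `seed`
#' argument is accepted for interface stability and reserved for optional
#' random restarts.
#'
#' @param g A `binary_graph`.
#' @param seed Ignored by the deterministic algorithm (reserved).
#' @return A `partition` with `source = "spectral"` and attribute `Q`, the
#'   achieved modularity.
#' @export
spectral_partition <- function(g, seed = NULL) {
  stopifnot(inherits(g, "binary_graph"))
  adj <- unclass(g)
  n <- nrow(adj)
  deg <- colSums(adj)
  m2 <- sum(adj)
  labels <- integer(n)

  if (m2 == 0) {
    labels <- seq_len(n)               # every isolated node its own module
  } else {
    next_label <- 0L
    comps <- graph_components(adj)
    for (comp in comps) {
      if (length(comp) == 1L || sum(adj[comp, comp]) == 0) {
        # isolated node(s): singleton modules
        for (v in comp) {
          next_label <- next_label + 1L
          labels[v] <- next_label
        }
        next
      }
      groups <- split_community(adj, comp, deg, m2)
      for (grp in groups) {
        next_label <- next_label + 1L
        labels[grp] <- next_label
      }
    }
  }
  if (m2 > 0) {
    labels <- refine_partition(adj, labels)
    if (n <= 100L) {
      # deterministic agglomerative restart: refining from all-singletons
      # guards against bisection local optima, which bite hardest on small
      # dense graphs; affordable at this size
      alt <- refine_partition(adj, seq_len(n))
      if (quick_q(adj, alt, deg, m2) > quick_q(adj, labels, deg, m2) + 1e-10) {
        labels <- alt
      }
    }
  }
  # contiguous labels by first appearance
  labels <- match(labels, unique(labels))
  p <- new_partition(stats::setNames(labels, colnames(adj)), source = "spectral")
  if (m2 > 0) attr(p, "Q") <- modularity_q(g, p)$Q
  p
}

# Recursively bisect the node set `idx` (indices into adj) using the leading
# eigenvector of the generalized modularity matrix. Returns a list of index
# vectors (the final modules within this community).
split_community <- function(adj, idx, deg, m2, tol = 1e-10) {
  ng <- length(idx)
  if (ng == 1L) return(list(idx))
  a_sub <- adj[idx, idx, drop = FALSE]
  k <- deg[idx]
  # generalized modularity matrix for a subgraph (Newman 2006):
  # B_ij = A_ij - k_i k_j / 2m, minus on the diagonal the row sums of B
  # restricted to the group, so splits are scored against whole-graph Q.
  b <- a_sub - outer(k, k) / m2
  diag(b) <- diag(b) - rowSums(b)
  es <- eigen(b, symmetric = TRUE)
  lead <- es$values[1L]
  if (lead <= tol) return(list(idx))   # indivisible
  v <- es$vectors[, 1L]
  s <- ifelse(v >= 0, 1, -1)
  if (all(s == s[1L])) return(list(idx))   # degenerate sign vector
  s <- refine_bisection(b, s, tol)
  if (all(s == s[1L])) return(list(idx))
  dq <- as.numeric(s %*% b %*% s) / (2 * m2)
  if (dq <= tol) return(list(idx))
  left <- idx[s > 0]
  right <- idx[s < 0]
  c(split_community(adj, left, deg, m2, tol),
    split_community(adj, right, deg, m2, tol))
}

# Kernighan-Lin-style refinement: sweep nodes in index order, flipping any
# node whose move increases s'Bs by more than tol; repeat until a sweep makes
# no flips. Deterministic given the sweep order.
refine_bisection <- function(b, s, tol = 1e-10, max_sweeps = 100L) {
  bs <- as.numeric(b %*% s)
  for (sweep in seq_len(max_sweeps)) {
    changed <- FALSE
    for (i in seq_along(s)) {
      # flipping s_i changes s'Bs by -4 s_i (bs_i - B_ii s_i)
      delta <- -4 * s[i] * (bs[i] - b[i, i] * s[i])
      if (delta > tol) {
        bs <- bs - 2 * s[i] * b[, i]
        s[i] <- -s[i]
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  s
}

# plain Q for an integer label vector (internal fast path)
quick_q <- function(adj, lab, deg, m2) {
  q <- 0
  for (c in unique(lab)) {
    idx <- lab == c
    q <- q + sum(adj[idx, idx]) / m2 - (sum(deg[idx]) / m2)^2
  }
  q
}

# Final Kernighan-Lin-style refinement on the full partition. Each pass
# moves every node exactly once to its best alternative module (an existing
# module or a fresh empty one), accepting the single best move at each step
# even when its immediate change in Q is negative, and then reverts to the
# best intermediate state of the pass. This escapes the local optima that
# pure greedy moves cannot leave and repairs bad early bisections. Passes
# repeat until no net improvement; fully deterministic (ties broken by the
# fixed node/module order of which.max).
refine_partition <- function(adj, labels, tol = 1e-10, max_passes = 30L) {
  n <- nrow(adj)
  deg <- colSums(adj)
  m <- sum(adj) / 2
  lab <- match(labels, unique(labels))
  for (pass in seq_len(max_passes)) {
    lab0 <- lab
    n_mod <- max(lab)
    # L[v, c] = edges from node v into module c; final column = empty module
    memb <- outer(lab, seq_len(n_mod), "==") + 0
    l_mat <- cbind(adj %*% memb, 0)
    ksum <- c(as.numeric(crossprod(memb, deg)), 0)
    moved <- logical(n)
    moves_v <- integer(n)
    moves_to <- integer(n)
    cum <- 0
    best_cum <- 0
    best_len <- 0L
    for (step in seq_len(n)) {
      n_cand <- length(ksum)
      cur <- lab
      l_cur <- l_mat[cbind(seq_len(n), cur)]
      k_excl <- ksum[cur] - deg
      # delta-Q of moving v to c: (l_vc - l_va)/m - k_v (K_c - K_a + k_v)/(2m^2)
      dq <- (l_mat - l_cur) / m -
        deg * (matrix(ksum, n, n_cand, byrow = TRUE) - k_excl) / (2 * m^2)
      dq[cbind(seq_len(n), cur)] <- -Inf
      dq[moved, ] <- -Inf
      pick <- arrayInd(which.max(dq), dim(dq))
      v <- pick[1L]
      b <- pick[2L]
      a <- lab[v]
      cum <- cum + dq[v, b]
      lab[v] <- b
      moved[v] <- TRUE
      moves_v[step] <- v
      moves_to[step] <- b
      l_mat[, a] <- l_mat[, a] - adj[, v]
      l_mat[, b] <- l_mat[, b] + adj[, v]
      ksum[a] <- ksum[a] - deg[v]
      ksum[b] <- ksum[b] + deg[v]
      if (b == n_cand) {          # empty module used; add a fresh candidate
        l_mat <- cbind(l_mat, 0)
        ksum <- c(ksum, 0)
      }
      if (cum > best_cum + tol) {
        best_cum <- cum
        best_len <- step
      }
    }
    lab <- lab0
    if (best_len == 0L) break
    max_lab <- max(lab)
    for (s in seq_len(best_len)) {
      lab[moves_v[s]] <- moves_to[s]
      max_lab <- max(max_lab, moves_to[s])
    }
    lab <- match(lab, unique(lab))
  }
  lab
}

# connected components of an adjacency matrix by BFS; returns list of index
# vectors
graph_components <- function(adj) {
  n <- nrow(adj)
  seen <- logical(n)
  comps <- list()
  for (start in seq_len(n)) {
    if (seen[start]) next
    queue <- start
    seen[start] <- TRUE
    members <- integer(0)
    while (length(queue)) {
      v <- queue[[1L]]
      queue <- queue[-1L]
      members <- c(members, v)
      nbr <- which(adj[v, ] > 0 & !seen)
      seen[nbr] <- TRUE
      queue <- c(queue, nbr)
    }
    comps[[length(comps) + 1L]] <- sort(members)
  }
  comps
}

#' Partition from a canonical node-to-module assignment table
#'
#' Builds a `partition` from a fixed published assignment of ROIs to
#' functional systems (e.g., the 13-system assignment of a cortical
#' parcellation: default mode, fronto-parietal, cingulo-opercular, salience,
#' attention, sensory-motor systems and an "unassigned" module).
#'
#' @param assignment_table Data frame with columns `roi` and `module` (or a
#'   named vector module labels, names = ROI ids).
#' @param rois Optional character vector of retained ROI ids; the table must
#'   cover all of them.
#' @return A `partition` with `source = "canonical"`.
#' @export
canonical_partition <- function(assignment_table, rois = NULL) {
  if (is.data.frame(assignment_table)) {
    stopifnot(all(c("roi", "module") %in% names(assignment_table)))
    ids <- as.character(assignment_table$roi)
    labs <- as.character(assignment_table$module)
  } else {
    ids <- names(assignment_table)
    labs <- as.character(assignment_table)
  }
  if (anyDuplicated(ids)) {
    stop("duplicate ROI id(s) in assignment table: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  }
  if (!is.null(rois)) {
    missing <- setdiff(rois, ids)
    if (length(missing)) {
      stop("ROI(s) missing from assignment table: ",
           paste(missing, collapse = ", "), call. = FALSE)
    }
    keep <- match(rois, ids)
    ids <- ids[keep]
    labs <- labs[keep]
  }
  new_partition(stats::setNames(labs, ids), source = "canonical")
}

as_partition <- function(p, nodes = NULL) {
  if (inherits(p, "partition")) return(p)
  if (is.null(names(p)) && !is.null(nodes) && length(p) == length(nodes)) {
    names(p) <- nodes
  }
  new_partition(p, source = "canonical")
}

new_partition <- function(assignment, source = c("spectral", "canonical")) {
  source <- match.arg(source)
  stopifnot(!is.null(names(assignment)), !anyNA(assignment))
  structure(
    list(assignment = assignment,
         m = length(unique(assignment)),
         source = source),
    class = "partition"
  )
}

#' @export
print.partition <- function(x, ...) {
  cat("<partition> ", length(x$assignment), " nodes in ", x$m,
      " modules (source: ", x$source, ")", sep = "")
  if (!is.null(attr(x, "Q"))) cat(", Q = ", format(attr(x, "Q"), digits = 6), sep = "")
  cat("\n")
  invisible(x)
}

#' Modularity contribution of a class of modules
#'
#' Sums the per-module contributions q_i = e_ii - a_i^2 over a chosen class
#' of modules (e.g., the association systems DMN, FP, CO, Sal, DAN, VAN
#' versus sensory-motor systems), evaluated on the whole-brain graph. This
#' decomposition is additive: summing over all modules recovers whole-brain
#' Q exactly. Alternatively (`method = "induced"`), modularity of the
#' subgraph induced by the class's nodes is returned.
#'
#' @param g A `binary_graph`.
#' @param p A `partition` (typically canonical).
#' @param modules Character vector of module labels defining the class. May
#'   be empty (returns 0 under the default method).
#' @param method `"contribution"` (default; sum of q_i over the class on the
#'   whole-brain graph) or `"induced"` (Q of the induced subgraph under the
#'   restricted partition).
#' @return A single numeric value.
#' @export
subnetwork_modularity <- function(g, p, modules,
                                  method = c("contribution", "induced")) {
  method <- match.arg(method)
  stopifnot(inherits(g, "binary_graph"))
  p <- as_partition(p, nodes = colnames(g))
  unknown <- setdiff(modules, unique(p$assignment))
  if (length(unknown)) {
    stop("unknown module label(s): ", paste(unknown, collapse = ", "), call. = FALSE)
  }
  if (method == "contribution") {
    if (!length(modules)) return(0)
    res <- modularity_q(g, p)
    sum(res$per_module_terms$q_term[res$per_module_terms$module %in% modules])
  } else {
    if (!length(modules)) stop("induced-subgraph modularity needs >= 1 module", call. = FALSE)
    nodes <- names(p$assignment)[p$assignment %in% modules]
    sub <- unclass(g)[nodes, nodes, drop = FALSE]
    if (sum(sub) == 0) stop("induced subgraph has no edges", call. = FALSE)
    gsub <- new_binary_graph(sub, cost = attr(g, "cost"))
    psub <- new_partition(p$assignment[nodes], source = p$source)
    modularity_q(gsub, psub)$Q
  }
}

#' Weighted module segregation
#'
#' Segregation = (Zw - Zb) / Zw on the full weighted Fisher-z matrix, where
#' Zw is the mean z over node pairs within the same module (restricted to
#' modules in scope) and Zb the mean z over pairs linking a scope module to
#' any other module. Unlike thresholded-graph modularity this metric retains
#' the weights of all connections.
#'
#' @param zm A `connectivity_matrix` on the `fisher_z` scale (not thresholded).
#' @param p A `partition` covering the nodes of `zm`.
#' @param modules Module labels in scope; `NULL` (default) uses all modules
#'   (whole-brain segregation).
#' @return A `segregation_result`: list with `segregation`, `Zw`, `Zb`,
#'   `scope`.
#' @export
module_segregation <- function(zm, p, modules = NULL) {
  stopifnot(inherits(zm, "connectivity_matrix"))
  if (cm_scale(zm) != "fisher_z") {
    stop("module_segregation() expects a fisher_z matrix", call. = FALSE)
  }
  p <- as_partition(p, nodes = colnames(zm))
  lab <- p$assignment[colnames(zm)]
  if (anyNA(lab)) stop("partition does not cover all nodes", call. = FALSE)
  all_mods <- unique(lab)
  scope <- if (is.null(modules)) all_mods else modules
  unknown <- setdiff(scope, all_mods)
  if (length(unknown)) {
    stop("unknown module label(s): ", paste(unknown, collapse = ", "), call. = FALSE)
  }
  m <- unclass(zm)
  n <- nrow(m)
  same <- outer(lab, lab, "==")
  in_scope_row <- lab %in% scope
  ut <- upper.tri(m)
  within_mask <- ut & same & outer(in_scope_row, in_scope_row, "&")
  between_mask <- ut & !same & (outer(in_scope_row, rep(TRUE, n), "&") |
                                  outer(rep(TRUE, n), in_scope_row, "&"))
  if (!any(within_mask)) stop("no within-module pairs in scope", call. = FALSE)
  if (!any(between_mask)) stop("no between-module pairs in scope", call. = FALSE)
  zw <- mean(m[within_mask])
  zb <- mean(m[between_mask])
  if (zw == 0) stop("Zw = 0: segregation undefined", call. = FALSE)
  structure(
    list(segregation = (zw - zb) / zw, Zw = zw, Zb = zb,
         scope = if (is.null(modules)) "whole_brain" else paste(scope, collapse = "+")),
    class = "segregation_result"
  )
}

#' @export
print.segregation_result <- function(x, ...) {
  cat("<segregation_result> ", format(x$segregation, digits = 6),
      " (Zw = ", format(x$Zw, digits = 4), ", Zb = ", format(x$Zb, digits = 4),
      ", scope: ", x$scope, ")\n", sep = "")
  invisible(x)
}
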
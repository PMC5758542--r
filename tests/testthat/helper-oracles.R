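# Independent oracles and fixture builders shared across tests.

# Brute-force modularity by explicit edge counting: for each module, count
# internal edge endpoints and total endpoints directly from the adjacency
# matrix. Kept deliberately naive and separate from the package's
# implementation.
oracle_modularity <- function(adj, lab) {
  m2 <- sum(adj)
  q <- 0
  for (c in unique(lab)) {
    idx <- which(lab == c)
    e_ii <- sum(adj[idx, idx]) / m2
    a_i <- sum(adj[idx, , drop = FALSE]) / m2
    q <- q + e_ii - a_i^2
  }
  q
}

# All set partitions of n items as restricted growth strings.
all_partitions <- function(n) {
  out <- list()
  rgs <- integer(n)
  rgs[1] <- 1L
  recurse <- function(i, mx) {
    if (i > n) {
      out[[length(out) + 1L]] <<- rgs[1:n]
      return(invisible())
    }
    for (v in 1:(mx + 1L)) {
      rgs[i] <<- v
      recurse(i + 1L, max(mx, v))
    }
  }
  if (n == 1L) return(list(1L))
  recurse(2L, 1L)
  out
}

exhaustive_max_q <- function(adj, partitions) {
  max(vapply(partitions, function(pp) oracle_modularity(adj, pp), numeric(1)))
}

# Pearson correlation by the raw sum-of-products formula.
oracle_pearson <- function(x, y) {
  n <- length(x)
  num <- n * sum(x * y) - sum(x) * sum(y)
  den <- sqrt(n * sum(x^2) - sum(x)^2) * sqrt(n * sum(y^2) - sum(y)^2)
  num / den
}

# Partial correlation via the inverse of the full correlation matrix.
oracle_partial_cor <- function(df, x, y, covs) {
  r <- stats::cor(as.matrix(df[c(x, y, covs)]))
  p <- solve(r)
  -p[1, 2] / sqrt(p[1, 1] * p[2, 2])
}

# Adjusted Rand index between two labelings.
ari <- function(a, b) {
  tab <- table(a, b)
  n <- sum(tab)
  sij <- sum(choose(tab, 2))
  si <- sum(choose(rowSums(tab), 2))
  sj <- sum(choose(colSums(tab), 2))
  expected <- si * sj / choose(n, 2)
  (sij - expected) / ((si + sj) / 2 - expected)
}

# Erdos-Renyi adjacency with at least one edge.
random_adjacency <- function(n, p = 0.4) {
  adj <- matrix(0, n, n)
  u <- upper.tri(adj)
  repeat {
    adj[u] <- stats::rbinom(sum(u), 1, p)
    if (sum(adj) > 0) break
  }
  adj + t(adj)
}

# Planted 4-block stochastic block model graph (60 nodes).
planted_block_graph <- function(p_in = 0.6, p_out = 0.05,
                                sizes = rep(15L, 4L)) {
  lab <- rep(seq_along(sizes), sizes)
  n <- length(lab)
  pm <- ifelse(outer(lab, lab, "=="), p_in, p_out)
  adj <- matrix(0, n, n)
  u <- upper.tri(adj)
  adj[u] <- stats::rbinom(sum(u), 1, pm[u])
  adj <- adj + t(adj)
  list(adj = adj, labels = lab)
}

# Two disconnected k-cliques.
two_cliques <- function(k = 3L) {
  n <- 2L * k
  adj <- matrix(0, n, n)
  adj[1:k, 1:k] <- 1
  adj[(k + 1):n, (k + 1):n] <- 1
  diag(adj) <- 0
  adj
}

# widen a cohort_modularity table: one row per subject, columns per source
q_by_source <- function(tab) {
  sp <- tab[tab$source == "spectral", c("subject_id", "Q")]
  ca <- tab[tab$source == "canonical", c("subject_id", "Q")]
  names(sp)[2] <- "spectral"
  names(ca)[2] <- "canonical"
  merge(sp, ca, by = "subject_id")
}

one_group_config <- function(n, seed, beta = 1.8, beta_int = -2.4, ...) {
  sim_config(
    n_subjects = n, seed = seed, beta_modularity = beta,
    beta_interaction = beta_int,
    groups = tibble::tibble(group = "walk", ef_gain_mean = 0.16,
                            crf_gain_mean = 0.54),
    ...
  )
}
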
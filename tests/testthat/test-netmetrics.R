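test_that("two disconnected triangles give Q = 0.5 under the component partition", {
  g <- as_binary_graph(two_cliques(3))
  res <- modularity_q(g, rep(c("a", "b"), each = 3))
  expect_equal(res$Q, 0.5, tolerance = 1e-15)
  expect_equal(res$per_module_terms$e_within, c(0.5, 0.5))
  expect_equal(res$per_module_terms$a_total, c(0.5, 0.5))
})

test_that("the single-module partition gives Q = 0 on any graph", {
  set.seed(17)
  for (k in 1:5) {
    adj <- random_adjacency(sample(4:10, 1))
    g <- as_binary_graph(adj)
    expect_equal(modularity_q(g, rep("all", nrow(adj)))$Q, 0, tolerance = 1e-15)
  }
})

test_that("modularity matches the edge-counting oracle on random graphs", {
  set.seed(29)
  for (k in 1:40) {
    n <- sample(4:8, 1)
    adj <- random_adjacency(n)
    lab <- sample(1:3, n, replace = TRUE)
    got <- modularity_q(as_binary_graph(adj), as.character(lab))$Q
    expect_equal(got, oracle_modularity(adj, lab), tolerance = 1e-12)
  }
})

test_that("modularity conservation identities hold", {
  set.seed(37)
  for (k in 1:10) {
    adj <- random_adjacency(10, 0.3)
    res <- modularity_q(as_binary_graph(adj), sample(1:4, 10, replace = TRUE))
    expect_equal(sum(res$per_module_terms$q_term), res$Q, tolerance = 1e-12)
    expect_equal(sum(res$per_module_terms$a_total), 1, tolerance = 1e-12)
    expect_lte(sum(res$per_module_terms$e_within), 1 + 1e-12)
  }
})

test_that("modularity is undefined on an edgeless graph", {
  adj <- matrix(0, 4, 4)
  expect_error(modularity_q(as_binary_graph(adj), rep("a", 4)), "edgeless")
})

test_that("spectral partitioning recovers disconnected cliques exactly", {
  g <- as_binary_graph(two_cliques(3))
  p <- spectral_partition(g)
  expect_equal(p$m, 2L)
  expect_equal(attr(p, "Q"), 0.5, tolerance = 1e-12)
  # brute-force over all partitions of 6 nodes confirms this is the optimum
  best <- exhaustive_max_q(two_cliques(3), all_partitions(6))
  expect_equal(attr(p, "Q"), best, tolerance = 1e-12)
})

test_that("a complete graph is a single module with Q = 0", {
  k8 <- matrix(1, 8, 8) - diag(8)
  p <- spectral_partition(as_binary_graph(k8))
  expect_equal(p$m, 1L)
  expect_equal(attr(p, "Q"), 0, tolerance = 1e-12)
})

test_that("spectral Q reaches at least 95% of the exhaustive optimum (small graphs)", {
  set.seed(41)
  parts <- lapply(4:8, all_partitions)
  for (k in 1:30) {
    n <- sample(4:8, 1)
    adj <- random_adjacency(n)
    best <- exhaustive_max_q(adj, parts[[n - 3]])
    got <- attr(spectral_partition(as_binary_graph(adj)), "Q")
    if (best > 0) expect_gte(got, 0.95 * best - 1e-12)
    else expect_gte(got, best - 1e-12)
  }
})

test_that("spectral partition agrees with an independent implementation on Q", {
  skip_if_not_installed("igraph")
  set.seed(53)
  for (k in 1:5) {
    pb <- planted_block_graph()
    g <- as_binary_graph(pb$adj)
    p <- spectral_partition(g)
    ig <- igraph::graph_from_adjacency_matrix(pb$adj, mode = "undirected")
    cl <- igraph::cluster_leading_eigen(ig)
    q_ig <- igraph::modularity(ig, igraph::membership(cl))
    # same objective; our refinement may only do better
    expect_gte(attr(p, "Q"), q_ig - 1e-8)
    # and our Q agrees with igraph's evaluation of our own partition
    expect_equal(igraph::modularity(ig, p$assignment), attr(p, "Q"),
                 tolerance = 1e-12)
  }
})

test_that("planted 4-block graphs are recovered with high ARI", {
  set.seed(61)
  ok <- 0L
  for (s in 1:20) {
    pb <- planted_block_graph()
    p <- spectral_partition(as_binary_graph(pb$adj))
    if (ari(p$assignment, pb$labels) >= 0.9) ok <- ok + 1L
  }
  expect_gte(ok, 19L)
})

test_that("isolated nodes become singleton modules", {
  adj <- matrix(0, 5, 5)
  adj[1, 2] <- adj[2, 1] <- 1
  p <- spectral_partition(as_binary_graph(adj))
  expect_equal(p$m, 4L)   # {1,2} plus three singletons
})

test_that("canonical partitions validate coverage, duplicates and row order", {
  tab <- tibble::tibble(roi = paste0("r", 1:6),
                        module = rep(c("DMN", "Vis"), each = 3))
  p <- canonical_partition(tab)
  expect_equal(p$m, 2L)
  expect_identical(p$source, "canonical")
  p2 <- canonical_partition(tab[sample(1:6), ])
  expect_identical(p2$assignment[paste0("r", 1:6)],
                   p$assignment[paste0("r", 1:6)])
  expect_error(canonical_partition(tab[c(1, 1, 2), ]), "duplicate")
  expect_error(canonical_partition(tab, rois = c(tab$roi, "r99")), "missing")
})

test_that("sub-network contributions sum to whole-brain Q and match hand values", {
  g <- as_binary_graph(two_cliques(3))
  p <- canonical_partition(tibble::tibble(
    roi = colnames(g), module = rep(c("assoc", "sensory"), each = 3)
  ))
  whole <- modularity_q(g, p)$Q
  expect_equal(subnetwork_modularity(g, p, c("assoc", "sensory")), whole,
               tolerance = 1e-12)
  expect_equal(subnetwork_modularity(g, p, character()), 0)
  # single clique contributes e - a^2 = 1/2 - 1/4
  expect_equal(subnetwork_modularity(g, p, "assoc"), 0.25, tolerance = 1e-12)
  expect_error(subnetwork_modularity(g, p, "nope"), "unknown module")
  # induced-subgraph alternative runs and is finite
  expect_true(is.finite(subnetwork_modularity(g, p, "assoc", method = "induced")))
})

test_that("segregation hits its closed-form limits and a hand-computed fixture", {
  ids <- paste0("n", 1:6)
  lab <- tibble::tibble(roi = ids, module = rep(c("m1", "m2"), each = 3))
  p <- canonical_partition(lab)
  block <- function(w, b) {
    m <- matrix(b, 6, 6, dimnames = list(ids, ids))
    m[1:3, 1:3] <- w
    m[4:6, 4:6] <- w
    diag(m) <- NA
    modgain:::new_connectivity_matrix(m, scale = "fisher_z")
  }
  expect_equal(module_segregation(block(0.6, 0), p)$segregation, 1,
               tolerance = 1e-12)
  expect_equal(module_segregation(block(0.4, 0.4), p)$segregation, 0,
               tolerance = 1e-12)
  # asymmetric hand-computed fixture
  m <- matrix(0.1, 6, 6, dimnames = list(ids, ids))
  m[1:3, 1:3] <- 0.5
  m[4:6, 4:6] <- 0.3
  m[2, 3] <- m[3, 2] <- 0.7
  diag(m) <- NA
  zm <- modgain:::new_connectivity_matrix(m, scale = "fisher_z")
  zw <- mean(c(0.5, 0.5, 0.7, 0.3, 0.3, 0.3))  # within pairs of both modules
  zb <- 0.1
  res <- module_segregation(zm, p)
  expect_equal(res$Zw, zw, tolerance = 1e-12)
  expect_equal(res$Zb, zb, tolerance = 1e-12)
  expect_equal(res$segregation, (zw - zb) / zw, tolerance = 1e-12)
  # scoped to one module
  res1 <- module_segregation(zm, p, modules = "m1")
  expect_equal(res1$Zw, mean(c(0.5, 0.5, 0.7)), tolerance = 1e-12)
})

test_that("spectral and canonical modularity correlate across simulated subjects", {
  cfg <- sim_config(n_subjects = 8, n_rois = 60, n_volumes = 120,
                    partition_spec = c(A = 15L, B = 15L, C = 15L, D = 15L),
                    seed = 71)
  tab <- cohort_modularity(cfg, costs = 0.1)
  wide <- q_by_source(tab)
  expect_gt(cor(wide$spectral, wide$canonical), 0)
})
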
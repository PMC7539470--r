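test_that("modularity closed forms: single edge and disconnected triangles", {
  A <- matrix(0, 2, 2); A[1, 2] <- 1
  expect_equal(modularity_score(A, c(1, 1), resolution = 1), 0)

  tri2 <- matrix(0, 6, 6)
  tri2[1, 2] <- tri2[2, 3] <- tri2[1, 3] <- 1
  tri2[4, 5] <- tri2[5, 6] <- tri2[4, 6] <- 1
  expect_equal(modularity_score(tri2, c(1, 1, 1, 2, 2, 2), resolution = 1),
               0.5)
})

test_that("modularity matches a direct-summation oracle and igraph", {
  for (s in 1:30) {
    A <- random_adjacency(6, seed = s)
    memb <- sample(1:3, 6, replace = TRUE)
    expect_equal(modularity_score(A, memb, resolution = 0.7),
                 q_oracle_sym(A, memb, 0.7), tolerance = 1e-12)
    expect_equal(modularity_score(A, memb, resolution = 0.7,
                                  mode = "directed"),
                 q_oracle_dir(A, memb, 0.7), tolerance = 1e-12)
    g <- igraph::graph_from_adjacency_matrix(A + t(A), mode = "undirected",
                                             weighted = TRUE)
    expect_equal(modularity_score(A, memb, resolution = 0.7),
                 igraph::modularity(g, memb, weights = igraph::E(g)$weight,
                                    resolution = 0.7),
                 tolerance = 1e-12)
  }
})

test_that("modularity is invariant under label permutation", {
  A <- random_adjacency(7, seed = 99)
  memb <- c(1, 1, 2, 2, 3, 3, 1)
  relab <- c(7, 7, 4, 4, 9, 9, 7)
  expect_identical(modularity_score(A, memb, 0.7),
                   modularity_score(A, relab, 0.7))
})

test_that("modularity of an edgeless graph is an error", {
  A <- matrix(0, 3, 3)
  expect_error(modularity_score(A, c(1, 2, 3), 0.7),
               class = "stigmanet_validation_error")
  expect_error(louvain(A, 0.7, seed = 1),
               class = "stigmanet_validation_error")
})

test_that("Louvain recovers disconnected cliques and is seed-deterministic", {
  A <- matrix(0, 8, 8)
  for (i in 1:3) for (j in (i + 1):4) A[i, j] <- 2
  for (i in 5:7) for (j in (i + 1):8) A[i, j] <- 2
  p <- louvain(A, resolution = 1, seed = 4)
  expect_equal(length(unique(p$membership)), 2)
  expect_equal(unname(p$membership[1:4]), rep(p$membership[[1]], 4))
  bf <- brute_force_partition(A, resolution = 1)
  expect_equal(p$Q, bf$Q, tolerance = 1e-12)

  p2 <- louvain(A, resolution = 1, seed = 4)
  expect_identical(p$membership, p2$membership)
  expect_identical(p$Q, p2$Q)
})

test_that("the brute-force oracle prefers merging a lone edge and resolution refines", {
  A <- matrix(0, 2, 2); A[1, 2] <- 1
  bf <- brute_force_partition(A, resolution = 0.7)
  expect_equal(length(unique(bf$membership)), 1)
  expect_equal(bf$Q, q_oracle_sym(A, c(1, 1), 0.7), tolerance = 1e-14)

  # path of 4 nodes: module count non-decreasing in gamma
  P <- matrix(0, 4, 4); P[1, 2] <- P[2, 3] <- P[3, 4] <- 1
  k_low <- length(unique(brute_force_partition(P, resolution = 0.7)$membership))
  k_high <- length(unique(brute_force_partition(P, resolution = 2)$membership))
  expect_gte(k_high, k_low)

  expect_error(brute_force_partition(random_adjacency(12, 1), max_nodes = 10),
               class = "stigmanet_validation_error")
})

test_that("resolution refinement is monotone on an enumeration battery", {
  for (s in 1:15) {
    A <- random_adjacency(sample(4:6, 1), seed = 200 + s)
    k1 <- length(unique(brute_force_partition(A, resolution = 0.7)$membership))
    k2 <- length(unique(brute_force_partition(A, resolution = 2)$membership))
    expect_gte(k2, k1)
  }
})

test_that("Louvain never beats the exact optimum on small graphs", {
  eq <- 0; n_graphs <- 40
  for (s in 1:n_graphs) {
    A <- random_adjacency(sample(4:8, 1), seed = 500 + s)
    bf <- brute_force_partition(A, resolution = 0.7)
    lv <- louvain(A, resolution = 0.7, seed = s)
    expect_lte(lv$Q, bf$Q + 1e-10)
    if (abs(lv$Q - bf$Q) < 1e-10) eq <- eq + 1
  }
  expect_gte(eq / n_graphs, 0.9)
})

test_that("consensus acceptance: single runs, unanimity and reproducibility", {
  A <- random_adjacency(8, seed = 77)
  c1 <- consensus_partitions(A, n_runs = 1, resolution = 0.7, base_seed = 3)
  expect_equal(c1$partitions[[1]]$frequency, 1)
  expect_false(is.null(c1$accepted))

  d <- generate_community(planted_config(5))
  net <- build_transfer_network(d$stigmas,
                                flowering_species = d$flower_survey$species)
  cons <- consensus_partitions(net, n_runs = 25, resolution = 0.7,
                               base_seed = 10)
  expect_equal(cons$partitions[[1]]$frequency, 1)
  expect_false(is.null(cons$accepted))

  cons2 <- consensus_partitions(net, n_runs = 25, resolution = 0.7,
                                base_seed = 10)
  expect_identical(lapply(cons$partitions, `[[`, "membership"),
                   lapply(cons2$partitions, `[[`, "membership"))
})

test_that("a symmetric cycle yields tied co-optimal partitions, none accepted", {
  # 4-cycle: at gamma = 1.2 the two opposite-edge pairings are the only
  # optima; run count and base seed realise an exact 50/50 split.
  A <- matrix(0, 4, 4); A[1, 2] <- A[2, 3] <- A[3, 4] <- A[4, 1] <- 1
  cons <- consensus_partitions(A, n_runs = 24, resolution = 1.2,
                               base_seed = 24000)
  expect_true(cons$co_optimal)
  expect_null(cons$accepted)
  freqs <- vapply(cons$partitions, `[[`, 0, "frequency")
  expect_equal(freqs, c(0.5, 0.5))
  qs <- vapply(cons$partitions, `[[`, 0, "Q")
  expect_equal(qs[1], qs[2], tolerance = 1e-12)
})

test_that("off-plot donors can be excluded from module detection", {
  d <- generate_community(sim_config(n_species = 10, n_offplot_donors = 3,
                                     hp_rate_between = 0.8, seed = 17))
  net <- build_transfer_network(d$stigmas,
                                flowering_species = d$flower_survey$species)
  p_with <- louvain(net, 0.7, seed = 1, include_offplot = TRUE)
  p_without <- louvain(net, 0.7, seed = 1, include_offplot = FALSE)
  expect_setequal(names(p_with$membership), net$nodes$species)
  expect_setequal(names(p_without$membership),
                  net$nodes$species[net$nodes$on_plot])
})
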
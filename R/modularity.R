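# Weighted modularity optimisation with a resolution parameter.
#
# Directed pollen-transfer weights are symmetrized (W = A + t(A)) before
# modularity is computed, mirroring how general-purpose network tools
# treat directed graphs when asked for classic Newman modularity; a
# directed (Leicht-Newman) variant is available via `mode = "directed"`.
# The Louvain optimiser is the greedy two-phase scheme (local moving +
# aggregation); randomness enters only through the seeded node visit
# order, and ties in the local-moving step are broken by lowest candidate
# module index, so a run is fully reproducible from its seed.

# Directed weighted adjacency over node order; accepts a transfer_network
# or a plain square matrix (taken as directed weights).
directed_adjacency <- function(x) {
  if (inherits(x, "transfer_network")) {
    sp <- x$nodes$species
    A <- matrix(0, length(sp), length(sp), dimnames = list(sp, sp))
    if (nrow(x$edges))
      A[cbind(match(x$edges$donor, sp), match(x$edges$receptor, sp))] <-
        x$edges$weight
    A
  } else if (is.matrix(x) && nrow(x) == ncol(x)) {
    if (is.null(rownames(x)))
      dimnames(x) <- list(paste0("n", seq_len(nrow(x))),
                          paste0("n", seq_len(nrow(x))))
    x
  } else stop(validation_error(
    "expected a transfer_network or a square adjacency matrix"))
}

drop_offplot <- function(network) {
  if (!inherits(network, "transfer_network")) return(network)
  keep <- network$nodes$species[network$nodes$on_plot]
  network$edges <- network$edges[network$edges$donor %in% keep &
                                   network$edges$receptor %in% keep, ,
                                 drop = FALSE]
  network$nodes <- network$nodes[network$nodes$on_plot, , drop = FALSE]
  network
}

new_partition <- function(membership, Q, resolution, seed = NA_integer_) {
  structure(list(membership = membership, Q = Q, resolution = resolution,
                 seed = seed),
            class = "partition")
}

#' @export
print.partition <- function(x, ...) {
  k <- length(unique(x$membership))
  cat(sprintf("Partition: %d module(s) over %d nodes, Q = %.4f (gamma = %g)\n",
              k, length(x$membership), x$Q, x$resolution))
  invisible(x)
}

# Relabel modules 1, 2, ... in order of first appearance, making label-free
# partition comparison a plain identical() on the vectors.
canonical_membership <- function(memb) {
  setNames(as.integer(match(memb, unique(memb))), names(memb))
}

# Q on a symmetric weight matrix (diagonal = twice the internal weight of
# an aggregated block, zero for simple graphs).
q_symmetric <- function(W, memb, gamma) {
  two_m <- sum(W)
  if (two_m <= 0)
    stop(validation_error("network has no edges; modularity undefined"))
  k <- rowSums(W)
  q <- 0
  for (c in unique(memb)) {
    idx <- which(memb == c)
    q <- q + sum(W[idx, idx]) - gamma * sum(k[idx])^2 / two_m
  }
  q / two_m
}

q_directed <- function(A, memb, gamma) {
  m <- sum(A)
  if (m <= 0)
    stop(validation_error("network has no edges; modularity undefined"))
  k_out <- rowSums(A); k_in <- colSums(A)
  q <- 0
  for (c in unique(memb)) {
    idx <- which(memb == c)
    q <- q + sum(A[idx, idx]) - gamma * sum(k_out[idx]) * sum(k_in[idx]) / m
  }
  q / m
}

#' Weighted modularity of a partition
#'
#' Computes `Q = (1/2m) * sum_ij [W_ij - gamma * k_i k_j / (2m)] *
#' delta(c_i, c_j)` on the symmetrized weighted adjacency
#' `W = A + t(A)` (default), or the Leicht-Newman directed variant
#' `Q = (1/m) * sum_ij [A_ij - gamma * k_i^out k_j^in / m] * delta(c_i,
#' c_j)` with `mode = "directed"`. `gamma` is the resolution parameter
#' scaling the null-model term.
#'
#' @param network A [transfer_network][build_transfer_network] or a square
#'   weighted adjacency matrix (directed weights).
#' @param partition A `partition` object or a membership vector named by
#'   node (must cover all nodes).
#' @param resolution Resolution parameter `gamma` (default 0.7).
#' @param mode `"symmetrized"` (default) or `"directed"`.
#' @return Modularity `Q` (a number in \[-1, 1\]).
#' @export
modularity_score <- function(network, partition, resolution = 0.7,
                             mode = c("symmetrized", "directed")) {
  mode <- match.arg(mode)
  A <- directed_adjacency(network)
  memb <- if (inherits(partition, "partition")) partition$membership
          else partition
  if (!is.null(names(memb))) {
    missing <- setdiff(rownames(A), names(memb))
    if (length(missing))
      stop(validation_error(paste("partition does not cover node(s):",
                                  paste(missing, collapse = ", "))))
    memb <- memb[rownames(A)]
  } else if (length(memb) != nrow(A)) {
    stop(validation_error("unnamed membership must have one label per node"))
  }
  if (mode == "symmetrized") q_symmetric(A + t(A), memb, resolution)
  else q_directed(A, memb, resolution)
}

# One Louvain level: local moving on symmetric W until no node moves.
# Returns the community labels (integers). Deterministic given the RNG
# state (visit order is the only stochastic ingredient).
louvain_local_move <- function(W, gamma) {
  n <- nrow(W)
  two_m <- sum(W)
  m <- two_m / 2
  k <- rowSums(W)
  comm <- seq_len(n)
  sigma_tot <- k  # total degree per community
  repeat {
    moved <- FALSE
    for (i in sample.int(n)) {
      ci <- comm[i]
      wi <- W[i, ]
      wi[i] <- 0  # self-weight moves with the node; cancels in all gains
      # weight from i to each community
      w_to <- tapply(wi, comm, sum)
      cand <- as.integer(names(w_to))
      sigma_excl <- sigma_tot[cand] - ifelse(cand == ci, k[i], 0)
      w_ic <- as.numeric(w_to)
      gain <- w_ic / m - gamma * k[i] * sigma_excl / (2 * m^2)
      stay <- gain[cand == ci]
      best <- max(gain)
      winners <- cand[gain >= best - 1e-14]
      target <- min(winners)
      if (target != ci && best > stay + 1e-12) {
        sigma_tot[ci] <- sigma_tot[ci] - k[i]
        sigma_tot[target] <- sigma_tot[target] + k[i]
        comm[i] <- target
        moved <- TRUE
      }
    }
    if (!moved) break
  }
  as.integer(match(comm, unique(comm)))
}

# Aggregate communities into supernodes: W2[a, b] = sum of W over the
# (a, b) block, so Q is invariant under aggregation.
aggregate_graph <- function(W, comm) {
  k <- max(comm)
  M <- matrix(0, nrow(W), k)
  M[cbind(seq_len(nrow(W)), comm)] <- 1
  t(M) %*% W %*% M
}

#' Louvain modularity optimisation
#'
#' Greedy two-phase Louvain: repeated local moving of nodes between
#' modules followed by aggregation of modules into supernodes, until a
#' full level yields no modularity gain. The node visit order is shuffled
#' from `seed`; local-moving ties are broken toward the lowest candidate
#' module index, so identical seeds give identical partitions.
#'
#' @inheritParams modularity_score
#' @param seed Integer run seed.
#' @param include_offplot Keep off-plot donor nodes in the optimisation
#'   (default `TRUE`; their links are part of the network).
#' @return A `partition`: named membership vector (labels 1, 2, ... in
#'   node order), `Q`, `resolution`, `seed`.
#' @export
louvain <- function(network, resolution = 0.7, seed = 1L,
                    include_offplot = TRUE) {
  if (!include_offplot) network <- drop_offplot(network)
  A <- directed_adjacency(network)
  if (sum(A) + sum(t(A)) <= 0)
    stop(validation_error("network has no edges; modularity undefined"))
  W0 <- A + t(A)
  set.seed(as.integer(seed))
  memb <- seq_len(nrow(W0))  # original node -> current community
  W <- W0
  repeat {
    comm <- louvain_local_move(W, resolution)
    if (max(comm) == nrow(W)) break  # no merge at this level: converged
    memb <- comm[memb]
    W <- aggregate_graph(W, comm)
  }
  memb <- canonical_membership(setNames(memb, rownames(W0)))
  new_partition(memb, Q = q_symmetric(W0, memb, resolution),
                resolution = resolution, seed = as.integer(seed))
}

#' Consensus over repeated Louvain runs
#'
#' Runs the seeded Louvain optimiser `n_runs` times (seeds `base_seed + 1`
#' to `base_seed + n_runs`), groups the resulting partitions up to label
#' permutation, and applies the majority acceptance rule: a partition is
#' accepted when its run frequency exceeds `threshold` (default 0.8).
#' When no partition is accepted and at least two partitions tie for the
#' highest frequency, the result is flagged co-optimal and all tied
#' partitions are reported with their modularities.
#'
#' @inheritParams louvain
#' @param n_runs Number of runs (default 25).
#' @param base_seed Base seed; run `j` uses seed `base_seed + j`.
#' @param threshold Acceptance frequency threshold, in (0, 1\].
#' @return An object of class `consensus_result`: `partitions` (list of
#'   distinct `partition`s, each with a `frequency`, sorted by
#'   frequency), `accepted` (the accepted `partition` or `NULL`),
#'   `co_optimal`, `n_runs`, `resolution`, `threshold`, `base_seed`.
#' @export
consensus_partitions <- function(network, n_runs = 25, resolution = 0.7,
                                 base_seed = 0L, threshold = 0.8,
                                 include_offplot = TRUE) {
  if (n_runs < 1) stop(validation_error("n_runs must be >= 1"))
  if (threshold <= 0 || threshold > 1)
    stop(validation_error("threshold must lie in (0, 1]"))
  runs <- lapply(seq_len(n_runs), function(j)
    louvain(network, resolution = resolution, seed = base_seed + j,
            include_offplot = include_offplot))
  sig <- vapply(runs, function(p)
    paste(p$membership, collapse = "."), character(1))
  counts <- table(sig)
  distinct <- lapply(names(counts), function(s) {
    p <- runs[[match(s, sig)]]
    p$frequency <- as.numeric(counts[[s]]) / n_runs
    p
  })
  distinct <- distinct[order(vapply(distinct, `[[`, 0, "frequency"),
                             vapply(distinct, `[[`, 0, "Q"),
                             decreasing = TRUE)]
  freqs <- vapply(distinct, `[[`, 0, "frequency")
  accepted <- if (freqs[1] > threshold) distinct[[1]] else NULL
  co_optimal <- is.null(accepted) && length(freqs) > 1 &&
    sum(abs(freqs - freqs[1]) < 1e-12) >= 2
  structure(list(partitions = distinct, accepted = accepted,
                 co_optimal = co_optimal, n_runs = n_runs,
                 resolution = resolution, threshold = threshold,
                 base_seed = as.integer(base_seed)),
            class = "consensus_result")
}

#' @export
print.consensus_result <- function(x, ...) {
  cat(sprintf("Consensus over %d Louvain runs (gamma = %g, threshold > %g):\n",
              x$n_runs, x$resolution, x$threshold))
  for (p in x$partitions)
    cat(sprintf("  %2.0f%% of runs: %d module(s), Q = %.4f\n",
                100 * p$frequency, length(unique(p$membership)), p$Q))
  if (!is.null(x$accepted)) cat("  -> one partition accepted\n")
  else if (x$co_optimal) cat("  -> co-optimal solutions; none accepted\n")
  else cat("  -> no partition accepted\n")
  invisible(x)
}

# All set partitions of n elements as membership vectors (restricted
# growth strings). Bell(10) = 115975 is the practical ceiling.
enumerate_set_partitions <- function(n) {
  out <- vector("list", 0)
  rec <- function(prefix, mx) {
    if (length(prefix) == n) {
      out[[length(out) + 1L]] <<- prefix
      return(invisible())
    }
    for (lab in seq_len(mx + 1L))
      rec(c(prefix, lab), max(mx, lab))
  }
  rec(integer(0), 0L)
  out
}

#' Exact maximum-modularity partition by enumeration
#'
#' Testing oracle: evaluates every set partition of the nodes and returns
#' the modularity maximum. Feasible only for small graphs (Bell numbers
#' grow super-exponentially), hence the `max_nodes` guard.
#'
#' @inheritParams louvain
#' @param max_nodes Refuse graphs with more nodes than this (default 10).
#' @return The optimal `partition` (first optimum in enumeration order on
#'   ties).
#' @export
brute_force_partition <- function(network, resolution = 0.7, max_nodes = 10,
                                  include_offplot = TRUE) {
  if (!include_offplot) network <- drop_offplot(network)
  A <- directed_adjacency(network)
  n <- nrow(A)
  if (n > max_nodes)
    stop(validation_error(sprintf(
      "%d nodes exceed max_nodes = %d for exhaustive enumeration",
      n, max_nodes)))
  W <- A + t(A)
  two_m <- sum(W)
  if (two_m <= 0)
    stop(validation_error("network has no edges; modularity undefined"))
  k <- rowSums(W)
  B <- W - resolution * outer(k, k) / two_m
  best_q <- -Inf; best <- NULL
  for (memb in enumerate_set_partitions(n)) {
    q <- 0
    for (c in unique(memb)) {
      idx <- which(memb == c)
      q <- q + sum(B[idx, idx])
    }
    q <- q / two_m
    if (q > best_q + 1e-15) { best_q <- q; best <- memb }
  }
  memb <- canonical_membership(setNames(best, rownames(A)))
  new_partition(memb, Q = best_q, resolution = resolution)
}
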
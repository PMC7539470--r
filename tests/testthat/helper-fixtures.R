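# Fixture builders shared across the suite. Everything is generated in
# code; no fixture files.

# Long-format stigma rows from a compact list: list(s1 = c(CONSPECIFIC = 10,
# SpA = 2), ...) with per-stigma focal species.
make_stigma_df <- function(counts, focal, community = "C1", plot = "plot1") {
  rows <- lapply(names(counts), function(id) {
    cc <- counts[[id]]
    data.frame(stigma_id = id, focal_species = focal[[id]],
               community = community, plot = plot,
               donor = names(cc), grains = as.integer(cc),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

# Random directed weighted adjacency with no self-loops; guaranteed at
# least one edge.
random_adjacency <- function(n, seed, max_w = 3, p = 0.5) {
  set.seed(seed)
  repeat {
    A <- matrix(rbinom(n * n, 1, p) * sample.int(max_w, n * n, replace = TRUE),
                n, n)
    diag(A) <- 0
    if (sum(A) > 0) return(A)
  }
}

# Independent direct-summation modularity oracle (ordered-pair double
# loop; no shared code with the package implementation).
q_oracle_sym <- function(A, memb, gamma) {
  W <- A + t(A)
  two_m <- sum(W)
  k <- rowSums(W)
  q <- 0
  for (i in seq_len(nrow(W))) for (j in seq_len(ncol(W)))
    if (memb[i] == memb[j])
      q <- q + W[i, j] - gamma * k[i] * k[j] / two_m
  q / two_m
}

q_oracle_dir <- function(A, memb, gamma) {
  m <- sum(A)
  ko <- rowSums(A); ki <- colSums(A)
  q <- 0
  for (i in seq_len(nrow(A))) for (j in seq_len(ncol(A)))
    if (memb[i] == memb[j])
      q <- q + A[i, j] - gamma * ko[i] * ki[j] / m
  q / m
}

# Mixed-model simulators used for recovery / type-I checks: 9 communities
# fully crossed with 20 species, random intercepts for both.
glmm_frame <- function(seed, sd_re = 0.3) {
  set.seed(seed)
  comm <- rep(sprintf("c%d", 1:9), each = 20)
  sp <- rep(sprintf("s%02d", 1:20), times = 9)
  list(comm = comm, sp = sp,
       x = rnorm(180),
       eta_re = rnorm(9, 0, sd_re)[as.integer(factor(comm))] +
         rnorm(20, 0, sd_re)[as.integer(factor(sp))])
}

simulate_beta_glmm <- function(beta, seed, phi = 20) {
  f <- glmm_frame(seed)
  mu <- plogis(-1 + beta * f$x + f$eta_re)
  y <- rbeta(180, mu * phi, (1 - mu) * phi)
  data.frame(y = pmin(pmax(y, 1e-6), 1 - 1e-6), x = f$x,
             community = f$comm, species = f$sp)
}

simulate_poisson_glmm <- function(beta, seed) {
  f <- glmm_frame(seed)
  data.frame(y = rpois(180, exp(1.5 + beta * f$x + f$eta_re)), x = f$x,
             community = f$comm, species = f$sp)
}

simulate_binomial_glmm <- function(beta, seed) {
  f <- glmm_frame(seed, sd_re = 0.4)
  n <- 20 + rpois(180, 60)
  hp <- rbinom(180, n, plogis(-2.5 + beta * f$x + f$eta_re))
  data.frame(hp = hp, cp = n - hp, x = f$x,
             community = f$comm, species = f$sp)
}

# Strongly modular planted-partition generator settings (donation-rate
# ratio 20).
planted_config <- function(seed) {
  sim_config(n_species = 24, n_modules = 3, n_stigmas_per_species = 10,
             hp_rate_within = 5, hp_rate_between = 0.25, seed = seed)
}

ari <- function(a, b) mclust::adjustedRandIndex(a, b)
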
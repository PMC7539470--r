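test_that("Shannon index hits its closed forms and bounds", {
  expect_equal(shannon_index(rep(5, 4)), log(4))
  expect_equal(shannon_index(c(0, 12, 0)), 0)
  expect_equal(shannon_index(c(10, 20, 70)),
               -sum(c(.1, .2, .7) * log(c(.1, .2, .7))), tolerance = 1e-12)
  expect_error(shannon_index(c(0, 0)), class = "stigmanet_validation_error")
  expect_error(shannon_index(c(-1, 2)), class = "stigmanet_validation_error")
})

test_that("community parameters assemble richness, abundance and diversity", {
  fl <- data.frame(community = rep("C1", 3), species = c("a", "b", "c"),
                   abundance = c(10L, 20L, 70L))
  be <- data.frame(community = "C1", species = c("x", "y"),
                   abundance = c(5L, 5L))
  par <- community_parameters(fl, be,
                              data.frame(community = "C1", modularity = 0.4))
  expect_equal(par$plant_richness, 3)
  expect_equal(par$flower_abundance, 100)
  expect_equal(par$flower_abundance_ln, log(100))
  expect_equal(par$bee_diversity, log(2))
  expect_lte(par$flower_diversity, log(par$plant_richness))
})

test_that("modularity regression on the nine-community reference table", {
  tab <- community_summary_table()
  par <- data.frame(modularity = tab$modularity,
                    plant_richness = tab$n_species_flowering)
  m <- fit_modularity_lm(par, "plant_richness")
  expect_identical(m$transform, "ln1p")
  expect_equal(round(m$adj_r2, 2), 0.76)
  expect_lt(m$p, 0.01)
  # forcing the raw scale gives the untransformed fit
  m_raw <- fit_modularity_lm(par, "plant_richness", transform = "none")
  expect_identical(m_raw$transform, "none")
  expect_gt(m_raw$adj_r2, m$adj_r2)
})

test_that("linear-model mechanics: collinearity, closed-form adjusted R2, errors", {
  par <- data.frame(modularity = c(0.1, 0.2, 0.3, 0.4),
                    x = c(1, 2, 3, 4), const = 1)
  m <- suppressWarnings(fit_modularity_lm(par, "x", transform = "none"))
  expect_equal(m$adj_r2, 1)  # perfect-fit fixture; summary.lm warns
  expect_error(fit_modularity_lm(par, "const"),
               class = "stigmanet_validation_error")
  expect_error(fit_modularity_lm(par[1:2, ], "x"),
               class = "stigmanet_validation_error")

  # hand-computed 3-point fixture: y = (1, 2, 4), x = (1, 2, 3)
  par3 <- data.frame(modularity = c(1, 2, 4), x = c(1, 2, 3))
  m3 <- fit_modularity_lm(par3, "x", transform = "none")
  r2 <- 1 - (1 / 6) / (14 / 3)  # SSE = 1/6, SST = 14/3
  expect_equal(m3$adj_r2, 1 - (1 - r2) * 2 / 1, tolerance = 1e-12)
})

test_that("the OLS slope is unbiased at nine communities", {
  set.seed(12)
  est <- replicate(1000, {
    x <- rnorm(9)
    y <- 0.05 * x + rnorm(9, 0, 0.1)
    coef(lm(y ~ x))[2]
  })
  expect_lt(abs(mean(est) - 0.05), 3 * sd(est) / sqrt(1000))
})

test_that("parameter correlations agree with the shared formula oracle", {
  par <- data.frame(a = c(1, 2, 3, 5), b = c(1, 2, 3, 5) * 2,
                    c = -c(1, 2, 3, 5))
  pc <- parameter_correlations(par, c("a", "b", "c"))
  expect_equal(pc$r["a", "b"], 1)
  expect_equal(pc$r["a", "c"], -1)
  set.seed(8)
  par2 <- data.frame(u = rnorm(10), v = rnorm(10))
  pc2 <- parameter_correlations(par2, c("u", "v"))
  x <- par2$u; y <- par2$v
  expect_equal(pc2$r["u", "v"],
               sum((x - mean(x)) * (y - mean(y))) /
                 sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2)),
               tolerance = 1e-12)
  par2$w <- 1
  expect_warning(parameter_correlations(par2, c("u", "w")), "zero variance")
})

test_that("degenerate mixed-model inputs error or flag cleanly", {
  d <- simulate_beta_glmm(0, 1)
  d$y <- 0.5
  expect_error(fit_degree_glmm(d, "y", "x"),
               class = "stigmanet_validation_error")
  d2 <- simulate_poisson_glmm(0, 1)
  d2$y <- 0L
  expect_error(fit_weighted_degree_glmm(d2, "y", "x"),
               class = "stigmanet_validation_error")
  d3 <- simulate_binomial_glmm(0.5, 1)
  d3$hp <- 0L
  res <- fit_hp_proportion_glmm(d3, "x")
  expect_true(res$boundary)
  expect_true(is.na(res$p))
  d4 <- simulate_binomial_glmm(0.5, 1)
  d4$cp <- -d4$hp  # trials = 0
  expect_error(fit_hp_proportion_glmm(d4, "x"),
               class = "stigmanet_validation_error")
})

test_that("doubling Poisson counts shifts the intercept by about ln 2", {
  d <- simulate_poisson_glmm(0.3, 42)
  m1 <- fit_weighted_degree_glmm(d, "y", "x")
  d2 <- transform(d, y = 2L * y)
  m2 <- fit_weighted_degree_glmm(d2, "y", "x")
  expect_lt(abs((m2$intercept - m1$intercept) - log(2)), 0.05)
  expect_lt(abs(m2$estimate - m1$estimate), 0.05)
})

test_that("without random-effect variance, marginal and conditional R2 coincide", {
  set.seed(5)
  x <- rnorm(200)
  n <- 50 + rpois(200, 30)
  hp <- rbinom(200, n, plogis(-2 + 0.8 * x))
  d <- data.frame(hp = hp, cp = n - hp, x = x,
                  community = rep(sprintf("c%d", 1:4), each = 50),
                  species = rep(sprintf("s%d", 1:20), times = 10))
  m <- fit_hp_proportion_glmm(d, "x")
  expect_lt(m$r2_conditional - m$r2_marginal, 0.03)
  expect_gte(m$r2_conditional, m$r2_marginal)
})

test_that("the likelihood-ratio p-value ignores row order", {
  d <- simulate_binomial_glmm(0.4, 9)
  m1 <- fit_hp_proportion_glmm(d, "x")
  set.seed(1)
  m2 <- fit_hp_proportion_glmm(d[sample.int(nrow(d)), ], "x")
  expect_equal(m1$p, m2$p, tolerance = 1e-6)
  expect_equal(m1$statistic, m2$statistic, tolerance = 1e-6)
})
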
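test_that("configuration validation rejects impossible settings", {
  expect_error(sim_config(n_species = 0), class = "stigmanet_config_error")
  expect_error(sim_config(n_modules = 9, n_species = 4),
               class = "stigmanet_config_error")
  expect_error(sim_config(unknown_fraction = 1.3),
               class = "stigmanet_config_error")
  expect_error(sim_config(hp_rate_within = -1),
               class = "stigmanet_config_error")
  expect_error(generate_trait_individuals(matrix(1, 2, 6), trait_sd = -0.1),
               class = "stigmanet_config_error")
})

test_that("with no between-module donation every identified donor is a module mate", {
  d <- generate_community(sim_config(n_species = 12, n_modules = 3,
                                     hp_rate_within = 3, hp_rate_between = 0,
                                     n_offplot_donors = 0, seed = 11))
  hp <- d$stigmas[!(d$stigmas$donor %in% c("CONSPECIFIC", "UNKNOWN")), ]
  expect_gt(nrow(hp), 0)
  expect_true(all(d$true_modules[hp$donor] == d$true_modules[hp$focal_species]))
})

test_that("zero heterospecific rates give pure-conspecific stigmas and an edgeless network", {
  d <- generate_community(sim_config(n_species = 6, hp_rate_within = 0,
                                     hp_rate_between = 0, seed = 3))
  expect_true(all(d$stigmas$donor == "CONSPECIFIC"))
  net <- build_transfer_network(d$stigmas)
  expect_identical(nrow(net$edges), 0L)
})

test_that("identical configurations reproduce bit-identical datasets", {
  cfg <- sim_config(n_species = 10, n_modules = 2, seed = 99)
  d1 <- generate_community(cfg)
  d2 <- generate_community(cfg)
  expect_identical(d1$stigmas, d2$stigmas)
  expect_identical(d1$traits, d2$traits)
  expect_identical(d1$flower_survey, d2$flower_survey)
  d3 <- generate_community(sim_config(n_species = 10, n_modules = 2,
                                      seed = 100))
  expect_false(identical(d1$stigmas, d3$stigmas))
})

test_that("unknown relabelling conserves heterospecific grain totals exactly", {
  for (s in 1:20) {
    d <- generate_community(sim_config(n_species = 8, n_modules = 2,
                                       unknown_fraction = 0.3, seed = s))
    st <- d$stigmas
    identified <- sum(st$grains[!(st$donor %in% c("CONSPECIFIC", "UNKNOWN"))])
    unknown <- sum(st$grains[st$donor == "UNKNOWN"])
    expect_identical(identified + unknown, as.integer(d$total_hp_generated))
  }
})

test_that("trait individuals collapse to the species mean at zero spread", {
  means <- matrix(c(5, 20, 4, 2, 15, 6), nrow = 3, ncol = 6, byrow = TRUE,
                  dimnames = list(c("a", "b", "c"), NULL))
  tr <- generate_trait_individuals(means, n_individuals = 4, trait_sd = 0,
                                   seed = 1)
  expect_equal(nrow(tr), 12)
  expect_true(all(tr$stamen_length_mm == 5))
  expect_true(all(tr$style_length_mm == 6))
  tr2 <- generate_trait_individuals(means, n_individuals = 4, trait_sd = 0,
                                    seed = 1)
  expect_identical(tr, tr2)
})

test_that("sample trait spread at five individuals matches its sampling distribution", {
  # Oracle: sd of 5 normal draws at sigma = 0.5 lies in [0.1, 1.2] with
  # probability ~0.998 (chi distribution, 4 df); demand >= 95% over 200
  # replicated species sets.
  means <- matrix(10, nrow = 5, ncol = 6,
                  dimnames = list(sprintf("sp%d", 1:5), NULL))
  sds <- unlist(lapply(1:200, function(s) {
    tr <- generate_trait_individuals(means, n_individuals = 5,
                                     trait_sd = 0.5, seed = s)
    tapply(tr$display_size_mm, tr$species, sd)
  }))
  expect_gte(mean(sds >= 0.1 & sds <= 1.2), 0.95)
})

test_that("mean conspecific percentage matches a Monte-Carlo oracle", {
  cfg <- sim_config(n_species = 40, n_modules = 4, n_stigmas_per_species = 10,
                    cp_mean = 100, cp_dispersion = 5, hp_rate_within = 5,
                    hp_rate_between = 0, n_offplot_donors = 0,
                    unknown_fraction = 0, seed = 7)
  d <- generate_community(cfg)
  obs <- stigma_presence_summary(d$stigmas)$pct_cp$mean

  # Independent oracle: resimulate %-CP from the stated distributions
  # (conspecific negative binomial, heterospecific Poisson with
  # abundance-weighted module rates) with 1e5 stigmas.
  set.seed(424242)
  abar <- mean(d$abundances)
  lam <- vapply(names(d$true_modules), function(s) {
    mates <- setdiff(names(d$true_modules)[
      d$true_modules == d$true_modules[s]], s)
    5 * sum(d$abundances[mates]) / abar
  }, numeric(1))
  n_mc <- 1e5
  sp_draw <- sample(names(lam), n_mc, replace = TRUE)
  cp <- rnbinom(n_mc, size = 5, mu = 100)
  hp <- rpois(n_mc, lam[sp_draw])
  keep <- cp + hp > 0
  expected <- mean(100 * cp[keep] / (cp + hp)[keep])
  expect_lt(abs(obs - expected), 2)
})

test_that("heterogeneous abundances induce right-skewed out-degree distributions", {
  skew <- function(x) mean((x - mean(x))^3) / (sd(x)^3 + 1e-12)
  nonneg <- vapply(1:100, function(s) {
    d <- generate_community(sim_config(seed = s))
    net <- build_transfer_network(d$stigmas,
                                  flowering_species = d$flower_survey$species)
    deg <- compute_degrees(net)
    skew(deg$out_degree) >= 0
  }, logical(1))
  expect_gte(mean(nonneg), 0.95)
})
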
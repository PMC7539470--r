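test_that("degrees count incoming and outgoing links and grains", {
  rec <- make_stigma_df(
    list(s1 = c(CONSPECIFIC = 2, A = 5), s2 = c(CONSPECIFIC = 1, C = 1)),
    list(s1 = "B", s2 = "B"))
  deg <- compute_degrees(build_transfer_network(rec))
  b <- deg[deg$species == "B", ]
  expect_equal(b$in_degree, 2L)
  expect_equal(b$w_in, 6L)
  expect_equal(b$out_degree, 0L)
  expect_equal(deg$out_degree[deg$species == "A"], 1L)
})

test_that("an edgeless network yields an all-zero degree table", {
  rec <- make_stigma_df(list(s1 = c(CONSPECIFIC = 5)), list(s1 = "A"))
  deg <- compute_degrees(build_transfer_network(rec))
  expect_true(all(deg$in_degree == 0) && all(deg$out_degree == 0))
  expect_true(all(deg$hub_class == "neutral"))
})

test_that("degrees match a naive per-edge counting oracle on random networks", {
  for (s in 1:40) {
    d <- generate_community(sim_config(n_species = 8, n_modules = 2,
                                       n_stigmas_per_species = 4, seed = s))
    net <- build_transfer_network(d$stigmas)
    deg <- compute_degrees(net)
    for (sp in deg$species) {
      expect_identical(deg$in_degree[deg$species == sp],
                       sum(net$edges$receptor == sp))
      expect_identical(deg$out_degree[deg$species == sp],
                       sum(net$edges$donor == sp))
      expect_identical(deg$w_in[deg$species == sp],
                       as.integer(sum(net$edges$weight[
                         net$edges$receptor == sp])))
    }
    # degree-sum identities
    expect_equal(sum(deg$in_degree), nrow(net$edges))
    expect_equal(sum(deg$out_degree), nrow(net$edges))
    expect_equal(sum(deg$w_in), sum(net$edges$weight))
    expect_equal(sum(deg$w_out), sum(net$edges$weight))
  }
})

test_that("hub classification follows the strict-inequality rule", {
  expect_identical(classify_hub(2, 5), "hub-donor")
  expect_identical(classify_hub(5, 2), "hub-receptor")
  expect_identical(classify_hub(0, 0), "neutral")
  # one donor, two receptors, one neutral -> 25 / 50 / 25
  tab <- data.frame(species = letters[1:4], on_plot = TRUE,
                    in_degree = c(1L, 3L, 2L, 2L),
                    out_degree = c(2L, 1L, 1L, 2L))
  tab$hub_class <- classify_hub(tab$in_degree, tab$out_degree)
  pct <- donor_receptor_percentages(tab)
  expect_equal(unname(pct), c(25, 50, 25))
})

test_that("donor/receptor percentages honour the denominator choice", {
  # 17 sampled species, one unlinked: 7 donors, 9 receptors of 16 linked
  tab <- data.frame(
    species = sprintf("s%02d", 1:17), on_plot = TRUE,
    in_degree = c(rep(1L, 9), rep(0L, 7), 0L),
    out_degree = c(rep(0L, 9), rep(2L, 7), 0L))
  tab$hub_class <- classify_hub(tab$in_degree, tab$out_degree)
  pct <- donor_receptor_percentages(tab, "linked_species")
  expect_equal(unname(pct), c(43.75, 56.25, 0))
  pct_all <- donor_receptor_percentages(tab, "all_sampled")
  expect_equal(unname(pct_all), c(7, 9, 1) / 17 * 100)
  # rescaling between denominators is the count ratio
  expect_equal(pct_all[1:2] * 17 / 16, pct[1:2], ignore_attr = TRUE)

  single <- data.frame(species = "a", on_plot = TRUE, in_degree = 1L,
                       out_degree = 1L, hub_class = "neutral")
  expect_equal(unname(donor_receptor_percentages(single)), c(0, 0, 100))
  none <- data.frame(species = "a", on_plot = TRUE, in_degree = 0L,
                     out_degree = 0L, hub_class = "neutral")
  expect_error(donor_receptor_percentages(none, "linked_species"),
               class = "stigmanet_validation_error")
})

test_that("standardized degrees follow the closed form and stay in (0, 1)", {
  expect_equal(standardize_degree(0, 10, 10), 0.05)
  expect_equal(standardize_degree(10, 10, 10), 0.95)
  vals <- standardize_degree(0:10, 10, 10)
  expect_true(all(diff(vals) > 0))
  expect_error(standardize_degree(11, 10, 10),
               class = "stigmanet_validation_error")
  expect_error(standardize_degree(1, 10, 1),
               class = "stigmanet_validation_error")
})

test_that("in/out-degree correlation matches the textbook formula", {
  tab <- data.frame(species = letters[1:5], on_plot = TRUE,
                    in_degree = 0:4, out_degree = 0:4)
  tab$hub_class <- classify_hub(tab$in_degree, tab$out_degree)
  expect_equal(inout_correlation(tab)$r, 1)

  tab$out_degree <- 4:0
  expect_equal(inout_correlation(tab)$r, -1)

  set.seed(31)
  tab <- data.frame(species = sprintf("s%d", 1:20), on_plot = TRUE,
                    in_degree = rpois(20, 3), out_degree = rpois(20, 3))
  tab$hub_class <- classify_hub(tab$in_degree, tab$out_degree)
  r <- inout_correlation(tab)$r
  x <- tab$in_degree; y <- tab$out_degree
  r_oracle <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(r, r_oracle, tolerance = 1e-12)

  tab$out_degree <- rep(2L, 20)
  expect_error(inout_correlation(tab), class = "stigmanet_validation_error")
})
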
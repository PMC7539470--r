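#' Configuration for a synthetic pollen-transfer community
#'
#' Bundles and validates the parameters of [generate_community()]. The
#' defaults describe a mid-sized temperate grassland community: roughly a
#' dozen insect-pollinated species whose stigmas carry about one hundred
#' conspecific grains and a handful of heterospecific grains each, with
#' strongly right-skewed flower abundances and a modest fraction of
#' unidentifiable heterospecific pollen.
#'
#' @param n_species Number of plant species sampled on the plots (receivers).
#' @param n_modules Number of planted pollen-sharing modules; species are
#'   assigned to modules in balanced round-robin order.
#' @param n_stigmas_per_species Stigmas collected per species.
#' @param trait_centroid_separation Distance between neighbouring module
#'   trait centroids, in units of `trait_sd` (per trait).
#' @param trait_sd Within-module standard deviation of species trait means,
#'   and of individuals around their species mean, in mm.
#' @param cp_mean Mean conspecific grains per stigma.
#' @param cp_dispersion Negative-binomial size (dispersion) of the
#'   conspecific load; small values give strongly overdispersed loads.
#' @param hp_rate_within Expected heterospecific grains per stigma donated
#'   by each same-module species of average flower abundance.
#' @param hp_rate_between The same expectation for donors outside the
#'   receiver's module (including off-plot donors).
#' @param n_offplot_donors Donor-only taxa flowering outside the survey
#'   plots; they donate pollen but are never sampled as receivers.
#' @param unknown_fraction Probability that an individual heterospecific
#'   grain cannot be identified and is relabelled `"UNKNOWN"`.
#' @param abundance_lognorm_mu,abundance_lognorm_sigma Meanlog and sdlog of
#'   the log-normal flower-abundance distribution (flowers per transect).
#' @param seed Integer seed; identical configurations yield bit-identical
#'   datasets.
#' @param community Community label written into every generated record.
#'
#' @return An object of class `sim_config` (a validated list).
#' @seealso [generate_community()]
#' @export
sim_config <- function(n_species = 16, n_modules = 3,
                       n_stigmas_per_species = 10,
                       trait_centroid_separation = 3, trait_sd = 0.5,
                       cp_mean = 100, cp_dispersion = 0.6,
                       hp_rate_within = 0.3, hp_rate_between = 0.03,
                       n_offplot_donors = 3, unknown_fraction = 0.10,
                       abundance_lognorm_mu = 4, abundance_lognorm_sigma = 2,
                       seed = 1L, community = "synthetic") {
  cfg <- list(
    n_species = n_species, n_modules = n_modules,
    n_stigmas_per_species = n_stigmas_per_species,
    trait_centroid_separation = trait_centroid_separation,
    trait_sd = trait_sd, cp_mean = cp_mean, cp_dispersion = cp_dispersion,
    hp_rate_within = hp_rate_within, hp_rate_between = hp_rate_between,
    n_offplot_donors = n_offplot_donors, unknown_fraction = unknown_fraction,
    abundance_lognorm_mu = abundance_lognorm_mu,
    abundance_lognorm_sigma = abundance_lognorm_sigma,
    seed = as.integer(seed), community = community
  )
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  chk <- function(ok, msg) if (!isTRUE(ok)) stop(config_error(msg))
  chk(cfg$n_species >= 1, "n_species must be >= 1")
  chk(cfg$n_modules >= 1 && cfg$n_modules <= cfg$n_species,
      "n_modules must be in [1, n_species]")
  chk(cfg$n_stigmas_per_species >= 1, "n_stigmas_per_species must be >= 1")
  chk(cfg$trait_sd >= 0, "trait_sd must be >= 0")
  chk(cfg$trait_centroid_separation >= 0,
      "trait_centroid_separation must be >= 0")
  chk(cfg$cp_mean >= 0, "cp_mean must be >= 0")
  chk(cfg$cp_dispersion > 0, "cp_dispersion must be > 0")
  chk(cfg$hp_rate_within >= 0 && cfg$hp_rate_between >= 0,
      "heterospecific donation rates must be >= 0")
  chk(cfg$n_offplot_donors >= 0, "n_offplot_donors must be >= 0")
  chk(cfg$unknown_fraction >= 0 && cfg$unknown_fraction <= 1,
      "unknown_fraction must lie in [0, 1]")
  chk(is.finite(cfg$seed), "seed must be a finite integer")
  invisible(cfg)
}

config_error <- function(msg) {
  errorCondition(paste0("invalid configuration: ", msg),
                 class = c("stigmanet_config_error", "error"))
}

# Deterministic per-species sub-seed, kept below 2^31.
derive_seed <- function(seed, i) {
  as.integer((as.numeric(seed) %% 2147483647 + 7919 * i) %% 2147483647)
}

# Baseline trait means (mm) for module 1: stamen length, inflorescence
# diameter, nectar tube depth, nectar tube width, display size, style length.
.TRAIT_BASE <- c(5, 20, 4, 2, 15, 6)

#' Generate a synthetic community of stigmatic pollen loads
#'
#' Simulates one community under a planted-module model. Species are split
#' into `n_modules` pollen-sharing modules; floral trait means sit on
#' module-specific centroids; flower abundances are log-normal. Each stigma
#' carries a negative-binomial conspecific load, plus independent Poisson
#' heterospecific contributions from every other taxon with expectation
#' `rate * abundance / mean(abundance)`, where `rate` is
#' `hp_rate_within` for same-module donors and `hp_rate_between` otherwise.
#' Each heterospecific grain is then independently relabelled `"UNKNOWN"`
#' with probability `unknown_fraction`, so identified + unknown grains
#' always equal the grains generated. Off-plot donors donate pollen (at the
#' between-module rate) but are never sampled as receivers, giving the
#' characteristic in-degree-only nodes of field pollen-transfer networks.
#'
#' @param config A [sim_config()].
#' @return An object of class `synthetic_community`: a list with elements
#'   `stigmas` (long stigma table: `stigma_id`, `focal_species`,
#'   `community`, `plot`, `donor`, `grains`), `traits` (per-individual
#'   trait table), `flower_survey` and `bee_survey` (abundance tables),
#'   `true_modules` (named integer vector over sampled species),
#'   `species_means` (matrix of species trait means),
#'   `total_hp_generated` (grand total of heterospecific grains drawn,
#'   before unknown relabelling) and `config`.
#' @examples
#' d <- generate_community(sim_config(n_species = 8, n_modules = 2, seed = 42))
#' head(d$stigmas)
#' d$true_modules
#' @export
generate_community <- function(config) {
  if (!inherits(config, "sim_config")) config <- do.call(sim_config, config)
  validate_sim_config(config)
  cfg <- config

  species <- sprintf("sp%02d", seq_len(cfg$n_species))
  offplot <- if (cfg$n_offplot_donors > 0)
    sprintf("offplot%02d", seq_len(cfg$n_offplot_donors)) else character(0)
  modules <- setNames(rep_len(seq_len(cfg$n_modules), cfg$n_species), species)

  set.seed(cfg$seed)
  abund_all <- pmax(1, round(rlnorm(cfg$n_species + cfg$n_offplot_donors,
                                    cfg$abundance_lognorm_mu,
                                    cfg$abundance_lognorm_sigma)))
  names(abund_all) <- c(species, offplot)
  abar <- mean(abund_all)

  # Species trait means: module centroids on a regular grid, species
  # jittered around their centroid by trait_sd.
  centroids <- outer(seq_len(cfg$n_modules) - 1,
                     rep(cfg$trait_centroid_separation * cfg$trait_sd, 6)) +
    matrix(.TRAIT_BASE, cfg$n_modules, 6, byrow = TRUE)
  species_means <- centroids[modules, , drop = FALSE] +
    matrix(rnorm(cfg$n_species * 6, 0, cfg$trait_sd), cfg$n_species, 6)
  species_means <- pmax(species_means, 0)
  dimnames(species_means) <- list(species, .TRAITS)

  traits <- generate_trait_individuals(species_means, n_individuals = 5,
                                       trait_sd = cfg$trait_sd,
                                       seed = derive_seed(cfg$seed, 0))

  rows <- vector("list", cfg$n_species)
  total_hp_generated <- 0L
  donors_all <- c(species, offplot)
  for (i in seq_len(cfg$n_species)) {
    s <- species[i]
    set.seed(derive_seed(cfg$seed, i))
    others <- setdiff(donors_all, s)
    same_mod <- vapply(others, function(d)
      d %in% species && modules[d] == modules[s], logical(1))
    rate <- ifelse(same_mod, cfg$hp_rate_within, cfg$hp_rate_between)
    lambda <- rate * abund_all[others] / abar

    n_st <- cfg$n_stigmas_per_species
    cp <- rnbinom(n_st, size = cfg$cp_dispersion, mu = cfg$cp_mean)
    sp_rows <- vector("list", n_st)
    for (k in seq_len(n_st)) {
      hp <- rpois(length(others), lambda)
      total_hp_generated <- total_hp_generated + sum(hp)
      unk <- rbinom(length(others), hp, cfg$unknown_fraction)
      ident <- hp - unk
      keep <- ident > 0
      sid <- sprintf("%s_st%03d", s, k)
      sp_rows[[k]] <- data.frame(
        stigma_id = sid,
        focal_species = s,
        community = cfg$community,
        plot = sprintf("plot%d", (k - 1L) %% 3L + 1L),
        donor = c(.CONSPECIFIC, others[keep],
                  if (sum(unk) > 0) .UNKNOWN),
        grains = as.integer(c(cp[k], ident[keep],
                              if (sum(unk) > 0) sum(unk))),
        stringsAsFactors = FALSE
      )
    }
    rows[[i]] <- do.call(rbind, sp_rows)
  }
  stigmas <- do.call(rbind, rows)
  rownames(stigmas) <- NULL

  flower_survey <- data.frame(community = cfg$community, species = species,
                              abundance = as.integer(abund_all[species]),
                              stringsAsFactors = FALSE)

  set.seed(derive_seed(cfg$seed, cfg$n_species + 1L))
  n_bee <- max(3L, round(0.75 * cfg$n_species))
  bee_survey <- data.frame(
    community = cfg$community,
    species = sprintf("bee%02d", seq_len(n_bee)),
    abundance = as.integer(pmax(1, round(rlnorm(n_bee, 2.5, 1)))),
    stringsAsFactors = FALSE
  )

  structure(list(
    stigmas = stigmas, traits = traits,
    flower_survey = flower_survey, bee_survey = bee_survey,
    true_modules = modules, species_means = species_means,
    offplot_donors = offplot,
    abundances = abund_all,
    total_hp_generated = total_hp_generated,
    config = cfg
  ), class = "synthetic_community")
}

#' @export
print.synthetic_community <- function(x, ...) {
  cat("Synthetic pollen-transfer community:", x$config$community, "\n")
  cat(sprintf("  %d species in %d planted modules, %d off-plot donors\n",
              x$config$n_species, x$config$n_modules,
              length(x$offplot_donors)))
  cat(sprintf("  %d stigmas, %d heterospecific grains generated\n",
              length(unique(x$stigmas$stigma_id)), x$total_hp_generated))
  invisible(x)
}

#' Draw per-individual floral trait measurements
#'
#' Simulates repeated trait measurements on individual plants: each
#' individual's six trait values are normal around its species mean with
#' standard deviation `trait_sd`, and negative draws are truncated to zero
#' (lengths and widths cannot be negative; nectar-tube fields are zero for
#' species without a nectar tube).
#'
#' @param species_means Numeric matrix of species trait means: one row per
#'   species (rownames are species), columns the six floral traits in mm.
#' @param n_individuals Individuals measured per species (field protocols
#'   typically measure five).
#' @param trait_sd Within-species standard deviation, mm.
#' @param seed Integer seed.
#' @return Data frame with columns `species`, `individual` and the six
#'   trait columns.
#' @export
generate_trait_individuals <- function(species_means, n_individuals = 5,
                                       trait_sd, seed = 1L) {
  if (trait_sd < 0) stop(config_error("trait_sd must be >= 0"))
  if (n_individuals < 1) stop(config_error("n_individuals must be >= 1"))
  species_means <- as.matrix(species_means)
  if (is.null(rownames(species_means)))
    rownames(species_means) <- sprintf("sp%02d", seq_len(nrow(species_means)))
  if (ncol(species_means) != length(.TRAITS))
    stop(config_error("species_means must have six trait columns"))
  set.seed(seed)
  n_sp <- nrow(species_means)
  out <- species_means[rep(seq_len(n_sp), each = n_individuals), ,
                       drop = FALSE] +
    matrix(rnorm(n_sp * n_individuals * 6, 0, trait_sd),
           n_sp * n_individuals, 6)
  out <- pmax(out, 0)
  df <- data.frame(
    species = rep(rownames(species_means), each = n_individuals),
    individual = rep(seq_len(n_individuals), times = n_sp),
    out, stringsAsFactors = FALSE
  )
  names(df)[-(1:2)] <- .TRAITS
  rownames(df) <- NULL
  df
}

#' Write a synthetic community to disk
#'
#' Writes the stigma, trait, flower-survey and bee-survey tables as CSV in
#' the dialects read by the package's readers, plus a ground-truth JSON
#' (planted modules and generating parameters).
#'
#' @param dataset A `synthetic_community`.
#' @param dir Output directory (created if missing).
#' @return Invisibly, the named vector of file paths written.
#' @export
write_community <- function(dataset, dir) {
  stopifnot(inherits(dataset, "synthetic_community"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- c(
    stigmas = file.path(dir, "stigmas.csv"),
    traits = file.path(dir, "traits.csv"),
    flower_survey = file.path(dir, "flower_survey.csv"),
    bee_survey = file.path(dir, "bee_survey.csv"),
    truth = file.path(dir, "ground_truth.json")
  )
  write_stigma_table(dataset$stigmas, paths[["stigmas"]])
  write_trait_table(dataset$traits, paths[["traits"]])
  write_survey_table(dataset$flower_survey, paths[["flower_survey"]])
  write_survey_table(dataset$bee_survey, paths[["bee_survey"]])
  truth <- list(
    true_modules = as.list(dataset$true_modules),
    offplot_donors = dataset$offplot_donors,
    total_hp_generated = dataset$total_hp_generated,
    config = unclass(dataset$config)
  )
  jsonlite::write_json(truth, paths[["truth"]], auto_unbox = TRUE,
                       digits = I(17), pretty = TRUE)
  invisible(paths)
}
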
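# End-to-end orchestration: simulate or read communities, build networks,
# compute degrees, detect modules by consensus, fit the community-level
# models and the trait random forests, and write every artefact to disk.

#' Configuration for [run_pipeline()]
#'
#' Either `sim_configs` (a list of [sim_config()]s, one per community) or
#' `inputs` (a list of per-community paths: `stigmas`, `traits`,
#' `flower_survey`, `bee_survey` CSVs) must be given.
#'
#' @param sim_configs List of [sim_config()]s to simulate communities.
#' @param inputs List of named path lists to read communities from disk.
#' @param out_dir Output directory.
#' @param resolution Louvain resolution (default 0.7).
#' @param n_runs Louvain runs per network for consensus (default 25).
#' @param threshold Consensus acceptance threshold (default 0.8).
#' @param base_seed Base seed for all stochastic stages.
#' @param denominator Hub-percentage denominator (see
#'   [donor_receptor_percentages()]).
#' @param include_offplot Keep off-plot donors in module detection.
#' @param n_trees,mtry Random-forest settings (defaults 10000 and 2).
#' @param do_models,do_forest Toggle the mixed-model and random-forest
#'   stages.
#' @return A validated list of class `pipeline_config`.
#' @export
pipeline_config <- function(sim_configs = NULL, inputs = NULL,
                            out_dir = tempfile("stigmanet_run_"),
                            resolution = 0.7, n_runs = 25, threshold = 0.8,
                            base_seed = 0L,
                            denominator = "linked_species",
                            include_offplot = TRUE,
                            n_trees = 10000, mtry = 2,
                            do_models = TRUE, do_forest = TRUE) {
  if (is.null(sim_configs) && is.null(inputs))
    stop(config_error("either sim_configs or inputs must be supplied"))
  if (threshold <= 0 || threshold > 1)
    stop(config_error("threshold must lie in (0, 1]"))
  if (n_runs < 1) stop(config_error("n_runs must be >= 1"))
  structure(list(sim_configs = sim_configs, inputs = inputs,
                 out_dir = out_dir, resolution = resolution,
                 n_runs = n_runs, threshold = threshold,
                 base_seed = as.integer(base_seed),
                 denominator = denominator,
                 include_offplot = include_offplot,
                 n_trees = n_trees, mtry = mtry,
                 do_models = do_models, do_forest = do_forest),
            class = "pipeline_config")
}

pipeline_stage <- function(stage, community, expr) {
  tryCatch(expr, error = function(e)
    stop(errorCondition(
      sprintf("pipeline stage '%s' failed for community '%s': %s",
              stage, community, conditionMessage(e)),
      class = c("stigmanet_pipeline_error", "error"))))
}

#' Run the full pollen-transfer analysis pipeline
#'
#' For every community: build the transfer network, write it as GraphML
#' and edge-list CSV, compute descriptive totals, the degree table and
#' hub percentages, and the Louvain consensus partition. Across
#' communities: study-level totals, the community-parameter table,
#' linear models of modularity on each community parameter, mixed models
#' of (standardized and weighted) degrees and per-stigma heterospecific
#' proportions on each floral trait and on ln flower abundance, and a
#' per-community random forest of module affiliation. Every stochastic
#' stage is seeded from `config$base_seed`, so a rerun with the same
#' configuration reproduces the outputs byte for byte.
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, the report bundle (list with `communities`,
#'   `totals`, `study_totals`, `parameters`, `modularity_lms`, `glmms`,
#'   `forest`, `settings`); the same content is written under
#'   `config$out_dir`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)

  datasets <- if (!is.null(config$sim_configs)) {
    lapply(config$sim_configs, generate_community)
  } else {
    lapply(config$inputs, function(p) {
      list(stigmas = read_stigma_table(p$stigmas),
           traits = read_trait_table(p$traits),
           flower_survey = aggregate_survey(read_survey_table(p$flower_survey)),
           bee_survey = aggregate_survey(read_survey_table(p$bee_survey)))
    })
  }

  per_comm <- list(); totals_rows <- list()
  for (d in datasets) {
    comm <- unique(d$stigmas$community)[1]
    odir <- file.path(config$out_dir, gsub("[^A-Za-z0-9_-]", "_", comm))
    dir.create(odir, showWarnings = FALSE)

    net <- pipeline_stage("network", comm,
      build_transfer_network(d$stigmas,
                             flowering_species = d$flower_survey$species,
                             community = comm))
    write_network(net, file.path(odir, "network.graphml"), "graphml")
    write_network(net, file.path(odir, "network_edges.csv"), "edgelist_csv")

    deg <- pipeline_stage("degrees", comm, compute_degrees(net))
    pct <- donor_receptor_percentages(deg, config$denominator)
    write.csv(deg, file.path(odir, "degrees.csv"), row.names = FALSE)

    cons <- if (nrow(net$edges)) pipeline_stage("modules", comm,
      consensus_partitions(net, n_runs = config$n_runs,
                           resolution = config$resolution,
                           base_seed = config$base_seed,
                           threshold = config$threshold,
                           include_offplot = config$include_offplot))
      else NULL
    if (!is.null(cons))
      write_partition(cons, file.path(odir, "consensus.json"))
    top <- if (!is.null(cons)) {
      if (!is.null(cons$accepted)) cons$accepted else cons$partitions[[1]]
    } else NULL

    totals_rows[[comm]] <- cbind(net$totals,
                                 as.data.frame(as.list(pct)),
                                 modularity = if (is.null(top)) NA_real_
                                 else top$Q)
    per_comm[[comm]] <- list(dataset = d, network = net, degrees = deg,
                             consensus = cons, top_partition = top)
  }
  totals <- do.call(rbind, totals_rows)
  rownames(totals) <- NULL
  write.csv(totals, file.path(config$out_dir, "community_totals.csv"),
            row.names = FALSE)
  study_totals <- sum_community_totals(totals)

  params <- mod_lms <- glmms <- forest <- NULL
  if (length(per_comm) >= 3) {
    flowers <- do.call(rbind, lapply(datasets, `[[`, "flower_survey"))
    bees <- do.call(rbind, lapply(datasets, `[[`, "bee_survey"))
    params <- community_parameters(
      flowers, bees,
      data.frame(community = totals$community,
                 modularity = totals$modularity))
    write.csv(params, file.path(config$out_dir,
                                "community_parameters.csv"),
              row.names = FALSE)
    if (config$do_models) {
      preds <- c("bee_richness", "bee_abundance", "bee_diversity",
                 "plant_richness", "flower_abundance_ln",
                 "flower_diversity")
      mod_lms <- lapply(setNames(preds, preds), function(p)
        fit_modularity_lm(params, p))
    }
  }

  if (config$do_models) {
    md <- assemble_degree_model_data(per_comm)
    glmms <- list()
    for (p in c(.TRAITS, "flower_abundance_ln")) {
      glmms[[paste0("std_in~", p)]] <-
        fit_degree_glmm(md$degrees, "std_in", p)
      glmms[[paste0("w_in~", p)]] <-
        fit_weighted_degree_glmm(md$degrees, "w_in", p)
    }
    glmms[["hp_prop~flower_abundance_ln"]] <-
      fit_hp_proportion_glmm(md$stigmas, "flower_abundance_ln")
    summ <- data.frame(
      model = names(glmms),
      family = vapply(glmms, `[[`, "", "family"),
      estimate = vapply(glmms, function(m) m$estimate %||% NA_real_, 0),
      statistic = vapply(glmms, function(m) m$statistic %||% NA_real_, 0),
      p = vapply(glmms, function(m) m$p %||% NA_real_, 0),
      stringsAsFactors = FALSE
    )
    write.csv(summ, file.path(config$out_dir, "model_summaries.csv"),
              row.names = FALSE)
  }

  if (config$do_forest) {
    reports <- list()
    for (comm in names(per_comm)) {
      pc <- per_comm[[comm]]
      if (is.null(pc$top_partition)) next
      memb <- pc$top_partition$membership
      rep_try <- tryCatch(
        fit_module_classifier(pc$dataset$traits, memb,
                              n_trees = config$n_trees, mtry = config$mtry,
                              seed = config$base_seed + 1L,
                              community = comm),
        stigmanet_no_classification = function(e) NULL)
      if (!is.null(rep_try)) reports[[comm]] <- rep_try
    }
    forest <- if (length(reports))
      c(summarize_importance(reports), list(reports = reports)) else NULL
    if (!is.null(forest)) {
      imp <- do.call(cbind, lapply(reports, function(r)
        r$importance[.TRAITS]))
      imp_df <- data.frame(trait = .TRAITS, imp, check.names = FALSE)
      imp_df <- rbind(imp_df,
                      c(trait = "OOB_error_pct",
                        as.list(vapply(reports, `[[`, 0, "oob"))))
      write.csv(imp_df, file.path(config$out_dir, "trait_importance.csv"),
                row.names = FALSE)
    }
  }

  settings <- unclass(config[c("resolution", "n_runs", "threshold",
                               "base_seed", "denominator",
                               "include_offplot", "n_trees", "mtry")])
  bundle <- list(communities = per_comm, totals = totals,
                 study_totals = study_totals, parameters = params,
                 modularity_lms = mod_lms, glmms = glmms, forest = forest,
                 settings = settings)
  summary_json <- list(
    settings = settings,
    study_totals = as.list(study_totals),
    communities = lapply(per_comm, function(pc) list(
      n_links = nrow(pc$network$edges),
      modularity = if (is.null(pc$top_partition)) NULL
      else pc$top_partition$Q,
      n_modules = if (is.null(pc$top_partition)) NULL
      else length(unique(pc$top_partition$membership)),
      co_optimal = if (is.null(pc$consensus)) NULL
      else pc$consensus$co_optimal))
  )
  jsonlite::write_json(summary_json,
                       file.path(config$out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = I(17), pretty = TRUE)
  invisible(bundle)
}

# Species-level model data pooled over communities: standardized and
# weighted degrees joined with species mean traits and ln flower
# abundance, plus per-stigma hp/cp counts for the proportion model.
assemble_degree_model_data <- function(per_comm) {
  deg_rows <- list(); stig_rows <- list()
  n_obs_total <- sum(vapply(per_comm, function(pc)
    sum(pc$degrees$on_plot), 0L))
  for (comm in names(per_comm)) {
    pc <- per_comm[[comm]]
    d <- pc$dataset
    deg <- pc$degrees[pc$degrees$on_plot, , drop = FALSE]
    deg$std_in <- standardize_degree(deg$in_degree,
                                     pc$network$s_flowering, n_obs_total)
    deg$std_out <- standardize_degree(deg$out_degree,
                                      pc$network$s_flowering, n_obs_total)
    sp_means <- aggregate(d$traits[.TRAITS],
                          by = list(species = d$traits$species), FUN = mean)
    ab <- setNames(d$flower_survey$abundance, d$flower_survey$species)
    deg$community <- comm
    deg <- merge(deg, sp_means, by = "species", all.x = TRUE)
    deg$flower_abundance_ln <- log(pmax(1, ab[deg$species]))
    deg_rows[[comm]] <- deg

    st <- d$stigmas
    ids <- unique(st$stigma_id)
    cp <- vapply(ids, function(id)
      sum(st$grains[st$stigma_id == id & st$donor == .CONSPECIFIC]), 0)
    hp <- vapply(ids, function(id)
      sum(st$grains[st$stigma_id == id & st$donor != .CONSPECIFIC]), 0)
    sp <- st$focal_species[match(ids, st$stigma_id)]
    keep <- cp + hp >= 1
    stig_rows[[comm]] <- data.frame(
      stigma_id = ids[keep], species = sp[keep], community = comm,
      hp = as.integer(hp[keep]), cp = as.integer(cp[keep]),
      flower_abundance_ln = log(pmax(1, ab[sp[keep]])),
      stringsAsFactors = FALSE)
  }
  degrees <- do.call(rbind, deg_rows)
  degrees <- degrees[stats::complete.cases(
    degrees[c(.TRAITS, "flower_abundance_ln")]), , drop = FALSE]
  rownames(degrees) <- NULL
  stigmas <- do.call(rbind, stig_rows)
  rownames(stigmas) <- NULL
  list(degrees = degrees, stigmas = stigmas)
}
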
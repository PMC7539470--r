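# Random-forest classification of module affiliation from floral traits.
# The classification unit is the measured plant individual (3-5 per
# species), each inheriting its species' module label, so within-species
# trait variation enters the out-of-bag error.

#' Random-forest classification of module affiliation from floral traits
#'
#' Trains a random forest to predict each trait individual's module
#' (inherited from its species) from the six floral traits, and reports
#' the out-of-bag misclassification rate and per-trait importance. The
#' default importance metric is unscaled permutation mean decrease in
#' accuracy; mean decrease in Gini impurity is available as an
#' alternative.
#'
#' @param traits Trait table (see [read_trait_table()]).
#' @param modules Named vector mapping species to module labels (e.g. the
#'   accepted consensus membership). Species absent from `modules` are
#'   dropped.
#' @param n_trees Trees in the forest (default 10000).
#' @param mtry Variables tried at each split (default 2).
#' @param seed Integer seed for the forest's bootstrap randomness.
#' @param importance `"permutation"` (default) or `"gini"`.
#' @param community Optional community label carried into the report.
#' @return An object of class `importance_report`: `community`, `oob`
#'   (OOB error, percent), `importance` (named vector over the six
#'   traits, sorted decreasing), `n_trees`, `mtry`, `seed`,
#'   `n_individuals`, `n_modules`.
#' @export
fit_module_classifier <- function(traits, modules, n_trees = 10000,
                                  mtry = 2, seed = 1L,
                                  importance = c("permutation", "gini"),
                                  community = NA_character_) {
  importance <- match.arg(importance)
  validate_trait_table(traits)
  traits <- traits[traits$species %in% names(modules), , drop = FALSE]
  if (nrow(traits) == 0)
    stop(validation_error("no trait individuals with a module label"))
  y <- factor(unname(modules[traits$species]))
  if (nlevels(droplevels(y)) < 2)
    stop(errorCondition(
      "fewer than two modules present; module classification undefined",
      class = c("stigmanet_no_classification", "stigmanet_validation_error",
                "error")))
  x <- traits[.TRAITS]
  set.seed(as.integer(seed))
  fit <- randomForest::randomForest(x = x, y = droplevels(y),
                                    ntree = n_trees, mtry = mtry,
                                    importance = TRUE)
  oob <- 100 * unname(fit$err.rate[n_trees, "OOB"])
  imp_mat <- randomForest::importance(fit,
                                      type = if (importance == "permutation")
                                        1 else 2,
                                      scale = FALSE)
  imp <- sort(setNames(imp_mat[, 1], rownames(imp_mat)), decreasing = TRUE)
  structure(list(
    community = community, oob = oob, importance = imp,
    n_trees = n_trees, mtry = mtry, seed = as.integer(seed),
    n_individuals = nrow(traits), n_modules = nlevels(droplevels(y)),
    metric = importance
  ), class = "importance_report")
}

#' @export
print.importance_report <- function(x, ...) {
  cat(sprintf("Module classification (%s): OOB error %.2f%%\n",
              if (is.na(x$community)) "random forest" else x$community,
              x$oob))
  cat(sprintf("  %d individuals, %d modules, ntree = %d, mtry = %d\n",
              x$n_individuals, x$n_modules, x$n_trees, x$mtry))
  top <- names(x$importance)[seq_len(min(3, length(x$importance)))]
  cat("  most important traits:", paste(top, collapse = ", "), "\n")
  invisible(x)
}

#' Summarize importance reports across communities
#'
#' Arithmetic mean and standard deviation of the OOB error, and for each
#' trait the number of communities in which it ranks among the two most
#' important.
#'
#' @param reports List of [importance_report][fit_module_classifier]s
#'   (at least one).
#' @return List with `oob_mean`, `oob_sd`, `top2_counts` (named integer
#'   vector over the six traits), `n_communities`.
#' @export
summarize_importance <- function(reports) {
  if (inherits(reports, "importance_report")) reports <- list(reports)
  if (!length(reports))
    stop(validation_error("need at least one importance report"))
  oob <- vapply(reports, `[[`, numeric(1), "oob")
  top2 <- setNames(integer(length(.TRAITS)), .TRAITS)
  for (r in reports) {
    nm <- names(r$importance)[seq_len(min(2, length(r$importance)))]
    top2[nm] <- top2[nm] + 1L
  }
  list(oob_mean = mean(oob),
       oob_sd = if (length(oob) > 1) sd(oob) else 0,
       top2_counts = top2,
       n_communities = length(reports))
}
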
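# Community-level statistics: diversity indices, linear models of
# modularity on community parameters, and the mixed models linking
# (standardized / weighted) degrees and per-stigma heterospecific
# proportions to floral traits and flower abundance.

#' Shannon-Wiener diversity index
#'
#' `H' = -sum(p_i * log(p_i))` over classes with positive abundance,
#' `p_i = a_i / sum(a)` (natural logarithm). Computed via
#' [vegan::diversity()].
#'
#' @param abundances Nonnegative abundance vector with at least one
#'   positive entry.
#' @return The index `H'` (0 for a single class, `log(k)` for `k` equal
#'   classes).
#' @export
shannon_index <- function(abundances) {
  if (any(abundances < 0) || any(!is.finite(abundances)))
    stop(validation_error("abundances must be finite and nonnegative"))
  if (sum(abundances) == 0)
    stop(validation_error("all abundances are zero; diversity undefined"))
  unname(vegan::diversity(abundances, index = "shannon"))
}

#' Assemble the community-parameter table
#'
#' One row per community: bee richness, abundance and Shannon diversity;
#' plant (flowering-species) richness; flower abundance (raw and
#' ln-transformed) and Shannon diversity; and the network modularity.
#'
#' @param flower_survey,bee_survey Pooled survey tables (`community`,
#'   `species`, `abundance`).
#' @param modularity Data frame with columns `community` and `modularity`.
#' @return Data frame of class `community_parameters`.
#' @export
community_parameters <- function(flower_survey, bee_survey, modularity) {
  validate_survey_table(flower_survey)
  validate_survey_table(bee_survey)
  require_columns(modularity, c("community", "modularity"),
                  "modularity table")
  one <- function(survey, comm) {
    s <- survey[survey$community == comm & survey$abundance > 0, ,
                drop = FALSE]
    list(richness = length(unique(s$species)),
         abundance = sum(s$abundance),
         diversity = if (nrow(s)) shannon_index(s$abundance) else NA_real_)
  }
  comms <- modularity$community
  rows <- lapply(comms, function(comm) {
    fl <- one(flower_survey, comm)
    be <- one(bee_survey, comm)
    data.frame(
      community = comm,
      bee_richness = be$richness, bee_abundance = be$abundance,
      bee_diversity = be$diversity,
      plant_richness = fl$richness,
      flower_abundance = fl$abundance,
      flower_abundance_ln = log(fl$abundance),
      flower_diversity = fl$diversity,
      modularity = modularity$modularity[modularity$community == comm],
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  structure(out, class = c("community_parameters", class(out)))
}

new_model_result <- function(...) {
  structure(list(...), class = "snet_model")
}

#' @export
print.snet_model <- function(x, ...) {
  cat(sprintf("%s model: %s ~ %s (n = %d)\n", x$family, x$response,
              x$predictor, x$n))
  if (!is.null(x$estimate))
    cat(sprintf("  slope = %.4g, %s = %.3f, p = %.4g\n",
                x$estimate, x$stat_name, x$statistic, x$p))
  if (!is.null(x$adj_r2)) cat(sprintf("  adjusted R2 = %.3f\n", x$adj_r2))
  if (!is.null(x$r2_marginal) && !is.na(x$r2_marginal))
    cat(sprintf("  R2 marginal = %.3f, R2 conditional = %.3f\n",
                x$r2_marginal, x$r2_conditional))
  if (!is.null(x$transform) && x$transform != "none")
    cat(sprintf("  response transform: %s\n", x$transform))
  if (!is.null(x$convergence) && length(x$convergence) > 1)
    cat("  convergence path:", paste(x$convergence, collapse = " -> "), "\n")
  invisible(x)
}

#' Linear model of modularity on one community parameter
#'
#' Ordinary least squares of network modularity on a single community
#' parameter across communities. With `transform = "auto"` the response
#' is ln(Q + 1)-transformed when a Shapiro-Wilk test on the raw-model
#' residuals signals non-normality at the screening level `alpha`
#' (default 0.10 — normality tests have little power at the typical
#' handful of communities, so screening is deliberately lenient). Flower
#' abundance should enter ln-transformed (use the `flower_abundance_ln`
#' column of [community_parameters()]).
#'
#' @param params Community-parameter table (>= 3 communities).
#' @param predictor Name of the predictor column.
#' @param transform `"auto"` (default), `"none"` or `"ln1p"`.
#' @param alpha Screening level of the normality trigger.
#' @return An `snet_model` with slope, t statistic, two-sided p,
#'   adjusted R2 and the transform applied.
#' @export
fit_modularity_lm <- function(params, predictor,
                              transform = c("auto", "none", "ln1p"),
                              alpha = 0.10) {
  transform <- match.arg(transform)
  require_columns(params, c("modularity", predictor), "parameter table")
  if (nrow(params) < 3)
    stop(validation_error("need at least 3 communities"))
  x <- params[[predictor]]
  if (length(unique(x)) < 2)
    stop(validation_error(paste("predictor", predictor,
                                "is constant: rank-deficient model")))
  d <- data.frame(y = params$modularity, x = x)
  fit_raw <- lm(y ~ x, data = d)
  applied <- "none"
  fit <- fit_raw
  if (transform == "ln1p" ||
      (transform == "auto" &&
       shapiro.test(resid(fit_raw))$p.value < alpha)) {
    d$y <- log1p(params$modularity)
    fit <- lm(y ~ x, data = d)
    applied <- "ln1p"
  }
  sm <- summary(fit)
  new_model_result(
    family = "gaussian-lm", response = "modularity", predictor = predictor,
    estimate = unname(coef(fit)[2]),
    se = sm$coefficients[2, 2],
    statistic = sm$coefficients[2, 3], stat_name = "t",
    p = sm$coefficients[2, 4],
    adj_r2 = sm$adj.r.squared,
    transform = applied, n = nrow(params), model = fit
  )
}

# ---- staged convergence policy -------------------------------------------

glmer_ok <- function(fit) {
  conv <- fit@optinfo$conv
  msgs <- conv$lme4$messages
  code_ok <- is.null(conv$opt) || conv$opt == 0
  msg_ok <- is.null(msgs) || !any(grepl("failed to converge", msgs))
  code_ok && msg_ok
}

# Fit a glmer model under the staged policy: default fit, then restart
# from the previous estimates with a larger iteration budget, then switch
# to the bobyqa optimizer. Returns list(fit, path).
glmer_staged <- function(formula, data, family) {
  quiet <- function(expr) suppressWarnings(suppressMessages(expr))
  path <- "default"
  fit <- quiet(lme4::glmer(formula, data = data, family = family))
  if (!glmer_ok(fit)) {
    path <- c(path, "restart")
    ss <- lme4::getME(fit, c("theta", "fixef"))
    fit2 <- try(quiet(stats::update(
      fit, start = ss,
      control = lme4::glmerControl(optCtrl = list(maxfun = 2e5)))),
      silent = TRUE)
    if (!inherits(fit2, "try-error")) fit <- fit2
  }
  if (!glmer_ok(fit)) {
    path <- c(path, "bobyqa")
    fit3 <- try(quiet(stats::update(
      fit, control = lme4::glmerControl(optimizer = "bobyqa",
                                        optCtrl = list(maxfun = 2e5)))),
      silent = TRUE)
    if (!inherits(fit3, "try-error")) fit <- fit3
  }
  if (!glmer_ok(fit))
    stop(errorCondition(
      paste("mixed model failed to converge after staged policy:",
            paste(path, collapse = " -> ")),
      class = c("stigmanet_convergence_error", "error")))
  list(fit = fit, path = path)
}

glmmTMB_ok <- function(fit) {
  isTRUE(fit$fit$convergence == 0) && isTRUE(fit$sdr$pdHess)
}

glmmTMB_staged <- function(formula, data, family) {
  quiet <- function(expr) suppressWarnings(suppressMessages(expr))
  path <- "default"
  fit <- quiet(glmmTMB::glmmTMB(formula, data = data, family = family))
  if (!glmmTMB_ok(fit)) {
    path <- c(path, "restart")
    fit2 <- try(quiet(glmmTMB::glmmTMB(
      formula, data = data, family = family,
      control = glmmTMB::glmmTMBControl(
        optCtrl = list(iter.max = 1e4, eval.max = 1e4)))), silent = TRUE)
    if (!inherits(fit2, "try-error")) fit <- fit2
  }
  if (!glmmTMB_ok(fit)) {
    path <- c(path, "optim-BFGS")
    fit3 <- try(quiet(glmmTMB::glmmTMB(
      formula, data = data, family = family,
      control = glmmTMB::glmmTMBControl(optimizer = stats::optim,
                                        optArgs = list(method = "BFGS")))),
      silent = TRUE)
    if (!inherits(fit3, "try-error")) fit <- fit3
  }
  if (!glmmTMB_ok(fit))
    stop(errorCondition(
      paste("beta mixed model failed to converge after staged policy:",
            paste(path, collapse = " -> ")),
      class = c("stigmanet_convergence_error", "error")))
  list(fit = fit, path = path)
}

check_glmm_data <- function(data, response, predictor) {
  require_columns(data, c(response, predictor, "community", "species"),
                  "model data")
  if (length(unique(data[[response]])) < 2)
    stop(validation_error(paste("response", response,
                                "is constant: degenerate fit")))
  if (length(unique(data[[predictor]])) < 2)
    stop(validation_error(paste("predictor", predictor, "is constant")))
  invisible(data)
}

#' Beta mixed model for standardized degrees
#'
#' Beta-family GLMM (logit link, constant precision) of a standardized
#' degree on one fixed predictor (a floral trait or ln flower abundance),
#' with random intercepts for community and plant species, estimated by
#' maximum likelihood with the Laplace approximation (glmmTMB). The fixed
#' effect is tested by its Wald z. Non-convergent fits are retried under
#' the staged policy (default fit, restart with a larger iteration
#' budget, alternative optimizer); the path taken is recorded.
#'
#' @param data Data frame with the response column (values strictly in
#'   (0, 1); see [standardize_degree()]), the predictor column, and
#'   `community` and `species` grouping columns.
#' @param response,predictor Column names.
#' @return An `snet_model` with slope, Wald z and p and the convergence
#'   path.
#' @export
fit_degree_glmm <- function(data, response, predictor) {
  check_glmm_data(data, response, predictor)
  if (any(data[[response]] <= 0 | data[[response]] >= 1))
    stop(validation_error("response must lie strictly in (0, 1)"))
  f <- as.formula(paste(response, "~", predictor,
                        "+ (1 | community) + (1 | species)"))
  st <- glmmTMB_staged(f, data, glmmTMB::beta_family())
  co <- summary(st$fit)$coefficients$cond
  new_model_result(
    family = "beta-glmm", response = response, predictor = predictor,
    estimate = co[predictor, "Estimate"], se = co[predictor, "Std. Error"],
    statistic = co[predictor, "z value"], stat_name = "z",
    p = co[predictor, "Pr(>|z|)"],
    r2_marginal = NA_real_, r2_conditional = NA_real_,
    convergence = st$path, n = nrow(data), model = st$fit
  )
}

#' Poisson mixed model for weighted degrees
#'
#' Poisson GLMM (log link) of a grain-weighted degree on one fixed
#' predictor, with random intercepts for community and species
#' (lme4::glmer, Laplace approximation). Reporting and convergence
#' handling as in [fit_degree_glmm()].
#'
#' @inheritParams fit_degree_glmm
#' @return An `snet_model`.
#' @export
fit_weighted_degree_glmm <- function(data, response, predictor) {
  check_glmm_data(data, response, predictor)
  y <- data[[response]]
  if (any(y < 0 | y != floor(y)))
    stop(validation_error("response must be nonnegative integer counts"))
  f <- as.formula(paste(response, "~", predictor,
                        "+ (1 | community) + (1 | species)"))
  st <- glmer_staged(f, data, stats::poisson())
  co <- summary(st$fit)$coefficients
  new_model_result(
    family = "poisson-glmm", response = response, predictor = predictor,
    estimate = co[predictor, "Estimate"], se = co[predictor, "Std. Error"],
    statistic = co[predictor, "z value"], stat_name = "z",
    p = co[predictor, "Pr(>|z|)"],
    intercept = co["(Intercept)", "Estimate"],
    convergence = st$path, n = nrow(data), model = st$fit
  )
}

# Nakagawa-Schielzeth variance decomposition on the link scale with the
# logit observation-level variance pi^2 / 3.
nakagawa_r2_logit <- function(fit) {
  X <- lme4::getME(fit, "X")
  var_f <- var(as.vector(X %*% lme4::fixef(fit)))
  vc <- lme4::VarCorr(fit)
  var_r <- sum(vapply(vc, function(v) v[1, 1], numeric(1)))
  var_e <- pi^2 / 3
  tot <- var_f + var_r + var_e
  c(marginal = var_f / tot, conditional = (var_f + var_r) / tot)
}

#' Binomial mixed model for per-stigma heterospecific proportions
#'
#' Models each stigma's heterospecific grain count out of its total load,
#' `cbind(hp, cp)`, with a logit link and random intercepts for community
#' and species. The fixed effect is tested by a likelihood-ratio test
#' against the random-effects-only model (chi-squared, 1 df), and
#' Nakagawa-Schielzeth marginal and conditional R2 are reported (logit
#' observation-level variance pi^2 / 3). All-conspecific (or
#' all-heterospecific) data put the fitted proportion at the boundary:
#' no model is fitted and the result is flagged.
#'
#' @param data Data frame with integer columns `hp` and `cp` (per stigma;
#'   `hp + cp >= 1`), the predictor column, and `community` and `species`.
#' @param predictor Predictor column name.
#' @return An `snet_model` with the LRT chi-squared statistic and p, R2
#'   marginal/conditional, the convergence path, and `boundary` flag.
#' @export
fit_hp_proportion_glmm <- function(data, predictor) {
  require_columns(data, c("hp", "cp", predictor, "community", "species"),
                  "model data")
  trials <- data$hp + data$cp
  if (any(trials < 1))
    stop(validation_error("each stigma needs at least one grain (hp+cp >= 1)"))
  if (all(data$hp == 0) || all(data$cp == 0)) {
    return(new_model_result(
      family = "binomial-glmm", response = "hp/(hp+cp)",
      predictor = predictor, estimate = NA_real_, statistic = NA_real_,
      stat_name = "chisq", p = NA_real_, boundary = TRUE,
      r2_marginal = NA_real_, r2_conditional = NA_real_,
      convergence = "degenerate", n = nrow(data), model = NULL
    ))
  }
  f1 <- as.formula(paste("cbind(hp, cp) ~", predictor,
                         "+ (1 | community) + (1 | species)"))
  f0 <- cbind(hp, cp) ~ (1 | community) + (1 | species)
  st1 <- glmer_staged(f1, data, stats::binomial())
  st0 <- glmer_staged(f0, data, stats::binomial())
  lrt <- anova(st0$fit, st1$fit)
  r2 <- nakagawa_r2_logit(st1$fit)
  co <- summary(st1$fit)$coefficients
  new_model_result(
    family = "binomial-glmm", response = "hp/(hp+cp)", predictor = predictor,
    estimate = co[predictor, "Estimate"], se = co[predictor, "Std. Error"],
    statistic = lrt$Chisq[2], stat_name = "chisq", p = lrt$`Pr(>Chisq)`[2],
    df = lrt$Df[2], boundary = FALSE,
    r2_marginal = unname(r2["marginal"]),
    r2_conditional = unname(r2["conditional"]),
    convergence = st1$path, n = nrow(data), model = st1$fit
  )
}

#' Pairwise Pearson correlations between community parameters
#'
#' @param params Community-parameter table (>= 3 communities).
#' @param names Columns to correlate.
#' @return List with matrices `r` and `p`; zero-variance columns give
#'   `NA` entries (with a warning).
#' @export
parameter_correlations <- function(params, names) {
  require_columns(params, names, "parameter table")
  if (nrow(params) < 3)
    stop(validation_error("need at least 3 communities"))
  k <- length(names)
  r <- p <- matrix(NA_real_, k, k, dimnames = list(names, names))
  diag(r) <- 1; diag(p) <- 0
  for (i in seq_len(k - 1)) for (j in (i + 1):k) {
    x <- params[[names[i]]]; y <- params[[names[j]]]
    if (var(x) == 0 || var(y) == 0) {
      warning(sprintf("zero variance in %s or %s; correlation undefined",
                      names[i], names[j]))
      next
    }
    ct <- cor.test(x, y, method = "pearson")
    r[i, j] <- r[j, i] <- unname(ct$estimate)
    p[i, j] <- p[j, i] <- ct$p.value
  }
  list(r = r, p = p)
}
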
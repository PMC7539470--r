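# Per-species degree statistics of a pollen-transfer network. In-degree =
# number of species whose pollen was found on a species' stigmas;
# out-degree = number of species it donated pollen to. Weighted versions
# sum grains over links. A species is a hub-donor when it donates to more
# species than it receives from, a hub-receptor in the converse case, and
# neutral at equality.

#' Compute the degree table of a transfer network
#'
#' @param network A [transfer_network][build_transfer_network].
#' @param standardize Add standardized degree columns `std_in`, `std_out`
#'   (see [standardize_degree()]); `n_obs` defaults to the number of
#'   on-plot species in the table.
#' @param n_obs Observation count for the standardizing transform; set it
#'   to the number of rows entering a downstream regression when degrees
#'   from several communities are pooled.
#' @return Data frame of class `degree_table`: one row per node with
#'   `species`, `on_plot`, `in_degree`, `out_degree`, `w_in`, `w_out`,
#'   `hub_class` and (optionally) `std_in`, `std_out`. Off-plot donors
#'   have in-degree 0 by construction.
#' @export
compute_degrees <- function(network, standardize = FALSE, n_obs = NULL) {
  stopifnot(inherits(network, "transfer_network"))
  sp <- network$nodes$species
  e <- network$edges
  tab <- data.frame(
    species = sp,
    on_plot = network$nodes$on_plot,
    in_degree = as.integer(table(factor(e$receptor, levels = sp))),
    out_degree = as.integer(table(factor(e$donor, levels = sp))),
    w_in = as.integer(sapply(sp, function(s)
      sum(e$weight[e$receptor == s]))),
    w_out = as.integer(sapply(sp, function(s)
      sum(e$weight[e$donor == s]))),
    stringsAsFactors = FALSE
  )
  tab$hub_class <- classify_hub(tab$in_degree, tab$out_degree)
  if (standardize) {
    n_obs <- n_obs %||% sum(tab$on_plot)
    tab$std_in <- standardize_degree(tab$in_degree, network$s_flowering, n_obs)
    tab$std_out <- standardize_degree(tab$out_degree, network$s_flowering,
                                      n_obs)
  }
  rownames(tab) <- NULL
  structure(tab, class = c("degree_table", class(tab)))
}

#' Classify species as hub-donor, hub-receptor or neutral
#'
#' Strict-inequality rule: in-degree < out-degree is a hub-donor,
#' in-degree > out-degree a hub-receptor, equality (including isolated
#' species) neutral.
#'
#' @param in_degree,out_degree Nonnegative integer vectors.
#' @return Character vector in `{"hub-donor", "hub-receptor", "neutral"}`.
#' @export
classify_hub <- function(in_degree, out_degree) {
  stopifnot(all(in_degree >= 0), all(out_degree >= 0))
  ifelse(in_degree < out_degree, "hub-donor",
         ifelse(in_degree > out_degree, "hub-receptor", "neutral"))
}

#' Percentages of donor, receptor and neutral species
#'
#' Percentages of hub-donor, hub-receptor and neutral (donor-receptor)
#' species over a chosen denominator. The default counts only species
#' with at least one link (the convention under which a community with 17
#' sampled species and one unlinked species prints 7/16 = 43.75% donors);
#' `"all_sampled"` uses every on-plot species.
#'
#' @param table A [degree_table][compute_degrees].
#' @param denominator `"linked_species"` (default) or `"all_sampled"`.
#' @return Named numeric vector `pct_donor`, `pct_receptor`, `pct_both`,
#'   summing to 100.
#' @export
donor_receptor_percentages <- function(table,
                                       denominator = c("linked_species",
                                                       "all_sampled")) {
  denominator <- match.arg(denominator)
  keep <- if (denominator == "linked_species")
    table$in_degree + table$out_degree > 0 else table$on_plot
  n <- sum(keep)
  if (n == 0)
    stop(validation_error("no species in the chosen denominator"))
  cls <- table$hub_class[keep]
  c(pct_donor = 100 * sum(cls == "hub-donor") / n,
    pct_receptor = 100 * sum(cls == "hub-receptor") / n,
    pct_both = 100 * sum(cls == "neutral") / n)
}

#' Standardize a degree into the open unit interval
#'
#' Divides the degree by the number of flowering plant species in the
#' community and applies the boundary-avoiding compression used for beta
#' regression: `y' = (y * (n_obs - 1) + 0.5) / n_obs`. The result lies
#' strictly inside (0, 1) for any admissible input, as the beta family
#' requires. `n_obs` is the number of observations entering the
#' regression model in which the standardized degrees are used.
#'
#' @param degree Degree value(s), `0 <= degree <= s_flowering`.
#' @param s_flowering Number of flowering plant species in the community.
#' @param n_obs Observation count (`>= 2`).
#' @return Numeric vector in (0, 1).
#' @export
standardize_degree <- function(degree, s_flowering, n_obs) {
  if (n_obs < 2) stop(validation_error("n_obs must be >= 2"))
  if (s_flowering < 1) stop(validation_error("s_flowering must be >= 1"))
  if (any(degree < 0) || any(degree > s_flowering))
    stop(validation_error("degrees must lie in [0, s_flowering]"))
  y <- degree / s_flowering
  (y * (n_obs - 1) + 0.5) / n_obs
}

#' Pearson correlation between in- and out-degree
#'
#' Product-moment correlation over the on-plot sampled species of a degree
#' table (off-plot donors are excluded: their structural zero in-degree
#' would bias the correlation).
#'
#' @param table A [degree_table][compute_degrees].
#' @return List with `r`, `p`, `n`.
#' @export
inout_correlation <- function(table) {
  tab <- table[table$on_plot, , drop = FALSE]
  if (nrow(tab) < 3)
    stop(validation_error("need at least 3 on-plot species"))
  if (var(tab$in_degree) == 0 || var(tab$out_degree) == 0)
    stop(validation_error(
      "degree vector has zero variance; correlation undefined"))
  ct <- cor.test(tab$in_degree, tab$out_degree, method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value, n = nrow(tab))
}
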
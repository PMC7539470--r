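# Directed, weighted interspecific pollen-transfer networks. A link
# donor -> receptor exists when at least one identified grain of the donor
# was found on a stigma of the receptor; its weight is the total number of
# such grains over all the receptor's stigmas. Grains labelled "UNKNOWN"
# never form links but are retained in the heterospecific totals.

#' Build the pollen-transfer network of one community
#'
#' Pools all stigmas of a community (plots are pooled) into a unipartite
#' directed network over plant taxa. Donor taxa absent from
#' `flowering_species` are flagged off-plot: they donate pollen (typically
#' from the surroundings or from earlier flowering) but are never sampled
#' as receivers, so their in-degree is structurally zero.
#'
#' @param records Stigma table (see [read_stigma_table()]).
#' @param flowering_species Character vector of species flowering on the
#'   community's plots; defaults to the sampled focal species. Sampled
#'   focal species are always treated as on-plot. The length of the union
#'   is stored as `s_flowering`, the standardization denominator for
#'   degrees.
#' @param community Community key; taken from the records when unique.
#' @param include_unknown_in_hp Count `"UNKNOWN"` grains in the
#'   heterospecific totals (default `TRUE`).
#' @return An object of class `transfer_network`: list with `community`,
#'   `nodes` (data frame `species`, `on_plot`), `edges` (data frame
#'   `donor`, `receptor`, `weight`), `s_flowering`, `unknown_hp` and
#'   `totals` (a `community_totals`, see [aggregate_totals()]).
#' @export
build_transfer_network <- function(records, flowering_species = NULL,
                                   community = NULL,
                                   include_unknown_in_hp = TRUE) {
  records <- validate_stigma_table(as.data.frame(records))
  comms <- unique(records$community)
  if (is.null(community)) {
    if (length(comms) > 1)
      stop(validation_error(
        "records span several communities; pass `community`"))
    community <- if (length(comms)) comms else NA_character_
  } else {
    records <- records[records$community == community, , drop = FALSE]
  }
  if (any(tolower(records$focal_species) == tolower(.UNKNOWN)))
    stop(validation_error("a stigma's focal species cannot be \"unknown\""))

  sampled <- sort(unique(records$focal_species))
  flowering <- sort(unique(c(sampled, flowering_species)))

  hp_rows <- records[!(records$donor %in% c(.CONSPECIFIC, .UNKNOWN)) &
                       records$grains > 0, , drop = FALSE]
  edges <- if (nrow(hp_rows)) {
    e <- aggregate(grains ~ donor + focal_species, data = hp_rows, FUN = sum)
    names(e) <- c("donor", "receptor", "weight")
    e$weight <- as.integer(e$weight)
    e[order(e$donor, e$receptor), , drop = FALSE]
  } else {
    data.frame(donor = character(0), receptor = character(0),
               weight = integer(0), stringsAsFactors = FALSE)
  }
  rownames(edges) <- NULL

  taxa <- sort(unique(c(sampled, edges$donor)))
  nodes <- data.frame(species = taxa,
                      on_plot = taxa %in% flowering,
                      stringsAsFactors = FALSE)

  totals <- aggregate_totals(records, flowering_species = flowering,
                             include_unknown_in_hp = include_unknown_in_hp)
  structure(list(
    community = community, nodes = nodes, edges = edges,
    s_flowering = length(flowering),
    unknown_hp = sum(records$grains[records$donor == .UNKNOWN]),
    totals = totals
  ), class = "transfer_network")
}

#' @export
print.transfer_network <- function(x, ...) {
  cat("Pollen-transfer network:", x$community, "\n")
  cat(sprintf("  %d taxa (%d on-plot, %d off-plot donors), %d links\n",
              nrow(x$nodes), sum(x$nodes$on_plot), sum(!x$nodes$on_plot),
              nrow(x$edges)))
  cat(sprintf("  %d identified heterospecific grains on links, %d unknown\n",
              sum(x$edges$weight), x$unknown_hp))
  invisible(x)
}

#' Resolve an ambiguous pollen-grain identification by abundance
#'
#' When a grain's identification is unclear between several taxa, the
#' candidate with the strictly higher flower abundance is assumed to be
#' the origin. An abundance tie is an error: silently picking one
#' candidate would corrupt the downstream network, so the caller must
#' decide.
#'
#' @param candidates Character vector of candidate taxa.
#' @param abundances Named numeric vector covering all candidates.
#' @return The single most abundant candidate.
#' @export
resolve_ambiguous_donor <- function(candidates, abundances) {
  if (!length(candidates))
    stop(validation_error("no candidate taxa supplied"))
  missing <- setdiff(candidates, names(abundances))
  if (length(missing))
    stop(validation_error(paste("no abundance for candidate(s):",
                                paste(missing, collapse = ", "))))
  if (length(candidates) == 1) return(candidates)
  a <- abundances[candidates]
  top <- candidates[a == max(a)]
  if (length(top) > 1)
    stop(errorCondition(
      paste0("abundance tie between candidates: ",
             paste(top, collapse = ", ")),
      class = c("stigmanet_tie_error", "stigmanet_validation_error", "error")))
  top
}

#' Descriptive totals of one community
#'
#' Number of sampled and flowering species, stigmas, total / conspecific /
#' heterospecific grain counts and the number of network links (including
#' links from off-plot donors). Unidentified (`"UNKNOWN"`) grains count
#' toward the heterospecific total by default, since heterospecific loads
#' are enumerated before donor identification.
#'
#' @inheritParams build_transfer_network
#' @return An object of class `community_totals` (a one-row data frame
#'   with columns `community`, `n_species_sampled`, `n_species_flowering`,
#'   `n_stigmas`, `total_grains`, `total_cp`, `total_hp`, `n_links`).
#' @export
aggregate_totals <- function(records, flowering_species = NULL,
                             include_unknown_in_hp = TRUE) {
  records <- validate_stigma_table(as.data.frame(records))
  sampled <- unique(records$focal_species)
  flowering <- unique(c(sampled, flowering_species))
  comm <- if (nrow(records)) unique(records$community)[1] else NA_character_

  cp <- sum(records$grains[records$donor == .CONSPECIFIC])
  unk <- sum(records$grains[records$donor == .UNKNOWN])
  ident_hp <- sum(records$grains[!(records$donor %in%
                                     c(.CONSPECIFIC, .UNKNOWN))])
  hp <- ident_hp + if (include_unknown_in_hp) unk else 0L

  hp_rows <- records[!(records$donor %in% c(.CONSPECIFIC, .UNKNOWN)) &
                       records$grains > 0, , drop = FALSE]
  n_links <- nrow(unique(hp_rows[c("donor", "focal_species")]))

  out <- data.frame(
    community = comm,
    n_species_sampled = length(sampled),
    n_species_flowering = length(flowering),
    n_stigmas = length(unique(records$stigma_id)),
    total_grains = cp + ident_hp + unk,
    total_cp = cp, total_hp = hp, n_links = n_links,
    stringsAsFactors = FALSE
  )
  structure(out, class = c("community_totals", class(out)))
}

#' Sum per-community totals into study-level totals
#'
#' Exact integer column sums over a table of per-community descriptive
#' totals (one row per community).
#'
#' @param totals Data frame with (at least) the numeric columns of
#'   [aggregate_totals()] output.
#' @return One-row data frame of the summed columns.
#' @export
sum_community_totals <- function(totals) {
  cols <- intersect(c("n_species_sampled", "n_stigmas", "total_grains",
                      "total_cp", "total_hp", "n_links"), names(totals))
  if (!length(cols))
    stop(validation_error("no summable totals columns present"))
  as.data.frame(lapply(totals[cols], function(x) sum(as.numeric(x))))
}

#' Per-stigma pollen presence and %-conspecific summary
#'
#' Fractions of stigmas carrying conspecific pollen, heterospecific pollen
#' (identified or unknown) and no pollen at all, plus the distribution of
#' the per-stigma conspecific percentage, `100 * CP / (CP + HP)`, over
#' stigmas with at least one grain (empty stigmas are excluded from that
#' distribution).
#'
#' @param records Stigma table.
#' @return List with `n_stigmas`, `frac_cp_present`, `frac_hp_present`,
#'   `frac_no_pollen`, and `pct_cp` (list: `mean`, `sd`, `min`, `max`,
#'   `values`).
#' @export
stigma_presence_summary <- function(records) {
  records <- validate_stigma_table(as.data.frame(records))
  ids <- unique(records$stigma_id)
  cp <- sapply(ids, function(id)
    sum(records$grains[records$stigma_id == id &
                         records$donor == .CONSPECIFIC]))
  hp <- sapply(ids, function(id)
    sum(records$grains[records$stigma_id == id &
                         records$donor != .CONSPECIFIC]))
  total <- cp + hp
  pct <- 100 * cp[total > 0] / total[total > 0]
  list(
    n_stigmas = length(ids),
    frac_cp_present = mean(cp > 0),
    frac_hp_present = mean(hp > 0),
    frac_no_pollen = mean(total == 0),
    pct_cp = list(
      mean = if (length(pct)) mean(pct) else NaN,
      sd = if (length(pct) > 1) sd(pct) else NA_real_,
      min = if (length(pct)) min(pct) else NA_real_,
      max = if (length(pct)) max(pct) else NA_real_,
      values = unname(pct)
    )
  )
}
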
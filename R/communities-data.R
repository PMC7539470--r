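#' Summary statistics of nine grassland pollen-transfer communities
#'
#' Published descriptive statistics for nine insect-pollinated plant
#' communities from three calcareous-grassland sites in Southern Germany
#' (EB, HT, RB), each sampled in early, mid and late summer. For every
#' community the table records the number of species whose stigmas were
#' sampled, the number of flowering plant species (some species were
#' protected or too rare to sample), the stigma count, total / conspecific
#' / heterospecific pollen-grain counts, the number of links in the
#' pollen-transfer network (including links from off-plot donors), the
#' hub-role percentages, the in/out-degree Pearson correlation and the
#' network modularity (Louvain optimisation, resolution 0.7, weighted by
#' grain counts).
#'
#' These values serve as reference inputs for study-level aggregation and
#' for the community-level modularity regressions. The degree correlation
#' of RB II is recorded as `NA`: the published value (-10.19) lies outside
#' \[-1, 1\] and is evidently a misprint.
#'
#' @return Data frame with one row per community and columns `community`,
#'   `site`, `season`, `n_species_sampled`, `n_species_flowering`,
#'   `n_stigmas`, `total_grains`, `total_cp`, `total_hp`, `n_links`,
#'   `pct_donor`, `pct_receptor`, `pct_both`, `degree_correlation`,
#'   `modularity`.
#' @examples
#' tab <- community_summary_table()
#' sum_community_totals(tab)
#' @export
community_summary_table <- function() {
  data.frame(
    community = c("EB I", "EB II", "EB III", "HT I", "HT II", "HT III",
                  "RB I", "RB II", "RB III"),
    site = rep(c("EB", "HT", "RB"), each = 3),
    season = rep(c("early", "mid", "late"), times = 3),
    n_species_sampled = c(4, 17, 7, 7, 16, 17, 8, 16, 22),
    n_species_flowering = c(4, 20, 9, 9, 19, 19, 9, 20, 24),
    n_stigmas = c(48, 160, 46, 72, 178, 156, 71, 162, 224),
    total_grains = c(11030, 21564, 8373, 8409, 13956, 11279, 9446, 9324,
                     23573),
    total_cp = c(10472, 20712, 8187, 8056, 12211, 10883, 9280, 8668, 21896),
    total_hp = c(558, 852, 186, 353, 1745, 396, 166, 656, 1677),
    n_links = c(8, 48, 14, 12, 57, 57, 11, 49, 91),
    pct_donor = c(25, 43.75, 28.57, 42.86, 20, 47.06, 37.5, 37.5, 36.36),
    pct_receptor = c(50, 56.25, 57.14, 57.14, 73.33, 47.06, 25, 56.25,
                     54.54),
    pct_both = c(25, 0, 14.29, 0, 6.77, 5.88, 37.5, 6.25, 9.1),
    degree_correlation = c(-0.30, -0.23, 0.62, -0.11, -0.23, -0.09, -0.53,
                           NA, -0.10),
    modularity = c(0, 0.38, 0.1, 0.25, 0.47, 0.48, 0.31, 0.56, 0.47),
    stringsAsFactors = FALSE
  )
}
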
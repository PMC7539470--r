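# Tabular IO. All tables are UTF-8 comma-separated with "." decimals and a
# header row; taxon names are opaque strings matched exactly.

validation_error <- function(msg, rows = NULL) {
  if (!is.null(rows) && length(rows))
    msg <- paste0(msg, " (rows: ", paste(rows, collapse = ", "), ")")
  errorCondition(msg, class = c("stigmanet_validation_error", "error"))
}

require_columns <- function(df, cols, what) {
  missing <- setdiff(cols, names(df))
  if (length(missing))
    stop(validation_error(sprintf("%s is missing column(s): %s", what,
                                  paste(missing, collapse = ", "))))
  invisible(df)
}

#' Read a long-format stigma table
#'
#' One row per (stigma, donor taxon); the reserved donor keys
#' `"CONSPECIFIC"` and `"UNKNOWN"` hold the conspecific load and
#' unidentifiable heterospecific grains. Every stigma must carry a
#' `CONSPECIFIC` row (possibly zero). Malformed rows are reported with
#' their file row numbers (header = row 1).
#'
#' @param path CSV file with columns `stigma_id`, `focal_species`,
#'   `community`, `plot`, `donor`, `grains`.
#' @return A validated data frame of class `stigma_table`.
#' @export
read_stigma_table <- function(path) {
  if (!file.exists(path)) stop(validation_error(paste("no such file:", path)))
  df <- read.csv(path, stringsAsFactors = FALSE)
  validate_stigma_table(df)
}

#' Validate an in-memory stigma table
#'
#' @param df Data frame in the layout of [read_stigma_table()].
#' @return `df` with class `stigma_table` prepended.
#' @export
validate_stigma_table <- function(df) {
  require_columns(df, c("stigma_id", "focal_species", "community", "plot",
                        "donor", "grains"), "stigma table")
  if (nrow(df) == 0)
    return(structure(df, class = c("stigma_table", class(df))))
  rowno <- seq_len(nrow(df)) + 1L  # file rows, after the header
  bad <- which(!is.finite(df$grains) | df$grains < 0 |
                 df$grains != floor(df$grains))
  if (length(bad))
    stop(validation_error("grain counts must be nonnegative integers",
                          rowno[bad]))
  dup <- which(duplicated(df[c("stigma_id", "donor")]))
  if (length(dup))
    stop(validation_error("duplicate (stigma_id, donor) pairs", rowno[dup]))
  self <- which(df$donor == df$focal_species & df$donor != .CONSPECIFIC)
  if (length(self))
    stop(validation_error(
      "focal species listed as its own heterospecific donor", rowno[self]))
  has_cp <- tapply(df$donor == .CONSPECIFIC, df$stigma_id, any)
  if (any(!has_cp))
    stop(validation_error(paste("stigmas without a CONSPECIFIC row:",
                                paste(names(has_cp)[!has_cp], collapse = ", "))))
  df$grains <- as.integer(df$grains)
  structure(df, class = unique(c("stigma_table", class(df))))
}

#' Write a stigma table
#' @param df A stigma table (validated before writing).
#' @param path Output CSV path.
#' @return Invisibly, `path`.
#' @export
write_stigma_table <- function(df, path) {
  validate_stigma_table(as.data.frame(df))
  write.csv(as.data.frame(df), path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' Read or write a per-individual floral trait table
#'
#' Columns: `species`, `individual`, then the six morphological traits
#' (mm): `stamen_length_mm`, `inflorescence_diameter_mm`,
#' `nectar_tube_depth_mm`, `nectar_tube_width_mm`, `display_size_mm`,
#' `style_length_mm`. Nectar-tube fields are zero for species without a
#' nectar tube; all values must be nonnegative.
#'
#' @param path CSV path.
#' @return A validated data frame.
#' @export
read_trait_table <- function(path) {
  if (!file.exists(path)) stop(validation_error(paste("no such file:", path)))
  validate_trait_table(read.csv(path, stringsAsFactors = FALSE))
}

validate_trait_table <- function(df) {
  require_columns(df, c("species", "individual", .TRAITS), "trait table")
  vals <- as.matrix(df[.TRAITS])
  bad <- which(apply(vals < 0 | !is.finite(vals), 1, any))
  if (length(bad))
    stop(validation_error("trait values must be nonnegative", bad + 1L))
  df
}

#' @rdname read_trait_table
#' @param df Trait data frame to write.
#' @export
write_trait_table <- function(df, path) {
  validate_trait_table(df)
  write.csv(df, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' Read or write an abundance survey table
#'
#' Columns: `community`, `species`, `abundance` (nonnegative integer), and
#' optionally `plot` for per-plot counts; [aggregate_survey()] pools plots.
#'
#' @param path CSV path.
#' @return A validated data frame.
#' @export
read_survey_table <- function(path) {
  if (!file.exists(path)) stop(validation_error(paste("no such file:", path)))
  validate_survey_table(read.csv(path, stringsAsFactors = FALSE))
}

validate_survey_table <- function(df) {
  require_columns(df, c("community", "species", "abundance"), "survey table")
  bad <- which(!is.finite(df$abundance) | df$abundance < 0 |
                 df$abundance != floor(df$abundance))
  if (length(bad))
    stop(validation_error("abundances must be nonnegative integers", bad + 1L))
  df
}

#' @rdname read_survey_table
#' @param df Survey data frame to write.
#' @export
write_survey_table <- function(df, path) {
  validate_survey_table(df)
  write.csv(df, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' Pool a survey over plots
#'
#' Sums abundances per (community, species), e.g. over the three plots of a
#' site.
#'
#' @param df Survey table, possibly with a `plot` column.
#' @return Survey table with one row per (community, species).
#' @export
aggregate_survey <- function(df) {
  validate_survey_table(df)
  out <- aggregate(abundance ~ community + species, data = df, FUN = sum)
  out[order(out$community, out$species), , drop = FALSE]
}

#' Serialize a transfer network
#'
#' `"edgelist_csv"` writes the columns `donor`, `receptor`, `weight`;
#' `"graphml"` writes a directed GraphML graph with the node attribute
#' `on_plot` and edge attribute `weight` (readable by igraph, Gephi and
#' other standard graph tools).
#'
#' @param network A [transfer_network][build_transfer_network].
#' @param path Output path.
#' @param format `"edgelist_csv"` or `"graphml"`.
#' @return Invisibly, `path`.
#' @export
write_network <- function(network, path,
                          format = c("edgelist_csv", "graphml")) {
  stopifnot(inherits(network, "transfer_network"))
  format <- match.arg(format)
  if (format == "edgelist_csv") {
    df <- network$edges[c("donor", "receptor", "weight")]
    write.csv(df, path, row.names = FALSE, quote = TRUE)
  } else {
    g <- as_igraph(network)
    igraph::write_graph(g, path, format = "graphml")
  }
  invisible(path)
}

#' Convert a transfer network to an igraph object
#' @param network A `transfer_network`.
#' @return A directed, weighted igraph graph with vertex attribute `on_plot`.
#' @export
as_igraph <- function(network) {
  stopifnot(inherits(network, "transfer_network"))
  g <- igraph::graph_from_data_frame(
    network$edges[c("donor", "receptor", "weight")],
    directed = TRUE, vertices = network$nodes
  )
  igraph::E(g)$weight <- network$edges$weight
  g
}

#' Read a network edge list written by [write_network()]
#' @param path Edge-list CSV path.
#' @return Data frame with columns `donor`, `receptor`, `weight`.
#' @export
read_network_edgelist <- function(path) {
  if (!file.exists(path)) stop(validation_error(paste("no such file:", path)))
  df <- read.csv(path, stringsAsFactors = FALSE)
  require_columns(df, c("donor", "receptor", "weight"), "edge list")
  if (any(df$weight < 1)) stop(validation_error("edge weights must be >= 1"))
  df
}

#' Serialize a partition or consensus result to JSON
#'
#' Module labels, modularity, resolution, seeds and (for consensus) run
#' frequencies are preserved at full precision.
#'
#' @param x A `partition` or `consensus_result`.
#' @param path Output JSON path.
#' @return Invisibly, `path`.
#' @export
write_partition <- function(x, path) {
  if (inherits(x, "partition")) {
    payload <- list(kind = "partition", membership = as.list(x$membership),
                    Q = x$Q, resolution = x$resolution, seed = x$seed)
  } else if (inherits(x, "consensus_result")) {
    payload <- list(
      kind = "consensus",
      n_runs = x$n_runs, resolution = x$resolution,
      threshold = x$threshold, base_seed = x$base_seed,
      co_optimal = x$co_optimal,
      accepted = if (is.null(x$accepted)) NULL else
        list(membership = as.list(x$accepted$membership), Q = x$accepted$Q),
      partitions = lapply(x$partitions, function(p)
        list(membership = as.list(p$membership), Q = p$Q,
             frequency = p$frequency))
    )
  } else stop(validation_error("x must be a partition or consensus_result"))
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = I(17),
                       pretty = TRUE, null = "null")
  invisible(path)
}

#' Read a partition JSON written by [write_partition()]
#' @param path JSON path.
#' @return A `partition` or a plain consensus list, matching what was
#'   written.
#' @export
read_partition <- function(path) {
  if (!file.exists(path)) stop(validation_error(paste("no such file:", path)))
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (identical(p$kind, "partition")) {
    new_partition(unlist(p$membership), Q = p$Q, resolution = p$resolution,
                  seed = p$seed)
  } else p
}
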
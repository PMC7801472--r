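# Tidy exports: the fixed-header metrics time series and weighted
# edge-list network snapshots.

.metrics_header <- c("seed", "round", "frac_spiteful", "a_bar", "a_social",
                     "a_spiteful", "share_soc_soc", "share_soc_spite",
                     "share_spite_soc", "share_spite_spite",
                     "mean_payoff_social", "median_payoff_social",
                     "mean_payoff_spiteful", "median_payoff_spiteful")

#' Write the metrics time series as CSV
#'
#' One row per recorded round per seed, with the fixed column order
#' `seed,round,frac_spiteful,a_bar,a_social,a_spiteful,share_soc_soc,`
#' `share_soc_spite,share_spite_soc,share_spite_spite,mean_payoff_social,`
#' `median_payoff_social,mean_payoff_spiteful,median_payoff_spiteful`.
#'
#' @param x a `"spite_sim"` object or a metrics data.frame (possibly from
#'   several runs bound together).
#' @param path file path to write.
#' @return `path`, invisibly.
#' @export
write_metrics_csv <- function(x, path) {
  df <- if (inherits(x, "spite_sim")) x$metrics else x
  stopifnot(is.data.frame(df), all(.metrics_header %in% names(df)))
  write.csv(df[, .metrics_header], path, row.names = FALSE)
  invisible(path)
}

#' Network snapshot as a weighted edge list
#'
#' Flattens a weight matrix into one row per strictly positive
#' off-diagonal entry, with visitor/host strategies attached; suitable for
#' CSV export or for building an igraph/graph object downstream.
#'
#' @param strategies strategy vector.
#' @param w weight matrix.
#' @param round round index stamped on every row.
#' @param path optional file path; when given the edge list is also
#'   written as CSV with header `round,source,target,weight,`
#'   `source_strategy,target_strategy`.
#' @return data.frame of edges, invisibly when `path` is given.
#' @export
network_edgelist <- function(strategies, w, round = NA_integer_, path = NULL) {
  s <- as_strategy(strategies)
  stopifnot(nrow(w) == length(s))
  idx <- which(w > 0 & row(w) != col(w), arr.ind = TRUE)
  lab <- strategy_labels(s)
  df <- data.frame(round = round, source = idx[, 1], target = idx[, 2],
                   weight = w[idx], source_strategy = lab[idx[, 1]],
                   target_strategy = lab[idx[, 2]])
  df <- df[order(df$source, df$target), ]
  rownames(df) <- NULL
  if (!is.null(path)) {
    write.csv(df, path, row.names = FALSE)
    return(invisible(df))
  }
  df
}
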
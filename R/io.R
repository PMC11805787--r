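# Plain-text readers/writers for the pipeline's tables and networks:
# long-format CSV trial tables, CSV profile tables, TSV dense matrices,
# whitespace edge lists, and JSON ground truth.

#' Read and write long-format trial tables
#'
#' Trial CSVs carry the columns `participant_id`, `task`, `hand`, `position`,
#' `rt_ms`, `correct`, `probe_positive`.
#'
#' @param trials Trial data frame.
#' @param path File path.
#' @return `read_trials_csv` returns the trial data frame;
#'   `write_trials_csv` returns `path` invisibly.
#' @export
write_trials_csv <- function(trials, path) {
  utils::write.csv(trials, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_trials_csv
#' @export
read_trials_csv <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Read and write participant profile tables
#'
#' @param profiles Profile data frame.
#' @param path File path.
#' @return `read_profiles_csv` returns the profile data frame.
#' @export
write_profiles_csv <- function(profiles, path) {
  utils::write.csv(profiles, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_profiles_csv
#' @export
read_profiles_csv <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Read and write dense symmetric matrices as TSV
#'
#' @param mat Numeric matrix.
#' @param path File path.
#' @return `read_matrix_tsv` returns the matrix.
#' @export
write_matrix_tsv <- function(mat, path) {
  utils::write.table(mat, path, sep = "\t", row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

#' @rdname write_matrix_tsv
#' @export
read_matrix_tsv <- function(path) {
  as.matrix(utils::read.table(path, sep = "\t", header = FALSE))
}

#' Read a whitespace-delimited edge list into an adjacency matrix
#'
#' Rows are `i j [weight]` (1-based node indices); missing weights default
#' to 1. The result is symmetrized.
#'
#' @param path File path.
#' @param n_nodes Number of nodes (defaults to the largest index seen).
#' @return A symmetric `n_nodes x n_nodes` weight matrix.
#' @export
read_edge_list <- function(path, n_nodes = NULL) {
  e <- utils::read.table(path, header = FALSE)
  stop_if_not(ncol(e) >= 2, "edge list needs at least two columns")
  w <- if (ncol(e) >= 3) e[[3]] else rep(1, nrow(e))
  n <- n_nodes %||% max(e[[1]], e[[2]])
  A <- matrix(0, n, n)
  A[cbind(e[[1]], e[[2]])] <- w
  A[cbind(e[[2]], e[[1]])] <- w
  A
}

#' Serialize generator ground truth as JSON
#'
#' @param ground_truth The `"ground_truth"` attribute of
#'   [generate_probe_trials()] output.
#' @param path File path.
#' @return `path`, invisibly.
#' @export
write_ground_truth_json <- function(ground_truth, path) {
  gt <- ground_truth
  gt$config <- unclass(gt$config)
  gt$config$l2_correlations <- as.data.frame(gt$config$l2_correlations)
  gt$config$tau <- as.data.frame(gt$config$tau)
  jsonlite::write_json(gt, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
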
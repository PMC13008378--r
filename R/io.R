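# Tab-separated serialization of score tables and null-test results.
# All outputs are UTF-8 TSV with header; undefined values are written NA.

#' Write a specialization-diversity score table
#'
#' @param scores a `specdiv` object or compatible data.frame.
#' @param path output path (tab-separated, header, NA for undefined).
#' @export
write_scores <- function(scores, path) {
  utils::write.table(as.data.frame(scores), path, sep = "\t",
                     quote = FALSE, row.names = FALSE, na = "NA")
  invisible(path)
}

#' Read a score table written by [write_scores]
#'
#' @param path input path.
#' @return data.frame of scores (class `specdiv`).
#' @export
read_scores <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, check.names = FALSE,
                          na.strings = "NA", quote = "",
                          colClasses = c(node_id = "character"))
  class(df) <- c("specdiv", "data.frame")
  df
}

#' Write per-node connectivity vectors
#'
#' One row per node and direction with a column per label (NA rows where
#' the vector is undefined).
#'
#' @param net an [annotated_network].
#' @param path output path.
#' @param exclude_self_loops drop self-loop edges (default `TRUE`).
#' @export
write_vectors <- function(net, path, exclude_self_loops = TRUE) {
  rows <- lapply(c("out", "in"), function(d) {
    cm <- .conn_matrix(net, d, exclude_self_loops)
    data.frame(node_id = net$nodes, direction = d, cm$rho,
               check.names = FALSE, stringsAsFactors = FALSE)
  })
  utils::write.table(do.call(rbind, rows), path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  invisible(path)
}

#' Append a null-test result to a TSV summary
#'
#' @param result a `specdiv_nulltest` (or list of them).
#' @param path output path; one row per result.
#' @export
write_nulltest <- function(result, path) {
  if (inherits(result, "specdiv_nulltest")) result <- list(result)
  rows <- do.call(rbind, lapply(result, function(x)
    data.frame(grouping = x$grouping, null_kind = x$null_kind,
               n_observed = x$n_observed, n_null = x$n_null,
               realizations = x$realizations,
               ks_statistic = x$ks_statistic, p_value = x$p_value,
               seed = if (is.null(x$seed)) NA_integer_ else x$seed,
               stringsAsFactors = FALSE)))
  utils::write.table(rows, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  invisible(path)
}
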
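# Reproducible end-to-end runs backing the command-line interface in
# inst/cli/specdiv.R. Each run writes its outputs plus a resolved
# run_config.yaml (inputs, column dialect, flags, seed, package version)
# so a run can be reproduced exactly from its output directory.

.write_run_config <- function(out_dir, config) {
  config$package_version <- as.character(utils::packageVersion("specdiv"))
  yaml::write_yaml(config, file.path(out_dir, "run_config.yaml"))
}

#' Compute scores for an edge list and annotation table on disk
#'
#' Reads the inputs, scores every node with [specdiv], and writes
#' `scores.tsv` (plus `vectors.tsv` when requested) and the resolved run
#' configuration to `out_dir`.
#'
#' @param edges_path,annotations_path input files.
#' @param out_dir output directory (created if needed).
#' @param label_col label column in the annotation table.
#' @param node_col node-id column in the annotation table.
#' @param source_col,target_col,weight_col edge-table column dialect.
#' @param exclude_self_loops drop self-loop edges (default `TRUE`).
#' @param dump_vectors also write per-node connectivity vectors.
#' @return The `specdiv` score table, invisibly.
#' @export
run_compute <- function(edges_path, annotations_path, out_dir,
                        label_col = "label", node_col = "node_id",
                        source_col = "source", target_col = "target",
                        weight_col = "weight",
                        exclude_self_loops = TRUE, dump_vectors = FALSE) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  net <- read_annotated_network(edges_path, annotations_path,
                                source_col, target_col, weight_col,
                                node_col, label_col)
  scores <- specdiv(net, exclude_self_loops = exclude_self_loops)
  write_scores(scores, file.path(out_dir, "scores.tsv"))
  if (dump_vectors)
    write_vectors(net, file.path(out_dir, "vectors.tsv"),
                  exclude_self_loops)
  .write_run_config(out_dir, list(
    command = "compute", edges = edges_path,
    annotations = annotations_path, label_col = label_col,
    node_col = node_col, source_col = source_col,
    target_col = target_col, weight_col = weight_col,
    exclude_self_loops = exclude_self_loops))
  invisible(scores)
}

#' Rank entropic hubs from a score table on disk
#'
#' @param scores_path path to a `scores.tsv` written by [run_compute].
#' @param out_dir output directory.
#' @param k number of hubs (default 10).
#' @return The hub table, invisibly; `hubs.tsv` gains a `tie_straddle`
#'   column flagging whether a tie straddles the cutoff.
#' @export
run_hubs <- function(scores_path, out_dir, k = 10L) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  scores <- read_scores(scores_path)
  hubs <- rank_entropic_hubs(scores, k = k)
  out <- cbind(hubs, tie_straddle = isTRUE(attr(hubs, "tie_straddle")))
  utils::write.table(out, file.path(out_dir, "hubs.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE, na = "NA")
  .write_run_config(out_dir, list(command = "hubs", scores = scores_path,
                                  k = k))
  invisible(hubs)
}

#' Run a null-model test from files on disk
#'
#' Joins the annotation metadata onto the score table, runs
#' [run_null_test], and writes `nulltest.tsv` plus optional distance
#' sidecars for plotting.
#'
#' @param scores_path path to `scores.tsv`.
#' @param annotations_path annotation table carrying the grouping columns.
#' @param group_col grouping column tested.
#' @param null_kind `"side_preserving"`, `"group_preserving"` or
#'   `"all_by_all"`.
#' @param out_dir output directory.
#' @param side_col,stratum_col columns for the sampling nulls.
#' @param node_col,label_col annotation-table dialect.
#' @param realizations,seed,pool passed to [run_null_test].
#' @param write_samples also write `observed_distances.tsv` and
#'   `null_distances.tsv`.
#' @return The `specdiv_nulltest`, invisibly.
#' @export
run_nulltest <- function(scores_path, annotations_path, group_col,
                         null_kind, out_dir,
                         side_col = NULL, stratum_col = NULL,
                         node_col = "node_id", label_col = "label",
                         realizations = 10L, seed = NULL, pool = TRUE,
                         write_samples = FALSE) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  scores <- read_scores(scores_path)
  ann <- read_annotations(annotations_path, node_col, label_col)
  meta <- ann$metadata
  add <- setdiff(colnames(meta), names(scores))
  if (length(add))
    scores <- cbind(as.data.frame(scores),
                    meta[match(scores$node_id, rownames(meta)), add,
                         drop = FALSE])
  res <- run_null_test(scores, group_col, null_kind,
                       side_col = side_col, stratum_col = stratum_col,
                       realizations = realizations, seed = seed,
                       pool = pool)
  write_nulltest(res, file.path(out_dir, "nulltest.tsv"))
  if (write_samples) {
    utils::write.table(data.frame(distance = res$observed),
                       file.path(out_dir, "observed_distances.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(data.frame(distance = res$null_sample),
                       file.path(out_dir, "null_distances.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  .write_run_config(out_dir, list(
    command = "nulltest", scores = scores_path,
    annotations = annotations_path, group_col = group_col,
    null_kind = null_kind, side_col = side_col,
    stratum_col = stratum_col, realizations = realizations, seed = seed,
    pool = pool))
  invisible(res)
}

#' Generate and write a synthetic fixture
#'
#' Writes `edges.csv`, `annotations.tsv`, `truth.tsv` and the resolved
#' `spec.yaml` (including the seed) to `out_dir`.
#'
#' @param spec a [synthetic_spec], or a path to a YAML file of
#'   [synthetic_spec] arguments.
#' @param out_dir output directory.
#' @return The generated simulation list, invisibly.
#' @export
run_simulate <- function(spec, out_dir) {
  if (is.character(spec))
    spec <- do.call(synthetic_spec, yaml::read_yaml(spec))
  stopifnot(inherits(spec, "synthetic_spec"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  sim <- generate_network(spec)
  e <- sim$network$edges
  utils::write.csv(e[order(e$source, e$target), ],
                   file.path(out_dir, "edges.csv"), row.names = FALSE,
                   quote = FALSE)
  ann <- data.frame(node_id = sim$network$nodes,
                    label = unname(sim$network$labels[sim$network$nodes]),
                    sim$network$metadata,
                    stringsAsFactors = FALSE)
  utils::write.table(ann, file.path(out_dir, "annotations.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "NA")
  utils::write.table(sim$truth, file.path(out_dir, "truth.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "NA")
  yaml::write_yaml(unclass(sim$spec), file.path(out_dir, "spec.yaml"))
  invisible(sim)
}
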
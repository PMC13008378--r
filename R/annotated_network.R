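#' Construct an annotated directed network
#'
#' Builds the central data structure of the package: a directed, weighted
#' network whose nodes may carry a categorical annotation label plus optional
#' metadata columns (side, pair id, cell type, ...). Parallel duplicate
#' `(source, target)` rows are summed into a single edge, matching the
#' synapse-count semantics of connectome edge lists.
#'
#' Node identifiers are opaque strings. The label set is the sorted unique
#' set of labels present; this lexicographic order fixes the component order
#' of every connectivity vector produced from the network, so serialized
#' vectors are comparable across runs. Unlabeled nodes are allowed; they
#' never contribute mass to any connectivity vector.
#'
#' @param edges data.frame with columns `source`, `target` and optionally
#'   `weight` (nonnegative; default 1 for every row when absent).
#' @param labels named character vector mapping node id to label. `NA` or
#'   empty-string labels mean "unlabeled" and are dropped.
#' @param metadata data.frame of optional per-node categorical columns with
#'   node ids as row names.
#' @return An object of class `annotated_network`: a list with elements
#'   `edges` (aggregated edge table), `nodes` (sorted id vector), `labels`
#'   (named character vector over labeled nodes), `label_set` (sorted label
#'   universe) and `metadata` (data.frame keyed by node id).
#' @examples
#' net <- annotated_network(
#'   data.frame(source = c("a", "a", "b"), target = c("b", "b", "c"),
#'              weight = c(2, 1, 1)),
#'   labels = c(a = "sensory", b = "inter", c = "motor"))
#' net$edges
#' @export
annotated_network <- function(edges, labels = NULL, metadata = NULL) {
  if (!is.data.frame(edges))
    stop("`edges` must be a data.frame")
  if (!all(c("source", "target") %in% names(edges)))
    stop("edge table must have 'source' and 'target' columns")
  src <- as.character(edges$source)
  tgt <- as.character(edges$target)
  w <- if ("weight" %in% names(edges)) as.numeric(edges$weight) else
    rep(1.0, length(src))
  bad <- which(!is.finite(w) | w < 0)
  if (length(bad))
    stop("negative or non-finite edge weight at row ", bad[1L])

  if (length(src)) {
    key <- paste(src, tgt, sep = "\x1f")
    agg <- rowsum(w, key)
    parts <- strsplit(rownames(agg), "\x1f", fixed = TRUE)
    edges <- data.frame(
      source = vapply(parts, `[`, character(1L), 1L),
      target = vapply(parts, `[`, character(1L), 2L),
      weight = as.numeric(agg),
      stringsAsFactors = FALSE)
  } else {
    edges <- data.frame(source = character(0), target = character(0),
                        weight = numeric(0), stringsAsFactors = FALSE)
  }

  if (!is.null(labels)) {
    labels <- labels[!is.na(labels) & labels != ""]
    labels <- vapply(labels, as.character, character(1L))
  } else {
    labels <- character(0)
  }

  nodes <- sort(unique(c(edges$source, edges$target, names(labels),
                         if (!is.null(metadata)) rownames(metadata))))

  meta <- data.frame(row.names = nodes)
  if (!is.null(metadata) && ncol(metadata) > 0) {
    for (cn in colnames(metadata)) {
      col <- rep(NA_character_, length(nodes))
      idx <- match(rownames(metadata), nodes)
      col[idx[!is.na(idx)]] <- as.character(metadata[[cn]][!is.na(idx)])
      meta[[cn]] <- col
    }
  }

  structure(
    list(edges = edges,
         nodes = nodes,
         labels = labels,
         label_set = sort(unique(unname(labels))),
         metadata = meta),
    class = "annotated_network")
}

#' @export
print.annotated_network <- function(x, ...) {
  cat("Annotated directed network\n")
  cat(sprintf("  nodes: %d (%d labeled over %d labels)\n",
              length(x$nodes), length(x$labels), length(x$label_set)))
  cat(sprintf("  edges: %d (total weight %.6g)\n",
              nrow(x$edges), sum(x$edges$weight)))
  if (ncol(x$metadata))
    cat("  metadata columns:", paste(colnames(x$metadata), collapse = ", "),
        "\n")
  invisible(x)
}

.guess_sep <- function(path) {
  if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
}

#' Read a directed weighted edge list
#'
#' Reads a delimited edge table (CSV when the file ends in `.csv`, TSV
#' otherwise, unless `sep` is given). Duplicate `(source, target)` rows are
#' summed; a missing weight column means every edge has weight 1.
#'
#' @param path file path.
#' @param source_col,target_col,weight_col column names in the file header.
#' @param sep field separator; `NULL` (default) guesses from the extension.
#' @return An [annotated_network] with edges only (no labels yet).
#' @export
read_edges <- function(path, source_col = "source", target_col = "target",
                       weight_col = "weight", sep = NULL) {
  if (is.null(sep)) sep <- .guess_sep(path)
  tab <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE, check.names = FALSE,
                           quote = "\"", comment.char = "")
  for (cn in c(source_col, target_col))
    if (!cn %in% names(tab))
      stop("edge file is missing required column '", cn, "'")
  w <- if (weight_col %in% names(tab)) as.numeric(tab[[weight_col]]) else
    rep(1.0, nrow(tab))
  bad <- which(!is.finite(w) | w < 0)
  if (length(bad))
    stop("negative or non-finite weight in edge file at data row ", bad[1L])
  annotated_network(data.frame(source = as.character(tab[[source_col]]),
                               target = as.character(tab[[target_col]]),
                               weight = w, stringsAsFactors = FALSE))
}

#' Read a node annotation table
#'
#' @param path file path of a delimited table with a node-id column, a label
#'   column (empty or NA cells mean "unlabeled") and any number of extra
#'   metadata columns, which are retained.
#' @param node_col name of the node-id column.
#' @param label_col name of the label column.
#' @param sep field separator; `NULL` guesses from the extension.
#' @return list with `labels` (named character vector over labeled nodes)
#'   and `metadata` (data.frame of the remaining columns, node ids as row
#'   names).
#' @export
read_annotations <- function(path, node_col = "node_id", label_col = "label",
                             sep = NULL) {
  if (is.null(sep)) sep <- .guess_sep(path)
  tab <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE, check.names = FALSE,
                           quote = "\"", comment.char = "",
                           na.strings = c("NA", ""))
  if (!node_col %in% names(tab))
    stop("annotation file is missing node-id column '", node_col, "'")
  if (!label_col %in% names(tab))
    stop("annotation file is missing label column '", label_col, "'")
  ids <- as.character(tab[[node_col]])
  dup <- ids[duplicated(ids)]
  if (length(dup))
    stop("duplicate node id(s) in annotation file: ",
         paste(unique(dup), collapse = ", "))
  lab <- as.character(tab[[label_col]])
  keep <- !is.na(lab) & lab != ""
  labels <- stats::setNames(lab[keep], ids[keep])
  meta_cols <- setdiff(names(tab), c(node_col, label_col))
  metadata <- tab[, meta_cols, drop = FALSE]
  rownames(metadata) <- ids
  list(labels = labels, metadata = metadata)
}

#' Attach annotations to a network
#'
#' Nodes present in the annotation table but absent from the edge set are
#' added as isolated nodes, with a warning.
#'
#' @param net an [annotated_network].
#' @param annotations the list returned by [read_annotations], or a named
#'   character vector of labels.
#' @return A new [annotated_network] carrying the labels and metadata.
#' @export
set_annotations <- function(net, annotations) {
  stopifnot(inherits(net, "annotated_network"))
  if (is.character(annotations))
    annotations <- list(labels = annotations,
                        metadata = data.frame(row.names =
                                                names(annotations)))
  extra <- setdiff(unique(c(names(annotations$labels),
                            rownames(annotations$metadata))), net$nodes)
  if (length(extra))
    warning(length(extra), " annotated node(s) absent from the edge set ",
            "added as isolated nodes: ",
            paste(utils::head(extra, 5L), collapse = ", "),
            if (length(extra) > 5L) ", ..." else "")
  annotated_network(net$edges, labels = annotations$labels,
                    metadata = annotations$metadata)
}

#' Read edges and annotations into one annotated network
#'
#' @inheritParams read_edges
#' @inheritParams read_annotations
#' @param edges_path,annotations_path file paths.
#' @return An [annotated_network].
#' @export
read_annotated_network <- function(edges_path, annotations_path,
                                   source_col = "source",
                                   target_col = "target",
                                   weight_col = "weight",
                                   node_col = "node_id",
                                   label_col = "label") {
  net <- read_edges(edges_path, source_col, target_col, weight_col)
  ann <- read_annotations(annotations_path, node_col, label_col)
  set_annotations(net, ann)
}

#' Write the aggregated edge table
#'
#' Tab-separated with header `source target weight`, rows sorted by
#' (source, target), so output is independent of the input row order.
#'
#' @param net an [annotated_network].
#' @param path output file path.
#' @export
write_edges <- function(net, path) {
  stopifnot(inherits(net, "annotated_network"))
  e <- net$edges[order(net$edges$source, net$edges$target), , drop = FALSE]
  utils::write.table(e, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# positive-weight edge rows, optionally without self-loops
.active_edges <- function(net, exclude_self_loops = TRUE) {
  e <- net$edges[net$edges$weight > 0, , drop = FALSE]
  if (exclude_self_loops) e <- e[e$source != e$target, , drop = FALSE]
  e
}

#' Upstream and downstream partner sets of a node
#'
#' Partners are unweighted: a partner appears once however strong the
#' connection. Self-loops are excluded by default, so a node is never its
#' own partner.
#'
#' @param net an [annotated_network].
#' @param node a node id.
#' @param exclude_self_loops drop self-loop edges (default `TRUE`).
#' @return list with sorted character vectors `upstream` (nodes with an edge
#'   into `node`) and `downstream` (nodes `node` sends an edge to).
#' @export
partner_sets <- function(net, node, exclude_self_loops = TRUE) {
  stopifnot(inherits(net, "annotated_network"))
  if (!node %in% net$nodes) stop("unknown node id: ", node)
  e <- .active_edges(net, exclude_self_loops)
  list(upstream = sort(unique(e$source[e$target == node])),
       downstream = sort(unique(e$target[e$source == node])))
}

#' Partner counts and normalized degree for every node
#'
#' Degree counts distinct partners in either direction (the union of the
#' upstream and downstream partner sets); a reciprocally connected partner
#' counts once. Normalized degree divides by the maximum degree in the
#' network (0 when the maximum is 0), an order-preserving rescaling to
#' `[0, 1]`.
#'
#' @inheritParams partner_sets
#' @return data.frame with columns `node_id`, `n_up`, `n_down`, `degree`,
#'   `normalized_degree`, one row per node in sorted id order.
#' @export
degree_stats <- function(net, exclude_self_loops = TRUE) {
  stopifnot(inherits(net, "annotated_network"))
  e <- .active_edges(net, exclude_self_loops)
  nodes <- net$nodes
  count_distinct <- function(owner, partner) {
    if (!length(owner))
      return(stats::setNames(integer(length(nodes)), nodes))
    key <- !duplicated(paste(owner, partner, sep = "\x1f"))
    tab <- table(factor(owner[key], levels = nodes))
    stats::setNames(as.integer(tab), nodes)
  }
  n_down <- count_distinct(e$source, e$target)
  n_up <- count_distinct(e$target, e$source)
  both <- count_distinct(c(e$source, e$target), c(e$target, e$source))
  mx <- if (length(both) && max(both) > 0) max(both) else NA_integer_
  data.frame(node_id = nodes,
             n_up = unname(n_up),
             n_down = unname(n_down),
             degree = unname(both),
             normalized_degree = if (is.na(mx)) rep(0, length(nodes)) else
               unname(both) / mx,
             stringsAsFactors = FALSE)
}
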
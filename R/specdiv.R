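#' Shannon entropy of a probability vector
#'
#' Natural-log Shannon entropy with the convention `0 * log(0) = 0`, in
#' nats. The vector must sum to 1 within `tol`; entropy of a connectivity
#' vector over M labels lies in `[0, log(M)]` — 0 means the node is fully
#' specialized in one label, `log(M)` means it connects to all labels
#' equally.
#'
#' @param p numeric vector of nonnegative components summing to 1.
#' @param tol normalization tolerance (default 1e-9).
#' @return Entropy in nats.
#' @examples
#' shannon_entropy(c(1, 0, 0))        # 0
#' shannon_entropy(rep(1 / 3, 3))     # log(3)
#' @export
shannon_entropy <- function(p, tol = 1e-9) {
  p <- as.numeric(p)
  if (any(!is.finite(p)) || any(p < 0))
    stop("probability components must be finite and nonnegative")
  if (abs(sum(p) - 1) > tol)
    stop("components must sum to 1 (got ", format(sum(p)), ")")
  p <- p[p > 0]
  -sum(p * log(p)) + 0   # + 0 normalizes IEEE negative zero
}

# row-wise entropy of a matrix of probability vectors (no validation)
.entropy_rows <- function(m) {
  ml <- m * log(m)
  ml[m == 0] <- 0
  -rowSums(ml) + 0
}

#' Specialization-diversity of a set of probability vectors
#'
#' For a set of N normalized connectivity vectors over a common label order,
#' computes the mean entropy `S_bar`, the componentwise mean vector `p_bar`
#' (itself a probability vector), its entropy `S(p_bar)`, and their
#' difference
#' \deqn{\Delta S = S(\bar p) - \bar S,}
#' the specialization-diversity. Jensen's inequality for the concave entropy
#' function guarantees \eqn{\Delta S \ge 0}; it is large only when the
#' vectors are individually specialized (low entropy) but in diverse labels
#' (high-entropy mean). Each vector counts once — the set is unweighted.
#'
#' @param vectors matrix with one probability vector per row, or a list of
#'   equal-length numeric vectors. At least one vector.
#' @param tol per-vector normalization tolerance.
#' @return list with `delta_s`, `mean_entropy` (S_bar), `entropy_of_mean`
#'   (S(p_bar)), and `n_vectors`.
#' @examples
#' # three vectors fully specialized in three distinct labels
#' specialization_diversity(diag(3))$delta_s          # log(3)
#' # identical fully-specialized vectors: S_bar = S(p_bar) = 0
#' specialization_diversity(rbind(c(1, 0), c(1, 0)))$delta_s  # 0
#' @export
specialization_diversity <- function(vectors, tol = 1e-9) {
  if (is.list(vectors) && !is.data.frame(vectors)) {
    len <- unique(lengths(vectors))
    if (length(len) != 1L)
      stop("all vectors must have the same length")
    vectors <- do.call(rbind, vectors)
  }
  m <- as.matrix(vectors)
  storage.mode(m) <- "double"
  if (nrow(m) < 1L) stop("need at least one vector")
  if (any(!is.finite(m)) || any(m < 0))
    stop("vector components must be finite and nonnegative")
  rs <- rowSums(m)
  if (any(abs(rs - 1) > tol))
    stop("every vector must sum to 1 within tolerance ", tol)
  s_bar <- mean(.entropy_rows(m))
  p_bar <- colMeans(m)
  s_pbar <- .entropy_rows(matrix(p_bar, nrow = 1L))
  list(delta_s = s_pbar - s_bar,
       mean_entropy = s_bar,
       entropy_of_mean = s_pbar,
       n_vectors = nrow(m))
}

# Connectivity vectors for all nodes in one direction.
# Returns list(nu, rho, mass, entropy); rho rows are NA where mass == 0
# (vector undefined: no labeled strength in that direction).
.conn_matrix <- function(net, direction = c("out", "in"),
                         exclude_self_loops = TRUE) {
  direction <- match.arg(direction)
  L <- net$label_set
  if (!length(L)) stop("network has no labeled nodes")
  e <- .active_edges(net, exclude_self_loops)
  if (direction == "out") {
    owner <- e$source; partner <- e$target
  } else {
    owner <- e$target; partner <- e$source
  }
  lab <- unname(net$labels[partner])        # NA for unlabeled partners
  keep <- !is.na(lab)
  owner <- owner[keep]; lab <- lab[keep]; w <- e$weight[keep]
  n <- length(net$nodes)
  nu <- matrix(0, n, length(L), dimnames = list(net$nodes, L))
  if (length(owner)) {
    cell <- (match(lab, L) - 1L) * n + match(owner, net$nodes)
    agg <- rowsum(w, cell)
    nu[as.integer(rownames(agg))] <- agg
  }
  mass <- rowSums(nu)
  rho <- nu / mass                          # rows with mass 0 become NaN
  rho[mass == 0, ] <- NA_real_
  ent <- rep(NA_real_, n)
  ok <- mass > 0
  if (any(ok)) ent[ok] <- .entropy_rows(rho[ok, , drop = FALSE])
  names(ent) <- net$nodes
  list(nu = nu, rho = rho, mass = mass, entropy = ent)
}

#' Annotation connectivity vector of a node
#'
#' The out-vector of node i has components \eqn{\nu_{ij} = \sum_z a_{iz}
#' b_{zj}}: the total edge weight from i to partners carrying label j,
#' normalized to the probability vector \eqn{\rho_i}. The in-vector uses the
#' transposed adjacency (weight into i). Unlabeled partners contribute
#' nothing; when the node has zero labeled strength in the requested
#' direction the vector is undefined and `NULL` is returned.
#'
#' @param net an [annotated_network].
#' @param node node id.
#' @param direction `"out"` or `"in"`.
#' @param exclude_self_loops drop self-loop edges (default `TRUE`).
#' @return Named numeric vector over the network's sorted label set, with
#'   attribute `raw_mass` (the unnormalized totals), or `NULL` when
#'   undefined.
#' @export
connectivity_vector <- function(net, node, direction = c("out", "in"),
                                exclude_self_loops = TRUE) {
  stopifnot(inherits(net, "annotated_network"))
  if (!node %in% net$nodes) stop("unknown node id: ", node)
  cm <- .conn_matrix(net, direction, exclude_self_loops)
  i <- match(node, net$nodes)
  if (cm$mass[i] == 0) return(NULL)
  structure(cm$rho[i, ], raw_mass = cm$nu[i, ])
}

# shared workhorse: full score table as plain data.frame
.score_table <- function(net, exclude_self_loops = TRUE) {
  cm_out <- .conn_matrix(net, "out", exclude_self_loops)
  cm_in <- .conn_matrix(net, "in", exclude_self_loops)
  e <- .active_edges(net, exclude_self_loops)
  down <- lapply(split(e$target, e$source), unique)
  up <- lapply(split(e$source, e$target), unique)

  one_side <- function(partners, cm) {
    # specialization-diversity over the defined vectors of `partners`
    if (is.null(partners))
      return(c(NA_real_, 0, 0))
    idx <- match(partners, net$nodes)
    idx <- idx[cm$mass[idx] > 0]
    n_dropped <- length(partners) - length(idx)
    if (!length(idx)) return(c(NA_real_, 0, n_dropped))
    p_bar <- colMeans(cm$rho[idx, , drop = FALSE])
    ds <- .entropy_rows(matrix(p_bar, 1L)) - mean(cm$entropy[idx])
    c(ds, length(idx), n_dropped)
  }

  n <- length(net$nodes)
  out <- matrix(NA_real_, n, 6L)
  for (i in seq_len(n)) {
    id <- net$nodes[i]
    out[i, 1:3] <- one_side(down[[id]], cm_out)
    out[i, 4:6] <- one_side(up[[id]], cm_in)
  }
  ds_d_out <- out[, 1]
  ds_u_in <- out[, 4]
  deg <- degree_stats(net, exclude_self_loops)
  df <- data.frame(
    node_id = net$nodes,
    ds_u_in = ds_u_in,
    ds_d_out = ds_d_out,
    ds_sum = ds_u_in + ds_d_out,
    ds_diff = ds_d_out - ds_u_in,
    n_up_vectors = as.integer(out[, 5]),
    n_down_vectors = as.integer(out[, 2]),
    n_up_dropped = as.integer(out[, 6]),
    n_down_dropped = as.integer(out[, 3]),
    degree = deg$degree,
    normalized_degree = deg$normalized_degree,
    stringsAsFactors = FALSE)
  if (ncol(net$metadata))
    df <- cbind(df, net$metadata[df$node_id, , drop = FALSE])
  rownames(df) <- NULL
  df
}

#' Specialization-diversity of one node
#'
#' The distributive score `ds_d_out` is the specialization-diversity of the
#' out-vectors of the node's distinct downstream partners; the integrative
#' score `ds_u_in` uses the in-vectors of its distinct upstream partners.
#' Partners whose relevant vector is undefined (no labeled strength) are
#' dropped and counted in the `*_dropped` diagnostics. A score is `NA` when
#' no partner vector remains — i.e. the node is on no directed two-path as
#' source (distributive) or sink (integrative). `NA` is distinct from 0,
#' which means the partner set is identically specialized.
#'
#' @inheritParams connectivity_vector
#' @return One-row data.frame with the same columns as [specdiv] output.
#' @export
node_specdiv <- function(net, node, exclude_self_loops = TRUE) {
  stopifnot(inherits(net, "annotated_network"))
  if (!node %in% net$nodes) stop("unknown node id: ", node)
  tab <- .score_table(net, exclude_self_loops)
  tab[tab$node_id == node, , drop = FALSE]
}

#' Score every node's specialization-diversity
#'
#' The main entry point: computes, for every node, the integrative
#' (`ds_u_in`) and distributive (`ds_d_out`) specialization-diversities,
#' their sum (the entropic-hub ranking quantity), their difference
#' (`ds_diff = ds_d_out - ds_u_in`, how much more distributive than
#' integrative a node is), partner-vector counts, and degree statistics.
#' Any metadata columns on the network are appended to the returned table.
#'
#' @param net an [annotated_network] with at least one labeled node.
#' @param exclude_self_loops drop self-loop edges throughout (default
#'   `TRUE`).
#' @return An object of class `specdiv` (a data.frame, one row per node in
#'   sorted id order) with print, summary and plot methods.
#' @examples
#' net <- annotated_network(
#'   data.frame(source = c("s", "s", "h1", "h2"),
#'              target = c("h1", "h2", "a", "b")),
#'   labels = c(h1 = "X", h2 = "X", a = "A", b = "B"))
#' specdiv(net)
#' @export
specdiv <- function(net, exclude_self_loops = TRUE) {
  stopifnot(inherits(net, "annotated_network"))
  df <- .score_table(net, exclude_self_loops)
  structure(df,
            labels = net$label_set,
            exclude_self_loops = exclude_self_loops,
            call = match.call(),
            class = c("specdiv", "data.frame"))
}

#' @export
as.data.frame.specdiv <- function(x, ...) {
  attr(x, "labels") <- NULL
  attr(x, "call") <- NULL
  attr(x, "exclude_self_loops") <- NULL
  class(x) <- "data.frame"
  x
}

#' @export
print.specdiv <- function(x, ...) {
  n_scored <- sum(!is.na(x$ds_sum))
  cat(sprintf(
    "Specialization-diversity scores: %d nodes (%d with both motifs), %d labels\n",
    nrow(x), n_scored, length(attr(x, "labels"))))
  print.data.frame(utils::head(as.data.frame(x), 10L), digits = 4)
  if (nrow(x) > 10L) cat("  ... ", nrow(x) - 10L, " more rows\n", sep = "")
  invisible(x)
}

#' @export
summary.specdiv <- function(object, k = 10L, ...) {
  res <- list(
    n_nodes = nrow(object),
    n_labels = length(attr(object, "labels")),
    n_scored = sum(!is.na(object$ds_sum)),
    ds_u_in = summary(object$ds_u_in),
    ds_d_out = summary(object$ds_d_out),
    hubs = rank_entropic_hubs(object, k = min(k, max(
      1L, sum(!is.na(object$ds_sum))))))
  class(res) <- "summary.specdiv"
  res
}

#' @export
print.summary.specdiv <- function(x, ...) {
  cat(sprintf("Specialization-diversity over %d nodes, %d labels (%d scored in both motifs)\n",
              x$n_nodes, x$n_labels, x$n_scored))
  cat("ds_u_in (integrative):\n"); print(x$ds_u_in)
  cat("ds_d_out (distributive):\n"); print(x$ds_d_out)
  cat("Top entropic hubs by ds_sum:\n")
  print.data.frame(x$hubs, digits = 4)
  invisible(x)
}

#' Scatter plot of integrative versus distributive scores
#'
#' Draws the per-node `(ds_d_out, ds_u_in)` scatter with the `y = x` guide
#' (equally integrative and distributive) and the top-`k` entropic hubs
#' highlighted as red squares.
#'
#' @param x a `specdiv` object.
#' @param k number of hubs to highlight (default 10).
#' @param ... passed to [graphics::plot].
#' @export
plot.specdiv <- function(x, k = 10L, ...) {
  ok <- !is.na(x$ds_sum)
  graphics::plot(x$ds_d_out[ok], x$ds_u_in[ok],
                 xlab = expression(Delta * S^{D * ",out"}),
                 ylab = expression(Delta * S^{U * ",in"}),
                 pch = 16, col = grDevices::adjustcolor("black", 0.35), ...)
  graphics::abline(0, 1, lty = 3, col = "red")
  if (any(ok)) {
    hubs <- rank_entropic_hubs(x, k = min(k, sum(ok)))
    sel <- match(hubs$node_id, x$node_id)
    graphics::points(x$ds_d_out[sel], x$ds_u_in[sel], pch = 15, col = "red")
  }
  invisible(x)
}

#' Rank entropic hubs
#'
#' Orders nodes by decreasing `ds_sum = ds_u_in + ds_d_out`, the summed
#' integrative and distributive specialization-diversity; the top 10 of this
#' ranking are the network's "entropic hubs". Nodes with an undefined
#' `ds_sum` are excluded. Ties are broken by node id ascending; when a tie
#' straddles the cutoff the result carries attribute `tie_straddle = TRUE`.
#'
#' @param scores a `specdiv` object or compatible data.frame.
#' @param k how many nodes to return (default 10). If `k` exceeds the number
#'   of scored nodes, all are returned with a warning.
#' @return data.frame with columns `rank`, `node_id`, `ds_u_in`, `ds_d_out`,
#'   `ds_sum`, `degree`, `normalized_degree`; attribute `tie_straddle`.
#' @export
rank_entropic_hubs <- function(scores, k = 10L) {
  if (k < 1L) stop("k must be >= 1")
  s <- as.data.frame(scores)
  s <- s[!is.na(s$ds_sum), , drop = FALSE]
  if (!nrow(s)) stop("no node has both motif scores defined")
  if (k > nrow(s)) {
    warning("k = ", k, " exceeds the ", nrow(s),
            " scored nodes; returning all")
    k <- nrow(s)
  }
  ord <- order(-s$ds_sum, s$node_id)
  s <- s[ord, , drop = FALSE]
  straddle <- k < nrow(s) && isTRUE(s$ds_sum[k] == s$ds_sum[k + 1L])
  cols <- intersect(c("node_id", "ds_u_in", "ds_d_out", "ds_sum",
                      "degree", "normalized_degree"), names(s))
  res <- cbind(rank = seq_len(k), s[seq_len(k), cols, drop = FALSE])
  rownames(res) <- NULL
  attr(res, "tie_straddle") <- straddle
  res
}
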
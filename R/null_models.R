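# Pairwise entropic distances and randomized null-model tests.
#
# A node's position in the (ds_d_out, ds_u_in) plane summarizes its
# distributive and integrative specialization-diversity; the Euclidean
# distance in that plane ("pairwise entropic vector distance") measures how
# similar two nodes are in this respect. The null models resample node
# groupings only — scores (and thus connectivity vectors) are never
# recomputed.

# evaluate expr under a temporary RNG state seeded with `seed`
.with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# matrix of (ds_d_out, ds_u_in) over fully-scored nodes, rownames node ids
.score_frame <- function(scores) {
  s <- as.data.frame(scores)
  for (cn in c("node_id", "ds_d_out", "ds_u_in"))
    if (!cn %in% names(s)) stop("scores table lacks column '", cn, "'")
  ok <- !is.na(s$ds_d_out) & !is.na(s$ds_u_in)
  m <- cbind(ds_d_out = s$ds_d_out[ok], ds_u_in = s$ds_u_in[ok])
  rownames(m) <- s$node_id[ok]
  m
}

#' Pairwise entropic distance between two scored nodes
#'
#' Euclidean distance in the (`ds_d_out`, `ds_u_in`) plane:
#' \deqn{d_{ij} = \sqrt{(\Delta S^{D,out}_i - \Delta S^{D,out}_j)^2 +
#'   (\Delta S^{U,in}_i - \Delta S^{U,in}_j)^2}.}
#'
#' @param s1,s2 one-row score records (as returned by [node_specdiv]) or
#'   numeric vectors `c(ds_d_out, ds_u_in)`. Both components must be
#'   defined.
#' @return Nonnegative distance; 0 iff the two score vectors are equal.
#' @export
entropic_distance <- function(s1, s2) {
  pick <- function(s) {
    if (is.numeric(s) && length(s) == 2L) return(as.numeric(s))
    s <- as.data.frame(s)
    c(s$ds_d_out[1L], s$ds_u_in[1L])
  }
  a <- pick(s1); b <- pick(s2)
  if (any(is.na(a)) || any(is.na(b)))
    stop("entropic distance requires both ds_d_out and ds_u_in defined")
  sqrt(sum((a - b)^2))
}

# all unordered pairwise distances among rows of a 2-column matrix
.pair_dists <- function(m) as.numeric(stats::dist(m))

#' Within-group pairwise entropic distances
#'
#' For every group (level of `group_col`) with at least two fully-scored
#' members, collects the entropic distances of all unordered within-group
#' pairs. Groups reduced below two scoreable members are skipped and listed
#' in the `skipped_groups` attribute.
#'
#' @param scores a `specdiv` object or data.frame containing `node_id`,
#'   `ds_u_in`, `ds_d_out` and the grouping column.
#' @param group_col name of the metadata column defining the fine grouping
#'   (e.g. a left-right pair id, serial-homologue group or cell type).
#' @return Numeric vector of distances with attributes `n_groups_used` and
#'   `skipped_groups`.
#' @export
within_group_distances <- function(scores, group_col) {
  s <- as.data.frame(scores)
  if (!group_col %in% names(s))
    stop("unknown grouping column '", group_col, "'")
  m <- .score_frame(s)
  grp <- s[[group_col]][match(rownames(m), s$node_id)]
  keep <- !is.na(grp)
  m <- m[keep, , drop = FALSE]
  grp <- grp[keep]
  all_groups <- unique(s[[group_col]][!is.na(s[[group_col]])])
  idx <- split(seq_len(nrow(m)), grp)
  usable <- vapply(idx, length, 1L) >= 2L
  d <- unlist(lapply(idx[usable], function(i)
    .pair_dists(m[i, , drop = FALSE])), use.names = FALSE)
  if (is.null(d)) d <- numeric(0)
  structure(d,
            n_groups_used = sum(usable),
            skipped_groups = sort(setdiff(all_groups,
                                          names(idx)[usable])))
}

#' Side-preserving null distances
#'
#' Samples `n_pairs` random pairs, one node uniformly from each body side
#' (so every null pair spans the two halves, like a genuine left-right
#' pair), and returns their entropic distances. Scores are resampled, never
#' recomputed. With more than two sides, each pair first draws two distinct
#' sides uniformly.
#'
#' @inheritParams within_group_distances
#' @param side_col metadata column giving each node's side.
#' @param n_pairs number of random pairs (>= 1).
#' @return Numeric vector of `n_pairs` distances.
#' @export
side_preserving_null <- function(scores, side_col, n_pairs) {
  if (n_pairs < 1L) stop("n_pairs must be >= 1")
  s <- as.data.frame(scores)
  if (!side_col %in% names(s))
    stop("unknown side column '", side_col, "'")
  m <- .score_frame(s)
  side <- s[[side_col]][match(rownames(m), s$node_id)]
  keep <- !is.na(side)
  m <- m[keep, , drop = FALSE]
  side <- side[keep]
  sides <- sort(unique(side))
  if (length(sides) < 2L)
    stop("need at least two sides with scoreable nodes")
  pool <- split(seq_len(nrow(m)), side)
  if (any(lengths(pool) == 0L))
    stop("a side has no scoreable nodes")
  if (length(sides) == 2L) {
    i1 <- pool[[1L]][sample.int(length(pool[[1L]]), n_pairs, replace = TRUE)]
    i2 <- pool[[2L]][sample.int(length(pool[[2L]]), n_pairs, replace = TRUE)]
  } else {
    i1 <- integer(n_pairs); i2 <- integer(n_pairs)
    for (p in seq_len(n_pairs)) {
      ss <- sample(sides, 2L)
      a <- pool[[ss[1L]]]; b <- pool[[ss[2L]]]
      i1[p] <- a[sample.int(length(a), 1L)]
      i2[p] <- b[sample.int(length(b), 1L)]
    }
  }
  sqrt(rowSums((m[i1, , drop = FALSE] - m[i2, , drop = FALSE])^2))
}

#' Stratum-preserving random-group null distances
#'
#' Builds `n_groups` random groups by drawing one scoreable node uniformly
#' from each stratum (e.g. one neuron per leg neuropil for serial-homologue
#' groups of six), pooling all within-group pairwise entropic distances.
#' The number of strata must equal the group size.
#'
#' @inheritParams within_group_distances
#' @param stratum_col metadata column giving each node's stratum.
#' @param group_size size of each random group; must equal the number of
#'   strata with scoreable members.
#' @param n_groups number of random groups (>= 1).
#' @return Numeric vector of `n_groups * choose(group_size, 2)` distances.
#' @export
group_preserving_null <- function(scores, stratum_col, group_size,
                                  n_groups) {
  if (n_groups < 1L) stop("n_groups must be >= 1")
  s <- as.data.frame(scores)
  if (!stratum_col %in% names(s))
    stop("unknown stratum column '", stratum_col, "'")
  m <- .score_frame(s)
  strat <- s[[stratum_col]][match(rownames(m), s$node_id)]
  keep <- !is.na(strat)
  m <- m[keep, , drop = FALSE]
  strat <- strat[keep]
  pool <- split(seq_len(nrow(m)), strat)
  if (any(lengths(pool) == 0L))
    stop("a stratum has no scoreable nodes")
  if (length(pool) != group_size)
    stop("number of strata (", length(pool),
         ") must equal group_size (", group_size, ")")
  out <- vector("list", n_groups)
  for (g in seq_len(n_groups)) {
    pick <- vapply(pool, function(ix) ix[sample.int(length(ix), 1L)], 1L)
    out[[g]] <- .pair_dists(m[pick, , drop = FALSE])
  }
  unlist(out, use.names = FALSE)
}

#' All-by-all null distances
#'
#' Entropic distances over every unordered pair of distinct scoreable
#' nodes. Deterministic — no sampling — and invariant to node ordering.
#'
#' @inheritParams within_group_distances
#' @return Numeric vector of `n * (n - 1) / 2` distances.
#' @export
all_by_all_null <- function(scores) {
  m <- .score_frame(as.data.frame(scores))
  m <- m[order(rownames(m)), , drop = FALSE]
  if (nrow(m) < 2L) stop("need at least two scoreable nodes")
  .pair_dists(m)
}

#' Null-model significance test of within-group similarity
#'
#' Compares the within-group entropic-distance sample against a randomized
#' null with a two-sample, two-sided Kolmogorov-Smirnov test. The null
#' sample pools `realizations` independent draws (default 10), each matched
#' in size to the observed sample; the all-by-all null is deterministic and
#' ignores `realizations`. Exact KS p-values are used automatically when
#' both samples have fewer than 30 observations, asymptotic otherwise.
#'
#' With `pool = FALSE` the KS test is instead run once per realization and
#' the median statistic and p-value are reported.
#'
#' @inheritParams within_group_distances
#' @param null_kind one of `"side_preserving"`, `"group_preserving"`,
#'   `"all_by_all"`.
#' @param side_col side column (side-preserving null only).
#' @param stratum_col stratum column (group-preserving null only). The group
#'   size is the number of strata.
#' @param realizations number of null realizations pooled (default 10).
#' @param seed integer seed; the whole result is reproducible given the
#'   seed and recorded in the output.
#' @param pool pool realizations into one null sample before a single KS
#'   test (default), or test per realization and report medians.
#' @return Object of class `specdiv_nulltest`: list with `grouping`,
#'   `null_kind`, `n_observed`, `n_null`, `realizations`, `ks_statistic`,
#'   `p_value`, `seed`, `pooled`, and the `observed` and `null_sample`
#'   distance vectors.
#' @export
run_null_test <- function(scores, group_col,
                          null_kind = c("side_preserving",
                                        "group_preserving", "all_by_all"),
                          side_col = NULL, stratum_col = NULL,
                          realizations = 10L, seed = NULL, pool = TRUE) {
  null_kind <- match.arg(null_kind)
  observed <- within_group_distances(scores, group_col)
  if (!length(observed))
    stop("no within-group distances: every group of '", group_col,
         "' has fewer than two scoreable members")
  n_obs <- length(observed)

  draw_null <- function() {
    switch(null_kind,
      side_preserving = {
        if (is.null(side_col))
          stop("side_col is required for the side-preserving null")
        side_preserving_null(scores, side_col, n_pairs = n_obs)
      },
      group_preserving = {
        if (is.null(stratum_col))
          stop("stratum_col is required for the group-preserving null")
        s <- as.data.frame(scores)
        g <- length(unique(stats::na.omit(
          s[[stratum_col]][!is.na(s$ds_d_out) & !is.na(s$ds_u_in)])))
        n_groups <- max(1L, round(n_obs / choose(g, 2)))
        group_preserving_null(scores, stratum_col, group_size = g,
                              n_groups = n_groups)
      })
  }

  res <- .with_seed(seed, {
    if (null_kind == "all_by_all") {
      null_sample <- all_by_all_null(scores)
      realizations <- 1L
      draws <- list(null_sample)
    } else {
      draws <- replicate(realizations, draw_null(), simplify = FALSE)
      null_sample <- unlist(draws, use.names = FALSE)
    }
    if (pool) {
      exact <- n_obs < 30L && length(null_sample) < 30L
      ks <- suppressWarnings(
        stats::ks.test(observed, null_sample, exact = exact))
      list(D = unname(ks$statistic), p = ks$p.value,
           null_sample = null_sample)
    } else {
      kss <- lapply(draws, function(d) {
        exact <- n_obs < 30L && length(d) < 30L
        suppressWarnings(stats::ks.test(observed, d, exact = exact))
      })
      list(D = stats::median(vapply(kss, function(k)
             unname(k$statistic), 1.0)),
           p = stats::median(vapply(kss, function(k) k$p.value, 1.0)),
           null_sample = null_sample)
    }
  })

  structure(
    list(grouping = group_col,
         null_kind = null_kind,
         n_observed = n_obs,
         n_null = length(res$null_sample),
         realizations = realizations,
         ks_statistic = res$D,
         p_value = res$p,
         seed = seed,
         pooled = pool,
         observed = as.numeric(observed),
         null_sample = res$null_sample),
    class = "specdiv_nulltest")
}

#' @export
print.specdiv_nulltest <- function(x, ...) {
  cat("Entropic-distance null-model test\n")
  cat(sprintf("  grouping: %s   null: %s\n", x$grouping, x$null_kind))
  cat(sprintf("  observed pairs: %d   null sample: %d (%d realization%s%s)\n",
              x$n_observed, x$n_null, x$realizations,
              if (x$realizations == 1L) "" else "s",
              if (x$pooled) ", pooled" else ", per-realization medians"))
  cat(sprintf("  KS statistic: %.4f   p-value: %.4g\n",
              x$ks_statistic, x$p_value))
  if (!is.null(x$seed)) cat("  seed:", x$seed, "\n")
  invisible(x)
}
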
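# Seeded generator of annotated directed networks with planted structure.
#
# The generator is the package's fixture source and parameter-recovery
# testbed: it produces connectome-like networks with (i) background nodes
# whose outgoing connectivity follows a Dirichlet label profile, (ii)
# planted "diverse hubs" whose two-hop neighborhoods are specialized in
# distinct labels (high specialization-diversity by construction), (iii)
# planted "same-specialization" controls whose neighborhoods are specialized
# in one shared label (near-zero specialization-diversity), and (iv)
# mirrored left-right node pairs with near-identical partner sets.

# symmetric Dirichlet draw via normalized gammas
.rdirichlet1 <- function(m, concentration) {
  g <- stats::rgamma(m, shape = concentration)
  s <- sum(g)
  if (s == 0) {                  # guard against deep underflow at tiny kappa
    out <- numeric(m)
    out[sample.int(m, 1L)] <- 1
    return(out)
  }
  g / s
}

#' Sample a label profile from a symmetric Dirichlet
#'
#' The concentration parameter is the single specialization knob: small
#' values (e.g. 0.02) put almost all mass on one label (a specialized
#' profile), large values (e.g. 1000) give near-uniform profiles. When
#' `dominant_label` is given, the maximal component is swapped into that
#' position, planting the specialization deterministically in expectation.
#'
#' @param n_labels number of labels M (>= 1).
#' @param concentration Dirichlet concentration (> 0).
#' @param dominant_label optional label index in `1:n_labels` to carry the
#'   maximal component.
#' @return Numeric probability vector of length `n_labels`.
#' @export
sample_label_vector <- function(n_labels, concentration,
                                dominant_label = NULL) {
  if (n_labels < 1L) stop("n_labels must be >= 1")
  if (!is.finite(concentration) || concentration <= 0)
    stop("concentration must be > 0")
  if (n_labels == 1L) return(1)
  p <- .rdirichlet1(n_labels, concentration)
  if (!is.null(dominant_label)) {
    if (dominant_label < 1L || dominant_label > n_labels)
      stop("dominant_label out of range")
    i <- which.max(p)
    tmp <- p[dominant_label]
    p[dominant_label] <- p[i]
    p[i] <- tmp
  }
  p
}

#' Specify a synthetic annotated network
#'
#' Collects the generator parameters; generation via [generate_network] is a
#' pure function of this specification (equal specs and seeds give identical
#' networks).
#'
#' @param n_nodes number of background nodes.
#' @param n_labels number of annotation labels M.
#' @param mean_out_partners mean number of outgoing background edges per
#'   background node (Poisson).
#' @param weight_mean mean of the positive integer edge-weight law
#'   (geometric, mimicking synapse counts; irrelevant to the scores by
#'   weight-scale invariance but realistic for fixtures).
#' @param concentration background Dirichlet concentration for out-profiles
#'   (default 0.1: background nodes are individually specialized in random
#'   labels).
#' @param n_planted_diverse number of planted diverse hubs K.
#' @param n_planted_same number of planted same-specialization controls.
#' @param plant_concentration Dirichlet concentration of planted partner
#'   profiles (default 0.02, near fully specialized).
#' @param hub_fanout planted partners per motif side; must not exceed
#'   `n_labels` when diverse hubs are planted.
#' @param plant_weight total synaptic mass realizing each planted partner
#'   profile; large relative to background weights so planted profiles stay
#'   specialized despite background contamination.
#' @param mirror_fraction fraction of background nodes duplicated as
#'   left-right mirror pairs.
#' @param mirror_fidelity probability a mirrored edge keeps the original
#'   partner (otherwise rerouted to a random node of the same label), so
#'   mirror pairs have near-identical but not byte-identical partner sets.
#' @param background_attach when `TRUE` (default) planted hubs, controls
#'   and their partners participate in background edge formation as
#'   targets, so planted motifs are embedded in the background graph and
#'   recovery is nontrivial. `FALSE` keeps planted two-hop neighborhoods
#'   clean.
#' @param seed integer seed.
#' @return Object of class `synthetic_spec` (a validated parameter list).
#' @export
synthetic_spec <- function(n_nodes = 300L, n_labels = 8L,
                           mean_out_partners = 2, weight_mean = 3,
                           concentration = 0.1,
                           n_planted_diverse = 3L, n_planted_same = 3L,
                           plant_concentration = 0.02,
                           hub_fanout = min(n_labels, 6L),
                           plant_weight = 200,
                           mirror_fraction = 0, mirror_fidelity = 0.9,
                           background_attach = TRUE, seed = 1L) {
  stopifnot(n_nodes >= 1, n_labels >= 1, mean_out_partners > 0,
            weight_mean >= 1, concentration > 0, n_planted_diverse >= 0,
            n_planted_same >= 0, plant_concentration > 0, hub_fanout >= 1,
            plant_weight >= 1, mirror_fraction >= 0, mirror_fraction <= 1,
            mirror_fidelity >= 0, mirror_fidelity <= 1)
  if (n_planted_diverse > 0 && hub_fanout > n_labels)
    stop("diverse planting requires hub_fanout <= n_labels ",
         "(distinct dominant labels)")
  structure(list(n_nodes = as.integer(n_nodes),
                 n_labels = as.integer(n_labels),
                 mean_out_partners = mean_out_partners,
                 weight_mean = weight_mean,
                 concentration = concentration,
                 n_planted_diverse = as.integer(n_planted_diverse),
                 n_planted_same = as.integer(n_planted_same),
                 plant_concentration = plant_concentration,
                 hub_fanout = as.integer(hub_fanout),
                 plant_weight = plant_weight,
                 mirror_fraction = mirror_fraction,
                 mirror_fidelity = mirror_fidelity,
                 background_attach = isTRUE(background_attach),
                 seed = as.integer(seed)),
            class = "synthetic_spec")
}

#' @export
print.synthetic_spec <- function(x, ...) {
  cat("Synthetic annotated-network specification\n")
  for (nm in names(x)) cat(sprintf("  %s: %s\n", nm, format(x[[nm]])))
  invisible(x)
}

# integer weights >= 1 with the given mean (shifted geometric)
.rweight <- function(n, mean_w) {
  if (mean_w <= 1) return(rep(1L, n))
  stats::rgeom(n, prob = 1 / mean_w) + 1L
}

.generate_impl <- function(spec) {
  M <- spec$n_labels
  label_set <- sprintf("T%02d", seq_len(M))
  bg <- sprintf("bg%03d", seq_len(spec$n_nodes))

  node_ids <- bg
  # balanced random assignment: uniform marginally, and every label is
  # represented whenever n_nodes >= n_labels, so planted profiles can
  # always realize their dominant-label edges
  node_lab <- sample(rep(label_set, length.out = spec$n_nodes))
  role <- rep("background", spec$n_nodes)
  plant_of <- rep(NA_character_, spec$n_nodes)
  dominant <- rep(NA_character_, spec$n_nodes)

  add_nodes <- function(ids, labs, rl, of = NA_character_,
                        dom = NA_character_) {
    node_ids <<- c(node_ids, ids)
    node_lab <<- c(node_lab, labs)
    role <<- c(role, rep(rl, length.out = length(ids)))
    plant_of <<- c(plant_of, rep(of, length.out = length(ids)))
    dominant <<- c(dominant, rep(dom, length.out = length(ids)))
  }

  hubs <- ctls <- character(0)
  if (spec$n_planted_diverse > 0) {
    hubs <- sprintf("hub%02d", seq_len(spec$n_planted_diverse))
    add_nodes(hubs, sample(label_set, length(hubs), replace = TRUE),
              "diverse_hub")
    for (h in hubs) {
      add_nodes(sprintf("%s_u%02d", h, seq_len(spec$hub_fanout)),
                sample(label_set, spec$hub_fanout, replace = TRUE),
                "hub_up_partner", of = h)
      add_nodes(sprintf("%s_d%02d", h, seq_len(spec$hub_fanout)),
                sample(label_set, spec$hub_fanout, replace = TRUE),
                "hub_down_partner", of = h)
    }
  }
  if (spec$n_planted_same > 0) {
    ctls <- sprintf("ctl%02d", seq_len(spec$n_planted_same))
    add_nodes(ctls, sample(label_set, length(ctls), replace = TRUE),
              "same_control")
    for (cc in ctls) {
      add_nodes(sprintf("%s_u%02d", cc, seq_len(spec$hub_fanout)),
                sample(label_set, spec$hub_fanout, replace = TRUE),
                "ctl_up_partner", of = cc)
      add_nodes(sprintf("%s_d%02d", cc, seq_len(spec$hub_fanout)),
                sample(label_set, spec$hub_fanout, replace = TRUE),
                "ctl_down_partner", of = cc)
    }
  }
  names(node_lab) <- node_ids

  # label pools for partner selection
  attach_ids <- if (spec$background_attach) node_ids else bg
  pools <- split(attach_ids, node_lab[attach_ids])
  pick_from_pool <- function(lab, exclude) {
    p <- setdiff(pools[[lab]], exclude)
    if (!length(p))    # fall back to any node of the label
      p <- setdiff(node_ids[node_lab == lab], exclude)
    if (!length(p)) return(NA_character_)
    p[sample.int(length(p), 1L)]
  }

  es <- et <- character(0)
  ew <- numeric(0)
  add_edges <- function(s, t, w) {
    es <<- c(es, s); et <<- c(et, t); ew <<- c(ew, w)
  }

  # background edges: each background node draws an out label profile and
  # realizes it over uniformly chosen partners within each drawn label
  for (b in bg) {
    k <- stats::rpois(1L, spec$mean_out_partners)
    if (k == 0L) next
    rho <- .rdirichlet1(M, spec$concentration)
    labs <- label_set[sample.int(M, k, replace = TRUE, prob = rho)]
    for (lb in labs) {
      tgt <- pick_from_pool(lb, b)
      if (!is.na(tgt)) add_edges(b, tgt, .rweight(1L, spec$weight_mean))
    }
  }

  # realize a planted partner profile as strong edges: `direction` is the
  # direction of the profile owned by `node`; the motif center is excluded
  # from the profile's partner pool so a planted partner never feeds the
  # center's own partner sets through its profile edges
  plant_profile <- function(node, direction, dom_idx, center) {
    rho <- sample_label_vector(M, spec$plant_concentration, dom_idx)
    nu <- round(rho * spec$plant_weight)
    if (nu[dom_idx] == 0) nu[dom_idx] <- 1
    for (j in which(nu > 0)) {
      other <- pick_from_pool(label_set[j], c(node, center))
      if (is.na(other)) next
      if (direction == "in") add_edges(other, node, nu[j])
      else add_edges(node, other, nu[j])
    }
  }

  plant_motif <- function(center, dom_up, dom_down) {
    ups <- sprintf("%s_u%02d", center, seq_len(spec$hub_fanout))
    downs <- sprintf("%s_d%02d", center, seq_len(spec$hub_fanout))
    for (i in seq_len(spec$hub_fanout)) {
      add_edges(ups[i], center, .rweight(1L, spec$weight_mean))
      plant_profile(ups[i], "in", dom_up[i], center)
      add_edges(center, downs[i], .rweight(1L, spec$weight_mean))
      plant_profile(downs[i], "out", dom_down[i], center)
    }
    dominant[match(ups, node_ids)] <<- label_set[dom_up]
    dominant[match(downs, node_ids)] <<- label_set[dom_down]
  }

  for (h in hubs)
    plant_motif(h, sample.int(M, spec$hub_fanout),
                sample.int(M, spec$hub_fanout))
  for (cc in ctls) {
    shared <- sample.int(M, 1L)
    plant_motif(cc, rep(shared, spec$hub_fanout),
                rep(shared, spec$hub_fanout))
    dominant[match(cc, node_ids)] <- label_set[shared]
  }

  # mirrored left-right pairs: duplicate selected background nodes; the
  # mirror keeps each partner with probability mirror_fidelity, otherwise
  # reroutes to a random node of the same label; weights are resampled
  side <- sample(c("L", "R"), length(node_ids), replace = TRUE)
  pair_id <- rep(NA_character_, length(node_ids))
  names(side) <- names(pair_id) <- node_ids
  n_mirror <- round(spec$mirror_fraction * spec$n_nodes)
  if (n_mirror > 0) {
    originals <- sort(sample(bg, n_mirror))
    mir_ids <- paste0(originals, "m")
    add_nodes(mir_ids, node_lab[originals], "mirror", of = originals)
    names(node_lab) <- node_ids
    side <- c(side, stats::setNames(rep("R", n_mirror), mir_ids))
    side[originals] <- "L"
    pair_id <- c(pair_id, stats::setNames(rep(NA_character_, n_mirror),
                                          mir_ids))
    pids <- sprintf("pair%03d", seq_len(n_mirror))
    pair_id[originals] <- pids
    pair_id[mir_ids] <- pids
    mirror_edge <- function(fixed, moved, out) {
      keep <- stats::runif(length(moved)) < spec$mirror_fidelity
      new_partner <- moved
      for (q in which(!keep)) {
        np <- pick_from_pool(node_lab[moved[q]], moved[q])
        if (!is.na(np)) new_partner[q] <- np
      }
      w <- .rweight(length(moved), spec$weight_mean)
      if (out) add_edges(fixed, new_partner, w)
      else add_edges(new_partner, fixed, w)
    }
    for (q in seq_len(n_mirror)) {
      b <- originals[q]; mid <- mir_ids[q]
      out_t <- et[es == b & et != b]
      in_s <- es[et == b & es != b]
      if (length(out_t)) mirror_edge(rep(mid, length(out_t)), out_t, TRUE)
      if (length(in_s)) mirror_edge(rep(mid, length(in_s)), in_s, FALSE)
    }
  }

  truth <- data.frame(node_id = node_ids,
                      role = role,
                      planted_ref = plant_of,
                      dominant_label = dominant,
                      side = unname(side[node_ids]),
                      pair_id = unname(pair_id[node_ids]),
                      stringsAsFactors = FALSE)
  metadata <- truth[, c("role", "side", "pair_id")]
  rownames(metadata) <- truth$node_id

  net <- annotated_network(
    data.frame(source = es, target = et, weight = ew,
               stringsAsFactors = FALSE),
    labels = node_lab, metadata = metadata)

  list(network = net, truth = truth, spec = spec)
}

#' Generate a synthetic annotated network
#'
#' Deterministic given the specification: the spec's seed is applied to a
#' temporary RNG state, so the caller's random stream is not disturbed.
#'
#' @param spec a [synthetic_spec].
#' @return list with `network` (an [annotated_network] carrying `role`,
#'   `side` and `pair_id` metadata), `truth` (per-node planted-role table)
#'   and the resolved `spec`.
#' @examples
#' sim <- generate_network(synthetic_spec(n_nodes = 50, seed = 7))
#' sim$network
#' table(sim$truth$role)
#' @export
generate_network <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  .with_seed(spec$seed, .generate_impl(spec))
}

#' Sample sets of label-profile vectors directly
#'
#' A network-free sampler of probability-vector sets in the three canonical
#' regimes: `"diverse"` (each vector's dominant label distinct, cycling
#' through the labels), `"same"` (all dominant labels equal), and
#' `"uniform"` (no planted dominant label; pass a large concentration for
#' near-uniform vectors). Useful for unit-testing
#' [specialization_diversity] against its limiting cases.
#'
#' @param n_sets number of vector sets.
#' @param n_vectors vectors per set (N).
#' @param n_labels labels per vector (M).
#' @param regime `"diverse"`, `"same"` or `"uniform"`.
#' @param concentration Dirichlet concentration.
#' @param seed optional integer seed.
#' @return list of `n_sets` matrices (`n_vectors` x `n_labels`).
#' @export
generate_vector_sets <- function(n_sets, n_vectors, n_labels,
                                 regime = c("diverse", "same", "uniform"),
                                 concentration = 0.1, seed = NULL) {
  regime <- match.arg(regime)
  stopifnot(n_sets >= 1, n_vectors >= 1, n_labels >= 1)
  .with_seed(seed, {
    lapply(seq_len(n_sets), function(s) {
      dom <- switch(regime,
        diverse = ((seq_len(n_vectors) - 1L) %% n_labels) + 1L,
        same = rep(sample.int(n_labels, 1L), n_vectors),
        uniform = rep(NA_integer_, n_vectors))
      m <- t(vapply(seq_len(n_vectors), function(i)
        sample_label_vector(n_labels, concentration,
                            if (is.na(dom[i])) NULL else dom[i]),
        numeric(n_labels)))
      colnames(m) <- sprintf("T%02d", seq_len(n_labels))
      m
    })
  })
}
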
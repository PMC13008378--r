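test_that("label-profile sampling tracks the concentration parameter", {
  set.seed(14)
  # near-uniform at high concentration
  flat <- replicate(200, sample_label_vector(4, 1000))
  expect_gt(mean(apply(abs(flat - 0.25) < 0.15, 2, all)), 0.99)
  # near one-hot at low concentration: P(max > 0.9) ~ 0.937 for
  # Dirichlet(0.01) over 4 labels (frozen from a 2e5-draw simulation)
  peaked <- replicate(2000, sample_label_vector(4, 0.01))
  expect_equal(mean(apply(peaked, 2, max) > 0.9), 0.937, tolerance = 0.04)
  # dominant label carries the maximal component
  dom <- replicate(100, sample_label_vector(5, 0.1, dominant_label = 3))
  expect_true(all(apply(dom, 2, which.max) == 3))
  # degenerate single label
  expect_equal(sample_label_vector(1, 0.5), 1)
  expect_error(sample_label_vector(3, 0), "concentration")
})

test_that("vector-set regimes reproduce the three canonical scenarios", {
  sets <- generate_vector_sets(20, 4, 4, "same", concentration = 1e-4,
                               seed = 2)
  ds_same <- vapply(sets, function(m)
    specialization_diversity(m)$delta_s, 1.0)
  expect_lt(max(ds_same), 0.05)

  sets <- generate_vector_sets(20, 4, 4, "diverse", concentration = 1e-4,
                               seed = 3)
  ds_div <- vapply(sets, function(m)
    specialization_diversity(m)$delta_s, 1.0)
  expect_gt(min(ds_div), log(4) - 0.05)

  sets <- generate_vector_sets(20, 3, 5, "uniform", concentration = 1e4,
                               seed = 4)
  r <- lapply(sets, specialization_diversity)
  expect_lt(max(vapply(r, `[[`, 1.0, "delta_s")), 0.01)
  expect_gt(min(vapply(r, `[[`, 1.0, "mean_entropy")), log(5) - 0.01)
})

test_that("generation is a pure function of the spec", {
  spec <- synthetic_spec(n_nodes = 40, mirror_fraction = 0.2, seed = 99)
  a <- generate_network(spec)
  b <- generate_network(spec)
  expect_identical(a$network$edges, b$network$edges)
  expect_identical(a$truth, b$truth)
  c <- generate_network(synthetic_spec(n_nodes = 40, mirror_fraction = 0.2,
                                       seed = 100))
  expect_false(identical(a$network$edges, c$network$edges))
  # generation does not disturb the caller's RNG stream
  set.seed(1); x <- runif(1)
  set.seed(1); invisible(generate_network(spec)); y <- runif(1)
  expect_identical(x, y)
})

test_that("spec validation rejects infeasible planting", {
  expect_error(synthetic_spec(n_labels = 4, hub_fanout = 6,
                              n_planted_diverse = 1), "hub_fanout")
  # same-only planting may exceed the label count restriction-free
  expect_s3_class(synthetic_spec(n_labels = 4, hub_fanout = 6,
                                 n_planted_diverse = 0), "synthetic_spec")
})

test_that("planted roles separate and clean controls match the direct sampler", {
  sep <- vapply(1:10, function(s) {
    sim <- generate_network(synthetic_spec(seed = s))
    sc <- specdiv(sim$network)
    tr <- sim$truth
    mean(sc$ds_sum[match(tr$node_id[tr$role == "diverse_hub"],
                         sc$node_id)]) -
      mean(sc$ds_sum[match(tr$node_id[tr$role == "same_control"],
                           sc$node_id)])
  }, 1.0)
  expect_gt(mean(sep), 1)                    # planted-role separation

  # without background embedding, control scores should be statistically
  # indistinguishable from the network-free same-regime sampler at the
  # planted construction's parameters (N = fanout, kappa = 0.02)
  ctl_ds <- unlist(lapply(1:20, function(s) {
    sim <- generate_network(synthetic_spec(n_nodes = 40, seed = s,
                                           background_attach = FALSE))
    sc <- as.data.frame(specdiv(sim$network))
    ctl <- sc[match(sim$truth$node_id[sim$truth$role == "same_control"],
                    sc$node_id), ]
    c(ctl$ds_u_in, ctl$ds_d_out)
  }))
  direct <- vapply(generate_vector_sets(500, 6, 8, "same",
                                        concentration = 0.02, seed = 90),
                   function(m) specialization_diversity(m)$delta_s, 1.0)
  expect_equal(mean(ctl_ds), mean(direct), tolerance = 0.075)
  expect_lt(max(ctl_ds), max(log(6), max(direct) + 0.3))
})

test_that("a high-degree node with one-label partners has near-zero scores", {
  # degree decoupling: entropic hubs are not synaptic hubs by construction
  sim <- generate_network(synthetic_spec(n_nodes = 120,
                                         n_planted_diverse = 0,
                                         n_planted_same = 0, seed = 7))
  net <- sim$network
  # attach a node sending to 30 partners whose outputs all hit label T01
  t01 <- names(net$labels)[net$labels == "T01"]
  sat <- sprintf("sat%02d", 1:30)
  extra <- rbind(
    data.frame(source = "bigdeg", target = sat, weight = 5),
    data.frame(source = sat, target = rep(t01[1], 30), weight = 50))
  net2 <- annotated_network(rbind(net$edges, extra),
                            labels = c(net$labels,
                                       stats::setNames(rep("T05", 30),
                                                       sat)))
  sc <- as.data.frame(specdiv(net2))
  big <- sc[sc$node_id == "bigdeg", ]
  expect_gt(big$degree, 25)
  expect_lt(big$ds_d_out, 0.05)
})

test_that("mirror pairs are closer than side-preserving null pairs", {
  sim <- generate_network(synthetic_spec(n_nodes = 120,
                                         mirror_fraction = 0.3,
                                         n_planted_diverse = 0,
                                         n_planted_same = 0, seed = 21))
  sc <- specdiv(sim$network)
  obs <- within_group_distances(sc, "pair_id")
  set.seed(22)
  null <- side_preserving_null(sc, "side", n_pairs = 300)
  mw <- stats::wilcox.test(obs, null, alternative = "less")
  expect_lt(mw$p.value, 1e-6)
})
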
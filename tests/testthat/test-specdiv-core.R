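test_that("shannon entropy matches closed forms and rejects bad input", {
  expect_equal(shannon_entropy(c(1, 0, 0)), 0)
  expect_equal(shannon_entropy(rep(1 / 3, 3)), log(3))
  expect_equal(shannon_entropy(c(0.5, 0.25, 0.25)), 1.039721,
               tolerance = 1e-6)
  expect_error(shannon_entropy(c(0.5, 0.4)), "sum to 1")
  expect_error(shannon_entropy(c(1.2, -0.2)), "nonnegative")
})

test_that("connectivity vectors follow the label-aggregation definition", {
  net <- annotated_network(
    edge_df(c("n", "n", "n"), c("a", "b", "c"), c(2, 1, 1)),
    labels = c(a = "A", b = "A", c = "B"))
  v <- connectivity_vector(net, "n", "out")
  expect_equal(unclass(v)[c("A", "B")], c(A = 0.75, B = 0.25),
               ignore_attr = TRUE)
  expect_equal(sum(v), 1)

  # all partners unlabeled -> undefined
  net2 <- annotated_network(edge_df(c("n", "n"), c("u1", "u2")),
                            labels = c(n = "A"))
  expect_null(connectivity_vector(net2, "n", "out"))

  # single labeled partner -> fully specialized whatever the weight
  net3 <- annotated_network(edge_df("n", "a", 37), labels = c(a = "A"))
  expect_equal(as.numeric(connectivity_vector(net3, "n", "out")), 1.0)

  expect_error(connectivity_vector(net, "zz", "out"), "unknown node")
})

test_that("specialization-diversity reproduces its limiting cases", {
  # fully specialized in distinct labels
  r <- specialization_diversity(diag(3))
  expect_equal(r$mean_entropy, 0)
  expect_equal(r$entropy_of_mean, log(3))
  expect_equal(r$delta_s, log(3))

  # identical fully-specialized vectors: S_bar = S(p_bar) = 0
  r <- specialization_diversity(matrix(rep(c(1, 0, 0), 3), 3,
                                       byrow = TRUE))
  expect_equal(r$mean_entropy, 0)
  expect_equal(r$entropy_of_mean, 0)
  expect_equal(r$delta_s, 0)

  # a singleton set always has delta_s = 0
  p <- c(0.2, 0.5, 0.3)
  expect_equal(specialization_diversity(rbind(p))$delta_s, 0)

  # uniform vectors: S_bar = S(p_bar) = log(M)
  u <- matrix(1 / 4, 2, 4)
  r <- specialization_diversity(u)
  expect_equal(r$mean_entropy, log(4))
  expect_equal(r$delta_s, 0)

  expect_error(specialization_diversity(matrix(0, 0, 3)), "at least one")
  expect_error(specialization_diversity(list(c(1, 0), c(1, 0, 0))),
               "same length")
})

test_that("interpolating two specializations toward each other shrinks delta_s to 0", {
  e1 <- c(1, 0); e2 <- c(0, 1)
  lam <- seq(0, 1, by = 0.1)
  ds <- vapply(lam, function(l) {
    # move both vectors toward their common midpoint
    v1 <- (1 - l) * e1 + l * c(0.5, 0.5)
    v2 <- (1 - l) * e2 + l * c(0.5, 0.5)
    specialization_diversity(rbind(v1, v2))$delta_s
  }, 1.0)
  expect_true(all(diff(ds) < 1e-12))
  expect_equal(ds[1], log(2))
  expect_equal(ds[length(ds)], 0)
})

test_that("per-node motif scores follow the two-hop definitions", {
  # chain a -> b -> c: a's single downstream partner gives delta_s = 0
  chain <- annotated_network(edge_df(c("a", "b"), c("b", "c")),
                             labels = c(b = "X", c = "Y"))
  s <- node_specdiv(chain, "a")
  expect_equal(s$ds_d_out, 0)
  expect_true(is.na(s$ds_u_in))          # no upstream partners
  expect_equal(s$n_down_vectors, 1L)

  # downstream partners wholly specialized in distinct labels -> log(3)
  m <- motif_net()
  expect_equal(node_specdiv(m, "div")$ds_d_out, log(3))
  expect_equal(node_specdiv(m, "sam")$ds_d_out, 0)

  # sink node: distributive side undefined, serialized NA
  expect_true(is.na(node_specdiv(chain, "c")$ds_d_out))

  # two-node network: no directed two-paths at all
  two <- annotated_network(edge_df("a", "b"),
                           labels = c(a = "A", b = "B"))
  sc <- specdiv(two)
  expect_true(all(is.na(sc$ds_u_in)) && all(is.na(sc$ds_d_out)))
  expect_equal(nrow(sc), 2L)
})

test_that("score_all matches the brute-force oracle on random networks", {
  set.seed(202)
  for (rep in 1:25) {
    rn <- random_edges(n_nodes = sample(4:8, 1),
                       n_labels = sample(2:3, 1))
    net <- annotated_network(rn$edges, labels = rn$labels)
    got <- as.data.frame(specdiv(net))
    want <- oracle_scores(rn$edges, rn$labels)
    expect_equal(got$node_id, want$node_id)
    expect_equal(got$ds_u_in, want$ds_u_in, tolerance = 1e-12)
    expect_equal(got$ds_d_out, want$ds_d_out, tolerance = 1e-12)
  }
})

test_that("scores are invariant to weight scaling and equivariant to label renaming", {
  set.seed(31)
  rn <- random_edges(n_nodes = 10, n_labels = 3, p_unlabeled = 0.1)
  net <- annotated_network(rn$edges, labels = rn$labels)
  base <- as.data.frame(specdiv(net))

  e2 <- rn$edges; e2$weight <- e2$weight * 0.37
  scaled <- as.data.frame(specdiv(annotated_network(e2,
                                                    labels = rn$labels)))
  expect_equal(scaled, base, tolerance = 1e-12)

  # permute label identities: every entropy, hence every score, unchanged
  perm <- c(A = "C", B = "A", C = "B")
  lab2 <- stats::setNames(perm[rn$labels], names(rn$labels))
  renamed <- as.data.frame(specdiv(annotated_network(rn$edges,
                                                     labels = lab2)))
  expect_equal(renamed$ds_u_in, base$ds_u_in, tolerance = 1e-12)
  expect_equal(renamed$ds_d_out, base$ds_d_out, tolerance = 1e-12)
})

test_that("defined scores respect the Jensen and mixture-entropy bounds", {
  set.seed(77)
  m_labels <- 4
  for (rep in 1:50) {
    n_vec <- sample(1:6, 1)
    vs <- t(vapply(seq_len(n_vec), function(i)
      sample_label_vector(m_labels, runif(1, 0.05, 5)),
      numeric(m_labels)))
    r <- specialization_diversity(vs)
    expect_gte(r$delta_s, -1e-12)
    expect_lte(r$delta_s, log(min(n_vec, m_labels)) + 1e-9)
  }
})

test_that("entropic-hub ranking orders, breaks ties, and flags straddles", {
  sc <- data.frame(node_id = c("a", "b", "c", "d"),
                   ds_u_in = c(1, 0.5, NA, 0.5),
                   ds_d_out = c(1, 0.5, 1, 0.5),
                   ds_sum = c(2, 1, NA, 1),
                   stringsAsFactors = FALSE)
  top2 <- rank_entropic_hubs(sc, 2)
  expect_equal(top2$node_id, c("a", "b"))       # tie b/d broken by id
  expect_true(attr(top2, "tie_straddle"))       # d has the same ds_sum
  top3 <- rank_entropic_hubs(sc, 3)
  expect_equal(top3$node_id, c("a", "b", "d"))
  expect_false(attr(top3, "tie_straddle"))
  expect_warning(all4 <- rank_entropic_hubs(sc, 10), "exceeds")
  expect_equal(nrow(all4), 3L)                  # NA-scored node excluded
  expect_error(rank_entropic_hubs(sc, 0), "k must be")
})
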
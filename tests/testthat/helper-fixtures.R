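# Fixture builders shared across test files. All fixtures are built in
# code; random-network draws are always made under an explicit seed.

edge_df <- function(source, target, weight = NULL) {
  if (is.null(weight)) weight <- rep(1, length(source))
  data.frame(source = source, target = target, weight = weight,
             stringsAsFactors = FALSE)
}

# two planted two-hop motifs around nodes "div" (downstream partners
# specialized in distinct labels) and "sam" (all in the same label)
motif_net <- function() {
  e <- edge_df(
    c("div", "div", "div", "p1", "p2", "p3",
      "sam", "sam", "sam", "q1", "q2", "q3"),
    c("p1", "p2", "p3", "a1", "b1", "c1",
      "q1", "q2", "q3", "a1", "a2", "a3"))
  labels <- c(p1 = "P", p2 = "P", p3 = "P", q1 = "P", q2 = "P", q3 = "P",
              a1 = "A", a2 = "A", a3 = "A", b1 = "B", c1 = "C")
  annotated_network(e, labels = labels)
}

# random edge table over n nodes with m labels; some nodes unlabeled,
# occasional self-loops; used for oracle cross-checks
random_edges <- function(n_nodes = 8, n_labels = 3, p_edge = 0.3,
                         p_unlabeled = 0.2, p_self = 0.1) {
  nodes <- sprintf("v%02d", seq_len(n_nodes))
  pairs <- expand.grid(source = nodes, target = nodes,
                       stringsAsFactors = FALSE)
  keep <- ifelse(pairs$source == pairs$target,
                 runif(nrow(pairs)) < p_self,
                 runif(nrow(pairs)) < p_edge)
  e <- pairs[keep, , drop = FALSE]
  e$weight <- sample(1:9, nrow(e), replace = TRUE)
  lab <- sample(LETTERS[seq_len(n_labels)], n_nodes, replace = TRUE)
  lab[runif(n_nodes) < p_unlabeled] <- NA
  keep_lab <- !is.na(lab)
  list(edges = e,
       labels = stats::setNames(lab[keep_lab], nodes[keep_lab]))
}

# score table with fabricated ds values and metadata, for null-model tests
fake_scores <- function(n = 20, seed = 1) {
  set.seed(seed)
  data.frame(node_id = sprintf("n%02d", seq_len(n)),
             ds_u_in = runif(n, 0, 2),
             ds_d_out = runif(n, 0, 2),
             side = rep(c("L", "R"), length.out = n),
             grp = rep(sprintf("g%d", seq_len(ceiling(n / 2))), each = 2,
                       length.out = n),
             stringsAsFactors = FALSE)
}
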
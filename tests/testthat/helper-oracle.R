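# Independent brute-force recomputation of per-node specialization-
# diversity, written directly from the defining formulas with explicit
# loops over dense matrices. Shares no code with the package internals.

oracle_entropy <- function(p) {
  s <- 0
  for (x in p) if (x > 0) s <- s - x * log(x)
  s
}

# edges: data.frame(source, target, weight); labels: named character vector.
# Self-loops excluded. Returns data.frame node_id, ds_u_in, ds_d_out.
oracle_scores <- function(edges, labels) {
  nodes <- sort(unique(c(as.character(edges$source),
                         as.character(edges$target), names(labels))))
  L <- sort(unique(unname(labels)))
  n <- length(nodes); m <- length(L)
  A <- matrix(0, n, n, dimnames = list(nodes, nodes))
  for (r in seq_len(nrow(edges))) {
    i <- as.character(edges$source[r]); j <- as.character(edges$target[r])
    A[i, j] <- A[i, j] + edges$weight[r]
  }
  diag(A) <- 0
  B <- matrix(0, n, m, dimnames = list(nodes, L))
  for (z in names(labels)) B[z, labels[[z]]] <- 1

  rho_dir <- function(i, transposed) {
    nu <- numeric(m)
    for (j in seq_len(m))
      for (z in seq_len(n))
        nu[j] <- nu[j] + (if (transposed) A[z, i] else A[i, z]) * B[z, j]
    tot <- sum(nu)
    if (tot == 0) NULL else nu / tot
  }

  delta_s <- function(vs) {
    if (!length(vs)) return(NA_real_)
    sbar <- mean(vapply(vs, oracle_entropy, 1.0))
    pbar <- Reduce(`+`, vs) / length(vs)
    oracle_entropy(pbar) - sbar
  }

  ds_u <- ds_d <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    downstream <- which(A[i, ] > 0)
    vs <- Filter(Negate(is.null),
                 lapply(downstream, rho_dir, transposed = FALSE))
    ds_d[i] <- delta_s(vs)
    upstream <- which(A[, i] > 0)
    vs <- Filter(Negate(is.null),
                 lapply(upstream, rho_dir, transposed = TRUE))
    ds_u[i] <- delta_s(vs)
  }
  data.frame(node_id = nodes, ds_u_in = ds_u, ds_d_out = ds_d,
             stringsAsFactors = FALSE)
}
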
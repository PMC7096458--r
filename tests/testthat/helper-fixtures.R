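# Shared fixtures and independent oracles used across test files.

# small expression matrix with explicit values
tiny_expression <- function(values = matrix(1:6, 3, 2),
                            genes = paste0("g", seq_len(nrow(values))),
                            samples = paste0("s", seq_len(ncol(values)))) {
  expression_matrix(values, gene_ids = genes, sample_ids = samples)
}

# dense-grid brute-force oracle for the distance from g to the convex hull
# of the rows of V (K = 1..4 vertices), with one local refinement pass
# around the best coarse grid point
grid_margin_oracle <- function(g, V, coarse = 0.01, fine = 2e-4) {
  K <- nrow(V)
  if (K == 4L) { coarse <- 0.04; fine <- 2e-3 }
  dist_for <- function(W) {
    M <- W %*% V
    sqrt(rowSums((M - matrix(g, nrow(M), length(g), byrow = TRUE))^2))
  }
  weights_grid <- function(lo, hi, by) {
    if (K == 1L) return(matrix(1, 1, 1))
    axes <- lapply(seq_len(K - 1L), function(d)
      seq(max(lo[d], 0), min(hi[d], 1), by = by))
    gr <- as.matrix(do.call(expand.grid, axes))
    gr <- gr[rowSums(gr) <= 1, , drop = FALSE]
    cbind(gr, 1 - rowSums(gr))
  }
  W <- weights_grid(rep(0, K), rep(1, K), coarse)
  d <- dist_for(W)
  best <- W[which.min(d), , drop = TRUE]
  W2 <- weights_grid(best - 2 * coarse, best + 2 * coarse, fine)
  min(min(d), min(dist_for(W2)))
}

# brute-force best row matching by total Pearson correlation over all K!
# permutations (perm[i] = true row matched to estimated row i)
brute_force_match <- function(P_est, P_true) {
  K <- nrow(P_est)
  M <- matrix(0, K, K)
  for (i in seq_len(K)) for (j in seq_len(K)) {
    if (sd(P_est[i, ]) > 0 && sd(P_true[j, ]) > 0)
      M[i, j] <- cor(P_est[i, ], P_true[j, ])
  }
  perms <- gtools_permutations(K)
  scores <- apply(perms, 1L, function(p) sum(M[cbind(seq_len(K), p)]))
  perms[which.max(scores), ]
}

# all permutations of 1..n (plain recursion; avoids extra dependencies)
gtools_permutations <- function(n) {
  if (n == 1L) return(matrix(1L, 1, 1))
  sub <- gtools_permutations(n - 1L)
  out <- NULL
  for (k in seq_len(n)) {
    block <- cbind(k, sub + (sub >= k))
    out <- rbind(out, block)
  }
  out
}

# noiseless mixture with truly exclusive marker blocks (off-column zero)
exclusive_marker_dataset <- function(m = 60, K = 3, markers_per_type = 5,
                                     fold = 10, n = 10, seed = 1) {
  sig <- make_signature(m, K, markers_per_type, fold, seed = seed)
  X0 <- sig$X
  for (ct in names(sig$markers))
    X0[sig$markers[[ct]], colnames(X0) != ct] <- 0
  P0 <- simulate_proportions(K, n, seed = seed + 1)
  Y <- expression_matrix(X0 %*% P0, rownames(X0), colnames(P0))
  list(Y = Y, X = X0, P = P0, markers = sig$markers)
}
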
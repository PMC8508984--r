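# Independent brute-force oracles used to check the vectorized/sparse paths.

# Random small association dataset.
random_dataset <- function(m, n, density = 0.3) {
  repeat {
    R <- matrix(rbinom(m * n, 1, density), m, n)
    if (sum(R) > 0) break
  }
  association_dataset(
    paste0("nc", seq_len(m)), paste0("dr", seq_len(n)),
    which(R == 1, arr.ind = TRUE)
  )
}

# Dense block assembly of A = [[0, R], [R^T, 0]] by explicit loops.
oracle_adjacency <- function(ds) {
  m <- n_ncrnas(ds); n <- n_drugs(ds)
  R <- association_matrix(ds)
  A <- matrix(0, m + n, m + n)
  for (i in seq_len(m)) {
    for (j in seq_len(n)) {
      A[i, m + j] <- R[i, j]
      A[m + j, i] <- R[i, j]
    }
  }
  A
}

# Entrywise spectral rule P_ij = A~_ij / sqrt(d~_i d~_j) by nested loops.
oracle_normalized <- function(ds) {
  A <- oracle_adjacency(ds)
  At <- A + diag(nrow(A))
  d <- rowSums(At)
  P <- matrix(0, nrow(At), ncol(At))
  for (i in seq_len(nrow(At))) {
    for (j in seq_len(ncol(At))) {
      P[i, j] <- At[i, j] / sqrt(d[i] * d[j])
    }
  }
  P
}

# One propagation step written as the per-node neighbor sums: the new
# embedding of node x is (e_x / d_x + sum_{y ~ x} e_y / sqrt(d_x d_y)) W,
# with d the self-looped degree.
oracle_one_step <- function(ds, E, W) {
  m <- n_ncrnas(ds); n <- n_drugs(ds)
  A <- oracle_adjacency(ds)
  d <- rowSums(A) + 1
  out <- matrix(0, m + n, ncol(E))
  for (x in seq_len(m + n)) {
    acc <- E[x, ] / d[x]
    for (y in which(A[x, ] == 1)) {
      acc <- acc + E[y, ] / sqrt(d[x] * d[y])
    }
    out[x, ] <- acc %*% W
  }
  out
}

# Residual score by explicit per-layer scalar loops.
oracle_scores <- function(layers, m, n, include_layer0 = TRUE) {
  ks <- if (include_layer0) seq_along(layers) else seq_along(layers)[-1]
  O <- matrix(0, m, n)
  for (i in seq_len(m)) {
    for (j in seq_len(n)) {
      for (k in ks) O[i, j] <- O[i, j] + sum(layers[[k]][i, ] * layers[[k]][m + j, ])
    }
  }
  O
}

# AUC by brute force over all positive-negative pairs (ties count 1/2).
oracle_auc <- function(scores, labels) {
  pos <- scores[labels == 1]; neg <- scores[labels == 0]
  tot <- 0
  for (p in pos) for (q in neg) tot <- tot + (p > q) + 0.5 * (p == q)
  tot / (length(pos) * length(neg))
}

trapezoid <- function(x, y) sum(diff(x) * (head(y, -1) + tail(y, -1)) / 2)
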
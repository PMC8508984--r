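#' Model hyperparameters
#'
#' Bundles the tunables of the linear residual graph-convolution model.
#' The defaults `K = 4` propagation layers and embedding dimension `S = 32`
#' are the cross-validated optima of the method on the curated
#' ncRNA-drug-resistance network; layer-0 embeddings are drawn from
#' N(0, `init_std`^2) with the reference standard deviation 0.1.
#'
#' @param K propagation depth (number of graph-convolution layers), >= 1.
#' @param S embedding dimension, >= 1.
#' @param init_std standard deviation of the normal layer-0 initialization
#'   (> 0).
#' @param lambda_reg L2 regularization strength applied to the layer-0
#'   embeddings and all transition matrices.
#' @param learning_rate Adam step size.
#' @param epochs number of training epochs; each epoch resamples Bayesian
#'   Personalized Ranking (BPR) triples and performs one full-batch update.
#' @param negatives_per_positive number of sampled negative drugs per
#'   observed positive pair per epoch.
#' @param shared_weights use a single transition matrix for every layer
#'   instead of one per layer.
#' @param include_layer0 include the layer-0 dot product as the base case of
#'   the residual score accumulation.
#' @param seed master seed; initialization and sampling run on named
#'   substreams derived from it.
#' @return A list of class `linkgcn_hyperparameters`.
#' @export
hyperparameters <- function(K = 4L, S = 32L, init_std = 0.1,
                            lambda_reg = 1e-4, learning_rate = 1e-3,
                            epochs = 200L, negatives_per_positive = 1L,
                            shared_weights = FALSE, include_layer0 = TRUE,
                            seed = 42L) {
  K <- assert_count(K, "K")
  S <- assert_count(S, "S")
  epochs <- assert_count(epochs, "epochs", min = 0L)
  negatives_per_positive <- assert_count(negatives_per_positive,
                                         "negatives_per_positive")
  if (!is.numeric(init_std) || init_std <= 0) {
    stop("`init_std` must be > 0", call. = FALSE)
  }
  if (lambda_reg < 0) stop("`lambda_reg` must be >= 0", call. = FALSE)
  if (learning_rate <= 0) stop("`learning_rate` must be > 0", call. = FALSE)
  structure(
    list(K = K, S = S, init_std = init_std, lambda_reg = lambda_reg,
         learning_rate = learning_rate, epochs = epochs,
         negatives_per_positive = negatives_per_positive,
         shared_weights = isTRUE(shared_weights),
         include_layer0 = isTRUE(include_layer0),
         seed = as.integer(seed)),
    class = "linkgcn_hyperparameters"
  )
}

#' Initialize model state
#'
#' Draws the (m + n) x S layer-0 embedding matrix E0 i.i.d. from
#' N(0, `init_std`^2) on the seeded "init" substream; rows 1..m are ncRNA
#' embeddings, rows m+1..m+n drug embeddings. Transition matrices are
#' initialized as identity plus N(0, 0.01) noise so that before training the
#' model behaves as near-pure layer propagation, which keeps early epochs
#' stable.
#'
#' @param m,n number of ncRNAs and drugs.
#' @param hp a [hyperparameters()] object.
#' @return A `linkgcn_model` state holding `E0`, the list `W` of K
#'   transition matrices, and bookkeeping; layer embeddings are not yet
#'   cached (run [propagate()]).
#' @export
init_embeddings <- function(m, n, hp) {
  stopifnot(inherits(hp, "linkgcn_hyperparameters"))
  m <- assert_count(m, "m"); n <- assert_count(n, "n")
  with_seed(substream_seed(hp$seed, "init"), {
    E0 <- matrix(stats::rnorm((m + n) * hp$S, 0, hp$init_std), m + n, hp$S)
    make_W <- function() diag(hp$S) + matrix(stats::rnorm(hp$S^2, 0, 0.01),
                                             hp$S, hp$S)
    W <- if (hp$shared_weights) {
      rep(list(make_W()), hp$K)
    } else {
      replicate(hp$K, make_W(), simplify = FALSE)
    }
    structure(
      list(E0 = E0, W = W, layers = NULL, m = m, n = n, hp = hp,
           ncrnas = NULL, drugs = NULL),
      class = "linkgcn_model"
    )
  })
}

#' @export
print.linkgcn_model <- function(x, ...) {
  cat(sprintf(
    "<linkgcn_model> %d ncRNAs + %d drugs, S = %d, K = %d layers%s\n",
    x$m, x$n, x$hp$S, x$hp$K,
    if (is.null(x$layers)) " (not propagated)" else ""
  ))
  invisible(x)
}

#' Linear forward propagation
#'
#' Runs K steps of linear graph convolution
#' \deqn{E^{k+1} = P\, E^k\, W^{k+1},}
#' where P is the symmetric spectrally normalized self-looped adjacency. No
#' nonlinear activation is applied at any layer, yet the receptive field
#' after K steps matches a K-layer GCN. All layer embeddings E^0..E^K are
#' cached on the returned state for residual scoring.
#'
#' @param state a `linkgcn_model` from [init_embeddings()].
#' @param P the propagation operator from [normalize_adjacency()], of side
#'   m + n.
#' @return The state with `layers` set to the list (E^0, ..., E^K).
#' @export
propagate <- function(state, P) {
  stopifnot(inherits(state, "linkgcn_model"))
  N <- state$m + state$n
  if (nrow(P) != N || ncol(P) != N) {
    stop(sprintf("operator side %d does not match m + n = %d", nrow(P), N),
         call. = FALSE)
  }
  layers <- vector("list", state$hp$K + 1L)
  layers[[1L]] <- state$E0
  for (k in seq_len(state$hp$K)) {
    layers[[k + 1L]] <- as.matrix(P %*% layers[[k]] %*% state$W[[k]])
  }
  state$layers <- layers
  state
}

#' Residual association scores
#'
#' Accumulates the per-layer ncRNA-drug dot products into the final
#' prediction, \eqn{\hat o_{nr} = \sum_k e_n^k \cdot e_r^k}, the residual
#' recursion \eqn{\hat o^{k+1}_{nr} = \hat o^k_{nr} + e_n^{k+1} \cdot
#' e_r^{k+1}}. The layer-0 term is the base case when
#' `hp$include_layer0` is `TRUE` (default); otherwise accumulation starts at
#' layer 1. Fusing every layer preserves low-layer signal against
#' over-smoothing.
#'
#' @param state a propagated `linkgcn_model` (see [propagate()]).
#' @return The m x n score matrix.
#' @export
score_matrix <- function(state) {
  stopifnot(inherits(state, "linkgcn_model"))
  if (is.null(state$layers)) {
    stop("model has no cached layer embeddings; run propagate() first",
         call. = FALSE)
  }
  m <- state$m; n <- state$n
  ks <- if (state$hp$include_layer0) seq_along(state$layers) else
    seq_along(state$layers)[-1L]
  O <- matrix(0, m, n)
  for (k in ks) {
    E <- state$layers[[k]]
    O <- O + E[seq_len(m), , drop = FALSE] %*%
      t(E[m + seq_len(n), , drop = FALSE])
  }
  dimnames(O) <- list(state$ncrnas, state$drugs)
  O
}

# Scores for an explicit set of (ncRNA, drug) index pairs, avoiding the full
# m x n matrix when only a few entries are needed.
score_pairs <- function(state, pairs) {
  if (is.null(state$layers)) {
    stop("model has no cached layer embeddings; run propagate() first",
         call. = FALSE)
  }
  ks <- if (state$hp$include_layer0) seq_along(state$layers) else
    seq_along(state$layers)[-1L]
  s <- numeric(nrow(pairs))
  for (k in ks) {
    E <- state$layers[[k]]
    s <- s + rowSums(E[pairs[, 1L], , drop = FALSE] *
                     E[state$m + pairs[, 2L], , drop = FALSE])
  }
  s
}

log1p_exp <- function(x) ifelse(x > 0, x + log1p(exp(-x)), log1p(exp(x)))

#' Bayesian Personalized Ranking loss
#'
#' Evaluates the pairwise ranking objective
#' \deqn{L = \sum_{(a,i,j)} -\ln \sigma(\hat o_{ai} - \hat o_{aj})
#'   + \lambda \lVert E^0 \rVert^2 + \lambda \lVert W \rVert^2,}
#' where each triple pairs a verified drug i of ncRNA a with a sampled
#' unverified drug j, and \eqn{\sigma} is the logistic function. Minimizing
#' L widens the score margin between observed and unobserved drugs of the
#' same ncRNA. Regularization covers the layer-0 embeddings and every
#' transition matrix.
#'
#' @param state a propagated `linkgcn_model`.
#' @param triples integer matrix with columns (ncrna, pos_drug, neg_drug).
#' @return The scalar loss.
#' @export
bpr_loss <- function(state, triples) {
  stopifnot(inherits(state, "linkgcn_model"))
  triples <- matrix(as.integer(triples), ncol = 3L)
  if (any(triples[, 2L] == triples[, 3L])) {
    stop("BPR triple has identical positive and negative drug", call. = FALSE)
  }
  margin <- score_pairs(state, triples[, c(1L, 2L), drop = FALSE]) -
    score_pairs(state, triples[, c(1L, 3L), drop = FALSE])
  lam <- state$hp$lambda_reg
  sum(log1p_exp(-margin)) +
    lam * sum(state$E0^2) +
    lam * sum(vapply(state$W, function(w) sum(w^2), numeric(1)))
}

# Analytic gradient of bpr_loss with respect to E0 and each W^k, obtained by
# backpropagating through the linear recursion E^k = P E^{k-1} W^k and the
# residual score sum_k e_n^k . e_r^k. Returns list(E0 = ..., W = list).
bpr_gradients <- function(state, P, triples) {
  m <- state$m; N <- m + state$n; S <- state$hp$S; K <- state$hp$K
  L <- state$layers
  lam <- state$hp$lambda_reg
  a <- triples[, 1L]; ip <- m + triples[, 2L]; jn <- m + triples[, 3L]

  margin <- score_pairs(state, triples[, c(1L, 2L), drop = FALSE]) -
    score_pairs(state, triples[, c(1L, 3L), drop = FALSE])
  w <- -1 / (1 + exp(margin))           # dL/d(score of positive pair)

  ks <- if (state$hp$include_layer0) seq_len(K + 1L) else 2L:(K + 1L)
  # dL/dE^k from the score terms, accumulated per node row
  G <- rep(list(NULL), K + 1L)
  for (k in ks) {
    E <- L[[k]]
    idx <- c(a, a, ip, jn)
    vals <- rbind(
      w * E[ip, , drop = FALSE],
      -w * E[jn, , drop = FALSE],
      w * E[a, , drop = FALSE],
      -w * E[a, , drop = FALSE]
    )
    agg <- rowsum(vals, idx)
    Gk <- matrix(0, N, S)
    Gk[as.integer(rownames(agg)), ] <- agg
    G[[k]] <- Gk
  }
  zero <- matrix(0, N, S)
  for (k in seq_len(K + 1L)) if (is.null(G[[k]])) G[[k]] <- zero

  gW <- vector("list", K)
  delta <- G[[K + 1L]]
  for (k in K:1L) {
    gW[[k]] <- crossprod(as.matrix(P %*% L[[k]]), delta) + 2 * lam * state$W[[k]]
    delta <- G[[k]] + as.matrix(P %*% (delta %*% t(state$W[[k]])))
  }
  list(E0 = delta + 2 * lam * state$E0, W = gW)
}

# One Adam step over a list of parameter matrices.
adam_step <- function(params, grads, opt, lr, t,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  for (i in seq_along(params)) {
    opt$m[[i]] <- beta1 * opt$m[[i]] + (1 - beta1) * grads[[i]]
    opt$v[[i]] <- beta2 * opt$v[[i]] + (1 - beta2) * grads[[i]]^2
    mhat <- opt$m[[i]] / (1 - beta1^t)
    vhat <- opt$v[[i]] / (1 - beta2^t)
    params[[i]] <- params[[i]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(params = params, opt = opt)
}

# Sample BPR triples: for each observed positive (a, i), draw
# negatives_per_positive unverified drugs j of a uniformly, excluding every
# known positive of a and any forbidden (a, j) pair.
sample_triples <- function(pairs, neg_pool, npp) {
  reps <- rep(seq_len(nrow(pairs)), each = npp)
  a <- pairs[reps, 1L]
  i <- pairs[reps, 2L]
  j <- vapply(a, function(aa) {
    pool <- neg_pool[[aa]]
    pool[sample.int(length(pool), 1L)]
  }, integer(1))
  cbind(a, i, j)
}

#' Train the linear residual graph-convolution model
#'
#' Builds the bipartite graph of the dataset, initializes embeddings, and
#' for each epoch samples BPR triples (one or more uniformly drawn
#' unverified drugs per observed positive), runs the linear forward
#' propagation, and updates the layer-0 embeddings and transition matrices
#' by Adam on the analytic gradient of the regularized BPR loss. The run is
#' fully reproducible from `hp$seed`.
#'
#' @param ds an [association_dataset] of training positives.
#' @param hp a [hyperparameters()] object.
#' @param forbidden_pairs optional two-column matrix of (ncRNA, drug) index
#'   pairs that must never be drawn as BPR negatives, in addition to the
#'   dataset's own positives (use this to shield held-out test pairs).
#' @return A propagated `linkgcn_model` with an attached `log` element: the
#'   per-epoch loss history.
#' @export
train_model <- function(ds, hp = hyperparameters(), forbidden_pairs = NULL) {
  stopifnot(inherits(ds, "association_dataset"))
  if (n_pairs(ds) == 0L) stop("training dataset has no positives", call. = FALSE)
  m <- n_ncrnas(ds); n <- n_drugs(ds)

  P <- normalize_adjacency(build_adjacency(ds))
  state <- init_embeddings(m, n, hp)
  state$ncrnas <- ds$ncrnas
  state$drugs <- ds$drugs

  blocked <- ds$pairs
  if (!is.null(forbidden_pairs) && nrow(forbidden_pairs) > 0L) {
    blocked <- rbind(blocked, forbidden_pairs[, 1:2, drop = FALSE])
  }
  blocked_by_nc <- split(blocked[, 2L], factor(blocked[, 1L], levels = seq_len(m)))
  neg_pool <- lapply(blocked_by_nc, function(b) setdiff(seq_len(n), b))
  sampled <- ds$pairs[lengths(neg_pool)[ds$pairs[, 1L]] > 0L, , drop = FALSE]
  if (nrow(sampled) == 0L && hp$epochs > 0L) {
    stop("no ncRNA has an available negative drug for BPR sampling",
         call. = FALSE)
  }

  losses <- numeric(hp$epochs)
  opt_E <- list(m = list(0 * state$E0), v = list(0 * state$E0))
  opt_W <- list(m = lapply(state$W, function(w) 0 * w),
                v = lapply(state$W, function(w) 0 * w))

  with_seed(substream_seed(hp$seed, "sampling"), {
    for (epoch in seq_len(hp$epochs)) {
      triples <- sample_triples(sampled, neg_pool, hp$negatives_per_positive)
      state <- propagate(state, P)
      loss <- bpr_loss(state, triples)
      if (!is.finite(loss)) {
        stop(sprintf("training diverged (non-finite loss) at epoch %d", epoch),
             call. = FALSE)
      }
      losses[epoch] <- loss
      g <- bpr_gradients(state, P, triples)

      stepE <- adam_step(list(state$E0), list(g$E0), opt_E,
                         hp$learning_rate, epoch)
      state$E0 <- stepE$params[[1L]]
      opt_E <- stepE$opt

      if (hp$shared_weights) {
        gsum <- Reduce(`+`, g$W)
        stepW <- adam_step(state$W[1L], list(gsum),
                           list(m = opt_W$m[1L], v = opt_W$v[1L]),
                           hp$learning_rate, epoch)
        state$W <- rep(stepW$params[1L], hp$K)
        opt_W$m[1L] <- stepW$opt$m; opt_W$v[1L] <- stepW$opt$v
      } else {
        stepW <- adam_step(state$W, g$W, opt_W, hp$learning_rate, epoch)
        state$W <- stepW$params
        opt_W <- stepW$opt
      }
    }
  })

  state <- propagate(state, P)
  state$pairs <- ds$pairs
  state$log <- losses
  state
}

#' Save / load a model checkpoint
#'
#' A checkpoint directory contains the layer-0 embeddings (`E0.tsv`), the
#' transition matrices (`W_<k>.tsv`), and a JSON sidecar with the
#' hyperparameters, vocabularies, and training pair set, from which the
#' propagation operator and layer embeddings are rebuilt on load.
#'
#' @param state a trained `linkgcn_model`.
#' @param dir checkpoint directory (created if missing).
#' @return `save_model()` returns `dir` invisibly; `load_model()` returns
#'   the propagated `linkgcn_model`.
#' @export
save_model <- function(state, dir) {
  stopifnot(inherits(state, "linkgcn_model"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  utils::write.table(state$E0, file.path(dir, "E0.tsv"),
                     sep = "\t", row.names = FALSE, col.names = FALSE)
  for (k in seq_along(state$W)) {
    utils::write.table(state$W[[k]], file.path(dir, sprintf("W_%d.tsv", k)),
                       sep = "\t", row.names = FALSE, col.names = FALSE)
  }
  side <- list(
    hyperparameters = unclass(state$hp),
    m = state$m, n = state$n,
    ncrnas = state$ncrnas, drugs = state$drugs,
    pairs = if (is.null(state$pairs)) NULL else state$pairs,
    node_order = "ncRNAs first (rows 1..m), then drugs (rows m+1..m+n)"
  )
  jsonlite::write_json(side, file.path(dir, "model.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' @rdname save_model
#' @export
load_model <- function(dir) {
  side <- jsonlite::read_json(file.path(dir, "model.json"),
                              simplifyVector = TRUE)
  hp <- do.call(hyperparameters, side$hyperparameters)
  state <- init_embeddings(side$m, side$n, hp)
  state$E0 <- as.matrix(utils::read.table(file.path(dir, "E0.tsv"), sep = "\t"))
  dimnames(state$E0) <- NULL
  state$W <- lapply(seq_len(hp$K), function(k) {
    w <- as.matrix(utils::read.table(file.path(dir, sprintf("W_%d.tsv", k)),
                                     sep = "\t"))
    dimnames(w) <- NULL
    w
  })
  state$ncrnas <- side$ncrnas
  state$drugs <- side$drugs
  if (!is.null(side$pairs)) {
    pairs <- matrix(as.integer(unlist(side$pairs)), ncol = 2L)
    state$pairs <- pairs
    ds <- association_dataset(side$ncrnas, side$drugs, pairs)
    state <- propagate(state, normalize_adjacency(build_adjacency(ds)))
  }
  state
}
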
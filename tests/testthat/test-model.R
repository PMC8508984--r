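make_state <- function(ds, hp) {
  st <- init_embeddings(n_ncrnas(ds), n_drugs(ds), hp)
  P <- normalize_adjacency(build_adjacency(ds))
  list(state = st, P = P)
}

test_that("hyperparameter invariants are enforced", {
  expect_error(hyperparameters(init_std = 0), "init_std")
  expect_error(hyperparameters(K = 0), "K")
  expect_error(hyperparameters(S = 0.5), "S")
  expect_error(hyperparameters(lambda_reg = -1), "lambda_reg")
  hp <- hyperparameters()
  expect_equal(hp$K, 4L)
  expect_equal(hp$S, 32L)
  expect_equal(hp$init_std, 0.1)
})

test_that("initialization is seeded and matches the requested spread", {
  hp <- hyperparameters(seed = 13)
  s1 <- init_embeddings(10, 4, hp)
  s2 <- init_embeddings(10, 4, hp)
  expect_identical(s1$E0, s2$E0)
  expect_identical(s1$W, s2$W)

  # reference network scale: 625 ncRNAs + 121 drugs, S = 32
  big <- init_embeddings(625, 121, hp)
  expect_lt(abs(sd(big$E0) - 0.1) / 0.1, 0.05)
})

test_that("propagation fixes the embeddings when P and W are identities", {
  ds <- association_dataset(paste0("n", 1:3), paste0("d", 1:2),
                            matrix(integer(0), ncol = 2))
  hp <- hyperparameters(K = 3, S = 4, seed = 2)
  ms <- make_state(ds, hp)
  expect_equal(max(abs(as.matrix(ms$P) - diag(5))), 0)  # self-loops only
  st <- ms$state
  st$W <- rep(list(diag(4)), 3)
  st <- propagate(st, ms$P)
  for (k in 1:4) expect_equal(st$layers[[k]], st$E0)
})

test_that("one propagation step equals the per-node neighbor-sum form", {
  set.seed(17)
  ds <- random_dataset(5, 3)
  hp <- hyperparameters(K = 1, S = 4, seed = 5)
  ms <- make_state(ds, hp)
  st <- propagate(ms$state, ms$P)
  expect_lt(max(abs(st$layers[[2]] -
                    oracle_one_step(ds, st$E0, st$W[[1]]))), 1e-9)
})

test_that("K layers compose K single steps with their own transforms", {
  set.seed(19)
  ds <- random_dataset(6, 4)
  hp <- hyperparameters(K = 4, S = 3, seed = 7)
  ms <- make_state(ds, hp)
  st <- propagate(ms$state, ms$P)
  E <- st$E0
  for (k in 1:4) {
    E <- as.matrix(ms$P %*% E %*% st$W[[k]])
    expect_equal(st$layers[[k + 1]], E, tolerance = 1e-12)
  }
  expect_error(propagate(ms$state, ms$P[1:5, 1:5]), "side")
})

test_that("propagation is linear in the layer-0 embeddings", {
  set.seed(23)
  ds <- random_dataset(7, 4)
  hp <- hyperparameters(K = 3, S = 5, seed = 3)
  ms <- make_state(ds, hp)
  st <- propagate(ms$state, ms$P)
  st2 <- ms$state
  st2$E0 <- 2.5 * st2$E0
  st2 <- propagate(st2, ms$P)
  for (k in seq_along(st$layers)) {
    expect_lt(max(abs(st2$layers[[k]] - 2.5 * st$layers[[k]])), 1e-9)
  }
})

test_that("residual scores accumulate per-layer dot products", {
  set.seed(29)
  ds <- random_dataset(4, 3)
  hp <- hyperparameters(K = 2, S = 3, seed = 9)
  ms <- make_state(ds, hp)
  expect_error(score_matrix(ms$state), "propagate")
  st <- propagate(ms$state, ms$P)
  expect_lt(max(abs(score_matrix(st) -
                    oracle_scores(st$layers, 4, 3))), 1e-9)

  # alternative base case: start accumulation at layer 1
  st0 <- st
  st0$hp$include_layer0 <- FALSE
  expect_lt(max(abs(score_matrix(st0) -
                    oracle_scores(st$layers, 4, 3, include_layer0 = FALSE))),
            1e-9)

  zero <- st
  zero$layers <- lapply(zero$layers, function(E) E * 0)
  expect_equal(max(abs(score_matrix(zero))), 0)
})

test_that("BPR loss reduces to T ln 2 at zero margin and vanishes at large margin", {
  ds <- association_dataset(paste0("n", 1:3), paste0("d", 1:3),
                            rbind(c(1L, 1L), c(2L, 2L), c(3L, 3L)))
  hp <- hyperparameters(K = 2, S = 4, lambda_reg = 0, seed = 1)
  ms <- make_state(ds, hp)
  st <- ms$state
  st$E0 <- st$E0 * 0
  st <- propagate(st, ms$P)
  triples <- cbind(1:3, c(1L, 2L, 3L), c(2L, 3L, 1L))
  expect_equal(bpr_loss(st, triples), 3 * log(2), tolerance = 1e-12)
  expect_error(bpr_loss(st, cbind(1L, 2L, 2L)), "identical")

  # hand-built single-layer state with a huge positive margin
  big <- structure(
    list(E0 = rbind(10, 10, -10), W = list(matrix(1)),
         layers = list(rbind(10, 10, -10)), m = 1L, n = 2L,
         hp = hyperparameters(K = 1, S = 1, lambda_reg = 0)),
    class = "linkgcn_model"
  )
  expect_lt(bpr_loss(big, cbind(1L, 1L, 2L)), 1e-10)
  # loss is monotone decreasing in the margin
  shrink <- big
  shrink$layers <- list(rbind(1, 1, -1))
  expect_gt(bpr_loss(shrink, cbind(1L, 1L, 2L)), bpr_loss(big, cbind(1L, 1L, 2L)))
})

test_that("BPR loss matches a scalar-by-scalar evaluation", {
  set.seed(31)
  ds <- random_dataset(5, 4)
  hp <- hyperparameters(K = 2, S = 3, lambda_reg = 0.05, seed = 4)
  ms <- make_state(ds, hp)
  st <- propagate(ms$state, ms$P)
  triples <- rbind(c(1L, 1L, 2L), c(2L, 3L, 4L), c(4L, 2L, 1L))
  manual <- 0
  for (t in seq_len(nrow(triples))) {
    a <- triples[t, 1]; i <- triples[t, 2]; j <- triples[t, 3]
    si <- 0; sj <- 0
    for (k in seq_along(st$layers)) {
      si <- si + sum(st$layers[[k]][a, ] * st$layers[[k]][5 + i, ])
      sj <- sj + sum(st$layers[[k]][a, ] * st$layers[[k]][5 + j, ])
    }
    manual <- manual - log(1 / (1 + exp(-(si - sj))))
  }
  manual <- manual + 0.05 * sum(st$E0^2) +
    0.05 * sum(sapply(st$W, function(w) sum(w^2)))
  expect_equal(bpr_loss(st, triples), manual, tolerance = 1e-10)
})

test_that("analytic gradients agree with finite differences", {
  set.seed(37)
  ds <- random_dataset(8, 5, density = 0.35)
  hp <- hyperparameters(K = 3, S = 4, lambda_reg = 1e-3, seed = 6)
  ms <- make_state(ds, hp)
  st <- propagate(ms$state, ms$P)
  pos <- ds$pairs
  neg <- vapply(pos[, 1], function(a) {
    sample(setdiff(1:5, pos[pos[, 1] == a, 2]), 1L)
  }, integer(1))
  triples <- cbind(pos, neg)
  g <- linkgcn:::bpr_gradients(st, ms$P, triples)
  f <- function(s) bpr_loss(propagate(s, ms$P), triples)
  eps <- 1e-6
  for (t in 1:10) {
    i <- sample(length(st$E0), 1)
    up <- st; up$E0[i] <- up$E0[i] + eps
    dn <- st; dn$E0[i] <- dn$E0[i] - eps
    fd <- (f(up) - f(dn)) / (2 * eps)
    expect_lt(abs(fd - g$E0[i]) / max(1e-8, abs(fd)), 1e-4)
  }
  for (t in 1:5) {
    k <- sample(3, 1); i <- sample(16, 1)
    up <- st; up$W[[k]][i] <- up$W[[k]][i] + eps
    dn <- st; dn$W[[k]][i] <- dn$W[[k]][i] - eps
    fd <- (f(up) - f(dn)) / (2 * eps)
    expect_lt(abs(fd - g$W[[k]][i]) / max(1e-8, abs(fd)), 1e-4)
  }
})

test_that("permuting ncRNA labels permutes score-matrix rows identically", {
  set.seed(41)
  ds <- random_dataset(6, 4)
  hp <- hyperparameters(K = 2, S = 3, seed = 8)
  ms <- make_state(ds, hp)
  st <- propagate(ms$state, ms$P)
  O <- score_matrix(st)

  perm <- sample(6)
  ds_p <- association_dataset(
    ds$ncrnas[perm], ds$drugs,
    cbind(match(ds$pairs[, 1], perm), ds$pairs[, 2])
  )
  stp <- init_embeddings(6, 4, hp)
  stp$E0 <- st$E0[c(perm, 7:10), ]       # same initialization, relabeled
  stp <- propagate(stp, normalize_adjacency(build_adjacency(ds_p)))
  expect_equal(score_matrix(stp), O[perm, ], tolerance = 1e-9,
               ignore_attr = TRUE)
})

test_that("a duplicated drug column yields identical score columns", {
  ds <- association_dataset(
    paste0("n", 1:4), c("d1", "d2", "d3"),
    rbind(c(1L, 1L), c(1L, 2L), c(2L, 1L), c(2L, 2L), c(3L, 3L))
  )  # d2 duplicates d1's neighborhood
  hp <- hyperparameters(K = 3, S = 4, seed = 10)
  ms <- make_state(ds, hp)
  st <- ms$state
  st$E0[6, ] <- st$E0[5, ]               # identical initial drug embeddings
  st <- propagate(st, ms$P)
  O <- score_matrix(st)
  expect_equal(O[, 1], O[, 2], tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("training descends the loss, reproducibly, and 0 epochs is a no-op", {
  sim <- generate_synthetic(100, 30, k_blocks = 2, density_in = 0.5,
                            density_out = 0.02, seed = 7)
  hp <- hyperparameters(seed = 7)
  model <- train_model(sim$dataset, hp)
  expect_length(model$log, 200L)
  expect_lt(tail(model$log, 1), model$log[1])

  hp_small <- hyperparameters(K = 2, S = 4, epochs = 5, seed = 3)
  small <- generate_synthetic(20, 8, k_blocks = 2, density_in = 0.6,
                              density_out = 0.05, seed = 3)
  m1 <- train_model(small$dataset, hp_small)
  m2 <- train_model(small$dataset, hp_small)
  expect_identical(m1$log, m2$log)
  expect_identical(m1$E0, m2$E0)

  hp0 <- hyperparameters(K = 2, S = 4, epochs = 0, seed = 3)
  m0 <- train_model(small$dataset, hp0)
  init <- init_embeddings(20, 8, hp0)
  expect_identical(m0$E0, init$E0)
  expect_identical(m0$W, init$W)
})

test_that("shared transition weights stay tied through training", {
  small <- generate_synthetic(15, 6, k_blocks = 2, density_in = 0.6,
                              density_out = 0.05, seed = 5)
  hp <- hyperparameters(K = 3, S = 4, epochs = 4, seed = 5,
                        shared_weights = TRUE)
  m <- train_model(small$dataset, hp)
  expect_identical(m$W[[1]], m$W[[2]])
  expect_identical(m$W[[1]], m$W[[3]])
})

test_that("checkpoints round-trip through save and load", {
  small <- generate_synthetic(12, 6, k_blocks = 2, density_in = 0.6,
                              density_out = 0.05, seed = 6)
  hp <- hyperparameters(K = 2, S = 4, epochs = 3, seed = 6)
  m <- train_model(small$dataset, hp)
  dir <- withr::local_tempdir()
  save_model(m, dir)
  m2 <- load_model(dir)
  expect_equal(score_matrix(m2), score_matrix(m), tolerance = 1e-9)
  expect_equal(m2$drugs, m$drugs)
})
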
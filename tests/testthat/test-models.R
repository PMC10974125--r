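test_that("scaled dot attention obeys its unit identities", {
  # single key: output is V's row regardless of Q/K
  a <- scaled_dot_attention(matrix(c(3, -2), 1, 2), matrix(c(0.5, 9), 1, 2),
                            matrix(c(4, 7), 1, 2))
  expect_equal(a$out, matrix(c(4, 7), 1, 2))
  # identical keys: uniform weights, output = column mean of V
  K <- matrix(1, 4, 2)
  V <- matrix(rnorm(8), 4, 2)
  a2 <- scaled_dot_attention(matrix(rnorm(2), 1, 2), K, V)
  expect_equal(as.numeric(a2$out), colMeans(V), tolerance = 1e-9)
  expect_equal(rowSums(a2$weights), 1, tolerance = 1e-9)
  # hand-evaluated 2x2 case
  a3 <- scaled_dot_attention(matrix(c(1, 0), 1, 2), rbind(c(1, 0), c(0, 1)),
                             rbind(c(1, 0), c(0, 1)))
  w1 <- exp(1 / sqrt(2)) / (exp(1 / sqrt(2)) + 1)
  expect_equal(as.numeric(a3$weights), c(w1, 1 - w1), tolerance = 1e-6)
  expect_equal(as.numeric(a3$out), c(w1, 1 - w1), tolerance = 1e-6)
  expect_equal(w1, 0.6698, tolerance = 1e-4)
})

test_that("masked keys receive exactly zero attention weight", {
  Q <- matrix(rnorm(6), 3, 2)
  K <- matrix(rnorm(8), 4, 2)
  V <- matrix(rnorm(8), 4, 2)
  a <- scaled_dot_attention(Q, K, V, mask = c(TRUE, FALSE, TRUE, FALSE))
  expect_true(all(a$weights[, c(2, 4)] == 0))
  expect_equal(rowSums(a$weights), rep(1, 3), tolerance = 1e-9)
  expect_error(scaled_dot_attention(Q, K, V, mask = rep(FALSE, 4)), "masked")
})

test_that("multi-head attention reduces to single-head with identity projections", {
  set.seed(2)
  X <- matrix(rnorm(12), 3, 4)
  I4 <- diag(4)
  mh <- multi_head_attention(X, I4, I4, I4, I4, n_heads = 1L)
  sh <- scaled_dot_attention(X, X, X)
  expect_equal(mh$out, sh$out, tolerance = 1e-9)
  expect_error(multi_head_attention(X, I4, I4, I4, I4, n_heads = 3L), "divisible")
})

test_that("self-attention is permutation-equivariant without position embedding", {
  set.seed(4)
  X <- matrix(rnorm(12), 3, 4)
  Wq <- glorot(4, 4); Wk <- glorot(4, 4); Wv <- glorot(4, 4); Wo <- glorot(4, 4)
  out1 <- multi_head_attention(X, Wq, Wk, Wv, Wo, n_heads = 2L)$out
  perm <- c(2, 1, 3)
  out2 <- multi_head_attention(X[perm, ], Wq, Wk, Wv, Wo, n_heads = 2L)$out
  expect_equal(out2, out1[perm, ], tolerance = 1e-9)
  # zero input gives zero output through the linear projections
  expect_equal(multi_head_attention(matrix(0, 3, 4), Wq, Wk, Wv, Wo, 2L)$out,
               matrix(0, 3, 4))
})

test_that("position embedding matches direct evaluation of the sinusoid table", {
  pe <- position_embedding(50, 8)
  expect_equal(dim(pe), c(50, 8))
  expect_true(all(pe >= -1 & pe <= 1))
  # p = 0: sine slots 0, cosine slots 1
  expect_equal(pe[1, ], rep(c(0, 1), 4))
  # p = 1, i = 0
  expect_equal(pe[2, 1], sin(1), tolerance = 1e-12)
  expect_equal(pe[2, 2], cos(1), tolerance = 1e-12)
  # independent pointwise evaluation
  direct <- matrix(0, 50, 8)
  for (p in 0:49) for (col in 1:8) {
    i <- (col - 1) %/% 2
    ang <- p / 10000^(2 * i / 8)
    direct[p + 1, col] <- if (col %% 2 == 1) sin(ang) else cos(ang)
  }
  expect_equal(pe, direct, tolerance = 1e-12)
  expect_equal(ncol(position_embedding(5, 3)), 3)
})

test_that("encoder layer preserves shape and isolates masked positions", {
  set.seed(6)
  cfg <- transformer_config(n_features = 4, n_heads = 2, d_ff = 8, dropout = 0)
  params <- transformer_init(cfg, seq_len = 5, out_len = 5, n_targets = 1)
  X <- matrix(rnorm(20), 5, 4)
  out <- encoder_layer_forward(X, params, cfg)
  expect_equal(dim(out), dim(X))
  expect_equal(out, encoder_layer_forward(X, params, cfg))  # deterministic
  # perturbing a masked row leaves the other rows' attention output unchanged
  mask <- c(TRUE, TRUE, TRUE, FALSE, FALSE)
  X2 <- X
  X2[4, ] <- X2[4, ] + 100
  a1 <- mha_fwd(X, params$Wq1, params$Wk1, params$Wv1, params$Wo1, 2, mask)
  a2 <- mha_fwd(X2, params$Wq1, params$Wk1, params$Wv1, params$Wo1, 2, mask)
  expect_equal(a1$out[mask, ], a2$out[mask, ], tolerance = 1e-9)
})

numeric_grad <- function(fn, x, eps = 1e-5) {
  g <- x * 0
  for (i in seq_along(x)) {
    xp <- x; xp[i] <- xp[i] + eps
    xm <- x; xm[i] <- xm[i] - eps
    g[i] <- (fn(xp) - fn(xm)) / (2 * eps)
  }
  g
}

test_that("transformer analytic gradients match numerical differentiation", {
  set.seed(11)
  cfg <- transformer_config(n_features = 4, n_heads = 2, n_layers = 1,
                            d_ff = 6, dropout = 0, seed = 11)
  S <- 4; B <- 2; nt <- 2
  params <- transformer_init(cfg, S, S, nt)
  pe <- position_embedding(S, 4)
  X <- array(rnorm(B * S * 4), c(B, S, 4))
  mask <- matrix(TRUE, B, S)
  y <- array(rnorm(B * S * nt), c(B, S, nt))
  loss_fn <- function(p) {
    f <- transformer_forward(p, X, mask, cfg, S, S, nt, pe, train = FALSE)
    mean((f$pred - y)^2)
  }
  f <- transformer_forward(params, X, mask, cfg, S, S, nt, pe, train = FALSE)
  grads <- transformer_backward(params, f, 2 * (f$pred - y) / length(y),
                                X, mask, cfg)
  for (nm in c("Wq1", "Wv1", "ln1g1", "W11", "b21", "ln2b1", "Wout", "bout")) {
    ng <- numeric_grad(function(v) {
      p2 <- params; p2[[nm]] <- v; loss_fn(p2)
    }, params[[nm]])
    expect_lt(max(abs(grads[[nm]] - ng)) / (max(abs(ng)) + 1e-8), 1e-4)
  }
})

test_that("recurrent analytic gradients match numerical differentiation", {
  set.seed(12)
  cfg <- transformer_config(n_features = 3, n_heads = 1, d_ff = 5, dropout = 0)
  S <- 4; B <- 2; nt <- 1
  X <- array(rnorm(B * S * 3), c(B, S, 3))
  mask <- matrix(c(TRUE, TRUE, TRUE, FALSE), B, S, byrow = TRUE)
  y <- array(rnorm(B * S * nt), c(B, S, nt))
  for (arch in c("rnn", "lstm")) {
    params <- recurrent_init(cfg, arch, S, S, nt)
    loss_fn <- function(p) {
      f <- recurrent_forward(p, X, mask, cfg, arch, S, nt, train = FALSE)
      mean((f$pred - y)^2)
    }
    f <- recurrent_forward(params, X, mask, cfg, arch, S, nt, train = FALSE)
    grads <- recurrent_backward(params, f, 2 * (f$pred - y) / length(y),
                                X, mask, cfg, arch)
    for (nm in names(params)) {
      ng <- numeric_grad(function(v) {
        p2 <- params; p2[[nm]] <- v; loss_fn(p2)
      }, params[[nm]])
      expect_lt(max(abs(grads[[nm]] - ng)) / (max(abs(ng)) + 1e-8), 1e-4)
    }
  }
})

test_that("training on a linearly coupled fixture shrinks the validation loss", {
  ds <- linear_fixture(n = 240)
  sp <- split_dataset(ds, 0.25, "by_example", seed = 1)
  cfg <- transformer_config(n_features = 4, n_heads = 2, d_ff = 32,
                            dropout = 0, lr = 3e-3, batch_size = 32,
                            epochs = 150, seed = 3)
  cfg0 <- cfg; cfg0$epochs <- 0L
  m0 <- train_estimator(sp$train, sp$test, cfg0)
  expect_equal(nrow(m0$history), 0L)
  m <- train_estimator(sp$train, sp$test, cfg)
  initial <- m$history$val_loss[1]
  expect_lt(min(m$history$val_loss), 0.1 * initial)
  # baselines learn the same fixture
  for (arch in c("rnn", "lstm")) {
    cfgb <- cfg; cfgb$epochs <- 25L
    mb <- train_estimator(sp$train, sp$test, cfgb, arch)
    expect_lt(min(mb$history$val_loss), 0.5 * mb$history$val_loss[1])
    expect_equal(dim(predict(mb, sp$test)),
                 c(n_examples(sp$test), 10, 2))
  }
})

test_that("training and prediction are seed-deterministic; batches independent", {
  ds <- linear_fixture(n = 60)
  sp <- split_dataset(ds, 0.25, "by_example", seed = 2)
  cfg <- transformer_config(n_features = 4, n_heads = 2, d_ff = 8,
                            dropout = 0.1, epochs = 3, seed = 9)
  m1 <- train_estimator(sp$train, sp$test, cfg)
  m2 <- train_estimator(sp$train, sp$test, cfg)
  expect_identical(m1$history, m2$history)
  expect_identical(m1$params, m2$params)
  p1 <- predict(m1, sp$test)
  # duplicating the batch duplicates predictions: no cross-example mixing
  dup <- dataset_bind(sp$test, sp$test)
  p2 <- predict(m1, dup)
  expect_equal(p2[seq_len(n_examples(sp$test)), , ], p1, tolerance = 1e-12)
  expect_equal(p2[n_examples(sp$test) + seq_len(n_examples(sp$test)), , ], p1,
               tolerance = 1e-12)
  expect_error(estimator_forward(m1, array(0, c(2, 10, 7))), "feature dimension")
})

test_that("r2_score matches hand arithmetic and rejects constant truth", {
  expect_equal(r2_score(c(1, 2, 3), c(1, 2, 3)), 1)
  y <- rnorm(20)
  expect_equal(r2_score(y, rep(mean(y), 20)), 0)
  expect_equal(r2_score(c(1, 2, 3), c(1, 2, 2)), 0.5)
  expect_error(r2_score(rep(1, 5), rnorm(5)), "constant")
})

test_that("evaluation reports order statistics invariant to trial order", {
  ds <- linear_fixture(n = 120)
  sp <- split_dataset(ds, 0.5, "by_example", seed = 4)
  cfg <- transformer_config(n_features = 4, n_heads = 2, d_ff = 16,
                            dropout = 0, lr = 3e-3, epochs = 20, seed = 5)
  m <- train_estimator(sp$train, sp$test, cfg)
  trials <- list(dataset_subset(sp$test, 1:20), dataset_subset(sp$test, 21:40),
                 dataset_subset(sp$test, 41:60))
  r <- evaluate(m, trials, "fusion")
  expect_equal(r$highest, max(r$r2_per_trial))
  expect_equal(r$lowest, min(r$r2_per_trial))
  expect_equal(r$mean, mean(r$r2_per_trial))
  r_perm <- evaluate(m, trials[c(3, 1, 2)], "fusion")
  expect_equal(r_perm$highest, r$highest)
  expect_equal(r_perm$mean, r$mean)
  r1 <- evaluate(m, trials[1], "fusion")
  expect_equal(r1$highest, r1$lowest)
  expect_equal(r1$highest, r1$mean)
  expect_s3_class(glance(r), "tbl_df")
  expect_equal(nrow(tidy(r)), 3)
  # empty trials are skipped with a warning; all-empty is an error
  empty <- dataset_subset(sp$test, integer(0))
  expect_warning(r_skip <- evaluate(m, list(trials[[1]], empty), "fusion"),
                 "empty")
  expect_length(r_skip$r2_per_trial, 1)
  expect_error(suppressWarnings(evaluate(m, list(empty), "fusion")), "empty")
})

test_that("grid search ranks hyperparameter points by validation R-squared", {
  ds <- linear_fixture(n = 80)
  sp <- split_dataset(ds, 0.25, "by_example", seed = 6)
  base <- transformer_config(n_features = 4, n_heads = 2, d_ff = 8,
                             dropout = 0, epochs = 4, seed = 2)
  g <- grid_search(sp$train, sp$test, base,
                   grid = list(n_heads = c(2L, 1L)))
  expect_equal(nrow(g), 2L)
  expect_true(all(diff(g$val_r2) <= 0))
  expect_s3_class(attr(g, "best_model"), "mmg_estimator")
})
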
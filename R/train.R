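#' Train a joint-acceleration estimator
#'
#' Minimizes mean squared error between predicted and target sub-window
#' sequences by mini-batch Adam. Targets are standardized internally per
#' channel using training-set statistics (predictions are returned on the
#' original scale). Per-epoch train/val loss is recorded and the parameters
#' with the best validation loss are returned. All randomness
#' (initialization, shuffling, dropout) derives from `config$seed`, so a
#' rerun with the same data and seed reproduces the loss history exactly.
#'
#' @param train a `supervised_dataset` (non-empty).
#' @param val a `supervised_dataset` used for checkpoint selection; pass the
#'   training set itself if no validation split is available.
#' @param config a [transformer_config()].
#' @param arch `"transformer"`, `"rnn"` or `"lstm"`.
#' @return an `mmg_estimator`: parameters, architecture, config, loss
#'   `history` tibble, target scaling, and dataset metadata. With
#'   `epochs = 0` the initialized parameters are returned with an empty
#'   history.
#' @export
train_estimator <- function(train, val, config = transformer_config(),
                            arch = c("transformer", "rnn", "lstm")) {
  arch <- match.arg(arch)
  stopifnot(inherits(train, "supervised_dataset"))
  if (n_examples(train) < 1L) stop("empty training set", call. = FALSE)
  if (dim(train$X)[3] != config$n_features) {
    stop("configuration error: dataset has ", dim(train$X)[3],
         " features but config expects ", config$n_features, call. = FALSE)
  }
  seq_len_ <- dim(train$X)[2]
  out_len <- dim(train$y)[2]
  n_targets <- dim(train$y)[3]

  set.seed(config$seed)
  params <- if (arch == "transformer") {
    transformer_init(config, seq_len_, out_len, n_targets)
  } else {
    recurrent_init(config, arch, seq_len_, out_len, n_targets)
  }
  pe <- position_embedding(seq_len_,
                           if (is.null(config$d_model)) config$n_features
                           else config$d_model)

  center <- apply(train$y, 3, mean)
  scale <- apply(train$y, 3, sd)
  scale[scale == 0] <- 1
  std_y <- function(y) {
    for (k in seq_len(n_targets)) y[, , k] <- (y[, , k] - center[k]) / scale[k]
    y
  }
  ytr <- std_y(train$y)
  yva <- std_y(val$y)

  adam_m <- lapply(params, function(p) p * 0)
  adam_v <- lapply(params, function(p) p * 0)
  beta1 <- 0.9; beta2 <- 0.999; eps <- 1e-8
  step <- 0L

  fwd_fn <- function(p, X, mask, train_mode) {
    if (arch == "transformer") {
      transformer_forward(p, X, mask, config, seq_len_, out_len, n_targets,
                          pe, train = train_mode)
    } else {
      recurrent_forward(p, X, mask, config, arch, out_len, n_targets,
                        train = train_mode)
    }
  }
  bwd_fn <- function(p, fwd, dpred, X, mask) {
    if (arch == "transformer") {
      transformer_backward(p, fwd, dpred, X, mask, config)
    } else {
      recurrent_backward(p, fwd, dpred, X, mask, config, arch)
    }
  }
  eval_loss <- function(p, ds, y) {
    n <- n_examples(ds)
    tot <- 0
    bs <- max(config$batch_size, 1L)
    for (at in seq(1L, n, by = bs)) {
      idx <- at:min(at + bs - 1L, n)
      f <- fwd_fn(p, ds$X[idx, , , drop = FALSE], ds$mask[idx, , drop = FALSE],
                  FALSE)
      tot <- tot + sum((f$pred - y[idx, , , drop = FALSE])^2)
    }
    tot / (n * out_len * n_targets)
  }

  history <- list()
  best_params <- params
  best_val <- Inf
  n <- n_examples(train)
  for (epoch in seq_len(config$epochs)) {
    ord <- sample.int(n)
    ep_loss <- 0
    n_batches <- 0L
    for (at in seq(1L, n, by = config$batch_size)) {
      idx <- ord[at:min(at + config$batch_size - 1L, n)]
      Xb <- train$X[idx, , , drop = FALSE]
      mb <- train$mask[idx, , drop = FALSE]
      yb <- ytr[idx, , , drop = FALSE]
      f <- fwd_fn(params, Xb, mb, TRUE)
      resid <- f$pred - yb
      loss <- mean(resid^2)
      if (!is.finite(loss)) {
        stop(sprintf("NaN/Inf loss (arch=%s, lr=%g, epoch=%d, batch index %d): try a lower learning rate",
                     arch, config$lr, epoch, n_batches + 1L), call. = FALSE)
      }
      dpred <- 2 * resid / length(resid)
      grads <- bwd_fn(params, f, dpred, Xb, mb)
      step <- step + 1L
      corr <- sqrt(1 - beta2^step) / (1 - beta1^step)
      for (nm in names(params)) {
        g <- grads[[nm]]
        adam_m[[nm]] <- beta1 * adam_m[[nm]] + (1 - beta1) * g
        adam_v[[nm]] <- beta2 * adam_v[[nm]] + (1 - beta2) * g^2
        params[[nm]] <- params[[nm]] -
          config$lr * corr * adam_m[[nm]] / (sqrt(adam_v[[nm]]) + eps)
      }
      ep_loss <- ep_loss + loss
      n_batches <- n_batches + 1L
    }
    val_loss <- eval_loss(params, val, yva)
    history[[epoch]] <- c(epoch = epoch, train_loss = ep_loss / n_batches,
                          val_loss = val_loss)
    if (val_loss < best_val) {
      best_val <- val_loss
      best_params <- params
    }
  }
  hist_df <- if (length(history)) {
    tibble::as_tibble(do.call(rbind, history))
  } else {
    tibble::tibble(epoch = numeric(), train_loss = numeric(), val_loss = numeric())
  }
  structure(list(params = best_params, arch = arch, config = config,
                 seq_len = seq_len_, out_len = out_len, n_targets = n_targets,
                 pe = pe, target_center = center, target_scale = scale,
                 feature_names = train$feature_names,
                 target_names = train$target_names,
                 history = hist_df, best_val_loss = best_val),
            class = "mmg_estimator")
}

#' @export
print.mmg_estimator <- function(x, ...) {
  cat(sprintf("<mmg_estimator: %s> %d feature(s) -> %d target(s), seq %d, %d epoch(s) trained\n",
              x$arch, x$config$n_features, x$n_targets, x$seq_len,
              nrow(x$history)))
  if (nrow(x$history)) {
    cat(sprintf("  best val MSE (standardized): %.5f\n", x$best_val_loss))
  }
  invisible(x)
}

#' @export
predict.mmg_estimator <- function(object, newdata, ...) {
  stopifnot(inherits(newdata, "supervised_dataset"))
  n <- n_examples(newdata)
  bs <- max(object$config$batch_size, 1L)
  preds <- array(NA_real_, c(n, object$out_len, object$n_targets))
  for (at in seq(1L, n, by = bs)) {
    idx <- at:min(at + bs - 1L, n)
    preds[idx, , ] <- estimator_forward(object,
                                        newdata$X[idx, , , drop = FALSE],
                                        newdata$mask[idx, , drop = FALSE])
  }
  preds
}

#' @export
tidy.mmg_estimator <- function(x, ...) x$history

#' @export
glance.mmg_estimator <- function(x, ...) {
  tibble::tibble(
    arch = x$arch,
    n_features = x$config$n_features,
    n_heads = x$config$n_heads,
    n_layers = x$config$n_layers,
    epochs_trained = nrow(x$history),
    best_val_loss = x$best_val_loss
  )
}

#' Plot a training history
#'
#' @param object an `mmg_estimator`.
#' @param ... unused.
#' @return a ggplot of train/val loss per epoch.
#' @export
autoplot.mmg_estimator <- function(object, ...) {
  h <- object$history
  df <- tibble::tibble(
    epoch = rep(h$epoch, 2),
    loss = c(h$train_loss, h$val_loss),
    split = rep(c("train", "val"), each = nrow(h))
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$epoch, y = .data$loss,
                                   linetype = .data$split)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "epoch", y = "MSE (standardized targets)")
}

#' Grid search over estimator hyperparameters
#'
#' Trains one model per grid point and selects by validation R-squared
#' (targets pooled). Mirrors the sweep axes reported for the reference
#' configuration: heads, encoder layers, and sequence length are the axes
#' that matter; batch size has little effect.
#'
#' @param train,val `supervised_dataset`s.
#' @param base_config a [transformer_config()] supplying fixed settings.
#' @param grid named list of hyperparameter vectors to cross (names must be
#'   `transformer_config` fields, e.g. `list(n_heads = c(8, 4, 2, 1))`).
#' @param arch estimator architecture.
#' @return tibble of grid points with validation R-squared, best first, with
#'   the winning model in `attr(, "best_model")`.
#' @export
grid_search <- function(train, val, base_config = transformer_config(),
                        grid = list(n_heads = c(8L, 4L, 2L, 1L)),
                        arch = "transformer") {
  pts <- expand.grid(grid, stringsAsFactors = FALSE)
  r2s <- numeric(nrow(pts))
  models <- vector("list", nrow(pts))
  for (i in seq_len(nrow(pts))) {
    cfg <- base_config
    for (nm in names(pts)) cfg[[nm]] <- pts[[nm]][i]
    m <- train_estimator(train, val, cfg, arch)
    pred <- predict(m, val)
    r2s[i] <- r2_score(as.numeric(val$y), as.numeric(pred))
    models[[i]] <- m
  }
  out <- tibble::as_tibble(pts)
  out$val_r2 <- r2s
  out <- out[order(-out$val_r2), ]
  attr(out, "best_model") <- models[[which.max(r2s)]]
  out
}

#' Recurrent baselines
#'
#' Convenience wrappers training the single-layer vanilla RNN (tanh) and
#' single-layer LSTM baselines (hidden width `d_ff`, same output head, loss,
#' optimizer, epoch and seed protocol as the transformer).
#'
#' @inheritParams train_estimator
#' @return an `mmg_estimator`.
#' @export
rnn_baseline <- function(train, val, config = transformer_config()) {
  train_estimator(train, val, config, arch = "rnn")
}

#' @rdname rnn_baseline
#' @export
lstm_baseline <- function(train, val, config = transformer_config()) {
  train_estimator(train, val, config, arch = "lstm")
}
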
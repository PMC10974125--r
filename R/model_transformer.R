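#' Estimator configuration
#'
#' Hyperparameters of the encoder-only transformer and the recurrent
#' baselines. Attention runs at width `d_model = n_features` (8 in the
#' standard fusion configuration: 4 MMG + 4 sEMG envelope channels) with no
#' input up-projection, so `n_features` must be divisible by `n_heads`.
#' `d_ff` is both the feedforward width of the encoder and the hidden width
#' of the RNN/LSTM baselines.
#'
#' @param n_features per-step input width.
#' @param d_model attention width; `NULL` (default) runs attention directly
#'   at `n_features` with no input projection. Setting a larger `d_model`
#'   inserts a per-position linear lift of the features (an optional
#'   capacity knob; the head count must then divide `d_model`).
#' @param n_heads attention heads; must divide `n_features`.
#' @param n_layers encoder layers.
#' @param d_ff position-wise feedforward width.
#' @param dropout dropout rate in `[0, 1)`, applied after attention and
#'   feedforward sublayers during training only.
#' @param lr Adam learning rate (default 3e-3, suited to the
#'   envelope-scale regression sizes this package trains at).
#' @param batch_size mini-batch size.
#' @param epochs training epochs.
#' @param seed RNG seed for initialization, shuffling and dropout.
#' @return a `transformer_config` list.
#' @export
transformer_config <- function(n_features = 8L, n_heads = 2L, n_layers = 1L,
                               d_ff = 64L, dropout = 0.1, lr = 3e-3,
                               batch_size = 64L, epochs = 50L, seed = 1L,
                               d_model = NULL) {
  width <- if (is.null(d_model)) as.integer(n_features) else as.integer(d_model)
  if (width %% n_heads != 0) {
    stop("configuration error: the attention width must be divisible by n_heads",
         call. = FALSE)
  }
  if (dropout < 0 || dropout >= 1) stop("dropout must be in [0, 1)", call. = FALSE)
  structure(list(n_features = as.integer(n_features), n_heads = as.integer(n_heads),
                 n_layers = as.integer(n_layers), d_ff = as.integer(d_ff),
                 dropout = dropout, lr = lr, batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs), seed = as.integer(seed),
                 d_model = width),
            class = "transformer_config")
}

glorot <- function(n_in, n_out) {
  lim <- sqrt(6 / (n_in + n_out))
  matrix(runif(n_in * n_out, -lim, lim), n_in, n_out)
}

transformer_init <- function(config, seq_len, out_len, n_targets) {
  d <- config$d_model; f <- config$d_ff
  params <- list()
  if (d != config$n_features) {
    params$Win <- glorot(config$n_features, d)
    params$bin <- rep(0, d)
  }
  for (l in seq_len(config$n_layers)) {
    params[[paste0("Wq", l)]] <- glorot(d, d)
    params[[paste0("Wk", l)]] <- glorot(d, d)
    params[[paste0("Wv", l)]] <- glorot(d, d)
    params[[paste0("Wo", l)]] <- glorot(d, d)
    params[[paste0("ln1g", l)]] <- rep(1, d)
    params[[paste0("ln1b", l)]] <- rep(0, d)
    params[[paste0("W1", l)]] <- glorot(d, f)
    params[[paste0("b1", l)]] <- rep(0, f)
    params[[paste0("W2", l)]] <- glorot(f, d)
    params[[paste0("b2", l)]] <- rep(0, d)
    params[[paste0("ln2g", l)]] <- rep(1, d)
    params[[paste0("ln2b", l)]] <- rep(0, d)
  }
  params$Wout <- glorot(seq_len * d, out_len * n_targets)
  params$bout <- rep(0, out_len * n_targets)
  params
}

#' One encoder layer, forward pass
#'
#' Sublayer 1: layer-norm(X + multi-head self-attention(X)); sublayer 2:
#' layer-norm(h + position-wise feedforward(h)). Shape is preserved.
#' Exposed for inspection and unit identities; training uses the internal
#' batched path.
#'
#' @param X input sequence `seq_len x d_model`.
#' @param params named parameter list for the layer (keys `Wq1, Wk1, Wv1,
#'   Wo1, ln1g1, ln1b1, W11, b11, W21, b21, ln2g1, ln2b1` — layer suffix 1).
#' @param config a [transformer_config()].
#' @param mask optional logical key mask of length `seq_len`.
#' @return matrix of the same shape as `X`.
#' @export
encoder_layer_forward <- function(X, params, config, mask = NULL) {
  a <- mha_fwd(X, params$Wq1, params$Wk1, params$Wv1, params$Wo1,
               config$n_heads, mask)
  h <- nn_layernorm_fwd(X + a$out, params$ln1g1, params$ln1b1)$out
  ff <- nn_relu_fwd(nn_linear_fwd(h, params$W11, params$b11)$out)
  ffo <- nn_linear_fwd(ff$out, params$W21, params$b21)$out
  nn_layernorm_fwd(h + ffo, params$ln2g1, params$ln2b1)$out
}

#' Run a fitted or initialized estimator forward
#'
#' Input plus sinusoidal position embedding, through the encoder stack (or
#' recurrent core for the baselines), then the final fully connected
#' projection to `[batch, out_len, n_targets]`. Deterministic in evaluation
#' mode (dropout disabled).
#'
#' @param model an `mmg_estimator` (see [train_estimator()]).
#' @param X input array `[batch x seq_len x n_features]`.
#' @param mask optional logical `[batch x seq_len]` padding mask; defaults
#'   to all valid.
#' @return predictions `[batch x out_len x n_targets]`, on the original
#'   target scale.
#' @export
estimator_forward <- function(model, X, mask = NULL) {
  stopifnot(inherits(model, "mmg_estimator"))
  if (length(dim(X)) != 3L || dim(X)[3] != model$config$n_features) {
    stop("input feature dimension does not match the model configuration",
         call. = FALSE)
  }
  if (is.null(mask)) mask <- matrix(TRUE, dim(X)[1], dim(X)[2])
  fwd <- switch(model$arch,
    transformer = transformer_forward(model$params, X, mask, model$config,
                                      model$seq_len, model$out_len,
                                      model$n_targets, model$pe, train = FALSE),
    rnn = ,
    lstm = recurrent_forward(model$params, X, mask, model$config, model$arch,
                             model$out_len, model$n_targets, train = FALSE)
  )
  pred <- fwd$pred
  # undo internal target standardization
  for (k in seq_len(model$n_targets)) {
    pred[, , k] <- pred[, , k] * model$target_scale[k] + model$target_center[k]
  }
  pred
}
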
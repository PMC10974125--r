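# Dense-layer primitives with hand-derived gradients. Everything operates on
# plain matrices; batched sequence tensors are handled by the model files.

nn_linear_fwd <- function(X, W, b = NULL) {
  out <- X %*% W
  if (!is.null(b)) out <- sweep(out, 2, b, "+")
  list(out = out, X = X)
}

nn_linear_bwd <- function(dout, cache, W, has_bias = TRUE) {
  list(dX = dout %*% t(W),
       dW = t(cache$X) %*% dout,
       db = if (has_bias) colSums(dout) else NULL)
}

nn_relu_fwd <- function(X) list(out = pmax(X, 0), mask = X > 0)
nn_relu_bwd <- function(dout, cache) dout * cache$mask

# layer normalization across the feature dimension of each row
nn_layernorm_fwd <- function(X, gamma, beta, eps = 1e-5) {
  mu <- rowMeans(X)
  xc <- X - mu
  v <- rowMeans(xc^2)
  inv_sd <- 1 / sqrt(v + eps)
  xhat <- xc * inv_sd
  out <- sweep(xhat, 2, gamma, "*")
  out <- sweep(out, 2, beta, "+")
  list(out = out, xhat = xhat, inv_sd = inv_sd)
}

nn_layernorm_bwd <- function(dout, cache, gamma) {
  xhat <- cache$xhat
  dxhat <- sweep(dout, 2, gamma, "*")
  m1 <- rowMeans(dxhat)
  m2 <- rowMeans(dxhat * xhat)
  dX <- (dxhat - m1 - xhat * m2) * cache$inv_sd
  list(dX = dX, dgamma = colSums(dout * xhat), dbeta = colSums(dout))
}

# row-wise softmax with an optional key mask (FALSE = excluded). Masked
# positions receive an additive -Inf before normalization and thus exactly
# zero weight; a fully masked row is an error (softmax undefined).
nn_masked_softmax <- function(logits, mask = NULL) {
  if (!is.null(mask)) {
    if (!any(mask)) stop("attention: all key positions masked in a row", call. = FALSE)
    logits[, !mask] <- -Inf
  }
  mx <- apply(logits, 1, max)
  e <- exp(logits - mx)
  e[!is.finite(e)] <- 0
  e / rowSums(e)
}

#' Scaled dot-product attention
#'
#' `softmax(Q K' / sqrt(d_k)) V`, row-wise. Key positions flagged `FALSE` in
#' `mask` receive an additive `-Inf` before the softmax and therefore exactly
#' zero weight; each weight row sums to 1 over the unmasked positions.
#'
#' @param Q query matrix `n x d_k`.
#' @param K key matrix `m x d_k`.
#' @param V value matrix `m x d_v` (`K` and `V` agree on `m`).
#' @param mask optional logical vector of length `m`; a row with every key
#'   masked is an error.
#' @return list with `out` (`n x d_v`) and `weights` (`n x m`).
#' @examples
#' a <- scaled_dot_attention(matrix(1, 1, 2), matrix(1, 1, 2), matrix(5, 1, 1))
#' a$out  # equals V's single row
#' @export
scaled_dot_attention <- function(Q, K, V, mask = NULL) {
  stopifnot(ncol(Q) == ncol(K), nrow(K) == nrow(V))
  logits <- Q %*% t(K) / sqrt(ncol(Q))
  P <- nn_masked_softmax(logits, mask)
  list(out = P %*% V, weights = P)
}

#' Sinusoidal position embedding table
#'
#' `PE_{2i}(p) = sin(p / 10000^{2i/d_pos})`,
#' `PE_{2i+1}(p) = cos(p / 10000^{2i/d_pos})`, for positions
#' `p = 0 .. max_len-1`. Every entry lies in `[-1, 1]`. An odd `d_pos` fills
#' the final sine slot only. The table is added elementwise to input
#' sequences before the encoder stack.
#'
#' @param max_len number of positions.
#' @param d_pos embedding width.
#' @return numeric matrix `max_len x d_pos`.
#' @export
position_embedding <- function(max_len, d_pos) {
  stopifnot(max_len >= 1, d_pos >= 1)
  p <- seq_len(max_len) - 1
  pe <- matrix(NA_real_, max_len, d_pos)
  for (col in seq_len(d_pos)) {
    i <- (col - 1) %/% 2                       # pair index
    angle <- p / 10000^(2 * i / d_pos)
    pe[, col] <- if (col %% 2 == 1) sin(angle) else cos(angle)
  }
  pe
}

#' Multi-head self-attention (single sequence)
#'
#' Projects the input with per-head query/key/value matrices, applies
#' [scaled_dot_attention()] per head, concatenates head outputs in stable
#' head order, and applies the output projection. Feature columns are
#' partitioned contiguously into `n_heads` groups of width
#' `d_model / n_heads`.
#'
#' @param X input sequence `n x d_model`.
#' @param Wq,Wk,Wv,Wo projection matrices `d_model x d_model` (`Wo` may be
#'   `NULL` to return the raw concatenation).
#' @param n_heads head count; must divide `d_model`.
#' @param mask optional logical key mask of length `n`.
#' @return list with `out` (`n x d_model`) and per-head `weights`.
#' @export
multi_head_attention <- function(X, Wq, Wk, Wv, Wo = NULL, n_heads = 2L,
                                 mask = NULL) {
  d <- ncol(X)
  if (d %% n_heads != 0) {
    stop("configuration error: d_model must be divisible by n_heads", call. = FALSE)
  }
  dh <- d %/% n_heads
  Q <- X %*% Wq; K <- X %*% Wk; V <- X %*% Wv
  outs <- vector("list", n_heads)
  wts <- vector("list", n_heads)
  for (h in seq_len(n_heads)) {
    cols <- ((h - 1) * dh + 1):(h * dh)
    a <- scaled_dot_attention(Q[, cols, drop = FALSE], K[, cols, drop = FALSE],
                              V[, cols, drop = FALSE], mask)
    outs[[h]] <- a$out
    wts[[h]] <- a$weights
  }
  concat <- do.call(cbind, outs)
  out <- if (is.null(Wo)) concat else concat %*% Wo
  list(out = out, weights = wts)
}

# full forward + backward of multi-head self-attention for one sequence,
# used inside the encoder layer
mha_fwd <- function(X, Wq, Wk, Wv, Wo, n_heads, mask = NULL) {
  d <- ncol(X); dh <- d %/% n_heads
  Q <- X %*% Wq; K <- X %*% Wk; V <- X %*% Wv
  P <- vector("list", n_heads)
  concat <- matrix(0, nrow(X), d)
  for (h in seq_len(n_heads)) {
    cols <- ((h - 1) * dh + 1):(h * dh)
    logits <- Q[, cols, drop = FALSE] %*% t(K[, cols, drop = FALSE]) / sqrt(dh)
    P[[h]] <- nn_masked_softmax(logits, mask)
    concat[, cols] <- P[[h]] %*% V[, cols, drop = FALSE]
  }
  list(out = concat %*% Wo,
       cache = list(X = X, Q = Q, K = K, V = V, P = P, concat = concat,
                    n_heads = n_heads, dh = dh, mask = mask))
}

mha_bwd <- function(dout, cache, Wq, Wk, Wv, Wo) {
  X <- cache$X; Q <- cache$Q; K <- cache$K; V <- cache$V
  n_heads <- cache$n_heads; dh <- cache$dh
  dconcat <- dout %*% t(Wo)
  dWo <- t(cache$concat) %*% dout
  dQ <- matrix(0, nrow(Q), ncol(Q))
  dK <- matrix(0, nrow(K), ncol(K))
  dV <- matrix(0, nrow(V), ncol(V))
  for (h in seq_len(n_heads)) {
    cols <- ((h - 1) * dh + 1):(h * dh)
    P <- cache$P[[h]]
    dOh <- dconcat[, cols, drop = FALSE]
    dP <- dOh %*% t(V[, cols, drop = FALSE])
    dV[, cols] <- t(P) %*% dOh
    dlogits <- P * (dP - rowSums(dP * P))
    dQ[, cols] <- dlogits %*% K[, cols, drop = FALSE] / sqrt(dh)
    dK[, cols] <- t(dlogits) %*% Q[, cols, drop = FALSE] / sqrt(dh)
  }
  list(dX = dQ %*% t(Wq) + dK %*% t(Wk) + dV %*% t(Wv),
       dWq = t(X) %*% dQ, dWk = t(X) %*% dK, dWv = t(X) %*% dV, dWo = dWo)
}
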
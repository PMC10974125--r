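# Batched encoder forward/backward: the whole mini-batch is carried as one
# (B*S) x d matrix (rows grouped by example) so linear, layer-norm and
# feedforward work are single BLAS calls; only the S x S attention runs in a
# per-example, per-head loop.

fast_softmax <- function(logits) {
  mx <- logits[cbind(seq_len(nrow(logits)), max.col(logits, ties.method = "first"))]
  e <- exp(logits - mx)
  e / rowSums(e)
}

transformer_forward <- function(params, X, mask, config, seq_len, out_len,
                                n_targets, pe, train = FALSE) {
  B <- dim(X)[1]; S <- dim(X)[2]
  keep <- 1 - config$dropout
  # (B*S) x features, rows grouped by example: row (b-1)*S + s
  Xflat <- matrix(aperm(X, c(2, 1, 3)), B * S, dim(X)[3])
  H <- if (is.null(params$Win)) Xflat else
    sweep(Xflat %*% params$Win, 2, params$bin, "+")
  d <- ncol(H)
  H <- H + pe[rep(seq_len(S), B), , drop = FALSE]
  mvec <- as.vector(t(mask))           # length B*S, example-major
  H[!mvec, ] <- 0
  all_valid <- all(mvec)
  caches <- vector("list", config$n_layers)
  for (l in seq_len(config$n_layers)) {
    Wq <- params[[paste0("Wq", l)]]; Wk <- params[[paste0("Wk", l)]]
    Wv <- params[[paste0("Wv", l)]]; Wo <- params[[paste0("Wo", l)]]
    Q <- H %*% Wq; K <- H %*% Wk; V <- H %*% Wv
    nh <- config$n_heads; dh <- d %/% nh
    concat <- matrix(0, B * S, d)
    P_list <- vector("list", B)
    for (b in seq_len(B)) {
      idx <- (b - 1L) * S + seq_len(S)
      mb <- if (all_valid) NULL else mask[b, ]
      Pb <- vector("list", nh)
      for (h in seq_len(nh)) {
        cols <- ((h - 1) * dh + 1):(h * dh)
        logits <- Q[idx, cols, drop = FALSE] %*%
          t(K[idx, cols, drop = FALSE]) / sqrt(dh)
        if (!is.null(mb)) {
          if (!any(mb)) stop("attention: all key positions masked", call. = FALSE)
          logits[, !mb] <- -Inf
        }
        P <- fast_softmax(logits)
        if (!is.null(mb)) P[!mb, ] <- 0  # padded query rows carry no signal
        Pb[[h]] <- P
        concat[idx, cols] <- P %*% V[idx, cols, drop = FALSE]
      }
      P_list[[b]] <- Pb
    }
    aout <- concat %*% Wo
    drop1 <- NULL
    if (train && config$dropout > 0) {
      drop1 <- matrix((runif(B * S * d) < keep) / keep, B * S, d)
      aout <- aout * drop1
    }
    ln1 <- nn_layernorm_fwd(H + aout, params[[paste0("ln1g", l)]],
                            params[[paste0("ln1b", l)]])
    lin1 <- nn_linear_fwd(ln1$out, params[[paste0("W1", l)]],
                          params[[paste0("b1", l)]])
    relu <- nn_relu_fwd(lin1$out)
    lin2 <- nn_linear_fwd(relu$out, params[[paste0("W2", l)]],
                          params[[paste0("b2", l)]])
    ffo <- lin2$out
    drop2 <- NULL
    if (train && config$dropout > 0) {
      drop2 <- matrix((runif(B * S * d) < keep) / keep, B * S, d)
      ffo <- ffo * drop2
    }
    ln2 <- nn_layernorm_fwd(ln1$out + ffo, params[[paste0("ln2g", l)]],
                            params[[paste0("ln2b", l)]])
    caches[[l]] <- list(H = H, Q = Q, K = K, V = V, P_list = P_list,
                        concat = concat, drop1 = drop1, ln1 = ln1,
                        lin1 = lin1, relu = relu, lin2 = lin2, drop2 = drop2,
                        ln2 = ln2)
    H <- ln2$out
  }
  # flatten each example's S x d block column-major into one row
  A <- array(t(H), c(d, S, B))
  flat <- t(matrix(aperm(A, c(2, 1, 3)), S * d, B))
  proj <- nn_linear_fwd(flat, params$Wout, params$bout)
  pred <- array(proj$out, c(B, out_len, n_targets))
  list(pred = pred, caches = caches, flat = flat, mvec = mvec,
       all_valid = all_valid, Xflat = Xflat)
}

transformer_backward <- function(params, fwd, dpred, X, mask, config) {
  B <- dim(X)[1]; S <- dim(X)[2]; d <- ncol(fwd$caches[[1]]$H)
  grads <- vector("list", length(params))
  names(grads) <- names(params)
  dflat <- matrix(dpred, B, length(dpred) / B)
  lb <- nn_linear_bwd(dflat, list(X = fwd$flat), params$Wout)
  grads$Wout <- lb$dW
  grads$bout <- lb$db
  # un-flatten: rows back to (B*S) x d
  A <- array(t(lb$dX), c(S, d, B))
  dH <- matrix(aperm(A, c(1, 3, 2)), B * S, d)
  nh <- config$n_heads; dh <- d %/% nh
  for (l in rev(seq_len(config$n_layers))) {
    cc <- fwd$caches[[l]]
    g2 <- nn_layernorm_bwd(dH, cc$ln2, params[[paste0("ln2g", l)]])
    grads[[paste0("ln2g", l)]] <- g2$dgamma
    grads[[paste0("ln2b", l)]] <- g2$dbeta
    dffo <- g2$dX
    if (!is.null(cc$drop2)) dffo <- dffo * cc$drop2
    l2 <- nn_linear_bwd(dffo, cc$lin2, params[[paste0("W2", l)]])
    grads[[paste0("W2", l)]] <- l2$dW
    grads[[paste0("b2", l)]] <- l2$db
    drelu <- nn_relu_bwd(l2$dX, cc$relu)
    l1 <- nn_linear_bwd(drelu, cc$lin1, params[[paste0("W1", l)]])
    grads[[paste0("W1", l)]] <- l1$dW
    grads[[paste0("b1", l)]] <- l1$db
    dln1_out <- g2$dX + l1$dX
    g1 <- nn_layernorm_bwd(dln1_out, cc$ln1, params[[paste0("ln1g", l)]])
    grads[[paste0("ln1g", l)]] <- g1$dgamma
    grads[[paste0("ln1b", l)]] <- g1$dbeta
    daout <- g1$dX
    if (!is.null(cc$drop1)) daout <- daout * cc$drop1
    Wq <- params[[paste0("Wq", l)]]; Wk <- params[[paste0("Wk", l)]]
    Wv <- params[[paste0("Wv", l)]]; Wo <- params[[paste0("Wo", l)]]
    dconcat <- daout %*% t(Wo)
    grads[[paste0("Wo", l)]] <- t(cc$concat) %*% daout
    dQ <- matrix(0, B * S, d); dK <- matrix(0, B * S, d)
    dV <- matrix(0, B * S, d)
    for (b in seq_len(B)) {
      idx <- (b - 1L) * S + seq_len(S)
      for (h in seq_len(nh)) {
        cols <- ((h - 1) * dh + 1):(h * dh)
        P <- cc$P_list[[b]][[h]]
        dOh <- dconcat[idx, cols, drop = FALSE]
        Vb <- cc$V[idx, cols, drop = FALSE]
        dP <- dOh %*% t(Vb)
        dV[idx, cols] <- t(P) %*% dOh
        dlogits <- P * (dP - rowSums(dP * P))
        dQ[idx, cols] <- dlogits %*% cc$K[idx, cols, drop = FALSE] / sqrt(dh)
        dK[idx, cols] <- t(dlogits) %*% cc$Q[idx, cols, drop = FALSE] / sqrt(dh)
      }
    }
    H <- cc$H
    grads[[paste0("Wq", l)]] <- t(H) %*% dQ
    grads[[paste0("Wk", l)]] <- t(H) %*% dK
    grads[[paste0("Wv", l)]] <- t(H) %*% dV
    dH <- g1$dX + dQ %*% t(Wq) + dK %*% t(Wk) + dV %*% t(Wv)
  }
  if (!is.null(params$Win)) {
    if (!fwd$all_valid) dH[!fwd$mvec, ] <- 0
    grads$Win <- t(fwd$Xflat) %*% dH
    grads$bin <- colSums(dH)
  }
  grads
}
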
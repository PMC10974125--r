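# Recurrent baselines: single-layer vanilla RNN (tanh) and single-layer
# LSTM, hidden width d_ff, followed by the same flatten-and-project output
# head as the transformer. Trained with the same loss, optimizer and seed
# protocol.

recurrent_init <- function(config, arch, seq_len, out_len, n_targets) {
  d <- config$n_features; h <- config$d_ff
  params <- list()
  if (arch == "rnn") {
    params$Wxh <- glorot(d, h)
    params$Whh <- glorot(h, h)
    params$bh <- rep(0, h)
  } else {
    gates <- c("i", "f", "g", "o")
    for (g in gates) {
      params[[paste0("Wx", g)]] <- glorot(d, h)
      params[[paste0("Wh", g)]] <- glorot(h, h)
      params[[paste0("b", g)]] <- if (g == "f") rep(1, h) else rep(0, h)
    }
  }
  params$Wout <- glorot(seq_len * h, out_len * n_targets)
  params$bout <- rep(0, out_len * n_targets)
  params
}

sigmoid <- function(x) 1 / (1 + exp(-x))

# X: [B, S, D]; returns pred [B, out, targets] plus caches for BPTT.
# Padded (mask FALSE) steps carry the previous state forward unchanged.
recurrent_forward <- function(params, X, mask, config, arch, out_len,
                              n_targets, train = FALSE) {
  B <- dim(X)[1]; S <- dim(X)[2]; hdim <- config$d_ff
  H <- matrix(0, B, hdim)
  C <- matrix(0, B, hdim)
  states <- vector("list", S)
  Hseq <- array(0, c(B, S, hdim))
  for (t in seq_len(S)) {
    Xt <- matrix(X[, t, ], B, dim(X)[3])
    mt <- mask[, t]
    if (arch == "rnn") {
      a <- Xt %*% params$Wxh + H %*% params$Whh +
        matrix(params$bh, B, hdim, byrow = TRUE)
      Hn <- tanh(a)
      Hn[!mt, ] <- H[!mt, ]
      states[[t]] <- list(Xt = Xt, Hprev = H, Hn = Hn, mt = mt)
      H <- Hn
    } else {
      ig <- sigmoid(Xt %*% params$Wxi + H %*% params$Whi +
                      matrix(params$bi, B, hdim, byrow = TRUE))
      fg <- sigmoid(Xt %*% params$Wxf + H %*% params$Whf +
                      matrix(params$bf, B, hdim, byrow = TRUE))
      gg <- tanh(Xt %*% params$Wxg + H %*% params$Whg +
                   matrix(params$bg, B, hdim, byrow = TRUE))
      og <- sigmoid(Xt %*% params$Wxo + H %*% params$Who +
                      matrix(params$bo, B, hdim, byrow = TRUE))
      Cn <- fg * C + ig * gg
      Hn <- og * tanh(Cn)
      Cn[!mt, ] <- C[!mt, ]
      Hn[!mt, ] <- H[!mt, ]
      states[[t]] <- list(Xt = Xt, Hprev = H, Cprev = C, ig = ig, fg = fg,
                          gg = gg, og = og, Cn = Cn, Hn = Hn, mt = mt)
      H <- Hn; C <- Cn
    }
    Hseq[, t, ] <- H
  }
  flat <- matrix(Hseq, B, S * hdim)
  proj <- nn_linear_fwd(flat, params$Wout, params$bout)
  list(pred = array(proj$out, c(B, out_len, n_targets)),
       states = states, flat = flat, Hseq = Hseq)
}

recurrent_backward <- function(params, fwd, dpred, X, mask, config, arch) {
  B <- dim(X)[1]; S <- dim(X)[2]; hdim <- config$d_ff
  grads <- lapply(params, function(p) p * 0)
  dflat <- matrix(dpred, B, length(dpred) / B)
  lb <- nn_linear_bwd(dflat, list(X = fwd$flat), params$Wout)
  grads$Wout <- lb$dW; grads$bout <- lb$db
  dHseq <- array(lb$dX, c(B, S, hdim))
  dHnext <- matrix(0, B, hdim)
  dCnext <- matrix(0, B, hdim)
  for (t in rev(seq_len(S))) {
    st <- fwd$states[[t]]
    dH <- matrix(dHseq[, t, ], B, hdim) + dHnext
    mt <- st$mt
    if (arch == "rnn") {
      da <- dH * (1 - st$Hn^2)
      da[!mt, ] <- 0
      grads$Wxh <- grads$Wxh + t(st$Xt) %*% da
      grads$Whh <- grads$Whh + t(st$Hprev) %*% da
      grads$bh <- grads$bh + colSums(da)
      dHnext <- da %*% t(params$Whh)
      dHnext[!mt, ] <- dHnext[!mt, ] + dH[!mt, ]
    } else {
      # masked rows pass state straight through: gradients flow by identity
      dHn <- dH; dHn[!mt, ] <- 0
      dC_keep <- dCnext
      dC <- dCnext; dC[!mt, ] <- 0
      tC <- tanh(st$Cn)
      dog <- dHn * tC
      dC <- dC + dHn * st$og * (1 - tC^2)
      dai <- (dC * st$gg) * st$ig * (1 - st$ig)
      daf <- (dC * st$Cprev) * st$fg * (1 - st$fg)
      dag <- (dC * st$ig) * (1 - st$gg^2)
      dao <- dog * st$og * (1 - st$og)
      dai[!mt, ] <- 0; daf[!mt, ] <- 0; dag[!mt, ] <- 0; dao[!mt, ] <- 0
      for (gl in list(list("i", dai), list("f", daf), list("g", dag),
                      list("o", dao))) {
        g <- gl[[1]]; da <- gl[[2]]
        grads[[paste0("Wx", g)]] <- grads[[paste0("Wx", g)]] + t(st$Xt) %*% da
        grads[[paste0("Wh", g)]] <- grads[[paste0("Wh", g)]] + t(st$Hprev) %*% da
        grads[[paste0("b", g)]] <- grads[[paste0("b", g)]] + colSums(da)
      }
      dHnext <- dai %*% t(params$Whi) + daf %*% t(params$Whf) +
        dag %*% t(params$Whg) + dao %*% t(params$Who)
      dHnext[!mt, ] <- dHnext[!mt, ] + dH[!mt, ]
      dCnext <- dC * st$fg
      dCnext[!mt, ] <- dC_keep[!mt, ]
    }
  }
  grads
}
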
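#' Empirical mode decomposition
#'
#' Classic sifting: at each step the upper and lower envelopes are cubic
#' splines through the local maxima/minima (endpoints clamped to the nearest
#' extremum), their mean is subtracted, and sifting stops on a Cauchy-style
#' standard-deviation criterion or after `max_sifts` passes. Extraction stops
#' when the residual has fewer than 2 interior extrema (monotone) or
#' `max_imfs` is reached. Sifting is exactly subtractive, so
#' `colSums(imfs) + residual` reconstructs the input to machine precision.
#'
#' @param signal numeric vector, length >= 8.
#' @param max_imfs maximum number of IMFs to extract.
#' @param sift_sd_threshold positive Cauchy criterion threshold
#'   (`sum((h_prev - h)^2) / sum(h_prev^2)` below this stops sifting).
#' @param max_sifts maximum sifting passes per IMF.
#' @return a `decomposition_result` with `method = "emd"` and
#'   `center_freqs_hz = NULL`. A signal with < 2 interior extrema yields zero
#'   IMFs and `residual = signal`.
#' @export
emd_decompose <- function(signal, max_imfs = 10L, sift_sd_threshold = 0.2,
                          max_sifts = 50L) {
  signal <- as.numeric(signal)
  if (length(signal) < 8L) stop("signal must have length >= 8", call. = FALSE)
  if (!all(is.finite(signal))) stop("signal contains NaN/Inf", call. = FALSE)
  if (sift_sd_threshold <= 0) stop("sift_sd_threshold must be positive", call. = FALSE)
  n <- length(signal)
  residual <- signal
  imfs <- list()
  for (k in seq_len(max_imfs)) {
    ext <- find_extrema(residual)
    if (length(ext$max_idx) + length(ext$min_idx) < 2L) break
    h <- residual
    sifted <- FALSE
    for (s in seq_len(max_sifts)) {
      env <- envelope_mean(h)
      if (is.null(env)) break  # too few extrema of one kind: stop sifting
      h_new <- h - env
      sd_crit <- sum((h - h_new)^2) / (sum(h^2) + .Machine$double.eps)
      h <- h_new
      sifted <- TRUE
      if (sd_crit < sift_sd_threshold) break
    }
    if (!sifted) break  # residual is effectively monotone: it stays residual
    imfs[[k]] <- h
    residual <- residual - h
  }
  imf_mat <- if (length(imfs)) do.call(rbind, imfs) else matrix(0, 0, n)
  new_decomposition_result(
    imfs = imf_mat, center_freqs_hz = NULL, residual = residual,
    n_iters = length(imfs), converged = TRUE, rel_recon_error = 0,
    method = "emd")
}

# interior local extrema (strict sign change of the first difference;
# flat runs take the run midpoint)
find_extrema <- function(x) {
  n <- length(x)
  d <- diff(x)
  # collapse exact ties so plateaus register one extremum
  nz <- which(d != 0)
  if (length(nz) < 2L) return(list(max_idx = integer(), min_idx = integer()))
  sgn <- sign(d[nz])
  turns <- which(diff(sgn) != 0)
  idx <- integer(length(turns)); kind <- integer(length(turns))
  for (i in seq_along(turns)) {
    a <- nz[turns[i]] + 1L         # start of the plateau/turn
    b <- nz[turns[i] + 1L]         # end of it
    idx[i] <- (a + b) %/% 2L
    kind[i] <- if (sgn[turns[i]] > 0) 1L else -1L
  }
  list(max_idx = idx[kind == 1L], min_idx = idx[kind == -1L])
}

# mean of the cubic-spline upper/lower envelopes, or NULL if too few
# extrema. Boundary knots are the first/last two extrema mirrored across the
# record ends, which suppresses end swings that would otherwise bleed slow
# trend energy into the IMFs.
envelope_mean <- function(x) {
  n <- length(x)
  ext <- find_extrema(x)
  if (length(ext$max_idx) < 2L || length(ext$min_idx) < 2L) return(NULL)
  mirror_knots <- function(idx, vals) {
    k <- length(idx)
    left_i <- 2 - idx[c(2, 1)]            # reflect first two about sample 1
    right_i <- 2 * n - idx[c(k, k - 1)]   # reflect last two about sample n
    xi <- c(left_i, idx, right_i)
    yi <- c(vals[c(2, 1)], vals, vals[c(k, k - 1)])
    keep <- !duplicated(xi)
    list(x = xi[keep], y = yi[keep])
  }
  up <- mirror_knots(ext$max_idx, x[ext$max_idx])
  lo <- mirror_knots(ext$min_idx, x[ext$min_idx])
  upper <- splinefun(up$x, up$y, method = "fmm")(seq_len(n))
  lower <- splinefun(lo$x, lo$y, method = "fmm")(seq_len(n))
  (upper + lower) / 2
}
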
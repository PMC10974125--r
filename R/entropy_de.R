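#' Envelope entropy
#'
#' Shannon-type entropy (base-10 logarithm) of the normalized Hilbert
#' envelope: with `a(j)` the envelope and `e_j = a(j) / sum(a)`, the entropy
#' is `-sum(e_j * log10(e_j))`, with `0 * log10(0)` taken as 0. Low values
#' indicate sparse, structured modes; the maximum `log10(N)` is reached by a
#' uniform envelope. Used as the fitness criterion when tuning VMD.
#'
#' @param signal finite numeric vector whose Hilbert envelope has positive sum.
#' @param envelope optional precomputed nonnegative envelope (skips the
#'   Hilbert transform; used by closed-form tests).
#' @return entropy in `[0, log10(N)]`.
#' @examples
#' envelope_entropy(envelope = rep(1, 100))  # log10(100) = 2
#' @export
envelope_entropy <- function(signal = NULL, envelope = NULL) {
  if (is.null(envelope)) {
    if (is.null(signal)) stop("provide `signal` or `envelope`", call. = FALSE)
    envelope <- hilbert_envelope(signal)
  }
  envelope <- as.numeric(envelope)
  if (any(envelope < 0)) stop("envelope must be nonnegative", call. = FALSE)
  tot <- sum(envelope)
  if (tot <= 0) stop("undefined entropy: envelope sums to zero", call. = FALSE)
  e <- envelope / tot
  e <- e[e > 0]
  -sum(e * log10(e))
}

#' Envelope-entropy fitness of a VMD parameter pair
#'
#' Decomposes the signal with the candidate `(K, alpha)` and aggregates the
#' per-IMF envelope entropies — by default the minimum ("most sparse single
#' mode" convention); `"mean"` is available as an alternative. A failed
#' decomposition returns the penalty `log10(N) + 1` instead of aborting the
#' search.
#'
#' @param signal numeric vector.
#' @param rate_hz sampling rate.
#' @param K integer mode count candidate.
#' @param alpha bandwidth penalty candidate.
#' @param vmd_defaults a [vmd_config()] supplying solver internals
#'   (`tau`, `tol`, `max_iter`, `init`); its `K`/`alpha` are overridden.
#' @param aggregation `"min"` or `"mean"` across per-IMF entropies.
#' @return nonnegative fitness value (lower is better).
#' @export
vmd_fitness <- function(signal, rate_hz, K, alpha,
                        vmd_defaults = vmd_config(),
                        aggregation = c("min", "mean")) {
  aggregation <- match.arg(aggregation)
  penalty <- log10(length(signal)) + 1
  cfg <- vmd_defaults
  cfg$K <- as.integer(round(K))
  cfg$alpha <- alpha
  ent <- tryCatch({
    dec <- vmd_decompose(signal, rate_hz, cfg)
    apply(dec$imfs, 1, function(u) {
      tryCatch(envelope_entropy(u), error = function(e) penalty)
    })
  }, error = function(e) penalty)
  if (!length(ent) || !all(is.finite(ent))) return(penalty)
  if (aggregation == "min") min(ent) else mean(ent)
}

#' Differential-evolution search configuration
#'
#' @param pop_size population size, >= 4 (DE/rand/1 needs three distinct
#'   partners besides the target).
#' @param F mutation factor in (0, 2].
#' @param CR crossover rate in `[0, 1]`.
#' @param generations number of generations.
#' @param K_bounds integer interval for the VMD mode count.
#' @param alpha_bounds positive interval for the bandwidth penalty.
#' @param patience stop early after this many generations without
#'   improvement of the best fitness (`Inf` disables).
#' @param seed RNG seed.
#' @return a `de_config` list.
#' @export
de_config <- function(pop_size = 15L, F = 0.5, CR = 0.9, generations = 30L,
                      K_bounds = c(2L, 8L), alpha_bounds = c(100, 10000),
                      patience = 8L, seed = 1L) {
  if (pop_size < 4L) stop("configuration error: pop_size must be >= 4", call. = FALSE)
  if (F <= 0 || F > 2) stop("F must be in (0, 2]", call. = FALSE)
  if (CR < 0 || CR > 1) stop("CR must be in [0, 1]", call. = FALSE)
  if (K_bounds[1] < 2L || K_bounds[2] < K_bounds[1]) {
    stop("K_bounds must satisfy 2 <= K_min <= K_max", call. = FALSE)
  }
  if (alpha_bounds[1] <= 0 || alpha_bounds[2] < alpha_bounds[1]) {
    stop("alpha_bounds must be positive and ordered", call. = FALSE)
  }
  structure(list(pop_size = as.integer(pop_size), F = F, CR = CR,
                 generations = as.integer(generations),
                 K_bounds = as.integer(K_bounds), alpha_bounds = alpha_bounds,
                 patience = patience, seed = as.integer(seed)),
            class = "de_config")
}

#' Bound-constrained DE/rand/1/bin minimizer
#'
#' Classic differential evolution: mutation `v = x_r1 + F * (x_r2 - x_r3)`,
#' binomial crossover at rate `CR` with one guaranteed crossover coordinate,
#' greedy selection. Dimensions flagged in `integer_dims` are rounded to the
#' nearest integer (and all dimensions clipped to bounds) before evaluation,
#' so every evaluated candidate is feasible.
#'
#' @param fn objective `function(x) -> scalar` to minimize.
#' @param lower,upper numeric bound vectors of equal length.
#' @param config a [de_config()] (`K_bounds`/`alpha_bounds` are ignored here;
#'   bounds come from `lower`/`upper`).
#' @param integer_dims indices of integer-valued dimensions.
#' @return list with `best_x`, `best_fitness`, and `trace` (a `fitness_trace`
#'   with non-increasing `best_fitness_per_generation` and the matching
#'   `best_params_per_generation`).
#' @export
de_minimize <- function(fn, lower, upper, config = de_config(),
                        integer_dims = integer()) {
  stopifnot(inherits(config, "de_config"), length(lower) == length(upper))
  d <- length(lower)
  np <- config$pop_size
  set.seed(config$seed)
  repair <- function(x) {
    x <- pmin(pmax(x, lower), upper)
    if (length(integer_dims)) x[integer_dims] <- round(x[integer_dims])
    x
  }
  pop <- t(replicate(np, repair(lower + runif(d) * (upper - lower))))
  fit <- apply(pop, 1, fn)
  best_hist <- numeric(0)
  param_hist <- list()
  stall <- 0L
  for (g in seq_len(config$generations)) {
    for (i in seq_len(np)) {
      partners <- sample(setdiff(seq_len(np), i), 3L)
      v <- pop[partners[1], ] + config$F * (pop[partners[2], ] - pop[partners[3], ])
      jrand <- sample.int(d, 1L)
      cross <- runif(d) < config$CR
      cross[jrand] <- TRUE
      u <- ifelse(cross, v, pop[i, ])
      u <- repair(u)
      fu <- fn(u)
      if (fu <= fit[i]) {
        pop[i, ] <- u
        fit[i] <- fu
      }
    }
    b <- which.min(fit)
    best_now <- fit[b]
    if (length(best_hist) && best_now >= tail(best_hist, 1) - 1e-15) {
      stall <- stall + 1L
      best_now <- min(best_now, tail(best_hist, 1))
    } else stall <- 0L
    best_hist <- c(best_hist, best_now)
    param_hist[[g]] <- pop[b, ]
    if (is.finite(config$patience) && stall >= config$patience) break
  }
  b <- which.min(fit)
  list(best_x = pop[b, ], best_fitness = fit[b],
       trace = structure(list(best_fitness_per_generation = best_hist,
                              best_params_per_generation = param_hist),
                         class = "fitness_trace"))
}

#' DE tuning of VMD parameters by envelope-entropy minimization
#'
#' Runs [de_minimize()] over `(K, alpha)` within the configured bounds, with
#' the envelope-entropy fitness of [vmd_fitness()]. `K` is handled by
#' rounding to the nearest integer after mutation. Fitness evaluations are
#' cached keyed on `(K, alpha rounded at 1e-3 relative)` since DE revisits
#' near-duplicates.
#'
#' @param signal numeric vector to tune on.
#' @param rate_hz sampling rate.
#' @param config a [de_config()].
#' @param vmd_defaults a [vmd_config()] of solver internals for fitness
#'   evaluations.
#' @param aggregation per-IMF entropy aggregation, `"min"` (default) or
#'   `"mean"`.
#' @return list with `chosen_K`, `chosen_alpha`, `trace` (fitness trace) and
#'   `best_fitness`.
#' @export
de_optimize <- function(signal, rate_hz, config = de_config(),
                        vmd_defaults = vmd_config(),
                        aggregation = c("min", "mean")) {
  aggregation <- match.arg(aggregation)
  cache <- new.env(parent = emptyenv())
  fn <- function(x) {
    K <- as.integer(round(x[1]))
    alpha <- x[2]
    key <- paste(K, signif(alpha, 4), sep = "_")
    hit <- get0(key, envir = cache)
    if (!is.null(hit)) return(hit)
    val <- vmd_fitness(signal, rate_hz, K, alpha, vmd_defaults, aggregation)
    assign(key, val, envir = cache)
    val
  }
  res <- de_minimize(fn,
                     lower = c(config$K_bounds[1], config$alpha_bounds[1]),
                     upper = c(config$K_bounds[2], config$alpha_bounds[2]),
                     config = config, integer_dims = 1L)
  list(chosen_K = as.integer(round(res$best_x[1])),
       chosen_alpha = res$best_x[2],
       trace = res$trace, best_fitness = res$best_fitness)
}

#' @export
print.fitness_trace <- function(x, ...) {
  n <- length(x$best_fitness_per_generation)
  cat(sprintf("<fitness_trace> %d generation(s), best %.6f -> %.6f\n",
              n, x$best_fitness_per_generation[1],
              x$best_fitness_per_generation[n]))
  invisible(x)
}

#' @export
as_tibble.fitness_trace <- function(x, ...) {
  tibble::tibble(
    generation = seq_along(x$best_fitness_per_generation),
    best_fitness = x$best_fitness_per_generation,
    K = vapply(x$best_params_per_generation, function(p) round(p[1]), numeric(1)),
    alpha = vapply(x$best_params_per_generation, function(p) p[2], numeric(1))
  )
}

#' Plot a DE fitness trace
#'
#' @param object a `fitness_trace`.
#' @param ... unused.
#' @return a ggplot object of best fitness per generation.
#' @export
autoplot.fitness_trace <- function(object, ...) {
  ggplot2::ggplot(as_tibble(object),
                  ggplot2::aes(x = .data$generation, y = .data$best_fitness)) +
    ggplot2::geom_step() +
    ggplot2::labs(x = "generation", y = "best envelope entropy")
}
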
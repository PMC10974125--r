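#' Default pipeline configuration
#'
#' Nested defaults for every stage: synthetic generation, VMD solver,
#' differential-evolution search, preprocessing, windowing and the estimator.
#' `load_config()` fills absent keys from these defaults and rejects unknown
#' keys with their dotted path; resolution is idempotent.
#'
#' @return nested named list of defaults.
#' @export
default_config <- function() {
  list(
    synthetic = list(
      exercise = "bicep_curl",
      n_trials = 5L,
      duration_s = 60,
      rate_hz = 1000,
      motion_freq_hz = c(0.3, 0.7),
      mmg_band_hz = c(10, 50),
      semg_band_hz = c(20, 450),
      pseudo_accel_cutoff_hz = 5,
      snr_db = 15,
      activation_delay_ms = 50,
      seed = 1L
    ),
    vmd = list(
      K = 3L, alpha = 2000, tau = 0, tol = 1e-7, max_iter = 500L,
      init = "uniform", dc_mode = FALSE
    ),
    de = list(
      pop_size = 15L, F = 0.5, CR = 0.9, generations = 30L,
      K_min = 2L, K_max = 8L, alpha_min = 100, alpha_max = 10000,
      patience = 8L, seed = 1L
    ),
    extract = list(
      mmg_band_hz = c(10, 50),
      tune_seconds = 8,
      fitness_max_iter = 200L,
      fitness_aggregation = "min"
    ),
    preprocess = list(
      band_low_hz = 10, band_high_hz = 450, filter_order = 4L,
      envelope_cutoff_hz = 5, normalization = "minmax_01"
    ),
    windowing = list(
      window_ms = 1000, step_ms = 200, seq_len = 20L, out_len = 20L,
      latency_budget_ms = 300, test_fraction = 0.2, split_scheme = "by_block"
    ),
    model = list(
      type = "transformer",
      n_features = 8L, n_heads = 2L, n_layers = 1L, d_ff = 64L,
      dropout = 0.1, lr = 1e-3, batch_size = 64L, epochs = 50L, seed = 1L
    )
  )
}

#' Load and resolve a configuration file
#'
#' Reads a YAML or JSON mapping, overlays it on [default_config()], and
#' validates it: unknown keys are rejected (reported with their dotted path,
#' e.g. `model.n_headz`) and values must match the type of the default they
#' replace.
#'
#' @param path file to read, or `NULL` for pure defaults.
#' @return the fully resolved configuration list.
#' @export
load_config <- function(path = NULL) {
  user <- list()
  if (!is.null(path)) {
    if (!file.exists(path)) stop("config file does not exist: ", path, call. = FALSE)
    user <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
      jsonlite::read_json(path, simplifyVector = TRUE)
    } else {
      yaml::read_yaml(path)
    }
    if (is.null(user)) user <- list()
    if (!is.list(user)) stop("config file must contain a mapping", call. = FALSE)
  }
  resolve_config(user)
}

#' @rdname load_config
#' @param overrides nested list of overrides (same shape as the defaults).
#' @export
resolve_config <- function(overrides = list()) {
  merge_checked(default_config(), overrides, path = character())
}

merge_checked <- function(defaults, overrides, path) {
  if (!length(overrides)) return(defaults)
  if (is.null(names(overrides)) || any(!nzchar(names(overrides)))) {
    stop("configuration error: unnamed entry under '",
         paste(path, collapse = "."), "'", call. = FALSE)
  }
  for (key in names(overrides)) {
    here <- paste(c(path, key), collapse = ".")
    if (!key %in% names(defaults)) {
      stop("configuration error: unknown key '", here, "'", call. = FALSE)
    }
    dval <- defaults[[key]]
    oval <- overrides[[key]]
    if (is.list(dval)) {
      if (!is.list(oval)) {
        stop("configuration error: '", here, "' must be a mapping", call. = FALSE)
      }
      defaults[[key]] <- merge_checked(dval, oval, c(path, key))
    } else {
      if (is.numeric(dval) && !is.numeric(oval)) {
        stop("configuration error: '", here, "' must be numeric", call. = FALSE)
      }
      if (is.character(dval) && !is.character(oval)) {
        stop("configuration error: '", here, "' must be a string", call. = FALSE)
      }
      if (is.logical(dval) && !is.logical(oval)) {
        stop("configuration error: '", here, "' must be logical", call. = FALSE)
      }
      if (is.integer(dval) && is.numeric(oval)) oval <- as.integer(round(oval))
      defaults[[key]] <- oval
    }
  }
  defaults
}
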
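#' Read a signal trace from disk
#'
#' Two on-disk forms are supported. `csv`: a `# rate_hz=<float>` comment line
#' (optionally followed by `# units=...`), then a header row of channel names,
#' then one numeric column per channel, one row per sample. `bundle`: an RDS
#' container holding the arrays `samples`, `rate_hz`, `channel_names` and
#' `units` at full floating precision.
#'
#' @param path file to read.
#' @param format `"csv"` or `"bundle"`; default guessed from the extension.
#' @param rate_hz sampling rate override for CSV files lacking the sidecar
#'   comment; ignored for bundles.
#' @return a validated [signal_trace()]; sample order preserved.
#' @export
read_trace <- function(path, format = c("auto", "csv", "bundle"), rate_hz = NULL) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "csv" else "bundle"
  }
  if (!file.exists(path)) stop("file does not exist: ", path, call. = FALSE)
  if (format == "bundle") {
    b <- readRDS(path)
    needed <- c("samples", "rate_hz", "channel_names", "units")
    if (!all(needed %in% names(b))) {
      stop("malformed bundle: missing ", paste(setdiff(needed, names(b)), collapse = ", "),
           call. = FALSE)
    }
    return(signal_trace(b$samples, b$rate_hz, b$channel_names, b$units))
  }
  lines <- readLines(path)
  units <- "a.u."
  while (length(lines) && startsWith(lines[1], "#")) {
    m <- regmatches(lines[1], regexec("^#\\s*rate_hz\\s*=\\s*([0-9.eE+-]+)", lines[1]))[[1]]
    if (length(m) == 2) rate_hz <- as.numeric(m[2])
    mu <- regmatches(lines[1], regexec("^#\\s*units\\s*=\\s*(.*)$", lines[1]))[[1]]
    if (length(mu) == 2) units <- strsplit(trimws(mu[2]), ",")[[1]]
    lines <- lines[-1]
  }
  if (is.null(rate_hz)) {
    stop("sampling rate missing: no '# rate_hz=' comment and no `rate_hz` argument",
         call. = FALSE)
  }
  if (!length(lines)) stop("malformed CSV: no header row", call. = FALSE)
  header <- strsplit(lines[1], ",", fixed = TRUE)[[1]]
  body <- lines[-1]
  body <- body[nzchar(body)]
  if (!length(body)) stop("malformed CSV: no data rows", call. = FALSE)
  cells <- strsplit(body, ",", fixed = TRUE)
  lens <- lengths(cells)
  bad <- which(lens != length(header))
  if (length(bad)) {
    stop(sprintf("malformed CSV: row %d has %d value(s), expected %d",
                 bad[1], lens[bad[1]], length(header)), call. = FALSE)
  }
  vals <- suppressWarnings(as.numeric(unlist(cells)))
  if (anyNA(vals)) {
    bad_row <- ceiling(which(is.na(vals))[1] / length(header))
    stop(sprintf("parse error: non-numeric cell in data row %d", bad_row), call. = FALSE)
  }
  samples <- matrix(vals, nrow = length(header))  # rows filled per CSV row -> channels x samples
  signal_trace(samples, rate_hz, trimws(header), units)
}

#' Write a signal trace to disk
#'
#' CSV files use '.' as decimal separator, ',' as delimiter and LF line ends,
#' with the sampling rate carried in a `# rate_hz=` comment; values are
#' serialized with 17 significant digits (round-trip within 1e-12 relative).
#' Bundles preserve full binary precision (bit-exact round trip).
#'
#' @param trace a [signal_trace()].
#' @param path destination; parent directory must exist.
#' @param format `"csv"` or `"bundle"`; default guessed from the extension.
#' @return `path`, invisibly.
#' @export
write_trace <- function(trace, path, format = c("auto", "csv", "bundle")) {
  stopifnot(inherits(trace, "signal_trace"))
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "csv" else "bundle"
  }
  if (!dir.exists(dirname(path))) {
    stop("parent directory does not exist: ", dirname(path), call. = FALSE)
  }
  if (format == "bundle") {
    saveRDS(list(samples = trace$samples, rate_hz = trace$rate_hz,
                 channel_names = trace$channel_names, units = trace$units),
            path)
    return(invisible(path))
  }
  con <- file(path, open = "wb")
  on.exit(close(con))
  hdr <- c(sprintf("# rate_hz=%s", format(trace$rate_hz, digits = 17)),
           sprintf("# units=%s", paste(trace$units, collapse = ",")),
           paste(trace$channel_names, collapse = ","))
  body <- apply(trace$samples, 2, function(col) {
    paste(sprintf("%.17g", col), collapse = ",")
  })
  writeLines(c(hdr, body), con, sep = "\n")
  invisible(path)
}

#' Write/read a generic named-array bundle
#'
#' Small helpers used for decomposition results, datasets and checkpoints:
#' an RDS container of named arrays, bit-exact on round trip.
#'
#' @param x named list of arrays/values.
#' @param path destination file.
#' @return `read_bundle()` returns the named list; `write_bundle()` the path,
#'   invisibly.
#' @export
write_bundle <- function(x, path) {
  stopifnot(is.list(x), !is.null(names(x)))
  if (!dir.exists(dirname(path))) {
    stop("parent directory does not exist: ", dirname(path), call. = FALSE)
  }
  saveRDS(x, path)
  invisible(path)
}

#' @rdname write_bundle
#' @export
read_bundle <- function(path) {
  if (!file.exists(path)) stop("file does not exist: ", path, call. = FALSE)
  readRDS(path)
}
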
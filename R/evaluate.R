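#' Coefficient of determination
#'
#' `R^2 = 1 - sum((y - yhat)^2) / sum((y - mean(y))^2)`. At most 1, unbounded
#' below; undefined (error) for constant `y_true`.
#'
#' @param y_true observed values (non-constant).
#' @param y_pred predicted values, same length.
#' @return a single numeric R-squared.
#' @examples
#' r2_score(c(1, 2, 3), c(1, 2, 2))  # 0.5
#' @export
r2_score <- function(y_true, y_pred) {
  y_true <- as.numeric(y_true); y_pred <- as.numeric(y_pred)
  stopifnot(length(y_true) == length(y_pred))
  ss_tot <- sum((y_true - mean(y_true))^2)
  if (ss_tot == 0) stop("R-squared undefined for constant y_true", call. = FALSE)
  1 - sum((y_true - y_pred)^2) / ss_tot
}

#' Evaluate an estimator across trials
#'
#' Per trial, R-squared is computed on the concatenated flattened
#' target/prediction sequences (all output positions and target channels
#' pooled); the report then gives the highest, lowest and mean across
#' trials — the standard reporting convention for this task. A per-axis
#' breakdown is included for diagnostics.
#'
#' @param model an `mmg_estimator`.
#' @param trials list of `supervised_dataset`s, one per trial (>= 1). Empty
#'   trials are skipped with a warning; all-empty is an error.
#' @param signal_mode `"fusion"` or `"mmg_only"`, recorded in the report.
#' @return an `eval_report`: `r2_per_trial`, `highest`, `lowest`, `mean`,
#'   `model_name`, `signal_mode`, and `r2_per_axis` (trials x targets).
#' @export
evaluate <- function(model, trials, signal_mode = c("fusion", "mmg_only")) {
  signal_mode <- match.arg(signal_mode)
  if (inherits(trials, "supervised_dataset")) trials <- list(trials)
  if (!length(trials)) stop("need at least one trial", call. = FALSE)
  keep <- vapply(trials, function(t) n_examples(t) > 0L, logical(1))
  if (!all(keep)) warning("skipping ", sum(!keep), " empty trial(s)")
  trials <- trials[keep]
  if (!length(trials)) stop("all trials empty", call. = FALSE)
  r2 <- numeric(length(trials))
  r2_axis <- matrix(NA_real_, length(trials), model$n_targets)
  for (i in seq_along(trials)) {
    pred <- predict(model, trials[[i]])
    r2[i] <- r2_score(as.numeric(trials[[i]]$y), as.numeric(pred))
    for (k in seq_len(model$n_targets)) {
      r2_axis[i, k] <- r2_score(as.numeric(trials[[i]]$y[, , k]),
                                as.numeric(pred[, , k]))
    }
  }
  structure(list(r2_per_trial = r2, highest = max(r2), lowest = min(r2),
                 mean = mean(r2), model_name = model$arch,
                 signal_mode = signal_mode, r2_per_axis = r2_axis),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("<eval_report> %s (%s), %d trial(s)\n",
              x$model_name, x$signal_mode, length(x$r2_per_trial)))
  cat(sprintf("  R^2 highest %.3f | lowest %.3f | mean %.3f\n",
              x$highest, x$lowest, x$mean))
  invisible(x)
}

#' @export
tidy.eval_report <- function(x, ...) {
  tibble::tibble(
    trial = seq_along(x$r2_per_trial),
    r2 = x$r2_per_trial,
    model = x$model_name,
    signal_mode = x$signal_mode
  )
}

#' @export
glance.eval_report <- function(x, ...) {
  tibble::tibble(
    model = x$model_name,
    signal_mode = x$signal_mode,
    n_trials = length(x$r2_per_trial),
    highest = x$highest,
    lowest = x$lowest,
    mean = x$mean
  )
}

#' Plot per-trial R-squared
#'
#' @param object an `eval_report`.
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.eval_report <- function(object, ...) {
  ggplot2::ggplot(tidy(object), ggplot2::aes(x = .data$trial, y = .data$r2)) +
    ggplot2::geom_point() +
    ggplot2::geom_hline(yintercept = object$mean, linetype = 2) +
    ggplot2::labs(x = "trial", y = expression(R^2),
                  title = sprintf("%s (%s)", object$model_name, object$signal_mode))
}

#' Serialize an evaluation report to JSON
#'
#' @param report an `eval_report`.
#' @param path destination file.
#' @return the path, invisibly.
#' @export
write_eval_report <- function(report, path) {
  stopifnot(inherits(report, "eval_report"))
  jsonlite::write_json(
    list(model = report$model_name, signal_mode = report$signal_mode,
         highest = report$highest, lowest = report$lowest, mean = report$mean,
         r2_per_trial = report$r2_per_trial),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
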
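#' @title Cross-validation results
#' @description Container returned by [loo()] and [leave_d_out()] methods.
#'   `errors` are predicted minus observed; `pmse` is the mean of squared
#'   errors (for replicated layouts, pooled over all scored cases, with the
#'   per-replicate breakdown in `per_replicate`).
#' @name cv_result
NULL

new_cv_result <- function(predictions, observed, method,
                          layout = NULL, per_replicate = NULL,
                          extra = list()) {
  errors <- predictions - observed
  res <- c(list(
    predictions = predictions,
    observed = observed,
    errors = errors,
    pmse = mean(errors^2),
    pred_corr = if (length(predictions) > 2L &&
                    stats::sd(predictions) > 0 && stats::sd(observed) > 0)
      stats::cor(predictions, observed) else NA_real_,
    method = method,
    layout = layout,
    per_replicate = per_replicate
  ), extra)
  class(res) <- "cv_result"
  res
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("Cross-validation result (%s): %d held-out predictions\n",
              x$method, length(x$predictions)))
  cat(sprintf("  PMSE = %.6g   predictive correlation = %.4f\n",
              x$pmse, x$pred_corr))
  if (!is.null(x$per_replicate))
    cat(sprintf("  %d replicates, median PMSE = %.6g\n",
                nrow(x$per_replicate), stats::median(x$per_replicate$pmse)))
  invisible(x)
}

#' @export
summary.cv_result <- function(object, ...) {
  out <- list(pmse = object$pmse, pred_corr = object$pred_corr,
              n_cases = length(object$predictions), method = object$method)
  if (!is.null(object$per_replicate))
    out$pmse_quantiles <- stats::quantile(object$per_replicate$pmse,
                                          c(0.05, 0.25, 0.5, 0.75, 0.95))
  class(out) <- "summary.cv_result"
  out
}

#' @export
print.summary.cv_result <- function(x, ...) {
  cat(sprintf("%s cross-validation over %d cases: PMSE %.6g, r %.4f\n",
              x$method, x$n_cases, x$pmse, x$pred_corr))
  if (!is.null(x$pmse_quantiles)) {
    cat("Per-replicate PMSE quantiles:\n")
    print(round(x$pmse_quantiles, 4))
  }
  invisible(x)
}

#' Leave-one-out cross-validation from a single fit
#'
#' Computes every held-out prediction in closed form from the full-data fit
#' using hat/smoother downdate identities; no model is ever refitted.
#' @param object a fitted model (`ols_fit`, `ridge_fit`, `kernel_fit`,
#'   `bikernel_fit`).
#' @param ... method-specific arguments.
#' @return a [cv_result] object.
#' @export
loo <- function(object, ...) UseMethod("loo")

#' Leave-d-out cross-validation from a single fit
#'
#' Exact held-out predictions for one test set or a replicated layout of test
#' sets, all from the single full-data fit.
#' @param object a fitted model.
#' @param test_sets integer vector of held-out row indices, or a list of such
#'   vectors (e.g. from [make_cv_layouts()]).
#' @param ... method-specific arguments.
#' @return a [cv_result] object; with a list layout, `per_replicate` holds a
#'   data.frame of (replicate, d, pmse).
#' @export
leave_d_out <- function(object, test_sets, ...) UseMethod("leave_d_out")

# Shared driver: applies a single-set engine over a layout.
run_layout <- function(test_sets, engine, observed_of, method) {
  if (!is.list(test_sets)) test_sets <- list(test_sets)
  preds <- obs <- numeric(0)
  per <- data.frame(replicate = integer(0), d = integer(0), pmse = numeric(0))
  flagged <- FALSE
  for (r in seq_along(test_sets)) {
    idx <- as.integer(test_sets[[r]])
    if (length(idx) == 0L) stop("empty test set in layout (replicate ", r, ")")
    one <- engine(idx)
    if (isTRUE(one$flag)) flagged <- TRUE
    preds <- c(preds, one$pred)
    o <- observed_of(idx)
    obs <- c(obs, o)
    per <- rbind(per, data.frame(replicate = r, d = length(idx),
                                 pmse = mean((one$pred - o)^2)))
  }
  new_cv_result(preds, obs, method,
                layout = test_sets,
                per_replicate = if (length(test_sets) > 1L) per else NULL,
                extra = list(rank_deficient = flagged))
}
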
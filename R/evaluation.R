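#' Evaluate predicted AGB against measured AGB
#'
#' The three headline accuracy metrics for biomass inversion:
#' * `mae  = sum(|Y_i - y_i|) / n` (g/m2),
#' * `rmse = sqrt(sum((Y_i - y_i)^2) / n)` (g/m2),
#' * `r2   = 1 - sum((Y_i - y_i)^2) / sum((Y_i - ybar)^2)`,
#'
#' with `Y_i` measured, `y_i` predicted. By default `ybar` is the mean of
#' the measured values (the standard coefficient of determination, which
#' can be negative on a holdout set); `r2_variant = "predicted-mean"`
#' instead centres on the mean of the predictions. The squared Pearson
#' correlation of the pair (`r2_fit`, always in [0, 1]) is reported
#' alongside as the fitted-line diagnostic.
#'
#' @param measured,predicted numeric vectors (g/m2), equal length, n >= 1.
#' @param model_id label carried into reports (default `"model"`).
#' @param r2_variant `"measured-mean"` (default) or `"predicted-mean"`.
#' @return object of class `agb_evaluation`: list with `model_id`, `n`,
#'   `mae`, `rmse`, `r2`, `r2_fit`, `r2_variant` and a fingerprint of the
#'   measured vector (guards model comparisons).
#' @export
evaluate <- function(measured, predicted, model_id = "model",
                     r2_variant = c("measured-mean", "predicted-mean")) {
  r2_variant <- match.arg(r2_variant)
  if (length(measured) != length(predicted))
    stop("measured and predicted lengths differ (", length(measured),
         " vs ", length(predicted), ")")
  n <- length(measured)
  if (n == 0L) stop("no validation pairs")
  if (!all(is.finite(measured)) || !all(is.finite(predicted)))
    stop("measured and predicted must be finite")
  err <- measured - predicted
  mae <- sum(abs(err)) / n
  rmse <- sqrt(sum(err^2) / n)
  center <- if (r2_variant == "measured-mean") mean(measured)
            else mean(predicted)
  ss_tot <- sum((measured - center)^2)
  r2 <- if (ss_tot == 0) NA_real_ else 1 - sum(err^2) / ss_tot
  r2_fit <- if (n >= 2 && stats::sd(measured) > 0 &&
                stats::sd(predicted) > 0)
    stats::cor(measured, predicted)^2 else NA_real_
  structure(list(model_id = model_id, n = n, mae = mae, rmse = rmse,
                 r2 = r2, r2_fit = r2_fit, r2_variant = r2_variant,
                 measured_fingerprint = object_hash(round(measured, 6))),
            class = "agb_evaluation")
}

#' @export
print.agb_evaluation <- function(x, ...) {
  cat(sprintf(
    "<agb_evaluation> %s: n = %d, MAE = %.2f, RMSE = %.2f g/m2\n",
    x$model_id, x$n, x$mae, x$rmse))
  cat(sprintf("  R2 = %s (%s), r2_fit = %s\n",
              formatC(x$r2, digits = 3, format = "f"), x$r2_variant,
              formatC(x$r2_fit, digits = 3, format = "f")))
  invisible(x)
}

#' Compare evaluation reports against a baseline model
#'
#' Assembles per-model metrics plus paired differences against the baseline
#' (candidate minus baseline), ranked by RMSE ascending. All reports must
#' come from the same validation set (checked by n and a fingerprint of the
#' measured values).
#'
#' @param reports list of `agb_evaluation` objects.
#' @param baseline `model_id` of the baseline report.
#' @return data.frame with columns `model_id, n, mae, rmse, r2, r2_fit,
#'   d_mae, d_rmse, d_r2, rank`.
#' @export
compare_models <- function(reports, baseline) {
  stopifnot(length(reports) >= 1,
            all(vapply(reports, inherits, TRUE, "agb_evaluation")))
  ids <- vapply(reports, `[[`, "", "model_id")
  if (!baseline %in% ids) stop("baseline '", baseline, "' not among reports")
  fps <- vapply(reports, `[[`, "", "measured_fingerprint")
  ns <- vapply(reports, `[[`, 1L, "n")
  if (length(unique(fps)) != 1L || length(unique(ns)) != 1L)
    stop("reports come from different validation sets")
  base <- reports[[match(baseline, ids)]]
  out <- data.frame(
    model_id = ids,
    n = ns,
    mae = vapply(reports, `[[`, 1, "mae"),
    rmse = vapply(reports, `[[`, 1, "rmse"),
    r2 = vapply(reports, `[[`, 1, "r2"),
    r2_fit = vapply(reports, `[[`, 1, "r2_fit"))
  out$d_mae <- out$mae - base$mae
  out$d_rmse <- out$rmse - base$rmse
  out$d_r2 <- out$r2 - base$r2
  out <- out[order(out$rmse), ]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}
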
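#' Fit a univariate AGB inversion model
#'
#' Fits one of the three single-predictor families relating an index value
#' `x` to measured AGB `y` (g/m2):
#' * linear: `y = b1 x + b0` (ordinary least squares),
#' * quadratic: `y = b2 x^2 + b1 x + b0` (OLS),
#' * exponential: `y = a exp(b x)`, fit by OLS of `log(y)` on `x` with
#'   `a = exp(intercept)` (optionally refined by nonlinear least squares
#'   when \pkg{minpack.lm} is available).
#'
#' The modeling R2 is the coefficient of determination
#' `1 - SSres / SStot` computed on the fitting rows, always on the original
#' AGB scale so families are comparable; a constant-`y` fit reports 0.
#'
#' @param table feature table with `agb` and index columns; when a `role`
#'   column carries assignments, only `"modeling"` rows are fit.
#' @param index_name predictor column name.
#' @param family `"linear"`, `"quadratic"` or `"exponential"`.
#' @param refine logical; refine the exponential fit by
#'   `minpack.lm::nlsLM()` starting from the log-linear estimate.
#' @return object of class `c("agb_univariate", "agb_model")` with
#'   `coefficients`, `modeling_r2`, `n_fit`, `fitted`, `residuals`, `data`.
#' @seealso [predict.agb_univariate()], [fit_validation_line()]
#' @export
fit_univariate <- function(table, index_name,
                           family = c("linear", "quadratic", "exponential"),
                           refine = FALSE) {
  family <- match.arg(family)
  if (!index_name %in% names(table))
    stop("index '", index_name, "' not in the feature table")
  use <- table
  if ("role" %in% names(table) && any(table$role %in% "modeling"))
    use <- table[table$role %in% "modeling", , drop = FALSE]
  x <- use[[index_name]]; y <- use$agb
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]; y <- y[keep]
  p <- switch(family, linear = 2L, quadratic = 3L, exponential = 2L)
  if (length(x) < p + 1L)
    stop("need at least ", p + 1L, " complete rows for a ", family, " fit")
  if (stats::sd(x) == 0) stop("singular design: '", index_name,
                              "' is constant on the fitting rows")
  route <- NULL
  if (family == "linear") {
    fit <- stats::lm(y ~ x)
    cf <- c(b1 = unname(stats::coef(fit)[2]),
            b0 = unname(stats::coef(fit)[1]))
    yhat <- unname(stats::fitted(fit))
  } else if (family == "quadratic") {
    fit <- stats::lm(y ~ x + I(x^2))
    if (anyNA(stats::coef(fit))) stop("singular design for quadratic fit")
    cf <- c(b2 = unname(stats::coef(fit)[3]),
            b1 = unname(stats::coef(fit)[2]),
            b0 = unname(stats::coef(fit)[1]))
    yhat <- unname(stats::fitted(fit))
  } else {
    if (any(y <= 0))
      stop("exponential family requires all AGB values > 0")
    fit <- stats::lm(log(y) ~ x)
    cf <- c(a = exp(unname(stats::coef(fit)[1])),
            b = unname(stats::coef(fit)[2]))
    route <- "log-linear OLS"
    if (refine) {
      if (!requireNamespace("minpack.lm", quietly = TRUE))
        stop("refine = TRUE needs the minpack.lm package")
      nl <- minpack.lm::nlsLM(y ~ a * exp(b * x),
                              start = list(a = cf[["a"]], b = cf[["b"]]))
      cf <- c(a = unname(stats::coef(nl)[["a"]]),
              b = unname(stats::coef(nl)[["b"]]))
      route <- "log-linear OLS + nlsLM refinement"
    }
    yhat <- cf[["a"]] * exp(cf[["b"]] * x)
  }
  ss_res <- sum((y - yhat)^2)
  ss_tot <- sum((y - mean(y))^2)
  r2 <- if (ss_tot == 0) 0 else 1 - ss_res / ss_tot
  structure(list(family = family, index_name = index_name,
                 coefficients = cf, modeling_r2 = r2, n_fit = length(x),
                 fitted = yhat, residuals = y - yhat,
                 data = data.frame(x = x, y = y), route = route,
                 call = match.call()),
            class = c("agb_univariate", "agb_model"))
}

eval_family <- function(family, cf, x) {
  switch(family,
    linear      = cf[["b1"]] * x + cf[["b0"]],
    quadratic   = cf[["b2"]] * x^2 + cf[["b1"]] * x + cf[["b0"]],
    exponential = cf[["a"]] * exp(cf[["b"]] * x))
}

#' Predict AGB from a univariate model
#'
#' @param object an `agb_univariate` model.
#' @param newdata numeric vector of index values, a data.frame containing
#'   the model's index column, or a single-band `agb_raster` of the index
#'   (missing pixels propagate).
#' @param ... unused.
#' @return predictions in g/m2, same shape as the input.
#' @export
predict.agb_univariate <- function(object, newdata, ...) {
  if (missing(newdata)) return(object$fitted)
  if (inherits(newdata, "agb_raster")) {
    v <- eval_family(object$family, object$coefficients, band(newdata))
    out <- newdata
    out$values <- array(v, dim(newdata$values))
    return(out)
  }
  x <- if (is.data.frame(newdata)) {
    if (!object$index_name %in% names(newdata))
      stop("newdata lacks column '", object$index_name, "'")
    newdata[[object$index_name]]
  } else as.numeric(newdata)
  eval_family(object$family, object$coefficients, x)
}

#' Fit the validation line (measured on predicted)
#'
#' Ordinary least squares of measured AGB on predicted AGB over the
#' validation pairs, reported as `measured = slope * predicted + intercept`
#' with the squared Pearson correlation of the pair. A perfect model gives
#' slope 1, intercept 0.
#'
#' @param predicted,measured numeric vectors (g/m2), equal length >= 3.
#' @return list with `slope`, `intercept`, `r2_fit`, `n`.
#' @export
fit_validation_line <- function(predicted, measured) {
  stopifnot(length(predicted) == length(measured))
  keep <- is.finite(predicted) & is.finite(measured)
  predicted <- predicted[keep]; measured <- measured[keep]
  if (length(predicted) < 3L) stop("need at least 3 validation pairs")
  if (stats::sd(predicted) == 0)
    return(list(slope = NA_real_, intercept = NA_real_, r2_fit = NA_real_,
                n = length(predicted)))
  fit <- stats::lm(measured ~ predicted)
  r <- stats::cor(predicted, measured)
  list(slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]),
       r2_fit = r^2, n = length(predicted))
}

#' @export
print.agb_univariate <- function(x, ...) {
  cf <- x$coefficients
  eqn <- switch(x$family,
    linear = sprintf("y = %.4g x + %.4g", cf[["b1"]], cf[["b0"]]),
    quadratic = sprintf("y = %.4g x^2 + %.4g x + %.4g",
                        cf[["b2"]], cf[["b1"]], cf[["b0"]]),
    exponential = sprintf("y = %.4g exp(%.4g x)", cf[["a"]], cf[["b"]]))
  cat(sprintf("<agb_univariate> %s model, AGB ~ %s\n  %s\n", x$family,
              x$index_name, eqn))
  cat(sprintf("  modeling R2 = %.3f on n = %d plots\n", x$modeling_r2,
              x$n_fit))
  invisible(x)
}

#' @export
coef.agb_univariate <- function(object, ...) object$coefficients

#' @export
residuals.agb_univariate <- function(object, ...) object$residuals

#' @export
fitted.agb_univariate <- function(object, ...) object$fitted

#' @export
summary.agb_univariate <- function(object, ...) {
  print(object)
  cat(sprintf("  residual sd = %.1f g/m2; x in [%.3g, %.3g]\n",
              stats::sd(object$residuals), min(object$data$x),
              max(object$data$x)))
  if (!is.null(object$route)) cat("  fit route:", object$route, "\n")
  invisible(object)
}

#' @export
plot.agb_univariate <- function(x, ...) {
  d <- x$data[order(x$data$x), ]
  graphics::plot(d$x, d$y, xlab = x$index_name, ylab = "AGB (g/m2)",
                 main = sprintf("%s fit, R2 = %.2f", x$family,
                                x$modeling_r2), ...)
  xs <- seq(min(d$x), max(d$x), length.out = 200)
  graphics::lines(xs, eval_family(x$family, x$coefficients, xs), col = 2)
  invisible(x)
}

#' Simulate AGB responses from a fitted univariate model
#'
#' Draws Gaussian noise around the fitted curve with the residual standard
#' deviation of the fit.
#'
#' @param object an `agb_univariate` model.
#' @param nsim number of simulated response vectors.
#' @param seed optional integer seed.
#' @param ... unused.
#' @return data.frame with `nsim` columns, rows matching the fitting data.
#' @export
simulate.agb_univariate <- function(object, nsim = 1, seed = NULL, ...) {
  s <- stats::sd(object$residuals)
  draw <- function() object$fitted + stats::rnorm(length(object$fitted),
                                                  0, s)
  sims <- if (is.null(seed)) replicate(nsim, draw())
          else with_seed(seed, replicate(nsim, draw()))
  out <- as.data.frame(sims)
  names(out) <- paste0("sim_", seq_len(nsim))
  out
}
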
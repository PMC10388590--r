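#' Training configuration for the feedforward network
#'
#' Control constants for Levenberg-Marquardt (LM) training of the
#' three-layer network. LM interpolates between Gauss-Newton and gradient
#' descent on the sum-of-squares objective: each step solves
#' `(J'J + mu I) delta = -J' e` and the damping `mu` is decreased after an
#' accepted step and increased after a rejected one.
#'
#' @param max_iterations maximum accepted LM steps (default 1000).
#' @param damping_init,damping_up,damping_down initial damping and its
#'   up/down factors (defaults 1e-3, 10, 0.1).
#' @param damping_max training stops when `mu` exceeds this (default 1e10).
#' @param grad_tol stop when the gradient infinity-norm falls below this
#'   (default 1e-10).
#' @param loss_tol stop when the mean squared error (scaled space) falls
#'   below this (default 1e-20).
#' @param seed integer seed for weight initialisation.
#' @param hidden_activation `"tanh"` (default) or `"sigmoid"`.
#' @param init `"uniform"` (seeded uniform in [-0.5, 0.5], default) or
#'   `"nguyen-widrow"`.
#' @param regularization generalisation control. `"bayes"` (default) trains
#'   on the Bayesian-evidence objective `beta * SSE + alpha * SSW` with
#'   `alpha`, `beta` re-estimated from the evidence after every accepted
#'   step (MacKay's framework; the effective number of parameters is
#'   reported in the training log). With as many free weights as samples
#'   and strongly collinear vegetation-index inputs, unregularised LM
#'   grows weights along near-null input directions unchecked and the
#'   network degrades away from the training points; evidence
#'   regularisation shrinks exactly those directions with no tuning
#'   constant. `"none"` gives plain sum-of-squares LM with the
#'   random-divide early-stopping monitor below.
#' @param val_fraction (`regularization = "none"` only) fraction of the
#'   modeling rows held out internally to monitor generalisation during
#'   training (default 0.15, the standard random-divide practice; 0
#'   disables the monitor).
#' @param patience accepted steps without monitor improvement before
#'   stopping (default 6); the returned weights are those of the best
#'   monitored iterate.
#' @return list of class `bpnn_config`.
#' @export
bpnn_config <- function(max_iterations = 1000L, damping_init = 1e-3,
                        damping_up = 10, damping_down = 0.1,
                        damping_max = 1e10, grad_tol = 1e-10,
                        loss_tol = 1e-20, seed = 1L,
                        hidden_activation = c("tanh", "sigmoid"),
                        init = c("uniform", "nguyen-widrow"),
                        regularization = c("bayes", "none"),
                        val_fraction = 0.15, patience = 6L) {
  stopifnot(max_iterations >= 1, damping_init > 0, damping_up > 1,
            damping_down > 0, damping_down < 1,
            val_fraction >= 0, val_fraction < 1, patience >= 1)
  structure(list(max_iterations = as.integer(max_iterations),
                 damping_init = damping_init, damping_up = damping_up,
                 damping_down = damping_down, damping_max = damping_max,
                 grad_tol = grad_tol, loss_tol = loss_tol,
                 seed = as.integer(seed),
                 hidden_activation = match.arg(hidden_activation),
                 init = match.arg(init),
                 regularization = match.arg(regularization),
                 val_fraction = val_fraction,
                 patience = as.integer(patience)),
            class = "bpnn_config")
}

## min-max scaling to [-1, 1], parameters stored per feature
fit_scaling <- function(x) {
  mins <- apply(x, 2, min); maxs <- apply(x, 2, max)
  if (any(maxs <= mins))
    stop("cannot scale: feature(s) ",
         paste(colnames(x)[maxs <= mins], collapse = ", "),
         " constant on the training rows")
  list(min = mins, max = maxs)
}
apply_scaling <- function(x, sc)
  sweep(sweep(x, 2, sc$min), 2, (sc$max - sc$min) / 2, "/") - 1
invert_scaling <- function(z, sc)
  (z + 1) * (sc$max - sc$min) / 2 + sc$min

act_fun <- function(kind) switch(kind,
  tanh = list(f = tanh, df = function(z) 1 - z^2),          # df in terms of f
  sigmoid = list(f = function(a) 1 / (1 + exp(-a)),
                 df = function(z) z * (1 - z)))

## forward pass in scaled space; X is n x p, weights W1 (m x p), b1 (m),
## w2 (m), b2 (scalar). Returns list(yhat, Z).
bpnn_forward <- function(X, w, act) {
  A <- X %*% t(w$W1) + matrix(w$b1, nrow(X), length(w$b1), byrow = TRUE)
  Z <- act$f(A)
  list(yhat = drop(Z %*% w$w2) + w$b2, Z = Z)
}

pack_weights <- function(w) c(as.vector(w$W1), w$b1, w$w2, w$b2)
unpack_weights <- function(theta, m, p) {
  W1 <- matrix(theta[seq_len(m * p)], m, p)
  b1 <- theta[m * p + seq_len(m)]
  w2 <- theta[m * p + m + seq_len(m)]
  b2 <- theta[m * p + 2 * m + 1]
  list(W1 = W1, b1 = b1, w2 = w2, b2 = b2)
}

## Jacobian of yhat wrt parameters, n x (m*p + 2m + 1), analytic backprop
bpnn_jacobian <- function(X, w, Z, act) {
  n <- nrow(X); m <- length(w$b1); p <- ncol(X)
  D <- act$df(Z)                          # n x m, dZ/dA
  S <- sweep(D, 2, w$w2, "*")             # n x m, dyhat/dA_j
  J <- matrix(0, n, m * p + 2 * m + 1)
  for (j in seq_len(m))                   # dyhat/dW1[j, k] = S[, j] * X[, k]
    J[, (j - 1) + m * (seq_len(p) - 1) + 1] <- S[, j] * X
  J[, m * p + seq_len(m)] <- S            # dyhat/db1
  J[, m * p + m + seq_len(m)] <- Z        # dyhat/dw2
  J[, m * p + 2 * m + 1] <- 1             # dyhat/db2
  J
}

#' Train the AGB inversion network by Levenberg-Marquardt
#'
#' A fully connected feedforward network with one hidden layer
#' (`n_inputs -> hidden -> 1`; bounded sigmoidal hidden units, linear
#' output) regressing measured AGB on a set of vegetation indices. Features
#' and target are min-max scaled to [-1, 1] (scaling parameters are stored
#' in the model); weights start from a seeded initialisation; full-batch LM
#' minimises the training objective on the modeling rows. Under the default
#' evidence regularisation the objective is `beta * SSE + alpha * SSW`
#' (see [bpnn_config()]); with `regularization = "none"` it is the plain
#' sum of squared errors, which is nonincreasing across accepted steps by
#' construction. Training is deterministic given the seed.
#'
#' @param table feature table with `agb` and index columns; rows with
#'   `role == "modeling"` are trained on (all rows when no roles assigned);
#'   `role == "validation"` rows feed the optional early-stopping monitor.
#' @param inputs character vector of predictor column names.
#' @param hidden number of hidden neurons (default 3).
#' @param config a [bpnn_config()].
#' @return object of class `c("agb_bpnn", "agb_model")` holding the
#'   architecture, weights, scaling parameters and a training log
#'   (iterations run, loss trace in scaled space, stop reason, seed).
#' @export
train_bpnn <- function(table, inputs, hidden = 3L, config = bpnn_config()) {
  stopifnot(inherits(config, "bpnn_config"), hidden >= 1)
  miss <- setdiff(inputs, names(table))
  if (length(miss)) stop("input(s) not in the feature table: ",
                         paste(miss, collapse = ", "))
  use <- table
  if ("role" %in% names(table) && any(table$role %in% "modeling"))
    use <- table[table$role %in% "modeling", , drop = FALSE]
  X <- as.matrix(use[, inputs, drop = FALSE])
  y <- use$agb
  keep <- stats::complete.cases(X) & is.finite(y)
  X <- X[keep, , drop = FALSE]; y <- y[keep]
  n <- nrow(X); p <- length(inputs); m <- as.integer(hidden)
  if (n < p + 2L) stop("need at least n_inputs + 2 = ", p + 2L,
                       " complete modeling rows, have ", n)
  in_sc <- fit_scaling(X)
  t_sc <- fit_scaling(matrix(y, dimnames = list(NULL, "agb")))
  Xall <- apply_scaling(X, in_sc)
  yall <- drop(apply_scaling(matrix(y), t_sc))
  act <- act_fun(config$hidden_activation)

  ## internal random divide (plain-LM mode only): a monitor subset of the
  ## modeling rows guards against weight growth along collinear directions
  bayes <- config$regularization == "bayes"
  n_mon <- if (!bayes && config$val_fraction > 0)
    max(2L, round(config$val_fraction * n)) else 0L
  mon_idx <- if (n_mon > 0 && n - n_mon >= p + 2L)
    with_seed(config$seed + 1L, sort(sample.int(n, n_mon)))
  else integer(0)
  tr_idx <- setdiff(seq_len(n), mon_idx)
  Xs <- Xall[tr_idx, , drop = FALSE]; ys <- yall[tr_idx]
  Xv <- if (length(mon_idx)) Xall[mon_idx, , drop = FALSE] else NULL
  yv <- yall[mon_idx]

  w <- with_seed(config$seed, {
    if (config$init == "uniform") {
      list(W1 = matrix(stats::runif(m * p, -0.5, 0.5), m, p),
           b1 = stats::runif(m, -0.5, 0.5),
           w2 = stats::runif(m, -0.5, 0.5),
           b2 = stats::runif(1, -0.5, 0.5))
    } else {                              # Nguyen-Widrow
      W1 <- matrix(stats::runif(m * p, -1, 1), m, p)
      norm <- sqrt(rowSums(W1^2))
      beta <- 0.7 * m^(1 / p)
      W1 <- beta * W1 / norm
      list(W1 = W1,
           b1 = stats::runif(m, -beta, beta),
           w2 = stats::runif(m, -0.5, 0.5),
           b2 = stats::runif(1, -0.5, 0.5))
    }
  })

  theta <- pack_weights(w)
  np <- length(theta)
  fw <- bpnn_forward(Xs, w, act)
  e <- fw$yhat - ys
  sse <- sum(e^2)
  n_tr <- length(ys)
  ## evidence hyperparameters (bayes mode); objective = beta*SSE + alpha*SSW
  alpha <- if (bayes) 0.01 else 0
  beta <- 1
  gamma_eff <- NA_real_
  objective <- function(sse_, theta_) beta * sse_ + alpha * sum(theta_^2)
  obj <- objective(sse, theta)
  mu <- config$damping_init
  loss_trace <- sse / n_tr
  stop_reason <- "max_iterations"
  iter <- 0L
  best_val <- Inf; since_best <- 0L; best_w <- w
  if (!is.null(Xv))
    best_val <- mean((bpnn_forward(Xv, w, act)$yhat - yv)^2)
  while (iter < config$max_iterations) {
    if (!is.finite(sse)) stop("training diverged to non-finite loss")
    J <- bpnn_jacobian(Xs, w, fw$Z, act)
    g <- 2 * beta * drop(crossprod(J, e)) + 2 * alpha * theta
    if (max(abs(g)) < config$grad_tol) { stop_reason <- "gradient"; break }
    H <- 2 * beta * crossprod(J) + 2 * alpha * diag(np)
    accepted <- FALSE
    while (!accepted && mu <= config$damping_max) {
      delta <- tryCatch(
        solve(H + mu * diag(np), -g),
        error = function(e2) NULL)
      if (!is.null(delta)) {
        w_new <- unpack_weights(theta + delta, m, p)
        fw_new <- bpnn_forward(Xs, w_new, act)
        sse_new <- sum((fw_new$yhat - ys)^2)
        obj_new <- objective(sse_new, theta + delta)
        if (is.finite(obj_new) && obj_new < obj) {
          theta <- theta + delta
          w <- w_new; fw <- fw_new
          e <- fw$yhat - ys; sse <- sse_new; obj <- obj_new
          mu <- max(mu * config$damping_down, 1e-20)
          accepted <- TRUE
        }
      }
      if (!accepted) mu <- mu * config$damping_up
    }
    if (!accepted) { stop_reason <- "damping_max"; break }
    iter <- iter + 1L
    loss_trace <- c(loss_trace, sse / n_tr)
    if (sse / n_tr < config$loss_tol) { stop_reason <- "loss_tol"; break }
    if (bayes) {
      ## MacKay evidence re-estimation of alpha, beta
      J <- bpnn_jacobian(Xs, w, fw$Z, act)
      H <- 2 * beta * crossprod(J) + 2 * alpha * diag(np)
      tr_hinv <- tryCatch(sum(diag(solve(H))), error = function(e2) NA)
      if (is.finite(tr_hinv)) {
        gamma_eff <- min(max(np - 2 * alpha * tr_hinv, 1), np)
        alpha <- gamma_eff / (2 * max(sum(theta^2), 1e-12))
        beta <- max(n_tr - gamma_eff, 1e-3) / (2 * max(sse, 1e-12))
      }
      obj <- objective(sse, theta)
    }
    if (!is.null(Xv)) {
      vloss <- mean((bpnn_forward(Xv, w, act)$yhat - yv)^2)
      if (vloss < best_val - 1e-12) {
        best_val <- vloss; since_best <- 0L; best_w <- w
      } else since_best <- since_best + 1L
      if (since_best >= config$patience) {
        stop_reason <- "early_stop"; break
      }
    }
  }
  if (!is.null(Xv)) w <- best_w
  yhat_all <- bpnn_forward(Xall, w, act)$yhat
  fitted_orig <- drop(invert_scaling(matrix(yhat_all), t_sc))
  structure(list(
    architecture = list(n_inputs = p, n_hidden = m, n_outputs = 1L,
                        hidden_activation = config$hidden_activation,
                        output_activation = "identity"),
    inputs = inputs, weights = w,
    fitted = fitted_orig, residuals = y - fitted_orig,
    input_scaling = in_sc, target_scaling = t_sc,
    training_log = list(iterations = iter, final_mse_scaled = sse / n_tr,
                        loss_trace = loss_trace, stop_reason = stop_reason,
                        seed = config$seed, final_damping = mu,
                        regularization = config$regularization,
                        effective_parameters = gamma_eff,
                        alpha = alpha, beta = beta,
                        n_train = n_tr, n_monitor = length(mon_idx),
                        best_monitor_mse = if (is.null(Xv)) NA_real_
                                           else best_val),
    n_fit = n, config = config, call = match.call()),
    class = c("agb_bpnn", "agb_model"))
}

#' Predict AGB from a trained network
#'
#' Scales the features with the stored parameters, runs the forward pass
#' and inverts the target scaling. Missing feature values propagate to
#' missing predictions.
#'
#' @param object an `agb_bpnn` model.
#' @param newdata data.frame or matrix containing the model's input
#'   columns, or a named list of single-band `agb_raster`s (a raster
#'   stack) covering them.
#' @param ... unused.
#' @return numeric vector of g/m2 predictions, or an `agb_raster` when
#'   `newdata` is a raster stack.
#' @export
predict.agb_bpnn <- function(object, newdata, ...) {
  act <- act_fun(object$architecture$hidden_activation)
  if (is.list(newdata) && !is.data.frame(newdata) &&
      all(vapply(newdata, inherits, TRUE, "agb_raster"))) {
    miss <- setdiff(object$inputs, names(newdata))
    if (length(miss)) stop("raster stack lacks input(s): ",
                           paste(miss, collapse = ", "))
    ref <- newdata[[object$inputs[1]]]
    X <- vapply(object$inputs,
                function(nm) as.vector(band(newdata[[nm]])),
                numeric(length(band(ref))))
    pred <- predict(object, as.data.frame(X))
    out <- ref
    out$values <- array(pred, dim(ref$values))
    return(out)
  }
  if (is.matrix(newdata)) newdata <- as.data.frame(newdata)
  miss <- setdiff(object$inputs, names(newdata))
  if (length(miss)) stop("newdata lacks input column(s): ",
                         paste(miss, collapse = ", "))
  X <- as.matrix(newdata[, object$inputs, drop = FALSE])
  ok <- stats::complete.cases(X)
  pred <- rep(NA_real_, nrow(X))
  if (any(ok)) {
    Xs <- apply_scaling(X[ok, , drop = FALSE], object$input_scaling)
    z <- bpnn_forward(Xs, object$weights, act)$yhat
    pred[ok] <- drop(invert_scaling(matrix(z), object$target_scaling))
  }
  pred
}

#' Choose the hidden-layer size by seeded repeats
#'
#' Candidate sizes follow the conventional rule
#' `m = round(sqrt(n_inputs + n_outputs)) + a`, `a = 1..10` (overridable).
#' Each candidate is trained `k` times with derived seeds and scored by its
#' median validation RMSE (g/m2); the smallest `m` wins ties.
#'
#' @inheritParams train_bpnn
#' @param candidates integer vector of hidden sizes to try; default derives
#'   the rule-based range from `length(inputs)`.
#' @param k training repeats per candidate (default 3).
#' @return list with `m` (chosen size) and `scores` (data.frame of
#'   candidate, median validation RMSE).
#' @export
select_hidden_neurons <- function(table, inputs, candidates = NULL, k = 3L,
                                  config = bpnn_config()) {
  if (is.null(candidates)) {
    base <- round(sqrt(length(inputs) + 1))
    candidates <- pmax(1L, base + 1:10)
  }
  candidates <- sort(unique(as.integer(candidates)))
  if (!length(candidates)) stop("empty candidate range")
  if (!"role" %in% names(table) || !any(table$role %in% "validation"))
    stop("hidden-size selection needs validation rows (role column)")
  val <- table[table$role %in% "validation", , drop = FALSE]
  scores <- vapply(candidates, function(m) {
    rmses <- vapply(seq_len(k), function(rep) {
      cfg <- config
      cfg$seed <- config$seed + 1000L * rep
      mod <- train_bpnn(table, inputs, hidden = m, config = cfg)
      pred <- predict(mod, val)
      sqrt(mean((val$agb - pred)^2))
    }, numeric(1))
    stats::median(rmses)
  }, numeric(1))
  best <- candidates[which.min(scores)]   # which.min takes the first tie
  list(m = best,
       scores = data.frame(m = candidates, val_rmse = scores))
}

#' @export
print.agb_bpnn <- function(x, ...) {
  a <- x$architecture
  cat(sprintf(
    "<agb_bpnn> %d-%d-1 feedforward network (%s hidden, linear output)\n",
    a$n_inputs, a$n_hidden, a$hidden_activation))
  cat("  inputs:", paste(x$inputs, collapse = ", "), "\n")
  tl <- x$training_log
  cat(sprintf(
    "  LM training: %d iterations, MSE (scaled) %.3g, stopped on %s\n",
    tl$iterations, tl$final_mse_scaled, tl$stop_reason))
  invisible(x)
}

#' @export
summary.agb_bpnn <- function(object, ...) {
  print(object)
  cat(sprintf("  n_fit = %d, seed = %d, final damping %.3g\n",
              object$n_fit, object$training_log$seed,
              object$training_log$final_damping))
  invisible(object)
}

#' @export
residuals.agb_bpnn <- function(object, ...) object$residuals

#' @export
fitted.agb_bpnn <- function(object, ...) object$fitted

#' @export
plot.agb_bpnn <- function(x, ...) {
  tr <- x$training_log$loss_trace
  graphics::plot(seq_along(tr) - 1, tr, type = "l", log = "y",
                 xlab = "accepted LM step", ylab = "training MSE (scaled)",
                 main = "LM training trajectory", ...)
  invisible(x)
}
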
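## ---------------------------------------------------------------------------
## low-level MLP machinery: weight packing, forward pass, analytic Jacobian
## ---------------------------------------------------------------------------

#' Network shape descriptor
#'
#' Low-level helper describing a single-hidden-layer perceptron:
#' `n_in` inputs, `hidden` hidden units with `activation` (`"tanh"` or
#' `"identity"`), `n_out` linear outputs. `hidden = 0` denotes the linear
#' mode: a direct affine map whose weights (including the bias) are all
#' penalized, which makes the fixed-hyperparameter optimum coincide with the
#' ridge-regression closed form.
#'
#' @param n_in,hidden,n_out layer sizes.
#' @param activation hidden activation.
#' @return A list with the shape fields plus `k`, the total weight count.
#' @export
mlp_shape <- function(n_in, hidden, n_out, activation = "tanh") {
  n_in <- as.integer(n_in); hidden <- as.integer(hidden)
  n_out <- as.integer(n_out)
  stopifnot(n_in >= 1, hidden >= 0, n_out >= 1,
            activation %in% c("tanh", "identity"))
  k <- if (hidden > 0L) {
    n_in * hidden + hidden + hidden * n_out + n_out
  } else {
    n_in * n_out + n_out
  }
  list(n_in = n_in, hidden = hidden, n_out = n_out,
       activation = activation, k = k)
}

unpack_weights <- function(w, shape) {
  if (shape$hidden == 0L) {
    nw <- shape$n_in * shape$n_out
    list(W = matrix(w[seq_len(nw)], shape$n_in, shape$n_out),
         b = w[nw + seq_len(shape$n_out)])
  } else {
    i <- 0L
    W1 <- matrix(w[i + seq_len(shape$n_in * shape$hidden)],
                 shape$n_in, shape$hidden)
    i <- i + shape$n_in * shape$hidden
    b1 <- w[i + seq_len(shape$hidden)]
    i <- i + shape$hidden
    W2 <- matrix(w[i + seq_len(shape$hidden * shape$n_out)],
                 shape$hidden, shape$n_out)
    i <- i + shape$hidden * shape$n_out
    b2 <- w[i + seq_len(shape$n_out)]
    list(W1 = W1, b1 = b1, W2 = W2, b2 = b2)
  }
}

#' Forward pass and analytic Jacobian of the network outputs
#'
#' `mlp_forward` evaluates the network for a weight vector `w` on the rows of
#' `X`. `mlp_jacobian` returns the `(n * n_out) x k` matrix of partial
#' derivatives of every output (stacked output-major, i.e. all rows for
#' output 1, then output 2) with respect to every weight, computed
#' analytically; it is validated against central finite differences in the
#' test-suite.
#'
#' @param w numeric weight vector of length `shape$k`.
#' @param X numeric input matrix, `n x n_in`.
#' @param shape an [mlp_shape()].
#' @return `mlp_forward`: `n x n_out` matrix of outputs.
#'   `mlp_jacobian`: `(n * n_out) x k` Jacobian matrix.
#' @export
mlp_forward <- function(w, X, shape) {
  X <- as.matrix(X)
  p <- unpack_weights(w, shape)
  if (shape$hidden == 0L) {
    return(X %*% p$W + matrix(p$b, nrow(X), shape$n_out, byrow = TRUE))
  }
  A <- X %*% p$W1 + matrix(p$b1, nrow(X), shape$hidden, byrow = TRUE)
  H <- if (shape$activation == "tanh") tanh(A) else A
  H %*% p$W2 + matrix(p$b2, nrow(X), shape$n_out, byrow = TRUE)
}

#' @rdname mlp_forward
#' @export
mlp_jacobian <- function(w, X, shape) {
  X <- as.matrix(X)
  n <- nrow(X); m <- shape$n_out
  J <- matrix(0, n * m, shape$k)
  p <- unpack_weights(w, shape)
  if (shape$hidden == 0L) {
    for (o in seq_len(m)) {
      rows <- (o - 1L) * n + seq_len(n)
      J[rows, (o - 1L) * shape$n_in + seq_len(shape$n_in)] <- X
      J[rows, shape$n_in * m + o] <- 1
    }
    return(J)
  }
  A <- X %*% p$W1 + matrix(p$b1, n, shape$hidden, byrow = TRUE)
  if (shape$activation == "tanh") {
    H <- tanh(A); D <- 1 - H^2
  } else {
    H <- A; D <- matrix(1, n, shape$hidden)
  }
  off_b1 <- shape$n_in * shape$hidden
  off_W2 <- off_b1 + shape$hidden
  off_b2 <- off_W2 + shape$hidden * m
  for (o in seq_len(m)) {
    rows <- (o - 1L) * n + seq_len(n)
    for (h in seq_len(shape$hidden)) {
      s <- p$W2[h, o] * D[, h]
      J[rows, (h - 1L) * shape$n_in + seq_len(shape$n_in)] <- X * s
      J[rows, off_b1 + h] <- s
      J[rows, off_W2 + (o - 1L) * shape$hidden + h] <- H[, h]
    }
    J[rows, off_b2 + o] <- 1
  }
  J
}

# tr(H^-1) of a symmetric positive-semidefinite matrix; small or negative
# eigenvalues are floored so a rank-deficient Jacobian (saturated units,
# alpha ~ 0) cannot make the effective-parameter update blow up
trace_inverse <- function(H) {
  ev <- eigen(H, symmetric = TRUE, only.values = TRUE)$values
  floor_val <- max(ev[1], 1) * .Machine$double.eps * nrow(H)
  sum(1 / pmax(ev, floor_val))
}

## ---------------------------------------------------------------------------
## Bayesian-regularized Levenberg-Marquardt training
## ---------------------------------------------------------------------------

#' Fit a Bayesian-regularized feed-forward regression network
#'
#' Trains a single-hidden-layer perceptron (tanh hidden units, linear
#' outputs) by Levenberg-Marquardt minimization of the regularized objective
#' \deqn{F = \beta E_D + \alpha E_W,}
#' where \eqn{E_D} is the sum of squared residuals and \eqn{E_W} the sum of
#' squared weights. Under Bayesian regularization the hyperparameters are
#' re-estimated after every accepted step from the evidence framework:
#' \deqn{\gamma = k - 2\alpha\,\mathrm{tr}(H^{-1}), \quad
#'       \alpha = \gamma / (2 E_W), \quad \beta = (n - \gamma) / (2 E_D),}
#' with \eqn{H \approx 2\beta J^\top J + 2\alpha I}, \eqn{k} the weight count
#' and \eqn{\gamma} the effective number of parameters. No validation set is
#' used; the evidence updates play that role. \eqn{\alpha} starts at 0 and
#' \eqn{\beta} at 1, so the first update happens after the initial LM cycle.
#'
#' Supplying both `alpha` and `beta` freezes the hyperparameters (plain
#' regularized LM), which is how the linear mode (`hidden = 0`) reproduces
#' the ridge closed form.
#'
#' Inputs and targets are expected on the normalized `[0, 1]` scale used by
#' the calibration pipeline; attach the fitted [fit_normalization()] object
#' via `normalization` so that [predict.brnet()] can map raw voltages in and
#' raw masses/coordinates out.
#'
#' @param x numeric input matrix (`n x n_in`), normalized.
#' @param y numeric target vector or matrix (`n x n_out`), normalized.
#' @param hidden number of hidden units (5 for the load networks, 10 for the
#'   location networks; 0 for the linear mode).
#' @param activation hidden activation, `"tanh"` (default) or `"identity"`.
#' @param max_epochs maximum number of accepted LM steps.
#' @param mu_init,mu_inc,mu_dec,mu_max LM damping schedule.
#' @param grad_tol stop when the objective-gradient norm falls below this.
#' @param alpha,beta optional fixed hyperparameters; both or neither.
#' @param init_range half-width of the uniform weight initialization.
#' @param seed optional integer seed for the initialization.
#' @param normalization optional `normalization_params` carried for
#'   prediction; `target_names` names the output columns.
#' @param target_names character names of the outputs (e.g. `"mass_kg"` or
#'   `c("x", "y")`).
#' @return An object of class `brnet` with components `weights` (packed
#'   vector), `shape`, `alpha`, `beta`, `gamma`, `history` (objective after
#'   each accepted step), `stop_reason`, `residuals`, and the attached
#'   normalization.
#' @seealso [predict.brnet()], [train_bundle()], [mlp_jacobian()]
#' @export
brnet <- function(x, y, hidden = 5L,
                  activation = c("tanh", "identity"),
                  max_epochs = 150L, mu_init = 1e-3, mu_inc = 10,
                  mu_dec = 0.1, mu_max = 1e10, grad_tol = 1e-6,
                  alpha = NULL, beta = NULL, init_range = 0.5,
                  seed = NULL, normalization = NULL, target_names = NULL) {
  activation <- match.arg(activation)
  X <- as.matrix(x)
  Y <- as.matrix(y)
  if (nrow(X) != nrow(Y)) stop("x and y row counts differ", call. = FALSE)
  if (!all(is.finite(X)) || !all(is.finite(Y))) {
    stop("x and y must be finite", call. = FALSE)
  }
  if (xor(is.null(alpha), is.null(beta))) {
    stop("supply both alpha and beta, or neither", call. = FALSE)
  }
  shape <- mlp_shape(ncol(X), hidden, ncol(Y), activation)
  n_res <- nrow(X) * shape$n_out
  fixed_hyper <- !is.null(alpha)
  if (!fixed_hyper && n_res <= shape$k) {
    stop("Bayesian hyperparameter updates need more residuals (", n_res,
         ") than weights (", shape$k, ")", call. = FALSE)
  }

  if (!is.null(seed)) set.seed(seed)
  w <- runif(shape$k, -init_range, init_range)
  alpha_cur <- if (fixed_hyper) alpha else 0
  beta_cur <- if (fixed_hyper) beta else 1

  ev <- function(w) {
    e <- as.vector(Y - mlp_forward(w, X, shape))
    list(e = e, ED = sum(e^2), EW = sum(w^2))
  }
  st <- ev(w)
  Fobj <- beta_cur * st$ED + alpha_cur * st$EW
  mu <- mu_init
  history <- numeric(0)
  stop_reason <- "max_epochs"
  gamma <- shape$k
  Ik <- diag(shape$k)

  for (epoch in seq_len(max_epochs)) {
    J <- mlp_jacobian(w, X, shape)
    g <- as.vector(-2 * beta_cur * crossprod(J, st$e) + 2 * alpha_cur * w)
    if (sqrt(sum(g^2)) < grad_tol) {
      stop_reason <- "gradient"
      break
    }
    JtJ <- crossprod(J)
    accepted <- FALSE
    while (mu <= mu_max) {
      Hmu <- 2 * beta_cur * JtJ + (2 * alpha_cur + mu) * Ik
      delta <- tryCatch(solve(Hmu, -g), error = function(err) NULL)
      if (!is.null(delta)) {
        w_new <- w + as.vector(delta)
        st_new <- ev(w_new)
        F_new <- beta_cur * st_new$ED + alpha_cur * st_new$EW
        if (is.finite(F_new) && F_new < Fobj) {
          w <- w_new
          st <- st_new
          Fobj <- F_new
          mu <- max(mu * mu_dec, 1e-20)
          accepted <- TRUE
          break
        }
      }
      mu <- mu * mu_inc
    }
    if (!accepted) {
      stop_reason <- "mu_max"
      break
    }
    if (!is.finite(Fobj)) {
      stop("non-finite training objective at epoch ", epoch, call. = FALSE)
    }
    if (!fixed_hyper) {
      tr_hinv <- trace_inverse(2 * beta_cur * JtJ + 2 * alpha_cur * Ik)
      gamma <- shape$k - 2 * alpha_cur * tr_hinv
      gamma <- min(max(gamma, 0), shape$k)
      alpha_cur <- gamma / (2 * max(st$EW, .Machine$double.eps))
      beta_cur <- (n_res - gamma) / (2 * max(st$ED, .Machine$double.eps))
      Fobj <- beta_cur * st$ED + alpha_cur * st$EW
    }
    history <- c(history, Fobj)
  }
  if (fixed_hyper) {
    gamma <- NA_real_
  } else {
    tr_hinv <- trace_inverse(
      2 * beta_cur * crossprod(mlp_jacobian(w, X, shape)) + 2 * alpha_cur * Ik)
    gamma <- shape$k - 2 * alpha_cur * tr_hinv
    gamma <- min(max(gamma, 0), shape$k)
  }

  structure(list(weights = w, shape = shape,
                 alpha = alpha_cur, beta = beta_cur, gamma = gamma,
                 fixed_hyper = fixed_hyper,
                 E_D = st$ED, E_W = st$EW, objective = Fobj,
                 history = history, stop_reason = stop_reason,
                 n_train = nrow(X),
                 residuals = matrix(st$e, nrow(X), shape$n_out),
                 normalization = normalization,
                 target_names = target_names),
            class = "brnet")
}

#' Split a dataset into training and test parts
#'
#' Random, seeded, disjoint and exhaustive row split; the training part has
#' `round(train_frac * n)` rows. The protocol uses 85% for training and 15%
#' for testing with no validation set (Bayesian regularization supplies its
#' own regularization, so none is needed).
#'
#' @param ds data frame.
#' @param train_frac training fraction (default 0.85).
#' @param seed optional integer seed.
#' @return List with elements `train` and `test`.
#' @export
split_dataset <- function(ds, train_frac = 0.85, seed = NULL) {
  n <- nrow(ds)
  if (n < 1L) stop("dataset is empty", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  n_train <- round(train_frac * n)
  if (n_train >= n) {
    n_train <- n
    warning("test split is empty (too few records)")
  }
  idx <- sample.int(n, n_train)
  list(train = ds[idx, , drop = FALSE],
       test = ds[setdiff(seq_len(n), idx), , drop = FALSE])
}

## ---------------------------------------------------------------------------
## methods
## ---------------------------------------------------------------------------

#' Predict load or location from a bridge reading
#'
#' Normalizes the three voltage deltas with the network's stored
#' normalization parameters, runs the forward pass, and de-normalizes the
#' outputs back to raw units (kilograms for a load network, grid units for a
#' location network). A pure function of `(object, newdata)`.
#'
#' @param object a fitted [brnet()] with attached normalization.
#' @param newdata a [bridge_reading()], or a numeric matrix / data frame of
#'   raw voltages with columns `dv1`, `dv2`, `dv3` (one row per reading).
#' @param ... unused.
#' @return Numeric matrix with one column per target (`mass_kg`, or
#'   `x` and `y`), one row per reading.
#' @export
predict.brnet <- function(object, newdata, ...) {
  if (is.null(object$normalization)) {
    stop("network has no attached normalization parameters; refusing to ",
         "predict on raw voltages", call. = FALSE)
  }
  if (inherits(newdata, "bridge_reading")) {
    newdata <- matrix(newdata$dv, nrow = 1,
                      dimnames = list(NULL, c("dv1", "dv2", "dv3")))
  }
  nd <- as.data.frame(newdata)
  if (!all(c("dv1", "dv2", "dv3") %in% names(nd))) {
    if (ncol(nd) == 3L) names(nd) <- c("dv1", "dv2", "dv3")
    else stop("newdata must have columns dv1, dv2, dv3", call. = FALSE)
  }
  np <- object$normalization
  Xn <- cbind(norm_affine(nd$dv1, np$inputs$dv1),
              norm_affine(nd$dv2, np$inputs$dv2),
              norm_affine(nd$dv3, np$inputs$dv3))
  Yn <- mlp_forward(object$weights, Xn, object$shape)
  targets <- object$target_names
  if (is.null(targets)) targets <- names(np$outputs)
  out <- sapply(seq_along(targets), function(j) {
    norm_affine_inv(Yn[, j], np$outputs[[targets[j]]])
  })
  out <- matrix(out, nrow = nrow(Xn), dimnames = list(NULL, targets))
  out
}

#' @export
print.brnet <- function(x, ...) {
  cat("Bayesian-regularized network: ", x$shape$n_in, "-", x$shape$hidden,
      "-", x$shape$n_out, " (", x$shape$activation, " hidden)\n", sep = "")
  cat(sprintf("  weights k = %d, trained on n = %d rows\n",
              x$shape$k, x$n_train))
  if (x$fixed_hyper) {
    cat(sprintf("  fixed alpha = %.4g, beta = %.4g\n", x$alpha, x$beta))
  } else {
    cat(sprintf("  alpha = %.4g, beta = %.4g, gamma = %.2f of %d\n",
                x$alpha, x$beta, x$gamma, x$shape$k))
  }
  cat(sprintf("  E_D = %.4g, stopped on %s after %d accepted steps\n",
              x$E_D, x$stop_reason, length(x$history)))
  invisible(x)
}

#' @export
summary.brnet <- function(object, ...) {
  res <- object$residuals
  structure(list(net = object,
                 rmse = sqrt(mean(res^2)),
                 mae = mean(abs(res))),
            class = "summary.brnet")
}

#' @export
print.summary.brnet <- function(x, ...) {
  print(x$net)
  cat(sprintf("  training RMSE = %.4g, MAE = %.4g (normalized scale)\n",
              x$rmse, x$mae))
  invisible(x)
}

#' @export
coef.brnet <- function(object, ...) {
  unpack_weights(object$weights, object$shape)
}

#' @export
residuals.brnet <- function(object, ...) object$residuals

#' Plot the training history of a network
#'
#' @param x a fitted [brnet()].
#' @param ... passed to [graphics::plot()].
#' @export
plot.brnet <- function(x, ...) {
  plot(seq_along(x$history), x$history, type = "l", log = "y",
       xlab = "accepted LM step", ylab = "objective F", ...)
  invisible(x)
}
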
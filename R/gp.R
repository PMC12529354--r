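## Gaussian-process surrogate over normalized compositions.
## Matern 5/2 kernel with one lengthscale per component (automatic
## relevance), plus a white-noise term; hyperparameters by marginal
## likelihood with a fixed number of seeded restarts, so a fit is fully
## deterministic given (X, y, seed).

matern52_cross <- function(X1, X2, lengthscales) {
  d2 <- matrix(0, nrow(X1), nrow(X2))
  for (j in seq_len(ncol(X1))) {
    d2 <- d2 + outer(X1[, j] / lengthscales[j], X2[, j] / lengthscales[j], "-")^2
  }
  r <- sqrt(pmax(d2, 0))
  (1 + sqrt(5) * r + 5 * r^2 / 3) * exp(-sqrt(5) * r)
}

gp_nll <- function(par, X, y) {
  d <- ncol(X)
  ls <- exp(par[seq_len(d)])
  amp <- exp(par[d + 1L])
  noise <- exp(par[d + 2L])
  n <- nrow(X)
  K <- amp^2 * matern52_cross(X, X, ls) + diag(noise^2 + 1e-8, n)
  ch <- tryCatch(chol(K), error = function(e) NULL)
  if (is.null(ch)) return(1e10)
  alpha <- backsolve(ch, forwardsolve(t(ch), y))
  0.5 * sum(y * alpha) + sum(log(diag(ch))) + 0.5 * n * log(2 * pi)
}

#' Fit the Gaussian-process yield surrogate
#'
#' Fits a GP regression of measured yields (or raw calibrated signals) on
#' normalized compositions in `[0,1]^d`, using a Matern 5/2 kernel with a
#' lengthscale per component plus a white-noise term. Responses are
#' standardized internally; hyperparameters maximize the marginal
#' likelihood over a fixed set of seeded restarts, so refitting on the same
#' data and seed reproduces the same model.
#'
#' @param X Numeric matrix of normalized compositions, one row per tested
#'   buffer, all entries in `[0, 1]` (see [normalize_features()]).
#' @param y Numeric vector of responses (fold-change yields or calibrated
#'   signals).
#' @param seed Integer seed for the restart draws.
#' @param n_restarts Extra random restarts beyond the default start.
#' @return An object of class `cfps_gp` with `predict`, `print` and
#'   `summary` methods.
#' @export
#' @examples
#' X <- matrix(runif(40), 20, 2)
#' y <- sin(3 * X[, 1]) + X[, 2]
#' fit <- fit_surrogate(X, y, seed = 1)
#' predict(fit, matrix(c(0.5, 0.5), 1, 2))
fit_surrogate <- function(X, y, seed = 1L, n_restarts = 2L) {
  X <- as.matrix(X)
  if (nrow(X) < 1L) stop("empty training set")
  if (length(y) != nrow(X)) stop("length(y) must match nrow(X)")
  if (anyNA(y) || any(!is.finite(y))) stop("NaN or non-finite values in y")
  if (anyNA(X)) stop("NaN in X")
  if (min(X) < -1e-9 || max(X) > 1 + 1e-9)
    stop("features must be normalized to [0, 1]")
  d <- ncol(X)
  mu_y <- mean(y)
  sd_y <- stats::sd(y)
  if (!is.finite(sd_y) || sd_y < 1e-12) sd_y <- 1
  ym <- (y - mu_y) / sd_y

  lower <- c(rep(log(0.05), d), log(0.05), log(1e-3))
  upper <- c(rep(log(10), d), log(10), log(2))
  starts <- list(c(rep(log(0.5), d), log(1), log(0.1)))
  if (n_restarts > 0) {
    set.seed(seed)
    for (r in seq_len(n_restarts)) {
      starts[[r + 1L]] <- stats::runif(d + 2L, lower, upper)
    }
  }
  best <- NULL
  for (st in starts) {
    fit <- tryCatch(
      stats::optim(st, gp_nll, X = X, y = ym, method = "L-BFGS-B",
                   lower = lower, upper = upper,
                   control = list(maxit = 100)),
      error = function(e) NULL)
    if (!is.null(fit) && (is.null(best) || fit$value < best$value)) best <- fit
  }
  if (is.null(best)) stop("GP hyperparameter optimization failed")
  par <- best$par
  ls <- exp(par[seq_len(d)])
  amp <- exp(par[d + 1L])
  noise <- exp(par[d + 2L])
  K <- amp^2 * matern52_cross(X, X, ls) + diag(noise^2 + 1e-8, nrow(X))
  ch <- chol(K)
  alpha <- backsolve(ch, forwardsolve(t(ch), ym))
  structure(list(X = X, y = y, ym = ym, mu_y = mu_y, sd_y = sd_y,
                 lengthscales = ls, amplitude = amp, noise = noise,
                 chol = ch, alpha = alpha, nll = best$value, seed = seed),
            class = "cfps_gp")
}

#' Posterior prediction from the GP surrogate
#'
#' @param object A `cfps_gp` fit.
#' @param newdata Matrix of normalized compositions.
#' @param ... Unused.
#' @return A list with `mean` and `sd` per row of `newdata`; `sd` is the
#'   predictive standard deviation of a new observation (latent uncertainty
#'   plus the fitted noise), on the response scale.
#' @export
predict.cfps_gp <- function(object, newdata, ...) {
  Xs <- as.matrix(newdata)
  if (ncol(Xs) != ncol(object$X))
    stop(sprintf("newdata has %d columns, model has %d features",
                 ncol(Xs), ncol(object$X)))
  Ks <- object$amplitude^2 * matern52_cross(Xs, object$X, object$lengthscales)
  mean_m <- drop(Ks %*% object$alpha)
  v <- forwardsolve(t(object$chol), t(Ks))
  var_f <- pmax(object$amplitude^2 - colSums(v^2), 0)
  list(mean = object$mu_y + object$sd_y * mean_m,
       sd = object$sd_y * sqrt(var_f + object$noise^2))
}

#' @export
print.cfps_gp <- function(x, ...) {
  cat(sprintf("GP surrogate: %d training points, %d features\n",
              nrow(x$X), ncol(x$X)))
  cat(sprintf("  Matern 5/2 lengthscales: %s\n",
              paste(sprintf("%.3g", x$lengthscales), collapse = ", ")))
  cat(sprintf("  amplitude %.3g, noise %.3g (standardized scale), nll %.3f\n",
              x$amplitude, x$noise, x$nll))
  invisible(x)
}

#' @export
summary.cfps_gp <- function(object, ...) {
  pr <- predict(object, object$X)
  cat(sprintf("GP surrogate on %d points; training RMSE %.4g, response range %.4g-%.4g\n",
              nrow(object$X), sqrt(mean((pr$mean - object$y)^2)),
              min(object$y), max(object$y)))
  print(object)
  invisible(object)
}
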
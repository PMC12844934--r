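#' Partial least squares regression by NIPALS
#'
#' Predictors and responses are autoscaled (mean 0, sd 1); components are
#' extracted by the NIPALS2 iteration (weight vector from the Y-projection,
#' convergence tolerance 1e-10, max 500 iterations per component) with
#' deflation of both blocks. Regression coefficients on the standardized
#' scale are W (P'W)^-1 C' and are also back-transformed to original units.
#'
#' @param X numeric matrix/data.frame, observations x predictors.
#' @param Y numeric matrix/data.frame (or vector), observations x responses.
#' @param n_components number of latent components (default 2; must not
#'   exceed the rank of X).
#' @return list of class `plsr_model`: `x_weights`, `x_loadings`,
#'   `y_loadings`, `x_scores`, `coefficients` (original units),
#'   `coefficients_std`, `intercept`, `x_means`/`x_sds`/`y_means`/`y_sds`,
#'   `fitted`, `r2_per_response`, `n_components`.
#' @export
plsr_fit <- function(X, Y, n_components = 2) {
  X <- as.matrix(X)
  if (is.null(dim(Y))) Y <- matrix(Y, ncol = 1)
  Y <- as.matrix(Y)
  stopifnot(nrow(X) == nrow(Y), n_components >= 1)
  xn <- colnames(X) %||% sprintf("X%d", seq_len(ncol(X)))
  yn <- colnames(Y) %||% sprintf("Y%d", seq_len(ncol(Y)))
  colnames(X) <- xn; colnames(Y) <- yn
  if (anyNA(X) || anyNA(Y)) stop("missing values not allowed")
  xm <- colMeans(X); xs <- apply(X, 2, stats::sd)
  ym <- colMeans(Y); ys <- apply(Y, 2, stats::sd)
  if (any(xs == 0)) stop("constant predictor column(s): ",
                         paste(xn[xs == 0], collapse = ", "))
  if (any(ys == 0)) stop("constant response column(s): ",
                         paste(yn[ys == 0], collapse = ", "))
  rk <- qr(sweep(X, 2, xm))$rank
  if (n_components > rk)
    stop("n_components (", n_components, ") exceeds rank(X) (", rk, ")")
  Xd <- sweep(sweep(X, 2, xm), 2, xs, "/")
  Yd <- sweep(sweep(Y, 2, ym), 2, ys, "/")
  n <- nrow(Xd); p <- ncol(Xd); q <- ncol(Yd)
  Wm <- matrix(0, p, n_components); Pm <- matrix(0, p, n_components)
  Cm <- matrix(0, q, n_components); Tm <- matrix(0, n, n_components)
  for (h in seq_len(n_components)) {
    u <- Yd[, which.max(apply(Yd, 2, stats::var))]
    t_old <- rep(Inf, n)
    for (it in seq_len(500)) {
      w <- crossprod(Xd, u) / drop(crossprod(u))
      w <- w / sqrt(drop(crossprod(w)))
      tt <- Xd %*% w
      cc <- crossprod(Yd, tt) / drop(crossprod(tt))
      u <- Yd %*% cc / drop(crossprod(cc))
      if (sqrt(sum((tt - t_old)^2)) / sqrt(sum(tt^2)) < 1e-10) break
      t_old <- tt
    }
    pp <- crossprod(Xd, tt) / drop(crossprod(tt))
    Xd <- Xd - tt %*% t(pp)
    Yd <- Yd - tt %*% t(cc)
    Wm[, h] <- w; Pm[, h] <- pp; Cm[, h] <- cc; Tm[, h] <- tt
  }
  dimnames(Wm) <- dimnames(Pm) <- list(xn, sprintf("LV%d", seq_len(n_components)))
  dimnames(Cm) <- list(yn, sprintf("LV%d", seq_len(n_components)))
  B_std <- Wm %*% solve(crossprod(Pm, Wm)) %*% t(Cm)
  # back-transform: y = ym + ys * (x - xm)/xs %*% B_std
  B <- sweep(sweep(B_std, 1, xs, "/"), 2, ys, "*")
  intercept <- ym - drop(xm %*% B)
  dimnames(B) <- list(xn, yn)
  model <- structure(list(
    n_components = n_components, x_weights = Wm, x_loadings = Pm,
    y_loadings = Cm, x_scores = Tm, coefficients = B,
    coefficients_std = B_std, intercept = intercept,
    x_means = xm, x_sds = xs, y_means = ym, y_sds = ys,
    x_names = xn, y_names = yn), class = "plsr_model")
  model$fitted <- plsr_predict(model, X)
  model$r2_per_response <- r2_per_response(model, X, Y)
  model
}

#' Predict responses from a fitted PLSR model
#'
#' @param model a [plsr_model][plsr_fit()].
#' @param X_new matrix/data.frame whose columns match the training
#'   predictors.
#' @return matrix of predicted responses in original units.
#' @export
plsr_predict <- function(model, X_new) {
  stopifnot(inherits(model, "plsr_model"))
  X_new <- as.matrix(X_new)
  if (ncol(X_new) != length(model$x_names))
    stop("predictor count mismatch")
  if (!is.null(colnames(X_new)) &&
      !identical(colnames(X_new), model$x_names)) {
    if (!setequal(colnames(X_new), model$x_names))
      stop("predictor columns do not match training predictors")
    X_new <- X_new[, model$x_names, drop = FALSE]
  }
  out <- sweep(X_new %*% model$coefficients, 2, model$intercept, "+")
  colnames(out) <- model$y_names
  out
}

#' Per-response coefficient of determination
#'
#' R^2 = 1 - SS_res / SS_tot for each response, computed in original units
#' on the supplied data. A zero-variance response yields `NA`.
#'
#' @param model a [plsr_model][plsr_fit()].
#' @param X,Y data on which to evaluate (e.g. the calibration data).
#' @return named numeric vector of R^2 values.
#' @export
r2_per_response <- function(model, X, Y) {
  if (is.null(dim(Y))) Y <- matrix(Y, ncol = 1,
                                   dimnames = list(NULL, model$y_names))
  Y <- as.matrix(Y)
  pred <- plsr_predict(model, X)
  vapply(seq_len(ncol(Y)), function(j) {
    ss_tot <- sum((Y[, j] - mean(Y[, j]))^2)
    if (ss_tot == 0) return(NA_real_)
    1 - sum((Y[, j] - pred[, j])^2) / ss_tot
  }, numeric(1)) |> stats::setNames(model$y_names)
}

#' @export
print.plsr_model <- function(x, ...) {
  cat(sprintf("PLSR (NIPALS), %d component(s): %d predictors -> %d responses\n",
              x$n_components, length(x$x_names), length(x$y_names)))
  print(round(x$r2_per_response, 3))
  invisible(x)
}
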
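#' Principal component analysis with optional varimax rotation
#'
#' Eigendecomposition of the covariance matrix of (optionally z-scored)
#' data. Loadings are eigenvectors scaled by sqrt(eigenvalue); each loading
#' column is oriented so its largest-magnitude entry is positive. With
#' `rotate = "varimax"` the retained loading columns are rotated (Kaiser
#' normalized) and explained variance is additionally reported as rotated
#' sums of squared loadings.
#'
#' Mixed-unit survey data (metals in hundreds of mg/kg next to percent
#' nutrients) should be standardized (`standardize = TRUE`, the default);
#' the raw covariance mode is retained for single-scale data.
#'
#' @param data numeric matrix/data.frame, observations x variables, no
#'   missing values.
#' @param standardize z-score columns first (default `TRUE`).
#' @param rotate `"none"` or `"varimax"`.
#' @param n_components number of components to retain (default 2).
#' @return list of class `pca_result`: `eigenvalues`, `explained_pct`,
#'   `loadings`, `scores`, `rotation`, plus `rot_explained_pct` when
#'   rotated; `center`/`scale` vectors for reprojection.
#' @export
pca_fit <- function(data, standardize = TRUE, rotate = c("none", "varimax"),
                    n_components = 2) {
  rotate <- match.arg(rotate)
  X <- as.matrix(data)
  stopifnot(is.numeric(X), nrow(X) >= 2)
  if (anyNA(X)) stop("missing values: impute or drop before PCA")
  vars <- colnames(X) %||% sprintf("V%d", seq_len(ncol(X)))
  ctr <- colMeans(X)
  scl <- if (standardize) apply(X, 2, stats::sd) else rep(1, ncol(X))
  if (any(scl == 0)) stop("constant column(s): ",
                          paste(vars[scl == 0], collapse = ", "))
  Xs <- sweep(sweep(X, 2, ctr), 2, scl, "/")
  S <- stats::cov(Xs)
  eig <- eigen(S, symmetric = TRUE)
  ev <- pmax(eig$values, 0)
  rk <- sum(ev > max(ev) * 1e-10)
  if (n_components > rk)
    stop("n_components (", n_components, ") exceeds rank (", rk, ")")
  V <- eig$vectors
  # deterministic sign: largest |entry| positive per column
  for (j in seq_len(ncol(V))) {
    i <- which.max(abs(V[, j]))
    if (V[i, j] < 0) V[, j] <- -V[, j]
  }
  dimnames(V) <- list(vars, sprintf("PC%d", seq_len(ncol(V))))
  scores <- Xs %*% V
  keep <- seq_len(n_components)
  load <- V[, keep, drop = FALSE] %*% diag(sqrt(ev[keep]), n_components)
  colnames(load) <- sprintf("PC%d", keep)
  res <- list(eigenvalues = ev, explained_pct = 100 * ev / sum(ev),
              loadings = load, scores = scores[, keep, drop = FALSE],
              all_vectors = V, rotation = rotate, center = ctr, scale = scl,
              standardized = standardize)
  if (rotate == "varimax" && n_components >= 2) {
    rot <- varimax_rotate(load, normalize = TRUE)
    R <- attr(rot, "rotmat")
    # orient rotated columns deterministically too
    for (j in seq_len(ncol(rot))) {
      i <- which.max(abs(rot[, j]))
      if (rot[i, j] < 0) { rot[, j] <- -rot[, j]; R[, j] <- -R[, j] }
    }
    res$loadings <- rot
    res$rot_explained_pct <- 100 * colSums(rot^2) / sum(ev)
    # regression scores for the rotated solution
    res$scores <- Xs %*% rot %*% solve(crossprod(rot))
    res$rotmat <- R
  }
  class(res) <- "pca_result"
  res
}

#' Varimax rotation of a loading matrix
#'
#' Orthogonal rotation maximizing the varimax criterion (variance of
#' squared loadings per column), via the classical iterative pairwise-angle
#' algorithm with optional Kaiser row normalization. The returned matrix is
#' `loadings %*% R` with `R` orthogonal (attached as attribute `rotmat`);
#' row communalities are invariant.
#'
#' @param loadings numeric matrix, variables x factors.
#' @param normalize Kaiser-normalize rows before rotating (default `TRUE`).
#' @param tol convergence tolerance on the relative criterion change.
#' @param max_sweeps maximum number of full pairwise sweeps.
#' @return rotated loading matrix with attribute `rotmat`.
#' @export
varimax_rotate <- function(loadings, normalize = TRUE, tol = 1e-6,
                           max_sweeps = 1000) {
  L <- as.matrix(loadings)
  m <- ncol(L)
  if (m < 2) {
    attr(L, "rotmat") <- diag(m)
    return(L)
  }
  h <- sqrt(rowSums(L^2))
  W <- if (normalize) L / ifelse(h > 0, h, 1) else L
  p <- nrow(W)
  R <- diag(m)
  crit <- function(A) sum(apply(A^2, 2, function(z) mean(z^2) - mean(z)^2))
  old <- crit(W)
  for (sweep in seq_len(max_sweeps)) {
    for (j in seq_len(m - 1)) {
      for (k in (j + 1):m) {
        x <- W[, j]; y <- W[, k]
        u <- x^2 - y^2; v <- 2 * x * y
        A <- sum(u); B <- sum(v)
        C <- sum(u^2 - v^2); D <- sum(2 * u * v)
        num <- D - 2 * A * B / p
        den <- C - (A^2 - B^2) / p
        phi <- atan2(num, den) / 4
        if (abs(phi) < 1e-12) next
        G <- diag(m)
        G[j, j] <- cos(phi); G[k, k] <- cos(phi)
        G[j, k] <- -sin(phi); G[k, j] <- sin(phi)
        W <- W %*% G
        R <- R %*% G
      }
    }
    new <- crit(W)
    if (new - old < tol * max(old, .Machine$double.eps)) break
    old <- new
  }
  out <- L %*% R
  dimnames(out) <- dimnames(L)
  attr(out, "rotmat") <- R
  out
}

#' @export
print.pca_result <- function(x, ...) {
  k <- ncol(x$loadings)
  cat(sprintf("PCA (%s, rotation: %s): %d components retained\n",
              if (x$standardized) "standardized" else "raw covariance",
              x$rotation, k))
  cat("explained variance (%):",
      paste(sprintf("%.2f", x$explained_pct[seq_len(k)]), collapse = ", "),
      "\n")
  invisible(x)
}
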
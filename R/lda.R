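# Wilks' lambda for a variable subset: det(W) / det(T) on those columns.
wilks_lambda <- function(X, groups, cols) {
  Xs <- X[, cols, drop = FALSE]
  W <- matrix(0, length(cols), length(cols))
  for (g in unique(groups)) {
    Xg <- Xs[groups == g, , drop = FALSE]
    Xg <- sweep(Xg, 2, colMeans(Xg))
    W <- W + crossprod(Xg)
  }
  Tt <- crossprod(sweep(Xs, 2, colMeans(Xs)))
  dW <- det(W); dT <- det(Tt)
  if (dT <= 0) return(NA_real_)
  dW / dT
}

#' Stepwise linear discriminant analysis (forward, Wilks' lambda)
#'
#' Forward selection: at each step the candidate minimizing Wilks' lambda
#' is admitted if its partial F-to-enter,
#' F = ((n - g - p) / (g - 1)) (Lambda_p / Lambda_p+1 - 1),
#' has p < `alpha_enter` (p = variables already entered, g = groups). The
#' discriminant axes are then the leading eigenvectors of W^-1 B on the
#' selected variables, scaled so the pooled within-group covariance of the
#' scores is the identity; structure coefficients are pooled within-group
#' correlations of each selected variable with the scores.
#'
#' @param data numeric matrix/data.frame, observations x variables.
#' @param groups group labels (>= 2 groups, each with >= 2 observations).
#' @param alpha_enter entry threshold on the F-to-enter p-value (default
#'   0.05).
#' @return list of class `lda_result`: `selected_vars`,
#'   `wilks_lambda_path`, `f_to_enter`, `p_to_enter`, `discriminant_axes`,
#'   `scores`, `group_centroids`, `loadings` (structure coefficients),
#'   `status` (`"ok"` or `"empty"`).
#' @export
lda_stepwise <- function(data, groups, alpha_enter = 0.05) {
  X <- as.matrix(data)
  stopifnot(is.numeric(X), nrow(X) == length(groups))
  groups <- as.character(groups)
  vars <- colnames(X) %||% sprintf("V%d", seq_len(ncol(X)))
  colnames(X) <- vars
  tab <- table(groups)
  g <- length(tab)
  if (g < 2 || any(tab < 2))
    stop("need >= 2 groups with >= 2 observations each")
  n <- nrow(X)
  selected <- character(0)
  path <- numeric(0); fpath <- numeric(0); ppath <- numeric(0)
  lambda_prev <- 1
  repeat {
    cand <- setdiff(vars, selected)
    if (!length(cand)) break
    lam <- vapply(cand, function(v)
      wilks_lambda(X, groups, c(selected, v)), numeric(1))
    lam[is.na(lam)] <- Inf
    best <- cand[which.min(lam)]
    lambda_new <- lam[which.min(lam)]
    p_in <- length(selected)
    df2 <- n - g - p_in
    if (df2 <= 0 || !is.finite(lambda_new) || lambda_new <= 0) break
    f <- (df2 / (g - 1)) * (lambda_prev / lambda_new - 1)
    pval <- stats::pf(f, g - 1, df2, lower.tail = FALSE)
    if (pval >= alpha_enter) break
    selected <- c(selected, best)
    path <- c(path, lambda_new); fpath <- c(fpath, f); ppath <- c(ppath, pval)
    lambda_prev <- lambda_new
  }
  if (!length(selected)) {
    warning("no variable passed the entry criterion")
    return(structure(list(selected_vars = character(0),
                          wilks_lambda_path = numeric(0),
                          f_to_enter = numeric(0), p_to_enter = numeric(0),
                          status = "empty"), class = "lda_result"))
  }
  Xs <- X[, selected, drop = FALSE]
  W <- matrix(0, length(selected), length(selected))
  gm <- matrix(0, g, length(selected),
               dimnames = list(names(tab), selected))
  grand <- colMeans(Xs)
  B <- matrix(0, length(selected), length(selected))
  for (gi in names(tab)) {
    Xg <- Xs[groups == gi, , drop = FALSE]
    mg <- colMeans(Xg)
    gm[gi, ] <- mg
    W <- W + crossprod(sweep(Xg, 2, mg))
    B <- B + nrow(Xg) * tcrossprod(mg - grand)
  }
  Wp <- W / (n - g)  # pooled within covariance
  eg <- eigen(solve(W) %*% B)
  nf <- min(g - 1, length(selected))
  A <- Re(eg$vectors[, seq_len(nf), drop = FALSE])
  # scale axes: a' Wp a = 1 (identity pooled within-group score covariance)
  for (j in seq_len(nf)) {
    a <- A[, j]
    A[, j] <- a / sqrt(drop(t(a) %*% Wp %*% a))
    i <- which.max(abs(A[, j]))
    if (A[i, j] < 0) A[, j] <- -A[, j]
  }
  dimnames(A) <- list(selected, sprintf("LD%d", seq_len(nf)))
  scores <- sweep(Xs, 2, grand) %*% A
  centroids <- sweep(gm, 2, grand) %*% A
  # structure coefficients: pooled within-group correlations var vs score
  sc_cov <- Wp %*% A
  sds <- sqrt(diag(Wp))
  loadings <- sweep(sc_cov, 1, sds, "/")  # score sd is 1 by construction
  structure(list(selected_vars = selected,
                 wilks_lambda_path = path, f_to_enter = fpath,
                 p_to_enter = ppath, discriminant_axes = A,
                 scores = scores, group_centroids = centroids,
                 loadings = loadings, status = "ok"),
            class = "lda_result")
}

#' @export
print.lda_result <- function(x, ...) {
  if (x$status == "empty") {
    cat("Stepwise LDA: no variable entered\n")
  } else {
    cat("Stepwise LDA: entered",
        paste(x$selected_vars, collapse = " > "), "\n")
    cat("Wilks' lambda path:",
        paste(sprintf("%.4f", x$wilks_lambda_path), collapse = " -> "), "\n")
  }
  invisible(x)
}
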
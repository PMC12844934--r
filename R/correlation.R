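#' Correlation matrix with significance and strength labels
#'
#' Pearson (or Spearman, computed as Pearson on midranks) correlations with
#' pairwise-complete deletion, two-tailed p-values from
#' t = r sqrt((n-2)/(1-r^2)), and conventional strength categories:
#' |r| < 0.2 none, 0.2-0.4 weak, 0.4-0.6 moderate, > 0.6 strong.
#' Correlations involving a constant variable are undefined (`NA`).
#'
#' @param data numeric matrix or data.frame, observations x variables.
#' @param method `"pearson"` or `"spearman"`.
#' @return list of class `correlation_matrix` with `variables`, `r`, `p`,
#'   `n`, `strength`, `stars`, `method`.
#' @export
correlation_matrix <- function(data, method = c("pearson", "spearman")) {
  method <- match.arg(method)
  X <- as.matrix(data)
  stopifnot(is.numeric(X), ncol(X) >= 2)
  vars <- colnames(X) %||% sprintf("V%d", seq_len(ncol(X)))
  colnames(X) <- vars
  pnum <- ncol(X)
  r <- p <- nmat <- matrix(NA_real_, pnum, pnum, dimnames = list(vars, vars))
  for (i in seq_len(pnum)) {
    for (j in i:pnum) {
      ok <- stats::complete.cases(X[, c(i, j)])
      n <- sum(ok)
      if (n < 3) next
      xi <- X[ok, i]; xj <- X[ok, j]
      if (method == "spearman") { xi <- rank(xi); xj <- rank(xj) }
      if (stats::sd(xi) == 0 || stats::sd(xj) == 0) {
        if (i == j) { r[i, j] <- NA; nmat[i, j] <- n }
        next
      }
      rij <- stats::cor(xi, xj)
      r[i, j] <- r[j, i] <- rij
      nmat[i, j] <- nmat[j, i] <- n
      if (i == j) { p[i, j] <- NA_real_; next }
      # guard |r| = 1 exactly
      tstat <- rij * sqrt((n - 2) / max(1 - rij^2, .Machine$double.eps))
      p[i, j] <- p[j, i] <- 2 * stats::pt(abs(tstat), n - 2,
                                          lower.tail = FALSE)
    }
  }
  strength <- matrix(ifelse(is.na(r), NA_character_,
                            ifelse(abs(r) < 0.2, "none",
                                   ifelse(abs(r) < 0.4, "weak",
                                          ifelse(abs(r) <= 0.6, "moderate",
                                                 "strong")))),
                     pnum, pnum, dimnames = list(vars, vars))
  stars <- matrix(NA_character_, pnum, pnum, dimnames = list(vars, vars))
  off <- !is.na(p)
  stars[off] <- star_code(p[off])
  structure(list(variables = vars, r = r, p = p, n = nmat,
                 strength = strength, stars = stars, method = method),
            class = "correlation_matrix")
}

#' Export a correlation matrix as a flat CSV of pairs
#'
#' @param cm a [correlation_matrix()].
#' @param path output CSV path.
#' @return the exported data.frame, invisibly.
#' @export
write_correlations <- function(cm, path) {
  stopifnot(inherits(cm, "correlation_matrix"))
  idx <- which(upper.tri(cm$r), arr.ind = TRUE)
  out <- data.frame(a = cm$variables[idx[, 1]], b = cm$variables[idx[, 2]],
                    r = cm$r[idx], p = cm$p[idx],
                    strength = cm$strength[idx], stars = cm$stars[idx],
                    stringsAsFactors = FALSE)
  utils::write.csv(out, path, row.names = FALSE)
  invisible(out)
}
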
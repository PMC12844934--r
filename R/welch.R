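#' Welch one-way ANOVA
#'
#' Heteroscedastic one-way ANOVA: group weights w_i = n_i / s_i^2, the
#' F statistic is the weighted between-group mean square divided by
#' 1 + 2(k-2)/(k^2-1) * Lambda with Lambda = sum (1 - w_i/W)^2 / (n_i - 1),
#' and the denominator degrees of freedom are (k^2 - 1) / (3 Lambda).
#'
#' @param groups list of numeric vectors, each of length >= 2 with positive
#'   variance.
#' @return list with `f_stat`, `df1`, `df2`, `p` (class `welch_anova`).
#' @export
welch_anova <- function(groups) {
  k <- length(groups)
  stopifnot(k >= 2)
  groups <- lapply(groups, function(g) g[!is.na(g)])
  n <- vapply(groups, length, numeric(1))
  if (any(n < 2)) stop("every group needs n >= 2")
  s2 <- vapply(groups, stats::var, numeric(1))
  if (any(s2 <= 0)) stop("zero-variance group: Welch statistic undefined")
  m <- vapply(groups, mean, numeric(1))
  w <- n / s2
  W <- sum(w)
  mw <- sum(w * m) / W
  A <- sum(w * (m - mw)^2) / (k - 1)
  lambda <- sum((1 - w / W)^2 / (n - 1))
  f <- A / (1 + 2 * (k - 2) / (k^2 - 1) * lambda)
  df2 <- (k^2 - 1) / (3 * lambda)
  structure(list(f_stat = f, df1 = k - 1, df2 = df2,
                 p = stats::pf(f, k - 1, df2, lower.tail = FALSE)),
            class = "welch_anova")
}

#' Games-Howell pairwise post hoc comparisons
#'
#' For each pair (i, j): t = |mean_i - mean_j| / sqrt(s_i^2/n_i + s_j^2/n_j),
#' Welch-Satterthwaite degrees of freedom, and the p-value from the
#' studentized range distribution with q = t * sqrt(2) and k groups. With
#' k = 2 this reduces exactly to the two-sample Welch t-test.
#'
#' @param groups named list of numeric vectors (>= 2 groups, each n >= 2,
#'   positive variance).
#' @return data.frame with columns `group_a`, `group_b`, `mean_diff`, `se`,
#'   `df`, `q_stat`, `p`, `sig_code`.
#' @export
games_howell <- function(groups) {
  k <- length(groups)
  stopifnot(k >= 2)
  if (is.null(names(groups))) names(groups) <- sprintf("G%d", seq_len(k))
  groups <- lapply(groups, function(g) g[!is.na(g)])
  n <- vapply(groups, length, numeric(1))
  if (any(n < 2)) stop("every group needs n >= 2")
  s2 <- vapply(groups, stats::var, numeric(1))
  if (any(s2 <= 0)) stop("zero-variance group: comparisons undefined")
  m <- vapply(groups, mean, numeric(1))
  pairs <- utils::combn(k, 2)
  out <- vapply(seq_len(ncol(pairs)), function(cix) {
    i <- pairs[1, cix]; j <- pairs[2, cix]
    se2 <- s2[i] / n[i] + s2[j] / n[j]
    df <- se2^2 / ((s2[i] / n[i])^2 / (n[i] - 1) +
                     (s2[j] / n[j])^2 / (n[j] - 1))
    tt <- abs(m[i] - m[j]) / sqrt(se2)
    q <- tt * sqrt(2)
    p <- stats::ptukey(q, nmeans = k, df = df, lower.tail = FALSE)
    c(diff = m[i] - m[j], se = sqrt(se2), df = df, q = q, p = p)
  }, c(diff = 0, se = 0, df = 0, q = 0, p = 0))
  res <- data.frame(group_a = names(groups)[pairs[1, ]],
                    group_b = names(groups)[pairs[2, ]],
                    mean_diff = out["diff", ], se = out["se", ],
                    df = out["df", ], q_stat = out["q", ], p = out["p", ],
                    stringsAsFactors = FALSE)
  res$sig_code <- star_code(res$p)
  rownames(res) <- NULL
  res
}

#' @export
print.welch_anova <- function(x, ...) {
  cat(sprintf("Welch one-way ANOVA: F(%g, %.2f) = %.4f, p = %.4g %s\n",
              x$df1, x$df2, x$f_stat, x$p, star_code(x$p)))
  invisible(x)
}
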
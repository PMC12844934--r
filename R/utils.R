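#' Round half away from zero
#'
#' Presentation rounding used when rendering tables: exact halves round away
#' from zero (so 3.516 -> 3.52 at 2 digits), unlike [base::round()]'s
#' round-half-to-even. Applied only at rendering time, never in storage.
#'
#' @param x numeric vector.
#' @param digits integer number of decimal places.
#' @return numeric vector rounded half-up (away from zero).
#' @export
#' @examples
#' round_half_up(3.516, 2)  # 3.52
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5 + sqrt(.Machine$double.eps)) / p
}

#' Adjusted Rand index between two partitions
#'
#' Chance-corrected agreement between two cluster assignments of the same
#' observations; 1 for identical partitions (up to relabeling), ~0 for
#' independent ones.
#'
#' @param a,b vectors of cluster labels of equal length.
#' @return scalar adjusted Rand index.
#' @export
adjusted_rand_index <- function(a, b) {
  stopifnot(length(a) == length(b), length(a) >= 2)
  tab <- table(a, b)
  ch2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(ch2(tab))
  sum_a <- sum(ch2(rowSums(tab)))
  sum_b <- sum(ch2(colSums(tab)))
  n <- length(a)
  expected <- sum_a * sum_b / ch2(n)
  mx <- (sum_a + sum_b) / 2
  if (mx == expected) return(1)
  (sum_ij - expected) / (mx - expected)
}

# Deterministic per-stage seed fan-out from a single global seed.
# Kept below 2^31 so it is a valid R integer seed.
derive_seed <- function(seed, label) {
  h <- 0
  for (k in utf8ToInt(label)) h <- (h * 131 + k) %% 1000003
  as.integer((abs(as.numeric(seed)) * 1000003 + h) %% 2147483647)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
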
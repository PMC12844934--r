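# Chlorophyll quantification from methanol-extract absorbances
# (Lichtenthaler-type linear coefficients for the 665.2 / 652.4 nm pair).
CHL_COEF <- matrix(c(16.82, -9.28,
                     -16.54, 36.92), nrow = 2, byrow = TRUE,
                   dimnames = list(c("chl_a", "chl_b"), c("a665_2", "a652_4")))

#' Chlorophyll a, b and their ratio from extract absorbances
#'
#' Applies the linear pigment equations
#' chl_a = 16.82 A665.2 - 9.28 A652.4 and
#' chl_b = 36.92 A652.4 - 16.54 A665.2 (ug/g FW), then the a/b ratio.
#' Negative computed pigments are physically implausible readings: they are
#' returned as-is but flagged, never clamped. The ratio is `NA` whenever
#' chl_b <= 0.
#'
#' @param a665_2,a652_4 non-negative absorbances (vectors of equal length).
#' @return data.frame with columns `chl_a`, `chl_b`, `ratio`, `flag`
#'   (`TRUE` when either pigment is negative).
#' @export
#' @examples
#' compute_pigments(1.0, 0.5)  # chl_a 12.18, chl_b 1.92, ratio 6.34375
compute_pigments <- function(a665_2, a652_4) {
  stopifnot(length(a665_2) == length(a652_4))
  if (any(!is.finite(a665_2)) || any(!is.finite(a652_4)) ||
      any(a665_2 < 0) || any(a652_4 < 0))
    stop("absorbances must be finite and non-negative")
  chl_a <- CHL_COEF["chl_a", 1] * a665_2 + CHL_COEF["chl_a", 2] * a652_4
  chl_b <- CHL_COEF["chl_b", 1] * a665_2 + CHL_COEF["chl_b", 2] * a652_4
  data.frame(chl_a = chl_a, chl_b = chl_b,
             ratio = ifelse(chl_b > 0, chl_a / chl_b, NA_real_),
             flag = chl_a < 0 | chl_b < 0)
}

#' Batch pigment computation from a CSV of absorbance readings
#'
#' Input columns: `sample_id`, `a665_2`, `a652_4`. Output adds `chl_a`,
#' `chl_b`, `ratio`, `flag`.
#'
#' @param path input CSV path.
#' @param out optional output CSV path; when given, results are also written.
#' @return data.frame of results.
#' @export
compute_pigments_file <- function(path, out = NULL) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  stopifnot(all(c("sample_id", "a665_2", "a652_4") %in% names(df)))
  res <- cbind(df["sample_id"], compute_pigments(df$a665_2, df$a652_4))
  if (!is.null(out)) utils::write.csv(res, out, row.names = FALSE)
  res
}
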
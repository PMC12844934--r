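#' Per-site mean and standard error for one analyte
#'
#' Mirrors the survey's site-summary tables: per-site mean and SEM over the
#' trees sampled at that site. SEM uses the sample standard deviation
#' (divisor n-1) divided by sqrt(n); for a site with a single tree the SEM is
#' undefined and reported as `NA`.
#'
#' @param table a [measurement_table()].
#' @param analyte analyte name present in the table.
#' @param compartment `"leaf"` or `"soil"`.
#' @return data.frame with columns `site_id`, `analyte`, `mean`, `sem`, `n`.
#' @export
summarize_sites <- function(table, analyte, compartment = c("leaf", "soil")) {
  stopifnot(inherits(table, "measurement_table"))
  compartment <- match.arg(compartment)
  sub <- table[table$analyte == analyte & table$compartment == compartment &
                 !is.na(table$value), , drop = FALSE]
  if (!nrow(sub))
    stop("analyte '", analyte, "' not present in compartment '",
         compartment, "'")
  sites <- sort(unique(sub$site_id))
  out <- do.call(rbind, lapply(sites, function(s) {
    v <- sub$value[sub$site_id == s]
    n <- length(v)
    data.frame(site_id = s, analyte = analyte,
               mean = mean(v),
               sem = if (n > 1) stats::sd(v) / sqrt(n) else NA_real_,
               n = n, stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Grand summary across site means
#'
#' Unweighted mean of the site means plus the extreme sites. Under a
#' balanced design (equal trees per site) this equals the tree-level mean.
#' Ties for the extreme sites are broken lexicographically by `site_id`.
#'
#' @param summaries data.frame with columns `site_id`, `analyte`, `mean`
#'   (as returned by [summarize_sites()] or the packaged fixtures filtered
#'   to one analyte).
#' @return list with `analyte`, `grand_mean`, `min_site`, `max_site`
#'   (each a list of `site_id` and `value`) and `n_sites`.
#' @export
grand_summary <- function(summaries) {
  stopifnot(all(c("site_id", "mean") %in% names(summaries)),
            nrow(summaries) >= 1)
  an <- unique(summaries$analyte %||% NA_character_)
  if (length(an) > 1)
    stop("mixed analytes in summaries: ", paste(an, collapse = ", "))
  m <- summaries$mean
  s <- as.character(summaries$site_id)
  ord_min <- order(m, s)[1]
  ord_max <- order(-m, s)[1]
  res <- list(analyte = an,
              grand_mean = mean(m),
              min_site = list(site_id = s[ord_min], value = m[ord_min]),
              max_site = list(site_id = s[ord_max], value = m[ord_max]),
              n_sites = nrow(summaries))
  stopifnot(res$min_site$value <= res$grand_mean + 1e-12,
            res$grand_mean <= res$max_site$value + 1e-12)
  res
}

#' Significance star codes
#'
#' Maps p-values to the conventional codes: `***` for p < 0.001, `**` for
#' p < 0.01, `*` for p < 0.05, `ns` otherwise. Boundaries are strict, so
#' p = 0.05 is `ns`.
#'
#' @param p numeric vector of probabilities in \[0, 1\].
#' @return character vector of codes.
#' @export
star_code <- function(p) {
  if (any(is.na(p)) || any(p < 0) || any(p > 1))
    stop("p must lie in [0, 1]")
  ifelse(p < 0.001, "***", ifelse(p < 0.01, "**", ifelse(p < 0.05, "*", "ns")))
}
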
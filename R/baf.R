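#' Per-tree bioaccumulation factors
#'
#' BAF = C_leaf / C_soil, the dimensionless ratio of an element's
#' concentration in leaf tissue to its concentration in soil (matched
#' units, dry-mass basis). With `soil_granularity = "site"` every tree at a
#' site is paired with that site's (composite) soil value; with `"tree"`
#' each leaf value is paired with the soil record of the same tree.
#'
#' @param table a [measurement_table()] containing the element in both
#'   compartments.
#' @param element element name.
#' @param soil_granularity `"site"` (default) or `"tree"`.
#' @return data.frame with columns `site_id`, `tree_id`, `element`, `baf`.
#' @export
compute_baf <- function(table, element,
                        soil_granularity = c("site", "tree")) {
  stopifnot(inherits(table, "measurement_table"))
  soil_granularity <- match.arg(soil_granularity)
  leaf <- table[table$analyte == element & table$compartment == "leaf" &
                  !is.na(table$value), , drop = FALSE]
  soil <- table[table$analyte == element & table$compartment == "soil" &
                  !is.na(table$value), , drop = FALSE]
  if (!nrow(leaf) || !nrow(soil))
    stop("element '", element, "' must be measured in both compartments")
  lu <- unique(leaf$units); su <- unique(soil$units)
  if (!identical(lu, su))
    stop("unit mismatch for '", element, "': leaf in ", lu, ", soil in ", su)
  if (any(soil$value <= 0))
    stop("non-positive soil concentration for '", element, "' at site(s): ",
         paste(unique(soil$site_id[soil$value <= 0]), collapse = ", "))
  if (soil_granularity == "site") {
    soil_by_site <- tapply(soil$value, soil$site_id, mean)
    denom <- soil_by_site[leaf$site_id]
    if (any(is.na(denom)))
      stop("no soil value for site(s): ",
           paste(unique(leaf$site_id[is.na(denom)]), collapse = ", "))
  } else {
    key <- function(d) paste(d$site_id, d$tree_id, sep = "\r")
    soil_by_tree <- stats::setNames(soil$value, key(soil))
    denom <- soil_by_tree[key(leaf)]
    if (any(is.na(denom)))
      stop("no tree-level soil value for: ",
           paste(unique(key(leaf)[is.na(denom)]), collapse = "; "))
  }
  out <- data.frame(site_id = leaf$site_id, tree_id = leaf$tree_id,
                    element = element, baf = leaf$value / unname(denom),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Grand summary of BAF values for one element
#'
#' Accepts either per-tree BAF records (aggregated first to site means) or a
#' site-summary table such as the packaged fixture filtered to one element.
#' Returns the unweighted grand mean of site means with extreme sites;
#' under a balanced design this equals the tree-level mean.
#'
#' @param records data.frame with either columns `site_id`, `element`,
#'   `baf` (tree records) or `site_id`, `element`, `mean` (site summaries).
#' @return a [grand_summary()] list.
#' @export
baf_grand_stats <- function(records) {
  if (!nrow(records)) stop("empty input")
  el <- unique(records$element)
  if (length(el) > 1)
    stop("mixed elements: ", paste(el, collapse = ", "))
  if ("baf" %in% names(records)) {
    m <- tapply(records$baf, records$site_id, mean)
    site_means <- data.frame(site_id = names(m), analyte = el,
                             mean = as.numeric(m), stringsAsFactors = FALSE)
  } else if ("mean" %in% names(records)) {
    site_means <- data.frame(site_id = records$site_id, analyte = el,
                             mean = records$mean, stringsAsFactors = FALSE)
  } else stop("records must carry a 'baf' or 'mean' column")
  grand_summary(site_means)
}

#' Classify accumulation behaviour from a BAF value
#'
#' An element is actively accumulated when its BAF strictly exceeds 1.
#'
#' @param baf positive numeric vector of BAF values.
#' @return character vector, `"accumulator"` or `"non_accumulator"`.
#' @export
classify_accumulation <- function(baf) {
  stopifnot(is.numeric(baf), all(baf > 0))
  ifelse(baf > 1, "accumulator", "non_accumulator")
}
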
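#' Packaged leaf site-summary table
#'
#' Site-level means and SEMs (n = 4 trees per site) of leaf macronutrients
#' (%), micronutrients and trace metals (mg/kg DW), SPAD index, chlorophyll
#' a/b (ug/g FW) and their ratio for the 20 monitored orchard sites, as
#' published. The `sig` column carries the published Welch-ANOVA star code.
#'
#' @return data.frame with columns `site_id`, `analyte`, `mean`, `sem`,
#'   `sig`, `units`.
#' @export
leaf_site_summaries <- function() {
  path <- system.file("extdata", "tables_1_2_leaf_site_summaries.csv",
                      package = "soil2leaf", mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Packaged BAF site-summary table
#'
#' Site-level means and SEMs of leaf/soil bioaccumulation factors for
#' Cd, Cu, Ni, Pb, Zn, Fe and Mn across the 20 monitored orchard sites,
#' as published.
#'
#' @return data.frame with columns `site_id`, `element`, `mean`, `sem`.
#' @export
baf_site_summaries <- function() {
  path <- system.file("extdata", "table_3_baf_site_summaries.csv",
                      package = "soil2leaf", mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Food-safety threshold configuration
#'
#' @param element element name (e.g. `"Cd"`).
#' @param limit strictly positive limit in mg/kg DW.
#' @param basis citation label for the limit.
#' @return data.frame row describing one threshold.
#' @export
threshold_config <- function(element, limit, basis = "") {
  stopifnot(is.numeric(limit), all(limit > 0))
  data.frame(element = element, limit = limit, basis = basis,
             stringsAsFactors = FALSE)
}

#' Default food-safety threshold sets
#'
#' Two named sets for leaf tissue, both in mg/kg DW: `"strict"` (Cd 0.1,
#' Pb 0.3) and `"general"` (Cd 0.2, Pb 2.0).
#'
#' @param set `"strict"` or `"general"`.
#' @return data.frame of [threshold_config()] rows.
#' @export
default_thresholds <- function(set = c("strict", "general")) {
  set <- match.arg(set)
  if (set == "strict")
    rbind(threshold_config("Cd", 0.1, "FAO/WHO leafy tissue"),
          threshold_config("Pb", 0.3, "FAO/WHO leafy tissue"))
  else
    rbind(threshold_config("Cd", 0.2, "FAO/WHO upper permissible"),
          threshold_config("Pb", 2.0, "FAO/WHO general"))
}
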
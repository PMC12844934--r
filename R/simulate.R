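# Synthetic orchard data generator.
#
# Emulates the monitoring design the analysis assumes: n_sites orchards,
# trees_per_site trees each, log-normal soil metal concentrations across
# sites, leaf metals = BAF x soil x multiplicative tree noise, normally
# distributed macronutrients with site effects, and SPAD / chlorophyll a
# linearly depressed by leaf Cd and Pb. Defaults are calibrated once to the
# published site-summary tables (see the methods vignette) and are not
# tuning knobs.

SIM_ELEMENTS <- c("Cd", "Pb", "Ni", "Zn", "Cu", "Fe", "Mn")

#' Configuration for the synthetic orchard generator
#'
#' All concentration parameters are strictly positive; geometric standard
#' deviations (GSDs) are >= 1 (a GSD of 1 switches that noise source off).
#' `cluster_profiles`, when given, is a list of named multiplier vectors
#' applied to `soil_geo_mean`, assigning sites to contamination clusters
#' round-robin; it is used to plant recoverable group structure.
#'
#' @param n_sites number of orchard sites (default 20).
#' @param trees_per_site trees sampled per site (default 4).
#' @param seed integer RNG seed.
#' @param soil_geo_mean named vector, geometric mean soil concentration per
#'   element (mg/kg).
#' @param soil_gsd named vector, geometric SD of soil concentration across
#'   sites (>= 1).
#' @param true_baf named vector, leaf/soil transfer ratio per element.
#' @param tree_noise_gsd geometric SD of multiplicative tree-level noise on
#'   leaf metals (>= 1).
#' @param nutrient_means,nutrient_site_sd,nutrient_tree_sd named vectors for
#'   the macronutrient model: tree value ~ N(site effect, tree sd), site
#'   effect ~ N(mean, site sd).
#' @param spad_baseline,chl_a_baseline unstressed SPAD / chlorophyll a level.
#' @param stress_slopes list with elements `spad` and `chl_a`, each a named
#'   vector `c(Cd=, Pb=)` giving the (negative) change per mg/kg leaf metal.
#' @param chl_ab_ratio target chlorophyll a/b ratio.
#' @param pigment_noise_sd additive noise SD on SPAD and pigments.
#' @param soil_granularity `"site"` (composite soil sample per site) or
#'   `"tree"` (soil sampled under each tree).
#' @param cluster_profiles optional list of named multiplier vectors.
#' @return an `orchard_sim_config` list.
#' @export
orchard_sim_config <- function(
    n_sites = 20, trees_per_site = 4, seed = 1,
    soil_geo_mean = c(Cd = 0.053, Pb = 41.5, Ni = 51.0, Zn = 88.8,
                      Cu = 19.6, Fe = 4.2, Mn = 3.5),
    soil_gsd = stats::setNames(rep(1.4, 7), SIM_ELEMENTS),
    true_baf = c(Cd = 3.52, Pb = 0.021, Ni = 0.09, Zn = 0.51,
                 Cu = 0.52, Fe = 36.26, Mn = 11.71),
    tree_noise_gsd = 1.15,
    nutrient_means = c(N = 2.58, P = 0.30, K = 1.96, Ca = 2.79,
                       Mg = 0.65, B = 51.4),
    nutrient_site_sd = c(N = 0.22, P = 0.035, K = 0.28, Ca = 0.46,
                         Mg = 0.10, B = 2.5),
    nutrient_tree_sd = nutrient_site_sd / 2,
    spad_baseline = 58, chl_a_baseline = 75,
    stress_slopes = list(spad = c(Cd = -60, Pb = -8),
                         chl_a = c(Cd = -100, Pb = -10)),
    chl_ab_ratio = 1.9, pigment_noise_sd = 2,
    soil_granularity = c("site", "tree"),
    cluster_profiles = NULL) {
  soil_granularity <- match.arg(soil_granularity)
  stopifnot(n_sites >= 1, trees_per_site >= 1,
            all(soil_geo_mean > 0), all(soil_gsd >= 1), all(true_baf > 0),
            tree_noise_gsd >= 1, all(nutrient_site_sd >= 0),
            all(nutrient_tree_sd >= 0), pigment_noise_sd >= 0,
            chl_ab_ratio > 0)
  els <- names(soil_geo_mean)
  if (!setequal(els, names(soil_gsd)) || !setequal(els, names(true_baf)))
    stop("soil_geo_mean, soil_gsd and true_baf must name the same elements")
  if (!is.null(cluster_profiles)) {
    ok <- vapply(cluster_profiles,
                 function(p) all(names(p) %in% els) && all(p > 0), logical(1))
    if (!all(ok)) stop("cluster_profiles must be positive multipliers on known elements")
  }
  structure(list(
    n_sites = n_sites, trees_per_site = trees_per_site, seed = seed,
    soil_geo_mean = soil_geo_mean, soil_gsd = soil_gsd, true_baf = true_baf,
    tree_noise_gsd = tree_noise_gsd, nutrient_means = nutrient_means,
    nutrient_site_sd = nutrient_site_sd, nutrient_tree_sd = nutrient_tree_sd,
    spad_baseline = spad_baseline, chl_a_baseline = chl_a_baseline,
    stress_slopes = stress_slopes, chl_ab_ratio = chl_ab_ratio,
    pigment_noise_sd = pigment_noise_sd, soil_granularity = soil_granularity,
    cluster_profiles = cluster_profiles), class = "orchard_sim_config")
}

#' Generate a synthetic orchard dataset
#'
#' Draws one complete long-format measurement table from the generative
#' model described in [orchard_sim_config()]. Deterministic given the
#' config seed.
#'
#' @param config an [orchard_sim_config()].
#' @return a [measurement_table()] with soil metal records (tree_id
#'   `"composite"` under site granularity), leaf metal and nutrient records
#'   per tree, and SPAD / chlorophyll records per tree. The true site
#'   cluster assignment (when `cluster_profiles` is set) is attached as
#'   attribute `"site_clusters"`.
#' @export
generate_orchard_dataset <- function(config) {
  stopifnot(inherits(config, "orchard_sim_config"))
  cf <- config
  set.seed(cf$seed)
  sites <- sprintf("S%d", seq_len(cf$n_sites))
  trees <- sprintf("T%d", seq_len(cf$trees_per_site))
  els <- names(cf$soil_geo_mean)

  mult <- matrix(1, cf$n_sites, length(els), dimnames = list(sites, els))
  clusters <- NULL
  if (!is.null(cf$cluster_profiles)) {
    clusters <- rep(seq_along(cf$cluster_profiles),
                    length.out = cf$n_sites)
    for (i in seq_len(cf$n_sites)) {
      p <- cf$cluster_profiles[[clusters[i]]]
      mult[i, names(p)] <- p
    }
  }

  rec <- list()
  add <- function(site, tree, comp, an, val, un)
    rec[[length(rec) + 1L]] <<- data.frame(
      site_id = site, tree_id = tree, compartment = comp, analyte = an,
      value = val, units = un, stringsAsFactors = FALSE)

  # soil + leaf metals (element by element so the RNG stream is stable)
  leaf_metal <- list()
  for (e in els) {
    soil_site <- cf$soil_geo_mean[[e]] * mult[, e] *
      exp(stats::rnorm(cf$n_sites, 0, log(cf$soil_gsd[[e]])))
    if (cf$soil_granularity == "site") {
      add(sites, "composite", "soil", e, soil_site, "mg/kg")
      soil_for_tree <- rep(soil_site, each = cf$trees_per_site)
    } else {
      soil_tree <- rep(soil_site, each = cf$trees_per_site) *
        exp(stats::rnorm(cf$n_sites * cf$trees_per_site, 0,
                         log(cf$tree_noise_gsd)))
      add(rep(sites, each = cf$trees_per_site), rep(trees, cf$n_sites),
          "soil", e, soil_tree, "mg/kg")
      soil_for_tree <- soil_tree
    }
    lv <- cf$true_baf[[e]] * soil_for_tree *
      exp(stats::rnorm(cf$n_sites * cf$trees_per_site, 0,
                       log(cf$tree_noise_gsd)))
    add(rep(sites, each = cf$trees_per_site), rep(trees, cf$n_sites),
        "leaf", e, lv, "mg/kg")
    leaf_metal[[e]] <- lv
  }

  # macronutrients: site effect + tree residual, truncated at 0
  for (a in names(cf$nutrient_means)) {
    site_eff <- stats::rnorm(cf$n_sites, cf$nutrient_means[[a]],
                             cf$nutrient_site_sd[[a]])
    v <- pmax(0, rep(site_eff, each = cf$trees_per_site) +
                stats::rnorm(cf$n_sites * cf$trees_per_site, 0,
                             cf$nutrient_tree_sd[[a]]))
    add(rep(sites, each = cf$trees_per_site), rep(trees, cf$n_sites),
        "leaf", a, v, if (a == "B") "mg/kg" else "%")
  }

  # pigments / SPAD coupled to leaf Cd and Pb
  n_tree <- cf$n_sites * cf$trees_per_site
  stress <- function(sl) sl[["Cd"]] * leaf_metal[["Cd"]] +
    sl[["Pb"]] * leaf_metal[["Pb"]]
  spad <- pmax(0, cf$spad_baseline + stress(cf$stress_slopes$spad) +
                 stats::rnorm(n_tree, 0, cf$pigment_noise_sd))
  chl_a <- pmax(0, cf$chl_a_baseline + stress(cf$stress_slopes$chl_a) +
                  stats::rnorm(n_tree, 0, cf$pigment_noise_sd))
  chl_b <- pmax(0, chl_a / cf$chl_ab_ratio +
                  stats::rnorm(n_tree, 0, cf$pigment_noise_sd))
  st <- rep(sites, each = cf$trees_per_site); tr <- rep(trees, cf$n_sites)
  add(st, tr, "leaf", "SPAD", spad, "index")
  add(st, tr, "leaf", "Chl_a", chl_a, "ug/g FW")
  add(st, tr, "leaf", "Chl_b", chl_b, "ug/g FW")

  out <- measurement_table(do.call(rbind, rec))
  if (!is.null(clusters))
    attr(out, "site_clusters") <- stats::setNames(clusters, sites)
  out
}

#' Absorbance pair reproducing target chlorophyll concentrations
#'
#' Inverts the two linear pigment equations: solves the 2x2 system for
#' (A665.2, A652.4) such that [compute_pigments()] recovers the targets.
#' Errors if a target is non-positive or the implied absorbances are
#' negative.
#'
#' @param chl_a_target,chl_b_target target pigment concentrations (ug/g FW).
#' @return data.frame with columns `a665_2`, `a652_4`.
#' @export
generate_absorbance_readings <- function(chl_a_target, chl_b_target) {
  stopifnot(length(chl_a_target) == length(chl_b_target))
  if (any(chl_a_target <= 0) || any(chl_b_target <= 0))
    stop("pigment targets must be strictly positive")
  A <- solve(CHL_COEF, rbind(chl_a_target, chl_b_target))
  if (any(A < 0))
    stop("targets imply negative absorbance")
  data.frame(a665_2 = A[1, ], a652_4 = A[2, ])
}
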
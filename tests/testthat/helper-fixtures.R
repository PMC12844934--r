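# Shared helpers: tiny in-code fixtures and independent oracles.

# Minimal long-format table: one leaf + one soil record per site/element.
toy_table <- function(leaf, soil, element = "Cd",
                      sites = sprintf("S%d", seq_along(leaf))) {
  measurement_table(rbind(
    data.frame(site_id = sites, tree_id = "T1", compartment = "leaf",
               analyte = element, value = leaf, units = "mg/kg"),
    data.frame(site_id = sites, tree_id = "composite", compartment = "soil",
               analyte = element, value = soil, units = "mg/kg")))
}

# Planted 4-cluster orchard world: four contamination signatures with
# tight within-cluster spread (sites in a cluster share a source).
planted_cluster_config <- function(seed) {
  els <- c("Cd", "Pb", "Ni", "Zn", "Cu", "Fe", "Mn")
  orchard_sim_config(
    seed = seed,
    soil_gsd = stats::setNames(rep(1.1, 7), els),
    cluster_profiles = list(
      c(Cd = 1),
      c(Cd = 10, Pb = 6, Ni = 2),
      c(Fe = 8, Mn = 8, Zn = 3),
      c(Cu = 6, Zn = 6, Cd = 0.2, Pb = 0.3)))
}

# Naive O(n^3) Ward agglomeration oracle: recompute, at every step, the
# ESS increase n_i n_j / (n_i + n_j) * ||c_i - c_j||^2 for every active
# pair and merge the minimum. Heights on the ward.D2 distance scale
# (sqrt of twice the ESS increase).
naive_ward <- function(X) {
  n <- nrow(X)
  clusters <- lapply(seq_len(n), function(i) i)
  heights <- numeric(n - 1)
  merges <- vector("list", n - 1)
  for (step in seq_len(n - 1)) {
    m <- length(clusters)
    best <- c(NA, NA); bd <- Inf
    for (i in seq_len(m - 1)) for (j in (i + 1):m) {
      ci <- colMeans(X[clusters[[i]], , drop = FALSE])
      cj <- colMeans(X[clusters[[j]], , drop = FALSE])
      ni <- length(clusters[[i]]); nj <- length(clusters[[j]])
      d <- ni * nj / (ni + nj) * sum((ci - cj)^2)
      if (d < bd - 1e-12) { bd <- d; best <- c(i, j) }
    }
    heights[step] <- sqrt(2 * bd)
    merges[[step]] <- sort(c(clusters[[best[1]]], clusters[[best[2]]]))
    clusters[[best[1]]] <- merges[[step]]
    clusters <- clusters[-best[2]]
  }
  list(heights = heights, merges = merges)
}

# Member sets per merge step of an hca_result (sorted), for comparison
# with the naive oracle independent of internal labeling.
hca_member_sets <- function(hca) {
  members <- vector("list", length(hca$height))
  for (step in seq_along(hca$height)) {
    side <- function(code) if (code < 0) -code else members[[code]]
    members[[step]] <- sort(c(side(hca$merge[step, 1]),
                              side(hca$merge[step, 2])))
  }
  members
}

expect_samesign_cols <- function(A, B, tol = 1e-6) {
  for (j in seq_len(ncol(A))) {
    d <- min(max(abs(A[, j] - B[, j])), max(abs(A[, j] + B[, j])))
    expect_lt(d, tol)
  }
}
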
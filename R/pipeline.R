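# End-to-end pipeline: summaries -> BAF -> inference -> correlation ->
# PCA -> HCA -> LDA -> PLSR -> MCS, every stage writing plain-text
# artifacts under the output directory, all randomness fanned out
# deterministically from one global seed.

PIPELINE_STAGES <- c("summaries", "baf", "stats", "correlation", "pca",
                     "hca", "lda", "plsr", "mcs")

#' Pipeline configuration
#'
#' Either `input` (a long-format CSV path), `table` (an in-memory
#' [measurement_table()]), `sim_config` (an [orchard_sim_config()], data
#' generated at run time), or `fixtures = TRUE` (run the desk-scale
#' analyses on the packaged published site summaries).
#'
#' @param input optional path to a long-format measurement CSV.
#' @param table optional in-memory measurement table.
#' @param sim_config optional generator config.
#' @param fixtures run from the packaged fixture tables instead.
#' @param outdir output directory (created if needed).
#' @param seed global seed; per-stage seeds are derived from it.
#' @param elements elements for the BAF stage.
#' @param analytes leaf analytes for the summary/ANOVA stages (default:
#'   all present).
#' @param standardize z-score variables before PCA/HCA/LDA.
#' @param n_components retained components for PCA and PLSR.
#' @param k_clusters clusters cut from the Ward tree (default 4).
#' @param alpha_enter stepwise-LDA entry threshold.
#' @param mcs_n_iter Monte Carlo iterations (default 10000).
#' @param threshold_set `"strict"` (Cd 0.1, Pb 0.3 mg/kg DW) or
#'   `"general"` (Cd 0.2, Pb 2.0).
#' @param mcs_granularity fit MCS distributions on `"site_means"` or
#'   `"tree_values"`.
#' @param stages subset of stages to run (default all).
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(input = NULL, table = NULL, sim_config = NULL,
                            fixtures = FALSE, outdir = tempfile("s2l_"),
                            seed = 1,
                            elements = c("Cd", "Pb", "Ni", "Zn", "Cu",
                                         "Fe", "Mn"),
                            analytes = NULL, standardize = TRUE,
                            n_components = 2, k_clusters = 4,
                            alpha_enter = 0.05, mcs_n_iter = 10000,
                            threshold_set = "strict",
                            mcs_granularity = "site_means",
                            stages = PIPELINE_STAGES) {
  n_src <- (!is.null(input)) + (!is.null(table)) + (!is.null(sim_config)) +
    isTRUE(fixtures)
  if (n_src != 1)
    stop("exactly one of input, table, sim_config, fixtures must be given")
  stopifnot(all(stages %in% PIPELINE_STAGES))
  structure(list(input = input, table = table, sim_config = sim_config,
                 fixtures = isTRUE(fixtures), outdir = outdir, seed = seed,
                 elements = elements, analytes = analytes,
                 standardize = standardize, n_components = n_components,
                 k_clusters = k_clusters, alpha_enter = alpha_enter,
                 mcs_n_iter = mcs_n_iter, threshold_set = threshold_set,
                 mcs_granularity = mcs_granularity, stages = stages),
            class = "pipeline_config")
}

#' Site-level feature matrix
#'
#' One row per site: site means of every leaf analyte, soil element means
#' (prefixed `soil_`) and BAF site means (prefixed `BAF_`). The standard
#' input for the multivariate stages.
#'
#' @param table a [measurement_table()].
#' @param elements elements for which BAF columns are added (those present
#'   in both compartments).
#' @return numeric matrix, sites x features.
#' @export
site_feature_matrix <- function(table, elements = character(0)) {
  stopifnot(inherits(table, "measurement_table"))
  sites <- sort(unique(table$site_id))
  cols <- list()
  for (a in sort(unique(table$analyte[table$compartment == "leaf"]))) {
    m <- tapply(table$value[table$analyte == a & table$compartment == "leaf"],
                table$site_id[table$analyte == a & table$compartment == "leaf"],
                mean, na.rm = TRUE)
    cols[[a]] <- as.numeric(m[sites])
  }
  for (a in sort(unique(table$analyte[table$compartment == "soil"]))) {
    m <- tapply(table$value[table$analyte == a & table$compartment == "soil"],
                table$site_id[table$analyte == a & table$compartment == "soil"],
                mean, na.rm = TRUE)
    cols[[paste0("soil_", a)]] <- as.numeric(m[sites])
  }
  soil_an <- unique(table$analyte[table$compartment == "soil"])
  for (e in intersect(elements, soil_an)) {
    b <- compute_baf(table, e)
    m <- tapply(b$baf, b$site_id, mean)
    cols[[paste0("BAF_", e)]] <- as.numeric(m[sites])
  }
  out <- do.call(cbind, cols)
  rownames(out) <- sites
  out
}

#' Run the full analysis pipeline
#'
#' Executes the configured stages in order and writes each stage's CSV/JSON
#' artifacts plus a run manifest (canonical config dump, seed, package
#' version, md5 of every text artifact) to `config$outdir`. Identical
#' configs and seeds produce byte-identical artifact sets.
#'
#' @param config a [pipeline_config()].
#' @return a `pipeline_bundle` list of stage results (invisible file paths
#'   in `$files`).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
  files <- character(0)
  put_csv <- function(df, name) {
    path <- file.path(config$outdir, name)
    utils::write.csv(df, path, row.names = FALSE)
    files <<- c(files, path)
    path
  }
  put_json <- function(x, name) {
    path <- file.path(config$outdir, name)
    jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
    files <<- c(files, path)
    path
  }
  bundle <- list(config = config, files = character(0))

  if (config$fixtures) {
    leaf <- leaf_site_summaries()
    baf <- baf_site_summaries()
    gm_leaf <- do.call(rbind, lapply(unique(leaf$analyte), function(a) {
      g <- grand_summary(leaf[leaf$analyte == a, ])
      data.frame(analyte = a, grand_mean = g$grand_mean,
                 min_site = g$min_site$site_id, min_value = g$min_site$value,
                 max_site = g$max_site$site_id, max_value = g$max_site$value)
    }))
    gm_baf <- do.call(rbind, lapply(unique(baf$element), function(e) {
      g <- baf_grand_stats(baf[baf$element == e, ])
      data.frame(element = e, grand_mean = g$grand_mean,
                 min_site = g$min_site$site_id, min_value = g$min_site$value,
                 max_site = g$max_site$site_id, max_value = g$max_site$value)
    }))
    put_csv(gm_leaf, "fixture_leaf_grand_means.csv")
    put_csv(gm_baf, "fixture_baf_grand_means.csv")
    bundle$grand_means <- list(leaf = gm_leaf, baf = gm_baf)
    if ("mcs" %in% config$stages) {
      th <- default_thresholds(config$threshold_set)
      mcs <- lapply(c("Cd", "Pb"), function(e) {
        fit <- fit_lognormal(leaf$mean[leaf$analyte == e], variable = e,
                             granularity = "site_means")
        run_simulation(fit, n_iter = config$mcs_n_iter,
                       seed = derive_seed(config$seed, paste0("mcs_", e)),
                       thresholds = th)
      })
      names(mcs) <- c("Cd", "Pb")
      bundle$mcs <- mcs
      put_json(lapply(mcs, unclass), "mcs_summary.json")
    }
    bundle$files <- files
    write_manifest(bundle)
    class(bundle) <- "pipeline_bundle"
    return(bundle)
  }

  tab <- if (!is.null(config$table)) config$table
  else if (!is.null(config$input)) load_measurements(config$input, "long")
  else {
    sc <- config$sim_config
    sc$seed <- derive_seed(config$seed, "simulate")
    generate_orchard_dataset(sc)
  }
  bundle$table <- tab
  put_path <- file.path(config$outdir, "measurements.csv")
  write_measurements(tab, put_path)
  files <- c(files, put_path)

  leaf_analytes <- config$analytes %||%
    sort(unique(tab$analyte[tab$compartment == "leaf"]))
  elements <- intersect(config$elements,
                        unique(tab$analyte[tab$compartment == "soil"]))

  if ("summaries" %in% config$stages) {
    summ <- do.call(rbind, lapply(leaf_analytes, function(a)
      summarize_sites(tab, a, "leaf")))
    put_csv(summ, "site_summaries.csv")
    bundle$summaries <- summ
  }
  if ("baf" %in% config$stages && length(elements)) {
    recs <- do.call(rbind, lapply(elements, function(e)
      compute_baf(tab, e, config$sim_config$soil_granularity %||% "site")))
    put_csv(recs, "baf_records.csv")
    baf_summ <- do.call(rbind, lapply(elements, function(e) {
      r <- recs[recs$element == e, ]
      m <- tapply(r$baf, r$site_id, mean)
      s <- tapply(r$baf, r$site_id, function(v)
        if (length(v) > 1) stats::sd(v) / sqrt(length(v)) else NA_real_)
      data.frame(site_id = names(m), element = e, mean = as.numeric(m),
                 sem = as.numeric(s), stringsAsFactors = FALSE)
    }))
    put_csv(baf_summ, "baf_site_summaries.csv")
    bundle$baf <- list(records = recs, site_summaries = baf_summ)
  }
  if ("stats" %in% config$stages) {
    anova_rows <- list(); gh_rows <- list()
    for (a in leaf_analytes) {
      sub <- tab[tab$analyte == a & tab$compartment == "leaf" &
                   !is.na(tab$value), ]
      groups <- split(sub$value, sub$site_id)
      groups <- groups[vapply(groups, function(g)
        length(g) >= 2 && stats::var(g) > 0, logical(1))]
      if (length(groups) < 2) next
      wa <- tryCatch(welch_anova(groups), error = function(e) NULL)
      if (is.null(wa)) next
      anova_rows[[a]] <- data.frame(
        analyte = a, f_stat = wa$f_stat, df1 = wa$df1, df2 = wa$df2,
        p = wa$p, sig_code = star_code(wa$p))
      gh <- tryCatch(games_howell(groups), error = function(e) NULL)
      if (!is.null(gh)) gh_rows[[a]] <- cbind(analyte = a, gh)
    }
    bundle$anova <- do.call(rbind, anova_rows)
    bundle$games_howell <- do.call(rbind, gh_rows)
    if (!is.null(bundle$anova)) put_csv(bundle$anova, "welch_anova.csv")
    if (!is.null(bundle$games_howell))
      put_csv(bundle$games_howell, "games_howell.csv")
  }

  feat <- site_feature_matrix(tab, elements)
  ok <- apply(feat, 2, function(v) !anyNA(v) && stats::sd(v) > 0)
  feat <- feat[, ok, drop = FALSE]
  bundle$features <- feat
  put_csv(data.frame(site_id = rownames(feat), feat, check.names = FALSE),
          "site_features.csv")

  if ("correlation" %in% config$stages) {
    cm <- correlation_matrix(feat, "pearson")
    bundle$correlation <- cm
    files <- c(files, file.path(config$outdir, "correlations.csv"))
    write_correlations(cm, file.path(config$outdir, "correlations.csv"))
  }
  if ("pca" %in% config$stages) {
    pca <- pca_fit(feat, standardize = config$standardize,
                   rotate = "varimax", n_components = config$n_components)
    bundle$pca <- pca
    put_csv(data.frame(variable = rownames(pca$loadings), pca$loadings,
                       check.names = FALSE), "pca_loadings.csv")
    put_csv(data.frame(site_id = rownames(pca$scores), pca$scores,
                       check.names = FALSE), "pca_scores.csv")
    put_csv(data.frame(component = seq_along(pca$eigenvalues),
                       eigenvalue = pca$eigenvalues,
                       explained_pct = pca$explained_pct),
            "pca_eigenvalues.csv")
  }
  clusters <- NULL
  if ("hca" %in% config$stages) {
    hca <- hca_ward(feat, standardize = config$standardize)
    clusters <- cut_clusters(hca, min(config$k_clusters, hca$n))
    bundle$hca <- hca
    bundle$clusters <- clusters
    put_csv(data.frame(a = hca$merge[, 1], b = hca$merge[, 2],
                       height = hca$height), "hca_merges.csv")
    put_csv(data.frame(site_id = names(clusters), cluster = clusters),
            "hca_clusters.csv")
  }
  if ("lda" %in% config$stages && !is.null(clusters) &&
      length(unique(clusters)) >= 2 && min(table(clusters)) >= 2) {
    Z <- if (config$standardize)
      scale(feat) else feat
    lda <- tryCatch(
      lda_stepwise(Z, clusters[rownames(feat)],
                   alpha_enter = config$alpha_enter),
      error = function(e) NULL, warning = function(w) NULL)
    bundle$lda <- lda
    if (!is.null(lda) && lda$status == "ok") {
      put_csv(data.frame(variable = lda$selected_vars,
                         wilks_lambda = lda$wilks_lambda_path,
                         f_to_enter = lda$f_to_enter,
                         p_to_enter = lda$p_to_enter), "lda_path.csv")
      put_csv(data.frame(variable = rownames(lda$loadings), lda$loadings,
                         check.names = FALSE), "lda_loadings.csv")
    }
  }
  if ("plsr" %in% config$stages) {
    preds <- intersect(paste0("soil_", c("Cd", "Pb", "Zn", "Ni")),
                       colnames(feat))
    resps <- intersect(c("N", "P", "K", "Ca", "Mg", "Cd", "Pb", "SPAD",
                         "Chl_a"), colnames(feat))
    if (length(preds) >= 1 && length(resps) >= 1) {
      pls <- plsr_fit(feat[, preds, drop = FALSE],
                      feat[, resps, drop = FALSE],
                      n_components = min(config$n_components, length(preds)))
      bundle$plsr <- pls
      put_csv(data.frame(response = names(pls$r2_per_response),
                         r2 = as.numeric(pls$r2_per_response)),
              "plsr_r2.csv")
      meas_pred <- data.frame(site_id = rep(rownames(feat), length(resps)),
                              response = rep(resps, each = nrow(feat)),
                              measured = as.vector(feat[, resps]),
                              predicted = as.vector(pls$fitted))
      put_csv(meas_pred, "plsr_measured_vs_predicted.csv")
    }
  }
  if ("mcs" %in% config$stages) {
    th <- default_thresholds(config$threshold_set)
    vars <- list(
      `BAF_Cd` = "BAF_Cd", `BAF_Pb` = "BAF_Pb", Cd = "Cd", Pb = "Pb",
      SPAD = "SPAD", Chl_a = "Chl_a")
    mcs <- list()
    for (v in names(vars)) {
      if (!(vars[[v]] %in% colnames(feat))) next
      vals <- if (config$mcs_granularity == "site_means")
        feat[, vars[[v]]]
      else {
        a <- sub("^BAF_", "", v)
        if (grepl("^BAF_", v)) bundle$baf$records$baf[
          bundle$baf$records$element == a]
        else tab$value[tab$analyte == v & tab$compartment == "leaf"]
      }
      vals <- vals[!is.na(vals) & vals > 0]
      if (length(vals) < 2) next
      elem <- sub("^BAF_", "", v)
      fit <- fit_lognormal(vals, variable = if (grepl("^BAF", v)) v else elem,
                           granularity = config$mcs_granularity)
      fit$variable <- elem  # threshold matching on the element name
      sim <- run_simulation(fit, n_iter = config$mcs_n_iter,
                            seed = derive_seed(config$seed,
                                               paste0("mcs_", v)),
                            thresholds = if (grepl("^BAF", v)) NULL else th)
      sim$variable <- v
      mcs[[v]] <- list(fit = unclass(fit), summary = unclass(sim))
    }
    bundle$mcs <- mcs
    put_json(mcs, "mcs_summary.json")
  }
  bundle$files <- files
  write_manifest(bundle)
  class(bundle) <- "pipeline_bundle"
  bundle
}

# Manifest: canonical config dump + md5 per artifact; no timestamps so a
# rerun with the same config and seed is hash-identical.
write_manifest <- function(bundle) {
  cf <- bundle$config
  cf_dump <- cf[setdiff(names(cf), c("table", "outdir"))]
  cf_dump$sim_config <- if (!is.null(cf$sim_config)) unclass(cf$sim_config)
  manifest <- list(
    package = "soil2leaf",
    version = as.character(utils::packageVersion("soil2leaf")),
    seed = cf$seed,
    config = cf_dump,
    artifacts = lapply(stats::setNames(bundle$files,
                                       basename(bundle$files)),
                       function(f) unname(tools::md5sum(f))))
  jsonlite::write_json(manifest, file.path(cf$outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}

#' Render a markdown report (with optional figures) from a pipeline bundle
#'
#' Writes `report.md` plus, when `figures = TRUE`, PDF figures (dendrogram,
#' PCA biplot, measured-vs-predicted panels, MCS histograms). Stages absent
#' from the bundle are marked "not run". Figures are excluded from the
#' manifest hashes (PDF embeds timestamps).
#'
#' @param bundle a [run_pipeline()] result.
#' @param path output markdown path (default `report.md` in the bundle's
#'   outdir).
#' @param figures also render PDF figures.
#' @return path to the markdown report, invisibly.
#' @export
write_report <- function(bundle, path = NULL, figures = TRUE) {
  outdir <- bundle$config$outdir %||% dirname(path %||% stop("need path"))
  path <- path %||% file.path(outdir, "report.md")
  con <- file(path, "w"); on.exit(close(con))
  w <- function(...) writeLines(sprintf(...), con)
  md_table <- function(df, digits = 3) {
    fmt <- vapply(df, function(col)
      if (is.numeric(col)) as.character(round_half_up(col, digits))
      else as.character(col), character(nrow(df))) |>
      matrix(nrow = nrow(df))
    w("| %s |", paste(names(df), collapse = " | "))
    w("| %s |", paste(rep("---", ncol(df)), collapse = " | "))
    for (i in seq_len(nrow(df))) w("| %s |", paste(fmt[i, ], collapse = " | "))
    w("")
  }
  w("# Soil-to-leaf transfer analysis report\n")
  if (!is.null(bundle$grand_means)) {
    w("## Grand means (fixture tables)\n")
    md_table(bundle$grand_means$leaf)
    md_table(bundle$grand_means$baf)
  }
  w("## Site summaries\n")
  if (is.null(bundle$summaries)) w("not run\n") else
    md_table(utils::head(bundle$summaries, 20), 4)
  w("## Bioaccumulation factors\n")
  if (is.null(bundle$baf)) w("not run\n") else
    md_table(utils::head(bundle$baf$site_summaries, 20), 3)
  w("## Welch ANOVA across sites\n")
  if (is.null(bundle$anova)) w("not run\n") else md_table(bundle$anova, 4)
  w("## PCA\n")
  if (is.null(bundle$pca)) w("not run\n") else {
    k <- ncol(bundle$pca$loadings)
    w("Explained variance (unrotated, %%): %s\n",
      paste(sprintf("%.2f", bundle$pca$explained_pct[seq_len(k)]),
            collapse = ", "))
    md_table(data.frame(variable = rownames(bundle$pca$loadings),
                        bundle$pca$loadings, check.names = FALSE))
  }
  w("## Ward clustering\n")
  if (is.null(bundle$clusters)) w("not run\n") else
    md_table(data.frame(site_id = names(bundle$clusters),
                        cluster = as.integer(bundle$clusters)))
  w("## Stepwise LDA\n")
  if (is.null(bundle$lda) || bundle$lda$status != "ok") w("not run\n") else
    md_table(data.frame(variable = bundle$lda$selected_vars,
                        wilks_lambda = bundle$lda$wilks_lambda_path))
  w("## PLSR\n")
  if (is.null(bundle$plsr)) w("not run\n") else
    md_table(data.frame(response = names(bundle$plsr$r2_per_response),
                        r2 = as.numeric(bundle$plsr$r2_per_response)))
  w("## Monte Carlo exceedance\n")
  if (is.null(bundle$mcs)) w("not run\n") else {
    for (v in names(bundle$mcs)) {
      s <- bundle$mcs[[v]]$summary %||% unclass(bundle$mcs[[v]])
      w("- **%s**: mean %.4g, p95 %.4g%s", v, s$mean, s$percentiles[["p95"]],
        if (length(s$exceedance))
          paste0("; ", paste(sprintf("P(%s) = %.3f", names(s$exceedance),
                                     s$exceedance), collapse = ", "))
        else "")
    }
    w("")
  }
  if (figures) render_figures(bundle, outdir)
  invisible(path)
}

render_figures <- function(bundle, outdir) {
  fig <- function(name, expr) {
    grDevices::pdf(file.path(outdir, name), width = 7, height = 5)
    on.exit(grDevices::dev.off())
    force(expr)
  }
  if (!is.null(bundle$hca))
    fig("dendrogram.pdf", plot(as_hclust(bundle$hca),
                               main = "Ward clustering of sites"))
  if (!is.null(bundle$pca))
    fig("pca_biplot.pdf", {
      sc <- bundle$pca$scores
      plot(sc[, 1], sc[, 2], pch = 19, xlab = "PC1", ylab = "PC2",
           main = "PCA scores")
      graphics::text(sc[, 1], sc[, 2], rownames(sc), pos = 3, cex = 0.7)
    })
  if (!is.null(bundle$plsr))
    fig("plsr_measured_vs_predicted.pdf", {
      r2 <- bundle$plsr$r2_per_response
      yn <- names(r2)
      graphics::par(mfrow = c(ceiling(length(yn) / 3), 3), mar = c(4, 4, 2, 1))
      for (j in yn) {
        meas <- bundle$features[, j]
        pred <- bundle$plsr$fitted[, j]
        plot(meas, pred, pch = 19, xlab = "measured", ylab = "predicted",
             main = sprintf("%s (R2 = %.3f)", j, r2[[j]]))
        graphics::abline(0, 1, lty = 2)
      }
    })
  if (!is.null(bundle$mcs) && length(bundle$mcs))
    fig("mcs_distributions.pdf", {
      graphics::par(mfrow = c(2, 3), mar = c(4, 4, 2, 1))
      for (v in names(bundle$mcs)) {
        s <- bundle$mcs[[v]]$fit %||% NULL
        if (is.null(s)) next
        x <- seq(exp(s$mu_ln - 3 * s$sigma_ln),
                 exp(s$mu_ln + 3 * s$sigma_ln), length.out = 200)
        plot(x, stats::dlnorm(x, s$mu_ln, s$sigma_ln), type = "l",
             xlab = v, ylab = "density", main = v)
      }
    })
  invisible(NULL)
}
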
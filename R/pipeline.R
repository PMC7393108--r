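# End-to-end orchestration: simulate -> extract -> allometry -> stats,
# with a manifest of content hashes for reproducibility checks.

#' Pipeline configuration
#'
#' Assembles the parameters of a full run with sensible defaults.  Any
#' entry can be overridden; unknown names are rejected.
#'
#' @param out_dir Output directory (created if missing).
#' @param clouds_dir Directory of input clouds; `NULL` to simulate.
#' @param n_trees Number of simulated trees (simulate stage).
#' @param n_plots Number of simulated plots (stats stage).
#' @param seed Master integer seed.
#' @param tau Quantile levels of the envelope fits.
#' @param slice_halfwidth,crown_layer,canopy_layer Extraction parameters
#'   (m).
#' @param pca_flip Trait columns negated in the PCA.
#' @param with_lai Run the (slower) gap-fraction LAI per tree.
#' @return A named list of class `pipeline_config`.
#' @export
pipeline_config <- function(out_dir = "treemorph_out", clouds_dir = NULL,
                            n_trees = 30L, n_plots = 36L, seed = 1L,
                            tau = c(0.05, 0.95), slice_halfwidth = 0.05,
                            crown_layer = 0.25, canopy_layer = 0.5,
                            pca_flip = c("ltd", "tdr"), with_lai = FALSE) {
  if (any(tau <= 0 | tau >= 1)) stopf("tau values must be in (0, 1)")
  structure(list(out_dir = out_dir, clouds_dir = clouds_dir,
                 n_trees = as.integer(n_trees), n_plots = as.integer(n_plots),
                 seed = as.integer(seed), tau = tau,
                 slice_halfwidth = slice_halfwidth,
                 crown_layer = crown_layer, canopy_layer = canopy_layer,
                 pca_flip = pca_flip, with_lai = isTRUE(with_lai)),
            class = "pipeline_config")
}

## internal: random but realistic tree parameters for the simulate stage
random_tree_params <- function(i, seed) {
  with_seed(seed + i, {
    h <- runif(1, 4, 14)
    cb <- runif(1, 0.25, 0.5) * h
    rz <- (h - cb) / 2
    rx <- runif(1, 0.8, 3.2)
    ry <- rx * runif(1, 0.85, 1.15)
    d <- runif(1, 0.12, 0.35)
    multi <- runif(1) < 0.3
    stems <- if (multi) c(d, runif(sample(1:2, 1), 0.12, d)) else d
    list(height = cb + 2 * rz, crown_base = cb, dbh = max(stems),
         crown_semi_axes = c(rx, ry, rz), stem_diameters_1m = stems,
         leaf_area_density = runif(1, 0.3, 0.9),
         leaf_point_count = 1500L, seed = seed + 1000L + i)
  })
}

#' Run the full analysis pipeline
#'
#' Executes the stages `simulate` (synthetic forest with ground truth),
#' `extract` (per-tree trait table), `allometry` (quantile envelopes of
#' CA against Height plus the theoretical-curve comparison) and `stats`
#' (correlation matrix, PCA, clustering on a plot table) in order, each
#' skippable, writing all artifacts plus a `manifest.json` of md5 content
#' hashes into `config$out_dir`.
#'
#' @param config A [pipeline_config()].
#' @param stages Character subset of
#'   `c("simulate", "extract", "allometry", "stats")`.
#' @return Invisibly, the manifest (named md5 vector).
#' @export
run_pipeline <- function(config = pipeline_config(),
                         stages = c("simulate", "extract", "allometry",
                                    "stats")) {
  stopifnot(inherits(config, "pipeline_config"))
  stages <- match.arg(stages, several.ok = TRUE)
  out <- config$out_dir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(out, "pipeline.log")
  logf <- function(...) cat(sprintf(...), "\n", sep = "", file = log_path,
                            append = TRUE)
  cat(sprintf("treemorph pipeline, seed %d\n", config$seed),
      file = log_path)

  clouds_dir <- config$clouds_dir
  if ("simulate" %in% stages) {
    clouds_dir <- file.path(out, "clouds")
    dir.create(clouds_dir, showWarnings = FALSE)
    truth_rows <- vector("list", config$n_trees)
    stem_rows <- list()
    for (i in seq_len(config$n_trees)) {
      prm <- random_tree_params(i, config$seed)
      tr <- make_tree(height = prm$height, crown_base = prm$crown_base,
                      dbh = prm$dbh, crown_semi_axes = prm$crown_semi_axes,
                      stem_diameters_1m = prm$stem_diameters_1m,
                      leaf_area_density = prm$leaf_area_density,
                      leaf_point_count = prm$leaf_point_count,
                      trunk_point_spacing = 0.03,
                      seed = prm$seed, tree_id = sprintf("tree_%03d", i))
      write_cloud(tr$cloud, file.path(clouds_dir,
                                      sprintf("tree_%03d.xyz", i)))
      truth_rows[[i]] <- data.frame(
        tree_id = sprintf("tree_%03d", i), height = tr$truth$height,
        crown_base = tr$truth$crown_base, dbh = tr$truth$dbh,
        ca = tr$truth$ca, tdr = tr$truth$tdr)
      stem_rows[[i]] <- data.frame(
        tree_id = sprintf("tree_%03d", i),
        diameter_1m = tr$truth$stem_diameters_1m)
      logf("simulate: tree_%03d (%d points)", i, nrow(tr$cloud$points))
    }
    write.csv(do.call(rbind, truth_rows),
              file.path(out, "ground_truth.csv"), row.names = FALSE)
    write.csv(do.call(rbind, stem_rows), file.path(out, "stems.csv"),
              row.names = FALSE)
  }

  if ("extract" %in% stages) {
    if (is.null(clouds_dir) || !dir.exists(clouds_dir))
      stopf("extract stage: clouds directory not found: %s",
            if (is.null(clouds_dir)) "<unset>" else clouds_dir)
    files <- sort(list.files(clouds_dir, pattern = "\\.(xyz|ply)$",
                             full.names = TRUE))
    if (!length(files)) stopf("extract stage: no clouds in %s", clouds_dir)
    stems_path <- file.path(out, "stems.csv")
    stems <- if (file.exists(stems_path)) read.csv(stems_path) else NULL
    rows <- lapply(files, function(f) {
      cl <- read_cloud(f)
      sd1 <- if (!is.null(stems))
        stems$diameter_1m[stems$tree_id == cl$tree_id] else NULL
      if (!length(sd1)) sd1 <- NULL
      logf("extract: %s", cl$tree_id)
      extract_traits(cl, stem_diameters_1m = sd1,
                     with_lai = config$with_lai,
                     crown_layer = config$crown_layer,
                     canopy_layer = config$canopy_layer)
    })
    write.csv(do.call(rbind, rows), file.path(out, "traits.csv"),
              row.names = FALSE)
  }

  if ("allometry" %in% stages) {
    tp <- file.path(out, "traits.csv")
    if (!file.exists(tp)) stopf("allometry stage: %s not found", tp)
    tr <- read.csv(tp)
    fits <- lapply(config$tau, function(tau)
      fit_power_quantile(tr$height, tr$ca, tau))
    names(fits) <- sprintf("tau_%g", config$tau)
    prop <- fit_proportional(tr$height, tr$ca)
    theory <- lpj_allometry()$ca_height
    jsonlite::write_json(
      c(lapply(fits, unclass),
        list(proportional = unclass(prop),
             theoretical = as.list(theory))),
      file.path(out, "fits.json"), auto_unbox = TRUE, digits = NA)
    grid <- seq(min(tr$height), max(tr$height), length.out = 50L)
    cmp <- compare_envelopes(fits[[1]], theory, grid)
    write.csv(cmp, file.path(out, "envelope_comparison.csv"),
              row.names = FALSE)
    logf("allometry: %d fits on n = %d trees", length(fits), nrow(tr))
  }

  if ("stats" %in% stages) {
    plots_path <- file.path(out, "plots.csv")
    if (!file.exists(plots_path)) {
      eff <- default_effect_matrix()
      pl <- make_plot_table(config$n_plots, eff, seed = config$seed + 7L)
      write.csv(pl, plots_path, row.names = FALSE)
    }
    pl <- read.csv(plots_path)
    em <- env_trait_matrix(pl)
    write.csv(data.frame(env = rownames(em$r),
                         matrix(sprintf("%.3f%s", em$r, em$stars),
                                nrow(em$r), dimnames = dimnames(em$r))),
              file.path(out, "corr_matrix.csv"), row.names = FALSE)
    pca <- pca_traits(pl[, trait_columns()], flip = config$pca_flip)
    write.csv(data.frame(trait = rownames(pca$loadings),
                         round(pca$loadings[, 1:2], 6)),
              file.path(out, "pca_loadings.csv"), row.names = FALSE)
    write.csv(data.frame(plot_id = pl$plot_id, round(pca$scores[, 1:2], 6)),
              file.path(out, "pca_scores.csv"), row.names = FALSE)
    hc <- cluster_traits(pl)
    write.csv(data.frame(step = seq_along(hc$height),
                         left = hc$merge[, 1], right = hc$merge[, 2],
                         height = hc$height),
              file.path(out, "cluster_merges.csv"), row.names = FALSE)
    logf("stats: n = %d plots; PC1 %.1f%%", nrow(pl),
         100 * pca$explained_fraction[1])
  }

  arts <- setdiff(list.files(out, recursive = TRUE), "manifest.json")
  manifest <- tools::md5sum(file.path(out, arts))
  names(manifest) <- arts
  jsonlite::write_json(as.list(manifest), file.path(out, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}

#' Default trait-environment correlation structure for simulations
#'
#' A valid 25 x 25 correlation matrix over
#' `c(trait_columns(), env_columns())` encoding a water-availability
#' gradient: height, DBH, CLR, leaf area and SLA increase with
#' precipitation-related variables, while TDR and leaf tissue density
#' increase with radiation-related variables; the remaining columns are
#' weakly coupled.  Projected to the nearest correlation matrix so it is
#' positive semi-definite by construction.
#'
#' @return A 25 x 25 correlation matrix.
#' @export
default_effect_matrix <- function() {
  cols <- c(trait_columns(), env_columns())
  p <- length(cols)
  M <- diag(p); dimnames(M) <- list(cols, cols)
  set_r <- function(a, b, r) {
    M[a, b] <<- r; M[b, a] <<- r
  }
  wet <- c("map", "aet", "pet", "mat", "cover")
  dry <- c("radiation", "altitude", "pdsi", "bd", "aspect")
  up <- c("height", "clr", "dbh", "la", "sla", "lv")
  down <- c("tdr", "ltd")
  for (w in wet) { for (u in up) set_r(w, u, 0.45); for (d in down) set_r(w, d, -0.4) }
  for (dr in dry) { for (u in up) set_r(dr, u, -0.4); for (d in down) set_r(dr, d, 0.45) }
  for (w in wet) for (dr in dry) set_r(w, dr, -0.35)
  for (a in wet) for (b in setdiff(wet, a)) set_r(a, b, 0.5)
  for (a in dry) for (b in setdiff(dry, a)) set_r(a, b, 0.5)
  for (a in up) for (b in setdiff(up, a)) set_r(a, b, 0.5)
  set_r("tdr", "ltd", 0.4)
  # nearest PSD correlation: clip eigenvalues and renormalize
  ev <- eigen(M, symmetric = TRUE)
  lam <- pmax(ev$values, 1e-6)
  S <- ev$vectors %*% diag(lam) %*% t(ev$vectors)
  D <- diag(1 / sqrt(diag(S)))
  out <- D %*% S %*% D
  out <- (out + t(out)) / 2
  diag(out) <- 1
  dimnames(out) <- list(cols, cols)
  out
}
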
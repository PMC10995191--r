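# End-to-end orchestration: simulate -> plots -> metrics -> fit -> map ->
# validate -> covariance metadata, per site and mapping resolution, with
# one master seed and a run manifest.

#' Assemble a pipeline run configuration
#'
#' @param sites list of \code{\link{site_config}} objects.
#' @param resolutions mapping resolutions in m, subset of c(100, 40).
#' @param n_sim Monte Carlo simulations at both modelling levels.
#' @param veg_threshold vegetation threshold on meanTCH (m); may be a named
#'   vector with per-site overrides.
#' @param buffer_m LOO-CV buffer radius (m).
#' @param scope_threshold_ha site/regional model threshold (ha).
#' @param pools named character vector site_id -> regional pool label (for
#'   sites below the threshold).
#' @param n_bins covariance bins.
#' @param min_valid_frac minimum valid 1-m cell fraction per map pixel.
#' @param seed master integer seed.
#' @return an object of class \code{run_config}.
#' @export
run_config <- function(sites, resolutions = c(100, 40), n_sim = 1000,
                       veg_threshold = 2, buffer_m = 100,
                       scope_threshold_ha = 10, pools = NULL, n_bins = 25,
                       min_valid_frac = 0.9, seed = 1L) {
  stopifnot(length(sites) >= 1,
            all(vapply(sites, inherits, TRUE, "site_config")),
            all(resolutions %in% c(100, 40)),
            n_sim >= 2, buffer_m >= 0, n_bins >= 1,
            min_valid_frac > 0, min_valid_frac <= 1)
  ids <- vapply(sites, `[[`, "", "site_id")
  if (anyDuplicated(ids)) stop("duplicate site ids", call. = FALSE)
  names(sites) <- ids
  structure(
    list(sites = sites, resolutions = resolutions, n_sim = n_sim,
         veg_threshold = veg_threshold, buffer_m = buffer_m,
         scope_threshold_ha = scope_threshold_ha, pools = pools,
         n_bins = n_bins, min_valid_frac = min_valid_frac,
         seed = as.integer(seed)),
    class = "run_config"
  )
}

.res_label <- function(res) if (res == 100) "1ha" else "0.16ha"

.site_veg_threshold <- function(config, site_id) {
  vt <- config$veg_threshold
  if (!is.null(names(vt)) && site_id %in% names(vt)) {
    unname(vt[site_id])
  } else {
    unname(vt[1])
  }
}

.config_digest <- function(config) {
  f <- tempfile()
  on.exit(unlink(f))
  saveRDS(config, f)   # scratch only; digest of the serialized config
  unname(tools::md5sum(f))
}

#' Run the full mapping pipeline
#'
#' Executes, for every site and mapping resolution: synthetic-site
#' generation, plot splitting, wood-density attribution, H-D fitting (site
#' level or pooled by the 10-ha rule), first-level Monte Carlo plot AGB,
#' canopy metrics, mapping-model ensembles (pooled per scope group),
#' AGB/uncertainty maps with bin numbers, buffered LOO-CV, extrapolation
#' accounting and covariance metadata, writing all artifacts under
#' \code{outdir/site/<id>/<resolution>/}. Re-running with an unchanged
#' config and existing outputs is a no-op (digest check) unless
#' \code{force = TRUE}.
#'
#' @param config a \code{\link{run_config}}.
#' @param outdir output directory (created).
#' @param force rerun even when a matching manifest exists.
#' @param quiet suppress per-stage messages.
#' @return the run manifest (list), invisibly written as YAML.
#' @export
run_pipeline <- function(config, outdir, force = FALSE, quiet = FALSE) {
  stopifnot(inherits(config, "run_config"))
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  digest <- .config_digest(config)
  manifest_path <- file.path(outdir, "manifest.yaml")
  if (!force && file.exists(manifest_path)) {
    old <- yaml::read_yaml(manifest_path)
    if (identical(old$config_digest, digest) &&
        all(file.exists(file.path(outdir, unlist(old$files))))) {
      if (!quiet) message("outputs up to date; skipping (use force = TRUE)")
      return(invisible(old))
    }
  }
  say <- function(...) if (!quiet) message(sprintf(...))
  t0 <- Sys.time()
  files <- list(); timings <- list()
  stage <- function(label, site_id, expr) {
    ts <- Sys.time()
    out <- tryCatch(expr, error = function(e) {
      stop(sprintf("stage '%s' failed for site '%s': %s",
                   label, site_id, conditionMessage(e)), call. = FALSE)
    })
    timings[[paste(site_id, label, sep = "/")]] <<-
      as.numeric(difftime(Sys.time(), ts, units = "secs"))
    out
  }

  ids <- names(config$sites)
  # --- scope assignment (10-ha rule) -----------------------------------
  areas <- vapply(config$sites, function(s) {
    s$n_plots * prod(s$plot_shape) / 1e4
  }, 0)
  scopes <- assign_scope(areas, pools = config$pools,
                         threshold_ha = config$scope_threshold_ha)

  # --- simulate sites ---------------------------------------------------
  sites <- list()
  for (id in ids) {
    say("simulating site %s", id)
    sites[[id]] <- stage("simulate", id, gen_site(config$sites[[id]]))
    sdir <- file.path(outdir, "site", id)
    dir.create(sdir, recursive = TRUE, showWarnings = FALSE)
    files[[paste0(id, "_inventory")]] <-
      file.path("site", id, "inventory.csv")
    write_inventory_csv(sites[[id]], file.path(sdir, "inventory.csv"))
    files[[paste0(id, "_plots")]] <- file.path("site", id, "plots.geojson")
    write_plots_geojson(sites[[id]]$plots, file.path(sdir, "plots.geojson"))
  }

  # --- H-D models per scope group --------------------------------------
  hd_models <- list()
  for (grp in unique(scopes$pool)) {
    members <- scopes$site[scopes$pool == grp]
    trees <- do.call(rbind, lapply(members, function(id) sites[[id]]$trees))
    hd_models[[grp]] <- stage("fit_hd", grp, fit_hd(trees))
  }

  results <- list()
  for (res in config$resolutions) {
    lab <- .res_label(res)
    # --- per-site plot AGB and metrics ---------------------------------
    per_site <- list()
    for (id in ids) {
      say("site %s @ %s: plots, first-level MC, metrics", id, lab)
      st <- sites[[id]]
      grp <- scopes$pool[scopes$site == id]
      sp <- stage("split_plots", id,
                  split_plots(st$plots, st$trees, target = res))
      trees <- stage("wood_density", id,
                     assign_wood_density(sp$trees, st$truth$wd_pool))
      drw <- stage("plot_agb_mc", id, plot_agb_mc(
        sp$subplots, trees, hd_models[[grp]],
        n_sim = config$n_sim,
        seed = child_seed(config$seed, paste0("mc-", id, "-", res))))
      pm <- stage("plot_metrics", id, plot_metrics(st$chm, sp$subplots))
      gm <- stage("grid_metrics", id,
                  grid_metrics(st$chm, cell = res,
                               min_valid_frac = config$min_valid_frac))
      per_site[[id]] <- list(split = sp, trees = trees, draws = drw,
                             plot_metrics = pm, grid = gm)
    }
    # --- ensembles per scope group -------------------------------------
    ensembles <- list()
    for (grp in unique(scopes$pool)) {
      members <- scopes$site[scopes$pool == grp]
      dm <- do.call(rbind, lapply(members,
                                  function(id) per_site[[id]]$draws$draws))
      tch <- unlist(lapply(members,
                           function(id) per_site[[id]]$plot_metrics$mean_tch))
      ensembles[[grp]] <- stage("build_ensemble", grp, build_ensemble(
        dm, tch, n_draws = config$n_sim,
        seed = child_seed(config$seed, paste0("ens-", grp, "-", res))))
    }
    # --- maps, validation, covariance per site -------------------------
    for (id in ids) {
      say("site %s @ %s: map, validation, covariance", id, lab)
      grp <- scopes$pool[scopes$site == id]
      ens <- ensembles[[grp]]
      vt <- .site_veg_threshold(config, id)
      ddir <- file.path(outdir, "site", id, lab)
      for (sub in c("maps", "tables", "meta")) {
        dir.create(file.path(ddir, sub), recursive = TRUE,
                   showWarnings = FALSE)
      }
      rel <- function(...) file.path("site", id, lab, ...)
      ps <- per_site[[id]]
      map <- stage("predict_map", id, predict_map(
        ens, ps$grid, veg_threshold = vt,
        seed = child_seed(config$seed, paste0("map-", id, "-", res)),
        keep_stack = TRUE))
      map <- stage("assign_bins", id,
                   assign_bins(map, n_bins = min(config$n_bins,
                                                 length(map$valid_idx))))
      cm <- stage("binned_covariance", id, binned_covariance(map))
      key <- paste(id, lab, sep = "_")
      files[[paste0(key, "_map")]] <- rel("maps", "agb_map.tif")
      write_agb_map(map, file.path(ddir, "maps", "agb_map.tif"))
      files[[paste0(key, "_cov_csv")]] <- rel("meta", "binned_covariance.csv")
      files[[paste0(key, "_cov_yaml")]] <-
        rel("meta", "binned_covariance.yaml")
      write_binned_covariance(cm,
                              file.path(ddir, "meta", "binned_covariance.csv"),
                              file.path(ddir, "meta", "binned_covariance.yaml"))

      # model table (per-group model evaluated for this site's resolution)
      mdl <- ensemble_model(ens, resolution = lab,
                            scope = scopes$scope[scopes$site == id])
      files[[paste0(key, "_model")]] <- rel("tables", "mapping_model.csv")
      write.csv(summary(mdl), file.path(ddir, "tables", "mapping_model.csv"),
                row.names = FALSE)
      files[[paste0(key, "_meta")]] <- rel("meta", "model_metadata.yaml")
      export_model_metadata(
        mdl, ps$trees, ps$draws$agb_ref,
        ps$grid$metrics$mean_tch[map$valid_idx],
        path = file.path(ddir, "meta", "model_metadata.yaml"))

      # buffered LOO-CV on this site's plots (regional models: geometry
      # within the site only; sites are far apart by construction)
      cvd <- data.frame(subplot_id = ps$split$subplots$subplot_id,
                        x0 = ps$split$subplots$x0,
                        y0 = ps$split$subplots$y0,
                        size = ps$split$subplots$size,
                        agb_ref = ps$draws$agb_ref,
                        mean_tch = ps$plot_metrics$mean_tch)
      cvd <- cvd[cvd$agb_ref > 0 & cvd$mean_tch > 0, ]
      cv <- if (nrow(cvd) >= 6) {
        stage("loocv", id, buffered_loocv(cvd, buffer_m = config$buffer_m,
                                          resolution = lab))
      } else NULL
      if (!is.null(cv)) {
        files[[paste0(key, "_cv")]] <- rel("tables", "loocv.csv")
        write.csv(data.frame(site = id, resolution = lab, r2 = cv$r2,
                             rmse = cv$rmse, rmse_pct = cv$rmse_pct,
                             n_folds = nrow(cv$folds),
                             n_skipped = cv$n_skipped),
                  file.path(ddir, "tables", "loocv.csv"), row.names = FALSE)
      }
      ext <- stage("extrapolation", id,
                   extrapolation_mask(ps$grid, mdl, veg_threshold = vt))
      files[[paste0(key, "_extrap")]] <- rel("tables", "extrapolation.csv")
      write.csv(cbind(site = id, resolution = lab, ext$summary),
                file.path(ddir, "tables", "extrapolation.csv"),
                row.names = FALSE)
      smap <- summary(map)
      results[[key]] <- cbind(
        site = id, resolution = lab, scope = scopes$scope[scopes$site == id],
        smap,
        r2_cv = if (is.null(cv)) NA else cv$r2,
        rmse_pct_cv = if (is.null(cv)) NA else cv$rmse_pct,
        pct_below = ext$summary$pct_below,
        pct_within = ext$summary$pct_within,
        pct_above = ext$summary$pct_above
      )
    }
  }
  summary_tab <- do.call(rbind, results)
  files[["summary"]] <- "summary.csv"
  write.csv(summary_tab, file.path(outdir, "summary.csv"), row.names = FALSE)

  manifest <- list(
    package_version = as.character(utils::packageVersion("agbref")),
    r_version = as.character(getRversion()),
    seed = config$seed,
    config_digest = digest,
    resolutions = config$resolutions,
    n_sim = config$n_sim,
    sites = ids,
    files = files,
    timings_s = lapply(timings, function(x) round(x, 3)),
    elapsed_s = round(as.numeric(difftime(Sys.time(), t0, units = "secs")), 2)
  )
  writeLines(yaml::as.yaml(manifest, precision = 15), manifest_path)
  say("pipeline complete in %.1f s", manifest$elapsed_s)
  invisible(manifest)
}

#' Summarise a completed pipeline run
#'
#' Reads the run's written tables back from disk and renders per-site,
#' per-resolution summaries: mapped area, mean AGB, mean CV\%, LOO-CV error
#' statistics and extrapolation shares. Numbers come from the artifacts,
#' not from memory, so the report doubles as a consistency check.
#'
#' @param outdir directory of a completed \code{\link{run_pipeline}} run
#'   (or a manifest list).
#' @return data.frame summary (also printed); missing artifacts are listed.
#' @export
pipeline_report <- function(outdir) {
  manifest_path <- if (is.list(outdir)) NULL else
    file.path(outdir, "manifest.yaml")
  if (!is.null(manifest_path) && !file.exists(manifest_path)) {
    stop("no manifest.yaml under ", outdir, call. = FALSE)
  }
  man <- if (is.list(outdir)) outdir else yaml::read_yaml(manifest_path)
  root <- if (is.list(outdir)) "." else outdir
  missing <- character(0)
  rows <- list()
  for (id in man$sites) {
    for (res in man$resolutions) {
      lab <- .res_label(res)
      key <- paste(id, lab, sep = "_")
      mdl_f <- file.path(root, "site", id, lab, "tables",
                         "mapping_model.csv")
      cv_f <- file.path(root, "site", id, lab, "tables", "loocv.csv")
      ex_f <- file.path(root, "site", id, lab, "tables",
                        "extrapolation.csv")
      map_f <- file.path(root, "site", id, lab, "maps", "agb_map.tif")
      if (!file.exists(map_f)) {
        missing <- c(missing, map_f)
        next
      }
      map <- read_agb_map(map_f)
      smap <- summary(map)
      row <- data.frame(site = id, resolution = lab, smap)
      row$r2_cv <- row$rmse_pct_cv <- NA_real_
      if (file.exists(cv_f)) {
        cv <- read.csv(cv_f)
        row$r2_cv <- cv$r2; row$rmse_pct_cv <- cv$rmse_pct
      } else missing <- c(missing, cv_f)
      if (file.exists(ex_f)) {
        ex <- read.csv(ex_f)
        row$pct_below <- ex$pct_below
        row$pct_within <- ex$pct_within
        row$pct_above <- ex$pct_above
      } else missing <- c(missing, ex_f)
      if (!file.exists(mdl_f)) missing <- c(missing, mdl_f)
      rows[[key]] <- row
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  cat("Pipeline report (", length(rows), " site x resolution maps)\n",
      sep = "")
  print(out, digits = 4)
  if (length(missing)) {
    cat("missing artifacts:\n")
    for (m in missing) cat("  -", m, "\n")
  }
  invisible(out)
}
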
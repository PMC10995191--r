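# Synthetic multi-site forest generator: inventories, plot layouts and
# co-registered 1-m CHMs with known generative parameters, so every
# downstream stage (plot AGB, metrics, mapping models, maps, validation,
# covariance metadata) can be tested against ground truth.

.default_wd_pool <- function() {
  # small invented taxon pool with realistic tropical wood-density spread
  data.frame(
    species = paste0("sp", 1:10),
    genus   = paste0("gen", c(1, 1, 2, 2, 3, 3, 4, 4, 5, 5)),
    family  = paste0("fam", c(1, 1, 1, 2, 2, 2, 3, 3, 3, 3)),
    mean    = c(0.35, 0.42, 0.48, 0.55, 0.58, 0.62, 0.67, 0.72, 0.78, 0.85),
    sd      = rep(0.07, 10),
    stringsAsFactors = FALSE
  )
}

#' Configuration of one synthetic sampling site
#'
#' Bundles every generative parameter of a site: plot layout, the true
#' height-diameter (H-D) law, the true log-log AGB ~ meanTCH mapping law,
#' stem density and diameter distribution, the wood-density taxon pool, and
#' CHM noise. The true parameter values are what downstream recovery tests
#' measure against.
#'
#' @param site_id short site label.
#' @param n_plots number of inventory plots.
#' @param plot_shape c(width, height) of each plot in m (multiples of 20 m).
#' @param hd_true c(a, b, c, sigma) of the H-D law
#'   \eqn{\ln H = a + b \ln D + c (\ln D)^2 + N(0, \sigma)} (D in cm, H in m).
#' @param map_true c(alpha, beta, rse) of the mapping law
#'   \eqn{\ln AGB = \alpha + \beta \ln meanTCH + RE_{site} + N(0, rse)}
#'   (AGB in Mg/ha, meanTCH in m), or \code{NULL} to skip CHM calibration.
#' @param re_site site random intercept of the mapping law (log units).
#' @param stem_density expected stems (D >= 10 cm) per ha.
#' @param dbh_distribution list with Weibull \code{shape}, \code{scale} (cm)
#'   and truncation bounds \code{min}/\code{max} within [10, 250] cm.
#' @param wd_pool data.frame(species, genus, family, mean, sd) of taxa.
#' @param chm_noise_sd per-cell CHM noise SD (m).
#' @param landscape_extent c(cols, rows) of the 1-m landscape grid.
#' @param measured_frac fraction of trees with a field height measurement
#'   (default 0.15, the typical share of height-measured stems).
#' @param plot_gap spacing between neighbouring plots in the deterministic
#'   layout (m, default 100 so distributed plots sit outside one another's
#'   100-m cross-validation buffers).
#' @param density_lnsd SD (log units) of the per-plot lognormal stem-density
#'   multiplier; drives the between-plot AGB range.
#' @param seed site master seed (integer).
#' @return an object of class \code{site_config}.
#' @export
site_config <- function(site_id, n_plots = 10, plot_shape = c(100, 100),
                        hd_true = c(a = -0.5, b = 1.4, c = -0.12, sigma = 0.2),
                        map_true = c(alpha = 2.0, beta = 1.2, rse = 0.1),
                        re_site = 0, stem_density = 450,
                        dbh_distribution = list(shape = 1.1, scale = 14,
                                                min = 10, max = 250),
                        wd_pool = .default_wd_pool(),
                        chm_noise_sd = 0.5,
                        landscape_extent = c(500, 500),
                        measured_frac = 0.15, density_lnsd = 0.4,
                        plot_gap = 100, seed = 1L) {
  stopifnot(length(plot_shape) == 2, all(plot_shape > 0),
            length(landscape_extent) == 2)
  if (stem_density <= 0) stop("stem_density must be > 0", call. = FALSE)
  if (any(plot_shape < 20)) {
    stop("plots must be at least 20 x 20 m (the quadrat unit)", call. = FALSE)
  }
  stopifnot(length(hd_true) == 4, hd_true[4] >= 0)
  if (!is.null(map_true)) stopifnot(length(map_true) == 3, map_true[3] >= 0)
  stop_if_not_scalar_num(chm_noise_sd, "chm_noise_sd", lower = 0)
  stop_if_not_scalar_num(measured_frac, "measured_frac", 0, 1)
  d <- dbh_distribution
  if (d$min < 10 || d$max > 250 || d$min >= d$max) {
    stop("dbh_distribution support must lie within [10, 250] cm", call. = FALSE)
  }
  stopifnot(all(c("species", "genus", "family", "mean", "sd") %in%
                  names(wd_pool)), nrow(wd_pool) >= 1)
  cfg <- list(site_id = site_id, n_plots = n_plots, plot_shape = plot_shape,
              hd_true = unname(hd_true), map_true = unname(map_true),
              re_site = re_site, stem_density = stem_density,
              dbh_distribution = d, wd_pool = wd_pool,
              chm_noise_sd = chm_noise_sd,
              landscape_extent = landscape_extent,
              measured_frac = measured_frac, density_lnsd = density_lnsd,
              plot_gap = plot_gap, seed = as.integer(seed))
  class(cfg) <- "site_config"
  .place_plots(cfg)   # fails early if plots cannot fit
  cfg
}

#' @export
print.site_config <- function(x, ...) {
  cat(sprintf("<site_config> %s: %d plots of %g x %g m in %g x %g m landscape\n",
              x$site_id, x$n_plots, x$plot_shape[1], x$plot_shape[2],
              x$landscape_extent[1], x$landscape_extent[2]))
  cat(sprintf("  H-D truth a=%g b=%g c=%g sigma=%g; ", x$hd_true[1],
              x$hd_true[2], x$hd_true[3], x$hd_true[4]))
  if (is.null(x$map_true)) cat("no mapping law (uncalibrated CHM)\n")
  else cat(sprintf("map truth alpha=%g beta=%g rse=%g\n",
                   x$map_true[1], x$map_true[2], x$map_true[3]))
  invisible(x)
}

# deterministic plot layout: plots on a spaced grid inside the landscape
.place_plots <- function(cfg) {
  w <- cfg$plot_shape[1]; h <- cfg$plot_shape[2]
  gap <- cfg$plot_gap %||% 100
  ex <- cfg$landscape_extent
  per_row <- floor((ex[1] + gap) / (w + gap))
  n_rows <- floor((ex[2] + gap) / (h + gap))
  if (per_row < 1 || per_row * n_rows < cfg$n_plots) {
    stop("landscape_extent too small to hold ", cfg$n_plots, " plots of ",
         w, " x ", h, " m", call. = FALSE)
  }
  k <- seq_len(cfg$n_plots) - 1L
  data.frame(
    plot_id = paste0(cfg$site_id, "-p", sprintf("%02d", k + 1L)),
    x0 = (k %% per_row) * (w + gap),
    y0 = (k %/% per_row) * (h + gap),
    width = w, height = h,
    stringsAsFactors = FALSE
  )
}

# inverse-CDF sampling of a truncated Weibull
.rtrunc_weibull <- function(n, shape, scale, lo, hi) {
  plo <- stats::pweibull(lo, shape, scale)
  phi <- stats::pweibull(hi, shape, scale)
  u <- runif(n, plo, phi)
  stats::qweibull(u, shape, scale)
}

.hd_height <- function(d, a, b, c0) exp(a + b * log(d) + c0 * log(d)^2)

#' Generate the tree inventory of a synthetic site
#'
#' Per plot, the stem count is Poisson(stem density x plot area) after a
#' per-plot lognormal density multiplier; diameters follow the configured
#' truncated Weibull (D >= 10 cm); every tree receives a latent true height
#' from the H-D law with lognormal residual, of which a random
#' \code{measured_frac} subsample is exposed as the field height measurement;
#' taxa are sampled from the wood-density pool; stem positions are uniform
#' within the plot. Deterministic under the config seed.
#'
#' @param config a \code{\link{site_config}}.
#' @return an object of class \code{synthetic_site} with elements
#'   \code{trees} (data.frame), \code{plots} (data.frame), \code{chm}
#'   (\code{NULL} until \code{\link{gen_chm}}), \code{truth} (the config).
#' @export
gen_inventory <- function(config) {
  stopifnot(inherits(config, "site_config"))
  plots <- .place_plots(config)
  with_seed(child_seed(config$seed, "inventory"), {
    area_ha <- config$plot_shape[1] * config$plot_shape[2] / 1e4
    mult <- exp(rnorm(nrow(plots), 0, config$density_lnsd))
    counts <- rpois(nrow(plots), config$stem_density * area_ha * mult)
    dd <- config$dbh_distribution
    hd <- config$hd_true
    tree_list <- lapply(seq_len(nrow(plots)), function(i) {
      n <- counts[i]
      if (n == 0L) return(NULL)
      dbh <- .rtrunc_weibull(n, dd$shape, dd$scale, dd$min, dd$max)
      h_true <- .hd_height(dbh, hd[1], hd[2], hd[3]) *
        exp(rnorm(n, 0, hd[4]))
      taxon <- config$wd_pool[sample.int(nrow(config$wd_pool), n, TRUE), ]
      measured <- runif(n) < config$measured_frac
      data.frame(
        site = config$site_id, plot = plots$plot_id[i],
        x = plots$x0[i] + runif(n, 0, plots$width[i]),
        y = plots$y0[i] + runif(n, 0, plots$height[i]),
        dbh_cm = dbh,
        h_true = h_true,
        h_m = ifelse(measured, h_true, NA_real_),
        species = taxon$species, genus = taxon$genus, family = taxon$family,
        wd_true = taxon$mean,
        stringsAsFactors = FALSE
      )
    })
    trees <- do.call(rbind, tree_list)
    rownames(trees) <- NULL
    structure(list(trees = trees, plots = plots, chm = NULL, truth = config),
              class = "synthetic_site")
  })
}

#' @export
print.synthetic_site <- function(x, ...) {
  cat(sprintf("<synthetic_site> %s: %d trees in %d plots%s\n",
              x$truth$site_id, nrow(x$trees), nrow(x$plots),
              if (is.null(x$chm)) " (no CHM yet)" else ", CHM attached"))
  invisible(x)
}

# stamp paraboloid crowns (apex H, radius 0.5 * D^0.6 m) onto a height grid;
# grid rows follow the map convention (row 1 = top)
.stamp_crowns <- function(vals, x, y, dbh, h, ymax_m) {
  nr <- nrow(vals); nc <- ncol(vals)
  r <- pmax(0.5 * dbh^0.6, 0.6)
  for (k in seq_along(x)) {
    rk <- r[k]
    j0 <- max(1L, floor(x[k] - rk) + 1L); j1 <- min(nc, ceiling(x[k] + rk))
    # row index from y (map convention)
    i_from_y <- function(yy) nr - floor(yy)     # cell containing yy
    i0 <- max(1L, nr - floor(y[k] + rk)); i1 <- min(nr, nr - floor(y[k] - rk))
    if (j0 > j1 || i0 > i1) next
    jj <- j0:j1; ii <- i0:i1
    cx <- jj - 0.5
    cy <- ymax_m - (ii - 0.5)
    d2 <- outer((cy - y[k])^2, (cx - x[k])^2, "+")
    crown <- h[k] * (1 - d2 / rk^2)
    crown[crown < 0] <- 0
    sub <- vals[ii, jj, drop = FALSE]
    upd <- pmax(sub, crown)
    vals[ii, jj] <- upd
  }
  vals
}

#' Generate the 1-m canopy height model of a synthetic site
#'
#' Builds a landscape canopy surface by stamping per-tree paraboloid crowns
#' (apex at the tree's true height, crown radius 0.5 D^0.6 m) for the
#' inventory trees plus Poisson background trees outside the plots, then adds
#' zero-mean Gaussian cell noise clipped at 0. When the site carries a
#' mapping law (\code{map_true}), each plot window of the canopy surface is
#' rescaled so that the plot's meanTCH follows the inverse of
#' \eqn{\ln AGB = \alpha + \beta \ln meanTCH + RE_{site} + N(0, rse)}
#' evaluated at the plot's deterministic tree-sum AGB — this is what makes
#' the generative mapping law recoverable downstream.
#'
#' @param site a \code{synthetic_site} from \code{\link{gen_inventory}}.
#' @param calibrate rescale plot windows to the mapping law (default: yes
#'   whenever \code{map_true} is present).
#' @param background stamp Poisson background trees outside the plots
#'   (default TRUE; disable for controlled single-tree scenes).
#' @return the site with \code{$chm} set (a \code{\link{chm_raster}}).
#' @export
gen_chm <- function(site, calibrate = !is.null(site$truth$map_true),
                    background = TRUE) {
  stopifnot(inherits(site, "synthetic_site"))
  cfg <- site$truth
  ex <- cfg$landscape_extent
  nc <- ex[1]; nr <- ex[2]
  plots <- site$plots
  if (any(plots$x0 + plots$width > nc | plots$y0 + plots$height > nr)) {
    stop("landscape extent too small to contain the plots", call. = FALSE)
  }
  with_seed(child_seed(cfg$seed, "chm"), {
    vals <- matrix(0, nr, nc)
    trees <- site$trees
    if (!is.null(trees) && nrow(trees)) {
      vals <- .stamp_crowns(vals, trees$x, trees$y, trees$dbh_cm,
                            trees$h_true, nr)
    }
    # background canopy outside plots keeps the landscape vegetated
    nbg <- if (background) rpois(1, cfg$stem_density * (nc * nr / 1e4)) else 0L
    if (nbg > 0) {
      dd <- cfg$dbh_distribution; hd <- cfg$hd_true
      bx <- runif(nbg, 0, nc); by <- runif(nbg, 0, nr)
      in_plot <- rep(FALSE, nbg)
      for (i in seq_len(nrow(plots))) {
        in_plot <- in_plot |
          (bx >= plots$x0[i] & bx < plots$x0[i] + plots$width[i] &
           by >= plots$y0[i] & by < plots$y0[i] + plots$height[i])
      }
      keep <- which(!in_plot)
      if (length(keep)) {
        bd <- .rtrunc_weibull(length(keep), dd$shape, dd$scale, dd$min, dd$max)
        bh <- .hd_height(bd, hd[1], hd[2], hd[3]) *
          exp(rnorm(length(keep), 0, hd[4]))
        vals <- .stamp_crowns(vals, bx[keep], by[keep], bd, bh, nr)
      }
    }
    if (calibrate) {
      if (is.null(cfg$map_true)) {
        stop("calibrate = TRUE requires a map_true law in the config",
             call. = FALSE)
      }
      al <- cfg$map_true[1]; be <- cfg$map_true[2]; rse <- cfg$map_true[3]
      eps <- rnorm(nrow(plots), 0, rse)
      for (i in seq_len(nrow(plots))) {
        ii <- (nr - plots$y0[i] - plots$height[i] + 1L):(nr - plots$y0[i])
        jj <- (plots$x0[i] + 1L):(plots$x0[i] + plots$width[i])
        pt <- trees[trees$plot == plots$plot_id[i], , drop = FALSE]
        if (!nrow(pt)) next
        area_ha <- plots$width[i] * plots$height[i] / 1e4
        agb <- sum(tree_agb(pt$dbh_cm, pt$h_true, pt$wd_true)) / 1000 / area_ha
        target <- exp((log(agb) - al - cfg$re_site - eps[i]) / be)
        cur <- mean(vals[ii, jj])
        if (cur > 0) vals[ii, jj] <- vals[ii, jj] * (target / cur)
      }
    }
    if (cfg$chm_noise_sd > 0) {
      vals <- vals + rnorm(length(vals), 0, cfg$chm_noise_sd)
      vals[vals < 0] <- 0
    }
    site$chm <- chm_raster(vals, xmin = 0, ymin = 0, res = 1)
    site
  })
}

#' Generate a complete synthetic site (inventory + CHM)
#'
#' @inheritParams gen_inventory
#' @param ... passed to \code{\link{gen_chm}}.
#' @return a \code{synthetic_site} with trees, plots and CHM.
#' @export
gen_site <- function(config, ...) gen_chm(gen_inventory(config), ...)

#' Write a synthetic inventory to CSV
#'
#' Columns: site, plot, x, y, dbh_cm, h_m, species, genus, family (latent
#' generative fields are dropped).
#' @param site a \code{synthetic_site}.
#' @param path output file.
#' @export
write_inventory_csv <- function(site, path) {
  cols <- c("site", "plot", "x", "y", "dbh_cm", "h_m",
            "species", "genus", "family")
  write.csv(site$trees[, cols], path, row.names = FALSE)
  invisible(path)
}

#' Read a tree inventory CSV
#'
#' Accepts either explicit stem coordinates (columns \code{x}, \code{y}) or
#' 1-based 20-m quadrat indices (\code{qrow}, \code{qcol}), which are
#' converted to quadrat-centroid coordinates.
#' @param path CSV file with columns site, plot, dbh_cm and either x/y or
#'   qrow/qcol; optional h_m, species, genus, family.
#' @return a tree data.frame.
#' @export
read_inventory_csv <- function(path) {
  tr <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("site", "plot", "dbh_cm")
  if (!all(need %in% names(tr))) {
    stop("inventory CSV must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  if (!all(c("x", "y") %in% names(tr))) {
    if (!all(c("qrow", "qcol") %in% names(tr))) {
      stop("inventory CSV needs either x/y or qrow/qcol columns",
           call. = FALSE)
    }
    tr$x <- (tr$qcol - 0.5) * 20
    tr$y <- (tr$qrow - 0.5) * 20
  }
  if (any(tr$dbh_cm < 10, na.rm = TRUE)) {
    warning("dropping ", sum(tr$dbh_cm < 10, na.rm = TRUE),
            " trees with D < 10 cm")
    tr <- tr[is.na(tr$dbh_cm) | tr$dbh_cm >= 10, ]
  }
  tr
}

#' Write plot polygons as GeoJSON
#'
#' @param plots plot data.frame (plot_id, x0, y0, width, height).
#' @param path output file.
#' @export
write_plots_geojson <- function(plots, path) {
  feats <- lapply(seq_len(nrow(plots)), function(i) {
    p <- plots[i, ]
    ring <- list(
      c(p$x0, p$y0), c(p$x0 + p$width, p$y0),
      c(p$x0 + p$width, p$y0 + p$height), c(p$x0, p$y0 + p$height),
      c(p$x0, p$y0)
    )
    list(type = "Feature",
         properties = list(plot_id = p$plot_id),
         geometry = list(type = "Polygon", coordinates = list(ring)))
  })
  jsonlite::write_json(list(type = "FeatureCollection", features = feats),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
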
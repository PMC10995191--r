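# Second-level Monte Carlo: one OLS mapping model per first-level plot-AGB
# realization, parameter uncertainty per model via the exact
# normal-inverse-gamma posterior (flat prior), and per-pixel residual noise
# when predicting over the meanTCH raster.

#' Build the ensemble of mapping models from plot AGB realizations
#'
#' For each first-level realization j of the plot AGB draws, fits
#' \eqn{\ln AGB_j \sim \ln meanTCH} by OLS, then draws \code{n_draws}
#' parameter sets from the exact posterior under a flat prior:
#' \eqn{\sigma^{*2} \sim (n-2) s_j^2 / \chi^2_{n-2}} and
#' \eqn{(a^*, b^*) \sim MVN(\hat\beta_j, \sigma^{*2} (X'X)^{-1})} — the same
#' target an MCMC sampler would converge to, sampled without tuning. Set
#' \code{sampler = "metropolis"} for a random-walk Metropolis chain over the
#' same posterior (fidelity comparisons; thinned to \code{n_draws}).
#'
#' @param draws a \code{\link{plot_agb_draws}} (or matrix n_subplots x n_sim
#'   of AGB realizations, Mg/ha).
#' @param mean_tch per-subplot meanTCH (m), aligned with the draw rows.
#' @param n_draws parameter draws per model (default 1000).
#' @param seed integer seed.
#' @param sampler \code{"exact"} (default) or \code{"metropolis"}.
#' @param min_plots minimum usable plots per realization (default 5).
#' @return an object of class \code{agb_ensemble}: per-realization
#'   coefficients and residual SDs, parameter-draw matrices \code{a_star},
#'   \code{b_star}, \code{rse_star} (n_sim x n_draws), the shared
#'   \eqn{(X'X)^{-1}}, and the meanTCH training range.
#' @export
build_ensemble <- function(draws, mean_tch, n_draws = 1000, seed = NULL,
                           sampler = c("exact", "metropolis"),
                           min_plots = 5) {
  sampler <- match.arg(sampler)
  m <- if (inherits(draws, "plot_agb_draws")) draws$draws else draws
  stopifnot(is.matrix(m), length(mean_tch) == nrow(m))
  ok <- is.finite(mean_tch) & mean_tch > 0 & apply(m > 0, 1, all)
  m <- m[ok, , drop = FALSE]
  x <- log(mean_tch[ok])
  n <- nrow(m); n_sim <- ncol(m)
  if (n < min_plots) {
    stop("fewer than ", min_plots, " usable plots after alignment",
         call. = FALSE)
  }
  X <- cbind(1, x)
  xtx_inv <- solve(crossprod(X))
  # all n_sim OLS fits at once: B is 2 x n_sim
  Y <- log(m)
  B <- xtx_inv %*% crossprod(X, Y)
  resid <- Y - X %*% B
  s2 <- colSums(resid^2) / (n - 2)

  with_seed(seed, {
    if (sampler == "exact") {
      # sigma2* ~ (n-2) s^2 / chisq(n-2); beta* = beta_hat + sigma* L z
      chi <- matrix(rchisq(n_sim * n_draws, df = n - 2), n_sim, n_draws)
      sig2 <- (n - 2) * s2 / chi
      L <- t(chol(xtx_inv))          # L L' = (X'X)^-1
      z1 <- matrix(rnorm(n_sim * n_draws), n_sim, n_draws)
      z2 <- matrix(rnorm(n_sim * n_draws), n_sim, n_draws)
      sg <- sqrt(sig2)
      a_star <- B[1, ] + sg * (L[1, 1] * z1)
      b_star <- B[2, ] + sg * (L[2, 1] * z1 + L[2, 2] * z2)
      rse_star <- sg
    } else {
      a_star <- b_star <- rse_star <- matrix(0, n_sim, n_draws)
      for (j in seq_len(n_sim)) {
        ch <- .metropolis_nig(Y[, j], X, xtx_inv, n_draws)
        a_star[j, ] <- ch$a; b_star[j, ] <- ch$b; rse_star[j, ] <- ch$rse
      }
    }
    structure(
      list(coefs = t(B), sigmas = sqrt(s2),
           a_star = a_star, b_star = b_star, rse_star = rse_star,
           n_plots = n, n_sim = n_sim, n_draws = n_draws,
           xtx_inv = xtx_inv, training_range = range(exp(x)),
           sampler = sampler),
      class = "agb_ensemble"
    )
  })
}

# random-walk Metropolis over (a, b, log sigma) targeting the flat-prior
# posterior of the log-log OLS model; burn-in 500, thinned to n_draws
.metropolis_nig <- function(y, X, xtx_inv, n_draws, burn = 500L, thin = 2L) {
  n <- length(y)
  bhat <- drop(xtx_inv %*% crossprod(X, y))
  s <- sqrt(sum((y - drop(X %*% bhat))^2) / (n - 2))
  logpost <- function(th) {
    r <- y - X %*% th[1:2]
    -n * th[3] - 0.5 * sum(r^2) / exp(2 * th[3])
  }
  step <- c(sqrt(diag(xtx_inv)) * s, 1 / sqrt(2 * n)) * 2.4 / sqrt(3)
  th <- c(bhat, log(s))
  lp <- logpost(th)
  total <- burn + n_draws * thin
  out <- matrix(0, n_draws, 3)
  k <- 0L
  for (i in seq_len(total)) {
    prop <- th + rnorm(3) * step
    lpp <- logpost(prop)
    if (log(runif(1)) < lpp - lp) { th <- prop; lp <- lpp }
    if (i > burn && (i - burn) %% thin == 0L) {
      k <- k + 1L
      out[k, ] <- th
    }
  }
  list(a = out[, 1], b = out[, 2], rse = exp(out[, 3]))
}

#' @export
print.agb_ensemble <- function(x, ...) {
  cat(sprintf("<agb_ensemble> %d models x %d parameter draws (%s sampler)\n",
              x$n_sim, x$n_draws, x$sampler))
  cat(sprintf("  median a = %.3f, b = %.3f, rse = %.3f; %d plots, meanTCH [%.1f, %.1f] m\n",
              stats::median(x$coefs[, 1]), stats::median(x$coefs[, 2]),
              stats::median(x$sigmas), x$n_plots,
              x$training_range[1], x$training_range[2]))
  invisible(x)
}

#' Consolidate an ensemble into a single mapping model
#'
#' Pools the per-realization coefficients: point estimates are the means
#' over realizations, the coefficient covariance is the empirical covariance
#' of the pooled parameter draws (carrying both modelling levels), and sigma
#' the mean residual SD. Used for calibration-domain bookkeeping and
#' metadata export.
#'
#' @param ensemble an \code{agb_ensemble}.
#' @param resolution,scope labels for the resulting model.
#' @return a \code{\link{lidar_agb_model}}.
#' @export
ensemble_model <- function(ensemble, resolution = "1ha", scope = "site") {
  ab <- cbind(as.vector(ensemble$a_star), as.vector(ensemble$b_star))
  lidar_agb_model(
    a = mean(ensemble$coefs[, 1]), b = mean(ensemble$coefs[, 2]),
    sigma = mean(ensemble$sigmas),
    training_range = ensemble$training_range,
    coef_vcov = cov(ab), scope = scope, resolution = resolution
  )
}

#' Predict the AGB map with propagated uncertainty
#'
#' For each ensemble member: one parameter set (a*, b*, RSE*) is selected at
#' random among the member's draws, pixel AGB is predicted on the log scale,
#' an independent residual N(0, RSE*) is added per pixel, and the result is
#' back-transformed with exp. The mean and SD over members form the map's
#' meanAGB and sdAGB layers. Pixels below \code{veg_threshold} are no-data.
#'
#' @param ensemble an \code{\link{agb_ensemble}}.
#' @param tch_raster meanTCH raster (a \code{\link{chm_raster}}-like object,
#'   typically one layer of \code{\link{grid_metrics}} output) or a
#'   \code{metric_stack} (its \code{mean_tch} layer is used).
#' @param veg_threshold vegetation threshold on meanTCH (m, default 2).
#' @param seed integer seed.
#' @param keep_stack retain the n_pixels x n_sim draw stack (needed by the
#'   covariance metadata; memory permitting).
#' @return an object of class \code{agb_map}: \code{mean_agb}, \code{sd_agb}
#'   and \code{nbin} matrices (nbin 0 until \code{\link{assign_bins}}), grid
#'   georeferencing, and optionally \code{draw_stack} with \code{valid_idx}.
#' @export
predict_map <- function(ensemble, tch_raster, veg_threshold = 2,
                        seed = NULL, keep_stack = FALSE) {
  stopifnot(inherits(ensemble, "agb_ensemble"))
  if (inherits(tch_raster, "metric_stack")) {
    tch_raster <- metric_raster(tch_raster, "mean_tch")
  }
  tch <- tch_raster$values
  valid <- !is.na(tch) & tch >= veg_threshold
  if (any(valid & tch <= 0)) {
    stop("vegetated pixel with meanTCH <= 0: inconsistent raster/threshold",
         call. = FALSE)
  }
  idx <- which(valid)
  np <- length(idx)
  if (np == 0) stop("no vegetated pixels above the threshold", call. = FALSE)
  ltch <- log(tch[idx])
  n_sim <- ensemble$n_sim

  with_seed(seed, {
    sum1 <- numeric(np); sum2 <- numeric(np)
    stack <- if (keep_stack) matrix(0, np, n_sim) else NULL
    for (j in seq_len(n_sim)) {
      k <- sample.int(ensemble$n_draws, 1L)
      mu <- ensemble$a_star[j, k] + ensemble$b_star[j, k] * ltch
      rse <- ensemble$rse_star[j, k]
      pred <- exp(mu + if (rse > 0) rnorm(np, 0, rse) else 0)
      sum1 <- sum1 + pred
      sum2 <- sum2 + pred^2
      if (keep_stack) stack[, j] <- pred
    }
    mn <- sum1 / n_sim
    vr <- pmax((sum2 - n_sim * mn^2) / (n_sim - 1), 0)
    mean_agb <- sd_agb <- matrix(NA_real_, nrow(tch), ncol(tch))
    mean_agb[idx] <- mn
    sd_agb[idx] <- sqrt(vr)
    nbin <- matrix(0L, nrow(tch), ncol(tch))
    structure(
      list(mean_agb = mean_agb, sd_agb = sd_agb, nbin = nbin,
           xmin = tch_raster$xmin, ymin = tch_raster$ymin,
           res = tch_raster$res, crs = tch_raster$crs,
           nodata = c(-9999, -9999, 0),
           veg_threshold = veg_threshold, n_sim = n_sim,
           draw_stack = stack, valid_idx = idx),
      class = "agb_map"
    )
  })
}

#' @export
print.agb_map <- function(x, ...) {
  ok <- !is.na(x$mean_agb)
  cat(sprintf("<agb_map> %d x %d pixels @ %g m; %d valid\n",
              nrow(x$mean_agb), ncol(x$mean_agb), x$res, sum(ok)))
  if (any(ok)) {
    cat(sprintf("  meanAGB [%.1f, %.1f] Mg/ha; mean CV %.1f%%\n",
                min(x$mean_agb[ok]), max(x$mean_agb[ok]),
                mean(100 * x$sd_agb[ok] / x$mean_agb[ok])))
  }
  invisible(x)
}

#' @export
summary.agb_map <- function(object, ...) {
  ok <- !is.na(object$mean_agb)
  data.frame(
    n_pixels = sum(ok),
    mean_agb = mean(object$mean_agb[ok]),
    min_agb = min(object$mean_agb[ok]), max_agb = max(object$mean_agb[ok]),
    mean_sd = mean(object$sd_agb[ok]),
    mean_cv_pct = mean(100 * object$sd_agb[ok] / object$mean_agb[ok])
  )
}

#' Coefficient-of-variation raster of an AGB map
#'
#' @param map an \code{agb_map}.
#' @return matrix of per-pixel CV in percent (100 sdAGB / meanAGB).
#' @export
cv_raster <- function(map) {
  stopifnot(inherits(map, "agb_map"))
  100 * map$sd_agb / map$mean_agb
}

#' Write an AGB map as a three-layer GeoTIFF
#'
#' Layers meanAGB and sdAGB (float32, no-data -9999) and Nbin (int16,
#' no-data 0), sharing the map grid.
#'
#' @param map an \code{agb_map}.
#' @param path output file.
#' @export
write_agb_map <- function(map, path) {
  nb <- map$nbin
  nb[nb == 0L] <- NA
  write_geotiff(
    path,
    layers = list(meanAGB = map$mean_agb, sdAGB = map$sd_agb, Nbin = nb),
    formats = c("float32", "float32", "int16"),
    xmin = map$xmin, ymax = map$ymin + nrow(map$mean_agb) * map$res,
    res = map$res, crs = map$crs, nodata = c(-9999, -9999, 0)
  )
}

#' Read a three-layer AGB map GeoTIFF
#'
#' @param path file written by \code{\link{write_agb_map}}.
#' @return an \code{agb_map} (without draw stack).
#' @export
read_agb_map <- function(path) {
  g <- read_geotiff(path)
  if (!all(c("meanAGB", "sdAGB", "Nbin") %in% names(g$layers))) {
    stop("file does not contain the meanAGB/sdAGB/Nbin layers", call. = FALSE)
  }
  nb <- g$layers$Nbin
  nb[is.na(nb)] <- 0L
  storage.mode(nb) <- "integer"
  structure(
    list(mean_agb = g$layers$meanAGB, sd_agb = g$layers$sdAGB, nbin = nb,
         xmin = g$xmin, ymin = g$ymax - nrow(nb) * g$res, res = g$res,
         crs = paste0("EPSG:", g$epsg), nodata = c(-9999, -9999, 0),
         veg_threshold = NA, n_sim = NA, draw_stack = NULL,
         valid_idx = which(!is.na(g$layers$meanAGB))),
    class = "agb_map"
  )
}
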
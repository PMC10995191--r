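# First-level Monte Carlo: propagate diameter, wood-density, height-model
# and allometric-model errors from trees to subplot AGB densities.

#' Configuration of the tree AGB allometry and its error model
#'
#' Holds the pantropical allometry \eqn{AGB = coef0 (WD D^2 H)^{exponent}}
#' and the error-model constants used by \code{\link{plot_agb_mc}}:
#' diameter measurement error (a mixture of small errors with
#' SD = 0.0062 D + 0.0904 cm and, with probability \code{gross_frac}, gross
#' errors with SD = 2.54 cm), bounds for wood density, the residual SD of
#' the allometry on the log scale, the covariance of the allometry
#' parameters (ln coef0, exponent), and the coefficient of variation applied
#' to measured heights during simulation.
#'
#' @param coef0 multiplicative constant (default 0.0673).
#' @param exponent power (default 0.976).
#' @param log_rse residual SD of the allometry on the log scale (0.357).
#' @param coef_vcov 2x2 covariance of (ln coef0, exponent) draws. The
#'   default is built by \code{\link{allometry_coef_vcov}}: exponent SD
#'   0.01 with the intercept anti-correlated through a pivot at
#'   ln(WD D^2 H) = 9.3 (SD 0.08 there), mimicking the strong negative
#'   intercept-slope correlation of regression posteriors so that the
#'   parameter contribution to plot AGB uncertainty stays at the few-percent
#'   level across the realistic size range.
#' @param dbh_error list(mode, small_sd_a, small_sd_b, gross_sd, gross_frac);
#'   mode \code{"chave2004"} or \code{"none"}.
#' @param wd_bounds physical wood-density bounds (g/cm^3).
#' @param height_cv CV of the perturbation applied to measured heights.
#' @return an object of class \code{allometry_config}.
#' @export
allometry_config <- function(coef0 = 0.0673, exponent = 0.976,
                             log_rse = 0.357,
                             coef_vcov = allometry_coef_vcov(),
                             dbh_error = list(mode = "chave2004",
                                              small_sd_a = 0.0062,
                                              small_sd_b = 0.0904,
                                              gross_sd = 2.54,
                                              gross_frac = 0.05),
                             wd_bounds = c(0.08, 1.39),
                             height_cv = 0.05) {
  stopifnot(coef0 > 0, exponent > 0, log_rse >= 0,
            all(dim(coef_vcov) == c(2, 2)),
            dbh_error$gross_frac >= 0, dbh_error$gross_frac <= 1,
            length(wd_bounds) == 2, wd_bounds[1] < wd_bounds[2],
            height_cv >= 0)
  structure(
    list(coef0 = coef0, exponent = exponent, log_rse = log_rse,
         coef_vcov = coef_vcov, dbh_error = dbh_error,
         wd_bounds = wd_bounds, height_cv = height_cv),
    class = "allometry_config"
  )
}

#' Allometry-parameter covariance from a pivot parameterisation
#'
#' Regression posteriors of log-log allometries have strongly
#' anti-correlated intercept and slope; parameter uncertainty is smallest at
#' the calibration-data centroid. This helper builds the 2x2 covariance of
#' (ln coef0, exponent) from the SD of the prediction at a pivot value of
#' \eqn{x = \ln(WD D^2 H)} and the SD of the exponent:
#' \eqn{Var(\ln coef0) = sd_{pivot}^2 + pivot^2 sd_{exp}^2},
#' \eqn{Cov = -pivot \, sd_{exp}^2}.
#'
#' @param sd_pivot SD of the log prediction at the pivot (default 0.08).
#' @param sd_exp SD of the exponent (default 0.01).
#' @param pivot pivot value of ln(WD D^2 H) (default 9.3, a mid-sized
#'   tropical tree).
#' @return 2x2 covariance matrix.
#' @export
allometry_coef_vcov <- function(sd_pivot = 0.08, sd_exp = 0.01,
                                pivot = 9.3) {
  matrix(c(sd_pivot^2 + pivot^2 * sd_exp^2, -pivot * sd_exp^2,
           -pivot * sd_exp^2, sd_exp^2), 2, 2)
}

#' Zero-uncertainty variant of an allometry config
#'
#' All stochastic components switched off; \code{\link{plot_agb_mc}} then
#' collapses to the deterministic tree-sum AGB.
#' @param allom base config.
#' @return an \code{allometry_config} with all error terms zero.
#' @export
allometry_config_exact <- function(allom = allometry_config()) {
  allom$log_rse <- 0
  allom$coef_vcov <- matrix(0, 2, 2)
  allom$dbh_error$mode <- "none"
  allom$height_cv <- 0
  allom
}

# truncated-normal draw by rejection on the fly (vectorised resampling)
.rnorm_trunc <- function(n, mean, sd, lo = -Inf, hi = Inf) {
  x <- rnorm(n, mean, sd)
  bad <- which(x < lo | x > hi)
  it <- 0L
  while (length(bad) && it < 100L) {
    x[bad] <- rnorm(length(bad),
                    if (length(mean) > 1) mean[bad] else mean,
                    if (length(sd) > 1) sd[bad] else sd)
    bad <- bad[x[bad] < lo | x[bad] > hi]
    it <- it + 1L
  }
  if (length(bad)) x[bad] <- pmin(pmax(x[bad], lo), hi)
  x
}

#' Monte Carlo propagation of tree-level errors to subplot AGB
#'
#' For each of \code{n_sim} simulations: diameters are perturbed by the
#' configured measurement-error mixture (truncated at 0.1 cm), wood density
#' drawn from a truncated normal around each tree's attributed value,
#' heights either perturbed (measured trees; CV \code{height_cv}) or
#' predicted from an H-D coefficient draw (multivariate normal around the
#' fitted coefficients) plus a per-tree lognormal residual, and tree AGB
#' computed from an allometry-parameter draw plus per-tree log residual.
#' Tree masses are summed per subplot and converted to Mg/ha; the mean over
#' simulations is the reference AGB (AGB_REF).
#'
#' Trees with a measured height are never routed through the H-D model.
#'
#' @param subplots subplot data.frame from \code{\link{split_plots}}.
#' @param trees tree data.frame with subplot_id, dbh_cm, h_m, wd, wd_sd.
#' @param hd an \code{\link{hd_model}} for trees without height.
#' @param allom an \code{\link{allometry_config}}.
#' @param n_sim number of simulations (default 1000, minimum 2).
#' @param seed integer seed.
#' @return an object of class \code{plot_agb_draws}: \code{subplots},
#'   \code{draws} (n_subplots x n_sim, Mg/ha), \code{agb_ref} (row means),
#'   \code{area_ha}, and \code{empty} flags for treeless subplots.
#' @export
plot_agb_mc <- function(subplots, trees, hd, allom = allometry_config(),
                        n_sim = 1000, seed = NULL) {
  if (n_sim < 2) stop("n_sim must be at least 2", call. = FALSE)
  stopifnot(inherits(hd, "hd_model"), inherits(allom, "allometry_config"))
  if (!all(c("wd", "wd_sd") %in% names(trees))) {
    stop("trees must carry wd and wd_sd (run assign_wood_density first)",
         call. = FALSE)
  }
  ns <- nrow(subplots)
  area_ha <- subplots$size^2 / 1e4
  sub_of_tree <- match(trees$subplot_id, subplots$subplot_id)
  if (any(is.na(sub_of_tree))) {
    stop("trees reference unknown subplot ids", call. = FALSE)
  }
  nt <- nrow(trees)
  measured <- !is.na(trees$h_m)

  with_seed(seed, {
    draws <- matrix(0, ns, n_sim)
    # per-sim coefficient draws (H-D and allometry) are shared by all trees
    hd_cf <- MASS::mvrnorm(n_sim, mu = c(hd$a, hd$b, hd$c),
                           Sigma = hd$coef_vcov)
    al_cf <- MASS::mvrnorm(n_sim, mu = c(log(allom$coef0), allom$exponent),
                           Sigma = allom$coef_vcov)
    de <- allom$dbh_error
    for (s in seq_len(n_sim)) {
      # diameter measurement error
      if (de$mode == "chave2004" && nt > 0) {
        gross <- runif(nt) < de$gross_frac
        sd_d <- ifelse(gross, de$gross_sd,
                       de$small_sd_a * trees$dbh_cm + de$small_sd_b)
        d_s <- pmax(trees$dbh_cm + rnorm(nt, 0, sd_d), 0.1)
      } else {
        d_s <- trees$dbh_cm
      }
      # wood density
      if (any(trees$wd_sd > 0)) {
        wd_s <- .rnorm_trunc(nt, trees$wd, trees$wd_sd,
                             allom$wd_bounds[1], allom$wd_bounds[2])
      } else {
        wd_s <- trees$wd
      }
      # heights
      h_s <- numeric(nt)
      if (any(measured)) {
        hm <- trees$h_m[measured]
        h_s[measured] <- if (allom$height_cv > 0) {
          pmax(hm + rnorm(sum(measured), 0, allom$height_cv * hm), 0.1)
        } else hm
      }
      if (any(!measured)) {
        ld <- log(d_s[!measured])
        lh <- hd_cf[s, 1] + hd_cf[s, 2] * ld + hd_cf[s, 3] * ld^2
        if (hd$sigma > 0) lh <- lh + rnorm(sum(!measured), 0, hd$sigma)
        h_s[!measured] <- exp(lh)
      }
      # allometry with parameter draw and per-tree log residual
      lagb <- al_cf[s, 1] + al_cf[s, 2] * log(wd_s * d_s^2 * h_s)
      if (allom$log_rse > 0) lagb <- lagb + rnorm(nt, 0, allom$log_rse)
      agb_kg <- exp(lagb)
      tot <- rep(0, ns)
      acc <- tapply(agb_kg, sub_of_tree, sum)
      tot[as.integer(names(acc))] <- acc
      draws[, s] <- tot / 1000 / area_ha
    }
    empty <- tabulate(sub_of_tree, nbins = ns) == 0L
    if (any(empty)) {
      message(sum(empty), " subplot(s) hold no trees; their draws are 0")
    }
    structure(
      list(subplots = subplots, draws = draws,
           agb_ref = rowMeans(draws), area_ha = area_ha, empty = empty,
           n_sim = n_sim),
      class = "plot_agb_draws"
    )
  })
}

#' @export
print.plot_agb_draws <- function(x, ...) {
  cat(sprintf("<plot_agb_draws> %d subplots x %d simulations\n",
              nrow(x$draws), ncol(x$draws)))
  cat(sprintf("  AGB_REF range [%.1f, %.1f] Mg/ha; mean within-plot CV %.1f%%\n",
              min(x$agb_ref), max(x$agb_ref),
              100 * mean(apply(x$draws, 1, sd) /
                           pmax(x$agb_ref, .Machine$double.eps))))
  invisible(x)
}

#' Deterministic subplot AGB (no error propagation)
#'
#' Direct summation of the allometry over trees, using measured heights
#' where present and Baskerville-corrected H-D predictions elsewhere;
#' the oracle that \code{\link{plot_agb_mc}} collapses to when every error
#' term is zero (with correction irrelevant at sigma = 0).
#'
#' @inheritParams plot_agb_mc
#' @param correct apply the Baskerville correction to predicted heights.
#' @return numeric vector of subplot AGB (Mg/ha).
#' @export
plot_agb_exact <- function(subplots, trees, hd, allom = allometry_config(),
                           correct = TRUE) {
  sub_of_tree <- match(trees$subplot_id, subplots$subplot_id)
  h <- ifelse(is.na(trees$h_m),
              predict_height(hd, trees$dbh_cm, correct = correct),
              trees$h_m)
  agb_kg <- tree_agb(trees$dbh_cm, h, trees$wd, allom)
  tot <- rep(0, nrow(subplots))
  acc <- tapply(agb_kg, sub_of_tree, sum)
  tot[as.integer(names(acc))] <- acc
  tot / 1000 / (subplots$size^2 / 1e4)
}

#' Persist plot AGB draws as a flat table
#'
#' @param draws a \code{plot_agb_draws}.
#' @param path CSV path; columns subplot, sim, agb.
#' @export
write_agb_draws_csv <- function(draws, path) {
  long <- data.frame(
    subplot = rep(draws$subplots$subplot_id, times = ncol(draws$draws)),
    sim = rep(seq_len(ncol(draws$draws)), each = nrow(draws$draws)),
    agb = as.vector(draws$draws)
  )
  write.csv(long, path, row.names = FALSE)
  invisible(path)
}
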
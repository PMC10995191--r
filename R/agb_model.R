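# Mapping-model specification: mixed-effects screening of canopy metrics
# as AGB predictors, the site/regional log-log mapping model, and the
# 10-ha rule assigning sites to model scope.

.bt_stats <- function(obs, pred_bt) {
  rmse <- sqrt(mean((obs - pred_bt)^2))
  list(
    r2 = 1 - sum((obs - pred_bt)^2) / sum((obs - mean(obs))^2),
    rmse = rmse,
    rmse_pct = 100 * rmse / mean(obs)
  )
}

#' Screen canopy metrics as AGB predictors with mixed-effects models
#'
#' Fits, for each candidate metric (or unordered metric pair when
#' \code{pairs = TRUE}), the model
#' \eqn{\ln AGB_{REF} = a + b \ln LCM (+ b_2 \ln LCM_2) + RE_{site} + \epsilon}
#' by maximum likelihood (ML, so AIC is comparable across fixed-effect
#' structures), ranks candidates by AIC, and reports back-transformed
#' goodness of fit: predictions \eqn{\exp(\hat y + \sigma^2/2)} (residual
#' sigma; plots belong to training sites, so the random intercept is
#' conditioned on), R2 as 1 - SSres/SStot, RMSE in Mg/ha and in percent of
#' the pooled observed mean.
#'
#' Candidates whose fit is singular or whose design is ill-conditioned are
#' flagged and excluded from the ranking rather than failing the screen.
#'
#' @param data data.frame with \code{agb_ref}, \code{site} and the metric
#'   columns (all strictly positive for the candidates used).
#' @param metrics candidate metric column names (default: the 15 canopy
#'   metrics present in \code{data}).
#' @param pairs screen unordered pairs of metrics instead of single metrics.
#' @param condition_cap condition-number cap for pair designs (default 1e8).
#' @return an object of class \code{agb_screen}: the ranked data.frame with
#'   columns candidate, aic, r2_bt, rmse_bt, rmse_pct, flag.
#' @export
screen_lmm <- function(data, metrics = NULL, pairs = FALSE,
                       condition_cap = 1e8) {
  stopifnot(all(c("agb_ref", "site") %in% names(data)))
  if (length(unique(data$site)) < 2) {
    stop("need at least 2 sites to estimate a site random intercept",
         call. = FALSE)
  }
  if (is.null(metrics)) {
    metrics <- intersect(canopy_metric_names(), names(data))
  }
  if (!length(metrics)) stop("no candidate metrics found", call. = FALSE)
  obs <- data$agb_ref
  if (any(obs <= 0)) stop("agb_ref must be > 0", call. = FALSE)

  cands <- if (pairs) {
    cmb <- utils::combn(metrics, 2)
    lapply(seq_len(ncol(cmb)), function(i) cmb[, i])
  } else {
    as.list(metrics)
  }

  fit_one <- function(vars) {
    x <- lapply(vars, function(v) data[[v]])
    if (any(vapply(x, function(z) any(!is.finite(log(z))), TRUE))) {
      return(list(flag = "nonpositive"))
    }
    df <- data.frame(y = log(obs), site = data$site)
    for (i in seq_along(x)) df[[paste0("x", i)]] <- log(x[[i]])
    if (length(vars) == 2) {
      kappa_x <- kappa(cbind(1, df$x1, df$x2), exact = TRUE)
      if (!is.finite(kappa_x) || kappa_x > condition_cap) {
        return(list(flag = "collinear"))
      }
    }
    fml <- stats::as.formula(paste(
      "y ~", paste(paste0("x", seq_along(x)), collapse = " + "), "+ (1 | site)"))
    fit <- tryCatch(
      suppressMessages(lme4::lmer(fml, data = df, REML = FALSE)),
      error = function(e) NULL
    )
    if (is.null(fit)) return(list(flag = "failed"))
    flag <- if (lme4::isSingular(fit, tol = 1e-5)) "singular_re" else ""
    s <- sigma(fit)
    pred_bt <- exp(fitted(fit) + s^2 / 2)
    st <- .bt_stats(obs, pred_bt)
    list(aic = AIC(fit), r2 = st$r2, rmse = st$rmse,
         rmse_pct = st$rmse_pct, flag = flag, fit = fit)
  }

  res <- lapply(cands, fit_one)
  tab <- data.frame(
    candidate = vapply(cands, paste, "", collapse = "+"),
    aic = vapply(res, function(r) r$aic %||% NA_real_, 0),
    r2_bt = vapply(res, function(r) r$r2 %||% NA_real_, 0),
    rmse_bt = vapply(res, function(r) r$rmse %||% NA_real_, 0),
    rmse_pct = vapply(res, function(r) r$rmse_pct %||% NA_real_, 0),
    flag = vapply(res, function(r) r$flag %||% "", ""),
    stringsAsFactors = FALSE
  )
  tab <- tab[order(is.na(tab$aic), tab$aic), ]
  rownames(tab) <- NULL
  structure(tab, class = c("agb_screen", "data.frame"))
}

#' @export
print.agb_screen <- function(x, ...) {
  cat("Canopy-metric screening (ranked by AIC, ML fits):\n")
  print.data.frame(head(as.data.frame(x), 15), digits = 4)
  if (nrow(x) > 15) cat("  ... ", nrow(x) - 15, " more candidates\n")
  invisible(x)
}

#' Fit the log-log AGB mapping model
#'
#' OLS of \eqn{\ln AGB_{REF}} on \eqn{\ln meanTCH} over the plots of one
#' model scope (a site, or a pooled regional set). Stores coefficients and
#' standard errors, the residual SD (log units), the coefficient covariance,
#' the meanTCH training range (the model's calibration domain), and
#' back-transformed calibration statistics.
#'
#' @param data data.frame with \code{agb_ref} (Mg/ha) and \code{mean_tch}
#'   (m), both strictly positive.
#' @param resolution label, e.g. \code{"1ha"} or \code{"0.16ha"}.
#' @param scope \code{"site"} or \code{"regional"}.
#' @param min_plots minimum number of plots (default 5).
#' @return an object of class \code{lidar_agb_model}.
#' @export
fit_mapping_model <- function(data, resolution = "1ha", scope = "site",
                              min_plots = 5) {
  stopifnot(all(c("agb_ref", "mean_tch") %in% names(data)))
  data <- data[complete.cases(data[, c("agb_ref", "mean_tch")]), ]
  if (nrow(data) < min_plots) {
    stop("need at least ", min_plots, " plots (got ", nrow(data), ")",
         call. = FALSE)
  }
  if (any(data$agb_ref <= 0) || any(data$mean_tch <= 0)) {
    stop("agb_ref and mean_tch must be > 0", call. = FALSE)
  }
  fit <- lm(log(agb_ref) ~ log(mean_tch), data = data)
  s <- summary(fit)$sigma
  cf <- unname(coef(fit)); se <- unname(summary(fit)$coefficients[, 2])
  pred_bt <- exp(fitted(fit) + s^2 / 2)
  st <- .bt_stats(data$agb_ref, pred_bt)
  structure(
    list(a = cf[1], b = cf[2], se_a = se[1], se_b = se[2], sigma = s,
         coef_vcov = unname(vcov(fit)), n = nrow(data),
         training_range = range(data$mean_tch),
         scope = scope, resolution = resolution,
         r2_bt = st$r2, rmse_bt = st$rmse, rmse_pct = st$rmse_pct),
    class = "lidar_agb_model"
  )
}

#' Construct a mapping model from known coefficients
#'
#' @param a,b coefficients of \eqn{\ln AGB = a + b \ln meanTCH}.
#' @param sigma residual SD (log units).
#' @param training_range c(min, max) of meanTCH in the training set (m).
#' @param coef_vcov optional 2x2 coefficient covariance.
#' @param scope,resolution labels.
#' @return a \code{lidar_agb_model}.
#' @export
lidar_agb_model <- function(a, b, sigma, training_range,
                            coef_vcov = matrix(0, 2, 2),
                            scope = "site", resolution = "1ha") {
  stopifnot(sigma >= 0, length(training_range) == 2,
            training_range[1] <= training_range[2])
  structure(
    list(a = a, b = b, se_a = sqrt(coef_vcov[1, 1]),
         se_b = sqrt(coef_vcov[2, 2]), sigma = sigma,
         coef_vcov = coef_vcov, n = NA_integer_,
         training_range = training_range, scope = scope,
         resolution = resolution,
         r2_bt = NA_real_, rmse_bt = NA_real_, rmse_pct = NA_real_),
    class = "lidar_agb_model"
  )
}

#' @export
print.lidar_agb_model <- function(x, ...) {
  cat(sprintf("LiDAR-AGB mapping model (%s, %s): ln(AGB) = a + b ln(meanTCH)\n",
              x$scope, x$resolution))
  cat(sprintf("  a = %.3f (%.3f), b = %.3f (%.3f), sigma = %.3f, n = %s\n",
              x$a, x$se_a, x$b, x$se_b, x$sigma, format(x$n)))
  cat(sprintf("  calibration domain: meanTCH in [%.1f, %.1f] m\n",
              x$training_range[1], x$training_range[2]))
  if (!is.na(x$r2_bt)) {
    cat(sprintf("  back-transformed R2 = %.2f, RMSE = %.1f Mg/ha (%.1f%%)\n",
                x$r2_bt, x$rmse_bt, x$rmse_pct))
  }
  invisible(x)
}

#' @export
coef.lidar_agb_model <- function(object, ...) c(a = object$a, b = object$b)

#' @export
vcov.lidar_agb_model <- function(object, ...) object$coef_vcov

#' @export
sigma.lidar_agb_model <- function(object, ...) object$sigma

#' @export
summary.lidar_agb_model <- function(object, ...) {
  data.frame(
    scope = object$scope, resolution = object$resolution,
    a = object$a, se_a = object$se_a, b = object$b, se_b = object$se_b,
    sigma = object$sigma, n = object$n,
    r2_bt = object$r2_bt, rmse_bt = object$rmse_bt,
    rmse_pct = object$rmse_pct,
    tch_min = object$training_range[1], tch_max = object$training_range[2]
  )
}

#' Predict AGB from meanTCH
#'
#' \eqn{\exp(a + b \ln meanTCH)}, with the Baskerville correction
#' \eqn{\exp(\sigma^2/2)} applied by default.
#'
#' @param object a \code{lidar_agb_model}.
#' @param mean_tch meanTCH values (m), > 0.
#' @param correct apply the lognormal back-transformation correction.
#' @param ... unused.
#' @return AGB predictions in Mg/ha.
#' @export
predict.lidar_agb_model <- function(object, mean_tch, correct = TRUE, ...) {
  if (any(mean_tch <= 0)) stop("mean_tch must be > 0", call. = FALSE)
  out <- exp(object$a + object$b * log(mean_tch))
  if (correct) out <- out * exp(object$sigma^2 / 2)
  out
}

#' Assign sites to model scope by the 10-ha rule
#'
#' Sites with a cumulated inventory area of at least \code{threshold_ha}
#' (default 10 ha, boundary inclusive) get their own site-level model;
#' smaller sites must belong to a configured regional pool sharing one
#' pooled model.
#'
#' @param areas named numeric vector: cumulated inventory area per site (ha).
#' @param pools named character vector mapping site ids to a regional pool
#'   label (only consulted for sites below the threshold).
#' @param threshold_ha scope threshold (default 10).
#' @return data.frame with site, area_ha, scope (site/regional), pool.
#' @export
assign_scope <- function(areas, pools = NULL, threshold_ha = 10) {
  stopifnot(!is.null(names(areas)), all(areas >= 0))
  scope <- ifelse(areas >= threshold_ha, "site", "regional")
  pool <- names(areas)
  low <- which(scope == "regional")
  pool[low] <- if (is.null(pools)) NA_character_ else
    unname(pools[names(areas)[low]])
  missing_pool <- scope == "regional" & (is.na(pool) | !nzchar(pool))
  if (any(missing_pool)) {
    stop("site(s) below ", threshold_ha, " ha with no regional pool: ",
         paste(names(areas)[missing_pool], collapse = ", "),
         " — configure a pool for them", call. = FALSE)
  }
  data.frame(site = names(areas), area_ha = unname(areas),
             scope = scope, pool = pool,
             row.names = NULL, stringsAsFactors = FALSE)
}
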
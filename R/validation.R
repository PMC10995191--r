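# Technical validation: buffered spatial leave-one-out cross-validation of
# mapping models, and extrapolation-domain accounting against the model's
# meanTCH calibration range.

# distance from a point to an axis-aligned rectangle (0 inside)
.rect_dist <- function(cx, cy, x0, y0, w, h) {
  dx <- pmax(x0 - cx, 0, cx - (x0 + w))
  dy <- pmax(y0 - cy, 0, cy - (y0 + h))
  sqrt(dx^2 + dy^2)
}

#' Buffered leave-one-out cross-validation of a mapping model
#'
#' For each test subplot, every subplot whose polygon intersects the open
#' disc of radius \code{buffer_m} around the test subplot's centre is
#' excluded from training (the test subplot always is) — so at 0.16-ha
#' resolution the sibling subplots of a 1-ha parent are never used to
#' predict one another, and with \code{buffer_m = 0} the procedure reduces
#' to classical LOO. The model is refit on the remainder and the test plot
#' predicted with the Baskerville correction. Test plots whose buffer
#' leaves fewer than \code{min_train} training plots are skipped and
#' counted.
#'
#' @param data data.frame with subplot_id, x0, y0, size (m, metric CRS),
#'   agb_ref and mean_tch.
#' @param buffer_m buffer radius in m (default 100).
#' @param resolution label carried into the result.
#' @param min_train minimum training plots per fold (default 5).
#' @return an object of class \code{cv_result}: fold table (observed,
#'   predicted, n_train), R2 (1 - SSres/SStot on back-transformed values,
#'   may be negative), RMSE (Mg/ha), RMSE (\% of mean observed), skip count.
#' @export
buffered_loocv <- function(data, buffer_m = 100, resolution = "1ha",
                           min_train = 5) {
  need <- c("subplot_id", "x0", "y0", "size", "agb_ref", "mean_tch")
  stopifnot(all(need %in% names(data)))
  n <- nrow(data)
  if (n < 6) stop("need at least 6 plots for buffered LOO-CV", call. = FALSE)
  cx <- data$x0 + data$size / 2; cy <- data$y0 + data$size / 2
  obs <- numeric(0); pred <- numeric(0); ids <- character(0)
  ntr <- integer(0); skipped <- 0L
  for (i in seq_len(n)) {
    d <- .rect_dist(cx[i], cy[i], data$x0, data$y0, data$size, data$size)
    train <- which(d >= buffer_m & seq_len(n) != i)
    if (length(train) < min_train) {
      skipped <- skipped + 1L
      next
    }
    fit <- lm(log(agb_ref) ~ log(mean_tch), data = data[train, ])
    s <- summary(fit)$sigma
    p <- exp(unname(predict(fit, newdata = data[i, ])) + s^2 / 2)
    obs <- c(obs, data$agb_ref[i]); pred <- c(pred, p)
    ids <- c(ids, data$subplot_id[i]); ntr <- c(ntr, length(train))
  }
  if (!length(obs)) stop("every fold was skipped; buffer too large",
                         call. = FALSE)
  st <- .bt_stats(obs, pred)
  structure(
    list(folds = data.frame(subplot_id = ids, observed = obs,
                            predicted = pred, n_train = ntr,
                            stringsAsFactors = FALSE),
         r2 = st$r2, rmse = st$rmse, rmse_pct = st$rmse_pct,
         buffer_m = buffer_m, resolution = resolution,
         n_skipped = skipped),
    class = "cv_result"
  )
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("Buffered LOO-CV (%g m buffer, %s): %d folds%s\n",
              x$buffer_m, x$resolution, nrow(x$folds),
              if (x$n_skipped) paste0(", ", x$n_skipped, " skipped") else ""))
  cat(sprintf("  R2 = %.2f, RMSE = %.1f Mg/ha (%.1f%%)\n",
              x$r2, x$rmse, x$rmse_pct))
  invisible(x)
}

#' Classify map pixels against the model calibration domain
#'
#' Vegetated pixels (meanTCH at or above \code{veg_threshold}) are
#' classified below / within / above the \code{[min, max]} meanTCH range of
#' the model's training set; proportions are reported over vegetated pixels
#' only. The classification raster codes 1 below, 2 within, 3 above, 0
#' no-data/non-vegetated.
#'
#' @param tch_raster meanTCH raster (\code{\link{chm_raster}}-like or a
#'   \code{metric_stack}).
#' @param model a \code{\link{lidar_agb_model}} carrying the training range.
#' @param veg_threshold vegetation threshold in m (default 2; lower it for
#'   savanna-mosaic landscapes).
#' @return list with \code{summary} (data.frame: pct_below, pct_within,
#'   pct_above, n_vegetated, training range, threshold) and \code{raster}
#'   (integer classification matrix).
#' @export
extrapolation_mask <- function(tch_raster, model, veg_threshold = 2) {
  stopifnot(inherits(model, "lidar_agb_model"))
  if (inherits(tch_raster, "metric_stack")) {
    tch_raster <- metric_raster(tch_raster, "mean_tch")
  }
  tch <- tch_raster$values
  veg <- !is.na(tch) & tch >= veg_threshold
  if (!any(veg)) stop("no vegetated pixels at this threshold", call. = FALSE)
  lo <- model$training_range[1]; hi <- model$training_range[2]
  cls <- matrix(0L, nrow(tch), ncol(tch))
  cls[veg & tch < lo] <- 1L
  cls[veg & tch >= lo & tch <= hi] <- 2L
  cls[veg & tch > hi] <- 3L
  nveg <- sum(veg)
  list(
    summary = data.frame(
      pct_below = 100 * sum(cls == 1L) / nveg,
      pct_within = 100 * sum(cls == 2L) / nveg,
      pct_above = 100 * sum(cls == 3L) / nveg,
      n_vegetated = nveg,
      tch_min = lo, tch_max = hi, veg_threshold = veg_threshold
    ),
    raster = cls
  )
}
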
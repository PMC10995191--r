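#' Construct a canopy-height-model raster
#'
#' Lightweight in-memory raster used throughout the package: a numeric matrix
#' on a regular metric grid. Row 1 is the northernmost row (map convention);
#' the centre of cell \code{[i, j]} sits at
#' \code{x = xmin + (j - 0.5) * res}, \code{y = ymin + (nrow - i + 0.5) * res}.
#'
#' @param values numeric matrix of heights (m). \code{NA} marks no-data.
#' @param xmin,ymin coordinates of the lower-left corner of the grid (m).
#' @param res cell size in m (CHMs in this package are 1 m).
#' @param crs free-form CRS tag, e.g. \code{"EPSG:32643"}.
#' @param nodata value used to encode \code{NA} on disk.
#' @return an object of class \code{chm_raster}.
#' @export
chm_raster <- function(values, xmin = 0, ymin = 0, res = 1,
                       crs = "EPSG:32643", nodata = -9999) {
  stopifnot(is.matrix(values), is.numeric(values))
  stop_if_not_scalar_num(res, "res", lower = 1e-9)
  values[!is.na(values) & values == nodata] <- NA_real_
  structure(
    list(values = values, xmin = xmin, ymin = ymin, res = res,
         crs = crs, nodata = nodata),
    class = "chm_raster"
  )
}

#' @export
dim.chm_raster <- function(x) dim(x$values)

#' @export
print.chm_raster <- function(x, ...) {
  v <- x$values
  cat(sprintf("<chm_raster> %d x %d cells @ %g m, origin (%g, %g), crs %s\n",
              nrow(v), ncol(v), x$res, x$xmin, x$ymin, x$crs))
  ok <- !is.na(v)
  if (any(ok)) {
    cat(sprintf("  valid %d/%d cells, range [%.2f, %.2f] m\n",
                sum(ok), length(v), min(v[ok]), max(v[ok])))
  } else {
    cat("  all cells no-data\n")
  }
  invisible(x)
}

# x/y centres of all cells
raster_xy <- function(r) {
  nr <- nrow(r$values); nc <- ncol(r$values)
  list(x = r$xmin + (seq_len(nc) - 0.5) * r$res,
       y = r$ymin + (nr - seq_len(nr) + 0.5) * r$res)
}

# matrix [i, j] indices of cells whose centres fall in [x0, x0+w) x [y0, y0+h)
raster_window_idx <- function(r, x0, y0, w, h) {
  cc <- raster_xy(r)
  j <- which(cc$x >= x0 & cc$x < x0 + w)
  i <- which(cc$y >= y0 & cc$y < y0 + h)
  list(rows = i, cols = j)
}

# extract window values (matrix); error if the window misses the raster
raster_window <- function(r, x0, y0, w, h, require_inside = TRUE) {
  idx <- raster_window_idx(r, x0, y0, w, h)
  if (!length(idx$rows) || !length(idx$cols)) {
    stop("window [", x0, ",", x0 + w, ") x [", y0, ",", y0 + h,
         ") falls outside the raster extent", call. = FALSE)
  }
  if (require_inside &&
      (length(idx$cols) < floor(w / r$res) || length(idx$rows) < floor(h / r$res))) {
    stop("window extends beyond the raster extent", call. = FALSE)
  }
  r$values[idx$rows, idx$cols, drop = FALSE]
}
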
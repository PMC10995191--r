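# Canopy metrics from 1-m CHMs: height percentiles, meanTCH, sdH, CV, QMCH,
# canopy cover fractions and the rumple index, over arbitrary windows,
# regular map grids (100 m / 40 m) and plot footprints.

.metric_names <- c("h40", "h50", "h60", "h70", "h80", "h90", "h98",
                   "mean_tch", "sd_h", "cv", "qmch",
                   "ccf2", "ccf5", "ccf10", "rumple")

#' Names of the 15 canopy metrics
#' @return character vector of metric names.
#' @export
canopy_metric_names <- function() .metric_names

# rumple: 3-D area of the triangulated 1-m surface over planimetric area.
# Corner heights are means of the adjacent valid cells (one-sided at edges);
# each cell quad is split into two triangles. NA cells are excluded from
# both areas.
.rumple <- function(m) {
  nr <- nrow(m); nc <- ncol(m)
  valid <- !is.na(m)
  if (!any(valid)) return(NA_real_)
  # corner grid (nr+1) x (nc+1): mean of adjacent valid cells
  acc <- matrix(0, nr + 1L, nc + 1L)
  cnt <- matrix(0L, nr + 1L, nc + 1L)
  m0 <- m; m0[!valid] <- 0
  v <- valid * 1L
  for (di in 0:1) for (dj in 0:1) {
    acc[(1:nr) + di, (1:nc) + dj] <- acc[(1:nr) + di, (1:nc) + dj] + m0
    cnt[(1:nr) + di, (1:nc) + dj] <- cnt[(1:nr) + di, (1:nc) + dj] + v
  }
  corner <- ifelse(cnt > 0, acc / pmax(cnt, 1L), NA_real_)
  c00 <- corner[1:nr, 1:nc]; c01 <- corner[1:nr, 2:(nc + 1L)]
  c10 <- corner[2:(nr + 1L), 1:nc]; c11 <- corner[2:(nr + 1L), 2:(nc + 1L)]
  # triangle (p1,p2,p3) area with unit horizontal offsets:
  # A = 0.5 * |(e1 x e2)|, e1/e2 edge vectors in 3-D
  tri_area <- function(z1, z2, z3, e1xy, e2xy) {
    # cross product of e1 = (e1xy, z2 - z1), e2 = (e2xy, z3 - z1)
    dz1 <- z2 - z1; dz2 <- z3 - z1
    nx <- e1xy[2] * dz2 - dz1 * e2xy[2]
    ny <- dz1 * e2xy[1] - e1xy[1] * dz2
    nz <- e1xy[1] * e2xy[2] - e1xy[2] * e2xy[1]
    0.5 * sqrt(nx^2 + ny^2 + nz^2)
  }
  # quad corners: c00 at (0,0), c10 at (0,1)?? use (row, col) -> (x=col, y=row)
  # triangle 1: c00 (0,0), c10 (0,1), c11 (1,1); triangle 2: c00, c11, c01
  a1 <- tri_area(c00, c10, c11, c(0, 1), c(1, 1))
  a2 <- tri_area(c00, c11, c01, c(1, 1), c(1, 0))
  surf <- sum((a1 + a2)[valid])
  surf / sum(valid)
}

#' Compute the 15 canopy metrics over one CHM window
#'
#' Percentiles (H40..H98) use linear interpolation between order statistics;
#' meanTCH is the plain mean; CV = sdH / meanTCH (no-data when meanTCH is
#' 0); QMCH is the quadratic mean; CCFx is the percentage of cells strictly
#' taller than x m; rumple is the triangulated 3-D surface area over the
#' planimetric area (1 for a flat surface).
#'
#' @param window numeric matrix (spatial window; needed for rumple) or
#'   vector of CHM values; \code{NA} marks no-data.
#' @return one-row data.frame with the 15 metrics.
#' @export
compute_metrics <- function(window) {
  v <- as.vector(window)
  v <- v[!is.na(v)]
  if (!length(v)) stop("window holds no valid cells", call. = FALSE)
  qs <- quantile(v, probs = c(.40, .50, .60, .70, .80, .90, .98),
                 names = FALSE, type = 7)
  m <- mean(v)
  s <- if (length(v) > 1) sd(v) else 0
  rum <- if (is.matrix(window)) .rumple(window) else NA_real_
  data.frame(
    h40 = qs[1], h50 = qs[2], h60 = qs[3], h70 = qs[4], h80 = qs[5],
    h90 = qs[6], h98 = qs[7],
    mean_tch = m, sd_h = s,
    cv = if (m > 0) s / m else NA_real_,
    qmch = sqrt(mean(v^2)),
    ccf2 = 100 * mean(v > 2), ccf5 = 100 * mean(v > 5),
    ccf10 = 100 * mean(v > 10),
    rumple = rum
  )
}

#' Aggregate a CHM to a metric raster stack
#'
#' Tiles the CHM into \code{cell} x \code{cell} m output pixels aligned to
#' the CHM origin (partial edge cells are dropped) and computes the 15
#' canopy metrics per pixel. Pixels whose fraction of valid 1-m cells falls
#' below \code{min_valid_frac} are set to no-data.
#'
#' @param chm a \code{\link{chm_raster}} at 1-m resolution.
#' @param cell output cell size in m (100 or 40 in routine use).
#' @param min_valid_frac minimum valid-cell fraction per pixel (default 0.9).
#' @return an object of class \code{metric_stack}: list with \code{metrics}
#'   (named list of matrices), \code{cell}, and grid georeferencing.
#' @export
grid_metrics <- function(chm, cell, min_valid_frac = 0.9) {
  stopifnot(inherits(chm, "chm_raster"))
  if (cell <= 0 || cell != round(cell)) {
    stop("cell must be a positive multiple of 1 m", call. = FALSE)
  }
  k <- as.integer(cell / chm$res)
  nr <- nrow(chm$values); nc <- ncol(chm$values)
  nro <- nr %/% k; nco <- nc %/% k
  if (nro < 1 || nco < 1) {
    stop("CHM extent smaller than one output cell", call. = FALSE)
  }
  out <- lapply(.metric_names, function(nm) matrix(NA_real_, nro, nco))
  names(out) <- .metric_names
  # output rows count from the top; partial bottom rows/right columns drop
  for (io in seq_len(nro)) {
    for (jo in seq_len(nco)) {
      win <- chm$values[((io - 1L) * k + 1L):(io * k),
                        ((jo - 1L) * k + 1L):(jo * k), drop = FALSE]
      frac <- mean(!is.na(win))
      if (frac < min_valid_frac || frac == 0) next
      mt <- compute_metrics(win)
      for (nm in .metric_names) out[[nm]][io, jo] <- mt[[nm]]
    }
  }
  structure(
    list(metrics = out, cell = cell,
         xmin = chm$xmin,
         ymin = chm$ymin + (nr - nro * k) * chm$res,  # top-aligned grid
         res = cell, crs = chm$crs, nodata = chm$nodata),
    class = "metric_stack"
  )
}

#' @export
print.metric_stack <- function(x, ...) {
  d <- dim(x$metrics[[1]])
  cat(sprintf("<metric_stack> %d x %d pixels @ %g m, %d metrics\n",
              d[1], d[2], x$cell, length(x$metrics)))
  invisible(x)
}

# one metric layer as a chm_raster-like object
metric_raster <- function(stack, name) {
  chm_raster(stack$metrics[[name]], xmin = stack$xmin, ymin = stack$ymin,
             res = stack$res, crs = stack$crs, nodata = stack$nodata)
}

#' Canopy metrics over subplot footprints
#'
#' Metrics are computed over CHM cells whose centres fall inside each
#' subplot rectangle (half-open membership, so adjacent subplots never share
#' a cell). A subplot falling outside the CHM is an error.
#'
#' @param chm a \code{\link{chm_raster}}.
#' @param subplots data.frame with subplot_id, x0, y0 and size (or
#'   width/height).
#' @return data.frame: subplot_id plus the 15 metrics, one row per subplot.
#' @export
plot_metrics <- function(chm, subplots) {
  stopifnot(inherits(chm, "chm_raster"))
  w <- subplots$size %||% subplots$width
  h <- subplots$size %||% subplots$height
  rows <- lapply(seq_len(nrow(subplots)), function(i) {
    win <- raster_window(chm, subplots$x0[i], subplots$y0[i], w[i], h[i])
    if (all(is.na(win))) {
      stop("subplot ", subplots$subplot_id[i],
           " holds no valid CHM cells", call. = FALSE)
    }
    cbind(data.frame(subplot_id = subplots$subplot_id[i],
                     stringsAsFactors = FALSE),
          compute_metrics(win))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Rasterise synthetic points by maximum per cell
#'
#' Auxiliary helper for synthetic point sets (not a point-cloud pipeline):
#' the highest point in each 1-m cell becomes the cell value, empty cells 0.
#'
#' @param x,y,z point coordinates (m) and heights (m).
#' @param extent c(cols, rows) of the 1-m grid.
#' @return a \code{\link{chm_raster}}.
#' @export
rasterize_max <- function(x, y, z, extent) {
  nc <- extent[1]; nr <- extent[2]
  vals <- matrix(0, nr, nc)
  j <- floor(x) + 1L
  i <- nr - floor(y)
  ok <- j >= 1L & j <= nc & i >= 1L & i <= nr
  for (k in which(ok)) {
    if (z[k] > vals[i[k], j[k]]) vals[i[k], j[k]] <- z[k]
  }
  chm_raster(vals)
}
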
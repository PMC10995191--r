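# Map-user metadata: equal-frequency pixel bins on meanAGB, the binned
# pairwise-covariance matrix of the Monte Carlo draw stack, a subregion
# mean-AGB uncertainty estimator built from the binned entries, and
# parameter variance-covariance exports for hierarchical-inference users.

#' Assign map pixels to equal-frequency bins
#'
#' Valid pixels are ranked by meanAGB (ties broken by pixel scan order,
#' i.e. matrix column-major linear index) and cut into \code{n_bins}
#' equal-frequency bins numbered 1..n_bins; invalid pixels keep bin 0.
#'
#' @param map an \code{\link{agb_map}}.
#' @param n_bins number of bins (default 25).
#' @return the map with its \code{nbin} layer filled.
#' @export
assign_bins <- function(map, n_bins = 25) {
  stopifnot(inherits(map, "agb_map"))
  idx <- which(!is.na(map$mean_agb))
  nv <- length(idx)
  if (nv < n_bins) {
    stop("fewer valid pixels (", nv, ") than bins (", n_bins, ")",
         call. = FALSE)
  }
  ord <- idx[order(map$mean_agb[idx])]   # order() is stable: scan-order ties
  bin <- as.integer(floor((seq_len(nv) - 1L) * n_bins / nv) + 1L)
  nbin <- matrix(0L, nrow(map$mean_agb), ncol(map$mean_agb))
  nbin[ord] <- bin
  map$nbin <- nbin
  map
}

#' Binned pairwise covariances of the map's Monte Carlo draws
#'
#' Reduces the n_pixels x n_pixels covariance matrix of pixel AGB draws to a
#' bins x bins summary: the between-bin entry (A, B) is the covariance of
#' the two bin means across simulations, which by bilinearity equals the
#' average of all pairwise pixel covariances cov(p, q), p in A, q in B. The
#' within-bin entry excludes the p = q pairs; the averaged within-bin pixel
#' variance is reported separately so the two pieces can be recombined
#' without double counting.
#'
#' @param map an \code{\link{agb_map}} with a filled \code{nbin} layer and a
#'   retained \code{draw_stack} (see \code{predict_map(keep_stack = TRUE)}),
#'   or pass \code{stack} explicitly.
#' @param stack optional n_pixels x n_sim draw matrix aligned with the map's
#'   valid pixels.
#' @return an object of class \code{binned_covariance}: \code{covbar}
#'   (bins x bins, diagonal = within-bin averaged pairwise covariance),
#'   \code{avg_var} (within-bin averaged pixel variance), \code{counts},
#'   \code{edges} (meanAGB range per bin), \code{n_sim}.
#' @export
binned_covariance <- function(map, stack = NULL) {
  stopifnot(inherits(map, "agb_map"))
  stack <- stack %||% map$draw_stack
  if (is.null(stack)) {
    stop("no draw stack: run predict_map(keep_stack = TRUE)", call. = FALSE)
  }
  idx <- map$valid_idx
  if (nrow(stack) != length(idx)) {
    stop("draw stack misaligned with the map's valid pixels", call. = FALSE)
  }
  if (ncol(stack) < 100) {
    stop("need at least 100 simulations for covariance metadata",
         call. = FALSE)
  }
  bins <- map$nbin[idx]
  if (any(bins == 0L)) stop("run assign_bins first", call. = FALSE)
  nb <- max(bins)
  n_sim <- ncol(stack)

  counts <- tabulate(bins, nbins = nb)
  # bin means per simulation (nb x n_sim)
  bm <- rowsum(stack, group = bins) / counts
  C <- cov(t(bm))                       # covariance of bin means
  pixel_var <- apply(stack, 1, var)
  avg_var <- as.vector(rowsum(pixel_var, bins) / counts)
  covbar <- C
  for (b in seq_len(nb)) {
    nbp <- counts[b]
    covbar[b, b] <- if (nbp > 1) {
      (nbp^2 * C[b, b] - nbp * avg_var[b]) / (nbp * (nbp - 1))
    } else 0
  }
  edges <- t(vapply(seq_len(nb), function(b) {
    range(map$mean_agb[idx][bins == b])
  }, numeric(2)))
  colnames(edges) <- c("min_agb", "max_agb")
  structure(
    list(covbar = covbar, avg_var = avg_var, counts = counts,
         edges = edges, n_bins = nb, n_sim = n_sim),
    class = "binned_covariance"
  )
}

#' @export
print.binned_covariance <- function(x, ...) {
  cat(sprintf("<binned_covariance> %d bins over %d pixels, %d simulations\n",
              x$n_bins, sum(x$counts), x$n_sim))
  cat(sprintf("  averaged pixel variance %.2f to %.2f (Mg/ha)^2\n",
              min(x$avg_var), max(x$avg_var)))
  invisible(x)
}

#' Uncertainty of the mean AGB of a map subregion
#'
#' Estimates the standard error of the subregion mean from the binned
#' covariance metadata: \eqn{Var(\bar{AGB}) = n^{-2} [\sum_p
#' \overline{var}(bin_p) + \sum_{p \ne q} \overline{cov}(bin_p, bin_q)]}.
#' With one bin per pixel this reproduces the exact Monte Carlo variance of
#' the subregion mean.
#'
#' @param region logical matrix over the map grid, or integer vector of
#'   pixel (linear) indices; must be a subset of the valid pixels.
#' @param map an \code{\link{agb_map}} with bins assigned.
#' @param cov_meta a \code{\link{binned_covariance}} for the same map.
#' @return list with \code{mean} (Mg/ha), \code{se} (Mg/ha), \code{n_pixels}.
#' @export
subregion_uncertainty <- function(region, map, cov_meta) {
  stopifnot(inherits(map, "agb_map"), inherits(cov_meta, "binned_covariance"))
  idx <- if (is.logical(region)) which(region) else as.integer(region)
  if (!length(idx)) stop("empty region", call. = FALSE)
  if (any(is.na(map$mean_agb[idx]))) {
    stop("region includes invalid (no-data) pixels", call. = FALSE)
  }
  bins <- map$nbin[idx]
  if (any(bins == 0L)) stop("region pixels lack bin numbers", call. = FALSE)
  n <- length(idx)
  m <- tabulate(bins, nbins = cov_meta$n_bins)   # region pixels per bin
  # sum over p != q of covbar(bin_p, bin_q): outer(m, m) pair counts minus
  # the n diagonal self-pairs
  pair_counts <- outer(m, m)
  diag(pair_counts) <- diag(pair_counts) - m
  total <- sum(m * cov_meta$avg_var) + sum(pair_counts * cov_meta$covbar)
  list(mean = mean(map$mean_agb[idx]), se = sqrt(total) / n, n_pixels = n)
}

#' Export model and inventory metadata for hierarchical-inference users
#'
#' Writes (as YAML) the mapping-model coefficient variance-covariance
#' matrix, the model summary, and min/mean/max summaries of tree DBH, plot
#' AGB and pixel meanTCH — the inputs a three-phase hierarchical
#' model-based inference over these maps requires.
#'
#' @param model a \code{\link{lidar_agb_model}} (e.g. from
#'   \code{\link{ensemble_model}}).
#' @param trees inventory tree data.frame (column dbh_cm).
#' @param agb_ref plot AGB values (Mg/ha).
#' @param pixel_tch vector of vegetated-pixel meanTCH values (m).
#' @param path output YAML file, or \code{NULL} to return the list only.
#' @return the metadata list, invisibly when written.
#' @export
export_model_metadata <- function(model, trees, agb_ref, pixel_tch,
                                  path = NULL) {
  stopifnot(inherits(model, "lidar_agb_model"))
  smm <- function(x) {
    x <- x[is.finite(x)]
    list(min = min(x), mean = mean(x), max = max(x), n = length(x))
  }
  meta <- list(
    model = list(
      scope = model$scope, resolution = model$resolution,
      a = model$a, b = model$b, sigma = model$sigma,
      coef_vcov = as.list(as.data.frame(model$coef_vcov)),
      training_range = as.list(setNames(model$training_range,
                                        c("min", "max")))
    ),
    dbh_cm = smm(trees$dbh_cm),
    plot_agb = smm(agb_ref),
    pixel_mean_tch = smm(pixel_tch)
  )
  if (!is.null(path)) {
    writeLines(yaml::as.yaml(meta, precision = 15), path)
    return(invisible(meta))
  }
  meta
}

#' Write a binned covariance matrix as CSV + YAML header
#'
#' @param cov_meta a \code{\link{binned_covariance}}.
#' @param csv_path matrix CSV path.
#' @param yaml_path header YAML (bin counts, edges, averaged variances).
#' @export
write_binned_covariance <- function(cov_meta, csv_path, yaml_path) {
  m <- as.data.frame(cov_meta$covbar)
  names(m) <- paste0("bin", seq_len(cov_meta$n_bins))
  write.csv(cbind(bin = paste0("bin", seq_len(cov_meta$n_bins)), m),
            csv_path, row.names = FALSE)
  hdr <- list(
    n_bins = cov_meta$n_bins, n_sim = cov_meta$n_sim,
    counts = as.list(cov_meta$counts),
    avg_var = as.list(cov_meta$avg_var),
    edges_min = as.list(cov_meta$edges[, 1]),
    edges_max = as.list(cov_meta$edges[, 2])
  )
  writeLines(yaml::as.yaml(hdr, precision = 15), yaml_path)
  invisible(csv_path)
}
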
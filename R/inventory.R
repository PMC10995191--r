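# Inventory processing: plot splitting into subplots, wood-density
# attribution, and the pantropical tree AGB allometry.

#' Split inventory plots into square subplots
#'
#' Tiles each plot into \code{target} x \code{target} m subplots anchored at
#' the plot edges along both axes. When a plot dimension is not a multiple of
#' the target, the residual central band is excluded and its trees dropped
#' (e.g. a 100 x 100 m plot split at 40 m yields four corner subplots and a
#' 20-m wide central cross that is left out). Plots smaller than the target
#' in any dimension are skipped with a warning.
#'
#' @param plots data.frame with plot_id, x0, y0, width, height (m).
#' @param trees tree data.frame with plot, x, y (m, same frame as plots).
#' @param target subplot side in m: 100 (1-ha) or 40 (0.16-ha).
#' @return list with \code{subplots} (subplot_id, plot_id, x0, y0, size),
#'   \code{trees} (input trees restricted to subplots, with subplot_id),
#'   \code{n_plots_skipped}, \code{n_trees_dropped}.
#' @export
split_plots <- function(plots, trees, target = c(100, 40)) {
  target <- match.arg(as.character(target[1]), c("100", "40"))
  target <- as.numeric(target)

  # tile positions along one axis: k tiles anchored from both edges,
  # residual central band excluded
  axis_tiles <- function(len) {
    k <- floor(len / target)
    if (k == 0L) return(numeric(0))
    n_left <- ceiling(k / 2); n_right <- k - n_left
    c((seq_len(n_left) - 1) * target,
      if (n_right > 0) len - rev(seq_len(n_right)) * target)
  }

  sub_list <- list(); skipped <- 0L
  for (i in seq_len(nrow(plots))) {
    p <- plots[i, ]
    if (p$width < target || p$height < target) {
      skipped <- skipped + 1L
      next
    }
    xs <- axis_tiles(p$width); ys <- axis_tiles(p$height)
    grid <- expand.grid(dx = xs, dy = ys)
    sub_list[[length(sub_list) + 1L]] <- data.frame(
      plot_id = p$plot_id,
      x0 = p$x0 + grid$dx, y0 = p$y0 + grid$dy, size = target,
      stringsAsFactors = FALSE
    )
  }
  if (skipped > 0) {
    warning(skipped, " plot(s) smaller than ", target, " m skipped")
  }
  if (!length(sub_list)) {
    stop("no plot large enough for a ", target, " m subplot", call. = FALSE)
  }
  subplots <- do.call(rbind, sub_list)
  subplots$subplot_id <- sprintf("%s_%dm_%02d", subplots$plot_id,
                                 target, stats::ave(seq_len(nrow(subplots)),
                                                    subplots$plot_id,
                                                    FUN = seq_along))
  subplots <- subplots[, c("subplot_id", "plot_id", "x0", "y0", "size")]

  trees$subplot_id <- NA_character_
  for (s in seq_len(nrow(subplots))) {
    sp <- subplots[s, ]
    hit <- trees$plot == sp$plot_id &
      trees$x >= sp$x0 & trees$x < sp$x0 + sp$size &
      trees$y >= sp$y0 & trees$y < sp$y0 + sp$size
    trees$subplot_id[hit] <- sp$subplot_id
  }
  dropped <- sum(is.na(trees$subplot_id) &
                   trees$plot %in% subplots$plot_id)
  keep <- !is.na(trees$subplot_id)
  list(subplots = subplots, trees = trees[keep, , drop = FALSE],
       n_plots_skipped = skipped, n_trees_dropped = dropped)
}

#' Attribute wood density to trees from a reference table
#'
#' Matches each tree at the finest available taxonomic level: exact species
#' match first, then the genus mean, then the family mean; trees that match
#' nowhere receive the mean wood density of the already-assigned trees in
#' their plot (with the table-wide mean SD). Values are clipped to
#' \code{wd_bounds}.
#'
#' @param trees tree data.frame with species/genus/family columns (may hold
#'   \code{NA}).
#' @param wd_table data.frame(species, genus, family, mean, sd) in g/cm^3.
#' @param wd_bounds physical bounds for wood density (g/cm^3).
#' @return trees with columns \code{wd}, \code{wd_sd}, \code{wd_level}.
#' @export
assign_wood_density <- function(trees, wd_table,
                                wd_bounds = c(0.08, 1.39)) {
  if (is.null(wd_table) || nrow(wd_table) == 0) {
    stop("empty wood-density table", call. = FALSE)
  }
  n <- nrow(trees)
  wd <- rep(NA_real_, n); wd_sd <- rep(NA_real_, n)
  lvl <- rep(NA_character_, n)

  sp_idx <- match(trees$species, wd_table$species)
  hit <- !is.na(sp_idx)
  wd[hit] <- wd_table$mean[sp_idx[hit]]
  wd_sd[hit] <- wd_table$sd[sp_idx[hit]]
  lvl[hit] <- "species"

  gen_tab <- aggregate(cbind(mean, sd) ~ genus, wd_table, mean)
  g_idx <- match(trees$genus, gen_tab$genus)
  use <- is.na(wd) & !is.na(g_idx)
  wd[use] <- gen_tab$mean[g_idx[use]]
  wd_sd[use] <- gen_tab$sd[g_idx[use]]
  lvl[use] <- "genus"

  fam_tab <- aggregate(cbind(mean, sd) ~ family, wd_table, mean)
  f_idx <- match(trees$family, fam_tab$family)
  use <- is.na(wd) & !is.na(f_idx)
  wd[use] <- fam_tab$mean[f_idx[use]]
  wd_sd[use] <- fam_tab$sd[f_idx[use]]
  lvl[use] <- "family"

  # plot-level fallback: mean of assigned trees in the plot
  table_sd <- mean(wd_table$sd)
  for (p in unique(trees$plot[is.na(wd)])) {
    in_plot <- trees$plot == p
    assigned <- in_plot & !is.na(wd)
    fallback <- if (any(assigned)) mean(wd[assigned]) else mean(wd_table$mean)
    use <- in_plot & is.na(wd)
    wd[use] <- fallback
    wd_sd[use] <- table_sd
    lvl[use] <- "plot"
  }
  trees$wd <- pmin(pmax(wd, wd_bounds[1]), wd_bounds[2])
  trees$wd_sd <- wd_sd
  trees$wd_level <- lvl
  trees
}

#' Tree aboveground biomass from the pantropical allometry
#'
#' \eqn{AGB = coef0 (WD D^2 H)^{exponent}} in kg, with WD in g/cm^3, D in cm
#' and H in m; the default coefficients are the pantropical model used for
#' tropical reference AGB work.
#'
#' @param dbh diameter at breast height (cm), > 0.
#' @param h tree height (m), > 0.
#' @param wd wood density (g/cm^3), > 0.
#' @param allom an \code{\link{allometry_config}} (defaults used if omitted).
#' @return AGB in kg (vectorised).
#' @examples
#' tree_agb(30, 20, 0.6)   # ~ 581.6 kg
#' @export
tree_agb <- function(dbh, h, wd, allom = allometry_config()) {
  if (any(dbh <= 0 | h <= 0 | wd <= 0, na.rm = TRUE)) {
    stop("dbh, h and wd must all be > 0", call. = FALSE)
  }
  allom$coef0 * (wd * dbh^2 * h)^allom$exponent
}
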
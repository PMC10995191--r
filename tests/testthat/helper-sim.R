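# Shared fixtures built in code: published coefficient tables used as
# generative truths, hand-built plot/tree tables, and small simulators.

# H-D coefficient sets (a, b, c, sigma) of the site-level second-order
# log-log models
hd_truth_table <- function() {
  rbind(
    betul      = c(-1.163, 1.857, -0.194, 0.148),
    achanakmar = c(-1.314, 1.770, -0.159, 0.250),
    yellapur   = c( 0.563, 0.851, -0.050, 0.231),
    uppangala  = c( 0.164, 1.123, -0.077, 0.249),
    khaoyai    = c( 1.094, 0.479,  0.025, 0.329),
    nachtigal  = c(-0.446, 1.457, -0.127, 0.223),
    mbalmayo   = c(-0.081, 1.286, -0.104, 0.243),
    mabounie   = c( 0.283, 1.102, -0.083, 0.236),
    rabi       = c( 1.234, 0.614, -0.022, 0.224)
  )
}

# a hand-built single plot with explicit tree positions
make_one_plot <- function(width = 100, height = 100, id = "p1") {
  data.frame(plot_id = id, x0 = 0, y0 = 0, width = width, height = height,
             stringsAsFactors = FALSE)
}

make_trees <- function(plot_id, x, y, dbh, h = NA, wd = 0.6, wd_sd = 0) {
  n <- length(x)
  data.frame(
    site = "s", plot = plot_id, x = x, y = y, dbh_cm = dbh,
    h_m = rep_len(h, n), species = NA_character_, genus = NA_character_,
    family = NA_character_, wd = rep_len(wd, n), wd_sd = rep_len(wd_sd, n),
    stringsAsFactors = FALSE
  )
}

# simulate a plot table from a log-log mapping law
sim_mapping_data <- function(n = 34, a = 2.043, b = 1.247, sigma = 0.095,
                             tch_range = c(8, 30)) {
  tch <- runif(n, tch_range[1], tch_range[2])
  agb <- exp(a + b * log(tch) + rnorm(n, 0, sigma))
  data.frame(agb_ref = agb, mean_tch = tch)
}

# multi-site screening table: meanTCH is the generative driver, the other
# canopy metrics are noisy monotone transforms of it
sim_screening_data <- function(n_sites = 3, n_plots = 20,
                               alpha = 2, beta = 1.2, rse = 0.15,
                               re_sd = 0.15, nuisance_cv = 0.12) {
  rows <- lapply(seq_len(n_sites), function(s) {
    re <- rnorm(1, 0, re_sd)
    tch <- runif(n_plots, 8, 35)
    agb <- exp(alpha + beta * log(tch) + re + rnorm(n_plots, 0, rse))
    noisy <- function(x) x * exp(rnorm(n_plots, 0, nuisance_cv))
    data.frame(
      site = paste0("site", s), agb_ref = agb, mean_tch = tch,
      h40 = noisy(0.8 * tch), h50 = noisy(0.9 * tch),
      h60 = noisy(1.0 * tch), h70 = noisy(1.1 * tch),
      h80 = noisy(1.2 * tch), h90 = noisy(1.3 * tch),
      h98 = noisy(1.45 * tch),
      sd_h = noisy(0.3 * tch), cv = noisy(5 / tch),
      qmch = noisy(1.05 * tch),
      ccf2 = pmin(noisy(3.2 * tch), 100),
      ccf5 = pmin(noisy(2.8 * tch), 100),
      ccf10 = pmin(noisy(2.2 * tch), 100),
      rumple = noisy(1 + 0.05 * tch),
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, rows)
}

# a degenerate ensemble with fixed parameters (a, b) and residual rse
constant_ensemble <- function(a, b, rse, n_sim = 100, n_draws = 50,
                              training_range = c(5, 40)) {
  structure(
    list(coefs = cbind(rep(a, n_sim), rep(b, n_sim)),
         sigmas = rep(rse, n_sim),
         a_star = matrix(a, n_sim, n_draws),
         b_star = matrix(b, n_sim, n_draws),
         rse_star = matrix(rse, n_sim, n_draws),
         n_plots = 10L, n_sim = n_sim, n_draws = n_draws,
         xtx_inv = diag(2), training_range = training_range,
         sampler = "exact"),
    class = "agb_ensemble"
  )
}

# naive reimplementation of the predict_map draw loop (same RNG order)
predict_map_oracle <- function(ensemble, tch, veg_threshold, seed) {
  valid <- !is.na(tch) & tch >= veg_threshold
  idx <- which(valid)
  ltch <- log(tch[idx])
  np <- length(idx)
  set.seed(as.integer(seed))
  stack <- matrix(0, np, ensemble$n_sim)
  for (j in seq_len(ensemble$n_sim)) {
    k <- sample.int(ensemble$n_draws, 1L)
    mu <- ensemble$a_star[j, k] + ensemble$b_star[j, k] * ltch
    rse <- ensemble$rse_star[j, k]
    stack[, j] <- exp(mu + if (rse > 0) rnorm(np, 0, rse) else 0)
  }
  list(mean = rowMeans(stack), sd = apply(stack, 1, sd), idx = idx,
       stack = stack)
}

# random correlated draw stack (shared multiplier + idiosyncratic noise)
sim_draw_stack <- function(n_px, n_sim, base_range = c(50, 400),
                           shared_sd = 0.1, noise_sd = 0.15) {
  mu <- runif(n_px, base_range[1], base_range[2])
  shared <- rnorm(n_sim, 0, shared_sd)
  stack <- outer(mu, exp(shared)) *
    matrix(exp(rnorm(n_px * n_sim, 0, noise_sd)), n_px, n_sim)
  stack
}

# wrap a draw stack as a minimal agb_map on an nr x nc grid
stack_as_map <- function(stack, nr, nc) {
  stopifnot(nrow(stack) <= nr * nc)
  mean_agb <- matrix(NA_real_, nr, nc)
  idx <- seq_len(nrow(stack))
  mean_agb[idx] <- rowMeans(stack)
  sd_agb <- matrix(NA_real_, nr, nc)
  sd_agb[idx] <- apply(stack, 1, sd)
  structure(
    list(mean_agb = mean_agb, sd_agb = sd_agb,
         nbin = matrix(0L, nr, nc), xmin = 0, ymin = 0, res = 100,
         crs = "EPSG:32643", nodata = c(-9999, -9999, 0),
         veg_threshold = 2, n_sim = ncol(stack), draw_stack = stack,
         valid_idx = idx),
    class = "agb_map"
  )
}
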
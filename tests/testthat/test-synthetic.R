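# Synthetic forest generator: determinism, generative laws, degenerate cases.

test_that("inventories are deterministic under a fixed seed", {
  cfg <- site_config("det", n_plots = 2, plot_shape = c(40, 40),
                     landscape_extent = c(120, 60), plot_gap = 20, seed = 11)
  s1 <- gen_inventory(cfg)
  s2 <- gen_inventory(cfg)
  expect_identical(s1$trees, s2$trees)
  c1 <- gen_chm(s1)
  c2 <- gen_chm(s2)
  expect_identical(c1$chm$values, c2$chm$values)
})

test_that("measured-height fraction controls which trees carry heights", {
  cfg0 <- site_config("f0", n_plots = 1, plot_shape = c(40, 40),
                      landscape_extent = c(60, 60),
                      measured_frac = 0, seed = 3)
  expect_true(all(is.na(gen_inventory(cfg0)$trees$h_m)))
  cfg1 <- site_config("f1", n_plots = 1, plot_shape = c(40, 40),
                      landscape_extent = c(60, 60),
                      measured_frac = 1, seed = 3)
  expect_true(all(!is.na(gen_inventory(cfg1)$trees$h_m)))
})

test_that("noise-free heights follow the configured H-D polynomial exactly", {
  hd <- hd_truth_table()["betul", ]
  cfg <- site_config("hd0", n_plots = 1, plot_shape = c(40, 40),
                     landscape_extent = c(60, 60),
                     hd_true = c(hd[1:3], 0), seed = 5)
  tr <- gen_inventory(cfg)$trees
  expect_equal(tr$h_true,
               exp(hd[1] + hd[2] * log(tr$dbh_cm) + hd[3] * log(tr$dbh_cm)^2),
               tolerance = 1e-12)
  # a 30-cm tree under this law stands ~18.33 m tall
  expect_equal(exp(hd[1] + hd[2] * log(30) + hd[3] * log(30)^2),
               18.3348509773, tolerance = 1e-9)
})

test_that("invalid site configurations are rejected", {
  expect_error(site_config("bad", stem_density = 0), "stem_density")
  expect_error(site_config("bad", plot_shape = c(10, 40)), "20 x 20")
  expect_error(site_config("bad", n_plots = 100,
                           landscape_extent = c(200, 200), plot_gap = 20),
               "too small")
  expect_error(site_config("bad",
                           dbh_distribution = list(shape = 1, scale = 14,
                                                   min = 5, max = 250)),
               "support")
})

test_that("empty scenes and single trees stamp the expected CHM", {
  cfg <- site_config("stamp", n_plots = 1, plot_shape = c(40, 40),
                     landscape_extent = c(60, 60), chm_noise_sd = 0,
                     map_true = NULL, seed = 2)
  site <- gen_inventory(cfg)
  site$trees <- site$trees[0, ]
  empty <- gen_chm(site, background = FALSE)
  expect_true(all(empty$chm$values == 0))
  # one tree at a cell centre: the apex equals the tree height
  site$trees <- make_trees("stamp-p01", x = 20.5, y = 20.5, dbh = 40, h = 20)
  site$trees$h_true <- 20
  site$trees$site <- "stamp"
  one <- gen_chm(site, background = FALSE)
  expect_equal(max(one$chm$values), 20)
  expect_equal(one$chm$values[60 - 20, 21], 20)
})

test_that("plot meanTCH is monotone in the stand height scale", {
  # identical stem maps across plots, heights scaled by a per-plot factor:
  # the uncalibrated CHM's plot meanTCH must increase with the factor
  cfg <- site_config("mono", n_plots = 6, plot_shape = c(40, 40),
                     landscape_extent = c(380, 80), map_true = NULL, plot_gap = 20,
                     chm_noise_sd = 0, seed = 9)
  st <- gen_inventory(cfg)
  base <- st$trees[st$trees$plot == st$plots$plot_id[1], ]
  fac <- c(0.5, 0.8, 1.0, 1.3, 1.6, 2.0)
  st$trees <- do.call(rbind, lapply(seq_len(6), function(i) {
    tr <- base
    tr$plot <- st$plots$plot_id[i]
    tr$x <- tr$x - st$plots$x0[1] + st$plots$x0[i]
    tr$y <- tr$y - st$plots$y0[1] + st$plots$y0[i]
    tr$h_true <- tr$h_true * fac[i]
    tr
  }))
  st <- gen_chm(st, background = FALSE)
  tch <- vapply(seq_len(nrow(st$plots)), function(i) {
    p <- st$plots[i, ]
    mean(agbref:::raster_window(st$chm, p$x0, p$y0, p$width, p$height))
  }, 0)
  expect_true(all(diff(tch) > 0))
})

test_that("the generative mapping slope is recovered from AGB_REF vs meanTCH", {
  cfg <- site_config("slope", n_plots = 50, plot_shape = c(40, 40),
                     landscape_extent = c(600, 300), plot_gap = 20,
                     map_true = c(2.0, 1.2, 0.1), seed = 21)
  st <- gen_site(cfg)
  sp <- split_plots(st$plots, st$trees, 40)
  tr <- assign_wood_density(sp$trees, cfg$wd_pool)
  hd <- fit_hd(st$trees)
  d <- plot_agb_mc(sp$subplots, tr, hd, n_sim = 100, seed = 1)
  pm <- plot_metrics(st$chm, sp$subplots)
  fit <- lm(log(d$agb_ref) ~ log(pm$mean_tch))
  slope <- coef(fit)[2]
  se <- summary(fit)$coefficients[2, 2]
  expect_lt(abs(slope - 1.2), 3 * se)
})

test_that("inventory CSV and plot GeoJSON round-trip", {
  cfg <- site_config("io", n_plots = 2, plot_shape = c(40, 40),
                     landscape_extent = c(120, 60), plot_gap = 20, seed = 4)
  st <- gen_inventory(cfg)
  f <- tempfile(fileext = ".csv")
  write_inventory_csv(st, f)
  back <- read_inventory_csv(f)
  expect_equal(nrow(back), nrow(st$trees))
  expect_equal(back$dbh_cm, st$trees$dbh_cm, tolerance = 1e-9)
  g <- tempfile(fileext = ".geojson")
  write_plots_geojson(st$plots, g)
  gj <- jsonlite::read_json(g)
  expect_equal(length(gj$features), 2L)
  expect_equal(gj$features[[1]]$properties$plot_id, st$plots$plot_id[1])
})

test_that("quadrat-indexed inventories map to quadrat centroids", {
  f <- tempfile(fileext = ".csv")
  write.csv(data.frame(site = "s", plot = "p", dbh_cm = c(15, 30),
                       qrow = c(1, 2), qcol = c(1, 3)),
            f, row.names = FALSE)
  tr <- read_inventory_csv(f)
  expect_equal(tr$x, c(10, 50))
  expect_equal(tr$y, c(10, 30))
})
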
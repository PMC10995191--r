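# Binned pairwise covariances, subregion uncertainty, metadata export.

test_that("equal-frequency bins balance counts and order by meanAGB", {
  stack <- sim_draw_stack(100, 120)
  map <- stack_as_map(stack, 10, 10)
  map <- assign_bins(map, 25)
  counts <- tabulate(map$nbin[map$valid_idx], 25)
  expect_equal(counts, rep(4L, 25))
  # monotone: bin number non-decreasing in meanAGB
  ord <- order(map$mean_agb[map$valid_idx])
  expect_true(all(diff(map$nbin[map$valid_idx][ord]) >= 0))
  expect_error(assign_bins(stack_as_map(stack[1:10, ], 10, 10), 25),
               "fewer valid pixels")
})

test_that("ties are broken by pixel scan order with balanced counts", {
  stack <- matrix(100, 12, 150) + matrix(rnorm(12 * 150), 12, 150)
  map <- stack_as_map(stack, 3, 4)
  map$mean_agb[map$valid_idx] <- 100       # identical pixel means
  map <- assign_bins(map, 4)
  expect_equal(tabulate(map$nbin[map$valid_idx], 4), rep(3L, 4))
  expect_equal(map$nbin[map$valid_idx], rep(1:4, each = 3))
})

test_that("two pixels in two bins reproduce their covariance directly", {
  set.seed(21)
  stack <- sim_draw_stack(2, 300)
  map <- stack_as_map(stack, 1, 2)
  map <- assign_bins(map, 2)
  cm <- binned_covariance(map, stack = stack)
  b1 <- map$nbin[map$valid_idx]
  i <- order(b1)
  expect_equal(cm$covbar[1, 2], cov(stack[i[1], ], stack[i[2], ]),
               tolerance = 1e-12)
  expect_equal(cm$avg_var, apply(stack[i, ], 1, var), tolerance = 1e-12)
  expect_equal(cm$covbar[1, 1], 0)   # single-pixel bin: no p != q pairs
})

test_that("binned entries equal brute-force averaged pairwise covariances", {
  set.seed(33)
  n_px <- 40
  stack <- sim_draw_stack(n_px, 200)
  map <- stack_as_map(stack, 5, 8)
  map <- assign_bins(map, 4)
  cm <- binned_covariance(map)
  bins <- map$nbin[map$valid_idx]
  full_cov <- cov(t(stack))
  for (a in 1:4) for (b in 1:4) {
    pa <- which(bins == a); pb <- which(bins == b)
    if (a != b) {
      expect_equal(cm$covbar[a, b], mean(full_cov[pa, pb]),
                   tolerance = 1e-10)
    } else {
      off <- full_cov[pa, pa]
      diag(off) <- NA
      expect_equal(cm$covbar[a, a], mean(off, na.rm = TRUE),
                   tolerance = 1e-10)
      expect_equal(cm$avg_var[a], mean(diag(full_cov[pa, pa])),
                   tolerance = 1e-10)
    }
  }
})

test_that("independent pixels give vanishing between-bin covariance", {
  set.seed(44)
  n_sim <- 4000
  stack <- matrix(rnorm(20 * n_sim, 100, 10), 20, n_sim)
  map <- stack_as_map(stack, 4, 5)
  map <- assign_bins(map, 4)
  cm <- binned_covariance(map)
  # MC standard error of an averaged pairwise covariance of N(100,10) draws
  mc_se <- 10 * 10 / sqrt(n_sim)
  off <- cm$covbar[upper.tri(cm$covbar)]
  expect_true(all(abs(off) < 3 * mc_se))
})

test_that("a duplicated pixel shows perfect between-bin correlation", {
  set.seed(5)
  base <- 150 * exp(rnorm(400, 0, 0.2))
  stack <- rbind(base, base + 1e-9)    # numerically identical draws
  map <- stack_as_map(stack, 1, 2)
  map <- assign_bins(map, 2)
  cm <- binned_covariance(map, stack = stack)
  expect_equal(cm$covbar[1, 2], var(base), tolerance = 1e-6)
})

test_that("exact-limit subregion SE matches the Monte Carlo SE", {
  set.seed(17)
  n_px <- 30
  stack <- sim_draw_stack(n_px, 250)
  map <- stack_as_map(stack, 5, 6)
  map <- assign_bins(map, n_px)         # one bin per pixel
  cm <- binned_covariance(map)
  su <- subregion_uncertainty(seq_len(n_px), map, cm)
  exact_se <- sd(colMeans(stack))
  expect_equal(su$se, exact_se, tolerance = 1e-10)
  expect_equal(su$mean, mean(rowMeans(stack)), tolerance = 1e-10)
  # a strict subregion too
  region <- 3:17
  su2 <- subregion_uncertainty(region, map, cm)
  expect_equal(su2$se, sd(colMeans(stack[region, ])), tolerance = 1e-10)
})

test_that("single-pixel regions return their bin's averaged variance", {
  set.seed(9)
  stack <- sim_draw_stack(20, 150)
  map <- assign_bins(stack_as_map(stack, 4, 5), 20)
  cm <- binned_covariance(map)
  su <- subregion_uncertainty(1L, map, cm)
  expect_equal(su$se, sqrt(cm$avg_var[map$nbin[1]]), tolerance = 1e-12)
  expect_error(subregion_uncertainty(integer(0), map, cm), "empty")
})

test_that("binned SE error shrinks as bins grow", {
  set.seed(26)
  stack <- sim_draw_stack(200, 300)
  map0 <- stack_as_map(stack, 10, 20)
  exact_se <- sd(colMeans(stack))
  errs <- vapply(c(2, 10, 50, 200), function(nb) {
    map <- assign_bins(map0, nb)
    cm <- binned_covariance(map)
    su <- subregion_uncertainty(seq_len(200), map, cm)
    abs(su$se - exact_se) / exact_se
  }, 0)
  expect_lt(errs[4], 1e-10)             # exact at one bin per pixel
  expect_lt(errs[3], errs[1] + 0.02)    # broadly decreasing
})

test_that("model metadata exports and reloads numerically", {
  set.seed(12)
  dat <- sim_mapping_data(n = 20)
  m <- fit_mapping_model(dat)
  trees <- make_trees("p", x = 1:5, y = 1:5, dbh = c(12, 25, 40, 60, 90))
  f <- tempfile(fileext = ".yaml")
  export_model_metadata(m, trees, dat$agb_ref, dat$mean_tch, path = f)
  back <- yaml::read_yaml(f)
  expect_equal(back$model$a, m$a, tolerance = 1e-9)
  expect_equal(unlist(back$model$coef_vcov, use.names = FALSE),
               as.vector(m$coef_vcov), tolerance = 1e-9)
  expect_equal(back$dbh_cm$min, 12)
  expect_equal(back$dbh_cm$mean, mean(trees$dbh_cm), tolerance = 1e-9)
  expect_equal(back$dbh_cm$max, 90)
  expect_equal(back$plot_agb$mean, mean(dat$agb_ref), tolerance = 1e-9)
})

test_that("binned covariance matrices persist as CSV + YAML", {
  set.seed(3)
  stack <- sim_draw_stack(40, 150)
  map <- assign_bins(stack_as_map(stack, 5, 8), 5)
  cm <- binned_covariance(map)
  fc <- tempfile(fileext = ".csv"); fy <- tempfile(fileext = ".yaml")
  write_binned_covariance(cm, fc, fy)
  tab <- read.csv(fc)
  expect_equal(as.matrix(tab[, -1]), unname(cm$covbar),
               tolerance = 1e-6, ignore_attr = TRUE)
  hdr <- yaml::read_yaml(fy)
  expect_equal(unlist(hdr$counts), cm$counts)
})
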
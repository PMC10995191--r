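# Second-level Monte Carlo: ensemble construction, map prediction, CV layer.

test_that("zero first-level variance yields identical ensemble fits", {
  tch <- seq(8, 30, length.out = 10)
  agb <- exp(2 + 1.2 * log(tch) + rnorm(10, 0, 0.1))
  draws <- matrix(agb, 10, 50)          # all realizations identical
  ens <- build_ensemble(draws, tch, n_draws = 40, seed = 1)
  expect_equal(max(abs(sweep(ens$coefs, 2, ens$coefs[1, ]))), 0)
  expect_equal(max(ens$sigmas) - min(ens$sigmas), 0)
  # parameter spread then reflects only the single-fit posterior
  expect_gt(sd(ens$b_star), 0)
})

test_that("ensembles are deterministic and reject short inputs", {
  set.seed(2)
  tch <- runif(8, 8, 30)
  draws <- matrix(exp(2 + 1.2 * log(tch)), 8, 20) *
    matrix(exp(rnorm(160, 0, 0.05)), 8, 20)
  e1 <- build_ensemble(draws, tch, n_draws = 30, seed = 7)
  e2 <- build_ensemble(draws, tch, n_draws = 30, seed = 7)
  expect_identical(e1$a_star, e2$a_star)
  expect_identical(e1$rse_star, e2$rse_star)
  expect_error(build_ensemble(draws[1:3, ], tch[1:3], seed = 1),
               "fewer than")
})

test_that("posterior parameter draws cover the generative coefficients", {
  hits <- 0L
  n_seeds <- 10
  for (s in seq_len(n_seeds)) {
    set.seed(s)
    dat <- sim_mapping_data(n = 40, a = 2, b = 1.2, sigma = 0.1,
                            tch_range = c(8, 35))
    draws <- matrix(dat$agb_ref, 40, 30)
    ens <- build_ensemble(draws, dat$mean_tch, n_draws = 400,
                          seed = 1000 + s)
    ci <- quantile(ens$b_star[1, ], c(.025, .975))
    if (ci[1] <= 1.2 && 1.2 <= ci[2]) hits <- hits + 1L
  }
  expect_gte(hits, n_seeds - 2)
})

test_that("the Metropolis sampler agrees with the exact posterior", {
  set.seed(4)
  dat <- sim_mapping_data(n = 30, a = 2, b = 1.2, sigma = 0.12)
  draws <- matrix(dat$agb_ref, 30, 2)
  e_ex <- build_ensemble(draws, dat$mean_tch, n_draws = 4000, seed = 5)
  e_mh <- build_ensemble(draws, dat$mean_tch, n_draws = 4000, seed = 5,
                         sampler = "metropolis")
  expect_equal(mean(e_mh$b_star[1, ]), mean(e_ex$b_star[1, ]),
               tolerance = 0.05)
  expect_equal(sd(e_mh$b_star[1, ]), sd(e_ex$b_star[1, ]), tolerance = 0.25)
})

test_that("a collapsed ensemble predicts the deterministic map", {
  ens <- constant_ensemble(a = 2, b = 1.2, rse = 0)
  tch <- chm_raster(matrix(c(10, 20, NA, 1), 2, 2), res = 100)
  map <- predict_map(ens, tch, veg_threshold = 2, seed = 1)
  expect_equal(map$mean_agb[1, 1], exp(2 + 1.2 * log(10)))
  expect_equal(map$mean_agb[2, 1], exp(2 + 1.2 * log(20)))
  expect_true(is.na(map$mean_agb[1, 2]))   # no-data propagates
  expect_true(is.na(map$mean_agb[2, 2]))   # below vegetation threshold
  expect_equal(map$sd_agb[1, 1], 0)
})

test_that("predict_map equals the naive per-pixel loop bit-for-bit", {
  set.seed(9)
  dat <- sim_mapping_data(n = 12)
  draws <- matrix(dat$agb_ref, 12, 25) *
    matrix(exp(rnorm(300, 0, 0.08)), 12, 25)
  ens <- build_ensemble(draws, dat$mean_tch, n_draws = 30, seed = 3)
  tch <- chm_raster(matrix(runif(30, 3, 35), 5, 6), res = 100)
  map <- predict_map(ens, tch, veg_threshold = 2, seed = 42,
                     keep_stack = TRUE)
  oracle <- predict_map_oracle(ens, tch$values, 2, 42)
  expect_identical(map$valid_idx, oracle$idx)
  expect_identical(map$draw_stack, oracle$stack)
  expect_equal(map$mean_agb[oracle$idx], oracle$mean, tolerance = 1e-12)
  expect_equal(map$sd_agb[oracle$idx], oracle$sd, tolerance = 1e-12)
})

test_that("pixel means show the lognormal back-transform bias", {
  rse <- 0.3
  ens <- constant_ensemble(a = 2, b = 1.2, rse = rse, n_sim = 4000)
  tch <- chm_raster(matrix(15, 1, 1), res = 100)
  map <- predict_map(ens, tch, seed = 8)
  mu <- 2 + 1.2 * log(15)
  mc_se <- exp(mu + rse^2 / 2) * sqrt(exp(rse^2) - 1) / sqrt(4000)
  expect_lt(abs(map$mean_agb[1, 1] - exp(mu + rse^2 / 2)), 4 * mc_se)
})

test_that("map uncertainty shrinks when first-level variance shrinks", {
  set.seed(14)
  tch_p <- runif(12, 8, 30)
  base <- exp(2 + 1.2 * log(tch_p))
  noisy <- matrix(base, 12, 40) * matrix(exp(rnorm(480, 0, 0.2)), 12, 40)
  tight <- matrix(base, 12, 40)
  tch <- chm_raster(matrix(runif(16, 5, 30), 4, 4), res = 100)
  e_noisy <- build_ensemble(noisy, tch_p, n_draws = 50, seed = 2)
  e_tight <- build_ensemble(tight, tch_p, n_draws = 50, seed = 2)
  m_noisy <- predict_map(e_noisy, tch, seed = 3)
  m_tight <- predict_map(e_tight, tch, seed = 3)
  expect_gt(mean(m_noisy$sd_agb, na.rm = TRUE),
            mean(m_tight$sd_agb, na.rm = TRUE))
})

test_that("the CV layer is simple arithmetic on the two AGB layers", {
  map <- stack_as_map(sim_draw_stack(6, 120), 2, 3)
  map$mean_agb[1, 1] <- 200
  map$sd_agb[1, 1] <- 30
  cv <- cv_raster(map)
  expect_equal(cv[1, 1], 15)
  expect_equal(cv[2, 1], 100 * map$sd_agb[2, 1] / map$mean_agb[2, 1])
})

test_that("high-noise sites map with larger mean CV than low-noise ones", {
  set.seed(6)
  tch_p <- runif(15, 8, 30)
  base <- exp(2 + 1.2 * log(tch_p))
  hi <- matrix(base, 15, 60) * matrix(exp(rnorm(900, 0, 0.3)), 15, 60)
  lo <- matrix(base, 15, 60) * matrix(exp(rnorm(900, 0, 0.05)), 15, 60)
  tch <- chm_raster(matrix(runif(25, 5, 30), 5, 5), res = 100)
  m_hi <- predict_map(build_ensemble(hi, tch_p, n_draws = 60, seed = 1),
                      tch, seed = 2)
  m_lo <- predict_map(build_ensemble(lo, tch_p, n_draws = 60, seed = 1),
                      tch, seed = 2)
  expect_gt(mean(cv_raster(m_hi), na.rm = TRUE),
            mean(cv_raster(m_lo), na.rm = TRUE))
})
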
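# Plot splitting, wood-density attribution, tree allometry and the H-D model.

test_that("splitting tiles from both edges and drops the central band", {
  plots <- make_one_plot(100, 100)
  set.seed(1)
  trees <- make_trees("p1", x = runif(500, 0, 100), y = runif(500, 0, 100),
                      dbh = runif(500, 10, 60))
  sp <- split_plots(plots, trees, 40)
  expect_equal(nrow(sp$subplots), 4L)
  expect_setequal(sp$subplots$x0, c(0, 60))
  expect_setequal(sp$subplots$y0, c(0, 60))
  # trees in the 20-m central cross are dropped; corner trees retained
  in_cross <- (trees$x >= 40 & trees$x < 60) | (trees$y >= 40 & trees$y < 60)
  expect_equal(sp$n_trees_dropped, sum(in_cross))
  expect_equal(nrow(sp$trees), sum(!in_cross))
  # every retained tree maps to exactly one subplot
  expect_true(all(!is.na(sp$trees$subplot_id)))
})

test_that("splitting at the plot's own size keeps everything", {
  plots <- make_one_plot(100, 100)
  trees <- make_trees("p1", x = c(1, 50, 99), y = c(1, 50, 99),
                      dbh = c(12, 30, 45))
  sp <- split_plots(plots, trees, 100)
  expect_equal(nrow(sp$subplots), 1L)
  expect_equal(sp$n_trees_dropped, 0L)
  expect_equal(nrow(sp$trees), 3L)
})

test_that("a 25-ha plot splits into 25 one-ha subplots", {
  plots <- make_one_plot(500, 500)
  trees <- make_trees("p1", x = 250, y = 250, dbh = 30)
  sp <- split_plots(plots, trees, 100)
  expect_equal(nrow(sp$subplots), 25L)
  # exact multiple: contiguous tiling, no tree lost
  expect_equal(sp$n_trees_dropped, 0L)
  expect_setequal(unique(sp$subplots$x0), c(0, 100, 200, 300, 400))
})

test_that("undersized plots are skipped with a warning", {
  plots <- rbind(make_one_plot(100, 100, "big"), make_one_plot(60, 60, "small"))
  trees <- make_trees(c("big", "small"), x = c(10, 10), y = c(10, 10),
                      dbh = c(20, 20))
  expect_warning(sp <- split_plots(plots, trees, 100), "skipped")
  expect_equal(nrow(sp$subplots), 1L)
})

test_that("wood density cascades species -> genus -> family -> plot", {
  tab <- data.frame(
    species = c("spA", "spB", "spC"),
    genus = c("genX", "genX", "genY"),
    family = c("famQ", "famQ", "famR"),
    mean = c(0.5, 0.6, 0.7), sd = c(0.05, 0.06, 0.07),
    stringsAsFactors = FALSE
  )
  trees <- data.frame(
    site = "s", plot = "p",
    species = c("spA", "zz", "zz", "zz"),
    genus = c("genX", "genX", "zz", "zz"),
    family = c("famQ", "famQ", "famR", "zz"),
    stringsAsFactors = FALSE
  )
  out <- assign_wood_density(trees, tab)
  expect_equal(out$wd_level, c("species", "genus", "family", "plot"))
  expect_equal(out$wd[1], 0.5)
  expect_equal(out$wd[2], 0.55)        # genus mean of spA, spB
  expect_equal(out$wd[3], 0.7)         # family famR
  expect_equal(out$wd[4], mean(c(0.5, 0.55, 0.7)))  # plot mean of assigned
  expect_equal(out$wd_sd[4], mean(tab$sd))
  expect_error(assign_wood_density(trees, tab[0, ]), "empty")
})

test_that("tree AGB follows the power law and its identities", {
  expect_equal(tree_agb(30, 20, 0.6), 581.616407544, tolerance = 1e-9)
  ident <- allometry_config(coef0 = 1, exponent = 1)
  expect_equal(tree_agb(30, 20, 0.6, ident), 0.6 * 900 * 20)
  # power-law homogeneity in wood density
  expect_equal(tree_agb(30, 20, 1.2) / tree_agb(30, 20, 0.6), 2^0.976)
  expect_error(tree_agb(-5, 20, 0.6), "> 0")
})

test_that("H-D fit interpolates noiseless log-linear data exactly", {
  d <- seq(10, 80, length.out = 50)
  h <- exp(1 + 0.5 * log(d))
  m <- suppressWarnings(fit_hd(d, h))  # exact fit by design
  expect_equal(unname(coef(m)), c(1, 0.5, 0), tolerance = 1e-8)
  expect_lt(sigma(m), 1e-10)
  expect_equal(predict_height(m, 30, correct = TRUE),
               predict_height(m, 30, correct = FALSE), tolerance = 1e-10)
})

test_that("duplicating the training data halves the coefficient covariance", {
  set.seed(42)
  d <- runif(200, 10, 90)
  h <- exp(-0.5 + 1.3 * log(d) - 0.1 * log(d)^2 + rnorm(200, 0, 0.2))
  m1 <- fit_hd(d, h)
  m2 <- fit_hd(c(d, d), c(h, h))
  expect_equal(coef(m1), coef(m2), tolerance = 1e-10)
  # OLS oracle: the doubled fit's vcov equals sigma2' * (2 X'X)^-1
  ld <- log(d)
  oracle <- vcov(lm(log(c(h, h)) ~ c(ld, ld) + I(c(ld, ld)^2)))
  expect_equal(vcov(m2), unname(oracle), tolerance = 1e-10)
  ratio <- diag(vcov(m2)) / diag(vcov(m1))
  # exactly 1/2 up to the residual-variance df correction
  expect_equal(ratio, rep(0.5, 3) * (sigma(m2)^2 / sigma(m1)^2),
               tolerance = 1e-10)
})

test_that("H-D refits recover the generative coefficients", {
  truth <- hd_truth_table()["betul", ]
  set.seed(7)
  d <- exp(runif(2000, log(10), log(120)))
  h <- exp(truth[1] + truth[2] * log(d) + truth[3] * log(d)^2 +
             rnorm(2000, 0, truth[4]))
  m <- fit_hd(d, h)
  z <- abs(unname(coef(m)) - truth[1:3]) / m$coef_se
  expect_true(all(z < 3))
  expect_equal(sigma(m), truth[4], tolerance = 0.1)
})

test_that("height predictions match hand-evaluated published rows", {
  tab <- hd_truth_table()
  # frozen hand evaluations of exp(a + b lnD + c (lnD)^2 [+ s^2/2]) at D = 30
  expected_corr <- c(betul = 18.5367578892, yellapur = 18.277892882,
                     rabi = 22.0414337093)
  for (nm in names(expected_corr)) {
    v <- tab[nm, ]
    m <- hd_model(v[1], v[2], v[3], v[4])
    expect_equal(predict_height(m, 30), expected_corr[[nm]],
                 tolerance = 1e-8)
  }
  my <- hd_model(0.563, 0.851, -0.050, 0.231)
  expect_equal(predict_height(my, 10), 9.81670482594, tolerance = 1e-8)
  expect_error(predict_height(my, 0), "> 0")
})

test_that("degenerate H-D designs fail loudly", {
  expect_error(fit_hd(rep(30, 50), rep(15, 50)), "rank-deficient")
  expect_error(fit_hd(runif(10, 10, 50), runif(10, 5, 20)), "at least 30")
})
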
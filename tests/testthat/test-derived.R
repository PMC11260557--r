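test_that("occupancy projection follows the colonization/extirpation recursion", {
  expect_equal(project_psi(0.5, 0.2, 0.3), c(0.5, 0.45))
  expect_equal(project_psi(0.37, rep(0, 4), rep(0, 4)), rep(0.37, 5))
  # psi1 at the equilibrium stays at the equilibrium
  g <- 0.25; e <- 0.4
  eq <- g / (g + e)
  expect_equal(project_psi(eq, rep(g, 6), rep(e, 6)), rep(eq, 7),
               tolerance = 1e-12)
  expect_error(project_psi(0.5, c(0.1, 0.2), 0.3), "equal length")
})

test_that("turnover, rate of change and decline proportion compute as defined", {
  expect_equal(turnover(0.45, 0.2, 0.3), 0.245)
  expect_equal(turnover(0.5, 0, 0), 0)
  expect_equal(turnover(1, 0.99, 1), 1)

  expect_equal(rate_of_change(0.4, 0.2), 0.5)
  expect_equal(rate_of_change(0.3, 0.3), 1)
  expect_warning(l0 <- rate_of_change(0, 0.2), "undefined")
  expect_true(is.na(l0))

  expect_equal(decline_proportion(c(0.5, 1.2, 0.9, 1.0)), 0.5)
  expect_equal(decline_proportion(rep(1, 5)), 0)  # strict inequality
  expect_equal(decline_proportion(c(0.1, 0.9)), 1)
})

test_that("stable state is gamma/(gamma+epsilon) and a fixed point", {
  expect_equal(stable_state(0.2, 0.3), 0.4)
  expect_equal(stable_state(0.7, 0.7), 0.5)
  expect_equal(stable_state(0.4, 0), 1)
  expect_warning(s0 <- stable_state(0, 0), "undefined")
  expect_true(is.na(s0))

  set.seed(123)
  for (r in 1:50) {
    g <- runif(1, 0.01, 0.99)
    e <- runif(1, 0.01, 0.99)
    eq <- stable_state(g, e)
    expect_lt(abs(project_psi(eq, g, e)[2] - eq), 1e-12)
    # contraction toward the equilibrium when gamma + epsilon < 1
    if (g + e < 1) {
      psi0 <- runif(1)
      traj <- project_psi(psi0, rep(g, 10), rep(e, 10))
      gaps <- abs(traj - eq)
      expect_true(all(diff(gaps) <= 1e-14))
    }
  }
})

test_that("turnover is bounded by the dynamic rates", {
  set.seed(321)
  psi <- runif(200); g <- runif(200); e <- runif(200)
  tau <- turnover(psi, g, e)
  expect_true(all(tau >= 0 & tau <= 1))
  expect_true(all(tau <= pmax(g, e) + pmin(g, e) + 1e-15))
})

make_small_fit <- function(seed = 51) {
  sc <- tiny_scenario()
  dat <- simulate_dataset(sc, seed)
  cfg <- quick_config(seed = seed, chains = 2, warmup = 250, draws = 400)
  list(fit = sample_posterior(dat$history, dat$truth$designs, cfg),
       dat = dat, sc = sc)
}

test_that("grid prediction masks developed/water cells before computing proportions", {
  ms <- make_small_fit()
  grid <- ms$dat$grid
  grid$high_development_fraction <- rep(c(0.1, 0.5), length.out = nrow(grid))
  grid$water <- FALSE
  grid$water[1] <- TRUE  # cell 1 has dev 0.1 but is water
  der <- predict_grid(ms$fit, grid, max_draws = 50)
  kept_expected <- grid$cell_id[grid$high_development_fraction <= 0.40 &
                                  !grid$water]
  expect_setequal(der$cells_retained, kept_expected)
  expect_true(all(der$psi$median >= 0 & der$psi$median <= 1))
  expect_true(all(der$psi_eq$median >= 0 & der$psi_eq$median <= 1))
  expect_true(all(der$lambda$median >= 0))
  expect_true(all(der$decline >= 0 & der$decline <= 1))
})

test_that("a grid cell identical to a fitted site reproduces its psi1", {
  ms <- make_small_fit(52)
  cov1 <- ms$dat$site_cov[3, ]
  grid <- data.frame(cell_id = "twin", moth = cov1$moth, cover = cov1$cover,
                     road_dist = cov1$road_dist, zone_area = cov1$zone_area,
                     high_development_fraction = 0, water = FALSE)
  der <- predict_grid(ms$fit, grid, max_draws = 1000)
  pooled <- pooled_draws(ms$fit)
  X1 <- ms$fit$designs$X_psi1[3, , drop = FALSE]
  psi1_draws <- expit(drop(pooled[, 1:4] %*% t(X1)))
  site_med <- median(psi1_draws)
  cell_med <- der$psi$median[der$psi$period == ms$fit$designs$periods[1]]
  expect_equal(cell_med, site_med, tolerance = 1e-6)
})

test_that("an all-equal grid yields zero spread in every derived map", {
  ms <- make_small_fit(53)
  grid <- data.frame(cell_id = c("a", "b", "c"), moth = 2, cover = 50,
                     road_dist = 0.4, zone_area = 1.5,
                     high_development_fraction = 0, water = FALSE)
  der <- predict_grid(ms$fit, grid, max_draws = 100)
  for (tab in list(der$psi, der$lambda, der$psi_eq)) {
    spread <- tapply(tab$median, tab[[2]], function(v) diff(range(v)))
    expect_true(all(spread == 0))
  }
})

test_that("derive-then-summarize differs from summarize-then-derive", {
  # the draw-wise path is the contract: medians of nonlinear functionals
  # are not the functionals of the medians
  set.seed(8)
  g <- rbeta(2000, 2, 5)
  e <- rbeta(2000, 4, 3)
  drawwise <- median(g / (g + e))
  plugin <- median(g) / (median(g) + median(e))
  expect_gt(abs(drawwise - plugin), 1e-4)
})
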
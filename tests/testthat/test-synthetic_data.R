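test_that("truth climatology honours seasonal modes and stays reproducible", {
  # uniform: all 12 surfaces identical and constant when the range collapses
  u <- generate_truth_climatology(6, 6, "uniform", p_range = 0.5, seed = 3)
  for (m in 1:12) expect_equal(u$grids[[m]]$values, matrix(0.5, 6, 6))

  # sinusoid: per-pixel monthly values trace the cosine exactly
  s <- generate_truth_climatology(5, 5, "sinusoid", p_range = 0.5,
                                  amplitude = 0.3, peak_month = 4, seed = 3)
  vals <- sapply(1:12, function(m) s$grids[[m]]$values[2, 2])
  expect_equal(vals, 0.5 + 0.3 * cos(2 * pi * ((1:12) - 4) / 12))
  expect_equal(which.max(vals), 4L)

  # bimodal: two equal peaks six months apart
  b <- generate_truth_climatology(5, 5, "bimodal", p_range = 0.5,
                                  amplitude = 0.2, peak_month = 2, seed = 3)
  vb <- sapply(1:12, function(m) b$grids[[m]]$values[1, 1])
  expect_equal(vb[2], vb[8])
  expect_equal(sort(order(vb, decreasing = TRUE)[1:2]), c(2L, 8L))

  # determinism and probability-range guard
  s2 <- generate_truth_climatology(5, 5, "sinusoid", p_range = 0.5,
                                   amplitude = 0.3, peak_month = 4, seed = 3)
  expect_identical(s$grids[[7]]$values, s2$grids[[7]]$values)
  expect_error(
    generate_truth_climatology(5, 5, "sinusoid", p_range = c(0.5, 0.9),
                               amplitude = 0.3),
    "\\[0, 1\\]")
})

test_that("cloud stacks obey their Bernoulli law and stripe gaps", {
  # p = 1: every valid observation is flagged cloudy
  t1 <- generate_truth_climatology(4, 4, "uniform", p_range = 1, seed = 1)
  s1 <- generate_cloud_stack(t1, years = 2000, days_per_month = 5, seed = 1)
  am <- s1$sensors$am
  expect_true(all(am$flags[am$valid]))

  # empirical monthly CF within 3 SE of truth on a pooled fixture
  t7 <- generate_truth_climatology(6, 6, "uniform", p_range = 0.7, seed = 2)
  s7 <- generate_cloud_stack(t7, years = 2000:2004, days_per_month = 30,
                             seed = 2)
  jan <- s7$sensors$am$dates$month == 1
  flags <- s7$sensors$am$flags[, , jan]
  valid <- s7$sensors$am$valid[, , jan]
  phat <- sum(flags & valid) / sum(valid)
  se <- sqrt(0.7 * 0.3 / sum(valid))
  expect_lt(abs(phat - 0.7), 3 * se)

  # stripe gaps: striped columns lose every gap-period-th day
  sensors <- list(list(name = "am", stripe_angle_deg = 15,
                       overpass_gap_period = 2L, stripe_amplitude = 0))
  sg <- generate_cloud_stack(t7, years = 2000, days_per_month = 30,
                             sensors = sensors, seed = 3)
  valid_n <- rowSums(sg$sensors$am$valid, dims = 2L)
  striped <- sg$sensors$am$striped
  expect_true(all(valid_n[striped] == 180))    # half of 360 days removed
  expect_true(all(valid_n[!striped] == 360))

  expect_error(generate_cloud_stack(t7, years = 2000, days_per_month = 0),
               "at least one")
})

test_that("station records reduce to footprint truth at zero noise", {
  truth <- generate_truth_climatology(30, 30, "sinusoid",
                                      p_range = c(0.3, 0.7),
                                      amplitude = 0.2, seed = 4)
  st <- generate_station_records(truth, n_stations = 15, noise_sd = 0,
                                 frac_low = 0, seed = 4)
  amounts <- as.matrix(st$stations[sprintf("amount_%02d", 1:12)])
  expect_equal(unname(amounts), unname(st$truth_amount), tolerance = 1e-12)
  # footprint mean recomputed independently for one station/month
  i <- 7
  expect_equal(
    st$truth_amount[i, 3],
    100 * station_footprint_mean(truth$grids[[3]], st$stations$lon[i],
                                 st$stations$lat[i], 16))
})

test_that("noisy stations reach the analytic signal-to-noise R-squared", {
  truth <- generate_truth_climatology(40, 40, "uniform",
                                      p_range = c(0.2, 0.8),
                                      smoothness = 2, seed = 9)
  st <- generate_station_records(truth, n_stations = 400, noise_sd = 5,
                                 frac_low = 0, seed = 9)
  x <- st$truth_amount[, 1]
  y <- st$stations$amount_01
  r2 <- summary(lm(y ~ x))$r.squared
  expected <- var(x) / (var(x) + 25)
  expect_lt(abs(r2 - expected), 0.05)
})

test_that("presence points are uniform under a null intensity and follow
           positive gradients otherwise", {
  cov_grid <- geo_grid(matrix(rep(seq(-1, 1, length.out = 40), each = 40),
                              40, 40))
  covs <- grid_stack(list(cov_grid), labels = "x")
  # zero coefficient: quadrat chi-square test rarely significant
  pvals <- vapply(1:20, function(s) {
    pts <- generate_presence_points(c(x = 0), covs, n_expected = 400,
                                    seed = s)
    qx <- cut(pts$lon, breaks = seq(0, 40 / 120, length.out = 5),
              include.lowest = TRUE)
    qy <- cut(pts$lat, breaks = seq(0, 40 / 120, length.out = 5),
              include.lowest = TRUE)
    suppressWarnings(chisq.test(table(qx, qy))$p.value)
  }, 0)
  expect_gte(mean(pvals > 0.01), 0.95)

  # strong positive slope: points concentrate where the covariate is high
  pts <- generate_presence_points(c(x = 2), covs, n_expected = 500, seed = 1)
  cells <- point_to_cell(cov_grid, pts$lon, pts$lat)
  at_points <- cov_grid$values[cells]
  expect_gt(mean(at_points), mean(cov_grid$values))

  # determinism
  p1 <- generate_presence_points(c(x = 1), covs, n_expected = 200, seed = 5)
  p2 <- generate_presence_points(c(x = 1), covs, n_expected = 200, seed = 5)
  expect_identical(p1, p2)
})

test_that("occupancy generator matches its zero-inflated binomial law", {
  # saturation: huge intercept and perfect detection
  sat <- generate_occupancy_data(c(10), 1, n_cells = 300, seed = 2)
  expect_true(mean(sat$data$y == sat$data$n) > 0.99)

  # delta = 0: no detections regardless of suitability
  none <- generate_occupancy_data(c(10), 0, n_cells = 300, seed = 2)
  expect_true(all(none$data$y == 0))

  # pooled detection rate theta * delta within 3 SE on 1e4 cells
  d <- generate_occupancy_data(c(0), 0.5,
                               trials_law = function(n) rep(10L, n),
                               n_cells = 1e4, seed = 3)
  rate <- mean(d$data$y / d$data$n)
  se <- sd(d$data$y / d$data$n) / sqrt(1e4)
  expect_lt(abs(rate - 0.25), 3 * se)

  expect_error(generate_occupancy_data(c(0), 1.2, n_cells = 10), "delta")
})

test_that("substreams are deterministic and distinct", {
  expect_identical(substream_seed(42, "stack"), substream_seed(42, "stack"))
  expect_false(substream_seed(42, "stack") == substream_seed(42, "points"))
  expect_true(substream_seed(1e9, "occupancy") < 2^31)
})
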
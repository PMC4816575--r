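template <- geo_grid(matrix(0, 3, 3))

test_that("monthly frequency is the percent of valid flagged days", {
  flags <- array(0, c(1, 1, 4)); flags[1, 1, ] <- c(1, 0, 1, 0)
  valid <- array(TRUE, c(1, 1, 4))
  out <- monthly_frequency(flags == 1, valid, geo_grid(matrix(0, 1, 1)))
  expect_equal(out$cf$values[1, 1], 50)
  expect_equal(out$n$values[1, 1], 4)

  # all observations invalid -> masked
  out2 <- monthly_frequency(flags == 1, valid & FALSE,
                            geo_grid(matrix(0, 1, 1)))
  expect_true(out2$cf$mask[1, 1])

  expect_error(monthly_frequency(array(0, c(2, 2, 3)), array(TRUE, c(2, 2, 2)),
                                 template), "shape")
})

test_that("climatological stats follow their two-year hand example", {
  cf <- array(NA_real_, c(1, 1, 12, 2))
  cf[1, 1, , 1] <- 40; cf[1, 1, , 2] <- 60
  cs <- climatological_stats(list(cf = cf, template = template,
                                  years = 2000:2001))
  expect_equal(cs$mu$grids[[1]]$values[1, 1], 50)
  expect_equal(cs$sigma$grids[[1]]$values[1, 1], sd(c(40, 60)))
  expect_equal(round(cs$sigma$grids[[1]]$values[1, 1], 3), 14.142)

  # identical years: sigma == 0; single year: sigma masked
  cf[1, 1, , 2] <- 40
  cs0 <- climatological_stats(list(cf = cf, template = template))
  expect_equal(cs0$sigma$grids[[5]]$values[1, 1], 0)
  cs1 <- climatological_stats(list(cf = cf[, , , 1, drop = FALSE],
                                   template = template))
  expect_equal(cs1$mu$grids[[5]]$values[1, 1], 40)
  expect_true(is.na(cs1$sigma$grids[[5]]$values[1, 1]))
})

test_that("sensor merge averages where both report and keeps the survivor", {
  a <- mu_stack_from(as.list(rep(40, 12)))
  b <- mu_stack_from(as.list(rep(60, 12)))
  ab <- merge_sensors(list(a, b))
  expect_equal(ab$grids[[1]]$values[1, 1], 50)

  b$grids[[1]]$values[1, 1] <- NA; b$grids[[1]]$mask[1, 1] <- TRUE
  ab2 <- merge_sensors(list(a, b))
  expect_equal(ab2$grids[[1]]$values[1, 1], 40)

  a$grids[[1]]$values[1, 1] <- NA; a$grids[[1]]$mask[1, 1] <- TRUE
  ab3 <- merge_sensors(list(a, b))
  expect_true(ab3$grids[[1]]$mask[1, 1])

  # merged mean annual invariant to sensor order
  set.seed(1)
  r1 <- mu_stack_from(as.list(runif(12, 20, 80)))
  r2 <- mu_stack_from(as.list(runif(12, 20, 80)))
  m12 <- derived_metrics(cloud_climatology(merge_sensors(list(r1, r2))))
  m21 <- derived_metrics(cloud_climatology(merge_sensors(list(r2, r1))))
  expect_equal(m12$mean_annual$values, m21$mean_annual$values)
})

test_that("derived metrics match their hand-computed values", {
  clim <- cloud_climatology(mu_stack_from(as.list(rep(50, 12))))
  clim <- derived_metrics(clim)
  expect_equal(clim$intra_annual$values[1, 1], 0)

  vals <- c(rep(80, 6), rep(20, 6))
  clim2 <- derived_metrics(cloud_climatology(mu_stack_from(as.list(vals))))
  expect_equal(clim2$mean_annual$values[1, 1], 50)
  expect_equal(round(clim2$intra_annual$values[1, 1], 3), 31.334)
  expect_equal(clim2$intra_annual$values[1, 1], sd(vals))

  sig <- mu_stack_from(as.list(rep(10, 12)))
  clim3 <- derived_metrics(cloud_climatology(mu_stack_from(as.list(vals)),
                                             sigma = sig))
  expect_equal(clim3$inter_annual$values[1, 1], 10)
})

test_that("seasonal concentration hits its anchors and symmetries", {
  expect_equal(seasonal_concentration(rep(50, 12))$index, 0)

  one <- seasonal_concentration(c(60, rep(0, 11)))
  expect_equal(one$index, 100)
  expect_equal(one$peak_month, 1L)

  jan_heavy <- seasonal_concentration(c(60, rep(20, 11)))
  expect_equal(jan_heavy$index, 100 * 40 / 280, tolerance = 1e-12)
  expect_equal(jan_heavy$peak_month, 1L)

  # two opposite months cancel
  expect_equal(
    seasonal_concentration(c(50, rep(0, 5), 50, rep(0, 5)))$index, 0)
})

test_that("concentration is scale-invariant and rotation-equivariant", {
  set.seed(8)
  for (i in 1:10) {
    mu <- runif(12, 0, 90)
    base <- seasonal_concentration(mu)
    expect_equal(seasonal_concentration(3.7 * mu)$index, base$index,
                 tolerance = 1e-9)
    k <- sample(1:11, 1)
    rot <- seasonal_concentration(mu[((seq_len(12) - 1 - k) %% 12) + 1])
    expect_equal(rot$index, base$index, tolerance = 1e-9)
    expect_equal(rot$peak_month, ((base$peak_month - 1 + k) %% 12) + 1)
  }
})

test_that("concentration masking follows the availability rules", {
  mu <- rep(50, 12); mu[3:12] <- NA       # two months available: defined
  expect_false(is.na(seasonal_concentration(mu)$index))
  mu1 <- c(50, rep(NA, 11))
  expect_true(is.na(seasonal_concentration(mu1)$index))
  expect_true(is.na(seasonal_concentration(rep(0, 12))$index))
})

test_that("hotspot classes reproduce an enumerable fixture", {
  set.seed(11)
  nr <- 10
  ma <- matrix(runif(100, 0, 100), nr)
  ia <- matrix(runif(100, 0, 30), nr)
  ie <- matrix(runif(100, 0, 20), nr)
  clim <- cloud_climatology(mu_stack_from(as.list(rep(1, 12)),
                                          geo_grid(matrix(0, nr, nr))))
  clim$mean_annual <- geo_grid(ma, cellsize = 1 / 120)
  clim$intra_annual <- geo_grid(ia, cellsize = 1 / 120)
  clim$inter_annual <- geo_grid(ie, cellsize = 1 / 120)
  hs <- hotspot_classification(clim)

  t_ma <- quantile(ma, 0.9); t_ia <- quantile(ia, 0.1)
  t_ie <- quantile(ie, 0.1)
  manual <- matrix(NA_real_, nr, nr)
  hot <- ma >= t_ma
  manual[hot] <- 0
  manual[hot & ia <= t_ia & ie > t_ie] <- 1
  manual[hot & ie <= t_ie & ia > t_ia] <- 2
  manual[hot & ia <= t_ia & ie <= t_ie] <- 3
  expect_equal(hs$classes$values, manual)

  # degenerate variability surface has no decile cutoffs
  clim$intra_annual <- geo_grid(matrix(5, nr, nr), cellsize = 1 / 120)
  expect_error(hotspot_classification(clim), "no variation")
})

test_that("independent uniform variabilities classify ~1% of cells as both", {
  set.seed(21)
  n <- 316  # ~1e5 cells
  clim <- cloud_climatology(mu_stack_from(as.list(rep(1, 12)),
                                          geo_grid(matrix(0, n, n))))
  clim$mean_annual <- geo_grid(matrix(runif(n * n), n), cellsize = 1 / 120)
  clim$intra_annual <- geo_grid(matrix(runif(n * n), n), cellsize = 1 / 120)
  clim$inter_annual <- geo_grid(matrix(runif(n * n), n), cellsize = 1 / 120)
  hs <- hotspot_classification(clim)
  frac_both <- sum(hs$classes$values == 3, na.rm = TRUE) / (n * n)
  p <- 0.1^3
  se <- sqrt(p * (1 - p) / (n * n))
  expect_lt(abs(frac_both - p), 3 * se)
})

test_that("climatology pipeline recovers synthetic monthly truth", {
  truth <- generate_truth_climatology(20, 20, "sinusoid",
                                      p_range = c(0.35, 0.65),
                                      amplitude = 0.25, seed = 31)
  sim <- generate_cloud_stack(truth, years = 2000:2004, days_per_month = 30,
                              seed = 31)
  mus <- lapply(names(sim$sensors), function(sn) {
    climatological_stats(monthly_cf_series(sim, sn))$mu
  })
  merged <- merge_sensors(mus)
  worst_z <- 0
  for (m in 1:12) {
    p <- truth$grids[[m]]$values
    n_eff <- 300  # 30 d x 5 y x 2 sensors, minus sparse stripe gaps
    se <- 100 * sqrt(p * (1 - p) / n_eff)
    z <- abs(merged$grids[[m]]$values - 100 * p) / se
    worst_z <- max(worst_z, quantile(z, 0.99))
  }
  expect_lt(worst_z, 3.5)   # multiplicity-aware recovery check
})
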
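# scaled-down MCMC settings used throughout the tests; the package defaults
# mirror the full production run (3 chains, 10k burn-in, 50k draws, thin 50)
short <- list(chains = 2, burnin = 600, iters = 2400, thin = 4)

test_that("checklist filtering applies the effort rules and aggregates", {
  rec <- data.frame(
    cell = c(1, 1, 1, 2, 2, 3),
    complete = c(TRUE, TRUE, FALSE, TRUE, TRUE, TRUE),
    duration_h = c(2, 4.0, 1, 3.9, 2, 2),
    distance_km = c(1, 1, 1, 20, 4, NA),
    area_ha = c(NA, NA, NA, 400, NA, 600),
    detected = c(1, 1, 1, 0, 1, 1)
  )
  # row 2 fails strict < 4 h; row 3 incomplete; row 4 rescued by area;
  # row 6 fails both distance (NA) and area
  out <- filter_checklists(rec)
  expect_equal(out$cell, c(1, 2))
  expect_equal(out$n, c(1, 2))
  expect_equal(out$y, c(1, 1))
})

test_that("the z full conditional matches exact enumeration", {
  theta <- c(0.3, 0.6, 0.9); delta <- 0.45; n <- c(2L, 5L, 0L)
  y <- c(0L, 0L, 0L)
  expect_equal(zib_z_conditional(theta, delta, n), zib_enum_pz(y, n, theta,
                                                               delta))
  expect_equal(zib_z_conditional(0.5, 0.5, 3, y = 2), 1)
})

test_that("MCMC z marginals agree with enumeration on a 3-cell toy", {
  # pin beta and gamma with a tight prior at the truth so the z draws are
  # governed by the exact full conditional alone
  beta_true <- 0.4; delta_true <- 0.45; gamma_true <- qlogis(delta_true)
  dat <- data.frame(n = c(2L, 5L, 4L), y = c(0L, 0L, 2L))
  # tight priors keep every Metropolis proposal near-accepted; the sampler's
  # acceptance-rate warning is expected here
  fit <- suppressWarnings(
    fit_zib(dat, ~ 1, chains = 2, burnin = 500, iters = 4000, thin = 1,
            seed = 7, prior_mean = c(beta_true, gamma_true),
            prior_var = 1e-8))
  pz <- zib_enum_pz(dat$y, dat$n, rep(plogis(beta_true), 3), delta_true)
  mc_se <- sqrt(pz * (1 - pz) / (2 * 4000))   # upper bound, draws correlate
  expect_lt(abs(fit$z_prob[1] - pz[1]), 6 * mc_se[1])
  expect_lt(abs(fit$z_prob[2] - pz[2]), 6 * mc_se[2])
  expect_equal(fit$z_prob[3], 1)
})

test_that("fixed seeds reproduce draws exactly", {
  d <- generate_occupancy_data(c(-0.5, 1), 0.6, n_cells = 150, seed = 3)
  f1 <- do.call(fit_zib, c(list(d$data, ~ x1, seed = 11), short))
  f2 <- do.call(fit_zib, c(list(d$data, ~ x1, seed = 11), short))
  expect_identical(f1$draws, f2$draws)
  expect_identical(f1$deviance, f2$deviance)
})

test_that("at perfect detection the fit reduces to Bernoulli logistic", {
  set.seed(9)
  d <- generate_occupancy_data(c(-0.3, 1.2), 1,
                               trials_law = function(n) rep(25L, n),
                               n_cells = 600, seed = 9)
  # at delta = 1 the detection intercept drifts to its boundary; the
  # acceptance-rate warning is expected
  fit <- suppressWarnings(
    do.call(fit_zib, c(list(d$data, ~ x1, seed = 21,
                            standardize = FALSE), short)))
  s <- summary(fit)
  # independent route: plain Bernoulli-logit fit on the detection indicator
  glm_fit <- glm((d$data$y > 0) ~ d$data$x1, family = binomial)
  ci <- confint.default(glm_fit)
  for (j in 1:2) {
    lo <- max(s$lower[j], ci[j, 1]); hi <- min(s$upper[j], ci[j, 2])
    expect_lt(lo, hi)   # 95% intervals overlap
  }
})

test_that("rank deficiency and empty data are rejected", {
  d <- generate_occupancy_data(c(0, 1), 0.5, n_cells = 50, seed = 5)
  d$data$x2 <- 2 * d$data$x1
  expect_error(fit_zib(d$data, ~ x1 + x2, chains = 1, burnin = 10,
                       iters = 20, thin = 1), "collinear")
  nodet <- d$data; nodet$y <- 0
  expect_error(fit_zib(nodet, ~ x1, chains = 1, burnin = 10, iters = 20,
                       thin = 1), "detection")
})

test_that("DIC collapses to the plug-in deviance for a degenerate posterior", {
  d <- generate_occupancy_data(c(0.2, 0.8), 0.5, n_cells = 200, seed = 13)
  fit <- do.call(fit_zib, c(list(d$data, ~ x1, seed = 31), short))
  frozen <- fit
  point <- colMeans(pool_draws <- do.call(rbind, lapply(1:2, function(ch) {
    fit$draws[, , ch]
  })))
  for (ch in 1:2) {
    frozen$draws[, , ch] <- matrix(point, nrow(fit$draws), length(point),
                                   byrow = TRUE)
  }
  # deviance recomputed at the frozen parameter point
  p <- ncol(frozen$X)
  theta <- plogis(drop(frozen$X %*% point[seq_len(p)]))
  delta <- plogis(point[p + 1])
  L <- theta * dbinom(frozen$y, frozen$n, delta) +
    (1 - theta) * (frozen$y == 0)
  frozen$deviance[] <- -2 * sum(log(pmax(L, 1e-300)))
  out <- dic(frozen)
  expect_equal(out$p_d, 0, tolerance = 1e-9)
  expect_equal(out$dic, out$d_hat, tolerance = 1e-9)

  # healthy fit: pD positive and near the parameter count
  out2 <- dic(fit)
  expect_gt(out2$p_d, 0)
})

test_that("DIC prefers the model with the informative covariate", {
  wins <- vapply(1:10, function(s) {
    d <- generate_occupancy_data(c(-0.5, 1.5), 0.5, n_cells = 500, seed = s)
    d$data$junk <- rnorm(500)
    ftrue <- fit_zib(d$data, ~ x1, chains = 1, burnin = 400, iters = 1600,
                     thin = 2, seed = s)
    fjunk <- fit_zib(d$data, ~ junk, chains = 1, burnin = 400, iters = 1600,
                     thin = 2, seed = s)
    dic(ftrue)$dic < dic(fjunk)$dic
  }, TRUE)
  expect_gte(mean(wins), 0.90)
})

test_that("MPSRF separates converged from divergent chains", {
  set.seed(17)
  n <- 1000
  base <- lapply(1:3, function(i) matrix(rnorm(2 * n), n, 2))
  # identical copies: below 1.01
  expect_lte(mpsrf(list(base[[1]], base[[1]] + 0, base[[1]])), 1.01)
  # same distribution: below 1.1 at n = 5000
  big <- lapply(1:3, function(i) matrix(rnorm(2 * 5000), 5000, 2))
  expect_lt(mpsrf(big), 1.1)
  # shifted means: far above 1.1
  apart <- lapply(1:3, function(i) matrix(rnorm(2 * n, mean = 3 * i), n, 2))
  expect_gt(mpsrf(apart), 2)
  expect_error(mpsrf(base[1]), "two chains")
})

test_that("predictions are probabilities with the right limiting behavior", {
  d <- generate_occupancy_data(c(0, 1), 0.5, n_cells = 300, seed = 23)
  fit <- do.call(fit_zib, c(list(d$data, ~ x1, seed = 41), short))
  # beta draws forced to zero: theta identically 0.5
  zfit <- fit
  zfit$draws[, seq_len(ncol(zfit$X)), ] <- 0
  covs <- grid_stack(list(geo_grid(matrix(seq(-2, 2, length.out = 16), 4))),
                     labels = "x1")
  pred0 <- predict_occurrence(zfit, covs)
  expect_true(all(abs(pred0$mean$values - 0.5) < 1e-12))

  # positive slope: monotone prediction surface
  pred <- predict_occurrence(fit, covs)
  v <- as.vector(pred$mean$values)
  o <- order(as.vector(covs$grids[[1]]$values))
  expect_true(all(diff(v[o]) >= 0))

  # more data concentrates the posterior: CI width shrinks
  d_big <- generate_occupancy_data(c(0, 1), 0.5, n_cells = 3000, seed = 23)
  fit_big <- do.call(fit_zib, c(list(d_big$data, ~ x1, seed = 41), short))
  pred_big <- predict_occurrence(fit_big, covs)
  expect_lt(mean(pred_big$upper$values - pred_big$lower$values),
            mean(pred$upper$values - pred$lower$values))
})

test_that("range size sums probabilities with no threshold", {
  expect_equal(range_size(c(0.5, 0.5)), 1)
  expect_equal(range_size(rep(0, 10)), 0)
  expect_equal(range_size(rep(1, 7)), 7)
  expect_error(range_size(c(0.5, 1.2)), "probabilities")
  # linearity over disjoint domains
  set.seed(2)
  a <- runif(30); b <- runif(50)
  expect_equal(range_size(c(a, b)), range_size(a) + range_size(b))
  g <- geo_grid(matrix(c(0.5, 0.5, NA, NA), 2, 2))
  expect_equal(range_size(g), 1)
})

test_that("occupancy evaluation behaves at its extremes", {
  # perfect ranking
  y <- c(0L, 0L, 1L, 3L); n <- rep(5L, 4)
  expect_equal(evaluate_occupancy(c(0.1, 0.2, 0.8, 0.9), y, n)$auc, 1)
  # constant predictions: correlation undefined, flagged
  expect_warning(res <- evaluate_occupancy(rep(0.5, 4), y, n), "undefined")
  expect_true(is.na(res$cor))
  # uninformative predictions hover near AUC 0.5
  set.seed(3)
  aucs <- vapply(1:30, function(i) {
    yy <- rbinom(200, 5, 0.3)
    evaluate_occupancy(runif(200), yy, rep(5L, 200))$auc
  }, 0)
  expect_lt(abs(mean(aucs) - 0.5), 3 * sd(aucs) / sqrt(30))
})

test_that("posterior recovery covers the truth across seeds", {
  # scaled-down version of the recovery design: beta = (-1, 2), delta = 0.5
  n_seeds <- 12
  cover <- matrix(NA, n_seeds, 3)
  for (s in seq_len(n_seeds)) {
    d <- generate_occupancy_data(c(-1, 2), 0.5, n_cells = 800, seed = s)
    fit <- fit_zib(d$data, ~ x1, chains = 1, burnin = 600, iters = 2400,
                   thin = 3, seed = s, standardize = FALSE)
    sm <- summary(fit)
    dl <- attr(sm, "delta")
    cover[s, ] <- c(sm$lower[1] <= -1 & -1 <= sm$upper[1],
                    sm$lower[2] <= 2 & 2 <= sm$upper[2],
                    dl["lower"] <= 0.5 & 0.5 <= dl["upper"])
  }
  expect_gte(min(colMeans(cover)), 0.90)
})
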
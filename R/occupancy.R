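#' Filter survey checklists to occupancy trials
#'
#' Keeps complete checklists (the observer looked for all species) with
#' survey duration strictly below 4 hours and either distance at most 5 km
#' or area at most 500 ha, then aggregates surviving records to per-cell
#' trial and presence counts.
#'
#' @param records data.frame with columns `cell` (or `lon`/`lat` plus a
#'   `grid` to assign cells), `complete` (logical), `duration_h`,
#'   `distance_km`, `area_ha`, `detected` (0/1). `NA` effort fields fail
#'   their condition.
#' @param grid optional `geo_grid` used to map `lon`/`lat` to cells when no
#'   `cell` column is present.
#' @return data.frame with `cell`, `n` (trials), `y` (presences), sorted by
#'   cell id.
#' @export
filter_checklists <- function(records, grid = NULL) {
  if (is.null(records$cell)) {
    if (is.null(grid)) stop("either a cell column or a grid is required")
    rc <- point_to_cell(grid, records$lon, records$lat)
    records$cell <- (rc[, "col"] - 1L) * nrow(grid$values) + rc[, "row"]
  }
  dist_ok <- !is.na(records$distance_km) & records$distance_km <= 5
  area_ok <- !is.na(records$area_ha) & records$area_ha <= 500
  keep <- records$complete %in% TRUE &
    !is.na(records$duration_h) & records$duration_h < 4 &
    (dist_ok | area_ok)
  kept <- records[keep, ]
  if (nrow(kept) == 0L) {
    return(data.frame(cell = integer(), n = integer(), y = integer()))
  }
  agg <- stats::aggregate(cbind(n = rep(1L, nrow(kept)),
                                y = as.integer(kept$detected > 0)),
                          by = list(cell = kept$cell), FUN = sum)
  agg[order(agg$cell), ]
}

#' Exact full conditional of the latent suitability indicator
#'
#' For a never-detected cell (`y = 0`), `P(z = 1 | y = 0)` has odds
#' `theta * (1 - delta)^n : (1 - theta)`; detected cells have `z = 1` with
#' certainty.
#'
#' @param theta suitability probability.
#' @param delta per-trial detection probability.
#' @param n trial count.
#' @param y detection count (default 0).
#' @return `P(z = 1 | y, theta, delta, n)`, vectorized.
#' @export
zib_z_conditional <- function(theta, delta, n, y = 0) {
  a <- theta * (1 - delta)^n
  y <- rep_len(y, length(a))
  ifelse(y > 0, 1, a / (a + (1 - theta)))
}

#' Fit the zero-inflated binomial occupancy model by MCMC
#'
#' Latent suitability `z_i ~ Bernoulli(logit^-1(x_i' beta))` with
#' detections `y_i ~ Binomial(n_i, z_i * delta)` and an intercept-only
#' detection probability `delta = logit^-1(gamma)`, fitted by
#' Metropolis-within-Gibbs (exact `z` conditional, adaptive random-walk
#' Metropolis for `beta` and `gamma` with adaptation confined to burn-in).
#' Priors are independent normals (default mean 0, variance 1e6).
#' Covariates are standardized internally; coefficients are reported on
#' both scales. Cells with `n = 0` are excluded from the likelihood but can
#' be predicted.
#'
#' @param data data.frame with columns `n`, `y` and covariates.
#' @param formula right-hand-side formula for the suitability submodel
#'   (default: all columns other than `cell`, `n`, `y`, `lon`, `lat`).
#' @param chains number of chains (default 3).
#' @param burnin burn-in iterations per chain (default 10000).
#' @param iters post-burn-in iterations per chain (default 50000).
#' @param thin thinning interval (default 50).
#' @param seed integer seed.
#' @param prior_mean prior mean for all coefficients (scalar or vector over
#'   `c(beta, gamma)`).
#' @param prior_var prior variance (default 1e6).
#' @param standardize center/scale covariate columns (default TRUE).
#' @return object of class `posterior_draws`: `draws` array
#'   (kept x parameters x chains; parameters are the standardized-scale
#'   betas plus `gamma`), `deviance` matrix (kept x chains), `z_prob`
#'   (posterior occupancy probability per fitted cell), acceptance rates,
#'   the design matrix and data, and the standardization record.
#' @export
fit_zib <- function(data, formula = NULL, chains = 3, burnin = 10000,
                    iters = 50000, thin = 50, seed = 1,
                    prior_mean = 0, prior_var = 1e6, standardize = TRUE) {
  stopifnot(all(c("n", "y") %in% names(data)))
  if (any(data$y > data$n)) stop("y must not exceed n")
  if (is.null(formula)) {
    covs <- setdiff(names(data), c("cell", "n", "y", "lon", "lat"))
    formula <- stats::as.formula(paste("~", paste(covs, collapse = " + ")))
  }
  fit_data <- data[data$n > 0, , drop = FALSE]
  if (sum(fit_data$y > 0) < 1L) stop("no cells with a detection")
  X <- build_design(formula, fit_data)
  xlev <- attr(X, "xlev")
  centers <- rep(0, ncol(X)); scales <- rep(1, ncol(X))
  names(centers) <- names(scales) <- colnames(X)
  if (standardize) {
    for (j in seq_len(ncol(X))[-1L]) {
      s <- stats::sd(X[, j])
      if (s > 0) {
        centers[j] <- mean(X[, j]); scales[j] <- s
        X[, j] <- (X[, j] - centers[j]) / s
      }
    }
  }
  p <- ncol(X)
  pm <- rep_len(prior_mean, p + 1L)
  par_names <- c(colnames(X), "gamma")

  kept <- iters %/% thin
  draws <- array(NA_real_, c(kept, p + 1L, chains),
                 dimnames = list(NULL, par_names, NULL))
  deviance <- matrix(NA_real_, kept, chains)
  z_prob <- matrix(NA_real_, nrow(fit_data), chains)
  acceptance <- matrix(NA_real_, p + 1L, chains,
                       dimnames = list(par_names, NULL))
  for (ch in seq_len(chains)) {
    set.seed(substream_seed(seed, paste0("zib_chain", ch)))
    beta0 <- stats::rnorm(p, 0, 0.5)   # overdispersed starts
    gamma0 <- stats::rnorm(1, 0, 0.5)
    res <- .zib_chain(as.integer(fit_data$y), as.integer(fit_data$n), X,
                      beta0, gamma0, pm, prior_var,
                      as.integer(burnin), as.integer(iters),
                      as.integer(thin), 0.2, TRUE)
    draws[, , ch] <- res$draws
    deviance[, ch] <- res$deviance
    z_prob[, ch] <- res$z_mean
    acceptance[, ch] <- res$acceptance
  }
  post_adapt <- acceptance
  if (any(post_adapt < 0.05 | post_adapt > 0.95, na.rm = TRUE)) {
    warning("Metropolis acceptance rate outside [5%, 95%] after adaptation")
  }
  structure(list(draws = draws, deviance = deviance,
                 z_prob = rowMeans(z_prob), acceptance = acceptance,
                 burnin = burnin, iters = iters, thin = thin, chains = chains,
                 X = X, y = fit_data$y, n = fit_data$n,
                 formula = formula, xlev = xlev,
                 centers = centers, scales = scales, seed = seed),
            class = "posterior_draws")
}

# all chains pooled, kept x params
pool_draws <- function(draws) {
  do.call(rbind, lapply(seq_len(dim(draws$draws)[3L]),
                        function(ch) draws$draws[, , ch, drop = FALSE][, , 1L]))
}

#' Summarize a ZIB posterior
#'
#' @param object a `posterior_draws`.
#' @param prob credible-interval mass (default 0.95).
#' @param ... unused.
#' @return data.frame with posterior mean, SD and equal-tailed CI per
#'   parameter on the standardized scale, plus the natural-scale
#'   coefficients (`estimate_raw`) and `delta` (the detection probability)
#'   as the transformed `gamma` row.
#' @export
summary.posterior_draws <- function(object, prob = 0.95, ...) {
  D <- pool_draws(object)
  a <- (1 - prob) / 2
  tab <- data.frame(
    parameter = colnames(D),
    mean = colMeans(D),
    sd = apply(D, 2L, stats::sd),
    lower = apply(D, 2L, stats::quantile, probs = a),
    upper = apply(D, 2L, stats::quantile, probs = 1 - a),
    row.names = NULL
  )
  # back-transform standardized betas to the covariate's natural scale
  p <- length(object$scales)
  raw <- tab$mean[seq_len(p)] / object$scales
  raw[1L] <- tab$mean[1L] - if (p > 1L) {
    sum(tab$mean[2:p] * object$centers[-1L] / object$scales[-1L])
  } else 0
  tab$estimate_raw <- c(raw, NA_real_)
  delta_draws <- stats::plogis(D[, "gamma"])
  attr(tab, "delta") <- c(mean = mean(delta_draws),
                          lower = stats::quantile(delta_draws, a,
                                                  names = FALSE),
                          upper = stats::quantile(delta_draws, 1 - a,
                                                  names = FALSE))
  tab
}

#' @export
print.posterior_draws <- function(x, ...) {
  cat(sprintf(
    "<posterior_draws> %d chains x %d kept draws (burnin %d, thin %d)\n",
    x$chains, dim(x$draws)[1L], x$burnin, x$thin))
  print(summary(x), digits = 3)
  invisible(x)
}

#' Deviance information criterion of a ZIB fit
#'
#' `DIC = Dbar + pD` with `pD = Dbar - D(posterior mean parameters)`, both
#' deviances on the z-marginalized likelihood
#' `L_i = theta_i Binom(y_i | n_i, delta) + (1 - theta_i) 1[y_i = 0]`.
#' Negative `pD` (a known DIC pathology under poor mixing or multimodality)
#' is reported with a warning, not an error.
#'
#' @param draws a `posterior_draws`.
#' @return list: `dic`, `dbar`, `d_hat`, `p_d`.
#' @export
dic <- function(draws) {
  stopifnot(inherits(draws, "posterior_draws"))
  dbar <- mean(draws$deviance)
  D <- pool_draws(draws)
  mp <- colMeans(D)
  p <- ncol(draws$X)
  eta <- drop(draws$X %*% mp[seq_len(p)])
  theta <- stats::plogis(eta)
  delta <- stats::plogis(mp[p + 1L])
  L <- theta * stats::dbinom(draws$y, draws$n, delta) +
    (1 - theta) * (draws$y == 0)
  d_hat <- -2 * sum(log(pmax(L, 1e-300)))
  p_d <- dbar - d_hat
  if (p_d < 0) warning(sprintf("negative effective parameter count pD = %.3f",
                               p_d))
  list(dic = dbar + p_d, dbar = dbar, d_hat = d_hat, p_d = p_d)
}

#' Brooks-Gelman multivariate potential scale reduction factor
#'
#' Convergence diagnostic across chains: values near 1 indicate the
#' between-chain covariance has collapsed into the within-chain
#' covariance.
#'
#' @param draws a `posterior_draws`, or a list of chains (each a draws
#'   matrix with identical columns).
#' @return the MPSRF (>= (n-1)/n by construction).
#' @export
mpsrf <- function(draws) {
  chains <- if (inherits(draws, "posterior_draws")) {
    lapply(seq_len(dim(draws$draws)[3L]),
           function(ch) draws$draws[, , ch, drop = FALSE][, , 1L])
  } else {
    draws
  }
  m <- length(chains)
  if (m < 2L) stop("MPSRF needs at least two chains")
  n <- nrow(chains[[1L]])
  W <- Reduce(`+`, lapply(chains, stats::cov)) / m
  means <- t(vapply(chains, colMeans, numeric(ncol(chains[[1L]]))))
  Bn <- stats::cov(means)                     # B/n
  lam <- tryCatch(
    max(Re(eigen(solve(W, Bn), only.values = TRUE)$values)),
    error = function(e) stop("within-chain covariance is singular: ",
                             conditionMessage(e)))
  (n - 1) / n + (m + 1) / m * lam
}

#' Posterior mean occurrence probability over a covariate stack
#'
#' @param draws a `posterior_draws`.
#' @param covariates `grid_stack` with band labels naming the covariates,
#'   or a data.frame.
#' @param prob credible-interval mass for the CI grids (default 0.95).
#' @return for a stack: list of `geo_grid`s `mean`, `lower`, `upper`;
#'   for a data.frame: matrix with those columns.
#' @export
predict_occurrence <- function(draws, covariates, prob = 0.95) {
  stopifnot(inherits(draws, "posterior_draws"))
  if (inherits(covariates, "grid_stack")) {
    df <- as.data.frame(lapply(covariates$grids, function(g) {
      v <- g$values; v[g$mask] <- NA; as.vector(v)
    }))
    names(df) <- covariates$labels
  } else {
    df <- covariates
  }
  mm <- build_design(draws$formula, df, xlev = draws$xlev)
  mm <- sweep(sweep(mm, 2L, draws$centers[colnames(mm)]), 2L,
              draws$scales[colnames(mm)], `/`)
  D <- pool_draws(draws)
  p <- ncol(mm)
  theta_draws <- stats::plogis(tcrossprod(mm, D[, seq_len(p), drop = FALSE]))
  a <- (1 - prob) / 2
  out <- cbind(mean = rowMeans(theta_draws),
               lower = apply(theta_draws, 1L, stats::quantile, probs = a,
                             na.rm = FALSE),
               upper = apply(theta_draws, 1L, stats::quantile, probs = 1 - a))
  if (inherits(covariates, "grid_stack")) {
    template <- covariates$grids[[1L]]
    nr <- nrow(template$values); nc <- ncol(template$values)
    list(mean = grid_from(matrix(out[, "mean"], nr, nc), template),
         lower = grid_from(matrix(out[, "lower"], nr, nc), template),
         upper = grid_from(matrix(out[, "upper"], nr, nc), template))
  } else {
    out
  }
}

#' Probabilistic range size
#'
#' The expected number of occupied cells: the sum of per-cell posterior
#' mean occurrence probabilities over the modeling domain, with no
#' threshold. Two cells at probability 0.5 contribute one cell.
#'
#' @param theta a `geo_grid` of occurrence probabilities, or a numeric
#'   vector.
#' @return expected occupied-cell count.
#' @export
range_size <- function(theta) {
  v <- if (is_geo_grid(theta)) theta$values[!theta$mask] else theta
  v <- v[!is.na(v)]
  if (any(v < 0 | v > 1)) stop("theta must be probabilities in [0, 1]")
  sum(v)
}

#' Evaluate occupancy predictions against cell-level detections
#'
#' AUC contrasts cells with at least one detection against never-detected
#' cells; COR is the Pearson correlation between the observed detection
#' rate `y/n` and the predicted occurrence probability.
#'
#' @param theta predicted occurrence probabilities at the surveyed cells.
#' @param y,n detection and trial counts at the same cells.
#' @return list: `auc`, `cor` (NA with a warning for constant
#'   predictions).
#' @export
evaluate_occupancy <- function(theta, y, n) {
  ok <- !is.na(theta) & n > 0
  theta <- theta[ok]; y <- y[ok]; n <- n[ok]
  pres <- y > 0
  auc <- rank_auc(theta[pres], theta[!pres])
  corv <- if (stats::sd(theta) == 0 || stats::sd(y / n) == 0) {
    warning("constant predictions or observations; correlation undefined")
    NA_real_
  } else {
    stats::cor(y / n, theta)
  }
  list(auc = auc, cor = corv)
}
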
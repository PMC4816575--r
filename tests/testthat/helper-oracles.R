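# Independent brute-force oracles; deliberately naive implementations that
# never share code paths with the package functions they check.

# double-loop circular focal statistic
focal_brute <- function(grid, radius, stat = "sd", sd_type = "sample") {
  v <- grid$values; msk <- grid$mask
  nr <- nrow(v); nc <- ncol(v)
  out <- matrix(NA_real_, nr, nc)
  for (r in seq_len(nr)) for (c_ in seq_len(nc)) {
    if (msk[r, c_]) next
    vals <- c()
    for (rr in seq_len(nr)) for (cc in seq_len(nc)) {
      if (!msk[rr, cc] && (rr - r)^2 + (cc - c_)^2 <= radius^2) {
        vals <- c(vals, v[rr, cc])
      }
    }
    if (stat == "mean") {
      if (length(vals) >= 1) out[r, c_] <- mean(vals)
    } else if (length(vals) >= 2) {
      out[r, c_] <- if (sd_type == "population") {
        sqrt(mean((vals - mean(vals))^2))
      } else {
        sd(vals)
      }
    }
  }
  out
}

# full-matrix double-sum Moran's I / Geary's C
dense_weights <- function(w) {
  W <- matrix(0, w$n_sites, w$n_sites)
  for (k in seq_along(w$i)) {
    W[w$i[k], w$j[k]] <- W[w$i[k], w$j[k]] + w$w[k]
    W[w$j[k], w$i[k]] <- W[w$j[k], w$i[k]] + w$w[k]
  }
  W
}

morans_brute <- function(x, w) {
  W <- dense_weights(w)
  n <- length(x); xb <- mean(x)
  num <- 0
  for (i in 1:n) for (j in 1:n) num <- num + W[i, j] * (x[i] - xb) * (x[j] - xb)
  (n / sum(W)) * num / sum((x - xb)^2)
}

gearys_brute <- function(x, w) {
  W <- dense_weights(w)
  n <- length(x); xb <- mean(x)
  num <- 0
  for (i in 1:n) for (j in 1:n) num <- num + W[i, j] * (x[i] - x[j])^2
  ((n - 1) / (2 * sum(W))) * num / sum((x - xb)^2)
}

# discretized inhomogeneous Poisson point-process log-likelihood, maximized
# by a generic optimizer: the independent route to the IWLR slope
ppm_poisson_mle <- function(pres_x, cell_x) {
  nll <- function(par) {
    eta_p <- par[1] + par[2] * pres_x
    eta_c <- par[1] + par[2] * cell_x
    -(sum(eta_p) - sum(exp(eta_c)))
  }
  optim(c(0, 0), nll, method = "BFGS",
        control = list(maxit = 500, reltol = 1e-14))$par
}

# exact P(z_i = 1 | y, beta, gamma) on a tiny ZIB model by summing the joint
# over all 2^k latent configurations
zib_enum_pz <- function(y, n, theta, delta) {
  k <- length(y)
  configs <- as.matrix(expand.grid(rep(list(0:1), k)))
  joint <- apply(configs, 1, function(z) {
    prod(ifelse(z == 1, theta, 1 - theta)) *
      prod(dbinom(y, n, z * delta))
  })
  sapply(seq_len(k), function(i) {
    sum(joint[configs[, i] == 1]) / sum(joint)
  })
}

# trapezoidal ROC integration (threshold sweep), independent of the rank AUC
auc_trapezoid <- function(pos, neg) {
  th <- sort(unique(c(pos, neg, -Inf, Inf)), decreasing = TRUE)
  tpr <- sapply(th, function(t) mean(pos >= t))
  fpr <- sapply(th, function(t) mean(neg >= t))
  sum(diff(fpr) * (head(tpr, -1) + tail(tpr, -1)) / 2)
}

rmse_to <- function(a, b) sqrt(mean((a - b)^2, na.rm = TRUE))

# random georeferenced grid with a few masked cells
random_grid <- function(nr = 10, nc = 10, n_masked = 3, seed = 1) {
  set.seed(seed)
  v <- matrix(runif(nr * nc), nr, nc)
  m <- matrix(FALSE, nr, nc)
  m[sample.int(nr * nc, n_masked)] <- TRUE
  geo_grid(v, mask = m, xmin = -5, ymax = 8, cellsize = 0.05)
}
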
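#' Synthetic world generators
#'
#' Everything the pipeline consumes can be generated here with known ground
#' truth: smooth monthly cloud-probability surfaces, twice-daily binary
#' cloud-flag stacks with orbital-gap stripes, station records, presence
#' points from an inhomogeneous point process, and cell-level
#' detection/nondetection data from a zero-inflated binomial. All draws are
#' reproducible from a single root seed via named substreams.
#'
#' @name synthetic_data
NULL

#' Derive a named substream seed from a root seed
#'
#' @param seed root integer seed.
#' @param name substream name (`"truth"`, `"stack"`, `"stations"`,
#'   `"points"`, `"occupancy"`, or any string).
#' @return an integer seed `< 2^31`, distinct per name.
#' @export
substream_seed <- function(seed, name) {
  h <- sum(utf8ToInt(name) * seq_along(utf8ToInt(name)))
  as.integer((abs(as.numeric(seed)) * 7919 + h * 104729) %% 2147483629)
}

# separable Gaussian smoothing with edge replication
gaussian_smooth <- function(m, sigma) {
  if (sigma <= 0) return(m)
  half <- max(1L, ceiling(3 * sigma))
  k <- stats::dnorm(-half:half, sd = sigma)
  k <- k / sum(k)
  pad_conv <- function(v) {
    vp <- c(rep(v[1L], half), v, rep(v[length(v)], half))
    as.numeric(stats::filter(vp, k, sides = 2))[(half + 1L):(half + length(v))]
  }
  m <- apply(m, 2L, pad_conv)
  t(apply(m, 1L, pad_conv))
}

#' Generate a ground-truth monthly cloud-probability climatology
#'
#' Builds 12 monthly probability surfaces as a spatially smooth base field
#' (Gaussian-filtered white noise rescaled to `p_range`) modulated by a
#' chosen seasonal structure: none (`"uniform"`), a single annual peak
#' (`"sinusoid"`), or two peaks six months apart (`"bimodal"`).
#'
#' @param nrow,ncol grid shape.
#' @param seasonal_mode `"uniform"`, `"sinusoid"` or `"bimodal"`.
#' @param p_range length-2 range of the annual-mean probability field; a
#'   single value gives a spatially constant field.
#' @param amplitude seasonal half-amplitude (probability units).
#' @param peak_month month (1-12) of maximum cloudiness.
#' @param smoothness Gaussian smoothing sigma, in cells, of the base field.
#' @param seed integer seed.
#' @param cellsize,xmin,ymax georeference passed to [geo_grid()].
#' @return a `grid_stack` of 12 probability grids labelled `"01".."12"`,
#'   with the generator parameters attached as attribute `truth`.
#' @export
generate_truth_climatology <- function(nrow, ncol,
                                       seasonal_mode = c("uniform", "sinusoid",
                                                         "bimodal"),
                                       p_range = c(0.3, 0.7), amplitude = 0,
                                       peak_month = 1, smoothness = 3,
                                       seed = 1, cellsize = 1 / 120,
                                       xmin = 0, ymax = NULL) {
  seasonal_mode <- match.arg(seasonal_mode)
  if (length(p_range) == 1L) p_range <- c(p_range, p_range)
  lo <- min(p_range); hi <- max(p_range)
  amp <- if (seasonal_mode == "uniform") 0 else amplitude
  if (lo - amp < 0 || hi + amp > 1) {
    stop("p_range with seasonal amplitude must stay within [0, 1]")
  }
  set.seed(substream_seed(seed, "truth"))
  base <- gaussian_smooth(matrix(stats::rnorm(nrow * ncol), nrow, ncol),
                          smoothness)
  rng <- range(base)
  base <- if (diff(rng) < .Machine$double.eps || lo == hi) {
    matrix((lo + hi) / 2, nrow, ncol)
  } else {
    lo + (base - rng[1L]) / diff(rng) * (hi - lo)
  }
  harmonics <- switch(seasonal_mode, uniform = 0, sinusoid = 1, bimodal = 2)
  months <- 1:12
  grids <- lapply(months, function(m) {
    p <- base + amp * cos(harmonics * 2 * pi * (m - peak_month) / 12)
    geo_grid(p, xmin = xmin, ymax = ymax, cellsize = cellsize)
  })
  out <- grid_stack(grids, labels = sprintf("%02d", months))
  attr(out, "truth") <- list(seasonal_mode = seasonal_mode, p_range = c(lo, hi),
                             amplitude = amp, peak_month = peak_month,
                             base = base, seed = seed)
  out
}

# rotated band coordinate: stripes run at `theta_deg` from vertical
stripe_member <- function(nrow, ncol, theta_deg, spacing, width) {
  th <- theta_deg * pi / 180
  r <- matrix(seq_len(nrow), nrow, ncol)
  c_ <- matrix(seq_len(ncol), nrow, ncol, byrow = TRUE)
  b <- c_ * cos(th) + r * sin(th)
  (floor(b) %% spacing) < width
}

#' Simulate per-sensor daily cloud-flag stacks
#'
#' Each simulated day draws a binary cloud flag per pixel from the month's
#' ground-truth Bernoulli probability, independently per pixel and day.
#' Orbital artifacts are emulated two ways: validity-gap stripes (cells
#' along the sensor's stripe orientation have no valid observation every
#' `overpass_gap_period` days) and, optionally, a persistent multiplicative
#' bias of the flag probability along those bands (`stripe_amplitude`),
#' which is what the destriping stage removes.
#'
#' @param truth 12-band `grid_stack` of monthly probabilities
#'   (from [generate_truth_climatology()]).
#' @param years vector of simulated years.
#' @param days_per_month days simulated per month (default 30).
#' @param sensors list of sensor specs, each a list with `name`,
#'   `stripe_angle_deg`, `overpass_gap_period`, `stripe_amplitude`, and
#'   optionally `stripe_spacing`/`stripe_width` (cells).
#' @param seed integer seed.
#' @return list with `sensors` (per sensor: logical arrays `flags` and
#'   `valid` of shape rows x cols x days, and a `dates` data.frame with
#'   year/month/day), plus the `truth` stack for recovery tests.
#' @export
generate_cloud_stack <- function(truth, years = 2000:2004, days_per_month = 30,
                                 sensors = default_sensors(), seed = 1) {
  stopifnot(inherits(truth, "grid_stack"), length(truth) == 12L)
  if (days_per_month < 1) stop("at least one simulated day per month required")
  nr <- nrow(truth$grids[[1L]]$values); nc <- ncol(truth$grids[[1L]]$values)
  dates <- expand.grid(day = seq_len(days_per_month), month = 1:12,
                       year = years)[, c("year", "month", "day")]
  nd <- nrow(dates)
  set.seed(substream_seed(seed, "stack"))
  out <- lapply(sensors, function(sn) {
    striped <- stripe_member(nr, nc, sn$stripe_angle_deg,
                             sn$stripe_spacing %||% 10L,
                             sn$stripe_width %||% 2L)
    flags <- array(FALSE, c(nr, nc, nd))
    valid <- array(TRUE, c(nr, nc, nd))
    amp <- sn$stripe_amplitude %||% 0
    for (d in seq_len(nd)) {
      p <- truth$grids[[dates$month[d]]]$values
      if (amp != 0) p <- ifelse(striped, pmin(1, pmax(0, p * (1 + amp))), p)
      flags[, , d] <- matrix(stats::runif(nr * nc) < p, nr, nc)
      if (d %% sn$overpass_gap_period == 0) valid[, , d][striped] <- FALSE
    }
    flags[!valid] <- FALSE
    list(name = sn$name, flags = flags, valid = valid, dates = dates,
         striped = striped)
  })
  names(out) <- vapply(sensors, `[[`, "", "name")
  list(sensors = out, truth = truth, dates = dates, seed = seed)
}

#' Default two-sensor design (morning/afternoon overpasses)
#'
#' @param stripe_amplitude multiplicative cloud-frequency bias along stripe
#'   bands (0 disables; destriping tests use 0.15).
#' @return list of two sensor specs with stripe orientations +15 and -15
#'   degrees and a 16-day overpass gap cycle.
#' @export
default_sensors <- function(stripe_amplitude = 0) {
  list(
    list(name = "am", stripe_angle_deg = 15, overpass_gap_period = 16L,
         stripe_amplitude = stripe_amplitude),
    list(name = "pm", stripe_angle_deg = -15, overpass_gap_period = 16L,
         stripe_amplitude = stripe_amplitude)
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Simulate monthly station cloud-amount records
#'
#' Station truth is the mean ground-truth monthly probability within a
#' circular footprint around the station (in percent), observed with
#' additive Gaussian noise. Per-month/per-year observation counts are drawn
#' so that a configurable fraction of stations fails the 20-observation
#' completeness filters, exercising the filtering stage.
#'
#' @param truth 12-band probability `grid_stack`.
#' @param n_stations number of stations, placed uniformly over the grid.
#' @param noise_sd observation noise SD in percent cloud amount (default 5).
#' @param radius_km footprint radius (default 16 km).
#' @param years years with observation counts.
#' @param frac_low fraction of stations given sparse reporting
#'   (mean ~10 obs/month, failing the >= 20 filter; the rest report
#'   several times daily, ~90 obs/month, and essentially always pass).
#' @param seed integer seed.
#' @return list: `stations` data.frame (`id`, `lon`, `lat`, `amount_01` ..
#'   `amount_12`), `obs_counts` long data.frame (`id`, `year`, `month`,
#'   `count`), and `truth_amount` matrix of noise-free footprint means (%).
#' @export
generate_station_records <- function(truth, n_stations = 100, noise_sd = 5,
                                     radius_km = 16, years = 2000:2009,
                                     frac_low = 0.2, seed = 1) {
  g1 <- truth$grids[[1L]]
  nr <- nrow(g1$values); nc <- ncol(g1$values)
  set.seed(substream_seed(seed, "stations"))
  lon <- stats::runif(n_stations, g1$xmin, g1$xmin + nc * g1$cellsize)
  lat <- stats::runif(n_stations, g1$ymax - nr * g1$cellsize, g1$ymax)
  rc <- point_to_cell(g1, lon, lat)
  if (anyNA(rc)) stop("station outside grid")
  truth_amount <- sapply(1:12, function(m) {
    vapply(seq_len(n_stations), function(i) {
      100 * station_footprint_mean(truth$grids[[m]], lon[i], lat[i],
                                   radius_km = radius_km)
    }, 0)
  })
  amounts <- truth_amount +
    matrix(stats::rnorm(n_stations * 12, sd = noise_sd), n_stations, 12)
  amounts <- pmin(pmax(amounts, 0), 100)   # matrix first: dims preserved
  stations <- data.frame(id = seq_len(n_stations), lon = lon, lat = lat)
  stations[sprintf("amount_%02d", 1:12)] <- as.data.frame(amounts)
  low <- stats::runif(n_stations) < frac_low
  counts <- expand.grid(month = 1:12, year = years, id = seq_len(n_stations))
  counts <- counts[, c("id", "year", "month")]
  lambda <- ifelse(low[counts$id], 10, 90)
  counts$count <- stats::rpois(nrow(counts), lambda)
  list(stations = stations, obs_counts = counts, truth_amount = truth_amount,
       noise_sd = noise_sd, low_reporting = low, seed = seed)
}

#' Simulate presence-only points from an inhomogeneous point process
#'
#' Cell intensities follow a log-linear model on the covariates; the total
#' intensity is scaled so the expected point count is `n_expected`, a
#' Poisson number of points is drawn, and points are placed by sampling
#' cells proportional to intensity and jittering uniformly within the cell
#' (equivalent to thinning a homogeneous Poisson process).
#'
#' @param intensity_coefs named numeric vector of slopes, one per covariate
#'   band in `covariates` (names must match band labels).
#' @param covariates `grid_stack` of covariate surfaces.
#' @param n_expected expected number of presence points.
#' @param region_breaks optional longitudes splitting the domain into
#'   labelled regions (`region1`, `region2`, ...).
#' @param seed integer seed.
#' @return data.frame (`lon`, `lat`, `region`) with attribute `truth`
#'   holding the coefficients and per-cell intensity.
#' @export
generate_presence_points <- function(intensity_coefs, covariates, n_expected,
                                     region_breaks = NULL, seed = 1) {
  stopifnot(inherits(covariates, "grid_stack"))
  if (!all(names(intensity_coefs) %in% covariates$labels)) {
    stop("intensity_coefs names must match covariate band labels")
  }
  g1 <- covariates$grids[[1L]]
  nr <- nrow(g1$values); nc <- ncol(g1$values)
  eta <- matrix(0, nr, nc)
  masked <- Reduce(`|`, lapply(covariates$grids, `[[`, "mask"))
  for (nm in names(intensity_coefs)) {
    eta <- eta + intensity_coefs[[nm]] * covariates$grids[[nm]]$values
  }
  lambda <- exp(eta)
  lambda[masked] <- 0
  lambda <- lambda / sum(lambda)
  set.seed(substream_seed(seed, "points"))
  n_pts <- stats::rpois(1L, n_expected)
  cells <- sample.int(nr * nc, n_pts, replace = TRUE, prob = as.vector(lambda))
  r <- (cells - 1L) %% nr + 1L
  c_ <- (cells - 1L) %/% nr + 1L
  lon <- g1$xmin + (c_ - stats::runif(n_pts)) * g1$cellsize
  lat <- g1$ymax - (r - stats::runif(n_pts)) * g1$cellsize
  region <- if (is.null(region_breaks)) {
    factor(rep("region1", n_pts))
  } else {
    factor(paste0("region", findInterval(lon, sort(region_breaks)) + 1L))
  }
  out <- data.frame(lon = lon, lat = lat, region = region)
  attr(out, "truth") <- list(coefs = intensity_coefs, lambda = lambda,
                             n_expected = n_expected, seed = seed)
  out
}

#' Simulate zero-inflated binomial occupancy data
#'
#' Latent suitability `z_i ~ Bernoulli(logit^-1(x_i' beta))`; detections
#' `y_i ~ Binomial(n_i, z_i * delta)` with constant detection probability
#' `delta` per trial, emulating per-cell counts of complete survey
#' checklists and detections.
#'
#' @param beta suitability coefficients; the first element is the intercept.
#' @param delta per-trial detection probability in `[0, 1]`.
#' @param X design matrix (cells x length(beta)) including the intercept
#'   column, or `NULL` to draw `n_cells` rows with standard-normal
#'   covariates.
#' @param n_cells number of cells when `X` is `NULL`.
#' @param trials_law function(n) returning `n` trial counts; default
#'   `1 + Poisson(4)` (sparse checklists).
#' @param seed integer seed.
#' @return list: `data` data.frame (`cell`, `n`, `y`, covariate columns
#'   `x1..`), latent `z`, and the generating `beta`, `delta`.
#' @export
generate_occupancy_data <- function(beta, delta, X = NULL, n_cells = 2000,
                                    trials_law = function(n)
                                      1L + stats::rpois(n, 4),
                                    seed = 1) {
  if (delta < 0 || delta > 1) stop("delta must be in [0, 1]")
  set.seed(substream_seed(seed, "occupancy"))
  p <- length(beta)
  if (is.null(X)) {
    X <- cbind(1, matrix(stats::rnorm(n_cells * (p - 1L)), n_cells, p - 1L))
  }
  n_cells <- nrow(X)
  stopifnot(ncol(X) == p)
  theta <- stats::plogis(drop(X %*% beta))
  z <- stats::rbinom(n_cells, 1L, theta)
  n <- trials_law(n_cells)
  y <- stats::rbinom(n_cells, n, z * delta)
  dat <- data.frame(cell = seq_len(n_cells), n = n, y = y)
  dat[paste0("x", seq_len(p - 1L))] <- as.data.frame(X[, -1L, drop = FALSE])
  list(data = dat, z = z, beta = beta, delta = delta, X = X, seed = seed)
}
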
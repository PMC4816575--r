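#' Monthly cloud frequency from daily flags
#'
#' Cloud frequency (CF) is the percentage of valid daily observations at a
#' pixel that carry a positive cloud flag. Cells with no valid observation
#' in the month are masked.
#'
#' @param flags logical (or 0/1) array rows x cols x days of daily flags.
#' @param valid logical array of the same shape marking valid observations.
#' @param template `geo_grid` supplying the georeference.
#' @return list: `cf` (`geo_grid`, percent) and `n` (`geo_grid`, valid
#'   observation counts).
#' @export
monthly_frequency <- function(flags, valid, template) {
  if (!identical(dim(flags), dim(valid))) {
    stop("flags and valid must have identical shape")
  }
  if (length(dim(flags)) == 2L) {
    dim(flags) <- c(dim(flags), 1L); dim(valid) <- c(dim(valid), 1L)
  }
  pos <- rowSums(flags & valid, dims = 2L)
  n <- rowSums(valid, dims = 2L)
  cf <- ifelse(n >= 1, 100 * pos / n, NA_real_)
  list(
    cf = geo_grid(cf, xmin = template$xmin, ymax = template$ymax,
                  cellsize = template$cellsize, crs = template$crs),
    n = geo_grid(n, xmin = template$xmin, ymax = template$ymax,
                 cellsize = template$cellsize, crs = template$crs)
  )
}

#' Monthly CF time series for one simulated sensor
#'
#' @param sim output of [generate_cloud_stack()].
#' @param sensor sensor name.
#' @return list: `cf` and `n` arrays of shape rows x cols x 12 x years
#'   (percent / counts, `NA` where no valid observation) plus the grid
#'   `template` and the `years` vector.
#' @export
monthly_cf_series <- function(sim, sensor) {
  sn <- sim$sensors[[sensor]]
  if (is.null(sn)) stop(sprintf("unknown sensor '%s'", sensor))
  template <- sim$truth$grids[[1L]]
  years <- sort(unique(sn$dates$year))
  nr <- dim(sn$flags)[1L]; nc <- dim(sn$flags)[2L]
  cf <- array(NA_real_, c(nr, nc, 12L, length(years)))
  n <- array(0, c(nr, nc, 12L, length(years)))
  for (yi in seq_along(years)) {
    for (m in 1:12) {
      idx <- which(sn$dates$month == m & sn$dates$year == years[yi])
      if (length(idx) == 0L) next
      pos <- rowSums(sn$flags[, , idx, drop = FALSE] &
                       sn$valid[, , idx, drop = FALSE], dims = 2L)
      nv <- rowSums(sn$valid[, , idx, drop = FALSE], dims = 2L)
      cf[, , m, yi] <- ifelse(nv >= 1, 100 * pos / nv, NA_real_)
      n[, , m, yi] <- nv
    }
  }
  list(cf = cf, n = n, template = template, years = years)
}

grid_from <- function(values, template) {
  geo_grid(values, xmin = template$xmin, ymax = template$ymax,
           cellsize = template$cellsize, crs = template$crs)
}

#' Climatological monthly means and inter-annual SDs
#'
#' For each month m, `mu[m]` is the mean over years of the monthly CF and
#' `sigma[m]` its sample SD over years; `sigma` is masked where fewer than
#' two years contribute.
#'
#' @param mcf output of [monthly_cf_series()] (or any list with a `cf`
#'   rows x cols x 12 x years array and a `template`).
#' @return list of two 12-band `grid_stack`s, `mu` and `sigma` (percent).
#' @export
climatological_stats <- function(mcf) {
  cf <- mcf$cf
  template <- mcf$template
  mu <- vector("list", 12L); sigma <- vector("list", 12L)
  for (m in 1:12) {
    x <- cf[, , m, , drop = FALSE]
    dim(x) <- dim(x)[c(1L, 2L, 4L)]
    navail <- rowSums(!is.na(x), dims = 2L)
    mean_m <- rowMeans(x, dims = 2L, na.rm = TRUE)
    mean_m[navail < 1] <- NA_real_
    dev2 <- sweep(x, 1:2, mean_m)^2
    ss <- rowSums(dev2, dims = 2L, na.rm = TRUE)
    sd_m <- ifelse(navail >= 2, sqrt(ss / (navail - 1)), NA_real_)
    mu[[m]] <- grid_from(mean_m, template)
    sigma[[m]] <- grid_from(sd_m, template)
  }
  list(mu = grid_stack(mu, labels = sprintf("%02d", 1:12)),
       sigma = grid_stack(sigma, labels = sprintf("%02d", 1:12)))
}

#' Merge per-sensor monthly climatologies
#'
#' Equal-weight mean of the sensors' monthly means where both are valid,
#' the available sensor where only one is valid, masked where neither is.
#'
#' @param mu_list list of 12-band `grid_stack`s, one per sensor.
#' @return combined 12-band `grid_stack`.
#' @export
merge_sensors <- function(mu_list) {
  stopifnot(length(mu_list) >= 1L)
  template <- mu_list[[1L]]$grids[[1L]]
  grids <- lapply(1:12, function(m) {
    vals <- lapply(mu_list, function(s) s$grids[[m]]$values)
    a <- Reduce(`+`, lapply(vals, function(v) ifelse(is.na(v), 0, v)))
    n <- Reduce(`+`, lapply(vals, function(v) !is.na(v)))
    grid_from(ifelse(n >= 1, a / n, NA_real_), template)
  })
  grid_stack(grids, labels = sprintf("%02d", 1:12))
}

#' Cloud climatology container
#'
#' Bundles the 12 climatological monthly means and SDs with the derived
#' annual metrics filled in by [derived_metrics()] and
#' [seasonal_concentration()].
#'
#' @param mu 12-band `grid_stack` of climatological monthly mean CF (%).
#' @param sigma optional 12-band `grid_stack` of inter-annual SDs (%).
#' @return object of class `cloud_climatology`.
#' @export
cloud_climatology <- function(mu, sigma = NULL) {
  stopifnot(inherits(mu, "grid_stack"), length(mu) == 12L)
  if (!is.null(sigma)) stopifnot(inherits(sigma, "grid_stack"),
                                 length(sigma) == 12L)
  structure(list(mu = mu, sigma = sigma), class = "cloud_climatology")
}

#' @export
print.cloud_climatology <- function(x, ...) {
  cat("<cloud_climatology>\n  monthly means:\n")
  print(x$mu$grids[[1L]])
  cat(sprintf("  derived metrics: %s\n",
              paste(intersect(names(x), c("mean_annual", "intra_annual",
                                          "inter_annual", "spatial_var",
                                          "concentration", "peak_month")),
                    collapse = ", ")))
  invisible(x)
}

stack_to_matrix <- function(stack) {
  matrix(vapply(stack$grids, function(g) as.vector(g$values),
                numeric(length(stack$grids[[1L]]$values))),
         ncol = length(stack$grids))
}

#' Annual summary metrics of a cloud climatology
#'
#' Fills in: `mean_annual` (mean of available monthly means), `intra_annual`
#' (sample SD of the monthly means — seasonality), `inter_annual` (mean of
#' the monthly inter-annual SDs — year-to-year stability), `spatial_var`
#' (circular moving-window SD of `mean_annual`) and `months_available`.
#' Cells with fewer than two available months are masked in `intra_annual`.
#'
#' @param clim a `cloud_climatology`.
#' @param window_radius radius (cells) of the spatial-variability window;
#'   `NULL` skips `spatial_var`.
#' @return the `cloud_climatology` with metric grids added.
#' @export
derived_metrics <- function(clim, window_radius = NULL) {
  stopifnot(inherits(clim, "cloud_climatology"))
  template <- clim$mu$grids[[1L]]
  nr <- nrow(template$values); nc <- ncol(template$values)
  M <- stack_to_matrix(clim$mu)                  # ncell x 12
  navail <- rowSums(!is.na(M))
  mean_ann <- rowMeans(M, na.rm = TRUE)
  mean_ann[navail < 1] <- NA_real_
  ss <- rowSums((M - mean_ann)^2, na.rm = TRUE)
  intra <- ifelse(navail >= 2, sqrt(ss / (navail - 1)), NA_real_)
  clim$mean_annual <- grid_from(matrix(mean_ann, nr, nc), template)
  clim$intra_annual <- grid_from(matrix(intra, nr, nc), template)
  clim$months_available <- grid_from(matrix(navail, nr, nc), template)
  if (!is.null(clim$sigma)) {
    S <- stack_to_matrix(clim$sigma)
    ns <- rowSums(!is.na(S))
    inter <- rowMeans(S, na.rm = TRUE)
    inter[ns < 1] <- NA_real_
    clim$inter_annual <- grid_from(matrix(inter, nr, nc), template)
  }
  if (!is.null(window_radius)) {
    clim$spatial_var <- circular_window_stat(clim$mean_annual, window_radius,
                                             stat = "sd")
  }
  clim
}

#' Seasonal concentration index and peak month
#'
#' Places the 12 climatological monthly means on a polar "month clock"
#' (month m at angle 2*pi*(m-1)/12), sums the vectors, and reports the
#' resultant magnitude normalized by total annual cloudiness, scaled to
#' 0..100: 0 means equal cloudiness in all months, 100 means all observed
#' clouds fall in a single month. The resultant direction gives the month
#' of peak cloudiness (ties broken toward the earlier calendar month).
#' Cells with fewer than two available months, or zero total cloudiness,
#' are masked.
#'
#' @param mu either a numeric vector of 12 monthly means (single pixel) or
#'   a `cloud_climatology`.
#' @param ... unused.
#' @return for a vector: list(`index`, `peak_month`); for a
#'   `cloud_climatology`: the object with `concentration` and `peak_month`
#'   grids added.
#' @export
seasonal_concentration <- function(mu, ...) UseMethod("seasonal_concentration")

concentration_core <- function(M) {
  # M: ncell x 12, NA = missing month
  phi <- 2 * pi * (0:11) / 12
  avail <- !is.na(M)
  M0 <- ifelse(avail, M, 0)
  sx <- drop(M0 %*% cos(phi)); sy <- drop(M0 %*% sin(phi))
  total <- rowSums(M0)
  navail <- rowSums(avail)
  index <- 100 * sqrt(sx^2 + sy^2) / total
  index[index < 1e-9] <- 0   # snap resultants that cancel to rounding noise
  bad <- navail < 2 | total <= 0
  index[bad] <- NA_real_
  ang <- atan2(sy, sx) %% (2 * pi)
  d <- abs(((outer(ang, phi, `-`) + pi) %% (2 * pi)) - pi)
  peak <- max.col(-d, ties.method = "first")
  peak[bad | sqrt(sx^2 + sy^2) < 1e-12 * pmax(total, 1)] <- NA_integer_
  list(index = pmin(100, index), peak_month = peak)
}

#' @rdname seasonal_concentration
#' @export
seasonal_concentration.numeric <- function(mu, ...) {
  stopifnot(length(mu) == 12L)
  res <- concentration_core(matrix(mu, nrow = 1L))
  list(index = res$index, peak_month = res$peak_month)
}

#' @rdname seasonal_concentration
#' @export
seasonal_concentration.cloud_climatology <- function(mu, ...) {
  clim <- mu
  template <- clim$mu$grids[[1L]]
  nr <- nrow(template$values); nc <- ncol(template$values)
  res <- concentration_core(stack_to_matrix(clim$mu))
  clim$concentration <- grid_from(matrix(res$index, nr, nc), template)
  clim$peak_month <- grid_from(matrix(res$peak_month, nr, nc), template)
  clim
}

#' Classify cloud-stability hotspots
#'
#' Cells in the top decile of mean annual cloud frequency are classified by
#' whether they also fall in the bottom decile of intra-annual variability
#' (`intra_stable`), inter-annual variability (`inter_stable`), both
#' (`both`), or neither (`none`). Quantiles are computed over unmasked
#' cells of the full domain.
#'
#' @param clim a `cloud_climatology` with `mean_annual`, `intra_annual` and
#'   `inter_annual` filled (see [derived_metrics()]).
#' @param q_top quantile of mean annual CF defining a hotspot (default 0.90).
#' @param q_bottom variability quantile defining stability (default 0.10).
#' @return list: `classes` `geo_grid` coded {0 none, 1 intra, 2 inter,
#'   3 both, NA below the mean-annual cutoff or masked} and `thresholds`.
#' @export
hotspot_classification <- function(clim, q_top = 0.90, q_bottom = 0.10) {
  for (nm in c("mean_annual", "intra_annual", "inter_annual")) {
    if (is.null(clim[[nm]])) stop(sprintf("climatology lacks %s", nm))
  }
  ma <- clim$mean_annual$values
  ia <- clim$intra_annual$values
  ie <- clim$inter_annual$values
  qs <- function(v, q, nm) {
    x <- v[!is.na(v)]
    if (length(unique(x)) < 2L) {
      stop(sprintf("%s has no variation; decile cutoffs undefined", nm))
    }
    stats::quantile(x, q, names = FALSE, type = 7)
  }
  t_ma <- qs(ma, q_top, "mean_annual")
  t_ia <- qs(ia, q_bottom, "intra_annual")
  t_ie <- qs(ie, q_bottom, "inter_annual")
  hot <- !is.na(ma) & ma >= t_ma
  cls <- matrix(NA_real_, nrow(ma), ncol(ma))
  cls[hot] <- 0
  intra_ok <- hot & !is.na(ia) & ia <= t_ia
  inter_ok <- hot & !is.na(ie) & ie <= t_ie
  cls[intra_ok & !inter_ok] <- 1
  cls[inter_ok & !intra_ok] <- 2
  cls[intra_ok & inter_ok] <- 3
  template <- clim$mean_annual
  list(classes = grid_from(cls, template),
       thresholds = c(mean_annual = t_ma, intra_annual = t_ia,
                      inter_annual = t_ie),
       value_map = c(none = 0, intra_stable = 1, inter_stable = 2, both = 3))
}

#' Biome-level summary table of a cloud metric
#'
#' Zonal statistics of a climatology metric within integer-coded biomes,
#' with the column layout used for per-biome cloud summaries (`icode`,
#' `n`, `min`, `max`, `mean`, `sd`, plus optional metadata columns).
#'
#' @param metric a `geo_grid` (for example `clim$mean_annual`).
#' @param biomes integer-labelled `geo_grid` of biome codes.
#' @param product name recorded in the `product` column.
#' @param meta optional data.frame keyed by `icode` with extra columns
#'   (`code`, `realm`, `biome`, `area`) merged onto the result.
#' @return data.frame with columns `icode`, `n`, `min`, `max`, `mean`,
#'   `sd`, `product` (and any merged metadata).
#' @export
biome_summary <- function(metric, biomes, product = "cloud_metric",
                          meta = NULL) {
  tab <- zonal_stats(metric, biomes)
  names(tab)[names(tab) == "zone"] <- "icode"
  tab$product <- product
  if (!is.null(meta)) tab <- merge(tab, meta, by = "icode", all.x = TRUE)
  tab
}
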
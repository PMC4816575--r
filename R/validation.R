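#' Great-circle distance
#'
#' Haversine distance on a spherical Earth of radius 6371 km.
#'
#' @param lon1,lat1,lon2,lat2 coordinates in degrees (vectorized).
#' @return distance in km.
#' @export
great_circle_km <- function(lon1, lat1, lon2, lat2) {
  r <- 6371
  to_rad <- pi / 180
  dlat <- (lat2 - lat1) * to_rad
  dlon <- (lon2 - lon1) * to_rad
  a <- sin(dlat / 2)^2 +
    cos(lat1 * to_rad) * cos(lat2 * to_rad) * sin(dlon / 2)^2
  2 * r * asin(pmin(1, sqrt(a)))
}

#' Mean of a raster within a circular station footprint
#'
#' Ground observers report the cloud amount of the visible sky, an area far
#' larger than one ~1 km pixel; gridded cloud frequency is therefore
#' averaged over a circular footprint (default 16 km radius) before being
#' compared to a station record. The mean is unweighted over cells whose
#' centers lie within the great-circle radius.
#'
#' @param grid a `geo_grid`.
#' @param lon,lat station coordinates, degrees.
#' @param radius_km footprint radius (default 16).
#' @return the footprint mean, or `NA` when no unmasked cell center falls
#'   inside the footprint.
#' @export
station_footprint_mean <- function(grid, lon, lat, radius_km = 16) {
  cc <- cell_centers(grid)
  # bounding box first, exact great-circle test after
  dlat <- radius_km / 111.195
  dlon <- radius_km / (111.195 * max(cos(lat * pi / 180), 1e-6))
  rows <- which(cc$lat >= lat - dlat & cc$lat <= lat + dlat)
  cols <- which(cc$lon >= lon - dlon & cc$lon <= lon + dlon)
  if (length(rows) == 0L || length(cols) == 0L) return(NA_real_)
  d <- outer(cc$lat[rows], cc$lon[cols],
             function(la, lo) great_circle_km(lon, lat, lo, la))
  sel <- d <= radius_km & !grid$mask[rows, cols, drop = FALSE]
  if (!any(sel)) return(NA_real_)
  mean(grid$values[rows, cols, drop = FALSE][sel])
}

#' Filter stations by observation completeness
#'
#' Two archive-quality filters: `modis_era` keeps stations with at least
#' `min_obs` observations in every month of every year of `window_years`;
#' `full_record` keeps stations with at least `min_years` qualifying years,
#' a year qualifying when all 12 months have at least `min_obs`
#' observations.
#'
#' @param obs_counts long data.frame with columns `id`, `year`, `month`,
#'   `count` (months absent from the table count as 0 observations).
#' @param mode `"modis_era"` or `"full_record"`.
#' @param window_years years of the satellite-era window (default
#'   2000:2009).
#' @param min_obs per-month observation floor (default 20).
#' @param min_years qualifying-year floor for `full_record` (default 20).
#' @return vector of station ids passing the filter.
#' @export
filter_stations <- function(obs_counts, mode = c("modis_era", "full_record"),
                            window_years = 2000:2009, min_obs = 20,
                            min_years = 20) {
  mode <- match.arg(mode)
  ids <- unique(obs_counts$id)
  year_ok <- function(sub, yr) {
    cnt <- sub$count[sub$year == yr]
    mon <- sub$month[sub$year == yr]
    length(unique(mon)) == 12L && all(tapply(cnt, mon, sum) >= min_obs)
  }
  keep <- vapply(ids, function(i) {
    sub <- obs_counts[obs_counts$id == i, ]
    if (mode == "modis_era") {
      all(vapply(window_years, function(yr) year_ok(sub, yr), TRUE))
    } else {
      sum(vapply(unique(sub$year), function(yr) year_ok(sub, yr), TRUE)) >=
        min_years
    }
  }, TRUE)
  ids[keep]
}

season_groups <- list(DJF = c(12L, 1L, 2L), MAM = 3:5, JJA = 6:8, SON = 9:11)

#' Validate a gridded climatology against station records
#'
#' Ordinary least squares of station monthly cloud amount on the
#' footprint-averaged gridded monthly mean, per calendar month and per
#' three-month season (DJF, MAM, JJA, SON; December belongs to the
#' following winter). Reports n, R-squared, RMSE (root mean squared
#' residual), slope and intercept, plus per-station residuals.
#'
#' @param stations data.frame with `id`, `lon`, `lat` and monthly columns
#'   `amount_01` .. `amount_12` (percent).
#' @param clim a `cloud_climatology` (its `mu` stack is used).
#' @param radius_km footprint radius (default 16).
#' @param min_n smallest station count for which a regression is fitted;
#'   months/seasons below it are skipped with a warning (default 3).
#' @return list of class `validation_result`: `monthly` and `seasonal`
#'   data.frames (`period`, `n`, `r_squared`, `rmse`, `slope`,
#'   `intercept`) and `residuals` (station id, lon, lat, month, observed,
#'   predicted from grid, residual).
#' @export
monthly_validation <- function(stations, clim, radius_km = 16, min_n = 3) {
  stopifnot(inherits(clim, "cloud_climatology"))
  n_st <- nrow(stations)
  if (n_st == 0L) stop("no stations to validate against")
  modcf <- sapply(1:12, function(m) {
    vapply(seq_len(n_st), function(i) {
      station_footprint_mean(clim$mu$grids[[m]], stations$lon[i],
                             stations$lat[i], radius_km = radius_km)
    }, 0)
  })
  amount <- as.matrix(stations[sprintf("amount_%02d", 1:12)])

  fit_one <- function(x, y, label) {
    ok <- !is.na(x) & !is.na(y)
    if (sum(ok) < min_n) {
      warning(sprintf("%s: only %d stations with data; skipped",
                      label, sum(ok)))
      return(data.frame(period = label, n = sum(ok), r_squared = NA_real_,
                        rmse = NA_real_, slope = NA_real_,
                        intercept = NA_real_))
    }
    fit <- stats::lm(y[ok] ~ x[ok])
    res <- stats::residuals(fit)
    data.frame(period = label, n = sum(ok),
               r_squared = summary(fit)$r.squared,
               rmse = sqrt(mean(res^2)),
               slope = unname(stats::coef(fit)[2L]),
               intercept = unname(stats::coef(fit)[1L]))
  }

  monthly <- do.call(rbind, lapply(1:12, function(m) {
    fit_one(modcf[, m], amount[, m], month.abb[m])
  }))
  seasonal <- do.call(rbind, lapply(names(season_groups), function(s) {
    ms <- season_groups[[s]]
    fit_one(rowMeans(modcf[, ms, drop = FALSE]),
            rowMeans(amount[, ms, drop = FALSE]), s)
  }))
  residuals <- do.call(rbind, lapply(1:12, function(m) {
    data.frame(id = stations$id, lon = stations$lon, lat = stations$lat,
               month = m, observed = amount[, m], modcf = modcf[, m],
               residual = amount[, m] - modcf[, m])
  }))
  structure(list(monthly = monthly, seasonal = seasonal,
                 residuals = residuals, radius_km = radius_km),
            class = "validation_result")
}

#' @export
print.validation_result <- function(x, ...) {
  cat("<validation_result>\n")
  print(x$monthly, row.names = FALSE)
  invisible(x)
}

#' Summarize validation residuals by latitude band and land-cover class
#'
#' Residuals are observed station amount minus footprint-averaged grid
#' value. Land-cover class per station is the modal class within the
#' station footprint; ties go to the lower class id.
#'
#' @param result a `validation_result`.
#' @param latitude_bands vector of band edges in degrees latitude
#'   (default `c(-90, -60, -30, 0, 30, 60, 90)`).
#' @param lulc optional `geo_grid` of integer land-cover classes.
#' @param radius_km footprint radius for the modal class (default the
#'   result's).
#' @return list of data.frames: `by_latitude` (`band_lo`, `band_hi`, `n`,
#'   `mean`, `sd`) and, when `lulc` is given, `by_class` (`class`, `n`,
#'   `mean`, `sd`).
#' @export
residual_summary <- function(result,
                             latitude_bands = c(-90, -60, -30, 0, 30, 60, 90),
                             lulc = NULL, radius_km = NULL) {
  res <- result$residuals
  res <- res[!is.na(res$residual), ]
  edges <- sort(latitude_bands)
  band <- findInterval(res$lat, edges, rightmost.closed = TRUE)
  by_lat <- do.call(rbind, lapply(seq_len(length(edges) - 1L), function(b) {
    r <- res$residual[band == b]
    data.frame(band_lo = edges[b], band_hi = edges[b + 1L], n = length(r),
               mean = if (length(r)) mean(r) else NA_real_,
               sd = if (length(r) >= 2L) stats::sd(r) else NA_real_)
  }))
  out <- list(by_latitude = by_lat)
  if (!is.null(lulc)) {
    if (is.null(radius_km)) radius_km <- result$radius_km
    st <- unique(res[c("id", "lon", "lat")])
    st$class <- vapply(seq_len(nrow(st)), function(i) {
      modal_class(lulc, st$lon[i], st$lat[i], radius_km)
    }, 0)
    res <- merge(res, st[c("id", "class")], by = "id")
    cls <- sort(unique(res$class[!is.na(res$class)]))
    out$by_class <- do.call(rbind, lapply(cls, function(k) {
      r <- res$residual[!is.na(res$class) & res$class == k]
      data.frame(class = k, n = length(r), mean = mean(r),
                 sd = if (length(r) >= 2L) stats::sd(r) else NA_real_)
    }))
  }
  out
}

# modal land-cover class within a circular footprint; ties -> lower class id
modal_class <- function(lulc, lon, lat, radius_km) {
  cc <- cell_centers(lulc)
  dlat <- radius_km / 111.195
  dlon <- radius_km / (111.195 * max(cos(lat * pi / 180), 1e-6))
  rows <- which(cc$lat >= lat - dlat & cc$lat <= lat + dlat)
  cols <- which(cc$lon >= lon - dlon & cc$lon <= lon + dlon)
  if (length(rows) == 0L || length(cols) == 0L) return(NA_real_)
  d <- outer(cc$lat[rows], cc$lon[cols],
             function(la, lo) great_circle_km(lon, lat, lo, la))
  sel <- d <= radius_km & !lulc$mask[rows, cols, drop = FALSE]
  if (!any(sel)) return(NA_real_)
  v <- lulc$values[rows, cols, drop = FALSE][sel]
  counts <- table(v)
  as.numeric(names(counts)[counts == max(counts)][1L])  # names sorted ascending
}

#' Spearman rank correlation
#'
#' Rank correlation with average ranks for ties, used to relate monthly
#' cloud frequency to monthly precipitation and similar monotone
#' associations.
#'
#' @param x,y numeric vectors.
#' @return Spearman's rho.
#' @export
rank_correlation <- function(x, y) {
  ok <- !is.na(x) & !is.na(y)
  stats::cor(x[ok], y[ok], method = "spearman")
}
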
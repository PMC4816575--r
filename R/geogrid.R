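#' Georeferenced raster grid
#'
#' `geo_grid()` is the package's lightweight raster container: a numeric
#' matrix with a congruent nodata mask and an affine georeference
#' (cell-center registration, row 1 = northernmost row, square cells in
#' degrees). All statistics in the package ignore masked cells.
#'
#' @param values numeric matrix; `NA` entries are added to the mask.
#' @param mask logical matrix of the same shape, `TRUE` = nodata. Defaults to
#'   `is.na(values)`.
#' @param xmin x (longitude) of the western edge of the grid, degrees.
#' @param ymax y (latitude) of the northern edge of the grid, degrees.
#' @param cellsize cell edge length in degrees; strictly positive. The
#'   default, 1/120 degree (30 arc-sec), matches a ~1 km global product.
#' @param crs coordinate reference system identifier (geographic WGS84 by
#'   default).
#' @return an object of class `geo_grid`.
#' @export
geo_grid <- function(values, mask = NULL, xmin = 0, ymax = NULL,
                     cellsize = 1 / 120, crs = "EPSG:4326") {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (!is.numeric(cellsize) || length(cellsize) != 1L || cellsize <= 0) {
    stop("cellsize must be a single strictly positive number")
  }
  if (is.null(mask)) mask <- is.na(values)
  mask <- as.matrix(mask)
  if (!identical(dim(mask), dim(values))) {
    stop("mask and values must have identical shape")
  }
  mask <- mask | is.na(values)
  values[mask] <- NA_real_
  if (is.null(ymax)) ymax <- nrow(values) * cellsize
  structure(
    list(values = values, mask = mask,
         xmin = as.numeric(xmin), ymax = as.numeric(ymax),
         cellsize = as.numeric(cellsize), crs = crs),
    class = "geo_grid"
  )
}

#' @export
print.geo_grid <- function(x, ...) {
  cat(sprintf(
    "<geo_grid> %d x %d cells, cellsize %.6g deg, origin (%.6g, %.6g), %s\n",
    nrow(x$values), ncol(x$values), x$cellsize, x$xmin, x$ymax, x$crs))
  v <- x$values[!x$mask]
  cat(sprintf("  %d unmasked cells; range [%.4g, %.4g]\n",
              length(v), suppressWarnings(min(v)), suppressWarnings(max(v))))
  invisible(x)
}

#' @export
dim.geo_grid <- function(x) dim(x$values)

is_geo_grid <- function(x) inherits(x, "geo_grid")

#' Test two grids for identical geometry
#'
#' @param a,b `geo_grid` objects.
#' @param tol numeric tolerance on the georeference.
#' @return logical scalar.
#' @export
same_geometry <- function(a, b, tol = 1e-9) {
  identical(dim(a$values), dim(b$values)) &&
    abs(a$xmin - b$xmin) < tol && abs(a$ymax - b$ymax) < tol &&
    abs(a$cellsize - b$cellsize) < tol && identical(a$crs, b$crs)
}

stopifnot_same_geometry <- function(a, b, what = "grids") {
  if (!same_geometry(a, b)) stop(sprintf("geometry mismatch between %s", what))
  invisible(TRUE)
}

#' Longitude/latitude of cell centers
#'
#' @param grid a `geo_grid`.
#' @return list with `lon` (length ncol) and `lat` (length nrow) of cell
#'   centers; row 1 is the northernmost row.
#' @export
cell_centers <- function(grid) {
  list(
    lon = grid$xmin + (seq_len(ncol(grid$values)) - 0.5) * grid$cellsize,
    lat = grid$ymax - (seq_len(nrow(grid$values)) - 0.5) * grid$cellsize
  )
}

#' Map points to cell row/column indices
#'
#' Uses half-open cell intervals so a point on a shared edge belongs to the
#' cell to its east/south in index order (consistent with row 1 = north).
#'
#' @param grid a `geo_grid`.
#' @param lon,lat point coordinates, degrees.
#' @return integer matrix with columns `row`, `col`; `NA` for points outside
#'   the grid extent.
#' @export
point_to_cell <- function(grid, lon, lat) {
  nr <- nrow(grid$values); nc <- ncol(grid$values)
  col <- floor((lon - grid$xmin) / grid$cellsize) + 1L
  row <- floor((grid$ymax - lat) / grid$cellsize) + 1L
  bad <- col < 1L | col > nc | row < 1L | row > nr
  row[bad] <- NA_integer_; col[bad] <- NA_integer_
  cbind(row = as.integer(row), col = as.integer(col))
}

#' Stack of grids sharing one geometry
#'
#' @param grids list of `geo_grid` objects with identical geometry.
#' @param labels character vector of unique band labels (date, month, year,
#'   sensor), one per grid.
#' @return an object of class `grid_stack`.
#' @export
grid_stack <- function(grids, labels = NULL) {
  stopifnot(is.list(grids), length(grids) >= 1L)
  if (is.null(labels)) labels <- paste0("band", seq_along(grids))
  labels <- as.character(labels)
  if (length(labels) != length(grids)) stop("one label per grid required")
  if (anyDuplicated(labels)) stop("stack labels must be unique")
  for (g in grids) {
    if (!is_geo_grid(g)) stop("all stack members must be geo_grid objects")
    stopifnot_same_geometry(grids[[1L]], g, "stack members")
  }
  structure(list(grids = stats::setNames(grids, labels), labels = labels),
            class = "grid_stack")
}

#' @export
print.grid_stack <- function(x, ...) {
  cat(sprintf("<grid_stack> %d bands: %s\n", length(x$grids),
              paste(utils::head(x$labels, 6), collapse = ", ")))
  print(x$grids[[1L]])
  invisible(x)
}

#' @export
length.grid_stack <- function(x) length(x$grids)

#' Moving-window statistic over a circular kernel
#'
#' Computes the mean or standard deviation of unmasked cells whose centers
#' lie within `radius_cells` of each cell, emulating the "one-degree
#' circular moving window" used to map spatial variability of cloud cover.
#' The window is defined in cell units with no great-circle correction.
#'
#' @param grid a `geo_grid`.
#' @param radius_cells kernel radius in cells, `>= 1`.
#' @param stat `"sd"` or `"mean"`.
#' @param sd_type `"sample"` (n-1 denominator, default) or `"population"`.
#' @return a `geo_grid`; masked where the center cell is masked, and (for
#'   `sd`) wherever fewer than two unmasked cells contribute.
#' @export
circular_window_stat <- function(grid, radius_cells,
                                 stat = c("sd", "mean"),
                                 sd_type = c("sample", "population")) {
  stat <- match.arg(stat)
  sd_type <- match.arg(sd_type)
  stopifnot(is_geo_grid(grid))
  if (!is.numeric(radius_cells) || radius_cells < 1) {
    stop("radius_cells must be >= 1")
  }
  nr <- nrow(grid$values); nc <- ncol(grid$values)
  if (radius_cells > max(nr, nc)) stop("radius larger than grid")

  r <- radius_cells
  ri <- floor(r)
  offsets <- expand.grid(dr = -ri:ri, dc = -ri:ri)
  offsets <- offsets[offsets$dr^2 + offsets$dc^2 <= r^2, , drop = FALSE]

  v <- grid$values
  v[grid$mask] <- 0
  ok <- !grid$mask
  s <- matrix(0, nr, nc); s2 <- matrix(0, nr, nc); n <- matrix(0, nr, nc)
  for (k in seq_len(nrow(offsets))) {
    dr <- offsets$dr[k]; dc <- offsets$dc[k]
    rs <- max(1L, 1L - dr):min(nr, nr - dr)   # destination rows
    cs <- max(1L, 1L - dc):min(nc, nc - dc)
    src_r <- rs + dr; src_c <- cs + dc
    s[rs, cs]  <- s[rs, cs]  + v[src_r, src_c] * ok[src_r, src_c]
    s2[rs, cs] <- s2[rs, cs] + v[src_r, src_c]^2 * ok[src_r, src_c]
    n[rs, cs]  <- n[rs, cs]  + ok[src_r, src_c]
  }

  if (stat == "mean") {
    out <- ifelse(n >= 1, s / n, NA_real_)
  } else {
    m <- s / n
    ss <- pmax(s2 - n * m^2, 0)  # guard tiny negative rounding
    denom <- if (sd_type == "population") n else n - 1
    out <- ifelse(n >= 2, sqrt(ss / denom), NA_real_)
  }
  out[grid$mask] <- NA_real_
  geo_grid(out, xmin = grid$xmin, ymax = grid$ymax,
           cellsize = grid$cellsize, crs = grid$crs)
}

#' Zonal summary of a metric raster
#'
#' Summarizes a metric within integer-labelled zones (for example biomes
#' within biogeographic realms), reporting per zone the count of unmasked
#' metric cells and their min, max, mean and sample SD. Cells masked in the
#' metric are excluded; zones whose metric cells are all masked get `n = 0`
#' and `NA` statistics.
#'
#' @param metric a `geo_grid` of the quantity to summarize.
#' @param zones a `geo_grid` of integer class labels, congruent geometry.
#' @return `data.frame` with columns `zone`, `n`, `min`, `max`, `mean`, `sd`.
#' @export
zonal_stats <- function(metric, zones) {
  stopifnot(is_geo_grid(metric), is_geo_grid(zones))
  stopifnot_same_geometry(metric, zones, "metric and zones")
  z <- zones$values; z[zones$mask] <- NA
  labels <- sort(unique(as.vector(z[!is.na(z)])))
  res <- lapply(labels, function(lab) {
    vals <- metric$values[!metric$mask & !is.na(z) & z == lab]
    if (length(vals) == 0L) {
      data.frame(zone = lab, n = 0L, min = NA_real_, max = NA_real_,
                 mean = NA_real_, sd = NA_real_)
    } else {
      data.frame(zone = lab, n = length(vals), min = min(vals),
                 max = max(vals), mean = mean(vals),
                 sd = if (length(vals) >= 2L) stats::sd(vals) else NA_real_)
    }
  })
  do.call(rbind, res)
}
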
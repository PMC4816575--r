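#' Spatial weights as a symmetric pair list
#'
#' @param i,j site indices of each weighted pair.
#' @param w weights (default 1, i.e. binary).
#' @param n_sites total number of sites.
#' @param style free-text description recorded in output metadata.
#' @return object of class `spatial_weights`; pairs are stored once and
#'   treated as symmetric (`w_ij = w_ji`), with `w_ii = 0` enforced.
#' @export
spatial_weights <- function(i, j, w = 1, n_sites = max(i, j),
                            style = "custom") {
  stopifnot(length(i) == length(j))
  w <- rep_len(w, length(i))
  keep <- i != j
  i <- i[keep]; j <- j[keep]; w <- w[keep]
  # store each unordered pair once
  lo <- pmin(i, j); hi <- pmax(i, j)
  key <- paste(lo, hi)
  first <- !duplicated(key)
  if (sum(first) == 0L) stop("weights must contain at least one nonzero pair")
  structure(list(i = lo[first], j = hi[first], w = w[first],
                 n_sites = n_sites, style = style),
            class = "spatial_weights")
}

#' Queen/rook contiguity weights for a raster's unmasked cells
#'
#' @param grid a `geo_grid`; unmasked cells become sites in column-major
#'   order.
#' @param style `"binary_queen"` (8 neighbors, default) or `"binary_rook"`
#'   (4 neighbors).
#' @return a `spatial_weights` over the unmasked cells, plus attribute
#'   `cells` giving each site's cell index in the grid.
#' @export
contiguity_weights <- function(grid, style = c("binary_queen",
                                               "binary_rook")) {
  style <- match.arg(style)
  stopifnot(is_geo_grid(grid))
  nr <- nrow(grid$values); nc <- ncol(grid$values)
  cells <- which(!grid$mask)
  site <- integer(nr * nc); site[cells] <- seq_along(cells)
  offs <- if (style == "binary_rook") {
    list(c(1L, 0L), c(0L, 1L))
  } else {
    list(c(1L, 0L), c(0L, 1L), c(1L, 1L), c(1L, -1L))
  }
  r <- (cells - 1L) %% nr + 1L
  c_ <- (cells - 1L) %/% nr + 1L
  ii <- integer(0); jj <- integer(0)
  for (o in offs) {
    r2 <- r + o[1L]; c2 <- c_ + o[2L]
    ok <- r2 >= 1L & r2 <= nr & c2 >= 1L & c2 <= nc
    nb <- (c2[ok] - 1L) * nr + r2[ok]
    ok2 <- !grid$mask[nb]
    ii <- c(ii, site[cells[ok]][ok2]); jj <- c(jj, site[nb][ok2])
  }
  out <- spatial_weights(ii, jj, 1, n_sites = length(cells), style = style)
  attr(out, "cells") <- cells
  out
}

#' Great-circle distance-band weights
#'
#' Binary weights linking site pairs whose great-circle distance falls in
#' `[d_lo, d_hi)`.
#'
#' @param lon,lat site coordinates, degrees.
#' @param d_lo,d_hi band edges in km.
#' @return a `spatial_weights` (possibly with zero pairs, flagged by
#'   attribute `n_pairs`).
#' @export
distance_band_weights <- function(lon, lat, d_lo, d_hi) {
  n <- length(lon)
  pr <- t(utils::combn(n, 2L))
  d <- great_circle_km(lon[pr[, 1L]], lat[pr[, 1L]],
                       lon[pr[, 2L]], lat[pr[, 2L]])
  sel <- d >= d_lo & d < d_hi
  if (!any(sel)) return(NULL)
  spatial_weights(pr[sel, 1L], pr[sel, 2L], 1, n_sites = n,
                  style = sprintf("distance_band(%g-%g km)", d_lo, d_hi))
}

wsum_cross <- function(values, weights, centered = TRUE) {
  x <- if (centered) values - mean(values) else values
  2 * sum(weights$w * x[weights$i] * x[weights$j])   # symmetric double sum
}

#' Moran's I spatial autocorrelation
#'
#' `I = (N / sum_ij w_ij) * sum_ij w_ij (x_i - xbar)(x_j - xbar) /
#' sum_i (x_i - xbar)^2`. Under the permutation null its expectation is
#' `-1/(N-1)`.
#'
#' @param values numeric vector, one value per site.
#' @param weights a `spatial_weights` over the same sites.
#' @return Moran's I, or `NA` (with a warning) for zero-variance input.
#' @export
morans_i <- function(values, weights) {
  stopifnot(inherits(weights, "spatial_weights"))
  n <- weights$n_sites
  if (length(values) != n) stop("values length must equal n_sites")
  if (n < 3L) stop("Moran's I needs at least 3 sites")
  x <- values - mean(values)
  s2 <- sum(x^2)
  if (s2 == 0) {
    warning("zero variance; Moran's I undefined")
    return(NA_real_)
  }
  s0 <- 2 * sum(weights$w)
  (n / s0) * wsum_cross(values, weights) / s2
}

#' Geary's C spatial autocorrelation
#'
#' `C = ((N - 1) / (2 sum_ij w_ij)) * sum_ij w_ij (x_i - x_j)^2 /
#' sum_i (x_i - xbar)^2`. 1 under independence, below 1 for positive
#' autocorrelation.
#'
#' @inheritParams morans_i
#' @return Geary's C, or `NA` (with a warning) for zero-variance input.
#' @export
gearys_c <- function(values, weights) {
  stopifnot(inherits(weights, "spatial_weights"))
  n <- weights$n_sites
  if (length(values) != n) stop("values length must equal n_sites")
  if (n < 3L) stop("Geary's C needs at least 3 sites")
  x <- values - mean(values)
  s2 <- sum(x^2)
  if (s2 == 0) {
    warning("zero variance; Geary's C undefined")
    return(NA_real_)
  }
  s0 <- 2 * sum(weights$w)
  num <- 2 * sum(weights$w * (values[weights$i] - values[weights$j])^2)
  ((n - 1) / (2 * s0)) * num / s2
}

#' Moran correlogram over great-circle distance bins
#'
#' Moran's I per distance bin with binary weights `w_ij = 1` iff the
#' great-circle distance between sites i and j falls in the bin; the
#' default bins are 10 equal-width classes up to half the maximum pairwise
#' distance.
#'
#' @param values numeric vector, one value per site.
#' @param lon,lat site coordinates, degrees.
#' @param bin_edges ascending distance-bin edges in km (`NULL` for the
#'   default).
#' @param n_bins number of default bins (default 10).
#' @return data.frame of class `correlogram`: `bin_lo`, `bin_hi`, `I`,
#'   `n_pairs` (`I = NA` for empty bins).
#' @export
correlogram <- function(values, lon, lat, bin_edges = NULL, n_bins = 10) {
  n <- length(values)
  stopifnot(length(lon) == n, length(lat) == n)
  if (is.null(bin_edges)) {
    pr <- t(utils::combn(n, 2L))
    dmax <- max(great_circle_km(lon[pr[, 1L]], lat[pr[, 1L]],
                                lon[pr[, 2L]], lat[pr[, 2L]]))
    bin_edges <- seq(0, dmax / 2, length.out = n_bins + 1L)
  }
  if (is.unsorted(bin_edges, strictly = TRUE)) {
    stop("bin_edges must be strictly ascending")
  }
  out <- do.call(rbind, lapply(seq_len(length(bin_edges) - 1L), function(b) {
    w <- distance_band_weights(lon, lat, bin_edges[b], bin_edges[b + 1L])
    if (is.null(w)) {
      data.frame(bin_lo = bin_edges[b], bin_hi = bin_edges[b + 1L],
                 I = NA_real_, n_pairs = 0L)
    } else {
      data.frame(bin_lo = bin_edges[b], bin_hi = bin_edges[b + 1L],
                 I = morans_i(values, w), n_pairs = length(w$i))
    }
  }))
  class(out) <- c("correlogram", class(out))
  out
}
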
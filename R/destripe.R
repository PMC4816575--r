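#' Oriented Gabor-type noise pattern
#'
#' An anisotropic Gaussian-envelope pattern (zero mean, unit L2 norm) that
#' describes one oriented stripe artifact: `sigma_y` stretches the envelope
#' along the stripe direction (`theta_deg` from vertical) and `sigma_x`
#' narrows it across stripes. Used as the known noise shape in
#' [remove_stationary_noise()]; the morning sensor's orbital stripes are
#' matched with theta = +15 degrees and the afternoon sensor's with -15.
#'
#' @param theta_deg stripe orientation in degrees, in (-90, 90].
#' @param sigma_x envelope scale across the stripe, cells (for
#'   `profile = "boxcar"`, the half-width of the stripe cross-section).
#' @param sigma_y envelope scale along the stripe, cells.
#' @param shape integer vector `c(rows, cols)` of the pattern support.
#' @param profile cross-stripe profile: `"gaussian"` (default) or
#'   `"boxcar"` (flat over `|x| <= sigma_x`, the natural choice when the
#'   artifact is a band of known width, e.g. missing-overpass swaths a
#'   couple of cells wide).
#' @return object of class `gabor_pattern` (fields `pattern` matrix,
#'   `theta_deg`, `sigma_x`, `sigma_y`, `profile`).
#' @export
gabor_pattern <- function(theta_deg, sigma_x, sigma_y, shape,
                          profile = c("gaussian", "boxcar")) {
  profile <- match.arg(profile)
  if (theta_deg <= -90 || theta_deg > 90) {
    stop("theta_deg must be in (-90, 90]")
  }
  stopifnot(sigma_x > 0, sigma_y > 0, length(shape) == 2L)
  nr <- shape[1L]; nc <- shape[2L]
  th <- theta_deg * pi / 180
  y <- matrix(seq_len(nr) - (nr + 1) / 2, nr, nc)
  x <- matrix(seq_len(nc) - (nc + 1) / 2, nr, nc, byrow = TRUE)
  xr <- x * cos(th) + y * sin(th)   # across-stripe coordinate
  yr <- -x * sin(th) + y * cos(th)  # along-stripe coordinate
  across <- if (profile == "gaussian") {
    exp(-0.5 * xr^2 / sigma_x^2)
  } else {
    as.numeric(abs(xr) <= sigma_x)
  }
  g <- across * exp(-0.5 * yr^2 / sigma_y^2)
  g <- g - mean(g)
  g <- g / sqrt(sum(g^2))
  structure(list(pattern = g, theta_deg = theta_deg,
                 sigma_x = sigma_x, sigma_y = sigma_y, profile = profile),
            class = "gabor_pattern")
}

# embed a pattern in an nr x nc array with its center wrapped to (1,1)
psf_to_otf <- function(pattern, nr, nc) {
  pr <- nrow(pattern); pc <- ncol(pattern)
  if (pr > nr || pc > nc) stop("pattern larger than image")
  big <- matrix(0, nr, nc)
  big[seq_len(pr), seq_len(pc)] <- pattern
  cr <- floor((pr + 1) / 2); cc <- floor((pc + 1) / 2)
  big <- big[c(cr:nr, seq_len(cr - 1L)), , drop = FALSE]
  big <- big[, c(cc:nc, seq_len(cc - 1L)), drop = FALSE]
  stats::fft(big)
}

# fill masked cells by repeated 3x3 neighborhood means (then global mean)
inpaint_mask <- function(values, mask) {
  v <- values; v[mask] <- NA_real_
  while (anyNA(v)) {
    filled <- FALSE
    nr <- nrow(v); nc <- ncol(v)
    s <- matrix(0, nr, nc); n <- matrix(0, nr, nc)
    ok <- !is.na(v); v0 <- ifelse(ok, v, 0)
    for (dr in -1:1) for (dc in -1:1) {
      rs <- max(1, 1 - dr):min(nr, nr - dr)
      cs <- max(1, 1 - dc):min(nc, nc - dc)
      s[rs, cs] <- s[rs, cs] + v0[rs + dr, cs + dc]
      n[rs, cs] <- n[rs, cs] + ok[rs + dr, cs + dc]
    }
    target <- is.na(v) & n > 0
    if (any(target)) {
      v[target] <- (s / n)[target]
      filled <- TRUE
    }
    if (!filled) {
      v[is.na(v)] <- mean(v, na.rm = TRUE)
      break
    }
  }
  v
}

#' Remove stationary oriented noise from a raster
#'
#' Estimates and subtracts a stripe field modelled as translates of one
#' oriented pattern, via the quadratic special case of variational
#' stationary noise removal: the stripe coefficient field `w` minimizes
#' `lambda * ||w||^2 + ||grad(u - psi * w)||^2`, solved in closed form in
#' the frequency domain. The image's domain mean is preserved exactly (the
#' gradient operator annihilates the DC component), and larger `lambda`
#' means weaker correction. Masked cells are inpainted by neighborhood
#' means before filtering and re-masked after.
#'
#' Two gain modes are offered. `"shrinkage"` applies the closed-form
#' per-frequency attenuation `|Psi|^2 |D|^2 / (|Psi|^2 |D|^2 + lambda)`
#' directly — the better estimator, but like any Wiener-type filter it is
#' not a projection, so re-applying it keeps shrinking. `"projection"`
#' thresholds the gain at 1/2 (a frequency is removed entirely where the
#' pattern model explains the majority of its gradient-weighted energy),
#' which is exactly idempotent at the cost of some stripe-band residual.
#'
#' @param image a `geo_grid`.
#' @param pattern a `gabor_pattern` (or plain matrix).
#' @param lambda_reg positive regularization weight; default 5.
#' @param gain `"shrinkage"` (default) or `"projection"`.
#' @return list: `corrected` `geo_grid` and `noise` `geo_grid` (the
#'   estimated stripe field).
#' @export
remove_stationary_noise <- function(image, pattern, lambda_reg = 5,
                                    gain = c("shrinkage", "projection")) {
  gain <- match.arg(gain)
  stopifnot(is_geo_grid(image))
  if (!is.numeric(lambda_reg) || length(lambda_reg) != 1L || lambda_reg <= 0) {
    stop("lambda_reg must be a positive number")
  }
  psi <- if (inherits(pattern, "gabor_pattern")) pattern$pattern else pattern
  nr <- nrow(image$values); nc <- ncol(image$values)
  u <- inpaint_mask(image$values, image$mask)
  if (any(!is.finite(u))) stop("image must be finite on unmasked cells")

  P <- psf_to_otf(psi, nr, nc)
  U <- stats::fft(u)
  kr <- (seq_len(nr) - 1L) / nr
  kc <- (seq_len(nc) - 1L) / nc
  d2 <- outer(abs(1 - exp(-2i * pi * kr))^2,
              abs(1 - exp(-2i * pi * kc))^2, `+`)
  G <- Mod(P)^2 * d2 / (Mod(P)^2 * d2 + lambda_reg)
  if (gain == "projection") G <- (G >= 0.5) + 0
  G[1L, 1L] <- 0   # mean preserved exactly
  noise <- Re(stats::fft(G * U, inverse = TRUE)) / (nr * nc)
  corrected <- u - noise
  corrected[image$mask] <- NA_real_
  noise[image$mask] <- NA_real_
  list(
    corrected = geo_grid(corrected, xmin = image$xmin, ymax = image$ymax,
                         cellsize = image$cellsize, crs = image$crs),
    noise = geo_grid(noise, xmin = image$xmin, ymax = image$ymax,
                     cellsize = image$cellsize, crs = image$crs)
  )
}

#' Flag albedo-contaminated cells
#'
#' Bright, seasonally varying surfaces (salt flats, ephemeral lakes) leak
#' into cloud flags as spuriously high cloud frequency. A cell is flagged
#' when its maximum monthly albedo exceeds `max_thresh` AND the
#' intra-annual (sample) SD of its monthly albedo exceeds `sd_thresh`.
#'
#' @param albedo_monthly 12-band `grid_stack` of monthly mean albedo (0-1).
#' @param max_thresh maximum-albedo threshold (default 0.5).
#' @param sd_thresh intra-annual albedo SD threshold (default 0.15).
#' @return list: `mask` (logical `geo_grid`, 1 = contaminated) and
#'   `thresholds`.
#' @export
detect_albedo_artifacts <- function(albedo_monthly, max_thresh = 0.5,
                                    sd_thresh = 0.15) {
  stopifnot(inherits(albedo_monthly, "grid_stack"))
  template <- albedo_monthly$grids[[1L]]
  A <- stack_to_matrix(albedo_monthly)
  amax <- apply(A, 1L, max, na.rm = TRUE)
  asd <- apply(A, 1L, stats::sd, na.rm = TRUE)
  flag <- !is.na(amax) & !is.na(asd) & amax > max_thresh & asd > sd_thresh
  nr <- nrow(template$values); nc <- ncol(template$values)
  list(mask = grid_from(matrix(as.numeric(flag), nr, nc), template),
       thresholds = c(max_thresh = max_thresh, sd_thresh = sd_thresh))
}

#' Gap-fill flagged cells by inverse-distance weighting
#'
#' Replaces flagged cells with the inverse-distance-weighted (power
#' `idw_power`) mean of unflagged, unmasked cells within `max_radius`
#' cells. Flagged cells with no donor in range stay masked.
#'
#' @param grid a `geo_grid`.
#' @param mask artifact mask: output of [detect_albedo_artifacts()], a
#'   logical matrix, or a `geo_grid` of 0/1 flags.
#' @param max_radius donor search radius in cells (default 10).
#' @param idw_power inverse-distance exponent (default 2).
#' @return a `geo_grid` with flagged cells filled or masked.
#' @export
gap_fill <- function(grid, mask, max_radius = 10, idw_power = 2) {
  stopifnot(is_geo_grid(grid))
  flag <- if (is.list(mask) && !is.null(mask$mask)) {
    mask$mask$values > 0
  } else if (is_geo_grid(mask)) {
    mask$values > 0
  } else {
    as.matrix(mask)
  }
  flag[is.na(flag)] <- FALSE
  nr <- nrow(grid$values); nc <- ncol(grid$values)
  stopifnot(identical(dim(flag), c(nr, nc)))
  donor_ok <- !grid$mask & !flag
  v <- grid$values
  out <- v
  idx <- which(flag, arr.ind = TRUE)
  ri <- floor(max_radius)
  for (k in seq_len(nrow(idx))) {
    r0 <- idx[k, 1L]; c0 <- idx[k, 2L]
    rs <- max(1L, r0 - ri):min(nr, r0 + ri)
    cs <- max(1L, c0 - ri):min(nc, c0 + ri)
    dr <- rs - r0; dc <- cs - c0
    d <- sqrt(outer(dr^2, dc^2, `+`))
    ok <- donor_ok[rs, cs, drop = FALSE] & d <= max_radius & d > 0
    if (!any(ok)) {
      out[r0, c0] <- NA_real_
      next
    }
    w <- 1 / d[ok]^idw_power
    out[r0, c0] <- sum(w * v[rs, cs][ok]) / sum(w)
  }
  geo_grid(out, xmin = grid$xmin, ymax = grid$ymax,
           cellsize = grid$cellsize, crs = grid$crs)
}
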
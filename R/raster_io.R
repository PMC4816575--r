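#' Raster file input/output
#'
#' Rasters are stored as ESRI ASCII grids (`.asc`) — a plain-text,
#' GDAL-readable exchange format — with a JSON sidecar (`<path>.json`)
#' carrying the CRS and, for multi-band stacks, the band labels and file
#' names. `read_raster(write_raster(x, p))` is the identity on values,
#' mask, georeference and CRS.
#'
#' @name raster_io
NULL

fmt_num <- function(x) formatC(x, digits = 17, format = "g")

write_asc <- function(values, mask, xmin, ymin, cellsize, path,
                      nodata = -9999) {
  v <- values
  v[mask | is.na(v)] <- nodata
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    paste("ncols", ncol(values)),
    paste("nrows", nrow(values)),
    paste("xllcorner", fmt_num(xmin)),
    paste("yllcorner", fmt_num(ymin)),
    paste("cellsize", fmt_num(cellsize)),
    paste("NODATA_value", fmt_num(nodata))
  ), con)
  utils::write.table(format(v, digits = 17, trim = TRUE, scientific = TRUE),
                     con, row.names = FALSE, col.names = FALSE,
                     quote = FALSE)
}

read_asc <- function(path) {
  lines <- readLines(path, n = 6L)
  kv <- strsplit(trimws(lines), "\\s+")
  keys <- tolower(vapply(kv, `[`, "", 1L))
  vals <- vapply(kv, `[`, "", 2L)
  hdr <- as.list(stats::setNames(vals, keys))
  req <- c("ncols", "nrows", "xllcorner", "yllcorner", "cellsize")
  if (!all(req %in% keys)) {
    stop(sprintf("'%s' is missing georeferencing header fields (%s)",
                 path, paste(setdiff(req, keys), collapse = ", ")))
  }
  n_header <- sum(keys %in% c(req, "nodata_value"))
  nodata <- if ("nodata_value" %in% keys) {
    as.numeric(hdr$nodata_value)
  } else {
    warning(sprintf("'%s' declares no nodata value; assuming no masked cells",
                    path))
    NA_real_
  }
  nr <- as.integer(hdr$nrows); nc <- as.integer(hdr$ncols)
  body <- scan(path, skip = n_header, quiet = TRUE)
  if (length(body) != nr * nc) {
    stop(sprintf("'%s': expected %d cells, found %d", path, nr * nc,
                 length(body)))
  }
  values <- matrix(body, nrow = nr, ncol = nc, byrow = TRUE)
  mask <- if (is.na(nodata)) {
    matrix(FALSE, nr, nc)
  } else {
    values == nodata
  }
  values[mask] <- NA_real_
  list(values = values, mask = mask,
       xmin = as.numeric(hdr$xllcorner),
       ymin = as.numeric(hdr$yllcorner),
       cellsize = as.numeric(hdr$cellsize))
}

#' Write a raster or stack to disk
#'
#' @param grid a `geo_grid` or `grid_stack`.
#' @param path output path ending in `.asc`. A stack writes one `.asc` per
#'   band (`<stem>_b01.asc`, ...) listed in the sidecar.
#' @return `path`, invisibly.
#' @export
write_raster <- function(grid, path) {
  if (is_geo_grid(grid)) {
    ymin <- grid$ymax - nrow(grid$values) * grid$cellsize
    write_asc(grid$values, grid$mask, grid$xmin, ymin, grid$cellsize, path)
    jsonlite::write_json(list(crs = grid$crs), paste0(path, ".json"),
                         auto_unbox = TRUE)
  } else if (inherits(grid, "grid_stack")) {
    stem <- sub("\\.asc$", "", path)
    files <- sprintf("%s_b%02d.asc", stem, seq_along(grid$grids))
    for (i in seq_along(grid$grids)) {
      g <- grid$grids[[i]]
      ymin <- g$ymax - nrow(g$values) * g$cellsize
      write_asc(g$values, g$mask, g$xmin, ymin, g$cellsize, files[i])
    }
    jsonlite::write_json(
      list(crs = grid$grids[[1L]]$crs,
           bands = data.frame(label = grid$labels, file = basename(files))),
      paste0(path, ".json"))
  } else {
    stop("grid must be a geo_grid or grid_stack")
  }
  invisible(path)
}

#' Read a raster or stack from disk
#'
#' @param path path to an `.asc` file written by [write_raster()] (for a
#'   stack, the path originally passed to `write_raster`).
#' @return a `geo_grid`, or a `grid_stack` when the sidecar lists bands.
#' @export
read_raster <- function(path) {
  sidecar <- paste0(path, ".json")
  if (!file.exists(sidecar)) {
    stop(sprintf("'%s' has no CRS: sidecar '%s' not found", path, sidecar))
  }
  meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  if (is.null(meta$crs)) {
    stop(sprintf("'%s' has no CRS declared in its sidecar", path))
  }
  as_grid <- function(a) {
    geo_grid(a$values, mask = a$mask, xmin = a$xmin,
             ymax = a$ymin + nrow(a$values) * a$cellsize,
             cellsize = a$cellsize, crs = meta$crs)
  }
  if (!is.null(meta$bands)) {
    files <- file.path(dirname(path), meta$bands$file)
    grids <- lapply(files, function(f) as_grid(read_asc(f)))
    grid_stack(grids, labels = meta$bands$label)
  } else {
    as_grid(read_asc(path))
  }
}
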
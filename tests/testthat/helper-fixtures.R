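# fixture builders shared across test files

make_counts <- function(id, years, count) {
  transform(expand.grid(id = id, year = years, month = 1:12), count = count)
}

# 1-D log-linear intensity world for the presence-only model
iwlr_world <- function(seed, n_cells = 400, slope = 1.5, n_expected = 500) {
  set.seed(seed)
  x <- seq(-1, 1, length.out = n_cells)
  lambda <- exp(slope * x); lambda <- lambda / sum(lambda)
  n_pts <- rpois(1, n_expected)
  cells <- sample.int(n_cells, n_pts, replace = TRUE, prob = lambda)
  list(x = x, pres_x = x[cells])
}

checkerboard <- function() {
  g <- geo_grid(matrix(c(1, 0, 0, 1), 2, 2), xmin = 0, ymax = 2,
                cellsize = 1)
  list(values = as.vector(g$values),
       w = contiguity_weights(g, "binary_rook"))
}

mu_stack_from <- function(vals12, template = geo_grid(matrix(0, 1, 1))) {
  grid_stack(lapply(vals12, function(v) {
    geo_grid(matrix(v, nrow(template$values), ncol(template$values)),
             cellsize = template$cellsize)
  }), labels = sprintf("%02d", 1:12))
}
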
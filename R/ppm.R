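#' Sample uniform background points over a raster domain
#'
#' Draws pseudo-absence ("background") points uniformly over the unmasked
#' cells of a domain grid, one cell per draw with replacement, jittered
#' uniformly within the cell.
#'
#' @param domain a `geo_grid`; masked cells are excluded.
#' @param n number of points (default 10000).
#' @param seed integer seed.
#' @return data.frame with `lon`, `lat`.
#' @export
sample_background <- function(domain, n = 10000, seed = 1) {
  stopifnot(is_geo_grid(domain))
  cells <- which(!domain$mask)
  if (length(cells) == 0L) stop("domain has no unmasked cells")
  set.seed(seed)
  nr <- nrow(domain$values)
  pick <- cells[sample.int(length(cells), n, replace = TRUE)]
  r <- (pick - 1L) %% nr + 1L
  c_ <- (pick - 1L) %/% nr + 1L
  data.frame(
    lon = domain$xmin + (c_ - stats::runif(n)) * domain$cellsize,
    lat = domain$ymax - (r - stats::runif(n)) * domain$cellsize
  )
}

#' Build a design matrix from a model formula
#'
#' Supports linear terms, `I(x^2)` squared terms, categorical expansion
#' (treatment contrasts; the reference level is the first alphabetically)
#' and factor-by-continuous interactions, as in `~ elev + I(elev^2) +
#' meanannual * region`. Errors on rank-deficient designs, naming the
#' offending column.
#'
#' @param formula_spec a formula or a string coercible to one (a bare
#'   right-hand side like `"x + I(x^2)"` is accepted).
#' @param data data.frame of covariates at points.
#' @param xlev optional factor-level list (to score new data against the
#'   levels seen in fitting).
#' @return numeric design matrix including the intercept column.
#' @export
build_design <- function(formula_spec, data, xlev = NULL) {
  f <- if (inherits(formula_spec, "formula")) {
    formula_spec
  } else {
    fs <- as.character(formula_spec)
    if (!grepl("~", fs)) fs <- paste("~", fs)
    stats::as.formula(fs)
  }
  f <- stats::update(f, NULL ~ .)
  mf <- stats::model.frame(f, data, na.action = stats::na.pass, xlev = xlev)
  mm <- stats::model.matrix(f, mf)
  ok <- stats::complete.cases(mm)
  qrd <- qr(mm[ok, , drop = FALSE])
  if (sum(ok) >= ncol(mm) && qrd$rank < ncol(mm)) {
    bad <- colnames(mm)[qrd$pivot[(qrd$rank + 1L):ncol(mm)]]
    stop(sprintf("design matrix is rank deficient; collinear column(s): %s",
                 paste(bad, collapse = ", ")))
  }
  attr(mm, "xlev") <- stats::.getXlevels(stats::terms(mf), mf)
  mm
}

# weighted logistic IRLS (Newton); own implementation so the convergence
# criterion and separation guard are explicit
iwlr_irls <- function(X, y, w, max_iter = 100, grad_tol = 1e-8,
                      coef_cap = 30) {
  beta <- numeric(ncol(X))
  grad_scale <- max(1, sqrt(sum(w)))
  for (it in seq_len(max_iter)) {
    eta <- drop(X %*% beta)
    p <- stats::plogis(eta)
    g <- drop(crossprod(X, w * (y - p)))
    wt <- w * p * (1 - p)
    H <- crossprod(X * sqrt(wt))
    step <- tryCatch(solve(H, g), error = function(e) {
      stop("IWLR Newton step failed (singular Hessian): ", conditionMessage(e))
    })
    beta <- beta + step
    if (max(abs(beta)) > coef_cap) {
      stop(sprintf(paste0("IWLR separation guard: |coefficient| exceeded %g ",
                          "at iteration %d"), coef_cap, it))
    }
    if (sqrt(sum(g^2)) / grad_scale < grad_tol ||
        sqrt(sum(step^2)) < 1e-13) {
      eta <- drop(X %*% beta)
      p <- stats::plogis(eta)
      if (min(p[y == 1]) > 1 - 1e-8 && max(p[y == 0]) < 1e-8) {
        stop("IWLR separation guard: classes are perfectly separated")
      }
      H <- crossprod(X * sqrt(w * p * (1 - p)))
      return(list(coef = beta, vcov = solve(H), iterations = it,
                  fitted = p,
                  grad_norm = sqrt(sum(crossprod(X, w * (y - p))^2))))
    }
  }
  stop(sprintf(paste0("IWLR did not converge in %d iterations ",
                      "(gradient norm %.3g, max |coef| %.3g)"),
               max_iter, sqrt(sum(g^2)), max(abs(beta))))
}

#' Fit a presence-only model by infinitely weighted logistic regression
#'
#' Logistic regression of a presence indicator on covariates with weight 1
#' on presence points and a large weight `W` on background points. As `W`
#' grows, the slope coefficients converge to the maximum-likelihood
#' estimate of an inhomogeneous Poisson point-process intensity (the
#' MaxEnt-equivalent presence-only model); only the intercept keeps
#' absorbing `W`.
#'
#' @param presence data.frame of covariates at presence points, or a design
#'   matrix.
#' @param background data.frame (or design matrix) for background points.
#' @param formula model formula (right-hand side), required when the inputs
#'   are data.frames.
#' @param W background weight (default 1e3).
#' @return object of class `ppm_fit`: coefficients, their covariance,
#'   weighted log-likelihood, `aic`, `bic` (with the presence count as the
#'   effective n), `auc` (background as pseudo-absence), `cor`
#'   (point-biserial), counts, `W`, and the coefficient table with Wald
#'   tests.
#' @export
fit_iwlr <- function(presence, background, formula = NULL, W = 1e3) {
  if (is.data.frame(presence)) {
    if (is.null(formula)) stop("formula required with data.frame input")
    all_data <- rbind(presence[, , drop = FALSE], background[, , drop = FALSE])
    mm <- build_design(formula, all_data)
    xlev <- attr(mm, "xlev")
    Xp <- mm[seq_len(nrow(presence)), , drop = FALSE]
    Xb <- mm[nrow(presence) + seq_len(nrow(background)), , drop = FALSE]
  } else {
    Xp <- as.matrix(presence); Xb <- as.matrix(background)
    if (is.null(colnames(Xp))) {
      colnames(Xp) <- colnames(Xb) <- paste0("b", seq_len(ncol(Xp)) - 1L)
    }
    xlev <- NULL
  }
  np <- nrow(Xp); nb <- nrow(Xb)
  X <- rbind(Xp, Xb)
  y <- c(rep(1, np), rep(0, nb))
  w <- c(rep(1, np), rep(W, nb))
  fit <- iwlr_irls(X, y, w)
  p <- fit$fitted
  ll <- sum(w * (y * log(pmax(p, 1e-300)) +
                   (1 - y) * log(pmax(1 - p, 1e-300))))
  k <- ncol(X)
  se <- sqrt(diag(fit$vcov))
  zval <- fit$coef / se
  coef_table <- data.frame(
    coefficient = colnames(X), estimate = fit$coef, se = se, z = zval,
    p_value = 2 * stats::pnorm(-abs(zval))
  )
  coef_table$stars <- stars_for(coef_table$p_value)
  structure(list(
    coefficients = stats::setNames(fit$coef, colnames(X)),
    vcov = fit$vcov, coef_table = coef_table,
    loglik = ll, aic = -2 * ll + 2 * k, bic = -2 * ll + k * log(np),
    auc = rank_auc(p[y == 1], p[y == 0]),
    cor = if (stats::sd(p) > 0) stats::cor(y, p) else NA_real_,
    W = W, n_presence = np, n_background = nb, k = k,
    formula = formula, xlev = xlev, iterations = fit$iterations
  ), class = "ppm_fit")
}

stars_for <- function(p) {
  ifelse(p < 0.001, "***", ifelse(p < 0.01, "**", ifelse(p < 0.05, "*", "")))
}

# AUC as the Mann-Whitney rank statistic
rank_auc <- function(pos, neg) {
  r <- rank(c(pos, neg))
  np <- length(pos); nn <- length(neg)
  if (np == 0L || nn == 0L) return(NA_real_)
  (sum(r[seq_len(np)]) - np * (np + 1) / 2) / (np * nn)
}

#' @export
print.ppm_fit <- function(x, ...) {
  cat(sprintf(
    "<ppm_fit> %d presences, %d background (W = %g)\n",
    x$n_presence, x$n_background, x$W))
  print(x$coef_table, row.names = FALSE, digits = 4)
  cat(sprintf("logLik %.2f  AIC %.2f  BIC %.2f  AUC %.3f  COR %.3f\n",
              x$loglik, x$aic, x$bic, x$auc, x$cor))
  invisible(x)
}

#' Predict relative occurrence rate over a covariate stack
#'
#' Exponentiates the fitted linear predictor over the domain and rescales
#' it to a maximum of 1 (relative occurrence rate): the intercept — which
#' under infinite weighting only tracks the background weight — cancels in
#' the rescaling, and ratios between cells are preserved.
#'
#' @param fit a `ppm_fit` fitted from data.frames with a formula.
#' @param covariates a `grid_stack` whose band labels name the covariates,
#'   or a data.frame of covariate values.
#' @return a `geo_grid` (for a stack) or numeric vector (for a
#'   data.frame), maximum 1; masked where any covariate is masked.
#' @export
predict_ror <- function(fit, covariates) {
  stopifnot(inherits(fit, "ppm_fit"))
  if (is.null(fit$formula)) stop("fit lacks a formula; refit from data.frames")
  if (inherits(covariates, "grid_stack")) {
    df <- as.data.frame(lapply(covariates$grids, function(g) {
      v <- g$values; v[g$mask] <- NA; as.vector(v)
    }))
    names(df) <- covariates$labels
  } else {
    df <- covariates
  }
  mm <- build_design(fit$formula, df, xlev = fit$xlev)
  eta <- drop(mm %*% fit$coefficients[colnames(mm)])
  ror <- exp(eta - max(eta, na.rm = TRUE))   # rescale: max = 1
  if (inherits(covariates, "grid_stack")) {
    template <- covariates$grids[[1L]]
    grid_from(matrix(ror, nrow(template$values), ncol(template$values)),
              template)
  } else {
    ror
  }
}

#' Compare presence-only model fits
#'
#' @param fits named list of `ppm_fit` objects.
#' @param baseline name of the reference fit for the deltas (default the
#'   first).
#' @return data.frame sorted by BIC ascending with `model`, `k`, `loglik`,
#'   `aic`, `bic`, `auc`, `cor` and deltas (`d_aic`, `d_bic`, `d_auc`,
#'   `d_cor`) relative to the baseline.
#' @export
compare_models <- function(fits, baseline = names(fits)[1L]) {
  stopifnot(length(fits) >= 1L, baseline %in% names(fits))
  tab <- do.call(rbind, lapply(names(fits), function(nm) {
    f <- fits[[nm]]
    data.frame(model = nm, k = f$k, loglik = f$loglik, aic = f$aic,
               bic = f$bic, auc = f$auc, cor = f$cor)
  }))
  b <- tab[tab$model == baseline, ]
  tab$d_aic <- tab$aic - b$aic
  tab$d_bic <- tab$bic - b$bic
  tab$d_auc <- tab$auc - b$auc
  tab$d_cor <- tab$cor - b$cor
  tab[order(tab$bic), ]
}
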
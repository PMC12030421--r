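#' Normalized difference vegetation index
#'
#' `NDVI = (NIR - Red) / (NIR + Red)` from red and near-infrared reflectance
#' fractions.  Vectorized.
#'
#' @param nir,red Reflectance fractions in `[0, 1]`.
#' @return NDVI in `[-1, 1]`.
#' @export
#' @examples
#' compute_ndvi(nir = 0.4, red = 0.1) # 0.6
compute_ndvi <- function(nir, red) {
  if (any(nir < 0 | nir > 1 | red < 0 | red > 1)) {
    stop("reflectance fractions must lie in [0, 1]", call. = FALSE)
  }
  if (any(nir + red == 0)) {
    stop("undefined NDVI: nir + red = 0", call. = FALSE)
  }
  (nir - red) / (nir + red)
}

#' Fit an exponential regression of LAI or PNA on NDVI
#'
#' Fits `y = a * exp(b * ndvi)` by nonlinear least squares on the original
#' scale, initialized from the log-linear regression `log(y) ~ ndvi`.  This
#' is the spectral-index calibration used to invert canopy NDVI readings
#' into LAI or PNA estimates.
#'
#' @param ndvi Numeric vector of NDVI values.
#' @param y Positive response values (LAI, dimensionless, or PNA, kg/ha).
#' @param target Which variable `y` is: `"LAI"` or `"PNA"`.
#' @return An `exp_regression` object: list with `a`, `b`, `r2` (squared
#'   Pearson correlation of fitted vs observed), `n`, `target`, and the NDVI
#'   range seen during fitting.
#' @export
#' @examples
#' nd <- seq(0.2, 0.9, length.out = 20)
#' fit <- fit_exponential(nd, 0.3 * exp(3 * nd), "LAI")
#' c(fit$a, fit$b)
fit_exponential <- function(ndvi, y, target = c("LAI", "PNA")) {
  target <- match.arg(target)
  if (length(ndvi) != length(y) || length(y) < 3L) {
    stop("need at least 3 paired (ndvi, y) observations", call. = FALSE)
  }
  if (any(y <= 0)) {
    stop("all y must be positive for the exponential fit (log-scale ",
         "initialization)", call. = FALSE)
  }
  if (sd(ndvi) < 1e-12) {
    stop("rank-deficient fit: ndvi is constant", call. = FALSE)
  }
  init <- coef(lm(log(y) ~ ndvi))
  start <- list(a = exp(unname(init[1L])), b = unname(init[2L]))
  fit <- tryCatch(
    minpack.lm::nlsLM(y ~ a * exp(b * ndvi),
                      start = start,
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  if (is.null(fit)) {
    ab <- c(start$a, start$b)   # log-linear fallback for degenerate refits
  } else {
    ab <- unname(coef(fit))
  }
  pred <- ab[1L] * exp(ab[2L] * ndvi)
  r2 <- if (sd(pred) < 1e-12 || sd(y) < 1e-12) 0 else cor(y, pred)^2
  structure(list(a = ab[1L], b = ab[2L], r2 = r2, n = length(y),
                 target = target, ndvi_range = range(ndvi)),
            class = "exp_regression")
}

#' Invert an exponential NDVI regression
#'
#' Evaluates `a * exp(b * ndvi)`: the spectral-index estimate of the target
#' variable (LAIe or PNAe).  Warns when `ndvi` falls outside the range seen
#' while fitting, where the regression extrapolates.
#'
#' @param model An `exp_regression` from [fit_exponential()].
#' @param ndvi NDVI value(s).
#' @return Estimated target value(s), strictly monotone in `ndvi` when
#'   `b != 0`.
#' @export
invert_spectral <- function(model, ndvi) {
  stopifnot(inherits(model, "exp_regression"))
  rng <- model$ndvi_range
  if (!is.null(rng) && any(ndvi < rng[1L] | ndvi > rng[2L])) {
    warning("ndvi outside fitted range [", signif(rng[1L], 3), ", ",
            signif(rng[2L], 3), "]; extrapolating", call. = FALSE)
  }
  model$a * exp(model$b * ndvi)
}

#' @export
print.exp_regression <- function(x, ...) {
  cat(sprintf("exp_regression (%s): y = %.4g * exp(%.4g * NDVI), R2 = %.3f, n = %d\n",
              x$target, x$a, x$b, x$r2, x$n))
  invisible(x)
}

#' Locate NDVI saturation along a forward model
#'
#' Scans a monotone non-decreasing forward NDVI model over a grid of the
#' state variable and reports the smallest grid value at which the local
#' slope `dNDVI/dstate` has fallen below `slope_frac` (default 5%) of the
#' slope at the grid start: the onset of the saturation regime where NDVI
#' stops resolving the canopy.
#'
#' @param forward Function mapping state value (LAI or PNA) to NDVI.
#' @param grid Increasing numeric grid of state values.
#' @param slope_frac Fraction of the initial slope defining saturation.
#' @return A list with `saturated` (logical), `onset` (state value or `NA`),
#'   `slope_ratio` (vector over grid midpoints) and a `message` such as
#'   `"saturated above 6.2"` or `"no saturation on grid"`.
#' @export
saturation_diagnostic <- function(forward, grid, slope_frac = 0.05) {
  stopifnot(length(grid) >= 3L, all(diff(grid) > 0))
  v <- vapply(grid, forward, numeric(1))
  if (any(diff(v) < -1e-9)) {
    stop("forward model must be monotone non-decreasing on the grid",
         call. = FALSE)
  }
  slope <- diff(v) / diff(grid)
  s0 <- slope[1L]
  if (s0 <= 0) {  # flat from the start: saturated everywhere
    return(list(saturated = TRUE, onset = grid[1L],
                slope_ratio = rep(0, length(slope)),
                message = sprintf("saturated above %g", grid[1L])))
  }
  ratio <- slope / s0
  hit <- which(ratio < slope_frac)
  if (length(hit) == 0L) {
    list(saturated = FALSE, onset = NA_real_, slope_ratio = ratio,
         message = "no saturation on grid")
  } else {
    onset <- grid[hit[1L]]
    list(saturated = TRUE, onset = onset, slope_ratio = ratio,
         message = sprintf("saturated above %g", onset))
  }
}
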
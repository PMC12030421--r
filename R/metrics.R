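#' Relative error between observed and simulated values
#'
#' `RE = (O - S) / O * 100` per item.  Items with a zero observed value have
#' an undefined RE; they are returned as `NA`, rendered as `"/"` by
#' [format_re()], and excluded from the means (zero-nitrogen treatments are
#' the canonical case).
#'
#' @param observed,simulated Equal-length numeric vectors.
#' @return List with `re` (percent, `NA` where undefined), `mean_signed`,
#'   `mean_abs` (both over defined items) and `undefined` (logical vector).
#' @export
#' @examples
#' relative_error(c(100, 0), c(90, 5))$re # 10, NA
relative_error <- function(observed, simulated) {
  stopifnot(length(observed) == length(simulated))
  undef <- observed == 0
  re <- ifelse(undef, NA_real_, (observed - simulated) / observed * 100)
  list(re = re,
       mean_signed = mean(re[!undef]),
       mean_abs = mean(abs(re[!undef])),
       undefined = undef)
}

#' Render relative errors, marking undefined entries as "/"
#' @param re Numeric vector (percent) with `NA` for undefined items.
#' @param digits Rounding digits.
#' @return Character vector.
#' @export
format_re <- function(re, digits = 2) {
  ifelse(is.na(re), "/", formatC(round(re, digits), format = "fg"))
}

#' Root mean square error
#'
#' `sqrt(sum((O - S)^2) / N)` over paired observed/simulated values.
#'
#' @param observed,simulated Equal-length numeric vectors (length >= 1).
#' @return Non-negative scalar in the units of the inputs.
#' @export
rmse <- function(observed, simulated) {
  stopifnot(length(observed) == length(simulated), length(observed) >= 1L)
  sqrt(mean((observed - simulated)^2))
}

#' Root mean square dispersion of an ensemble of estimates
#'
#' `sqrt(sum((S_j - mean(S))^2) / K)`: the spread of an ensemble around its
#' own mean (population form, denominator `K`).  Used on posterior-predictive
#' ensembles as the uncertainty measure per stage/variable and for yield.
#'
#' @param estimates Numeric vector (length >= 1).
#' @return Non-negative scalar.
#' @export
rmsd <- function(estimates) {
  stopifnot(length(estimates) >= 1L)
  sqrt(mean((estimates - mean(estimates))^2))
}

#' Coefficient of determination
#'
#' By default the squared Pearson correlation of observed vs simulated (the
#' scatter-plot convention); `method = "ss"` gives the 1 - SSE/SST variant,
#' which can be negative for badly biased predictions.
#'
#' @param observed,simulated Equal-length numeric vectors.
#' @param method `"pearson"` (default) or `"ss"`.
#' @return Scalar; `<= 1` always, `>= 0` for `"pearson"`.
#' @export
r_squared <- function(observed, simulated, method = c("pearson", "ss")) {
  method <- match.arg(method)
  stopifnot(length(observed) == length(simulated), length(observed) >= 2L)
  if (method == "pearson") {
    if (sd(observed) == 0 || sd(simulated) == 0) return(NA_real_)
    cor(observed, simulated)^2
  } else {
    1 - sum((observed - simulated)^2) / sum((observed - mean(observed))^2)
  }
}

#' Compare assimilation against spectral inversion
#'
#' Per-variable goodness of fit of two estimation methods against the same
#' measured (or true) series: R squared and RMSE each, plus a per-variable
#' improvement flag (assimilation RMSE strictly below spectral RMSE).
#'
#' @param measured Data frame (or list) with `lai` and `pna` reference
#'   series.
#' @param spectral,assimilated Same-shape estimates from the spectral-index
#'   method and from the assimilation.
#' @return A `method_comparison`: list with `table` (variable x method R2 and
#'   RMSE) and `improved` (named logical per variable; `NA` when the methods
#'   tie exactly).
#' @export
compare_methods <- function(measured, spectral, assimilated) {
  vars <- c("lai", "pna")
  rows <- list()
  improved <- setNames(logical(length(vars)), vars)
  for (v in vars) {
    m <- measured[[v]]; sp <- spectral[[v]]; as_ <- assimilated[[v]]
    if (length(m) != length(sp) || length(m) != length(as_)) {
      stop("mismatched series lengths for variable ", v, call. = FALSE)
    }
    r_sp <- rmse(m, sp); r_as <- rmse(m, as_)
    rows[[length(rows) + 1L]] <- data.frame(
      variable = v, method = c("spectral", "assimilation"),
      r2 = c(r_squared(m, sp), r_squared(m, as_)),
      rmse = c(r_sp, r_as))
    improved[v] <- if (r_as == r_sp) NA else r_as < r_sp
  }
  structure(list(table = do.call(rbind, rows), improved = improved),
            class = "method_comparison")
}

#' @export
print.method_comparison <- function(x, ...) {
  cat("method_comparison (reference vs spectral / assimilation):\n")
  print(x$table, digits = 4, row.names = FALSE)
  for (v in names(x$improved)) {
    verdict <- if (is.na(x$improved[v])) "tie" else
      if (x$improved[v]) "assimilation wins" else "spectral wins"
    cat(sprintf("  %s: %s\n", v, verdict))
  }
  invisible(x)
}
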
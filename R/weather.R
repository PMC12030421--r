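#' Default synthetic climate configuration
#'
#' A humid subtropical annual cycle (rice-growing latitude ~30 N): sinusoidal
#' daily mean temperature peaking in late July, a fixed diurnal range, and a
#' sinusoidal solar radiation cycle, plus seeded day-to-day Gaussian noise.
#'
#' @return A list of climatology parameters with units in the names:
#'   `temp_mean_c`, `temp_amp_c` (annual mean and half-amplitude, deg C),
#'   `temp_peak_doy`, `diurnal_range_c`, `temp_noise_sd_c`,
#'   `srad_mean`, `srad_amp` (MJ m-2 d-1), `srad_peak_doy`, `srad_noise_sd`,
#'   `srad_min`.
#' @export
default_climate <- function() {
  list(temp_mean_c = 17, temp_amp_c = 11, temp_peak_doy = 205,
       diurnal_range_c = 8, temp_noise_sd_c = 1.5,
       srad_mean = 15, srad_amp = 7, srad_peak_doy = 172,
       srad_noise_sd = 2.5, srad_min = 2)
}

#' Generate a synthetic daily weather series
#'
#' Daily minimum/maximum air temperature and solar radiation from a sinusoidal
#' seasonal climatology with seeded Gaussian day-to-day noise.  `tmax >= tmin`
#' is enforced by construction (noise is added to the daily mean, not to the
#' two extremes independently).
#'
#' @param n_days Number of days to generate.
#' @param climate Climatology list, see [default_climate()].
#' @param seed Integer RNG seed; the same seed reproduces the series exactly.
#' @param start_doy Day-of-year of the first row (default 1).
#' @param start_year Calendar year used to construct ISO dates (default 2015).
#' @return A `data.frame` with columns `date` (ISO-8601), `doy`, `tmin`,
#'   `tmax` (deg C) and `srad` (MJ m-2 d-1).
#' @export
#' @examples
#' w <- generate_weather(30, seed = 1)
#' all(w$tmax >= w$tmin)
generate_weather <- function(n_days, climate = default_climate(), seed = 1L,
                             start_doy = 1L, start_year = 2015L) {
  stopifnot(n_days >= 1)
  set.seed(seed)
  doy <- seq.int(start_doy, length.out = n_days)
  tmean <- climate$temp_mean_c +
    climate$temp_amp_c * cos(2 * pi * (doy - climate$temp_peak_doy) / 365) +
    rnorm(n_days, 0, climate$temp_noise_sd_c)
  half <- climate$diurnal_range_c / 2
  srad <- climate$srad_mean +
    climate$srad_amp * cos(2 * pi * (doy - climate$srad_peak_doy) / 365) +
    rnorm(n_days, 0, climate$srad_noise_sd)
  date <- as.Date(doy - 1, origin = sprintf("%d-01-01", start_year))
  out <- data.frame(date = format(date, "%Y-%m-%d"), doy = doy,
                    tmin = round(tmean - half, 2),
                    tmax = round(tmean + half, 2),
                    srad = round(pmax(srad, climate$srad_min), 2))
  validate_weather(out)
}

#' Read a daily weather series from delimited text
#'
#' Expects a comma-separated file with header `date,tmin,tmax,srad`
#' (ISO-8601 dates); a `doy` column is derived when absent.
#'
#' @param path Path to the CSV file.
#' @return A validated weather `data.frame` as from [generate_weather()].
#' @export
read_weather <- function(path) {
  w <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("date", "tmin", "tmax", "srad")
  missing <- setdiff(need, names(w))
  if (length(missing)) {
    stop("weather file ", path, " is missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  if (!"doy" %in% names(w)) {
    w$doy <- as.integer(strftime(as.Date(w$date), "%j")) +
      365L * (as.integer(strftime(as.Date(w$date), "%Y")) -
                as.integer(strftime(as.Date(w$date[1]), "%Y")))
  }
  validate_weather(w[, c("date", "doy", "tmin", "tmax", "srad")])
}

#' Write a weather series to delimited text
#' @param weather Weather `data.frame`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_weather <- function(weather, path) {
  write.csv(weather[, c("date", "doy", "tmin", "tmax", "srad")], path,
            row.names = FALSE, quote = FALSE)
  invisible(path)
}

validate_weather <- function(w) {
  if (any(w$tmax < w$tmin)) {
    stop("invalid weather: tmax < tmin on ", sum(w$tmax < w$tmin), " day(s)",
         call. = FALSE)
  }
  if (nrow(w) > 1 && any(diff(w$doy) != 1L)) {
    stop("invalid weather: dates are not contiguous daily", call. = FALSE)
  }
  w
}
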
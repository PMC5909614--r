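#' Temperature response of development
#'
#' The pair of cardinal temperatures converting daily air temperature to a
#' thermal-time increment: development accrues linearly above `tbase` and is
#' capped at `topt`.
#'
#' @param tbase Base temperature (degrees C) below which no thermal time
#'   accumulates. Default 8.
#' @param topt Optimum temperature (degrees C) at which the daily increment
#'   saturates. Default 34. Must exceed `tbase`.
#' @return A list of class `temperature_response`.
#' @examples
#' temperature_response()
#' @export
temperature_response <- function(tbase = 8, topt = 34) {
  stopifnot(is.numeric(tbase), is.numeric(topt), length(tbase) == 1,
            length(topt) == 1)
  if (!(topt > tbase)) {
    abort("`topt` must be strictly greater than `tbase`.")
  }
  structure(list(tbase = tbase, topt = topt), class = "temperature_response")
}

#' @export
print.temperature_response <- function(x, ...) {
  cat(sprintf("<temperature_response> tbase = %g C, topt = %g C\n",
              x$tbase, x$topt))
  invisible(x)
}

#' Daily thermal-time increment (growing degree-days)
#'
#' Converts a day's maximum and minimum air temperature into a thermal-time
#' increment: `max(0, min((tmax + tmin)/2, topt) - tbase)`. The increment is
#' zero at or below the base temperature and constant (`topt - tbase`) at or
#' above the optimum. Vectorised over days.
#'
#' @param tmax,tmin Daily maximum and minimum temperature (degrees C);
#'   `tmax >= tmin` element-wise.
#' @param resp A [temperature_response()].
#' @param dates Optional vector of dates used to name offending records in
#'   error messages.
#' @return Numeric vector of growing degree-days (degree C-days).
#' @examples
#' daily_thermal_time(30, 20)  # mean 25, linear region: 17
#' @export
daily_thermal_time <- function(tmax, tmin, resp = temperature_response(),
                               dates = NULL) {
  stopifnot(length(tmax) == length(tmin))
  bad <- which(tmax < tmin)
  if (length(bad) > 0) {
    lab <- if (!is.null(dates)) paste(dates[bad[1]]) else paste("record", bad[1])
    abort(sprintf("invalid weather record (%s): tmax (%g) < tmin (%g)",
                  lab, tmax[bad[1]], tmin[bad[1]]))
  }
  pmax(0, pmin((tmax + tmin) / 2, resp$topt) - resp$tbase)
}

#' Astronomical day length including twilight
#'
#' Day length in hours from solar declination and the sunset hour angle at a
#' given solar depression below the horizon. With `depression = 6` (civil
#' twilight, the convention used for maize photoperiod response) the day is
#' longer than the sunrise-to-sunset value at `depression = 0`.
#'
#' Declination uses the standard annual sinusoid
#' `delta = -23.45 * cos(2 * pi * (doy + 10) / 365)` degrees; the hour angle
#' solves `cos(omega) = (sin(-depression) - sin(phi) sin(delta)) /
#' (cos(phi) cos(delta))` with the cosine argument clamped to `[-1, 1]`, so
#' polar day and night return 24 and 0 h.
#'
#' @param latitude Latitude in degrees (+N), `|latitude| <= 90`.
#' @param doy Day of year (1-366); vectorised.
#' @param depression Solar depression angle below the horizon in degrees
#'   (>= 0). Default 6 (civil twilight).
#' @return Day length in hours, in `[0, 24]`.
#' @examples
#' photoperiod(42.73, 172)       # midsummer at 42.73 N, civil twilight
#' photoperiod(0, 80, depression = 0)  # equatorial equinox: ~12 h
#' @export
photoperiod <- function(latitude, doy, depression = 6) {
  stopifnot(length(latitude) == 1, abs(latitude) <= 90,
            all(doy >= 1), all(doy <= 366), depression >= 0)
  rad <- pi / 180
  decl <- -23.45 * cos(2 * pi * (doy + 10) / 365) * rad
  phi <- latitude * rad
  num <- sin(-depression * rad) - sin(phi) * sin(decl)
  den <- cos(phi) * cos(decl)
  cosw <- pmin(1, pmax(-1, num / den))
  2 * acos(cosw) / rad / 15
}

#' Assemble a site-year record
#'
#' A site-year is one location by growing-season combination: latitude,
#' sowing day of year and a daily weather series. Site-years are stored as
#' rows of a tibble with the weather as a list-column so that a set of them
#' pipes through the usual dplyr verbs.
#'
#' @param site_id Short label, e.g. `"NY6"`.
#' @param latitude Degrees north (-90 to 90).
#' @param longitude Degrees east (informational).
#' @param year Calendar year of sowing.
#' @param sowing_doy Day of year of sowing (1-366).
#' @param weather A tibble with columns `date` (Date, strictly consecutive
#'   days), `tmax`, `tmin` (degrees C, `tmax >= tmin`). Must cover at least
#'   `horizon` days after sowing; series may wrap across the year end.
#' @param horizon Required post-sowing weather coverage in days (default 250).
#' @return A one-row tibble with columns `site_id`, `latitude`, `longitude`,
#'   `year`, `sowing_doy`, `sowing_date`, `weather` (list-column).
#' @export
site_year <- function(site_id, latitude, longitude, year, sowing_doy, weather,
                      horizon = 250) {
  stopifnot(abs(latitude) <= 90, sowing_doy >= 1, sowing_doy <= 366)
  validate_weather(weather)
  sowing_date <- as.Date(sprintf("%d-01-01", year)) + (sowing_doy - 1)
  need_last <- sowing_date + horizon
  if (min(weather$date) > sowing_date || max(weather$date) < need_last) {
    abort(sprintf(
      "weather for %s covers %s..%s but must cover %s..%s (sowing + %d days)",
      site_id, min(weather$date), max(weather$date), sowing_date, need_last,
      horizon))
  }
  tibble::tibble(site_id = site_id, latitude = latitude,
                 longitude = longitude, year = as.integer(year),
                 sowing_doy = as.integer(sowing_doy),
                 sowing_date = sowing_date,
                 weather = list(weather))
}

#' Validate a daily weather series
#'
#' Checks the series invariants: consecutive daily dates with no gaps, and
#' `tmax >= tmin` on every record. Errors name the first offending record.
#'
#' @param weather Tibble with `date`, `tmax`, `tmin`.
#' @return The weather tibble, invisibly.
#' @export
validate_weather <- function(weather) {
  need <- c("date", "tmax", "tmin")
  miss <- setdiff(need, names(weather))
  if (length(miss) > 0) {
    abort(paste("weather is missing column(s):", paste(miss, collapse = ", ")))
  }
  d <- diff(as.integer(as.Date(weather$date)))
  if (any(d != 1)) {
    i <- which(d != 1)[1]
    abort(sprintf("weather dates must be consecutive days: gap after %s (line %d)",
                  weather$date[i], i + 1))
  }
  bad <- which(weather$tmax < weather$tmin)
  if (length(bad) > 0) {
    abort(sprintf("invalid weather record (%s, line %d): tmax < tmin",
                  weather$date[bad[1]], bad[1] + 1))
  }
  invisible(weather)
}

#' Read a daily weather file and assemble a site-year
#'
#' The weather CSV dialect is `date,tmax,tmin` with ISO-8601 dates and
#' temperatures in degrees C.
#'
#' @param path Path to the weather CSV.
#' @inheritParams site_year
#' @return A one-row site-year tibble (see [site_year()]).
#' @export
read_weather <- function(path, site_id, latitude, longitude, year, sowing_doy,
                         horizon = 250) {
  if (!file.exists(path)) abort(paste("weather file not found:", path))
  weather <- readr::read_csv(path, col_types = readr::cols(
    date = readr::col_date(), tmax = readr::col_double(),
    tmin = readr::col_double()))
  site_year(site_id, latitude, longitude, year, sowing_doy, weather,
            horizon = horizon)
}

#' Write a daily weather series to CSV
#'
#' @param weather Weather tibble (`date`, `tmax`, `tmin`).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_weather <- function(weather, path) {
  validate_weather(weather)
  readr::write_csv(weather[c("date", "tmax", "tmin")], path)
  invisible(path)
}

#' Read a site metadata table and its weather files
#'
#' The site CSV dialect is
#' `site_id,latitude,longitude,year,sowing_doy,weather_file`; weather paths
#' are resolved relative to the metadata file.
#'
#' @param path Path to the site metadata CSV.
#' @param horizon Required post-sowing coverage in days.
#' @return A site-year tibble, one row per site-year.
#' @export
read_sites <- function(path, horizon = 250) {
  meta <- readr::read_csv(path, col_types = readr::cols(
    site_id = readr::col_character(), latitude = readr::col_double(),
    longitude = readr::col_double(), year = readr::col_integer(),
    sowing_doy = readr::col_integer(), weather_file = readr::col_character()))
  purrr::pmap_dfr(meta, function(site_id, latitude, longitude, year,
                                 sowing_doy, weather_file) {
    read_weather(file.path(dirname(path), weather_file), site_id, latitude,
                 longitude, year, sowing_doy, horizon = horizon)
  })
}

# Per-day environment table for one site-year: day after sowing, doy,
# temperatures and civil-twilight day length. Internal workhorse shared by
# the R and compiled simulators.
site_environment <- function(sy, horizon = 250, depression = 6) {
  w <- sy$weather[[1]]
  start <- sy$sowing_date + 1
  idx <- match(seq(start, start + horizon - 1, by = "day"), w$date)
  if (anyNA(idx)) abort(sprintf("weather for %s does not cover horizon", sy$site_id))
  days <- w[idx, ]
  doy <- as.integer(format(days$date, "%j"))
  tibble::tibble(
    dap = seq_len(horizon), date = days$date, doy = doy,
    tmax = days$tmax, tmin = days$tmin,
    daylength = photoperiod(sy$latitude, doy, depression))
}
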
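# Default 11-site-year template: the latitude / sowing-day structure of the
# multi-site maize NAM trials (six US sites, 2006-2007, latitudes 18.00 to
# 42.73 N, sowings from spring (DOY 120-138) to late-year tropical plantings
# (DOY 265-314)). Climate means follow a simple latitude gradient; the
# weather generator is a sinusoid plus noise, not a climate model.
default_site_templates <- function() {
  tibble::tibble(
    site_id = c("NY6", "NY7", "NC6", "NC7", "MO6", "MO7",
                "IL6", "IL7", "FL6", "FL7", "PR6"),
    latitude = c(42.73, 42.73, 35.67, 35.67, 38.89, 38.89,
                 40.08, 40.08, 25.51, 25.51, 18.00),
    longitude = c(-76.66, -76.66, -78.49, -78.49, -92.23, -92.23,
                  -88.20, -88.20, -80.49, -80.49, -66.51),
    year = c(2006L, 2007L, 2006L, 2007L, 2006L, 2007L,
             2006L, 2007L, 2006L, 2007L, 2006L),
    sowing_doy = c(128L, 135L, 122L, 120L, 137L, 138L,
                   128L, 137L, 265L, 280L, 314L),
    tmax_mean = 36 - 0.3 * c(42.73, 42.73, 35.67, 35.67, 38.89, 38.89,
                             40.08, 40.08, 25.51, 25.51, 18.00),
    tmax_amplitude = 0.35 * c(42.73, 42.73, 35.67, 35.67, 38.89, 38.89,
                              40.08, 40.08, 25.51, 25.51, 18.00),
    diurnal_range = 10,
    noise_sd = 2,
    peak_doy = 200)
}

#' Synthetic study configuration
#'
#' Bundles the design of a synthetic multi-site anthesis trial: the
#' site-year templates, population size, true-parameter box, observation
#' noise and missingness.
#'
#' @param site_templates Tibble of site templates (see
#'   `phenoscan:::default_site_templates()` for the column set); the default
#'   reproduces the 11-site-year span of the real multi-site trials
#'   (latitudes 18.00-42.73 N, sowing DOY 120-314).
#' @param n_lines Number of lines (default 600).
#' @param box True-parameter box (default [default_parameter_box()]).
#' @param noise_sd Observation noise standard deviation in days, applied as
#'   a rounded Gaussian since anthesis is scored in whole days (default 1.5).
#' @param missing_rate Independent per-(line, site-year) missingness
#'   probability (default 0.15).
#' @param horizon Weather coverage after sowing, days (default 280).
#' @return A list of class `synth_config`.
#' @export
synth_config <- function(site_templates = default_site_templates(),
                         n_lines = 600, box = default_parameter_box(),
                         noise_sd = 1.5, missing_rate = 0.15, horizon = 280) {
  stopifnot(noise_sd >= 0, missing_rate >= 0, missing_rate <= 1, n_lines >= 1)
  structure(list(site_templates = site_templates, n_lines = n_lines,
                 box = box, noise_sd = noise_sd,
                 missing_rate = missing_rate, horizon = horizon),
            class = "synth_config")
}

#' Generate a synthetic daily weather series
#'
#' Annual sinusoid plus Gaussian noise:
#' `tmax = mean + amplitude * cos(2 pi (doy - peak_doy) / 365) + noise`,
#' `tmin = tmax - diurnal_range + noise`, clipped so `tmax >= tmin`.
#'
#' @param template One site template row (see [synth_config()]).
#' @param seed Integer seed; generation is deterministic given the seed.
#' @param horizon Days of coverage after sowing.
#' @return A weather tibble `date`, `tmax`, `tmin` passing
#'   [validate_weather()].
#' @export
make_weather <- function(template, seed = 1, horizon = 280) {
  sowing <- as.Date(sprintf("%d-01-01", template$year)) + (template$sowing_doy - 1)
  dates <- seq(sowing - 5, sowing + horizon + 5, by = "day")
  doy <- as.integer(format(dates, "%j"))
  n <- length(dates)
  withr::with_seed(seed, {
    tmax <- template$tmax_mean +
      template$tmax_amplitude * cos(2 * pi * (doy - template$peak_doy) / 365) +
      rnorm(n, 0, template$noise_sd)
    tmin <- tmax - template$diurnal_range + rnorm(n, 0, template$noise_sd)
  })
  tmin <- pmin(tmin, tmax)
  tibble::tibble(date = dates, tmax = tmax, tmin = tmin)
}

#' Generate the synthetic site-years
#'
#' One site-year per template row, each with its own generated weather
#' series. Deterministic given the seed; per-site seeds are derived from the
#' master seed.
#'
#' @param cfg A [synth_config()].
#' @param seed Master integer seed.
#' @return A site-year tibble (rows as from [site_year()]).
#' @export
make_siteyears <- function(cfg = synth_config(), seed = 1) {
  tpl <- cfg$site_templates
  purrr::map_dfr(seq_len(nrow(tpl)), function(i) {
    s <- as.integer((as.numeric(seed) * 1000 + i) %% 2147483647)
    w <- make_weather(tpl[i, ], seed = s, horizon = cfg$horizon)
    site_year(tpl$site_id[i], tpl$latitude[i], tpl$longitude[i], tpl$year[i],
              tpl$sowing_doy[i], w, horizon = cfg$horizon)
  })
}

#' Draw a true-parameter population
#'
#' Independent uniform draws per axis inside the box.
#'
#' @param n_lines Number of lines.
#' @param box A [parameter_box()].
#' @param seed Integer seed.
#' @return A tibble `line_id` plus one column per box axis.
#' @export
make_population <- function(n_lines, box = default_parameter_box(), seed = 1) {
  stopifnot(n_lines >= 1)
  withr::with_seed(seed, {
    cols <- purrr::map(seq_len(nrow(box)), function(j) {
      runif(n_lines, box$min[j], box$max[j])
    })
  })
  dplyr::bind_cols(tibble::tibble(line_id = sprintf("L%04d", seq_len(n_lines))),
                   tibble::as_tibble(rlang::set_names(cols, box$name)))
}

#' Sample a true population from generated parameter sets
#'
#' Draws lines whose true parameters are rows of an existing quasi-random
#' design, so the truth is guaranteed to sit on the database grid
#' (closed-loop identifiability experiments).
#'
#' @param sets Parameter sets (e.g. [generate_sobol_sets()] output).
#' @param n_lines Number of lines to draw.
#' @param seed Integer seed.
#' @return A tibble `line_id`, `set_row` (source row), plus the parameters.
#' @export
sample_population_from_sets <- function(sets, n_lines, seed = 1) {
  stopifnot(n_lines >= 1, nrow(sets) >= n_lines)
  rows <- withr::with_seed(seed, sample.int(nrow(sets), n_lines))
  dplyr::bind_cols(
    tibble::tibble(line_id = sprintf("L%04d", seq_len(n_lines)),
                   set_row = rows),
    tibble::as_tibble(sets)[rows, ])
}

#' Generate observed anthesis dates for a population
#'
#' Simulates each line's true parameters in every site-year, adds rounded
#' Gaussian observation noise (anthesis is scored in whole days), deletes
#' entries independently at the missingness rate, and drops entries where
#' the simulation did not flower (mirroring field panels where late sowings
#' leave lines unobserved).
#'
#' @param pop Population tibble (`line_id` + parameter columns).
#' @param siteyears Site-year tibble.
#' @param control A [phenology_control()].
#' @param noise_sd Observation noise sd in days (>= 0).
#' @param missing_rate Independent missingness probability in `[0, 1]`.
#' @param site_bias Optional named numeric vector of systematic per-site-year
#'   shifts in days (rounded to whole days), emulating structural model error
#'   that varies across environments; estimates obtained from different
#'   environment subsets then genuinely differ, which the stability test
#'   should detect. Default none.
#' @param seed Integer seed.
#' @return A long tibble `line_id`, `site_year`, `anthesis_dap`.
#' @export
make_observations <- function(pop, siteyears, control = phenology_control(),
                              noise_sd = 1.5, missing_rate = 0.15,
                              site_bias = NULL, seed = 1) {
  stopifnot(noise_sd >= 0, missing_rate >= 0, missing_rate <= 1)
  n <- nrow(pop)
  sim <- matrix(NA_integer_, n, nrow(siteyears),
                dimnames = list(pop$line_id, siteyears$site_id))
  for (j in seq_len(nrow(siteyears))) {
    sim[, j] <- simulate_anthesis_batch(siteyears[j, ], pop, control)
  }
  withr::with_seed(seed, {
    noise <- matrix(as.integer(round(rnorm(length(sim), 0, noise_sd))),
                    n, ncol(sim))
    miss <- matrix(runif(length(sim)) < missing_rate, n, ncol(sim))
  })
  obs <- sim + noise
  if (!is.null(site_bias)) {
    b <- as.integer(round(site_bias[colnames(sim)]))
    b[is.na(b)] <- 0L
    obs <- obs + matrix(b, n, ncol(sim), byrow = TRUE)
  }
  obs[sim < 0 | miss] <- NA_integer_
  obs[!is.na(obs) & obs < 1L] <- 1L # noise cannot move an observation before sowing
  tibble::as_tibble(obs) |>
    dplyr::mutate(line_id = pop$line_id, .before = 1) |>
    tidyr::pivot_longer(-"line_id", names_to = "site_year",
                        values_to = "anthesis_dap") |>
    dplyr::filter(!is.na(.data$anthesis_dap))
}

#' Generate a complete synthetic study
#'
#' Site-years, true population and observations in one call.
#'
#' @param cfg A [synth_config()].
#' @param control A [phenology_control()].
#' @param seed Master integer seed.
#' @param population Optional pre-built population (overrides the uniform
#'   draw, e.g. from [sample_population_from_sets()]).
#' @return A list `siteyears`, `population`, `observations`, `cfg`, `seed`.
#' @export
make_synthetic_study <- function(cfg = synth_config(),
                                 control = phenology_control(), seed = 1,
                                 population = NULL) {
  siteyears <- make_siteyears(cfg, seed = seed)
  population <- population %||%
    make_population(cfg$n_lines, cfg$box, seed = seed + 1L)
  observations <- make_observations(population, siteyears, control,
                                    noise_sd = cfg$noise_sd,
                                    missing_rate = cfg$missing_rate,
                                    seed = seed + 2L)
  list(siteyears = siteyears, population = population,
       observations = observations, cfg = cfg, seed = seed)
}

#' Simulate a GSP estimate panel from the crossed random-effects model
#'
#' Draws `estimate[l, e] = mu + a_l + b_e + eps` with independent Gaussian
#' effects — the generating model of the stability test, used for its
#' calibration and power studies.
#'
#' @param n_lines,n_subsets Panel dimensions.
#' @param mu Grand mean.
#' @param sd_line,sd_subset,sd_resid Effect standard deviations (>= 0).
#' @param seed Integer seed.
#' @return A long tibble `line_id`, `subset_id`, `estimate`.
#' @export
simulate_gsp_panel <- function(n_lines, n_subsets, mu = 100, sd_line = 10,
                               sd_subset = 0, sd_resid = 5, seed = 1) {
  stopifnot(sd_line >= 0, sd_subset >= 0, sd_resid > 0)
  withr::with_seed(seed, {
    a <- rnorm(n_lines, 0, sd_line)
    b <- rnorm(n_subsets, 0, sd_subset)
    eps <- rnorm(n_lines * n_subsets, 0, sd_resid)
  })
  tidyr::expand_grid(line_id = sprintf("L%04d", seq_len(n_lines)),
                     subset_id = sprintf("S%03d", seq_len(n_subsets))) |>
    dplyr::mutate(estimate = mu + rep(a, each = n_subsets) +
                    rep(b, times = n_lines) + eps)
}
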
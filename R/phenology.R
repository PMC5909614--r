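#' Phenology simulation settings
#'
#' Collects the non-genotypic constants of the anthesis-date submodel.
#'
#' @param tbase,topt Default cardinal temperatures (degrees C) used when a
#'   parameter set does not carry its own; see [temperature_response()].
#' @param emergence_gdd Thermal time from sowing to emergence (growing
#'   degree-days). Emergence is modelled as a fixed thermal-time lag; default
#'   45 GDD.
#' @param stage2_mode `"daily"` (default) accumulates a daily development
#'   fraction `1 / (4 + p2 * max(0, daylength - p2o))` until it reaches 1;
#'   `"fixed"` computes the stage duration once from the day length at the
#'   end of the juvenile phase (sensitivity variant).
#' @param sumdtt_from Origin of the thermal-time sum entering the leaf-number
#'   calculation: `"emergence"` (default) or `"end_juvenile"`.
#' @param max_horizon_days Simulation horizon in days after sowing; a run
#'   that has not flowered by then returns the failure sentinel.
#' @param depression Solar depression (degrees) for the photoperiod; 6 =
#'   civil twilight.
#' @return A list of class `phenology_control`.
#' @export
phenology_control <- function(tbase = 8, topt = 34, emergence_gdd = 45,
                              stage2_mode = c("daily", "fixed"),
                              sumdtt_from = c("emergence", "end_juvenile"),
                              max_horizon_days = 250, depression = 6) {
  stage2_mode <- match.arg(stage2_mode)
  sumdtt_from <- match.arg(sumdtt_from)
  stopifnot(emergence_gdd > 0, max_horizon_days > 1)
  resp <- temperature_response(tbase, topt) # validates topt > tbase
  structure(list(tbase = resp$tbase, topt = resp$topt,
                 emergence_gdd = emergence_gdd, stage2_mode = stage2_mode,
                 sumdtt_from = sumdtt_from,
                 max_horizon_days = as.integer(max_horizon_days),
                 depression = depression),
            class = "phenology_control")
}

#' Genotype-specific parameters of the anthesis submodel
#'
#' @param p1 Thermal time from emergence to end of the juvenile phase
#'   (GDD, degrees C-days); > 0.
#' @param p2 Photoperiod sensitivity: extra days in the photoperiod-sensitive
#'   stage per hour of day length beyond `p2o`; >= 0.
#' @param p2o Critical short day length (h) at or below which the stage takes
#'   its minimum four-day duration; in (0, 24].
#' @param phint Phyllochron interval (GDD between successive leaf tips); > 0.
#' @param tbase,topt Optional per-genotype cardinal temperatures; if `NA`
#'   (default) the [phenology_control()] defaults apply.
#' @return A one-row tibble with columns `p1`, `p2`, `p2o`, `phint`,
#'   `tbase`, `topt`.
#' @examples
#' cultivar_params(220, 0.5, 12.5, 44)
#' @export
cultivar_params <- function(p1, p2, p2o, phint, tbase = NA_real_,
                            topt = NA_real_) {
  stopifnot(p1 > 0, p2 >= 0, p2o > 0, p2o <= 24, phint > 0)
  if (!is.na(tbase) && !is.na(topt)) stopifnot(topt > tbase)
  tibble::tibble(p1 = p1, p2 = p2, p2o = p2o, phint = phint,
                 tbase = tbase, topt = topt)
}

#' Daily development fraction of the photoperiod-sensitive stage
#'
#' `1 / (4 + p2 * max(0, daylength - p2o))`: the stage completes in exactly
#' four days under short days (`daylength <= p2o`) and is stretched by `p2`
#' extra days per hour of day length beyond the critical photoperiod.
#'
#' @param daylength Day length in hours (including twilight); vectorised.
#' @param p2 Photoperiod sensitivity (days per hour), >= 0.
#' @param p2o Critical short day length (h).
#' @return Development fraction per day, in (0, 0.25].
#' @examples
#' stage2_daily_increment(13, 2, 14)  # short day: 0.25 (four-day stage)
#' stage2_daily_increment(15, 2, 14)  # 1/6
#' @export
stage2_daily_increment <- function(daylength, p2, p2o) {
  stopifnot(all(is.finite(daylength)), p2 >= 0)
  1 / (4 + p2 * pmax(0, daylength - p2o))
}

#' Total leaf number at the end of the photoperiod-sensitive stage
#'
#' `sumdtt / (phint * 0.5) + 5`: five embryonic leaves plus two new leaves
#' initiated per phyllochron interval of accumulated thermal time.
#'
#' @param sumdtt Thermal time accumulated through tassel initiation (GDD).
#' @param phint Phyllochron interval (GDD); > 0.
#' @return Leaf count (real, >= 5).
#' @examples
#' total_leaf_number(0, 44)    # embryonic leaves only: 5
#' total_leaf_number(220, 44)  # 15
#' @export
total_leaf_number <- function(sumdtt, phint) {
  if (any(phint <= 0)) abort("`phint` must be positive.")
  stopifnot(all(sumdtt >= 0))
  sumdtt / (phint * 0.5) + 5
}

# Fill per-set cardinal temperatures with control defaults and return the
# 6-column matrix the compiled simulator expects.
params_matrix <- function(params, control) {
  need <- c("p1", "p2", "p2o", "phint")
  miss <- setdiff(need, names(params))
  if (length(miss) > 0) {
    abort(paste("parameter set is missing column(s):", paste(miss, collapse = ", ")))
  }
  tbase <- if ("tbase" %in% names(params)) params$tbase else NA_real_
  topt <- if ("topt" %in% names(params)) params$topt else NA_real_
  tbase <- ifelse(is.na(tbase), control$tbase, tbase)
  topt <- ifelse(is.na(topt), control$topt, topt)
  cbind(p1 = params$p1, p2 = params$p2, p2o = params$p2o,
        phint = params$phint, tbase = tbase, topt = topt)
}

#' Simulate the anthesis date for one genotype in one site-year
#'
#' Runs the three-stage daily loop: emergence after a fixed thermal-time lag
#' from sowing; Stage 1 (juvenile) ends the first day accumulated thermal
#' time since emergence reaches `p1`; Stage 2 accumulates a daily
#' photoperiod-dependent development fraction until tassel initiation; Stage
#' 3 ends (anthesis) the first day thermal time since tassel initiation
#' reaches `(TOLN + 0.5) * phint - SUMDTT`, where `SUMDTT` is the thermal
#' time through tassel initiation and `TOLN` the total leaf number.
#'
#' @param sy A one-row site-year tibble (see [site_year()]).
#' @param params A one-row parameter tibble (see [cultivar_params()]).
#' @param control A [phenology_control()].
#' @return A one-row tibble: `emergence_dap`, `end_juvenile_dap`,
#'   `tassel_initiation_dap`, `anthesis_dap` (integer days after sowing;
#'   `NA` with `flowered = FALSE` if the horizon is exhausted), `sumdtt`
#'   (GDD), `toln` (leaves), `flowered` (logical).
#' @examples
#' \dontrun{
#' sy <- make_siteyears(seed = 1)[1, ]
#' simulate_anthesis(sy, cultivar_params(220, 0.5, 12.5, 44))
#' }
#' @export
simulate_anthesis <- function(sy, params, control = phenology_control()) {
  stopifnot(nrow(params) == 1)
  env <- site_environment(sy, control$max_horizon_days, control$depression)
  pm <- params_matrix(params, control)
  resp <- temperature_response(pm[1, "tbase"], pm[1, "topt"])
  gdd <- daily_thermal_time(env$tmax, env$tmin, resp, dates = env$date)
  cum <- cumsum(gdd)

  fail <- tibble::tibble(emergence_dap = NA_integer_,
                         end_juvenile_dap = NA_integer_,
                         tassel_initiation_dap = NA_integer_,
                         anthesis_dap = NA_integer_,
                         sumdtt = NA_real_, toln = NA_real_, flowered = FALSE)

  first_at <- function(cumsum_vec, from, target) {
    # first day (> from) with cumsum - cumsum[from] >= target; 0 = sowing
    base <- if (from == 0) 0 else cumsum_vec[from]
    rest <- if (from == 0) cumsum_vec else cumsum_vec[-seq_len(from)]
    i <- which(rest - base >= target)
    if (length(i) == 0) NA_integer_ else from + i[1]
  }

  emergence <- first_at(cum, 0L, control$emergence_gdd)
  if (is.na(emergence)) return(fail)
  end_juv <- first_at(cum, emergence, params$p1)
  if (is.na(end_juv)) return(fail)

  if (control$stage2_mode == "daily") {
    inc <- stage2_daily_increment(env$daylength, params$p2, params$p2o)
    s2 <- cumsum(inc[-seq_len(end_juv)])
    i <- which(s2 >= 1 - 1e-12)
    ti <- if (length(i) == 0) NA_integer_ else end_juv + i[1]
  } else {
    dur <- 4 + params$p2 * max(0, env$daylength[end_juv] - params$p2o)
    ti <- end_juv + as.integer(ceiling(dur))
    if (ti > nrow(env)) ti <- NA_integer_
  }
  if (is.na(ti)) return(fail)

  origin <- if (control$sumdtt_from == "emergence") emergence else end_juv
  sumdtt <- cum[ti] - cum[origin]
  toln <- total_leaf_number(sumdtt, params$phint)
  thresh <- (toln + 0.5) * params$phint - sumdtt
  anthesis <- first_at(cum, ti, thresh)
  if (is.na(anthesis)) return(fail)

  tibble::tibble(emergence_dap = as.integer(emergence),
                 end_juvenile_dap = as.integer(end_juv),
                 tassel_initiation_dap = as.integer(ti),
                 anthesis_dap = as.integer(anthesis),
                 sumdtt = sumdtt, toln = toln, flowered = TRUE)
}

#' Simulate anthesis dates for many parameter sets in one site-year
#'
#' Compiled batch version of [simulate_anthesis()]: one pass over the daily
#' environment per parameter set. Used to build simulation databases and as
#' the objective engine of the continuous search.
#'
#' @param sy A one-row site-year tibble.
#' @param params Tibble of parameter sets (columns `p1`, `p2`, `p2o`,
#'   `phint`, optionally `tbase`, `topt`).
#' @param control A [phenology_control()].
#' @return Integer vector of anthesis days after sowing, `-1` where the
#'   horizon was exhausted ("did not flower").
#' @export
simulate_anthesis_batch <- function(sy, params, control = phenology_control()) {
  env <- site_environment(sy, control$max_horizon_days, control$depression)
  pm <- params_matrix(params, control)
  cpp_simulate_batch(env$tmax, env$tmin, env$daylength, pm,
                     control$emergence_gdd,
                     control$stage2_mode == "fixed",
                     control$sumdtt_from == "end_juvenile")
}
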
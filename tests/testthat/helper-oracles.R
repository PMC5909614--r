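# Independent oracles and small fixture builders. Everything here is written
# deliberately differently from the package internals (explicit loops,
# root-finding, brute force) so agreement is informative.

# --- fixtures -----------------------------------------------------------

# constant-weather site-year: tmax/tmin flat, latitude controls daylength
const_siteyear <- function(tmax = 30, tmin = 20, latitude = 20,
                           sowing_doy = 10, year = 2006, id = "CST",
                           days = 650) {
  w <- tibble::tibble(
    date = seq(as.Date(sprintf("%d-01-01", year)), by = "day",
               length.out = days),
    tmax = tmax, tmin = tmin)
  site_year(id, latitude, 0, year, sowing_doy, w)
}

# hand-built sim_database from an explicit anthesis matrix
toy_database <- function(anthesis, sets = NULL) {
  n <- nrow(anthesis)
  if (is.null(colnames(anthesis))) {
    colnames(anthesis) <- paste0("S", seq_len(ncol(anthesis)))
  }
  sets <- sets %||% tibble::tibble(p1 = 150 + seq_len(n), p2 = 0.5,
                                   p2o = 12, phint = 40)
  storage.mode(anthesis) <- "integer"
  structure(list(sets = sets,
                 siteyears = tibble::tibble(site_id = colnames(anthesis)),
                 anthesis = anthesis,
                 meta = list(schema_version = 1L, n_sets = n,
                             site_ids = colnames(anthesis))),
            class = "sim_database")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# --- day length oracle: root-finding on the solar elevation model --------

# solar elevation (degrees) at hour angle h (degrees from solar noon)
solar_elevation <- function(latitude, doy, hour_angle) {
  rad <- pi / 180
  decl <- -23.45 * cos(2 * pi * (doy + 10) / 365) * rad
  phi <- latitude * rad
  asin(sin(phi) * sin(decl) +
         cos(phi) * cos(decl) * cos(hour_angle * rad)) / rad
}

oracle_daylength <- function(latitude, doy, depression = 6) {
  f <- function(h) solar_elevation(latitude, doy, h) + depression
  if (f(0) <= 0) return(0)    # sun never above the threshold
  if (f(180) >= 0) return(24) # never below
  r <- uniroot(f, c(0, 180), tol = 1e-10)
  2 * r$root / 15
}

# --- phenology oracle: explicit day-by-day state machine -----------------

oracle_anthesis <- function(sy, p1, p2, p2o, phint, tbase = 8, topt = 34,
                            emergence_gdd = 45, horizon = 250) {
  w <- sy$weather[[1]]
  start <- sy$sowing_date + 1
  day_dates <- seq(start, start + horizon - 1, by = "day")
  i0 <- match(day_dates, w$date)
  stopifnot(!anyNA(i0))
  cum <- 0
  cum_mark <- NA
  stage <- "pre"
  s2 <- 0
  sumdtt <- NA
  thresh <- NA
  for (t in seq_len(horizon)) {
    tmean <- (w$tmax[i0[t]] + w$tmin[i0[t]]) / 2
    g <- max(0, min(tmean, topt) - tbase)
    cum <- cum + g
    dl <- oracle_daylength(sy$latitude,
                           as.integer(format(day_dates[t], "%j")), 6)
    if (stage == "pre") {
      if (cum >= emergence_gdd) { stage <- "juv"; cum_mark <- cum; cum_emerg <- cum }
    } else if (stage == "juv") {
      if (cum - cum_emerg >= p1) { stage <- "photo" }
    } else if (stage == "photo") {
      s2 <- s2 + 1 / (4 + p2 * max(0, dl - p2o))
      if (s2 >= 1 - 1e-12) {
        sumdtt <- cum - cum_emerg
        toln <- sumdtt / (phint * 0.5) + 5
        thresh <- (toln + 0.5) * phint - sumdtt
        cum_ti <- cum
        stage <- "leaf"
      }
    } else {
      if (cum - cum_ti >= thresh) return(t)
    }
  }
  -1L
}

# --- brute-force first-best-found / tie-count oracle ---------------------

oracle_scan <- function(sim, obs, cols) {
  best <- Inf; idx <- NA; tied <- integer(0)
  for (i in seq_len(nrow(sim))) {
    use <- cols[!is.na(obs[cols])]
    if (any(sim[i, use] < 0)) next
    sse <- sum((sim[i, use] - obs[use])^2)
    if (sse < best) { best <- sse; idx <- i; tied <- i }
    else if (sse == best) tied <- c(tied, i)
  }
  list(best_row = idx, sse = best, n_ties = length(tied) - 1, tied = tied)
}

# --- centred L2 discrepancy (Hickernell) --------------------------------

centered_l2_discrepancy <- function(x) {
  n <- nrow(x); d <- ncol(x)
  z <- abs(x - 0.5)
  term1 <- (13 / 12)^d
  term2 <- mean(apply(1 + 0.5 * z - 0.5 * z^2, 1, prod))
  s3 <- 0
  for (j in seq_len(d)) {
    m <- 1 + 0.5 * outer(z[, j], z[, j], "+") -
      0.5 * abs(outer(x[, j], x[, j], "-"))
    s3 <- if (j == 1) m else s3 * m
  }
  sqrt(term1 - 2 * term2 + sum(s3) / n^2)
}
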
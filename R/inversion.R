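# Pivot long observations (line_id, site_year, anthesis_dap) into an
# integer matrix, one row per line, NA where unobserved.
obs_matrix <- function(observations, site_ids) {
  need <- c("line_id", "site_year", "anthesis_dap")
  miss <- setdiff(need, names(observations))
  if (length(miss) > 0) {
    abort(paste("observations missing column(s):", paste(miss, collapse = ", ")))
  }
  unknown <- setdiff(unique(observations$site_year), site_ids)
  if (length(unknown) > 0) {
    abort(paste("observations reference unknown site-years:",
                paste(unknown, collapse = ", ")))
  }
  if (anyDuplicated(observations[c("line_id", "site_year")]) > 0) {
    abort("duplicated (line_id, site_year) observation")
  }
  if (any(observations$anthesis_dap <= 0)) {
    abort("observed anthesis_dap values must be positive")
  }
  wide <- tidyr::pivot_wider(observations, id_cols = "line_id",
                             names_from = "site_year",
                             values_from = "anthesis_dap")
  lines <- wide$line_id
  m <- matrix(NA_integer_, nrow = nrow(wide), ncol = length(site_ids),
              dimnames = list(lines, site_ids))
  for (s in intersect(site_ids, names(wide))) {
    m[, s] <- as.integer(wide[[s]])
  }
  m
}

#' Score one line's fit as integer SSE and RMSE
#'
#' The objective of the database scan: over the scored site-years,
#' `sse = sum((simulated - observed)^2)` in exact integer arithmetic and
#' `rmse = sqrt(sse / n)` in days.
#'
#' @param sim Named integer vector of simulated anthesis days (days after
#'   sowing) by site-year.
#' @param obs Named integer vector of observed anthesis days by site-year.
#' @param subset Site-year ids to score; default the intersection of the
#'   names of `sim` and `obs`.
#' @return A one-row tibble: `sse` (integer), `n_obs`, `rmse` (days).
#' @examples
#' score_line(c(NY6 = 70, NY7 = 72), c(NY6 = 71, NY7 = 73))
#' @export
score_line <- function(sim, obs, subset = NULL) {
  subset <- subset %||% intersect(names(sim), names(obs))
  subset <- subset[!is.na(obs[subset])]
  if (length(subset) == 0) {
    abort("undefined score: no scored site-year has both a simulated and observed value")
  }
  d <- as.integer(sim[subset]) - as.integer(obs[subset])
  sse <- sum(d * d)
  tibble::tibble(sse = as.integer(sse), n_obs = length(subset),
                 rmse = sqrt(sse / length(subset)))
}

#' First-best-found database estimate for each line
#'
#' Scans the database rows in generation order for every line: the running
#' best is replaced only on a strictly smaller integer SSE, so the reported
#' estimate is the first one encountered attaining the minimum. The number
#' of later rows tying that minimum is the line's equifinality extent
#' (`n_ties`). Rows whose simulation failed ("did not flower") on any scored
#' site-year are ineligible for that line.
#'
#' @param db A `sim_database`.
#' @param observations Long tibble `line_id`, `site_year`, `anthesis_dap`
#'   (integer days after sowing). Site-years a line lacks are simply not
#'   scored for it (unbalanced panel).
#' @param subset Character vector of site-year ids to score; default all
#'   site-years in the database.
#' @return A tibble, one row per line: `line_id`, best parameters (`p1`,
#'   `p2`, `p2o`, `phint`, ...), `best_row`, `sse`, `n_obs`, `rmse`,
#'   `n_ties`. Lines for which every row is ineligible get `NA` estimates
#'   and a warning ("inexpressible within horizon").
#' @export
invert_lines <- function(db, observations, subset = NULL) {
  stopifnot(inherits(db, "sim_database"))
  site_ids <- colnames(db$anthesis)
  subset <- subset %||% site_ids
  bad <- setdiff(subset, site_ids)
  if (length(bad) > 0) {
    abort(paste("subset site-years not in database:", paste(bad, collapse = ", ")))
  }
  om <- obs_matrix(observations, site_ids)
  cols <- match(subset, site_ids)
  scan <- cpp_scan_lines(db$anthesis, om, cols)
  if (any(scan$n_obs == 0)) {
    abort("some lines have no observations in the scored subset")
  }
  if (anyNA(scan$best_row)) {
    warn(sprintf("%d line(s) had no eligible database row (did not flower anywhere); estimates are NA",
                 sum(is.na(scan$best_row))))
  }
  est <- db$sets[pmax(scan$best_row, 1L), ]
  est[is.na(scan$best_row), ] <- NA_real_
  dplyr::bind_cols(
    tibble::tibble(line_id = rownames(om)),
    est,
    tibble::tibble(best_row = scan$best_row, sse = scan$sse,
                   n_obs = scan$n_obs,
                   rmse = sqrt(scan$sse / scan$n_obs),
                   n_ties = scan$n_ties))
}

#' @rdname invert_lines
#' @param line_id Single line to estimate.
#' @export
first_best_found <- function(db, observations, subset = NULL,
                             line_id = NULL) {
  if (!is.null(line_id)) {
    observations <- dplyr::filter(observations, .data$line_id %in% !!line_id)
  }
  invert_lines(db, observations, subset = subset)
}

#' Differential evolution settings
#'
#' Classic rand/1/bin differential evolution over a bound-constrained box.
#'
#' @param pop Population size (default 60).
#' @param f Differential weight F in (0, 2]; default 0.7.
#' @param cr Crossover rate in \[0, 1\]; default 0.9.
#' @param max_gen Maximum generations; default 500.
#' @param tol Stop early when the population's objective spread falls below
#'   `tol` for `patience` consecutive generations; default 1e-8.
#' @param patience Consecutive quiet generations required to stop; default 30.
#' @return A list of class `de_control`.
#' @export
de_control <- function(pop = 60, f = 0.7, cr = 0.9, max_gen = 500,
                       tol = 1e-8, patience = 30) {
  stopifnot(pop >= 5, f > 0, f <= 2, cr >= 0, cr <= 1, max_gen >= 1)
  structure(list(pop = as.integer(pop), f = f, cr = cr,
                 max_gen = as.integer(max_gen), tol = tol,
                 patience = as.integer(patience)),
            class = "de_control")
}

# Generic bound-constrained DE minimiser (rand/1/bin). `objective` maps a
# matrix of candidate rows to a numeric vector; non-finite values are
# treated as rejected candidates. The initial population is a Sobol design
# over the bounds, so the final best can never be worse than the best of
# that quasi-random scan.
de_minimise <- function(objective, lower, upper, control = de_control(),
                        seed = 1) {
  d <- length(lower)
  stopifnot(length(upper) == d, all(upper > lower))
  withr::with_seed(seed, {
    np <- control$pop
    pop <- sobol_sequence(np, d) %*% diag(upper - lower, d) +
      matrix(lower, np, d, byrow = TRUE)
    fit <- objective(pop)
    fit[!is.finite(fit)] <- Inf
    quiet <- 0L
    for (gen in seq_len(control$max_gen)) {
      r <- matrix(0L, np, 3)
      for (i in seq_len(np)) r[i, ] <- sample(seq_len(np)[-i], 3)
      mut <- pop[r[, 1], , drop = FALSE] +
        control$f * (pop[r[, 2], , drop = FALSE] - pop[r[, 3], , drop = FALSE])
      mut <- pmin(pmax(mut, matrix(lower, np, d, byrow = TRUE)),
                  matrix(upper, np, d, byrow = TRUE))
      cross <- matrix(runif(np * d) < control$cr, np, d)
      jrand <- cbind(seq_len(np), sample.int(d, np, replace = TRUE))
      cross[jrand] <- TRUE
      trial <- ifelse(cross, mut, pop)
      tfit <- objective(trial)
      tfit[!is.finite(tfit)] <- Inf
      take <- tfit <= fit
      pop[take, ] <- trial[take, ]
      fit[take] <- tfit[take]
      spread <- max(fit[is.finite(fit)]) - min(fit)
      quiet <- if (is.finite(spread) && spread < control$tol) quiet + 1L else 0L
      if (quiet >= control$patience) break
    }
    best <- which.min(fit)
    list(par = pop[best, ], value = fit[best], generations = gen)
  })
}

#' Continuous parameter search by differential evolution
#'
#' Fits one line's observed anthesis dates by minimising the RMSE of the
#' simulated dates over a continuous parameter box — the cross-check on the
#' discrete database scan. The initial population is a Sobol design over the
#' bounds, so the result is never worse than the best of that quasi-random
#' scan of the same size.
#'
#' @param observations Long observations tibble for a single line (or use
#'   `line_id` to select one).
#' @param siteyears Site-year tibble covering the observed site-years.
#' @param bounds A [parameter_box()]; default [extended_parameter_box()].
#' @param control A [phenology_control()].
#' @param de A [de_control()].
#' @param seed Integer seed; the search is seed-reproducible.
#' @param line_id Optional line to select from `observations`.
#' @return A one-row tibble: parameters, `rmse` (days), `sse`, `n_obs`,
#'   `generations`.
#' @export
de_search <- function(observations, siteyears,
                      bounds = extended_parameter_box(),
                      control = phenology_control(), de = de_control(),
                      seed = 1, line_id = NULL) {
  if (!is.null(line_id)) {
    observations <- dplyr::filter(observations, .data$line_id %in% !!line_id)
  }
  if (length(unique(observations$line_id)) != 1) {
    abort("de_search fits one line at a time; filter or pass `line_id`")
  }
  sy_ids <- intersect(siteyears$site_id, unique(observations$site_year))
  if (length(sy_ids) == 0) abort("no observed site-year is covered by `siteyears`")
  sys <- siteyears[match(sy_ids, siteyears$site_id), ]
  obs <- observations$anthesis_dap[match(sy_ids, observations$site_year)]
  envs <- purrr::map(seq_len(nrow(sys)), function(j) {
    site_environment(sys[j, ], control$max_horizon_days, control$depression)
  })

  objective <- function(cand) {
    colnames(cand) <- bounds$name
    cand_tbl <- tibble::as_tibble(cand)
    pm <- params_matrix(cand_tbl, control)
    sse <- numeric(nrow(cand))
    for (j in seq_along(envs)) {
      e <- envs[[j]]
      sim <- cpp_simulate_batch(e$tmax, e$tmin, e$daylength, pm,
                                control$emergence_gdd,
                                control$stage2_mode == "fixed",
                                control$sumdtt_from == "end_juvenile")
      sse <- sse + ifelse(sim < 0, Inf, (sim - obs[j])^2)
    }
    sqrt(sse / length(envs))
  }

  res <- de_minimise(objective, bounds$min, bounds$max, control = de,
                     seed = seed)
  par <- rlang::set_names(as.list(res$par), bounds$name)
  dplyr::bind_cols(
    tibble::tibble(line_id = observations$line_id[1]),
    tibble::as_tibble(par),
    tibble::tibble(rmse = res$value,
                   sse = res$value^2 * length(envs),
                   n_obs = length(envs), generations = res$generations))
}
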
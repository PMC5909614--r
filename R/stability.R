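#' Enumerate k-subsets of site-years
#'
#' All `choose(n, k)` subsets in lexicographic order.
#'
#' @param n Number of site-years (or a character vector of site-year ids).
#' @param k Subset size, `1 <= k <= n`.
#' @return A list of integer vectors (or character vectors when `n` is a
#'   character vector), length `choose(n, k)`.
#' @examples
#' length(enumerate_subsets(11, 7))  # 330
#' @export
enumerate_subsets <- function(n, k) {
  ids <- NULL
  if (is.character(n)) {
    ids <- n
    n <- length(ids)
  }
  if (k > n || k < 1) abort("`k` must satisfy 1 <= k <= n")
  idx <- utils::combn(n, k, simplify = FALSE)
  if (is.null(ids)) idx else purrr::map(idx, ~ ids[.x])
}

#' Build the cross-environment stability dataset
#'
#' Runs a first-best-found search for every (line, site-year subset) pair,
#' discards searches with ties (equifinality would dilute the test), then
#' drops subsets retaining fewer than `min_lines` tie-free lines. Only lines
#' observed in every site-year of the database are used.
#'
#' @param db A `sim_database`.
#' @param observations Long observations tibble.
#' @param k Subset size (default 7).
#' @param min_lines Minimum surviving lines per subset (default 100).
#' @return A tibble of class `stability_dataset`: one row per retained
#'   (line, subset) search with `line_id`, `subset_id`, the estimated
#'   parameters, `rmse` and `n_ties` (all 0). Attributes: `subsets` (id ->
#'   site-years), `n_searches`, `n_dropped_ties`, `n_subsets_dropped`,
#'   `n_lines_complete`.
#' @export
build_stability_dataset <- function(db, observations, k = 7, min_lines = 100) {
  stopifnot(inherits(db, "sim_database"))
  site_ids <- colnames(db$anthesis)
  om <- obs_matrix(observations, site_ids)
  complete <- rowSums(is.na(om)) == 0
  om <- om[complete, , drop = FALSE]
  if (nrow(om) == 0) abort("no line is observed in all site-years")
  subsets <- enumerate_subsets(site_ids, k)
  subset_ids <- vapply(subsets, paste, "", collapse = "+")

  per_subset <- purrr::map(seq_along(subsets), function(e) {
    cols <- match(subsets[[e]], site_ids)
    scan <- cpp_scan_lines(db$anthesis, om, cols)
    keep <- !is.na(scan$best_row) & scan$n_ties == 0L
    tibble::tibble(line_id = rownames(om)[keep],
                   subset_id = subset_ids[e],
                   best_row = scan$best_row[keep],
                   rmse = sqrt(scan$sse[keep] / scan$n_obs[keep]),
                   n_ties = 0L)
  })
  dat <- dplyr::bind_rows(per_subset)
  dropped_ties <- nrow(om) * length(subsets) - nrow(dat)
  surv <- dplyr::count(dat, .data$subset_id)
  keep_subsets <- surv$subset_id[surv$n >= min_lines]
  if (length(keep_subsets) == 0) {
    abort(sprintf("no subset retains >= %d tie-free lines; nothing to analyse",
                  min_lines))
  }
  dat <- dat[dat$subset_id %in% keep_subsets, ]
  dat <- dplyr::bind_cols(dat[c("line_id", "subset_id")],
                          db$sets[dat$best_row, ],
                          dat[c("rmse", "n_ties")])
  structure(dat,
            subsets = rlang::set_names(subsets, subset_ids),
            n_searches = nrow(om) * length(subsets),
            n_dropped_ties = as.integer(dropped_ties),
            n_subsets_dropped = length(subsets) - length(keep_subsets),
            n_lines_complete = nrow(om),
            class = c("stability_dataset", class(dat)))
}

#' Pivot a stability dataset to one row per (GSP, line, subset) estimate
#'
#' @param dataset A [build_stability_dataset()] result (or any tibble with
#'   `line_id`, `subset_id` and parameter columns).
#' @param gsps Parameter columns to keep; default the four anthesis GSPs.
#' @return A long tibble `gsp`, `line_id`, `subset_id`, `estimate`.
#' @export
stability_long <- function(dataset, gsps = c("p1", "p2", "p2o", "phint")) {
  tidyr::pivot_longer(dataset[c("line_id", "subset_id", gsps)],
                      dplyr::all_of(gsps), names_to = "gsp",
                      values_to = "estimate")
}

# Profiled ML deviance machinery for the crossed two-way random-effects
# model y = mu + a_line + b_subset + e, a ~ N(0, s2_l), b ~ N(0, s2_e),
# e ~ N(0, s2_r). Random effects are integrated out with the Woodbury
# identity on the q x q (q = n_lines + n_subsets) inner matrix, and mu and
# s2_r are profiled analytically, leaving a 1- or 2-dimensional bounded
# optimisation over the variance ratios lambda = s2 / s2_r.
vc_profile <- function(y, line, subset) {
  line <- factor(line)
  subset <- factor(subset)
  L <- nlevels(line)
  E <- nlevels(subset)
  N <- length(y)
  li <- as.integer(line)
  ei <- as.integer(subset)
  # U = [Z_line Z_subset]; precompute U'U, U'y, U'1
  nl <- tabulate(li, L)
  ne <- tabulate(ei, E)
  C <- matrix(0, L, E)
  cnt <- dplyr::count(tibble::tibble(l = li, e = ei), .data$l, .data$e)
  C[cbind(cnt$l, cnt$e)] <- cnt$n
  UtU <- rbind(cbind(diag(nl, L), C), cbind(t(C), diag(ne, E)))
  Uty <- c(rowsum(y, li)[, 1], rowsum(y, ei)[, 1])
  Ut1 <- c(nl, ne)
  yy <- sum(y * y)
  sy <- sum(y)

  # minus twice the profiled log-likelihood at variance ratios lambda
  dev <- function(lam_l, lam_e) {
    # optimisers may probe a rounding error below the zero bound
    lam <- pmax(c(rep(lam_l, L), rep(lam_e, E)), 0)
    sl <- sqrt(lam)
    M <- UtU * tcrossprod(sl)
    diag(M) <- diag(M) + 1
    big <- 1e12 # finite penalty: L-BFGS-B cannot digest Inf
    R <- tryCatch(chol(M), error = function(e) NULL)
    if (is.null(R)) return(big)
    logdet <- 2 * sum(log(diag(R)))
    solveM <- function(b) backsolve(R, forwardsolve(t(R), b))
    wy <- sl * Uty
    w1 <- sl * Ut1
    My <- solveM(wy)
    M1 <- solveM(w1)
    # quadratic forms under W = (I + U Lam U')^{-1}
    yWy <- yy - sum(wy * My)
    oW1 <- N - sum(w1 * M1)
    yW1 <- sy - sum(wy * M1)
    mu <- yW1 / oW1
    q <- yWy - 2 * mu * yW1 + mu^2 * oW1
    s2r <- q / N
    if (!is.finite(s2r) || s2r <= 0) return(big)
    list_dev <- N * log(2 * pi * s2r) + logdet + N
    if (!is.finite(list_dev)) return(big)
    attr(list_dev, "mu") <- mu
    attr(list_dev, "s2r") <- s2r
    list_dev
  }
  list(dev = dev, L = L, E = E, N = N)
}

#' Fit the crossed random-effects variance-components model
#'
#' Maximum-likelihood fit of
#' `estimate = mu + line_effect + subset_effect + residual` with both
#' effects random (full model) or the line effect only (reduced model).
#' The likelihood is profiled over `mu` and the residual variance and
#' maximised over the nonnegative variance ratios, so boundary estimates
#' (a variance of exactly zero) are permitted.
#'
#' @param data Tibble with one estimate per (line, subset).
#' @param value,line,subset Column names (strings) of the estimate, line id
#'   and subset id; defaults `"estimate"`, `"line_id"`, `"subset_id"`.
#' @param include_subset_effect `TRUE` (full model) or `FALSE` (reduced).
#' @param polish Run a derivative-free polish pass after the bounded
#'   quasi-Newton optimisation (default `TRUE`); disable for large
#'   simulation studies where the quasi-Newton optimum is sufficient.
#' @return A `vc_fit` object: `mu`, `var_line`, `var_subset` (`NA` in the
#'   reduced model), `var_resid`, `loglik`, `n_params`, `AIC`, `BIC`,
#'   `converged`, `n_obs`, `n_lines`, `n_subsets`.
#' @export
fit_variance_model <- function(data, value = "estimate", line = "line_id",
                               subset = "subset_id",
                               include_subset_effect = TRUE, polish = TRUE) {
  y <- data[[value]]
  stopifnot(is.numeric(y), length(y) >= 4)
  prof <- vc_profile(y, data[[line]], data[[subset]])
  if (prof$L < 2) abort("need at least 2 lines")
  if (include_subset_effect && prof$E < 2) abort("need at least 2 subsets")

  vtot <- var(y)
  start <- c(0.5, if (include_subset_effect) 0.5 else NULL)
  if (include_subset_effect) {
    obj <- function(p) as.numeric(prof$dev(p[1], p[2]))
  } else {
    obj <- function(p) as.numeric(prof$dev(p[1], 0))
  }
  fit <- optim(start, obj, method = "L-BFGS-B", lower = rep(0, length(start)),
               upper = rep(1e6, length(start)),
               control = list(factr = 1e4, maxit = 500))
  converged <- fit$convergence == 0
  if (polish && length(start) == 2) {
    # polish with a derivative-free pass (guarded against the boundary)
    pol <- optim(pmax(fit$par, 1e-10), function(p) {
      if (any(p < 0)) return(Inf)
      obj(p)
    }, method = "Nelder-Mead", control = list(reltol = 1e-12, maxit = 2000))
    if (pol$value < fit$value) {
      fit <- pol
      converged <- pol$convergence == 0
    }
  }
  lam <- fit$par
  d <- prof$dev(lam[1], if (include_subset_effect) lam[2] else 0)
  s2r <- attr(d, "s2r")
  mu <- attr(d, "mu")
  loglik <- -as.numeric(d) / 2
  n_params <- if (include_subset_effect) 4 else 3
  structure(list(
    mu = mu,
    var_line = lam[1] * s2r,
    var_subset = if (include_subset_effect) lam[2] * s2r else NA_real_,
    var_resid = s2r,
    loglik = loglik, n_params = n_params,
    AIC = -2 * loglik + 2 * n_params,
    BIC = -2 * loglik + n_params * log(prof$N),
    converged = converged,
    n_obs = prof$N, n_lines = prof$L, n_subsets = prof$E,
    include_subset_effect = include_subset_effect),
    class = "vc_fit")
}

#' @export
print.vc_fit <- function(x, ...) {
  cat(sprintf("<vc_fit> %s model, ML: mu = %.4g, var(line) = %.4g, var(subset) = %s, var(resid) = %.4g\n",
              if (x$include_subset_effect) "full" else "line-only",
              x$mu, x$var_line,
              if (is.na(x$var_subset)) "-" else sprintf("%.4g", x$var_subset),
              x$var_resid))
  cat(sprintf("  logLik %.4f, AIC %.1f, BIC %.1f (N = %d)\n",
              x$loglik, x$AIC, x$BIC, x$n_obs))
  invisible(x)
}

#' @export
tidy.vc_fit <- function(x, ...) {
  tibble::tibble(
    term = c("mu", "var_line", "var_subset", "var_resid"),
    estimate = c(x$mu, x$var_line, x$var_subset, x$var_resid))
}

#' @export
glance.vc_fit <- function(x, ...) {
  tibble::tibble(logLik = x$loglik, AIC = x$AIC, BIC = x$BIC,
                 n_params = x$n_params, nobs = x$n_obs,
                 converged = x$converged)
}

# Chernoff upper bound on the upper tail of chi-square(df) at x > df,
# on the log10 scale: log P(X >= x) <= [df log(x/df) + df - x] / 2.
chernoff_log10_tail <- function(x, df) {
  ifelse(x <= df, 0, (df * log(x / df) + df - x) / (2 * log(10)))
}

#' Likelihood-ratio stability statistics for one GSP
#'
#' Compares the full and reduced fits: `LRT = 2 (logLik_full -
#' logLik_reduced)`, with the null reference for a variance component tested
#' on its boundary. `"half_df"` (default) refers the statistic to a central
#' chi-square with 0.5 degrees of freedom; `"mixture"` uses the conventional
#' 50:50 mixture of a point mass at zero and chi-square(1), reported as
#' `p = 0.5 P(chisq_1 >= LRT)`. Extreme statistics underflow double
#' precision, so `log10_p` is always reported, switching to a Chernoff tail
#' bound (`log10 P <= [df log(x/df) + df - x] / (2 ln 10)`) when the exact
#' tail underflows; the `p_method` field records which was used.
#'
#' Also computes the Index of Variability, `100 * sd(subset effect) / mu`,
#' and the share of total variance attributed to subsets,
#' `100 * var_subset / (var_line + var_subset + var_resid)`.
#'
#' @param full,reduced `vc_fit` objects with and without the subset effect.
#' @param null Null reference: `"half_df"` or `"mixture"`.
#' @return A one-row tibble: `lrt`, `p_value`, `log10_p`, `p_method`,
#'   `null`, `iov_pct`, `var_pct_subset`, plus the component variances.
#' @export
stability_statistics <- function(full, reduced,
                                 null = c("half_df", "mixture")) {
  null <- match.arg(null)
  stopifnot(inherits(full, "vc_fit"), inherits(reduced, "vc_fit"),
            full$include_subset_effect, !reduced$include_subset_effect)
  if (!full$converged || !reduced$converged) {
    abort("both fits must have converged for the likelihood-ratio test")
  }
  lrt <- 2 * (full$loglik - reduced$loglik)
  if (lrt < -1e-6 * max(1, abs(full$loglik))) {
    abort(sprintf("reduced log-likelihood exceeds full (LRT = %.6g): convergence inconsistency",
                  lrt))
  }
  lrt <- max(lrt, 0)
  if (null == "half_df") {
    p <- pchisq(lrt, df = 0.5, lower.tail = FALSE)
    lp_exact <- pchisq(lrt, df = 0.5, lower.tail = FALSE, log.p = TRUE) / log(10)
    lp_bound <- chernoff_log10_tail(lrt, 0.5)
  } else {
    tail1 <- pchisq(lrt, df = 1, lower.tail = FALSE)
    p <- 0.5 * tail1
    lp_exact <- log10(0.5) +
      pchisq(lrt, df = 1, lower.tail = FALSE, log.p = TRUE) / log(10)
    lp_bound <- log10(0.5) + chernoff_log10_tail(lrt, 1)
  }
  underflow <- !is.finite(lp_exact) || p == 0
  tot <- full$var_line + full$var_subset + full$var_resid
  tibble::tibble(
    lrt = lrt,
    p_value = p,
    log10_p = if (underflow) lp_bound else lp_exact,
    p_method = if (underflow) "chernoff_bound" else "exact_tail",
    null = null,
    iov_pct = 100 * sqrt(full$var_subset) / full$mu,
    var_pct_subset = 100 * full$var_subset / tot,
    mu = full$mu, var_line = full$var_line, var_subset = full$var_subset,
    var_resid = full$var_resid,
    loglik_full = full$loglik, loglik_reduced = reduced$loglik,
    aic_full = full$AIC, aic_reduced = reduced$AIC,
    bic_full = full$BIC, bic_reduced = reduced$BIC)
}

#' Cross-environment stability analysis of all GSPs
#'
#' For each genotype-specific parameter, fits the crossed random-effects
#' model with and without the site-year-subset effect and reports the
#' boundary likelihood-ratio test, information criteria, Index of
#' Variability and subset variance share.
#'
#' @param dataset A [build_stability_dataset()] result (or compatible
#'   tibble).
#' @param gsps Parameter columns to analyse.
#' @param null Null reference passed to [stability_statistics()].
#' @return A tibble of class `gsp_stability`, one row per GSP; attribute
#'   `fits` holds the underlying `vc_fit` pairs.
#' @export
stability_analysis <- function(dataset, gsps = c("p1", "p2", "p2o", "phint"),
                               null = c("half_df", "mixture")) {
  null <- match.arg(null)
  long <- stability_long(dataset, gsps)
  fits <- list()
  rows <- purrr::map_dfr(gsps, function(g) {
    d <- long[long$gsp == g, ]
    full <- fit_variance_model(d, include_subset_effect = TRUE)
    reduced <- fit_variance_model(d, include_subset_effect = FALSE)
    fits[[g]] <<- list(full = full, reduced = reduced)
    dplyr::bind_cols(tibble::tibble(gsp = g),
                     stability_statistics(full, reduced, null = null))
  })
  structure(rows, fits = fits, class = c("gsp_stability", class(rows)))
}

#' @export
tidy.gsp_stability <- function(x, ...) {
  tibble::as_tibble(x)[c("gsp", "mu", "var_line", "var_subset", "var_resid",
                         "iov_pct", "var_pct_subset", "lrt", "p_value",
                         "log10_p", "p_method", "null")]
}

#' @export
glance.gsp_stability <- function(x, ...) {
  tibble::tibble(n_gsps = nrow(x),
                 all_significant = all(x$p_value < 0.05),
                 max_iov_pct = max(x$iov_pct),
                 min_iov_pct = min(x$iov_pct))
}
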
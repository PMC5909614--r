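test_that("subset enumeration is exhaustive, ordered and validated", {
  s <- enumerate_subsets(11, 7)
  expect_length(s, choose(11, 7))
  expect_length(s, 330)
  expect_false(any(duplicated(s)))
  # lexicographic order
  expect_equal(s[[1]], 1:7)
  expect_equal(s[[330]], 5:11)
  expect_length(enumerate_subsets(4, 4), 1)
  expect_length(enumerate_subsets(5, 2), 10)
  expect_error(enumerate_subsets(5, 6), "1 <= k <= n")
  named <- enumerate_subsets(c("a", "b", "c"), 2)
  expect_equal(named[[1]], c("a", "b"))
})

test_that("the stability dataset applies tie and coverage filters faithfully", {
  sets <- generate_sobol_sets(default_parameter_box(), 600)
  sys <- make_siteyears(seed = 50)[1:5, ]
  db <- build_database(sets, sys)
  pop <- make_population(40, seed = 51)
  obs <- make_observations(pop, sys, noise_sd = 1.5, missing_rate = 0.1,
                           seed = 52)
  om <- phenoscan:::obs_matrix(obs, sys$site_id)
  n_complete <- sum(rowSums(is.na(om)) == 0)
  k <- 3
  sdat <- build_stability_dataset(db, obs, k = k, min_lines = 2)
  expect_equal(attr(sdat, "n_searches"), n_complete * choose(5, k))
  expect_equal(attr(sdat, "n_lines_complete"), n_complete)
  expect_true(all(sdat$n_ties == 0))
  expect_false(any(duplicated(sdat[c("line_id", "subset_id")])))
  # brute-force recount of surviving rows from per-search tie flags
  complete_ids <- rownames(om)[rowSums(is.na(om)) == 0]
  obs_c <- obs[obs$line_id %in% complete_ids, ]
  survivors <- 0
  for (sub in enumerate_subsets(sys$site_id, k)) {
    est <- invert_lines(db, obs_c, subset = sub)
    n_ok <- sum(!is.na(est$n_ties) & est$n_ties == 0)
    if (n_ok >= 2) survivors <- survivors + n_ok
  }
  expect_equal(nrow(sdat), survivors)
  # long pivot: one row per (gsp, line, subset)
  expect_equal(nrow(stability_long(sdat)), 4 * nrow(sdat))
})

test_that("ML log-likelihoods match the reference mixed-model fit to 1e-4", {
  skip_if_not_installed("lme4")
  d <- simulate_gsp_panel(80, 25, mu = 260, sd_line = 40, sd_subset = 12,
                          sd_resid = 15, seed = 53)
  full <- fit_variance_model(d)
  red <- fit_variance_model(d, include_subset_effect = FALSE)
  m1 <- lme4::lmer(estimate ~ (1 | line_id) + (1 | subset_id), data = d,
                   REML = FALSE)
  m0 <- lme4::lmer(estimate ~ (1 | line_id), data = d, REML = FALSE)
  expect_equal(full$loglik, as.numeric(stats::logLik(m1)), tolerance = 1e-4)
  expect_equal(red$loglik, as.numeric(stats::logLik(m0)), tolerance = 1e-4)
  vc <- as.data.frame(lme4::VarCorr(m1))
  expect_equal(full$var_line, vc$vcov[vc$grp == "line_id"], tolerance = 1e-3)
  expect_equal(full$var_subset, vc$vcov[vc$grp == "subset_id"], tolerance = 1e-3)
  expect_equal(full$AIC, stats::AIC(m1), tolerance = 1e-3)
  expect_equal(full$BIC, stats::BIC(m1), tolerance = 1e-3)
  # an unbalanced panel (random 20% of cells deleted) must also agree
  withr::with_seed(54, d2 <- d[runif(nrow(d)) > 0.2, ])
  f2 <- fit_variance_model(d2)
  m2 <- lme4::lmer(estimate ~ (1 | line_id) + (1 | subset_id), data = d2,
                   REML = FALSE)
  expect_equal(f2$loglik, as.numeric(stats::logLik(m2)), tolerance = 1e-4)
})

test_that("a null subset effect is estimated at the boundary", {
  d <- simulate_gsp_panel(150, 40, mu = 100, sd_line = 10, sd_subset = 0,
                          sd_resid = 5, seed = 55)
  full <- fit_variance_model(d)
  red <- fit_variance_model(d, include_subset_effect = FALSE)
  tot <- full$var_line + full$var_subset + full$var_resid
  expect_lte(full$var_subset / tot, 0.01)
  st <- stability_statistics(full, red, null = "mixture")
  expect_lt(st$lrt, qchisq(0.95, 1)) # not significant at the boundary null
  expect_gt(st$p_value, 0.05)
})

test_that("variance parameters are recovered across replicates", {
  reps <- 30
  est <- purrr::map_dfr(seq_len(reps), function(r) {
    d <- simulate_gsp_panel(200, 50, mu = 100, sd_line = 10, sd_subset = 20,
                            sd_resid = 5, seed = 5500 + r)
    f <- fit_variance_model(d, polish = FALSE)
    tibble::tibble(mu = f$mu, var_line = f$var_line,
                   var_subset = f$var_subset, var_resid = f$var_resid)
  })
  expect_equal(mean(est$mu), 100, tolerance = 0.10)
  expect_equal(mean(est$var_line), 100, tolerance = 0.10)
  expect_equal(mean(est$var_subset), 400, tolerance = 0.10)
  expect_equal(mean(est$var_resid), 25, tolerance = 0.10)
})

test_that("boundary LRT p-values follow the configured null reference", {
  f0 <- structure(list(mu = 100, var_line = 1, var_subset = 1, var_resid = 2,
                       loglik = -10, n_params = 4, AIC = 28, BIC = 30,
                       converged = TRUE, n_obs = 100, n_lines = 10,
                       n_subsets = 10, include_subset_effect = TRUE),
                  class = "vc_fit")
  r0 <- structure(list(mu = 100, var_line = 1, var_subset = NA, var_resid = 2,
                       loglik = -10, n_params = 3, AIC = 26, BIC = 28,
                       converged = TRUE, n_obs = 100, n_lines = 10,
                       n_subsets = 10, include_subset_effect = FALSE),
                  class = "vc_fit")
  expect_equal(stability_statistics(f0, r0, null = "half_df")$p_value, 1)
  expect_equal(stability_statistics(f0, r0, null = "mixture")$p_value, 0.5)
  # lrt = 2.706 under the mixture: p = 0.5 * P(chisq_1 > 2.706) ~ 0.0499
  r1 <- r0; r1$loglik <- -10 - 2.706 / 2
  expect_equal(stability_statistics(f0, r1, null = "mixture")$p_value, 0.0499,
               tolerance = 2e-3)
  # IoV and variance share formulas
  st <- stability_statistics(f0, r0)
  expect_equal(st$iov_pct, 100 * sqrt(1) / 100)
  expect_equal(st$var_pct_subset, 25)
  # extreme statistics switch to the documented Chernoff bound
  r2 <- r0; r2$loglik <- -10 - 30714 / 2
  st2 <- stability_statistics(f0, r2)
  expect_equal(st2$p_method, "chernoff_bound")
  expect_lt(st2$log10_p, -6000)
  # convergence inconsistency is reported
  r3 <- r0; r3$loglik <- -9
  expect_error(stability_statistics(f0, r3), "convergence")
})

test_that("information criteria favour the full model when a subset effect exists", {
  wins <- vapply(1:20, function(r) {
    d <- simulate_gsp_panel(60, 20, mu = 100, sd_line = 10, sd_subset = 8,
                            sd_resid = 5, seed = 600 + r)
    f <- fit_variance_model(d, polish = FALSE)
    g <- fit_variance_model(d, include_subset_effect = FALSE)
    f$AIC < g$AIC && f$BIC < g$BIC
  }, logical(1))
  expect_gte(sum(wins), 19)
})

test_that("the full analysis flags a planted environment-dependent bias", {
  sets <- generate_sobol_sets(default_parameter_box(), 1024)
  sys <- make_siteyears(seed = 57)[1:6, ]
  db <- build_database(sets, sys)
  pop <- make_population(60, seed = 58)
  bias <- rlang::set_names(c(-4, 3, -2, 5, -3, 4), sys$site_id)
  obs <- make_observations(pop, sys, noise_sd = 1, missing_rate = 0,
                           site_bias = bias, seed = 59)
  sdat <- build_stability_dataset(db, obs, k = 4, min_lines = 5)
  st <- stability_analysis(sdat, null = "mixture")
  expect_s3_class(st, "gsp_stability")
  expect_equal(nrow(st), 4)
  # the environment-subset effect must be detected for at least one GSP
  expect_true(any(st$var_pct_subset > 1 & st$p_value < 0.05))
  expect_true(all(st$lrt >= 0))
  td <- tidy(st)
  expect_named(td, c("gsp", "mu", "var_line", "var_subset", "var_resid",
                     "iov_pct", "var_pct_subset", "lrt", "p_value",
                     "log10_p", "p_method", "null"))
})
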
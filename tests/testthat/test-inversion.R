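test_that("score_line computes exact integer SSE and RMSE in days", {
  s <- score_line(c(A = 70, B = 72), c(A = 70, B = 72))
  expect_equal(s$sse, 0L)
  expect_equal(s$rmse, 0)
  s <- score_line(c(A = 70, B = 72), c(A = 71, B = 73))
  expect_identical(s$sse, 2L)
  expect_equal(s$rmse, 1)
  s <- score_line(c(A = 65), c(A = 68))
  expect_identical(s$sse, 9L)
  expect_equal(s$rmse, 3)
  expect_error(score_line(c(A = 65), c(B = 68)), "undefined score")
})

test_that("first-best-found keeps the earliest minimum and counts later ties", {
  # rows engineered to give SSE (4, 1, 1, 3, 1) against obs = 10
  db <- toy_database(matrix(c(12, 11, 9, 13, 11), ncol = 1,
                            dimnames = list(NULL, "S1")))
  obs <- tibble::tibble(line_id = "L1", site_year = "S1", anthesis_dap = 10L)
  est <- first_best_found(db, obs)
  expect_equal(est$best_row, 2L)
  expect_equal(est$sse, 1)
  expect_equal(est$n_ties, 2L)
  expect_equal(est$p1, db$sets$p1[2])
})

test_that("noise-free observations from an in-database truth score RMSE zero", {
  sets <- generate_sobol_sets(default_parameter_box(), 200)
  sys <- make_siteyears(seed = 8)[c(1, 2, 7), ]
  db <- build_database(sets, sys)
  pop <- sample_population_from_sets(sets, 10, seed = 9)
  obs <- make_observations(pop, sys, noise_sd = 0, missing_rate = 0, seed = 10)
  est <- invert_lines(db, obs)
  expect_true(all(est$rmse == 0))
  # the generating row must be in the tied set: its own SSE is zero
  om <- phenoscan:::obs_matrix(obs, colnames(db$anthesis))
  gen_sse <- rowSums((db$anthesis[pop$set_row, ] - om[pop$line_id, ])^2)
  expect_true(all(gen_sse == 0))
})

test_that("the compiled scan matches the brute-force oracle on random panels", {
  withr::with_seed(77, {
    sim <- matrix(sample(c(60:90, -1L), 200 * 4, replace = TRUE,
                         prob = c(rep(1, 31), 3)), 200, 4,
                  dimnames = list(NULL, paste0("S", 1:4)))
    obs <- matrix(sample(60:90, 50 * 4, replace = TRUE), 50, 4)
    obs[runif(200) < 0.2] <- NA
  })
  keep <- rowSums(!is.na(obs)) > 0
  obs <- obs[keep, , drop = FALSE]
  db <- toy_database(sim)
  colnames(obs) <- paste0("S", 1:4)
  long <- tibble::as_tibble(obs) |>
    dplyr::mutate(line_id = sprintf("L%02d", seq_len(nrow(obs)))) |>
    tidyr::pivot_longer(-"line_id", names_to = "site_year",
                        values_to = "anthesis_dap") |>
    dplyr::filter(!is.na(.data$anthesis_dap))
  est <- invert_lines(db, long)
  for (l in seq_len(nrow(obs))) {
    ora <- oracle_scan(sim, obs[l, ], seq_len(4))
    row <- est[est$line_id == sprintf("L%02d", l), ]
    expect_equal(row$best_row, ora$best_row)
    expect_equal(row$sse, ora$sse)
    expect_equal(row$n_ties, ora$n_ties)
  }
})

test_that("scoring is invariant to the listed order of the subset", {
  sets <- generate_sobol_sets(default_parameter_box(), 150)
  sys <- make_siteyears(seed = 12)[1:4, ]
  db <- build_database(sets, sys)
  pop <- make_population(8, seed = 13)
  obs <- make_observations(pop, sys, noise_sd = 1, missing_rate = 0, seed = 14)
  a <- invert_lines(db, obs, subset = sys$site_id)
  b <- invert_lines(db, obs, subset = rev(sys$site_id))
  expect_equal(a, b)
})

test_that("rows that did not flower on a scored site-year are ineligible", {
  sim <- matrix(c(70, -1,   # row 1 fails on S2
                  70, 75),
                nrow = 2, byrow = TRUE, dimnames = list(NULL, c("S1", "S2")))
  db <- toy_database(sim)
  obs <- tibble::tibble(line_id = "L1", site_year = c("S1", "S2"),
                        anthesis_dap = c(70L, 75L))
  est <- first_best_found(db, obs)
  expect_equal(est$best_row, 2L) # row 1 would have tied on S1 alone
  # all rows ineligible -> NA estimate with a warning
  db2 <- toy_database(matrix(c(-1L, -1L), 2, 1,
                             dimnames = list(NULL, "S1")))
  expect_warning(
    est2 <- first_best_found(db2, tibble::tibble(line_id = "L1",
                                                 site_year = "S1",
                                                 anthesis_dap = 70L)),
    "no eligible")
  expect_true(is.na(est2$best_row))
})

test_that("zero-RMSE tie sets shrink as site-years are added", {
  sets <- generate_sobol_sets(default_parameter_box(), 2000)
  sys <- make_siteyears(seed = 15)
  db <- build_database(sets, sys)
  pop <- sample_population_from_sets(sets, 15, seed = 16)
  obs <- make_observations(pop, sys, noise_sd = 0, missing_rate = 0, seed = 17)
  om <- phenoscan:::obs_matrix(obs, colnames(db$anthesis))
  for (l in seq_len(nrow(om))) {
    prev <- NULL
    for (k in c(2, 5, 8, 11)) {
      cols <- seq_len(k)
      zero <- which(rowSums((db$anthesis[, cols, drop = FALSE] -
                               matrix(om[l, cols], nrow(db$anthesis), k,
                                      byrow = TRUE))^2) == 0)
      if (!is.null(prev)) expect_true(all(zero %in% prev))
      prev <- zero
    }
  }
})

test_that("differential evolution recovers a sphere optimum to high precision", {
  box <- default_parameter_box() # axes: p1, p2o, p2, phint
  centre <- c(300, 12, 1, 50)
  res <- phenoscan:::de_minimise(
    function(x) rowSums((x - matrix(centre, nrow(x), 4, byrow = TRUE))^2 /
                          matrix((box$max - box$min)^2, nrow(x), 4, byrow = TRUE)),
    box$min, box$max,
    control = de_control(pop = 40, max_gen = 300, tol = 1e-14, patience = 50),
    seed = 21)
  expect_lt(sum(abs(res$par - centre) / (box$max - box$min)), 1e-5)
})

test_that("DE drives a zero-noise synthetic line to a perfect fit", {
  sys <- make_siteyears(seed = 22)[c(1, 2), ]
  truth <- cultivar_params(260, 0.6, 12.5, 45)
  truth_obs <- tibble::tibble(
    line_id = "L1", site_year = sys$site_id,
    anthesis_dap = vapply(seq_len(2), function(j) {
      simulate_anthesis(sys[j, ], truth)$anthesis_dap
    }, integer(1)))
  fit <- de_search(truth_obs, sys, bounds = extended_parameter_box(),
                   de = de_control(pop = 40, max_gen = 120), seed = 23)
  expect_equal(fit$rmse, 0)
})

test_that("DE never does worse than the database scan on expressible lines", {
  sets <- generate_sobol_sets(default_parameter_box(), 1500)
  sys <- make_siteyears(seed = 24)[c(1, 2), ]
  db <- build_database(sets, sys)
  pop <- sample_population_from_sets(sets, 3, seed = 25)
  obs <- make_observations(pop, sys, noise_sd = 1, missing_rate = 0, seed = 26)
  est <- invert_lines(db, obs)
  for (l in est$line_id) {
    fit <- de_search(obs, sys, bounds = extended_parameter_box(),
                     de = de_control(pop = 40, max_gen = 80),
                     seed = 27, line_id = l)
    expect_lte(fit$rmse, est$rmse[est$line_id == l])
  }
})
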
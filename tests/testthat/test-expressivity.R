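test_that("achievable tuples deduplicate with first-witness bookkeeping", {
  sim <- matrix(c(70, 72,
                  70, 72,
                  75, 78), ncol = 2, byrow = TRUE,
                dimnames = list(NULL, c("S1", "S2")))
  ach <- achievable_tuples(toy_database(sim))
  expect_equal(nrow(ach$tuples), 2)
  expect_equal(ach$witness[1], 1) # earlier duplicate wins
  expect_equal(unname(ach$tuples[1, ]), c(70, 72))
  # one-dimensional subset: distinct scalar dates
  ach1 <- achievable_tuples(toy_database(sim), "S1")
  expect_equal(sort(ach1$tuples[, 1]), c(70, 75))
})

test_that("achievable-set size equals a brute-force pass over rows", {
  withr::with_seed(31, {
    sim <- matrix(sample(c(65:80, -1L), 300 * 2, replace = TRUE), 300, 2,
                  dimnames = list(NULL, c("S1", "S2")))
  })
  ach <- achievable_tuples(toy_database(sim))
  ok <- sim[, 1] > 0 & sim[, 2] > 0
  brute <- unique(paste(sim[ok, 1], sim[ok, 2]))
  expect_equal(nrow(ach$tuples), length(brute))
  expect_error(achievable_tuples(toy_database(sim), character(0)), "at least one")
})

test_that("classification is exact-match for expressible, nearest-RMSE otherwise", {
  sim <- matrix(c(70, 70,
                  80, 80), ncol = 2, byrow = TRUE,
                dimnames = list(NULL, c("S1", "S2")))
  db <- toy_database(sim)
  ach <- achievable_tuples(db)
  obs <- tibble::tibble(line_id = c("A", "B"),
                        s1 = c(70L, 70L), s2 = c(70L, 72L)) |>
    tidyr::pivot_longer(-"line_id", names_to = "site_year",
                        values_to = "anthesis_dap") |>
    dplyr::mutate(site_year = toupper(.data$site_year))
  rep <- classify_lines(ach, obs, db = db)
  a <- rep[rep$line_id == "A", ]
  expect_true(a$expressible)
  expect_equal(a$distance_days, 0)
  expect_equal(a$p1, db$sets$p1[1])
  b <- rep[rep$line_id == "B", ]
  expect_false(b$expressible)
  expect_equal(c(b$nearest_S1, b$nearest_S2), c(70, 70))
  expect_equal(b$distance_days, sqrt(4 / 2)) # RMSE of (0, 2) over two sites
})

test_that("inexpressible lines inherit exactly the first-best-found parameters", {
  sets <- generate_sobol_sets(default_parameter_box(), 800)
  sys <- make_siteyears(seed = 32)[c(1, 2), ]
  db <- build_database(sets, sys)
  pop <- make_population(40, seed = 33)
  obs <- make_observations(pop, sys, noise_sd = 3, missing_rate = 0, seed = 34)
  ach <- achievable_tuples(db)
  rep <- classify_lines(ach, obs, db = db)
  est <- invert_lines(db, obs)
  merged <- dplyr::inner_join(rep, est, by = "line_id",
                              suffix = c("_cls", "_fbf"))
  expect_gt(nrow(merged), 0)
  expect_equal(merged$rmse, merged$distance_days)
  inx <- merged[!merged$expressible, ]
  expect_gt(nrow(inx), 0) # noise pushes some lines off the achievable set
  expect_equal(inx$p1_cls, inx$p1_fbf)
  expect_equal(inx$p2_cls, inx$p2_fbf)
  expect_equal(inx$p2o_cls, inx$p2o_fbf)
  expect_equal(inx$phint_cls, inx$phint_fbf)
})

test_that("growing the database can only grow the achievable set", {
  sets <- generate_sobol_sets(default_parameter_box(), 1200)
  sys <- make_siteyears(seed = 35)[c(1, 2), ]
  db_small <- build_database(sets[1:300, ], sys)
  db_big <- build_database(sets, sys)
  ach_s <- achievable_tuples(db_small)
  ach_b <- achievable_tuples(db_big)
  key_s <- paste(ach_s$tuples[, 1], ach_s$tuples[, 2])
  key_b <- paste(ach_b$tuples[, 1], ach_b$tuples[, 2])
  expect_true(all(key_s %in% key_b))
  # hence inexpressible counts are nonincreasing in database size
  pop <- make_population(30, seed = 36)
  obs <- make_observations(pop, sys, noise_sd = 3, missing_rate = 0, seed = 37)
  n_s <- expressivity_summary(classify_lines(ach_s, obs))$n_inexpressible
  n_b <- expressivity_summary(classify_lines(ach_b, obs))$n_inexpressible
  expect_lte(n_b, n_s)
})

test_that("summaries count expressibility and recount under noise", {
  sets <- generate_sobol_sets(default_parameter_box(), 500)
  sys <- make_siteyears(seed = 38)[c(1, 2), ]
  db <- build_database(sets, sys)
  ach <- achievable_tuples(db)
  pop <- sample_population_from_sets(sets, 25, seed = 39)
  # noise-free in-database truths: everything expressible
  obs0 <- make_observations(pop, sys, noise_sd = 0, missing_rate = 0, seed = 40)
  s0 <- expressivity_summary(classify_lines(ach, obs0), ach, db)
  expect_equal(s0$n_inexpressible, 0)
  expect_equal(s0$n_expressible, 25)
  # shifting far beyond the achievable set strands every line
  obs_far <- dplyr::mutate(obs0, anthesis_dap = .data$anthesis_dap +
                             max(ach$tuples) + 30L)
  s_far <- expressivity_summary(classify_lines(ach, obs_far), ach, db)
  expect_equal(s_far$n_inexpressible, 25)
  # +-3 day noise: counts equal a brute-force membership recount
  obs3 <- make_observations(pop, sys, noise_sd = 3, missing_rate = 0, seed = 41)
  rep3 <- classify_lines(ach, obs3)
  om <- phenoscan:::obs_matrix(obs3, sys$site_id)
  key <- paste(ach$tuples[, 1], ach$tuples[, 2])
  brute <- sum(!(paste(om[, 1], om[, 2]) %in% key))
  expect_equal(expressivity_summary(rep3, ach, db)$n_inexpressible, brute)
  # the 2-D tableau marks achievable cells with witness P1, stranded cells with counts
  tab <- expressivity_summary(rep3, ach, db)$tableau
  expect_true(all(!is.na(tab$witness_p1[tab$achievable])))
  expect_equal(sum(tab$n_inexpressible, na.rm = TRUE), brute)
})

test_that("lines projecting to the same frontier point share identical estimates", {
  sim <- matrix(c(70, 70,
                  75, 75), ncol = 2, byrow = TRUE,
                dimnames = list(NULL, c("S1", "S2")))
  db <- toy_database(sim)
  ach <- achievable_tuples(db)
  obs <- tibble::tibble(line_id = rep(c("A", "B", "C"), each = 2),
                        site_year = rep(c("S1", "S2"), 3),
                        anthesis_dap = c(69L, 71L, 68L, 72L, 70L, 69L))
  rep <- classify_lines(ach, obs, db = db)
  expect_true(all(!rep$expressible))
  expect_equal(unique(rep$witness_row), 1L) # all banded onto the same witness
  expect_equal(length(unique(rep$p1)), 1)
})

test_that("frontier cells are the lattice boundary of the achievable set", {
  # a full 3x3 block: the centre cell is interior, the ring is the frontier
  grid <- as.matrix(expand.grid(70:72, 80:82))
  colnames(grid) <- c("S1", "S2")
  ach <- achievable_tuples(toy_database(grid))
  fr <- frontier_cells(ach)
  expect_equal(nrow(fr), 8)
  expect_false(any(fr$date_1 == 71 & fr$date_2 == 81))
})
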
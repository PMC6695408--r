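test_that("a zero-year horizon returns an empty series and leaves the population alone", {
  scn <- frozen_scenario()
  pop <- build_initial_population(scn$init_dist, 200, seed = 3)
  res <- simulate_horizon(pop, scn, 0, seed = 1)
  expect_equal(nrow(res$outcomes), 0)
  expect_identical(res$population, pop)
})

test_that("frozen dynamics give zero incidence and constant prevalence", {
  scn <- frozen_scenario()
  pop <- build_initial_population(scn$init_dist, 3000, seed = 3)
  res <- simulate_horizon(pop, scn, 10, seed = 1)
  expect_true(all(res$outcomes$new_cases == 0))
  expect_true(all(res$outcomes$deaths == 0))
  expect_true(all(res$outcomes$incidence_rate == 0))
  expect_equal(length(unique(res$outcomes$prevalence_rate)), 1)
  expect_equal(sort(res$population$id), sort(pop$id))
  # ages still advance deterministically
  expect_equal(sum(res$population$age), sum(pop$age) + 10 * nrow(pop))
})

test_that("identical seeds give bit-identical runs", {
  scn <- make_default_scenario(seed = 1, n_agents = 2000)
  pop <- build_initial_population(scn$init_dist, 2000, seed = 5)
  r1 <- simulate_horizon(pop, scn, 8, seed = 17)
  r2 <- simulate_horizon(pop, scn, 8, seed = 17)
  expect_identical(r1$outcomes, r2$outcomes)
  expect_identical(r1$population, r2$population)
  r3 <- simulate_horizon(pop, scn, 8, seed = 18)
  expect_false(identical(r1$outcomes, r3$outcomes))
})

test_that("population accounting is conserved every year", {
  scn <- make_default_scenario(seed = 1, n_agents = 5000)
  pop <- build_initial_population(scn$init_dist, 5000, seed = 2)
  res <- simulate_horizon(pop, scn, 12, seed = 9)
  o <- res$outcomes
  expect_equal(o$n_alive, o$n_alive_start - o$deaths)
  expect_equal(o$n_alive_start[-1], o$n_alive[-nrow(o)] + o$entrants[-nrow(o)])
  # all-time agents: every baseline or entrant row is retained
  expect_equal(nrow(res$population), 5000 + sum(o$entrants))
  expect_true(all(o$new_cases <= o$at_risk))
  expect_true(all(o$new_cases >= 0 & o$deaths >= 0))
})

test_that("with zero mortality and no entrants the population size is constant", {
  scn <- scenario(default_init_dist(),
                  entry_schedule(tibble::tibble(year = 0:9, count = 0),
                                 zero_band_dist()),
                  no_diabetes_tpms(), flat_life_table(0), negligible_dm(),
                  null_drift())
  pop <- build_initial_population(scn$init_dist, 1500, seed = 4)
  res <- simulate_horizon(pop, scn, 10, seed = 6)
  expect_true(all(res$outcomes$n_alive == 1500))
})

test_that("two-step transition frequencies match the matrix-power oracle", {
  # frozen covariates: immortal cohort, no drift, homogeneous matrix
  P <- matrix(c(0.7, 0.3, 0, 0.4, 0.6, 0, 0, 0, 1), 3, byrow = TRUE)
  scn <- scenario(default_init_dist(),
                  entry_schedule(tibble::tibble(year = 0:1, count = 0),
                                 zero_band_dist()),
                  uniform_tpm_set(P), flat_life_table(0), negligible_dm(),
                  null_drift())
  n <- 40000
  pop <- new_population(age = rep(40, n), gender = "female", bmi = 24,
                        glycemic = "no_diabetes")
  res <- simulate_horizon(pop, scn, 2, seed = 21)
  P2 <- P %*% P # independent oracle
  frac_no <- mean(res$population$glycemic == "no_diabetes")
  sigma <- sqrt(P2[1, 1] * (1 - P2[1, 1]) / n)
  expect_lt(abs(frac_no - P2[1, 1]), 3 * sigma)
})

test_that("tidy, glance and autoplot expose the run", {
  scn <- make_default_scenario(seed = 1, n_agents = 1000)
  pop <- build_initial_population(scn$init_dist, 1000, seed = 2)
  res <- simulate_horizon(pop, scn, 5, seed = 3)
  expect_identical(tidy(res), res$outcomes)
  g <- glance(res)
  expect_equal(nrow(g), 1)
  expect_equal(g$total_new_cases, sum(res$outcomes$new_cases))
  expect_s3_class(ggplot2::autoplot(res), "ggplot")
})
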
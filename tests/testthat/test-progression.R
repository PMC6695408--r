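test_that("annual death probability follows the life table for non-diabetics", {
  pop <- new_population(age = c(40, 40), gender = "male", bmi = 24,
                        glycemic = "no_diabetes")
  expect_equal(annual_death_probability(pop, flat_life_table(0),
                                        negligible_dm()), c(0, 0))
  lt <- flat_life_table(0.25)
  expect_equal(annual_death_probability(pop, lt, negligible_dm()),
               c(0.25, 0.25))
})

test_that("diabetic death probability matches the hazard closed form", {
  # beta = 0, c = 0, h0 = 0.02 -> p = 1 - exp(-0.02)
  dm <- diabetic_mortality(h0 = 0.02)
  pop <- new_population(age = 50, gender = "female", bmi = 28,
                        glycemic = "diabetes")
  expect_equal(annual_death_probability(pop, flat_life_table(0), dm),
               1 - exp(-0.02))
  # large positive calibration constant drives the probability to 1
  dm_hi <- diabetic_mortality(h0 = 0.02, constant = 30)
  expect_equal(annual_death_probability(pop, flat_life_table(0), dm_hi), 1,
               tolerance = 1e-12)
  # covariates move the probability monotonically
  dm_b <- diabetic_mortality(h0 = 0.02, beta_age = 0.08, beta_male = 0.3,
                             beta_bmi = 0.03)
  older <- new_population(age = 70, gender = "female", bmi = 28,
                          glycemic = "diabetes")
  expect_gt(annual_death_probability(older, flat_life_table(0), dm_b),
            annual_death_probability(pop, flat_life_table(0), dm_b))
})

test_that("mortality draws match their probabilities (binomial oracle)", {
  pop <- new_population(age = rep(40, 10000), gender = "female", bmi = 24,
                        glycemic = "no_diabetes")
  res0 <- apply_mortality(pop, flat_life_table(0), negligible_dm(), 0, seed = 1)
  expect_equal(res0$deaths, 0)
  res1 <- apply_mortality(pop, flat_life_table(1), negligible_dm(), 0, seed = 1)
  expect_equal(res1$deaths, 10000)
  expect_true(all(res1$population$death_year == 0))
  res <- apply_mortality(pop, flat_life_table(0.1), negligible_dm(), 3, seed = 2)
  sigma <- sqrt(10000 * 0.1 * 0.9)
  expect_lt(abs(res$deaths - 1000), 3 * sigma)
  expect_equal(sum(!res$population$alive), res$deaths)
})

test_that("age increments deterministically and BMI drift has the stated mean", {
  pop <- new_population(age = 37, gender = "male", bmi = 30,
                        glycemic = "no_diabetes")
  grid <- tidyr::expand_grid(age_group = 0:16, gender = c("male", "female"))
  # p_change = 1 with zero spread: BMI moves by exactly the mean change
  d1 <- bmi_drift(dplyr::mutate(grid, mean_change = 0.2, p_change = 1), sd = 0)
  out <- update_age_bmi(pop, d1, seed = 1)
  expect_equal(out$age, 38L)
  expect_equal(out$bmi, 30.2)
  # p_change = 0.5, conditional mean 0.4 -> unconditional mean 0.2
  d2 <- bmi_drift(dplyr::mutate(grid, mean_change = 0.2, p_change = 0.5),
                  sd = 0.3)
  n <- 1e5
  big <- new_population(age = rep(40, n), gender = "female", bmi = 30,
                        glycemic = "no_diabetes")
  out2 <- update_age_bmi(big, d2, seed = 8)
  change <- out2$bmi - 30
  # Monte Carlo mean vs closed form: sd of the mean = sd(change)/sqrt(n)
  sd_change <- sqrt(0.5 * (0.3^2 + 0.4^2) - 0.2^2)
  expect_lt(abs(mean(change) - 0.2), 3 * sd_change / sqrt(n))
  expect_true(all(out2$bmi >= 15))
})

test_that("transition set validation enforces stochastic rows and absorbing diabetes", {
  P_bad <- matrix(c(0.7, 0.2, 0.05, 0.1, 0.8, 0.1, 0, 0, 1), 3, byrow = TRUE)
  expect_error(uniform_tpm_set(P_bad), "sum to 1")
  P_rev <- matrix(c(0.9, 0.1, 0, 0.1, 0.8, 0.1, 0.2, 0, 0.8), 3, byrow = TRUE)
  expect_error(uniform_tpm_set(P_rev), "absorbing")
  incomplete <- tibble::as_tibble(identity_tpms())[-1, ]
  expect_error(tpm_set(incomplete), "one row per stratum")
})

test_that("glycemic transitions follow their stratum row", {
  pop <- new_population(age = rep(40, 5), gender = "male", bmi = 27,
                        glycemic = c("no_diabetes", "no_diabetes",
                                     "prediabetes", "diabetes", "diabetes"))
  frozen <- glycemic_transition(pop, identity_tpms(), 0, seed = 1)
  expect_identical(frozen$glycemic, pop$glycemic)
  # absorbing state never leaves even under a reverting-looking draw
  expect_true(all(frozen$glycemic[4:5] == "diabetes"))

  # multinomial oracle on a fixed row
  P <- matrix(c(0.2, 0.5, 0.3, 0.1, 0.6, 0.3, 0, 0, 1), 3, byrow = TRUE)
  tp <- uniform_tpm_set(P)
  n <- 1e5
  big <- new_population(age = rep(50, n), gender = "female", bmi = 24,
                        glycemic = "no_diabetes")
  out <- glycemic_transition(big, tp, 2, seed = 31)
  freq <- table(factor(out$glycemic,
                       levels = c("no_diabetes", "prediabetes", "diabetes"))) / n
  for (j in 1:3) {
    sigma <- sqrt(P[1, j] * (1 - P[1, j]) / n)
    expect_lt(abs(freq[[j]] - P[1, j]), 3 * sigma)
  }
  onset <- dplyr::filter(out, glycemic == "diabetes")
  expect_true(all(onset$diabetes_onset_year == 2))
  expect_true(all(onset$ever_diabetic))
})
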
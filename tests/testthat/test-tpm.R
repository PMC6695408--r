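# A minimal hand-built panel: visits 12 months apart, ages/bmi fixed so all
# subjects share one stratum when estimated without stratification.
toy_panel <- function(states_by_subject) {
  purrr::imap_dfr(states_by_subject, function(states, i) {
    tibble::tibble(subject_id = as.integer(i),
                   visit_month = 12 * (seq_along(states) - 1),
                   age = 45, gender = "male", bmi = 27,
                   glycemic_state = states)
  })
}

test_that("row estimates are counting MLEs", {
  # 10 pairs from no_diabetes: 6 stay, 4 move to prediabetes
  subjects <- c(rep(list(c("no_diabetes", "no_diabetes")), 6),
                rep(list(c("no_diabetes", "prediabetes")), 4),
                list(c("prediabetes", "prediabetes")))
  tp <- estimate_tpms(toy_panel(subjects), strata = character(0))
  row <- dplyr::filter(tibble::as_tibble(tp), age_group == 5,
                       gender == "male", bmi_cat == "overweight",
                       from == "no_diabetes")
  expect_equal(as.numeric(row[c("to_no_diabetes", "to_prediabetes",
                                "to_diabetes")]), c(0.6, 0.4, 0))
})

test_that("observed diabetes reversion is overridden by the absorbing rule", {
  subjects <- list(c("diabetes", "prediabetes"),
                   c("prediabetes", "diabetes"),
                   c("no_diabetes", "no_diabetes"))
  tp <- estimate_tpms(toy_panel(subjects), strata = character(0))
  dia_rows <- dplyr::filter(tibble::as_tibble(tp), from == "diabetes")
  expect_true(all(dia_rows$to_diabetes == 1))
  expect_true(all(dia_rows$to_no_diabetes == 0))
})

test_that("visit spacing outside the slack is dropped", {
  panel <- tibble::tibble(subject_id = 1L, visit_month = c(0, 4, 16, 28),
                          age = 45, gender = "male", bmi = 27,
                          glycemic_state = c("no_diabetes", "prediabetes",
                                             "prediabetes", "prediabetes"))
  # gaps: 4 (dropped), 12 (kept), 12 (kept)
  pairs <- prediasim:::panel_pairs(panel, 12, 0.25)
  expect_equal(nrow(pairs), 2)
  expect_error(estimate_tpms(panel[1:2, ], strata = character(0)),
               "no transition pairs")
})

test_that("estimation recovers a known homogeneous truth as subjects grow", {
  P <- matrix(c(0.85, 0.13, 0.02,
                0.15, 0.77, 0.08,
                0,    0,    1), 3, byrow = TRUE)
  truth <- uniform_tpm_set(P)
  err_at <- function(n) {
    panel <- generate_panel(truth, n, n_visits = 4, seed = 1234)
    est <- estimate_tpms(panel, strata = character(0))
    Pe <- as.matrix(tibble::as_tibble(est)[1:3, c("to_no_diabetes",
                                                  "to_prediabetes",
                                                  "to_diabetes")])
    max(abs(Pe - P))
  }
  e500 <- err_at(500)
  e5000 <- err_at(5000)
  expect_lt(e5000, 0.02)
  expect_lt(e5000, e500 + 0.005) # error shrinks with sample size
})

test_that("six-month panels annualize to the annual truth (matrix-square oracle)", {
  P_annual <- matrix(c(0.85, 0.13, 0.02,
                       0.15, 0.77, 0.08,
                       0,    0,    1), 3, byrow = TRUE)
  # ground-truth 6-month matrix: the square root of the annual one
  P6 <- prediasim:::annualize_tpm(P_annual, 0.5)
  expect_equal(P6 %*% P6, P_annual, tolerance = 1e-8)
  panel <- generate_panel(uniform_tpm_set(P6), 20000, n_visits = 4,
                          interval = 6, seed = 77)
  est <- estimate_tpms(panel, interval = 6, strata = character(0))
  Pe <- as.matrix(tibble::as_tibble(est)[1:3, c("to_no_diabetes",
                                                "to_prediabetes",
                                                "to_diabetes")])
  expect_lt(max(abs(Pe - P_annual)), 0.03)
})

test_that("sparse strata are pooled hierarchically and the path is logged", {
  # data only in one stratum; every other stratum must borrow it
  subjects <- rep(list(c("no_diabetes", "prediabetes", "prediabetes",
                         "diabetes")), 30)
  tp <- estimate_tpms(toy_panel(subjects))
  expect_s3_class(tp, "tpm_set")
  pool <- attr(tp, "pooling")
  expect_true(any(pool$level != "stratum"))
  rows <- tibble::as_tibble(tp)
  expect_true(all(abs(rowSums(rows[c("to_no_diabetes", "to_prediabetes",
                                     "to_diabetes")]) - 1) < 1e-9))
})

test_that("additive smoothing behaves at its limits", {
  subjects <- c(rep(list(c("no_diabetes", "no_diabetes")), 3),
                list(c("prediabetes", "prediabetes")))
  tp <- estimate_tpms(toy_panel(subjects), strata = character(0))
  expect_identical(smooth_tpms(tp, 0), tp)
  heavy <- tibble::as_tibble(smooth_tpms(tp, 1e9))
  nd <- dplyr::filter(heavy, from == "no_diabetes")
  expect_equal(nd$to_no_diabetes, rep(1 / 3, nrow(nd)), tolerance = 1e-6)
  # diabetes row stays absorbing under any smoothing
  expect_true(all(dplyr::filter(heavy, from == "diabetes")$to_diabetes == 1))
})

test_that("mortality calibration recovers a known constant on a deterministic cohort", {
  dm <- diabetic_mortality(h0 = 0.015, beta_age = 0.08, beta_male = 0.3,
                           beta_bmi = 0.02)
  set.seed(10)
  cohort <- new_population(age = sample(30:80, 400, replace = TRUE),
                           gender = sample(c("male", "female"), 400, TRUE),
                           bmi = runif(400, 20, 40), glycemic = "diabetes")
  c_true <- 0.8
  # independent closed-form oracle for the expected annual mortality rate
  lp <- 0.08 * (cohort$age - 50) + 0.3 * (cohort$gender == "male") +
    0.02 * (cohort$bmi - 28)
  target <- 100 * mean(1 - exp(-0.015 * exp(lp + c_true)))
  cal <- calibrate_mortality_constant(cohort, dm, target, tolerance = 1e-9)
  expect_lt(abs(cal$constant - c_true), 1e-6)
  expect_true(cal$converged)
  expect_equal(cal$model$constant, cal$constant)

  # monotonicity: a larger target needs a larger constant
  cal2 <- calibrate_mortality_constant(cohort, dm, min(2 * target, 99),
                                       tolerance = 1e-9)
  expect_gt(cal2$constant, cal$constant)

  # fixed point: target equal to the rate at c = 0 returns c ~ 0
  target0 <- 100 * mean(1 - exp(-0.015 * exp(lp)))
  cal0 <- calibrate_mortality_constant(cohort, dm, target0, tolerance = 1e-9)
  expect_lt(abs(cal0$constant), 1e-6)

  expect_error(calibrate_mortality_constant(cohort, dm, 1e-7),
               "unreachable")
})

test_that("stochastic calibration is reproducible under a fixed seed", {
  cohort <- new_population(age = rep(60, 5000), gender = "female", bmi = 30,
                           glycemic = "diabetes")
  dm <- diabetic_mortality(h0 = 0.02)
  c1 <- calibrate_mortality_constant(cohort, dm, 3, method = "simulate",
                                     seed = 4, tolerance = 0.02,
                                     relative = FALSE)
  c2 <- calibrate_mortality_constant(cohort, dm, 3, method = "simulate",
                                     seed = 4, tolerance = 0.02,
                                     relative = FALSE)
  expect_identical(c1$constant, c2$constant)
})
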
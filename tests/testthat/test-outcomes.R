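test_that("incidence follows its printed definition", {
  expect_equal(incidence_rate(0, 1000, 0), 0)
  expect_equal(incidence_rate(5, 1000, 200), 0.625)
  expect_error(incidence_rate(1, 100, 100), "positive")
})

test_that("improvement follows its printed definition", {
  r <- improvement(1.0, 0.97)
  expect_equal(r$difference, 0.03)
  expect_equal(r$improvement_pct, 3.0)
  expect_equal(improvement(2, 2)$improvement_pct, 0)
  expect_error(improvement(0, 0.5), "undefined")
  # consistency with a published difference/improvement pair: difference
  # 0.03 at improvement 2.99% implies a baseline rate near 1.003 per 100
  rate_ni <- 0.03 / 0.0299
  r2 <- improvement(rate_ni, rate_ni - 0.03)
  expect_equal(r2$improvement_pct, 2.99, tolerance = 1e-9)
  expect_equal(rate_ni, 1.003, tolerance = 1e-3)
})

test_that("a null intervention leaves paired arms bit-identical with zero dfs gain", {
  scn <- make_default_scenario(seed = 1, n_agents = 3000)
  null_spec <- intervention_spec("null", 0.05, 0, 100)
  pr <- paired_run(scn, null_spec, horizon = 8, n_agents = 3000, seed = 42)
  expect_identical(pr$control$outcomes, pr$intervention$outcomes)
  expect_identical(pr$control$population, pr$intervention$population)
  g <- dfs_gain(pr$control$population, pr$intervention$population, 8)
  expect_equal(g$mean_gain, 0)
  expect_true(all(g$gains$gain == 0))
})

test_that("paired runs are deterministic in the master seed", {
  scn <- make_default_scenario(seed = 1, n_agents = 2000)
  spec <- intervention_preset("help_pd")
  p1 <- paired_run(scn, spec, horizon = 6, n_agents = 2000, seed = 7)
  p2 <- paired_run(scn, spec, horizon = 6, n_agents = 2000, seed = 7)
  expect_identical(p1$control$population, p2$control$population)
  expect_identical(p1$intervention$population, p2$intervention$population)
  expect_identical(glance(p1), glance(p2))
})

test_that("dfs gain applies the onset, censoring and exclusion rules", {
  base <- new_population(age = rep(40, 6), gender = "male", bmi = 28,
                         glycemic = "prediabetes")
  H <- 10
  ctl <- base; trt <- base
  set_onset <- function(pop, i, yr) {
    pop$diabetes_onset_year[i] <- yr
    pop$ever_diabetic[i] <- TRUE
    pop$glycemic[i] <- "diabetes"
    pop
  }
  # id 1: both develop, control year 5, intervention year 8 -> gain +3
  ctl <- set_onset(ctl, 1, 5L); trt <- set_onset(trt, 1, 8L)
  # id 2: neither develops -> 0
  # id 3: control-only at year 6 -> H - 6 = +4
  ctl <- set_onset(ctl, 3, 6L)
  # id 4: intervention-only at year 7 -> -(H - 7) = -3
  trt <- set_onset(trt, 4, 7L)
  # id 5: dies before onset in control -> excluded
  ctl$alive[5] <- FALSE; ctl$death_year[5] <- 2L
  # id 6: develops in both at the same year -> 0
  ctl <- set_onset(ctl, 6, 4L); trt <- set_onset(trt, 6, 4L)
  g <- dfs_gain(ctl, trt, H)
  expect_equal(g$gains$gain[1:4], c(3, 0, 4, -3))
  expect_false(g$gains$included[5])
  expect_equal(g$n_included, 5)
  expect_equal(g$mean_gain, mean(c(3, 0, 4, -3, 0)))
  expect_error(dfs_gain(ctl[-1, ], trt, H), "same id set")
})

test_that("cost-effectiveness identities hold exactly", {
  ce <- cost_effectiveness(258780, intervention_cost = 31074700000)
  expect_identical(ce$total_savings,
                   ce$aversion_savings - ce$intervention_cost)
  expect_identical(ce$aversion_savings, 258780 * 85200)
  neg <- cost_effectiveness(100, intervention_cost = 2e7)
  expect_lt(neg$total_savings, 0)
})

test_that("paired cost-effectiveness rescales agents to persons", {
  scn <- make_default_scenario(seed = 1, n_agents = 4000)
  scn$agent_scale <- 1000
  pr <- paired_run(scn, intervention_preset("help_pd"), horizon = 10,
                   n_agents = 4000, seed = 3)
  ce <- cost_effectiveness(pr)
  averted_agents <- sum(pr$control$outcomes$new_cases) -
    sum(pr$intervention$outcomes$new_cases)
  expect_equal(ce$diabetes_averted, averted_agents * 1000)
  expect_equal(ce$intervention_cost,
               pr$intervention$participants * 1000 *
                 intervention_preset("help_pd")$per_person_cost)
  expect_equal(ce$total_savings, ce$aversion_savings - ce$intervention_cost)
  # undiscounted accounting equals the discount_rate = 0 path
  ce0 <- cost_effectiveness(pr, discount_rate = 0)
  expect_identical(ce, ce0)
  # discounting only shrinks the magnitude of aversion savings
  ce3 <- cost_effectiveness(pr, discount_rate = 0.03)
  expect_lt(abs(ce3$aversion_savings), abs(ce$aversion_savings) + 1e-9)
})

test_that("widening the age band never shrinks participants or cost", {
  scn <- make_default_scenario(seed = 1, n_agents = 4000)
  tab <- compare_age_bands(scn, "dpp_ymca",
                           bands = list(c(55, 65), c(45, 65), c(35, 65),
                                        c(25, 65)),
                           horizon = 5, n_agents = 4000, seed = 2)
  expect_equal(nrow(tab), 4)
  expect_true(all(diff(tab$participants) >= 0))
  expect_true(all(diff(tab$intervention_cost) >= 0))
})
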
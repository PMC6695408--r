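# Synthetic study conditions: a fully specified, plausible parameter set
# (transition matrices, life table, diabetic mortality, BMI drift, baseline
# joint distribution, entry schedule) and a longitudinal panel generator for
# transition-matrix recovery. These stand in for the restricted
# individual-level inputs a real analysis would use (a longitudinal lifestyle
# trial panel, census/NHANES-style distribution tables); magnitudes are
# chosen so 15-year incidence is on the order of 1 per 100 and diabetes
# prevalence near 8-12 per 100, the plausible U.S. adult range.

# Stratum-level risk multiplier: rises with age band and BMI category,
# slightly higher for men.
risk_multiplier <- function(age_group, gender, bmi_cat) {
  (1 + 0.06 * age_group) *
    unname(c(normal = 1, overweight = 1.3, obese = 1.7)[bmi_cat]) *
    ifelse(gender == "male", 1.1, 1)
}

#' Default synthetic transition matrices
#'
#' Annual glycemic transition probabilities increasing with age band and BMI
#' category: normoglycemia-to-prediabetes ~3\% at the youngest normal-weight
#' stratum rising to ~11\%, prediabetes-to-diabetes ~1.8\% rising to ~7\%,
#' with regression from prediabetes to normoglycemia declining with age.
#' Diabetes is absorbing.
#'
#' @return A [tpm_set()].
#' @export
default_tpms <- function() {
  grid <- tidyr::expand_grid(age_group = 0:(N_AGE_GROUPS - 1L),
                             gender = GENDER_LEVELS, bmi_cat = BMI_LEVELS)
  r <- risk_multiplier(grid$age_group, grid$gender, grid$bmi_cat)
  no_pre <- pmin(0.030 * r, 0.20)
  no_dia <- pmin(0.0015 * r, 0.02)
  pre_dia <- pmin(0.018 * r, 0.12)
  pre_no <- pmax(0.18 - 0.008 * grid$age_group, 0.02)
  rows <- dplyr::bind_rows(
    dplyr::mutate(grid, from = "no_diabetes",
                  to_no_diabetes = 1 - no_pre - no_dia,
                  to_prediabetes = no_pre, to_diabetes = no_dia),
    dplyr::mutate(grid, from = "prediabetes",
                  to_no_diabetes = pre_no,
                  to_prediabetes = 1 - pre_no - pre_dia,
                  to_diabetes = pre_dia),
    dplyr::mutate(grid, from = "diabetes",
                  to_no_diabetes = 0, to_prediabetes = 0, to_diabetes = 1)
  )
  tpm_set(rows)
}

#' Default synthetic life table
#'
#' Gompertz-shaped annual death probabilities for ages 20-110, male
#' mortality 1.6x female, capped at 0.7.
#'
#' @return A [life_table()].
#' @export
default_life_table <- function() {
  ages <- 20:110
  qf <- pmin(0.00035 * exp(0.088 * (ages - 20)), 0.7)
  life_table(tibble::tibble(
    age = rep(ages, 2),
    gender = rep(c("female", "male"), each = length(ages)),
    q = c(qf, pmin(qf * 1.6, 0.7))
  ))
}

#' Default synthetic diabetic mortality model
#'
#' Proportional-hazards annual mortality for ever-diabetic individuals,
#' centered at a 50-year-old woman with BMI 28 (baseline hazard 0.02/yr),
#' with log-hazard slopes 0.085 per year of age, 0.35 for men and 0.025 per
#' BMI unit. The calibration constant defaults to 0.
#'
#' @return A [diabetic_mortality()] model.
#' @export
default_diabetic_mortality <- function() {
  diabetic_mortality(h0 = 0.02, beta_age = 0.085, beta_male = 0.35,
                     beta_bmi = 0.025, constant = 0,
                     age_center = 50, bmi_center = 28)
}

#' Default synthetic BMI drift model
#'
#' Mean annual BMI change declining with age (about +0.18 kg/m^2/yr in the
#' youngest band to about -0.1 in the oldest, women +0.01), realized with
#' change probability 0.7 and conditional spread 0.5 kg/m^2.
#'
#' @return A [bmi_drift()] model.
#' @export
default_bmi_drift <- function() {
  grid <- tidyr::expand_grid(age_group = 0:(N_AGE_GROUPS - 1L),
                             gender = GENDER_LEVELS)
  bmi_drift(dplyr::mutate(
    grid,
    mean_change = 0.18 - 0.018 * .data$age_group +
      ifelse(.data$gender == "female", 0.01, 0),
    p_change = 0.7
  ))
}

#' Default synthetic baseline distribution
#'
#' Joint distribution over age band, gender, BMI category and glycemic state
#' resembling a contemporary U.S. adult population: an age pyramid thinning
#' after 60, BMI split near 35/35/30 shifting heavier in midlife, diabetes
#' prevalence rising with age and adiposity, prediabetes around a quarter of
#' adults.
#'
#' @return A [pop_distribution()].
#' @export
default_init_dist <- function() {
  age_w <- c(9, 9, 9.5, 10, 10.5, 10, 8.5, 7.5, 6.5, 5.5, 4.5, 3.5, 2.5,
             1.6, 1, 0.4, 0.1)
  age_w <- age_w / sum(age_w)
  grid <- tidyr::expand_grid(age_group = 0:(N_AGE_GROUPS - 1L),
                             gender = GENDER_LEVELS, bmi_cat = BMI_LEVELS,
                             glycemic = GLYCEMIC_LEVELS)
  # BMI split drifts heavier through midlife then back
  mid <- pmin(grid$age_group, 9)
  w_bmi <- dplyr::case_when(
    grid$bmi_cat == "normal" ~ 0.42 - 0.015 * mid,
    grid$bmi_cat == "overweight" ~ 0.33 + 0.005 * mid,
    TRUE ~ 0.25 + 0.010 * mid
  )
  r <- risk_multiplier(grid$age_group, grid$gender, grid$bmi_cat)
  p_dia <- pmin(0.035 * r, 0.25)
  p_pre <- pmin(0.16 * sqrt(r), 0.40)
  w_gly <- dplyr::case_when(
    grid$glycemic == "diabetes" ~ p_dia,
    grid$glycemic == "prediabetes" ~ p_pre,
    TRUE ~ 1 - p_dia - p_pre
  )
  grid$probability <- age_w[grid$age_group + 1] * 0.5 * w_bmi * w_gly
  grid$probability <- grid$probability / sum(grid$probability)
  pop_distribution(grid)
}

#' Default synthetic entry schedule
#'
#' Annual entrants (people turning 20) equal to about 1.8\% of the baseline
#' agent count, mostly normoglycemic (87\%) with 12\% prediabetes and 1\%
#' diabetes, BMI split 45/30/25.
#'
#' @param n_agents Baseline agent count the proportion refers to.
#' @param horizon Number of scheduled years (0-based years `0:(horizon-1)`).
#' @return An [entry_schedule()].
#' @export
default_entry_schedule <- function(n_agents, horizon = 40) {
  grid <- tidyr::expand_grid(age_group = 0L, gender = GENDER_LEVELS,
                             bmi_cat = BMI_LEVELS, glycemic = GLYCEMIC_LEVELS)
  w_bmi <- unname(c(normal = 0.45, overweight = 0.30,
                    obese = 0.25)[grid$bmi_cat])
  w_gly <- unname(c(no_diabetes = 0.87, prediabetes = 0.12,
                    diabetes = 0.01)[grid$glycemic])
  grid$probability <- 0.5 * w_bmi * w_gly
  entry_schedule(
    counts = tibble::tibble(year = 0:(horizon - 1),
                            count = round(0.018 * n_agents)),
    dist = pop_distribution(grid)
  )
}

#' Default synthetic scenario
#'
#' Bundles all default synthetic models into a ready-to-run [scenario()].
#' The construction is deterministic; `seed` is recorded as the scenario's
#' default master seed for downstream sampling. With `agent_scale` at its
#' default, a 50,000-agent baseline represents a 234-million adult
#' population (1 agent = 4,680 persons).
#'
#' @param seed Default master seed recorded on the scenario.
#' @param n_agents Baseline agent count the entry schedule is proportioned
#'   to (default 50,000).
#' @param horizon Maximum scheduled horizon in years (default 40).
#' @param agent_scale Persons per agent (default `234e6 / n_agents`).
#' @return A `sim_scenario` with fields `seed` and `n_agents` recording the
#'   intended run configuration.
#' @examples
#' scn <- make_default_scenario(seed = 1, n_agents = 500)
#' pop <- build_initial_population(scn$init_dist, 500, seed = scn$seed)
#' @export
make_default_scenario <- function(seed = 1, n_agents = 50000, horizon = 40,
                                  agent_scale = 234e6 / n_agents) {
  scn <- scenario(
    init_dist = default_init_dist(),
    entry = default_entry_schedule(n_agents, horizon),
    tpms = default_tpms(),
    lt = default_life_table(),
    dm = default_diabetic_mortality(),
    drift = default_bmi_drift(),
    agent_scale = agent_scale,
    start_year = 2010
  )
  scn$seed <- as.integer(seed)
  scn$n_agents <- as.integer(n_agents)
  scn
}

#' Generate a synthetic longitudinal panel
#'
#' Simulates a short visit panel (subject id, visit month, age, gender, BMI,
#' glycemic state) whose state sequences evolve by a known transition set --
#' the ground truth for parameter-recovery tests of [estimate_tpms()].
#' Covariates are drawn once per subject (age uniform over
#' `age_range`, gender balanced, BMI normal around 28) and BMI is held fixed
#' across visits so each subject's stratum is stable; age advances with
#' calendar time.
#'
#' @param truth A [tpm_set()] giving the per-interval transition law.
#' @param n_subjects Number of subjects (>= 1).
#' @param n_visits Visits per subject (>= 2).
#' @param interval Spacing between visits in months (default 12).
#' @param seed Integer RNG seed.
#' @param age_range Baseline age range (default 25-75).
#' @param state_probs Baseline state distribution (default 55/35/10).
#' @return A panel tibble (see [validate_panel()]).
#' @export
generate_panel <- function(truth, n_subjects, n_visits = 4, interval = 12,
                           seed = 1, age_range = c(25, 75),
                           state_probs = c(0.55, 0.35, 0.10)) {
  stopifnot(inherits(truth, "tpm_set"), n_subjects >= 1, n_visits >= 2)
  set.seed(seed)
  age0 <- sample(seq(age_range[1], age_range[2]), n_subjects, replace = TRUE)
  gender <- sample(GENDER_LEVELS, n_subjects, replace = TRUE)
  bmi <- pmin(pmax(stats::rnorm(n_subjects, 28, 4.5), 19), 55)
  state <- sample(1:3, n_subjects, replace = TRUE, prob = state_probs)
  g_int <- match(gender, GENDER_LEVELS)
  records <- vector("list", n_visits)
  for (v in seq_len(n_visits)) {
    month <- (v - 1L) * interval
    age <- age0 + month %/% 12L
    records[[v]] <- tibble::tibble(
      subject_id = seq_len(n_subjects), visit_month = month, age = age,
      gender = gender, bmi = bmi, glycemic_state = GLYCEMIC_LEVELS[state])
    if (v < n_visits) {
      sid <- stratum_id(age, g_int, bmi)
      state <- next_state(truth, sid, state, stats::runif(n_subjects))
    }
  }
  dplyr::arrange(dplyr::bind_rows(records), .data$subject_id,
                 .data$visit_month)
}
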
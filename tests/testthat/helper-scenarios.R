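# Shared fixture builders. Everything is generated in code; no stored data.

# Life table with constant q for all ages/genders.
flat_life_table <- function(q = 0) {
  ages <- 20:110
  life_table(tibble::tibble(
    age = rep(ages, 2),
    gender = rep(c("male", "female"), each = length(ages)),
    q = q
  ))
}

# Drift model that never moves BMI.
null_drift <- function() {
  grid <- tidyr::expand_grid(age_group = 0:16, gender = c("male", "female"))
  bmi_drift(dplyr::mutate(grid, mean_change = 0, p_change = 1), sd = 0)
}

# Mortality model with negligible hazard (h0 must be > 0).
negligible_dm <- function() diabetic_mortality(h0 = 1e-12)

# Identity transitions: nobody ever changes glycemic state.
identity_tpms <- function() uniform_tpm_set(diag(3))

# Scenario with frozen dynamics: no deaths, no drift, no transitions, no
# entrants. Useful for conservation and determinism checks.
frozen_scenario <- function(horizon = 20) {
  scenario(
    init_dist = default_init_dist(),
    entry = entry_schedule(
      tibble::tibble(year = 0:(horizon - 1), count = 0),
      zero_band_dist()
    ),
    tpms = identity_tpms(),
    lt = flat_life_table(0),
    dm = negligible_dm(),
    drift = null_drift()
  )
}

# A distribution concentrated in the youngest band (for entry schedules).
zero_band_dist <- function(glycemic_probs = c(0.8, 0.2, 0)) {
  pop_distribution(tibble::tibble(
    age_group = 0L, gender = "female", bmi_cat = "overweight",
    glycemic = c("no_diabetes", "prediabetes", "diabetes"),
    probability = glycemic_probs / sum(glycemic_probs)
  ))
}

# Point-mass distribution in a single joint cell.
point_mass_dist <- function(age_group = 4L, gender = "male",
                            bmi_cat = "obese", glycemic = "prediabetes") {
  pop_distribution(tibble::tibble(
    age_group = age_group, gender = gender, bmi_cat = bmi_cat,
    glycemic = glycemic, probability = 1
  ))
}

# A homogeneous one-matrix transition law with no path into diabetes,
# so frozen-mortality cohorts stay immortal.
no_diabetes_tpms <- function() {
  uniform_tpm_set(matrix(c(0.7, 0.3, 0,
                           0.4, 0.6, 0,
                           0,   0,   1), nrow = 3, byrow = TRUE))
}
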
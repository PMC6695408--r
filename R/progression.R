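# Model objects driving the annual cycle: a life table for non-diabetic
# mortality, a Cox-derived annual death probability for diabetic individuals
# (with a calibration constant on the log-hazard), a stochastic BMI drift
# model, and the stratified 3x3 glycemic transition matrices.

#' Life table of annual death probabilities
#'
#' Annual probability of death `q` by single year of age and gender, applied
#' to individuals who have never been diabetic. The table must cover every
#' age from 20 up to some maximum; the last value is reused beyond it.
#'
#' @param table Data frame with columns `age`, `gender`, `q` (each `q` in
#'   \[0,1\]), one row per age x gender from age 20 upward with no gaps.
#' @return A `life_table` object.
#' @export
life_table <- function(table) {
  table <- tibble::as_tibble(table)
  stopifnot(all(c("age", "gender", "q") %in% names(table)))
  if (any(table$q < 0 | table$q > 1)) {
    stop("life-table probabilities must lie in [0,1]", call. = FALSE)
  }
  if (!all(table$gender %in% GENDER_LEVELS)) {
    stop("`gender` must be male/female", call. = FALSE)
  }
  ages <- as.integer(sort(unique(table$age)))
  if (ages[1] != 20L || !identical(ages, seq(20L, max(ages)))) {
    stop("life table must cover every age from 20 with no gaps", call. = FALSE)
  }
  qmat <- matrix(NA_real_, nrow = length(ages), ncol = 2,
                 dimnames = list(NULL, GENDER_LEVELS))
  qmat[cbind(as.integer(table$age) - 19L,
             match(table$gender, GENDER_LEVELS))] <- table$q
  if (anyNA(qmat)) stop("life table must cover both genders at every age",
                        call. = FALSE)
  structure(list(table = table, qmat = qmat, max_age = max(ages)),
            class = "life_table")
}

lt_lookup <- function(lt, age, gender_int) {
  idx <- pmin(age, lt$max_age) - 19L
  lt$qmat[cbind(idx, gender_int)]
}

#' Diabetic mortality model
#'
#' Annual death probability for individuals who have ever been diabetic,
#' derived from a proportional-hazards linear predictor in age, gender and
#' BMI: `p = 1 - exp(-h0 * exp(lp + c))` with
#' `lp = beta_age * (age - age_center) + beta_male * [male] +
#' beta_bmi * (bmi - bmi_center)`. The additive constant `c` shifts the
#' baseline hazard and is the handle used by [calibrate_mortality_constant()]
#' to compensate for risk factors dropped from the original covariate set.
#'
#' @param h0 Baseline annual hazard (> 0) at the covariate centers.
#' @param beta_age,beta_male,beta_bmi Log-hazard coefficients.
#' @param constant Calibration constant `c` added to the log-hazard.
#' @param age_center,bmi_center Centering values for age and BMI.
#' @return A `diabetic_mortality` object.
#' @export
diabetic_mortality <- function(h0, beta_age = 0, beta_male = 0, beta_bmi = 0,
                               constant = 0, age_center = 50, bmi_center = 28) {
  stopifnot(h0 > 0)
  structure(list(h0 = h0, beta_age = beta_age, beta_male = beta_male,
                 beta_bmi = beta_bmi, constant = constant,
                 age_center = age_center, bmi_center = bmi_center),
            class = "diabetic_mortality")
}

dm_prob <- function(dm, age, gender_int, bmi, constant = dm$constant) {
  lp <- dm$beta_age * (age - dm$age_center) +
    dm$beta_male * (gender_int == 1L) +
    dm$beta_bmi * (bmi - dm$bmi_center)
  1 - exp(-dm$h0 * exp(lp + constant))
}

#' Annual death probability for each individual
#'
#' Individuals who have never been diabetic use the life table; individuals
#' who have ever been diabetic use the diabetic mortality model (with its
#' calibration constant). The probability is evaluated at the individual's
#' current age, so a newly incident diabetic -- whose state changes after the
#' mortality phase -- is priced by the diabetic model only from the following
#' year.
#'
#' @param pop Population tibble.
#' @param lt A [life_table()].
#' @param dm A [diabetic_mortality()] model.
#' @return Numeric vector of probabilities, one per row of `pop`.
#' @export
annual_death_probability <- function(pop, lt, dm) {
  g <- match(pop$gender, GENDER_LEVELS)
  p <- lt_lookup(lt, pop$age, g)
  dia <- pop$ever_diabetic
  if (any(dia)) {
    p[dia] <- dm_prob(dm, pop$age[dia], g[dia], pop$bmi[dia])
  }
  p
}

#' Apply one year of mortality
#'
#' Each alive individual dies independently with its annual death
#' probability; the death year is recorded and the individual is retained in
#' the population with `alive = FALSE`.
#'
#' @inheritParams annual_death_probability
#' @param year 0-based simulation year recorded as `death_year`.
#' @param seed Integer RNG seed.
#' @return A list with `population` (updated tibble) and `deaths` (count).
#' @export
apply_mortality <- function(pop, lt, dm, year, seed) {
  set.seed(seed)
  u <- stats::runif(nrow(pop))
  p <- annual_death_probability(pop, lt, dm)
  dies <- pop$alive & u < p
  pop$alive[dies] <- FALSE
  pop$death_year[dies] <- year
  list(population = pop, deaths = sum(dies))
}

#' Stochastic BMI drift model
#'
#' Each year an individual's BMI changes with probability `p_change`; when it
#' changes, the magnitude is drawn from a normal distribution with mean
#' `mean_change / p_change` and standard deviation `sd`, so the unconditional
#' expected annual change equals `mean_change`, the trend produced by an
#' age-group x gender regression of population BMI. BMI is floored at
#' `bmi_floor` after the update.
#'
#' @param params Data frame with columns `age_group` (0..16), `gender`,
#'   `mean_change` (kg/m^2 per year) and `p_change` (in (0,1\]), covering all
#'   34 age-group x gender strata.
#' @param sd Standard deviation of the conditional change (kg/m^2).
#' @param bmi_floor Lower bound applied after every update (kg/m^2).
#' @return A `bmi_drift` object.
#' @export
bmi_drift <- function(params, sd = 0.5, bmi_floor = 15) {
  params <- tibble::as_tibble(params)
  stopifnot(all(c("age_group", "gender", "mean_change", "p_change")
                %in% names(params)))
  if (any(params$p_change <= 0 | params$p_change > 1)) {
    stop("`p_change` must lie in (0,1]", call. = FALSE)
  }
  full <- tidyr::expand_grid(age_group = 0:(N_AGE_GROUPS - 1L),
                             gender = GENDER_LEVELS)
  key <- paste(params$age_group, params$gender)
  miss <- setdiff(paste(full$age_group, full$gender), key)
  if (length(miss) > 0) {
    stop("BMI drift parameters missing for strata: ",
         paste(utils::head(miss, 5), collapse = "; "), call. = FALSE)
  }
  # dense lookup: row index = age_group * 2 + gender_int
  ord <- match(paste(full$age_group, full$gender), key)
  structure(list(params = params,
                 mean_change = params$mean_change[ord],
                 p_change = params$p_change[ord],
                 sd = sd, bmi_floor = bmi_floor),
            class = "bmi_drift")
}

drift_index <- function(age, gender_int) {
  ag <- pmin((pmax(age, 20L) - 20L) %/% 5L, N_AGE_GROUPS - 1L)
  ag * 2L + gender_int
}

#' Advance age and BMI one year
#'
#' Age increments deterministically by one; BMI changes stochastically per
#' the drift model. Applied to alive individuals only.
#'
#' @param pop Population tibble.
#' @param drift A [bmi_drift()] model.
#' @param seed Integer RNG seed.
#' @return Updated population tibble.
#' @export
update_age_bmi <- function(pop, drift, seed) {
  set.seed(seed)
  n <- nrow(pop)
  u_change <- stats::runif(n)
  z <- stats::rnorm(n)
  g <- match(pop$gender, GENDER_LEVELS)
  idx <- drift_index(pop$age, g)
  changes <- pop$alive & u_change < drift$p_change[idx]
  delta <- drift$mean_change[idx] / drift$p_change[idx] + drift$sd * z
  pop$age[pop$alive] <- pop$age[pop$alive] + 1L
  pop$bmi[changes] <- pmax(pop$bmi[changes] + delta[changes], drift$bmi_floor)
  pop
}

#' Stratified glycemic transition matrices
#'
#' One 3x3 row-stochastic matrix per stratum (age band x gender x BMI
#' category): entry (i, j) is the one-year probability of moving from
#' glycemic state i to state j. Diabetes is absorbing, so every diabetes row
#' must be (0, 0, 1).
#'
#' @param table Data frame with columns `age_group` (0..16), `gender`,
#'   `bmi_cat`, `from`, `to_no_diabetes`, `to_prediabetes`, `to_diabetes`
#'   and optionally `n_pairs` (transition pairs behind the row), covering all
#'   306 stratum x from-state rows.
#' @return A `tpm_set` object (a tibble with a fast lookup attribute).
#' @seealso [uniform_tpm_set()] to build a set from a single matrix,
#'   [estimate_tpms()] to estimate one from panel data.
#' @export
tpm_set <- function(table) {
  table <- tibble::as_tibble(table)
  pcols <- c("to_no_diabetes", "to_prediabetes", "to_diabetes")
  stopifnot(all(c("age_group", "gender", "bmi_cat", "from", pcols)
                %in% names(table)))
  if (!"n_pairs" %in% names(table)) table$n_pairs <- NA_real_
  if (!all(table$from %in% GLYCEMIC_LEVELS)) {
    stop("`from` must be a valid glycemic state", call. = FALSE)
  }
  P <- as.matrix(table[pcols])
  if (any(P < -1e-12)) stop("transition probabilities must be >= 0", call. = FALSE)
  rs <- rowSums(P)
  if (any(abs(rs - 1) > 1e-9)) {
    bad <- which.max(abs(rs - 1))
    stop(sprintf("TPM row does not sum to 1 (age_group %d, %s, %s, from %s: %.12f)",
                 table$age_group[bad], table$gender[bad], table$bmi_cat[bad],
                 table$from[bad], rs[bad]), call. = FALSE)
  }
  dia <- table$from == "diabetes"
  if (any(abs(P[dia, 3] - 1) > 1e-9)) {
    stop("diabetes must be absorbing: every diabetes row must be (0,0,1)",
         call. = FALSE)
  }
  sid <- (table$age_group * 2L + (match(table$gender, GENDER_LEVELS) - 1L)) * 3L +
    match(table$bmi_cat, BMI_LEVELS)
  n_strata <- N_AGE_GROUPS * 2L * 3L
  if (!setequal(paste(sid, table$from), paste(rep(1:n_strata, each = 3),
                                              rep(GLYCEMIC_LEVELS, n_strata)))) {
    stop("TPM table must contain exactly one row per stratum x from-state",
         call. = FALSE)
  }
  # cumulative-probability lookup matrix: row = (stratum - 1) * 3 + from
  cum <- matrix(NA_real_, nrow = n_strata * 3L, ncol = 3)
  rows <- (sid - 1L) * 3L + match(table$from, GLYCEMIC_LEVELS)
  cum[rows, ] <- t(apply(pmax(P, 0), 1, cumsum))
  cum[, 3] <- 1
  structure(table, class = c("tpm_set", class(table)), cum = cum)
}

#' Build a transition set from one matrix
#'
#' Convenience constructor applying the same 3x3 matrix to every stratum --
#' useful for homogeneous scenarios and for parameter-recovery fixtures.
#'
#' @param P 3x3 row-stochastic matrix ordered no_diabetes, prediabetes,
#'   diabetes; the diabetes row must be (0, 0, 1).
#' @return A `tpm_set`.
#' @export
uniform_tpm_set <- function(P) {
  stopifnot(is.matrix(P), all(dim(P) == c(3, 3)))
  grid <- tidyr::expand_grid(age_group = 0:(N_AGE_GROUPS - 1L),
                             gender = GENDER_LEVELS, bmi_cat = BMI_LEVELS,
                             from = GLYCEMIC_LEVELS)
  i <- match(grid$from, GLYCEMIC_LEVELS)
  grid$to_no_diabetes <- P[i, 1]
  grid$to_prediabetes <- P[i, 2]
  grid$to_diabetes <- P[i, 3]
  tpm_set(grid)
}

# Draw next glycemic states for given internal codes using uniforms u.
next_state <- function(tpms, sid, state, u) {
  cum <- attr(tpms, "cum")
  row <- (sid - 1L) * 3L + state
  1L + (u > cum[row, 1]) + (u > cum[row, 2])
}

#' Apply one year of glycemic transitions
#'
#' Each alive individual's next state is drawn from the transition row of its
#' current stratum (age band, gender, BMI category evaluated after this
#' year's age/BMI update). Entry into diabetes records the onset year and
#' sets `ever_diabetic`; diabetes is absorbing.
#'
#' @param pop Population tibble.
#' @param tpms A [tpm_set()].
#' @param year 0-based simulation year recorded as the onset year for new
#'   cases.
#' @param seed Integer RNG seed.
#' @return Updated population tibble.
#' @export
glycemic_transition <- function(pop, tpms, year, seed) {
  set.seed(seed)
  u <- stats::runif(nrow(pop))
  g <- match(pop$gender, GENDER_LEVELS)
  sid <- stratum_id(pop$age, g, pop$bmi)
  state <- match(pop$glycemic, GLYCEMIC_LEVELS)
  nxt <- next_state(tpms, sid, state, u)
  nxt[!pop$alive] <- state[!pop$alive]
  new_case <- pop$alive & nxt == 3L & state != 3L
  pop$glycemic <- GLYCEMIC_LEVELS[nxt]
  pop$diabetes_onset_year[new_case] <- year
  pop$ever_diabetic[new_case] <- TRUE
  pop
}
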
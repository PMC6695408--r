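# Domain vocabulary shared by every module: the three glycemic states, the
# three BMI categories, the seventeen 5-year age bands, and the per-person
# record ("individual") that the annual cycle updates.

GLYCEMIC_LEVELS <- c("no_diabetes", "prediabetes", "diabetes")
GENDER_LEVELS <- c("male", "female")
BMI_LEVELS <- c("normal", "overweight", "obese")
N_AGE_GROUPS <- 17L

# Fixed phase order of the annual cycle. Mortality is decided at the start of
# the year; the intervention (first year only) precedes aging/BMI drift so a
# first-year BMI reduction changes the stratum used by that year's glycemic
# transition.
ANNUAL_PHASES <- c("mortality", "intervention", "bmi_change", "bmi_magnitude",
                   "transition", "entry")
# "baseline" is an extra substream used once, to sample the initial population.
SUBSTREAM_PHASES <- c(ANNUAL_PHASES, "baseline")

#' Categorize a continuous BMI value
#'
#' Maps body-mass index (kg/m^2) to the three categories used to stratify
#' glycemic transition matrices: `normal` (< 25), `overweight` (25 to < 30)
#' and `obese` (>= 30). Intervals are half-open on the right, so 25.0 is
#' `overweight` and 30.0 is `obese`. Values below 20 are treated as `normal`
#' for stratum lookup; the underweight guard used by interventions (BMI
#' < 18.5) is applied separately in [apply_intervention()].
#'
#' @param bmi Numeric vector of BMI values (kg/m^2), all > 0.
#' @return Character vector with values in `"normal"`, `"overweight"`,
#'   `"obese"`.
#' @examples
#' bmi_category(c(24.9, 25, 31.2))
#' @export
bmi_category <- function(bmi) {
  if (!is.numeric(bmi) || anyNA(bmi) || any(bmi <= 0)) {
    stop("`bmi` must be positive and non-missing", call. = FALSE)
  }
  BMI_LEVELS[findInterval(bmi, c(25, 30)) + 1L]
}

#' Assign an age to its 5-year band
#'
#' Ages 20 and over are discretized into 17 bands: 20-25, 25-30, ..., 95-100,
#' and 100+. Bands are half-open, so age 25 falls in band 1 (25-30). The
#' returned index is zero-based: band 0 is ages 20-24, band 16 is 100+.
#'
#' @param age Numeric vector of ages in years, all >= 20.
#' @return Integer vector of band indices in 0..16.
#' @examples
#' age_group(c(20, 64, 103))
#' age_group_label(age_group(64))
#' @export
age_group <- function(age) {
  if (!is.numeric(age) || anyNA(age) || any(age < 20)) {
    stop("`age` must be >= 20 and non-missing", call. = FALSE)
  }
  as.integer(pmin(floor((age - 20) / 5), N_AGE_GROUPS - 1L))
}

#' @rdname age_group
#' @param group Integer vector of band indices as returned by [age_group()].
#' @export
age_group_label <- function(group) {
  stopifnot(all(group %in% 0:(N_AGE_GROUPS - 1L)))
  labs <- c(paste0(seq(20, 95, by = 5), "-", seq(25, 100, by = 5)), "100+")
  labs[group + 1L]
}

#' Construct a population tibble
#'
#' A population is an ordinary tibble with one row per simulated individual
#' and columns `id`, `age`, `gender`, `bmi`, `glycemic`, `alive`,
#' `ever_diabetic`, `diabetes_onset_year`, `death_year`, `entry_year`.
#' Dead individuals are retained (flagged by `alive = FALSE`) so that
#' denominators and paired-run bookkeeping stay well defined.
#'
#' @param age,gender,bmi,glycemic Per-individual attributes; recycled to a
#'   common length. `gender` in `"male"`/`"female"`, `glycemic` in
#'   `"no_diabetes"`/`"prediabetes"`/`"diabetes"`.
#' @param id Integer ids; defaults to `1:n`.
#' @param entry_year Simulation year the individual entered (0 = baseline).
#' @return A validated population tibble.
#' @examples
#' new_population(age = c(40, 62), gender = "female", bmi = c(27, 31),
#'                glycemic = c("prediabetes", "no_diabetes"))
#' @export
new_population <- function(age, gender, bmi, glycemic, id = NULL,
                           entry_year = 0L) {
  n <- max(length(age), length(gender), length(bmi), length(glycemic))
  gly <- rep_len(as.character(glycemic), n)
  entry <- as.integer(rep_len(entry_year, n))
  # Individuals who enter already diabetic were diagnosed before they joined
  # the simulation: onset is recorded as the year before entry so they count
  # as prevalent, never incident.
  pop <- tibble::tibble(
    id = if (is.null(id)) seq_len(n) else as.integer(id),
    age = as.integer(rep_len(age, n)),
    gender = rep_len(as.character(gender), n),
    bmi = as.numeric(rep_len(bmi, n)),
    glycemic = gly,
    alive = TRUE,
    ever_diabetic = gly == "diabetes",
    diabetes_onset_year = as.integer(ifelse(gly == "diabetes", entry - 1L, NA)),
    death_year = NA_integer_,
    entry_year = entry
  )
  validate_population(pop)
  pop
}

#' Validate a population tibble
#'
#' Checks the structural invariants of a population: required columns,
#' legal factor levels, ages >= 20, positive BMI, onset year present iff
#' `ever_diabetic`, death year present iff dead, and that current diabetes
#' implies `ever_diabetic` (diabetes is absorbing).
#'
#' @param pop A population tibble.
#' @return `pop`, invisibly, if valid; otherwise an error.
#' @export
validate_population <- function(pop) {
  req <- c("id", "age", "gender", "bmi", "glycemic", "alive", "ever_diabetic",
           "diabetes_onset_year", "death_year", "entry_year")
  missing_cols <- setdiff(req, names(pop))
  if (length(missing_cols) > 0) {
    stop("population is missing columns: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(pop$id)) stop("population ids must be unique", call. = FALSE)
  if (!all(pop$gender %in% GENDER_LEVELS)) {
    stop("`gender` must be one of: ", paste(GENDER_LEVELS, collapse = ", "),
         call. = FALSE)
  }
  if (!all(pop$glycemic %in% GLYCEMIC_LEVELS)) {
    stop("`glycemic` must be one of: ", paste(GLYCEMIC_LEVELS, collapse = ", "),
         call. = FALSE)
  }
  if (any(pop$age < 20)) stop("ages must be >= 20", call. = FALSE)
  if (any(pop$bmi <= 0)) stop("BMI must be positive", call. = FALSE)
  if (!identical(is.na(pop$diabetes_onset_year), !pop$ever_diabetic)) {
    stop("diabetes_onset_year must be set exactly for ever-diabetic individuals",
         call. = FALSE)
  }
  if (!identical(is.na(pop$death_year), pop$alive)) {
    stop("death_year must be set exactly for dead individuals", call. = FALSE)
  }
  if (any(pop$glycemic == "diabetes" & !pop$ever_diabetic)) {
    stop("current diabetes implies ever_diabetic", call. = FALSE)
  }
  invisible(pop)
}

# --- internal fast representation -----------------------------------------
# The annual cycle works on plain atomic vectors with integer codings
# (gender 1/2, glycemic 1/2/3); the tibble form is converted once per run.

pop_to_internal <- function(pop) {
  list(
    id = as.integer(pop$id),
    age = as.integer(pop$age),
    gender = match(pop$gender, GENDER_LEVELS),
    bmi = as.numeric(pop$bmi),
    glycemic = match(pop$glycemic, GLYCEMIC_LEVELS),
    alive = pop$alive,
    ever_diabetic = pop$ever_diabetic,
    onset = as.integer(pop$diabetes_onset_year),
    death = as.integer(pop$death_year),
    entry = as.integer(pop$entry_year)
  )
}

pop_from_internal <- function(p) {
  tibble::tibble(
    id = p$id,
    age = p$age,
    gender = GENDER_LEVELS[p$gender],
    bmi = p$bmi,
    glycemic = GLYCEMIC_LEVELS[p$glycemic],
    alive = p$alive,
    ever_diabetic = p$ever_diabetic,
    diabetes_onset_year = p$onset,
    death_year = p$death,
    entry_year = p$entry
  )
}

# Stratum id in 1..(17*2*3) from integer codings; age capped into last band.
stratum_id <- function(age, gender_int, bmi) {
  ag <- pmin((pmax(age, 20L) - 20L) %/% 5L, N_AGE_GROUPS - 1L)
  bc <- findInterval(bmi, c(25, 30)) + 1L
  (ag * 2L + (gender_int - 1L)) * 3L + bc
}

#' Derive a per-(year, phase) substream seed
#'
#' Every random phase of every simulated year draws from its own
#' deterministic substream of the master seed, so consuming draws in one
#' phase never desynchronizes another and paired runs share common random
#' numbers. All derived seeds stay below 2^31 - 1.
#'
#' @param master Master integer seed.
#' @param year Simulation year (0-based).
#' @param phase One of the annual phases (`"mortality"`, `"intervention"`,
#'   `"bmi_change"`, `"bmi_magnitude"`, `"transition"`, `"entry"`) or
#'   `"baseline"` for baseline-population sampling.
#' @return An integer seed.
#' @examples
#' substream_seed(1, 0, "baseline")
#' @export
substream_seed <- function(master, year, phase) {
  ph <- match(phase, SUBSTREAM_PHASES)
  if (is.na(ph)) stop("unknown phase: ", phase, call. = FALSE)
  v <- (as.double(master) %% 2147483647) * 48271 + year * 6007 + ph * 389
  as.integer(v %% 2147483629)
}
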
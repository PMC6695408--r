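# Baseline population construction and annual entrants ("births": people
# turning 20). Both sample from a joint distribution over age band, gender,
# BMI category and glycemic state; continuous BMI and exact age are drawn
# uniformly within the sampled cell.

#' Define a joint population distribution
#'
#' A population distribution is a tibble with one row per cell of the joint
#' space age band x gender x BMI category x glycemic state and a
#' `probability` column summing to one. It drives sampling of both the
#' baseline population and annual entrants.
#'
#' @param cells A data frame with columns `age_group` (0..16), `gender`,
#'   `bmi_cat`, `glycemic`, `probability`.
#' @param bmi_max Upper bound used when drawing a continuous BMI inside the
#'   obese category (default 60 kg/m^2).
#' @return A `pop_distribution` tibble.
#' @export
pop_distribution <- function(cells, bmi_max = 60) {
  cells <- tibble::as_tibble(cells)
  req <- c("age_group", "gender", "bmi_cat", "glycemic", "probability")
  missing_cols <- setdiff(req, names(cells))
  if (length(missing_cols) > 0) {
    stop("distribution is missing columns: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (!all(cells$age_group %in% 0:(N_AGE_GROUPS - 1L))) {
    stop("`age_group` must be in 0..16", call. = FALSE)
  }
  if (!all(cells$gender %in% GENDER_LEVELS)) {
    stop("`gender` must be male/female", call. = FALSE)
  }
  if (!all(cells$bmi_cat %in% BMI_LEVELS)) {
    stop("`bmi_cat` must be normal/overweight/obese", call. = FALSE)
  }
  if (!all(cells$glycemic %in% GLYCEMIC_LEVELS)) {
    stop("`glycemic` must be a valid glycemic state", call. = FALSE)
  }
  if (any(cells$probability < 0)) {
    stop("cell probabilities must be non-negative", call. = FALSE)
  }
  total <- sum(cells$probability)
  if (abs(total - 1) > 1e-9) {
    stop(sprintf("cell probabilities must sum to 1 (joint margin sums to %.10f)",
                 total), call. = FALSE)
  }
  structure(cells, class = c("pop_distribution", class(cells)),
            bmi_max = bmi_max)
}

# Draw n individuals' attributes from a pop_distribution; returns a tibble
# without ids (the caller assigns ids and entry year). Exact age is uniform
# over the integer ages of the band (100+ band spans 100..109); continuous
# BMI is uniform over the category interval, obese truncated at bmi_max.
sample_from_distribution <- function(dist, n) {
  bmi_max <- attr(dist, "bmi_max") %||% 60
  cell <- sample.int(nrow(dist), n, replace = TRUE, prob = dist$probability)
  ag <- dist$age_group[cell]
  age_lo <- 20L + 5L * ag
  age_span <- ifelse(ag == N_AGE_GROUPS - 1L, 10L, 5L)
  age <- age_lo + as.integer(floor(stats::runif(n) * age_span))
  bc <- match(dist$bmi_cat[cell], BMI_LEVELS)
  lo <- c(20, 25, 30)[bc]
  hi <- c(25, 30, bmi_max)[bc]
  bmi <- lo + stats::runif(n) * (hi - lo)
  tibble::tibble(age = age, gender = dist$gender[cell], bmi = bmi,
                 glycemic = dist$glycemic[cell])
}

#' Sample a baseline population
#'
#' Draws `n_agents` individuals independently from a joint population
#' distribution. Empirical cell frequencies converge to the distribution as
#' `n_agents` grows; sampling is reproducible under a fixed seed.
#'
#' @param dist A [pop_distribution()].
#' @param n_agents Number of simulated individuals (>= 1). One agent may
#'   represent many real persons; see the `agent_scale` argument of
#'   [scenario()].
#' @param seed Integer RNG seed.
#' @return A population tibble (see [new_population()]) with `entry_year = 0`.
#' @examples
#' d <- pop_distribution(tibble::tibble(
#'   age_group = 4, gender = "male", bmi_cat = "obese",
#'   glycemic = "prediabetes", probability = 1))
#' build_initial_population(d, 5, seed = 1)
#' @export
build_initial_population <- function(dist, n_agents, seed) {
  if (!inherits(dist, "pop_distribution")) dist <- pop_distribution(dist)
  stopifnot(n_agents >= 1)
  set.seed(seed)
  attrs <- sample_from_distribution(dist, n_agents)
  new_population(age = attrs$age, gender = attrs$gender, bmi = attrs$bmi,
                 glycemic = attrs$glycemic, entry_year = 0L)
}

#' Define an annual entry schedule
#'
#' Entrants model population growth: each simulation year a given number of
#' 20-year-olds (in agent units) joins the population, drawn from a
#' distribution restricted to the youngest age band.
#'
#' @param counts Data frame with columns `year` (0-based simulation year) and
#'   `count` (entrant agents, >= 0).
#' @param dist A [pop_distribution()] whose mass lies entirely in age band 0.
#' @return An `entry_schedule` object.
#' @export
entry_schedule <- function(counts, dist) {
  counts <- tibble::as_tibble(counts)
  stopifnot(all(c("year", "count") %in% names(counts)))
  if (any(counts$count < 0)) stop("entrant counts must be >= 0", call. = FALSE)
  if (!inherits(dist, "pop_distribution")) dist <- pop_distribution(dist)
  if (any(dist$age_group != 0L & dist$probability > 0)) {
    stop("entrant distribution must be restricted to age band 0 (20-24)",
         call. = FALSE)
  }
  structure(list(counts = counts, dist = dist), class = "entry_schedule")
}

#' Inject one year's entrants into a population
#'
#' Appends the scheduled number of new individuals (aged 20-24) for the given
#' simulation year. Ids continue from the current maximum so that paired runs
#' sharing a seed assign identical ids.
#'
#' @param pop A population tibble.
#' @param schedule An [entry_schedule()].
#' @param year 0-based simulation year; must appear in the schedule.
#' @param seed Integer RNG seed.
#' @return The population with entrants appended.
#' @export
inject_entrants <- function(pop, schedule, year, seed) {
  stopifnot(inherits(schedule, "entry_schedule"))
  i <- match(year, schedule$counts$year)
  if (is.na(i)) stop("year ", year, " is outside the entry schedule", call. = FALSE)
  n <- as.integer(round(schedule$counts$count[i]))
  if (n == 0L) return(pop)
  set.seed(seed)
  attrs <- sample_from_distribution(schedule$dist, n)
  entrants <- new_population(
    age = attrs$age, gender = attrs$gender, bmi = attrs$bmi,
    glycemic = attrs$glycemic,
    id = max(pop$id, 0L) + seq_len(n), entry_year = year
  )
  dplyr::bind_rows(pop, entrants)
}
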
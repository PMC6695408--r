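# One-year lifestyle interventions. Eligibility is shared across programs
# (prediabetes, BMI >= 25, a configurable age band, default 25-65); a program
# is characterized by the fraction of BMI removed, the achievement rate (the
# proportion of participants who receive the full stated reduction; the rest
# receive none), and a per-person cost charged to every participant.

#' Define a lifestyle intervention
#'
#' @param name Program label.
#' @param reduction_fraction Fraction of BMI removed from achievers, in
#'   (0, 1).
#' @param achievement_rate Probability a participant achieves the full
#'   reduction, in \[0, 1\].
#' @param per_person_cost Cost in dollars charged per participant (achiever
#'   or not).
#' @param age_range Eligible age interval, inclusive (default 25-65).
#' @param min_bmi Minimum eligible BMI (default 25 kg/m^2).
#' @param underweight_floor BMI below which no reduction is ever applied, and
#'   below which a reduction never pushes anyone (default 18.5 kg/m^2).
#' @return An `intervention_spec` object.
#' @seealso [intervention_preset()] for the three built-in programs.
#' @export
intervention_spec <- function(name, reduction_fraction, achievement_rate,
                              per_person_cost, age_range = c(25, 65),
                              min_bmi = 25, underweight_floor = 18.5) {
  stopifnot(reduction_fraction > 0, reduction_fraction < 1,
            achievement_rate >= 0, achievement_rate <= 1,
            per_person_cost >= 0, length(age_range) == 2,
            age_range[1] <= age_range[2])
  structure(list(name = name, reduction_fraction = reduction_fraction,
                 achievement_rate = achievement_rate,
                 per_person_cost = per_person_cost,
                 age_range = as.numeric(age_range), min_bmi = min_bmi,
                 underweight_floor = underweight_floor),
            class = "intervention_spec")
}

#' Built-in intervention presets
#'
#' Three proven lifestyle diabetes-prevention programs, modeled as a one-year
#' BMI reduction: DPP (at least 7\% BMI reduction achieved by 38\% of
#' participants), its YMCA group-session translation DPP-YMCA (5\% for
#' 32.4\%), and the community-health-worker program HELP-PD (5\% for 58.5\%).
#' Default per-person costs are program-cost estimates from the trials'
#' published cost analyses; override them for local price assumptions.
#'
#' @param name One of `"dpp"`, `"dpp_ymca"`, `"help_pd"`.
#' @param age_range Eligible age interval (default 25-65).
#' @param per_person_cost Optional override of the default cost.
#' @return An `intervention_spec`.
#' @examples
#' intervention_preset("help_pd", age_range = c(55, 65))
#' @export
intervention_preset <- function(name = c("dpp", "dpp_ymca", "help_pd"),
                                age_range = c(25, 65),
                                per_person_cost = NULL) {
  name <- match.arg(name)
  defaults <- list(
    dpp = list(reduction = 0.07, achievement = 0.38, cost = 1400),
    dpp_ymca = list(reduction = 0.05, achievement = 0.324, cost = 346),
    help_pd = list(reduction = 0.05, achievement = 0.585, cost = 452)
  )[[name]]
  intervention_spec(
    name = name,
    reduction_fraction = defaults$reduction,
    achievement_rate = defaults$achievement,
    per_person_cost = per_person_cost %||% defaults$cost,
    age_range = age_range
  )
}

#' Intervention eligibility
#'
#' An alive individual is eligible when their age lies in the program's age
#' range, BMI is at least the program minimum, and their glycemic state is
#' prediabetes. All programs share this eligibility definition so their
#' impacts are compared on the same sub-population.
#'
#' @param pop Population tibble.
#' @param spec An [intervention_spec()].
#' @return Logical vector, one element per row of `pop`.
#' @export
is_eligible <- function(pop, spec) {
  pop$alive &
    pop$age >= spec$age_range[1] & pop$age <= spec$age_range[2] &
    pop$bmi >= spec$min_bmi &
    pop$glycemic == "prediabetes"
}

# Core intervention arithmetic on internal vectors; u is a per-row uniform.
# All eligible individuals participate; achievers' BMI is multiplied by
# (1 - reduction_fraction) but never applied below the underweight floor nor
# allowed to push BMI under it.
apply_intervention_bmi <- function(bmi, eligible, u, spec) {
  achiever <- eligible & u < spec$achievement_rate
  floor_ok <- bmi >= spec$underweight_floor
  apply <- achiever & floor_ok
  bmi[apply] <- pmax(bmi[apply] * (1 - spec$reduction_fraction),
                     spec$underweight_floor)
  list(bmi = bmi, achiever = achiever & floor_ok)
}

#' Apply an intervention to a population
#'
#' Every eligible individual participates (and incurs the per-person cost);
#' each participant independently achieves the full BMI reduction with the
#' program's achievement rate. The reduction is applied once -- interventions
#' here are one-year programs whose BMI effect is realized immediately -- and
#' never to individuals below the underweight floor.
#'
#' @param pop Population tibble.
#' @param spec An [intervention_spec()].
#' @param seed Integer RNG seed.
#' @return A list with `population` (updated tibble), `participants` and
#'   `achievers` (counts, in agents).
#' @export
apply_intervention <- function(pop, spec, seed) {
  set.seed(seed)
  u <- stats::runif(nrow(pop))
  eligible <- is_eligible(pop, spec)
  res <- apply_intervention_bmi(pop$bmi, eligible, u, spec)
  pop$bmi <- res$bmi
  list(population = pop, participants = sum(eligible),
       achievers = sum(res$achiever))
}

#' Total cost of an intervention
#'
#' Participants times per-person cost, rescaled from agents to persons by the
#' agent-scale factor.
#'
#' @param participants Participant count in agents (>= 0).
#' @param spec An [intervention_spec()].
#' @param agent_scale Persons represented by one agent (default 1).
#' @return Cost in dollars.
#' @export
total_intervention_cost <- function(participants, spec, agent_scale = 1) {
  stopifnot(participants >= 0)
  participants * agent_scale * spec$per_person_cost
}
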
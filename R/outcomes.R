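# Performance measures and economics: incidence/improvement formulas, paired
# intervention-vs-control runs under common random numbers, per-individual
# diabetes-free-survival gain, and cost-effectiveness accounting.

#' Diabetes incidence rate
#'
#' New diabetes cases in a year divided by the population excluding those
#' previously diagnosed, expressed per 100.
#'
#' @param new_cases New diabetes cases in the year.
#' @param population Alive population count.
#' @param previously_diagnosed Alive individuals diagnosed in an earlier
#'   year.
#' @return Rate per 100 (vectorized).
#' @examples
#' incidence_rate(5, 1000, 200) # 0.625
#' @export
incidence_rate <- function(new_cases, population, previously_diagnosed = 0) {
  denom <- population - previously_diagnosed
  if (any(denom <= 0)) {
    stop("incidence rate undefined: at-risk denominator must be positive",
         call. = FALSE)
  }
  100 * new_cases / denom
}

#' Improvement of an intervention over no intervention
#'
#' For any per-100 performance measure, the difference is
#' `rate_no_intervention - rate_intervention` and the improvement is the
#' difference divided by the no-intervention rate, in percent.
#'
#' @param rate_no_intervention End-of-horizon rate without intervention
#'   (> 0).
#' @param rate_intervention End-of-horizon rate with intervention.
#' @return A tibble with `rate_no_intervention`, `rate_intervention`,
#'   `difference` and `improvement_pct`.
#' @examples
#' improvement(1.0, 0.97) # difference 0.03, improvement 3%
#' @export
improvement <- function(rate_no_intervention, rate_intervention) {
  if (any(rate_no_intervention <= 0)) {
    stop("improvement undefined when the no-intervention rate is zero",
         call. = FALSE)
  }
  diff <- rate_no_intervention - rate_intervention
  tibble::tibble(
    rate_no_intervention = rate_no_intervention,
    rate_intervention = rate_intervention,
    difference = diff,
    improvement_pct = 100 * diff / rate_no_intervention
  )
}

#' Paired intervention-vs-control simulation
#'
#' Builds one baseline population and simulates it twice over the same
#' horizon with the same master seed: once untouched (control) and once with
#' the intervention applied in year 0. Because every random phase draws from
#' a seed-derived substream over all row positions, the two arms share common
#' random numbers: with a null intervention they are bit-identical, and any
#' difference isolates the intervention effect individual by individual.
#'
#' @param scn A [scenario()].
#' @param spec An [intervention_spec()], or `NULL` for a control-control
#'   pair.
#' @param horizon Years to simulate.
#' @param n_agents Baseline population size in agents.
#' @param seed Master integer seed.
#' @param rebound Passed to [simulate_horizon()].
#' @return A `paired_sim` list with elements `control` and `intervention`
#'   (both `sim_result`), plus the intervention spec and run metadata.
#'   Supports `tidy()`,
#'   `glance()`, `autoplot()` and [cost_effectiveness()].
#' @export
paired_run <- function(scn, spec, horizon, n_agents, seed, rebound = FALSE) {
  pop <- build_initial_population(scn$init_dist, n_agents,
                                  seed = substream_seed(seed, 0L, "baseline"))
  control <- simulate_horizon(pop, scn, horizon, seed, intervention = NULL)
  interv <- simulate_horizon(pop, scn, horizon, seed, intervention = spec,
                             rebound = rebound)
  structure(list(control = control, intervention = interv, spec = spec,
                 horizon = horizon, seed = seed,
                 agent_scale = scn$agent_scale),
            class = "paired_sim")
}

#' Diabetes-free-survival gain between paired arms
#'
#' For each individual present in both arms, the delay in diabetes onset
#' attributable to the intervention: if both arms develop diabetes, the
#' control onset year is subtracted from the intervention onset year (so a
#' postponed onset is a positive gain); if neither develops, the delay is 0;
#' if only the control arm develops at year t, the gain is censored at
#' `horizon - t`; if only the intervention arm develops at year t, the loss
#' `-(horizon - t)` is recorded. Individuals who die before developing
#' diabetes in either arm are excluded from the mean.
#'
#' @param control_pop,intervention_pop Final population tibbles of the two
#'   arms, sharing the same id set.
#' @param horizon Simulated horizon in years.
#' @return List with `mean_gain` (years, over included individuals),
#'   `n_included`, `n_excluded`, and `gains` (per-id tibble).
#' @export
dfs_gain <- function(control_pop, intervention_pop, horizon) {
  if (!setequal(control_pop$id, intervention_pop$id)) {
    stop("paired populations must share the same id set", call. = FALSE)
  }
  ctl <- control_pop[order(control_pop$id), ]
  trt <- intervention_pop[match(ctl$id, intervention_pop$id), ]
  on_c <- ctl$diabetes_onset_year
  on_i <- trt$diabetes_onset_year
  died_before_onset <- (!ctl$alive & is.na(on_c)) | (!trt$alive & is.na(on_i))
  gain <- dplyr::case_when(
    !is.na(on_c) & !is.na(on_i) ~ as.numeric(on_i - on_c),
    !is.na(on_c) & is.na(on_i) ~ as.numeric(horizon - on_c),
    is.na(on_c) & !is.na(on_i) ~ -as.numeric(horizon - on_i),
    TRUE ~ 0
  )
  gains <- tibble::tibble(id = ctl$id, onset_control = on_c,
                          onset_intervention = on_i, gain = gain,
                          included = !died_before_onset)
  inc <- gains$gain[gains$included]
  list(mean_gain = if (length(inc) > 0) mean(inc) else NA_real_,
       n_included = length(inc), n_excluded = sum(!gains$included),
       gains = gains)
}

#' Cost-effectiveness accounting
#'
#' Aversion savings are averted diabetes cases times the per-case benefit
#' (the lifetime medical cost associated with a diabetes case, default
#' $85,200); total savings are aversion savings minus the intervention cost.
#' The identities `aversion_savings == diabetes_averted * benefit_per_case`
#' and `total_savings == aversion_savings - intervention_cost` hold exactly.
#'
#' The default method takes the already-measured quantities; the
#' `paired_sim` method computes them from a paired run, rescaling agent
#' counts to persons.
#'
#' @param x Averted diabetes case count (persons), or a `paired_sim`.
#' @param ... Passed between methods.
#' @return A one-row tibble with (at least) `diabetes_averted`,
#'   `intervention_cost`, `aversion_savings`, `total_savings`
#'   and `benefit_per_case`, all monetary values in dollars.
#' @examples
#' cost_effectiveness(258780, intervention_cost = 31074700000)
#' @export
cost_effectiveness <- function(x, ...) UseMethod("cost_effectiveness")

#' @rdname cost_effectiveness
#' @param intervention_cost Total program cost in dollars.
#' @param benefit_per_case Dollars saved per averted case (default 85200).
#' @param deaths_averted,mean_dfs_gain Optional extra measures carried
#'   through to the output.
#' @export
cost_effectiveness.default <- function(x, intervention_cost,
                                       benefit_per_case = 85200,
                                       deaths_averted = NA_real_,
                                       mean_dfs_gain = NA_real_, ...) {
  stopifnot(benefit_per_case > 0)
  aversion <- x * benefit_per_case
  tibble::tibble(
    diabetes_averted = x,
    deaths_averted = deaths_averted,
    mean_dfs_gain = mean_dfs_gain,
    intervention_cost = intervention_cost,
    aversion_savings = aversion,
    total_savings = aversion - intervention_cost,
    benefit_per_case = benefit_per_case
  )
}

#' @rdname cost_effectiveness
#' @param discount_rate Annual discount rate applied to aversion savings by
#'   the simulation year in which each case is averted (default 0, i.e.
#'   undiscounted; the intervention cost falls in year 0 and is never
#'   discounted).
#' @export
cost_effectiveness.paired_sim <- function(x, benefit_per_case = 85200,
                                          discount_rate = 0, ...) {
  scale <- x$agent_scale
  cases_c <- sum(x$control$outcomes$new_cases)
  cases_i <- sum(x$intervention$outcomes$new_cases)
  deaths_c <- sum(x$control$outcomes$deaths)
  deaths_i <- sum(x$intervention$outcomes$deaths)
  ddeaths_c <- sum(x$control$outcomes$diabetes_deaths)
  ddeaths_i <- sum(x$intervention$outcomes$diabetes_deaths)
  g <- dfs_gain(x$control$population, x$intervention$population, x$horizon)
  cost <- total_intervention_cost(x$intervention$participants, x$spec,
                                  agent_scale = scale)
  out <- cost_effectiveness.default(
    (cases_c - cases_i) * scale,
    intervention_cost = cost,
    benefit_per_case = benefit_per_case,
    deaths_averted = (deaths_c - deaths_i) * scale,
    mean_dfs_gain = g$mean_gain
  )
  if (discount_rate > 0) {
    per_year <- (x$control$outcomes$new_cases -
                   x$intervention$outcomes$new_cases) * scale
    disc <- (1 + discount_rate)^(-x$control$outcomes$year)
    out$aversion_savings <- sum(per_year * disc) * benefit_per_case
    out$total_savings <- out$aversion_savings - out$intervention_cost
  }
  out$diabetes_deaths_averted <- (ddeaths_c - ddeaths_i) * scale
  out$participants <- x$intervention$participants * scale
  out$intervention <- if (is.null(x$spec)) NA_character_ else x$spec$name
  out
}

#' Compare an intervention across candidate age bands
#'
#' Runs one paired simulation per age band (each from the same master seed)
#' and stacks the cost-effectiveness rows, ready to pick the band with
#' maximum total savings.
#'
#' @param scn A [scenario()].
#' @param preset Intervention preset name (see [intervention_preset()]) or an
#'   `intervention_spec` whose age range will be overridden per band.
#' @param bands List of length-2 age ranges (default the four bands 25-65,
#'   35-65, 45-65, 55-65).
#' @param horizon,n_agents,seed As in [paired_run()].
#' @param benefit_per_case Dollars per averted case.
#' @return Tibble with one row per band.
#' @export
compare_age_bands <- function(scn, preset,
                              bands = list(c(25, 65), c(35, 65),
                                           c(45, 65), c(55, 65)),
                              horizon = 10, n_agents = 10000, seed = 1,
                              benefit_per_case = 85200, discount_rate = 0) {
  purrr::map_dfr(bands, function(b) {
    spec <- if (inherits(preset, "intervention_spec")) {
      intervention_spec(preset$name, preset$reduction_fraction,
                        preset$achievement_rate, preset$per_person_cost,
                        age_range = b, min_bmi = preset$min_bmi,
                        underweight_floor = preset$underweight_floor)
    } else {
      intervention_preset(preset, age_range = b)
    }
    pr <- paired_run(scn, spec, horizon, n_agents, seed)
    ce <- cost_effectiveness(pr, benefit_per_case = benefit_per_case,
                             discount_rate = discount_rate)
    ce$age_band <- paste0(b[1], "-", b[2])
    dplyr::relocate(ce, "age_band")
  })
}

# --- broom-style methods and plots ----------------------------------------

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @export
tidy.sim_result <- function(x, ...) x$outcomes

#' @export
glance.sim_result <- function(x, ...) {
  last <- x$outcomes[nrow(x$outcomes), ]
  tibble::tibble(
    horizon = x$horizon,
    n_agents_final = nrow(x$population),
    n_alive_final = sum(x$population$alive),
    total_new_cases = sum(x$outcomes$new_cases),
    total_deaths = sum(x$outcomes$deaths),
    incidence_rate_final = last$incidence_rate,
    prevalence_rate_final = last$prevalence_rate,
    diabetes_mortality_rate_final = last$diabetes_mortality_rate,
    participants = x$participants,
    achievers = x$achievers
  )
}

#' @export
tidy.paired_sim <- function(x, ...) {
  dplyr::bind_rows(
    dplyr::mutate(x$control$outcomes, arm = "control"),
    dplyr::mutate(x$intervention$outcomes, arm = "intervention")
  )
}

#' @export
glance.paired_sim <- function(x, ...) cost_effectiveness(x, ...)

#' Plot per-year rates of a simulation
#'
#' @param object A `sim_result` or `paired_sim`.
#' @param ... Unused.
#' @return A ggplot of incidence, prevalence and diabetes mortality (per
#'   100) over simulation years, faceted by measure (and colored by arm for
#'   paired runs).
#' @export
autoplot.sim_result <- function(object, ...) {
  df <- tidyr::pivot_longer(
    object$outcomes,
    c("incidence_rate", "prevalence_rate", "diabetes_mortality_rate"),
    names_to = "measure", values_to = "rate")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$calendar_year, y = .data$rate)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~measure, scales = "free_y") +
    ggplot2::labs(x = "year", y = "rate per 100")
}

#' @rdname autoplot.sim_result
#' @export
autoplot.paired_sim <- function(object, ...) {
  df <- tidyr::pivot_longer(
    tidy(object),
    c("incidence_rate", "prevalence_rate", "diabetes_mortality_rate"),
    names_to = "measure", values_to = "rate")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$calendar_year, y = .data$rate,
                                   color = .data$arm)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~measure, scales = "free_y") +
    ggplot2::labs(x = "year", y = "rate per 100", color = NULL)
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @export
print.paired_sim <- function(x, ...) {
  cat(sprintf("<paired_sim> %d years, seed %d%s\n", x$horizon, x$seed,
              if (is.null(x$spec)) "" else paste0(", intervention: ",
                                                  x$spec$name)))
  print(glance(x))
  invisible(x)
}
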
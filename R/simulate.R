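# The annual-cycle engine. Each simulated year applies, in fixed order:
# (1) mortality decision, (2) intervention (first year only), (3) age
# increment + BMI drift, (4) glycemic transition, then injects that year's
# entrants. All randomness flows from one master seed through per-
# (year, phase) substreams, and uniforms are drawn for every row (dead
# included), which keeps paired runs with a shared master seed aligned
# row-for-row (common random numbers).

#' Bundle a simulation scenario
#'
#' Collects every model input the annual cycle needs: the baseline joint
#' distribution, the entry schedule, the transition matrices, the mortality
#' models and the BMI drift model, plus the agent-scale factor mapping one
#' simulated agent to a number of real persons.
#'
#' @param init_dist A [pop_distribution()] for the baseline population.
#' @param entry An [entry_schedule()].
#' @param tpms A [tpm_set()].
#' @param lt A [life_table()].
#' @param dm A [diabetic_mortality()] model.
#' @param drift A [bmi_drift()] model.
#' @param agent_scale Persons per agent (default 1).
#' @param start_year Calendar year of simulation year 0 (label only).
#' @return A `sim_scenario` object.
#' @export
scenario <- function(init_dist, entry, tpms, lt, dm, drift, agent_scale = 1,
                     start_year = 2010) {
  stopifnot(inherits(init_dist, "pop_distribution"),
            inherits(entry, "entry_schedule"), inherits(tpms, "tpm_set"),
            inherits(lt, "life_table"), inherits(dm, "diabetic_mortality"),
            inherits(drift, "bmi_drift"), agent_scale > 0)
  structure(list(init_dist = init_dist, entry = entry, tpms = tpms, lt = lt,
                 dm = dm, drift = drift, agent_scale = agent_scale,
                 start_year = start_year),
            class = "sim_scenario")
}

#' Simulate a population over a horizon
#'
#' Runs the annual cycle for `horizon` years starting from `pop`, optionally
#' applying a one-year lifestyle intervention in year 0, and records per-year
#' counts and rates. Identical inputs and seed give bit-identical results.
#'
#' @param pop Baseline population tibble (see [build_initial_population()]).
#' @param scn A [scenario()].
#' @param horizon Number of years to simulate (>= 0).
#' @param seed Master integer seed; every phase of every year derives its own
#'   substream from it.
#' @param intervention Optional [intervention_spec()] applied in year 0.
#' @param rebound If `TRUE`, the BMI removed by the intervention is restored
#'   at the start of year 1 (sensitivity analysis); the default `FALSE` lets
#'   ordinary drift act on the reduced value.
#' @return A `sim_result` list with `outcomes` (per-year tibble, see
#'   [incidence_rate()] for the rate definitions), `population` (final
#'   tibble), `participants`, `achievers` and run metadata. Supports
#'   [generics::tidy()], [generics::glance()] and [ggplot2::autoplot()].
#' @export
simulate_horizon <- function(pop, scn, horizon, seed, intervention = NULL,
                             rebound = FALSE) {
  stopifnot(inherits(scn, "sim_scenario"), horizon >= 0)
  validate_population(pop)
  p <- pop_to_internal(pop)
  participants <- 0L
  achievers <- 0L
  removed_bmi <- NULL
  years <- integer(0); n_alive_start <- integer(0); n_alive <- integer(0)
  deaths <- integer(0); dia_deaths <- integer(0); new_cases <- integer(0)
  n_dia <- integer(0); n_pre <- integer(0); at_risk <- integer(0)
  entrants <- integer(0)

  for (t in seq_len(horizon) - 1L) {
    n <- length(p$id)
    alive0 <- sum(p$alive)

    # (1) mortality
    set.seed(substream_seed(seed, t, "mortality"))
    u <- stats::runif(n)
    q <- lt_lookup(scn$lt, p$age, p$gender)
    if (any(p$ever_diabetic)) {
      ed <- p$ever_diabetic
      q[ed] <- dm_prob(scn$dm, p$age[ed], p$gender[ed], p$bmi[ed])
    }
    dies <- p$alive & u < q
    d_all <- sum(dies)
    d_dia <- sum(dies & p$ever_diabetic)
    p$alive[dies] <- FALSE
    p$death[dies] <- t

    # (2) intervention, first simulated year only
    if (!is.null(intervention) && t == 0L) {
      set.seed(substream_seed(seed, t, "intervention"))
      ui <- stats::runif(n)
      eligible <- p$alive &
        p$age >= intervention$age_range[1] &
        p$age <= intervention$age_range[2] &
        p$bmi >= intervention$min_bmi & p$glycemic == 2L
      res <- apply_intervention_bmi(p$bmi, eligible, ui, intervention)
      if (rebound) removed_bmi <- p$bmi - res$bmi
      p$bmi <- res$bmi
      participants <- sum(eligible)
      achievers <- sum(res$achiever)
    }
    if (rebound && t == 1L && !is.null(removed_bmi)) {
      p$bmi <- p$bmi + c(removed_bmi, numeric(length(p$bmi) - length(removed_bmi)))
      removed_bmi <- NULL
    }

    # (3) age increment + BMI drift
    set.seed(substream_seed(seed, t, "bmi_change"))
    u_change <- stats::runif(n)
    set.seed(substream_seed(seed, t, "bmi_magnitude"))
    z <- stats::rnorm(n)
    idx <- drift_index(p$age, p$gender)
    changes <- p$alive & u_change < scn$drift$p_change[idx]
    delta <- scn$drift$mean_change[idx] / scn$drift$p_change[idx] +
      scn$drift$sd * z
    p$age[p$alive] <- p$age[p$alive] + 1L
    p$bmi[changes] <- pmax(p$bmi[changes] + delta[changes], scn$drift$bmi_floor)

    # (4) glycemic transition
    set.seed(substream_seed(seed, t, "transition"))
    ut <- stats::runif(n)
    sid <- stratum_id(p$age, p$gender, p$bmi)
    nxt <- next_state(scn$tpms, sid, p$glycemic, ut)
    nxt[!p$alive] <- p$glycemic[!p$alive]
    incident <- p$alive & nxt == 3L & p$glycemic != 3L
    p$glycemic <- nxt
    p$onset[incident] <- t
    p$ever_diabetic[incident] <- TRUE

    # bookkeeping before entrants: rates describe the simulated cohort's year
    alive_end <- p$alive
    n_alive_end <- sum(alive_end)
    prev_diag <- sum(alive_end & !is.na(p$onset) & p$onset < t)
    years <- c(years, t)
    n_alive_start <- c(n_alive_start, alive0)
    deaths <- c(deaths, d_all)
    dia_deaths <- c(dia_deaths, d_dia)
    new_cases <- c(new_cases, sum(incident))
    n_dia <- c(n_dia, sum(alive_end & p$glycemic == 3L))
    n_pre <- c(n_pre, sum(alive_end & p$glycemic == 2L))
    at_risk <- c(at_risk, n_alive_end - prev_diag)
    n_alive <- c(n_alive, n_alive_end)

    # (5) entrants for this year
    i <- match(t, scn$entry$counts$year)
    n_new <- if (is.na(i)) 0L else as.integer(round(scn$entry$counts$count[i]))
    entrants <- c(entrants, n_new)
    if (n_new > 0L) {
      set.seed(substream_seed(seed, t, "entry"))
      attrs <- sample_from_distribution(scn$entry$dist, n_new)
      gly_int <- match(attrs$glycemic, GLYCEMIC_LEVELS)
      p$id <- c(p$id, max(p$id, 0L) + seq_len(n_new))
      p$age <- c(p$age, attrs$age)
      p$gender <- c(p$gender, match(attrs$gender, GENDER_LEVELS))
      p$bmi <- c(p$bmi, attrs$bmi)
      p$glycemic <- c(p$glycemic, gly_int)
      p$alive <- c(p$alive, rep(TRUE, n_new))
      p$ever_diabetic <- c(p$ever_diabetic, gly_int == 3L)
      p$onset <- c(p$onset, ifelse(gly_int == 3L, t - 1L, NA_integer_))
      p$death <- c(p$death, rep(NA_integer_, n_new))
      p$entry <- c(p$entry, rep(t, n_new))
    }
  }

  outcomes <- tibble::tibble(
    year = years,
    calendar_year = scn$start_year + years,
    n_alive_start = n_alive_start,
    n_alive = n_alive,
    entrants = entrants,
    deaths = deaths,
    diabetes_deaths = dia_deaths,
    new_cases = new_cases,
    at_risk = at_risk,
    prevalent_diabetes = n_dia,
    prevalent_prediabetes = n_pre,
    incidence_rate = ifelse(at_risk > 0, 100 * new_cases / at_risk, NA_real_),
    prevalence_rate = ifelse(n_alive > 0, 100 * n_dia / n_alive, NA_real_),
    diabetes_mortality_rate = ifelse(n_alive_start > 0,
                                     100 * dia_deaths / n_alive_start,
                                     NA_real_)
  )
  structure(list(outcomes = outcomes, population = pop_from_internal(p),
                 participants = participants, achievers = achievers,
                 intervention = intervention, agent_scale = scn$agent_scale,
                 horizon = horizon, seed = seed,
                 start_year = scn$start_year),
            class = "sim_result")
}

#' @export
print.sim_result <- function(x, ...) {
  cat(sprintf("<sim_result> %d years, %d agents (%d alive at end)\n",
              x$horizon, nrow(x$population), sum(x$population$alive)))
  if (!is.null(x$intervention)) {
    cat(sprintf("  intervention: %s (%d participants, %d achievers)\n",
                x$intervention$name, x$participants, x$achievers))
  }
  print(x$outcomes, n = 5)
  invisible(x)
}
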
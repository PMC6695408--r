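# Estimation of stratified glycemic transition matrices from longitudinal
# panel data, additive smoothing, and calibration of the diabetic-mortality
# baseline-hazard constant.

#' Validate a longitudinal panel
#'
#' A panel holds repeated glycemic-state observations: columns `subject_id`,
#' `visit_month` (months from baseline, strictly increasing within subject),
#' `age`, `gender`, `bmi`, `glycemic_state`.
#'
#' @param panel Data frame of visit records.
#' @return `panel` as a tibble, invisibly validated.
#' @export
validate_panel <- function(panel) {
  panel <- tibble::as_tibble(panel)
  req <- c("subject_id", "visit_month", "age", "gender", "bmi",
           "glycemic_state")
  missing_cols <- setdiff(req, names(panel))
  if (length(missing_cols) > 0) {
    stop("panel is missing columns: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  if (!all(panel$glycemic_state %in% GLYCEMIC_LEVELS)) {
    stop("`glycemic_state` must be a valid glycemic state", call. = FALSE)
  }
  if (!all(panel$gender %in% GENDER_LEVELS)) {
    stop("`gender` must be male/female", call. = FALSE)
  }
  ord <- order(panel$subject_id, panel$visit_month)
  panel <- panel[ord, ]
  same <- panel$subject_id[-1] == panel$subject_id[-nrow(panel)]
  if (any(same & diff(panel$visit_month) <= 0)) {
    stop("visit months must be strictly increasing within subject",
         call. = FALSE)
  }
  panel
}

# Consecutive-visit transition pairs whose spacing matches the target
# interval within the given relative slack.
panel_pairs <- function(panel, interval, slack) {
  panel <- validate_panel(panel)
  n <- nrow(panel)
  i <- seq_len(n - 1)
  keep <- panel$subject_id[i] == panel$subject_id[i + 1]
  gap <- panel$visit_month[i + 1] - panel$visit_month[i]
  keep <- keep & abs(gap - interval) <= slack * interval
  tibble::tibble(
    age = panel$age[i][keep],
    gender = panel$gender[i][keep],
    bmi = panel$bmi[i][keep],
    from = match(panel$glycemic_state[i], GLYCEMIC_LEVELS)[keep],
    to = match(panel$glycemic_state[i + 1], GLYCEMIC_LEVELS)[keep]
  )
}

# Transition counts aggregated to (age_group, gender_int, bmi_int, from, to).
pair_counts <- function(pairs) {
  ag <- pmin((pmax(pairs$age, 20) - 20) %/% 5, N_AGE_GROUPS - 1)
  g <- match(pairs$gender, GENDER_LEVELS)
  b <- findInterval(pairs$bmi, c(25, 30)) + 1
  lin <- 1 + ag + N_AGE_GROUPS * ((g - 1) + 2 * ((b - 1) +
           3 * ((pairs$from - 1) + 3 * (pairs$to - 1))))
  array(tabulate(lin, nbins = N_AGE_GROUPS * 2 * 3 * 3 * 3),
        dim = c(N_AGE_GROUPS, 2, 3, 3, 3))
}

#' Estimate stratified transition matrices from a panel
#'
#' Maximum-likelihood count proportions of observed state changes between
#' consecutive visits spaced one estimation interval apart (within a relative
#' slack). Counts are stratified by the covariates named in `strata`,
#' evaluated at the first visit of each pair; sparse strata are pooled
#' hierarchically (drop the BMI split first, then gender, then widen over
#' adjacent age bands) until every row has at least `min_pairs` pairs.
#' Matrices estimated at a non-annual interval are converted to annual ones
#' by a matrix power (eigendecomposition for fractional powers, with each row
#' projected back onto the probability simplex); a non-embeddable matrix
#' falls back to linear rescaling with a warning. The diabetes row is forced
#' absorbing and rows renormalized.
#'
#' @param panel Visit records (see [validate_panel()]).
#' @param interval Target spacing between paired visits, months (default 12).
#' @param slack Relative spacing tolerance (default 0.25).
#' @param strata Character subset of `c("age", "gender", "bmi")`: which
#'   covariates split the matrices. An empty vector pools everything into a
#'   single matrix replicated across strata.
#' @param min_pairs Minimum transition pairs a row needs before pooling
#'   stops (default 1).
#' @return A [tpm_set()] whose `n_pairs` column records the pairs behind each
#'   row; the pooling decisions are in `attr(, "pooling")`.
#' @export
estimate_tpms <- function(panel, interval = 12, slack = 0.25,
                          strata = c("age", "gender", "bmi"),
                          min_pairs = 1) {
  stopifnot(all(strata %in% c("age", "gender", "bmi")))
  pairs <- panel_pairs(panel, interval, slack)
  if (nrow(pairs) == 0) {
    stop("no transition pairs at spacing ", interval, " +/- ",
         round(slack * 100), "% months", call. = FALSE)
  }
  counts <- pair_counts(pairs)
  # collapse dimensions excluded from stratification up front
  if (!"bmi" %in% strata) {
    s <- apply(counts, c(1, 2, 4, 5), sum)
    for (b in 1:3) counts[, , b, , ] <- s
  }
  if (!"gender" %in% strata) {
    s <- apply(counts, c(1, 3, 4, 5), sum)
    for (g in 1:2) counts[, g, , , ] <- s
  }
  if (!"age" %in% strata) {
    s <- apply(counts, c(2, 3, 4, 5), sum)
    for (a in 1:N_AGE_GROUPS) counts[a, , , , ] <- s
  }

  grid <- tidyr::expand_grid(age_group = 0:(N_AGE_GROUPS - 1L),
                             gender = GENDER_LEVELS, bmi_cat = BMI_LEVELS,
                             from = GLYCEMIC_LEVELS)
  probs <- matrix(NA_real_, nrow(grid), 3)
  n_pairs <- numeric(nrow(grid))
  pool_level <- character(nrow(grid))
  failed <- character(0)
  for (r in seq_len(nrow(grid))) {
    a <- grid$age_group[r] + 1L
    g <- match(grid$gender[r], GENDER_LEVELS)
    b <- match(grid$bmi_cat[r], BMI_LEVELS)
    f <- match(grid$from[r], GLYCEMIC_LEVELS)
    if (f == 3L) { # absorbing row needs no data
      probs[r, ] <- c(0, 0, 1); n_pairs[r] <- sum(counts[a, g, b, 3, ])
      pool_level[r] <- "absorbing"
      next
    }
    cnt <- counts[a, g, b, f, ]
    lvl <- "stratum"
    if (sum(cnt) < min_pairs) { cnt <- apply(counts[a, g, , f, , drop = FALSE],
                                             5, sum); lvl <- "pooled_bmi" }
    if (sum(cnt) < min_pairs) { cnt <- apply(counts[a, , , f, , drop = FALSE],
                                             5, sum); lvl <- "pooled_bmi_gender" }
    w <- 0L
    while (sum(cnt) < min_pairs && w < N_AGE_GROUPS) {
      w <- w + 1L
      lo <- max(1L, a - w); hi <- min(N_AGE_GROUPS, a + w)
      cnt <- apply(counts[lo:hi, , , f, , drop = FALSE], 5, sum)
      lvl <- sprintf("pooled_age_pm%d", w)
    }
    if (sum(cnt) < min_pairs) {
      failed <- c(failed, sprintf("age_group %d, %s, %s, from %s",
                                  grid$age_group[r], grid$gender[r],
                                  grid$bmi_cat[r], grid$from[r]))
      next
    }
    probs[r, ] <- cnt / sum(cnt)
    n_pairs[r] <- sum(counts[a, g, b, f, ])
    pool_level[r] <- lvl
  }
  if (length(failed) > 0) {
    stop("no transition pairs available even after pooling for rows: ",
         paste(utils::head(failed, 6), collapse = "; "), call. = FALSE)
  }

  if (interval != 12) {
    power <- 12 / interval
    for (s in seq(1, nrow(grid), by = 3)) {
      P <- probs[s:(s + 2), ]
      P[3, ] <- c(0, 0, 1)
      probs[s:(s + 2), ] <- annualize_tpm(P, power)
    }
  }
  probs[grid$from == "diabetes", ] <- rep(c(0, 0, 1), each = sum(grid$from == "diabetes"))
  probs <- probs / rowSums(probs)

  grid$to_no_diabetes <- probs[, 1]
  grid$to_prediabetes <- probs[, 2]
  grid$to_diabetes <- probs[, 3]
  grid$n_pairs <- n_pairs
  out <- tpm_set(grid)
  attr(out, "pooling") <- tibble::tibble(
    age_group = grid$age_group, gender = grid$gender, bmi_cat = grid$bmi_cat,
    from = grid$from, level = pool_level)
  out
}

# Raise a 3x3 stochastic matrix to a (possibly fractional) power. Integer
# powers use repeated multiplication; fractional powers use the
# eigendecomposition, with rows projected back onto the probability simplex.
# Matrices without a real eigendecomposition (non-embeddable at this
# interval) fall back to linear rescaling of the generator.
annualize_tpm <- function(P, power) {
  if (abs(power - round(power)) < 1e-9 && power >= 1) {
    out <- diag(3)
    for (k in seq_len(round(power))) out <- out %*% P
    return(out)
  }
  eg <- eigen(P)
  ok <- all(abs(Im(eg$values)) < 1e-12) && all(Re(eg$values) > 1e-12) &&
    abs(det(eg$vectors)) > 1e-12
  if (ok) {
    Pa <- Re(eg$vectors %*% diag(Re(eg$values)^power) %*% solve(eg$vectors))
    Pa <- t(apply(Pa, 1, project_simplex))
  } else {
    warning("transition matrix not embeddable at this interval; ",
            "falling back to linear rescaling", call. = FALSE)
    Pa <- diag(3) + power * (P - diag(3))
    Pa <- t(apply(Pa, 1, project_simplex))
  }
  Pa
}

# Euclidean projection of a vector onto the probability simplex.
project_simplex <- function(v) {
  u <- sort(v, decreasing = TRUE)
  css <- cumsum(u)
  rho <- max(which(u + (1 - css) / seq_along(u) > 0))
  theta <- (1 - css[rho]) / rho
  pmax(v + theta, 0)
}

#' Additive (Dirichlet) smoothing of estimated transition matrices
#'
#' Adds a pseudo-count `alpha` to each cell of the transition counts behind
#' every non-absorbing row and renormalizes; `alpha = 0` returns the input
#' unchanged and `alpha -> Inf` pulls rows toward uniform. Rows with no
#' recorded pairs become uniform for any positive `alpha`. The diabetes row
#' stays absorbing.
#'
#' @param tpms A [tpm_set()] with an `n_pairs` column (as produced by
#'   [estimate_tpms()]).
#' @param alpha Pseudo-count per cell, >= 0.
#' @return A smoothed [tpm_set()].
#' @export
smooth_tpms <- function(tpms, alpha) {
  stopifnot(inherits(tpms, "tpm_set"), alpha >= 0)
  if (alpha == 0) return(tpms)
  tab <- tibble::as_tibble(tpms)
  n <- ifelse(is.na(tab$n_pairs), 0, tab$n_pairs)
  P <- as.matrix(tab[c("to_no_diabetes", "to_prediabetes", "to_diabetes")])
  sm <- (P * n + alpha) / (n + 3 * alpha)
  keep <- tab$from == "diabetes"
  sm[keep, ] <- rep(c(0, 0, 1), each = sum(keep))
  tab$to_no_diabetes <- sm[, 1]
  tab$to_prediabetes <- sm[, 2]
  tab$to_diabetes <- sm[, 3]
  tpm_set(tab)
}

#' Calibrate the diabetic-mortality baseline-hazard constant
#'
#' Finds the additive log-hazard constant `c` at which the cohort's annual
#' diabetic mortality rate matches a target, by bisection on `c` in
#' \[-10, 10\]. The rate is monotone increasing in `c` by construction of the
#' probability `1 - exp(-h0 * exp(lp + c))`. The default `"expected"` method
#' uses the deterministic expected death count (mean of individual
#' probabilities); `"simulate"` draws deaths once per evaluation under a
#' fixed seed, so repeated calls are reproducible.
#'
#' @param cohort Population tibble; only rows with `ever_diabetic` (or all
#'   rows if none are flagged) enter the rate.
#' @param dm A [diabetic_mortality()] model; its current `constant` is
#'   ignored.
#' @param target_rate Target annual diabetic mortality rate per 100, in
#'   (0, 100).
#' @param tolerance Convergence tolerance on the rate (default `1e-3`,
#'   relative when `relative = TRUE`).
#' @param relative Interpret `tolerance` relative to `target_rate`?
#' @param method `"expected"` (deterministic) or `"simulate"` (Monte Carlo).
#' @param seed Seed for the `"simulate"` method.
#' @param max_iter Bisection iteration cap (default 50).
#' @return List with `constant`, `achieved_rate`, `iterations`, `converged`,
#'   and `model` (the input model with the calibrated constant).
#' @export
calibrate_mortality_constant <- function(cohort, dm, target_rate,
                                         tolerance = 1e-3, relative = TRUE,
                                         method = c("expected", "simulate"),
                                         seed = 1, max_iter = 50) {
  method <- match.arg(method)
  stopifnot(target_rate > 0, target_rate < 100, tolerance > 0)
  sel <- if (any(cohort$ever_diabetic)) cohort$ever_diabetic else
    rep(TRUE, nrow(cohort))
  age <- cohort$age[sel]
  g <- match(cohort$gender[sel], GENDER_LEVELS)
  bmi <- cohort$bmi[sel]
  n <- length(age)
  rate_at <- function(cc) {
    p <- dm_prob(dm, age, g, bmi, constant = cc)
    if (method == "expected") return(100 * mean(p))
    set.seed(seed)
    100 * mean(stats::runif(n) < p)
  }
  lo <- -10; hi <- 10
  r_lo <- rate_at(lo); r_hi <- rate_at(hi)
  if (target_rate < r_lo || target_rate > r_hi) {
    stop(sprintf(paste0("target rate %.4f per 100 unreachable for c in ",
                        "[-10, 10] (bracket rates: %.4f at -10, %.4f at 10)"),
                 target_rate, r_lo, r_hi), call. = FALSE)
  }
  tol <- if (relative) tolerance * target_rate else tolerance
  iter <- 0L; mid <- 0; r_mid <- rate_at(mid)
  if (abs(r_mid - target_rate) > tol) {
    if (r_mid < target_rate) lo <- mid else hi <- mid
    repeat {
      iter <- iter + 1L
      mid <- (lo + hi) / 2
      r_mid <- rate_at(mid)
      if (abs(r_mid - target_rate) <= tol || iter >= max_iter) break
      if (r_mid < target_rate) lo <- mid else hi <- mid
    }
  }
  out <- dm
  out$constant <- mid
  list(constant = mid, achieved_rate = r_mid, iterations = iter,
       converged = abs(r_mid - target_rate) <= tol, model = out)
}
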
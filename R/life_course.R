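# Life-course model: disability-specific mortality, survival curves,
# (discounted, disability-adjusted) life expectancy.
#
# Conventions: annual cycles over ages 0..omega-1; deaths uniform within the
# year of age, so person-years in year a are L(a) = (l(a) + l(a+1)) / 2;
# survivorship is forced to zero at the terminal age omega; discounting and
# disability adjustment are evaluated at mid-interval, D(a) = (1+r)^-(a+0.5).

#' Disability-state mortality schedule
#'
#' The no-disability state uses the baseline schedule. The minor state uses
#' the baseline multiplied by `minor_rr` (1 in the base case; the elevated
#' minor-disability mortality sensitivity sets it above 1). The major state
#' multiplies the baseline by an age-banded relative-risk schedule. All
#' products are capped at 1.
#'
#' @param lt a [life_table()].
#' @param state `"none"`, `"minor"` or `"major"`.
#' @param rr age-banded relative risks for the major state: data.frame with
#'   `age_start`, `age_end`, `rr` covering `[0, omega)`.
#' @param minor_rr scalar mortality multiplier for the minor state.
#' @return numeric vector of annual mortality probabilities per age.
#' @export
state_mortality <- function(lt, state = c("none", "minor", "major"),
                            rr = NULL, minor_rr = 1) {
  state <- match.arg(state)
  q <- lt$q
  if (state == "minor") {
    q <- pmin(1, q * minor_rr)
  } else if (state == "major") {
    if (is.null(rr)) stop("major state requires a relative-risk schedule")
    rr_by_age <- expand_bands(rr, lt$omega, "rr")
    q <- pmin(1, q * rr_by_age)
  }
  q
}

#' Build a survival curve from an annual mortality schedule
#'
#' @param q annual mortality probabilities for ages `0..omega-1`.
#' @return a `survival_curve`: list with `age` (0..omega), survivorship `l`
#'   (with `l[omega] = 0` forced) and person-years `L` per year interval.
#' @export
build_survival <- function(q) {
  omega <- length(q)
  l <- cumprod(c(1, 1 - q))
  l[omega + 1L] <- 0  # terminal closure: nobody survives past omega
  L <- (head(l, -1L) + tail(l, -1L)) / 2
  structure(list(age = 0:omega, l = l, L = L), class = "survival_curve")
}

#' Export a survival curve to CSV
#'
#' @param curve a `survival_curve`.
#' @param path output file; columns `age`, `l`, `L` (the last interval's `L`
#'   is paired with the closing age row as `NA`-free length alignment:
#'   `L` has one fewer entry, padded with `NA` on the terminal row).
#' @return `path`, invisibly.
#' @export
write_survival_curve <- function(curve, path) {
  write.csv(
    data.frame(age = curve$age, l = curve$l, L = c(curve$L, NA)),
    path, row.names = FALSE
  )
  invisible(path)
}

# Healthy fraction H(a, state): joint adjustment for the state's disability
# weight and the age-specific background disability weight.
healthy_fraction <- function(w_state, b, rule) {
  switch(rule,
    complement_product = (1 - w_state) * (1 - b),
    literal_product = 1 - w_state * b,
    stop("unknown combination_rule: ", rule)
  )
}

state_weight <- function(weights, state) {
  switch(state, none = 0, minor = weights$w_minor, major = weights$w_major,
         stop("unknown state: ", state))
}

#' Per-person health summary for one disability state
#'
#' Computes, from a state-specific survival curve: undiscounted life
#' expectancy `le = sum(L)`; disability-free life expectancy `dfle`
#' (equal to `le` for the no-disability state, 0 for disabled states); and
#' discounted disability-adjusted life expectancy
#' `dale = sum(D(a) * L(a) * H(a))` with mid-interval discount factor
#' `D(a) = (1+r)^-(a+0.5)` and healthy fraction `H` combining the state
#' disability weight with the age-specific background weight under the
#' scenario's combination rule.
#'
#' @param curve `survival_curve` built from the matching state mortality.
#' @param weights disability weights list (`w_minor`, `w_major`,
#'   `combination_rule`).
#' @param lt the [life_table()] supplying background weights `b(a)`.
#' @param econ economic settings (`discount_rate`).
#' @param state `"none"`, `"minor"` or `"major"`.
#' @return list with `le`, `dfle`, `dale` (years).
#' @export
person_summary <- function(curve, weights, lt, econ,
                           state = c("none", "minor", "major")) {
  state <- match.arg(state)
  ages <- head(curve$age, -1L)
  D <- (1 + econ$discount_rate)^-(ages + 0.5)
  H <- healthy_fraction(state_weight(weights, state), lt$b,
                        weights$combination_rule)
  le <- sum(curve$L)
  list(
    le = le,
    dfle = if (state == "none") le else 0,
    dale = sum(D * curve$L * H)
  )
}

#' Strategy-level expectation over neonatal outcomes
#'
#' Probability-weighted average of the per-state summaries under the
#' neonatal outcome distribution; neonatal death contributes zero years to
#' all three measures.
#'
#' @param dist a `neonatal_outcomes` distribution from [evaluate_tree()].
#' @param summaries named list (`none`, `minor`, `major`) of
#'   [person_summary()] results.
#' @return list with per-infant `le`, `dfle`, `dale` (years).
#' @export
strategy_expectation <- function(dist, summaries) {
  acc <- list(le = 0, dfle = 0, dale = 0)
  for (state in c("none", "minor", "major")) {
    p <- outcome_prob(dist, state)
    s <- summaries[[state]]
    acc$le <- acc$le + p * s$le
    acc$dfle <- acc$dfle + p * s$dfle
    acc$dale <- acc$dale + p * s$dale
  }
  acc
}

# All state-level objects a scenario needs downstream: mortality schedules,
# survival curves, health summaries, discounted long-term cost per survivor.
state_profiles <- function(scenario) {
  lt <- scenario$life_table
  out <- list()
  for (state in c("none", "minor", "major")) {
    q <- state_mortality(lt, state, rr = scenario$rr_major,
                         minor_rr = scenario$minor_mortality_rr)
    curve <- build_survival(q)
    summ <- person_summary(curve, scenario$disability_weights, lt,
                           scenario$econ, state)
    cost <- if (state == "none") 0 else {
      sched <- rescale_longterm_costs(
        scenario$unit_costs$longterm_annual[[state]],
        scenario$unit_costs$longterm_multiplier
      )
      longterm_disability_cost(curve, sched, scenario$econ)
    }
    out[[state]] <- list(q = q, curve = curve, summary = summ,
                         longterm_cost = cost)
  }
  out
}
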
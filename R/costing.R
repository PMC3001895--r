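# Ingredients-based costing: initial hospitalization, rehospitalization,
# discounted long-term disability costs, and the per-infant breakdown.

#' Expected initial-hospitalization cost components per infant
#'
#' Bed-day costs mix survivor and death lengths of stay by the neonatal
#' mortality probability; the ventilated share of bed-days splits them
#' between ventilated and non-ventilated unit prices. Surfactant doses and
#' surgery probabilities apply to all live-born infants. The nosocomial
#' infection increment is `p_infection * infection_markup` times the
#' baseline initial-hospitalization cost (bed-days + surfactant + surgery).
#'
#' @param rq resource quantities (`days_surv`, `days_death`, `frac_vent`,
#'   `p_infection`, `infection_markup`, `surfactant_doses`, `p_surgery`).
#' @param uc unit costs (`vent_day`, `nonvent_day`, `surfactant_dose`,
#'   `surgery` price map).
#' @param p_mort neonatal mortality probability for the strategy.
#' @return list of US$ components: `vent`, `nonvent`, `surfactant`,
#'   `surgery`, `infection`.
#' @export
#' @examples
#' rq <- list(days_surv = 116, days_death = 16, frac_vent = 0.47,
#'            p_infection = 0.93, infection_markup = 0.11,
#'            surfactant_doses = 1,
#'            p_surgery = list(rop_laser = 0.19, vp_shunt = 0.02,
#'                             pda_ligation = 0.31, nec_surgery = 0.08))
#' uc <- list(vent_day = 83, nonvent_day = 60, surfactant_dose = 272,
#'            surgery = list(rop_laser = 714, vp_shunt = 1710,
#'                           pda_ligation = 6250, nec_surgery = 1450))
#' initial_hospitalization_cost(rq, uc, p_mort = 0.53)
initial_hospitalization_cost <- function(rq, uc, p_mort) {
  days <- (1 - p_mort) * rq$days_surv + p_mort * rq$days_death
  vent <- days * rq$frac_vent * uc$vent_day
  nonvent <- days * (1 - rq$frac_vent) * uc$nonvent_day
  surfactant <- rq$surfactant_doses * uc$surfactant_dose
  surgery_types <- names(rq$p_surgery)
  surgery <- sum(vapply(
    surgery_types,
    function(s) rq$p_surgery[[s]] * uc$surgery[[s]],
    numeric(1)
  ))
  infection <- rq$p_infection * rq$infection_markup *
    (vent + nonvent + surfactant + surgery)
  list(vent = vent, nonvent = nonvent, surfactant = surfactant,
       surgery = surgery, infection = infection)
}

#' Expected first-year rehospitalization cost per infant
#'
#' Applies only to neonatal survivors: `(1 - p_mort) * rehosp_days *
#' rehosp_day price`.
#'
#' @inheritParams initial_hospitalization_cost
#' @return US$ per live-born infant.
#' @export
rehospitalization_cost <- function(rq, uc, p_mort) {
  (1 - p_mort) * rq$rehosp_days * uc$rehosp_day
}

#' Discounted lifetime disability cost for one state
#'
#' Applies an age-banded annual cost schedule along the state's survival
#' curve with mid-interval discounting:
#' `sum(D(a) * L(a) * c(a))`, `D(a) = (1+r)^-(a+0.5)`.
#'
#' @param curve `survival_curve` for the matching disability state.
#' @param schedule data.frame `age_start`, `age_end`, `cost` (US$/person/yr)
#'   covering `[0, omega)`.
#' @param econ economic settings (`discount_rate`).
#' @return discounted US$ per person entering the state at age 0.
#' @export
longterm_disability_cost <- function(curve, schedule, econ) {
  omega <- length(curve$L)
  cost_by_age <- expand_bands(schedule, omega, "cost")
  ages <- 0:(omega - 1L)
  D <- (1 + econ$discount_rate)^-(ages + 0.5)
  sum(D * curve$L * cost_by_age)
}

#' Rescale an annual long-term cost schedule
#'
#' Multiplies every band by a constant ratio, e.g. a GDP-per-capita ratio
#' when transferring cost estimates between countries.
#'
#' @param schedule data.frame with a `cost` column.
#' @param gdp_ratio positive scale factor.
#' @return the rescaled schedule.
#' @export
rescale_longterm_costs <- function(schedule, gdp_ratio) {
  if (gdp_ratio <= 0) stop("gdp_ratio must be > 0")
  schedule$cost <- schedule$cost * gdp_ratio
  schedule
}

#' Per-infant lifetime cost breakdown for one GA group and strategy
#'
#' With intensive care the total is initial hospitalization (bed-days,
#' surfactant, surgery, infection increment) + rehospitalization +
#' probability-weighted discounted long-term disability cost. Without
#' intensive care no initial-hospitalization components accrue: only
#' survivor-weighted rehospitalization and long-term disability costs.
#'
#' @param dist `neonatal_outcomes` for this GA group and strategy.
#' @param rq,uc resource quantities and unit costs.
#' @param longterm named list (`none`, `minor`, `major`) of discounted
#'   long-term cost per survivor in that state (see [state_profiles]
#'   internals or [longterm_disability_cost()]).
#' @param strategy `"nicu"` or `"no_nicu"`.
#' @return a `cost_breakdown`: list of US$ components `vent`, `nonvent`,
#'   `surfactant`, `surgery`, `infection`, `rehosp`, `longterm`, `total`,
#'   with `total` the exact sum of the components.
#' @export
strategy_cost <- function(dist, rq, uc, longterm,
                          strategy = c("nicu", "no_nicu")) {
  strategy <- match.arg(strategy)
  p_mort <- outcome_prob(dist, "death")
  zero <- list(vent = 0, nonvent = 0, surfactant = 0, surgery = 0,
               infection = 0)
  initial <- if (strategy == "nicu") {
    initial_hospitalization_cost(rq, uc, p_mort)
  } else {
    zero
  }
  rehosp <- rehospitalization_cost(rq, uc, p_mort)
  lt_cost <- sum(vapply(
    c("none", "minor", "major"),
    function(s) outcome_prob(dist, s) * longterm[[s]],
    numeric(1)
  ))
  out <- c(initial, list(rehosp = rehosp, longterm = lt_cost))
  out$total <- sum(unlist(out))
  structure(out, class = "cost_breakdown")
}

#' Per-infant cost table across GA groups and strategies
#'
#' Mirrors the published cost table: one row per cost category and strategy,
#' one column per GA group, US$ per infant (unrounded; use
#' [write_cost_table()] for the thousands/one-decimal rendering).
#'
#' @param scenario a validated `nicu_scenario`.
#' @return data.frame with columns `strategy`, `component`, then GA labels.
#' @export
cost_table <- function(scenario) {
  profiles <- state_profiles(scenario)
  longterm <- lapply(profiles, `[[`, "longterm_cost")
  labs <- names(scenario$ga_groups)
  components <- c("vent", "nonvent", "surfactant", "surgery", "infection",
                  "rehosp", "longterm", "total")
  rows <- list()
  for (strat in c("nicu", "no_nicu")) {
    bd <- lapply(labs, function(lab) {
      g <- scenario$ga_groups[[lab]]
      dist <- evaluate_tree(g, g[[strat]])
      strategy_cost(dist, g$resources, scenario$unit_costs, longterm, strat)
    })
    for (comp in components) {
      r <- data.frame(strategy = strat, component = comp)
      r[labs] <- lapply(bd, `[[`, comp)
      rows[[length(rows) + 1L]] <- r
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Write a cost table to CSV or JSON
#'
#' CSV cells are rendered in thousands at one decimal with the `"<0.1"`
#' convention for positive sub-threshold values; JSON keeps unrounded US$.
#'
#' @param tab output of [cost_table()].
#' @param path output file.
#' @param format `"csv"` or `"json"`.
#' @return `path`, invisibly.
#' @export
write_cost_table <- function(tab, path, format = c("csv", "json")) {
  format <- match.arg(format)
  if (format == "csv") {
    num <- vapply(tab, is.numeric, TRUE)
    tab[num] <- lapply(tab[num], format_thousands)
    write.csv(tab, path, row.names = FALSE)
  } else {
    jsonlite::write_json(tab, path, dataframe = "rows", digits = NA)
  }
  invisible(path)
}
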
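# Synthetic stand-ins for the demographic inputs the model needs but that
# are not part of the published input tables: an annual background mortality
# schedule for a middle-income country (infant hump + childhood floor +
# Gompertz adult rise), age-banded background disability weights, and a
# complete example scenario bundle.

#' Specification for a synthetic annual mortality schedule
#'
#' Parametric middle-income-country shape: an elevated infant mortality
#' probability at age 0, a childhood/young-adult floor, and a Gompertz
#' (exponential-in-age) adult rise `a_g * exp(b_g * age)`, capped at 1.
#' Defaults emulate the Mexican schedule of the mid-2000s (infant mortality
#' near 18 per 1,000; life expectancy at birth in the low-to-mid 70s).
#'
#' @param infant_q mortality probability at age 0.
#' @param child_floor minimum annual mortality probability at ages >= 1.
#' @param gompertz_a,gompertz_b level and slope of the adult rise.
#' @param omega terminal age (years).
#' @param seed recorded for provenance; the schedule itself is a
#'   deterministic function of the other parameters.
#' @return list of class `synthetic_life_table_spec`.
#' @export
synthetic_life_table_spec <- function(infant_q = 0.018,
                                      child_floor = 4e-4,
                                      gompertz_a = 8e-5,
                                      gompertz_b = 0.085,
                                      omega = 100,
                                      seed = 1L) {
  spec <- list(infant_q = infant_q, child_floor = child_floor,
               gompertz_a = gompertz_a, gompertz_b = gompertz_b,
               omega = omega, seed = seed)
  stopifnot(infant_q > 0, child_floor > 0, gompertz_a > 0, gompertz_b > 0,
            omega > 0)
  structure(spec, class = "synthetic_life_table_spec")
}

#' Generate a synthetic annual mortality schedule
#'
#' `q(0) = infant_q`; for ages `a >= 1`,
#' `q(a) = max(child_floor, gompertz_a * exp(gompertz_b * a))`, capped at 1.
#' Deterministic given the spec.
#'
#' @param spec a [synthetic_life_table_spec()].
#' @return data.frame `age_start`, `age_end`, `annual_mortality_probability`
#'   with one row per year of age in `[0, omega)`.
#' @export
make_life_table <- function(spec = synthetic_life_table_spec()) {
  ages <- 0:(spec$omega - 1L)
  q <- pmax(spec$child_floor, spec$gompertz_a * exp(spec$gompertz_b * ages))
  q[1] <- spec$infant_q
  q <- pmin(1, q)
  if (any(q <= 0 | q > 1)) {
    stop("spec yields mortality probabilities outside (0, 1]")
  }
  data.frame(age_start = ages, age_end = ages + 1L,
             annual_mortality_probability = q)
}

#' Generate synthetic age-banded background disability weights
#'
#' Non-decreasing piecewise-constant weights in `[0, 0.3]` over standard
#' demographic age bands, emulating the shape of published regional
#' age-specific average disability levels: low in childhood, rising through
#' adulthood and old age.
#'
#' @param omega terminal age; the last band closes at `omega`.
#' @param zero if `TRUE`, return an all-zero schedule (useful for isolating
#'   the state disability weights).
#' @return data.frame `age_start`, `age_end`, `background_disability_weight`.
#' @export
make_background_weights <- function(omega = 100, zero = FALSE) {
  starts <- c(0, 15, 45, 60, 70, 80)
  w <- if (zero) rep(0, 6) else c(0.03, 0.08, 0.12, 0.17, 0.22, 0.27)
  data.frame(
    age_start = starts,
    age_end = c(starts[-1], omega),
    background_disability_weight = w
  )
}

# The published base-case input set (natural history, resources, unit
# costs, births). Table percentages are divided by 100 here — the single
# place where the percent-to-proportion conversion happens.
base_case_inputs <- function() {
  labs <- c("24-26 wk", "27-29 wk", "30-33 wk")
  pct <- function(x) x / 100

  strategies <- list(
    nicu = list(
      `24-26 wk` = list(p_mort = pct(53), p_minor = pct(38), p_major = pct(25)),
      `27-29 wk` = list(p_mort = pct(26), p_minor = pct(32), p_major = pct(19)),
      `30-33 wk` = list(p_mort = pct(10), p_minor = pct(12), p_major = pct(16))
    ),
    no_nicu = list(
      `24-26 wk` = list(p_mort = pct(94), p_minor = pct(46), p_major = pct(38)),
      `27-29 wk` = list(p_mort = pct(87), p_minor = pct(46), p_major = pct(38)),
      `30-33 wk` = list(p_mort = pct(55), p_minor = pct(25), p_major = pct(37))
    )
  )

  resources <- list(
    `24-26 wk` = list(
      days_surv = 116, days_death = 16, frac_vent = pct(47),
      p_infection = pct(93), infection_markup = pct(11),
      rehosp_days = 7.4, surfactant_doses = 1.0,
      p_surgery = list(rop_laser = pct(19), vp_shunt = pct(2),
                       pda_ligation = pct(31), nec_surgery = pct(8))
    ),
    `27-29 wk` = list(
      days_surv = 86, days_death = 24, frac_vent = pct(31),
      p_infection = pct(52), infection_markup = pct(11),
      rehosp_days = 4.0, surfactant_doses = 0.3,
      p_surgery = list(rop_laser = pct(2), vp_shunt = pct(1),
                       pda_ligation = pct(11), nec_surgery = pct(5))
    ),
    `30-33 wk` = list(
      days_surv = 49, days_death = 21, frac_vent = pct(17),
      p_infection = pct(41), infection_markup = pct(11),
      rehosp_days = 2.6, surfactant_doses = 0.4,
      p_surgery = list(rop_laser = pct(0.2), vp_shunt = pct(0.1),
                       pda_ligation = pct(3), nec_surgery = pct(3))
    )
  )

  list(
    labels = labs,
    births = c(4.6, 8.2, 29.1),
    strategies = strategies,
    resources = resources,
    rr_major = list(
      list(age_start = 0, age_end = 10, rr = 24.6),
      list(age_start = 10, age_end = 20, rr = 8.5),
      list(age_start = 20, age_end = 40, rr = 3.6),
      list(age_start = 40, age_end = 70, rr = 2.2),
      list(age_start = 70, age_end = 100, rr = 1.5)
    ),
    unit_costs = list(
      vent_day = 83, nonvent_day = 60, rehosp_day = 83,
      surfactant_dose = 272,
      surgery = list(rop_laser = 714, vp_shunt = 1710,
                     pda_ligation = 6250, nec_surgery = 1450),
      longterm_annual = list(
        minor = list(
          list(age_start = 0, age_end = 6, cost = 853),
          list(age_start = 6, age_end = 18, cost = 229),
          list(age_start = 18, age_end = 26, cost = 54),
          list(age_start = 26, age_end = 36, cost = 11),
          list(age_start = 36, age_end = 65, cost = 43),
          list(age_start = 65, age_end = 100, cost = 43)
        ),
        major = list(
          list(age_start = 0, age_end = 6, cost = 1893),
          list(age_start = 6, age_end = 18, cost = 670),
          list(age_start = 18, age_end = 26, cost = 491),
          list(age_start = 26, age_end = 36, cost = 955),
          list(age_start = 36, age_end = 65, cost = 1776),
          list(age_start = 65, age_end = 100, cost = 1620)
        )
      ),
      longterm_multiplier = 1
    ),
    econ = list(discount_rate = 0.03, gdp_per_capita = 8200,
                max_age = 100, base_year_currency = "2005 USD"),
    # Placeholder category weights: plausible values for the two composite
    # categories, overridable in the config; acceptance of results that
    # depend on them is property-based, not value-based.
    disability_weights = list(w_minor = 0.12, w_major = 0.40,
                              combination_rule = "complement_product")
  )
}

# Default sensitivity ranges: mortality-with-care upper bounds as published
# (0.75 / 0.51 / 0.14); unit costs halved and doubled; everything else
# +/-25% around base, clipped to legal ranges.
default_sensitivity_ranges <- function(inputs) {
  labs <- inputs$labels
  clip01 <- function(x) min(1, max(0, x))
  rng <- list()
  add <- function(path, low, high, dist = "uniform") {
    rng[[length(rng) + 1L]] <<- list(path = path, low = low, high = high,
                                     distribution = dist)
  }

  mort_high <- c(`24-26 wk` = 0.75, `27-29 wk` = 0.51, `30-33 wk` = 0.14)
  for (lab in labs) {
    st <- inputs$strategies
    add(paste0("ga_groups.", lab, ".nicu.p_mort"),
        clip01(0.75 * st$nicu[[lab]]$p_mort), mort_high[[lab]])
    add(paste0("ga_groups.", lab, ".no_nicu.p_mort"),
        clip01(0.75 * st$no_nicu[[lab]]$p_mort),
        clip01(1.25 * st$no_nicu[[lab]]$p_mort))
    for (strat in c("nicu", "no_nicu")) {
      for (f in c("p_minor", "p_major")) {
        base <- st[[strat]][[lab]][[f]]
        add(paste0("ga_groups.", lab, ".", strat, ".", f),
            clip01(0.75 * base), clip01(1.25 * base))
      }
    }
    rq <- inputs$resources[[lab]]
    for (f in c("days_surv", "days_death", "rehosp_days",
                "surfactant_doses")) {
      add(paste0("ga_groups.", lab, ".resources.", f),
          0.75 * rq[[f]], 1.25 * rq[[f]])
    }
    for (f in c("frac_vent", "p_infection", "infection_markup")) {
      add(paste0("ga_groups.", lab, ".resources.", f),
          clip01(0.75 * rq[[f]]), clip01(1.25 * rq[[f]]))
    }
  }

  uc <- inputs$unit_costs
  for (f in c("vent_day", "nonvent_day", "rehosp_day", "surfactant_dose")) {
    add(paste0("unit_costs.", f), uc[[f]] / 2, uc[[f]] * 2)
  }
  for (s in names(uc$surgery)) {
    add(paste0("unit_costs.surgery.", s), uc$surgery[[s]] / 2,
        uc$surgery[[s]] * 2)
  }
  add("unit_costs.longterm_multiplier", 0.5, 2)

  dw <- inputs$disability_weights
  add("disability_weights.w_minor", clip01(0.75 * dw$w_minor),
      clip01(1.25 * dw$w_minor))
  add("disability_weights.w_major", clip01(0.75 * dw$w_major),
      clip01(1.25 * dw$w_major))
  rng
}

#' Write a complete example scenario bundle
#'
#' Emits, into `dir`: the scenario YAML holding the published base-case
#' inputs (natural history, resources, unit costs, births), placeholder
#' disability weights, default sensitivity ranges, and paths to the two
#' synthetic CSVs (mortality schedule and background disability weights)
#' which are written alongside. The bundle passes [validate_scenario()] and
#' is byte-identical across calls with the same `seed`.
#'
#' Existing files are never silently overwritten.
#'
#' @param dir target directory (created if needed).
#' @param seed seed recorded in the synthetic life-table spec.
#' @param overwrite allow replacing existing bundle files.
#' @return path to the written YAML config, invisibly.
#' @export
make_example_config <- function(dir, seed = 1L, overwrite = FALSE) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  targets <- file.path(dir, c("scenario.yaml", "life_table.csv",
                              "background_weights.csv"))
  if (!overwrite && any(file.exists(targets))) {
    stop("refusing to overwrite existing files in ", dir,
         " (set overwrite = TRUE)")
  }

  inputs <- base_case_inputs()
  spec <- synthetic_life_table_spec(seed = seed)
  qdf <- make_life_table(spec)
  bdf <- make_background_weights(inputs$econ$max_age)

  raw <- list(
    ga_groups = lapply(seq_along(inputs$labels), function(i) {
      list(label = inputs$labels[i], births = inputs$births[i])
    }),
    strategies = inputs$strategies,
    resources = inputs$resources,
    rr_major = inputs$rr_major,
    unit_costs = inputs$unit_costs,
    econ = inputs$econ,
    disability_weights = inputs$disability_weights,
    minor_mortality_rr = 1,
    life_table_path = "life_table.csv",
    background_weights_path = "background_weights.csv",
    sensitivity_ranges = default_sensitivity_ranges(inputs)
  )

  writeLines(yaml::as.yaml(raw, precision = 15), targets[1])
  write.csv(qdf, targets[2], row.names = FALSE, quote = FALSE)
  write.csv(bdf, targets[3], row.names = FALSE, quote = FALSE)
  invisible(targets[1])
}

#' Load the example scenario directly
#'
#' Convenience wrapper: writes the example bundle to a fresh temporary
#' directory and loads it.
#'
#' @param seed passed to [make_example_config()].
#' @return a validated `nicu_scenario`.
#' @export
example_scenario <- function(seed = 1L) {
  dir <- tempfile("neocea-example-")
  cfg <- make_example_config(dir, seed = seed)
  load_scenario(cfg)
}
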
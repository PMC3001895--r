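# Scenario configuration: parsing, validation, serialization.
#
# A scenario is a plain list with class "nicu_scenario":
#   ga_groups  named list (by GA label): births (thousands), nicu / no_nicu
#              strategy parameters, resources
#   rr_major   age-banded relative risks of mortality for major disability
#   unit_costs scalar unit prices, surgery price map, long-term annual cost
#              schedules (minor/major) and a long-term cost multiplier
#   econ       discount rate, GDP per capita, terminal age omega, currency
#   disability_weights  w_minor, w_major, combination rule
#   minor_mortality_rr  optional excess-mortality multiplier for the minor
#              state (1 = base case)
#   life_table life_table object (see read_life_table)
#   sensitivity_ranges  list of (path, low, high, distribution)
#
# All probabilities and proportions are stored on the [0,1] scale. The
# printed-table percentages are divided by 100 in exactly one place
# (base_case_inputs), so configs on disk are already proportions.

PROB_FIELDS <- c(
  "p_mort", "p_minor", "p_major", "frac_vent", "p_infection",
  "infection_markup", "w_minor", "w_major"
)

# Is the addressed field a probability/proportion? Surgery probabilities are
# recognized by their parent key so that surgery *prices* (same leaf names
# under unit_costs.surgery) are left alone.
is_prob_path <- function(keys) {
  last <- keys[length(keys)]
  last %in% PROB_FIELDS ||
    (length(keys) >= 2 && keys[length(keys) - 1L] == "p_surgery")
}

#' Load and validate a scenario bundle
#'
#' Reads the YAML configuration, resolves the life-table CSV paths relative
#' to the config file, attaches the life table, and validates every model
#' invariant. Fails with a report listing all violations at once.
#'
#' @param path path to a scenario YAML file (see [make_example_config()] for
#'   the schema and a complete example).
#' @return a validated `nicu_scenario` object.
#' @seealso [validate_scenario()], [write_scenario()]
#' @export
load_scenario <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  raw <- yaml::read_yaml(path)
  base_dir <- dirname(normalizePath(path))
  scenario <- parse_scenario(raw, base_dir)
  validate_scenario(scenario)
}

# Turn the parsed YAML list into the internal scenario structure.
parse_scenario <- function(raw, base_dir = ".") {
  need <- c("ga_groups", "strategies", "resources", "rr_major", "unit_costs",
            "econ", "disability_weights", "life_table_path",
            "background_weights_path")
  missing <- setdiff(need, names(raw))
  if (length(missing)) {
    stop("config is missing top-level keys: ", paste(missing, collapse = ", "))
  }

  ga_groups <- list()
  for (g in raw$ga_groups) {
    lab <- g$label
    ga_groups[[lab]] <- list(
      label = lab,
      births = g$births,
      nicu = raw$strategies$nicu[[lab]],
      no_nicu = raw$strategies$no_nicu[[lab]],
      resources = raw$resources[[lab]]
    )
  }

  to_band_df <- function(x) {
    do.call(rbind, lapply(x, function(b) as.data.frame(b)))
  }

  uc <- raw$unit_costs
  uc$longterm_annual <- list(
    minor = to_band_df(raw$unit_costs$longterm_annual$minor),
    major = to_band_df(raw$unit_costs$longterm_annual$major)
  )
  if (is.null(uc$longterm_multiplier)) uc$longterm_multiplier <- 1

  lt_path <- file.path(base_dir, raw$life_table_path)
  bw_path <- file.path(base_dir, raw$background_weights_path)
  lt <- read_life_table(lt_path, bw_path, omega = raw$econ$max_age)

  ranges <- lapply(raw$sensitivity_ranges, function(r) {
    r$distribution <- if (is.null(r$distribution)) "uniform" else r$distribution
    r
  })

  structure(
    list(
      ga_groups = ga_groups,
      rr_major = to_band_df(raw$rr_major),
      unit_costs = uc,
      econ = raw$econ,
      disability_weights = raw$disability_weights,
      minor_mortality_rr =
        if (is.null(raw$minor_mortality_rr)) 1 else raw$minor_mortality_rr,
      life_table = lt,
      sensitivity_ranges = ranges,
      paths = list(life_table = lt_path, background_weights = bw_path)
    ),
    class = "nicu_scenario"
  )
}

#' Validate a scenario against every model invariant
#'
#' Checks probabilities, probability-pair budgets (`p_minor + p_major <= 1`),
#' non-negative resources and prices, contiguous age bands for relative
#' risks and long-term cost schedules, disability-weight ordering, economic
#' settings, life-table coverage and sensitivity-range ordering. All
#' violations are collected and reported together.
#'
#' @param scenario a `nicu_scenario` (from [parse_scenario()] internals or
#'   built in code).
#' @return the scenario, invisibly, when valid; otherwise an error of class
#'   `neocea_validation_error` whose message lists every violation with the
#'   path of the offending field.
#' @seealso [scenario_violations()] for the non-throwing variant.
#' @export
validate_scenario <- function(scenario) {
  v <- scenario_violations(scenario)
  if (length(v)) {
    msg <- paste0("invalid scenario (", length(v), " violation",
                  if (length(v) > 1) "s" else "", "):\n  - ",
                  paste(v, collapse = "\n  - "))
    cond <- structure(
      class = c("neocea_validation_error", "error", "condition"),
      list(message = msg, call = sys.call(-1), violations = v)
    )
    stop(cond)
  }
  invisible(scenario)
}

#' List scenario invariant violations without throwing
#'
#' @inheritParams validate_scenario
#' @return character vector of violation messages; `character(0)` when the
#'   scenario is valid.
#' @export
scenario_violations <- function(scenario) {
  v <- character(0)
  omega <- scenario$econ$max_age

  if (length(scenario$ga_groups) == 0) {
    v <- c(v, "ga_groups: at least one gestational-age group is required")
  }
  labs <- vapply(scenario$ga_groups, `[[`, "", "label")
  if (anyDuplicated(labs)) v <- c(v, "ga_groups: labels must be unique")

  for (g in scenario$ga_groups) {
    at <- function(f) paste0("ga_groups.", g$label, ".", f)
    if (!is_nonneg(g$births) || g$births <= 0) {
      v <- c(v, paste0(at("births"), ": births must be > 0"))
    }
    for (strat in c("nicu", "no_nicu")) {
      sp <- g[[strat]]
      if (is.null(sp)) {
        v <- c(v, paste0(at(strat), ": missing strategy parameters"))
        next
      }
      for (f in c("p_mort", "p_minor", "p_major")) {
        if (!is_prob(sp[[f]])) {
          v <- c(v, paste0(at(paste0(strat, ".", f)),
                           ": must be a probability in [0,1]"))
        }
      }
      if (is_prob(sp$p_minor) && is_prob(sp$p_major) &&
          sp$p_minor + sp$p_major > 1 + 1e-12) {
        v <- c(v, paste0(at(strat), ": p_minor + p_major <= 1 violated"))
      }
    }
    rq <- g$resources
    if (is.null(rq)) {
      v <- c(v, paste0(at("resources"), ": missing resource quantities"))
    } else {
      for (f in c("days_surv", "days_death", "rehosp_days",
                  "surfactant_doses")) {
        if (!is_nonneg(rq[[f]])) {
          v <- c(v, paste0(at(paste0("resources.", f)), ": must be >= 0"))
        }
      }
      for (f in c("frac_vent", "p_infection", "infection_markup")) {
        if (!is_prob(rq[[f]])) {
          v <- c(v, paste0(at(paste0("resources.", f)),
                           ": must be a proportion in [0,1]"))
        }
      }
      for (s in names(rq$p_surgery)) {
        if (!is_prob(rq$p_surgery[[s]])) {
          v <- c(v, paste0(at(paste0("resources.p_surgery.", s)),
                           ": must be a probability in [0,1]"))
        }
      }
    }
  }

  v <- c(v, band_violations(scenario$rr_major, omega, "rr_major"))
  if (!is.null(scenario$rr_major$rr) && any(scenario$rr_major$rr < 1)) {
    v <- c(v, "rr_major.rr: relative risks must be >= 1")
  }

  uc <- scenario$unit_costs
  for (f in c("vent_day", "nonvent_day", "rehosp_day", "surfactant_dose")) {
    if (!is_nonneg(uc[[f]])) {
      v <- c(v, paste0("unit_costs.", f, ": must be >= 0"))
    }
  }
  for (s in names(uc$surgery)) {
    if (!is_nonneg(uc$surgery[[s]])) {
      v <- c(v, paste0("unit_costs.surgery.", s, ": must be >= 0"))
    }
  }
  for (state in c("minor", "major")) {
    sched <- uc$longterm_annual[[state]]
    where <- paste0("unit_costs.longterm_annual.", state)
    v <- c(v, band_violations(sched, omega, where))
    if (!is.null(sched$cost) && any(sched$cost < 0)) {
      v <- c(v, paste0(where, ".cost: must be >= 0"))
    }
  }
  if (!is_nonneg(uc$longterm_multiplier)) {
    v <- c(v, "unit_costs.longterm_multiplier: must be >= 0")
  }

  ec <- scenario$econ
  if (!is_nonneg(ec$discount_rate)) {
    v <- c(v, "econ.discount_rate: must be >= 0")
  }
  if (!is_nonneg(ec$gdp_per_capita) || ec$gdp_per_capita <= 0) {
    v <- c(v, "econ.gdp_per_capita: must be > 0")
  }
  if (!is.numeric(omega) || length(omega) != 1L || is.na(omega) || omega <= 0) {
    v <- c(v, "econ.max_age: terminal age must be > 0")
  }

  dw <- scenario$disability_weights
  if (!is_prob(dw$w_minor) || !is_prob(dw$w_major)) {
    v <- c(v, "disability_weights: w_minor and w_major must lie in [0,1]")
  } else if (dw$w_minor > dw$w_major) {
    v <- c(v, "disability_weights: w_minor <= w_major violated")
  }
  if (!dw$combination_rule %in% c("complement_product", "literal_product")) {
    v <- c(v, "disability_weights.combination_rule: must be complement_product or literal_product")
  }
  if (!is_nonneg(scenario$minor_mortality_rr)) {
    v <- c(v, "minor_mortality_rr: must be >= 0")
  }

  lt <- scenario$life_table
  if (is.null(lt)) {
    v <- c(v, "life_table: missing")
  } else {
    if (length(lt$q) != omega || any(lt$q < 0 | lt$q > 1)) {
      v <- c(v, "life_table.q: one mortality probability in [0,1] per age in [0, omega)")
    }
    if (length(lt$b) != omega || any(lt$b < 0 | lt$b > 1)) {
      v <- c(v, "life_table.b: one background disability weight in [0,1] per age")
    }
  }

  for (r in scenario$sensitivity_ranges) {
    base <- tryCatch(get_param(scenario, r$path), error = function(e) NULL)
    if (is.null(base)) {
      v <- c(v, paste0("sensitivity_ranges.", r$path, ": path not found"))
    } else if (r$low > base + 1e-12 || r$high < base - 1e-12) {
      v <- c(v, paste0("sensitivity_ranges.", r$path,
                       ": requires low <= base <= high"))
    }
    if (!r$distribution %in% c("uniform", "triangular", "beta", "gamma")) {
      v <- c(v, paste0("sensitivity_ranges.", r$path,
                       ": unknown distribution '", r$distribution, "'"))
    }
  }

  v
}

#' Serialize a scenario bundle back to disk
#'
#' Writes the YAML config plus the two life-table CSVs into `dir`, in the
#' same schema that [load_scenario()] reads, so that a load/write/load
#' round-trip reproduces the scenario field-by-field.
#'
#' @param scenario a validated `nicu_scenario`.
#' @param dir output directory (created if needed).
#' @param name stem for the YAML file.
#' @return path to the written YAML file, invisibly.
#' @export
write_scenario <- function(scenario, dir, name = "scenario") {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  from_band_df <- function(df) {
    lapply(seq_len(nrow(df)), function(i) as.list(df[i, , drop = FALSE]))
  }
  labs <- names(scenario$ga_groups)
  raw <- list(
    ga_groups = lapply(scenario$ga_groups, function(g) {
      list(label = g$label, births = g$births)
    }),
    strategies = list(
      nicu = setNames(lapply(scenario$ga_groups, `[[`, "nicu"), labs),
      no_nicu = setNames(lapply(scenario$ga_groups, `[[`, "no_nicu"), labs)
    ),
    resources = setNames(lapply(scenario$ga_groups, `[[`, "resources"), labs),
    rr_major = from_band_df(scenario$rr_major),
    unit_costs = c(
      scenario$unit_costs[setdiff(names(scenario$unit_costs),
                                  "longterm_annual")],
      list(longterm_annual = list(
        minor = from_band_df(scenario$unit_costs$longterm_annual$minor),
        major = from_band_df(scenario$unit_costs$longterm_annual$major)
      ))
    ),
    econ = scenario$econ,
    disability_weights = scenario$disability_weights,
    minor_mortality_rr = scenario$minor_mortality_rr,
    life_table_path = "life_table.csv",
    background_weights_path = "background_weights.csv",
    sensitivity_ranges = scenario$sensitivity_ranges
  )
  raw$ga_groups <- unname(raw$ga_groups)
  yaml_path <- file.path(dir, paste0(name, ".yaml"))
  writeLines(yaml::as.yaml(raw, precision = 15), yaml_path)
  write_life_table(scenario$life_table,
                   file.path(dir, "life_table.csv"),
                   file.path(dir, "background_weights.csv"))
  invisible(yaml_path)
}

#' Frequency-weighted aggregation of disability weights
#'
#' Collapses severity-specific disability weights into a single weight for a
#' broad disability category, weighting each component by its frequency:
#' `sum(f * w) / sum(f)`.
#'
#' @param frequencies non-negative component frequencies, not all zero.
#' @param weights disability weights in `[0, 1]`, same length.
#' @return a single weight in `[0, 1]`, bounded by the range of `weights`.
#' @export
#' @examples
#' aggregate_disability_weight(c(3, 1), c(0.1, 0.5)) # 0.2
aggregate_disability_weight <- function(frequencies, weights) {
  if (length(frequencies) == 0 || length(frequencies) != length(weights)) {
    stop("frequencies and weights must be non-empty and equal length")
  }
  if (any(frequencies < 0)) stop("frequencies must be >= 0")
  if (any(weights < 0 | weights > 1)) stop("weights must lie in [0, 1]")
  total <- sum(frequencies)
  if (total == 0) stop("at least one frequency must be positive")
  sum(frequencies * weights) / total
}

#' Read a model parameter by dotted path
#'
#' Paths address the internal scenario structure, e.g.
#' `"ga_groups.24-26 wk.nicu.p_mort"`, `"unit_costs.vent_day"`,
#' `"unit_costs.surgery.pda_ligation"`, `"disability_weights.w_major"`,
#' `"minor_mortality_rr"`.
#'
#' @param scenario a `nicu_scenario`.
#' @param path dotted parameter path.
#' @return the parameter value.
#' @export
get_param <- function(scenario, path) {
  keys <- strsplit(path, ".", fixed = TRUE)[[1]]
  pluck_in(unclass(scenario), keys, path)
}

#' Set a model parameter by dotted path
#'
#' Probability-type fields are clamped to `[0, 1]`. When setting one member
#' of a morbidity pair pushes `p_minor + p_major` above 1, the untouched
#' partner is clipped down to restore the budget and a warning is issued.
#'
#' @inheritParams get_param
#' @param value new value.
#' @return the modified scenario.
#' @export
set_param <- function(scenario, path, value) {
  keys <- strsplit(path, ".", fixed = TRUE)[[1]]
  pluck_in(unclass(scenario), keys, path)  # existence check
  last <- keys[length(keys)]
  if (is_prob_path(keys)) value <- min(1, max(0, value))
  out <- assign_in(unclass(scenario), keys, value)

  if (last %in% c("p_minor", "p_major") && length(keys) >= 2) {
    partner <- if (last == "p_minor") "p_major" else "p_minor"
    parent_keys <- keys[-length(keys)]
    parent <- pluck_in(out, parent_keys, path)
    if (!is.null(parent[[partner]]) && value + parent[[partner]] > 1) {
      warning("clipping ", partner, " to keep p_minor + p_major <= 1 after setting ",
              path, call. = FALSE)
      out <- assign_in(out, c(parent_keys, partner), 1 - value)
    }
  }
  structure(out, class = "nicu_scenario")
}

#' @export
print.nicu_scenario <- function(x, ...) {
  cat("<nicu_scenario>\n")
  cat("  GA groups: ", paste(names(x$ga_groups), collapse = ", "), "\n", sep = "")
  cat("  births (thousands): ",
      paste(vapply(x$ga_groups, `[[`, 0, "births"), collapse = ", "),
      "\n", sep = "")
  cat("  omega: ", x$econ$max_age, " y; discount ",
      100 * x$econ$discount_rate, "%/y; GDP pc US$",
      x$econ$gdp_per_capita, "\n", sep = "")
  cat("  disability weights: minor ", x$disability_weights$w_minor,
      ", major ", x$disability_weights$w_major, " (",
      x$disability_weights$combination_rule, ")\n", sep = "")
  cat("  sensitivity ranges: ", length(x$sensitivity_ranges), "\n", sep = "")
  invisible(x)
}
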
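# Incremental cost-effectiveness analysis.

#' Incremental cost-effectiveness ratio with dominance handling
#'
#' @param delta_cost incremental cost (US$ per infant), intervention minus
#'   comparator.
#' @param dalys_averted incremental effect (DALYs averted per infant).
#' @return an `icer` object: list with `status` (`"ratio"`, `"dominant"`,
#'   `"dominated"` or `"undefined"`) and `value` (US$/DALY; `NA` when the
#'   effect difference is zero or the intervention is dominated).
#'   `"dominant"` means lower cost and greater effect; its (negative) ratio
#'   is retained in `value` for completeness.
#' @export
#' @examples
#' icer(100, 4)    # ratio 25
#' icer(-10, 2)    # dominant
#' icer(50, 0)     # undefined
icer <- function(delta_cost, dalys_averted) {
  stopifnot(is.finite(delta_cost), is.finite(dalys_averted))
  if (dalys_averted == 0) {
    res <- list(status = "undefined", value = NA_real_)
  } else if (dalys_averted > 0 && delta_cost < 0) {
    res <- list(status = "dominant", value = delta_cost / dalys_averted)
  } else if (dalys_averted < 0 && delta_cost >= 0) {
    res <- list(status = "dominated", value = NA_real_)
  } else {
    res <- list(status = "ratio", value = delta_cost / dalys_averted)
  }
  structure(res, class = "icer")
}

#' @export
print.icer <- function(x, ...) {
  if (x$status == "ratio") {
    cat("ICER:", format(signif(x$value, 4), big.mark = ","), "US$/DALY\n")
  } else {
    cat("ICER:", x$status, "\n")
  }
  invisible(x)
}

#' Classify an ICER against GDP-per-capita thresholds
#'
#' Interventions with ratios strictly below one GDP per capita are `highly
#' cost-effective`; between one and three times GDP per capita (inclusive)
#' `potentially cost-effective`; above three times, `not cost-effective`.
#' Dominant results classify as `dominant`; undefined or dominated results
#' as `not cost-effective`.
#'
#' @param x an [icer()] result or a plain ratio (US$/DALY).
#' @param econ economic settings with `gdp_per_capita`.
#' @return one of `"dominant"`, `"highly cost-effective"`,
#'   `"potentially cost-effective"`, `"not cost-effective"`.
#' @export
classify_icer <- function(x, econ) {
  gdp <- econ$gdp_per_capita
  stopifnot(gdp > 0)
  if (inherits(x, "icer")) {
    if (x$status == "dominant") return("dominant")
    if (x$status %in% c("undefined", "dominated")) return("not cost-effective")
    x <- x$value
  }
  if (x < gdp) {
    "highly cost-effective"
  } else if (x <= 3 * gdp) {
    "potentially cost-effective"
  } else {
    "not cost-effective"
  }
}

# Run the full pipeline once: per-GA, per-strategy outcome distributions,
# expectations and costs, plus incremental results. The workhorse behind
# base_case_report(), tornado() and run_psa().
evaluate_scenario <- function(scenario) {
  profiles <- state_profiles(scenario)
  summaries <- lapply(profiles, `[[`, "summary")
  longterm <- lapply(profiles, `[[`, "longterm_cost")

  per_ga <- lapply(scenario$ga_groups, function(g) {
    res <- lapply(c(nicu = "nicu", no_nicu = "no_nicu"), function(strat) {
      dist <- evaluate_tree(g, g[[strat]])
      list(
        dist = dist,
        expectation = strategy_expectation(dist, summaries),
        cost = strategy_cost(dist, g$resources, scenario$unit_costs,
                             longterm, strat)
      )
    })
    delta_cost <- res$nicu$cost$total - res$no_nicu$cost$total
    dalys <- res$nicu$expectation$dale - res$no_nicu$expectation$dale
    ic <- icer(delta_cost, dalys)
    res$cea <- list(
      delta_le = res$nicu$expectation$le - res$no_nicu$expectation$le,
      delta_dfle = res$nicu$expectation$dfle - res$no_nicu$expectation$dfle,
      dalys_averted = dalys,
      delta_cost = delta_cost,
      icer = ic,
      classification = classify_icer(ic, scenario$econ)
    )
    res
  })
  list(profiles = profiles, per_ga = per_ga)
}

#' Base-case incremental results per GA group
#'
#' Runs the complete pipeline and reports, per GA group, the per-infant
#' changes attributable to neonatal intensive care: undiscounted LE and
#' DFLE, discounted DALYs averted, discounted incremental cost, the ICER
#' and its GDP-threshold classification.
#'
#' @param scenario a validated `nicu_scenario`.
#' @return data.frame with one row per GA group and columns `ga`,
#'   `delta_le`, `delta_dfle`, `dalys_averted`, `delta_cost`, `icer`
#'   (unrounded US$/DALY, `NA` when undefined), `icer_status`,
#'   `classification`.
#' @export
base_case_report <- function(scenario) {
  ev <- evaluate_scenario(scenario)
  rows <- lapply(names(ev$per_ga), function(lab) {
    cea <- ev$per_ga[[lab]]$cea
    data.frame(
      ga = lab,
      delta_le = cea$delta_le,
      delta_dfle = cea$delta_dfle,
      dalys_averted = cea$dalys_averted,
      delta_cost = cea$delta_cost,
      icer = cea$icer$value,
      icer_status = cea$icer$status,
      classification = cea$classification
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Write an incremental-results table to CSV or JSON
#'
#' CSV output applies display rounding (years to whole numbers, costs to the
#' nearest hundred US$, ICERs to two significant figures, mirroring the
#' published presentation); JSON keeps unrounded values.
#'
#' @param tab output of [base_case_report()].
#' @param path output file.
#' @param format `"csv"` or `"json"`.
#' @return `path`, invisibly.
#' @export
write_cea_table <- function(tab, path, format = c("csv", "json")) {
  format <- match.arg(format)
  if (format == "csv") {
    disp <- tab
    disp$delta_le <- round(disp$delta_le)
    disp$delta_dfle <- round(disp$delta_dfle)
    disp$dalys_averted <- round(disp$dalys_averted)
    disp$delta_cost <- round(disp$delta_cost / 100) * 100
    disp$icer <- signif(disp$icer, 2)
    write.csv(disp, path, row.names = FALSE)
  } else {
    jsonlite::write_json(tab, path, dataframe = "rows", digits = NA)
  }
  invisible(path)
}
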
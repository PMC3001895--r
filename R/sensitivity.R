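# Sensitivity machinery: one-way (tornado) analysis, cumulative
# bias-against-intervention presets, Monte Carlo PSA, CEACs.

ga_icer_value <- function(scenario, ga) {
  ev <- evaluate_scenario(scenario)
  if (!ga %in% names(ev$per_ga)) stop("unknown GA group: ", ga)
  ev$per_ga[[ga]]$cea$icer$value
}

#' One-way (tornado) sensitivity analysis
#'
#' Substitutes each ranged parameter one at a time — all others held at base
#' — at its low and high bound, and records the resulting ICER for the
#' requested GA group. Rows are ordered by decreasing ICER spread.
#'
#' @param scenario a validated `nicu_scenario`.
#' @param ga GA-group label.
#' @param ranges list of ranges (`path`, `low`, `high`); defaults to the
#'   scenario's `sensitivity_ranges`.
#' @return data.frame `path`, `low`, `high`, `icer_low`, `icer_high`,
#'   `spread`, sorted by `spread` descending (`NA` spreads last).
#' @export
tornado <- function(scenario, ga, ranges = scenario$sensitivity_ranges) {
  if (length(ranges) == 0) stop("at least one parameter range is required")
  rows <- lapply(ranges, function(r) {
    lo <- ga_icer_value(set_param(scenario, r$path, r$low), ga)
    hi <- ga_icer_value(set_param(scenario, r$path, r$high), ga)
    data.frame(path = r$path, low = r$low, high = r$high,
               icer_low = lo, icer_high = hi,
               spread = abs(hi - lo))
  })
  out <- do.call(rbind, rows)
  out <- out[order(-out$spread, na.last = TRUE), ]
  rownames(out) <- NULL
  out
}

#' Bias-against-intervention scenario presets
#'
#' Three cumulative presets, each including the previous:
#' \describe{
#'   \item{`no_morbidity_benefit`}{intensive care confers survival benefit
#'     only: its minor/major disability probabilities are raised to the
#'     no-care values in every GA group.}
#'   \item{`plus_high_mortality`}{additionally raises the with-care neonatal
#'     mortality probabilities to the upper bounds of their sensitivity
#'     ranges.}
#'   \item{`plus_double_costs`}{additionally doubles every unit cost
#'     (bed-days, surfactant, surgeries, rehospitalization, long-term
#'     schedules); resource quantities are unchanged.}
#' }
#'
#' @param name preset name.
#' @param scenario the base `nicu_scenario`.
#' @return the modified scenario.
#' @export
scenario_preset <- function(name = c("no_morbidity_benefit",
                                     "plus_high_mortality",
                                     "plus_double_costs"),
                            scenario) {
  name <- match.arg(name)
  out <- scenario

  # stage 1: no morbidity benefit
  for (lab in names(out$ga_groups)) {
    g <- out$ga_groups[[lab]]
    out$ga_groups[[lab]]$nicu$p_minor <- g$no_nicu$p_minor
    out$ga_groups[[lab]]$nicu$p_major <- g$no_nicu$p_major
  }
  if (name == "no_morbidity_benefit") return(out)

  # stage 2: + mortality at the upper bound of its range
  for (lab in names(out$ga_groups)) {
    path <- paste0("ga_groups.", lab, ".nicu.p_mort")
    hit <- Filter(function(r) r$path == path, out$sensitivity_ranges)
    if (length(hit) == 0) {
      stop("preset '", name, "' needs a sensitivity range for ", path)
    }
    out$ga_groups[[lab]]$nicu$p_mort <- hit[[1]]$high
  }
  if (name == "plus_high_mortality") return(out)

  # stage 3: + all unit costs doubled
  uc <- out$unit_costs
  for (f in c("vent_day", "nonvent_day", "rehosp_day", "surfactant_dose")) {
    uc[[f]] <- uc[[f]] * 2
  }
  uc$surgery <- lapply(uc$surgery, `*`, 2)
  uc$longterm_annual <- lapply(uc$longterm_annual, rescale_longterm_costs, 2)
  out$unit_costs <- uc
  out
}

# One random draw from a parameter's range. `base` anchors the triangular
# mode and the beta/gamma means.
sample_range <- function(r, base) {
  lo <- r$low
  hi <- r$high
  if (hi <= lo) return(lo)
  switch(r$distribution,
    uniform = runif(1, lo, hi),
    triangular = {
      # inverse-CDF draw, mode at the base-case value
      m <- min(max(base, lo), hi)
      u <- runif(1)
      fc <- (m - lo) / (hi - lo)
      if (u < fc) lo + sqrt(u * (hi - lo) * (m - lo))
      else hi - sqrt((1 - u) * (hi - lo) * (hi - m))
    },
    beta = {
      # beta on [lo, hi], mean at base, fixed concentration
      m <- (min(max(base, lo), hi) - lo) / (hi - lo)
      m <- min(max(m, 1e-6), 1 - 1e-6)
      conc <- 4
      lo + (hi - lo) * rbeta(1, m * conc, (1 - m) * conc)
    },
    gamma = {
      # mean at base, (lo, hi) read as an approximate 95% interval
      mu <- max(base, 1e-12)
      sd <- (hi - lo) / (2 * 1.96)
      if (sd <= 0) return(mu)
      shape <- (mu / sd)^2
      rgamma(1, shape = shape, rate = shape / mu)
    },
    stop("unknown distribution: ", r$distribution)
  )
}

#' Monte Carlo probabilistic sensitivity analysis
#'
#' For each of `n` draws, samples every ranged parameter independently from
#' its distribution, re-runs the full pipeline, and records the incremental
#' cost and DALYs averted for every GA group. Deterministic given `seed`.
#'
#' @param scenario a validated `nicu_scenario`.
#' @param n number of draws (`>= 1`).
#' @param seed RNG seed (required for reproducibility).
#' @param ranges parameter ranges; defaults to the scenario's
#'   `sensitivity_ranges`.
#' @return a `psa_result`: list with `draws` (data.frame `draw`, `ga`,
#'   `delta_cost`, `dalys_averted`), `n`, `seed`.
#' @export
run_psa <- function(scenario, n, seed, ranges = scenario$sensitivity_ranges) {
  if (n < 1) stop("n must be >= 1")
  if (missing(seed) || is.null(seed)) stop("a seed is required for the PSA")
  bases <- lapply(ranges, function(r) get_param(scenario, r$path))
  labs <- names(scenario$ga_groups)

  draws <- with_seed(seed, {
    out <- vector("list", n)
    for (i in seq_len(n)) {
      scen_i <- scenario
      for (j in seq_along(ranges)) {
        val <- sample_range(ranges[[j]], bases[[j]])
        scen_i <- suppressWarnings(set_param(scen_i, ranges[[j]]$path, val))
      }
      ev <- evaluate_scenario(scen_i)
      out[[i]] <- data.frame(
        draw = i,
        ga = labs,
        delta_cost = vapply(labs, function(l) ev$per_ga[[l]]$cea$delta_cost,
                            numeric(1)),
        dalys_averted = vapply(labs,
                               function(l) ev$per_ga[[l]]$cea$dalys_averted,
                               numeric(1))
      )
    }
    do.call(rbind, out)
  })
  rownames(draws) <- NULL
  structure(list(draws = draws, n = n, seed = seed), class = "psa_result")
}

#' @export
print.psa_result <- function(x, ...) {
  cat("<psa_result>", x$n, "draws, seed", x$seed, "\n")
  print(aggregate(cbind(delta_cost, dalys_averted) ~ ga, data = x$draws, mean))
  invisible(x)
}

#' Cost-effectiveness acceptability curves
#'
#' For each willingness-to-pay value `lambda`, the probability that the
#' intervention is cost-effective is estimated as the fraction of PSA draws
#' with positive net monetary benefit,
#' `lambda * dalys_averted - delta_cost > 0`.
#'
#' @param psa a [run_psa()] result.
#' @param lambda_grid non-negative willingness-to-pay values (US$/DALY).
#' @return data.frame `ga`, `lambda`, `p_ce`.
#' @export
ceac <- function(psa, lambda_grid) {
  if (length(lambda_grid) == 0) stop("lambda grid must be non-empty")
  if (any(lambda_grid < 0)) stop("lambda values must be >= 0")
  draws <- psa$draws
  rows <- list()
  for (lab in unique(draws$ga)) {
    d <- draws[draws$ga == lab, ]
    p <- vapply(lambda_grid, function(lam) {
      mean(lam * d$dalys_averted - d$delta_cost > 0)
    }, numeric(1))
    rows[[lab]] <- data.frame(ga = lab, lambda = lambda_grid, p_ce = p)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Default willingness-to-pay grid
#'
#' 0 to three times GDP per capita in steps of `step` (default 100 US$).
#'
#' @param econ economic settings with `gdp_per_capita`.
#' @param step grid step (US$/DALY).
#' @return numeric vector.
#' @export
default_lambda_grid <- function(econ, step = 100) {
  seq(0, 3 * econ$gdp_per_capita, by = step)
}
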
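degenerate_ranges <- function(scen, paths) {
  lapply(paths, function(p) {
    b <- get_param(scen, p)
    list(path = p, low = b, high = b, distribution = "uniform")
  })
}

test_that("tornado with degenerate ranges reproduces the base-case ICER", {
  scen <- the_scenario()
  base <- base_case_report(scen)
  base_icer <- base$icer[base$ga == "24-26 wk"]
  paths <- c("unit_costs.vent_day", "ga_groups.24-26 wk.nicu.p_mort",
             "disability_weights.w_major", "unit_costs.longterm_multiplier")
  tab <- tornado(scen, "24-26 wk", degenerate_ranges(scen, paths))
  expect_equal(tab$icer_low, rep(base_icer, 4), tolerance = 1e-12)
  expect_equal(tab$icer_high, rep(base_icer, 4), tolerance = 1e-12)
  expect_true(all(tab$spread == 0))
})

test_that("tornado is ordered by spread and rejects unknown paths", {
  scen <- the_scenario()
  tab <- tornado(scen, "30-33 wk")
  expect_true(all(diff(tab$spread) <= 0))
  expect_error(
    tornado(scen, "30-33 wk",
            list(list(path = "unit_costs.nope", low = 0, high = 1,
                      distribution = "uniform"))),
    "not found"
  )
  expect_error(tornado(scen, "36-40 wk"), "unknown GA group")
})

test_that("doubling the ventilated bed-day price raises every ICER", {
  scen <- the_scenario()
  base <- base_case_report(scen)
  doubled <- base_case_report(
    set_param(scen, "unit_costs.vent_day",
              2 * get_param(scen, "unit_costs.vent_day"))
  )
  expect_true(all(doubled$icer > base$icer))
})

test_that("scenario presets are cumulative and set the published bounds", {
  scen <- the_scenario()

  s1 <- scenario_preset("no_morbidity_benefit", scen)
  for (lab in names(scen$ga_groups)) {
    expect_equal(s1$ga_groups[[lab]]$nicu$p_minor,
                 scen$ga_groups[[lab]]$no_nicu$p_minor)
    expect_equal(s1$ga_groups[[lab]]$nicu$p_major,
                 scen$ga_groups[[lab]]$no_nicu$p_major)
    expect_equal(s1$ga_groups[[lab]]$nicu$p_mort,
                 scen$ga_groups[[lab]]$nicu$p_mort)
  }

  s2 <- scenario_preset("plus_high_mortality", scen)
  expect_equal(s2$ga_groups[["24-26 wk"]]$nicu$p_mort, 0.75)
  expect_equal(s2$ga_groups[["27-29 wk"]]$nicu$p_mort, 0.51)
  expect_equal(s2$ga_groups[["30-33 wk"]]$nicu$p_mort, 0.14)
  expect_equal(s2$ga_groups[["24-26 wk"]]$nicu$p_minor,
               s1$ga_groups[["24-26 wk"]]$nicu$p_minor)

  s3 <- scenario_preset("plus_double_costs", scen)
  expect_equal(s3$unit_costs$vent_day, 2 * scen$unit_costs$vent_day)
  expect_equal(s3$unit_costs$surgery$pda_ligation,
               2 * scen$unit_costs$surgery$pda_ligation)
  expect_equal(s3$unit_costs$longterm_annual$major$cost,
               2 * scen$unit_costs$longterm_annual$major$cost)
  expect_equal(s3$ga_groups[["27-29 wk"]]$nicu$p_mort, 0.51)
})

test_that("each cumulative preset weakly increases the ICER", {
  scen <- the_scenario()
  icers <- function(s) base_case_report(s)$icer
  seq_icers <- rbind(
    icers(scen),
    icers(scenario_preset("no_morbidity_benefit", scen)),
    icers(scenario_preset("plus_high_mortality", scen)),
    icers(scenario_preset("plus_double_costs", scen))
  )
  expect_true(all(diff(seq_icers) >= 0))
})

test_that("the PSA is reproducible and collapses to base at degenerate ranges", {
  scen <- the_scenario()
  base <- base_case_report(scen)

  dr <- degenerate_ranges(scen, c("unit_costs.vent_day",
                                  "ga_groups.30-33 wk.nicu.p_mort"))
  one <- run_psa(scen, n = 1, seed = 5, ranges = dr)
  expect_equal(one$draws$delta_cost, base$delta_cost, tolerance = 1e-9)
  expect_equal(one$draws$dalys_averted, base$dalys_averted, tolerance = 1e-9)

  p1 <- run_psa(scen, n = 25, seed = 11)
  p2 <- run_psa(scen, n = 25, seed = 11)
  expect_identical(p1$draws, p2$draws)
  p3 <- run_psa(scen, n = 25, seed = 12)
  expect_false(identical(p1$draws, p3$draws))
  expect_error(run_psa(scen, n = 0, seed = 1), ">= 1")
  expect_error(run_psa(scen, n = 5), "seed")
})

test_that("symmetric uniform ranges keep the PSA mean near the base case", {
  scen <- the_scenario()
  # symmetric +/-25% ranges on near-linear inputs
  paths <- c("ga_groups.30-33 wk.resources.days_surv",
             "ga_groups.30-33 wk.resources.rehosp_days",
             "ga_groups.30-33 wk.nicu.p_minor",
             "ga_groups.30-33 wk.nicu.p_major")
  ranges <- lapply(paths, function(p) {
    b <- get_param(scen, p)
    list(path = p, low = 0.75 * b, high = 1.25 * b,
         distribution = "uniform")
  })
  psa <- run_psa(scen, n = 400, seed = 17, ranges = ranges)
  d <- psa$draws[psa$draws$ga == "30-33 wk", ]
  base <- base_case_report(scen)
  base_de <- base$dalys_averted[base$ga == "30-33 wk"]
  se <- sd(d$dalys_averted) / sqrt(nrow(d))
  expect_lt(abs(mean(d$dalys_averted) - base_de), 3 * se + 1e-9)
})

test_that("triangular, beta and gamma draws stay inside sensible ranges", {
  scen <- the_scenario()
  for (dist in c("triangular", "beta")) {
    r <- list(path = "unit_costs.vent_day", low = 40, high = 170,
              distribution = dist)
    psa <- run_psa(scen, n = 40, seed = 23, ranges = list(r))
    expect_true(all(is.finite(psa$draws$delta_cost)))
  }
  rg <- list(path = "unit_costs.vent_day", low = 41.5, high = 166,
             distribution = "gamma")
  expect_s3_class(run_psa(scen, n = 10, seed = 29, ranges = list(rg)),
                  "psa_result")
  bad <- list(path = "unit_costs.vent_day", low = 40, high = 170,
              distribution = "cauchy")
  expect_error(run_psa(scen, n = 2, seed = 3, ranges = list(bad)),
               "unknown distribution")
})

test_that("CEACs are probabilities, respect the definition at lambda = 0, and rise to 1", {
  scen <- the_scenario()
  psa <- run_psa(scen, n = 150, seed = 41)
  grid <- c(0, 500, 1000, 5000, 8200, 5e5)
  cc <- ceac(psa, grid)
  expect_true(all(cc$p_ce >= 0 & cc$p_ce <= 1))

  for (lab in unique(cc$ga)) {
    d <- psa$draws[psa$draws$ga == lab, ]
    expect_equal(cc$p_ce[cc$ga == lab & cc$lambda == 0],
                 mean(d$delta_cost < 0))
    if (all(d$dalys_averted >= 0)) {
      expect_true(all(diff(cc$p_ce[cc$ga == lab]) >= 0))
    }
    if (all(d$dalys_averted > 0)) {
      expect_equal(cc$p_ce[cc$ga == lab & cc$lambda == 5e5], 1)
    }
  }
  expect_error(ceac(psa, numeric(0)), "non-empty")
  expect_error(ceac(psa, c(-1, 10)), ">= 0")
})
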
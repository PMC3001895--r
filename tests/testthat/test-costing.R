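base_rq <- function(lab) the_scenario()$ga_groups[[lab]]$resources
base_uc <- function() the_scenario()$unit_costs

test_that("initial hospitalization components reproduce the printed cells", {
  uc <- base_uc()
  # 24-26 wk with care: survivor/death bed-day mixture at p_mort = 0.53
  c24 <- initial_hospitalization_cost(base_rq("24-26 wk"), uc, 0.53)
  expect_equal(round(c24$vent / 1000, 1), 2.5)
  expect_equal(round(c24$nonvent / 1000, 1), 2.0)
  expect_equal(round(c24$surfactant / 1000, 1), 0.3)
  expect_equal(round(c24$surgery / 1000, 1), 2.2)
  expect_equal(round(c24$infection / 1000, 1), 0.7)

  # 27-29 wk ventilated cell from first principles
  c27 <- initial_hospitalization_cost(base_rq("27-29 wk"), uc, 0.26)
  expect_equal(c27$vent, 0.74 * (86 * 0.31 * 83) + 0.26 * (24 * 0.31 * 83))
  expect_equal(round(c27$vent / 1000, 1), 1.8)

  c30 <- initial_hospitalization_cost(base_rq("30-33 wk"), uc, 0.10)
  expect_equal(round(c30$vent / 1000, 1), 0.7)
  expect_equal(round(c30$nonvent / 1000, 1), 2.3)

  # zero prices give zero components
  uc0 <- modifyList(uc, list(vent_day = 0, nonvent_day = 0,
                             surfactant_dose = 0,
                             surgery = lapply(uc$surgery, function(x) 0)))
  z <- initial_hospitalization_cost(base_rq("24-26 wk"), uc0, 0.53)
  expect_true(all(unlist(z) == 0))
})

test_that("rehospitalization accrues to survivors only", {
  uc <- base_uc()
  expect_equal(rehospitalization_cost(base_rq("24-26 wk"), uc, 0.53),
               0.47 * 7.4 * 83)
  expect_equal(rehospitalization_cost(base_rq("24-26 wk"), uc, 1), 0)
  # 30-33 wk without care: 0.45 * 2.6 * 83 ~ 97 US$, printed as 0.1 thousand
  r <- rehospitalization_cost(base_rq("30-33 wk"), uc, 0.55)
  expect_equal(r, 0.45 * 2.6 * 83)
  expect_equal(format_thousands(r), "0.1")
})

test_that("long-term cost closed forms and rescaling hold", {
  omega <- 30
  curve <- build_survival(rep(0, omega))
  econ0 <- list(discount_rate = 0)

  zero_sched <- one_band(omega, 0, "cost")
  expect_equal(longterm_disability_cost(curve, zero_sched, econ0), 0)

  # undiscounted constant schedule on an immortal cohort: k * (omega - 0.5)
  k_sched <- one_band(omega, 120, "cost")
  expect_equal(longterm_disability_cost(curve, k_sched, econ0),
               120 * (omega - 0.5))

  expect_equal(rescale_longterm_costs(k_sched, 1)$cost, k_sched$cost)
  expect_equal(rescale_longterm_costs(one_band(10, 100, "cost"), 0.5)$cost[1],
               50)
  expect_error(rescale_longterm_costs(k_sched, 0), "> 0")

  # discounting strictly reduces a positive schedule's cost
  scen <- the_scenario()
  major_curve <- build_survival(
    state_mortality(scen$life_table, "major", scen$rr_major)
  )
  sched <- scen$unit_costs$longterm_annual$major
  c_r <- longterm_disability_cost(major_curve, sched,
                                  list(discount_rate = 0.03))
  c_0 <- longterm_disability_cost(major_curve, sched, econ0)
  expect_lt(c_r, c_0)

  # matches the brute-force direct summation
  q_major <- state_mortality(scen$life_table, "major", scen$rr_major)
  cost_by_age <- neocea:::expand_bands(sched, scen$econ$max_age, "cost")
  expect_equal(c_r, brute_longterm_cost(q_major, cost_by_age, 0.03),
               tolerance = 1e-9)
})

test_that("the cost table reproduces every printed with-care component cell", {
  tab <- cost_table(the_scenario())
  cell <- function(strat, comp, lab) {
    round(tab[tab$strategy == strat & tab$component == comp, lab] / 1000, 1)
  }
  printed <- list(
    vent = c(2.5, 1.8, 0.7), nonvent = c(2.0, 2.9, 2.3),
    surfactant = c(0.3, 0.1, 0.1), surgery = c(2.2, 0.8, 0.2),
    infection = c(0.7, 0.3, 0.1), rehosp = c(0.3, 0.2, 0.2)
  )
  for (comp in names(printed)) {
    got <- vapply(GA_LABELS, function(l) cell("nicu", comp, l), numeric(1))
    expect_equal(unname(got), printed[[comp]], info = comp)
  }
})

test_that("without intensive care only rehospitalization and long-term costs accrue", {
  scen <- the_scenario()
  tab <- cost_table(scen)
  nn <- tab[tab$strategy == "no_nicu", ]
  for (comp in c("vent", "nonvent", "surfactant", "surgery", "infection")) {
    expect_true(all(nn[nn$component == comp, GA_LABELS] == 0))
  }
  rehosp <- unlist(nn[nn$component == "rehosp", GA_LABELS])
  expect_equal(unname(format_thousands(rehosp)), c("<0.1", "<0.1", "0.1"))

  # the with-care 24-26 wk initial-care subtotal
  w <- tab[tab$strategy == "nicu", ]
  subtotal <- sum(vapply(
    c("vent", "nonvent", "surfactant", "surgery", "infection", "rehosp"),
    function(comp) w[w$component == comp, "24-26 wk"], numeric(1)
  ))
  expect_equal(round(subtotal / 1000, 2), 7.96)
})

test_that("totals are additive and scale linearly with unit costs", {
  scen <- the_scenario()
  tab <- cost_table(scen)
  for (strat in c("nicu", "no_nicu")) {
    for (lab in GA_LABELS) {
      s <- tab[tab$strategy == strat, ]
      expect_lt(abs(s[s$component == "total", lab] -
                      sum(s[s$component != "total", lab])), 1e-6)
    }
  }

  # currency homogeneity: scaling every unit price by k scales all costs by k
  k <- 3.7
  scen_k <- scen
  uc <- scen$unit_costs
  for (f in c("vent_day", "nonvent_day", "rehosp_day", "surfactant_dose")) {
    scen_k$unit_costs[[f]] <- uc[[f]] * k
  }
  scen_k$unit_costs$surgery <- lapply(uc$surgery, `*`, k)
  scen_k$unit_costs$longterm_annual <-
    lapply(uc$longterm_annual, rescale_longterm_costs, k)
  tab_k <- cost_table(scen_k)
  expect_equal(as.matrix(tab_k[, GA_LABELS]), as.matrix(tab[, GA_LABELS]) * k,
               tolerance = 1e-12)
})
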
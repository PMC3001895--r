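test_that("state mortality applies the relative-risk schedule and caps at 1", {
  lt <- life_table(q = rep(0.001, 50))
  rr <- data.frame(age_start = 0, age_end = 50, rr = 24.6)
  q_major <- state_mortality(lt, "major", rr)
  expect_equal(q_major[6], 0.0246)  # age 5

  lt_hi <- life_table(q = rep(0.2, 50))
  expect_true(all(state_mortality(lt_hi, "major", rr) == 1))

  rr1 <- data.frame(age_start = 0, age_end = 50, rr = 1)
  expect_equal(state_mortality(lt_hi, "major", rr1), lt_hi$q)

  # minor state: baseline unless an excess-mortality multiplier is set
  expect_equal(state_mortality(lt, "minor"), lt$q)
  expect_equal(state_mortality(lt, "minor", minor_rr = 2), lt$q * 2)
})

test_that("survival closed forms hold", {
  # q = 0 throughout: terminal closure leaves omega - 0.5 person-years
  omega <- 40
  curve0 <- build_survival(rep(0, omega))
  expect_equal(sum(curve0$L), omega - 0.5)

  # constant q = 1/2: geometric survivorship, LE -> 2 - 0.5 = 1.5
  curve_half <- build_survival(rep(0.5, 60))
  expect_equal(sum(curve_half$L), 1.5, tolerance = 1e-9)

  # survivorship is non-increasing, starts at 1 and closes at 0
  expect_equal(curve_half$l[1], 1)
  expect_equal(curve_half$l[length(curve_half$l)], 0)
  expect_true(all(diff(curve_half$l) <= 0))
})

test_that("annual person-years match a day-step integration of the curve", {
  qdf <- make_life_table(synthetic_life_table_spec(seed = 1))
  q <- qdf$annual_mortality_probability
  curve <- build_survival(q)

  # deaths uniform within each year of age: integrate daily survivorship
  steps <- 365
  l <- c(head(curve$l, -1))
  l_next <- c(tail(curve$l, -1))
  fine <- 0
  for (a in seq_along(q)) {
    frac <- (seq_len(steps) - 0.5) / steps
    fine <- fine + sum(l[a] + frac * (l_next[a] - l[a])) / steps
  }
  expect_lt(abs(fine - sum(curve$L)) / sum(curve$L), 0.005)
})

test_that("person summary reduces to LE without weights or discounting", {
  q <- c(0.1, 0.2, 0.5, 1)
  lt <- life_table(q, b = rep(0, 4))
  curve <- build_survival(q)
  w0 <- list(w_minor = 0, w_major = 0, combination_rule = "complement_product")
  s <- person_summary(curve, w0, lt, list(discount_rate = 0), "none")
  expect_equal(s$dale, s$le)
  expect_equal(s$dfle, s$le)

  # a full disability weight annihilates the adjusted expectation
  w1 <- list(w_minor = 0.5, w_major = 1, combination_rule = "complement_product")
  s1 <- person_summary(curve, w1, lt, list(discount_rate = 0.03), "major")
  expect_equal(s1$dale, 0)
  expect_equal(s1$dfle, 0)
})

test_that("the two-year toy table matches the hand-summed DALE", {
  q <- c(0.5, 1)
  lt <- life_table(q, b = rep(0.1, 2))
  curve <- build_survival(q)
  w <- list(w_minor = 0.2, w_major = 0.9,
            combination_rule = "complement_product")
  s <- person_summary(curve, w, lt, list(discount_rate = 0.03), "minor")
  # L = (0.75, 0.25); H = (1 - 0.2)(1 - 0.1) = 0.72
  hand <- 0.72 * (0.75 * 1.03^-0.5 + 0.25 * 1.03^-1.5)
  expect_equal(s$dale, hand, tolerance = 1e-12)
  expect_equal(hand, 0.7042713, tolerance = 1e-7)

  # literal rule: H = 1 - w * b = 0.98
  w2 <- modifyList(w, list(combination_rule = "literal_product"))
  s2 <- person_summary(curve, w2, lt, list(discount_rate = 0.03), "minor")
  expect_equal(s2$dale, 0.98 * (0.75 * 1.03^-0.5 + 0.25 * 1.03^-1.5))
})

test_that("strategy expectation is the probability-weighted state mix", {
  scen <- the_scenario()
  profiles <- neocea:::state_profiles(scen)
  summaries <- lapply(profiles, `[[`, "summary")

  g <- scen$ga_groups[["30-33 wk"]]
  dist <- evaluate_tree(g, g$nicu)
  got <- strategy_expectation(dist, summaries)

  brute <- 0
  for (state in c("none", "minor", "major")) {
    p <- dist$probability[dist$outcome == state]
    brute <- brute + p * summaries[[state]]$le
  }
  expect_equal(got$le, brute, tolerance = 1e-12)
  expect_equal(got$dfle,
               dist$probability[dist$outcome == "none"] * summaries$none$le)

  # all mass on death: zero years
  d0 <- evaluate_tree(g, list(p_mort = 1, p_minor = 0, p_major = 0))
  z <- strategy_expectation(d0, summaries)
  expect_equal(unlist(z), c(le = 0, dfle = 0, dale = 0))

  # all mass on the no-disability state: the state LE itself
  d1 <- evaluate_tree(g, list(p_mort = 0, p_minor = 0, p_major = 0))
  expect_equal(strategy_expectation(d1, summaries)$le, summaries$none$le)
})

test_that("discounting and excess mortality move expectations the right way", {
  scen <- the_scenario()
  lt <- scen$life_table
  w <- scen$disability_weights
  q <- state_mortality(lt, "none")
  curve <- build_survival(q)
  dale_r <- person_summary(curve, w, lt, list(discount_rate = 0.03), "none")$dale
  dale_0 <- person_summary(curve, w, lt, list(discount_rate = 0), "none")$dale
  expect_lt(dale_r, dale_0)

  # rr > 1 strictly shortens major-state life expectancy
  q_major <- state_mortality(lt, "major", scen$rr_major)
  expect_lt(sum(build_survival(q_major)$L), sum(curve$L))
})

test_that("lower neonatal mortality alone yields positive DALYs averted", {
  scen <- the_scenario()
  for (lab in names(scen$ga_groups)) {
    g <- scen$ga_groups[[lab]]
    scen$ga_groups[[lab]]$no_nicu <- g$nicu
    scen$ga_groups[[lab]]$no_nicu$p_mort <- min(1, g$nicu$p_mort + 0.2)
  }
  rep <- base_case_report(scen)
  expect_true(all(rep$dalys_averted > 0))
})

test_that("the synthetic life table gives a plausible life expectancy", {
  scen <- the_scenario()
  le <- sum(build_survival(state_mortality(scen$life_table, "none"))$L)
  expect_gt(le, 60)
  expect_lt(le, 80)
})
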
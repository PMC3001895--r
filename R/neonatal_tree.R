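# Neonatal-period decision tree.
#
# For one GA group under one strategy the tree has two chance stages:
# neonatal death vs survival to 28 days, then (conditional on survival)
# long-term disability category {none, minor, major}. Morbidity
# probabilities are conditional on neonatal survival.

OUTCOMES <- c("death", "none", "minor", "major")

#' Evaluate the neonatal decision tree for one GA group and strategy
#'
#' @param group list with `label` and `births` (thousands of live births).
#' @param strat strategy parameters: `p_mort` (neonatal mortality), and
#'   `p_minor`, `p_major` (disability probabilities conditional on neonatal
#'   survival, with `p_minor + p_major <= 1`).
#' @return a `neonatal_outcomes` data.frame with one row per outcome
#'   (`death`, `none`, `minor`, `major`) and columns `probability`
#'   (unconditional) and `count` (thousands). Probabilities sum to 1 and
#'   counts to `births`.
#' @export
#' @examples
#' evaluate_tree(list(label = "30-33 wk", births = 29.1),
#'               list(p_mort = 0.10, p_minor = 0.12, p_major = 0.16))
evaluate_tree <- function(group, strat) {
  surv <- 1 - strat$p_mort
  p <- c(
    death = strat$p_mort,
    none  = surv * (1 - strat$p_minor - strat$p_major),
    minor = surv * strat$p_minor,
    major = surv * strat$p_major
  )
  out <- data.frame(
    outcome = OUTCOMES,
    probability = unname(p),
    count = unname(p) * group$births,
    row.names = NULL
  )
  structure(out, class = c("neonatal_outcomes", "data.frame"),
            births = group$births, label = group$label)
}

outcome_prob <- function(dist, outcome) {
  dist$probability[match(outcome, dist$outcome)]
}

#' Population outcome table across GA groups and strategies
#'
#' Mirrors the layout of the published population-outcome table: births and,
#' per strategy, neonatal deaths and survival with no/minor/major disability,
#' in thousands, with an `All` column summed over GA groups on unrounded
#' values (rounding, if any, happens only at rendering).
#'
#' @param scenario a validated `nicu_scenario`.
#' @return data.frame with columns `strategy`, `outcome`, one column per GA
#'   label, and `All`.
#' @seealso [write_population_table()], [format_population_table()]
#' @export
population_table <- function(scenario) {
  labs <- names(scenario$ga_groups)
  rows <- list(data.frame(strategy = "", outcome = "births"))
  births <- vapply(scenario$ga_groups, `[[`, 0, "births")
  rows[[1]][labs] <- as.list(unname(births))

  for (strat in c("nicu", "no_nicu")) {
    counts <- sapply(labs, function(lab) {
      g <- scenario$ga_groups[[lab]]
      d <- evaluate_tree(g, g[[strat]])
      setNames(d$count, d$outcome)
    })
    for (o in OUTCOMES) {
      r <- data.frame(strategy = strat, outcome = o)
      r[labs] <- as.list(unname(counts[o, ]))
      rows[[length(rows) + 1L]] <- r
    }
  }
  out <- do.call(rbind, rows)
  out$All <- rowSums(out[, labs, drop = FALSE])
  rownames(out) <- NULL
  out
}

#' Render a population table at one-decimal precision (thousands)
#'
#' Totals are computed before rounding; each printed cell is rounded last.
#'
#' @param tab output of [population_table()].
#' @return data.frame of the same shape with numeric cells rounded to one
#'   decimal.
#' @export
format_population_table <- function(tab) {
  num <- vapply(tab, is.numeric, TRUE)
  tab[num] <- lapply(tab[num], round, digits = 1)
  tab
}

#' Write a population table to CSV or JSON
#'
#' CSV output is display-rounded (one decimal, thousands); JSON keeps the
#' unrounded values for machine consumers.
#'
#' @param tab output of [population_table()].
#' @param path output file.
#' @param format `"csv"` or `"json"`.
#' @return `path`, invisibly.
#' @export
write_population_table <- function(tab, path, format = c("csv", "json")) {
  format <- match.arg(format)
  if (format == "csv") {
    write.csv(format_population_table(tab), path, row.names = FALSE)
  } else {
    jsonlite::write_json(tab, path, dataframe = "rows", digits = NA)
  }
  invisible(path)
}

#' Microsimulation oracle for the decision tree
#'
#' Draws `n` infants through the two chance stages (death, then disability
#' category among survivors) and reports empirical outcome frequencies.
#' Deterministic given `seed`; used as an independent cross-check of
#' [evaluate_tree()].
#'
#' @inheritParams evaluate_tree
#' @param n number of simulated infants (`>= 1`).
#' @param seed RNG seed.
#' @return named numeric vector of outcome frequencies summing to 1.
#' @export
microsimulate_tree <- function(group, strat, n, seed) {
  if (n < 1) stop("n must be >= 1")
  with_seed(seed, {
    died <- runif(n) < strat$p_mort
    n_surv <- sum(!died)
    counts <- c(death = sum(died), none = 0, minor = 0, major = 0)
    if (n_surv > 0) {
      u <- runif(n_surv)
      counts["minor"] <- sum(u < strat$p_minor)
      counts["major"] <- sum(u >= strat$p_minor &
                               u < strat$p_minor + strat$p_major)
      counts["none"] <- n_surv - counts["minor"] - counts["major"]
    }
    counts / n
  })
}
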
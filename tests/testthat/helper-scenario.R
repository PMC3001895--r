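# Shared fixtures: the example scenario is built once per test run, and the
# brute-force summation oracles stay independent of the package's vectorized
# implementations.

the_scenario <- local({
  cached <- NULL
  function() {
    if (is.null(cached)) cached <<- example_scenario(seed = 1)
    cached
  }
})

GA_LABELS <- c("24-26 wk", "27-29 wk", "30-33 wk")

# Direct summation of the model's defining formulas, written as plain loops.
brute_le <- function(q) {
  omega <- length(q)
  l <- 1
  total <- 0
  for (a in seq_len(omega)) {
    l_next <- if (a == omega) 0 else l * (1 - q[a])
    total <- total + (l + l_next) / 2
    l <- l * (1 - q[a])
  }
  total
}

brute_dale <- function(q, w_state, b, r, rule = "complement_product") {
  omega <- length(q)
  l <- 1
  total <- 0
  for (a in seq_len(omega)) {
    l_next <- if (a == omega) 0 else l * (1 - q[a])
    L <- (l + l_next) / 2
    D <- (1 + r)^-((a - 1) + 0.5)
    H <- if (rule == "complement_product") {
      (1 - w_state) * (1 - b[a])
    } else {
      1 - w_state * b[a]
    }
    total <- total + D * L * H
    l <- l * (1 - q[a])
  }
  total
}

brute_longterm_cost <- function(q, cost_by_age, r) {
  omega <- length(q)
  l <- 1
  total <- 0
  for (a in seq_len(omega)) {
    l_next <- if (a == omega) 0 else l * (1 - q[a])
    L <- (l + l_next) / 2
    total <- total + (1 + r)^-((a - 1) + 0.5) * L * cost_by_age[a]
    l <- l * (1 - q[a])
  }
  total
}

# Random two-stage tree parameters with a legal morbidity budget.
random_tree_params <- function() {
  split <- runif(2)
  list(p_mort = runif(1),
       p_minor = split[1] * split[2],
       p_major = split[1] * (1 - split[2]))
}

one_band <- function(omega, value, col) {
  df <- data.frame(age_start = 0, age_end = omega)
  df[[col]] <- value
  df
}
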
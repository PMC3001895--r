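# Life-table container and CSV I/O.

#' Construct a life table from per-age vectors
#'
#' @param q annual mortality probabilities, one per integer age `0..omega-1`.
#' @param b background disability weights, one per age (defaults to zero).
#' @return an object of class `life_table` with fields `q`, `b`, `omega`.
#' @export
life_table <- function(q, b = rep(0, length(q))) {
  stopifnot(length(q) == length(b))
  if (any(q < 0 | q > 1)) stop("mortality probabilities must lie in [0, 1]")
  if (any(b < 0 | b > 1)) stop("background weights must lie in [0, 1]")
  structure(list(q = as.numeric(q), b = as.numeric(b), omega = length(q)),
            class = "life_table")
}

#' Read a life table from the two-CSV format
#'
#' The mortality file has header `age_start,age_end,annual_mortality_probability`
#' and the background-weight file `age_start,age_end,background_disability_weight`;
#' both use half-open age bands `[age_start, age_end)` that together cover
#' `[0, omega)`. Bands are expanded to annual ages as piecewise-constant
#' values.
#'
#' @param mortality_path path to the mortality CSV.
#' @param weights_path path to the background-disability-weight CSV; `NULL`
#'   for all-zero background weights.
#' @param omega terminal age; defaults to the maximum `age_end` in the
#'   mortality file.
#' @return a `life_table`.
#' @export
read_life_table <- function(mortality_path, weights_path = NULL, omega = NULL) {
  if (!file.exists(mortality_path)) {
    stop("life-table file not found: ", mortality_path)
  }
  qdf <- read.csv(mortality_path)
  need <- c("age_start", "age_end", "annual_mortality_probability")
  if (!all(need %in% names(qdf))) {
    stop("mortality CSV needs columns: ", paste(need, collapse = ", "))
  }
  if (is.null(omega)) omega <- max(qdf$age_end)
  q <- expand_bands(qdf, omega, "annual_mortality_probability")
  b <- rep(0, omega)
  if (!is.null(weights_path)) {
    if (!file.exists(weights_path)) {
      stop("background-weight file not found: ", weights_path)
    }
    bdf <- read.csv(weights_path)
    b <- expand_bands(bdf, omega, "background_disability_weight")
  }
  life_table(q, b)
}

#' Write a life table to the two-CSV format
#'
#' Inverse of [read_life_table()]: one row per year of age.
#'
#' @param lt a `life_table`.
#' @param mortality_path,weights_path output CSV paths.
#' @return invisibly, the two paths.
#' @export
write_life_table <- function(lt, mortality_path, weights_path) {
  ages <- seq_len(lt$omega) - 1L
  write.csv(
    data.frame(age_start = ages, age_end = ages + 1L,
               annual_mortality_probability = lt$q),
    mortality_path, row.names = FALSE, quote = FALSE
  )
  write.csv(
    data.frame(age_start = ages, age_end = ages + 1L,
               background_disability_weight = lt$b),
    weights_path, row.names = FALSE, quote = FALSE
  )
  invisible(c(mortality_path, weights_path))
}

#' @export
print.life_table <- function(x, ...) {
  cat("<life_table> omega =", x$omega, "y; q(0) =", signif(x$q[1], 4),
      "; mean background weight =", signif(mean(x$b), 3), "\n")
  invisible(x)
}
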
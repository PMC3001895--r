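# Internal helpers shared across modules.

#' Expand age bands to a per-age vector
#'
#' Age bands use the half-open convention `[age_start, age_end)` in whole
#' years. The returned vector has one element per integer age `0..omega-1`,
#' piecewise constant within bands.
#'
#' @param bands data.frame with columns `age_start`, `age_end` and the value
#'   column named by `value_col`.
#' @param omega terminal age (years); ages at or above `omega` are dropped.
#' @param value_col name of the value column to expand.
#' @return numeric vector of length `omega`.
#' @keywords internal
expand_bands <- function(bands, omega, value_col) {
  out <- rep(NA_real_, omega)
  for (i in seq_len(nrow(bands))) {
    a0 <- bands$age_start[i]
    a1 <- min(bands$age_end[i], omega)
    if (a1 > a0) out[(a0 + 1):a1] <- bands[[value_col]][i]
  }
  if (anyNA(out)) {
    stop("age bands do not cover every age in [0, ", omega, ")")
  }
  out
}

# Violation messages (character(0) when fine) for an age-band table that
# must be contiguous, non-overlapping and cover [0, omega).
band_violations <- function(bands, omega, where) {
  v <- character(0)
  if (is.null(bands) || nrow(bands) == 0) {
    return(paste0(where, ": bands must cover [0, ", omega, ")"))
  }
  o <- order(bands$age_start)
  bands <- bands[o, , drop = FALSE]
  if (bands$age_start[1] != 0) {
    v <- c(v, paste0(where, ": first band must start at age 0"))
  }
  if (any(bands$age_end <= bands$age_start)) {
    v <- c(v, paste0(where, ": every band needs age_end > age_start"))
  }
  if (nrow(bands) > 1) {
    gaps <- bands$age_start[-1] != bands$age_end[-nrow(bands)]
    if (any(gaps)) {
      v <- c(v, paste0(where, ": bands must be contiguous and non-overlapping"))
    }
  }
  if (max(bands$age_end) < omega) {
    v <- c(v, paste0(where, ": bands must cover [0, ", omega, ")"))
  }
  v
}

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# Recursive [[ access along a dotted path; errors on a missing key.
pluck_in <- function(x, keys, full_path) {
  for (k in keys) {
    if (is.null(x) || is.null(x[[k]])) {
      stop("parameter path not found: ", full_path, call. = FALSE)
    }
    x <- x[[k]]
  }
  x
}

assign_in <- function(x, keys, value) {
  if (length(keys) == 1L) {
    x[[keys]] <- value
    return(x)
  }
  x[[keys[1L]]] <- assign_in(x[[keys[1L]]], keys[-1L], value)
  x
}

is_prob <- function(x) is.numeric(x) && length(x) == 1L && !is.na(x) &&
  x >= 0 && x <= 1

is_nonneg <- function(x) is.numeric(x) && length(x) == 1L && !is.na(x) && x >= 0

#' Render a dollar amount in thousands for report tables
#'
#' Values are shown in thousands to one decimal; positive amounts that would
#' display as 0.0 are rendered `"<0.1"`, matching the convention of the
#' published cost tables.
#'
#' @param x US$ amounts (not thousands).
#' @return character vector.
#' @export
#' @examples
#' format_thousands(c(2457.6, 36.9, 0))
format_thousands <- function(x) {
  out <- sprintf("%.1f", x / 1000)
  out[x > 0 & x < 50] <- "<0.1"
  out
}
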
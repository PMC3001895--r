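# Report rendering and run orchestration: the functions behind the CLI
# subcommands. Every run writes a manifest recording the inputs, seed,
# package version and produced files.

write_manifest <- function(out_dir, command, outputs, config_path = NULL,
                           seed = NULL) {
  manifest <- list(
    command = command,
    config = if (is.null(config_path)) NA else normalizePath(config_path),
    config_md5 = if (is.null(config_path)) NA else
      unname(tools::md5sum(config_path)),
    seed = if (is.null(seed)) NA else seed,
    version = as.character(packageVersion("neocea")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    outputs = vapply(outputs, basename, "")
  )
  path <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA)
  stopifnot(all(file.exists(outputs)))
  path
}

#' Run the base-case pipeline and write all report tables
#'
#' Produces the three report files — population outcomes
#' (`population_outcomes`), per-infant costs (`cost_per_infant`) and
#' incremental results (`cea_results`) — plus `manifest.json`.
#'
#' @param config path to a scenario YAML, or an already-validated
#'   `nicu_scenario`.
#' @param out_dir output directory (created if needed).
#' @param format `"csv"` (display-rounded) or `"json"` (unrounded).
#' @return character vector of written files, invisibly.
#' @export
run_report <- function(config, out_dir, format = c("csv", "json")) {
  format <- match.arg(format)
  config_path <- NULL
  if (is.character(config)) {
    config_path <- config
    scenario <- load_scenario(config)
  } else {
    scenario <- validate_scenario(config)
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  ext <- format

  files <- c(
    write_population_table(population_table(scenario),
                           file.path(out_dir, paste0("population_outcomes.", ext)),
                           format),
    write_cost_table(cost_table(scenario),
                     file.path(out_dir, paste0("cost_per_infant.", ext)),
                     format),
    write_cea_table(base_case_report(scenario),
                    file.path(out_dir, paste0("cea_results.", ext)),
                    format)
  )
  manifest <- write_manifest(out_dir, "run", files, config_path)
  invisible(c(files, manifest))
}

#' Run a sensitivity stage and write its outputs
#'
#' Modes:
#' \describe{
#'   \item{`tornado`}{one-way ICER ranges per parameter, one CSV per GA
#'     group.}
#'   \item{`psa`}{Monte Carlo draws of incremental cost and DALYs averted
#'     (`psa_draws.csv`); requires `seed`.}
#'   \item{`ceac`}{PSA plus acceptability curves (`ceac.csv`); requires
#'     `seed`.}
#'   \item{`scenario`}{ICERs per GA group under the three cumulative
#'     bias-against-intervention presets (`scenario_icers.csv`).}
#' }
#'
#' @param config scenario YAML path or `nicu_scenario`.
#' @param mode one of `"tornado"`, `"psa"`, `"ceac"`, `"scenario"`.
#' @param out_dir output directory.
#' @param seed RNG seed (required for `psa` and `ceac`).
#' @param draws number of PSA draws.
#' @param lambda_max,lambda_step CEAC willingness-to-pay grid; defaults to
#'   0..3x GDP per capita in steps of 100.
#' @return character vector of written files, invisibly.
#' @export
run_sensitivity <- function(config, mode = c("tornado", "psa", "ceac",
                                             "scenario"),
                            out_dir, seed = NULL, draws = 1000,
                            lambda_max = NULL, lambda_step = 100) {
  mode <- match.arg(mode)
  config_path <- NULL
  if (is.character(config)) {
    config_path <- config
    scenario <- load_scenario(config)
  } else {
    scenario <- validate_scenario(config)
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  files <- character(0)

  if (mode == "tornado") {
    for (lab in names(scenario$ga_groups)) {
      tab <- tornado(scenario, lab)
      f <- file.path(out_dir,
                     paste0("tornado_", gsub("[^0-9A-Za-z]+", "_", lab), ".csv"))
      write.csv(tab, f, row.names = FALSE)
      files <- c(files, f)
    }
  } else if (mode %in% c("psa", "ceac")) {
    if (is.null(seed)) stop("mode '", mode, "' requires a seed")
    psa <- run_psa(scenario, n = draws, seed = seed)
    f <- file.path(out_dir, "psa_draws.csv")
    write.csv(psa$draws, f, row.names = FALSE)
    files <- c(files, f)
    if (mode == "ceac") {
      if (is.null(lambda_max)) {
        grid <- default_lambda_grid(scenario$econ, lambda_step)
      } else {
        grid <- seq(0, lambda_max, by = lambda_step)
      }
      f2 <- file.path(out_dir, "ceac.csv")
      write.csv(ceac(psa, grid), f2, row.names = FALSE)
      files <- c(files, f2)
    }
  } else {
    presets <- c("no_morbidity_benefit", "plus_high_mortality",
                 "plus_double_costs")
    rows <- list()
    base <- base_case_report(scenario)
    rows[[1]] <- cbind(preset = "base_case",
                       base[, c("ga", "dalys_averted", "delta_cost", "icer")])
    for (p in presets) {
      rep_p <- base_case_report(scenario_preset(p, scenario))
      rows[[length(rows) + 1L]] <-
        cbind(preset = p,
              rep_p[, c("ga", "dalys_averted", "delta_cost", "icer")])
    }
    tab <- do.call(rbind, rows)
    f <- file.path(out_dir, "scenario_icers.csv")
    write.csv(tab, f, row.names = FALSE)
    files <- c(files, f)
  }

  manifest <- write_manifest(out_dir, paste0("sensitivity:", mode), files,
                             config_path, seed)
  invisible(c(files, manifest))
}

#' Tornado bar chart
#'
#' Horizontal bars from the low- to the high-bound ICER per parameter,
#' widest spread on top. Requires ggplot2.
#'
#' @param tab output of [tornado()].
#' @param top show only the `top` widest parameters.
#' @return a ggplot object.
#' @export
plot_tornado <- function(tab, top = 12) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("plot_tornado requires ggplot2")
  }
  tab <- head(tab[order(-tab$spread), ], top)
  tab$path <- factor(tab$path, levels = rev(tab$path))
  tab$lo <- pmin(tab$icer_low, tab$icer_high)
  tab$hi <- pmax(tab$icer_low, tab$icer_high)
  ggplot2::ggplot(tab) +
    ggplot2::geom_segment(
      ggplot2::aes(x = lo, xend = hi, y = path, yend = path),
      linewidth = 4, colour = "steelblue"
    ) +
    ggplot2::labs(x = "ICER (US$/DALY)", y = NULL) +
    ggplot2::theme_minimal()
}

#' Cost-effectiveness acceptability curves
#'
#' One line per GA group. Requires ggplot2.
#'
#' @param ceac_tab output of [ceac()].
#' @return a ggplot object.
#' @export
plot_ceac <- function(ceac_tab) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("plot_ceac requires ggplot2")
  }
  ggplot2::ggplot(ceac_tab,
                  ggplot2::aes(x = lambda, y = p_ce, colour = ga)) +
    ggplot2::geom_line() +
    ggplot2::ylim(0, 1) +
    ggplot2::labs(x = "Willingness to pay (US$/DALY)",
                  y = "P(cost-effective)", colour = "GA group") +
    ggplot2::theme_minimal()
}
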
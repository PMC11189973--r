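#' Three-significant-figure presentation rounding
#'
#' Report tables round to 3 significant figures at the formatting boundary
#' only (the model always computes exact values), with halves rounded away
#' from zero so that e.g. 4725 prints as 4730.
#'
#' @param x Numeric vector.
#' @return Numeric vector rounded to 3 significant figures.
#' @export
signif3 <- function(x) {
  out <- x
  idx <- is.finite(x) & x != 0
  e <- floor(log10(abs(x[idx])))
  scale <- 10^(e - 2)
  out[idx] <- sign(x[idx]) * floor(abs(x[idx]) / scale + 0.5) * scale
  out
}

#' Format a removal rate as a percentage
#'
#' Converts a fractional removal rate to percent with 3 significant figures:
#' `0.0060606` renders as `"0.606%"`.
#'
#' @param k Removal rate as a fraction per year.
#' @return Character vector.
#' @export
format_percent <- function(k) {
  vapply(k, function(x) {
    if (!is.finite(x)) return(as.character(x))
    paste0(format_sig3(x * 100), "%")
  }, character(1))
}

#' Format a time in years
#'
#' 3 significant figures; values of 1000 years and above use a thin-space
#' thousands separator (`3 570`) following common typographic practice for
#' year counts. Machine-readable outputs (CSV/JSON) are never formatted.
#'
#' @param t Time in years.
#' @return Character vector.
#' @export
format_years <- function(t) {
  vapply(t, function(x) {
    if (!is.finite(x)) return(as.character(x))
    if (x == 0) return("0")
    s <- signif3(x)
    if (s >= 1000) {
      formatC(s, format = "d", big.mark = " ")
    } else {
      format_sig3(x)
    }
  }, character(1))
}

format_sig3 <- function(x) {
  if (x == 0) return("0")
  s <- signif3(x)
  decimals <- max(0, 2 - floor(log10(abs(s))))
  formatC(s, format = "f", digits = decimals)
}

#' Render a simulation as a human-readable report
#'
#' Mode with the 90% uncertainty interval in `[p5; p95]` brackets, removal
#' rate as percent, times in years. All rounding is presentation-only.
#'
#' @param sim A `phyto_sim`.
#' @return Character vector of report lines.
#' @export
render_report <- function(sim) {
  s <- function(out, col) sim$summary[[col]][sim$summary$output == out]
  fmt <- function(out, f) {
    sprintf(
      "%s [%s; %s]",
      f(s(out, "mode")), f(s(out, "p5")), f(s(out, "p95"))
    )
  }
  lines <- c(
    sprintf("  Extraction potential E: %s [%s; %s] mg/year",
      format_sig3(s("e", "mode")), format_sig3(s("e", "p5")),
      format_sig3(s("e", "p95"))
    ),
    sprintf("  Removal rate k:         %s per year", fmt("k", format_percent)),
    sprintf("  Remediation time (linear):      %s years",
      fmt("t_linear", format_years)
    ),
    sprintf("  Remediation time (exponential): %s years",
      fmt("t_exponential", format_years)
    )
  )
  inf_share <- max(sim$summary$share_infinite)
  if (inf_share > 0) {
    lines <- c(lines, sprintf(
      "  (%.2f%% of draws gave non-finite times and are excluded)",
      100 * inf_share
    ))
  }
  lines
}

#' Render an efficiency-gradient scenario table
#'
#' Formats the output of [run_scenario_a()] the way gradient results are
#' conventionally tabulated: one row per concentration with soil mass
#' (3 significant figures), removal rate as percent and both remediation
#' times as `mode [p5; p95]` strings.
#'
#' @param scenario Output of [run_scenario_a()].
#' @return A tibble of formatted character columns.
#' @export
render_scenario_table <- function(scenario) {
  bracket <- function(mode, p5, p95, f) {
    sprintf("%s [%s; %s]", f(mode), f(p5), f(p95))
  }
  tibble::tibble(
    level = if ("level" %in% names(scenario)) scenario$level else NA,
    efficiency = paste0(round(100 * scenario$efficiency), "%"),
    c_soil_i_mg_per_kg = scenario$c_soil_i,
    m_soil_i_mg = signif3(scenario$m_soil_i),
    k_pct_per_yr = bracket(
      scenario$k_mode, scenario$k_p5, scenario$k_p95, format_percent
    ),
    t_linear_yr = bracket(
      scenario$t_linear_mode, scenario$t_linear_p5, scenario$t_linear_p95,
      format_years
    ),
    t_exponential_yr = bracket(
      scenario$t_exponential_mode, scenario$t_exponential_p5,
      scenario$t_exponential_p95, format_years
    )
  )
}

#' Write simulation artifacts
#'
#' `write_simulation_json()` writes the summary, sensitivity table,
#' infinite-draw shares and a complete configuration echo (including the
#' serialised input distributions and the seed) as JSON; the echo parses
#' back into an equivalent runnable configuration via [parse_run_config()].
#' `write_draws_csv()` writes the per-iteration draw table with units in the
#' column headers.
#'
#' @param sim A `phyto_sim`.
#' @param path Output file path.
#' @return The path, invisibly.
#' @export
write_simulation_json <- function(sim, path) {
  payload <- list(
    summary = sim$summary,
    sensitivity = sim$sensitivity,
    m_soil_i_mg = sim$m_soil_i,
    m_soil_f_mg = sim$m_soil_f,
    degenerate = sim$degenerate,
    config = sim$meta
  )
  jsonlite::write_json(payload, path,
    auto_unbox = TRUE, digits = NA, pretty = TRUE, na = "null"
  )
  invisible(path)
}

#' @rdname write_simulation_json
#' @export
write_draws_csv <- function(sim, path) {
  out <- sim$draws
  names(out) <- c(
    "baf_stem_ratio", "baf_leaves_ratio",
    "bmp_stem_kg_per_m2_yr", "bmp_leaves_kg_per_m2_yr",
    "e_mg_per_yr", "k_frac_per_yr", "t_linear_yr", "t_exponential_yr"
  )
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' Parse a run configuration
#'
#' Reads a JSON (or YAML, if the `yaml` package is installed) configuration
#' —  either a fresh user-written one or the `config` echo of a previous
#' run — and validates it into the pieces [run_simulation()] needs. A
#' configuration names either a packaged `dataset` (with optional
#' `assignment`) or gives inline `specs`; the `soil` block carries
#' `c_soil_i` and optionally `c_target`, `bulk_density`, `depth`, `area`.
#'
#' @param config A file path or an already-parsed list.
#' @return A list with elements `specs` (named [phyto_dist] list), `soil`
#'   (a [soil_compartment()]), `n_iterations`, `efficiency` and `seed`.
#' @export
parse_run_config <- function(config) {
  if (is.character(config)) {
    config <- if (grepl("\\.ya?ml$", config)) {
      if (!requireNamespace("yaml", quietly = TRUE)) {
        stop("YAML configs need the 'yaml' package", call. = FALSE)
      }
      yaml::read_yaml(config)
    } else {
      jsonlite::read_json(config)
    }
  }
  if (!is.null(config$config)) config <- config$config # a run's JSON echo
  if (!is.list(config)) stop("config must be a list or a file", call. = FALSE)

  specs <- if (!is.null(config$specs)) {
    lapply(config$specs, dist_from_config)
  } else if (!is.null(config$dataset)) {
    dataset_specs(
      config$dataset,
      assignment = config$assignment %||% "default"
    )
  } else {
    stop("config needs either 'dataset' or inline 'specs'", call. = FALSE)
  }
  validate_specs(specs)

  soil_args <- config$soil
  if (is.null(soil_args$c_soil_i)) {
    stop("config$soil$c_soil_i is required", call. = FALSE)
  }
  soil <- do.call(soil_compartment, lapply(soil_args, as.numeric))

  list(
    specs = specs,
    soil = soil,
    n_iterations = as.numeric(config$n_iterations %||% 10000),
    efficiency = as.numeric(config$efficiency %||% 1),
    seed = if (is.null(config$seed)) NULL else as.integer(config$seed)
  )
}

`%||%` <- function(x, y) if (is.null(x)) y else x
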
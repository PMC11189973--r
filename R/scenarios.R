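#' Scenario A: efficiency gradient across initial concentrations
#'
#' Runs the model over the nine (initial concentration, efficiency factor)
#' pairs of [efficiency_gradient()]: the extraction potential of every draw
#' is multiplied by the gradient factor for that concentration, and each
#' concentration is remediated to the same target. Reports the structure of
#' the published gradient table: removal rate and both remediation times as
#' mode and 5th/95th percentile per row.
#'
#' @param specs Input distribution specifications (default the literature
#'   dataset).
#' @param gradient Tibble of `c_soil_i`, `efficiency` (and optionally
#'   `level`) pairs; default [efficiency_gradient()].
#' @param c_target Target concentration, mg/kg dw (default 1).
#' @param n_iterations,seed Passed to the per-row simulations; a single seed
#'   reproduces the full table.
#' @param ... Further arguments to [soil_compartment()] (bulk density, depth,
#'   area).
#' @return A tibble with one row per gradient step: `level`, `efficiency`,
#'   `c_soil_i`, `m_soil_i`, and `mode`/`p5`/`p95` columns for `k`,
#'   `t_linear` and `t_exponential`, plus a list-column `sim` with the full
#'   simulation objects.
#' @export
run_scenario_a <- function(specs = dataset_specs("literature"),
                           gradient = efficiency_gradient(),
                           c_target = 1, n_iterations = 10000, seed = NULL,
                           ...) {
  run_all <- function() {
    purrr::pmap_dfr(
      gradient[c("c_soil_i", "efficiency")],
      function(c_soil_i, efficiency) {
        soil <- soil_compartment(c_soil_i, c_target = c_target, ...)
        sim <- run_simulation(specs, soil,
          n_iterations = n_iterations,
          efficiency = efficiency, seed = NULL
        )
        stat <- function(out, col) sim$summary[[col]][sim$summary$output == out]
        tibble::tibble(
          efficiency = efficiency,
          c_soil_i = c_soil_i,
          m_soil_i = sim$m_soil_i,
          k_mode = stat("k", "mode"),
          k_p5 = stat("k", "p5"),
          k_p95 = stat("k", "p95"),
          t_linear_mode = stat("t_linear", "mode"),
          t_linear_p5 = stat("t_linear", "p5"),
          t_linear_p95 = stat("t_linear", "p95"),
          t_exponential_mode = stat("t_exponential", "mode"),
          t_exponential_p5 = stat("t_exponential", "p5"),
          t_exponential_p95 = stat("t_exponential", "p95"),
          sim = list(sim)
        )
      }
    )
  }
  out <- if (is.null(seed)) run_all() else withr::with_seed(seed, run_all())
  if ("level" %in% names(gradient)) {
    out <- dplyr::bind_cols(gradient["level"], out)
  }
  out
}

#' Scenario B: BAF sweep against a remediation deadline
#'
#' For each combination of a fixed (point-valued) stem bioaccumulation
#' factor and initial concentration, the probability of reaching the target
#' concentration within a time horizon under the linear model:
#' `P(t_linear <= horizon)`, estimated as the fraction of Monte Carlo draws
#' meeting the deadline. The swept BAF is a deterministic lever ("what BAF
#' would be needed?"), the other three variables keep their distributions.
#'
#' The non-swept variables are drawn once and the draws are shared across
#' every grid cell (common random numbers): the success probability is then
#' exactly non-decreasing in BAF and non-increasing in initial
#' concentration, instead of only up to Monte Carlo noise.
#'
#' @param specs Input specifications for the non-swept variables (default
#'   literature).
#' @param baf_values Swept stem BAF values (default `c(8, 10, 12, 14, 16,
#'   18)`).
#' @param c_values Initial concentrations to test, mg/kg dw (default `10:2`).
#' @param horizon Deadline in years (default 25).
#' @param c_target Target concentration (default 1 mg/kg dw).
#' @param n_iterations,seed Monte Carlo size and seed.
#' @param ... Further [soil_compartment()] arguments.
#' @return Tibble with columns `baf_stem`, `c_soil_i`, `probability`.
#' @export
run_scenario_b <- function(specs = dataset_specs("literature"),
                           baf_values = c(8, 10, 12, 14, 16, 18),
                           c_values = 10:2, horizon = 25, c_target = 1,
                           n_iterations = 10000, seed = NULL, ...) {
  stopifnot(all(baf_values > 0), horizon > 0)
  validate_specs(specs)
  draw_shared <- function() {
    tibble::tibble(
      baf_leaves = dist_sample(specs$baf_leaves, n_iterations),
      bmp_stem = dist_sample(specs$bmp_stem, n_iterations),
      bmp_leaves = dist_sample(specs$bmp_leaves, n_iterations)
    )
  }
  shared <- if (is.null(seed)) draw_shared() else {
    withr::with_seed(seed, draw_shared())
  }
  grid <- tidyr::expand_grid(baf_stem = baf_values, c_soil_i = c_values)
  purrr::pmap_dfr(grid, function(baf_stem, c_soil_i) {
    soil <- soil_compartment(c_soil_i, c_target = c_target, ...)
    e <- extraction_potential(
      baf_stem, shared$baf_leaves, shared$bmp_stem, shared$bmp_leaves,
      c_soil_i = c_soil_i
    )
    t_lin <- time_linear(soil_mass(soil), soil_mass(soil, c_target), e)
    tibble::tibble(
      baf_stem = baf_stem, c_soil_i = c_soil_i,
      probability = mean(t_lin <= horizon)
    )
  })
}

#' Scenario C: optimised biomass production
#'
#' Mixes the datasets: site-measured bioaccumulation factors combined with
#' literature-derived biomass production, emulating a site where plant growth
#' (but not uptake) is brought up to the levels reported elsewhere.
#'
#' @param baf_specs Specifications supplying `baf_stem` and `baf_leaves`
#'   (default the site-specific dataset).
#' @param bmp_specs Specifications supplying `bmp_stem` and `bmp_leaves`
#'   (default the literature dataset).
#' @param soil A [soil_compartment()] (default 10 -> 1 mg/kg dw).
#' @param n_iterations,seed,efficiency Passed to [run_simulation()].
#' @return A `phyto_sim`.
#' @export
run_scenario_c <- function(baf_specs = dataset_specs("site_specific"),
                           bmp_specs = dataset_specs("literature"),
                           soil = soil_compartment(c_soil_i = 10),
                           n_iterations = 10000, seed = NULL,
                           efficiency = 1) {
  specs <- list(
    baf_stem = baf_specs$baf_stem,
    baf_leaves = baf_specs$baf_leaves,
    bmp_stem = bmp_specs$bmp_stem,
    bmp_leaves = bmp_specs$bmp_leaves
  )
  run_simulation(specs, soil,
    n_iterations = n_iterations,
    efficiency = efficiency, seed = seed
  )
}

#' Plot a BAF-sweep probability grid
#'
#' Line plot of the probability of meeting the deadline against initial
#' concentration, one line per swept BAF value.
#'
#' @param grid Output of [run_scenario_b()].
#' @param horizon Deadline label for the title (years).
#' @return A ggplot object.
#' @export
plot_scenario_b <- function(grid, horizon = 25) {
  ggplot2::ggplot(
    grid,
    ggplot2::aes(
      x = .data$c_soil_i, y = .data$probability,
      colour = factor(.data$baf_stem), group = .data$baf_stem
    )
  ) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::scale_x_reverse(breaks = sort(unique(grid$c_soil_i))) +
    ggplot2::scale_y_continuous(labels = function(x) paste0(100 * x, "%")) +
    ggplot2::labs(
      x = "initial soil concentration (mg/kg dw)",
      y = sprintf("P(target reached within %g years)", horizon),
      colour = "stem BAF",
      title = "Required bioaccumulation factor vs. remediation deadline"
    )
}
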
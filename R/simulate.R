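#' Run a probabilistic phytoextraction simulation
#'
#' Propagates the four uncertain plant inputs through the extraction model:
#' each iteration draws `baf_stem`, `baf_leaves`, `bmp_stem` and `bmp_leaves`
#' (in that fixed order, independently — no correlation structure is assumed)
#' and computes the extraction potential `E`, the removal rate `k = E / m_i`,
#' and the remediation times of both the linear steady-state model
#' (`t = (m_i - m_f)/E`) and the first-order exponential decay model
#' (`t = ln(m_i/m_f)/k`). Times are summarised from the per-draw time
#' distribution, not from the summarised rate: for skewed outputs
#' `mode(t) != t(mode(k))`, and the per-draw route is what produces the wide,
#' right-skewed time intervals characteristic of this kind of assessment.
#'
#' Draws with `E = 0` give infinite times; summaries are computed on finite
#' draws and the infinite fraction is reported (`share_infinite`). A run
#' where more than half of the time draws are non-finite is flagged
#' degenerate.
#'
#' @param specs Named list of four [phyto_dist] objects (`baf_stem`,
#'   `baf_leaves`, `bmp_stem`, `bmp_leaves`), e.g. from [dataset_specs()].
#' @param soil A [soil_compartment()].
#' @param n_iterations Number of Monte Carlo iterations (default 10 000,
#'   minimum 100).
#' @param efficiency Multiplicative efficiency factor applied to E.
#' @param seed Optional integer seed; identical seed and configuration give
#'   bitwise-identical results. `NULL` uses (and advances) the current RNG
#'   state.
#' @return An object of class `phyto_sim`: a list with `draws` (tibble, one
#'   row per iteration), `summary` (tibble: output, mode, mean, p5, p50, p95,
#'   share_infinite), `sensitivity` (Spearman rank correlations, see
#'   [spearman_sensitivity()]), `soil`, `meta` (config echo) and `degenerate`.
#' @examples
#' sim <- run_simulation(dataset_specs("literature"),
#'   soil_compartment(c_soil_i = 10),
#'   n_iterations = 1000, seed = 1
#' )
#' tidy(sim)
#' @export
run_simulation <- function(specs, soil, n_iterations = 10000,
                           efficiency = 1, seed = NULL) {
  validate_specs(specs)
  stopifnot(inherits(soil, "soil_compartment"))
  if (n_iterations < 100) stop("n_iterations must be >= 100", call. = FALSE)
  if (efficiency <= 0) stop("efficiency must be > 0", call. = FALSE)

  vars <- c("baf_stem", "baf_leaves", "bmp_stem", "bmp_leaves")
  draw_inputs <- function() {
    tibble::as_tibble(lapply(
      setNames(vars, vars),
      function(v) dist_sample(specs[[v]], n_iterations)
    ))
  }
  draws <- if (is.null(seed)) draw_inputs() else {
    withr::with_seed(seed, draw_inputs())
  }

  m_i <- soil_mass(soil)
  m_f <- soil_mass(soil, soil$c_target)
  draws$e <- extraction_potential(
    draws$baf_stem, draws$baf_leaves, draws$bmp_stem, draws$bmp_leaves,
    c_soil_i = soil$c_soil_i, efficiency = efficiency
  )
  draws$k <- removal_rate(draws$e, m_i)
  draws$t_linear <- time_linear(m_i, m_f, draws$e)
  draws$t_exponential <- if (m_f > 0) {
    time_exponential(m_i, m_f, draws$k)
  } else {
    rep(Inf, n_iterations) # exponential decay never reaches a zero target
  }

  outputs <- c("e", "k", "t_linear", "t_exponential")
  summary <- purrr::map_dfr(setNames(outputs, outputs), function(v) {
    x <- draws[[v]]
    finite <- x[is.finite(x)]
    if (length(finite) == 0) {
      return(tibble::tibble(
        mode = NA_real_, mean = NA_real_, p5 = NA_real_, p50 = NA_real_,
        p95 = NA_real_, share_infinite = 1
      ))
    }
    pi_ <- percentile_interval(finite)
    tibble::tibble(
      mode = estimate_mode(finite),
      mean = mean(finite),
      p5 = pi_[["p5"]],
      p50 = unname(quantile(finite, 0.5)),
      p95 = pi_[["p95"]],
      share_infinite = mean(!is.finite(x))
    )
  }, .id = "output")

  degenerate <- any(
    summary$share_infinite[summary$output %in% c("t_linear", "t_exponential")]
    > 0.5
  )
  if (degenerate) {
    warning("degenerate simulation: > 50% non-finite time draws",
      call. = FALSE
    )
  }

  res <- structure(
    list(
      draws = draws,
      summary = summary,
      sensitivity = NULL,
      soil = soil,
      m_soil_i = m_i,
      m_soil_f = m_f,
      degenerate = degenerate,
      meta = list(
        n_iterations = n_iterations,
        efficiency = efficiency,
        seed = seed,
        specs = lapply(specs, dist_config),
        soil = unclass(soil)[c(
          "c_soil_i", "c_target", "bulk_density", "depth", "area"
        )]
      )
    ),
    class = "phyto_sim"
  )
  res$sensitivity <- spearman_sensitivity(res)
  res
}

validate_specs <- function(specs) {
  vars <- c("baf_stem", "baf_leaves", "bmp_stem", "bmp_leaves")
  if (!is.list(specs) || !all(vars %in% names(specs))) {
    stop(
      "specs must be a named list with elements ",
      paste(vars, collapse = ", "),
      call. = FALSE
    )
  }
  ok <- vapply(specs[vars], inherits, logical(1), "phyto_dist")
  if (!all(ok)) stop("all specs must be phyto_dist objects", call. = FALSE)
  invisible(specs)
}

#' Most-likely value (mode) of a Monte Carlo sample
#'
#' The peak of a Gaussian kernel density estimate on the original scale of
#' the draws (512-point grid), with the Sheather-Jones plug-in bandwidth:
#' Silverman's rule systematically oversmooths the strongly right-skewed
#' outputs of this model and biases their density peak upward (verified
#' against large-sample references), while the plug-in bandwidth tracks the
#' peak much more closely. Where the plug-in selector fails (tied or sparse
#' samples) it falls back to Silverman's rule.
#'
#' Heavy right tails (remediation times span orders of magnitude when the
#' extraction potential draws near zero) would stretch the evaluation grid
#' and erode its resolution in the bulk, so the density is evaluated on the
#' draws below the `trim` quantile; the extreme tail cannot carry the global
#' density maximum of these unimodal right-skewed outputs.
#'
#' The density argmax is an unstable statistic (a flat peak lets sampling
#' noise move it considerably), so the estimate is bagged: the argmax is
#' averaged over `bag` bootstrap resamples of the draws, all evaluated at
#' the bandwidth selected once on the full sample. Bagging roughly halves
#' the estimator's standard error here without adding bias. The bootstrap
#' uses a fixed internal seed, so the estimate is a deterministic function
#' of the draws and leaves the caller's RNG state untouched.
#'
#' @param draws Numeric vector of finite draws.
#' @param trim Upper quantile beyond which draws are excluded from density
#'   evaluation (default 0.995; `1` disables trimming).
#' @param bag Number of bootstrap resamples to average over (default 20;
#'   `1` disables bagging).
#' @return The estimated mode (inside `[min(draws), max(draws)]`);
#'   deterministic given the draws.
#' @examples
#' set.seed(1)
#' estimate_mode(rnorm(10000, 10, 1)) # close to 10
#' @export
estimate_mode <- function(draws, trim = 0.995, bag = 20) {
  draws <- draws[is.finite(draws)]
  if (length(draws) == 0) stop("no finite draws", call. = FALSE)
  if (diff(range(draws)) < .Machine$double.eps * max(1, abs(draws[1]))) {
    return(draws[1])
  }
  if (trim < 1) draws <- draws[draws <= quantile(draws, trim)]
  bw <- tryCatch(stats::bw.SJ(draws), error = function(e) stats::bw.nrd0(draws))
  peak <- function(x) {
    d <- density(x, bw = bw, n = 512)
    d$x[which.max(d$y)]
  }
  if (bag <= 1) {
    return(peak(draws))
  }
  withr::with_seed(0, {
    mean(vapply(
      seq_len(bag),
      function(b) peak(sample(draws, replace = TRUE)),
      numeric(1)
    ))
  })
}

#' Empirical uncertainty interval
#'
#' The 5th/95th percentile band (by default) of the finite draws, with linear
#' interpolation between order statistics (R's default quantile type 7).
#'
#' @param draws Numeric vector of draws (non-finite values dropped).
#' @param lo,hi Probability bounds (defaults 0.05 and 0.95).
#' @return Named vector `c(p5 = ..., p95 = ...)` (names follow `lo`/`hi`).
#' @export
percentile_interval <- function(draws, lo = 0.05, hi = 0.95) {
  draws <- draws[is.finite(draws)]
  q <- quantile(draws, c(lo, hi), names = FALSE)
  setNames(q, paste0("p", c(lo, hi) * 100))
}

#' Spearman rank sensitivity of outputs to inputs
#'
#' Spearman rank correlation between each input draw vector and each output,
#' identifying the variables that contribute most to output uncertainty.
#' Constant (point-valued) inputs have no rank variation; they are reported
#' with `rho = 0` and `constant = TRUE`.
#'
#' @param sim A `phyto_sim`, or a draws tibble with input and output columns.
#' @param outputs Output columns to correlate against (default all four).
#' @return Tibble with columns `output`, `input`, `rho`, `constant`, sorted
#'   by `abs(rho)` within output.
#' @export
spearman_sensitivity <- function(sim,
                                 outputs = c(
                                   "e", "k", "t_linear", "t_exponential"
                                 )) {
  draws <- if (inherits(sim, "phyto_sim")) sim$draws else sim
  inputs <- c("baf_stem", "baf_leaves", "bmp_stem", "bmp_leaves")
  outputs <- intersect(outputs, names(draws))
  grid <- tidyr::expand_grid(output = outputs, input = inputs)
  res <- purrr::pmap_dfr(grid, function(output, input) {
    x <- draws[[input]]
    y <- draws[[output]]
    keep <- is.finite(x) & is.finite(y)
    constant <- sum(keep) < 2 ||
      stats::sd(x[keep]) == 0 || stats::sd(y[keep]) == 0
    rho <- if (constant) 0 else cor(x[keep], y[keep], method = "spearman")
    tibble::tibble(output = output, input = input, rho = rho,
      constant = constant)
  })
  dplyr::arrange(
    res, .data$output, dplyr::desc(abs(.data$rho))
  )
}

#' @export
print.phyto_sim <- function(x, ...) {
  cat(sprintf(
    "Phytoextraction simulation: %d iterations, c_soil %g -> %g mg/kg dw\n",
    x$meta$n_iterations, x$soil$c_soil_i, x$soil$c_target
  ))
  cat(render_report(x), sep = "\n")
  invisible(x)
}

#' Tidy a simulation result
#'
#' `tidy()` returns the per-output summary table (mode, mean, percentiles,
#' infinite-draw share); `glance()` a one-row overview.
#'
#' @param x A `phyto_sim` object.
#' @param ... Unused.
#' @return A tibble.
#' @method tidy phyto_sim
#' @export
tidy.phyto_sim <- function(x, ...) {
  x$summary
}

#' @rdname tidy.phyto_sim
#' @method glance phyto_sim
#' @export
glance.phyto_sim <- function(x, ...) {
  s <- function(out, col) x$summary[[col]][x$summary$output == out]
  tibble::tibble(
    n_iterations = x$meta$n_iterations,
    seed = if (is.null(x$meta$seed)) NA_integer_ else x$meta$seed,
    efficiency = x$meta$efficiency,
    m_soil_i = x$m_soil_i,
    m_soil_f = x$m_soil_f,
    k_mode = s("k", "mode"),
    t_linear_mode = s("t_linear", "mode"),
    t_exponential_mode = s("t_exponential", "mode"),
    degenerate = x$degenerate
  )
}

#' Plot the output distributions of a simulation
#'
#' Kernel-density panels of the finite draws of each output on a log10 axis
#' (all outputs are positive and right-skewed), with the most-likely value
#' (solid) and the 5th/95th-percentile band (dashed) marked.
#'
#' @param object A `phyto_sim`.
#' @param outputs Which outputs to show.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot phyto_sim
#' @export
autoplot.phyto_sim <- function(object,
                               outputs = c("k", "t_linear", "t_exponential"),
                               ...) {
  long <- object$draws |>
    dplyr::select(dplyr::all_of(outputs)) |>
    tidyr::pivot_longer(dplyr::everything(),
      names_to = "output", values_to = "value"
    ) |>
    dplyr::filter(is.finite(.data$value), .data$value > 0)
  marks <- object$summary |>
    dplyr::filter(.data$output %in% outputs) |>
    tidyr::pivot_longer(c("mode", "p5", "p95"),
      names_to = "statistic", values_to = "value"
    )
  ggplot2::ggplot(long, ggplot2::aes(x = .data$value)) +
    ggplot2::geom_density(fill = "grey85", colour = "grey30") +
    ggplot2::geom_vline(
      data = marks,
      ggplot2::aes(xintercept = .data$value, linetype = .data$statistic),
      colour = "steelblue"
    ) +
    ggplot2::scale_x_log10() +
    ggplot2::scale_linetype_manual(
      values = c(mode = "solid", p5 = "dashed", p95 = "dashed")
    ) +
    ggplot2::facet_wrap(~output, scales = "free") +
    ggplot2::labs(
      x = "value (log scale)", y = "density",
      linetype = NULL,
      title = "Simulated output distributions",
      subtitle = "mode (solid) and 5th/95th percentiles (dashed)"
    )
}
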
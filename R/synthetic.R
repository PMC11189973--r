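#' Generate a synthetic field study
#'
#' Emulates the per-plot records of a phytoextraction field experiment:
#' soil concentration, tissue concentrations (stems, leaves, roots) and
#' harvested dry weights for each plot, generated around known true BAF, BMP
#' and translocation-factor values with multiplicative lognormal noise
#' (concentrations and biomasses are positive and right-skewed, so
#' mean-one lognormal noise is the natural perturbation). Used to exercise
#' the replicate-fitting path ([fit_from_replicates()]) and for
#' parameter-recovery testing; it is synthetic plumbing, not field data.
#'
#' Features of real field campaigns that are deliberately not emulated:
#' spatial correlation between neighbouring plots, measurement censoring at
#' detection limits, and year effects.
#'
#' @param truth Named list of generating values: `c_soil` (mg/kg dw),
#'   `baf_stem`, `baf_leaves`, `tf` (stem/root concentration ratio),
#'   `bmp_stem`, `bmp_leaves`, `bmp_root` (kg dw/m2/yr), `area` (plot m2).
#'   Defaults are the site-specific means.
#' @param n_plots Number of plots (`>= 3`).
#' @param noise_cv Coefficient of variation of the lognormal noise (`>= 0`;
#'   `0` gives exact noiseless records).
#' @param seed Optional seed for reproducibility.
#' @return A tibble with one row per plot (`plot`, `c_soil`, `c_stem`,
#'   `c_leaves`, `c_root`, `dw_stem`, `dw_leaves`, `dw_root`, `area`,
#'   `imputed`), carrying `truth` as an attribute.
#' @examples
#' study <- generate_synthetic_study(n_plots = 6, noise_cv = 0.3, seed = 1)
#' fit_study(study)
#' @export
generate_synthetic_study <- function(truth = list(), n_plots = 6,
                                     noise_cv = 0.3, seed = NULL) {
  defaults <- list(
    c_soil = 10, baf_stem = 0.89, baf_leaves = 0.13, tf = 1.2,
    bmp_stem = 0.0783, bmp_leaves = 0.190, bmp_root = 0.05, area = 1
  )
  truth <- utils::modifyList(defaults, truth)
  if (any(unlist(truth) <= 0)) stop("truth values must be > 0", call. = FALSE)
  if (n_plots < 3) stop("n_plots must be >= 3", call. = FALSE)
  if (noise_cv < 0) stop("noise_cv must be >= 0", call. = FALSE)

  gen <- function() {
    noise <- function(n) {
      if (noise_cv == 0) {
        rep(1, n)
      } else {
        s2 <- log(1 + noise_cv^2)
        rlnorm(n, meanlog = -s2 / 2, sdlog = sqrt(s2)) # mean-one noise
      }
    }
    c_soil <- truth$c_soil * noise(n_plots)
    c_stem <- truth$baf_stem * c_soil * noise(n_plots)
    tibble::tibble(
      plot = seq_len(n_plots),
      c_soil = c_soil,
      c_stem = c_stem,
      c_leaves = truth$baf_leaves * c_soil * noise(n_plots),
      c_root = c_stem / truth$tf * noise(n_plots),
      dw_stem = truth$bmp_stem * truth$area * noise(n_plots),
      dw_leaves = truth$bmp_leaves * truth$area * noise(n_plots),
      dw_root = truth$bmp_root * truth$area * noise(n_plots),
      area = truth$area,
      imputed = FALSE
    )
  }
  study <- if (is.null(seed)) gen() else withr::with_seed(seed, gen())
  attr(study, "truth") <- truth
  study
}

#' Per-plot replicate values derived from a field study
#'
#' Computes per-plot BAF (tissue / soil concentration) and BMP (dry weight /
#' plot area) replicates — the quantities [fit_from_replicates()] consumes.
#'
#' @param study A study tibble as from [generate_synthetic_study()].
#' @return Tibble with columns `plot`, `baf_stem`, `baf_leaves`, `bmp_stem`,
#'   `bmp_leaves`, `tf`.
#' @export
study_replicates <- function(study) {
  dplyr::transmute(study,
    plot = .data$plot,
    baf_stem = .data$c_stem / .data$c_soil,
    baf_leaves = .data$c_leaves / .data$c_soil,
    bmp_stem = .data$dw_stem / .data$area,
    bmp_leaves = .data$dw_leaves / .data$area,
    tf = .data$c_stem / .data$c_root
  )
}

#' Fit input distributions from a field study
#'
#' Runs [fit_from_replicates()] on the per-plot BAF/BMP replicates of a
#' study, giving the four named specifications a simulation needs.
#'
#' @inheritParams study_replicates
#' @return Named list of four [phyto_dist] objects.
#' @export
fit_study <- function(study) {
  reps <- study_replicates(study)
  vars <- c("baf_stem", "baf_leaves", "bmp_stem", "bmp_leaves")
  lapply(setNames(vars, vars), function(v) fit_from_replicates(reps[[v]]))
}

#' Repair a study with damaged above-ground harvests
#'
#' Plots whose stems were destroyed before harvest (recorded as `NA`
#' `c_stem`) are completed by extrapolating the stem concentration from the
#' surviving root measurement and a reference translocation factor:
#' `c_stem = tf_reference * c_root`. Imputed rows are flagged; plots missing
#' the root measurement as well are dropped with a warning.
#'
#' @param study A study tibble, possibly with `NA` stem concentrations.
#' @param tf_reference Reference translocation factor (`> 0`). When `NULL`,
#'   derived as the mean `c_stem / c_root` of the intact plots.
#' @return The completed study tibble with the `imputed` flag set on
#'   repaired rows.
#' @export
adjust_damaged_harvest <- function(study, tf_reference = NULL) {
  damaged <- is.na(study$c_stem)
  if (!any(damaged)) {
    return(study)
  }
  if (is.null(tf_reference)) {
    intact <- !damaged & !is.na(study$c_root)
    if (!any(intact)) {
      stop("no intact plots to derive a reference translocation factor",
        call. = FALSE
      )
    }
    tf_reference <- mean(
      translocation_factor(study$c_stem[intact], study$c_root[intact])
    )
  }
  if (tf_reference <= 0) stop("tf_reference must be > 0", call. = FALSE)
  no_root <- damaged & is.na(study$c_root)
  if (any(no_root)) {
    warning(
      sum(no_root), " damaged plot(s) also lack root data and were dropped",
      call. = FALSE
    )
    study <- study[!no_root, ]
    damaged <- is.na(study$c_stem)
  }
  study$c_stem[damaged] <- stem_concentration_from_tf(
    tf_reference, study$c_root[damaged]
  )
  study$imputed[damaged] <- TRUE
  study
}
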
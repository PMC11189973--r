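#' Declarative input distributions
#'
#' Uncertain model inputs (bioaccumulation factors, biomass production) are
#' described by small declarative specification objects rather than raw
#' sampler functions, so a whole simulation configuration can be printed,
#' serialised and replayed. Three kinds are supported:
#'
#' * `dist_pert(min, mode, max)` — a Beta-PERT distribution, the standard
#'   three-point ("minimum / most likely / maximum") elicitation distribution:
#'   a Beta rescaled to `[min, max]` with shape parameters
#'   `alpha1 = 1 + 4 (mode - min)/(max - min)` and
#'   `alpha2 = 1 + 4 (max - mode)/(max - min)`, implying mean
#'   `(min + 4 mode + max)/6`.
#' * `dist_normal(mean, sd)` — a Normal distribution, by default truncated at
#'   zero (negative draws rejected and resampled) because BAF and BMP are
#'   physically non-negative.
#' * `dist_point(value)` — a degenerate point mass, used for fixed inputs and
#'   for sweep levers.
#'
#' @param min,mode,max Beta-PERT minimum, most-likely and maximum values;
#'   `min <= mode <= max` is required. A degenerate `min == max` collapses to
#'   a point mass.
#' @param mean,sd Normal mean and standard deviation (`sd >= 0`; `sd == 0`
#'   collapses to a point mass).
#' @param truncate_at_zero Reject negative draws and resample (default `TRUE`).
#' @param value The value of a point mass.
#'
#' @return An object of class `phyto_dist`.
#' @examples
#' dist_pert(0, 1, 2)
#' dist_normal(5.74, 3.35)
#' dist_sample(dist_point(2), 3)
#' @name phyto_dist
NULL

new_phyto_dist <- function(kind, params, truncate_at_zero = FALSE) {
  structure(
    list(kind = kind, params = params, truncate_at_zero = truncate_at_zero),
    class = "phyto_dist"
  )
}

#' @rdname phyto_dist
#' @export
dist_pert <- function(min, mode, max) {
  stopifnot(is.numeric(min), is.numeric(mode), is.numeric(max))
  if (!(min <= mode && mode <= max)) {
    stop("PERT requires min <= mode <= max", call. = FALSE)
  }
  if (max - min < .Machine$double.eps * base::max(1, abs(max))) {
    return(dist_point(mode))
  }
  new_phyto_dist("pert", list(min = min, mode = mode, max = max))
}

#' @rdname phyto_dist
#' @export
dist_normal <- function(mean, sd, truncate_at_zero = TRUE) {
  stopifnot(is.numeric(mean), is.numeric(sd))
  if (sd < 0) stop("sd must be >= 0", call. = FALSE)
  if (sd == 0) return(dist_point(mean))
  new_phyto_dist("normal", list(mean = mean, sd = sd), truncate_at_zero)
}

#' @rdname phyto_dist
#' @export
dist_point <- function(value) {
  stopifnot(is.numeric(value))
  new_phyto_dist("point", list(value = value))
}

#' @export
print.phyto_dist <- function(x, ...) {
  cat(format(x), "\n")
  invisible(x)
}

#' @export
format.phyto_dist <- function(x, ...) {
  p <- x$params
  switch(x$kind,
    pert = sprintf("<pert min=%g mode=%g max=%g>", p$min, p$mode, p$max),
    normal = sprintf(
      "<normal mean=%g sd=%g%s>", p$mean, p$sd,
      if (x$truncate_at_zero) " truncated at 0" else ""
    ),
    point = sprintf("<point %g>", p$value)
  )
}

#' Beta-PERT shape parameters
#'
#' The two shape parameters of the Beta distribution underlying a PERT
#' specification on `[min, max]`.
#'
#' @inheritParams phyto_dist
#' @return Named numeric vector `c(alpha1, alpha2)`.
#' @examples
#' pert_shape(0, 1, 2) # symmetric: c(3, 3)
#' @export
pert_shape <- function(min, mode, max) {
  if (!(min < max)) stop("PERT shape requires min < max", call. = FALSE)
  if (!(min <= mode && mode <= max)) {
    stop("PERT requires min <= mode <= max", call. = FALSE)
  }
  c(
    alpha1 = 1 + 4 * (mode - min) / (max - min),
    alpha2 = 1 + 4 * (max - mode) / (max - min)
  )
}

#' Theoretical mean of a distribution specification
#'
#' Closed-form mean: `(min + 4 mode + max)/6` for PERT, the zero-truncated
#' Normal mean `mean + sd * phi(a)/(1 - Phi(a))` with `a = -mean/sd` when
#' truncation is active, and the value itself for a point mass. Used as the
#' independent oracle in simulation-mean checks.
#'
#' @param spec A `phyto_dist`.
#' @return A number.
#' @export
dist_mean <- function(spec) {
  stopifnot(inherits(spec, "phyto_dist"))
  p <- spec$params
  switch(spec$kind,
    point = p$value,
    pert = (p$min + 4 * p$mode + p$max) / 6,
    normal = {
      if (spec$truncate_at_zero) {
        a <- -p$mean / p$sd
        p$mean + p$sd * dnorm(a) / (1 - pnorm(a))
      } else {
        p$mean
      }
    }
  )
}

#' Fit a PERT specification from replicate measurements
#'
#' Builds a Beta-PERT from a set of replicate field measurements: the sample
#' minimum and maximum become the PERT range and the most-likely value is
#' chosen so that the PERT mean equals the sample mean
#' (`mode = (6 mean - min - max)/4`, clamped into `[min, max]`). A sample mode
#' of a handful of replicates is ill-defined; preserving the sample mean is
#' both stable and exactly invertible.
#'
#' @param values Numeric vector of at least 3 finite, non-negative replicates.
#' @return A `phyto_dist` (`pert`, or `point` if all values are equal).
#' @examples
#' fit_from_replicates(c(0, 1, 2))
#' @export
fit_from_replicates <- function(values) {
  values <- as.numeric(values)
  if (length(values) < 3 || any(!is.finite(values))) {
    stop("need at least 3 finite replicate values", call. = FALSE)
  }
  if (any(values < 0)) stop("replicates must be non-negative", call. = FALSE)
  a <- min(values)
  c_ <- max(values)
  if (c_ - a < .Machine$double.eps * max(1, c_)) return(dist_point(a))
  b <- (6 * mean(values) - a - c_) / 4
  dist_pert(a, min(max(b, a), c_), c_)
}

#' Fit a specification from printed summary statistics
#'
#' When only a mean and standard deviation are reported (the usual situation
#' for literature-derived parameters), two constructions are available:
#'
#' * `kind = "normal"`: a zero-truncated Normal — faithful to the printed
#'   moments and keeps genuine mass near zero (appropriate when the underlying
#'   data include near-failures, e.g. a destroyed harvest season).
#' * `kind = "pert"`: a Beta-PERT whose range is reconstructed as
#'   `mean +/- d_n * sd`, where `d_n` is the expected deviation of the extreme
#'   order statistic of a Normal sample of size `n` (`d_6 = 1.267`,
#'   `d_15 = 1.736`), i.e. the range one would expect the original sample of
#'   `n` values to have shown; the most-likely value preserves the mean via
#'   the PERT identity and the lower bound is clamped at zero. Appropriate
#'   when the summarised collection is known to have a bounded range.
#'
#' @param mean Reported mean (must be `> 0`).
#' @param sd Reported standard deviation (`>= 0`; `0` gives a point mass).
#' @param kind `"normal"` (default) or `"pert"`.
#' @param n Sample size behind the summary; required for `kind = "pert"`.
#' @return A `phyto_dist`.
#' @examples
#' fit_from_summary(5.74, 3.35)
#' fit_from_summary(5.74, 3.35, kind = "pert", n = 15)
#' @export
fit_from_summary <- function(mean, sd, kind = c("normal", "pert"), n = NULL) {
  kind <- match.arg(kind)
  if (!is.numeric(mean) || mean <= 0) {
    stop("summary mean must be > 0", call. = FALSE)
  }
  if (!is.numeric(sd) || sd < 0) stop("sd must be >= 0", call. = FALSE)
  if (sd == 0) return(dist_point(mean))
  if (kind == "normal") {
    return(dist_normal(mean, sd, truncate_at_zero = TRUE))
  }
  if (is.null(n) || n < 2) {
    stop("kind = \"pert\" needs the sample size n behind the summary",
      call. = FALSE
    )
  }
  d <- expected_extreme_deviation(n)
  a <- max(0, mean - d * sd)
  c_ <- mean + d * sd
  b <- min(max((6 * mean - a - c_) / 4, a), c_)
  dist_pert(a, b, c_)
}

#' Expected standardised extreme of a Normal sample
#'
#' `E[max(Z_1, ..., Z_n)]` for standard-Normal draws, by numerical
#' integration of the order-statistic density. Used to reconstruct a plausible
#' sample range from a printed mean, SD and sample size.
#'
#' @param n Sample size (`>= 2`).
#' @return A positive number (1.267 for n = 6, 1.736 for n = 15).
#' @export
expected_extreme_deviation <- function(n) {
  stopifnot(n >= 2)
  stats::integrate(
    function(x) x * n * dnorm(x) * pnorm(x)^(n - 1),
    -Inf, Inf
  )$value
}

#' Sample from a distribution specification
#'
#' Draws `n` values. Truncated-Normal specifications use rejection resampling
#' (never clipping, which would pile probability mass at zero and distort the
#' mode statistic); a specification whose acceptance probability is below 1%
#' is rejected as unusable. Reproducible under `set.seed()`.
#'
#' @param spec A `phyto_dist`.
#' @param n Number of draws (`>= 1`).
#' @return Numeric vector of length `n`; all values non-negative when the
#'   specification is truncated or bounded at zero.
#' @examples
#' set.seed(1)
#' dist_sample(dist_pert(0, 1, 2), 5)
#' @export
dist_sample <- function(spec, n) {
  stopifnot(inherits(spec, "phyto_dist"), n >= 1)
  p <- spec$params
  switch(spec$kind,
    point = rep(p$value, n),
    pert = {
      sh <- pert_shape(p$min, p$mode, p$max)
      p$min + (p$max - p$min) * rbeta(n, sh[["alpha1"]], sh[["alpha2"]])
    },
    normal = {
      if (!spec$truncate_at_zero) {
        return(rnorm(n, p$mean, p$sd))
      }
      accept <- 1 - pnorm(0, p$mean, p$sd)
      if (accept < 0.01) {
        stop(
          "truncated-normal spec has acceptance probability < 1%; ",
          "mean is too far below zero", call. = FALSE
        )
      }
      out <- numeric(0)
      while (length(out) < n) {
        batch <- rnorm(ceiling((n - length(out)) / accept) + 10, p$mean, p$sd)
        out <- c(out, batch[batch >= 0])
      }
      out[seq_len(n)]
    }
  )
}

#' Serialise / deserialise a distribution specification
#'
#' Plain-list form used in JSON/YAML run configurations:
#' `list(kind = "pert|normal|point", params = list(...), truncate_at_zero =
#' logical)`.
#'
#' @param spec A `phyto_dist`.
#' @param config A plain list in the serialised form.
#' @return `dist_config()` returns a plain list; `dist_from_config()` a
#'   `phyto_dist`.
#' @export
dist_config <- function(spec) {
  stopifnot(inherits(spec, "phyto_dist"))
  list(
    kind = spec$kind,
    params = spec$params,
    truncate_at_zero = isTRUE(spec$truncate_at_zero)
  )
}

#' @rdname dist_config
#' @export
dist_from_config <- function(config) {
  stopifnot(is.list(config), !is.null(config$kind))
  p <- lapply(config$params, as.numeric)
  switch(as.character(config$kind),
    pert = dist_pert(p$min, p$mode, p$max),
    normal = dist_normal(p$mean, p$sd, isTRUE(config$truncate_at_zero)),
    point = dist_point(p$value),
    stop("unknown distribution kind: ", config$kind, call. = FALSE)
  )
}
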
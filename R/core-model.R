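#' Soil compartment undergoing phytoextraction
#'
#' The fixed soil-side geometry and concentrations of a run: initial and
#' target contaminant concentrations, bulk density, depth and area. The
#' defaults describe a 1 m2 unit area of the field to plough depth (0.35 m)
#' at a bulk density of 1500 kg/m3, with the Swedish soil guideline value of
#' 1 mg/kg dw as target.
#'
#' @param c_soil_i Initial soil concentration, mg contaminant / kg soil dw
#'   (`> 0`).
#' @param c_target Target (final) soil concentration, mg/kg dw
#'   (`0 <= c_target < c_soil_i`).
#' @param bulk_density Soil bulk density, kg/m3 (`> 0`).
#' @param depth Treated depth, m (`> 0`).
#' @param area Treated area, m2 (`> 0`).
#' @return An object of class `soil_compartment`.
#' @examples
#' soil <- soil_compartment(c_soil_i = 10)
#' soil_mass(soil) # 5250 mg over 1 m2 x 0.35 m at 1500 kg/m3
#' @export
soil_compartment <- function(c_soil_i, c_target = 1, bulk_density = 1500,
                             depth = 0.35, area = 1) {
  stopifnot(
    is.numeric(c_soil_i), is.numeric(c_target), is.numeric(bulk_density),
    is.numeric(depth), is.numeric(area)
  )
  if (c_soil_i <= 0) stop("c_soil_i must be > 0", call. = FALSE)
  if (c_target < 0 || c_target >= c_soil_i) {
    stop("c_target must satisfy 0 <= c_target < c_soil_i", call. = FALSE)
  }
  if (bulk_density <= 0 || depth <= 0 || area <= 0) {
    stop("bulk_density, depth and area must all be > 0", call. = FALSE)
  }
  structure(
    list(
      c_soil_i = c_soil_i, c_target = c_target,
      bulk_density = bulk_density, depth = depth, area = area,
      volume = area * depth
    ),
    class = "soil_compartment"
  )
}

#' @export
print.soil_compartment <- function(x, ...) {
  cat(sprintf(
    "<soil_compartment %g -> %g mg/kg dw, %g kg/m3 x %g m3 (m_i = %g mg)>\n",
    x$c_soil_i, x$c_target, x$bulk_density, x$volume, soil_mass(x)
  ))
  invisible(x)
}

#' Contaminant mass in the soil compartment
#'
#' `m_soil = rho * V * C_soil`: with density in kg/m3, volume in m3 and
#' concentration in mg/kg the result is in mg.
#'
#' @param soil A [soil_compartment()].
#' @param c_soil Concentration to evaluate at, mg/kg dw; defaults to the
#'   compartment's initial concentration.
#' @return Mass in mg (vectorised over `c_soil`).
#' @export
soil_mass <- function(soil, c_soil = soil$c_soil_i) {
  stopifnot(inherits(soil, "soil_compartment"), is.numeric(c_soil))
  if (any(c_soil < 0)) stop("concentration must be >= 0", call. = FALSE)
  soil$bulk_density * soil$volume * c_soil
}

#' Tissue concentration implied by a bioaccumulation factor
#'
#' Inverts the BAF definition `BAF = C_plant / C_soil`.
#'
#' @param baf Bioaccumulation factor, (mg/kg plant dw)/(mg/kg soil dw),
#'   `>= 0`.
#' @param c_soil Soil concentration, mg/kg dw (`> 0`).
#' @return Plant-tissue concentration, mg/kg dw.
#' @export
plant_concentration <- function(baf, c_soil) {
  stopifnot(is.numeric(baf), is.numeric(c_soil))
  if (any(c_soil <= 0)) stop("c_soil must be > 0", call. = FALSE)
  if (any(baf < 0)) stop("baf must be >= 0", call. = FALSE)
  baf * c_soil
}

#' Annual contaminant extraction potential
#'
#' `E = (BAF_stem * C_soil,i) * BMP_stem + (BAF_leaves * C_soil,i) *
#' BMP_leaves`, optionally scaled by an efficiency factor. Stems and leaves
#' are the only harvest compartments (fruits are excluded for lack of data;
#' roots are not harvested). All arguments are vectorised.
#'
#' @param baf_stem,baf_leaves Bioaccumulation factors (dimensionless, `>= 0`).
#' @param bmp_stem,bmp_leaves Harvestable biomass production, kg dw per m2
#'   per year (`>= 0`).
#' @param c_soil_i Initial soil concentration, mg/kg dw (`> 0`).
#' @param efficiency Multiplicative efficiency factor on E (fraction, `> 0`).
#' @return Extraction potential in mg contaminant per year (per m2 when BMP
#'   is per m2).
#' @examples
#' extraction_potential(5.74, 0.435, 0.799, 0.410, c_soil_i = 10) # 47.646
#' @export
extraction_potential <- function(baf_stem, baf_leaves, bmp_stem, bmp_leaves,
                                 c_soil_i, efficiency = 1) {
  if (any(c(baf_stem, baf_leaves, bmp_stem, bmp_leaves) < 0)) {
    stop("BAF and BMP values must be >= 0", call. = FALSE)
  }
  if (any(c_soil_i <= 0)) stop("c_soil_i must be > 0", call. = FALSE)
  if (any(efficiency <= 0)) stop("efficiency must be > 0", call. = FALSE)
  efficiency *
    ((baf_stem * c_soil_i) * bmp_stem + (baf_leaves * c_soil_i) * bmp_leaves)
}

#' Annual removal rate
#'
#' `k = E / m_soil,i`, the fraction of the initial soil contaminant mass
#' removed per year. Stored as a fraction; multiply by 100 (or use
#' [format_percent()]) only at the reporting boundary, since the exponential
#' model needs the fractional form.
#'
#' @param e Extraction potential, mg/year (`>= 0`).
#' @param m_soil_i Initial soil contaminant mass, mg (`> 0`).
#' @return Removal rate, fraction per year.
#' @export
removal_rate <- function(e, m_soil_i) {
  if (any(e < 0)) stop("e must be >= 0", call. = FALSE)
  if (any(m_soil_i <= 0)) stop("m_soil_i must be > 0", call. = FALSE)
  e / m_soil_i
}

#' Remediation time, linear steady-state model
#'
#' `t = (m_i - m_f) / E`: with extraction held constant, the theoretically
#' shortest possible time. Returns `Inf` when `E = 0` and mass must still be
#' removed — zero extraction never reaches the target, and Monte Carlo draws
#' can legitimately produce a zero after truncation, so this is a documented
#' sentinel rather than an error.
#'
#' @param m_i Initial contaminant mass, mg (`>= m_f`).
#' @param m_f Final (target) contaminant mass, mg (`>= 0`).
#' @param e Extraction potential, mg/year (`>= 0`).
#' @return Years (vectorised; `Inf` where `e = 0` and `m_i > m_f`).
#' @export
time_linear <- function(m_i, m_f, e) {
  if (any(m_f < 0)) stop("m_f must be >= 0", call. = FALSE)
  if (any(m_f > m_i)) stop("m_f must not exceed m_i", call. = FALSE)
  if (any(e < 0)) stop("e must be >= 0", call. = FALSE)
  out <- (m_i - m_f) / e
  out[m_i == m_f] <- 0 # 0/0 when e is also zero
  out
}

#' Remediation time, first-order exponential decay model
#'
#' `t = ln(m_i / m_f) / k`, the time for a removal proportional to the
#' remaining pool to reach the target mass. The exponential model never
#' reaches zero mass, so `m_f = 0` is a domain error; `k = 0` yields the
#' `Inf` sentinel.
#'
#' @param m_i Initial contaminant mass, mg.
#' @param m_f Final mass, mg (`0 < m_f <= m_i`).
#' @param k Removal rate, fraction per year (`>= 0`).
#' @return Years (vectorised; `Inf` where `k = 0` and `m_i > m_f`).
#' @export
time_exponential <- function(m_i, m_f, k) {
  if (any(m_f <= 0)) {
    stop("m_f must be > 0: the exponential model never reaches zero",
      call. = FALSE
    )
  }
  if (any(m_f > m_i)) stop("m_f must not exceed m_i", call. = FALSE)
  if (any(k < 0)) stop("k must be >= 0", call. = FALSE)
  out <- log(m_i / m_f) / k
  out[m_i == m_f] <- 0
  out
}

#' Contaminant mass remaining after t years
#'
#' Exponential: `m(t) = m_i * exp(-k t)`. Linear: constant annual removal
#' `k * m_i`, floored at zero once the pool is exhausted.
#'
#' @param m_i Initial mass, mg.
#' @param k Removal rate, fraction per year.
#' @param t Time, years (`>= 0`).
#' @param model `"exponential"` or `"linear"`.
#' @return Mass in mg.
#' @export
mass_at_time <- function(m_i, k, t, model = c("exponential", "linear")) {
  model <- match.arg(model)
  if (any(t < 0)) stop("t must be >= 0", call. = FALSE)
  if (model == "exponential") m_i * exp(-k * t) else pmax(0, m_i * (1 - k * t))
}

#' Translocation factor and stem-concentration repair
#'
#' `TF = C_stem / C_root`, the ratio of stem to root tissue concentration.
#' Its inverse use, `C_stem = TF * C_root`, extrapolates the stem uptake of
#' plots whose above-ground harvest was lost (e.g. eaten by slugs) from the
#' surviving root measurements and a reference TF from an intact season.
#'
#' @param c_stem Stem concentration, mg/kg dw (`>= 0`).
#' @param c_root Root concentration, mg/kg dw (`> 0`).
#' @param tf Reference translocation factor (`> 0`).
#' @return `translocation_factor()`: dimensionless ratio;
#'   `stem_concentration_from_tf()`: mg/kg dw.
#' @export
translocation_factor <- function(c_stem, c_root) {
  if (any(c_root <= 0)) stop("c_root must be > 0", call. = FALSE)
  if (any(c_stem < 0)) stop("c_stem must be >= 0", call. = FALSE)
  c_stem / c_root
}

#' @rdname translocation_factor
#' @export
stem_concentration_from_tf <- function(tf, c_root) {
  if (any(tf <= 0)) stop("tf must be > 0", call. = FALSE)
  if (any(c_root <= 0)) stop("c_root must be > 0", call. = FALSE)
  tf * c_root
}
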
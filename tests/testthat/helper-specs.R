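# Shared fixtures: point-valued specifications at the dataset means, and a
# standard 10 -> 1 mg/kg dw soil compartment.

lit_means <- c(
  baf_stem = 5.74, baf_leaves = 0.435, bmp_stem = 0.799, bmp_leaves = 0.410
)
site_means <- c(
  baf_stem = 0.89, baf_leaves = 0.134, bmp_stem = 0.0783, bmp_leaves = 0.190
)

point_specs <- function(values) {
  lapply(as.list(values), dist_point)
}

soil_10 <- function() soil_compartment(c_soil_i = 10, c_target = 1)
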
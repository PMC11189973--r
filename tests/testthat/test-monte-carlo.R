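# The Monte Carlo engine: propagation, summaries, mode estimation and
# Spearman sensitivity.

test_that("point-valued inputs reduce the simulation to the arithmetic", {
  sim <- run_simulation(point_specs(lit_means), soil_10(),
    n_iterations = 200, seed = 1
  )
  e_oracle <- 5.74 * 10 * 0.799 + 0.435 * 10 * 0.410
  expect_true(all(sim$draws$e == e_oracle))
  expect_true(all(sim$draws$t_linear == 4725 / e_oracle))
  expect_equal(glance(sim)$t_linear_mode, 4725 / e_oracle)
  # doubling both biomass inputs halves the linear time exactly
  doubled <- point_specs(lit_means * c(1, 1, 2, 2))
  sim2 <- run_simulation(doubled, soil_10(), n_iterations = 200, seed = 1)
  expect_equal(sim2$draws$t_linear, sim$draws$t_linear / 2)
})

test_that("mode estimation finds the density peak", {
  expect_equal(estimate_mode(rep(3.2, 500)), 3.2)
  x <- withr::with_seed(1, rnorm(1e5, 10, 1))
  expect_equal(estimate_mode(x), 10, tolerance = 0.02)
  # lognormal(0, 1) has closed-form mode exp(-1)
  y <- withr::with_seed(2, rlnorm(1e5))
  expect_equal(estimate_mode(y), exp(-1), tolerance = 0.1)
  # the mode never leaves the observed range
  z <- withr::with_seed(3, rexp(5000))
  m <- estimate_mode(z)
  expect_true(m >= min(z) && m <= max(z))
})

test_that("percentile interval matches closed-form quantiles", {
  u <- withr::with_seed(4, runif(1e5))
  pi_ <- percentile_interval(u)
  expect_equal(unname(pi_), c(0.05, 0.95), tolerance = 0.01)
  expect_equal(unname(percentile_interval(rep(7, 200))), c(7, 7))
  x <- withr::with_seed(5, rgamma(5000, 2))
  expect_lt(percentile_interval(x)[["p5"]], median(x))
  expect_gt(percentile_interval(x)[["p95"]], median(x))
})

test_that("summary invariants hold for distributional inputs", {
  sim <- run_simulation(dataset_specs("literature"), soil_10(),
    n_iterations = 2000, seed = 7
  )
  s <- sim$summary
  expect_true(all(s$p5 <= s$p50 & s$p50 <= s$p95))
  for (out in s$output) {
    x <- sim$draws[[out]]
    expect_true(s$mode[s$output == out] >= min(x))
    expect_true(s$mode[s$output == out] <= max(x))
  }
  expect_equal(nrow(sim$draws), 2000)
  # per-draw model ordering at a 90% reduction
  fin <- is.finite(sim$draws$t_linear) & is.finite(sim$draws$t_exponential)
  expect_true(all(
    sim$draws$t_exponential[fin] >= sim$draws$t_linear[fin]
  ))
})

test_that("simulation mean of E matches the independent-product oracle", {
  specs <- dataset_specs("literature")
  sim <- run_simulation(specs, soil_10(), n_iterations = 10000, seed = 11)
  closed <- 10 * (
    dist_mean(specs$baf_stem) * dist_mean(specs$bmp_stem) +
      dist_mean(specs$baf_leaves) * dist_mean(specs$bmp_leaves)
  )
  se <- sd(sim$draws$e) / sqrt(nrow(sim$draws))
  expect_lt(abs(mean(sim$draws$e) - closed), 3 * se)
})

test_that("identical seed and config reproduce the run bitwise", {
  specs <- dataset_specs("site_specific")
  a <- run_simulation(specs, soil_10(), n_iterations = 500, seed = 99)
  b <- run_simulation(specs, soil_10(), n_iterations = 500, seed = 99)
  expect_identical(a$summary, b$summary)
  expect_identical(a$draws, b$draws)
})

test_that("rank sensitivity identifies the dominant input", {
  # only baf_stem varies: E is a strictly increasing function of it
  specs <- point_specs(lit_means)
  specs$baf_stem <- dist_pert(1, 5, 12)
  sim <- run_simulation(specs, soil_10(), n_iterations = 500, seed = 3)
  sens <- sim$sensitivity
  e_rows <- sens[sens$output == "e", ]
  expect_equal(e_rows$rho[e_rows$input == "baf_stem"], 1)
  expect_true(all(e_rows$constant[e_rows$input != "baf_stem"]))
  expect_true(all(e_rows$rho[e_rows$input != "baf_stem"] == 0))
  # t_linear is strictly decreasing in the same input
  t_rows <- sens[sens$output == "t_linear", ]
  expect_equal(t_rows$rho[t_rows$input == "baf_stem"], -1)
  # with the full literature distributions the stem BAF dominates the leaf
  sim2 <- run_simulation(dataset_specs("literature"), soil_10(),
    n_iterations = 4000, seed = 13
  )
  s2 <- sim2$sensitivity[sim2$sensitivity$output == "e", ]
  expect_gt(
    abs(s2$rho[s2$input == "baf_stem"]),
    abs(s2$rho[s2$input == "baf_leaves"])
  )
})

test_that("zero extraction flags a degenerate simulation", {
  specs <- point_specs(c(
    baf_stem = 0, baf_leaves = 0, bmp_stem = 0.8, bmp_leaves = 0.4
  ))
  expect_warning(
    sim <- run_simulation(specs, soil_10(), n_iterations = 200, seed = 1),
    "degenerate"
  )
  expect_true(sim$degenerate)
  s <- sim$summary
  expect_equal(s$share_infinite[s$output == "t_linear"], 1)
})

test_that("config round-trips through the JSON echo", {
  cfg <- parse_run_config(list(
    dataset = "literature",
    soil = list(c_soil_i = 10, c_target = 1),
    n_iterations = 300, seed = 5
  ))
  sim <- run_simulation(cfg$specs, cfg$soil,
    n_iterations = cfg$n_iterations, seed = cfg$seed
  )
  path <- withr::local_tempfile(fileext = ".json")
  write_simulation_json(sim, path)
  cfg2 <- parse_run_config(path)
  sim2 <- run_simulation(cfg2$specs, cfg2$soil,
    n_iterations = cfg2$n_iterations, seed = cfg2$seed
  )
  expect_equal(sim$summary, sim2$summary)
  expect_error(
    parse_run_config(list(soil = list(c_soil_i = 10))), "dataset"
  )
  expect_error(
    parse_run_config(list(dataset = "literature", soil = list())),
    "c_soil_i"
  )
})

test_that("tidy, glance and autoplot expose the result", {
  sim <- run_simulation(dataset_specs("literature"), soil_10(),
    n_iterations = 500, seed = 2
  )
  td <- tidy(sim)
  expect_s3_class(td, "tbl_df")
  expect_setequal(td$output, c("e", "k", "t_linear", "t_exponential"))
  gl <- glance(sim)
  expect_equal(gl$m_soil_i, 5250)
  expect_equal(gl$m_soil_f, 525)
  p <- ggplot2::autoplot(sim)
  expect_s3_class(p, "ggplot")
})
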
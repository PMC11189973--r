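# Deterministic mass-balance arithmetic: extraction potential, soil mass,
# removal rate and the two remediation-time models.

test_that("soil mass follows rho * V * C with the field defaults", {
  soil <- soil_10()
  expect_equal(soil_mass(soil), 1500 * 0.35 * 10) # 5250 mg
  expect_equal(soil_mass(soil, 2), 1050)
  expect_equal(soil_mass(soil, 0), 0)
  # unit consistency: the default compartment weighs 525 mg per mg/kg
  cs <- c(0.1, 1, 2.7, 9, 15)
  expect_equal(soil_mass(soil, cs), 525 * cs)
  expect_error(soil_mass(soil, -1), "concentration")
})

test_that("soil compartment validates its geometry and concentrations", {
  expect_error(soil_compartment(0), "c_soil_i")
  expect_error(soil_compartment(10, c_target = 10), "c_target")
  expect_error(soil_compartment(10, c_target = -1), "c_target")
  expect_error(soil_compartment(10, depth = 0), "> 0")
  expect_equal(soil_compartment(10, depth = 0.5, area = 2)$volume, 1)
})

test_that("plant concentration inverts the BAF definition", {
  expect_equal(plant_concentration(0.89, 10), 8.9)
  expect_equal(plant_concentration(5.74, 10), 57.4)
  expect_equal(plant_concentration(0, 10), 0)
  expect_error(plant_concentration(0.5, 0), "c_soil")
  expect_error(plant_concentration(-0.1, 10), "baf")
})

test_that("extraction potential sums the stem and leaf harvest terms", {
  # hand arithmetic on the two-tissue sum at the dataset means
  lit_e <- 5.74 * 10 * 0.799 + 0.435 * 10 * 0.410
  expect_equal(
    extraction_potential(5.74, 0.435, 0.799, 0.410, c_soil_i = 10), lit_e
  )
  expect_equal(lit_e, 47.6461, tolerance = 1e-6)
  site_e <- 0.89 * 10 * 0.0783 + 0.134 * 10 * 0.190
  expect_equal(
    extraction_potential(0.89, 0.134, 0.0783, 0.190, c_soil_i = 10), site_e
  )
  expect_equal(site_e, 0.95147, tolerance = 1e-6)
  expect_equal(extraction_potential(0, 0, 0.8, 0.4, c_soil_i = 10), 0)
  # efficiency factor scales E linearly
  expect_equal(
    extraction_potential(5.74, 0.435, 0.799, 0.410, 10, efficiency = 1.55),
    1.55 * lit_e
  )
  expect_error(extraction_potential(-1, 0, 1, 1, 10), ">= 0")
})

test_that("removal rate is E over initial mass, stored as a fraction", {
  expect_equal(removal_rate(47.6461, 5250), 47.6461 / 5250)
  expect_equal(removal_rate(47.6461, 5250), 0.009075, tolerance = 1e-3)
  expect_equal(removal_rate(0, 5250), 0)
  expect_equal(removal_rate(0.95147, 5250), 1.8123e-4, tolerance = 1e-4)
  expect_error(removal_rate(1, 0), "m_soil_i")
})

test_that("linear remediation time closes the mass balance", {
  expect_equal(time_linear(5250, 525, 47.6461), 4725 / 47.6461)
  expect_equal(time_linear(5250, 525, 47.6461), 99.17, tolerance = 1e-4)
  expect_equal(time_linear(5250, 525, 0.95147), 4966, tolerance = 1e-3)
  expect_equal(time_linear(5250, 5250, 3), 0)
  expect_equal(time_linear(5250, 525, 0), Inf)
  expect_error(time_linear(525, 5250, 1), "m_f")
  # closure: m_i - E * t == m_f exactly
  for (e in c(0.1, 1, 47.6461)) {
    t <- time_linear(5250, 525, e)
    expect_equal(5250 - e * t, 525)
  }
})

test_that("exponential remediation time inverts the decay law", {
  k <- 47.6461 / 5250
  expect_equal(time_exponential(5250, 525, k), log(10) / k)
  expect_equal(time_exponential(5250, 525, 0.009075), 253.7, tolerance = 1e-3)
  expect_equal(time_exponential(100, 100, 0.5), 0)
  expect_equal(time_exponential(5250, 525, 0), Inf)
  expect_error(time_exponential(5250, 0, 0.1), "m_f")
  # closure: mass at the computed time equals the target
  for (kk in c(0.001, 0.01, 0.5)) {
    t <- time_exponential(5250, 525, kk)
    expect_equal(mass_at_time(5250, kk, t, "exponential"), 525)
  }
})

test_that("fixed-rate model ordering: exponential always at least linear", {
  # at equal k the ratio is ln(m_i/m_f) / (1 - m_f/m_i); for a 90% reduction
  # that is ln(10)/0.9
  k <- 0.0123
  t_lin <- time_linear(5250, 525, k * 5250)
  t_exp <- time_exponential(5250, 525, k)
  expect_equal(t_exp / t_lin, log(10) / 0.9)
  withr::with_seed(7, {
    m_i <- runif(50, 10, 1e5)
    frac <- runif(50, 0.01, 0.99)
    k <- runif(50, 1e-4, 0.5)
    t_l <- time_linear(m_i, frac * m_i, k * m_i)
    t_e <- time_exponential(m_i, frac * m_i, k)
    expect_true(all(t_e >= t_l))
    expect_equal(t_e / t_l, log(1 / frac) / (1 - frac))
  })
})

test_that("times scale correctly in E, k and problem size", {
  # strictly decreasing in E (k); at fixed reduction fraction the times
  # depend on m_i only through (m_i - m_f)/E resp. ln(m_i/m_f)/k
  e <- c(1, 2, 5, 20)
  expect_true(all(diff(time_linear(5250, 525, e)) < 0))
  expect_true(all(diff(time_exponential(5250, 525, e / 5250)) < 0))
  expect_equal(
    time_exponential(1e6, 1e5, 0.01), time_exponential(10, 1, 0.01)
  )
  expect_equal(
    time_linear(10500, 1050, 2 * 47.6461), time_linear(5250, 525, 47.6461)
  )
})

test_that("mass_at_time matches both decay laws", {
  k <- 0.009075
  expect_equal(mass_at_time(5250, k, 0, "exponential"), 5250)
  expect_equal(mass_at_time(5250, k, 10, "exponential"), 5250 * exp(-0.09075))
  expect_equal(mass_at_time(5250, k, 10, "exponential"), 4794.6,
    tolerance = 1e-4
  )
  expect_equal(mass_at_time(5250, k, 10, "linear"), 5250 * (1 - 0.09075))
  expect_equal(mass_at_time(5250, k, 10, "linear"), 4773.6, tolerance = 1e-4)
  # linear model floors at zero once the pool is exhausted
  expect_equal(mass_at_time(100, 0.2, 10, "linear"), 0)
  expect_error(mass_at_time(100, 0.1, -1), "t must")
})

test_that("translocation factor and its inverse repair round-trip", {
  expect_equal(translocation_factor(8.9, 8.9), 1)
  expect_equal(translocation_factor(0, 5), 0)
  expect_error(translocation_factor(1, 0), "c_root")
  withr::with_seed(11, {
    a <- runif(20, 0, 10)
    b <- runif(20, 0.1, 10)
    expect_equal(stem_concentration_from_tf(translocation_factor(a, b), b), a)
  })
})
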
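test_that("two-state fit recovers a noiseless sigmoid exactly and is affine-invariant", {
  T <- seq(40, 70, by = 0.25)
  y <- 1 / (1 + exp((55 - T) / 1.5))
  f <- fit_two_state(T, y)
  expect_true(f$converged)
  expect_equal(f$tm, 55, tolerance = 1e-6)
  expect_equal(f$width, 1.5, tolerance = 1e-6)
  # doubling/shifting every intensity leaves Tm unchanged
  f2 <- fit_two_state(T, 2 * y + 3)
  expect_equal(f2$tm, f$tm, tolerance = 1e-8)
})

test_that("two-state fit refuses flat traces and undersampled windows", {
  T <- seq(40, 70, by = 1)
  set.seed(4)
  expect_error(fit_two_state(T, rnorm(length(T), 10, 0.01)),
               class = "sk_no_transition")
  expect_error(fit_two_state(T[1:5], (1:5) / 5),
               class = "sk_insufficient_data")
})

test_that("fitted Tm matches the kinetic midpoint of simulated melts", {
  # independent transcendental oracle: A exp(-Ea/RTm) R Tm^2 / (v Ea) = ln 2
  # for Ea = 280 kJ/mol, A = 1e43 /min, v = 1 K/min gives Tm = 334.84 K;
  # fine-grid integration of dN/dT places the N = 1/2 crossing at 334.90 K
  s <- simulate_melt(melt_scheme(1e43, 280), v = 1, t_range_C = c(20, 94))
  expect_equal(s$true_tm_K, 334.90, tolerance = 0.01)
  f <- fit_two_state(s$trace$temperature_C, s$trace$signal)
  expect_lt(abs(celsius_to_kelvin(f$tm) - 335), 1)

  # scenario calibrated to the published wild-type midpoint at 1 degC/min
  sch <- calibrate_melt_scheme(282.2, 58.6, 1)
  s2 <- simulate_melt(sch, 1)
  f2 <- fit_two_state(s2$trace$temperature_C, s2$trace$signal)
  expect_lt(abs(f2$tm - 58.6), 0.5)
})

test_that("ramp series conversion, aggregation and count rules hold", {
  sr <- build_ramp_series(c(0.5, 1, 2, 4), c(56.5, 58.6, 61.4, 63.0),
                          variant = "M")
  expect_equal(sr$tm_K, c(329.65, 331.75, 334.55, 336.15))
  # duplicate scan rates aggregate to the mean Tm
  sr2 <- build_ramp_series(c(1, 1, 2, 4), c(55, 57, 60, 62))
  expect_equal(sr2$tm_K[sr2$v == 1], celsius_to_kelvin(56))
  expect_error(build_ramp_series(c(1, 2), c(55, 60)),
               class = "sk_insufficient_data")
  expect_error(build_ramp_series(c(1, -2, 3), c(55, 60, 62)),
               class = "sk_domain_error")
})

test_that("scan-rate regression reproduces hand-computed activation energies", {
  tab <- aat_tm_table()
  # frozen oracle: independent OLS of ln(v/Tm^2) on 1/Tm (scipy linregress)
  m <- subset(tab, variant == "M")
  ea_m <- ramp_rate_activation_energy(
    build_ramp_series(m$v_C_per_min, m$tm_C, m$tm_se_C, "M"))
  expect_equal(ea_m$ea_kJ_mol, 277.98757, tolerance = 1e-6)
  expect_equal(ea_m$ea_se_kJ_mol, 20.26112, tolerance = 1e-5)
  expect_true(ea_m$kinetic)
  expect_equal(ea_m$ea_kJ_mol, -ea_m$slope * 8.314 / 1000)

  g <- subset(tab, variant == "Gly192Cys")
  ea_g <- ramp_rate_activation_energy(
    build_ramp_series(g$v_C_per_min, g$tm_C, g$tm_se_C, "G192C"))
  expect_equal(ea_g$ea_kJ_mol, 308.69034, tolerance = 1e-6)

  # ln(v) mode differs by roughly 2 R Tm (~5.5 kJ/mol here)
  ea_lnv <- ramp_rate_activation_energy(
    build_ramp_series(m$v_C_per_min, m$tm_C), mode = "lnv")
  expect_equal(ea_lnv$ea_kJ_mol, 283.52259, tolerance = 1e-6)
})

test_that("activation energy is invariant to the scan-rate unit", {
  tms <- c(56.5, 58.6, 61.4, 63.0)
  v_min <- c(0.5, 1, 2, 4)
  ea1 <- ramp_rate_activation_energy(build_ramp_series(v_min, tms))
  ea2 <- ramp_rate_activation_energy(build_ramp_series(v_min / 60, tms))
  expect_equal(ea1$ea_kJ_mol, ea2$ea_kJ_mol, tolerance = 1e-9)
  expect_false(isTRUE(all.equal(ea1$intercept, ea2$intercept)))
})

test_that("non-monotone Tm series are flagged as non-kinetic", {
  expect_warning(
    ea <- ramp_rate_activation_energy(
      build_ramp_series(c(0.5, 1, 2, 4), c(58, 57, 59, 60))),
    class = "sk_nonkinetic_warning")
  expect_false(ea$kinetic)
})

test_that("simulated melts have scan-rate-increasing midpoints and recoverable Ea", {
  sch <- calibrate_melt_scheme(280, 58.6, 1)
  v <- c(0.5, 1, 2, 4)
  sims <- lapply(v, function(vi) simulate_melt(sch, vi))
  tm_true <- vapply(sims, `[[`, 1, "true_tm_K")
  expect_true(all(diff(tm_true) > 0))

  tms <- vapply(sims, function(s)
    fit_two_state(s$trace$temperature_C, s$trace$signal)$tm, 1)
  ea <- ramp_rate_activation_energy(build_ramp_series(v, tms))
  expect_lt(abs(ea$ea_kJ_mol - 280) / 280, 0.05)
})
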
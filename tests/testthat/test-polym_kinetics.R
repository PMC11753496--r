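test_that("half-time matches closed forms and is affine-invariant", {
  t <- seq(0, 100, by = 0.5)
  logi <- 1 / (1 + exp(-(t - 50) / 5))
  expect_equal(half_time(t, logi)$t05, 50, tolerance = 1e-3)
  expect_equal(half_time(t, 3 * logi + 7)$t05, 50, tolerance = 1e-3)

  t2 <- seq(0, 300, by = 0.5)
  expr <- 1 - exp(-t2 / 30)
  expect_equal(half_time(t2, expr)$t05, 30 * log(2), tolerance = 1e-2)
  expect_equal(half_time(t2, expr, method = "exponential_fit")$t05,
               30 * log(2), tolerance = 1e-6)
})

test_that("incomplete curves are rejected in plateau mode but usable in exponential mode", {
  t <- seq(0, 20, by = 0.25)        # only ~half of a tau=30 rise
  y <- 1 - exp(-t / 30)
  expect_error(half_time(t, y), class = "sk_incomplete_curve")
  h <- half_time(t, y, method = "exponential_fit")
  expect_true(h$incomplete)
  expect_equal(h$t05, 30 * log(2), tolerance = 1e-3)
})

test_that("pipeline half-times agree with the dense ODE oracle within one step", {
  sch <- polym_scheme()
  Ts <- celsius_to_kelvin(seq(50, 65, length.out = 6))
  for (T in Ts) {
    s <- simulate_polym(sch, T)
    h <- half_time(s$trace$time_s, s$trace$signal, temperature_K = T)
    dt <- diff(s$trace$time_s[1:2])
    expect_lt(abs(h$t05 - s$true_t05_s), dt)
  }
})

test_that("Arrhenius fit recovers exact generating parameters and flags bad input", {
  Tk <- c(323, 328, 333, 338)
  slope <- 200 * 1000 / 8.314
  t05 <- exp(-55 + slope / Tk)
  af <- arrhenius_fit(Tk, t05)
  expect_equal(af$ea_kJ_mol, 200, tolerance = 1e-9)
  expect_equal(af$r_squared, 1, tolerance = 1e-9)

  # 5% lognormal noise: recovered within 10% for >= 95% of 100 seeds
  errs <- vapply(1:100, function(seed) {
    set.seed(seed)
    noisy <- t05 * exp(rnorm(4, 0, 0.05))
    abs(arrhenius_fit(Tk, noisy)$ea_kJ_mol - 200) / 200
  }, 1)
  expect_gte(mean(errs < 0.1), 0.95)
  set.seed(7)
  expect_lt(abs(arrhenius_fit(Tk, t05 * exp(rnorm(4, 0, 0.05)))$ea_kJ_mol - 200) / 200,
            0.1)

  expect_error(arrhenius_fit(c(323, 328), c(100, 10)),
               class = "sk_insufficient_data")
  expect_error(arrhenius_fit(Tk, c(1, 2, -3, 4)), class = "sk_domain_error")
})

test_that("interpolation reproduces nodes, is log-linear, and flags extrapolation", {
  # line through (327.95 K, 100 s) and (337.95 K, 10 s) plus its own midpoint
  T1 <- 327.95; T2 <- 337.95
  slope <- log(100 / 10) / (1 / T1 - 1 / T2)
  ic <- log(100) - slope / T1
  Tmid <- 1 / mean(c(1 / T1, 1 / T2))
  af <- arrhenius_fit(c(T1, Tmid, T2), exp(ic + slope / c(T1, Tmid, T2)))
  expect_equal(interpolate_half_time(af, T1)$t05, 100, tolerance = 1e-9)
  # midway in 1/T: geometric mean of the node values
  expect_equal(interpolate_half_time(af, Tmid)$t05, sqrt(100 * 10),
               tolerance = 1e-9)
  expect_warning(out <- interpolate_half_time(af, T2 + 5),
                 class = "sk_extrapolation_warning")
  expect_true(out$extrapolated)
})

test_that("fold change is exact for identical fits and reciprocal between variants", {
  Tk <- c(323, 328, 333, 338)
  t05 <- exp(-55 + 200000 / 8.314 / Tk)
  af <- arrhenius_fit(Tk, t05)
  tref <- celsius_to_kelvin(54.8)
  expect_equal(fold_change(af, af, tref)$ratio, 1)
  af2 <- arrhenius_fit(Tk, t05 / 3)
  fc <- fold_change(af, af2, tref)
  expect_equal(fc$ratio * fold_change(af2, af, tref)$ratio, 1, tolerance = 1e-12)
  expect_equal(fc$ratio, 3, tolerance = 1e-9)
})

test_that("scheme pairs built to differ 4-fold are recovered through the pipeline", {
  sch_a <- polym_scheme()
  sch_b <- scale_scheme(sch_a, 4)       # exact 4x faster at every T
  Ts <- celsius_to_kelvin(seq(50, 65, length.out = 6))
  t05 <- function(sch, T) {
    s <- simulate_polym(sch, T)
    half_time(s$trace$time_s, s$trace$signal)$t05
  }
  fa <- arrhenius_fit(Ts, vapply(Ts, function(T) t05(sch_a, T), 1), "a")
  fb <- arrhenius_fit(Ts, vapply(Ts, function(T) t05(sch_b, T), 1), "b")
  expect_gt(fa$r_squared, 0.98)
  fc <- fold_change(fa, fb, celsius_to_kelvin(54.8))
  expect_lt(abs(fc$ratio - 4) / 4, 0.05)
})
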
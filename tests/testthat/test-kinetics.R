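test_that("single-exponential fit recovers noiseless parameters exactly", {
  # log-spaced half-life sweep, both rising and decaying traces
  for (t_half in c(5, 17, 60, 200)) {
    tr <- generate_folding_trace(t_half, noise_sd = 0, seed = 1)
    fit <- fit_single_exponential(tr)
    expect_false(fit$no_transition)
    expect_lt(abs(fit$t_half - t_half) / t_half, 1e-6)
    expect_lt(abs(fit$s_inf - 1), 1e-6)
  }
  decay <- generate_folding_trace(30, noise_sd = 0, seed = 1,
                                  s0 = 1, s_inf = 0.2)
  fitd <- fit_single_exponential(decay)
  expect_lt(abs(fitd$t_half - 30) / 30, 1e-6)

  # rate ln2 per time unit has unit half-life
  tt <- kinetic_trace(seq(0, 8, length.out = 40),
                      exp(-log(2) * seq(0, 8, length.out = 40)), "h")
  expect_equal(fit_single_exponential(tt)$t_half, 1, tolerance = 1e-6)
})

test_that("flat traces report no transition instead of a fit", {
  flat <- kinetic_trace(1:20, rep(2.5, 20), "min")
  fit <- fit_single_exponential(flat)
  expect_true(fit$no_transition)
  expect_true(is.na(fit$k))

  noisy_flat <- generate_folding_trace(Inf, noise_sd = 0.02, seed = 3)
  expect_true(fit_single_exponential(noisy_flat)$no_transition)
})

test_that("mono HDX fit recovers quartet exchange rates", {
  # noiseless recovery at a measured quartet rate
  ser <- generate_hdx_series("mono", list(I0 = 0.99, k = 0.0054),
                             noise_sd = 0, seed = 1)
  fit <- fit_hdx_mono(ser)
  expect_lt(abs(fit$k_ex - 0.0054) / 0.0054, 1e-6)
  expect_equal(fit$Iinf, 0)
  expect_equal(fit$t_half, log(2) / fit$k_ex)

  # seeded noisy recovery within 10%
  sern <- generate_hdx_series("mono", list(I0 = 1, k = 0.009),
                              noise_sd = 0.02, seed = 5)
  fitn <- fit_hdx_mono(sern)
  expect_lt(abs(fitn$k_ex - 0.009) / 0.009, 0.10)

  # unconstrained floor is also recoverable
  tms <- seq(0.5, 300, by = 1.5)
  ser_floor <- exchange_series(tms, 0.2 + 0.8 * exp(-0.01 * tms))
  fit_floor <- fit_hdx_mono(ser_floor, constrain_floor_to_zero = FALSE)
  expect_lt(abs(fit_floor$Iinf - 0.2), 1e-6)
  expect_lt(abs(fit_floor$k_ex - 0.01) / 0.01, 1e-6)
})

test_that("undetectable decay is flagged as a zero-rate boundary", {
  short <- exchange_series(seq(0.3, 2, by = 0.25), rep(1, 7))
  fit <- fit_hdx_mono(short)
  expect_true(fit$boundary_zero_rate)
  expect_equal(fit$k_ex, 0)
})

test_that("biexponential fit recovers two-phase exchange", {
  # noiseless: exact recovery of all four parameters
  p13 <- list(I0 = 1.14, f = 0.502, k_fast = 1.34, k_slow = 0.008)
  ser0 <- generate_hdx_series("biexp", p13, noise_sd = 0, seed = 1)
  fit0 <- fit_hdx_biexponential(ser0)
  expect_equal(fit0$model, "biexp")
  expect_lt(abs(fit0$k_ex_fast - 1.34) / 1.34, 1e-6)
  expect_lt(abs(fit0$k_ex_slow - 0.008) / 0.008, 1e-6)
  expect_lt(abs(fit0$fast_fraction - 0.502), 1e-6)
  expect_lt(abs(fit0$I0 - 1.14), 1e-6)

  # with noise: seeded recovery close to the generating ratio
  sern <- generate_hdx_series("biexp", p13, noise_sd = 0.02, seed = 2)
  fitn <- fit_hdx_biexponential(sern)
  expect_equal(fitn$model, "biexp")
  expect_lt(abs(fitn$fast_fraction - 0.502), 0.05)
})

test_that("degenerate biexponential inputs fall back to the mono fit", {
  # f = 0: no fast phase, slow rate recovered
  ser_f0 <- generate_hdx_series("biexp",
                                list(I0 = 1, f = 0, k_fast = 1, k_slow = 0.006),
                                noise_sd = 0, seed = 1)
  fit_f0 <- fit_hdx_biexponential(ser_f0)
  expect_equal(fit_f0$model, "mono")
  expect_true(fit_f0$degenerate)
  expect_lt(abs(fit_f0$k_ex - 0.006) / 0.006, 1e-6)

  # equal generating rates: rate collapse flagged
  ser_eq <- generate_hdx_series("biexp",
                                list(I0 = 1, f = 0.5, k_fast = 0.01,
                                     k_slow = 0.01),
                                noise_sd = 0, seed = 1)
  fit_eq <- fit_hdx_biexponential(ser_eq)
  expect_true(fit_eq$degenerate)
  expect_lt(abs(fit_eq$k_ex - 0.01) / 0.01, 1e-4)
})

test_that("a biphasic series is fit worse by the mono model", {
  ser <- generate_hdx_series("biexp",
                             list(I0 = 1.1, f = 0.5, k_fast = 1.3,
                                  k_slow = 0.008),
                             noise_sd = 0.01, seed = 9)
  expect_gt(fit_hdx_biexponential(ser)$fit_r2, fit_hdx_mono(ser)$fit_r2)
})

test_that("Boltzmann melt fit recovers Tm on clean and noisy curves", {
  m0 <- generate_melt_curve(51.5, noise_sd = 0, seed = 1)
  fit0 <- fit_boltzmann_melt(m0)
  expect_lt(abs(fit0$Tm - 51.5), 1e-5)
  expect_true(fit0$Tm_in_range)

  # looped-construct stability, 2% noise: within half a degree
  mn <- generate_melt_curve(33.1, noise_sd = 0.02, seed = 4)
  expect_lt(abs(fit_boltzmann_melt(mn)$Tm - 33.1), 0.5)

  # rising-signal melts are accepted too
  mr <- generate_melt_curve(45, A1 = 0, A2 = 3, noise_sd = 0, seed = 1)
  expect_lt(abs(fit_boltzmann_melt(mr)$Tm - 45), 1e-5)

  # the fitted midpoint sits at half amplitude
  p <- fit_boltzmann_melt(m0)
  y_tm <- p$A2 + (p$A1 - p$A2) / 2
  grid_y <- p$A2 + (p$A1 - p$A2) / (1 + exp((p$Tm - p$Tm) / p$dT))
  expect_equal(grid_y, y_tm)

  expect_error(fit_boltzmann_melt(kinetic_trace(seq(20, 80, 5),
                                                rep(1, 13), "C")),
               "no sigmoidal")
})

test_that("rate and half-life conversions match the printed kinetics", {
  # 13 min folding half-life corresponds to ~0.0009 per second
  k_s <- rate_from_halflife(convert_time(13, "min", "s"))
  expect_equal(k_s, 0.0009, tolerance = 0.02)
  # G17 quartet: k = 0.0114 per hour ~ 60.7 h half-life (printed rounding)
  expect_equal(halflife_from_rate(0.0114), 60.7, tolerance = 0.005)
  expect_equal(halflife_from_rate(log(2)), 1)

  # exact inverses and ln 2 identity over a log sweep
  for (k in 10^seq(-6, 2)) {
    expect_equal(rate_from_halflife(halflife_from_rate(k)), k)
    expect_equal(halflife_from_rate(k) * k, log(2))
  }
  expect_equal(convert_rate(convert_rate(0.3, "h", "s"), "s", "h"), 0.3)
  expect_equal(convert_time(1, "day", "min"), 1440)
  expect_error(halflife_from_rate(0))
  expect_error(rate_from_halflife(-1))
})

test_that("split fits agree for consistent regions and flag constructed inconsistency", {
  tms <- hdx_default_schedule()
  half <- generate_hdx_series("mono", list(I0 = 0.5, k = 0.01),
                              noise_sd = 0, seed = 1)
  global <- exchange_series(tms, 2 * half$integrals)
  rep_ok <- split_fit_consistency(global, list(half, half))
  expect_lt(rep_ok$max_rel_discrepancy, 1e-8)
  expect_true(rep_ok$consistent)

  # halves generated with 2x different rates disagree with the global fit
  h1 <- exchange_series(tms, 0.5 * exp(-0.005 * tms))
  h2 <- exchange_series(tms, 0.5 * exp(-0.010 * tms))
  global2 <- exchange_series(tms, h1$integrals + h2$integrals)
  rep_bad <- split_fit_consistency(global2, list(h1, h2))
  expect_false(rep_bad$consistent)
  expect_gt(rep_bad$max_rel_discrepancy, 0.25)
  # the global rate lies between the regional rates
  expect_true(rep_bad$k_global > min(rep_bad$k_regions) &&
                rep_bad$k_global < max(rep_bad$k_regions))
})
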
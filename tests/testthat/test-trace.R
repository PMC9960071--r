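# Trace-level procedures: peak extraction, blank subtraction, tail fitting,
# the fractional-inactivation statistic, reversal estimation, linear fits.

make_flat_rec <- function(level = 1, n = 100) {
  recording(data.frame(sweep = 1L, time_s = seq(0, 1, length.out = n),
                       current = rep(level, n)),
            data.frame(segment = "depol", start_s = 0, end_s = 1,
                       voltage_mV = 60))
}

test_that("peak_current: constant, programmed and all-zero segments", {
  expect_equal(unname(peak_current(make_flat_rec(1), "depol")), 1)
  expect_equal(unname(peak_current(make_flat_rec(0), "depol")), 0)
  g <- gen_tevc_trace(trace_config(noise_sd = 0), seed = 1)
  expect_equal(unname(peak_current(g$rec, "depol")), g$truth$peak)
  expect_error(peak_current(make_flat_rec(), "nope"), "not found")
})

test_that("subtract_unspecific is an elementwise difference with blank-n
          metadata", {
  s <- c(1.0, 0.9, 0.8)
  expect_equal(as.numeric(subtract_unspecific(s, rep(0, 3))), s)
  expect_equal(as.numeric(subtract_unspecific(1.0, 0.1)), 0.9)
  out <- subtract_unspecific(s, rep(0.1, 3), n_blanks = 4L)
  expect_equal(attr(out, "n_blanks"), 4L)
  expect_error(subtract_unspecific(s, c(0, 0)), "lengths differ")
})

test_that("fit_tail_multiexp recovers components and nests cleanly", {
  # pure single exponential: 2-component fit finds a negligible second
  t <- seq(0, 2, by = 5e-4)
  rec <- recording(data.frame(sweep = 1L, time_s = t,
                              current = -1.5 * exp(-t / 0.2)),
                   data.frame(segment = "tail", start_s = 0, end_s = 2,
                              voltage_mV = -100))
  f <- fit_tail_multiexp(rec, "tail", n_components = 2,
                         cursors = c(0, 1.94))
  big <- which.max(abs(f$components$amplitude))
  expect_equal(f$components$amplitude[big], -1.5, tolerance = 1e-5)
  expect_equal(f$components$tau_s[big], 0.2, tolerance = 1e-5)
  expect_lt(abs(f$components$amplitude[-big]) / 1.5, 0.01)
  # hooked synthetic tail: all programmed components recovered within 2%
  g <- gen_tevc_trace(trace_config(inact_fraction = 0.35, noise_sd = 0),
                      seed = 1)
  f3 <- fit_tail_multiexp(g$rec, "tail")
  truth <- g$truth$tail_components
  truth <- truth[order(truth$tau_s), ]
  expect_equal(f3$components$tau_s, truth$tau_s, tolerance = 0.02)
  expect_equal(f3$components$amplitude, truth$amplitude, tolerance = 0.02)
  # default cursors: 7.5 ms after segment start to 97% of the segment
  pr <- g$rec$protocol[g$rec$protocol$segment == "tail", ]
  expect_equal(f3$window[1], pr$start_s + 0.0075)
  expect_equal(f3$window[2], pr$start_s + 0.97 * (pr$end_s - pr$start_s))
})

test_that("three-component fit of two-exponential truth yields a negligible
          third amplitude", {
  t <- seq(0, 2.5, by = 5e-4)
  y <- -0.7 * exp(-t / 0.15) - 1.3 * exp(-t / 0.7)
  rec <- recording(data.frame(sweep = 1L, time_s = t, current = y),
                   data.frame(segment = "tail", start_s = 0, end_s = 2.5,
                              voltage_mV = -100))
  f <- fit_tail_multiexp(rec, "tail", n_components = 3)
  # either the automatic fallback dropped it or its amplitude is negligible
  if (nrow(f$components) == 3) {
    a <- abs(f$components$amplitude)
    expect_lt(min(a) / sum(a), 0.01)
  } else {
    expect_equal(nrow(f$components), 2)
  }
})

test_that("fractional inactivation: arithmetic, sign-invariance and
          generator recovery", {
  # constructed fit: Y = -2.0, X = -1.4 at the cursor -> 0.30
  f <- exp_fit(a0 = 0, amplitudes = c(0.6, -0.7, -1.3),
               taus = c(0.012, 0.15, 0.7), window = c(0, 2), t0 = 0)
  r <- fractional_inactivation(f)
  expect_equal(r$Y, -2.0)
  expect_equal(r$X, -1.4)
  expect_equal(r$fraction, 0.30, tolerance = 1e-12)
  # outward tail with the same geometry gives the same fraction
  f_out <- exp_fit(a0 = 0, amplitudes = c(-0.6, 0.7, 1.3),
                   taus = c(0.012, 0.15, 0.7), window = c(0, 2), t0 = 0)
  expect_equal(fractional_inactivation(f_out)$fraction, 0.30,
               tolerance = 1e-12)
  # only decaying components (no hook) -> 0
  f0 <- exp_fit(a0 = 0, amplitudes = c(-0.7, -1.3), taus = c(0.15, 0.7),
                window = c(0, 2), t0 = 0)
  expect_equal(fractional_inactivation(f0)$fraction, 0)
  # zero total current is rejected
  fz <- exp_fit(a0 = 1, amplitudes = c(-1, 0.2), taus = c(0.2, 0.01),
                window = c(0, 2), t0 = 0)
  expect_error(fractional_inactivation(fz), "zero")
  # noiseless generator trace: programmed fraction recovered to < 1e-3
  g <- gen_tevc_trace(trace_config(inact_fraction = 0.35, noise_sd = 0),
                      seed = 1)
  fr <- fractional_inactivation(fit_tail_multiexp(g$rec, "tail"))
  expect_equal(fr$fraction, 0.35, tolerance = 1e-3)
  expect_equal(fr$Y, g$truth$Y, tolerance = 1e-3)
})

test_that("inactivation_series aggregates per axis value with SEM", {
  df <- data.frame(axis_value = c(-40, -40, 0, 0, 0, 40),
                   fraction = c(0.1, 0.2, 0.3, 0.4, 0.5, 0.45))
  out <- inactivation_series(df)
  expect_equal(out$axis_value, c(-40, 0, 40))
  expect_equal(out$fraction, c(0.15, 0.4, 0.45))
  expect_equal(out$n, c(2, 3, 1))
  expect_equal(out$sem[2], sd(c(0.3, 0.4, 0.5)) / sqrt(3))
  expect_true(is.na(out$sem[3]))
  # recordings path: programmed monotone voltage dependence is recovered
  fr_prog <- c(0.1, 0.3, 0.5)
  recs <- lapply(seq_along(fr_prog), function(i) {
    g <- gen_tevc_trace(trace_config(inact_fraction = fr_prog[i]),
                        seed = 20 + i)
    g$rec$metadata$prepulse_voltage <- c(-20, 20, 60)[i]
    g$rec
  })
  out2 <- inactivation_series(recs, axis = "prepulse_voltage")
  expect_true(all(diff(out2$fraction) > 0))
  expect_equal(out2$fraction, fr_prog, tolerance = 0.02)
  recs[[1]]$metadata$prepulse_voltage <- NULL
  expect_error(inactivation_series(recs, axis = "prepulse_voltage"),
               "metadata tag")
})

test_that("delta_I_rel: identity, derived values, antisymmetry", {
  expect_equal(delta_I_rel(1, 0.5, 1, 0.5)$delta_I_rel, 0)
  expect_equal(delta_I_rel(1.0, 0.8, 1.0, 0.5)$delta_I_rel, -0.3)
  expect_equal(delta_I_rel(1.0, 1.2, 1.0, 0.5)$delta_I_rel, -0.7)
  # swapping mutant and wild type flips the sign
  set.seed(3)
  for (i in 1:10) {
    a <- runif(4, 0.2, 1.5)
    expect_equal(delta_I_rel(a[1], a[2], a[3], a[4])$delta_I_rel,
                 -delta_I_rel(a[3], a[4], a[1], a[2])$delta_I_rel)
  }
  expect_error(delta_I_rel(0, 1, 1, 1), "nonzero")
})

test_that("estimate_reversal: interpolation, GHK data, error contract", {
  expect_equal(estimate_reversal(c(-10, 10), c(-1, 1)), 0)
  # noiseless GHK IV sampled at 10 mV spacing: within 0.5 mV of Nernst
  vv <- seq(-140, 0, 10)
  erev <- estimate_reversal(vv, ghk_flux(1e-4, 108, 2, vv))
  expect_lt(abs(erev - (-100.7117491)), 0.5)
  expect_error(estimate_reversal(c(0, 20, 40), c(1, 2, 3)), "sign")
})

test_that("linear_fit_with_correlation: exact line, degenerate y, noisy
          recovery", {
  x <- 1:10
  f <- linear_fit_with_correlation(x, 2 * x + 1)
  expect_equal(f$slope, 2)
  expect_equal(f$intercept, 1)
  expect_equal(f$r, 1)
  fc <- linear_fit_with_correlation(x, rep(3, 10))
  expect_equal(fc$slope, 0)
  expect_true(is.na(fc$r) && fc$flagged)
  expect_error(linear_fit_with_correlation(rep(1, 5), 1:5), "variance in x")
  set.seed(9)
  fn <- linear_fit_with_correlation(x, -0.5 * x + 2 + rnorm(10, 0, 0.1))
  expect_lt(abs(fn$slope - (-0.5)), 3 * fn$slope_se)
})
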
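# Concentration-series pipeline: stabilization, series building, GHK
# correction, Hill fitting with per-cell aggregation.

test_that("detect_stabilization applies the sliding-window rule", {
  expect_equal(detect_stabilization(rep(1, 6)), 1L)
  # run-up: first window with < 5% spread starts at the 4th pulse
  expect_equal(detect_stabilization(c(0.5, 0.8, 0.95, 1.0, 1.01, 1.0)), 4L)
  expect_warning(i <- detect_stabilization(2^(0:7)), "never stabilized")
  expect_true(is.na(i))
  expect_error(detect_stabilization(c(1, 1, 1)), "at least 4")
})

test_that("build_series subtracts blanks, keeps stabilized triplets and
          excludes incomplete series", {
  concs <- c(0.2, 2, 5, 20, 100)
  # cell with run-up at the reference concentration and a known leak
  leak <- 0.15
  mk <- function(conc, amps) {
    data.frame(cell = 1, concentration_mM = conc,
               point_index = seq_along(amps), amplitude = amps + leak)
  }
  true_triplet <- c(1.0, 1.01, 1.0)
  pulses <- rbind(mk(0.2, c(0.5, 0.8, 0.95, true_triplet)),
                  mk(2, c(0.9, 0.91, 0.9)), mk(5, c(0.8, 0.8, 0.8)),
                  mk(20, c(0.6, 0.6, 0.6)), mk(100, c(0.5, 0.5, 0.5)))
  blanks <- pulses
  blanks$cell <- 99
  blanks$amplitude <- leak
  s <- build_series(pulses, blanks = blanks, concs = concs)
  expect_s3_class(s, "ko_conc_series")
  # blank-corrected reference triplet is the stabilized one
  ref <- s$points$amplitude[s$points$concentration_mM == 0.2]
  expect_equal(ref, true_triplet)
  expect_equal(nrow(s$points), 15)  # exactly three points per concentration
  expect_equal(s$normalized$value[s$normalized$concentration_mM == 100],
               0.5 / mean(true_triplet))
  # no blanks: raw triplet means
  s2 <- build_series(mk(0.2, true_triplet)[, ],
                     concs = c(0.2))
  expect_equal(s2$norm_ref, mean(true_triplet) + leak)
  # missing the highest concentration -> excluded with reason
  expect_warning(
    s3 <- build_series(pulses[pulses$concentration_mM < 100, ],
                       concs = concs),
    "100 mM")
  expect_null(s3)
})

test_that("ghk_correct reproduces the theoretical ratio and both modes", {
  obs <- data.frame(concentration_mM = c(0.2, 2, 5, 20, 100),
                    value = hill_inhibition(c(0.2, 2, 5, 20, 100),
                                            0.55, 7.67, 1.02))
  cor_add <- ghk_correct(obs, vm = 60, kin = 108)
  # at the reference concentration Ith = 1 and the correction is a no-op
  expect_equal(cor_add$ith[1], 1)
  expect_equal(cor_add$corrected[1], cor_add$observed[1])
  # at 100 vs 0.2 mM, Ith ~ 0.914: additive mode adds ~0.086
  expect_equal(cor_add$ith[5], 0.9141597197, tolerance = 1e-9)
  expect_equal(cor_add$corrected[5] - cor_add$observed[5],
               1 - 0.9141597197, tolerance = 1e-9)
  # additive and multiplicative agree to first order while |1 - Ith| << 1
  cor_mul <- ghk_correct(obs, vm = 60, kin = 108, mode = "multiplicative")
  small <- cor_add$concentration_mM <= 20   # |1 - Ith| < 0.02 here
  expect_lt(max(abs(cor_add$corrected[small] - cor_mul$corrected[small])),
            0.01)
  # a pure driving-force channel corrects to ~1 and fits imax ~ 0
  null_obs <- data.frame(concentration_mM = obs$concentration_mM,
                         value = ghk_current_ratio(108,
                                                   obs$concentration_mM,
                                                   108, 0.2, 60))
  null_cor <- ghk_correct(null_obs, vm = 60, kin = 108,
                          mode = "multiplicative")
  expect_equal(null_cor$corrected, rep(1, 5), tolerance = 1e-12)
  f <- fit_hill(null_cor$concentration_mM, null_cor$corrected)
  expect_lt(f$params["imax"], 1e-6)
})

test_that("fit_series: exact single-cell recovery and per-cell aggregation
          shape", {
  g <- gen_dose_response(0.55, 7.67, 1.02, noise_sd = 0, n_cells = 1,
                         seed = 1)
  means <- aggregate(amplitude ~ concentration_mM, g$data, mean)
  fit <- fit_series(data.frame(cell = 1,
                               concentration_mM = means$concentration_mM,
                               value = means$amplitude))
  expect_equal(unname(fit$mean), c(0.55, 7.67, 1.02), tolerance = 1e-6)
  expect_equal(fit$n, 1)
  # pooled mode returns a single fit over all points
  g8 <- gen_dose_response(0.55, 7.67, 1.02, noise_sd = 0.02, n_cells = 8,
                          seed = 2)
  means8 <- aggregate(amplitude ~ cell + concentration_mM, g8$data, mean)
  names(means8)[3] <- "value"
  pooled <- fit_series(means8, aggregate = "pooled")
  expect_s3_class(pooled, "ko_fit")
  percell <- fit_series(means8)
  expect_equal(percell$n, 8)
  expect_equal(nrow(percell$per_cell), 8)
  expect_true(all(c("imax", "ic50", "nh") %in% names(percell$sem)))
})

test_that("two_point_inhibition matches the Hill-model identity", {
  expect_equal(two_point_inhibition(1, 1), 0)
  expect_equal(two_point_inhibition(1.0, 0.45), 0.55)
  expect_equal(two_point_inhibition(1.0, 1.2), -0.2)
  expect_error(two_point_inhibition(0, 1), "zero")
  # on noiseless model data: 1 - I(100)/I(0.2)
  i_low <- hill_inhibition(0.2, 0.55, 7.67, 1.02)
  i_high <- hill_inhibition(100, 0.55, 7.67, 1.02)
  expect_equal(two_point_inhibition(i_low, i_high),
               1 - i_high / i_low, tolerance = 1e-9)
})

test_that("end-to-end parameter recovery is unbiased across the parameter
          box", {
  # simulate 8-cell experiments from several parameter sets with sd 0.02
  # noise; pooled per-cell fits recover each parameter within 2 SEM
  params <- list(c(0.2, 2, 1.4), c(0.5, 10, 0.8), c(0.8, 25, 1.1),
                 c(0.35, 5, 1.0))
  for (i in seq_along(params)) {
    p <- params[[i]]
    g <- gen_dose_response(p[1], p[2], p[3], noise_sd = 0.02, n_cells = 8,
                           seed = 40 + i)
    means <- aggregate(amplitude ~ cell + concentration_mM, g$data, mean)
    names(means)[3] <- "value"
    fit <- fit_series(means)
    for (j in 1:3) {
      nm <- c("imax", "ic50", "nh")[j]
      tol <- 2 * fit$sem[nm] + 0.02 * p[j]  # SEM plus solver slack
      expect_lt(abs(fit$mean[nm] - p[j]), tol)
    }
  }
})
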
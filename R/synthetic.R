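# Seeded generators with ground-truth logs. Every generator is deterministic
# given (config, seed): the RNG state is set locally and restored on exit.

.with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
      get(".Random.seed", globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        rm(".Random.seed", envir = globalenv())
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(seed)
  }
  force(code)
}

#' Configuration for the synthetic TEVC trace generator
#'
#' Defaults emulate a KCNQ1-like two-electrode voltage-clamp episode: a
#' saturating activation at +60 mV with partial fast inactivation, and on
#' repolarization a hooked tail composed of a fast capacitive spike, one
#' recovering (hook) component and two deactivating components plus offset.
#'
#' The hook amplitude is calibrated in closed form so that the tail-fit
#' statistic `1 - X/Y`, evaluated with the default analysis cursors, equals
#' the programmed `inact_fraction` exactly on noiseless data.
#'
#' @param inact_fraction programmed fast-inactivation fraction in `[0, 0.6]`.
#' @param tail_amp total tail amplitude `Y` (signed; inward negative).
#' @param peak_amp depolarizing-segment peak current.
#' @param act_tau_s activation time constant (s).
#' @param recovery_tau_s hook (recovery-from-inactivation) time constant (s).
#' @param deact_tau_s the two deactivation time constants (s).
#' @param deact_split amplitude split of the deactivating components (sums
#'   to 1).
#' @param a0 steady-state offset current.
#' @param leak constant leak current added to every sample.
#' @param cap_tau_s,cap_factor capacitive-transient time constant and
#'   amplitude (as a multiple of `tail_amp`).
#' @param noise_sd additive Gaussian noise SD; default 1.5% of `|tail_amp|`
#'   (roughly 36 dB SNR on the tail).
#' @param sample_rate sampling rate (Hz).
#' @param cursor_start_s analysis cursor offset after tail start that the
#'   hook calibration targets (the analyzer default).
#' @return A list of class `ko_trace_config`.
#' @export
trace_config <- function(inact_fraction = 0.35, tail_amp = -2.0,
                         peak_amp = 2.3, act_tau_s = 0.25,
                         recovery_tau_s = 0.012,
                         deact_tau_s = c(0.15, 0.7),
                         deact_split = c(0.35, 0.65), a0 = 0, leak = 0,
                         cap_tau_s = 8e-4, cap_factor = 3,
                         noise_sd = 0.015 * abs(tail_amp),
                         sample_rate = 2000, cursor_start_s = 0.0075) {
  if (inact_fraction < 0 || inact_fraction > 0.6) {
    stop("'inact_fraction' must be in [0, 0.6]", call. = FALSE)
  }
  stopifnot(all(c(act_tau_s, recovery_tau_s, deact_tau_s, cap_tau_s) > 0),
            abs(sum(deact_split) - 1) < 1e-9)
  structure(as.list(environment()), class = "ko_trace_config")
}

#' Generate a synthetic TEVC recording with a hooked tail
#'
#' Builds one sweep over a depolarize-then-repolarize protocol. The truth log
#' records the programmed inactivation fraction together with the consistent
#' `X` and `Y` values (`1 - X/Y` equals the fraction), the analytic peak of
#' the depolarizing segment and all tail components.
#'
#' @param cfg a [trace_config()].
#' @param protocol data.frame as in [recording()]; default 2 s at +60 mV
#'   ("depol") then 2.5 s at -100 mV ("tail").
#' @param seed integer seed.
#' @return List with `rec` (a [recording()]) and `truth`.
#' @export
gen_tevc_trace <- function(cfg = trace_config(), protocol = NULL, seed = 1) {
  if (is.null(protocol)) {
    protocol <- data.frame(segment = c("depol", "tail"),
                           start_s = c(0, 2), end_s = c(2, 4.5),
                           voltage_mV = c(60, -100))
  }
  dep <- protocol[protocol$segment == "depol", ]
  tl <- protocol[protocol$segment == "tail", ]
  if (nrow(dep) != 1 || nrow(tl) != 1) {
    stop("protocol needs one 'depol' and one 'tail' segment", call. = FALSE)
  }
  dt <- 1 / cfg$sample_rate
  f <- cfg$inact_fraction
  # depolarizing segment: activation envelope with a sag toward (1 - f)
  t_dep <- seq(dep$start_s, dep$end_s - dt, by = dt)
  td <- t_dep - dep$start_s
  sag_tau <- 4 * cfg$recovery_tau_s
  i_dep <- cfg$peak_amp * (1 - exp(-td / cfg$act_tau_s)) *
    (1 - f * (1 - exp(-td / sag_tau)))
  # tail segment
  t_tail <- seq(tl$start_s, tl$end_s, by = dt)
  tt <- t_tail - tl$start_s
  a_d <- (cfg$tail_amp - cfg$a0) * cfg$deact_split
  d_c1 <- cfg$a0 + sum(a_d * exp(-cfg$cursor_start_s / cfg$deact_tau_s))
  a_h <- ((1 - f) * cfg$tail_amp - d_c1) *
    exp(cfg$cursor_start_s / cfg$recovery_tau_s)
  a_c <- cfg$cap_factor * cfg$tail_amp
  i_tail <- cfg$a0 +
    a_d[1] * exp(-tt / cfg$deact_tau_s[1]) +
    a_d[2] * exp(-tt / cfg$deact_tau_s[2]) +
    a_h * exp(-tt / cfg$recovery_tau_s) +
    a_c * exp(-tt / cfg$cap_tau_s)
  time_s <- c(t_dep, t_tail)
  clean <- c(i_dep, i_tail) + cfg$leak
  current <- .with_seed(seed, clean + stats::rnorm(length(clean),
                                                   0, cfg$noise_sd))
  rec <- recording(data.frame(sweep = 1L, time_s = time_s,
                              current = current),
                   protocol, sample_rate = cfg$sample_rate,
                   metadata = list(seed = seed, generator = "gen_tevc_trace"))
  truth <- list(inact_fraction = f, X = (1 - f) * cfg$tail_amp,
                Y = cfg$tail_amp, peak = max(i_dep) + cfg$leak,
                a0 = cfg$a0, leak = cfg$leak,
                tail_components = data.frame(
                  amplitude = c(a_h, a_d),
                  tau_s = c(cfg$recovery_tau_s, cfg$deact_tau_s),
                  role = c("recovery", "deactivation", "deactivation")),
                capacitive = c(amplitude = a_c, tau_s = cfg$cap_tau_s),
                noise_sd = cfg$noise_sd, seed = seed)
  list(rec = rec, truth = truth)
}

#' Generate synthetic concentration-response triplets
#'
#' Emits `n_points` blank-corrected, normalized amplitudes per concentration
#' per cell: `hill + noise`, optionally multiplied by the GHK driving-force
#' ratio relative to the reference (lowest) concentration so the full
#' correction pipeline can be exercised. An optional absolute `scale` (with
#' lognormal cell-to-cell spread) and constant `leak` turn the output into
#' raw-amplitude pulses for the blank-subtraction path.
#'
#' @param imax,ic50,nh generating Hill parameters.
#' @param concs concentrations (mM).
#' @param noise_sd Gaussian noise SD on the normalized scale.
#' @param n_cells number of cells.
#' @param n_points points per concentration (default 3).
#' @param ghk_effect multiply by the GHK ratio `Ith(C)` (driving-force loss).
#' @param vm,kin voltage (mV) and internal K+ (mM) for the GHK effect.
#' @param scale absolute amplitude scale (default 1 = normalized output).
#' @param cell_spread lognormal SD of the per-cell scale.
#' @param leak constant unspecific current added to every point.
#' @param seed integer seed.
#' @return List with `data` (cell, concentration_mM, point_index, amplitude)
#'   and `truth`.
#' @export
gen_dose_response <- function(imax, ic50, nh, concs = c(0.2, 2, 5, 20, 100),
                              noise_sd = 0.02, n_cells = 8, n_points = 3,
                              ghk_effect = FALSE, vm = 60, kin = 108,
                              scale = 1, cell_spread = 0, leak = 0,
                              seed = 1) {
  base <- hill_inhibition(concs, imax, ic50, nh)
  ith <- if (ghk_effect) {
    ghk_current_ratio(kin, concs, kin, concs[1], vm)
  } else rep(1, length(concs))
  .with_seed(seed, {
    cell_scale <- scale * exp(stats::rnorm(n_cells, 0, cell_spread))
    rows <- expand.grid(point_index = seq_len(n_points),
                        concentration_mM = concs, cell = seq_len(n_cells))
    mu <- (base * ith)[match(rows$concentration_mM, concs)]
    amp <- (mu + stats::rnorm(nrow(rows), 0, noise_sd)) *
      cell_scale[rows$cell] + leak
    data <- data.frame(cell = rows$cell,
                       concentration_mM = rows$concentration_mM,
                       point_index = rows$point_index, amplitude = amp)
    truth <- list(imax = imax, ic50 = ic50, nh = nh, concs = concs,
                  ith = ith, ghk_effect = ghk_effect, vm = vm, kin = kin,
                  noise_sd = noise_sd, scale = scale,
                  cell_scale = cell_scale, leak = leak, seed = seed)
    list(data = data, truth = truth)
  })
}

#' Generate synthetic GHK current-voltage data
#'
#' Currents from [ghk_flux()] with multiplicative Gaussian noise.
#'
#' @param p permeability (cm/s).
#' @param ki,ko internal/external K+ (mM).
#' @param voltages voltages (mV).
#' @param noise_sd multiplicative noise fraction (0.05 = 5%).
#' @param n_rep replicate IV datasets.
#' @param temp_K temperature (K).
#' @param seed integer seed.
#' @return List with `data` (replicate, vm_mV, current) and `truth`.
#' @export
gen_iv_ghk <- function(p, ki, ko, voltages = seq(-40, 80, 20),
                       noise_sd = 0.05, n_rep = 1,
                       temp_K = ko_constants$T_default, seed = 1) {
  mu <- ghk_flux(p, ki, ko, voltages, temp_K)
  .with_seed(seed, {
    data <- do.call(rbind, lapply(seq_len(n_rep), function(r) {
      data.frame(replicate = r, vm_mV = voltages,
                 current = mu * (1 + stats::rnorm(length(mu), 0, noise_sd)))
    }))
    list(data = data,
         truth = list(p = p, ki = ki, ko = ko, temp_K = temp_K,
                      noise_sd = noise_sd, seed = seed))
  })
}

#' Generate synthetic conductance-voltage data
#'
#' [boltzmann_offset()] values plus additive Gaussian noise.
#'
#' @param vhalf,z,gmin generating Boltzmann parameters.
#' @param voltages voltages (mV).
#' @param noise_sd additive noise SD.
#' @param n number of datasets.
#' @param temp_K temperature (K).
#' @param seed integer seed.
#' @return List with `data` (dataset, vm_mV, g_norm) and `truth`.
#' @export
gen_gv_data <- function(vhalf = -1.56, z = 2, gmin = 0.20,
                        voltages = seq(-100, 60, 20), noise_sd = 0.03,
                        n = 8, temp_K = ko_constants$T_default, seed = 1) {
  mu <- boltzmann_offset(voltages, vhalf, z, gmin, temp_K)
  .with_seed(seed, {
    data <- do.call(rbind, lapply(seq_len(n), function(d) {
      data.frame(dataset = d, vm_mV = voltages,
                 g_norm = mu + stats::rnorm(length(mu), 0, noise_sd))
    }))
    list(data = data,
         truth = list(vhalf = vhalf, z = z, gmin = gmin,
                      noise_sd = noise_sd, seed = seed))
  })
}

#' Generate synthetic reversal-potential shifts
#'
#' Samples `n` reversal-potential shifts around the bi-ionic value
#' \eqn{\Delta E_{rev} = (RT/zF) \ln(ratio)}.
#'
#' @param true_ratio generating permeability ratio `P_X/P_K`, `> 0`.
#' @param z ion valence.
#' @param noise_sd_mV Gaussian noise SD (mV).
#' @param n number of cells.
#' @param temp_K temperature (K).
#' @param seed integer seed.
#' @return List with `data` (numeric shifts, mV) and `truth`.
#' @export
gen_reversal_shifts <- function(true_ratio, z = 1, noise_sd_mV = 1, n = 5,
                                temp_K = ko_constants$T_default, seed = 1) {
  if (true_ratio <= 0) stop("'true_ratio' must be > 0", call. = FALSE)
  mu <- .rt_over_f_mV(temp_K) / z * log(true_ratio)
  .with_seed(seed, {
    list(data = mu + stats::rnorm(n, 0, noise_sd_mV),
         truth = list(true_ratio = true_ratio, mean_shift_mV = mu, z = z,
                      noise_sd_mV = noise_sd_mV, seed = seed))
  })
}

#' Generate synthetic single-channel sweeps
#'
#' A k-level telegraph signal (exponential dwells, next level drawn by
#' weight), plus Gaussian noise, low-pass filtered with a 4-pole digital
#' filter at `filter_hz` to emulate the 200 Hz analysis bandwidth of slow
#' single-channel recordings. Baseline (level 0) must be among the levels.
#'
#' @param levels current levels (pA); must include 0.
#' @param weights stationary weights of the levels (normalized internally).
#' @param dwell_s mean dwell time per visit (s).
#' @param noise_sd pre-filter Gaussian noise SD (pA).
#' @param filter_hz low-pass corner frequency (Hz); `NULL` disables.
#' @param sample_rate sampling rate (Hz).
#' @param sweep_s sweep duration (s).
#' @param n_sweeps number of sweeps.
#' @param seed integer seed.
#' @return List with `sweeps` (list of numeric vectors), `time_s`, and
#'   `truth` (levels, weights, post-filter noise SD estimate).
#' @export
gen_single_channel <- function(levels = c(0, 0.5), weights = c(0.5, 0.5),
                               dwell_s = 0.05, noise_sd = 0.15,
                               filter_hz = 200, sample_rate = 5000,
                               sweep_s = 4, n_sweeps = 11, seed = 1) {
  if (!any(levels == 0)) stop("levels must include baseline 0", call. = FALSE)
  stopifnot(length(levels) == length(weights), all(weights > 0))
  w <- weights / sum(weights)
  n <- round(sweep_s * sample_rate)
  filt <- if (!is.null(filter_hz)) {
    signal::butter(4, filter_hz / (sample_rate / 2), type = "low")
  } else NULL
  .with_seed(seed, {
    sweeps <- lapply(seq_len(n_sweeps), function(s) {
      state <- sample(seq_along(levels), 1, prob = w)
      sig <- numeric(n)
      i <- 1
      while (i <= n) {
        len <- max(1L, round(stats::rexp(1, 1 / dwell_s) * sample_rate))
        j <- min(n, i + len - 1L)
        sig[i:j] <- levels[state]
        i <- j + 1L
        if (length(levels) > 1) {
          others <- setdiff(seq_along(levels), state)
          state <- if (length(others) == 1) others else {
            sample(others, 1, prob = w[others])
          }
        }
      }
      x <- sig + stats::rnorm(n, 0, noise_sd)
      if (!is.null(filt)) x <- signal::filtfilt(filt, x)
      x
    })
    post_sd <- if (is.null(filt)) noise_sd else {
      noise_sd * sqrt(2 * filter_hz / sample_rate)
    }
    list(sweeps = sweeps, time_s = seq(0, by = 1 / sample_rate,
                                       length.out = n),
         truth = list(levels = levels, weights = w, dwell_s = dwell_s,
                      noise_sd_pre = noise_sd, noise_sd_post = post_sd,
                      filter_hz = filter_hz, sample_rate = sample_rate,
                      seed = seed))
  })
}
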
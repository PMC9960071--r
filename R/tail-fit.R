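#' Construct a multi-exponential tail fit object
#'
#' Model \eqn{I(t) = a_0 + \sum_i a_i e^{-(t - t_0)/\tau_i}} with the time
#' origin `t0` at the tail-segment start. Components are stored sorted by
#' time constant.
#'
#' @param a0 constant (steady-state) amplitude.
#' @param amplitudes component amplitudes `a_i` (model space: a component may
#'   have either sign).
#' @param taus component time constants (s), `> 0`.
#' @param window cursor window `c(start_s, end_s)` used for fitting, in
#'   absolute recording time.
#' @param t0 tail-segment start time (s).
#' @param stderr optional named standard errors of all parameters.
#' @param residual_norm residual sum of squares of the fit.
#' @param converged convergence flag.
#' @param n_points number of samples fitted.
#' @param raw_x raw data value at the first cursor, if available.
#' @return An object of class `ko_expfit`.
#' @export
exp_fit <- function(a0, amplitudes, taus, window, t0 = window[1],
                    stderr = NULL, residual_norm = NA_real_,
                    converged = TRUE, n_points = NA_integer_,
                    raw_x = NA_real_) {
  stopifnot(length(amplitudes) == length(taus))
  if (any(taus <= 0)) stop("time constants must be > 0", call. = FALSE)
  if (!length(amplitudes) %in% 1:3) {
    stop("number of components must be 1-3", call. = FALSE)
  }
  ord <- order(taus)
  structure(list(a0 = a0,
                 components = data.frame(amplitude = amplitudes[ord],
                                         tau_s = taus[ord]),
                 window = window, t0 = t0, stderr = stderr,
                 residual_norm = residual_norm, converged = converged,
                 n_points = n_points, raw_x = raw_x),
            class = "ko_expfit")
}

#' @export
print.ko_expfit <- function(x, ...) {
  cat(sprintf("<ko_expfit> %d component(s), a0 = %.4g, window [%.4g, %.4g] s\n",
              nrow(x$components), x$a0, x$window[1], x$window[2]))
  print(x$components, digits = 4)
  invisible(x)
}

# model value(s) at absolute time t
.expfit_eval <- function(fit, t) {
  dt <- t - fit$t0
  out <- rep(fit$a0, length(t))
  for (i in seq_len(nrow(fit$components))) {
    out <- out + fit$components$amplitude[i] *
      exp(-dt / fit$components$tau_s[i])
  }
  out
}

# multiexponential LM fit at fixed component count; amplitudes initialized by
# linear least squares at the tau seed.  Returns NULL on failure.
.fit_multiexp_k <- function(t, y, t0, k, tau_seed) {
  basis <- function(taus) {
    cbind(1, vapply(taus, function(tau) exp(-(t - t0) / tau),
                    numeric(length(t))))
  }
  amps0 <- tryCatch(stats::lsfit(basis(tau_seed), y,
                                 intercept = FALSE)$coefficients,
                    error = function(e) c(mean(y), rep(0, k)))
  start <- as.list(c(a0 = unname(amps0[1]),
                     stats::setNames(unname(amps0[-1]), paste0("a", 1:k)),
                     stats::setNames(log(tau_seed), paste0("ltau", 1:k))))
  fn <- function(p) {
    taus <- exp(unlist(p[paste0("ltau", 1:k)]))
    amps <- unlist(p[paste0("a", 1:k)])
    drop(basis(taus) %*% c(p$a0, amps))
  }
  r <- .nls_fit(fn, start, y, maxiter = 400)
  if (is.null(r)) return(NULL)
  taus <- exp(unname(r$params[paste0("ltau", 1:k)]))
  amps <- unname(r$params[paste0("a", 1:k)])
  # delta method: se(tau) = tau * se(log tau)
  se <- r$stderr
  se_amp <- unname(se[paste0("a", 1:k)])
  se_tau <- taus * unname(se[paste0("ltau", 1:k)])
  list(a0 = unname(r$params["a0"]), amps = amps, taus = taus,
       se = c(a0 = unname(se["a0"]),
              stats::setNames(se_amp, paste0("a", 1:k)),
              stats::setNames(se_tau, paste0("tau", 1:k))),
       rss = r$rss, converged = r$converged)
}

#' Fit a tail current with two or three exponential components
#'
#' Fits \eqn{a_0 + \sum a_i e^{-(t-t_0)/\tau_i}} between two cursors, with the
#' time origin at the tail-segment start so that extrapolation to the segment
#' beginning is evaluation at `t = t0`. The default window starts 7.5 ms after
#' the segment start (past the capacitive transient) and ends at 97% of the
#' segment. Several geometric tau seeds are tried and the lowest-RSS converged
#' fit is kept. With `n_components = 3` the fit falls back to 2 components
#' when the third amplitude is smaller than its standard error.
#'
#' @param rec a [recording()].
#' @param tail_segment protocol segment label of the tail.
#' @param n_components 2 or 3 (default 3, with automatic fallback).
#' @param cursors optional window `c(start_s, end_s)` in absolute time;
#'   default `t0 + 7.5 ms` to `t0 + 0.97 * segment length`.
#' @param sweep sweep id to fit (default: first sweep).
#' @return A [exp_fit()] object.
#' @export
fit_tail_multiexp <- function(rec, tail_segment, n_components = 3,
                              cursors = NULL, sweep = NULL) {
  stopifnot(n_components %in% 2:3)
  pr <- rec$protocol[rec$protocol$segment == tail_segment, , drop = FALSE]
  if (nrow(pr) != 1) stop("tail segment not found", call. = FALSE)
  t0 <- pr$start_s
  seg_len <- pr$end_s - pr$start_s
  if (is.null(cursors)) cursors <- c(t0 + 0.0075, t0 + 0.97 * seg_len)
  if (is.null(sweep)) sweep <- rec$data$sweep[1]
  dd <- rec$data[rec$data$sweep == sweep, ]
  sel <- dd$time_s >= cursors[1] & dd$time_s <= cursors[2]
  t <- dd$time_s[sel]; y <- dd$current[sel]
  if (length(t) < 2 * n_components + 2) {
    stop("fewer points than parameters in fit window", call. = FALSE)
  }
  raw_x <- y[1]
  span <- cursors[2] - cursors[1]
  seeds <- list(span * c(0.03, 0.3), span * c(0.01, 0.15), span * c(0.1, 0.6))
  if (n_components == 3) {
    seeds <- list(span * c(0.01, 0.1, 0.5), span * c(0.02, 0.2, 0.8),
                  span * c(0.005, 0.05, 0.3))
  }
  best <- NULL
  for (s in seeds) {
    r <- .fit_multiexp_k(t, y, t0, n_components, s)
    if (!is.null(r) && (is.null(best) || r$rss < best$rss)) best <- r
    if (!is.null(best) && best$converged &&
        best$rss < 1e-16 * max(sum(y^2), 1)) break
  }
  if (is.null(best)) {
    return(exp_fit(mean(y), rep(0, n_components),
                   rep(span / 10, n_components), cursors, t0,
                   converged = FALSE, n_points = length(t), raw_x = raw_x))
  }
  # fallback: drop an unresolved third component
  if (n_components == 3) {
    a3 <- abs(best$amps)
    i_min <- which.min(a3)
    se3 <- best$se[paste0("a", i_min)]
    if (is.finite(se3) && a3[i_min] < se3) {
      r2 <- .fit_multiexp_k(t, y, t0, 2,
                            sort(best$taus[-i_min]))
      if (!is.null(r2) && r2$converged) best <- r2
    }
  }
  exp_fit(best$a0, best$amps, best$taus, cursors, t0, stderr = best$se,
          residual_norm = best$rss, converged = best$converged,
          n_points = length(t), raw_x = raw_x)
}

#' Fractional fast inactivation from a tail fit
#'
#' From a fitted hooked tail: `Y` is the total current extrapolated to the
#' tail-segment start using the constant `a0` plus the deactivating
#' components only; `X` is the current of open channels immediately after the
#' capacitive transient (fitted model value at the first cursor by default,
#' or the raw sample there). The statistic is `1 - X/Y`.
#'
#' Deactivating components are identified in model space as those whose
#' amplitude has the same sign as the tail's displacement from baseline at
#' the first cursor (the deactivation direction); the recovering "hook"
#' component opposes it. The ratio `X/Y` is sign-invariant, so the statistic
#' works identically for inward and outward tails. If no recovering component
#' exists the fraction is 0. Values outside `[0, 1)` are clipped with a
#' warning.
#'
#' @param fit a [exp_fit()] object.
#' @param x_source `"fitted"` (default) evaluates the model at the first
#'   cursor; `"raw"` uses the stored raw sample there.
#' @return List with `fraction`, `X`, `Y` and the component classification.
#' @export
fractional_inactivation <- function(fit, x_source = c("fitted", "raw")) {
  x_source <- match.arg(x_source)
  stopifnot(inherits(fit, "ko_expfit"))
  c1 <- fit$window[1]
  m_c1 <- .expfit_eval(fit, c1)
  d <- sign(m_c1 - fit$a0)
  if (d == 0) d <- sign(sum(fit$components$amplitude))
  deact <- sign(fit$components$amplitude) == d
  Y <- fit$a0 + sum(fit$components$amplitude[deact])
  if (abs(Y) < .Machine$double.eps * 100) {
    stop("extrapolated total Y is zero; fraction undefined", call. = FALSE)
  }
  X <- if (x_source == "raw") fit$raw_x else m_c1
  if (!any(!deact)) {
    return(list(fraction = 0, X = X, Y = Y, deactivating = deact))
  }
  fraction <- 1 - X / Y
  if (fraction < 0 || fraction >= 1) {
    warning(sprintf("fractional inactivation %.3f outside [0, 1); clipped",
                    fraction))
    fraction <- min(max(fraction, 0), 1 - 1e-12)
  }
  list(fraction = fraction, X = X, Y = Y, deactivating = deact)
}

#' Aggregate fractional inactivation along a protocol axis
#'
#' Computes (or takes precomputed) per-recording inactivation fractions and
#' aggregates them per axis value (prepulse voltage or pulse duration) as
#' mean, SEM and n.
#'
#' @param recs either a list of [recording()] objects, each carrying its axis
#'   value in `metadata[[axis]]`, or a data.frame with columns `axis_value`
#'   and `fraction`.
#' @param axis `"prepulse_voltage"` or `"pulse_duration"`; names the metadata
#'   tag used when `recs` is a list of recordings.
#' @param tail_segment tail segment label (recordings input only).
#' @param ... passed to [fit_tail_multiexp()].
#' @return data.frame with columns `axis_value`, `fraction`, `sem`, `n`.
#' @export
inactivation_series <- function(recs, axis = c("prepulse_voltage",
                                               "pulse_duration"),
                                tail_segment = "tail", ...) {
  axis <- match.arg(axis)
  if (is.data.frame(recs)) {
    df <- recs
    if (!all(c("axis_value", "fraction") %in% names(df))) {
      stop("data.frame input needs columns axis_value, fraction",
           call. = FALSE)
    }
  } else {
    vals <- lapply(recs, function(r) r$metadata[[axis]])
    if (any(vapply(vals, is.null, logical(1)))) {
      stop(sprintf("every recording must carry metadata tag '%s'", axis),
           call. = FALSE)
    }
    fr <- vapply(recs, function(r) {
      fractional_inactivation(fit_tail_multiexp(r, tail_segment, ...))$fraction
    }, numeric(1))
    df <- data.frame(axis_value = unlist(vals), fraction = fr)
  }
  agg <- split(df$fraction, df$axis_value)
  out <- data.frame(
    axis_value = as.numeric(names(agg)),
    fraction = vapply(agg, mean, numeric(1)),
    sem = vapply(agg, function(v) {
      if (length(v) > 1) stats::sd(v) / sqrt(length(v)) else NA_real_
    }, numeric(1)),
    n = vapply(agg, length, numeric(1)), row.names = NULL)
  out[order(out$axis_value), ]
}

#' Mutant-vs-wild-type relative inhibition statistic
#'
#' \deqn{\Delta I_{rel} = [1 - I_{high}^{Mut}/I_{low}^{Mut}] -
#'                        [1 - I_{high}^{WT}/I_{low}^{WT}]}
#' Negative values mean the mutant is less inhibited (or more potentiated) by
#' the high external K+ condition than the wild type.
#'
#' @param mut_low,mut_high mutant current at the reference (low) and test
#'   (high) external K+ concentration.
#' @param wt_low,wt_high same for the wild type.
#' @return List with `mut_ratio`, `wt_ratio` and `delta_I_rel`.
#' @export
delta_I_rel <- function(mut_low, mut_high, wt_low, wt_high) {
  if (mut_low == 0 || wt_low == 0) {
    stop("low-condition amplitudes must be nonzero", call. = FALSE)
  }
  mr <- mut_high / mut_low
  wr <- wt_high / wt_low
  list(mut_ratio = mr, wt_ratio = wr, delta_I_rel = (1 - mr) - (1 - wr))
}

#' Reversal potential from an instantaneous IV relation
#'
#' Linear interpolation of the zero-current crossing between the two voltage
#' points bracketing the sign change.
#'
#' @param vm voltages (mV).
#' @param current currents at `vm`.
#' @return Reversal potential (mV).
#' @export
estimate_reversal <- function(vm, current) {
  stopifnot(length(vm) == length(current))
  ord <- order(vm)
  vm <- vm[ord]; current <- current[ord]
  if (any(current == 0)) return(vm[which(current == 0)[1]])
  s <- sign(current)
  cross <- which(diff(s) != 0)
  if (!length(cross)) {
    stop("currents do not change sign; no reversal in range", call. = FALSE)
  }
  i <- cross[1]
  vm[i] + (0 - current[i]) * (vm[i + 1] - vm[i]) /
    (current[i + 1] - current[i])
}

#' Least-squares line with Pearson correlation
#'
#' @param x,y numeric vectors, at least 3 points.
#' @return List with `slope`, `intercept`, `r`, standard errors and a
#'   `flagged` logical set when `y` has zero variance (r undefined).
#' @export
linear_fit_with_correlation <- function(x, y) {
  stopifnot(length(x) == length(y))
  if (length(x) < 3) stop("need at least 3 points", call. = FALSE)
  if (stats::var(x) == 0) stop("zero variance in x", call. = FALSE)
  fit <- stats::lm(y ~ x)
  # exact lines are legitimate input; silence the perfect-fit warning
  co <- suppressWarnings(summary(fit))$coefficients
  flagged <- stats::var(y) == 0
  r <- if (flagged) NA_real_ else stats::cor(x, y)
  list(slope = unname(co["x", "Estimate"]),
       intercept = unname(co["(Intercept)", "Estimate"]),
       r = r,
       slope_se = unname(co["x", "Std. Error"]),
       intercept_se = unname(co["(Intercept)", "Std. Error"]),
       flagged = flagged)
}
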
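#' Fit the Hill inhibition equation to concentration-response data
#'
#' Least-squares fit of [hill_inhibition()] with parameters `imax`, `ic50`,
#' `nh`. Starting values come from heuristics (initial `ic50` is the geometric
#' midpoint of the concentration range, `imax` from the response span,
#' `nh = 1`); the first converged local optimum from that start is reported.
#' Non-convergence is flagged on the result, never raised.
#'
#' @param concs concentrations (mM), at least 4 distinct values.
#' @param responses normalized current fractions, same length.
#' @return A [fit_result()] with parameters `imax`, `ic50`, `nh`.
#' @examples
#' cc <- c(0.2, 2, 5, 20, 100)
#' fit_hill(cc, hill_inhibition(cc, 0.55, 7.67, 1.02))
#' @export
fit_hill <- function(concs, responses) {
  stopifnot(length(concs) == length(responses))
  if (length(unique(concs)) < 4) {
    stop("need at least 4 distinct concentrations", call. = FALSE)
  }
  .assert_finite(concs, "concs"); .assert_finite(responses, "responses")
  pos <- concs[concs > 0]
  start <- list(imax = min(max(1 - min(responses), 0.05), 0.95),
                ic50 = sqrt(min(pos) * max(pos)),
                nh = 1)
  fn <- function(p) hill_inhibition(concs, p$imax, p$ic50, p$nh)
  r <- .nls_fit(fn, start,
                y = responses,
                lower = c(imax = 0, ic50 = 1e-9, nh = 0.05),
                upper = c(imax = 1, ic50 = 1e9, nh = 10))
  if (is.null(r)) {
    return(fit_result(unlist(start), rep(Inf, 3), Inf, FALSE,
                      length(concs), "hill"))
  }
  fit_result(r$params, r$stderr, r$rss, r$converged, length(concs), "hill")
}

#' Fit absolute permeability with the GHK flux equation
#'
#' The GHK current is linear in the permeability `p`, so the fit is an exact
#' weighted linear least-squares projection of the measured currents on the
#' GHK voltage shape; no iteration is involved.
#'
#' The fitted `p` is in the same unit system as [ghk_flux()] (cm/s with
#' currents as GHK current densities). If the currents carry an arbitrary
#' scale (e.g. single-channel pA), the fitted `p` absorbs it; ratios of
#' permeabilities between conditions are scale-free.
#'
#' @param vm voltages (mV), at least 3.
#' @param current measured currents at `vm` (outward positive).
#' @param ki,ko internal/external K+ (mM).
#' @param temp_K temperature (K).
#' @return A [fit_result()] with parameter `p` (cm/s).
#' @export
fit_ghk_permeability <- function(vm, current, ki, ko,
                                 temp_K = ko_constants$T_default) {
  stopifnot(length(vm) == length(current))
  if (length(vm) < 3) stop("need at least 3 voltages", call. = FALSE)
  if (all(current == 0)) stop("all-zero currents", call. = FALSE)
  g <- ghk_flux(1, ki, ko, vm, temp_K)   # shape at unit permeability
  p_hat <- sum(current * g) / sum(g^2)
  resid <- current - p_hat * g
  rss <- sum(resid^2)
  dof <- length(vm) - 1
  se <- if (dof > 0) sqrt(rss / dof / sum(g^2)) else Inf
  fit_result(c(p = max(p_hat, 0)), c(p = se), rss, TRUE, length(vm), "ghk",
             extra = list(ki = ki, ko = ko, temp_K = temp_K))
}

#' Fit a Boltzmann activation curve with offset
#'
#' Fits [boltzmann_offset()] to normalized conductance-voltage data with free
#' parameters `vhalf`, `z` and `gmin` (`z` may be fixed via `fix_z`).
#' The starting `vhalf` is the voltage where the data cross half of their
#' range. Unidentifiable data (e.g. saturated over the whole voltage range)
#' are flagged via `converged = FALSE` when the covariance is singular or the
#' `vhalf` uncertainty exceeds the voltage span.
#'
#' @param v voltages (mV), at least 5.
#' @param g normalized conductances (G/Gmax).
#' @param fix_z optional numeric; when given, `z` is held at this value.
#' @param temp_K temperature (K).
#' @return A [fit_result()] with parameters `vhalf`, `z`, `gmin`.
#' @export
fit_boltzmann <- function(v, g, fix_z = NULL,
                          temp_K = ko_constants$T_default) {
  stopifnot(length(v) == length(g))
  if (length(v) < 5) stop("need at least 5 voltages", call. = FALSE)
  span <- diff(range(v))
  half <- (max(g) + min(g)) / 2
  v0 <- tryCatch(stats::approx(g, v, xout = half, ties = mean)$y,
                 error = function(e) NA_real_)
  if (!is.finite(v0)) v0 <- stats::median(v)
  if (is.null(fix_z)) {
    start <- list(vhalf = v0, z = 1.5, gmin = max(min(g), 0) * 0.9)
    fn <- function(p) boltzmann_offset(v, p$vhalf, p$z, p$gmin, temp_K)
    lower <- c(vhalf = min(v) - 10 * span, z = 0.01, gmin = 0)
    upper <- c(vhalf = max(v) + 10 * span, z = 20, gmin = 0.999)
  } else {
    start <- list(vhalf = v0, gmin = max(min(g), 0) * 0.9)
    fn <- function(p) boltzmann_offset(v, p$vhalf, fix_z, p$gmin, temp_K)
    lower <- c(vhalf = min(v) - 10 * span, gmin = 0)
    upper <- c(vhalf = max(v) + 10 * span, gmin = 0.999)
  }
  r <- .nls_fit(fn, start, y = g, lower = lower, upper = upper)
  if (is.null(r)) {
    pp <- unlist(start)
    if (!is.null(fix_z)) pp <- c(pp[1], z = fix_z, pp[-1])
    return(fit_result(pp, rep(Inf, length(pp)), Inf, FALSE, length(v),
                      "boltzmann"))
  }
  params <- r$params; stderr <- r$stderr
  if (!is.null(fix_z)) {
    params <- c(params["vhalf"], z = fix_z, params["gmin"])
    stderr <- c(stderr["vhalf"], z = 0, stderr["gmin"])
  }
  converged <- r$converged && is.finite(stderr["vhalf"]) &&
    stderr["vhalf"] <= span
  fit_result(params, stderr, r$rss, converged, length(v), "boltzmann",
             extra = list(fixed_z = !is.null(fix_z)))
}
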
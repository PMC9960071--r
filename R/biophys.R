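#' Goldman-Hodgkin-Katz flux equation
#'
#' Constant-field current density carried by a single monovalent cation:
#' \deqn{I = P \frac{V_m F^2}{RT} \frac{K_i - K_o e^{-V_m F/RT}}{1 - e^{-V_m F/RT}}}
#' with outward current positive. Near `vm = 0` the expression is evaluated by
#' its second-order series expansion (the limit at 0 is `P*F*(Ki - Ko)` in the
#' internal unit system), keeping the function continuous through the
#' removable singularity.
#'
#' Units: `p` in cm/s, concentrations in mM (mol/m^3), `vm` in mV. The
#' returned value is a current density in A/m^2 (P is converted to m/s
#' internally); most analyses use only ratios of this quantity, so the
#' absolute scale cancels.
#'
#' @param p absolute permeability (cm/s), `p >= 0`.
#' @param ki internal ion concentration (mM), `> 0`.
#' @param ko external ion concentration (mM), `>= 0`.
#' @param vm membrane potential (mV); may be a vector.
#' @param temp_K temperature in K (default 293).
#' @return Current density (A/m^2), outward positive; same length as `vm`.
#' @examples
#' ghk_flux(5.82e-4, ki = 135, ko = 5, vm = 60)
#' ghk_flux(1e-4, ki = 100, ko = 100, vm = 0)  # no driving force -> 0
#' @export
ghk_flux <- function(p, ki, ko, vm, temp_K = ko_constants$T_default) {
  .assert_finite(p, "p"); .assert_finite(ki, "ki")
  .assert_finite(ko, "ko"); .assert_finite(vm, "vm")
  if (p < 0) stop("permeability 'p' must be >= 0", call. = FALSE)
  if (ki <= 0) stop("'ki' must be > 0", call. = FALSE)
  if (ko < 0) stop("'ko' must be >= 0", call. = FALSE)
  p_ms <- p / 100                       # cm/s -> m/s
  u <- .reduced_voltage(vm, temp_K)     # dimensionless
  scale <- p_ms * ko_constants$F        # A/m^2 per (mol/m^3)
  out <- numeric(length(u))
  small <- abs(u) < 1e-4
  # (ki - ko e^-u) u/(1 - e^-u) = (ki-ko)(1 + u/2 + u^2/12) + ko u + O(u^3)
  if (any(small)) {
    us <- u[small]
    out[small] <- scale * ((ki - ko) * (1 + us / 2 + us^2 / 12) + ko * us)
  }
  if (any(!small)) {
    ub <- u[!small]
    out[!small] <- scale * ub * (ki - ko * exp(-ub)) / (1 - exp(-ub))
  }
  out
}

#' GHK current ratio between two ionic conditions
#'
#' Ratio of GHK currents at a common voltage and permeability for two pairs of
#' internal/external concentrations:
#' \deqn{I_{C1}/I_{C2} = \frac{K_{in}(C1) - K_o(C1) e^{-V_m F/RT}}
#'                            {K_{in}(C2) - K_o(C2) e^{-V_m F/RT}}}
#' This is the "theoretical reduction" used to correct dose-response data for
#' the loss of outward driving force at elevated external K+.
#'
#' @param kin1,ko1 internal/external concentration (mM) in condition 1.
#' @param kin2,ko2 internal/external concentration (mM) in condition 2.
#' @param vm membrane potential (mV).
#' @param temp_K temperature (K).
#' @return Dimensionless current ratio.
#' @examples
#' ghk_current_ratio(108, 100, 108, 0.2, vm = 60)  # ~0.914
#' @export
ghk_current_ratio <- function(kin1, ko1, kin2, ko2, vm,
                              temp_K = ko_constants$T_default) {
  for (nm in c("kin1", "ko1", "kin2", "ko2", "vm")) {
    .assert_finite(get(nm), nm)
  }
  eu <- exp(-.reduced_voltage(vm, temp_K))
  den <- kin2 - ko2 * eu
  if (any(abs(den) < .Machine$double.eps * 100 * max(kin2, 1))) {
    stop("degenerate denominator in GHK current ratio", call. = FALSE)
  }
  (kin1 - ko1 * eu) / den
}

#' Hill inhibition curve
#'
#' Fractional current remaining at inhibitor concentration `conc`:
#' \deqn{I(C) = (1 - I_{max}) + \frac{I_{max}}{1 + (C/IC_{50})^{n_H}}}
#' so that `I(0) = 1` and `I(Inf) = 1 - imax`.
#'
#' @param conc concentration (mM), `>= 0`; may be a vector.
#' @param imax maximal fractional inhibition in `[0, 1]`.
#' @param ic50 half-maximal concentration (mM), `> 0`.
#' @param nh Hill coefficient, `> 0`.
#' @return Normalized current fraction.
#' @examples
#' hill_inhibition(7.67, imax = 0.55, ic50 = 7.67, nh = 1.02)  # 0.725
#' @export
hill_inhibition <- function(conc, imax, ic50, nh) {
  if (any(conc < 0)) stop("'conc' must be >= 0", call. = FALSE)
  if (imax < 0 || imax > 1) stop("'imax' must be in [0, 1]", call. = FALSE)
  if (ic50 <= 0) stop("'ic50' must be > 0", call. = FALSE)
  if (nh <= 0) stop("'nh' must be > 0", call. = FALSE)
  (1 - imax) + imax / (1 + (conc / ic50)^nh)
}

#' Boltzmann activation curve with a voltage-independent offset
#'
#' Normalized conductance
#' \deqn{G/G_{max} = \frac{1 - G_{min}}{1 + e^{(V_{1/2} - V) Z F / RT}} + G_{min}}
#' where `gmin` is the voltage-independent conductance fraction (the lower
#' horizontal asymptote) and `z` the equivalent gating charge.
#'
#' @param v voltage (mV); may be a vector.
#' @param vhalf half-activation voltage (mV).
#' @param z equivalent gating charge (elementary charges), `> 0` for
#'   depolarization-activated channels.
#' @param gmin voltage-independent fraction in `[0, 1)`.
#' @param temp_K temperature (K).
#' @return Normalized conductance in `(gmin, 1)`.
#' @export
boltzmann_offset <- function(v, vhalf, z, gmin = 0,
                             temp_K = ko_constants$T_default) {
  if (gmin < 0 || gmin >= 1) stop("'gmin' must be in [0, 1)", call. = FALSE)
  (1 - gmin) / (1 + exp((vhalf - v) * z / .rt_over_f_mV(temp_K))) + gmin
}

#' Permeability ratio from a reversal-potential shift
#'
#' Bi-ionic permeability ratio \eqn{P_X/P_K = \exp(\Delta E_{rev} Z F / RT)}
#' where `d_erv` is the mean reversal-potential shift on replacing external K+
#' with ion X.
#'
#' @param d_erv reversal-potential shift (mV).
#' @param z ion valence (default 1).
#' @param temp_K temperature (K).
#' @return Positive permeability ratio; `d_erv = 0` gives 1.
#' @examples
#' permeability_ratio(-7.26)  # ~0.75
#' @export
permeability_ratio <- function(d_erv, z = 1, temp_K = ko_constants$T_default) {
  .assert_finite(d_erv, "d_erv")
  exp(d_erv * z / .rt_over_f_mV(temp_K))
}
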
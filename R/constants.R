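#' Physical constants used throughout the package
#'
#' Faraday constant `F` (96485 C/mol), gas constant `R` (8.314 J/(mol K)),
#' default temperature `T_default` (293 K, room temperature for oocyte
#' recordings) and the elementary charge `e` (1.602e-19 C).
#'
#' All voltages at the package interface are in mV and all concentrations in
#' mM (= mol/m^3); conversion to SI happens inside the model equations.
#'
#' @format A named list with elements `F`, `R`, `T_default`, `e`.
#' @export
ko_constants <- list(
  F = 96485,       # C/mol
  R = 8.314,       # J/(mol K)
  T_default = 293, # K
  e = 1.602e-19    # C
)

# dimensionless reduced voltage u = Vm*F/(R*T), Vm in mV
.reduced_voltage <- function(vm_mV, temp_K) {
  vm_mV / 1000 * ko_constants$F / (ko_constants$R * temp_K)
}

# RT/F in mV
.rt_over_f_mV <- function(temp_K) {
  1000 * ko_constants$R * temp_K / ko_constants$F
}

.assert_finite <- function(x, name) {
  if (!is.numeric(x) || any(!is.finite(x))) {
    stop(sprintf("'%s' must be finite numeric", name), call. = FALSE)
  }
  invisible(x)
}
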
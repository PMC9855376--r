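# 2019 SI exact values (CODATA)
.ELEMENTARY_CHARGE_C <- 1.602176634e-19
.PLANCK_JS <- 6.62607015e-34

#' Conductance quantum in microsiemens
#'
#' The conductance quantum \eqn{G_0 = 2e^2/h} is the natural unit for
#' single-molecule junction conductance.  The value is computed from the
#' exact SI values of the elementary charge and the Planck constant.
#'
#' @return The conductance quantum in microsiemens (about 77.48).
#' @examples
#' conductance_quantum_uS()
#' @export
conductance_quantum_uS <- function() {
  2 * .ELEMENTARY_CHARGE_C^2 / .PLANCK_JS * 1e6
}

#' Convert a conductance from units of G0 to microsiemens
#'
#' @param value Numeric vector of conductances in units of the conductance
#'   quantum \eqn{G_0}.  Must be non-negative.
#' @return `value * 2e^2/h`, in microsiemens.
#' @examples
#' g0_to_microsiemens(1)        # 77.48 uS
#' g0_to_microsiemens(3.55e-3)  # a typical G-quadruplex junction
#' @export
g0_to_microsiemens <- function(value) {
  if (!is.numeric(value)) {
    stop("`value` must be numeric", call. = FALSE)
  }
  if (any(value < 0, na.rm = TRUE)) {
    stop("conductance must be non-negative", call. = FALSE)
  }
  value * conductance_quantum_uS()
}

# Conductance floor implied by a preamplifier current limit at a given bias,
# expressed in G0 units.
noise_floor_g0 <- function(bias_V, floor_pA = 10) {
  (floor_pA * 1e-12 / bias_V) / (conductance_quantum_uS() * 1e-6)
}
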
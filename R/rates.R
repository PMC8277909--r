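#' Right-hand sides of the excitable neuron equations
#'
#' Vectorised rate functions for the voltage, gating and synapse state of an
#' excitable cell. `v`, `eta` and `s` may be vectors (whole lattice fields);
#' `r` is the total synaptic plus external drive and enters the voltage
#' rate additively with unit gain.
#'
#' @param v,eta,s state values (any common length).
#' @param params an [excitable_params()] object.
#' @param r input drive (scalar or vector, default 0).
#' @return Numeric vector of time derivatives (per ms).
#' @export
voltage_rate <- function(v, eta, params, r = 0) {
  -(params$a1 + params$a2 * eta) * v +
    params$a3 * v^2 / (params$a4 + v^2) + params$a5 + r
}

#' @rdname voltage_rate
#' @export
gating_rate <- function(v, eta, params) {
  if (params$gating_kind == "type3") {
    -params$c1 * eta + params$c2 * v
  } else {
    vp <- pmax(v, 0)
    -params$d1 * eta + params$d2 * vp^3 / (params$d3 + vp^3) + params$d4
  }
}

#' @rdname voltage_rate
#' @export
synapse_rate <- function(v, s, params) {
  H <- synapse_gate(v)
  (H - s) / (params$t1 * (params$s1 - H))
}

#' Synaptic activation function
#'
#' The sigmoidal gate \eqn{H(v) = (1+\tanh(120(v-0.1)))/2} that converts a
#' voltage excursion into synaptic output drive.
#'
#' @param v voltage (vector).
#' @return Values in (0, 1).
#' @export
synapse_gate <- function(v) 0.5 * (1 + tanh(120 * (v - 0.1)))

## Analytic Jacobian of the (v, eta) subsystem at a point.
.jacobian_ve <- function(v, eta, params) {
  dvdv <- -(params$a1 + params$a2 * eta) +
    params$a3 * 2 * v * params$a4 / (params$a4 + v^2)^2
  dvde <- -params$a2 * v
  if (params$gating_kind == "type3") {
    dedv <- params$c2
    dede <- -params$c1
  } else {
    dedv <- if (v > 0) {
      params$d2 * 3 * v^2 * params$d3 / (params$d3 + v^3)^2
    } else 0
    dede <- -params$d1
  }
  matrix(c(dvdv, dvde, dedv, dede), 2, 2, byrow = TRUE)
}
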
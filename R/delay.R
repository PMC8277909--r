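#' Transmission-delay chains of fictitious rebound neurons
#'
#' Axonal transmission delays are modelled without delay-differential
#' equations: the source synapse field is fed, as an inhibitory pulse, to a
#' chain of "fictitious" type-3 units whose post-inhibitory rebound spike
#' re-emits a synaptic pulse about 2 ms after the input pulse. Each element
#' adds one 2-ms rebound wait, so a chain of `n_elements` delays the signal
#' by `2 * n_elements` ms; `n_elements = 0` is the identity.
#'
#' The element is a thalamic-type cell whose gating rate `c1` is calibrated
#' (see [calibrate_delay_element()]) so that the measured input-peak to
#' output-peak lag is 2.0 ms.
#'
#' @param n_elements chain length (0 to 3 in the delay scenarios).
#' @param n_cells how many lattice cells the chain carries in parallel.
#' @param params element parameters; default [delay_element_params()].
#' @param w_inh,i_p inhibitory coupling of the pulse onto each element.
#' @return An object of class `delay_chain`.
#' @export
make_delay_chain <- function(n_elements, n_cells = 1,
                             params = delay_element_params(),
                             w_inh = 3, i_p = 5) {
  stopifnot(n_elements >= 0, n_elements == round(n_elements))
  rs <- rest_state(params, 0)
  el <- lapply(seq_len(n_elements), function(k)
    list(v = rep(rs$v, n_cells), eta = rep(rs$eta, n_cells),
         s = rep(0, n_cells)))
  structure(list(elements = el, n_elements = n_elements,
                 n_active = n_elements, n_cells = n_cells,
                 params = params, w_inh = w_inh, i_p = i_p),
            class = "delay_chain")
}

#' Parameters of one calibrated delay element
#'
#' The thalamic type-3 set with the gating rate `c1` replaced by the
#' calibrated value that yields a 2.0-ms rebound wait (see
#' [calibrate_delay_element()], which recomputes it from scratch).
#'
#' @param c1 gating rate; default the shipped calibrated value.
#' @return An [excitable_params()] object.
#' @export
delay_element_params <- function(c1 = .DELAY_C1) {
  p <- tc_params()
  p$c1 <- c1
  p
}

## Shipped calibration for the 2-ms element (reproduced by
## calibrate_delay_element(); see tests).
.DELAY_C1 <- 0.04

#' Advance a delay chain by one time step
#'
#' Each element receives its predecessor's synapse (the first element the
#' external input field) as an inhibitory pulse
#' \eqn{-w_{inh}\,s_{in}\,(v + i_p)} and is integrated by one Euler step.
#' The chain output is the synapse field of element `n_active` (so a
#' mid-run delay switch just moves the tap), or the input itself when
#' `n_active == 0`.
#'
#' @param chain a `delay_chain`.
#' @param s_in input synapse field (length `n_cells`).
#' @param dt time step (ms).
#' @return The updated chain, with the current output in `$output`.
#' @export
delay_chain_step <- function(chain, s_in, dt) {
  p <- chain$params
  drive <- s_in
  for (k in seq_len(chain$n_elements)) {
    el <- chain$elements[[k]]
    r <- -chain$w_inh * drive * (el$v + chain$i_p)
    ## same scheme as the network integrator: implicit leak, floored gating
    ## (sustained inhibitory input trains must not drive eta into runaway)
    el$v <- semi_implicit_v(el$v, el$eta, p, r, dt)
    de <- gating_rate(el$v, el$eta, p)
    el$eta <- pmax(el$eta + dt * de, -1)
    ds <- synapse_rate(el$v, el$s, p)
    el$s <- el$s + dt * ds
    chain$elements[[k]] <- el
    drive <- el$s
  }
  chain$output <- if (chain$n_active == 0) s_in
                  else chain$elements[[chain$n_active]]$s
  chain
}

#' Set the active length of a chain (mid-run delay switch)
#'
#' @param chain a `delay_chain`.
#' @param n_active new tap position, `0 <= n_active <= n_elements`.
#' @return The chain.
#' @export
set_chain_tap <- function(chain, n_active) {
  stopifnot(n_active >= 0, n_active <= chain$n_elements)
  chain$n_active <- n_active
  chain
}

#' Canonical synaptic test pulse
#'
#' The synapse waveform of a post-inhibitory rebound spike of a standard
#' thalamic cell (inhibited for 5 ms, then released): a single ~1.2-ms
#' pulse with a well-defined peak, shaped like the pulses that actually
#' travel through the network's rebound pathways. Used as the reference
#' input for delay calibration and measurement.
#'
#' @param duration,dt trace length and step (ms).
#' @param inh_from,inh_to inhibition window (ms).
#' @return data.frame `t`, `s`.
#' @export
canonical_pulse <- function(duration = 30, dt = 0.002,
                            inh_from = 2, inh_to = 7) {
  tr <- simulate_neuron(tc_params(), duration, dt,
                        inh_fun = function(t)
                          as.numeric(t >= inh_from & t < inh_to),
                        w_inh = 3, i_p = 5)
  data.frame(t = tr$t, s = tr$s)
}

#' Measure the pulse lag through a delay chain
#'
#' Drives the chain with a single synaptic pulse and returns the time
#' between the input pulse peak and the output pulse peak (of the first
#' output pulse).
#'
#' @param chain a `delay_chain` (with `n_cells = 1`).
#' @param pulse input pulse as from [canonical_pulse()]; its sampling step
#'   is used as the integration step.
#' @return Lag in ms (`NA` if no output pulse was emitted).
#' @export
measure_chain_lag <- function(chain, pulse = canonical_pulse()) {
  dt <- pulse$t[2] - pulse$t[1]
  out <- numeric(nrow(pulse))
  for (i in seq_len(nrow(pulse))) {
    chain <- delay_chain_step(chain, pulse$s[i], dt)
    out[i] <- chain$output
  }
  if (max(out) < 0.5) return(NA_real_)
  i1 <- which(out > 0.5)[1]
  rest <- which(out[i1:length(out)] < 0.5)
  iend <- if (length(rest)) i1 + rest[1] - 1 else length(out)
  (which.max(out[1:iend]) - which.max(pulse$s)) * dt
}

#' Calibrate the 2-ms delay element
#'
#' One-parameter search on the element's gating rate `c1` so that a single
#' element delays the canonical pulse by `target` ms. The rebound wait is
#' monotone decreasing in `c1` on the single-pulse regime, so a root
#' bracket suffices. Fails loudly if no `c1` in the bracket reaches the
#' tolerance.
#'
#' @param target desired lag (ms).
#' @param tol acceptance tolerance on the re-measured lag (ms).
#' @param bracket `c1` search interval (single-rebound regime).
#' @param pulse reference pulse.
#' @return The calibrated [excitable_params()], with the measured lag in
#'   attribute `"measured_lag_ms"`.
#' @export
calibrate_delay_element <- function(target = 2.0, tol = 0.1,
                                    bracket = c(0.038, 0.06),
                                    pulse = canonical_pulse()) {
  lag_of <- function(c1) {
    ch <- make_delay_chain(1, params = delay_element_params(c1))
    measure_chain_lag(ch, pulse)
  }
  f <- function(c1) lag_of(c1) - target
  lo <- f(bracket[1]); hi <- f(bracket[2])
  if (!is.finite(lo) || !is.finite(hi) || lo * hi > 0)
    stop("calibration bracket does not straddle the target lag")
  c1 <- stats::uniroot(f, bracket, tol = 1e-5)$root
  got <- lag_of(c1)
  if (!is.finite(got) || abs(got - target) > tol)
    stop("delay element calibration failed: measured lag ",
         format(got, digits = 4), " ms")
  p <- delay_element_params(c1)
  attr(p, "measured_lag_ms") <- got
  p
}
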
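#' Simulate a single excitable neuron
#'
#' Forward (Euler) integration of one neuron under a piecewise-constant
#' drive protocol and/or an inhibitory synaptic conductance trace. The
#' inhibitory drive enters as \eqn{-w_{inh}\, s_{in}(t)\,(v + i_p)}, the
#' form used by the network's inhibitory synapses, so post-inhibitory
#' rebound of type-3 cells can be probed directly.
#'
#' @param params an [excitable_params()] object.
#' @param duration total time (ms).
#' @param dt time step (ms).
#' @param r_fun drive as a function of time (ms) returning a scalar, or a
#'   single number. Steps can be expressed with [piecewise_protocol()].
#' @param inh_fun optional inhibitory synapse trace `s_in(t)` in `[0, 1]`.
#' @param w_inh,i_p inhibitory coupling weight and offset.
#' @param init initial state; default the resting state at `r = r_fun(0)`
#'   truncated to the baseline drive.
#' @param spike_level voltage level whose upward crossing marks a spike.
#' @return A data.frame `t`, `v`, `eta`, `s` with attribute `"spikes"`
#'   (spike times, ms).
#' @export
simulate_neuron <- function(params, duration, dt = 0.005,
                            r_fun = 0, inh_fun = NULL,
                            w_inh = 3, i_p = 5,
                            init = NULL, spike_level = 0.5) {
  stopifnot(dt > 0, duration > 0)
  if (is.numeric(r_fun)) { r0 <- r_fun; r_fun <- function(t) r0 }
  if (is.null(init)) {
    rs <- rest_state(params, 0)
    init <- c(v = rs$v, eta = rs$eta, s = 0)
  }
  n <- round(duration / dt)
  out <- matrix(NA_real_, n + 1, 4,
                dimnames = list(NULL, c("t", "v", "eta", "s")))
  v <- init[["v"]]; eta <- init[["eta"]]; s <- init[["s"]]
  out[1, ] <- c(0, v, eta, s)
  spikes <- numeric(0)
  above <- v > spike_level
  for (i in seq_len(n)) {
    t <- (i - 1) * dt
    r <- r_fun(t)
    if (!is.null(inh_fun)) r <- r - w_inh * inh_fun(t) * (v + i_p)
    dv <- voltage_rate(v, eta, params, r)
    de <- gating_rate(v, eta, params)
    ds <- synapse_rate(v, s, params)
    v <- v + dt * dv; eta <- eta + dt * de; s <- s + dt * ds
    if (!is.finite(v) || !is.finite(eta) || !is.finite(s))
      stop("non-finite state at t = ", t, " ms")
    if (!above && v > spike_level) { spikes <- c(spikes, t + dt); above <- TRUE }
    if (above && v < spike_level) above <- FALSE
    out[i + 1, ] <- c(i * dt, v, eta, s)
  }
  res <- as.data.frame(out)
  attr(res, "spikes") <- spikes
  res
}

#' Piecewise-constant drive protocol
#'
#' @param times step onset times (ms), starting at 0.
#' @param values drive value from each onset until the next.
#' @return A function of time.
#' @export
piecewise_protocol <- function(times, values) {
  stopifnot(length(times) == length(values), times[1] <= 0)
  function(t) values[findInterval(t, times)]
}

#' Spike times and mean firing frequency of a trace
#'
#' @param trace a data.frame from [simulate_neuron()].
#' @param from ignore spikes before this time (ms), e.g. a transient.
#' @return `spike_times`: numeric vector (ms). `firing_frequency`: mean
#'   1/ISI in Hz (`NA` if fewer than 2 spikes).
#' @export
spike_times <- function(trace, from = 0) {
  sp <- attr(trace, "spikes")
  sp[sp >= from]
}

#' @rdname spike_times
#' @export
firing_frequency <- function(trace, from = 0) {
  sp <- spike_times(trace, from)
  if (length(sp) < 2) return(NA_real_)
  1000 / mean(diff(sp))
}
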
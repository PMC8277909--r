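#' Parameters of a two-state excitable neuron
#'
#' Bundles the coefficients of the voltage, gating and synapse equations of
#' one cell class. The voltage equation is
#' \deqn{\dot v = -(a_1 + a_2\eta)\,v + a_3 v^2/(a_4 + v^2) + a_5 + r,}
#' where \eqn{r} is the synaptic/external drive. The gating variable follows
#' either the linear "type-3" law \eqn{\dot\eta = -c_1\eta + c_2 v}
#' (thalamic relay and reticular cells: single spike to a step, rebound
#' spike after release from inhibition) or the saturating "type-1" law
#' \eqn{\dot\eta = -d_1\eta + d_2 v_+^3/(d_3 + v_+^3) + d_4}
#' (cortical cells: saddle-node threshold, firing rate grows continuously
#' with drive). \eqn{v_+ = \max(v, 0)}: the Hill term is evaluated on the
#' rectified voltage so that it stays a bounded sigmoid for the inhibited
#' (negative-voltage) branch as well. The synapse obeys
#' \deqn{\dot s = (H(v) - s) / (t_1 (s_1 - H(v))),\qquad
#'       H(v) = (1 + \tanh(120 (v - 0.1)))/2.}
#'
#' Time is measured in milliseconds throughout: all rate coefficients are
#' per-ms, and delays and frame intervals quoted elsewhere in the package
#' are in ms.
#'
#' @param a1,a2,a3,a4,a5 voltage-equation coefficients; `a4 > 0`.
#' @param gating_kind `"type3"` (linear gating) or `"type1"` (saturating).
#' @param c1,c2 type-3 gating coefficients (used when `gating_kind ==
#'   "type3"`).
#' @param d1,d2,d3,d4 type-1 gating coefficients. `d3` is the Hill
#'   denominator, `d4` the additive offset that sets the resting position of
#'   the gating nullcline (the "operational threshold" knob).
#' @param s1,t1 synapse-equation coefficients; `s1 > 1`, `t1 > 0`.
#' @return An object of class `excitable_params`.
#' @seealso [tc_params()], [cx_params()] for the standard parameter sets.
#' @export
excitable_params <- function(a1, a2, a3, a4, a5,
                             gating_kind = c("type3", "type1"),
                             c1 = NULL, c2 = NULL,
                             d1 = NULL, d2 = NULL, d3 = NULL, d4 = NULL,
                             s1, t1) {
  gating_kind <- match.arg(gating_kind)
  stopifnot(is.finite(a4), a4 > 0, is.finite(t1), t1 > 0,
            is.finite(s1), s1 > 1)
  if (gating_kind == "type3") {
    if (is.null(c1) || is.null(c2))
      stop("type3 gating requires c1 and c2")
  } else {
    if (is.null(d1) || is.null(d2) || is.null(d3) || is.null(d4))
      stop("type1 gating requires d1..d4")
    stopifnot(d1 > 0, d3 > 0)
  }
  structure(
    list(a1 = a1, a2 = a2, a3 = a3, a4 = a4, a5 = a5,
         gating_kind = gating_kind,
         c1 = c1, c2 = c2, d1 = d1, d2 = d2, d3 = d3, d4 = d4,
         s1 = s1, t1 = t1),
    class = "excitable_params")
}

#' @export
print.excitable_params <- function(x, ...) {
  cat("<excitable_params> gating:", x$gating_kind, "\n")
  cat("  a =", paste(format(c(x$a1, x$a2, x$a3, x$a4, x$a5)), collapse = ", "), "\n")
  if (x$gating_kind == "type3")
    cat("  c =", paste(format(c(x$c1, x$c2)), collapse = ", "), "\n")
  else
    cat("  d =", paste(format(c(x$d1, x$d2, x$d3, x$d4)), collapse = ", "), "\n")
  cat("  synapse (s1, t1) =", x$s1, ",", x$t1, "\n")
  invisible(x)
}

## Shared voltage/synapse coefficients of the model: all four cell
## classes use the same inverted-N voltage nullcline and synapse law.
.VOLT <- list(a1 = 0.167, a2 = 16.67, a3 = 167, a4 = 1.2, a5 = 1.47)
.SYN <- list(s1 = 10, t1 = 0.01)

#' Standard neuron parameter sets
#'
#' The four named parameter sets of the model. `tc_params()` returns the
#' type-3 thalamic set used for both the relay (TC) and reticular (RE)
#' layers of the three-layer network; `cx_params()` the type-1 cortical set.
#' `cx_params_reduced()` and `th_params_reduced()` return the modified
#' cortical and collapsed-thalamic sets of the reduced two-layer model.
#'
#' @return An [excitable_params()] object.
#' @export
tc_params <- function() {
  do.call(excitable_params,
          c(.VOLT, list(gating_kind = "type3", c1 = 0.05, c2 = 1.5), .SYN))
}

#' @rdname tc_params
#' @export
cx_params <- function() {
  do.call(excitable_params,
          c(.VOLT, list(gating_kind = "type1",
                        d1 = 0.09, d2 = 0.6, d3 = 0.3, d4 = 0.18), .SYN))
}

#' @rdname tc_params
#' @export
cx_params_reduced <- function() {
  do.call(excitable_params,
          c(.VOLT, list(gating_kind = "type1",
                        d1 = 0.3, d2 = 2, d3 = 0.3, d4 = 0.6), .SYN))
}

#' @rdname tc_params
#' @export
th_params_reduced <- function() {
  ## c1 = 0.2: gating four times faster than the three-layer thalamic cells
  ## (shorter rebound wait / refractory). The gating-line slope c2/c1 must
  ## exceed ~16 for an excitable rest to exist at all (the line has to pass
  ## above the fold of the voltage nullcline); it is kept at the thalamic
  ## value 30, so c2 = 6.
  do.call(excitable_params,
          c(.VOLT, list(gating_kind = "type3", c1 = 0.2, c2 = 6), .SYN))
}

#' Look up a named neuron parameter set
#'
#' @param name one of `"tc_table1"`, `"cx_table1"`, `"cx_table2"`,
#'   `"th_table2"`.
#' @return An [excitable_params()] object.
#' @export
neuron_params <- function(name) {
  switch(name,
         tc_table1 = tc_params(),
         cx_table1 = cx_params(),
         cx_table2 = cx_params_reduced(),
         th_table2 = th_params_reduced(),
         stop("unknown neuron parameter set: ", name))
}

#' Modulate the activation threshold of a parameter set
#'
#' The two threshold knobs of the model: for type-3 cells the slope of the
#' (linear) gating nullcline `c2/c1` is scaled; for type-1 cells the
#' additive gating offset `d4` is shifted, which moves the gating nullcline
#' vertically. Lowering the nullcline (negative `offset`, or `scale < 1`)
#' moves the equilibrium closer to the fold and lowers the threshold.
#'
#' @param params an [excitable_params()] object.
#' @param scale multiplicative factor on the type-3 nullcline slope
#'   (applied to `c2`).
#' @param offset additive shift of the type-1 offset `d4`.
#' @return Modified `excitable_params`.
#' @export
with_threshold <- function(params, scale = NULL, offset = NULL) {
  stopifnot(inherits(params, "excitable_params"))
  if (!is.null(scale)) {
    if (params$gating_kind != "type3")
      stop("slope scaling applies to type3 gating")
    params$c2 <- params$c2 * scale
  }
  if (!is.null(offset)) {
    if (params$gating_kind != "type1")
      stop("offset shift applies to type1 gating")
    params$d4 <- params$d4 + offset
  }
  params
}

#' Weight sets of the network models
#'
#' All inter- and intra-layer coupling weights, the inhibitory synapse
#' constant `i_p`, the intracortical gain `k_n`, the reticular input floor
#' and the cortical noise parameters. `weights_three_layer()` is the
#' three-layer default; `weights_reduced()` the reduced two-layer default
#' (which also carries the lateral thalamic weight `w_TH` and the TH-CX
#' weights).
#'
#' @param ... named overrides of individual weights.
#' @return A named list with class `tc_weights`.
#' @export
weights_three_layer <- function(...) {
  w <- list(w_RE_TC = 3, w_TC_RE = 12, w_RE_CX = 0.02, w_TC_CX = 25,
            w_CX_TC = 0.75, w_CX_RE = 7.5,
            w_E = 3, w_I = 6, k_n = 16.2, i_p = 5,
            mu = 0, sigma = 0.1, re_floor = -60)
  .apply_overrides(w, list(...))
}

#' @rdname weights_three_layer
#' @export
weights_reduced <- function(...) {
  w <- list(w_TH_CX = 7, w_CX_TH = 1, w_TH = 15,
            w_E = 6, w_I = 6, k_n = 9.72, i_p = 5,
            mu = 0, sigma = 0.1, re_floor = -60)
  .apply_overrides(w, list(...))
}

.apply_overrides <- function(w, over) {
  if (length(over)) {
    bad <- setdiff(names(over), names(w))
    if (length(bad)) stop("unknown weight name(s): ", paste(bad, collapse = ", "))
    w[names(over)] <- over
  }
  stopifnot(all(vapply(w, is.numeric, TRUE)))
  structure(w, class = "tc_weights")
}

#' Scale named weights (scenario multipliers)
#'
#' Applies multiplicative scenario factors (e.g. reticular inhibition
#' x300, cortical excitation x2) to a weight set and records them in the
#' `"multipliers"` attribute so that run manifests can report them.
#'
#' @param w a `tc_weights` object.
#' @param ... named multipliers, e.g. `w_RE_CX = 300`.
#' @return The scaled weight set.
#' @export
scale_weights <- function(w, ...) {
  mult <- list(...)
  bad <- setdiff(names(mult), names(w))
  if (length(bad)) stop("unknown weight name(s): ", paste(bad, collapse = ", "))
  for (nm in names(mult)) w[[nm]] <- w[[nm]] * mult[[nm]]
  prev <- attr(w, "multipliers")
  attr(w, "multipliers") <- c(prev, mult)
  w
}
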
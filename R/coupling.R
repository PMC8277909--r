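#' Gather presynaptic synapse fields through a connectivity structure
#'
#' A connectivity structure is either a sparse matrix whose row gathers the
#' presynaptic synapse values of the corresponding cell, or a 0/1
#' topographic mask vector (cell-to-matching-cell projection). No per-row
#' normalisation is applied.
#'
#' @param conn sparse matrix (post x pre) or numeric mask vector.
#' @param s presynaptic synapse field.
#' @return Numeric field over postsynaptic cells.
#' @export
gather <- function(conn, s) {
  if (is.numeric(conn) && is.null(dim(conn))) conn * s
  else as.numeric(conn %*% s)
}

#' Input field to the thalamic relay (TC) layer
#'
#' \deqn{T_{inp} = -w_{RE\text{-}TC}\,(C_{TH} R_s)\,(T_v + i_p)
#'               + w_{CX\text{-}TC}\,(M C_s)\,T_v}
#' The first term is reticular inhibition via the 4-neighbour cross map;
#' the second, excitatory cortical feedback. Both are multiplicative in the
#' postsynaptic voltage as printed in the model definition, so the
#' excitatory drive vanishes at `T_v = 0` (implemented literally).
#'
#' @param R_s,C_s,T_v fields over the lattice (equal length).
#' @param c_th cross map (sparse matrix).
#' @param m_conn CX-to-thalamus connectivity (matrix or mask).
#' @param w a `tc_weights` set.
#' @return Input field.
#' @export
tc_input <- function(R_s, C_s, T_v, c_th, m_conn, w) {
  stopifnot(length(R_s) == length(T_v), length(C_s) == length(T_v))
  -w$w_RE_TC * gather(c_th, R_s) * (T_v + w$i_p) +
    w$w_CX_TC * gather(m_conn, C_s) * T_v
}

#' Input field to the thalamic reticular (RE) layer
#'
#' \deqn{R_{inp} = w_{TC\text{-}RE}\,T_s R_v + w_{CX\text{-}RE}\,(M C_s)\,R_v,}
#' clamped from below at `floor` to prevent numerical runaway under strong
#' scenario scalings. Both terms are excitatory; the relay drive is
#' point-to-point (reciprocal TC-RE pairing).
#'
#' @param T_s,C_s,R_v fields.
#' @param m_conn CX-to-thalamus connectivity (matrix or mask).
#' @param w a `tc_weights` set.
#' @param floor lower clamp (default `w$re_floor`).
#' @return Input field.
#' @export
re_input <- function(T_s, C_s, R_v, m_conn, w, floor = w$re_floor) {
  stopifnot(length(T_s) == length(R_v), is.finite(floor))
  pmax(w$w_TC_RE * T_s * R_v + w$w_CX_RE * gather(m_conn, C_s) * R_v, floor)
}

#' Input field to the cortical (CX) layer
#'
#' Sum of up to six components:
#' 1. excitatory relay drive `+w_TC_CX (W T_s) C_v`;
#' 2. reticular inhibition `-w_RE_CX (W R_s)(C_v + i_p)` (the delayed field
#'    `R_delay` replaces `R_s` when a feedback delay chain is active);
#' 3. intracortical excitation `+w_E (k_n/sqrt(N)) (X C_s)` restricted to
#'    excitatory presynaptic cells;
#' 4. intracortical inhibition `-w_I (k_n/sqrt(N)) (X C_s)` restricted to
#'    inhibitory presynaptic cells;
#' 5. collapsed-thalamic inhibition `-w_TH_CX (W_TH L_s)(C_v + i_p)`
#'    (reduced model only);
#' 6. Gaussian noise, which is added by the integrator (not here), under
#'    its own step-size contract.
#'
#' `active` selects the components: the three-layer model uses 1-4 (+6),
#' the reduced model 3, 5 (+6).
#'
#' @param C_v cortical voltage field.
#' @param T_s,R_s,C_s,L_s synapse fields (those required by `active`).
#' @param conn list with elements `w_conn` (thalamus-to-CX), `x_e`, `x_i`
#'   (intracortical adjacency split by presynaptic E/I label), `wth_conn`
#'   (reduced-model TH-to-CX), as needed.
#' @param w a `tc_weights` set.
#' @param n_total total number of cells N (for the `k_n/sqrt(N)` gain).
#' @param active integer vector of component numbers.
#' @return Input field.
#' @export
cx_input <- function(C_v, T_s = NULL, R_s = NULL, C_s = NULL, L_s = NULL,
                     conn = list(), w, n_total,
                     active = c(1, 2, 3, 4)) {
  kn <- w$k_n / sqrt(n_total)
  inp <- numeric(length(C_v))
  if (1 %in% active)
    inp <- inp + w$w_TC_CX * gather(conn$w_conn, T_s) * C_v
  if (2 %in% active)
    inp <- inp - w$w_RE_CX * gather(conn$w_conn_re %||% conn$w_conn, R_s) *
      (C_v + w$i_p)
  if (3 %in% active)
    inp <- inp + w$w_E * kn * gather(conn$x_e, C_s)
  if (4 %in% active)
    inp <- inp - w$w_I * kn * gather(conn$x_i, C_s)
  if (5 %in% active) {
    if (is.null(conn$wth_conn))
      stop("component 5 requires the reduced-model TH-CX connectivity")
    inh <- w$w_TH_CX * gather(conn$wth_conn, L_s) * (C_v + w$i_p)
    if (!is.null(conn$wth_recv)) inh <- inh * conn$wth_recv
    inp <- inp - inh
  }
  inp
}

#' Clamp an input field from below
#'
#' Inputs are saturated at a minimum to prevent numerical runaway under
#' strong (long-range or scenario-scaled) drive; the reticular input uses
#' this via [re_input()], and the integrator applies it to the cortical
#' input as well.
#'
#' @param inp input field.
#' @param floor lower clamp.
#' @return Clamped field.
#' @export
input_floor <- function(inp, floor = -60) pmax(inp, floor)

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Input field to the collapsed thalamic layer (reduced model)
#'
#' \deqn{L_{inp} = w_{TH}\,C_{TH}(L_v \odot L_s)
#'              + w_{CX\text{-}TH}\,(W_{TH} C_s)\,L_v}
#' Lateral intra-thalamic excitation over the 4-neighbour map (gathering
#' the presynaptic product \eqn{L_v L_s} of each neighbour, which keeps
#' the strong lateral drive bounded by the presynaptic pulse) plus
#' cortical drive multiplicative in the postsynaptic thalamic voltage.
#'
#' @param L_v,L_s,C_s fields.
#' @param c_th lateral 4-neighbour map.
#' @param wth_conn CX-to-TH connectivity (matrix or mask).
#' @param w a `tc_weights` set (reduced).
#' @return Input field.
#' @export
th_input_reduced <- function(L_v, L_s, C_s, c_th, wth_conn, w) {
  stopifnot(length(L_v) == length(L_s))
  w$w_TH * gather(c_th, L_v * L_s) +
    w$w_CX_TH * gather(wth_conn, C_s) * L_v
}
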
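#' Simulation configuration
#'
#' Assembles every knob of a network simulation. All defaults are the
#' reference three-layer operating point: 60 x 60 layers, 99% intracortical
#' connectivity, 80/20 cortical E/I composition, 1% corticothalamic
#' feedback and 10% thalamocortical projection, cortical noise sigma 0.1,
#' 2-ms frame recording.
#'
#' @param model `"three_layer"` or `"reduced"`.
#' @param rows,cols lattice size.
#' @param dt integration step (ms).
#' @param duration simulated time (ms).
#' @param record_every frame interval (ms); must be a multiple of `dt`.
#' @param seed RNG seed used for connectivity and noise.
#' @param weights a `tc_weights` set; default matches `model`.
#' @param x_fraction intracortical connectivity fraction of the full
#'   4-neighbour lattice.
#' @param cluster optional [cluster_spec()] replacing uniform thinning.
#' @param e_fraction cortical excitatory fraction.
#' @param m_fraction corticothalamic feedback fraction (three-layer).
#' @param w_fraction thalamocortical projection fraction (three-layer).
#' @param share_m if `TRUE` (default) the same feedback mask serves CX->TC
#'   and CX->RE.
#' @param share_w if `TRUE` the same projection mask serves TC->CX and
#'   RE->CX; default `FALSE` (independent draws).
#' @param wth_fraction TH->CX connectivity fraction (reduced model).
#' @param unconnected_cells cell indices whose TH->CX input is removed
#'   (the "uninhibited nodes" of the reduced-model scenarios).
#' @param conn_style `"topographic"` (default: a fraction of source cells
#'   project to their matching lattice position) or `"bipartite"` (random
#'   pairwise matrix of the same fraction).
#' @param sigma cortical noise amplitude; `noise_mode` `"diffusion"` scales
#'   it by `sqrt(dt)` per step (stochastic-Euler contract), `"input"` by
#'   `dt` (noise as a plain input component), `"off"` disables it.
#' @param noise_mode see `sigma`.
#' @param boundary_width absorbing ring width (cells).
#' @param cx_gating_offset operational-threshold shift added to the
#'   cortical `d4`.
#' @param triggers list of triggers, each
#'   `list(layer = "CX", cells = "center" or indices, dv = 1.5)`, applied
#'   to the initial voltage field.
#' @param delay_ms_th_cx thalamus-to-cortex transmission delay (0, 2, 4 or
#'   6 ms), realised as a rebound-delay chain on the inhibitory synapse
#'   field (reduced model: on `L_s`; three-layer: on `R_s`).
#' @param delay_ms_cx_th cortex-to-thalamus delay on `C_s` (three-layer).
#' @param modifiers list of scheduled modifiers, see [apply_modifier()].
#' @param preset optional preset name recorded in the manifest.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(model = c("three_layer", "reduced"),
                       rows = 60, cols = 60,
                       dt = 0.005, duration = 400, record_every = 2,
                       seed = 1,
                       weights = NULL,
                       x_fraction = 0.99, cluster = NULL,
                       e_fraction = 0.8,
                       m_fraction = 0.01, w_fraction = 0.10,
                       share_m = TRUE, share_w = FALSE,
                       wth_fraction = 1.0, unconnected_cells = integer(0),
                       conn_style = c("topographic", "bipartite"),
                       sigma = NULL,
                       noise_mode = c("diffusion", "input", "off"),
                       boundary_width = 1,
                       cx_gating_offset = 0,
                       triggers = list(list(layer = "CX", cells = "center",
                                            dv = 1.5)),
                       delay_ms_th_cx = 0, delay_ms_cx_th = 0,
                       modifiers = list(),
                       preset = NULL) {
  model <- match.arg(model)
  conn_style <- match.arg(conn_style)
  noise_mode <- match.arg(noise_mode)
  if (is.null(weights))
    weights <- if (model == "three_layer") weights_three_layer()
               else weights_reduced()
  if (is.null(sigma)) sigma <- weights$sigma
  stopifnot(dt > 0, duration > 0,
            abs(record_every / dt - round(record_every / dt)) < 1e-9,
            delay_ms_th_cx %in% c(0, 2, 4, 6),
            delay_ms_cx_th %in% c(0, 2, 4, 6))
  structure(
    list(model = model, rows = rows, cols = cols, dt = dt,
         duration = duration, record_every = record_every, seed = seed,
         weights = weights, x_fraction = x_fraction, cluster = cluster,
         e_fraction = e_fraction, m_fraction = m_fraction,
         w_fraction = w_fraction, share_m = share_m, share_w = share_w,
         wth_fraction = wth_fraction, unconnected_cells = unconnected_cells,
         conn_style = conn_style, sigma = sigma, noise_mode = noise_mode,
         boundary_width = boundary_width,
         cx_gating_offset = cx_gating_offset,
         triggers = triggers,
         delay_ms_th_cx = delay_ms_th_cx, delay_ms_cx_th = delay_ms_cx_th,
         modifiers = modifiers, preset = preset),
    class = "sim_config")
}

#' Cell indices of the absorbing boundary ring
#'
#' @param spec a [lattice_spec()].
#' @param width ring width in cells.
#' @return Integer vector of cell indices.
#' @export
boundary_ring <- function(spec, width = 1) {
  i <- rep(seq_len(spec$rows), spec$cols)
  j <- rep(seq_len(spec$cols), each = spec$rows)
  which(i <= width | i > spec$rows - width |
        j <= width | j > spec$cols - width)
}

#' Resolve a trigger cell specification
#'
#' @param cells `"center"`, a matrix of (row, col) pairs, or cell indices.
#' @param spec a [lattice_spec()].
#' @return Integer cell indices.
#' @export
resolve_cells <- function(cells, spec) {
  if (is.character(cells) && identical(cells, "center"))
    return(cell_index(round(spec$rows / 2), round(spec$cols / 2), spec$rows))
  if (is.matrix(cells))
    return(cell_index(cells[, 1], cells[, 2], spec$rows))
  as.integer(cells)
}

#' Build a network model from a configuration
#'
#' Realises the connectivity (consuming the current RNG stream; callers
#' that need reproducibility should `set.seed()` first, as
#' [run_simulation()] does), computes the resting state of every layer,
#' applies the initial triggers and sets up the absorbing boundary and any
#' delay chains.
#'
#' @param config a [sim_config()].
#' @return A list of class `tc_model` with elements `spec`, `params`,
#'   `conn`, `weights`, `state`, `boundary`, `chains`, `audit` (realised
#'   connectivity fractions).
#' @export
build_model <- function(config) {
  spec <- lattice_spec(config$rows, config$cols)
  n <- spec$n
  w <- config$weights

  ## --- intracortical adjacency (full -> thinned or clustered)
  x_full <- build_lattice4(spec)
  full_edges <- edge_count(x_full)
  x <- if (!is.null(config$cluster)) {
    thin_clustered(x_full, spec, config$cluster)
  } else if (config$x_fraction < 1) {
    thin_uniform(x_full, config$x_fraction, full_edges)
  } else x_full
  ei <- assign_ei(n, config$e_fraction)
  e_num <- as.numeric(ei == "E")
  x_e <- x %*% Matrix::Diagonal(n, e_num)
  x_i <- x %*% Matrix::Diagonal(n, 1 - e_num)
  c_th <- build_c_th(spec)

  mk_conn <- function(fraction) {
    if (config$conn_style == "topographic") topographic_mask(n, fraction)
    else random_bipartite(n, n, fraction)
  }

  conn <- list(x = x, x_e = x_e, x_i = x_i, c_th = c_th, ei = ei)
  audit <- list(x_fraction = edge_count(x) / full_edges,
                e_fraction = mean(e_num))

  params <- list()
  state <- list()
  if (config$model == "three_layer") {
    conn$m_tc <- mk_conn(config$m_fraction)
    conn$m_re <- if (config$share_m) conn$m_tc else mk_conn(config$m_fraction)
    conn$w_tc <- mk_conn(config$w_fraction)
    conn$w_re <- if (config$share_w) conn$w_tc else mk_conn(config$w_fraction)
    audit$m_fraction <- sum(conn$m_tc != 0) / n
    audit$w_fraction <- sum(conn$w_tc != 0) / n
    params$TC <- tc_params()
    params$RE <- tc_params()
    params$CX <- with_threshold(cx_params(), offset = config$cx_gating_offset)
  } else {
    ## W_sparse-TH: long-range random bipartite projections (10% of all
    ## pairs at default), one draw per direction; on top, a per-CX-cell
    ## receive mask realises the "TH-CX connectivity percentage" and the
    ## unconnected (uninhibited) nodes.
    conn$wth_down <- random_bipartite(n, n, config$w_fraction)
    conn$wth_up <- random_bipartite(n, n, config$w_fraction)
    recv <- topographic_mask(n, config$wth_fraction)
    recv[config$unconnected_cells] <- 0
    conn$wth_recv <- recv
    audit$wth_fraction <- mean(recv != 0)
    params$CX <- with_threshold(cx_params_reduced(),
                                offset = config$cx_gating_offset)
    params$TH <- th_params_reduced()
  }

  ## --- resting states and trigger
  for (layer in names(params)) {
    rs <- rest_state(params[[layer]], 0)
    state[[layer]] <- list(v = rep(rs$v, n), eta = rep(rs$eta, n),
                           s = rep(0, n), rest = rs)
  }
  for (tr in config$triggers) {
    layer <- tr$layer %||% "CX"
    if (!layer %in% names(state)) next
    cells <- resolve_cells(tr$cells, spec)
    state[[layer]]$v[cells] <- state[[layer]]$v[cells] + (tr$dv %||% 1.5)
  }

  ring <- boundary_ring(spec, config$boundary_width)

  chains <- list()
  if (config$delay_ms_th_cx > 0)
    chains$th_cx <- make_delay_chain(config$delay_ms_th_cx / 2, n_cells = n)
  if (config$delay_ms_cx_th > 0)
    chains$cx_th <- make_delay_chain(config$delay_ms_cx_th / 2, n_cells = n)

  structure(list(spec = spec, params = params, conn = conn, weights = w,
                 state = state, boundary = ring, chains = chains,
                 audit = audit, config = config),
            class = "tc_model")
}

#' @export
print.tc_model <- function(x, ...) {
  cat("<tc_model>", x$config$model, sprintf("%dx%d", x$spec$rows, x$spec$cols),
      "layers:", paste(names(x$params), collapse = ", "), "\n")
  cat("  realised:", paste(sprintf("%s=%.4f", names(x$audit),
                                   unlist(x$audit)), collapse = "  "), "\n")
  invisible(x)
}

#' Build a small fully auditable model instance
#'
#' A tiny (default 3 x 3) network built from a preset configuration, for
#' hand-checkable input-field computations.
#'
#' @param rows,cols lattice size.
#' @param preset preset name (see [preset_catalog()]).
#' @param seed RNG seed.
#' @param ... overrides passed to the preset.
#' @return A `tc_model`.
#' @export
make_micro_network <- function(rows = 3, cols = 3,
                               preset = "closed_loop_default", seed = 1, ...) {
  cfg <- preset_config(preset, rows = rows, cols = cols, seed = seed, ...)
  set.seed(cfg$seed)
  build_model(cfg)
}
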
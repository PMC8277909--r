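#' Catalogue of named scenario presets
#'
#' Each preset resolves to a full [sim_config()] via [preset_config()].
#' The catalogue covers the named study scenarios: open/closed loop,
#' clustered cortices, the reduced-model delay scenarios (0/2/4/6 ms),
#' unconnected-node wave steering, the reverse-oscillation node line, the
#' spiral through a ten-fold inhibition drop, the E/I weight scalings and
#' the 80 x 80 array.
#'
#' @return A data.frame with `name` and `description`.
#' @export
preset_catalog <- function() {
  data.frame(
    name = c("open_loop", "closed_loop_deterministic", "closed_loop_default",
             "connectivity_sweep", "clustered_25_90",
             "two_cluster_open", "two_cluster_closed",
             "reduced_delay", "reduced_90pct_unconnected",
             "node_inside_field", "node_at_edge", "two_nodes", "node_line",
             "spiral_inhibition_drop",
             "re_inhibition_x300", "cx_tc_x10", "we_x2", "big_array_80"),
    description = c(
      "three-layer, no corticothalamic feedback, 99% E, ~99% intracortical",
      "closed loop, 99% E, single-cell trigger, no noise",
      "closed loop, 80/20 E/I, 99% intracortical, noise sigma 0.1",
      "closed_loop_default with x_fraction set by `fraction`",
      "closed loop, one 20x20 cluster at 90% intra / 25% overall",
      "cortex only, two 15x15 clusters at 99% intra / 31% overall",
      "as two_cluster_open but with the thalamus in closed loop",
      "reduced model, delay set by `delay_ms` (0/2/4/6), full TH-CX",
      "reduced model, delay 4 ms, TH-CX connectivity dropped to 90%",
      "reduced, one unconnected node at the centre of the firing field",
      "reduced, one unconnected node at the edge of the firing field",
      "reduced, two unconnected nodes launching opposing waves",
      "reduced, a line of unconnected nodes (reverse oscillation)",
      "reduced, ten-fold thalamic inhibition drop at t0 = 28 ms",
      "closed loop, 90% E, reticular inhibition scaled by `factor`",
      "closed loop, corticothalamic excitation scaled by `factor`",
      "closed loop, cortical excitatory weight scaled by `factor`",
      "node_at_edge on an 80x80 lattice"),
    stringsAsFactors = FALSE)
}

#' Resolve a preset into a simulation configuration
#'
#' @param name preset name from [preset_catalog()].
#' @param rows,cols lattice size (defaults per preset).
#' @param seed RNG seed.
#' @param duration simulated time (ms; defaults per preset).
#' @param fraction intracortical fraction for `connectivity_sweep`.
#' @param delay_ms thalamocortical delay for `reduced_delay`.
#' @param factor weight multiplier for the E/I scaling presets
#'   (`re_inhibition_x300` default 300, `cx_tc_x10` default 10, `we_x2`
#'   default 2; `factor = 1` gives the matched control).
#' @param ... further overrides forwarded to [sim_config()].
#' @return A [sim_config()].
#' @export
preset_config <- function(name, rows = NULL, cols = NULL, seed = 1,
                          duration = NULL, fraction = NULL, delay_ms = 4,
                          factor = NULL, ...) {
  ## cx_gating_offset = 0.01 is the operational-threshold calibration of
  ## the three-layer model: the cortical gating offset is raised until the
  ## closed-loop rhythm falls into the 10-20 Hz operating band (at the
  ## printed offset alone the loop free-runs near 26 Hz)
  base <- function(rows_d = 60, cols_d = 60, dur_d = 400,
                   cx_gating_offset = 0.01, ...)
    sim_config(rows = rows %||% rows_d, cols = cols %||% cols_d,
               seed = seed, duration = duration %||% dur_d,
               preset = name, cx_gating_offset = cx_gating_offset, ...)
  ctr <- function(spec) c(round(spec[1] / 2), round(spec[2] / 2))
  rr <- rows %||% 60; cc <- cols %||% 60

  ## reduced-model scenarios share this core
  reduced_base <- function(dur_d = 200, delay = delay_ms, wth = 1.0,
                           uncells = integer(0), mods = list(), ...)
    base(dur_d = dur_d, model = "reduced", e_fraction = 1,
         x_fraction = 1, wth_fraction = wth, unconnected_cells = uncells,
         delay_ms_th_cx = delay, sigma = 0, modifiers = mods,
         cx_gating_offset = 0, ...)

  switch(name,
    open_loop = base(
      m_fraction = 0, e_fraction = 0.99, x_fraction = 0.99, sigma = 0,
      triggers = list(list(layer = "CX", cells = "center", dv = 1.5),
                      list(layer = "TC", cells = "center", dv = 1.5)), ...),
    closed_loop_deterministic = base(
      e_fraction = 0.99, sigma = 0, ...),
    closed_loop_default = base(...),
    connectivity_sweep = base(
      x_fraction = fraction %||% 0.5, ...),
    clustered_25_90 = base(
      cluster = cluster_spec(
        list(list(rows = .block(rr, round(rr / 3)),
                  cols = .block(cc, round(cc / 3)))),
        intra_fraction = 0.90, overall_fraction = 0.25), ...),
    two_cluster_open = base(
      m_fraction = 0, w_fraction = 0, sigma = 0,
      cluster = .two_clusters(rr, cc, 0.99, 0.31),
      triggers = list(list(layer = "CX",
                           cells = .cluster_center(rr, cc, 1), dv = 1.5)), ...),
    two_cluster_closed = base(
      cluster = .two_clusters(rr, cc, 0.99, 0.31), sigma = 0,
      triggers = list(list(layer = "CX",
                           cells = .cluster_center(rr, cc, 1), dv = 1.5)), ...),
    reduced_delay = reduced_base(...),
    reduced_90pct_unconnected = reduced_base(wth = 0.9, ...),
    node_inside_field = reduced_base(
      uncells = cell_index(ctr(c(rr, cc))[1], ctr(c(rr, cc))[2], rr), ...),
    node_at_edge = reduced_base(
      uncells = .offset_cell(rr, cc, 12), ...),
    two_nodes = reduced_base(
      uncells = c(.offset_cell(rr, cc, 12), .offset_cell(rr, cc, -12)), ...),
    node_line = reduced_base(
      uncells = cell_index(ctr(c(rr, cc))[1],
                           pmax(2, pmin(cc - 1, seq(round(cc * 0.25),
                                                    round(cc * 0.75)))), rr),
      mods = list(list(type = "threshold_block",
                       cells = .half_sheet(rr, cc), t_on = 1, t_off = 10,
                       offset = 2)), ...),
    spiral_inhibition_drop = reduced_base(
      mods = list(list(type = "inhibition_scale", factor = 0.1, t0 = 28)), ...),
    re_inhibition_x300 = base(
      e_fraction = 0.9, x_fraction = 1,
      weights = scale_weights(weights_three_layer(),
                              w_RE_CX = factor %||% 300), ...),
    cx_tc_x10 = base(
      e_fraction = 0.9, x_fraction = 1,
      weights = scale_weights(weights_three_layer(),
                              w_CX_TC = factor %||% 10), ...),
    we_x2 = base(
      weights = scale_weights(weights_three_layer(),
                              w_E = factor %||% 2), ...),
    big_array_80 = preset_config("node_at_edge", rows = rows %||% 80,
                                 cols = cols %||% 80, seed = seed,
                                 duration = duration, delay_ms = delay_ms,
                                 ...),
    stop("unknown preset: ", name))
}

## centred square block of side `side` (clipped to the interior)
.block <- function(extent, side) {
  lo <- max(2, round((extent - side) / 2) + 1)
  lo:min(extent - 1, lo + side - 1)
}

## two square clusters centred at (25%, 25%) and (75%, 75%), each side a
## quarter of the lattice (15 x 15 at the reference 60 x 60)
.two_clusters <- function(rr, cc, intra, overall) {
  s1 <- max(3, round(rr / 4)); s2 <- max(3, round(cc / 4))
  lo <- function(extent, at, side) {
    l <- round(extent * at - side / 2)
    max(2, min(extent - side, l))
  }
  r1 <- lo(rr, 0.25, s1) + 0:(s1 - 1); c1 <- lo(cc, 0.25, s2) + 0:(s2 - 1)
  r2 <- lo(rr, 0.75, s1) + 0:(s1 - 1); c2 <- lo(cc, 0.75, s2) + 0:(s2 - 1)
  cluster_spec(list(list(rows = r1, cols = c1),
                    list(rows = r2, cols = c2)),
               intra_fraction = intra, overall_fraction = overall)
}

.cluster_center <- function(rr, cc, which_cluster) {
  at <- if (which_cluster == 1) 0.25 else 0.75
  cell_index(round(rr * at), round(cc * at), rr)
}

.offset_cell <- function(rr, cc, offset) {
  i <- round(rr / 2); j <- round(cc / 2) + offset
  cell_index(i, max(2, min(cc - 1, j)), rr)
}

.half_sheet <- function(rr, cc) {
  ij <- expand.grid(i = 2:(rr - 1), j = 2:(round(cc / 2) - 1))
  cell_index(ij$i, ij$j, rr)
}

#' Run a preset
#'
#' @param name preset name.
#' @param seed RNG seed.
#' @param ... overrides forwarded to [preset_config()].
#' @inheritParams run_simulation
#' @return A `tc_trajectory`.
#' @export
run_preset <- function(name, seed = 1, progress = FALSE, ...) {
  run_simulation(preset_config(name, seed = seed, ...), progress = progress)
}
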
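#' Run a configured network simulation
#'
#' Integrates the coupled system with the explicit stochastic Euler scheme:
#' deterministic rates advance by `dt`, cortical noise is added per step
#' according to the configured noise contract, boundary-ring cells are held
#' at rest (absorbing, unexcitable boundary), and scheduled modifiers are
#' applied at their onset times. Voltage fields of every layer are recorded
#' every `record_every` ms.
#'
#' @param config a [sim_config()].
#' @param progress print progress every 10 ms of model time.
#' @return A `tc_trajectory`: list with `movies` (one [activity_movie()]
#'   per layer), `times` (frame times, ms), `model` (final state) and
#'   `manifest` (config echo, seed, realised connectivity, multipliers,
#'   wall time).
#' @export
run_simulation <- function(config, progress = FALSE) {
  t0 <- Sys.time()
  set.seed(config$seed)
  model <- build_model(config)
  res <- run_core(model, duration = config$duration,
                  record_every = config$record_every, progress = progress)
  frame_dt <- config$record_every
  movies <- lapply(res$movies, function(m)
    activity_movie(array(m, dim = c(nrow(m), model$spec$rows, model$spec$cols)),
                   frame_dt = frame_dt))
  manifest <- list(
    preset = config$preset, model = config$model,
    rows = config$rows, cols = config$cols,
    dt = config$dt, duration = config$duration,
    record_every = config$record_every, seed = config$seed,
    sigma = config$sigma, noise_mode = config$noise_mode,
    realised = model$audit,
    weight_multipliers = attr(config$weights, "multipliers"),
    wall_time_s = as.numeric(Sys.time() - t0, units = "secs"))
  structure(list(movies = movies, times = res$times, model = res$model,
                 manifest = manifest, config = config),
            class = "tc_trajectory")
}

#' @export
print.tc_trajectory <- function(x, ...) {
  cat("<tc_trajectory>", x$manifest$model,
      sprintf("%dx%d", x$manifest$rows, x$manifest$cols),
      "duration", x$manifest$duration, "ms, seed", x$manifest$seed, "\n")
  if (!is.null(x$manifest$preset)) cat("  preset:", x$manifest$preset, "\n")
  cat("  layers:", paste(names(x$movies), collapse = ", "),
      " frames:", length(x$times), "\n")
  invisible(x)
}

#' Advance a model by one integration step
#'
#' Single-step contract of the integrator (same code path as
#' [run_simulation()]). Deterministic when `sigma = 0`.
#'
#' @param model a `tc_model` from [build_model()].
#' @param dt step (ms); defaults to the model's configured `dt`.
#' @return The updated model (clock advanced by `dt`).
#' @export
step_model <- function(model, dt = model$config$dt) {
  run_core(model, duration = dt, record_every = NULL, dt = dt)$model
}

## The integration engine. `duration` is relative to the model clock.
run_core <- function(model, duration, record_every = NULL,
                     dt = model$config$dt, progress = FALSE) {
  cfg <- model$config
  spec <- model$spec; n <- spec$n
  w <- model$weights
  three <- cfg$model == "three_layer"
  conn <- model$conn
  ring <- model$boundary
  clock0 <- model$clock %||% 0

  nsteps <- round(duration / dt)
  rec_stride <- if (is.null(record_every)) NA_integer_
                else round(record_every / dt)
  layers <- names(model$state)
  movies <- NULL; times <- NULL
  if (!is.na(rec_stride)) {
    nfr <- nsteps %/% rec_stride
    movies <- lapply(layers, function(l) matrix(NA_real_, nfr, n))
    names(movies) <- layers
    times <- numeric(nfr)
  }

  ## local state
  S <- model$state
  rest <- lapply(S, `[[`, "rest")
  chains <- model$chains

  ## noise scaling per contract
  noise_amp <- if (cfg$noise_mode == "off" || cfg$sigma == 0) 0
               else if (cfg$noise_mode == "diffusion") cfg$sigma * sqrt(dt)
               else cfg$sigma * dt
  interior <- setdiff(seq_len(n), ring)

  ## modifier schedule
  mods <- cfg$modifiers
  mod_times <- vapply(mods, function(m) m$t_on %||% m$t %||% m$t0 %||% 0, 0)
  pending <- order(mod_times)
  goff <- lapply(S, function(x) NULL)      # active threshold blocks
  stim <- NULL                             # active stimulus field
  active_blocks <- list(); active_stim <- list()

  cx_components <- if (three) c(1, 2, 3, 4) else c(3, 5)
  cx_conn <- if (three)
    list(w_conn = conn$w_tc, w_conn_re = conn$w_re,
         x_e = conn$x_e, x_i = conn$x_i)
  else
    list(x_e = conn$x_e, x_i = conn$x_i, wth_conn = conn$wth_down,
         wth_recv = conn$wth_recv)

  fr <- 0
  for (st in seq_len(nsteps)) {
    t <- clock0 + (st - 1) * dt

    ## -- scheduled modifiers: onsets
    while (length(pending) && mod_times[pending[1]] <= t + 1e-9) {
      m <- mods[[pending[1]]]
      applied <- apply_modifier_runtime(m, w, chains, spec)
      w <- applied$w; chains <- applied$chains
      if (!is.null(applied$block)) active_blocks <- c(active_blocks, list(applied$block))
      if (!is.null(applied$stim)) active_stim <- c(active_stim, list(applied$stim))
      pending <- pending[-1]
    }
    ## -- windowed modifiers: rebuild offsets/stimulus when windows change
    goff_cx <- NULL
    for (b in active_blocks) if (t >= b$t_on && t < b$t_off) {
      if (is.null(goff_cx)) goff_cx <- numeric(n)
      goff_cx[b$cells] <- goff_cx[b$cells] + b$offset
    }
    stim <- NULL
    for (sdef in active_stim) if (t >= sdef$t_on && t < sdef$t_off) {
      if (is.null(stim)) stim <- numeric(n)
      stim <- stim + sdef$field
    }

    ## -- delayed synapse fields
    if (three) {
      cs_th <- if (!is.null(chains$cx_th)) chains$cx_th$output %||% S$CX$s
               else S$CX$s
      rs_cx <- if (!is.null(chains$th_cx)) chains$th_cx$output %||% S$RE$s
               else S$RE$s
    } else {
      ls_cx <- if (!is.null(chains$th_cx)) chains$th_cx$output %||% S$TH$s
               else S$TH$s
      cs_th <- if (!is.null(chains$cx_th)) chains$cx_th$output %||% S$CX$s
               else S$CX$s
    }

    ## -- input fields
    if (three) {
      t_inp <- input_floor(tc_input(S$RE$s, cs_th, S$TC$v, conn$c_th,
                                    conn$m_tc, w), w$re_floor)
      r_inp <- re_input(S$TC$s, cs_th, S$RE$v, conn$m_re, w)
      c_inp <- cx_input(S$CX$v, T_s = S$TC$s, R_s = rs_cx, C_s = S$CX$s,
                        conn = cx_conn, w = w, n_total = n,
                        active = cx_components)
    } else {
      l_inp <- input_floor(th_input_reduced(S$TH$v, S$TH$s, cs_th,
                                            conn$c_th, conn$wth_up, w),
                           w$re_floor)
      c_inp <- cx_input(S$CX$v, C_s = S$CX$s, L_s = ls_cx,
                        conn = cx_conn, w = w, n_total = n,
                        active = cx_components)
    }
    if (!is.null(stim)) c_inp <- c_inp + stim
    c_inp <- input_floor(c_inp, w$re_floor)

    ## -- stochastic-Euler update with semi-implicit voltage leak: after a
    ## spike the gating-driven leak a1 + a2*eta reaches hundreds per ms, so
    ## the linear-in-v part is treated implicitly wherever it is damping
    ## (unconditionally stable); the remaining terms stay explicit. The
    ## type-3 gating variable is floored (sustained strong inhibition would
    ## otherwise drive eta so negative that the leak changes sign and the
    ## voltage runs away; the floor leaves rebound dynamics intact).
    upd <- function(layer, inp, extra_goff = NULL) {
      st_ <- S[[layer]]; p <- model$params[[layer]]
      st_$v <- semi_implicit_v(st_$v, st_$eta, p, inp, dt)
      de <- gating_rate(st_$v, st_$eta, p)
      if (!is.null(extra_goff)) de <- de + extra_goff
      eta_new <- st_$eta + dt * de
      if (p$gating_kind == "type3") eta_new <- pmax(eta_new, .ETA_FLOOR)
      ds <- synapse_rate(st_$v, st_$s, p)
      st_$eta <- eta_new
      st_$s <- st_$s + dt * ds
      st_
    }
    if (three) {
      S$TC <- upd("TC", t_inp)
      S$RE <- upd("RE", r_inp)
      S$CX <- upd("CX", c_inp, goff_cx)
    } else {
      S$TH <- upd("TH", l_inp)
      S$CX <- upd("CX", c_inp, goff_cx)
    }
    if (noise_amp > 0)
      S$CX$v[interior] <- S$CX$v[interior] + noise_amp * stats::rnorm(length(interior))

    ## -- absorbing boundary: ring held at rest
    for (l in layers) {
      S[[l]]$v[ring] <- rest[[l]]$v
      S[[l]]$eta[ring] <- rest[[l]]$eta
      S[[l]]$s[ring] <- 0
    }

    ## -- delay chains advance on their source fields
    if (!is.null(chains$th_cx))
      chains$th_cx <- delay_chain_step(chains$th_cx,
                                      if (three) S$RE$s else S$TH$s, dt)
    if (!is.null(chains$cx_th))
      chains$cx_th <- delay_chain_step(chains$cx_th, S$CX$s, dt)

    if (any(!is.finite(S$CX$v)))
      stop("non-finite cortical state at t = ", t + dt, " ms")

    if (!is.na(rec_stride) && st %% rec_stride == 0) {
      fr <- fr + 1
      for (l in layers) movies[[l]][fr, ] <- S[[l]]$v
      times[fr] <- clock0 + st * dt
    }
    if (progress && st %% round(10 / dt) == 0)
      message("t = ", format(clock0 + st * dt), " ms")
  }

  model$state <- S
  model$chains <- chains
  model$weights <- w
  model$clock <- clock0 + nsteps * dt
  list(movies = movies, times = times, model = model)
}

## Lower bound on the type-3 gating variable inside the network integrator.
.ETA_FLOOR <- -1

## One voltage step: the leak -(a1 + a2 eta) v implicitly when damping,
## everything else (Hill term, offset, inputs evaluated at v_n) explicitly.
semi_implicit_v <- function(v, eta, p, inp, dt) {
  leak <- p$a1 + p$a2 * eta
  b <- p$a3 * v^2 / (p$a4 + v^2) + p$a5 + inp
  ifelse(leak > 0,
         (v + dt * b) / (1 + dt * leak),
         v + dt * (b - leak * v))
}

#' Scheduled scenario modifiers
#'
#' A modifier is a list with a `type` and a schedule:
#' \describe{
#' \item{`weight_scale`}{`list(type, name, factor, t)`: multiply weight
#'   `name` by `factor` from time `t` on. `name` may be a character vector
#'   (e.g. cutting all corticothalamic feedback).}
#' \item{`inhibition_scale`}{`list(type, factor, t0)`: scale the dominant
#'   thalamic inhibition weight (`w_TH_CX` in the reduced model,
#'   `w_RE_CX` in the three-layer model) by `factor` from `t0`.}
#' \item{`threshold_block`}{`list(type, cells, t_on, t_off, offset)`:
#'   raise the cortical gating offset of `cells` during the window
#'   (transiently unexcitable cells).}
#' \item{`stimulus`}{`list(type, cells or field, amplitude, sign, t_on,
#'   t_off)`: add a signed external field to the cortical input.}
#' \item{`delay_switch`}{`list(type, t, n_elements)`: change the active
#'   length of the thalamocortical delay chain mid-run (the chain must
#'   have been built at least `n_elements` long).}
#' }
#' `apply_modifier()` validates one modifier against a configuration and
#' returns it (used when assembling configs); the runtime application
#' happens inside [run_simulation()].
#'
#' @param config a [sim_config()].
#' @param modifier a modifier list.
#' @return The validated modifier.
#' @export
apply_modifier <- function(config, modifier) {
  stopifnot(is.list(modifier), !is.null(modifier$type))
  switch(modifier$type,
    weight_scale = stopifnot(all(modifier$name %in% names(config$weights))),
    inhibition_scale = stopifnot(is.numeric(modifier$factor)),
    threshold_block = stopifnot(!is.null(modifier$cells),
                                modifier$t_off > modifier$t_on),
    stimulus = stopifnot(!is.null(modifier$cells) || !is.null(modifier$field)),
    delay_switch = stopifnot(modifier$n_elements >= 0),
    stop("unknown modifier type: ", modifier$type))
  modifier
}

## Runtime application at the modifier's onset time.
apply_modifier_runtime <- function(m, w, chains, spec) {
  out <- list(w = w, chains = chains)
  if (m$type == "weight_scale") {
    for (nm in m$name) out$w[[nm]] <- out$w[[nm]] * m$factor
  } else if (m$type == "inhibition_scale") {
    nm <- if (!is.null(out$w$w_TH_CX)) "w_TH_CX" else "w_RE_CX"
    out$w[[nm]] <- out$w[[nm]] * m$factor
  } else if (m$type == "threshold_block") {
    out$block <- list(cells = resolve_cells(m$cells, spec),
                      t_on = m$t_on, t_off = m$t_off,
                      offset = m$offset %||% 2)
  } else if (m$type == "stimulus") {
    field <- if (!is.null(m$field)) m$field else {
      f <- numeric(spec$n)
      f[resolve_cells(m$cells, spec)] <- m$amplitude %||% 1
      f
    }
    out$stim <- list(field = (m$sign %||% 1) * field,
                     t_on = m$t_on %||% 0, t_off = m$t_off %||% Inf)
  } else if (m$type == "delay_switch") {
    if (!is.null(out$chains$th_cx))
      out$chains$th_cx <- set_chain_tap(out$chains$th_cx, m$n_elements)
  }
  out
}
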
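## Correctness tests run at small lattice sizes and short durations; the
## acceptance suite exercises the reference problem sizes.

test_that("fixed point: uncoupled resting network stays at rest", {
  cfg <- sim_config(rows = 8, cols = 8, duration = 5, sigma = 0,
                    noise_mode = "off",
                    m_fraction = 0, w_fraction = 0, x_fraction = 0.99,
                    triggers = list())
  set.seed(cfg$seed)
  m <- build_model(cfg)
  v0 <- m$state$CX$v
  m2 <- m
  for (k in 1:100) m2 <- step_model(m2)
  ## resting synapses carry ~1e-4 of drive, so "unchanged" means to within
  ## the integrator's resting drift, well below any spike scale
  expect_lt(max(abs(m2$state$CX$v - v0)), 1e-3)
  expect_lt(max(abs(m2$state$TC$v - m$state$TC$v)), 1e-3)
})

test_that("seed determinism: identical trajectories end to end", {
  cfg <- preset_config("closed_loop_default", rows = 16, cols = 16,
                       duration = 20, seed = 5)
  t1 <- run_simulation(cfg)
  t2 <- run_simulation(cfg)
  expect_identical(t1$movies$CX$frames, t2$movies$CX$frames)
  expect_identical(t1$movies$RE$frames, t2$movies$RE$frames)
  ## a different seed changes the realisation
  t3 <- run_simulation(preset_config("closed_loop_default", rows = 16,
                                     cols = 16, duration = 20, seed = 6))
  expect_false(identical(t1$movies$CX$frames, t3$movies$CX$frames))
})

test_that("halving dt changes the solution by less than 1% RMS", {
  ## convergence is checked on a horizon short enough that the network's
  ## sensitive dependence (spike-timing chaos) has not amplified the
  ## discretisation difference
  run_at <- function(dt) {
    cfg <- preset_config("closed_loop_deterministic", rows = 16, cols = 16,
                         duration = 6, seed = 2)
    cfg$dt <- dt
    run_simulation(cfg)$movies$CX$frames
  }
  a <- run_at(0.005); b <- run_at(0.0025)
  last_a <- a[dim(a)[1], , ]; last_b <- b[dim(b)[1], , ]
  rms_diff <- sqrt(mean((last_a - last_b)^2))
  rms_sig <- sqrt(mean(last_b^2))
  expect_lt(rms_diff / rms_sig, 0.01)
})

test_that("absorbing boundary ring never spikes", {
  tr <- cached_run("cld_24", run_preset("closed_loop_default", seed = 1,
                                        rows = 24, cols = 24,
                                        duration = 150))
  for (l in names(tr$movies)) {
    fr <- tr$movies[[l]]$frames
    ring <- fr[, c(1, 24), ]; ring2 <- fr[, , c(1, 24)]
    expect_lt(max(ring, ring2), 0.5)
  }
})

test_that("closed loop sustains activity; cutting feedback kills the thalamus", {
  tr <- cached_run("cld_24", run_preset("closed_loop_default", seed = 1,
                                        rows = 24, cols = 24,
                                        duration = 150))
  act_tc <- apply(tr$movies$TC$frames > 0.5, 1, sum)
  expect_gt(sum(act_tc[la <- (length(act_tc) - 24):length(act_tc)]), 0)
  ## same run with the corticothalamic feedback cut mid-run
  cfg <- preset_config("closed_loop_default", rows = 24, cols = 24,
                       duration = 150, seed = 1)
  cfg$modifiers <- list(list(type = "weight_scale",
                             name = c("w_CX_TC", "w_CX_RE"),
                             factor = 0, t = 40))
  tr2 <- run_simulation(cfg)
  act2 <- apply(tr2$movies$TC$frames > 0.5, 1, sum)
  ## thalamic activity decays to zero within ~60 ms of the cut
  expect_equal(sum(act2[(length(act2) - 24):length(act2)]), 0)
})

test_that("open loop: isolated thalamic wave lurches and then extinguishes", {
  ## recorded at 0.5 ms so the rebound-paced hops (one lattice step per
  ## ~2-3 ms) are resolved against the much faster cortical sweep
  cfg <- preset_config("open_loop", rows = 24, cols = 24, duration = 200,
                       seed = 1)
  cfg$record_every <- 0.5
  tr <- run_simulation(cfg)
  act <- apply(tr$movies$TC$frames > 0.5, 1, sum)
  expect_gt(max(act), 0)              # the wave existed
  alive <- which(act > 0)
  expect_lt(max(alive), length(act))  # and died before the run ended
  ## the thalamic front advances in rebound-paced hops: its stall fraction
  ## along a mid-row scan exceeds the smooth cortical wave's
  mid <- 12
  lT <- lurch_index(kymograph(tr$movies$TC, list(row = mid)))
  lC <- lurch_index(kymograph(tr$movies$CX, list(row = mid)))
  expect_gt(lT, lC + 0.3)
  expect_lt(lC, 0.1)
})

test_that("every preset instantiates and steps at test scale", {
  for (nm in preset_catalog()$name) {
    cfg <- preset_config(nm, rows = 20, cols = 20, duration = 2, seed = 1)
    expect_s3_class(cfg, "sim_config")
    tr <- run_simulation(cfg)
    expect_false(any(!is.finite(tr$movies$CX$frames)), info = nm)
  }
  expect_error(preset_config("nope"), "unknown preset")
})

test_that("default wiring audit matches the reference wiring fractions", {
  cfg <- preset_config("closed_loop_default", rows = 60, cols = 60)
  set.seed(1)
  m <- build_model(cfg)
  expect_equal(m$audit$e_fraction, 0.8)
  expect_equal(m$audit$m_fraction, 0.01)
  expect_equal(m$audit$w_fraction, 0.10)
  expect_equal(m$audit$x_fraction, 0.99, tolerance = 1e-3)
  ## three 60x60 layers: 10,800 cells, cortex 2880 E / 720 I
  expect_equal(3 * m$spec$n, 10800)
  expect_equal(sum(m$conn$ei == "E"), 2880)
  ## reduced delay preset: fully connected all-excitatory cortex
  cfg2 <- preset_config("reduced_delay", rows = 20, cols = 20)
  set.seed(1)
  m2 <- build_model(cfg2)
  expect_equal(m2$audit$x_fraction, 1)
  expect_equal(m2$audit$e_fraction, 1)
})

test_that("modifiers: identity leaves the trajectory unchanged; events land", {
  base_cfg <- preset_config("closed_loop_deterministic", rows = 16,
                            cols = 16, duration = 20, seed = 3)
  id_cfg <- base_cfg
  id_cfg$modifiers <- list(list(type = "weight_scale", name = "w_E",
                                factor = 1, t = 5))
  expect_identical(run_simulation(base_cfg)$movies$CX$frames,
                   run_simulation(id_cfg)$movies$CX$frames)
  ## threshold block keeps the blocked region subthreshold while the wave
  ## sweeps the rest of the sheet
  blk <- base_cfg
  blocked <- as.matrix(expand.grid(3:14, 12:14))
  blk$modifiers <- list(apply_modifier(blk, list(
    type = "threshold_block", cells = blocked, t_on = 0, t_off = 20,
    offset = 5)))
  trb <- run_simulation(blk)
  expect_lt(max(trb$movies$CX$frames[, 3:14, 12:14]), 0.5)
  expect_gt(max(trb$movies$CX$frames[, , 2:10]), 0.5)
  ## delay switch mid-run is accepted by the reduced model
  sw <- preset_config("reduced_delay", rows = 16, cols = 16, duration = 30,
                      delay_ms = 6)
  sw$modifiers <- list(list(type = "delay_switch", t = 0, n_elements = 2),
                       list(type = "delay_switch", t = 22, n_elements = 3))
  expect_no_error(run_simulation(sw))
  ## unknown modifier types are rejected at validation
  expect_error(apply_modifier(base_cfg, list(type = "nope")), "unknown")
})

test_that("trajectory frame count and manifest support replay", {
  tr <- cached_run("cld_24", run_preset("closed_loop_default", seed = 1,
                                        rows = 24, cols = 24,
                                        duration = 150))
  expect_equal(dim(tr$movies$CX$frames)[1],
               tr$manifest$duration / tr$manifest$record_every)
  expect_equal(tr$manifest$seed, 1)
  d <- file.path(tempdir(), "trajsave")
  save_trajectory(tr, d, "t")
  man <- jsonlite::read_json(file.path(d, "t_manifest.json"))
  expect_equal(man$rows, 24)
  tr2 <- load_trajectory(file.path(d, "t.rds"))
  expect_identical(tr2$movies$CX$frames, tr$movies$CX$frames)
})

test_that("micro network exposes auditable structures", {
  m <- make_micro_network(3, 3, seed = 1)
  expect_equal(edge_count(m$conn$x), 12)
  m2 <- make_micro_network(3, 3, seed = 1)
  expect_identical(m$conn$ei, m2$conn$ei)
})
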
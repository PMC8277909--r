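make_fields <- function(n, val = 0) rep(val, n)

test_that("thalamic relay input matches hand evaluation on a micro lattice", {
  m <- make_micro_network(3, 3, seed = 1)
  n <- m$spec$n
  w <- m$weights
  ## everything silent -> zero field
  z <- tc_input(make_fields(n), make_fields(n), make_fields(n, 0.1),
                m$conn$c_th, m$conn$m_tc, w)
  expect_equal(z, rep(0, n))
  ## uniform reticular synapse 1, T_v = 0: interior cell -w_RE_TC * 4 * i_p
  tin <- tc_input(make_fields(n, 1), make_fields(n), make_fields(n),
                  m$conn$c_th, m$conn$m_tc, w)
  expect_equal(tin[5], -w$w_RE_TC * 4 * w$i_p)   # centre: -3*4*5 = -60
  expect_equal(tin[1], -w$w_RE_TC * 2 * w$i_p)   # corner: -30
  ## linearity in the reticular field
  tin2 <- tc_input(make_fields(n, 2), make_fields(n), make_fields(n),
                   m$conn$c_th, m$conn$m_tc, w)
  expect_equal(tin2, 2 * tin)
})

test_that("reticular input is excitatory, pointwise, and floored", {
  n <- 9; w <- weights_three_layer()
  mconn <- rep(0, n)
  r <- re_input(make_fields(n, 1), make_fields(n), make_fields(n, 1),
                mconn, w)
  expect_equal(r, rep(w$w_TC_RE, n))          # 12 = weight from TC to RE
  expect_equal(re_input(make_fields(n), make_fields(n), make_fields(n, 1),
                        mconn, w), rep(0, n))
  ## values below the floor are clamped exactly
  w2 <- scale_weights(w, w_TC_RE = -100)      # adversarial scaling
  r2 <- re_input(make_fields(n, 1), make_fields(n), make_fields(n, 1),
                 mconn, w2)
  expect_equal(r2, rep(w$re_floor, n))
})

test_that("cortical input components follow the printed gains and E/I split", {
  spec <- lattice_spec(6, 6); n <- spec$n
  x <- build_lattice4(spec)
  ei <- rep(c("E", "I"), length.out = n)
  e_num <- as.numeric(ei == "E")
  conn <- list(x_e = x %*% Matrix::Diagonal(n, e_num),
               x_i = x %*% Matrix::Diagonal(n, 1 - e_num))
  w <- weights_three_layer()
  ## all synapses silent -> zero
  expect_equal(cx_input(make_fields(n), C_s = make_fields(n), conn = conn,
                        w = w, n_total = 3600, active = c(3, 4)),
               rep(0, n))
  ## component 3 per-link gain w_E * k_n / sqrt(N) = 3 * 16.2/60 = 0.81
  cs <- make_fields(n); cs[15] <- 1  # one active presynaptic cell
  inp <- cx_input(make_fields(n), C_s = cs, conn = conn, w = w,
                  n_total = 3600, active = c(3, 4))
  gain <- if (ei[15] == "E") w$w_E * w$k_n / 60 else -w$w_I * w$k_n / 60
  nb <- which(x[, 15] != 0)
  expect_equal(inp[nb], rep(gain, length(nb)))
  expect_equal(sum(inp != 0), length(nb))
  ## a presynaptic cell drives exactly one of components 3 or 4
  i3 <- cx_input(make_fields(n), C_s = cs, conn = conn, w = w,
                 n_total = 3600, active = 3)
  i4 <- cx_input(make_fields(n), C_s = cs, conn = conn, w = w,
                 n_total = 3600, active = 4)
  expect_true(xor(any(i3 != 0), any(i4 != 0)))
  ## component 5 without the reduced layer errors
  expect_error(cx_input(make_fields(n), L_s = cs, conn = conn, w = w,
                        n_total = n, active = 5), "component 5")
})

test_that("reduced thalamic input: lateral 4-neighbour excitation", {
  spec <- lattice_spec(3, 3); n <- spec$n
  cth <- build_c_th(spec)
  w <- weights_reduced()
  expect_equal(th_input_reduced(make_fields(n, 1), make_fields(n),
                                make_fields(n), cth, rep(0, n), w),
               rep(0, n))
  ## neighbours with L_s = 1 and L_v = 1: centre gets w_TH * 4 = 60
  lin <- th_input_reduced(make_fields(n, 1), make_fields(n, 1),
                          make_fields(n), cth, rep(0, n), w)
  expect_equal(lin[5], w$w_TH * 4)
  ## second term scales linearly in w_CX_TH
  up <- rep(1, n)
  l1 <- th_input_reduced(make_fields(n, 1), make_fields(n),
                         make_fields(n, 1), cth, up, w)
  w2 <- scale_weights(w, w_CX_TH = 3)
  l3 <- th_input_reduced(make_fields(n, 1), make_fields(n),
                         make_fields(n, 1), cth, up, w2)
  expect_equal(l3, 3 * l1)
})

test_that("input operators are linear in each synaptic field", {
  m <- make_micro_network(4, 4, seed = 2)
  n <- m$spec$n; w <- m$weights
  set.seed(9)
  rs <- runif(n); cs <- runif(n); tv <- runif(n, 0, 0.2)
  f <- function(a) tc_input(a * rs, cs, tv, m$conn$c_th, m$conn$m_tc, w) -
    tc_input(rep(0, n), cs, tv, m$conn$c_th, m$conn$m_tc, w)
  expect_equal(f(2), 2 * f(1), tolerance = 1e-12)
})

test_that("scenario multipliers commute with the computation and are logged", {
  w <- scale_weights(weights_three_layer(), w_RE_CX = 300, w_E = 2)
  expect_equal(w$w_RE_CX, 6)
  expect_equal(w$w_E, 6)
  expect_equal(attr(w, "multipliers"), list(w_RE_CX = 300, w_E = 2))
  ## scale-then-sum equals sum-then-scale for a pure component
  spec <- lattice_spec(4, 4); n <- spec$n
  x <- build_lattice4(spec)
  conn <- list(x_e = x, x_i = x * 0)
  cs <- runif(n)
  base <- cx_input(rep(0, n), C_s = cs, conn = conn,
                   w = weights_three_layer(), n_total = 3600, active = 3)
  scaled <- cx_input(rep(0, n), C_s = cs, conn = conn,
                     w = scale_weights(weights_three_layer(), w_E = 2),
                     n_total = 3600, active = 3)
  expect_equal(scaled, 2 * base)
})

test_that("delay chains delay by 2 ms per element and conserve pulses", {
  pulse <- canonical_pulse()
  l1 <- measure_chain_lag(make_delay_chain(1), pulse)
  expect_equal(l1, 2.0, tolerance = 0.1)
  l3 <- measure_chain_lag(make_delay_chain(3), pulse)
  expect_equal(l3, 6.0, tolerance = 0.3)
  ## n = 0 chain is the identity
  ch0 <- make_delay_chain(0)
  ch0 <- delay_chain_step(ch0, 0.7, 0.01)
  expect_equal(ch0$output, 0.7)
  ## pulse conservation: one input pulse -> exactly one output pulse
  ch <- make_delay_chain(2)
  dt <- pulse$t[2] - pulse$t[1]
  out <- numeric(nrow(pulse))
  for (i in seq_len(nrow(pulse))) {
    ch <- delay_chain_step(ch, pulse$s[i], dt)
    out[i] <- ch$output
  }
  expect_equal(sum(diff(out > 0.5) == 1), 1)
})

test_that("delay calibration converges and is monotone in the gating rate", {
  p <- calibrate_delay_element()
  expect_equal(attr(p, "measured_lag_ms"), 2.0, tolerance = 0.1)
  ## deterministic: recalibration gives the same parameter
  p2 <- calibrate_delay_element()
  expect_equal(p$c1, p2$c1, tolerance = 1e-6)
  ## slower gating -> longer rebound wait
  pulse <- canonical_pulse()
  lags <- vapply(c(0.040, 0.046, 0.052), function(c1)
    measure_chain_lag(make_delay_chain(1, params = delay_element_params(c1)),
                      pulse), 0)
  expect_true(all(diff(lags) < 0))
})
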
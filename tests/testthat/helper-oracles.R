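## Independent oracles used across the suite.

## Brute-force equilibrium scan: equilibria lie on the gating nullcline, so
## scan a dense v grid, take eta from the gating law, and bisect sign
## changes of the voltage rate. Independent of find_equilibria()'s
## nullcline-difference formulation.
oracle_equilibria <- function(params, r = 0, v_range = c(-2, 3),
                              n = 20000) {
  gnull <- function(v) {
    if (params$gating_kind == "type3") (params$c2 / params$c1) * v
    else {
      vp <- pmax(v, 0)
      (params$d2 * vp^3 / (params$d3 + vp^3) + params$d4) / params$d1
    }
  }
  f <- function(v) voltage_rate(v, gnull(v), params, r)
  vs <- seq(v_range[1], v_range[2], length.out = n)
  fv <- f(vs)
  roots <- c()
  for (i in which(diff(sign(fv)) != 0)) {
    root <- tryCatch(uniroot(f, c(vs[i], vs[i + 1]), tol = 1e-12)$root,
                     error = function(e) NA_real_)
    if (!is.na(root)) roots <- c(roots, root)
  }
  data.frame(v = roots, eta = gnull(roots))
}

## Finite-difference Jacobian eigenvalues (central differences).
oracle_eigenvalues <- function(params, v, eta, r = 0, h = 1e-6) {
  J <- matrix(c(
    (voltage_rate(v + h, eta, params, r) - voltage_rate(v - h, eta, params, r)) / (2 * h),
    (voltage_rate(v, eta + h, params, r) - voltage_rate(v, eta - h, params, r)) / (2 * h),
    (gating_rate(v + h, eta, params) - gating_rate(v - h, eta, params)) / (2 * h),
    (gating_rate(v, eta + h, params) - gating_rate(v, eta - h, params)) / (2 * h)),
    2, 2, byrow = TRUE)
  eigen(J, only.values = TRUE)$values
}

## Dense grid scan for the fold point (local minimum of the v-nullcline).
oracle_fold <- function(params, r = 0, v_max = 2.5, n = 400000) {
  vs <- seq(1e-4, v_max, length.out = n)
  ev <- eta_vnull(vs, params, r)
  d <- diff(ev)
  k <- which(d[-length(d)] < 0 & d[-1] >= 0)[1] + 1
  list(v = vs[k], eta = ev[k])
}

## Shared small-run cache so expensive simulations are computed once per
## test session.
.run_cache <- new.env(parent = emptyenv())
cached_run <- function(key, expr) {
  if (!exists(key, envir = .run_cache))
    assign(key, force(expr), envir = .run_cache)
  get(key, envir = .run_cache)
}
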
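#' Nullclines of the excitable neuron in the (v, eta) plane
#'
#' The voltage nullcline has the inverted-N shape
#' \deqn{\eta_v(v) = \frac{-a_1 v + a_3 v^2/(a_4+v^2) + a_5 + r}{a_2 v}}
#' and is singular at `v = 0`; raising the drive `r` raises it for `v > 0`.
#' The gating nullcline is the line \eqn{\eta = (c_2/c_1)v} for type-3
#' gating, and the bounded sigmoid
#' \eqn{\eta = (d_2 v_+^3/(d_3+v_+^3) + d_4)/d_1} for type-1.
#'
#' @param params an [excitable_params()] object.
#' @param r input drive.
#' @param v_grid voltages at which to evaluate (default 400 points on
#'   (0, 3]).
#' @return A data.frame with columns `v`, `eta_vnull`, `eta_gnull`.
#'   Rows with `v == 0` get `NA` for `eta_vnull` and a warning.
#' @export
nullclines <- function(params, r = 0, v_grid = NULL) {
  if (is.null(v_grid)) v_grid <- seq(0.0025, 3, length.out = 400)
  if (any(v_grid == 0))
    warning("v = 0 is a singularity of the voltage nullcline; returning NA")
  ev <- ifelse(v_grid == 0, NA_real_, eta_vnull(v_grid, params, r))
  eg <- eta_gnull(v_grid, params)
  data.frame(v = v_grid, eta_vnull = ev, eta_gnull = eg)
}

#' @rdname nullclines
#' @export
eta_vnull <- function(v, params, r = 0) {
  (-params$a1 * v + params$a3 * v^2 / (params$a4 + v^2) + params$a5 + r) /
    (params$a2 * v)
}

#' @rdname nullclines
#' @export
eta_gnull <- function(v, params) {
  if (params$gating_kind == "type3") {
    (params$c2 / params$c1) * v
  } else {
    vp <- pmax(v, 0)
    (params$d2 * vp^3 / (params$d3 + vp^3) + params$d4) / params$d1
  }
}

#' Fold point of the voltage nullcline
#'
#' Locates the local minimum "p" of the inverted-N voltage nullcline on
#' `v > 0`. When the equilibrium "m" reaches this point the system loses
#' stability and starts self-sustained oscillation.
#'
#' @inheritParams nullclines
#' @param interval search interval for the minimum.
#' @return A list with `v`, `eta` of the fold point.
#' @export
fold_point <- function(params, r = 0, interval = c(1e-3, 2.5)) {
  ## the v-nullcline diverges at 0+, dips to the fold, rises, and declines
  ## again at large v; locate the first interior local minimum by grid scan
  ## and polish it (a bare optimize() can be caught by the far branch)
  vs <- exp(seq(log(interval[1]), log(interval[2]), length.out = 2000))
  ev <- eta_vnull(vs, params, r)
  d <- diff(ev)
  k <- which(d[-length(d)] < 0 & d[-1] >= 0)
  if (!length(k))
    stop("no interior minimum of the voltage nullcline in the interval")
  k <- k[1] + 1
  op <- stats::optimize(function(v) eta_vnull(v, params, r),
                        c(vs[max(k - 2, 1)], vs[min(k + 2, length(vs))]),
                        tol = 1e-10)
  list(v = op$minimum, eta = op$objective)
}

#' Equilibria of the two-state neuron
#'
#' Finds all intersections of the voltage and gating nullclines within a
#' search box by a dense sign-change scan of
#' \eqn{f(v) = \eta_v(v) - \eta_g(v)} followed by root polishing. Every
#' returned point satisfies `|voltage_rate| < tol` and
#' `|gating_rate| < tol`.
#'
#' @inheritParams nullclines
#' @param v_range search range for `v` (excludes the `v = 0` singularity by
#'   construction; the scan covers both signs of `v`).
#' @param n_scan number of scan points per sign.
#' @param tol residual tolerance.
#' @return A data.frame with columns `v`, `eta` (possibly 0 rows).
#' @export
find_equilibria <- function(params, r = 0, v_range = c(-2, 3),
                            n_scan = 4000, tol = 1e-8) {
  f <- function(v) eta_vnull(v, params, r) - eta_gnull(v, params)
  segs <- list()
  if (v_range[1] < 0) segs <- c(segs, list(seq(v_range[1], -1e-4, length.out = n_scan)))
  if (v_range[2] > 0) segs <- c(segs, list(seq(1e-4, v_range[2], length.out = n_scan)))
  out <- list()
  for (vs in segs) {
    fv <- f(vs)
    ok <- is.finite(fv)
    sgn <- which(diff(sign(fv)) != 0 & ok[-length(ok)] & ok[-1])
    for (i in sgn) {
      root <- tryCatch(
        stats::uniroot(f, c(vs[i], vs[i + 1]), tol = 1e-12)$root,
        error = function(e) NA_real_)
      if (is.na(root)) next
      eta <- eta_gnull(root, params)
      if (abs(voltage_rate(root, eta, params, r)) < tol &&
          abs(gating_rate(root, eta, params)) < tol)
        out[[length(out) + 1]] <- c(v = root, eta = eta)
    }
  }
  if (!length(out)) return(data.frame(v = numeric(0), eta = numeric(0)))
  df <- as.data.frame(do.call(rbind, out))
  ## dedupe near-identical roots from adjacent scan cells
  df <- df[!duplicated(round(df$v, 9)), , drop = FALSE]
  rownames(df) <- NULL
  df
}

#' Linear stability of an equilibrium
#'
#' Eigenvalues of the analytic 2x2 Jacobian of (voltage_rate, gating_rate)
#' at a point. The point is checked to be an equilibrium to `tol`; if not, a
#' warning is issued and the eigenvalues are still returned.
#'
#' @param params an [excitable_params()] object.
#' @param point list or numeric vector with `v`, `eta`.
#' @param r input drive.
#' @param tol equilibrium residual tolerance for the warning.
#' @return List with `eigenvalues` (complex length-2) and `stable` (logical:
#'   both real parts negative).
#' @export
stability <- function(params, point, r = 0, tol = 1e-6) {
  v <- point[["v"]]; eta <- point[["eta"]]
  if (abs(voltage_rate(v, eta, params, r)) > tol ||
      abs(gating_rate(v, eta, params)) > tol)
    warning("point is not an equilibrium to tolerance ", tol)
  ev <- eigen(.jacobian_ve(v, eta, params), only.values = TRUE)$values
  list(eigenvalues = ev, stable = all(Re(ev) < 0))
}

#' Activation threshold of the neuron
#'
#' The Euclidean distance in the (v, eta) plane between the stable
#' equilibrium "m" and the fold point "p" of the voltage nullcline. It
#' shrinks to zero as the drive `r` pushes the equilibrium into the fold
#' (the bifurcation at which self-sustained oscillation starts).
#'
#' @inheritParams nullclines
#' @return The threshold (scalar >= 0), or `NA` with a warning when no
#'   stable equilibrium exists (post-bifurcation regime).
#' @export
activation_threshold <- function(params, r = 0) {
  eq <- find_equilibria(params, r)
  if (!nrow(eq)) {
    warning("no equilibrium found; post-bifurcation regime")
    return(NA_real_)
  }
  st <- vapply(seq_len(nrow(eq)), function(i)
    stability(params, eq[i, ], r)$stable, TRUE)
  if (!any(st)) {
    warning("no stable equilibrium; post-bifurcation regime")
    return(NA_real_)
  }
  p <- fold_point(params, r)
  d <- sqrt((eq$v - p$v)^2 + (eq$eta - p$eta)^2)
  d[!st] <- Inf
  min(d)  # the stable equilibrium m adjacent to the fold
}

#' Resting state of a cell class
#'
#' The stable equilibrium at drive `r`, as a list with `v`, `eta` and the
#' resting synapse value `s = H(v)` (its fixed point).
#'
#' @inheritParams nullclines
#' @return List with `v`, `eta`, `s`.
#' @export
rest_state <- function(params, r = 0) {
  eq <- find_equilibria(params, r)
  if (!nrow(eq)) stop("no equilibrium at r = ", r)
  st <- vapply(seq_len(nrow(eq)), function(i)
    stability(params, eq[i, ], r)$stable, TRUE)
  if (!any(st)) stop("no stable equilibrium at r = ", r)
  p <- fold_point(params, r)
  d <- sqrt((eq$v - p$v)^2 + (eq$eta - p$eta)^2)
  d[!st] <- Inf
  m <- eq[which.min(d), ]  # the physiological rest branch next to the fold
  list(v = m$v, eta = m$eta, s = synapse_gate(m$v))
}

#' Full phase-plane report
#'
#' Nullclines, equilibria with eigenvalues and stability flags, fold point
#' and activation threshold, in one object; exportable as CSV via
#' [write_phaseplane_csv()].
#'
#' @inheritParams nullclines
#' @return An object of class `phase_plane_report`: list with `nullclines`
#'   (data.frame), `equilibria` (data.frame with `v`, `eta`, `re1`, `im1`,
#'   `re2`, `im2`, `stable`), `fold` and `threshold`.
#' @export
phase_plane_report <- function(params, r = 0, v_grid = NULL) {
  nc <- nullclines(params, r, v_grid)
  eq <- find_equilibria(params, r)
  if (nrow(eq)) {
    st <- lapply(seq_len(nrow(eq)), function(i) stability(params, eq[i, ], r))
    eq$re1 <- vapply(st, function(x) Re(x$eigenvalues[1]), 0)
    eq$im1 <- vapply(st, function(x) Im(x$eigenvalues[1]), 0)
    eq$re2 <- vapply(st, function(x) Re(x$eigenvalues[2]), 0)
    eq$im2 <- vapply(st, function(x) Im(x$eigenvalues[2]), 0)
    eq$stable <- vapply(st, function(x) x$stable, TRUE)
  }
  thr <- suppressWarnings(activation_threshold(params, r))
  structure(list(nullclines = nc, equilibria = eq,
                 fold = fold_point(params, r), threshold = thr, r = r),
            class = "phase_plane_report")
}

#' @export
print.phase_plane_report <- function(x, ...) {
  cat("<phase_plane_report> r =", x$r, "\n")
  cat("  fold p: v =", format(x$fold$v, digits = 5),
      " eta =", format(x$fold$eta, digits = 5), "\n")
  cat("  threshold ||m - p|| =", format(x$threshold, digits = 5), "\n")
  if (nrow(x$equilibria)) {
    cat("  equilibria:\n")
    print(x$equilibria, digits = 5)
  } else cat("  no equilibria in search box\n")
  invisible(x)
}

#' Export a phase-plane report as CSV
#'
#' Writes the nullcline table (`v`, `eta_vnull`, `eta_gnull`) and, in a
#' second file, the equilibrium table.
#'
#' @param report a [phase_plane_report()] object.
#' @param path path of the nullcline CSV; the equilibrium table goes to
#'   `sub(".csv", "_equilibria.csv", path)`.
#' @return `path`, invisibly.
#' @export
write_phaseplane_csv <- function(report, path) {
  utils::write.csv(report$nullclines, path, row.names = FALSE)
  eqpath <- sub("\\.csv$", "_equilibria.csv", path)
  utils::write.csv(report$equilibria, eqpath, row.names = FALSE)
  invisible(path)
}
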
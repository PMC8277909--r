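#' Save / load a simulation trajectory
#'
#' The trajectory (layer movies plus final state) is stored as an RDS
#' file; the run manifest is written alongside as JSON so a run can be
#' audited and replayed without loading the data.
#'
#' @param traj a `tc_trajectory`.
#' @param dir output directory (created if needed).
#' @param name base file name; default the preset name or "run".
#' @return The directory, invisibly.
#' @export
save_trajectory <- function(traj, dir, name = NULL) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  name <- name %||% traj$manifest$preset %||% "run"
  saveRDS(traj, file.path(dir, paste0(name, ".rds")))
  jsonlite::write_json(traj$manifest,
                       file.path(dir, paste0(name, "_manifest.json")),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(dir)
}

#' @rdname save_trajectory
#' @param path path of a saved `.rds` trajectory.
#' @export
load_trajectory <- function(path) readRDS(path)

#' Append wave metrics to a CSV file
#'
#' Writes one row per layer of the trajectory (see [movie_metrics()]);
#' appends if the file exists, otherwise creates it with a header.
#'
#' @param traj a `tc_trajectory` (or a single [activity_movie()]).
#' @param path CSV path.
#' @param ... passed to [movie_metrics()].
#' @return The metric rows, invisibly.
#' @export
append_metrics_csv <- function(traj, path, ...) {
  rows <- if (inherits(traj, "tc_trajectory")) {
    do.call(rbind, lapply(names(traj$movies), function(l)
      movie_metrics(traj$movies[[l]], layer = l,
                    preset = traj$manifest$preset %||% NA,
                    seed = traj$manifest$seed, ...)))
  } else movie_metrics(traj, ...)
  utils::write.table(rows, path, sep = ",", row.names = FALSE,
                     col.names = !file.exists(path), append = file.exists(path))
  invisible(rows)
}

#' Plot one movie frame
#'
#' @param movie an [activity_movie()].
#' @param frame frame index.
#' @param ... passed to [graphics::image()].
#' @export
plot_frame <- function(movie, frame, ...) {
  m <- movie$frames[frame, , ]
  graphics::image(t(m)[, nrow(m):1], axes = FALSE, asp = 1,
                  col = grDevices::hcl.colors(64, "viridis"), ...)
  graphics::title(sprintf("t = %g ms", (frame - 1) * movie$frame_dt))
}

#' Plot a kymograph
#'
#' @param kymo a [kymograph()].
#' @param ... passed to [graphics::image()].
#' @export
plot_kymograph <- function(kymo, ...) {
  k <- unclass(kymo)
  fd <- attr(kymo, "frame_dt") %||% 2
  graphics::image(x = (seq_len(nrow(k)) - 1) * fd, y = seq_len(ncol(k)),
                  z = k, xlab = "time (ms)", ylab = "position (px)",
                  col = grDevices::hcl.colors(64, "viridis"), ...)
}

#' Run a named comparison protocol
#'
#' Runs a battery of seeds for one of the named comparison protocols and
#' returns the per-run metric table together with the condition comparison
#' (two-sample t test over seeds):
#' \describe{
#' \item{`speed_ordering`}{cortical vs thalamic wave speed of the default
#'   closed loop.}
#' \item{`area_vs_connectivity`}{mean cortical wave area across
#'   intracortical connectivity fractions.}
#' \item{`delay_duration`}{reduced-model wave-activity duration across
#'   delays 2/4/6 ms.}
#' \item{`re_inhibition`}{cortical dominant frequency at 1x vs 300x
#'   reticular inhibition.}
#' \item{`we_scaling`}{cortical frequency and speed at 1x vs 2x cortical
#'   excitation.}
#' }
#'
#' @param experiment protocol name.
#' @param seeds seeds of the battery (default 1:5).
#' @param rows,cols,duration problem size (defaults chosen so a battery
#'   runs in minutes).
#' @param ... forwarded to [preset_config()].
#' @return A list with `metrics` (data.frame) and, where applicable,
#'   `comparison` (from [compare_conditions()]).
#' @export
reproduce_experiment <- function(experiment = c("speed_ordering",
                                                "area_vs_connectivity",
                                                "delay_duration",
                                                "re_inhibition",
                                                "we_scaling"),
                                 seeds = 1:5, rows = 30, cols = 30,
                                 duration = 300, ...) {
  experiment <- match.arg(experiment)
  run_row <- function(preset, seed, layer = "CX", ...) {
    tr <- run_preset(preset, seed = seed, rows = rows, cols = cols,
                     duration = duration, ...)
    movie_metrics(tr$movies[[layer]], layer = layer, preset = preset,
                  seed = seed)
  }
  if (experiment == "speed_ordering") {
    mx <- do.call(rbind, lapply(seeds, function(s) rbind(
      run_row("closed_loop_default", s, "CX"),
      run_row("closed_loop_default", s, "TC"))))
    cmp <- compare_conditions(mx$speed_cm_s[mx$layer == "CX"],
                              mx$speed_cm_s[mx$layer == "TC"],
                              c("CX", "TC"))
    list(metrics = mx, comparison = cmp)
  } else if (experiment == "area_vs_connectivity") {
    fracs <- c(0.25, 0.5, 0.75, 0.99)
    mx <- do.call(rbind, lapply(fracs, function(fr)
      do.call(rbind, lapply(seeds, function(s) {
        r <- run_row("connectivity_sweep", s, "CX", fraction = fr)
        r$x_fraction <- fr; r
      }))))
    list(metrics = mx)
  } else if (experiment == "delay_duration") {
    delays <- c(2, 4, 6)
    mx <- do.call(rbind, lapply(delays, function(d)
      do.call(rbind, lapply(seeds, function(s) {
        r <- run_row("reduced_90pct_unconnected", s, "CX", delay_ms = d)
        r$delay_ms <- d; r
      }))))
    list(metrics = mx)
  } else if (experiment == "re_inhibition") {
    mx <- do.call(rbind, lapply(c(1, 300), function(f)
      do.call(rbind, lapply(seeds, function(s) {
        r <- run_row("re_inhibition_x300", s, "CX", factor = f)
        r$factor <- f; r
      }))))
    cmp <- compare_conditions(mx$freq_hz[mx$factor == 1],
                              mx$freq_hz[mx$factor == 300],
                              c("RE x1", "RE x300"))
    list(metrics = mx, comparison = cmp)
  } else {
    mx <- do.call(rbind, lapply(c(1, 2), function(f)
      do.call(rbind, lapply(seeds, function(s) {
        r <- run_row("we_x2", s, "CX", factor = f)
        r$factor <- f; r
      }))))
    cmp <- compare_conditions(mx$freq_hz[mx$factor == 2],
                              mx$freq_hz[mx$factor == 1],
                              c("wE x2", "wE x1"))
    list(metrics = mx, comparison = cmp)
  }
}
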
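#' Synthetic activity movies with known ground truth
#'
#' Geometric fixture movies for validating the wave-analysis toolkit
#' independently of the simulator. Kinds:
#' \describe{
#' \item{planar}{a band of width `band_width` translating at `speed`
#'   px/frame along `direction`.}
#' \item{radial}{a ring expanding from the centre at `speed` px/frame.}
#' \item{rotating}{an Archimedean spiral arm rotating at `2*pi/period`
#'   rad/frame.}
#' \item{staircase}{a planar band that advances `speed * period` px once
#'   every `period` frames and stalls in between (a lurching front with
#'   stall fraction `(period-1)/period`).}
#' \item{constant}{a static band.}
#' }
#' Gaussian pixel noise of sd `noise_sd` is added on top; amplitude is 1
#' inside the wave and 0 outside, so the default segmentation level works.
#'
#' @param kind fixture kind.
#' @param rows,cols,n_frames movie geometry.
#' @param speed px/frame (mean speed for `staircase`).
#' @param direction degrees (0 = rightward, 90 = upward).
#' @param period frames per lurch cycle (`staircase`) or frames per
#'   revolution (`rotating`).
#' @param band_width band thickness (px).
#' @param noise_sd additive noise.
#' @param frame_dt,pixel_pitch calibration passed to the movie.
#' @param seed RNG seed for the noise.
#' @return An [activity_movie()] with attribute `"ground_truth"`: list
#'   with `kind`, `speed_px_frame`, `speed_cm_s`, `direction_deg`,
#'   `period_frames`, `stall_fraction`.
#' @export
make_movie <- function(kind = c("planar", "radial", "rotating", "staircase",
                                "constant"),
                       rows = 60, cols = 60, n_frames = 40,
                       speed = 1, direction = 0, period = 4,
                       band_width = 3, noise_sd = 0,
                       frame_dt = 2, pixel_pitch = 0.4, seed = 1) {
  kind <- match.arg(kind)
  stopifnot(speed >= 0, rows > 0, cols > 0, n_frames >= 2)
  set.seed(seed)
  fr <- array(0, c(n_frames, rows, cols))
  ii <- matrix(rep(seq_len(rows), cols), rows, cols)
  jj <- matrix(rep(seq_len(cols), each = rows), rows, cols)
  th <- direction * pi / 180
  ## signed coordinate along the travel direction (0 deg = +col,
  ## 90 deg = -row i.e. upward)
  u <- cos(th) * jj - sin(th) * ii
  u0 <- min(u) - band_width
  cr <- (rows + 1) / 2; cc <- (cols + 1) / 2
  stall_fraction <- NA_real_
  for (f in seq_len(n_frames)) {
    if (kind == "planar") {
      pos <- u0 + speed * (f - 1)
      m <- u >= pos & u < pos + band_width
    } else if (kind == "constant") {
      pos <- (min(u) + max(u)) / 2
      m <- u >= pos & u < pos + band_width
    } else if (kind == "staircase") {
      pos <- u0 + speed * period * ((f - 1) %/% period)
      m <- u >= pos & u < pos + band_width
      stall_fraction <- (period - 1) / period
    } else if (kind == "radial") {
      r <- sqrt((ii - cr)^2 + (jj - cc)^2)
      rad <- speed * (f - 1)
      m <- r >= rad & r < rad + band_width
    } else { # rotating spiral arm
      ang <- atan2(-(ii - cr), jj - cc)
      r <- sqrt((ii - cr)^2 + (jj - cc)^2)
      phase <- (ang - 2 * pi * (f - 1) / period - r / 6) %% (2 * pi)
      m <- phase < (2 * pi * 0.12) & r > 2 & r < min(rows, cols) / 2 - 1
    }
    fr[f, , ] <- as.numeric(m)
  }
  if (noise_sd > 0) fr <- fr + stats::rnorm(length(fr), 0, noise_sd)
  mv <- activity_movie(fr, frame_dt = frame_dt, pixel_pitch = pixel_pitch)
  attr(mv, "ground_truth") <- list(
    kind = kind,
    speed_px_frame = if (kind %in% c("constant")) 0 else speed,
    speed_cm_s = (if (kind == "constant") 0 else speed) *
      pixel_pitch / frame_dt * 100,
    direction_deg = if (kind %in% c("planar", "staircase")) direction
                    else NA_real_,
    period_frames = if (kind %in% c("staircase", "rotating")) period
                    else NA_real_,
    stall_fraction = stall_fraction)
  mv
}

#' Ground truth record of a fixture movie
#'
#' @param movie a movie from [make_movie()].
#' @return The ground-truth list.
#' @export
ground_truth <- function(movie) attr(movie, "ground_truth")

#' Write a fixture movie with its ground-truth sidecar
#'
#' The frames go to an RDS file, the ground truth to a JSON sidecar.
#'
#' @param movie a fixture movie.
#' @param path output path (`.rds`).
#' @return `path`, invisibly.
#' @export
write_movie <- function(movie, path) {
  saveRDS(movie, path)
  gt <- ground_truth(movie)
  if (!is.null(gt))
    jsonlite::write_json(gt, paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_movie
#' @export
read_movie <- function(path) readRDS(path)
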
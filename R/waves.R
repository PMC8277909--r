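#' Activity movie container
#'
#' A recorded voltage movie of one layer: a `T x rows x cols` array plus
#' its temporal and spatial calibration. The default pixel pitch maps the
#' 60-cell sheet onto a 24 x 24 mm recording array (0.4 mm per cell); the
#' default frame interval is 2 ms.
#'
#' @param frames `T x rows x cols` numeric array.
#' @param frame_dt frame interval (ms).
#' @param pixel_pitch electrode pitch (mm per cell).
#' @return An object of class `activity_movie`.
#' @export
activity_movie <- function(frames, frame_dt = 2, pixel_pitch = 0.4) {
  stopifnot(length(dim(frames)) == 3, frame_dt > 0, pixel_pitch > 0)
  structure(list(frames = frames, frame_dt = frame_dt,
                 pixel_pitch = pixel_pitch),
            class = "activity_movie")
}

#' @export
print.activity_movie <- function(x, ...) {
  d <- dim(x$frames)
  cat(sprintf("<activity_movie> %d frames of %dx%d, frame_dt=%g ms, pitch=%g mm\n",
              d[1], d[2], d[3], x$frame_dt, x$pixel_pitch))
  invisible(x)
}

#' Default segmentation level of a movie
#'
#' Midpoint between the resting voltage (movie median) and the spike peak
#' (0.999 quantile), estimated per movie.
#'
#' @param movie an [activity_movie()] or numeric array.
#' @return Scalar level.
#' @export
segmentation_level <- function(movie) {
  fr <- if (inherits(movie, "activity_movie")) movie$frames else movie
  as.numeric((stats::median(fr) + stats::quantile(fr, 0.999)) / 2)
}

#' Segment the wavefront of one frame
#'
#' Thresholds the frame at `level` and labels the 4-connected components.
#'
#' @param frame numeric matrix.
#' @param level threshold.
#' @return Integer label matrix (0 = background); attribute `"n_patches"`
#'   gives the component count.
#' @export
segment_wavefront <- function(frame, level) {
  mask <- frame > level
  lab <- label_components(mask)
  attr(lab, "n_patches") <- max(lab)
  lab
}

#' Label 4-connected components of a binary mask
#'
#' @param mask logical matrix.
#' @return Integer matrix of component labels (0 = background).
#' @export
label_components <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  lab <- matrix(0L, nr, nc); cur <- 0L
  di <- c(-1L, 1L, 0L, 0L); dj <- c(0L, 0L, -1L, 1L)
  for (j0 in seq_len(nc)) for (i0 in seq_len(nr)) {
    if (mask[i0, j0] && lab[i0, j0] == 0L) {
      cur <- cur + 1L
      qi <- integer(256); qj <- integer(256)
      qi[1] <- i0; qj[1] <- j0; head <- 1L; tail <- 1L
      lab[i0, j0] <- cur
      while (head <= tail) {
        ci <- qi[head]; cj <- qj[head]; head <- head + 1L
        for (d in 1:4) {
          ni <- ci + di[d]; nj <- cj + dj[d]
          if (ni >= 1L && ni <= nr && nj >= 1L && nj <= nc &&
              mask[ni, nj] && lab[ni, nj] == 0L) {
            tail <- tail + 1L
            if (tail > length(qi)) {
              qi <- c(qi, integer(length(qi)))
              qj <- c(qj, integer(length(qj)))
            }
            qi[tail] <- ni; qj[tail] <- nj
            lab[ni, nj] <- cur
          }
        }
      }
    }
  }
  lab
}

#' Boundary pixels of a mask
#'
#' Pixels of the mask with at least one non-mask 4-neighbour within the
#' image (the image border itself is not treated as a wave edge).
#'
#' @param mask logical matrix.
#' @return Two-column matrix of (row, col) positions.
#' @export
boundary_pixels <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  pad <- matrix(TRUE, nr + 2, nc + 2)
  pad[2:(nr + 1), 2:(nc + 1)] <- mask
  inner <- pad[1:nr, 2:(nc + 1)] & pad[3:(nr + 2), 2:(nc + 1)] &
           pad[2:(nr + 1), 1:nc] & pad[2:(nr + 1), 3:(nc + 2)]
  which(mask & !inner, arr.ind = TRUE)
}

#' Nearest-edge wave speed between two frames
#'
#' For every advancing boundary pixel of the wavefront in frame `n+1`
#' (boundary pixels not already covered by the wave in frame `n`), the
#' Euclidean distance to the closest boundary pixel of the wavefront in
#' frame `n` is computed; the mean distance, converted with the pixel
#' pitch and frame interval, is the wave speed in cm/s. Restricting to
#' advancing pixels makes the estimator exactly linear in the displacement
#' of a rigidly translating front (identical masks give 0; a band moving
#' k px/frame gives k px/frame).
#'
#' @param mask_n,mask_next logical masks of consecutive frames.
#' @param frame_dt frame interval (ms).
#' @param pixel_pitch pitch (mm per cell).
#' @return Speed in cm/s; 0 if the front did not advance; `NA` if either
#'   mask is empty.
#' @export
wave_speed <- function(mask_n, mask_next, frame_dt = 2, pixel_pitch = 0.4) {
  if (!any(mask_n) || !any(mask_next)) return(NA_real_)
  b1 <- boundary_pixels(mask_next)
  adv <- !mask_n[b1]                      # boundary pixels newly recruited
  if (!any(adv)) return(0)
  b1 <- b1[adv, , drop = FALSE]
  b0 <- boundary_pixels(mask_n)
  if (!nrow(b0)) return(NA_real_)  # edgeless (full-sheet) reference mask
  d2 <- outer(b1[, 1], b0[, 1], "-")^2 + outer(b1[, 2], b0[, 2], "-")^2
  mean_px <- mean(sqrt(.rowMins(d2)))
  mean_px * pixel_pitch / frame_dt * 100  # mm/ms -> cm/s
}

.rowMins <- function(m) {
  if (is.null(dim(m))) return(min(m))
  do.call(pmin, as.data.frame(m))
}

#' Wave speed series of a movie
#'
#' Applies [wave_speed()] to every consecutive frame pair whose masks both
#' contain at least `min_cells` pixels (propagating episodes); other pairs
#' yield `NA`.
#'
#' @param movie an [activity_movie()].
#' @param level segmentation level; default [segmentation_level()].
#' @param min_cells minimal active cells per frame for a valid pair.
#' @return Numeric vector of length `T - 1` (cm/s, `NA` outside episodes).
#' @export
movie_speed_series <- function(movie, level = NULL, min_cells = 5) {
  fr <- movie$frames
  if (is.null(level)) level <- segmentation_level(movie)
  nT <- dim(fr)[1]
  out <- rep(NA_real_, nT - 1)
  m_prev <- fr[1, , ] > level
  for (f in 2:nT) {
    m_cur <- fr[f, , ] > level
    if (sum(m_prev) >= min_cells && sum(m_cur) >= min_cells)
      out[f - 1] <- wave_speed(m_prev, m_cur, movie$frame_dt,
                               movie$pixel_pitch)
    m_prev <- m_cur
  }
  out
}

#' Kymograph (space-time line scan)
#'
#' Extracts the voltage along a scan line over all frames.
#'
#' @param movie an [activity_movie()].
#' @param line `list(row = i)` or `list(col = j)` or an n x 2 matrix of
#'   (row, col) points.
#' @return A `T x L` matrix (class `kymograph`, with `frame_dt`
#'   attribute).
#' @export
kymograph <- function(movie, line) {
  fr <- movie$frames
  if (is.matrix(line)) {
    k <- sapply(seq_len(nrow(line)), function(p) fr[, line[p, 1], line[p, 2]])
  } else if (!is.null(line$row)) {
    k <- fr[, line$row, ]
  } else if (!is.null(line$col)) {
    k <- fr[, , line$col]
  } else stop("line must give a row, a col, or a point matrix")
  structure(k, frame_dt = movie$frame_dt, class = c("kymograph", "matrix"))
}

#' Dominant oscillation frequency
#'
#' Peak of the raw periodogram of a trace (or of the spatial-mean trace of
#' a movie), excluding the zero-frequency bin. The trace is detrended by
#' mean removal; an optional leading transient can be dropped.
#'
#' @param x numeric trace, or an [activity_movie()] (spatial mean is
#'   used).
#' @param frame_dt sample interval (ms); taken from the movie if given.
#' @param drop_ms initial transient to discard (ms).
#' @return Frequency in Hz; `NA` with a warning for traces shorter than 4
#'   samples or with no variance.
#' @export
dominant_frequency <- function(x, frame_dt = 2, drop_ms = 50) {
  if (inherits(x, "activity_movie")) {
    frame_dt <- x$frame_dt
    x <- apply(x$frames, 1, mean)
  }
  drop <- min(round(drop_ms / frame_dt), max(length(x) - 8, 0))
  if (drop > 0) x <- x[-seq_len(drop)]
  n <- length(x)
  if (n < 4) { warning("trace too short for a spectral estimate"); return(NA_real_) }
  x <- x - mean(x)
  if (stats::sd(x) == 0) { warning("constant trace; frequency undefined"); return(NA_real_) }
  p <- Mod(stats::fft(x))^2
  k <- 2:floor(n / 2)
  freqs <- (k - 1) / (n * frame_dt / 1000)
  freqs[which.max(p[k])]
}

#' Spectral resolution of a trace
#'
#' Width of one frequency bin (Hz) for a trace of the given length.
#'
#' @param n_samples number of samples.
#' @param frame_dt sample interval (ms).
#' @return Hz per bin.
#' @export
spectral_bin <- function(n_samples, frame_dt = 2) 1000 / (n_samples * frame_dt)

#' Lurch index of a kymograph
#'
#' Operationalises "staggered in time": the fraction of inter-frame
#' intervals, over the lifetime of the propagating front, in which the
#' front's leading edge fails to advance. The leading edge is the
#' active-pixel extremum along the scan in the overall direction of
#' propagation; frames with no activity while the front is alive count as
#' stalls (the temporal gaps of a lurching wave). Smooth constant-velocity
#' fronts give ~0; staircase fronts give the stall fraction.
#'
#' @param kymo a [kymograph()] (or `T x L` matrix).
#' @param level segmentation level; default [segmentation_level()].
#' @param min_advance minimal advance (px) counted as movement.
#' @return Stall fraction in `[0, 1]`, or `NA` if no front is detected.
#' @export
lurch_index <- function(kymo, level = NULL, min_advance = 0.5) {
  k <- unclass(kymo)
  if (is.null(level)) level <- segmentation_level(k)
  act <- k > level
  alive <- which(rowSums(act) > 0)
  if (length(alive) < 3) return(NA_real_)
  span <- alive[1]:alive[length(alive)]
  edge_hi <- vapply(span, function(f) if (any(act[f, ])) max(which(act[f, ])) else NA_real_, 0)
  edge_lo <- vapply(span, function(f) if (any(act[f, ])) min(which(act[f, ])) else NA_real_, 0)
  carry <- function(e) { # persist last known edge through gap frames
    for (i in seq_along(e)) if (is.na(e[i]) && i > 1) e[i] <- e[i - 1]
    e
  }
  ## stalls are counted over the front's expansion episode only: from the
  ## first frame to the frame where the leading edge first attains its
  ## extreme (afterwards the front has traversed the scan and "no advance"
  ## would be trivially counted)
  stall_frac <- function(e, sgn) {
    e <- sgn * carry(e)
    end <- which.max(e)
    if (end < 3) return(NA_real_)
    d <- diff(e[1:end])
    if (all(is.na(d))) return(NA_real_)
    mean(d < min_advance, na.rm = TRUE)
  }
  range_hi <- diff(range(edge_hi, na.rm = TRUE))
  range_lo <- diff(range(edge_lo, na.rm = TRUE))
  if (range_hi >= range_lo) stall_frac(edge_hi, 1) else stall_frac(edge_lo, -1)
}

#' Wave area per frame and wave duration
#'
#' `wave_area_series()` counts the cells engaged in the wavefront per
#' frame. `wave_duration()` is the time from the first to the last frame
#' whose area exceeds `min_cells`.
#'
#' @param movie an [activity_movie()].
#' @param level segmentation level; default [segmentation_level()].
#' @param min_cells minimal engaged cells for "wave present".
#' @return `wave_area_series`: integer vector (cells per frame).
#'   `wave_duration`: duration in ms (0 if never above cutoff).
#' @export
wave_area_series <- function(movie, level = NULL) {
  if (is.null(level)) level <- segmentation_level(movie)
  apply(movie$frames > level, 1, sum)
}

#' @rdname wave_area_series
#' @export
wave_duration <- function(movie, level = NULL, min_cells = 5) {
  a <- wave_area_series(movie, level)
  on <- which(a >= min_cells)
  if (!length(on)) return(0)
  (on[length(on)] - on[1] + 1) * movie$frame_dt
}

#' Mean wave direction
#'
#' Angle of the mean centroid displacement of the segmented activity
#' across frames. Convention: 0 deg points along increasing column
#' (rightward), 90 deg along decreasing row (upward).
#'
#' @param movie an [activity_movie()].
#' @param level segmentation level.
#' @param min_cells frames with fewer active cells are skipped.
#' @return Direction in degrees in (-180, 180], or `NA` if stationary.
#' @export
wave_direction <- function(movie, level = NULL, min_cells = 5) {
  fr <- movie$frames
  if (is.null(level)) level <- segmentation_level(movie)
  nT <- dim(fr)[1]
  cent <- t(vapply(seq_len(nT), function(f) {
    m <- which(fr[f, , ] > level, arr.ind = TRUE)
    if (nrow(m) < min_cells) return(c(NA_real_, NA_real_))
    c(mean(m[, 1]), mean(m[, 2]))
  }, numeric(2)))
  ok <- stats::complete.cases(cent)
  runs <- which(ok[-1] & ok[-nT])
  if (!length(runs)) return(NA_real_)
  drow <- mean(cent[runs + 1, 1] - cent[runs, 1])
  dcol <- mean(cent[runs + 1, 2] - cent[runs, 2])
  if (sqrt(drow^2 + dcol^2) < 1e-6) return(NA_real_)
  atan2(-drow, dcol) * 180 / pi
}

#' Compare a wave metric between two conditions
#'
#' Mean difference with SEM and a two-sided two-sample Student t test (the
#' statistics used to compare simulation batteries, typically 5 seeds per
#' condition).
#'
#' @param a,b numeric metric samples.
#' @param labels condition names.
#' @return A one-row data.frame: means, mean difference, SEM of the
#'   difference, `t`, `df`, `p`. Degenerate (zero-variance) inputs are
#'   flagged via `warning` and give `p = NA` unless the samples are
#'   identical (then `t = 0`, `p = 1`).
#' @export
compare_conditions <- function(a, b, labels = c("A", "B")) {
  stopifnot(length(a) >= 2, length(b) >= 2)
  sem <- sqrt(stats::var(a) / length(a) + stats::var(b) / length(b))
  if (stats::var(a) == 0 && stats::var(b) == 0) {
    warning("degenerate (zero-variance) samples")
    same <- isTRUE(all.equal(mean(a), mean(b)))
    tt <- list(statistic = if (same) 0 else NA_real_,
               parameter = length(a) + length(b) - 2,
               p.value = if (same) 1 else NA_real_)
  } else {
    tt <- stats::t.test(a, b)
  }
  data.frame(condition_a = labels[1], condition_b = labels[2],
             mean_a = mean(a), mean_b = mean(b),
             diff = mean(a) - mean(b), sem = sem,
             t = unname(tt$statistic), df = unname(tt$parameter),
             p = tt$p.value)
}

#' Summary metrics of a movie
#'
#' One row of wave metrics for a layer movie: mean area, patch count,
#' mean/median speed over propagating episodes, dominant frequency, wave
#' duration, direction and lurch index (along the middle row scan).
#'
#' @param movie an [activity_movie()].
#' @param level segmentation level; default [segmentation_level()].
#' @param layer,preset,seed identifiers copied into the row.
#' @return A one-row data.frame.
#' @export
movie_metrics <- function(movie, level = NULL, layer = NA, preset = NA,
                          seed = NA) {
  if (is.null(level)) level <- segmentation_level(movie)
  sp <- movie_speed_series(movie, level)
  area <- wave_area_series(movie, level)
  patches <- vapply(seq_len(dim(movie$frames)[1]), function(f)
    attr(segment_wavefront(movie$frames[f, , ], level), "n_patches"),
    integer(1))
  mid <- round(dim(movie$frames)[2] / 2)
  data.frame(
    preset = preset, seed = seed, layer = layer,
    speed_cm_s = mean(sp, na.rm = TRUE),
    speed_med_cm_s = stats::median(sp, na.rm = TRUE),
    freq_hz = suppressWarnings(dominant_frequency(movie)),
    area_mean = mean(area),
    patches_mean = mean(patches),
    duration_ms = wave_duration(movie, level),
    direction_deg = wave_direction(movie, level),
    lurch = lurch_index(kymograph(movie, list(row = mid)), level))
}
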
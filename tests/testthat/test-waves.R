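test_that("wavefront segmentation counts areas and patches", {
  z <- matrix(0, 60, 60)
  expect_equal(attr(segment_wavefront(z, 0.5), "n_patches"), 0)
  ## band of width 3 across all 60 columns: area 180, one patch
  b <- z; b[30:32, ] <- 1
  lab <- segment_wavefront(b, 0.5)
  expect_equal(sum(lab > 0), 180)
  expect_equal(attr(lab, "n_patches"), 1)
  ## two disjoint bands -> 2 patches
  b2 <- z; b2[10:12, ] <- 1; b2[40:42, ] <- 1
  expect_equal(attr(segment_wavefront(b2, 0.5), "n_patches"), 2)
  ## diagonal touching pixels are separate under 4-connectivity
  d <- z; d[1, 1] <- 1; d[2, 2] <- 1
  expect_equal(attr(segment_wavefront(d, 0.5), "n_patches"), 2)
})

test_that("nearest-edge speed is linear in displacement and scale-invariant", {
  band <- function(at) { m <- matrix(FALSE, 40, 40); m[, at:(at + 2)] <- TRUE; m }
  expect_equal(wave_speed(band(10), band(10)), 0)
  ## 1 px/frame at 0.4 mm pitch and 2 ms frames -> 20 cm/s
  expect_equal(wave_speed(band(10), band(11)), 20)
  expect_equal(wave_speed(band(10), band(12)), 40)
  ## empty masks are reported as missing, not zero
  expect_true(is.na(wave_speed(matrix(FALSE, 4, 4), band(10)[1:4, 1:4])))
  ## invariant to mask intensity scaling happens upstream (masks are binary)
  mv <- make_movie("planar", speed = 1, n_frames = 30)
  mv2 <- mv; mv2$frames <- mv2$frames * 7
  s1 <- movie_speed_series(mv); s2 <- movie_speed_series(mv2)
  expect_equal(stats::median(s1, na.rm = TRUE),
               stats::median(s2, na.rm = TRUE))
})

test_that("kymographs reproduce constant, diagonal and orthogonal patterns", {
  cm <- make_movie("constant", n_frames = 10)
  k <- kymograph(cm, list(row = 30))
  expect_true(all(apply(unclass(k), 2, stats::sd) == 0))
  ## planar wave along the scan: activity centre moves 1 px/frame
  pm <- make_movie("planar", speed = 1, direction = 0, n_frames = 30)
  kp <- unclass(kymograph(pm, list(row = 30)))
  pos <- apply(kp, 1, function(rw) if (any(rw > 0.5)) mean(which(rw > 0.5)) else NA)
  d <- diff(pos); d <- d[is.finite(d)]
  expect_equal(stats::median(d), 1, tolerance = 0.05)
  ## wave orthogonal to the scan: every position crosses simultaneously
  ko <- unclass(kymograph(pm, list(col = 30)))
  on_t <- apply(ko, 2, function(tr) which(tr > 0.5)[1])
  expect_lt(diff(range(on_t, na.rm = TRUE)), 3)
  ## point-list scan
  pts <- cbind(30, 5:55)
  expect_equal(dim(kymograph(pm, pts)), c(30, 51))
})

test_that("dominant frequency finds spectral peaks and flags bad traces", {
  t <- seq(0, 0.5, by = 0.002)  # 500 Hz sampling
  expect_equal(dominant_frequency(sin(2 * pi * 15 * t), 2, drop_ms = 0),
               15, tolerance = spectral_bin(length(t), 2))
  mix <- 5 * sin(2 * pi * 10 * t) + 1 * sin(2 * pi * 50 * t)
  expect_equal(dominant_frequency(mix, 2, drop_ms = 0), 10,
               tolerance = spectral_bin(length(t), 2))
  expect_warning(f <- dominant_frequency(rep(1, 100), 2), "constant")
  expect_true(is.na(f))
  expect_warning(f2 <- dominant_frequency(c(1, 2), 2, drop_ms = 0), "short")
  expect_true(is.na(f2))
})

test_that("lurch index separates smooth from staircase fronts", {
  sm <- make_movie("planar", speed = 1, n_frames = 40)
  expect_equal(lurch_index(kymograph(sm, list(row = 30))), 0,
               tolerance = 0.05)
  st <- make_movie("staircase", speed = 1, period = 4, n_frames = 40)
  expect_equal(lurch_index(kymograph(st, list(row = 30))), 0.75,
               tolerance = 0.05)
  ## zero overlap between the families across seeds and noise
  ls <- vapply(1:5, function(s) lurch_index(kymograph(
    make_movie("planar", speed = 1, n_frames = 40, noise_sd = 0.05,
               seed = s), list(row = 30))), 0)
  lt <- vapply(1:5, function(s) lurch_index(kymograph(
    make_movie("staircase", speed = 1, period = 4, n_frames = 40,
               noise_sd = 0.05, seed = s), list(row = 30))), 0)
  expect_lt(max(ls), min(lt))
  ## no detectable front -> missing
  expect_true(is.na(lurch_index(matrix(0, 10, 10), level = 0.5)))
})

test_that("wave area and duration track the fixture lifetime", {
  empty <- activity_movie(array(0, c(10, 20, 20)))
  expect_equal(wave_duration(empty, level = 0.5), 0)
  ## a wave alive for 40 frames of 2 ms -> 80 ms within one frame
  mv <- make_movie("planar", speed = 2, n_frames = 60, cols = 80, rows = 20)
  a <- wave_area_series(mv, 0.5)
  alive <- sum(a >= 5) * mv$frame_dt
  expect_equal(wave_duration(mv, 0.5), alive)
  ## growing radial wave: area non-decreasing until boundary contact
  rv <- make_movie("radial", speed = 1, n_frames = 25)
  ar <- wave_area_series(rv, 0.5)
  expect_true(all(diff(ar[1:20]) >= 0))
})

test_that("wave direction follows the centroid convention", {
  expect_equal(wave_direction(make_movie("planar", direction = 0,
                                         n_frames = 30)), 0,
               tolerance = 2)
  expect_equal(wave_direction(make_movie("planar", direction = 90,
                                         n_frames = 30)), 90,
               tolerance = 2)
  ## reversing fixture: successive window directions differ by 180 deg
  fwd <- make_movie("planar", direction = 0, n_frames = 16)
  rev_frames <- fwd$frames[16:1, , , drop = FALSE]
  rv <- activity_movie(rev_frames)
  d1 <- wave_direction(fwd); d2 <- wave_direction(rv)
  expect_equal(abs(d1 - d2), 180, tolerance = 4)
  expect_true(is.na(wave_direction(make_movie("constant", n_frames = 10))))
})

test_that("condition comparison implements the two-sample t contract", {
  a <- c(1, 2, 3, 4, 5)
  r <- compare_conditions(a, a)
  expect_equal(r$t, 0, tolerance = 1e-12)
  expect_equal(r$p, 1, tolerance = 1e-12)
  ## constant samples are degenerate and flagged
  expect_warning(rd <- compare_conditions(rep(1, 3), rep(1, 3)),
                 "degenerate")
  expect_equal(rd$p, 1)
  ## a large shift at n = 5 is highly significant; cross-check vs analytic t
  b <- a + 10
  r2 <- compare_conditions(b, a)
  expect_lt(r2$p, 0.01)
  t_manual <- (mean(b) - mean(a)) /
    sqrt(var(a) / 5 + var(b) / 5)
  expect_equal(r2$t, t_manual)
  ## reproducible
  expect_identical(compare_conditions(b, a), compare_conditions(b, a))
})

test_that("fixture ground truth is recovered by the analysis toolkit", {
  for (sp in c(1, 2)) for (dir in c(0, 90)) {
    mv <- make_movie("planar", speed = sp, direction = dir, n_frames = 30,
                     noise_sd = 0.02, seed = sp + dir)
    gt <- ground_truth(mv)
    est <- stats::median(movie_speed_series(mv), na.rm = TRUE)
    expect_equal(est, gt$speed_cm_s, tolerance = 0.05 * gt$speed_cm_s)
    expect_equal(wave_direction(mv), gt$direction_deg, tolerance = 5)
  }
  ## staircase: lurch within 0.05 of the constructed stall fraction
  st <- make_movie("staircase", speed = 1, period = 4, n_frames = 40,
                   noise_sd = 0.02)
  expect_equal(lurch_index(kymograph(st, list(row = 30))),
               ground_truth(st)$stall_fraction, tolerance = 0.05)
  ## periodic radial emission recovers its frequency within one bin
  t <- seq(0, 0.6, by = 0.002)
  trace <- sin(2 * pi * 12 * t)
  expect_equal(dominant_frequency(trace, 2, drop_ms = 0), 12,
               tolerance = spectral_bin(length(t), 2))
})

test_that("movie metrics assemble one labelled row", {
  mv <- make_movie("planar", speed = 1, n_frames = 30)
  row <- movie_metrics(mv, layer = "CX", preset = "fixture", seed = 7)
  expect_equal(nrow(row), 1)
  expect_true(all(c("speed_cm_s", "freq_hz", "area_mean", "duration_ms",
                    "lurch") %in% names(row)))
  expect_equal(row$layer, "CX")
})
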
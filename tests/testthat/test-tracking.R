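test_that("correlate_window recovers integer and fractional shifts", {
  ref <- speckle_segment(n = 128)
  # self-correlation
  cw <- correlate_window(ref, ref, max_lag = 10)
  expect_equal(cw$lag, 0)
  expect_equal(cw$peak_coefficient, 1, tolerance = 1e-12)
  # integer shift of a speckle segment
  shifted <- speckle_segment(n = 128, shift = 3)
  cw <- correlate_window(ref, shifted, max_lag = 10)
  expect_equal(round(cw$lag), 3)
  expect_gt(cw$peak_coefficient, 0.99)
  # fractional shifts against the brute-force upsampled oracle
  for (s in c(-1.75, -0.6, 0.25, 0.4, 1.3)) {
    cur <- speckle_segment(n = 128, shift = s)
    cw <- correlate_window(ref, cur, max_lag = 8,
                           subsample_method = "cosine")
    oracle <- brute_force_lag(ref, cur, max_lag = 8)
    expect_lt(abs(cw$lag - oracle), 0.05)
    expect_lt(abs(cw$lag - s), 0.05)
  }
  # carrier-phase refinement at the nominal two-way carrier (pi/2 per
  # sample on the lambda/8 grid) matches the imposed shift
  for (s in c(-0.4, 0.3, 1.2)) {
    cur <- speckle_segment(n = 128, shift = s)
    cw <- correlate_window(ref, cur, max_lag = 8, "phase",
                           carrier_omega = pi / 2)
    expect_lt(abs(cw$lag - s), 0.06)
  }
  expect_error(correlate_window(ref, ref, 4, "phase"), "carrier_omega")
  # zero-variance segment flags degenerate
  cw <- correlate_window(rep(0, 64), rep(0, 64), max_lag = 5)
  expect_true(cw$degenerate)
  expect_equal(cw$lag, 0)
  expect_equal(cw$peak_coefficient, 0)
})

test_that("static noiseless series tracks zero displacement with no updates", {
  f <- small_field(pwv = 5, duration = 0.3, n_cycles = 0, n_positions = 6)
  bf <- render_speckle_lines(f, seed = 2)
  tr <- arfd_track(bf, config = tracking_config(dz = bf$depths[2] - bf$depths[1]))
  expect_true(all(abs(tr$displacement) < 1e-6))
  expect_equal(sum(lengths(tr$ref_updates)), 0)
  expect_true(all(tr$corr_coeff >= 0.999))
})

test_that("tracked propagating pulse matches ground truth without decorrelation", {
  f <- generate_wall_displacement_field(pwv_true = 5, duration = 1.0,
                                        n_cycles = 1, n_positions = 12)
  bf <- render_speckle_lines(f, seed = 4)
  tr <- arfd_track(bf, config = tracking_config(
    dz = bf$depths[2] - bf$depths[1], subsample_method = "cosine"))
  truth <- f$posterior_disp
  peak_true <- apply(truth, 1, max)
  peak_est <- apply(tr$displacement, 1, max)
  expect_true(all(abs(peak_est - peak_true) / peak_true < 0.10))
})

test_that("adaptive reference updates fire exactly when coherence drops below threshold", {
  f <- small_field(pwv = 5, duration = 0.5, n_cycles = 0, n_positions = 4)
  bf <- render_speckle_lines(f, decorrelation_rate = 0.05, seed = 11)
  tr <- arfd_track(bf, config = tracking_config(dz = bf$depths[2] - bf$depths[1]))
  for (i in seq_len(nrow(tr$displacement))) {
    ev <- tr$ref_updates[[i]]
    cc <- tr$corr_coeff[i, ]
    expect_true(length(ev) > 0)
    expect_true(all(diff(ev) > 0))
    # updates exactly at frames whose running NCC fell below threshold
    expect_identical(ev, which(cc < 0.9))
  }
})

test_that("ARFD terminal drift does not exceed fixed-reference drift under decorrelation", {
  wins <- 0L; total <- 0L
  for (seed in 1:8) {
    f <- small_field(pwv = 5, duration = 0.6, n_cycles = 1, n_positions = 2,
                     heart_rate = 100, foot_time = 50)
    bf <- render_speckle_lines(f, decorrelation_rate = 0.05, seed = seed,
                               n_lines = 2)
    cfg <- tracking_config(dz = bf$depths[2] - bf$depths[1],
                           subsample_method = "cosine")
    tr_a <- arfd_track(bf, config = cfg, adaptive = TRUE)
    tr_f <- arfd_track(bf, config = cfg, adaptive = FALSE)
    truth <- f$posterior_disp[c(1, 2), ]
    nfr <- ncol(truth)
    drift_a <- abs(tr_a$displacement[, nfr] - truth[, nfr])
    drift_f <- abs(tr_f$displacement[, nfr] - truth[, nfr])
    wins <- wins + sum(drift_a <= drift_f)
    total <- total + length(drift_a)
  }
  expect_gte(wins / total, 0.75)
})

test_that("threshold monotonicity: lowering the threshold never adds updates", {
  f <- small_field(pwv = 5, duration = 0.4, n_cycles = 0, n_positions = 3)
  bf <- render_speckle_lines(f, decorrelation_rate = 0.04, seed = 9)
  dz <- bf$depths[2] - bf$depths[1]
  n_up <- vapply(c(0.95, 0.9, 0.8, 0.6), function(th) {
    tr <- arfd_track(bf, config = tracking_config(dz = dz, corr_threshold = th))
    sum(lengths(tr$ref_updates))
  }, numeric(1))
  expect_true(all(diff(n_up) <= 0))
})

test_that("shift-equivariance: delaying the series delays the track", {
  f <- generate_wall_displacement_field(pwv_true = 5, duration = 0.8,
                                        n_cycles = 1, n_positions = 3,
                                        heart_rate = 75, foot_time = 200)
  bf <- render_speckle_lines(f, seed = 6)
  cfg <- tracking_config(dz = bf$depths[2] - bf$depths[1],
                         subsample_method = "cosine")
  tr <- arfd_track(bf, config = cfg)
  k <- 40
  bf2 <- bf
  nfr <- dim(bf$data)[1]
  bf2$data <- bf$data[c(rep(1, k), 1:(nfr - k)), , , drop = FALSE]
  tr2 <- arfd_track(bf2, config = cfg)
  expect_equal(tr2$displacement[, (k + 1):nfr],
               tr$displacement[, 1:(nfr - k)], tolerance = 1e-9)
})

test_that("segment_wall finds two-band geometry and flags degenerate input", {
  # synthetic two-bright-band envelope image at depths 50 and 70 mm
  depths <- seq(40, 80, by = 0.1)
  img <- exp(-0.5 * (depths - 50)^2 / 0.4^2) +
    exp(-0.5 * (depths - 70)^2 / 0.4^2)
  dat <- array(0, c(4, length(depths), 3))
  for (f in 1:4) for (l in 1:3) dat[f, , l] <- img
  bf <- structure(list(data = dat, depths = depths,
                       line_angles_deg = 1:3, lateral_mm = 1:3,
                       frame_rate = 1000, center_freq = 5,
                       sound_speed = 1540, compounded = TRUE,
                       is_envelope = TRUE, grid = list(wall = NULL)),
                  class = "bf_series")
  ct <- segment_wall(bf, smooth = 1)
  expect_equal(mean(ct$anterior), 50, tolerance = 0.05)
  expect_equal(mean(ct$posterior), 70, tolerance = 0.05)
  expect_equal(mean(ct$diameter), 20, tolerance = 0.1)
  # uniform image: unsegmentable everywhere
  bf$data[] <- 1
  ct2 <- segment_wall(bf, smooth = 1)
  expect_true(all(is.na(ct2$diameter)))
})

test_that("segment_wall recovers the pulsating diameter of a rendered phantom", {
  f <- generate_wall_displacement_field(pwv_true = 5, duration = 1.0,
                                        n_cycles = 1, n_positions = 4,
                                        segment_length = 12,
                                        anterior_depth = 55,
                                        posterior_depth = 75)
  ba <- render_speckle_lines(f, wall = "anterior", band = 0.15, density = 300,
                             seed = 13)
  bp <- render_speckle_lines(f, wall = "posterior", band = 0.15, density = 300,
                             seed = 14)
  # stitch the two bands into one series with a gap between them
  gap_depths <- seq(max(ba$depths) + 0.05, min(bp$depths) - 0.05, by = 0.0385)
  nfr <- dim(ba$data)[1]
  depths <- c(ba$depths, gap_depths, bp$depths)
  dat <- array(0, c(nfr, length(depths), 4))
  dat[, seq_along(ba$depths), ] <- ba$data
  dat[, length(ba$depths) + length(gap_depths) + seq_along(bp$depths), ] <- bp$data
  bf <- ba; bf$data <- dat; bf$depths <- depths
  ct <- segment_wall(envelope(bf))
  lambda <- 0.308
  dia_t <- rowMeans(ct$diameter) # per-frame mean over lines
  dia_true_sys <- 20 + (max(f$posterior_disp) - min(f$anterior_disp)) / 1000
  expect_lt(abs(min(dia_t) - 20), 0.5 * lambda)
  expect_lt(abs(max(dia_t) - dia_true_sys), 0.5 * lambda)
})
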
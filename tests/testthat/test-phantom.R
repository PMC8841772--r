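test_that("pulse waveform rises as parameterized and integrates in closed form", {
  # linear ramp midpoint: half peak at foot + rise/2
  v <- generate_pulse_waveform(foot_time = 100, peak_velocity = 10,
                               rise_time = 20, decay_time = 150,
                               n_samples = 300, frame_rate = 1000,
                               shape = "linear")
  expect_equal(v[111], 5) # t = 110 ms
  expect_true(all(v[1:100] == 0))
  # degenerate amplitude
  v0 <- generate_pulse_waveform(100, 0, 20, 150, 300, 1000)
  expect_true(all(v0 == 0))
  # dominant positive systolic lobe, shallow diastolic recoil that closes
  # the cycle's displacement integral
  v1 <- generate_pulse_waveform(100, 8, 60, 150, 1100, 1000)
  expect_equal(which.max(v1), 161, tolerance = 1) # peak at foot + rise
  expect_lt(max(-v1), max(v1) / 2)                # recoil lobe is shallower
  d1 <- cumsum(v1)
  expect_lt(abs(d1[1101 - 1]) / max(d1), 0.01)    # displacement closes
  # closed-form displacement matches numerical integration
  t <- (0:999)
  d_num <- cumsum(aortapwv:::pulse_velocity_at(t, 100, 8, 60, 150)) * 1
  d_cf <- aortapwv:::pulse_displacement_at(t, 100, 8, 60, 150)
  expect_lt(max(abs(d_num - d_cf)) / max(d_cf), 0.01)
  # analytic 50% upstroke time
  expect_equal(pulse_upstroke_time(100, 60, 0.5), 130)
  expect_equal(pulse_upstroke_time(100, 60, 0.5, "linear"), 130)
  # parameter validation
  expect_error(generate_pulse_waveform(100, 8, -1, 150, 300, 1000), "rise")
  expect_error(generate_pulse_waveform(100, 8, 20, 150, 300, -5), "frame_rate")
})

test_that("50% upstroke crossing of the default pulse is recovered within one frame", {
  f <- small_field(pwv = 5, n_positions = 8)
  tr <- track_from_field(f)
  vm <- wall_velocity(tr)
  mk <- detect_upstrokes(vm, c(0, 1000))
  expect_true(all(mk$valid))
  expect_lt(max(abs(mk$arrival_time - f$t50_times[, 1])), 1.0) # 1 frame @ 1 kHz
})

test_that("wall displacement field obeys the pure-delay propagation model", {
  f <- generate_wall_displacement_field(pwv_true = 5, segment_length = 50,
                                        n_positions = 11, duration = 1,
                                        n_cycles = 1)
  # foot arrival at far end lags near end by distance/speed = 10 ms
  expect_equal(f$foot_times[11, 1] - f$foot_times[1, 1], 10)
  # pure delay: 10 mm apart at 10 m/s = 1 ms (2 frames at 2 kHz)
  f2 <- generate_wall_displacement_field(pwv_true = 10, segment_length = 10,
                                         n_positions = 2, duration = 1,
                                         n_cycles = 1, frame_rate = 2000)
  n <- length(f2$times)
  expect_equal(f2$posterior_disp[2, 3:n],
               f2$posterior_disp[1, 1:(n - 2)], tolerance = 1e-12)
  # zero before the first foot, everywhere
  for (i in c(1, 6, 11)) {
    before <- f$times < f$foot_times[i, 1]
    expect_true(all(f$posterior_disp[i, before] == 0))
  }
  # anterior mirrors posterior
  expect_equal(f$anterior_disp, -f$posterior_disp)
  # ground-truth foot table monotone in position
  expect_true(all(diff(f$foot_times[, 1]) > 0))
  # unresolvable transit errors out
  expect_error(generate_wall_displacement_field(pwv_true = 100,
                                                segment_length = 10,
                                                frame_rate = 500,
                                                duration = 1, n_cycles = 1),
               "resolvable")
})

test_that("cross-correlation lag of noiseless waveforms matches separation/pwv", {
  for (pwv in c(3, 7, 13)) {
    f <- generate_wall_displacement_field(pwv_true = pwv, segment_length = 60,
                                          n_positions = 4, duration = 1.2,
                                          n_cycles = 1)
    a <- diff(f$posterior_disp[1, ]); b <- diff(f$posterior_disp[4, ])
    cc <- stats::ccf(b, a, lag.max = 60, plot = FALSE)
    lag_frames <- cc$lag[which.max(cc$acf)]
    expect_equal(lag_frames, 60 / pwv, tolerance = 0.5 + 1e-9)
  }
})

test_that("pressure trace extrema and periodicity are exact; feet are counted", {
  tr <- generate_pressure_trace(sbp = 120, dbp = 80, heart_rate = 75,
                                duration = 3.0)
  expect_equal(max(tr$pressure), 120)
  expect_equal(min(tr$pressure), 80)
  expect_equal(pulse_pressure(tr), 40)
  # one full period apart, same value
  per <- 60000 / 75; idx <- round(per)
  expect_equal(tr$pressure[1:500], tr$pressure[(1 + idx):(500 + idx)],
               tolerance = 1e-9)
  expect_equal(length(pressure_feet(tr)), 4) # feet at 0, 0.8, 1.6, 2.4 s
  # near-degenerate pulse pressure
  tr2 <- generate_pressure_trace(80.01, 80, duration = 1.1, heart_rate = 60)
  expect_equal(pulse_pressure(tr2), 0.01)
  expect_error(generate_pressure_trace(80, 90), "sbp > dbp")
})

test_that("scatterer and RF generation are deterministic under a fixed seed", {
  f <- small_field(pwv = 5, duration = 0.05, n_cycles = 0, n_positions = 8)
  s1 <- generate_scatterers(f, seed = 7)
  s2 <- generate_scatterers(f, seed = 7)
  expect_identical(s1, s2)
  s3 <- generate_scatterers(f, seed = 8)
  expect_false(identical(s1$positions$lateral, s3$positions$lateral))
  geom <- make_geometry(8, 60, 1.5)
  ws <- virtual_sources(geom, 0)
  r1 <- render_rf_sequence(f, s1, geom, ws, seed = 7, frames = 1:3,
                           decorrelation_rate = 0.1)
  r2 <- render_rf_sequence(f, s1, geom, ws, seed = 7, frames = 1:3,
                           decorrelation_rate = 0.1)
  expect_identical(r1$data, r2$data)
})

test_that("cohort generator honours group structure and degenerate variances", {
  co <- generate_cohort(seed = 5)
  expect_equal(nrow(co), 69)
  expect_equal(as.integer(table(co$group)), c(31, 22, 16))
  ga <- assign_groups(co$frs)
  expect_equal(as.character(ga$group3), as.character(co$group))
  expect_true(all(co$systolic_diameter > co$diastolic_diameter))
  expect_true(all(co$sbp > co$dbp))
  # sample means within 3 sd/sqrt(n) of the specified group means
  n <- c(31, 22, 16); mu <- c(5.3, 8.3, 10.8); sdv <- c(1.1, 3.1, 2.5)
  mns <- tapply(co$ufcpwv, co$group, mean)
  expect_true(all(abs(mns - mu) < 3 * sdv / sqrt(n)))
  # zero within-group sd collapses the spread
  co0 <- generate_cohort(sds = c(0, 0, 0), bh_sds = c(0, 0, 0), seed = 5)
  expect_equal(max(abs(tapply(co0$ufcpwv, co0$group, sd))), 0)
  # diameters reproduce the tabulated theoretical PWV (self-consistency)
  back <- bh_pwv(area_from_diameter(co$diastolic_diameter),
                 area_from_diameter(co$systolic_diameter) -
                   area_from_diameter(co$diastolic_diameter),
                 co$sbp - co$dbp)
  expect_equal(back, co$bhpwv, tolerance = 1e-9)
  expect_error(generate_cohort(n_per_group = c(1, 5, 5)), "at least 2")
})
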
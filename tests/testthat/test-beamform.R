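test_that("curved-array geometry places elements on the arc", {
  g <- make_geometry(2, radius = 60, pitch = 0.6)
  expect_equal(g$element_x, 60 * sin(c(-0.005, 0.005)))
  expect_equal(g$element_x[1], -g$element_x[2])
  expect_equal(diff(g$element_angles) * 60, 0.6) # arc separation = pitch
  g <- make_geometry(128, 60, 0.6)
  expect_equal((128 - 1) * g$pitch, 76.2)
  # all elements exactly on the circle of radius 60 about (0, -60)
  expect_equal(sqrt(g$element_x^2 + (g$element_z + 60)^2), rep(60, 128))
  # chord between adjacent centers = 2 R sin(pitch / (2 R))
  chord <- sqrt(diff(g$element_x)^2 + diff(g$element_z)^2)
  expect_equal(chord, rep(2 * 60 * sin(0.6 / 120), 127), tolerance = 1e-12)
  expect_error(make_geometry(400, 10, 0.6), "non-physical")
})

test_that("virtual sources sit on the array circle with mirror symmetry", {
  g <- make_geometry(64, 60, 0.6)
  ws <- virtual_sources(g, c(-12, 0, 12))
  expect_equal(ws$source_x[2], 0)
  expect_equal(ws$source_z[2], 0)
  expect_equal(ws$source_x[1], -ws$source_x[3])
  expect_equal(ws$source_z[1], ws$source_z[3])
  expect_equal(sqrt(ws$source_x^2 + (ws$source_z + 60)^2), rep(60, 3))
  # transmit delay profile |source - element| is convex with its minimum at
  # the element nearest the source
  d <- sqrt((ws$source_x[3] - g$element_x)^2 + (ws$source_z[3] - g$element_z)^2)
  k <- which.min(d)
  ang <- g$element_angles * 180 / pi
  expect_equal(ang[k], 12, tolerance = g$pitch / 60 * 180 / pi)
  expect_true(all(diff(d[1:k]) < 0) && all(diff(d[k:length(d)]) > 0))
  expect_error(virtual_sources(g, 95), "abs")
})

test_that("beamforming is linear and zero in equals zero out", {
  f <- small_field(pwv = 5, duration = 0.003, n_cycles = 0, n_positions = 4)
  sc <- as_scatterer_field(data.frame(lateral = c(25, 35), axial = c(74, 76),
                                      amplitude = c(1, -0.5)))
  g <- make_geometry(16, 60, 1.5)
  ws <- virtual_sources(g, c(-12, 0, 12))
  rf <- render_rf_sequence(f, sc, g, ws, frames = 1)
  grid <- grid_for_field(g, f, n_lines = 8, band = 3)
  bf1 <- das_beamform(rf, g, ws, grid)
  rf2 <- rf; rf2$data <- 2 * rf$data
  bf2 <- das_beamform(rf2, g, ws, grid)
  for (a in 1:3) expect_equal(bf2[[a]]$data, 2 * bf1[[a]]$data,
                              tolerance = 1e-12)
  rf0 <- rf; rf0$data[] <- 0
  bf0 <- das_beamform(rf0, g, ws, grid)
  expect_true(all(bf0[[1]]$data == 0))
})

test_that("compounding averages aligned series and rejects mismatched grids", {
  f <- small_field(pwv = 5, duration = 0.003, n_cycles = 0, n_positions = 4)
  sc <- as_scatterer_field(data.frame(lateral = 30, axial = 75, amplitude = 1))
  g <- make_geometry(16, 60, 1.5)
  ws <- virtual_sources(g, c(-12, 0, 12))
  rf <- render_rf_sequence(f, sc, g, ws, frames = 1)
  grid <- grid_for_field(g, f, n_lines = 8, band = 3)
  pa <- das_beamform(rf, g, ws, grid)
  # identical inputs per angle: compound equals any input
  cp_same <- compound(list(pa[[2]], pa[[2]], pa[[2]]))
  expect_equal(cp_same$data, pa[[2]]$data)
  expect_true(cp_same$compounded)
  # single-angle compounding is the identity
  cp1 <- compound(pa[2])
  expect_equal(cp1$data, pa[[2]]$data)
  # mean of the three angles
  cp <- compound(pa)
  expect_equal(cp$data, (pa[[1]]$data + pa[[2]]$data + pa[[3]]$data) / 3)
  # grid mismatch errors
  bad <- pa[[2]]; bad$depths <- bad$depths + 0.1
  expect_error(compound(list(pa[[1]], bad)), "grid mismatch")
})

test_that("envelope detection recovers amplitude and the rendered Gaussian", {
  # pure tone scanline of amplitude A: envelope ~ A away from edges
  n <- 256
  x <- 3 * cos(2 * pi * 0.2 * seq_len(n))
  env <- aortapwv:::analytic_envelope(x)
  expect_equal(env[30:(n - 30)], rep(3, n - 59), tolerance = 0.01)
  expect_true(all(aortapwv:::analytic_envelope(rep(0, 64)) == 0))
  # Gaussian-enveloped tone: interior RMS error within 2%
  sigma_z <- 0.077; lambda <- 0.308
  z <- seq(-3, 3, by = lambda / 8)
  sig <- exp(-0.5 * z^2 / sigma_z^2) * cos(4 * pi * z / lambda)
  env <- aortapwv:::analytic_envelope(sig)
  truth <- exp(-0.5 * z^2 / sigma_z^2)
  interior <- abs(z) < 2
  rms <- sqrt(mean((env[interior] - truth[interior])^2)) /
    sqrt(mean(truth[interior]^2))
  expect_lt(rms, 0.02)
})

test_that("point scatterer localizes within a resolution cell per angle and compounded", {
  f <- generate_wall_displacement_field(pwv_true = 8, duration = 0.002,
                                        n_cycles = 0, posterior_depth = 70)
  sc <- as_scatterer_field(data.frame(lateral = 35, axial = 70, amplitude = 1))
  g <- make_geometry(128, 60, 0.6)
  ws <- virtual_sources(g, c(-12, 0, 12))
  rf <- render_rf_sequence(f, sc, g, ws, frames = 1)
  lambda <- 1.54 / 5
  xs <- seq(3, 7, by = 0.05)
  al <- atan(xs / 130) * 180 / pi
  depths <- seq(67, 73, by = lambda / 8)
  grid <- make_grid(g, depths, al, lateral_mm = xs)
  pa <- das_beamform(rf, g, ws, grid, f_number = 1.5)
  locate <- function(b) {
    e <- envelope(b)
    ij <- arrayInd(which.max(e$data[1, , ]), dim(e$data[1, , ]))
    a <- al[ij[2]] * pi / 180
    c(x = (depths[ij[1]] + 60) * sin(a),
      z = (depths[ij[1]] + 60) * cos(a) - 60)
  }
  for (b in pa) {
    p <- locate(b)
    expect_lt(abs(p["z"] - 70), lambda)        # axial within one cell
    expect_lt(abs(p["x"] - 5), lambda * 1.5)   # lateral within lambda * f#
  }
  p <- locate(compound(pa))
  expect_lt(abs(p["z"] - 70), lambda)
  expect_lt(abs(p["x"] - 5), lambda * 1.5)
})

test_that("round trip: imposed uniform shift is recovered to an eighth of a sample", {
  # same speckle rendered twice, walls rigidly displaced by 100 um
  f1 <- small_field(pwv = 5, duration = 0.002, n_cycles = 0, n_positions = 4)
  sc <- generate_scatterers(f1, walls = "posterior", seed = 21,
                            lateral_margin = 1)
  g <- make_geometry(32, 60, 1.5)
  ws <- virtual_sources(g)
  grid <- grid_for_field(g, f1, n_lines = 5, band = 4)
  rf1 <- render_rf_sequence(f1, sc, g, ws, frames = 1, seed = 21)
  sc2 <- sc; sc2$positions$axial <- sc$positions$axial + 0.1
  rf2 <- render_rf_sequence(f1, sc2, g, ws, frames = 1, seed = 21,
                            pulse_sigma = rf1$pulse_sigma)
  b1 <- compound(das_beamform(rf1, g, ws, grid))
  b2 <- compound(das_beamform(rf2, g, ws, grid))
  dz <- b1$depths[2] - b1$depths[1]
  l <- 3; w <- 64; m <- 20
  i0 <- round(length(b1$depths) / 2) - w / 2
  ref <- b1$data[1, i0:(i0 + w - 1), l]
  cur <- b2$data[1, (i0 - m):(i0 + w - 1 + m), l]
  cw <- correlate_window(ref, cur, max_lag = m, subsample_method = "cosine")
  expect_lt(abs(cw$lag * dz - 0.1), dz / 8)
})
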
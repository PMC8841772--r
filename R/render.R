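# Synthetic RF channel data: far-field point-scatterer superposition with a
# Gaussian-enveloped carrier. No attenuation and no elevational focusing;
# out-of-plane motion is emulated by amplitude-preserving random replacement
# of a fraction of scatterers per frame.

# Interpolate a wall's displacement (um) at arbitrary lateral positions.
# Positions beyond the stored segment use the closed-form propagating pulse
# (noiseless extrapolation), so margin scatterers carry properly delayed
# motion instead of a clamped end waveform.
field_disp_at <- function(field, wall, lateral, frame) {
  m <- if (wall == "anterior") field$anterior_disp else field$posterior_disp
  out <- approx(field$lateral_positions, m[, frame], xout = lateral,
                rule = 2)$y
  rng <- range(field$lateral_positions)
  ext <- lateral < rng[1] | lateral > rng[2]
  if (any(ext)) {
    p <- field$params
    t <- field$times[frame]
    sgn <- if (wall == "anterior") -0.5 else 0.5
    out[ext] <- sgn * pulse_displacement_at(
      t - lateral[ext] / field$pwv_true, p$foot_time, p$peak_velocity,
      p$rise_time, p$decay_time, p$shape, 60000 / p$heart_rate,
      field$n_cycles)
  }
  out
}

# Centered lateral coordinate of the phantom on the array axis.
field_centered_lateral <- function(field, lateral) {
  lateral - mean(range(field$lateral_positions))
}

#' Render synthetic RF channel data for a phantom
#'
#' Produces per-transmit channel data (frames x elements x samples): every
#' frame is the superposition of one Gaussian-modulated sinusoidal pulse
#' echo per scatterer and receive element, at the round-trip delay
#' `(|source - scatterer| + |scatterer - element|) / c`. Scatterer axial
#' positions are advected by the local wall displacement of the phantom. All
#' tilted transmits of a compounded frame observe the same wall state (the
#' simulator emits compounded frame sets directly at the field frame rate;
#' pulse-repetition timing inside a triplet is not modeled). At
#' `decorrelation_rate = 0` and `noise_sd = 0`, consecutive frames differ
#' only by the wall displacement.
#'
#' @param field a `wall_field`.
#' @param scatterers a `scatterer_field` (see [generate_scatterers()]).
#' @param geometry a `curved_array`. @param waveset a `diverging_wave_set`.
#' @param center_freq MHz transmit center frequency.
#' @param sampling_freq MHz RF sampling rate (>= 4 x `center_freq`
#'   recommended; < 2 x is an error).
#' @param sound_speed m/s.
#' @param decorrelation_rate fraction of scatterers replaced (new random
#'   position inside their wall band, amplitude preserved) per frame, in
#'   `[0, 1)`; emulates out-of-plane motion.
#' @param noise_sd additive white RF noise (same units as echo amplitude).
#' @param seed integer; `NULL` means "continue the current RNG stream"
#'   (used by [acquire_bf()] for chunked rendering).
#' @param frames field-frame indices to render (default: all).
#' @param state internal scatterer state from a previous chunk.
#' @param pulse_sigma us, Gaussian envelope SD of the pulse (default
#'   `0.5 / center_freq`).
#' @param elem_width mm, element width for the soft-baffled piston receive
#'   directivity (`sinc(w sin(phi)/lambda) cos(phi)`); default 0.9 x pitch,
#'   0 disables directivity (idealized omnidirectional elements).
#' @return An `rf_series`: `data[frame, element, sample]`, acquisition
#'   metadata, a transmit schedule mapping rendered frames to tilt angles
#'   and field frames, and the final scatterer state.
#' @export
render_rf_sequence <- function(field, scatterers, geometry, waveset,
                               center_freq = 5, sampling_freq = 20,
                               sound_speed = 1540,
                               decorrelation_rate = 0, noise_sd = 0,
                               seed = 1, frames = NULL, state = NULL,
                               pulse_sigma = NULL, elem_width = NULL) {
  stopifnot(inherits(field, "wall_field"),
            inherits(scatterers, "scatterer_field"),
            inherits(geometry, "curved_array"),
            inherits(waveset, "diverging_wave_set"))
  if (sampling_freq < 2 * center_freq)
    stop("sampling_freq < 2 x center_freq: RF would alias")
  if (decorrelation_rate < 0 || decorrelation_rate >= 1)
    stop("decorrelation_rate must be in [0, 1)")
  if (is.null(frames)) frames <- seq_along(field$times)
  if (!is.null(seed)) set.seed(derive_seed(seed, "rf-render"))
  sigma <- pulse_sigma %||% (0.5 / center_freq)
  if (is.null(elem_width)) elem_width <- 0.9 * geometry$pitch
  c_mm_us <- sound_speed / 1000
  pos <- if (is.null(state)) scatterers$positions else state
  na <- waveset$n_transmits; ne <- geometry$n_elements
  xc <- field_centered_lateral(field, pos$lateral)

  # recorded time window: per-scatterer min/max round trip plus motion and
  # pulse-support padding
  zpad <- 0.8 # mm motion headroom
  d_src <- sqrt(outer(xc, waveset$source_x, "-")^2 +
                outer(pos$axial, waveset$source_z, "-")^2)
  d_el <- sqrt(outer(xc, geometry$element_x, "-")^2 +
               outer(pos$axial, geometry$element_z, "-")^2)
  rt <- range(apply(d_src, 1, min) + apply(d_el, 1, min),
              apply(d_src, 1, max) + apply(d_el, 1, max))
  t_lo <- (rt[1] - 2 * zpad) / c_mm_us - 5 * sigma
  t_hi <- (rt[2] + 2 * zpad) / c_mm_us + 5 * sigma
  t0 <- t_lo
  n_samp <- ceiling((t_hi - t_lo) * sampling_freq) + 1

  nfr <- length(frames)
  data <- array(0, c(nfr * na, ne, n_samp))
  sched <- data.frame(frame = seq_len(nfr * na),
                      angle = rep(waveset$angles, nfr),
                      field_frame = rep(frames, each = na))
  ant <- pos$wall == "anterior"
  th <- scatterers$wall_thickness
  z_ant <- field$params$anterior_depth
  z_post <- field$params$posterior_depth
  lat_b <- scatterers$bounds$lateral
  for (i in seq_len(nfr)) {
    f <- frames[i]
    if (decorrelation_rate > 0) {
      repl <- runif(nrow(pos)) < decorrelation_rate
      if (any(repl)) {
        pos$lateral[repl] <- runif(sum(repl), lat_b[1], lat_b[2])
        z0 <- ifelse(ant[repl], z_ant, z_post)
        pos$axial[repl] <- runif(sum(repl), z0 - th / 2, z0 + th / 2)
        xc <- field_centered_lateral(field, pos$lateral)
      }
    }
    dz <- numeric(nrow(pos))
    if (any(ant)) dz[ant] <- field_disp_at(field, "anterior", pos$lateral[ant], f)
    if (any(!ant)) dz[!ant] <- field_disp_at(field, "posterior", pos$lateral[!ant], f)
    fr <- cpp_render_frame(xc, pos$axial + dz / 1000, pos$amplitude,
                           geometry$element_x, geometry$element_z,
                           waveset$source_x, waveset$source_z,
                           c_mm_us, sampling_freq, center_freq,
                           sigma, t0, as.integer(n_samp),
                           geometry$radius, elem_width)
    for (a in seq_len(na))
      data[(i - 1) * na + a, , ] <- t(fr[, , a])
  }
  if (noise_sd > 0)
    data <- data + array(rnorm(length(data), 0, noise_sd), dim(data))
  structure(list(data = data, sampling_freq = sampling_freq,
                 center_freq = center_freq, sound_speed = sound_speed,
                 frame_rate = field$frame_rate, t0_us = t0,
                 transmit_schedule = sched, pulse_sigma = sigma,
                 state = pos),
            class = "rf_series")
}

#' @export
print.rf_series <- function(x, ...) {
  d <- dim(x$data)
  cat("<rf_series>", d[1], "transmit frames x", d[2], "elements x", d[3],
      "samples @", x$sampling_freq, "MHz; f0", x$center_freq, "MHz\n")
  invisible(x)
}

#' Render, beamform and compound a whole acquisition in chunks
#'
#' Convenience pipeline over [render_rf_sequence()], [das_beamform()] and
#' [compound()] that processes the acquisition in frame chunks so the raw
#' channel data never has to be held in memory at once. Scatterer
#' decorrelation state and the RNG stream carry across chunks, so the result
#' is identical to a single-call render.
#'
#' @inheritParams render_rf_sequence
#' @inheritParams das_beamform
#' @param grid a `bf_grid` (see [grid_for_field()]).
#' @param chunk frames per chunk.
#' @return A compounded `bf_series` covering every field frame.
#' @export
acquire_bf <- function(field, scatterers, geometry, waveset, grid,
                       center_freq = 5, sampling_freq = 20,
                       sound_speed = 1540, decorrelation_rate = 0,
                       noise_sd = 0, seed = 1, f_number = 1.5,
                       apodization = "hann", chunk = 64) {
  set.seed(derive_seed(seed, "rf-render"))
  nfr <- length(field$times)
  nd <- length(grid$depths); nl <- length(grid$line_angles_deg)
  out <- array(0, c(nfr, nd, nl))
  state <- NULL
  template <- NULL
  for (lo in seq(1, nfr, by = chunk)) {
    hi <- min(lo + chunk - 1, nfr)
    rf <- render_rf_sequence(field, scatterers, geometry, waveset,
                             center_freq, sampling_freq, sound_speed,
                             decorrelation_rate, noise_sd, seed = NULL,
                             frames = lo:hi, state = state)
    state <- rf$state
    per_angle <- das_beamform(rf, geometry, waveset, grid, f_number,
                              apodization)
    cp <- compound(per_angle)
    out[lo:hi, , ] <- cp$data
    template <- cp
  }
  template$data <- out
  template$field_frames <- seq_len(nfr)
  template
}

#' Directly synthesized speckle A-line series
#'
#' Fast-path generator of a beamformed-like series without diffraction
#' modeling: each scanline is an independent 1-D speckle signal on a depth
#' grid, built from point scatterers with a Gaussian envelope and a two-way
#' carrier at `2 / lambda`, rigidly advected by the phantom wall
#' displacement at that lateral position. Out-of-plane motion is again
#' amplitude-preserving random scatterer replacement. Useful for exercising
#' the tracker at scales where full RF rendering is unnecessary.
#'
#' @param field a `wall_field`. @param wall which wall the band follows.
#' @param n_lines number of lateral positions (taken from the field grid).
#' @param band mm of speckle band (centered on the resting wall).
#' @param dz mm depth step; default lambda/8.
#' @param density scatterers per mm of band depth per line.
#' @param center_freq MHz. @param sound_speed m/s.
#' @param decorrelation_rate fraction of scatterers replaced per frame.
#' @param noise_sd additive white noise SD (signal units).
#' @param seed integer seed.
#' @return A `bf_series` (compounded = NA; synthetic A-lines).
#' @export
render_speckle_lines <- function(field, wall = c("posterior", "anterior"),
                                 n_lines = NULL, band = 6, dz = NULL,
                                 density = 12, center_freq = 5,
                                 sound_speed = 1540,
                                 decorrelation_rate = 0, noise_sd = 0,
                                 seed = 1) {
  wall <- match.arg(wall)
  set.seed(derive_seed(seed, "speckle-lines"))
  lambda <- sound_speed / 1000 / center_freq
  if (is.null(dz)) dz <- lambda / 8
  sigma_z <- sound_speed / 1000 * (0.5 / center_freq) / 2
  z_w <- if (wall == "posterior") field$params$posterior_depth else
    field$params$anterior_depth
  lat <- field$lateral_positions
  if (!is.null(n_lines) && n_lines != length(lat))
    lat <- seq(min(lat), max(lat), length.out = n_lines)
  pad <- 0.8
  zgrid <- seq(z_w - band / 2 - pad, z_w + band / 2 + pad, by = dz)
  nfr <- length(field$times)
  nz <- length(zgrid)
  out <- array(0, c(nfr, nz, length(lat)))
  n_sc <- round(density * band)
  for (j in seq_along(lat)) {
    zi <- runif(n_sc, z_w - band / 2, z_w + band / 2)
    ai <- rnorm(n_sc)
    disp <- field_disp_at_series(field, wall, lat[j]) / 1000 # mm per frame
    if (decorrelation_rate == 0) {
      out[, , j] <- t(cpp_speckle_line(zgrid, zi, ai, disp, lambda, sigma_z))
    } else {
      for (f in seq_len(nfr)) {
        repl <- runif(n_sc) < decorrelation_rate
        if (any(repl)) zi[repl] <- runif(sum(repl), z_w - band / 2, z_w + band / 2)
        out[f, , j] <- cpp_speckle_line(zgrid, zi, ai, disp[f], lambda, sigma_z)
      }
    }
  }
  if (noise_sd > 0)
    out <- out + array(rnorm(length(out), 0, noise_sd), dim(out))
  structure(list(data = out, depths = zgrid,
                 line_angles_deg = seq_along(lat), # nominal
                 lateral_mm = lat,
                 frame_rate = field$frame_rate, angle = NA_real_,
                 center_freq = center_freq, sound_speed = sound_speed,
                 compounded = NA, is_envelope = FALSE,
                 wall_contour = rep(z_w, length(lat))),
            class = "bf_series")
}

# Displacement time series (um) of one wall at a single lateral position.
field_disp_at_series <- function(field, wall, lateral) {
  m <- if (wall == "anterior") field$anterior_disp else field$posterior_disp
  i <- findInterval(lateral, field$lateral_positions,
                    all.inside = TRUE)
  x0 <- field$lateral_positions[i]; x1 <- field$lateral_positions[i + 1]
  w <- if (x1 > x0) (lateral - x0) / (x1 - x0) else 0
  (1 - w) * m[i, ] + w * m[i + 1, ]
}
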
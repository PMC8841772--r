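#' Parametric systolic wall-velocity pulse
#'
#' Closed-form single-cycle wall-velocity waveform used by the phantom: a
#' rising limb (raised-cosine by default, or linear) from the pulse foot to
#' the systolic peak over `rise_time`, followed by an exponential decay with
#' time constant `decay_time`. For both rise shapes the 50% upstroke crossing
#' is analytically `foot_time + rise_time / 2`, which makes the systolic-foot
#' detector directly testable against a known answer.
#'
#' @param foot_time ms, time of the pulse foot (waveform is zero before it).
#' @param peak_velocity mm/s at the systolic peak.
#' @param rise_time ms, foot-to-peak duration (> 0).
#' @param decay_time ms, exponential decay constant after the peak.
#' @param n_samples number of samples to generate.
#' @param frame_rate Hz, sampling rate of the waveform.
#' @param shape `"cosine"` (raised-cosine rise) or `"linear"`.
#' @param heart_rate beats/min; cycles repeat with period `60000/heart_rate` ms.
#' @param n_cycles number of cycles to superpose.
#' @return Numeric vector of velocities (mm/s) sampled at
#'   `t = (0:(n_samples-1)) * 1000 / frame_rate` ms.
#' @seealso [pulse_upstroke_time()] for the analytic 50% crossing.
#' @export
generate_pulse_waveform <- function(foot_time, peak_velocity, rise_time,
                                    decay_time, n_samples, frame_rate,
                                    shape = c("cosine", "linear"),
                                    heart_rate = 60, n_cycles = 1) {
  shape <- match.arg(shape)
  if (rise_time <= 0) stop("rise_time must be positive")
  if (frame_rate <= 0) stop("frame_rate must be positive")
  if (decay_time <= 0) stop("decay_time must be positive")
  t <- (seq_len(n_samples) - 1) * 1000 / frame_rate
  if (foot_time < 0 || foot_time > max(t))
    stop("foot_time must lie within the generated trace")
  pulse_velocity_at(t, foot_time, peak_velocity, rise_time, decay_time,
                    shape, 60000 / heart_rate, n_cycles)
}

# Velocity (mm/s) at arbitrary times (ms); vectorized closed form.
# With a finite period each cycle is self-contained: the systolic lobe
# (rise + exponential decay) is followed by a shallow raised-cosine
# diastolic recoil lobe sized so the cycle's displacement integral closes
# exactly to zero (the wall returns to its diastolic position, as an
# elastic vessel must). With period = Inf the pulse is a single transient
# with no recoil.
recoil_params <- function(peak, rise, decay, period) {
  u0 <- rise + decay                # recoil begins as the decay fades
  if (!is.finite(period) || period <= u0 + 1e-6)
    return(NULL)
  L <- period - u0
  area_pos <- peak * rise / 2 +
    peak * decay * (1 - exp(-(period - rise) / decay))
  list(u0 = u0, L = L, R = 2 * area_pos / L)
}

pulse_velocity_at <- function(t, foot_time, peak, rise, decay,
                              shape = "cosine", period = Inf, n_cycles = 1) {
  v <- numeric(length(t))
  rc <- recoil_params(peak, rise, decay, period)
  for (k in seq_len(n_cycles) - 1) {
    u <- t - foot_time - if (k == 0) 0 else k * period
    if (is.finite(period)) u[u >= period] <- -1 # outside this cycle
    risen <- u >= 0 & u <= rise
    if (shape == "cosine") {
      v[risen] <- v[risen] + peak * (1 - cos(pi * u[risen] / rise)) / 2
    } else {
      v[risen] <- v[risen] + peak * u[risen] / rise
    }
    post <- u > rise
    v[post] <- v[post] + peak * exp(-(u[post] - rise) / decay)
    if (!is.null(rc)) {
      rec <- u > rc$u0
      v[rec] <- v[rec] -
        rc$R * (1 - cos(2 * pi * (u[rec] - rc$u0) / rc$L)) / 2
    }
  }
  v
}

# Closed-form time integral of the pulse: displacement in um when peak is
# mm/s and times are ms (mm/s * ms = um). Zero at every cycle boundary when
# the period is finite (recoil closes the cycle).
pulse_displacement_at <- function(t, foot_time, peak, rise, decay,
                                  shape = "cosine", period = Inf,
                                  n_cycles = 1) {
  d <- numeric(length(t))
  d_rise <- peak * rise / 2
  rc <- recoil_params(peak, rise, decay, period)
  for (k in seq_len(n_cycles) - 1) {
    u <- t - foot_time - if (k == 0) 0 else k * period
    if (is.finite(period)) u[u >= period] <- -1 # cycle closed: contributes 0
    risen <- u >= 0 & u <= rise
    if (shape == "cosine") {
      d[risen] <- d[risen] +
        peak * (u[risen] - (rise / pi) * sin(pi * u[risen] / rise)) / 2
    } else {
      d[risen] <- d[risen] + peak * u[risen]^2 / (2 * rise)
    }
    post <- u > rise
    d[post] <- d[post] + d_rise +
      peak * decay * (1 - exp(-(u[post] - rise) / decay))
    if (!is.null(rc)) {
      rec <- u > rc$u0
      ur <- u[rec] - rc$u0
      d[rec] <- d[rec] -
        rc$R * (ur - (rc$L / (2 * pi)) * sin(2 * pi * ur / rc$L)) / 2
    }
  }
  d
}

#' Analytic fractional-upstroke crossing time of the phantom pulse
#'
#' For both supported rise shapes the velocity rises monotonically from 0 to
#' the peak, so the time at which it first reaches `fraction * peak` has a
#' closed form.
#'
#' @param foot_time ms. @param rise_time ms.
#' @param fraction upstroke fraction in (0, 1); 0.5 is the systolic foot
#'   marker used throughout.
#' @param shape rise shape, as in [generate_pulse_waveform()].
#' @return Crossing time in ms.
#' @export
pulse_upstroke_time <- function(foot_time, rise_time, fraction = 0.5,
                                shape = c("cosine", "linear")) {
  shape <- match.arg(shape)
  stopifnot(fraction > 0, fraction < 1)
  if (shape == "cosine")
    foot_time + rise_time * acos(1 - 2 * fraction) / pi
  else
    foot_time + rise_time * fraction
}

#' Ground-truth propagating wall-displacement field
#'
#' Generates the kinematic ground truth of a straight vessel segment whose
#' walls distend under a pulse wave travelling at `pwv_true`: the wall
#' velocity waveform at lateral position `x` is the closed-form pulse delayed
#' by `x / pwv_true`, and displacement is its exact time integral (no
#' numerical quadrature), so the pure-delay property holds analytically.
#' Half of the lumen distension is assigned to each wall: the posterior wall
#' moves deeper (+), the anterior wall moves shallower (-).
#'
#' @param pwv_true m/s, prescribed pulse wave velocity (> 0).
#' @param segment_length mm of imaged vessel.
#' @param n_positions lateral sample count along the vessel.
#' @param frame_rate Hz (>= 500 Hz recommended: the transit time across the
#'   segment must span at least two frame intervals to be resolvable).
#' @param duration s of acquisition.
#' @param n_cycles cardiac cycles within `duration`.
#' @param noise_sd um of additive white displacement noise per wall.
#' @param seed integer; noise sub-stream is derived from it.
#' @param heart_rate beats/min.
#' @param foot_time ms of the first pulse foot at the near end.
#' @param peak_velocity mm/s lumen-distension velocity peak (each wall gets
#'   half).
#' @param rise_time,decay_time ms, pulse shape parameters.
#' @param shape rise shape.
#' @param anterior_depth,posterior_depth mm, resting wall depths (used when
#'   the field is imaged).
#' @return A `wall_field` object: lateral positions (mm), times (ms),
#'   anterior/posterior displacement matrices (um, positions x times),
#'   ground-truth foot and 50%-upstroke time tables (positions x cycles), and
#'   the generating parameters.
#' @export
generate_wall_displacement_field <- function(pwv_true, segment_length = 60,
                                             n_positions = 64,
                                             frame_rate = 1000,
                                             duration = 3.0, n_cycles = 3,
                                             noise_sd = 0, seed = 1,
                                             heart_rate = 60,
                                             foot_time = 150,
                                             peak_velocity = 5,
                                             rise_time = 60,
                                             decay_time = 150,
                                             shape = "cosine",
                                             anterior_depth = 55,
                                             posterior_depth = 75) {
  if (pwv_true <= 0) stop("pwv_true must be positive")
  period <- 60000 / heart_rate
  if (duration * 1000 < n_cycles * period)
    stop("duration must cover n_cycles cardiac cycles")
  transit_ms <- segment_length / pwv_true # pwv in m/s == mm/ms
  if (transit_ms < 2 * 1000 / frame_rate)
    stop("segment transit time spans < 2 frame intervals; PWV is not ",
         "resolvable. Increase frame_rate or segment_length.")
  times <- seq(0, by = 1000 / frame_rate, length.out = round(duration * frame_rate))
  lat <- seq(0, segment_length, length.out = n_positions)
  delay <- lat / pwv_true # ms
  disp <- vapply(delay, function(d)
    pulse_displacement_at(times - d, foot_time, peak_velocity, rise_time,
                          decay_time, shape, period, n_cycles),
    numeric(length(times)))
  disp <- t(disp) # positions x times, um (lumen distension)
  ant <- -disp / 2
  post <- disp / 2
  if (noise_sd > 0) {
    set.seed(derive_seed(seed, "wall-noise"))
    ant <- ant + matrix(rnorm(length(ant), 0, noise_sd), nrow(ant))
    post <- post + matrix(rnorm(length(post), 0, noise_sd), nrow(post))
  }
  cyc <- seq_len(n_cycles) - 1
  foot_times <- outer(delay, cyc * period, "+") + foot_time
  t50 <- foot_times + (pulse_upstroke_time(0, rise_time, 0.5, shape))
  structure(list(
    lateral_positions = lat, times = times,
    anterior_disp = ant, posterior_disp = post,
    pwv_true = pwv_true, frame_rate = frame_rate, n_cycles = n_cycles,
    foot_times = foot_times, t50_times = t50,
    params = list(segment_length = segment_length, heart_rate = heart_rate,
                  foot_time = foot_time, peak_velocity = peak_velocity,
                  rise_time = rise_time, decay_time = decay_time,
                  shape = shape, noise_sd = noise_sd, seed = seed,
                  anterior_depth = anterior_depth,
                  posterior_depth = posterior_depth)),
    class = "wall_field")
}

#' @export
print.wall_field <- function(x, ...) {
  cat("<wall_field> pwv_true =", x$pwv_true, "m/s,",
      length(x$lateral_positions), "positions x", length(x$times), "frames @",
      x$frame_rate, "Hz,", x$n_cycles, "cycles\n")
  invisible(x)
}

#' Random point-scatterer field for the vessel walls
#'
#' Places amplitude-weighted point scatterers uniformly inside the anterior
#' and/or posterior wall bands of a phantom (plus optional surrounding
#' tissue), the speckle substrate for tracking. Amplitudes are standard
#' normal (fully developed speckle in the many-scatterer limit).
#'
#' @param field a `wall_field`.
#' @param walls which wall bands to populate.
#' @param wall_thickness mm band thickness per wall.
#' @param density scatterers per mm^2 of band.
#' @param lateral_margin mm of extra band beyond the segment ends.
#' @param seed integer seed (sub-stream derived).
#' @return A `scatterer_field`: data.frame with lateral/axial position (mm),
#'   amplitude and wall label, plus the seed.
#' @export
generate_scatterers <- function(field, walls = c("posterior", "anterior"),
                                wall_thickness = 1.5, density = 11,
                                lateral_margin = 2, seed = 1) {
  walls <- match.arg(walls, c("posterior", "anterior"), several.ok = TRUE)
  set.seed(derive_seed(seed, "scatterers"))
  lat_lo <- min(field$lateral_positions) - lateral_margin
  lat_hi <- max(field$lateral_positions) + lateral_margin
  out <- do.call(rbind, lapply(walls, function(w) {
    z0 <- if (w == "anterior") field$params$anterior_depth else
      field$params$posterior_depth
    n <- round(density * (lat_hi - lat_lo) * wall_thickness)
    data.frame(
      lateral = runif(n, lat_lo, lat_hi),
      axial = runif(n, z0 - wall_thickness / 2, z0 + wall_thickness / 2),
      amplitude = rnorm(n),
      wall = w, stringsAsFactors = FALSE)
  }))
  structure(list(positions = out, seed = seed,
                 wall_thickness = wall_thickness,
                 bounds = list(lateral = c(lat_lo, lat_hi))),
            class = "scatterer_field")
}

#' Wrap explicit scatterer positions as a scatterer field
#'
#' For fixtures such as single point targets or custom layouts. Columns:
#' `lateral`, `axial` (mm), `amplitude`; an optional `wall` column
#' ("anterior"/"posterior") controls which wall's motion advects each
#' scatterer (default posterior).
#'
#' @param positions data.frame as above.
#' @param wall_thickness mm band used if decorrelation replacement is on.
#' @return A `scatterer_field`.
#' @export
as_scatterer_field <- function(positions, wall_thickness = 1.5) {
  stopifnot(all(c("lateral", "axial", "amplitude") %in% names(positions)))
  if (is.null(positions$wall)) positions$wall <- "posterior"
  structure(list(positions = positions, seed = NA_integer_,
                 wall_thickness = wall_thickness,
                 bounds = list(lateral = range(positions$lateral))),
            class = "scatterer_field")
}

#' Central pressure waveform surrogate
#'
#' Periodic arterial pressure trace with exact systolic/diastolic extrema:
#' a raised-cosine upstroke from `dbp` to `sbp` followed by an exponential
#' relaxation rescaled to return exactly to `dbp` at the end of each cycle,
#' emulating the calibrated central waveform an applanation tonometer would
#' deliver.
#'
#' @param sbp,dbp mmHg, systolic/diastolic pressure (`sbp > dbp > 0`).
#' @param heart_rate beats/min.
#' @param frame_rate Hz sampling rate.
#' @param duration s.
#' @param foot_time ms of the first foot.
#' @param rise_time ms foot-to-peak.
#' @param decay_time ms relaxation constant.
#' @return A `pressure_trace`: times (ms), pressure (mmHg), sbp, dbp,
#'   heart_rate.
#' @export
generate_pressure_trace <- function(sbp, dbp, heart_rate = 60,
                                    frame_rate = 1000, duration = 3.0,
                                    foot_time = 0, rise_time = 100,
                                    decay_time = 250) {
  if (!(sbp > dbp && dbp > 0)) stop("need sbp > dbp > 0")
  period <- 60000 / heart_rate
  if (rise_time >= period) stop("rise_time must be shorter than the period")
  t <- seq(0, by = 1000 / frame_rate, length.out = round(duration * frame_rate))
  u <- (t - foot_time) %% period
  w <- numeric(length(t))
  risen <- u <= rise_time
  w[risen] <- (1 - cos(pi * u[risen] / rise_time)) / 2
  post <- !risen
  e_end <- exp(-(period - rise_time) / decay_time)
  w[post] <- (exp(-(u[post] - rise_time) / decay_time) - e_end) / (1 - e_end)
  structure(list(times = t, pressure = dbp + (sbp - dbp) * w,
                 sbp = sbp, dbp = dbp, heart_rate = heart_rate,
                 foot_time = foot_time, frame_rate = frame_rate),
            class = "pressure_trace")
}

#' Detect pulse feet on a pressure trace
#'
#' Upward crossings of `dbp + fraction * (sbp - dbp)`; a trace starting at a
#' foot counts it.
#'
#' @param trace a `pressure_trace`.
#' @param fraction threshold fraction of pulse pressure above diastole.
#' @return Foot times in ms.
#' @export
pressure_feet <- function(trace, fraction = 0.05) {
  lev <- trace$dbp + fraction * (trace$sbp - trace$dbp)
  above <- trace$pressure >= lev
  idx <- which(diff(above) == 1) + 1
  if (above[1]) idx <- c(1, idx)
  trace$times[idx]
}

#' Synthetic risk-stratified cohort
#'
#' Draws a cohort of subjects in three cardiovascular risk strata (low /
#' intermediate / high 10-year risk score bands). Within each stratum the
#' directly-measured PWV (`ufcpwv`) and the distensibility-derived PWV
#' (`bhpwv`) are drawn as a correlated bivariate normal (correlation
#' `latent_cor`), so agreement statistics on the cohort have known expected
#' behavior. Diameters are generated self-consistently: the systolic
#' diameter is derived from the subject's `bhpwv`, pulse pressure and
#' diastolic diameter through the Bramwell-Hill relation, so recomputing the
#' theoretical PWV from the tabulated diameters and pressures reproduces the
#' `bhpwv` column.
#'
#' Default group means/SDs are the reference operating point of the method's
#' feasibility cohort: ufcPWV 5.3 +/- 1.1, 8.3 +/- 3.1, 10.8 +/- 2.5 m/s and
#' theoretical PWV 5.1 +/- 0.9, 7.7 +/- 2.0, 9.8 +/- 2.5 m/s for the low /
#' intermediate / high groups, with sizes 31 / 22 / 16.
#'
#' @param n_per_group integer vector (low, intermediate, high), each >= 2.
#' @param means,sds m/s, per-group mean/SD of `ufcpwv`.
#' @param bh_means,bh_sds m/s, per-group mean/SD of `bhpwv`.
#' @param latent_cor within-group correlation between the two PWV measures.
#' @param sbp_means,dbp_means mmHg per-group blood-pressure means.
#' @param bp_sd mmHg SD of either pressure.
#' @param seed integer seed.
#' @return A data.frame (`cohort_table`) with columns id, frs, group,
#'   ufcpwv, bhpwv, sbp, dbp, diastolic_diameter, systolic_diameter.
#' @export
generate_cohort <- function(n_per_group = c(low = 31, intermediate = 22, high = 16),
                            means = c(5.3, 8.3, 10.8),
                            sds = c(1.1, 3.1, 2.5),
                            bh_means = c(5.1, 7.7, 9.8),
                            bh_sds = c(0.9, 2.0, 2.5),
                            latent_cor = 0.85,
                            sbp_means = c(124.7, 128.8, 127.0),
                            dbp_means = c(74.9, 78.5, 76.1),
                            bp_sd = 12, seed = 1) {
  if (any(n_per_group < 2)) stop("each group needs at least 2 subjects")
  if (any(sds < 0) || any(bh_sds < 0)) stop("sds must be non-negative")
  set.seed(derive_seed(seed, "cohort"))
  groups <- c("low", "intermediate", "high")
  frs_lo <- c(0, 10, 20); frs_hi <- c(10, 20, 45)
  rows <- lapply(1:3, function(g) {
    n <- n_per_group[g]
    z1 <- rnorm(n); z2 <- rnorm(n)
    ufc <- means[g] + sds[g] * z1
    bh <- bh_means[g] + bh_sds[g] *
      (latent_cor * z1 + sqrt(1 - latent_cor^2) * z2)
    ufc <- pmax(ufc, 0.5); bh <- pmax(bh, 0.5)
    frs <- runif(n, frs_lo[g], frs_hi[g])
    if (g == 1) frs <- pmin(frs, 10 - 1e-6)
    sbp <- rnorm(n, sbp_means[g], bp_sd)
    dbp <- pmin(rnorm(n, dbp_means[g], bp_sd * 0.8), sbp - 10)
    dd <- rnorm(n, 18, 1.5)
    ad <- area_from_diameter(dd)
    da <- ad * (sbp - dbp) * MMHG_TO_PA / (1060 * bh^2)
    sdm <- 10 * 2 * sqrt((ad + da) / pi)
    data.frame(frs = frs, group = groups[g], ufcpwv = ufc, bhpwv = bh,
               sbp = sbp, dbp = dbp, diastolic_diameter = dd,
               systolic_diameter = sdm, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- cbind(id = sprintf("S%03d", seq_len(nrow(out))), out)
  out$group <- factor(out$group, levels = groups)
  class(out) <- c("cohort_table", "data.frame")
  out
}
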
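#' Curved-array transducer geometry
#'
#' Element centers are spaced by `pitch` of arc length along a circle of the
#' stated curvature radius. Coordinates: x lateral (mm), z depth into the
#' body (mm); the central point of the array surface is the origin and the
#' curvature center sits at (0, -radius). The exact element count, radius
#' and pitch of clinical convex probes vary; the defaults are generic
#' convex-array values.
#'
#' @param n_elements number of elements (>= 2).
#' @param radius mm, curvature radius.
#' @param pitch mm, arc length between adjacent element centers.
#' @param jitter fraction of the pitch (in `[0, 0.5)`) by which interior
#'   element positions are aperiodically displaced along the arc, using a
#'   fixed golden-ratio sequence (deterministic, no RNG). Zero (the
#'   default) gives a strictly periodic array. Aperiodic spacing is the
#'   standard remedy when a sparse aperture (pitch of several wavelengths)
#'   would otherwise form coherent grating-lobe images of off-axis
#'   structures.
#' @return A `curved_array` with element angles (rad) and positions.
#' @export
make_geometry <- function(n_elements = 128, radius = 60, pitch = 0.6,
                          jitter = 0) {
  stopifnot(n_elements >= 2, radius > 0, pitch > 0,
            jitter >= 0, jitter < 0.5)
  arc <- (n_elements - 1) * pitch
  if (arc / radius >= pi) stop("aperture arc angle >= pi: non-physical array")
  s <- (seq_len(n_elements) - 1 - (n_elements - 1) / 2) * pitch
  if (jitter > 0 && n_elements > 2) {
    g <- (sqrt(5) - 1) / 2
    u <- (seq_len(n_elements) * g) %% 1 # low-discrepancy in [0, 1)
    off <- (u - 0.5) * 2 * jitter * pitch
    off[c(1, n_elements)] <- 0 # keep the aperture extent exact
    s <- s + off
  }
  phi <- s / radius
  structure(list(
    n_elements = n_elements, radius = radius, pitch = pitch,
    jitter = jitter,
    element_angles = phi,
    element_x = radius * sin(phi),
    element_z = radius * cos(phi) - radius),
    class = "curved_array")
}

#' @export
print.curved_array <- function(x, ...) {
  cat("<curved_array>", x$n_elements, "elements, radius", x$radius,
      "mm, pitch", x$pitch, "mm, aperture arc",
      round((x$n_elements - 1) * x$pitch, 2), "mm\n")
  invisible(x)
}

#' Diverging-wave virtual sources
#'
#' Each transmit is an unfocused diverging wave whose virtual point source
#' lies on the circle of the array's curvature radius, at angular offset
#' theta from the array center; theta = 0 puts the source at the central
#' point of the array surface. Transmit time zero is the instant the
#' wavefront leaves the virtual source.
#'
#' @param geometry a `curved_array`.
#' @param angles degrees; default three tilts in linear increments from -12
#'   to +12.
#' @return A `diverging_wave_set` with source positions per angle.
#' @export
virtual_sources <- function(geometry, angles = c(-12, 0, 12)) {
  stopifnot(inherits(geometry, "curved_array"), all(abs(angles) < 90))
  th <- angles * pi / 180
  R <- geometry$radius
  structure(list(
    angles = angles, n_transmits = length(angles),
    source_x = R * sin(th),
    source_z = R * cos(th) - R),
    class = "diverging_wave_set")
}

#' Polar beamforming grid
#'
#' Pixels along scanlines emanating from the curvature center: a scanline at
#' angle alpha (rad) and depth d (mm from the array surface) sits at
#' `((R + d) sin(alpha), (R + d) cos(alpha) - R)`. The grid is rectangular
#' in (depth, line angle).
#'
#' @param geometry a `curved_array`.
#' @param depths mm along the scanline, strictly increasing.
#' @param line_angles_deg scanline angles in degrees, strictly increasing.
#' @param lateral_mm optional lateral coordinate (mm) to report per line
#'   (e.g., the straight-vessel intersection abscissa); defaults to the arc
#'   length at the mean depth.
#' @return A `bf_grid`.
#' @export
make_grid <- function(geometry, depths, line_angles_deg, lateral_mm = NULL) {
  stopifnot(all(diff(depths) > 0), all(diff(line_angles_deg) > 0))
  al <- line_angles_deg * pi / 180
  R <- geometry$radius
  if (is.null(lateral_mm))
    lateral_mm <- al * (R + mean(depths))
  # pixel arrays, depth fastest (column-major image depth x line)
  px <- outer(depths + R, sin(al)); pz <- outer(depths + R, cos(al)) - R
  structure(list(depths = depths, line_angles_deg = line_angles_deg,
                 lateral_mm = lateral_mm, radius = R,
                 pix_x = as.numeric(px), pix_z = as.numeric(pz),
                 pix_depth = rep(depths, times = length(al))),
            class = "bf_grid")
}

#' Grid tailored to a phantom's imaged wall
#'
#' Chooses scanline angles whose straight-vessel intersections reproduce the
#' phantom's lateral positions (centered on the array axis) and a depth band
#' enclosing the wall contour plus motion headroom.
#'
#' @param geometry a `curved_array`. @param field a `wall_field`.
#' @param wall which wall the band encloses.
#' @param n_lines number of scanlines.
#' @param band mm of depth band around the resting wall contour.
#' @param dz mm depth step; default lambda/8 at `center_freq`.
#' @param center_freq MHz (used for the default dz).
#' @param sound_speed m/s.
#' @return A `bf_grid`.
#' @export
grid_for_field <- function(geometry, field, wall = c("posterior", "anterior"),
                           n_lines = 64, band = 5, dz = NULL,
                           center_freq = 5, sound_speed = 1540) {
  wall <- match.arg(wall)
  lambda <- sound_speed / 1000 / center_freq # mm
  if (is.null(dz)) dz <- lambda / 8
  z_w <- if (wall == "posterior") field$params$posterior_depth else
    field$params$anterior_depth
  lat <- field$lateral_positions
  x <- seq(min(lat), max(lat), length.out = n_lines) - mean(range(lat))
  al <- atan(x / (z_w + geometry$radius))
  d_w <- (z_w + geometry$radius) / cos(al) - geometry$radius
  pad <- 0.8 # mm headroom for wall motion
  depths <- seq(min(d_w) - band / 2 - pad, max(d_w) + band / 2 + pad, by = dz)
  g <- make_grid(geometry, depths, al * 180 / pi, lateral_mm = x + mean(range(lat)))
  g$wall <- wall
  g$wall_contour <- d_w # resting wall depth per line
  g
}

#' Delay-and-sum beamforming of diverging-wave RF data
#'
#' For every pixel, receive-element samples are read at the round-trip time
#' `(|source - pixel| + |pixel - element|) / c` (transmit time zero at the
#' virtual source, matching the renderer) with linear interpolation, and
#' summed over the elements inside the receive f-number aperture (Hann
#' apodized by default). Pixels mapping outside the recorded time window
#' contribute zero and are tallied in `out_of_range`.
#'
#' @param rf an `rf_series` from [render_rf_sequence()].
#' @param geometry,waveset the acquisition geometry used to record `rf`.
#' @param grid a `bf_grid`.
#' @param f_number receive f-number (aperture = depth / f_number).
#' @param apodization `"hann"` or `"none"`.
#' @param angles which transmit angles to beamform (default: all in `rf`).
#' @return A list of `bf_series`, one per transmit angle.
#' @export
das_beamform <- function(rf, geometry, waveset, grid, f_number = 1.5,
                         apodization = c("hann", "none"), angles = NULL) {
  apodization <- match.arg(apodization)
  stopifnot(inherits(rf, "rf_series"), inherits(grid, "bf_grid"))
  if (is.null(angles)) angles <- waveset$angles
  c_mm_us <- rf$sound_speed / 1000
  nd <- length(grid$depths); nl <- length(grid$line_angles_deg)
  al <- grid$line_angles_deg * pi / 180
  sin_al <- sin(al); cos_al <- cos(al)
  lapply(angles, function(ang) {
    a <- match(ang, waveset$angles)
    if (is.na(a)) stop("angle not in waveset: ", ang)
    sel <- which(rf$transmit_schedule$angle == ang)
    ff <- rf$transmit_schedule$field_frame[sel]
    out <- array(0, c(length(sel), nd, nl))
    oor <- 0
    for (i in seq_along(sel)) {
      r <- cpp_das_frame(t(rf$data[sel[i], , , drop = TRUE]),
                         geometry$element_x, geometry$element_z,
                         waveset$source_x[a], waveset$source_z[a],
                         grid$depths, sin_al, cos_al, grid$radius,
                         rf$sampling_freq, rf$t0_us, c_mm_us,
                         f_number, as.integer(apodization == "hann"))
      out[i, , ] <- matrix(r$image, nd, nl)
      oor <- oor + r$out_of_range
    }
    structure(list(data = out, depths = grid$depths,
                   line_angles_deg = grid$line_angles_deg,
                   lateral_mm = grid$lateral_mm, grid = grid,
                   field_frames = ff,
                   frame_rate = rf$frame_rate, angle = ang,
                   center_freq = rf$center_freq,
                   sound_speed = rf$sound_speed,
                   compounded = FALSE, is_envelope = FALSE,
                   out_of_range = oor),
              class = "bf_series")
  })
}

#' Coherent compounding of per-angle beamformed series
#'
#' Pre-envelope mean across the tilted transmits of each frame triplet.
#'
#' @param per_angle list of `bf_series` on identical grids with aligned
#'   frames.
#' @return A single compounded `bf_series`.
#' @export
compound <- function(per_angle) {
  stopifnot(length(per_angle) >= 1)
  ref <- per_angle[[1]]
  for (b in per_angle[-1]) {
    if (!isTRUE(all.equal(b$depths, ref$depths)) ||
        !isTRUE(all.equal(b$line_angles_deg, ref$line_angles_deg)))
      stop("grid mismatch between per-angle series")
    if (!identical(dim(b$data), dim(ref$data)))
      stop("frame count mismatch between per-angle series")
  }
  acc <- ref$data
  for (b in per_angle[-1]) acc <- acc + b$data
  out <- ref
  out$data <- acc / length(per_angle)
  out$compounded <- TRUE
  out$angle <- vapply(per_angle, `[[`, numeric(1), "angle")
  out
}

#' Envelope detection
#'
#' Per-scanline analytic-signal magnitude along depth.
#'
#' @param bf a real-valued `bf_series`.
#' @return A `bf_series` with non-negative envelope data.
#' @export
envelope <- function(bf) {
  stopifnot(inherits(bf, "bf_series"))
  out <- bf
  for (f in seq_len(dim(bf$data)[1]))
    out$data[f, , ] <- analytic_envelope(bf$data[f, , , drop = TRUE])
  out$is_envelope <- TRUE
  out
}

#' @export
print.bf_series <- function(x, ...) {
  d <- dim(x$data)
  cat("<bf_series>", d[1], "frames x", d[2], "depth samples x", d[3],
      "lines;", if (x$compounded) "compounded;" else
        paste0("angle ", x$angle, " deg;"),
      if (x$is_envelope) "envelope" else "RF", "\n")
  invisible(x)
}
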
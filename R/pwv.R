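#' Spatiotemporal wall-velocity map
#'
#' Temporal derivative of the tracked wall displacement at every lateral
#' position via a Savitzky-Golay digital differentiator (9 points, order 2
#' by default), producing the 2-D (position x time) wall-velocity map from
#' which pulse propagation is read. Edge frames are handled by the
#' polynomial boundary fits of the Savitzky-Golay filter matrix.
#'
#' @param track a `wall_track`.
#' @param sg_points odd filter length (frames).
#' @param sg_order polynomial order (< `sg_points`).
#' @return A `velocity_map`: velocity (mm/s, positions x times), lateral
#'   positions (mm), times (ms), frame rate.
#' @export
wall_velocity <- function(track, sg_points = 9, sg_order = 2) {
  stopifnot(inherits(track, "wall_track"), sg_order < sg_points,
            sg_points %% 2 == 1)
  nfr <- ncol(track$displacement)
  if (nfr < sg_points) stop("track has fewer frames than sg_points")
  dt_ms <- 1000 / track$frame_rate
  # um/ms == mm/s
  v <- t(apply(track$displacement, 1, function(x)
    signal::sgolayfilt(x, p = sg_order, n = sg_points, m = 1, ts = dt_ms)))
  structure(list(lateral_positions = track$lateral_positions,
                 times = track$times, velocity = v,
                 frame_rate = track$frame_rate, wall = track$wall),
            class = "velocity_map")
}

#' @export
print.velocity_map <- function(x, ...) {
  cat("<velocity_map>", nrow(x$velocity), "positions x", ncol(x$velocity),
      "frames @", x$frame_rate, "Hz\n")
  invisible(x)
}

#' Detect cardiac cycle windows on a velocity map
#'
#' Prominence-based peak finding on the spatially averaged wall-velocity
#' trace; one window per systolic event, bounded by the midpoints between
#' adjacent peaks (and the trace ends).
#'
#' @param velocity_map a `velocity_map`.
#' @param expected_cycles if the found count differs, a warning reports it
#'   (processing proceeds with the found windows).
#' @param min_peak_frac minimum peak height as a fraction of the global
#'   maximum.
#' @return A data.frame with `start`, `end`, `peak_time` (ms) per cycle.
#' @export
detect_cycles <- function(velocity_map, expected_cycles = NULL,
                          min_peak_frac = 0.4) {
  vbar <- colMeans(velocity_map$velocity)
  t <- velocity_map$times
  # systolic peaks are at least ~250 ms apart at physiologic heart rates
  pk <- pracma::findpeaks(vbar, minpeakheight = min_peak_frac * max(vbar),
                          minpeakdistance = max(3, round(0.25 * velocity_map$frame_rate)))
  if (is.null(pk)) stop("no systolic peaks found on the mean velocity trace")
  ip <- sort(pk[, 2])
  if (!is.null(expected_cycles) && length(ip) != expected_cycles)
    warning("found ", length(ip), " cycle(s), expected ", expected_cycles)
  bounds <- c(t[1], if (length(ip) > 1) (t[ip[-length(ip)]] + t[ip[-1]]) / 2,
              t[length(t)])
  data.frame(start = bounds[-length(bounds)], end = bounds[-1],
             peak_time = t[ip])
}

#' Detect fractional-upstroke arrival times (systolic foot markers)
#'
#' Within one cycle window and per lateral position: finds the systolic
#' velocity peak, the preceding baseline (a robust 5th-percentile floor of
#' the pre-peak trace, which on noisy data estimates the pre-upstroke
#' minimum without the downward bias of a raw minimum), and the first
#' sustained time the velocity crosses
#' `baseline + fraction * (peak - baseline)`, refined by linear
#' interpolation between the bracketing frames. Positions whose peak
#' velocity falls below `noise_floor_frac` of the map's global peak are
#' flagged invalid.
#'
#' @param velocity_map a `velocity_map`.
#' @param cycle_window `c(start, end)` ms (one row of [detect_cycles()]).
#' @param fraction upstroke fraction in (0, 1); 0.5 marks the systolic foot.
#' @param noise_floor_frac invalidation threshold for weak positions.
#' @return An `upstroke_markers` data.frame: position (mm), arrival_time
#'   (ms), peak_velocity (mm/s), valid flag.
#' @export
detect_upstrokes <- function(velocity_map, cycle_window, fraction = 0.5,
                             noise_floor_frac = 0.1) {
  stopifnot(fraction > 0, fraction < 1)
  if (is.data.frame(cycle_window))
    cycle_window <- c(cycle_window$start[1], cycle_window$end[1])
  t <- velocity_map$times
  sel <- which(t >= cycle_window[1] & t <= cycle_window[2])
  if (length(sel) < 3) stop("cycle window too short")
  floor_v <- noise_floor_frac * max(velocity_map$velocity)
  res <- lapply(seq_len(nrow(velocity_map$velocity)), function(i) {
    v <- velocity_map$velocity[i, sel]
    ip <- which.max(v)
    peak <- v[ip]
    if (!is.finite(peak) || peak < floor_v)
      return(c(NA_real_, peak, FALSE))
    # pre-upstroke baseline: a robust (5th percentile) floor of the trace
    # before the peak, insensitive to single-frame noise excursions
    pre <- v[1:ip]
    base <- if (ip > 4) unname(quantile(pre, 0.05, names = FALSE)) else min(pre)
    ib <- if (ip == 1) 1 else which.min(pre)
    level <- base + fraction * (peak - base)
    # first sustained (two-frame) crossing after the pre-peak minimum
    seg <- v[ib:ip]
    above <- seg >= level
    sustained <- which(above & c(above[-1], TRUE))
    if (!length(sustained)) return(c(NA_real_, peak, FALSE))
    k <- ib + sustained[1] - 1
    if (k == 1) return(c(t[sel[1]], peak, TRUE))
    # linear interpolation between bracketing frames
    t0 <- t[sel[k - 1]]; t1 <- t[sel[k]]
    v0 <- v[k - 1]; v1 <- v[k]
    tc <- if (v1 > v0) t0 + (level - v0) / (v1 - v0) * (t1 - t0) else t1
    c(tc, peak, TRUE)
  })
  m <- do.call(rbind, res)
  structure(data.frame(position = velocity_map$lateral_positions,
                       arrival_time = m[, 1], peak_velocity = m[, 2],
                       valid = as.logical(m[, 3])),
            class = c("upstroke_markers", "data.frame"))
}

#' Time-distance regression of upstroke markers: the PWV estimate
#'
#' Ordinary least squares of arrival time on distance along the vessel;
#' PWV (m/s) is the reciprocal of the fitted slope (ms/mm). The coefficient
#' of determination of the same fit gates reliability: estimates with
#' `r^2 < min_r2` (default 0.5) are rejected. Zero or negative fitted
#' slopes (retrograde or implausible propagation) are flagged and never
#' accepted. With `direction = "distance_on_time"` the regression is run
#' the other way and PWV is the slope directly; the two agree for clean
#' data and differ under noise (reciprocal-slope attenuation).
#'
#' @param markers an `upstroke_markers` data.frame (>= 3 valid positions).
#' @param min_r2 acceptance threshold on r^2.
#' @param direction which variable is regressed on which.
#' @return A `pwv_estimate`: slope (m/s), intercept (ms), r_squared,
#'   accepted flag, n_points.
#' @export
fit_pwv <- function(markers, min_r2 = 0.5,
                    direction = c("time_on_distance", "distance_on_time")) {
  direction <- match.arg(direction)
  ok <- !is.na(markers$arrival_time) & markers$valid
  if (sum(ok) < 3)
    return(structure(list(slope = NA_real_, intercept = NA_real_,
                          r_squared = NA_real_, accepted = FALSE,
                          n_points = sum(ok), reason = "fewer than 3 valid positions"),
                     class = "pwv_estimate"))
  x <- markers$position[ok]; y <- markers$arrival_time[ok]
  if (direction == "time_on_distance") {
    fit <- lm(y ~ x)
    b <- coef(fit)[2]
    pwv <- if (is.finite(b) && b != 0) 1 / b else NA_real_ # mm/ms == m/s
  } else {
    fit <- lm(x ~ y)
    pwv <- coef(fit)[2]
  }
  r2 <- suppressWarnings(summary(fit)$r.squared)
  plausible <- is.finite(pwv) && pwv > 0
  structure(list(slope = unname(pwv), intercept = unname(coef(fit)[1]),
                 r_squared = r2,
                 accepted = plausible && r2 >= min_r2,
                 n_points = sum(ok),
                 reason = if (!plausible) "non-positive slope"
                          else if (r2 < min_r2) "r_squared below threshold"
                          else NULL),
            class = "pwv_estimate")
}

#' Average per-cycle PWV estimates
#'
#' Mean over accepted cycles only; invalid overall if no cycle is accepted.
#'
#' @param per_cycle list of `pwv_estimate`s (>= 1).
#' @return A `pwv_estimate` with `mean_pwv`, `n_cycles_used`, `per_cycle`.
#' @export
average_cycles <- function(per_cycle) {
  if (!length(per_cycle)) stop("no per-cycle estimates supplied")
  acc <- vapply(per_cycle, function(e) isTRUE(e$accepted), logical(1))
  pwvs <- vapply(per_cycle, function(e) e$slope %||% NA_real_, numeric(1))
  structure(list(
    mean_pwv = if (any(acc)) mean(pwvs[acc]) else NA_real_,
    n_cycles_used = sum(acc),
    per_cycle = data.frame(cycle = seq_along(per_cycle), pwv = pwvs,
                           r_squared = vapply(per_cycle, `[[`, numeric(1), "r_squared"),
                           accepted = acc),
    accepted = any(acc),
    reason = if (!any(acc)) "no accepted cycles" else NULL),
    class = "pwv_estimate")
}

#' @export
print.pwv_estimate <- function(x, ...) {
  if (!is.null(x$per_cycle)) {
    cat("<pwv_estimate> mean PWV over", x$n_cycles_used, "accepted cycle(s):",
        round(x$mean_pwv, 3), "m/s\n")
    print(transform(x$per_cycle, pwv = round(pwv, 3),
                    r_squared = round(r_squared, 3)), row.names = FALSE)
  } else {
    cat("<pwv_estimate>", round(x$slope, 3), "m/s, r^2 =",
        round(x$r_squared, 3),
        if (x$accepted) "(accepted)" else paste0("(rejected: ", x$reason, ")"),
        "\n")
  }
  invisible(x)
}

#' End-to-end PWV estimation from a wall track
#'
#' Convenience chain: velocity map, cycle windows, per-cycle 50%-upstroke
#' markers and time-distance fits, and the cycle average.
#'
#' @param track a `wall_track`.
#' @param expected_cycles cycles to look for (warning if different).
#' @param fraction upstroke fraction. @param min_r2 acceptance gate.
#' @param sg_points,sg_order differentiator settings.
#' @param noise_floor_frac weak-position invalidation threshold.
#' @param direction regression direction, see [fit_pwv()].
#' @return A `pwv_estimate` (cycle average with per-cycle table).
#' @export
estimate_pwv <- function(track, expected_cycles = NULL, fraction = 0.5,
                         min_r2 = 0.5, sg_points = 9, sg_order = 2,
                         noise_floor_frac = 0.1,
                         direction = "time_on_distance") {
  vm <- wall_velocity(track, sg_points, sg_order)
  cyc <- detect_cycles(vm, expected_cycles)
  per <- lapply(seq_len(nrow(cyc)), function(i) {
    mk <- detect_upstrokes(vm, c(cyc$start[i], cyc$end[i]), fraction,
                           noise_floor_frac)
    fit_pwv(mk, min_r2, direction)
  })
  out <- average_cycles(per)
  out$cycles <- cyc
  out
}
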
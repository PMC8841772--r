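#' Speckle-tracking configuration
#'
#' Holds the 1-D cross-correlation tracking parameters. The operating point
#' mirrors standard ultrafast wall-tracking practice: a correlation window
#' of 8 wavelengths, a search range of 9 times the window, 90% window
#' overlap along depth and a reference-update correlation threshold of 0.9.
#'
#' @param center_freq MHz. @param sound_speed m/s.
#' @param dz mm, depth sample spacing of the series to be tracked.
#' @param window_lambda window length in wavelengths.
#' @param search_mult search-range length as a multiple of the window.
#' @param overlap fractional window overlap along depth, in (0, 1).
#' @param corr_threshold NCC threshold in (0, 1] below which the reference
#'   frame is updated.
#' @param subsample_method `"cosine"` (three-point cosine fit, the default
#'   for RF tracking: the correlation function of RF speckle oscillates at
#'   roughly the two-way carrier, which the cosine model fits with far less
#'   bias than a parabola), `"parabolic"`, or `"phase"` (carrier-phase
#'   refinement at the nominal `4*pi*dz/lambda` rad/sample; lowest bias when
#'   the beamformed carrier matches the nominal one exactly).
#' @return A `tracking_config` with window/search sizes in depth samples and
#'   the carrier frequency (rad/sample) used by the phase refinement.
#' @export
tracking_config <- function(center_freq = 5, sound_speed = 1540,
                            dz = NULL,
                            window_lambda = 8, search_mult = 9,
                            overlap = 0.9, corr_threshold = 0.9,
                            subsample_method = c("cosine", "parabolic",
                                                 "phase")) {
  subsample_method <- match.arg(subsample_method)
  stopifnot(overlap > 0, overlap < 1,
            corr_threshold > 0, corr_threshold <= 1)
  lambda <- sound_speed / 1000 / center_freq
  if (is.null(dz)) dz <- lambda / 8
  window <- max(8L, as.integer(round(window_lambda * lambda / dz)))
  search <- as.integer(round(search_mult * window))
  structure(list(lambda = lambda, dz = dz,
                 window_size = window, search_range = search,
                 max_lag = as.integer((search - window) %/% 2),
                 overlap = overlap, corr_threshold = corr_threshold,
                 subsample_method = subsample_method,
                 carrier_omega = 4 * pi * dz / lambda),
            class = "tracking_config")
}

# Subsample refinement of an NCC peak from the peak and its two neighbours.
subsample_peak <- function(cm, c0, cp, method = "parabolic") {
  den <- cm - 2 * c0 + cp
  if (method == "cosine") {
    # three-point cosine fit; falls back to parabolic when unstable
    arg <- (cm + cp) / (2 * c0)
    if (is.finite(arg) && abs(arg) < 1) {
      w <- acos(arg)
      th <- atan2(cm - cp, 2 * c0 * sin(w))
      return(-th / w)
    }
  }
  if (!is.finite(den) || den >= 0) return(0)
  d <- 0.5 * (cm - cp) / den
  max(min(d, 0.5), -0.5)
}

#' Normalized cross-correlation of a tracking window
#'
#' Computes the normalized cross-correlation (per-lag mean removal and
#' unit-energy normalization, so the coefficient is bounded in `[-1, 1]`)
#' of a reference window against a current segment over integer lags
#' `-max_lag..max_lag`, then refines the peak lag to subsample precision by
#' fitting the chosen interpolator to the peak and its two neighbours. The
#' current segment may equal the reference in length (overlap correlation)
#' or be longer (search segment; lag 0 aligns the window with its center).
#'
#' @param reference_segment,current_segment numeric vectors (equal length of
#'   at least 8 samples, or current longer by an even margin).
#' @param max_lag maximum integer lag (< reference length).
#' @param subsample_method `"parabolic"`, `"cosine"` or `"phase"` (the
#'   latter requires `carrier_omega`).
#' @param carrier_omega rad/sample frequency of the correlation function's
#'   carrier oscillation (`4*pi*dz/lambda` for RF sampled every `dz`); used
#'   only by the `"phase"` method, which falls back to cosine interpolation
#'   when the peak is too close to the lag boundary.
#' @return List with `lag` (samples, subsample-refined), `peak_coefficient`
#'   (NCC at the integer peak), `degenerate` flag (zero-variance window:
#'   coefficient 0, lag 0), and the full `ncc` vector.
#' @export
correlate_window <- function(reference_segment, current_segment, max_lag,
                             subsample_method = c("parabolic", "cosine",
                                                  "phase"),
                             carrier_omega = NULL) {
  subsample_method <- match.arg(subsample_method)
  if (subsample_method == "phase" && is.null(carrier_omega))
    stop("the phase method needs carrier_omega")
  n <- length(reference_segment)
  stopifnot(n >= 8, length(current_segment) >= n,
            max_lag < length(current_segment))
  if (var(reference_segment) == 0 || var(current_segment) == 0)
    return(list(lag = 0, peak_coefficient = 0, degenerate = TRUE,
                ncc = rep(0, 2 * max_lag + 1)))
  ncc <- cpp_ncc(reference_segment, current_segment, as.integer(max_lag),
                 min_overlap = max(8L, n %/% 2))
  if (all(is.na(ncc)))
    return(list(lag = 0, peak_coefficient = 0, degenerate = TRUE, ncc = ncc))
  k <- which.max(ncc)
  lag <- k - max_lag - 1
  delta <- 0
  refined <- ncc[k]
  if (k > 1 && k < length(ncc) && !is.na(ncc[k - 1]) && !is.na(ncc[k + 1]) &&
      ncc[k] < 1 - 1e-12) { # a perfect match is already at an integer lag
    if (subsample_method == "phase" && k > 2 && k < length(ncc) - 1 &&
        !anyNA(ncc[(k - 2):(k + 2)])) {
      # phase of the carrier oscillation of the correlation function at the
      # peak; Hann-weighted 5-point estimate suppresses the conjugate term
      wt <- c(0.25, 0.75, 1, 0.75, 0.25)
      C <- sum(wt * ncc[(k - 2):(k + 2)] * exp(-1i * carrier_omega * (-2:2)))
      delta <- max(min(-Arg(C) / carrier_omega, 1), -1)
    } else {
      delta <- subsample_peak(ncc[k - 1], ncc[k], ncc[k + 1],
                              if (subsample_method == "phase") "cosine"
                              else subsample_method)
    }
    refined <- peak_magnitude(ncc[k - 1], ncc[k], ncc[k + 1])
  }
  list(lag = lag + delta, peak_coefficient = ncc[k],
       peak_refined = refined, degenerate = FALSE, ncc = ncc)
}

# Subsample-refined peak magnitude of an NCC triplet.  On RF data the
# correlation function oscillates at the (two-way) carrier, so for shifts
# near a half-sample the integer-lattice maximum undershoots the true peak;
# a three-point cosine fit recovers the envelope amplitude.  Falls back to
# the parabolic peak value when the cosine model is ill-conditioned.
peak_magnitude <- function(cm, c0, cp) {
  if (c0 > 0) {
    arg <- (cm + cp) / (2 * c0)
    if (is.finite(arg) && abs(arg) < 1) {
      w <- acos(arg)
      if (sin(w) > 1e-6) {
        a <- sqrt(c0^2 + ((cm - cp) / (2 * sin(w)))^2)
        return(min(a, 1))
      }
    }
  }
  den <- cm - 2 * c0 + cp
  if (is.finite(den) && den < 0)
    return(min(max(c0 - (cm - cp)^2 / (8 * den), c0), 1))
  c0
}

#' Adaptive-reference-frame speckle tracking of wall displacement
#'
#' Tracks the accumulated axial displacement of one wall at every lateral
#' position (scanline) of a beamformed series by 1-D normalized
#' cross-correlation against a reference window. The running correlation
#' compared to the threshold is the subsample-refined peak magnitude of the
#' correlation function: on RF data the integer-lattice NCC dips at
#' half-sample shifts purely through sampling, and gating on the raw
#' lattice value would trigger spurious reference updates during every
#' systolic excursion. The reference is adaptive:
#' while the running peak correlation stays at or above
#' `config$corr_threshold`, displacement is the reference's base offset
#' plus the measured lag; when it drops below, the reference is replaced by
#' the current frame, the new reference inherits the last accepted absolute
#' displacement as its base offset (keeping displacement continuous), a
#' reference-update event is recorded, and the triggering frame's
#' displacement equals the inherited offset. Windows are Lagrangian: each
#' reference window is re-anchored at the wall contour advected by the
#' accumulated displacement. With `adaptive = FALSE` the first frame stays
#' the reference throughout (the drift-prone baseline the adaptive scheme
#' is designed to beat).
#'
#' @param series a `bf_series` (RF, not envelope) with >= 2 frames.
#' @param contour resting wall depth (mm): a scalar, a per-line vector, or
#'   `NULL` to use `series$wall_contour`.
#' @param config a [tracking_config()]; its `dz` must match the series.
#' @param adaptive update the reference adaptively (default) or keep frame 1.
#' @param lines subset of scanline indices to track (default: all).
#' @return A `wall_track`: `displacement` (um, positions x frames),
#'   `corr_coeff` (running NCC per accepted/triggering frame),
#'   `ref_updates` (list of frame indices per position), lateral positions
#'   (mm) and times (ms).
#' @export
arfd_track <- function(series, contour = NULL, config = tracking_config(),
                       adaptive = TRUE, lines = NULL) {
  stopifnot(inherits(series, "bf_series"))
  nfr <- dim(series$data)[1]
  if (nfr < 2) stop("series needs at least 2 frames")
  nz <- dim(series$data)[2]; nl <- dim(series$data)[3]
  dz <- series$depths[2] - series$depths[1]
  if (abs(dz - config$dz) > 1e-9)
    config <- tracking_config(series$center_freq, series$sound_speed, dz,
                              overlap = config$overlap,
                              corr_threshold = config$corr_threshold,
                              subsample_method = config$subsample_method)
  contour <- contour %||% series$wall_contour
  if (is.null(contour)) stop("no wall contour supplied")
  contour <- rep_len(contour, nl)
  if (is.null(lines)) lines <- seq_len(nl)
  w <- config$window_size
  max_lag <- min(config$max_lag, max(4L, (nz - w) %/% 2L))
  half_w <- w %/% 2

  disp <- matrix(NA_real_, length(lines), nfr)
  corr <- matrix(NA_real_, length(lines), nfr)
  updates <- vector("list", length(lines))
  degenerate_all <- TRUE
  for (li in seq_along(lines)) {
    l <- lines[li]
    anchor0 <- contour[l] # mm
    sig <- series$data[, , l] # frames x depth
    ref_frame <- 1L
    base_offset <- 0 # um
    ref_center <- anchor0
    ctr_idx <- function(center_mm) {
      i <- round((center_mm - series$depths[1]) / dz) + 1
      # keep at least one sample of search margin on either side
      min(max(i, half_w + 2), nz - w + half_w)
    }
    ri <- ctr_idx(ref_center)
    ref_seg <- sig[ref_frame, (ri - half_w):(ri - half_w + w - 1)]
    disp[li, 1] <- 0; corr[li, 1] <- 1
    ev <- integer(0)
    for (f in 2:nfr) {
      # shrink the lag range near the series edges so the search segment
      # stays centered on the reference window (no alignment correction)
      ml <- max(1L, min(max_lag, ri - half_w - 1L,
                        nz - (ri - half_w + w - 1L)))
      lo <- ri - half_w - ml
      hi <- ri - half_w + w - 1 + ml
      cur <- sig[f, lo:hi]
      cw <- correlate_window(ref_seg, cur, ml, config$subsample_method,
                             carrier_omega = config$carrier_omega)
      if (!cw$degenerate) degenerate_all <- FALSE
      cc <- cw$peak_refined %||% cw$peak_coefficient
      corr[li, f] <- cc
      if (adaptive && cc < config$corr_threshold && !cw$degenerate) {
        # update reference: inherit last accepted absolute displacement
        base_offset <- disp[li, f - 1]
        ref_frame <- f
        ref_center <- anchor0 + base_offset / 1000
        ri <- ctr_idx(ref_center)
        ref_seg <- sig[f, (ri - half_w):(ri - half_w + w - 1)]
        disp[li, f] <- base_offset # re-correlation against itself: lag 0
        ev <- c(ev, f)
      } else {
        disp[li, f] <- base_offset + cw$lag * dz * 1000
      }
    }
    updates[[li]] <- ev
  }
  if (degenerate_all) stop("all tracking windows are degenerate (zero variance)")
  structure(list(
    lateral_positions = series$lateral_mm[lines],
    times = (seq_len(nfr) - 1) * 1000 / series$frame_rate,
    displacement = disp, corr_coeff = corr, ref_updates = updates,
    wall = series$grid$wall %||% "posterior",
    frame_rate = series$frame_rate, config = config, adaptive = adaptive),
    class = "wall_track")
}

#' @export
print.wall_track <- function(x, ...) {
  cat("<wall_track>", nrow(x$displacement), "positions x",
      ncol(x$displacement), "frames;", x$wall, "wall;",
      sum(lengths(x$ref_updates)), "reference updates\n")
  invisible(x)
}

#' Ground-truth wall track from a phantom field
#'
#' Bypasses imaging and tracking: packages a phantom's own displacement
#' field as a `wall_track` (correlation 1 everywhere). This is the
#' displacement-field path used to validate the PWV estimator in isolation
#' from the imaging chain.
#'
#' @param field a `wall_field`. @param wall which wall.
#' @return A `wall_track`.
#' @export
track_from_field <- function(field, wall = c("posterior", "anterior")) {
  wall <- match.arg(wall)
  m <- if (wall == "anterior") field$anterior_disp else field$posterior_disp
  structure(list(
    lateral_positions = field$lateral_positions, times = field$times,
    displacement = m, corr_coeff = matrix(1, nrow(m), ncol(m)),
    ref_updates = rep(list(integer(0)), nrow(m)),
    wall = wall, frame_rate = field$frame_rate,
    config = NULL, adaptive = NA),
    class = "wall_track")
}

#' Segment anterior and posterior wall echoes
#'
#' Per frame and scanline, locates the two dominant envelope peaks inside a
#' depth region of interest (the anterior and posterior wall echoes, sorted
#' by depth) and applies temporal median smoothing. Positions/frames where
#' fewer than two local maxima exist in the ROI are flagged unsegmentable
#' (NA).
#'
#' @param envelope_series an envelope `bf_series` (see [envelope()]).
#' @param roi `c(min_depth, max_depth)` mm; default: full depth range.
#' @param smooth odd window length of the temporal running median
#'   (1 disables).
#' @param min_separation mm, minimum depth separation between the two wall
#'   echoes (prevents two speckle maxima inside one wall band from being
#'   read as both walls).
#' @return A `wall_contour`: anterior/posterior depth (mm) and lumen
#'   diameter arrays (frames x lines).
#' @export
segment_wall <- function(envelope_series, roi = NULL, smooth = 5,
                         min_separation = 5) {
  stopifnot(inherits(envelope_series, "bf_series"))
  if (!isTRUE(envelope_series$is_envelope))
    envelope_series <- envelope(envelope_series)
  d <- envelope_series$depths
  sel <- if (is.null(roi)) seq_along(d) else which(d >= roi[1] & d <= roi[2])
  if (length(sel) < 5) stop("ROI contains too few depth samples")
  dat <- envelope_series$data
  nfr <- dim(dat)[1]; nl <- dim(dat)[3]
  ant <- post <- matrix(NA_real_, nfr, nl)
  for (l in seq_len(nl)) for (f in seq_len(nfr)) {
    y <- dat[f, sel, l]
    pk <- which(diff(sign(diff(y))) == -2) + 1
    if (length(pk) < 2) next
    p1 <- pk[which.max(y[pk])]
    far <- pk[abs(d[sel[pk]] - d[sel[p1]]) >= min_separation]
    if (!length(far)) next
    p2 <- far[which.max(y[far])]
    top2 <- c(p1, p2)
    # refine each peak by parabolic interpolation on the envelope
    refine <- function(i) {
      if (i <= 1 || i >= length(y)) return(d[sel[i]])
      dd <- subsample_peak(y[i - 1], y[i], y[i + 1], "parabolic")
      d[sel[i]] + dd * (d[2] - d[1])
    }
    zz <- sort(vapply(top2, refine, numeric(1)))
    ant[f, l] <- zz[1]; post[f, l] <- zz[2]
  }
  if (smooth > 1 && nfr >= smooth) {
    for (l in seq_len(nl)) {
      if (!anyNA(ant[, l])) ant[, l] <- runmed(ant[, l], smooth)
      if (!anyNA(post[, l])) post[, l] <- runmed(post[, l], smooth)
    }
  }
  structure(list(anterior = ant, posterior = post,
                 diameter = post - ant,
                 lateral_mm = envelope_series$lateral_mm,
                 times = (seq_len(nfr) - 1) * 1000 / envelope_series$frame_rate),
            class = "wall_contour")
}
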
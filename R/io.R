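# HDF5 containers for RF / displacement / beamformed series and CSV cohort
# tables.  Layout: /rf (frame x element x sample) or /bf (frame x depth x
# line) plus grid datasets, /meta (one JSON string with the acquisition
# metadata), /truth/foot_times and /truth/pwv_true when phantom ground truth
# is available.

h5_overwrite <- function(path) {
  if (file.exists(path)) unlink(path)
  rhdf5::h5createFile(path)
}

meta_json <- function(lst) jsonlite::toJSON(lst, auto_unbox = TRUE, digits = NA)

#' Write an RF frame series (optionally with phantom ground truth) to HDF5
#'
#' @param rf an `rf_series`. @param path output file.
#' @param field optional `wall_field` whose foot-time table and true PWV are
#'   stored under `/truth`.
#' @return `path`, invisibly.
#' @export
write_frames <- function(rf, path, field = NULL) {
  stopifnot(inherits(rf, "rf_series"))
  h5_overwrite(path)
  rhdf5::h5write(rf$data, path, "rf")
  rhdf5::h5write(as.character(meta_json(list(
    sampling_freq = rf$sampling_freq, center_freq = rf$center_freq,
    sound_speed = rf$sound_speed, frame_rate = rf$frame_rate,
    t0_us = rf$t0_us, pulse_sigma = rf$pulse_sigma))), path, "meta")
  rhdf5::h5write(rf$transmit_schedule$angle, path, "schedule_angle")
  rhdf5::h5write(rf$transmit_schedule$field_frame, path, "schedule_field_frame")
  if (!is.null(field)) {
    rhdf5::h5createGroup(path, "truth")
    rhdf5::h5write(field$foot_times, path, "truth/foot_times")
    rhdf5::h5write(field$pwv_true, path, "truth/pwv_true")
  }
  rhdf5::h5closeAll()
  invisible(path)
}

#' Read an RF frame series written by [write_frames()]
#'
#' @param path HDF5 file.
#' @return An `rf_series` (with a `truth` element if present in the file).
#' @export
read_frames <- function(path) {
  meta <- jsonlite::fromJSON(rhdf5::h5read(path, "meta"))
  out <- structure(list(
    data = rhdf5::h5read(path, "rf"),
    sampling_freq = meta$sampling_freq, center_freq = meta$center_freq,
    sound_speed = meta$sound_speed, frame_rate = meta$frame_rate,
    t0_us = meta$t0_us, pulse_sigma = meta$pulse_sigma,
    transmit_schedule = data.frame(
      frame = seq_along(rhdf5::h5read(path, "schedule_angle")),
      angle = as.numeric(rhdf5::h5read(path, "schedule_angle")),
      field_frame = as.integer(rhdf5::h5read(path, "schedule_field_frame")))),
    class = "rf_series")
  contents <- rhdf5::h5ls(path)$name
  if ("truth" %in% contents)
    out$truth <- list(foot_times = rhdf5::h5read(path, "truth/foot_times"),
                      pwv_true = as.numeric(rhdf5::h5read(path, "truth/pwv_true")))
  rhdf5::h5closeAll()
  out
}

#' Write / read a beamformed series to HDF5
#'
#' Datasets: `/bf` (frame x depth x line), `/depths`, `/lateral_mm`,
#' `/line_angles_deg`, `/meta` (JSON).
#'
#' @param bf a `bf_series`. @param path HDF5 file.
#' @return `path` invisibly / the `bf_series`.
#' @export
write_bf <- function(bf, path) {
  stopifnot(inherits(bf, "bf_series"))
  h5_overwrite(path)
  rhdf5::h5write(bf$data, path, "bf")
  rhdf5::h5write(bf$depths, path, "depths")
  rhdf5::h5write(bf$lateral_mm, path, "lateral_mm")
  rhdf5::h5write(as.numeric(bf$line_angles_deg), path, "line_angles_deg")
  if (!is.null(bf$wall_contour %||% bf$grid$wall_contour))
    rhdf5::h5write(bf$wall_contour %||% bf$grid$wall_contour, path, "wall_contour")
  rhdf5::h5write(as.character(meta_json(list(
    frame_rate = bf$frame_rate, center_freq = bf$center_freq,
    sound_speed = bf$sound_speed, compounded = bf$compounded,
    is_envelope = bf$is_envelope, wall = bf$grid$wall %||% NA))),
    path, "meta")
  rhdf5::h5closeAll()
  invisible(path)
}

#' @rdname write_bf
#' @export
read_bf <- function(path) {
  meta <- jsonlite::fromJSON(rhdf5::h5read(path, "meta"))
  contents <- rhdf5::h5ls(path)$name
  out <- structure(list(
    data = rhdf5::h5read(path, "bf"),
    depths = as.numeric(rhdf5::h5read(path, "depths")),
    lateral_mm = as.numeric(rhdf5::h5read(path, "lateral_mm")),
    line_angles_deg = as.numeric(rhdf5::h5read(path, "line_angles_deg")),
    frame_rate = meta$frame_rate, center_freq = meta$center_freq,
    sound_speed = meta$sound_speed, compounded = meta$compounded,
    is_envelope = meta$is_envelope,
    grid = list(wall = if (is.null(meta$wall) || is.na(meta$wall)) NULL else meta$wall)),
    class = "bf_series")
  if ("wall_contour" %in% contents)
    out$wall_contour <- as.numeric(rhdf5::h5read(path, "wall_contour"))
  rhdf5::h5closeAll()
  out
}

cohort_columns <- c("id", "frs", "group", "ufcpwv", "bhpwv", "sbp", "dbp",
                    "diastolic_diameter", "systolic_diameter")

#' Write / read a cohort table as CSV
#'
#' The schema is fixed: columns `id, frs, group, ufcpwv, bhpwv, sbp, dbp,
#' diastolic_diameter, systolic_diameter`. Reading validates it and errors
#' listing any missing columns.
#'
#' @param cohort a `cohort_table`. @param path CSV file.
#' @return `path` invisibly / the validated `cohort_table`.
#' @export
write_cohort <- function(cohort, path) {
  miss <- setdiff(cohort_columns, names(cohort))
  if (length(miss)) stop("cohort is missing columns: ",
                         paste(miss, collapse = ", "))
  write.csv(as.data.frame(cohort)[, cohort_columns], path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  miss <- setdiff(cohort_columns, names(df))
  if (length(miss)) stop("cohort CSV schema violation; missing columns: ",
                         paste(miss, collapse = ", "))
  df$group <- factor(df$group, levels = c("low", "intermediate", "high"))
  class(df) <- c("cohort_table", "data.frame")
  df
}
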
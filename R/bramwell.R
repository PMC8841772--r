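# Theoretical PWV from arterial distensibility: the Bramwell-Hill relation
# links the relative systolic-diastolic cross-sectional area change per unit
# local pulse pressure to the wave speed,
#   PWV = sqrt( A_d * PP / (rho * dA) ),
# with A_d the diastolic area, dA the systolic-diastolic area difference,
# PP the local pulse pressure and rho the blood density.

#' Cross-sectional area of a circular vessel
#'
#' @param diameter mm (> 0); the lumen is assumed circular.
#' @return Area in cm^2.
#' @export
area_from_diameter <- function(diameter) {
  if (any(diameter <= 0)) stop("diameter must be positive")
  pi * (diameter / 20)^2 # mm -> cm radius
}

#' Local pulse pressure of a pressure trace
#'
#' Max minus min over the whole cycles contained in the trace.
#'
#' @param trace a `pressure_trace`.
#' @return PP in mmHg (0 is flagged with a warning: degenerate trace).
#' @export
pulse_pressure <- function(trace) {
  stopifnot(inherits(trace, "pressure_trace"))
  period <- 60000 / trace$heart_rate
  dt <- 1000 / (trace$frame_rate %||% (1000 / diff(trace$times[1:2])))
  span <- max(trace$times) - min(trace$times) + dt # sample-count coverage
  if (span < period - 1e-9) stop("trace spans less than one cardiac cycle")
  n_whole <- floor(span / period + 1e-9)
  sel <- trace$times < min(trace$times) + n_whole * period + 1e-9
  pp <- max(trace$pressure[sel]) - min(trace$pressure[sel])
  if (pp == 0) warning("flat pressure trace: pulse pressure is zero")
  pp
}

#' Bramwell-Hill theoretical pulse wave velocity
#'
#' `sqrt(A_d * PP / (rho * dA))` with the pulse pressure converted from
#' mmHg to Pa (1 mmHg = 133.322 Pa). The area ratio is dimensionless, so
#' any consistent area unit works; cm^2 is the package convention.
#'
#' @param A_d diastolic cross-sectional area, cm^2 (> 0).
#' @param delta_A systolic-diastolic area difference, cm^2 (positive; a
#'   value of `A_d` or more triggers a warning, not an error).
#' @param PP local pulse pressure, mmHg (> 0).
#' @param rho blood density, kg/m^3 (default 1060).
#' @return PWV in m/s.
#' @export
bh_pwv <- function(A_d, delta_A, PP, rho = 1060) {
  if (any(A_d <= 0) || any(delta_A <= 0) || any(PP <= 0) || any(rho <= 0))
    stop("A_d, delta_A, PP and rho must all be positive")
  if (any(delta_A >= A_d))
    warning("delta_A >= A_d: unusually large distension")
  sqrt(A_d * PP * MMHG_TO_PA / (rho * delta_A))
}

#' Bramwell-Hill PWV from tabulated diameters and pressures
#'
#' Appends a `bhpwv_ms` column computed from `diastolic_diameter_mm`,
#' `systolic_diameter_mm` and `pp_mmhg` columns (the cohort-table column
#' names `diastolic_diameter` / `systolic_diameter` with `sbp` / `dbp` are
#' also accepted).
#'
#' @param df data.frame with the columns above.
#' @param rho blood density, kg/m^3.
#' @return `df` with `bhpwv_ms` appended.
#' @export
bh_pwv_table <- function(df, rho = 1060) {
  dd <- df$diastolic_diameter_mm %||% df$diastolic_diameter
  sdm <- df$systolic_diameter_mm %||% df$systolic_diameter
  pp <- df$pp_mmhg %||% (df$sbp - df$dbp)
  if (is.null(dd) || is.null(sdm) || is.null(pp))
    stop("need diastolic/systolic diameter and pulse-pressure columns")
  A_d <- area_from_diameter(dd)
  dA <- area_from_diameter(sdm) - A_d
  if (any(dA <= 0))
    stop("systolic area must exceed diastolic area; pre-screen noisy rows")
  df$bhpwv_ms <- bh_pwv(A_d, dA, pp, rho)
  df
}
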
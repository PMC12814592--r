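# Inhalation dosimetry and clearance kinetics: ventilation rate, total
# applied (inhaled) mass, deposition fraction, mono-/biphasic first-order
# clearance fits and the lung-overload check.

#' Lung ventilation rate
#'
#' `rate = coefficient * body weight`, unrounded. The rat allometric
#' coefficient is 0.8 L/min per kg body weight.
#'
#' @param body_weight_kg body weight (kg, > 0).
#' @param coefficient_l_min_kg L/min per kg (default 0.8).
#' @return ventilation rate (L/min).
#' @examples
#' ventilation_rate(0.270)  # 0.216 (displayed rounded as 0.22)
#' @export
ventilation_rate <- function(body_weight_kg, coefficient_l_min_kg = 0.8) {
  if (body_weight_kg <= 0) stop("body weight must be > 0")
  if (coefficient_l_min_kg < 0) stop("coefficient must be >= 0")
  if (coefficient_l_min_kg == 0)
    warning("zero ventilation coefficient: degenerate scenario")
  coefficient_l_min_kg * body_weight_kg
}

#' Exposure scenario
#'
#' @param concentration_mg_m3 aerosol concentration (mg/m^3).
#' @param minutes_per_day exposure minutes per exposure day (360 for
#'   6 h/day).
#' @param exposure_days number of exposure days (20 for 5 days/week over
#'   4 weeks).
#' @param body_weight_kg body weight (kg).
#' @param coefficient_l_min_kg ventilation coefficient (L/min/kg).
#' @return object of class `exposure_scenario`.
#' @export
exposure_scenario <- function(concentration_mg_m3, minutes_per_day = 360,
                              exposure_days = 20, body_weight_kg,
                              coefficient_l_min_kg = 0.8) {
  stopifnot(concentration_mg_m3 > 0, minutes_per_day > 0,
            exposure_days >= 0, body_weight_kg > 0,
            coefficient_l_min_kg > 0)
  structure(list(concentration_mg_m3 = concentration_mg_m3,
                 minutes_per_day = minutes_per_day,
                 exposure_days = exposure_days,
                 body_weight_kg = body_weight_kg,
                 coefficient_l_min_kg = coefficient_l_min_kg),
            class = "exposure_scenario")
}

#' Total applied (inhaled) mass
#'
#' `mass [mg] = exposure time [min] x ventilation rate [L/min] x aerosol
#' concentration [mg/m^3] / 1000`, with the exposure time the product of
#' minutes per day and exposure days and the ventilation rate used
#' unrounded.
#'
#' @param scenario [exposure_scenario()].
#' @return total applied mass (mg).
#' @examples
#' sc <- exposure_scenario(50, 360, 20, 0.270)
#' total_applied_mass(sc)  # 77.76 -> printed as 77.8
#' @export
total_applied_mass <- function(scenario) {
  stopifnot(inherits(scenario, "exposure_scenario"))
  rate <- ventilation_rate(scenario$body_weight_kg,
                           scenario$coefficient_l_min_kg)
  minutes <- scenario$minutes_per_day * scenario$exposure_days
  minutes * rate * scenario$concentration_mg_m3 / 1000
}

#' Deposition fraction
#'
#' Retained lung burden as a percentage of the total applied mass.
#'
#' @param lung_burden_mg retained burden (mg, >= 0).
#' @param applied_mass_mg total applied mass (mg, > 0).
#' @return percent.
#' @examples
#' deposition_fraction(4.2, 77.76)  # ~5.4
#' @export
deposition_fraction <- function(lung_burden_mg, applied_mass_mg) {
  if (any(applied_mass_mg <= 0)) stop("applied mass must be > 0")
  if (any(lung_burden_mg < 0)) stop("burden must be >= 0")
  100 * lung_burden_mg / applied_mass_mg
}

#' Fit first-order clearance (mono- or biphasic)
#'
#' Within each phase, `N(t) = N_start * exp(-lambda * (t - t_start))` with
#' `t_half = ln 2 / lambda`. With exactly two timepoints in a phase the
#' clearance constant is the closed form
#' `lambda = ln(N_start / N_end) / dt`; with more, a log-linear least
#' squares fit is used. Biphasic fits split the observations at the
#' user-supplied boundary days (the sampling days, not change-point
#' detection) and fit consecutive intervals separately; boundary
#' observations anchor both adjacent phases, so the fitted curve is
#' continuous there.
#'
#' @param observations data.frame with columns `day` and `burden` (mean
#'   burden per timepoint, any consistent mass unit, > 0). One row per
#'   timepoint.
#' @param phase_boundaries optional interior boundary days for biphasic
#'   (or multi-phase) fits; must be observed days.
#' @return object of class `clearance_fit`: `n0` (burden at day 0 of the
#'   fit), `phases` data.frame (`start_day`, `end_day`, `lambda_per_day`,
#'   `half_time_days`), `timepoints`.
#' @examples
#' obs <- data.frame(day = c(0, 46), burden = c(4.2, 2.1))
#' clearance_fit(obs)$phases$half_time_days  # 46
#' @export
clearance_fit <- function(observations, phase_boundaries = NULL) {
  stopifnot(is.data.frame(observations),
            all(c("day", "burden") %in% names(observations)))
  obs <- observations[order(observations$day), ]
  if (nrow(obs) < 2) stop("need at least 2 timepoints")
  if (any(obs$burden <= 0)) stop("burdens must be > 0")
  if (anyDuplicated(obs$day)) stop("one mean burden per day expected")
  bounds <- sort(unique(phase_boundaries))
  if (length(bounds) > 0 && !all(bounds %in% obs$day))
    stop("phase boundaries must be observed days")
  edges <- c(min(obs$day), bounds, max(obs$day))
  phases <- do.call(rbind, lapply(seq_len(length(edges) - 1), function(i) {
    seg <- obs[obs$day >= edges[i] & obs$day <= edges[i + 1], ]
    if (nrow(seg) < 2) stop("each phase needs at least 2 timepoints")
    if (nrow(seg) == 2) {
      lambda <- log(seg$burden[1] / seg$burden[2]) / diff(seg$day)
    } else {
      lambda <- -unname(coef(lm(log(burden) ~ day, data = seg))[2])
    }
    data.frame(start_day = edges[i], end_day = edges[i + 1],
               lambda_per_day = lambda,
               half_time_days = log(2) / lambda)
  }))
  if (any(phases$lambda_per_day <= 0))
    warning("non-positive clearance constant: burden increased (growth, not clearance)")
  structure(list(n0 = obs$burden[1], phases = phases, timepoints = obs),
            class = "clearance_fit")
}

#' @export
print.clearance_fit <- function(x, ...) {
  cat(sprintf("clearance fit: N0 = %.3g, %d phase(s)\n", x$n0,
              nrow(x$phases)))
  for (i in seq_len(nrow(x$phases)))
    cat(sprintf("  day %g-%g: lambda %.4g /day, t1/2 %.4g days\n",
                x$phases$start_day[i], x$phases$end_day[i],
                x$phases$lambda_per_day[i], x$phases$half_time_days[i]))
  invisible(x)
}

#' Lung-overload check
#'
#' Poorly soluble low-toxicity particles above ~1 mg per gram lung impair
#' alveolar-macrophage clearance ("lung particle overload"). The flag uses
#' a strict inequality: exactly 1.0 mg/g is not flagged.
#'
#' @param burden_mg lung burden (mg).
#' @param lung_weight_g lung wet weight (g, > 0).
#' @param threshold_mg_g overload threshold (mg/g, default 1).
#' @return list: `ratio_mg_g`, `overload` (logical), `threshold_mg_g`.
#' @examples
#' overload_check(4.2, 1.63)  # 2.58 mg/g -> overload
#' @export
overload_check <- function(burden_mg, lung_weight_g, threshold_mg_g = 1) {
  if (lung_weight_g <= 0) stop("lung weight must be > 0")
  ratio <- burden_mg / lung_weight_g
  list(ratio_mg_g = ratio, overload = ratio > threshold_mg_g,
       threshold_mg_g = threshold_mg_g)
}
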
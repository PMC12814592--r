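# Pyrolysis-GC/MS quantification: external calibration, organ
# back-calculation through the extract/aliquot dilution factor, detection
# limits and spike recovery.

#' Fit an external calibration curve
#'
#' Ordinary least squares of peak area on analyte mass, with intercept (the
#' intercept absorbs any baseline). Residual SD and the replicate table are
#' retained for detection limits.
#'
#' @param mass_ng calibration masses (ng); at least 3 distinct values.
#' @param area peak areas.
#' @return object of class `calibration_curve`: `slope` (area/ng),
#'   `intercept`, `residual_sd`, `range_ng`, `replicates` (input table),
#'   `fit` (the `lm`).
#' @export
fit_calibration <- function(mass_ng, area) {
  stopifnot(length(mass_ng) == length(area), all(mass_ng >= 0))
  if (length(unique(mass_ng)) < 3)
    stop("need at least 3 distinct calibration masses")
  fit <- lm(area ~ mass_ng)
  slope <- unname(coef(fit)[2])
  if (!is.finite(slope) || slope <= 0)
    stop("calibration slope must be positive")
  structure(list(
    slope = slope,
    intercept = unname(coef(fit)[1]),
    residual_sd = if (fit$df.residual > 0)
      sqrt(sum(fit$residuals^2) / fit$df.residual) else 0,
    range_ng = range(mass_ng),
    replicates = data.frame(mass_ng = mass_ng, area = area),
    fit = fit
  ), class = "calibration_curve")
}

#' @export
print.calibration_curve <- function(x, ...) {
  cat(sprintf("calibration: area = %.4g + %.4g * mass_ng (residual SD %.3g), %g-%g ng\n",
              x$intercept, x$slope, x$residual_sd,
              x$range_ng[1], x$range_ng[2]))
  invisible(x)
}

#' Back-calculate polymer mass per organ from a peak area
#'
#' Crucible mass = (area - intercept) / slope; the organ mass scales the
#' crucible mass by the dilution factor extract volume / aliquot volume
#' (e.g. 20 mL extract, 20 uL aliquot -> factor 1000). Areas at or below
#' the intercept are reported as 0 with `below_range = TRUE`.
#'
#' @param area peak area of the sample crucible.
#' @param curve [fit_calibration()] result.
#' @param aliquot_ul aliquot pipetted into the crucible (uL, > 0).
#' @param extract_ml total extract volume (mL, > 0).
#' @param organ_weight_g optional organ wet weight (g).
#' @param organ organ label.
#' @return list: `crucible_mass_ng`, `dilution_factor`, `organ_mass_ug`,
#'   `organ_mass_mg`, `mass_per_g_mg` (if weight given), `below_range`.
#' @export
quantify_organ <- function(area, curve, aliquot_ul, extract_ml,
                           organ_weight_g = NULL, organ = "lung") {
  stopifnot(inherits(curve, "calibration_curve"))
  if (aliquot_ul <= 0) stop("aliquot volume must be > 0")
  if (extract_ml <= 0) stop("extract volume must be > 0")
  if (aliquot_ul > extract_ml * 1000)
    stop("aliquot cannot exceed the extract volume")
  crucible <- (area - curve$intercept) / curve$slope
  below <- crucible <= 0
  crucible <- max(crucible, 0)
  dilution <- extract_ml * 1000 / aliquot_ul
  organ_ng <- crucible * dilution
  out <- list(organ = organ,
              crucible_mass_ng = crucible,
              dilution_factor = dilution,
              organ_mass_ug = organ_ng * 1e-3,
              organ_mass_mg = organ_ng * 1e-6,
              below_range = below)
  if (!is.null(organ_weight_g)) {
    stopifnot(organ_weight_g > 0)
    out$organ_weight_g <- organ_weight_g
    out$mass_per_g_mg <- out$organ_mass_mg / organ_weight_g
  }
  out
}

#' Detection and quantification limits scaled to the organ
#'
#' The LOQ is the lowest calibration mass scaled by the dilution factor.
#' The LOD subtracts a multiple of the replicate SD at the lowest mass
#' before scaling: `LOD = (m_low - k * SD_low) * dilution`. When no
#' replicate SD is available (or `k` is NULL) the subtraction defaults to
#' 20% of the lowest mass, the value that makes the printed lymph-node
#' limits (LOD 1.2, LOQ 1.5 ug) internally consistent; this reconstruction
#' is a documented assumption.
#'
#' @param curve [fit_calibration()] result.
#' @param dilution_factor extract/aliquot dilution factor (e.g. 75 for a
#'   3 mL extract and 40 uL aliquot).
#' @param k multiplier on the replicate SD at the lowest mass; NULL uses
#'   the 20% default subtraction.
#' @return object of class `detection_limits`: `lod_ug`, `loq_ug`,
#'   `dilution_factor`, `lowest_mass_ng`.
#' @export
detection_limits <- function(curve, dilution_factor, k = NULL) {
  stopifnot(inherits(curve, "calibration_curve"), dilution_factor > 0)
  m_low <- min(curve$replicates$mass_ng[curve$replicates$mass_ng > 0])
  reps <- curve$replicates$area[curve$replicates$mass_ng == m_low]
  loq_ng <- m_low * dilution_factor
  if (is.null(k)) {
    sub <- 0.2 * m_low
  } else if (length(reps) >= 2 && sd(reps) > 0) {
    sub <- k * sd(reps) / curve$slope   # SD in area units -> ng
  } else {
    warning("no replicate SD at the lowest mass; LOD set equal to LOQ")
    sub <- 0
  }
  sub <- min(sub, m_low)  # never negative LOD
  lod_ng <- (m_low - sub) * dilution_factor
  structure(list(lod_ug = lod_ng * 1e-3, loq_ug = loq_ng * 1e-3,
                 dilution_factor = dilution_factor,
                 lowest_mass_ng = m_low),
            class = "detection_limits")
}

#' @export
print.detection_limits <- function(x, ...) {
  cat(sprintf("LOD %.3g ug / LOQ %.3g ug per organ (dilution %g, lowest standard %g ng)\n",
              x$lod_ug, x$loq_ug, x$dilution_factor, x$lowest_mass_ng))
  invisible(x)
}

#' Spike recovery
#'
#' `recovery = 100 * (measured - endogenous) / spiked` (percent).
#'
#' @param measured_ug total measured mass after spiking (ug).
#' @param spiked_ug spiked mass (ug, > 0).
#' @param endogenous_ug pre-spike endogenous mass (ug).
#' @return recovery in percent.
#' @examples
#' spike_recovery(163, 100, endogenous_ug = 100)  # 63
#' @export
spike_recovery <- function(measured_ug, spiked_ug, endogenous_ug = 0) {
  if (any(spiked_ug <= 0)) stop("spiked mass must be > 0")
  100 * (measured_ug - endogenous_ug) / spiked_ug
}

#' Censor burdens below the detection limit
#'
#' Below-LOD results are reported as censored (`"<LOD"`) rather than zero;
#' group means over censored data substitute LOD/2 by default (configurable
#' via `substitute`), or drop censored animals with
#' `substitute = "exclude"`.
#'
#' @param values_ug measured burdens (ug).
#' @param lod_ug detection limit (ug).
#' @param substitute `"half_lod"`, `"exclude"`, or a numeric value.
#' @return list: `censored` (logical), `display` (character, `"<LOD"` where
#'   censored), `mean_ug` (group mean under the chosen rule).
#' @export
censor_below_lod <- function(values_ug, lod_ug, substitute = "half_lod") {
  cens <- values_ug < lod_ug
  vals <- values_ug
  if (identical(substitute, "half_lod")) {
    vals[cens] <- lod_ug / 2
    m <- mean(vals)
  } else if (identical(substitute, "exclude")) {
    m <- if (all(cens)) NA_real_ else mean(values_ug[!cens])
  } else if (is.numeric(substitute)) {
    vals[cens] <- substitute
    m <- mean(vals)
  } else stop("unknown substitution rule")
  list(censored = cens,
       display = ifelse(cens, "<LOD", format(values_ug, digits = 4)),
       mean_ug = m)
}
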
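# Aerosol metrics: gravimetric atmosphere concentration and MMAD/GSD from
# cascade-impactor stage masses by log-probit regression.

#' Gravimetric aerosol concentration
#'
#' Concentration = filter mass gain / sampled air volume, with the sampled
#' volume in m^3 (`flow_l_min * time_min / 1000`).
#'
#' @param mass_gain_mg filter mass gain (mg, >= 0).
#' @param flow_l_min sampling flow rate (L/min, > 0); 3 L/min typical.
#' @param time_min sampling time (min, > 0); 120 min (low) or 40 min (high
#'   concentration) typical.
#' @return concentration in mg/m^3.
#' @examples
#' gravimetric_concentration(6.084, 3, 40)  # 50.7 mg/m^3
#' @export
gravimetric_concentration <- function(mass_gain_mg, flow_l_min, time_min) {
  if (any(mass_gain_mg < 0)) stop("mass gain must be >= 0")
  if (flow_l_min <= 0 || time_min <= 0)
    stop("flow rate and sampling time must be > 0")
  mass_gain_mg / (flow_l_min * time_min / 1000)
}

#' MMAD and GSD from cascade-impactor stage masses
#'
#' Log-probit regression of the cumulative undersize mass fraction on the
#' log cutoff diameter: with the final filter counted as the sub-smallest-
#' cutoff stage (mass closure), the cumulative fraction below each cutoff
#' is regressed as `qnorm(F) ~ ln(cutoff)` (unweighted; points at exactly
#' 0 or 1 are excluded since the probit is undefined there). Then
#' `MMAD = exp(-intercept / slope)` and `GSD = exp(1 / slope)`.
#'
#' @param run data.frame with `cutoff_um` (decreasing, NA for the final
#'   filter) and `mass_mg`, as produced by [generate_impactor_run()].
#' @return list with `mmad_um`, `gsd`, `fit` (the `lm`), and the
#'   cumulative table used.
#' @examples
#' run <- generate_impactor_run(1.51, 2.04, 10)
#' fit_mmad_gsd(run)[c("mmad_um", "gsd")]
#' @export
fit_mmad_gsd <- function(run) {
  stopifnot(is.data.frame(run), all(c("cutoff_um", "mass_mg") %in% names(run)))
  if (any(run$mass_mg < 0)) stop("stage masses must be >= 0")
  cuts <- run$cutoff_um[!is.na(run$cutoff_um)]
  if (length(cuts) < 4) stop("need at least 4 impactor stages")
  if (is.unsorted(rev(cuts), strictly = TRUE))
    stop("cutoffs must be strictly decreasing")
  total <- sum(run$mass_mg)
  if (total <= 0) stop("no mass collected")
  stage_mass <- run$mass_mg[!is.na(run$cutoff_um)]
  filter_mass <- sum(run$mass_mg[is.na(run$cutoff_um)])
  # cumulative mass fraction below each cutoff: everything on later stages
  # plus the final filter
  below <- rev(cumsum(rev(c(stage_mass[-1], filter_mass))))
  frac <- below / total
  keep <- frac > 0 & frac < 1   # probit undefined at the endpoints
  # fractions within ~1e-9 of 1 carry almost no precision (stored as 1 - eps
  # with eps at the double epsilon); drop such saturated tail points when
  # enough interior points remain for the regression
  crisp <- frac > 1e-12 & frac < 1 - 1e-9
  if (sum(crisp) >= 3) keep <- crisp
  if (sum(keep) < 3)
    stop("degenerate size distribution: fewer than 3 interior cumulative points")
  probit <- qnorm(frac[keep])
  lncut <- log(cuts[keep])
  fit <- lm(probit ~ lncut)
  slope <- unname(coef(fit)[2])
  if (!is.finite(slope) || slope <= 0)
    stop("cumulative distribution not increasing with cutoff; cannot fit")
  list(mmad_um = exp(-unname(coef(fit)[1]) / slope),
       gsd = exp(1 / slope),
       fit = fit,
       cumulative = data.frame(cutoff_um = cuts, fraction_below = frac))
}

#' Summarise an aerosol atmosphere
#'
#' Bundles replicate gravimetric concentrations with an impactor fit and
#' pass-through SMPS summaries (total count concentration and geometric
#' mean diameter are instrument outputs, averaged, not refit).
#'
#' @param concentrations_mg_m3 replicate gravimetric concentrations.
#' @param impactor_run optional impactor table for [fit_mmad_gsd()].
#' @param tcc_n_cm3,gmd_nm optional replicate SMPS readings.
#' @return object of class `aerosol_summary`.
#' @export
aerosol_summary <- function(concentrations_mg_m3, impactor_run = NULL,
                            tcc_n_cm3 = NULL, gmd_nm = NULL) {
  out <- list(mean_mg_m3 = mean(concentrations_mg_m3),
              sd_mg_m3 = if (length(concentrations_mg_m3) > 1)
                sd(concentrations_mg_m3) else NA_real_,
              mmad_um = NA_real_, gsd = NA_real_,
              tcc_n_cm3 = if (is.null(tcc_n_cm3)) NA_real_ else mean(tcc_n_cm3),
              gmd_nm = if (is.null(gmd_nm)) NA_real_ else mean(gmd_nm))
  if (!is.null(impactor_run)) {
    f <- fit_mmad_gsd(impactor_run)
    out$mmad_um <- f$mmad_um
    out$gsd <- f$gsd
  }
  structure(out, class = "aerosol_summary")
}

#' @export
print.aerosol_summary <- function(x, ...) {
  cat(sprintf("aerosol: %.3g +/- %.2g mg/m^3, MMAD %.3g um, GSD %.3g\n",
              x$mean_mg_m3, x$sd_mg_m3, x$mmad_um, x$gsd))
  invisible(x)
}
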
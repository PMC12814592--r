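# Synthetic cascade-impactor runs from a lognormal aerosol mass
# distribution.

#' Effective aerodynamic cutoff diameters of the 8-stage Marple personal
#' cascade impactor (um), largest first.
#' @export
marple_cutoffs <- c(21, 15, 10, 6.5, 3.5, 1, 0.7, 0.4)

#' Generate synthetic impactor stage masses
#'
#' The aerosol mass distribution is lognormal with mass median aerodynamic
#' diameter `mmad` and geometric standard deviation `gsd`. Stage k (between
#' cutoffs c_{k-1} and c_k, with c_0 = Inf) collects the mass fraction
#' `Phi(ln(c_{k-1}/mmad)/ln gsd) - Phi(ln(c_k/mmad)/ln gsd)`; the final
#' filter collects the remainder below the smallest cutoff, so the stage
#' masses sum to the total. Optional multiplicative lognormal noise with
#' coefficient of variation `noise_cv` perturbs each stage.
#'
#' @param mmad mass median aerodynamic diameter (um).
#' @param gsd geometric standard deviation (> 1).
#' @param total_mass_mg total collected mass (mg).
#' @param cutoffs_um strictly decreasing cutoff diameters (um).
#' @param noise_cv multiplicative noise CV (0 = noise-free).
#' @param seed integer seed (required when `noise_cv > 0`).
#' @return data.frame with `stage` ("S1".."Sk", "filter"), `cutoff_um`
#'   (NA for the filter) and `mass_mg`.
#' @export
generate_impactor_run <- function(mmad, gsd, total_mass_mg,
                                  cutoffs_um = marple_cutoffs,
                                  noise_cv = 0, seed = NULL) {
  stopifnot(mmad > 0, total_mass_mg >= 0, noise_cv >= 0)
  if (gsd <= 1) stop("gsd must be > 1")
  if (is.unsorted(rev(cutoffs_um), strictly = TRUE))
    stop("cutoffs must be strictly decreasing")
  undersize <- plnorm(cutoffs_um, meanlog = log(mmad), sdlog = log(gsd))
  frac <- c(1, undersize) - c(undersize, 0)   # stages then filter
  mass <- total_mass_mg * frac
  if (noise_cv > 0) {
    if (is.null(seed)) stop("a seed is required when noise_cv > 0")
    sdlog <- sqrt(log(1 + noise_cv^2))
    mass <- mass * with_seed(seed,
      rlnorm(length(mass), meanlog = -sdlog^2 / 2, sdlog = sdlog))
  }
  data.frame(
    stage = c(paste0("S", seq_along(cutoffs_um)), "filter"),
    cutoff_um = c(cutoffs_um, NA),
    mass_mg = mass
  )
}
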
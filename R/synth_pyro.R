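# Synthetic pyrolysis-GC/MS runs: peak areas linear in analyte mass with
# additive Gaussian replicate noise. Stands in for the instrument; the
# chromatography itself is not modelled.

#' Generate a synthetic pyrolysis-GC/MS run
#'
#' Peak area for each crucible is `intercept + slope * mass + e`,
#' `e ~ N(0, noise_sd)`. Reproducible under the seed.
#'
#' @param mass_ng true analyte mass per crucible (ng, >= 0).
#' @param slope detector response (area per ng, > 0).
#' @param intercept baseline area.
#' @param noise_sd Gaussian noise SD on the area (>= 0).
#' @param seed integer seed.
#' @return data.frame with `crucible`, `true_mass_ng`, `peak_area`.
#' @examples
#' generate_pyro_run(c(0, 50, 100), slope = 2, intercept = 0,
#'                   noise_sd = 0, seed = 1)
#' @export
generate_pyro_run <- function(mass_ng, slope, intercept = 0,
                              noise_sd = 0, seed) {
  if (missing(seed)) stop("a seed is required")
  if (any(mass_ng < 0)) stop("masses must be >= 0")
  if (slope <= 0) stop("slope must be > 0")
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  area <- intercept + slope * mass_ng +
    with_seed(seed, rnorm(length(mass_ng), 0, noise_sd))
  data.frame(crucible = seq_along(mass_ng),
             true_mass_ng = mass_ng,
             peak_area = area)
}

#' Calibration masses from a stock dilution series
#'
#' Mass pipetted into a crucible from a two-step dilution: `stock_mg` of
#' polymer in `stock_ml` solvent, of which `transfer_ul` is diluted to
#' `final_ml`, and `aliquot_ul` of that dilution is pipetted.
#'
#' @param stock_mg,stock_ml stock preparation (mg polymer, mL solvent).
#' @param transfer_ul,final_ml dilution step (uL transferred into mL).
#' @param aliquot_ul aliquot(s) pipetted into the crucible (uL).
#' @return mass(es) in ng.
#' @examples
#' # 62 mg / 25 mL stock, 50 uL to 10 mL, 3 uL pipetted -> ~37 ng
#' dilution_series_mass(62, 25, 50, 10, 3)
#' @export
dilution_series_mass <- function(stock_mg, stock_ml, transfer_ul, final_ml,
                                 aliquot_ul) {
  stopifnot(stock_mg > 0, stock_ml > 0, transfer_ul > 0, final_ml > 0,
            all(aliquot_ul > 0))
  conc_ng_ul <- stock_mg * 1e6 / (stock_ml * 1000)        # ng per uL stock
  diluted <- conc_ng_ul * transfer_ul / (final_ml * 1000) # ng per uL diluted
  diluted * aliquot_ul
}
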
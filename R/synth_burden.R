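# Synthetic per-animal organ-burden time courses under phase-wise
# first-order clearance with lognormal inter-animal variability.

#' Specification of a burden time course
#'
#' Phase-wise first-order decay `N(t) = N0 * exp(-lambda * t)` with
#' `lambda = ln 2 / t_half` within each phase; the curve is continuous
#' across phase boundaries. Inter-animal variability is a multiplicative
#' lognormal factor with unit mean and coefficient of variation `cv`.
#'
#' @param n0_mg mean initial burden shortly after the last exposure (mg).
#' @param phases data.frame with columns `end_day` (day at which the phase
#'   ends; use `Inf` for the final phase) and `half_time` (days). Phases
#'   must be in increasing `end_day` order.
#' @param cv inter-animal lognormal coefficient of variation (>= 0).
#' @param sampling_days days post-exposure at which animals are sacrificed.
#' @param n_animals animals per sampling day.
#' @param organ organ label carried through to the output.
#' @param seed integer seed.
#' @return object of class `burden_timecourse_spec`.
#' @export
burden_timecourse_spec <- function(n0_mg, phases, cv = 0.3,
                                   sampling_days, n_animals = 5,
                                   organ = "lung", seed) {
  if (missing(seed)) stop("a seed is required")
  stopifnot(is.data.frame(phases),
            all(c("end_day", "half_time") %in% names(phases)),
            nrow(phases) >= 1, n0_mg > 0, cv >= 0, n_animals >= 1)
  if (any(phases$half_time <= 0)) stop("half-times must be > 0")
  if (is.unsorted(phases$end_day, strictly = TRUE))
    stop("phases must have strictly increasing end_day")
  if (any(sampling_days < 0)) stop("sampling days must be >= 0")
  if (any(sampling_days > max(phases$end_day)))
    stop("sampling day beyond the end of the last phase")
  structure(list(n0_mg = n0_mg, phases = phases, cv = cv,
                 sampling_days = sampling_days,
                 n_animals = as.integer(n_animals), organ = organ,
                 seed = as.integer(seed)),
            class = "burden_timecourse_spec")
}

#' Deterministic phase-wise exponential clearance curve
#'
#' @param n0_mg initial burden (mg).
#' @param phases data.frame of `end_day` / `half_time` as in
#'   [burden_timecourse_spec()].
#' @param days days at which to evaluate.
#' @return burdens (mg) at `days`.
#' @examples
#' # one phase, exact halving
#' clearance_curve(4.2, data.frame(end_day = Inf, half_time = 46), 46)
#' @export
clearance_curve <- function(n0_mg, phases, days) {
  starts <- c(0, phases$end_day[-nrow(phases)])
  vapply(days, function(t) {
    if (t < 0) stop("days must be >= 0")
    # time spent in each phase up to t
    dt <- pmax(0, pmin(t, phases$end_day) - starts)
    n0_mg * exp(-sum(log(2) / phases$half_time * dt))
  }, numeric(1))
}

#' Generate per-animal burden observations
#'
#' Each animal's burden is the deterministic curve at its sampling day
#' multiplied by a lognormal factor with mean 1 and CV `spec$cv`, so the
#' expectation over animals equals the curve.
#'
#' @param spec [burden_timecourse_spec()].
#' @return data.frame with columns `animal`, `day`, `organ`, `burden_mg`.
#' @export
generate_burden_timecourse <- function(spec) {
  stopifnot(inherits(spec, "burden_timecourse_spec"))
  days <- rep(spec$sampling_days, each = spec$n_animals)
  base <- clearance_curve(spec$n0_mg, spec$phases, days)
  sdlog <- sqrt(log(1 + spec$cv^2))
  fac <- with_seed(spec$seed,
                   rlnorm(length(days), meanlog = -sdlog^2 / 2, sdlog = sdlog))
  data.frame(
    animal = paste0("A", seq_along(days)),
    day = days,
    organ = spec$organ,
    burden_mg = base * fac
  )
}
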
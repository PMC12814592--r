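# Study-level orchestration: reference tables from the published study,
# end-to-end run over synthetic or supplied inputs, and the summary table.

#' Per-animal confocal particle counts and mass concentrations
#'
#' Published per-animal results for the high-concentration polystyrene
#' group: absolute number of detected particles and polystyrene mass per
#' (100 um)^3 in lung and lung-draining lymph node, for the main group
#' (sacrificed one day after the last exposure) and the five-week
#' post-exposure group.
#'
#' @return data.frame: `group`, `animal`, `organ`, `n_particles`,
#'   `mass_ng_per_100um3`.
#' @export
psnr_particle_table <- function() {
  read.csv(system.file("extdata", "psnr_particle_table.csv",
                       package = "nanoburden"))
}

#' Reference constants of the inhalation study
#'
#' Printed study parameters and findings used as inputs and comparison
#' values throughout the analysis: exposure design, body weights, organ
#' volumes and weights, detection limits, printed burdens, half-times and
#' the external dosimetry-model predictions (comparison constants only,
#' not recomputed here).
#'
#' @return nested list, one element per polymer (`ps`, `pa6`) plus shared
#'   constants.
#' @export
study_reference <- function() {
  list(
    exposure = list(minutes_per_day = 360, exposure_days = 20,
                    concentration_mg_m3 = 50),
    lung_volume_ml = 10, ln_volume_ml = 0.03,
    overload_threshold_mg_g = 1,
    impactor_cutoffs_um = marple_cutoffs,
    ps = list(
      body_weight_kg = 0.270,
      lung_weight_g = 1.63,
      mean_conc_lung_ng_100um3 = 0.42,
      mean_conc_ln_ng_100um3 = 0.48,
      lung_burden_mg = 4.2, ln_burden_ug = 14.5,
      deposition_pct = 5.4, half_time_days = 46,
      mmad_um = 1.32, gsd = 2.11,
      loq_volume_um3 = 4e-4, scanned_volume_mm3 = 0.43,
      mppd_deposition_pct = 6.8
    ),
    pa6 = list(
      body_weight_kg = 0.200,
      lung_weight_g = 1.05,
      lung_burden_mg = 3.8, ln_burden_ug = 2.95,
      deposition_pct = 6.6,
      half_times_days = c(initial = 68, slow = 226),
      phase_boundary_days = 35, final_day = 91,
      lung_burden_13wk_mg = 2.31,
      mmad_um = 1.51, gsd = 2.04,
      lod_ug_ln = 1.2, loq_ug_ln = 1.5,
      lod_ug_lung = 36, loq_ug_lung = 100,
      ln_dilution_factor = 75, lung_dilution_factor = 1000,
      cal_range_lung_ng = c(37, 3700), cal_range_ln_ng = c(20, 1140),
      mppd_deposition_pct = 6.9
    )
  )
}

#' Run an end-to-end study analysis
#'
#' Executes the configured stages — synthetic input generation where
#' requested, burden quantification (confocal or pyrolysis route), aerosol
#' metrics, dosimetry and clearance kinetics — and writes `summary.json`,
#' `summary.csv`, per-stage CSVs and `run.log` under `config$out_dir`
#' (omitted when `out_dir` is NULL). Deterministic given `config$seed`:
#' stage seeds are derived from the master seed.
#'
#' Config fields (all optional except `polymer` and `exposure`):
#' \describe{
#'   \item{polymer}{`name`, `density_g_cm3`, `packing`.}
#'   \item{exposure}{`concentration_mg_m3`, `minutes_per_day`,
#'     `exposure_days`, `body_weight_kg`.}
#'   \item{mode}{`"confocal"` or `"pyro"`.}
#'   \item{lung, ln}{`volume_ml`, `weight_g` and, for supplied
#'     measurements, `conc_ng_100um3` (confocal) or `burden_ug` (pyro).}
#'   \item{confocal_synthetic}{`nx, ny, nz, n_objects, intensity, ...`:
#'     generate a stack, segment and quantify instead of using a supplied
#'     concentration.}
#'   \item{pyro}{`cal_mass_ng`, `slope`, `intercept`, `noise_sd`,
#'     `aliquot_ul`, `extract_ml`, `dilution_factor_ln`.}
#'   \item{aerosol}{`mmad_um`, `gsd`, plus either supplied filter gains or
#'     nothing (noise-free impactor run generated).}
#'   \item{kinetics}{`observations` (data.frame day/burden) or
#'     `synthetic` (`n0_mg`, `phases`, `cv`, `sampling_days`,
#'     `n_animals`); `phase_boundaries`.}
#' }
#'
#' @param config nested list as above, or the path to a YAML file with the
#'   same structure.
#' @return object of class `study_summary`.
#' @export
run_study <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  stopifnot(is.list(config), !is.null(config$polymer),
            !is.null(config$exposure))
  seed <- if (is.null(config$seed)) 1L else as.integer(config$seed)
  out_dir <- config$out_dir
  if (!is.null(out_dir)) dir.create(out_dir, showWarnings = FALSE,
                                    recursive = TRUE)
  cfg_str <- paste(deparse(config), collapse = "")
  cfg_hash <- sprintf("%08x",
                      sum(utf8ToInt(cfg_str) *
                            (seq_len(nchar(cfg_str)) %% 251)) %% 2^28)
  log_lines <- c(sprintf("nanoburden %s | R %s",
                         as.character(utils::packageVersion("nanoburden")),
                         paste(R.version$major, R.version$minor, sep = ".")),
                 sprintf("master seed: %d", seed),
                 sprintf("config hash: %s", cfg_hash))

  polymer <- polymer_spec(config$polymer$name, config$polymer$density_g_cm3,
                          if (is.null(config$polymer$packing)) 0.64
                          else config$polymer$packing)
  sc <- exposure_scenario(config$exposure$concentration_mg_m3,
                          config$exposure$minutes_per_day,
                          config$exposure$exposure_days,
                          config$exposure$body_weight_kg)
  applied <- total_applied_mass(sc)

  mode <- if (is.null(config$mode)) "confocal" else config$mode
  lung_burden_mg <- NA_real_
  ln_burden_ug <- NA_real_
  limits <- NULL
  stage_tables <- list()

  if (mode == "confocal") {
    conc <- config$lung$conc_ng_100um3
    if (is.null(conc) && !is.null(config$confocal_synthetic)) {
      cs <- config$confocal_synthetic
      grid <- image_grid(cs$nx, cs$ny, cs$nz)
      scene <- random_scene(grid, cs$n_objects,
                            intensity = if (is.null(cs$intensity)) 100
                            else cs$intensity,
                            seed = seed + 101L)
      stk <- generate_stack(grid, scene)
      objs <- filter_noise(extract_objects(segment_stack(stk), stk))
      objs <- objs[!objs$touches_edge, , drop = FALSE]
      scan <- tissue_concentration(objs, scanned_volume(grid), polymer)
      conc <- scan$mass_ng_per_100um3
      stage_tables$objects <- as.data.frame(objs)
      log_lines <- c(log_lines,
                     sprintf("confocal stage: %d objects retained", nrow(objs)))
    }
    if (is.null(conc)) stop("confocal mode needs lung$conc_ng_100um3 or confocal_synthetic")
    lungb <- organ_burden(conc, config$lung$volume_ml,
                          config$lung$weight_g, organ = "lung")
    lung_burden_mg <- lungb$total_mass_mg
    if (!is.null(config$ln$conc_ng_100um3))
      ln_burden_ug <- organ_burden(config$ln$conc_ng_100um3,
                                   config$ln$volume_ml,
                                   organ = "LN")$total_mass_ug
  } else if (mode == "pyro") {
    py <- config$pyro
    run <- generate_pyro_run(py$cal_mass_ng, py$slope,
                             if (is.null(py$intercept)) 0 else py$intercept,
                             if (is.null(py$noise_sd)) 0 else py$noise_sd,
                             seed = seed + 202L)
    curve <- fit_calibration(run$true_mass_ng, run$peak_area)
    stage_tables$calibration <- run
    if (!is.null(config$lung$burden_ug)) {
      lung_burden_mg <- config$lung$burden_ug * 1e-3
    } else if (!is.null(py$lung_true_mass_mg)) {
      # synthesise one lung sample: true organ mass -> crucible area
      crucible_ng <- py$lung_true_mass_mg * 1e6 /
        (py$extract_ml * 1000 / py$aliquot_ul)
      smp <- generate_pyro_run(crucible_ng, py$slope,
                               if (is.null(py$intercept)) 0 else py$intercept,
                               if (is.null(py$noise_sd)) 0 else py$noise_sd,
                               seed = seed + 203L)
      q <- quantify_organ(smp$peak_area, curve, py$aliquot_ul, py$extract_ml,
                          config$lung$weight_g)
      lung_burden_mg <- q$organ_mass_mg
    }
    if (!is.null(config$ln$burden_ug)) ln_burden_ug <- config$ln$burden_ug
    limits <- detection_limits(curve,
                               if (is.null(py$dilution_factor_ln))
                                 py$extract_ml * 1000 / py$aliquot_ul
                               else py$dilution_factor_ln)
  } else stop("unknown analysis mode: ", mode)

  aero <- NULL
  if (!is.null(config$aerosol)) {
    run <- generate_impactor_run(config$aerosol$mmad_um, config$aerosol$gsd,
                                 total_mass_mg = 10)
    aero <- aerosol_summary(sc$concentration_mg_m3, impactor_run = run)
    stage_tables$impactor <- run
  }

  kin <- NULL
  if (!is.null(config$kinetics)) {
    kx <- config$kinetics
    obs <- kx$observations
    if (is.null(obs) && !is.null(kx$synthetic)) {
      ks <- kx$synthetic
      spec <- burden_timecourse_spec(ks$n0_mg, as.data.frame(ks$phases),
                                     cv = if (is.null(ks$cv)) 0 else ks$cv,
                                     sampling_days = ks$sampling_days,
                                     n_animals = if (is.null(ks$n_animals)) 5
                                     else ks$n_animals,
                                     seed = seed + 303L)
      tc <- generate_burden_timecourse(spec)
      obs <- aggregate(burden_mg ~ day, tc, mean)
      names(obs)[2] <- "burden"
      stage_tables$timecourse <- tc
    }
    if (!is.null(obs)) {
      obs <- as.data.frame(obs)
      kin <- clearance_fit(obs, kx$phase_boundaries)
    }
  }

  dep <- if (is.finite(lung_burden_mg))
    deposition_fraction(lung_burden_mg, applied) else NA_real_
  over <- if (is.finite(lung_burden_mg) && !is.null(config$lung$weight_g))
    overload_check(lung_burden_mg, config$lung$weight_g) else NULL

  summary <- structure(list(
    polymer = polymer$name,
    applied_mass_mg = applied,
    lung_burden_mg = lung_burden_mg,
    ln_burden_ug = ln_burden_ug,
    deposition_pct = dep,
    half_times_days = if (is.null(kin)) NULL else kin$phases$half_time_days,
    lod_ug = if (is.null(limits)) NA_real_ else limits$lod_ug,
    loq_ug = if (is.null(limits)) NA_real_ else limits$loq_ug,
    overload = if (is.null(over)) NA else over$overload,
    mmad_um = if (is.null(aero)) NA_real_ else aero$mmad_um,
    gsd = if (is.null(aero)) NA_real_ else aero$gsd,
    seed = seed,
    kinetics = kin
  ), class = "study_summary")

  if (!is.null(out_dir)) {
    flat <- summary[!vapply(summary, is.null, logical(1))]
    flat$kinetics <- NULL
    jsonlite::write_json(flat, file.path(out_dir, "summary.json"),
                         auto_unbox = TRUE, digits = NA)
    df <- data.frame(quantity = names(flat),
                     value = vapply(flat, function(v)
                       paste(format(v, digits = 10), collapse = ";"),
                       character(1)))
    write.csv(df, file.path(out_dir, "summary.csv"), row.names = FALSE)
    for (nm in names(stage_tables))
      write.csv(stage_tables[[nm]],
                file.path(out_dir, paste0(nm, ".csv")), row.names = FALSE)
    writeLines(log_lines, file.path(out_dir, "run.log"))
  }
  summary
}

#' @export
print.study_summary <- function(x, ...) {
  cat(sprintf("study summary (%s):\n", x$polymer))
  cat(sprintf("  applied mass: %.4g mg; lung burden: %.3g mg; deposition: %.3g%%\n",
              x$applied_mass_mg, x$lung_burden_mg, x$deposition_pct))
  if (is.finite(x$ln_burden_ug))
    cat(sprintf("  LN burden: %.3g ug\n", x$ln_burden_ug))
  if (!is.null(x$half_times_days))
    cat(sprintf("  half-time(s): %s days\n",
                paste(signif(x$half_times_days, 4), collapse = ", ")))
  if (is.finite(x$lod_ug))
    cat(sprintf("  LOD/LOQ: %.3g / %.3g ug\n", x$lod_ug, x$loq_ug))
  invisible(x)
}
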
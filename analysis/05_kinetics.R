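#!/usr/bin/env Rscript
# Dosimetry and clearance kinetics: inhaled mass, deposition fraction,
# retention half-times and the lung-overload check for both polymers.
# Outputs under results/kinetics/.

library(nanoburden)

out <- "results/kinetics"
dir.create(out, showWarnings = FALSE, recursive = TRUE)
ref <- study_reference()

# -- dosimetry
ps_sc <- exposure_scenario(50, 360, 20, ref$ps$body_weight_kg)
pa_sc <- exposure_scenario(50, 360, 20, ref$pa6$body_weight_kg)
tab <- psnr_particle_table()
lung_conc <- mean(tab$mass_ng_per_100um3[tab$group == "MG" &
                                           tab$organ == "lung"])
ps_burden <- organ_burden(lung_conc, ref$lung_volume_ml)$total_mass_mg
dosim <- data.frame(
  polymer = c("PS-NR", "PA-6"),
  ventilation_l_min = c(ventilation_rate(ref$ps$body_weight_kg),
                        ventilation_rate(ref$pa6$body_weight_kg)),
  inhaled_mg = c(total_applied_mass(ps_sc), total_applied_mass(pa_sc)),
  lung_burden_mg = c(ps_burden, ref$pa6$lung_burden_mg))
dosim$deposition_pct <- deposition_fraction(dosim$lung_burden_mg,
                                            dosim$inhaled_mg)
write.csv(dosim, file.path(out, "dosimetry.csv"), row.names = FALSE)
print(dosim, row.names = FALSE, digits = 4)

# -- PS clearance from the two sampled timepoints (day 0 and day 35 means)
peg1_conc <- mean(tab$mass_ng_per_100um3[tab$group == "PEG1" &
                                           tab$organ == "lung"])
cf_ps <- clearance_fit(data.frame(day = c(0, 35),
                                  burden = c(lung_conc, peg1_conc)))
cat(sprintf("\nPS retention half-time from group means: %.1f days\n",
            cf_ps$phases$half_time_days))

# -- PA-6 biphasic clearance from a synthetic per-animal time course
spec <- burden_timecourse_spec(ref$pa6$lung_burden_mg,
                               data.frame(end_day = c(35, Inf),
                                          half_time = c(68, 226)),
                               cv = 0.3, sampling_days = c(0, 35, 91),
                               n_animals = 5, seed = 20260925L)
tc <- generate_burden_timecourse(spec)
means <- aggregate(burden_mg ~ day, tc, mean)
names(means)[2] <- "burden"
cf_pa <- clearance_fit(means, phase_boundaries = 35)
print(cf_pa)
write.csv(cf_pa$phases, file.path(out, "pa6_clearance_phases.csv"),
          row.names = FALSE)
# with only 5 animals per timepoint at 30% inter-animal CV, a single study
# scatters widely around the generating half-times; the noise-free group
# means recover them exactly:
exact <- clearance_fit(data.frame(
  day = c(0, 35, 91),
  burden = clearance_curve(ref$pa6$lung_burden_mg,
                           data.frame(end_day = c(35, Inf),
                                      half_time = c(68, 226)),
                           c(0, 35, 91))), phase_boundaries = 35)
cat(sprintf("noise-free means recover the generating half-times: %s days\n",
            paste(signif(exact$phases$half_time_days, 4), collapse = ", ")))

# -- overload
ov <- data.frame(
  case = c("PS 50 mg/m^3", "PA-6 50 mg/m^3", "PA-6 10 mg/m^3",
           "PA-6 2 mg/m^3"),
  burden_mg = c(ps_burden, 3.8, 1.2, 0.26),
  lung_g = c(1.63, 1.05, 0.94, 0.91))
ov$mg_per_g <- ov$burden_mg / ov$lung_g
ov$overload <- vapply(seq_len(nrow(ov)), function(i)
  overload_check(ov$burden_mg[i], ov$lung_g[i])$overload, logical(1))
write.csv(ov, file.path(out, "overload.csv"), row.names = FALSE)
print(ov, row.names = FALSE, digits = 3)
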
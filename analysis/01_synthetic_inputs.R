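#!/usr/bin/env Rscript
# Generates the synthetic study inputs that stand in for the animal
# experiment: a ground-truthed confocal stack, a per-animal lung-burden
# time course, a pyrolysis calibration run and a cascade-impactor run.
# Outputs under results/synthetic/.

library(nanoburden)

out <- "results/synthetic"
dir.create(out, showWarnings = FALSE, recursive = TRUE)
seed <- 20260920L

# -- confocal stack: 23 x 23 x 14.4 um sub-volume, 50 agglomerates with the
#    in-tissue size distribution (mode ~0.9 um), high SNR
grid <- image_grid(192, 192, 48)
scene <- random_scene(grid, 50, meanlog = log(0.9), sdlog = 0.15,
                      intensity = 100, min_separation = 3, margin = 2,
                      seed = seed)
stk <- generate_stack(grid, scene)
write_stack_tiff(stk, file.path(out, "lung_stack.tif"))
write_scene_yaml(scene, file.path(out, "lung_scene.yaml"))
cat(sprintf("stack: %d x %d x %d voxels, %d ground-truth agglomerates, %s\n",
            grid$nx, grid$ny, grid$nz, nrow(scene$agglomerates),
            "written with JSON ground-truth sidecar"))

# -- per-animal lung burdens: biphasic clearance (68 d to day 35, then
#    226 d), inter-animal CV 30%, 5 animals at days 0 / 35 / 91
spec <- burden_timecourse_spec(3.8,
                               data.frame(end_day = c(35, Inf),
                                          half_time = c(68, 226)),
                               cv = 0.3, sampling_days = c(0, 35, 91),
                               n_animals = 5, seed = seed + 1L)
tc <- generate_burden_timecourse(spec)
write.csv(tc, file.path(out, "lung_burden_timecourse.csv"), row.names = FALSE)
cat(sprintf("burden time course: %d animals, group means %s mg\n", nrow(tc),
            paste(signif(tapply(tc$burden_mg, tc$day, mean), 3),
                  collapse = " / ")))

# -- pyrolysis calibration: lymph-node series from the 49 mg / 25 mL stock
masses <- dilution_series_mass(49, 25, 50, 10, c(2, 10, 40, 115))
cal <- generate_pyro_run(rep(masses, each = 3), slope = 2.2, intercept = 8,
                         noise_sd = 15, seed = seed + 2L)
write.csv(cal, file.path(out, "pyro_calibration.csv"), row.names = FALSE)
cat(sprintf("pyro calibration: %d crucibles over %.3g-%.4g ng\n",
            nrow(cal), min(masses), max(masses)))

# -- impactor run at the PA-6 high-concentration size distribution
imp <- generate_impactor_run(1.51, 2.04, total_mass_mg = 10,
                             noise_cv = 0.05, seed = seed + 3L)
write.csv(imp, file.path(out, "impactor_run.csv"), row.names = FALSE)
cat(sprintf("impactor run: %d stages + filter, %.3g mg collected\n",
            sum(!is.na(imp$cutoff_um)), sum(imp$mass_mg)))
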
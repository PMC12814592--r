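# Shared fixtures: small grids and scenes built in code.

# grid with the standard anisotropic voxel (0.12 / 0.12 / 0.30 um)
small_grid <- function(nx = 64, ny = 64, nz = 24) image_grid(nx, ny, nz)

# scene with explicitly placed spheres; fade disabled unless asked for
placed_scene <- function(grid, x, y, z, diameter, intensity = 100,
                         fade_length = 1e6, shot_scale = 0,
                         read_noise_sd = 0, seed = 1) {
  ground_truth_scene(
    data.frame(x = x, y = y, z = z, diameter = diameter,
               intensity = intensity),
    background = 1, fade_length = fade_length, shot_scale = shot_scale,
    read_noise_sd = read_noise_sd, seed = seed)
}

empty_scene <- function(seed = 1, background = 1) {
  ground_truth_scene(
    data.frame(x = numeric(0), y = numeric(0), z = numeric(0),
               diameter = numeric(0), intensity = numeric(0)),
    background = background, shot_scale = 0.05, read_noise_sd = 0.2,
    seed = seed)
}

# classifier trained on a ground-truthed stack, labelling voxels well inside
# spheres as foreground and voxels far from any signal as background
trained_classifier <- function(seed = 7) {
  g <- image_grid(128, 128, 36)
  sc <- random_scene(g, 10, meanlog = log(0.9), sdlog = 0.15,
                     intensity = 100, min_separation = 3, margin = 2,
                     fade_length = 1e6, seed = seed)
  stk <- generate_stack(g, sc)
  sig <- stk$clean - sc$background
  labs <- array(NA_real_, dim(stk$data))
  labs[sig > 50] <- 1
  labs[sig < 2] <- 0
  train_pixel_classifier(stk, labs, seed = seed + 1)
}

# the standard high-SNR recovery scene used for imaging-recovery checks
recovery_stack <- function(n = 50, seed = 42) {
  g <- image_grid(192, 192, 48)
  sc <- random_scene(g, n, meanlog = log(0.9), sdlog = 0.15,
                     intensity = 100, min_separation = 3, margin = 2,
                     fade_length = 1e6, seed = seed)
  generate_stack(g, sc)
}

biphasic_phases <- function() {
  data.frame(end_day = c(35, Inf), half_time = c(68, 226))
}
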
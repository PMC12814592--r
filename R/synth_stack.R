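# Synthetic confocal stack generator: ground-truthed fluorescent agglomerates
# rendered into an anisotropic voxel grid, blurred with a Gaussian PSF,
# attenuated with depth and corrupted with shot + read noise.

#' Ground-truth scene for a synthetic confocal stack
#'
#' Holds the emitters (spherical agglomerates) and the optical/noise
#' parameters used to synthesise a stack. Positions and diameters are in
#' micrometres; intensities are arbitrary units per fully occupied voxel.
#'
#' @param agglomerates data.frame with columns `x`, `y`, `z` (centre, um),
#'   `diameter` (um) and `intensity` (a.u.). May have zero rows.
#' @param background constant autofluorescence level (a.u.).
#' @param fade_length depth-fade length scale L (um): emitter signal at depth
#'   z is scaled by `exp(-z / L)`. The default puts contrast at 53 um depth
#'   at ~25% of the surface value, matching the depth beyond which objects
#'   stop being detectable in fixed lung tissue.
#' @param shot_scale scale of the mean-proportional (shot) noise term: the
#'   noise SD contribution is `shot_scale * sqrt(signal)`.
#' @param read_noise_sd additive Gaussian read-noise SD (a.u.).
#' @param seed integer seed; mandatory, recorded in the scene.
#' @return object of class `ground_truth_scene`.
#' @export
ground_truth_scene <- function(agglomerates,
                               background = 1,
                               fade_length = 53 / log(4),
                               shot_scale = 0.1,
                               read_noise_sd = 0.5,
                               seed) {
  if (missing(seed)) stop("a seed is required")
  stopifnot(is.data.frame(agglomerates),
            all(c("x", "y", "z", "diameter", "intensity") %in%
                  names(agglomerates)))
  if (nrow(agglomerates) > 0 && any(agglomerates$diameter <= 0))
    stop("agglomerate diameters must be > 0")
  if (background < 0) stop("background must be >= 0")
  if (fade_length <= 0) stop("fade_length must be > 0")
  if (shot_scale < 0 || read_noise_sd < 0)
    stop("noise parameters must be >= 0")
  structure(list(agglomerates = agglomerates, background = background,
                 fade_length = fade_length, shot_scale = shot_scale,
                 read_noise_sd = read_noise_sd, seed = as.integer(seed)),
            class = "ground_truth_scene")
}

#' Randomly placed, non-overlapping scene
#'
#' Draws `n` agglomerates with lognormal diameters (defaults emulate the
#' broad in-tissue size distribution peaking between 0.5 and 1 um), placed
#' uniformly at random with a minimum centre-to-centre separation and a
#' margin to the stack faces so no object touches an edge.
#'
#' @param grid [image_grid()].
#' @param n number of agglomerates.
#' @param meanlog,sdlog lognormal diameter parameters (log-um).
#' @param intensity emitter intensity (a.u. per occupied voxel).
#' @param min_separation minimum centre separation (um); default 3 um keeps
#'   objects resolvable at ~0.2/0.5 um resolution.
#' @param margin distance kept from all faces (um).
#' @param seed integer seed.
#' @inheritParams ground_truth_scene
#' @return `ground_truth_scene`.
#' @export
random_scene <- function(grid, n, meanlog = log(0.7), sdlog = 0.3,
                         intensity = 100, min_separation = 3, margin = 2,
                         background = 1, fade_length = 53 / log(4),
                         shot_scale = 0.1, read_noise_sd = 0.5, seed) {
  if (missing(seed)) stop("a seed is required")
  stopifnot(inherits(grid, "image_grid"), n >= 0)
  with_seed(seed, {
    d <- rlnorm(n, meanlog, sdlog)
    lo <- c(margin, margin, margin)
    hi <- c(grid$field_x - margin, grid$field_y - margin, grid$depth - margin)
    if (any(hi <= lo)) stop("grid too small for the requested margin")
    pts <- matrix(NA_real_, nrow = n, ncol = 3)
    placed <- 0
    tries <- 0
    while (placed < n) {
      tries <- tries + 1
      if (tries > 20000 * max(n, 1))
        stop("could not place non-overlapping agglomerates; reduce n or min_separation")
      p <- lo + stats::runif(3) * (hi - lo)
      if (placed == 0 ||
          all(sqrt(colSums((t(pts[seq_len(placed), , drop = FALSE]) - p)^2)) >=
                min_separation)) {
        placed <- placed + 1
        pts[placed, ] <- p
      }
    }
    agg <- data.frame(x = pts[, 1], y = pts[, 2], z = pts[, 3],
                      diameter = d, intensity = intensity)
    ground_truth_scene(agg, background = background,
                       fade_length = fade_length, shot_scale = shot_scale,
                       read_noise_sd = read_noise_sd, seed = seed)
  })
}

#' Synthesise a confocal image stack from a ground-truth scene
#'
#' Renders each spherical agglomerate into the voxel grid with sub-voxel
#' occupancy sampling, convolves with the separable Gaussian PSF, attenuates
#' the emitter signal with depth (`exp(-z / fade_length)`), adds the constant
#' background and then mean-proportional shot noise plus Gaussian read noise.
#' Negative noisy values are clipped at zero.
#'
#' @param grid [image_grid()].
#' @param scene [ground_truth_scene()].
#' @param psf [psf_model()]; `NULL` skips blurring.
#' @return object of class `image_stack`: list with `data` (3D array,
#'   dim `c(nx, ny, nz)`), `grid`, `channel` and the `scene` (ground truth,
#'   returned unchanged).
#' @export
generate_stack <- function(grid, scene, psf = psf_model()) {
  stopifnot(inherits(grid, "image_grid"),
            inherits(scene, "ground_truth_scene"))
  agg <- scene$agglomerates
  if (nrow(agg) > 0) {
    if (any(agg$diameter > min(grid$field_x, grid$field_y, grid$depth)))
      stop("agglomerate diameter exceeds the field extent")
    out_of_grid <- agg$x < 0 | agg$x > grid$field_x |
      agg$y < 0 | agg$y > grid$field_y | agg$z < 0 | agg$z > grid$depth
    if (any(out_of_grid))
      warning(sum(out_of_grid), " agglomerate centre(s) outside the grid")
  }
  dims <- c(grid$nx, grid$ny, grid$nz)
  img <- numeric(prod(dims))
  dim(img) <- dims
  for (i in seq_len(nrow(agg))) {
    # finer sub-voxel occupancy sampling for spheres near the voxel scale
    nsub <- min(16L, max(4L, as.integer(ceiling(
      8 * max(grid$dx, grid$dy, grid$dz) / agg$diameter[i]))))
    add_sphere_3d(img, dims, c(grid$dx, grid$dy, grid$dz),
                  c(agg$x[i], agg$y[i], agg$z[i]),
                  agg$diameter[i], agg$intensity[i], nsub = nsub)
  }
  if (!is.null(psf)) {
    stopifnot(inherits(psf, "psf_model"))
    sig <- c(psf$sigma_lateral / grid$dx, psf$sigma_lateral / grid$dy,
             psf$sigma_axial / grid$dz)
    img <- gaussian_blur_3d(img, as.integer(dims), sig)
    dim(img) <- dims
  }
  z_depth <- (seq_len(grid$nz) - 0.5) * grid$dz
  fade <- exp(-z_depth / scene$fade_length)
  img <- sweep(img, 3, fade, `*`)
  clean <- img + scene$background
  noisy <- with_seed(scene$seed, {
    clean +
      rnorm(length(clean), 0, 1) * scene$shot_scale * sqrt(clean) +
      rnorm(length(clean), 0, scene$read_noise_sd)
  })
  noisy[noisy < 0] <- 0
  dim(noisy) <- dims
  structure(list(data = noisy, clean = clean, grid = grid,
                 channel = "fluorescence", scene = scene),
            class = "image_stack")
}

#' @export
print.image_stack <- function(x, ...) {
  cat(sprintf("image_stack (%s): %d x %d x %d voxels, %d ground-truth object(s)\n",
              x$channel, x$grid$nx, x$grid$ny, x$grid$nz,
              nrow(x$scene$agglomerates)))
  invisible(x)
}

# Run code with a private RNG stream; the caller's .Random.seed is restored.
with_seed <- function(seed, code) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  code
}
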
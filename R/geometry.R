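#' Confocal image grid geometry
#'
#' Describes the voxel raster of a confocal xyz stack: anisotropic voxels
#' (lateral size `dx = dy`, axial size `dz`, all in micrometres) on an
#' `nx x ny x nz` grid. Defaults follow a high-NA oil-immersion setup:
#' 0.12 um lateral voxels over a 246 um field and 0.30 um axial steps.
#'
#' @param nx,ny,nz voxel counts along x, y and z.
#' @param dx,dy lateral voxel size (um); must be equal.
#' @param dz axial voxel size (um).
#' @return An object of class `image_grid` with the voxel counts, voxel
#'   sizes, physical field extents (`field_x`, `field_y`, `depth`, um) and
#'   the voxel volume (`voxel_volume`, um^3).
#' @examples
#' g <- image_grid(nx = 64, ny = 64, nz = 20)
#' g$voxel_volume   # 0.12 * 0.12 * 0.30 = 0.00432 um^3
#' @export
image_grid <- function(nx = 2050, ny = 2050, nz = 334,
                       dx = 0.12, dy = 0.12, dz = 0.30) {
  stopifnot(nx >= 1, ny >= 1, nz >= 1, dx > 0, dz > 0)
  if (!isTRUE(all.equal(dx, dy)))
    stop("lateral voxel sizes dx and dy must be equal")
  structure(list(
    nx = as.integer(nx), ny = as.integer(ny), nz = as.integer(nz),
    dx = dx, dy = dy, dz = dz,
    field_x = nx * dx, field_y = ny * dy, depth = nz * dz,
    voxel_volume = dx * dy * dz
  ), class = "image_grid")
}

#' @export
print.image_grid <- function(x, ...) {
  cat(sprintf("image_grid: %d x %d x %d voxels (%.3g x %.3g x %.3g um), voxel %g x %g x %g um\n",
              x$nx, x$ny, x$nz, x$field_x, x$field_y, x$depth,
              x$dx, x$dy, x$dz))
  invisible(x)
}

#' Point-spread-function model
#'
#' Separable anisotropic Gaussian surrogate for the confocal PSF,
#' parameterised by its lateral and axial full width at half maximum.
#' Defaults correspond to a 1.40 NA objective (about 200 nm lateral,
#' 500 nm axial resolution). `sigma = FWHM / (2 sqrt(2 ln 2))`.
#'
#' @param fwhm_lateral,fwhm_axial resolution (um); axial must be >= lateral.
#' @return An object of class `psf_model` with FWHMs and Gaussian sigmas.
#' @export
psf_model <- function(fwhm_lateral = 0.2, fwhm_axial = 0.5) {
  stopifnot(fwhm_lateral > 0)
  if (fwhm_axial < fwhm_lateral)
    stop("axial FWHM must be >= lateral FWHM")
  k <- 2 * sqrt(2 * log(2))  # 2.3548
  structure(list(fwhm_lateral = fwhm_lateral, fwhm_axial = fwhm_axial,
                 sigma_lateral = fwhm_lateral / k,
                 sigma_axial = fwhm_axial / k),
            class = "psf_model")
}

#' Equivalent sphere diameter of a volume
#'
#' Diameter of the sphere with the same volume, `(6 V / pi)^(1/3)`.
#'
#' @param volume_um3 volume(s) in um^3.
#' @return diameter(s) in um.
#' @examples
#' eq_sphere_diameter(pi / 6)  # 1
#' @export
eq_sphere_diameter <- function(volume_um3) {
  stopifnot(all(volume_um3 >= 0))
  (6 * volume_um3 / pi)^(1 / 3)
}

#' Volume of a sphere from its diameter
#' @param diameter_um diameter(s) in um.
#' @return volume(s) in um^3.
#' @export
sphere_volume <- function(diameter_um) pi / 6 * diameter_um^3
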
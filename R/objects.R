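# Per-object morphometrics, noise filtering, packing-density mass model and
# organ extrapolation.

#' Polymer specification for mass conversion
#'
#' @param name polymer name.
#' @param density_g_cm3 bulk density (g/cm^3); 1.05 for polystyrene
#'   (helium pycnometry).
#' @param packing packing density of primary particles within an irregular
#'   agglomerate (0 < packing <= 1); 0.64 corresponds to random close
#'   packing.
#' @return object of class `polymer_spec`.
#' @examples
#' polystyrene <- polymer_spec("PS", 1.05, 0.64)
#' @export
polymer_spec <- function(name, density_g_cm3, packing = 0.64) {
  stopifnot(density_g_cm3 > 0, packing > 0, packing <= 1)
  structure(list(name = name, density_g_cm3 = density_g_cm3,
                 packing = packing), class = "polymer_spec")
}

#' Extract per-object metrics from a label field
#'
#' For each labelled connected component: voxel count, physical volume
#' (voxel count x voxel volume), equivalent sphere diameter
#' `(6V/pi)^(1/3)`, mean intensity, deepest z position (um, voxel-centre
#' convention) and whether the object touches any of the six stack faces.
#'
#' @param labels integer label array from [segment_stack()].
#' @param stack the segmented `image_stack`.
#' @return data.frame of class `segmented_objects`, one row per object:
#'   `label`, `voxels`, `volume_um3`, `eq_diameter_um`, `mean_intensity`,
#'   `deepest_z_um`, `touches_edge`.
#' @export
extract_objects <- function(labels, stack) {
  stopifnot(inherits(stack, "image_stack"),
            all(dim(labels) == dim(stack$data)))
  grid <- stack$grid
  idx <- which(labels > 0)
  out <- data.frame(label = integer(0), voxels = integer(0),
                    volume_um3 = numeric(0), eq_diameter_um = numeric(0),
                    mean_intensity = numeric(0), deepest_z_um = numeric(0),
                    touches_edge = logical(0))
  if (length(idx) > 0) {
    lab <- labels[idx]
    ints <- stack$data[idx]
    co <- arrayInd(idx, dim(labels))
    voxels <- as.integer(table(lab))
    ulab <- as.integer(names(table(lab)))
    mean_int <- as.numeric(tapply(ints, lab, mean))
    deepest_vox <- as.integer(tapply(co[, 3], lab, max))
    edge <- as.logical(tapply(
      co[, 1] == 1 | co[, 1] == grid$nx |
        co[, 2] == 1 | co[, 2] == grid$ny |
        co[, 3] == 1 | co[, 3] == grid$nz,
      lab, any))
    vol <- voxels * grid$voxel_volume
    out <- data.frame(label = ulab, voxels = voxels, volume_um3 = vol,
                      eq_diameter_um = eq_sphere_diameter(vol),
                      mean_intensity = mean_int,
                      deepest_z_um = (deepest_vox - 0.5) * grid$dz,
                      touches_edge = edge)
  }
  class(out) <- c("segmented_objects", "data.frame")
  out
}

#' Remove noise-sized objects
#'
#' Objects spanning fewer than `min_voxels` voxels are removed (the default
#' keeps objects of at least 6 voxels, i.e. excludes those of <= 5 voxels,
#' the size at or below which detections are considered background noise).
#' Order is preserved; the operation is idempotent.
#'
#' @param objects `segmented_objects` from [extract_objects()].
#' @param min_voxels smallest retained voxel count (>= 1).
#' @return filtered `segmented_objects`.
#' @export
filter_noise <- function(objects, min_voxels = 6) {
  stopifnot(min_voxels >= 1)
  out <- objects[objects$voxels >= min_voxels, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Polymer mass of a segmented object
#'
#' `mass = volume x packing x density`, with the um^3 -> cm^3 conversion
#' (1 um^3 = 1e-12 cm^3), so the result is in grams.
#'
#' @param objects `segmented_objects` (or any data.frame with
#'   `volume_um3`), or a numeric vector of volumes in um^3.
#' @param polymer [polymer_spec()].
#' @return mass(es) in grams.
#' @examples
#' ps <- polymer_spec("PS", 1.05, 0.64)
#' object_mass(sphere_volume(1.0), ps)  # ~3.52e-13 g = 0.352 pg
#' @export
object_mass <- function(objects, polymer) {
  if (missing(polymer) || !inherits(polymer, "polymer_spec"))
    stop("a polymer_spec is required")
  vol <- if (is.data.frame(objects)) objects$volume_um3 else objects
  stopifnot(all(vol >= 0))
  vol * polymer$packing * polymer$density_g_cm3 * 1e-12
}

#' Tissue concentrations per (100 um)^3
#'
#' Number and mass concentrations of retained objects, expressed per cubic
#' volume with 100 um edge length (1e6 um^3). Edge-touching objects must
#' already be excluded (`filter_noise()` + edge exclusion); the function
#' drops any remaining `touches_edge` rows defensively.
#'
#' @param objects filtered `segmented_objects`.
#' @param scanned_volume_um3 total scanned tissue volume (um^3, > 0).
#' @param polymer [polymer_spec()] used for the mass concentration.
#' @return object of class `tissue_scan`: list with `n_objects`,
#'   `total_mass_ng`, `scanned_volume_um3`, `number_per_100um3` and
#'   `mass_ng_per_100um3`.
#' @export
tissue_concentration <- function(objects, scanned_volume_um3, polymer) {
  if (scanned_volume_um3 <= 0) stop("scanned volume must be > 0")
  if ("touches_edge" %in% names(objects))
    objects <- objects[!objects$touches_edge, , drop = FALSE]
  mass_ng <- sum(object_mass(objects, polymer)) * 1e9
  ref_vols <- scanned_volume_um3 / 1e6
  structure(list(
    n_objects = nrow(objects),
    total_mass_ng = mass_ng,
    scanned_volume_um3 = scanned_volume_um3,
    number_per_100um3 = nrow(objects) / ref_vols,
    mass_ng_per_100um3 = mass_ng / ref_vols
  ), class = "tissue_scan")
}

#' Scanned volume of a stack
#'
#' Physical volume of the scanned raster. By default the configured stack
#' extent; with `truncate_at_deepest = TRUE` the axial extent is truncated
#' at the deepest detected object (the depth down to which objects are
#' actually detectable), a stricter reading of "all scanned tissue
#' volumes".
#'
#' @param grid [image_grid()].
#' @param objects optional `segmented_objects` (needed for truncation).
#' @param truncate_at_deepest logical.
#' @return volume in um^3.
#' @export
scanned_volume <- function(grid, objects = NULL, truncate_at_deepest = FALSE) {
  depth <- grid$depth
  if (truncate_at_deepest) {
    if (is.null(objects) || nrow(objects) == 0)
      stop("truncation needs detected objects")
    depth <- max(objects$deepest_z_um) + 0.5 * grid$dz
  }
  grid$field_x * grid$field_y * depth
}

#' Extrapolate a tissue concentration to an organ burden
#'
#' Total organ mass = mass concentration per (100 um)^3 x organ volume
#' expressed in (100 um)^3 units (1 mL = 1 cm^3 = 1e6 x (100 um)^3).
#'
#' @param scan `tissue_scan` from [tissue_concentration()], or a bare mass
#'   concentration in ng per (100 um)^3.
#' @param organ_volume_ml organ volume (mL, > 0); e.g. ~10 mL whole lung,
#'   ~0.03 mL lymph node.
#' @param organ_weight_g optional organ wet weight (g) for the per-gram
#'   value.
#' @param organ organ label.
#' @return object of class `burden_estimate`: `organ`, `organ_volume_ml`,
#'   `total_mass_mg`, `total_mass_ug`, and (if weight given)
#'   `organ_weight_g`, `mass_per_g_mg`.
#' @examples
#' organ_burden(0.42, organ_volume_ml = 10)$total_mass_mg  # 4.2
#' @export
organ_burden <- function(scan, organ_volume_ml, organ_weight_g = NULL,
                         organ = "lung") {
  conc <- if (inherits(scan, "tissue_scan")) scan$mass_ng_per_100um3 else scan
  if (organ_volume_ml <= 0) stop("organ volume must be > 0")
  if (conc < 0) stop("mass concentration must be >= 0")
  total_ng <- conc * organ_volume_ml * 1e6  # (100 um)^3 units per mL
  out <- list(organ = organ, organ_volume_ml = organ_volume_ml,
              total_mass_mg = total_ng * 1e-6,
              total_mass_ug = total_ng * 1e-3)
  if (!is.null(organ_weight_g)) {
    if (organ_weight_g <= 0) stop("organ weight must be > 0")
    out$organ_weight_g <- organ_weight_g
    out$mass_per_g_mg <- out$total_mass_mg / organ_weight_g
  }
  structure(out, class = "burden_estimate")
}

#' @export
print.burden_estimate <- function(x, ...) {
  cat(sprintf("%s burden: %.3g mg (%.3g ug) in %.3g mL",
              x$organ, x$total_mass_mg, x$total_mass_ug, x$organ_volume_ml))
  if (!is.null(x$mass_per_g_mg))
    cat(sprintf("; %.3g mg/g (%.3g g wet)", x$mass_per_g_mg, x$organ_weight_g))
  cat("\n")
  invisible(x)
}

#' Relative-frequency size histogram of segmented objects
#'
#' @param objects `segmented_objects` (uses `eq_diameter_um`).
#' @param breaks bin edges (um) covering the observed diameters.
#' @return data.frame `bin_lo`, `bin_hi`, `mid`, `count`, `frequency`
#'   (frequencies sum to 1); zero rows for empty input.
#' @export
size_histogram <- function(objects, breaks = seq(0, 10, by = 0.5)) {
  d <- objects$eq_diameter_um
  if (length(d) == 0)
    return(data.frame(bin_lo = numeric(0), bin_hi = numeric(0),
                      mid = numeric(0), count = integer(0),
                      frequency = numeric(0)))
  if (min(d) < min(breaks) || max(d) > max(breaks))
    stop("breaks do not cover the observed diameters")
  h <- hist(d, breaks = breaks, plot = FALSE)
  data.frame(bin_lo = head(breaks, -1), bin_hi = breaks[-1],
             mid = h$mids, count = h$counts,
             frequency = h$counts / sum(h$counts))
}
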
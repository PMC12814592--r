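# I/O: multi-page 16-bit TIFF stacks with a JSON ground-truth sidecar,
# CSV tables, YAML generator specs.

#' Write an image stack as multi-page TIFF plus JSON sidecar
#'
#' One 16-bit page per z-slice. Intensities are scaled into [0, 1] by
#' `max_intensity` (defaults to the stack maximum) before quantisation; the
#' scale and grid geometry go into the sidecar together with the ground
#' truth, so the stack can be re-read quantitatively.
#'
#' @param stack `image_stack`.
#' @param path TIFF path; the sidecar is written next to it as
#'   `<path>.json`.
#' @param max_intensity intensity mapped to the 16-bit maximum.
#' @return `path`, invisibly.
#' @export
write_stack_tiff <- function(stack, path, max_intensity = NULL) {
  stopifnot(inherits(stack, "image_stack"))
  x <- stack$data
  if (is.null(max_intensity)) max_intensity <- max(x, 1e-12)
  pages <- lapply(seq_len(dim(x)[3]), function(z)
    pmin(x[, , z] / max_intensity, 1))
  tiff::writeTIFF(pages, path, bits.per.sample = 16L)
  g <- stack$grid
  sidecar <- list(
    grid = list(nx = g$nx, ny = g$ny, nz = g$nz,
                dx = g$dx, dy = g$dy, dz = g$dz),
    channel = stack$channel,
    max_intensity = max_intensity,
    ground_truth = list(
      agglomerates = stack$scene$agglomerates,
      background = stack$scene$background,
      fade_length = stack$scene$fade_length,
      shot_scale = stack$scene$shot_scale,
      read_noise_sd = stack$scene$read_noise_sd,
      seed = stack$scene$seed
    )
  )
  jsonlite::write_json(sidecar, paste0(path, ".json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")
  invisible(path)
}

#' Read a multi-page TIFF stack (with optional sidecar)
#'
#' @param path TIFF path. If `<path>.json` exists, grid geometry, intensity
#'   scale and ground truth are restored from it; otherwise `grid` must be
#'   supplied and intensities stay in [0, 1].
#' @param grid [image_grid()] used when no sidecar is present.
#' @return `image_stack`.
#' @export
read_stack_tiff <- function(path, grid = NULL) {
  pages <- tiff::readTIFF(path, all = TRUE)
  nz <- length(pages)
  arr <- array(unlist(pages), dim = c(dim(pages[[1]]), nz))
  sidecar_path <- paste0(path, ".json")
  scene <- NULL
  scale <- 1
  if (file.exists(sidecar_path)) {
    sc <- jsonlite::read_json(sidecar_path, simplifyVector = TRUE)
    grid <- image_grid(sc$grid$nx, sc$grid$ny, sc$grid$nz,
                       sc$grid$dx, sc$grid$dy, sc$grid$dz)
    scale <- sc$max_intensity
    agg <- as.data.frame(sc$ground_truth$agglomerates)
    if (nrow(agg) == 0)
      agg <- data.frame(x = numeric(0), y = numeric(0), z = numeric(0),
                        diameter = numeric(0), intensity = numeric(0))
    scene <- ground_truth_scene(agg,
                                background = sc$ground_truth$background,
                                fade_length = sc$ground_truth$fade_length,
                                shot_scale = sc$ground_truth$shot_scale,
                                read_noise_sd = sc$ground_truth$read_noise_sd,
                                seed = sc$ground_truth$seed)
  }
  if (is.null(grid)) stop("no sidecar found; supply a grid")
  stopifnot(grid$nx == dim(arr)[1], grid$ny == dim(arr)[2], grid$nz == nz)
  if (is.null(scene))
    scene <- ground_truth_scene(
      data.frame(x = numeric(0), y = numeric(0), z = numeric(0),
                 diameter = numeric(0), intensity = numeric(0)), seed = 0)
  structure(list(data = arr * scale, grid = grid,
                 channel = "fluorescence", scene = scene),
            class = "image_stack")
}

#' Write / read a scene specification as YAML
#'
#' @param scene `ground_truth_scene`.
#' @param path YAML file path.
#' @return `path` (write) or a `ground_truth_scene` (read).
#' @export
write_scene_yaml <- function(scene, path) {
  stopifnot(inherits(scene, "ground_truth_scene"))
  yaml::write_yaml(list(
    agglomerates = lapply(seq_len(nrow(scene$agglomerates)), function(i)
      as.list(scene$agglomerates[i, ])),
    background = scene$background,
    fade_length = scene$fade_length,
    shot_scale = scene$shot_scale,
    read_noise_sd = scene$read_noise_sd,
    seed = scene$seed
  ), path)
  invisible(path)
}

#' @rdname write_scene_yaml
#' @export
read_scene_yaml <- function(path) {
  y <- yaml::read_yaml(path)
  agg <- if (length(y$agglomerates) > 0)
    do.call(rbind, lapply(y$agglomerates, as.data.frame))
  else
    data.frame(x = numeric(0), y = numeric(0), z = numeric(0),
               diameter = numeric(0), intensity = numeric(0))
  ground_truth_scene(agg, background = y$background,
                     fade_length = y$fade_length,
                     shot_scale = y$shot_scale,
                     read_noise_sd = y$read_noise_sd, seed = y$seed)
}

#' Write segmented objects to CSV
#'
#' One row per object: label, voxels, volume_um3, eq_diameter_um,
#' mean_intensity, deepest_z_um, edge flag.
#'
#' @param objects `segmented_objects`.
#' @param path CSV path.
#' @export
write_objects_csv <- function(objects, path) {
  write.csv(as.data.frame(objects), path, row.names = FALSE)
  invisible(path)
}
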
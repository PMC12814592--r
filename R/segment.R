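# 3D segmentation of the fluorescence channel: global Otsu or absolute
# thresholding, or a small trained pixel classifier on multi-scale Gaussian
# features, followed by 26-connectivity connected components.

#' Segment fluorescent objects in a 3D stack
#'
#' Produces an integer label field (0 = background) by thresholding or pixel
#' classification followed by 3D connected-component labelling
#' (26-connectivity by default).
#'
#' Backends:
#' * `"otsu"` — global Otsu threshold over all voxels ([EBImage::otsu]).
#' * `"absolute"` — fixed intensity threshold `threshold`.
#' * `"classifier"` — per-voxel foreground probability from a classifier
#'   trained with [train_pixel_classifier()]; voxels with probability
#'   > 0.5 are foreground.
#'
#' The `sensitive` preset lowers the effective threshold (Otsu/absolute
#' backends: threshold scaled by `sensitivity_factor`), emulating a more
#' sensitive but less separative configuration used for remote organs.
#'
#' @param stack an `image_stack` (fluorescence channel).
#' @param method `"otsu"`, `"absolute"` or `"classifier"`.
#' @param threshold absolute intensity threshold (`method = "absolute"`).
#' @param classifier fitted classifier from [train_pixel_classifier()].
#' @param connectivity 6 or 26.
#' @param sensitive logical; apply the sensitive preset.
#' @param sensitivity_factor multiplier (< 1) applied to the threshold in
#'   sensitive mode.
#' @return integer array of labels, same dimensions as the stack, with
#'   attributes `n_labels` and `threshold` (NA for the classifier backend).
#' @export
segment_stack <- function(stack, method = c("otsu", "absolute", "classifier"),
                          threshold = NULL, classifier = NULL,
                          connectivity = 26, sensitive = FALSE,
                          sensitivity_factor = 0.5) {
  stopifnot(inherits(stack, "image_stack"))
  method <- match.arg(method)
  x <- stack$data
  if (anyNA(x)) stop("stack contains NA voxels")
  stopifnot(all(x >= 0))
  dims <- dim(x)
  if (method == "classifier") {
    if (is.null(classifier)) stop("method 'classifier' needs a classifier")
    prob <- predict_voxel_prob(classifier, x, stack$grid)
    mask <- prob > 0.5
    thr <- NA_real_
  } else {
    if (method == "otsu") {
      rng <- range(x)
      if (diff(rng) == 0) {
        # flat stack: nothing to separate
        thr <- Inf
      } else {
        thr <- EBImage::otsu(EBImage::Image(matrix(as.vector(x), nrow = dims[1])),
                             range = rng, levels = 4096)
      }
    } else {
      if (is.null(threshold)) stop("method 'absolute' needs a threshold")
      thr <- threshold
    }
    if (sensitive) thr <- thr * sensitivity_factor
    mask <- x > thr
  }
  labels <- label_components_3d(as.vector(mask), as.integer(dims),
                                as.integer(connectivity))
  attr(labels, "threshold") <- if (method == "classifier") NA_real_ else thr
  labels
}

# Multi-scale Gaussian features per voxel: raw intensity, Gaussian blurs at
# each scale, and difference-of-Gaussian bands between consecutive scales.
voxel_features <- function(x, grid, scales_um = c(0.15, 0.4, 1.0)) {
  dims <- dim(x)
  blurs <- lapply(scales_um, function(s) {
    sig <- c(s / grid$dx, s / grid$dy, s / grid$dz)
    as.vector(gaussian_blur_3d(as.vector(x), as.integer(dims), sig))
  })
  feats <- c(list(raw = as.vector(x)), setNames(blurs, paste0("g", seq_along(blurs))))
  for (i in seq_len(length(blurs) - 1))
    feats[[paste0("dog", i)]] <- blurs[[i]] - blurs[[i + 1]]
  as.data.frame(feats)
}

#' Train a pixel classifier on labelled voxels
#'
#' A random forest on multi-scale Gaussian features (raw intensity, blurs at
#' several physical scales, difference-of-Gaussian bands), the desk-scale
#' analogue of an interactively trained pixel classifier. Labels mark a
#' subset of voxels as foreground (1) or background (0); a balanced sample
#' of at most `max_train` voxels is used.
#'
#' @param stack training `image_stack`.
#' @param labels integer/logical array of the same dimensions: 1 foreground,
#'   0 background, NA unlabelled.
#' @param scales_um feature scales (um).
#' @param ntree random-forest size.
#' @param max_train cap on training voxels per class.
#' @param seed integer seed for sampling and forest growth.
#' @return object of class `pixel_classifier`.
#' @export
train_pixel_classifier <- function(stack, labels, scales_um = c(0.15, 0.4, 1.0),
                                   ntree = 50, max_train = 5000, seed = 1) {
  stopifnot(inherits(stack, "image_stack"),
            all(dim(labels) == dim(stack$data)))
  feats <- voxel_features(stack$data, stack$grid, scales_um)
  lab <- as.vector(labels)
  keep <- which(!is.na(lab))
  with_seed(seed, {
    fg <- keep[lab[keep] == 1]
    bg <- keep[lab[keep] == 0]
    if (length(fg) == 0 || length(bg) == 0)
      stop("need labelled voxels of both classes")
    if (length(fg) > max_train) fg <- sample(fg, max_train)
    if (length(bg) > max_train) bg <- sample(bg, max_train)
    idx <- c(fg, bg)
    fit <- randomForest::randomForest(
      x = feats[idx, , drop = FALSE],
      y = factor(lab[idx], levels = c(0, 1)),
      ntree = ntree)
    structure(list(forest = fit, scales_um = scales_um),
              class = "pixel_classifier")
  })
}

predict_voxel_prob <- function(classifier, x, grid) {
  stopifnot(inherits(classifier, "pixel_classifier"))
  feats <- voxel_features(x, grid, classifier$scales_um)
  as.numeric(predict(classifier$forest, feats, type = "prob")[, "1"])
}
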
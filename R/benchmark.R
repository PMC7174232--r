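#' Build a labelled synthetic benchmark dataset
#'
#' Renders enough plates (default 4 x 4 grid per frame, emulating the 16-25
#' buds per shot of the acquisition protocol) to yield exactly `n_per_class`
#' instances per class, runs the full processing pipeline on each frame, and
#' assembles per-instance morphology features (gel branch) and colour crops
#' (phone branch) with type and stage labels. With the same seed the result
#' is identical, byte for byte.
#'
#' @param classes named list of [class_profile()] objects.
#' @param n_per_class instances per class (>= 1).
#' @param seed integer master seed.
#' @param mode `"both"`, `"gel"` or `"phone"`.
#' @param grid instances grid per plate.
#' @param min_area speck filter passed to [segment_components()].
#' @param use_truth if `TRUE`, skip segmentation on gel plates and use the
#'   generator's ground-truth masks directly (fast path for fixtures).
#' @param warp_strength corner jitter of the per-plate random homography
#'   (phone mode).
#' @return Object of class `bud_dataset`: `features` (data.frame with id,
#'   plate, class, stage + 14 descriptor columns), `crops` (list of RGB
#'   crops), `type`, `stage` (factors), `ids`, plus bookkeeping.
#' @export
make_benchmark_dataset <- function(classes, n_per_class, seed = 1L,
                                   mode = c("both", "gel", "phone"),
                                   grid = c(4L, 4L), min_area = 64,
                                   use_truth = FALSE, warp_strength = 0.05) {
  mode <- match.arg(mode)
  if (n_per_class < 1) stopf("n_per_class must be >= 1")
  k <- length(classes)
  total <- k * n_per_class
  queue <- rep_len(seq_len(k), total)  # cycling keeps plates mixed
  per_plate <- prod(grid)
  n_plates <- ceiling(total / per_plate)
  rng <- with_seed(seed, {
    list(plate_seeds = sample.int(2^31 - 2, 2 * n_plates),
         homographies = lapply(seq_len(n_plates), function(i)
           random_homography(640 + 2 * 48, c(800, 800), warp_strength)))
  })
  chunks <- split(queue, ceiling(seq_along(queue) / per_plate))
  feat_rows <- list(); crops <- list()
  type_lab <- character(); stage_lab <- character(); ids <- character()
  for (p in seq_len(n_plates)) {
    cells <- c(chunks[[p]], rep(NA_integer_, per_plate - length(chunks[[p]])))
    if (mode %in% c("both", "gel")) {
      ps <- plate_spec("gel16", grid = grid, cells = cells,
                       seed = rng$plate_seeds[p])
      ren <- render_gel_plate(classes, ps)
      inst <- if (use_truth) {
        lapply(ren$truth, as_instance_mask)
      } else {
        den <- median_denoise(ren$image)
        seg <- segment_components(otsu_threshold(den)$mask,
                                  min_area = min_area)
        if (length(seg) != length(ren$truth))
          stopf("plate %d: segmentation found %d instances, expected %d",
                p, length(seg), length(ren$truth))
        seg
      }
      for (i in seq_along(inst)) {
        m <- compute_morphology(inst[[i]])
        gt <- ren$truth[[i]]
        feat_rows[[length(feat_rows) + 1]] <- data.frame(
          id = sprintf("gel%03d_%02d", p, i), plate = p,
          class = gt$class, stage = gt$stage, t(m))
      }
    }
    if (mode %in% c("both", "phone")) {
      ps <- plate_spec("phone8", grid = grid, cells = cells,
                       seed = rng$plate_seeds[n_plates + p],
                       homography = rng$homographies[[p]])
      ren <- render_phone_plate(classes, ps)
      corners <- detect_finder_patterns(ren$image)
      rect <- correct_perspective(ren$image, corners, ren$rect_px + 1L)
      seg <- segment_components(otsu_threshold(rgb_to_gray(rect))$mask,
                                min_area = min_area, exclude_border = TRUE)
      if (length(seg) != length(ren$truth))
        stopf("phone plate %d: segmentation found %d instances, expected %d",
              p, length(seg), length(ren$truth))
      cr <- crop_instances(rect, seg, margin_px = 4)
      for (i in seq_along(cr)) {
        gt <- ren$truth[[i]]
        crops[[length(crops) + 1]] <- cr[[i]]
        type_lab <- c(type_lab, gt$class)
        stage_lab <- c(stage_lab, gt$stage)
        ids <- c(ids, sprintf("ph%03d_%02d", p, i))
      }
    }
  }
  features <- if (length(feat_rows)) do.call(rbind, feat_rows) else NULL
  cls_names <- names(classes) %||%
    vapply(classes, `[[`, "", "name")
  stage_of <- vapply(classes, `[[`, "", "stage")
  out <- list(features = features, crops = if (length(crops)) crops,
              type = if (length(type_lab))
                factor(type_lab, levels = cls_names),
              stage = if (length(stage_lab))
                factor(stage_lab, levels = c("bloom", "fetal")),
              ids = if (length(ids)) ids,
              classes = cls_names, class_stage = stage_of,
              n_per_class = n_per_class, seed = seed, mode = mode)
  class(out) <- "bud_dataset"
  out
}

#' @export
print.bud_dataset <- function(x, ...) {
  nf <- if (is.null(x$features)) 0L else nrow(x$features)
  nc <- length(x$crops %||% list())
  cat(sprintf("<bud_dataset> %d classes x %d per class; %d feature rows, %d crops (seed %d)\n",
              length(x$classes), x$n_per_class, nf, nc, x$seed))
  invisible(x)
}

#' Extract the n x 14 descriptor matrix of a benchmark dataset
#'
#' @param ds a `bud_dataset` with a feature table.
#' @return Numeric matrix with columns in [morphology_features()] order.
#' @export
feature_matrix <- function(ds) {
  stopifnot(!is.null(ds$features))
  as.matrix(ds$features[, morphology_features()])
}
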
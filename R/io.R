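# Plate and dataset I/O: 16-bit grayscale TIFF for gel frames, 8-bit RGB PNG
# for phone frames, one JSON ground-truth sidecar per plate (masks run-length
# encoded), and a CSV manifest per dataset.

rle_encode_mask <- function(mask) {
  r <- rle(as.vector(mask))
  list(first = as.logical(r$values[1]), lengths = as.integer(r$lengths),
       nrow = nrow(mask), ncol = ncol(mask))
}

rle_decode_mask <- function(enc) {
  vals <- rep(rep(c(enc$first, !enc$first),
                  length.out = length(enc$lengths)), enc$lengths)
  matrix(vals, enc$nrow, enc$ncol)
}

#' Write a rendered plate to disk
#'
#' Gel frames are written as 16-bit grayscale TIFF, phone frames as 8-bit
#' RGB PNG; the ground truth (class, stage, shape parameters, bounding box,
#' centroid, run-length-encoded mask) goes to a JSON sidecar next to the
#' image.
#'
#' @param render output of [render_gel_plate()] or [render_phone_plate()].
#' @param path image path (`.tiff`/`.tif` or `.png`); the sidecar replaces
#'   the extension with `.json`.
#' @return Invisibly, a list of the two file paths.
#' @export
write_plate <- function(render, path) {
  img <- render$image
  if (img$mode == "gel16") {
    tiff::writeTIFF(img$pixels / 65535, path, bits.per.sample = 16L)
  } else {
    png::writePNG(img$pixels / 255, path)
  }
  side <- paste0(tools::file_path_sans_ext(path), ".json")
  truth <- lapply(seq_along(render$truth), function(i) {
    gt <- render$truth[[i]]
    list(index = i, class = gt$class, stage = gt$stage,
         family = gt$spec$family, scale_px = gt$spec$scale_px,
         elongation = gt$spec$elongation,
         frill_amplitude = gt$spec$frill_amplitude,
         frill_count = gt$spec$frill_count,
         offset = gt$offset, area = gt$area, centroid = gt$centroid,
         mask = rle_encode_mask(gt$mask))
  })
  meta <- list(mode = img$mode, instances = truth)
  if (!is.null(render$homography)) {
    meta$homography <- render$homography
    meta$corners <- render$corners
    meta$rect_px <- render$rect_px
  }
  jsonlite::write_json(meta, side, auto_unbox = TRUE, digits = NA)
  invisible(list(image = path, sidecar = side))
}

#' Read a plate image
#'
#' @param path `.tif`/`.tiff` (gel, 16-bit grayscale) or `.png` (phone, RGB).
#' @return A [plate_image()].
#' @export
read_plate <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("tif", "tiff")) {
    px <- tiff::readTIFF(path)
    if (length(dim(px)) == 3) px <- px[, , 1]
    plate_image(round(px * 65535), "gel16")
  } else if (ext == "png") {
    px <- png::readPNG(path)
    if (length(dim(px)) == 2) stopf("expected an RGB PNG")
    plate_image(round(px[, , 1:3] * 255), "phone8")
  } else stopf("unsupported plate format '.%s'", ext)
}

#' Read a plate's ground-truth sidecar
#'
#' @param path the `.json` sidecar written by [write_plate()].
#' @return List of ground-truth records with decoded masks.
#' @export
read_ground_truth <- function(path) {
  meta <- jsonlite::read_json(path, simplifyVector = TRUE,
                              simplifyDataFrame = FALSE)
  lapply(meta$instances, function(gt) {
    gt$mask <- rle_decode_mask(gt$mask)
    gt$offset <- as.numeric(gt$offset)
    gt$centroid <- as.numeric(gt$centroid)
    gt
  })
}

#' Write the per-instance feature table as CSV
#'
#' One row per instance: id, plate, class, stage, then the fourteen
#' descriptors under their canonical column names.
#'
#' @param ds a `bud_dataset` (or its `features` data.frame).
#' @param path output CSV path.
#' @return Invisibly, the path.
#' @export
write_features_csv <- function(ds, path) {
  df <- if (inherits(ds, "bud_dataset")) ds$features else ds
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}
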
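#' Median denoising (3 x 3)
#'
#' Replaces each pixel by the median of its 3 x 3 neighbourhood with edge
#' replication at the borders; the standard de-speckling step before
#' thresholding a backlit plate. Idempotent on constant images.
#'
#' @param img `plate_image` (gel16) or numeric matrix.
#' @return Same type as the input.
#' @export
median_denoise <- function(img) {
  if (inherits(img, "plate_image")) {
    if (img$mode != "gel16")
      stopf("median_denoise applies to the gel16 branch")
    out <- img
    out$pixels <- .cpp_median3x3(img$pixels)
    out
  } else {
    .cpp_median3x3(img)
  }
}

#' Otsu threshold with dark foreground
#'
#' Builds a 256-bin histogram of the (min-max rescaled) intensities and
#' selects the bin split maximizing the between-class variance. Objects are
#' dark on a bright field in both acquisition modes, so the dark side is
#' returned as foreground.
#'
#' @param img `plate_image` (gel16), or a single-channel numeric matrix.
#' @return List with `threshold` (intensity on the input scale; foreground is
#'   strictly below it) and `mask` (logical matrix of the dark class).
#' @export
otsu_threshold <- function(img) {
  px <- as_pixels(img)
  if (length(dim(px)) == 3)
    stopf("otsu_threshold needs a single-channel image (see rgb_to_gray)")
  lo <- min(px); hi <- max(px)
  if (hi <= lo) stopf("degenerate histogram: constant image")
  nb <- 256L
  bin <- pmin(floor((px - lo) / (hi - lo) * nb), nb - 1L)
  counts <- tabulate(as.vector(bin) + 1L, nbins = nb)
  n <- sum(counts)
  p <- counts / n
  mids <- seq_len(nb) - 1
  w0 <- cumsum(p)
  mu0 <- cumsum(p * mids)
  mu_t <- mu0[nb]
  # between-class variance for split after bin t (t = 1..nb-1 in 1-based)
  w0c <- w0[-nb]; mu0c <- mu0[-nb]
  valid <- w0c > 0 & w0c < 1
  sigma_b <- rep(-Inf, nb - 1L)
  sigma_b[valid] <- (mu_t * w0c[valid] - mu0c[valid])^2 /
    (w0c[valid] * (1 - w0c[valid]))
  t_best <- which.max(sigma_b)  # first maximum in bin order
  thr <- lo + t_best / nb * (hi - lo)
  mask <- matrix(bin <= (t_best - 1L), nrow(px), ncol(px))
  list(threshold = thr, mask = mask)
}

#' Segment a binary mask into instance masks
#'
#' 8-connected components of the foreground, filtered by a minimum area,
#' each returned on its tight bounding box and ordered row-major by
#' bounding-box top-left (ties by left edge) to match the plate's organized
#' reading order.
#'
#' @param mask logical matrix (from [otsu_threshold()]).
#' @param min_area minimum component area in px^2 (speck filter).
#' @param exclude_border drop components touching the image border (used on
#'   rectified phone plates, where quarter fiducials sit in the corners).
#' @return List of `instance_mask` objects: `mask` (logical, local), `offset`
#'   = c(x0, y0) 0-based plate coordinates of the box, `area`, `index`.
#' @export
segment_components <- function(mask, min_area = 64, exclude_border = FALSE) {
  lab <- .cpp_label_components(mask)
  n <- max(lab)
  if (n == 0) return(list())
  H <- nrow(mask); W <- ncol(mask)
  out <- list()
  for (i in seq_len(n)) {
    idx <- which(lab == i, arr.ind = TRUE)
    if (nrow(idx) < min_area) next
    y0 <- min(idx[, 1]); y1 <- max(idx[, 1])
    x0 <- min(idx[, 2]); x1 <- max(idx[, 2])
    if (exclude_border && (y0 == 1 || x0 == 1 || y1 == H || x1 == W)) next
    m <- matrix(FALSE, y1 - y0 + 1, x1 - x0 + 1)
    m[cbind(idx[, 1] - y0 + 1, idx[, 2] - x0 + 1)] <- TRUE
    out[[length(out) + 1]] <-
      structure(list(mask = m, offset = c(x0 - 1, y0 - 1),
                     area = nrow(idx), index = NA_integer_),
                class = "instance_mask")
  }
  if (!length(out)) return(list())
  # row-major reading order: instances whose vertical spans overlap form one
  # row (plates never overlap vertically across rows); rows top to bottom,
  # left to right within a row
  y0 <- vapply(out, function(s) s$offset[2], 0)
  y1 <- vapply(out, function(s) s$offset[2] + nrow(s$mask) - 1, 0)
  x0 <- vapply(out, function(s) s$offset[1], 0)
  by_top <- order(y0)
  row_id <- integer(length(out))
  cur_row <- 0L; cur_bottom <- -Inf
  for (i in by_top) {
    if (y0[i] > cur_bottom) {
      cur_row <- cur_row + 1L
      cur_bottom <- y1[i]
    } else cur_bottom <- max(cur_bottom, y1[i])
    row_id[i] <- cur_row
  }
  out <- out[order(row_id, x0)]
  for (i in seq_along(out)) out[[i]]$index <- i
  out
}

as_instance_mask <- function(x) {
  if (inherits(x, "instance_mask")) return(x)
  if (inherits(x, "ground_truth_instance"))
    return(structure(list(mask = x$mask, offset = x$offset, area = x$area,
                          index = NA_integer_), class = "instance_mask"))
  if (is.logical(x) && is.matrix(x))
    return(structure(list(mask = x, offset = c(0, 0), area = sum(x),
                          index = NA_integer_), class = "instance_mask"))
  stopf("cannot interpret object of class '%s' as an instance mask",
        paste(class(x), collapse = "/"))
}

#' Trace the outer contour of an instance mask
#'
#' Moore-neighbour border following (Suzuki-style outer boundary): an ordered,
#' closed, 8-connected chain of boundary pixels, counter-clockwise, holes
#' ignored. Points are in plate coordinates (the instance offset is applied).
#'
#' @param inst `instance_mask` (or logical matrix / ground-truth instance).
#' @return n x 2 integer matrix of (x, y), class `bud_contour`.
#' @export
extract_contour <- function(inst) {
  inst <- as_instance_mask(inst)
  if (inst$area < 4) stopf("contour degenerate: mask has %d px", inst$area)
  pts <- .cpp_trace_contour(inst$mask)
  pts[, 1] <- pts[, 1] + inst$offset[1]
  pts[, 2] <- pts[, 2] + inst$offset[2]
  colnames(pts) <- c("x", "y")
  structure(pts, class = c("bud_contour", class(pts)))
}

#' Fill a closed contour back into a mask
#'
#' Inverse of [extract_contour()] for simply connected shapes: 4-connected
#' background flood from outside the chain; unreached pixels are interior.
#'
#' @param contour n x 2 matrix of (x, y) plate coordinates.
#' @return List with `mask` (logical) and `offset` as in `instance_mask`.
#' @export
fill_contour <- function(contour) {
  x0 <- min(contour[, 1]); y0 <- min(contour[, 2])
  pts <- cbind(contour[, 1] - x0, contour[, 2] - y0)
  H <- max(pts[, 2]) + 1L; W <- max(pts[, 1]) + 1L
  list(mask = .cpp_fill_contour(pts, H, W), offset = c(x0, y0))
}

#' Crop instance regions out of a plate image
#'
#' Bounding box plus margin per instance, clipped at the image edges;
#' background pixels are retained (no masking), matching how raw-image crops
#' are fed to the network.
#'
#' @param img `plate_image` or matrix/array (typically a rectified colour
#'   plate whose grayscale projection produced `instances`).
#' @param instances list of `instance_mask` objects.
#' @param margin_px margin added around each bounding box.
#' @return List of crops (same channel structure as `img`), order preserved.
#' @export
crop_instances <- function(img, instances, margin_px = 0) {
  px <- as_pixels(img)
  d <- dim(px)
  lapply(instances, function(inst) {
    x0 <- max(inst$offset[1] - margin_px, 0)
    y0 <- max(inst$offset[2] - margin_px, 0)
    x1 <- min(inst$offset[1] + ncol(inst$mask) - 1 + margin_px, d[2] - 1)
    y1 <- min(inst$offset[2] + nrow(inst$mask) - 1 + margin_px, d[1] - 1)
    if (length(d) == 2) px[(y0 + 1):(y1 + 1), (x0 + 1):(x1 + 1), drop = FALSE]
    else px[(y0 + 1):(y1 + 1), (x0 + 1):(x1 + 1), , drop = FALSE]
  })
}
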
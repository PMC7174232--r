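#' Fit a projective homography from four point correspondences
#'
#' Direct linear transform: solves the 8 unknowns of the 3 x 3 homography
#' (normalized so `H[3,3] = 1`) mapping `src[i, ]` to `dst[i, ]`.
#'
#' @param src,dst 4 x 2 matrices of (x, y) points.
#' @return 3 x 3 homography matrix.
#' @export
fit_homography <- function(src, dst) {
  stopifnot(nrow(src) == 4, nrow(dst) == 4)
  A <- matrix(0, 8, 8); b <- numeric(8)
  for (i in 1:4) {
    x <- src[i, 1]; y <- src[i, 2]; u <- dst[i, 1]; v <- dst[i, 2]
    A[2 * i - 1, ] <- c(x, y, 1, 0, 0, 0, -u * x, -u * y)
    A[2 * i, ]     <- c(0, 0, 0, x, y, 1, -v * x, -v * y)
    b[2 * i - 1] <- u; b[2 * i] <- v
  }
  h <- tryCatch(solve(A, b),
                error = function(e) stopf("degenerate corner configuration: %s",
                                          conditionMessage(e)))
  matrix(c(h, 1), 3, 3, byrow = TRUE)
}

#' Apply a homography to points
#'
#' @param H 3 x 3 homography.
#' @param pts n x 2 matrix of (x, y).
#' @return n x 2 matrix of mapped points.
#' @export
apply_homography <- function(H, pts) {
  pts <- matrix(pts, ncol = 2)
  p <- cbind(pts, 1) %*% t(H)
  p[, 1:2, drop = FALSE] / p[, 3]
}

# vectorized bilinear lookup at fractional 0-based (sx, sy); outside -> fill
bilinear_sample <- function(mat, sx, sy, fill = 0) {
  H <- nrow(mat); W <- ncol(mat)
  x0 <- floor(sx); y0 <- floor(sy)
  fx <- sx - x0; fy <- sy - y0
  ok <- sx >= 0 & sy >= 0 & sx <= W - 1 & sy <= H - 1
  x0c <- clamp(x0, 0, W - 1); y0c <- clamp(y0, 0, H - 1)
  x1c <- clamp(x0 + 1, 0, W - 1); y1c <- clamp(y0 + 1, 0, H - 1)
  g <- function(yy, xx) mat[cbind(yy + 1, xx + 1)]
  v <- (1 - fx) * (1 - fy) * g(y0c, x0c) + fx * (1 - fy) * g(y0c, x1c) +
    (1 - fx) * fy * g(y1c, x0c) + fx * fy * g(y1c, x1c)
  v[!ok] <- fill
  v
}

#' Warp an image under a homography
#'
#' Resamples an output frame of size `out_h` x `out_w` by inverse mapping
#' through `H` (which maps input pixel coordinates to output pixel
#' coordinates) with bilinear interpolation.
#'
#' @param img matrix or H x W x C array.
#' @param H 3 x 3 homography (input -> output pixel coordinates, 0-based).
#' @param out_h,out_w output size.
#' @param fill value for output pixels that map outside the input.
#' @return Warped matrix or array.
#' @export
warp_image <- function(img, H, out_h, out_w, fill = 0) {
  Hi <- solve(H)
  xs <- rep(0:(out_w - 1), each = out_h)
  ys <- rep(0:(out_h - 1), times = out_w)
  src <- apply_homography(Hi, cbind(xs, ys))
  d <- dim(img)
  if (length(d) == 2) {
    out <- matrix(bilinear_sample(img, src[, 1], src[, 2], fill), out_h, out_w)
  } else {
    out <- array(0, c(out_h, out_w, d[3]))
    for (ch in seq_len(d[3]))
      out[, , ch] <- matrix(bilinear_sample(img[, , ch], src[, 1], src[, 2],
                                            fill), out_h, out_w)
  }
  out
}

# component statistics shared by the fiducial detector
component_stats <- function(lab, gray = NULL) {
  n <- max(lab)
  if (n == 0) return(NULL)
  idx <- which(lab > 0, arr.ind = TRUE)
  id <- lab[idx]
  xs <- idx[, 2] - 1; ys <- idx[, 1] - 1
  out <- lapply(seq_len(n), function(i) {
    sel <- id == i
    x <- xs[sel]; y <- ys[sel]
    bw <- diff(range(x)) + 1; bh <- diff(range(y)) + 1
    list(id = i, area = sum(sel), x0 = min(x), y0 = min(y), w = bw, h = bh,
         extent = sum(sel) / (bw * bh), cx = mean(x), cy = mean(y))
  })
  out
}

#' Detect the four corner finder patterns of a colour plate
#'
#' Finder patterns are QR-like concentric-square fiducials (dark 3x3-module
#' core, white ring, dark 1-module border) printed so that their centres mark
#' the corners of the square sample area. Detection is structural: dark
#' components are paired into (border-ring, core) candidates by concentricity
#' and the 7:3 size ratio, and each fiducial is localized to sub-pixel
#' precision by a darkness-weighted centroid over the pair.
#'
#' @param img `plate_image` (phone8) or RGB array.
#' @return 4 x 2 matrix of corner (x, y) pixel coordinates ordered TL, TR,
#'   BR, BL.
#' @export
detect_finder_patterns <- function(img) {
  gray <- rgb_to_gray(img)
  ot <- otsu_threshold(gray)
  lab <- .cpp_label_components(ot$mask)
  st <- component_stats(lab)
  if (is.null(st)) stopf("detected 0 of 4 finder patterns")
  cores <- Filter(function(s) s$extent >= 0.70 && s$area >= 25 &&
                    s$w / s$h > 0.5 && s$w / s$h < 2.0, st)
  rings <- Filter(function(s) s$extent <= 0.68 && s$area >= 50, st)
  centres <- list()
  for (r in rings) {
    for (co in cores) {
      ratio_w <- r$w / co$w; ratio_h <- r$h / co$h
      if (ratio_w < 1.7 || ratio_w > 3.4 || ratio_h < 1.7 || ratio_h > 3.4)
        next
      if (abs(r$cx - co$cx) > 0.2 * r$w || abs(r$cy - co$cy) > 0.2 * r$h)
        next
      sel <- lab == r$id | lab == co$id
      wgt <- pmax(ot$threshold - gray, 0) * sel
      tot <- sum(wgt)
      xg <- sum(wgt * matrix(0:(ncol(gray) - 1), nrow(gray), ncol(gray),
                             byrow = TRUE)) / tot
      yg <- sum(wgt * matrix(0:(nrow(gray) - 1), nrow(gray), ncol(gray))) / tot
      centres[[length(centres) + 1]] <- c(xg, yg)
      break
    }
  }
  if (length(centres) != 4)
    stopf("detected %d of 4 finder patterns", length(centres))
  pts <- do.call(rbind, centres)
  ang <- atan2(pts[, 2] - mean(pts[, 2]), pts[, 1] - mean(pts[, 1]))
  pts[order(ang), , drop = FALSE]  # TL, TR, BR, BL (y increases downwards)
}

#' Rectify the sample area of a colour plate
#'
#' Solves the homography sending the four detected corners to the corners of
#' an `out_px` x `out_px` output (corner pixel centres map to the first and
#' last pixel centres) and resamples with bilinear interpolation. The output
#' covers the square sample area bounded by the fiducial centres.
#'
#' @param img `plate_image` (phone8) or matrix/array.
#' @param corners 4 x 2 matrix ordered TL, TR, BR, BL
#'   (from [detect_finder_patterns()]).
#' @param out_px output side length, pixels.
#' @return Rectified image (same channel structure as input).
#' @export
correct_perspective <- function(img, corners, out_px) {
  px <- as_pixels(img)
  o <- out_px - 1
  dst <- rbind(c(0, 0), c(o, 0), c(o, o), c(0, o))
  H <- fit_homography(as.matrix(corners), dst)
  warp_image(px, H, out_px, out_px, fill = 0)
}
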
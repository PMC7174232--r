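#' Parametric bud silhouette specification
#'
#' Describes one silhouette in the synthetic plate model. Canonical families
#' (`circle`, `ellipse`, `square`) have closed-form morphology
#' (see [analytic_morphology()]); the `bud` family is a star polygon
#' `r(theta) = R * (1 + a * cos(k * theta))` optionally carrying extra smooth
#' low-order harmonics, which emulates the petal frill of a dried flower bud.
#' All families are star-shaped about their centre, so rasterization is an
#' exact per-pixel-centre inclusion test.
#'
#' @param family one of `"circle"`, `"ellipse"`, `"square"`, `"bud"`.
#' @param scale_px characteristic radius in pixels (> 2): circle radius,
#'   ellipse semi-major axis, square half-side, or bud base radius `R`.
#' @param elongation axis ratio >= 1; the silhouette is stretched by this
#'   factor along its rotated x-axis (for an ellipse, semi-minor axis is
#'   `scale_px / elongation`).
#' @param frill_amplitude petal modulation amplitude `a` in `[0, 1)`
#'   (bud family only).
#' @param frill_count integer number of petals `k >= 0`.
#' @param rotation_rad rotation of the shape's own axes, radians.
#' @param center optional `(x, y)` centre in plate pixel coordinates.
#' @param perturb optional list with numeric vectors `amp` and `phase`
#'   (harmonics 1..length(amp)) adding smooth random irregularity to a bud.
#' @return An object of class `shape_spec`.
#' @examples
#' shape_spec("circle", scale_px = 50)
#' shape_spec("bud", 40, frill_amplitude = 0.15, frill_count = 9)
#' @export
shape_spec <- function(family = c("circle", "ellipse", "square", "bud"),
                       scale_px, elongation = 1, frill_amplitude = 0,
                       frill_count = 0L, rotation_rad = 0,
                       center = c(NA_real_, NA_real_), perturb = NULL) {
  family <- match.arg(family)
  if (scale_px <= 2) stopf("scale_px must exceed 2 px (got %g)", scale_px)
  if (elongation < 1) stopf("elongation must be >= 1 (got %g)", elongation)
  if (frill_amplitude < 0 || frill_amplitude >= 1)
    stopf("frill_amplitude must lie in [0, 1) (got %g)", frill_amplitude)
  if (frill_count < 0) stopf("frill_count must be >= 0")
  total_amp <- frill_amplitude + sum(abs(perturb$amp %||% 0))
  if (total_amp >= 1)
    stopf("total radial modulation %.3f leaves no positive radius", total_amp)
  structure(list(family = family, scale_px = scale_px, elongation = elongation,
                 frill_amplitude = frill_amplitude,
                 frill_count = as.integer(frill_count),
                 rotation_rad = rotation_rad, center = as.numeric(center),
                 perturb = perturb),
            class = "shape_spec")
}

#' @export
print.shape_spec <- function(x, ...) {
  cat(sprintf("<shape_spec> %s R=%.1f px, elongation %.2f, frill a=%.2f k=%d\n",
              x$family, x$scale_px, x$elongation, x$frill_amplitude,
              x$frill_count))
  invisible(x)
}

# Maximum distance from centre to boundary, used for cell-fitting checks.
shape_extent <- function(spec) {
  base <- switch(spec$family,
    circle = spec$scale_px,
    ellipse = spec$scale_px,
    square = spec$scale_px * sqrt(2),
    bud = spec$scale_px *
      (1 + spec$frill_amplitude + sum(abs(spec$perturb$amp %||% 0))))
  base * if (spec$family %in% c("bud", "circle", "square")) spec$elongation else 1
}

# Radial boundary function r(theta) of the base (unelongated) shape; theta in
# the shape's own frame. Vectorised over theta.
shape_radius <- function(spec, theta) {
  switch(spec$family,
    circle = rep(spec$scale_px, length(theta)),
    ellipse = {
      a <- spec$scale_px; b <- spec$scale_px / spec$elongation
      a * b / sqrt((b * cos(theta))^2 + (a * sin(theta))^2)
    },
    square = spec$scale_px / pmax(abs(cos(theta)), abs(sin(theta))),
    bud = {
      r <- 1 + spec$frill_amplitude * cos(spec$frill_count * theta)
      if (!is.null(spec$perturb)) {
        for (j in seq_along(spec$perturb$amp))
          r <- r + spec$perturb$amp[j] * cos(j * theta + spec$perturb$phase[j])
      }
      spec$scale_px * r
    })
}

#' Rasterize a shape specification into a binary mask
#'
#' Exact inclusion test at pixel centres: pixel `(x, y)` (0-based, x = column)
#' is foreground iff its centre lies inside the continuous silhouette. Returns
#' the mask on its tight bounding box together with the box offset.
#'
#' @param spec a [shape_spec()] with a finite `center`.
#' @param bounds optional `c(W, H)` plate size; the mask is clipped to it.
#' @return List with `mask` (logical matrix, rows = y), `offset` = c(x0, y0)
#'   (0-based top-left of the box), and `area` (pixel count).
#' @export
rasterize_shape <- function(spec, bounds = NULL) {
  cx <- spec$center[1]; cy <- spec$center[2]
  if (anyNA(c(cx, cy))) stopf("shape has no centre set")
  ext <- ceiling(shape_extent(spec)) + 1
  x0 <- floor(cx - ext); x1 <- ceiling(cx + ext)
  y0 <- floor(cy - ext); y1 <- ceiling(cy + ext)
  if (!is.null(bounds)) {
    x0 <- max(x0, 0); y0 <- max(y0, 0)
    x1 <- min(x1, bounds[1] - 1); y1 <- min(y1, bounds[2] - 1)
  }
  xs <- x0:x1; ys <- y0:y1
  dx <- matrix(xs - cx, nrow = length(ys), ncol = length(xs), byrow = TRUE)
  dy <- matrix(ys - cy, nrow = length(ys), ncol = length(xs))
  # into the shape frame: rotate by -rotation, undo elongation along own x
  co <- cos(-spec$rotation_rad); si <- sin(-spec$rotation_rad)
  xr <- dx * co - dy * si
  yr <- dx * si + dy * co
  if (spec$family != "ellipse") xr <- xr / spec$elongation
  eps <- 1e-9
  inside <- switch(spec$family,
    circle = xr^2 + yr^2 <= (spec$scale_px + eps)^2,
    square = pmax(abs(xr), abs(yr)) <= spec$scale_px + eps,
    ellipse = {
      a <- spec$scale_px; b <- spec$scale_px / spec$elongation
      (xr / a)^2 + (yr / b)^2 <= 1 + eps
    },
    bud = {
      th <- atan2(yr, xr)
      sqrt(xr^2 + yr^2) <= shape_radius(spec, th)
    })
  dim(inside) <- dim(dx)
  # tighten the bounding box
  rows <- which(rowSums(inside) > 0)
  cols <- which(colSums(inside) > 0)
  if (!length(rows)) stopf("shape rasterized to an empty mask")
  inside <- inside[rows, cols, drop = FALSE]
  list(mask = inside,
       offset = c(x0 + cols[1] - 1, y0 + rows[1] - 1),
       area = sum(inside))
}

#' Closed-form morphology of canonical shapes
#'
#' Returns the continuous-geometry value of the fourteen contour descriptors
#' for `circle`, `ellipse` and `square` silhouettes (the `bud` family has no
#' closed form). The ellipse perimeter uses the complete elliptic integral of
#' the second kind; its radial-variance descriptors integrate the boundary
#' distance against uniform arc length by quadrature.
#'
#' @param spec a [shape_spec()] with family `circle`, `ellipse` or `square`.
#' @param n_quad quadrature points for the ellipse radial variance.
#' @return Named numeric vector of length 14 in canonical descriptor order
#'   (see [morphology_features()]).
#' @examples
#' analytic_morphology(shape_spec("circle", 50))[["circularity"]]  # exactly 1
#' @export
analytic_morphology <- function(spec, n_quad = 1e5) {
  if (spec$family == "bud")
    stopf("bud shapes have no closed-form morphology")
  R <- spec$scale_px
  v <- switch(spec$family,
    circle = {
      c(perimeter = 2 * pi * R, area = pi * R^2, long_axis = 2 * R,
        short_axis = 2 * R, incircle_r = R, excircle_r = R,
        eq_diameter = 2 * R, circularity = 1, shape_param = 4 * pi,
        aspect_ratio = 1, compactness = 1, roundness = 1,
        irregularity = 0, norm_irregularity = 0)
    },
    ellipse = {
      a <- R; b <- R / spec$elongation
      m <- 1 - (b / a)^2
      P <- 4 * a * pracma::ellipke(m)$e
      A <- pi * a * b
      th <- (seq_len(n_quad) - 0.5) / n_quad * 2 * pi
      w <- sqrt((a * sin(th))^2 + (b * cos(th))^2)  # arc-length weights
      d <- sqrt((a * cos(th))^2 + (b * sin(th))^2)
      mu <- sum(w * d) / sum(w)
      irr <- sum(w * (d - mu)^2) / sum(w)
      c(perimeter = P, area = A, long_axis = 2 * a, short_axis = 2 * b,
        incircle_r = b, excircle_r = a, eq_diameter = 2 * sqrt(a * b),
        circularity = 4 * pi * A / P^2, shape_param = P^2 / A,
        aspect_ratio = a / b, compactness = sqrt(b / a), roundness = b / a,
        irregularity = irr, norm_irregularity = irr / mu^2)
    },
    square = {
      s <- 2 * R  # side
      P <- 4 * s; A <- s^2
      Ed <- (s / 4) * (sqrt(2) + asinh(1))   # mean boundary distance
      Ed2 <- s^2 / 3                         # mean squared boundary distance
      irr <- Ed2 - Ed^2
      c(perimeter = P, area = A, long_axis = s * sqrt(2),
        short_axis = s * sqrt(2), incircle_r = s / 2,
        excircle_r = s * sqrt(2) / 2, eq_diameter = 2 * s / sqrt(pi),
        circularity = pi / 4, shape_param = 16, aspect_ratio = 1,
        compactness = sqrt(2 / pi), roundness = 1 / sqrt(2),
        irregularity = irr, norm_irregularity = irr / Ed^2)
    })
  v[morphology_features()]
}
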
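#' Canonical names of the fourteen contour descriptors
#'
#' Fixed reporting order: perimeter, area, long/short axis, incircle and
#' excircle radii, area-equivalent diameter, circularity, shape parameter,
#' aspect ratio, compactness, roundness, irregularity and normalized
#' irregularity.
#'
#' @return Character vector of length 14.
#' @export
morphology_features <- function() {
  c("perimeter", "area", "long_axis", "short_axis", "incircle_r",
    "excircle_r", "eq_diameter", "circularity", "shape_param",
    "aspect_ratio", "compactness", "roundness", "irregularity",
    "norm_irregularity")
}

#' Area centroid of an instance mask
#'
#' Arithmetic mean of the foreground pixel coordinates (centre of mass of the
#' filled region), in plate coordinates.
#'
#' @param inst `instance_mask`, ground-truth instance, or logical matrix.
#' @return Numeric `(x, y)`.
#' @export
centroid <- function(inst) {
  inst <- as_instance_mask(inst)
  if (inst$area == 0) stopf("empty mask has no centroid")
  idx <- which(inst$mask, arr.ind = TRUE)
  c(x = inst$offset[1] + mean(idx[, 2]) - 1,
    y = inst$offset[2] + mean(idx[, 1]) - 1)
}

#' Contour perimeter
#'
#' Summed Euclidean distances between consecutive contour points, including
#' the closing edge (steps of 1 or sqrt(2) on an 8-connected chain).
#'
#' @param contour n x 2 matrix of (x, y) points.
#' @return Perimeter in pixels.
#' @export
perimeter <- function(contour) {
  p <- rbind(contour, contour[1, , drop = FALSE])
  sum(sqrt(diff(p[, 1])^2 + diff(p[, 2])^2))
}

#' Long and short axis of a shape
#'
#' Long axis: the exact maximum pairwise distance over contour points
#' (computed on the convex hull, which attains the maximum). Short axis: the
#' extent of the filled mask along the line through the centre of mass
#' perpendicular to the long axis (pixels whose centres lie within half a
#' pixel of the line).
#'
#' @param contour n x 2 matrix of contour points.
#' @param inst the matching `instance_mask` (filled region).
#' @return List with `long_axis`, `short_axis`, `direction` (unit vector of
#'   the long axis).
#' @export
principal_extents <- function(contour, inst) {
  pts <- contour[, 1:2, drop = FALSE]
  if (nrow(pts) < 2) stopf("need at least two contour points")
  uni <- unique(pts)
  hull <- if (nrow(uni) >= 3) uni[grDevices::chull(uni), , drop = FALSE] else uni
  dmat <- as.matrix(stats::dist(hull))
  long <- max(dmat)
  if (long < 1e-12) {
    warning("degenerate contour: zero long axis")
    return(list(long_axis = 0, short_axis = 0, direction = c(1, 0)))
  }
  # all farthest pairs (squared distances of integer points tie exactly);
  # measuring the perpendicular extent for every tied direction and keeping
  # the largest makes the result invariant under exact rotations
  ties <- which(dmat == long, arr.ind = TRUE)
  ties <- ties[ties[, 1] < ties[, 2], , drop = FALSE]
  dirs <- lapply(seq_len(nrow(ties)), function(i) {
    d <- hull[ties[i, 2], ] - hull[ties[i, 1], ]
    d / sqrt(sum(d^2))
  })
  dirs <- unique(lapply(dirs, function(d) round(d * sign(d[1] + 1e-12), 12)))
  inst <- as_instance_mask(inst)
  ctr <- centroid(inst)
  idx <- which(inst$mask, arr.ind = TRUE)
  px <- inst$offset[1] + idx[, 2] - 1 - ctr[1]
  py <- inst$offset[2] + idx[, 1] - 1 - ctr[2]
  short <- 0; dir_best <- dirs[[1]]
  for (dir in dirs) {
    # coordinates along the long axis (v) and perpendicular to it (u)
    v <- px * dir[1] + py * dir[2]
    u <- -px * dir[2] + py * dir[1]
    on_line <- abs(v) <= 0.5
    ext <- if (any(on_line)) diff(range(u[on_line])) else 0
    if (ext > short) { short <- ext; dir_best <- dir }
  }
  if (short == 0) warning("degenerate short axis (collinear mask)")
  list(long_axis = unname(long), short_axis = unname(short),
       direction = unname(dir_best))
}

#' Radius of the largest inscribed circle
#'
#' Maximum over foreground pixels of the exact Euclidean distance to the
#' nearest background pixel (pixels outside the image count as background).
#'
#' @param inst `instance_mask` or logical matrix.
#' @return Incircle radius in pixels.
#' @export
max_inscribed_circle <- function(inst) {
  inst <- as_instance_mask(inst)
  if (inst$area == 0) stopf("empty mask")
  max(.cpp_edt(inst$mask))
}

#' Radius of the smallest enclosing circle
#'
#' Exact minimum enclosing circle of the contour points by Welzl's
#' randomized algorithm (deterministic here: the point order is shuffled
#' with a fixed internal seed).
#'
#' @param contour n x 2 matrix of contour points.
#' @return Excircle radius in pixels; the centre is attached as attribute
#'   `center`.
#' @export
min_enclosing_circle <- function(contour) {
  pts <- unique(contour[, 1:2, drop = FALSE])
  storage.mode(pts) <- "double"
  ord <- with_seed(193L, sample.int(nrow(pts)))
  res <- .cpp_min_enclosing_circle(pts, ord)
  structure(res[3], center = res[1:2])
}

#' Radial variance irregularity descriptors
#'
#' Distances from every contour point to the centre of mass; irregularity is
#' their population variance (px^2) and normalized irregularity the
#' population variance after dividing by the mean distance (scale-free).
#'
#' @param contour n x 2 matrix of contour points.
#' @param center `(x, y)` centre of mass (see [centroid()]).
#' @return Named vector `c(irregularity, norm_irregularity)`.
#' @export
radial_variance <- function(contour, center) {
  if (nrow(contour) < 4) stopf("need at least 4 contour points")
  d <- sqrt((contour[, 1] - center[1])^2 + (contour[, 2] - center[2])^2)
  mu <- mean(d)
  if (mu <= 0) stopf("mean contour distance is zero")
  pv <- function(x) mean((x - mean(x))^2)  # population variance
  c(irregularity = pv(d), norm_irregularity = pv(d / mu))
}

#' Compute the fourteen contour descriptors of one instance
#'
#' Assembles the full morphology vector from the primitive operations:
#' perimeter and area, long/short axis, incircle/excircle radii, then the
#' derived ratios (area-equivalent diameter `sqrt(4A/pi)`, circularity
#' `4*pi*A/P^2`, shape parameter `P^2/A`, aspect ratio, compactness,
#' roundness `incircle/excircle`) and the radial-variance irregularity pair.
#'
#' @param inst `instance_mask` (or logical matrix / ground-truth instance).
#' @param contour optional matching contour; traced from `inst` if missing.
#' @return Named numeric vector of length 14 in [morphology_features()]
#'   order.
#' @examples
#' ras <- rasterize_shape(shape_spec("circle", 50, center = c(60, 60)))
#' round(compute_morphology(ras$mask)[["circularity"]], 2)
#' @export
compute_morphology <- function(inst, contour = NULL) {
  inst <- as_instance_mask(inst)
  if (is.null(contour)) contour <- extract_contour(inst)
  A <- inst$area
  P <- perimeter(contour)
  ctr <- centroid(inst)
  ext <- principal_extents(contour, inst)
  inc <- max_inscribed_circle(inst)
  exc <- as.numeric(min_enclosing_circle(contour))
  irr <- radial_variance(contour, ctr)
  eqd <- sqrt(4 * A / pi)
  v <- c(perimeter = P, area = A, long_axis = ext$long_axis,
         short_axis = ext$short_axis, incircle_r = inc, excircle_r = exc,
         eq_diameter = eqd, circularity = 4 * pi * A / P^2,
         shape_param = P^2 / A, aspect_ratio = ext$long_axis / ext$short_axis,
         compactness = eqd / ext$long_axis, roundness = inc / exc,
         irregularity = unname(irr["irregularity"]),
         norm_irregularity = unname(irr["norm_irregularity"]))
  if (any(!is.finite(v)))
    stopf("non-finite morphology values: %s",
          paste(names(v)[!is.finite(v)], collapse = ", "))
  v[morphology_features()]
}
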
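#' Plate rendering specification
#'
#' Describes one synthetic frame: acquisition mode, instance grid, geometry,
#' noise and (phone mode) illumination, shadow and projective distortion.
#' Instances are placed on a `grid_rows` x `grid_cols` grid in row-major
#' order with a small centre jitter; a shape whose radial extent exceeds 45%
#' of the cell pitch is rejected, which also guarantees non-overlap and a
#' stable row-major reading order.
#'
#' @param mode `"gel16"` (backlit grayscale) or `"phone8"` (colour on paper).
#' @param grid `c(rows, cols)` instances per frame.
#' @param image_size `c(H, W)` in pixels (gel mode; phone frame size is
#'   `frame_size`).
#' @param background,foreground gel intensity levels (16-bit scale).
#' @param noise_sigma Gaussian noise SD on the native intensity scale.
#' @param salt_pepper fraction of pixels replaced by extreme values (gel).
#' @param cells optional integer vector (length rows*cols, row-major) of
#'   class indices per grid cell; `NA` leaves a cell empty. Defaults to
#'   cycling through the class list.
#' @param rect_px side of the square sample area, pixels (phone).
#' @param margin_px paper margin around the sample area (phone); the four
#'   finder patterns are centred on the sample-area corners.
#' @param finder_px finder pattern side (7 modules; phone).
#' @param frame_size `c(H, W)` of the warped output frame (phone).
#' @param illumination amplitude of the linear illumination gradient (phone).
#' @param shadow strength of the soft cast shadow (phone).
#' @param homography 3 x 3 projective map from paper (canvas) pixel
#'   coordinates to frame coordinates, or `NULL` for a centred identity.
#' @param seed integer; every renderer is a pure function of (spec, seed).
#' @return Object of class `plate_spec`.
#' @export
plate_spec <- function(mode = c("gel16", "phone8"), grid = c(4, 4),
                       image_size = c(640, 640), background = 58000,
                       foreground = 7000, noise_sigma = NULL,
                       salt_pepper = NULL, cells = NULL, rect_px = 640,
                       margin_px = 48, finder_px = 42, frame_size = c(800, 800),
                       illumination = 0.08, shadow = 0.12, homography = NULL,
                       seed = 1L) {
  mode <- match.arg(mode)
  if (prod(grid) < 1) stopf("grid must hold at least one instance")
  if (is.null(noise_sigma)) noise_sigma <- if (mode == "gel16") 600 else 2
  if (is.null(salt_pepper)) salt_pepper <- if (mode == "gel16") 0.001 else 0
  if (!is.null(homography)) {
    if (abs(det(homography)) < 1e-12) stopf("homography is not invertible")
  }
  structure(list(mode = mode, grid = as.integer(grid),
                 image_size = as.integer(image_size),
                 background = background, foreground = foreground,
                 noise_sigma = noise_sigma, salt_pepper = salt_pepper,
                 cells = cells, rect_px = rect_px, margin_px = margin_px,
                 finder_px = finder_px, frame_size = as.integer(frame_size),
                 illumination = illumination, shadow = shadow,
                 homography = homography, seed = as.integer(seed)),
            class = "plate_spec")
}

new_ground_truth <- function(profile, spec, ras, color = NULL) {
  idx <- which(ras$mask, arr.ind = TRUE)
  ctr <- c(ras$offset[1] + mean(idx[, 2]) - 1,
           ras$offset[2] + mean(idx[, 1]) - 1)
  structure(list(class = profile$name, stage = profile$stage, spec = spec,
                 mask = ras$mask, offset = ras$offset, area = ras$area,
                 centroid = ctr, color = color,
                 analytic = if (spec$family != "bud")
                   analytic_morphology(spec) else NULL),
            class = "ground_truth_instance")
}

# draw one instance per occupied grid cell; pitch/origin define the cell
# lattice in target coordinates. Returns list(spec=..., profile=...) draws.
sample_grid_instances <- function(classes, plate, pitch, origin) {
  rows <- plate$grid[1]; cols <- plate$grid[2]
  cells <- plate$cells %||% rep_len(seq_along(classes), rows * cols)
  if (length(cells) != rows * cols)
    stopf("cells must have length grid_rows * grid_cols")
  lim <- 0.45 * min(pitch)
  out <- list()
  for (r in seq_len(rows)) {
    for (cc in seq_len(cols)) {
      ci <- cells[(r - 1) * cols + cc]
      if (is.na(ci)) next
      prof <- classes[[ci]]
      spec <- sample_shape_spec(prof)
      ext <- shape_extent(spec)
      if (ext > lim)
        stopf("shape for class '%s' (extent %.1f px) too large for the %.0f x %.0f grid cell (limit %.1f px)",
              prof$name, ext, pitch[1], pitch[2], lim)
      jx <- runif(1, -0.04, 0.04) * pitch[2]
      jy <- runif(1, -0.04, 0.04) * pitch[1]
      spec$center <- c(origin[1] + (cc - 0.5) * pitch[2] + jx,
                       origin[2] + (r - 0.5) * pitch[1] + jy)
      out[[length(out) + 1]] <- list(profile = prof, spec = spec)
    }
  }
  out
}

#' Render a synthetic gel-imager plate
#'
#' Backlit transmittance frame: dark filled silhouettes on a bright field,
#' arranged on a non-overlapping row-major grid, with Gaussian and
#' salt-and-pepper noise. Identical `(classes, plate)` including the seed
#' give a bit-identical image.
#'
#' @param classes list of [class_profile()] objects.
#' @param plate a [plate_spec()] with mode `"gel16"`.
#' @return List with `image` (a [plate_image()]), and `truth` (list of
#'   ground-truth instances ordered row-major, each with mask, offset, class,
#'   stage, shape spec and -- for canonical families -- analytic morphology).
#' @export
render_gel_plate <- function(classes, plate) {
  if (plate$mode != "gel16") stopf("plate spec must have mode 'gel16'")
  if (!length(classes)) stopf("class list is empty")
  with_seed(plate$seed, {
    H <- plate$image_size[1]; W <- plate$image_size[2]
    pitch <- c(H / plate$grid[1], W / plate$grid[2])
    draws <- sample_grid_instances(classes, plate, pitch, origin = c(0, 0))
    img <- matrix(plate$background, H, W)
    truth <- vector("list", length(draws))
    for (i in seq_along(draws)) {
      ras <- rasterize_shape(draws[[i]]$spec, bounds = c(W, H))
      ys <- ras$offset[2] + seq_len(nrow(ras$mask))
      xs <- ras$offset[1] + seq_len(ncol(ras$mask))
      sub <- img[ys, xs, drop = FALSE]
      sub[ras$mask] <- plate$foreground
      img[ys, xs] <- sub
      truth[[i]] <- new_ground_truth(draws[[i]]$profile, draws[[i]]$spec, ras)
    }
    if (plate$noise_sigma > 0)
      img <- img + matrix(rnorm(H * W, 0, plate$noise_sigma), H, W)
    if (plate$salt_pepper > 0) {
      n_sp <- round(plate$salt_pepper * H * W)
      if (n_sp > 0) {
        at <- sample.int(H * W, n_sp)
        img[at] <- rep_len(c(0, 65535), n_sp)
      }
    }
    img <- round(clamp(img, 0, 65535))
    list(image = plate_image(img, "gel16"), truth = truth)
  })
}

draw_finder <- function(canvas, cx, cy, finder_px, dark = 20 / 255) {
  u <- finder_px / 7
  half <- ceiling(3.5 * u)
  xs <- clamp((round(cx) - half):(round(cx) + half), 0, ncol(canvas[, , 1]) - 1)
  ys <- clamp((round(cy) - half):(round(cy) + half), 0, nrow(canvas[, , 1]) - 1)
  xs <- unique(xs); ys <- unique(ys)
  dx <- matrix(abs(xs - cx), length(ys), length(xs), byrow = TRUE)
  dy <- matrix(abs(ys - cy), length(ys), length(xs))
  cheb <- pmax(dx, dy)
  sel <- cheb <= 3.5 * u & !(cheb > 1.5 * u & cheb <= 2.5 * u)
  dim(sel) <- dim(cheb)
  for (ch in 1:3) {
    sub <- canvas[ys + 1, xs + 1, ch]
    sub[sel] <- dark
    canvas[ys + 1, xs + 1, ch] <- sub
  }
  canvas
}

#' Render a synthetic phone plate
#'
#' Colour frame emulating a hand-held shot: white paper with four
#' concentric-square finder patterns centred on the corners of the square
#' sample area, coloured textured bud silhouettes inside, then a linear
#' illumination gradient, a soft cast shadow, a projective warp and sensor
#' noise. Ground truth (masks, centroids) is recorded in rectified
#' sample-area pixel coordinates, i.e. before the warp, so downstream
#' morphology targets are warp-independent.
#'
#' @inheritParams render_gel_plate
#' @param plate a [plate_spec()] with mode `"phone8"`.
#' @return List with `image` (warped [plate_image()]), `truth` (instances in
#'   rectified coordinates), `corners` (true fiducial centres in frame
#'   coordinates, TL TR BR BL), `homography` (canvas -> frame) and `rect_px`.
#' @export
render_phone_plate <- function(classes, plate) {
  if (plate$mode != "phone8") stopf("plate spec must have mode 'phone8'")
  if (!length(classes)) stopf("class list is empty")
  with_seed(plate$seed, {
    m <- plate$margin_px; rp <- plate$rect_px
    cv <- rp + 2 * m  # canvas side
    canvas <- array(250 / 255, c(cv, cv, 3))
    corners_cv <- rbind(c(m, m), c(m + rp, m), c(m + rp, m + rp),
                        c(m, m + rp))
    for (i in 1:4)
      canvas <- draw_finder(canvas, corners_cv[i, 1], corners_cv[i, 2],
                            plate$finder_px)
    pitch <- c(rp / plate$grid[1], rp / plate$grid[2])
    draws <- sample_grid_instances(classes, plate, pitch, origin = c(m, m))
    truth <- vector("list", length(draws))
    for (i in seq_along(draws)) {
      d <- draws[[i]]
      ras <- rasterize_shape(d$spec, bounds = c(cv, cv))
      col <- clamp(d$profile$color + rnorm(3, 0, d$profile$color_jitter),
                   0, 255) / 255
      tex <- 1 + d$profile$texture_strength *
        smooth_noise_field(nrow(ras$mask), ncol(ras$mask))
      ys <- ras$offset[2] + seq_len(nrow(ras$mask))
      xs <- ras$offset[1] + seq_len(ncol(ras$mask))
      for (ch in 1:3) {
        sub <- canvas[ys, xs, ch]
        sub[ras$mask] <- clamp(col[ch] * tex[ras$mask], 0, 1)
        canvas[ys, xs, ch] <- sub
      }
      # ground truth in rectified sample coordinates (origin = TL corner)
      ras$offset <- ras$offset - m
      d$spec$center <- d$spec$center - m
      truth[[i]] <- new_ground_truth(d$profile, d$spec, ras,
                                     color = round(col * 255))
    }
    # scene-anchored lighting: linear gradient + soft elliptical shadow
    xg <- matrix(0:(cv - 1), cv, cv, byrow = TRUE) / cv
    yg <- matrix(0:(cv - 1), cv, cv) / cv
    light <- matrix(1, cv, cv)
    if (plate$illumination > 0) {
      th <- runif(1, 0, 2 * pi)
      g <- cos(th) * xg + sin(th) * yg
      g <- (g - min(g)) / max(1e-9, diff(range(g)))
      light <- light * (1 - plate$illumination * g)
    }
    if (plate$shadow > 0) {
      sx <- runif(1, 0.2, 0.8); sy <- runif(1, 0.2, 0.8)
      sig <- runif(1, 0.25, 0.45)
      light <- light * (1 - plate$shadow *
                          exp(-((xg - sx)^2 + (yg - sy)^2) / (2 * sig^2)))
    }
    for (ch in 1:3) canvas[, , ch] <- canvas[, , ch] * light
    fh <- plate$frame_size[1]; fw <- plate$frame_size[2]
    H <- plate$homography %||% {
      tx <- (fw - cv) / 2; ty <- (fh - cv) / 2
      matrix(c(1, 0, tx, 0, 1, ty, 0, 0, 1), 3, 3, byrow = TRUE)
    }
    corners_frame <- apply_homography(H, corners_cv)
    if (any(corners_frame[, 1] < 0 | corners_frame[, 1] > fw - 1 |
            corners_frame[, 2] < 0 | corners_frame[, 2] > fh - 1))
      stopf("homography maps the sample area outside the frame")
    frame <- warp_image(canvas, H, fh, fw, fill = 90 / 255)
    if (plate$noise_sigma > 0)
      frame <- frame + array(rnorm(length(frame), 0,
                                   plate$noise_sigma / 255), dim(frame))
    frame <- round(clamp(frame, 0, 1) * 255)
    list(image = plate_image(frame, "phone8"), truth = truth,
         corners = corners_frame, homography = H, rect_px = rp,
         margin_px = m)
  })
}

#' Draw a mild random projective distortion
#'
#' Jitters the four corners of the canvas by up to `strength` of its side and
#' fits the induced homography, emulating a hand-held camera pose.
#'
#' @param canvas_px canvas (paper) side length, pixels.
#' @param frame_size `c(H, W)` output frame.
#' @param strength maximum relative corner displacement.
#' @return 3 x 3 homography (canvas -> frame coordinates).
#' @export
random_homography <- function(canvas_px, frame_size = c(800, 800),
                              strength = 0.05) {
  tx <- (frame_size[2] - canvas_px) / 2; ty <- (frame_size[1] - canvas_px) / 2
  src <- rbind(c(0, 0), c(canvas_px - 1, 0), c(canvas_px - 1, canvas_px - 1),
               c(0, canvas_px - 1))
  dst <- src + matrix(runif(8, -strength, strength) * canvas_px, 4, 2)
  dst[, 1] <- dst[, 1] + tx; dst[, 2] <- dst[, 2] + ty
  fit_homography(src, dst)
}
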
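test_that("homography fit/apply round-trips four correspondences", {
  set.seed(7)
  src <- rbind(c(0, 0), c(100, 0), c(100, 100), c(0, 100))
  dst <- src + matrix(runif(8, -10, 10), 4, 2)
  H <- fit_homography(src, dst)
  expect_equal(apply_homography(H, src), dst, tolerance = 1e-8)
  # extra points follow the same projective map
  Hi <- solve(H)
  p <- matrix(runif(20, 0, 100), 10, 2)
  expect_equal(apply_homography(Hi, apply_homography(H, p)), p,
               tolerance = 1e-6)
  expect_error(fit_homography(rbind(c(0, 0), c(1, 1), c(2, 2), c(3, 3)), src),
               "degenerate")
})

test_that("finder patterns are detected at their rendered positions", {
  cls <- default_class_profiles()
  ren <- render_phone_plate(cls, plate_spec("phone8", seed = 2))
  co <- detect_finder_patterns(ren$image)
  expect_equal(dim(co), c(4, 2))
  expect_lt(max(abs(co - ren$corners)), 1.5)
})

test_that("detected corners track a known projective warp", {
  cls <- default_class_profiles()
  H <- with_seed(9L, random_homography(736, strength = 0.06))
  ren <- render_phone_plate(cls, plate_spec("phone8", seed = 4,
                                            homography = H))
  co <- detect_finder_patterns(ren$image)
  # oracle: apply the known H to the true rectified corner positions
  truth <- apply_homography(H, rbind(c(48, 48), c(688, 48), c(688, 688),
                                     c(48, 688)))
  expect_lt(max(abs(co - truth)), 1.5)
})

test_that("an occluded fiducial raises an error, not silent misuse", {
  cls <- default_class_profiles()
  ren <- render_phone_plate(cls, plate_spec("phone8", seed = 2))
  px <- ren$image$pixels
  px[1:120, 1:120, ] <- 250  # paint over the TL pattern
  expect_error(detect_finder_patterns(plate_image(px, "phone8")),
               "3 of 4")
})

test_that("rectification undoes the warp and is idempotent", {
  cls <- default_class_profiles()
  H <- with_seed(21L, random_homography(736, strength = 0.05))
  ren <- render_phone_plate(cls, plate_spec("phone8", seed = 6,
                                            homography = H))
  co <- detect_finder_patterns(ren$image)
  rect <- correct_perspective(ren$image, co, ren$rect_px + 1L)
  # ground-truth masks are stored in rectified coordinates: IoU >= 0.95
  seg <- segment_components(otsu_threshold(rgb_to_gray(rect))$mask,
                            min_area = 64, exclude_border = TRUE)
  expect_length(seg, length(ren$truth))
  for (i in seq_along(seg)) {
    gt <- ren$truth[[i]]
    canvas <- matrix(FALSE, ren$rect_px + 1, ren$rect_px + 1)
    a <- canvas; a[gt$offset[2] + seq_len(nrow(gt$mask)),
                   gt$offset[1] + seq_len(ncol(gt$mask))] <- gt$mask
    b <- canvas; b[seg[[i]]$offset[2] + seq_len(nrow(seg[[i]]$mask)),
                   seg[[i]]$offset[1] + seq_len(ncol(seg[[i]]$mask))] <-
      seg[[i]]$mask
    expect_gt(sum(a & b) / sum(a | b), 0.95)
  }
  # rectifying the rectified image with its own corners is near-identity
  o <- ren$rect_px
  corners2 <- rbind(c(0, 0), c(o, 0), c(o, o), c(0, o))
  rect2 <- correct_perspective(rect, corners2, ren$rect_px + 1L)
  expect_lte(max(abs(rect2 - rect)), 2)
})

test_that("identity-homography rectification is a crop", {
  cls <- default_class_profiles()
  ren <- render_phone_plate(cls, plate_spec(
    "phone8", seed = 8, illumination = 0, shadow = 0, noise_sigma = 0))
  m <- 48 + (800 - 736) / 2  # margin + centring offset
  corners <- rbind(c(m, m), c(m + 640, m), c(m + 640, m + 640),
                   c(m, m + 640))
  rect <- correct_perspective(ren$image, corners, 641L)
  crop <- ren$image$pixels[(m + 1):(m + 641), (m + 1):(m + 641), ]
  expect_lte(max(abs(rect - crop)), 1)
})
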
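test_that("centroid is the enumeration mean and handles edge cases", {
  L <- matrix(FALSE, 10, 10)
  L[2:9, 2] <- TRUE; L[9, 2:7] <- TRUE
  idx <- which(L, arr.ind = TRUE)
  expect_equal(unname(centroid(L)),
               c(mean(idx[, 2] - 1), mean(idx[, 1] - 1)))
  one <- matrix(FALSE, 5, 5); one[3, 4] <- TRUE
  expect_equal(unname(centroid(one)), c(3, 2))
  expect_error(centroid(matrix(FALSE, 4, 4)), "empty")
})

test_that("perimeter sums the chain and is traversal-symmetric", {
  ras <- rasterize_shape(shape_spec("circle", 100, center = c(110, 110)))
  ct <- extract_contour(ras$mask)
  expect_lt(abs(perimeter(ct) / (2 * pi * 100) - 1), 0.06)
  expect_equal(perimeter(ct), perimeter(ct[nrow(ct):1, ]))
})

test_that("long axis equals the all-pairs brute force", {
  set.seed(29)
  for (i in 1:12) {
    m <- random_blob(48)
    ct <- extract_contour(m)
    ext <- principal_extents(ct, m)
    expect_equal(ext$long_axis, oracle_long_axis(ct[, 1:2]), tolerance = 1e-9)
  }
})

test_that("principal extents recover ellipse axes", {
  ras <- rasterize_shape(shape_spec("ellipse", 80, elongation = 2,
                                    rotation_rad = 0.6, center = c(120, 120)))
  ct <- extract_contour(ras$mask)
  ext <- principal_extents(ct, ras$mask)
  expect_lt(abs(ext$long_axis - 160), 2)
  expect_lt(abs(ext$short_axis - 80), 2)
  expect_lt(abs(ext$long_axis / ext$short_axis - 2), 0.05)
})

test_that("incircle radius equals the brute-force distance maximum", {
  sq <- matrix(TRUE, 100, 100)
  expect_lt(abs(max_inscribed_circle(sq) - 50), 1)
  ras <- rasterize_shape(shape_spec("circle", 60, center = c(70, 70)))
  expect_lt(abs(max_inscribed_circle(ras$mask) - 60), 1)
  set.seed(31)
  for (i in 1:10) {
    m <- random_blob(40)
    expect_equal(max_inscribed_circle(m), oracle_incircle(m),
                 tolerance = 1e-9)
  }
})

test_that("excircle radius is the exact minimum enclosing circle", {
  tri <- rbind(c(0, 0), c(1, 0), c(0.5, sqrt(3) / 2))
  expect_equal(as.numeric(min_enclosing_circle(tri)), 1 / sqrt(3),
               tolerance = 1e-9)
  ras <- rasterize_shape(shape_spec("square", 50, center = c(70, 70)))
  ct <- extract_contour(ras$mask)
  expect_lt(abs(as.numeric(min_enclosing_circle(ct)) - 50 * sqrt(2)), 0.8)
  set.seed(37)
  for (i in 1:15) {
    pts <- matrix(runif(2 * sample(5:20, 1), 0, 60), ncol = 2)
    expect_equal(as.numeric(min_enclosing_circle(pts)), oracle_excircle(pts),
                 tolerance = 1e-6)
  }
})

test_that("radial variance behaves like a population variance of distances", {
  ras <- rasterize_shape(shape_spec("circle", 80, center = c(90, 90)))
  ct <- extract_contour(ras$mask)
  rv <- radial_variance(ct, centroid(ras$mask))
  expect_lt(rv[["irregularity"]], 0.3)
  expect_lt(rv[["norm_irregularity"]], 1e-4)
  # scaling a contour by 2 scales irregularity by 4, normalized unchanged
  ct2 <- ct; ct2[, 1:2] <- ct[, 1:2] * 2
  rv2 <- radial_variance(ct2, centroid(ras$mask) * 2)
  expect_equal(rv2[["irregularity"]], 4 * rv[["irregularity"]],
               tolerance = 1e-9)
  expect_equal(rv2[["norm_irregularity"]], rv[["norm_irregularity"]],
               tolerance = 1e-6)
})

test_that("star irregularity matches the dense generating-curve oracle", {
  sp <- shape_spec("bud", 50, frill_amplitude = 0.2, frill_count = 8,
                   center = c(80, 80))
  ras <- rasterize_shape(sp)
  ct <- extract_contour(ras$mask)
  rv <- radial_variance(ct, centroid(ras$mask))
  # oracle: 1e5 samples of r(theta) = 50 (1 + 0.2 cos 8 theta), uniform in
  # arc length via speed weights
  th <- (seq_len(1e5) - 0.5) / 1e5 * 2 * pi
  r <- 50 * (1 + 0.2 * cos(8 * th))
  dr <- -50 * 0.2 * 8 * sin(8 * th)
  w <- sqrt(r^2 + dr^2)
  mu <- sum(w * r) / sum(w)
  expect_lt(abs(rv[["irregularity"]] / (sum(w * (r - mu)^2) / sum(w)) - 1),
            0.05)
})

test_that("the assembled morphology vector has the canonical form", {
  ras <- rasterize_shape(shape_spec("circle", 80, center = c(90, 90)))
  m <- compute_morphology(ras$mask)
  expect_named(m, morphology_features())
  expect_length(m, 14)
  expect_lt(abs(m[["circularity"]] - 1), 0.12)
  expect_lt(abs(m[["roundness"]] - 1), 0.03)
  expect_lt(abs(m[["compactness"]] - 1), 0.03)
  expect_lt(abs(m[["aspect_ratio"]] - 1), 0.03)
  sq <- rasterize_shape(shape_spec("square", 50, center = c(70, 70)))
  ms <- compute_morphology(sq$mask)
  expect_lt(abs(ms[["shape_param"]] - 16), 0.8)
})

test_that("all descriptors are invariant under 90-degree rotations", {
  set.seed(43)
  for (i in 1:6) {
    m <- rasterize_shape(random_bud_spec())$mask
    v0 <- compute_morphology(m)
    for (k in 1:3) {
      vk <- compute_morphology(rotate_mask_90(m, k))
      expect_equal(vk, v0, tolerance = 1e-9)
    }
  }
})

test_that("descriptors scale correctly with resolution", {
  set.seed(47)
  for (i in 1:5) {
    sp <- random_bud_spec(scale = runif(1, 40, 50))
    sp2 <- sp; sp2$scale_px <- sp$scale_px * 2; sp2$center <- c(220, 220)
    v1 <- compute_morphology(rasterize_shape(sp)$mask)
    v2 <- compute_morphology(rasterize_shape(sp2)$mask)
    expect_lt(abs(v2[["perimeter"]] / v1[["perimeter"]] - 2), 0.04)
    expect_lt(abs(v2[["area"]] / v1[["area"]] - 4), 0.08)
    for (f in c("circularity", "shape_param", "aspect_ratio",
                "compactness", "roundness"))
      expect_lt(abs(v2[[f]] / v1[[f]] - 1), 0.03, label = f)
    expect_lt(abs(v2[["irregularity"]] / v1[["irregularity"]] - 4), 0.2)
    expect_lt(abs(v2[["norm_irregularity"]] / v1[["norm_irregularity"]] - 1),
              0.05)
  }
})

test_that("the circle is extremal among equal-area shapes", {
  A <- pi * 60^2
  shapes <- list(
    circle = shape_spec("circle", 60, center = c(110, 110)),
    ellipse = shape_spec("ellipse", 60 * sqrt(2), elongation = 2,
                         center = c(110, 110)),
    square = shape_spec("square", sqrt(A) / 2, center = c(110, 110)),
    star = shape_spec("bud", 60 / sqrt(1 + 0.3^2 / 2), frill_amplitude = 0.3,
                      frill_count = 8, center = c(110, 110)))
  vals <- lapply(shapes, function(s) compute_morphology(rasterize_shape(s)$mask))
  areas <- vapply(vals, `[[`, 0, "area")
  expect_true(all(abs(areas / A - 1) < 0.05))
  for (f in c("circularity", "roundness"))
    expect_true(all(vals$circle[[f]] >= vapply(vals[-1], `[[`, 0, f)),
                label = f)
  expect_true(all(vals$circle[["norm_irregularity"]] <=
                    vapply(vals[-1], `[[`, 0, "norm_irregularity")))
})
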
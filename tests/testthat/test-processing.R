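test_that("median filter matches the per-pixel oracle and its fixed points", {
  const <- matrix(7, 20, 20)
  expect_identical(median_denoise(const), const)
  salt <- matrix(100, 32, 32); salt[16, 16] <- 60000
  expect_true(all(median_denoise(salt) == 100))
  set.seed(5)
  img <- matrix(sample(0:255, 64 * 64, TRUE), 64, 64)
  expect_equal(median_denoise(img), oracle_median3(img))
})

test_that("otsu threshold equals the exhaustive between-class scan", {
  # perfectly bimodal image
  v <- c(rep(10, 40), rep(200, 60))
  img <- matrix(v[sample.int(100)], 10, 10)
  ot <- otsu_threshold(img)
  expect_gt(ot$threshold, 10)
  expect_lt(ot$threshold, 200)
  expect_equal(mean(ot$mask), 0.40)
  # exhaustive oracle on random mixtures
  set.seed(17)
  for (i in 1:25) {
    px <- matrix(c(rnorm(600, 80, 25), rnorm(400, 180, 20)), 25, 40)
    px <- pmin(pmax(px, 0), 255)
    ot <- otsu_threshold(px)
    tb <- oracle_otsu_bin(px)
    lo <- min(px); hi <- max(px)
    expect_equal(ot$threshold, lo + (tb + 1) / 256 * (hi - lo),
                 tolerance = 1e-9)
  }
  expect_error(otsu_threshold(matrix(5, 10, 10)), "degenerate histogram")
})

test_that("inverting the image flips foreground but keeps components", {
  set.seed(3)
  m <- random_blob(40)
  img <- matrix(200, 40, 40); img[m] <- 30
  ot <- otsu_threshold(img)
  ot_inv <- otsu_threshold(255 - img)
  expect_identical(ot$mask, !ot_inv$mask)
  expect_equal(max(budvision:::.cpp_label_components(ot$mask)),
               max(budvision:::.cpp_label_components(!ot_inv$mask)))
})

test_that("component labelling equals a flood-fill oracle", {
  set.seed(23)
  for (i in 1:10) {
    m <- random_blob(40, n_discs = 2) | random_blob(40, n_discs = 2)
    lab <- budvision:::.cpp_label_components(m)
    ref <- oracle_label(m)
    expect_equal(max(lab), max(ref))
    # same partition: label images agree up to renumbering
    expect_equal(length(unique(paste(lab[m], ref[m]))), max(ref))
  }
})

test_that("segmentation filters specks and orders row-major", {
  m <- matrix(FALSE, 100, 100)
  m[10:30, 10:30] <- TRUE        # row 1 left
  m[12:20, 60:80] <- TRUE        # row 1 right (smaller, higher top)
  m[60:90, 40:70] <- TRUE        # row 2
  m[50, 5] <- TRUE               # speck
  seg <- segment_components(m, min_area = 64)
  expect_length(seg, 3)
  expect_equal(vapply(seg, function(s) s$offset[1], 0), c(9, 59, 39))
  expect_equal(vapply(seg, function(s) s$index, 0L), 1:3)
  seg_all <- segment_components(m, min_area = 1)
  expect_length(seg_all, 4)
  expect_length(segment_components(matrix(FALSE, 40, 40)), 0)
})

test_that("contour tracing has the documented chain properties", {
  sq <- matrix(TRUE, 10, 10)
  ct <- extract_contour(sq)
  expect_equal(nrow(ct), 36)
  expect_equal(perimeter(ct), 36)
  # 8-connected consecutive steps, closed
  p2 <- rbind(ct, ct[1, ])
  steps <- pmax(abs(diff(p2[, 1])), abs(diff(p2[, 2])))
  expect_true(all(steps == 1))
  # counter-clockwise: positive shoelace area with y upwards
  x <- ct[, 1]; y <- -ct[, 2]
  expect_gt(sum(x * c(y[-1], y[1]) - c(x[-1], x[1]) * y) / 2, 0)
  # disk boundary count close to the boundary-pixel enumeration
  ras <- rasterize_shape(shape_spec("circle", 50, center = c(60, 60)))
  ctd <- extract_contour(ras$mask)
  # oracle: enumerate boundary pixels (foreground with a 4-adjacent
  # background pixel, i.e. unit distance to background)
  boundary_count <- sum(budvision:::.cpp_edt(ras$mask) == 1)
  expect_lt(abs(nrow(ctd) / boundary_count - 1), 0.02)
  expect_error(extract_contour(matrix(c(TRUE, TRUE, FALSE, FALSE), 2, 2)),
               "degenerate")
})

test_that("filling a traced contour reproduces the mask", {
  set.seed(11)
  for (i in 1:8) {
    sp <- random_bud_spec()
    ras <- rasterize_shape(sp)
    ct <- extract_contour(ras$mask)
    fl <- fill_contour(ct)
    expect_identical(fl$mask, ras$mask)
  }
})

test_that("gel pipeline is invariant to linear intensity rescaling", {
  ren <- render_gel_plate(default_class_profiles(),
                          plate_spec("gel16", grid = c(2, 2), seed = 5))
  img <- ren$image$pixels
  m1 <- otsu_threshold(median_denoise(img))$mask
  m2 <- otsu_threshold(median_denoise(img * 0.4 + 1000))$mask
  expect_identical(m1, m2)
})

test_that("crops preserve order, margins and image bounds", {
  arr <- array(runif(60 * 60 * 3), c(60, 60, 3)) * 255
  insts <- list(
    structure(list(mask = matrix(TRUE, 10, 10), offset = c(0, 0), area = 100,
                   index = 1L), class = "instance_mask"),
    structure(list(mask = matrix(TRUE, 8, 8), offset = c(50, 52), area = 64,
                   index = 2L), class = "instance_mask"))
  cr0 <- crop_instances(arr, insts, margin_px = 0)
  expect_equal(dim(cr0[[1]]), c(10, 10, 3))
  cr5 <- crop_instances(arr, insts, margin_px = 5)
  expect_equal(dim(cr5[[1]]), c(15, 15, 3))   # clipped at the corner
  expect_equal(dim(cr5[[2]]), c(13, 15, 3))   # clipped bottom-right
  expect_length(crop_instances(arr, insts[c(1, 2, 1)]), 3)
})
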
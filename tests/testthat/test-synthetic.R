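test_that("noiseless gel rendering equals its ground-truth masks exactly", {
  prof <- list(c1 = class_profile("c1", "bloom", family = "circle",
                                  scale_px = c(50, 50),
                                  frill_amplitude = c(0, 0),
                                  frill_count = c(0L, 0L),
                                  elongation = c(1, 1), perturb_max = 0))
  ps <- plate_spec("gel16", grid = c(1, 1), image_size = c(512, 512),
                   noise_sigma = 0, salt_pepper = 0, seed = 3)
  ren <- render_gel_plate(prof, ps)
  fg <- sum(ren$image$pixels < 30000)
  expect_identical(fg, sum(ren$truth[[1]]$mask))
  expect_equal(ren$truth[[1]]$area, fg)
})

test_that("gel rendering is a pure function of (spec, seed)", {
  cls <- default_class_profiles()
  ps <- plate_spec("gel16", grid = c(2, 2), seed = 7)
  r1 <- render_gel_plate(cls, ps)
  r2 <- render_gel_plate(cls, ps)
  expect_identical(r1$image$pixels, r2$image$pixels)
  expect_identical(r1$truth, r2$truth)
})

test_that("a 4x4 grid yields 16 instances in row-major order", {
  cls <- default_class_profiles()
  ren <- render_gel_plate(cls, plate_spec("gel16", grid = c(4, 4), seed = 1))
  expect_length(ren$truth, 16)
  cy <- vapply(ren$truth, function(t) t$centroid[2], 0)
  cx <- vapply(ren$truth, function(t) t$centroid[1], 0)
  rows <- rep(1:4, each = 4)
  expect_true(all(tapply(cy, rows, max) < c(tapply(cy, rows, min)[-1], Inf)))
  expect_true(all(tapply(cx, rows, function(x) all(diff(x) > 0))))
})

test_that("renderer errors are informative", {
  expect_error(render_gel_plate(list(), plate_spec("gel16")), "empty")
  big <- list(class_profile("big", "bloom", scale_px = c(300, 300)))
  expect_error(render_gel_plate(big, plate_spec("gel16", grid = c(4, 4),
                                                seed = 1)),
               "too large")
  expect_error(render_gel_plate(default_class_profiles(),
                                plate_spec("phone8")), "gel16")
})

test_that("an off-frame homography is rejected", {
  H <- matrix(c(1, 0, 700, 0, 1, 0, 0, 0, 1), 3, 3, byrow = TRUE)
  expect_error(render_phone_plate(default_class_profiles(),
                                  plate_spec("phone8", seed = 1,
                                             homography = H)),
               "outside the frame")
})

test_that("classes identical in shape differ only in colour", {
  prof <- color_only_profiles()
  ren <- render_phone_plate(prof[c("HB", "KX")],
                            plate_spec("phone8", grid = c(2, 2), seed = 5))
  cols <- t(vapply(ren$truth, function(t) as.numeric(t$color), numeric(3)))
  cl <- vapply(ren$truth, `[[`, "", "class")
  expect_gt(sum(abs(colMeans(cols[cl == "HB", , drop = FALSE]) -
                      colMeans(cols[cl == "KX", , drop = FALSE]))), 50)
  # shape sampling ranges are the identical object for every class
  expect_identical(prof$HB$scale_px, prof$KX$scale_px)
  expect_identical(prof$HB$frill_amplitude, prof$KX$frill_amplitude)
})

test_that("benchmark dataset bookkeeping is exact and seeded", {
  cls <- default_class_profiles()
  ds <- make_benchmark_dataset(cls, 4, seed = 13, mode = "gel",
                               use_truth = TRUE)
  expect_equal(nrow(ds$features), 28)
  expect_true(all(table(ds$features$class) == 4))
  # canonical stage labelling: 3 bloom, 4 fetal products
  st <- unique(ds$features[, c("class", "stage")])
  expect_equal(sum(st$stage == "bloom"), 3)
  expect_equal(sum(st$stage == "fetal"), 4)
  ds2 <- make_benchmark_dataset(cls, 4, seed = 13, mode = "gel",
                                use_truth = TRUE)
  expect_identical(ds$features, ds2$features)
})

test_that("ground truth carries analytic morphology exactly for canonical shapes", {
  prof <- list(e = class_profile("e", "bloom", family = "ellipse",
                                 scale_px = c(40, 40), elongation = c(2, 2),
                                 frill_amplitude = c(0, 0),
                                 frill_count = c(0L, 0L), perturb_max = 0))
  ren <- render_gel_plate(prof, plate_spec("gel16", grid = c(1, 1),
                                           image_size = c(256, 256),
                                           noise_sigma = 0, salt_pepper = 0,
                                           seed = 2))
  gt <- ren$truth[[1]]
  expect_false(is.null(gt$analytic))
  expect_equal(gt$analytic[["aspect_ratio"]], 2)
  # measured morphology close to the analytic values
  v <- compute_morphology(gt)
  expect_lt(abs(v[["area"]] / gt$analytic[["area"]] - 1), 0.02)
  expect_lt(abs(v[["long_axis"]] / gt$analytic[["long_axis"]] - 1), 0.03)
})
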
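test_that("crop preprocessing feeds the 7,500-neuron input layer", {
  crop <- array(runif(50 * 50 * 3) * 255, c(50, 50, 3))
  out <- preprocess_crop(crop)
  expect_equal(length(out), 7500)
  expect_equal(out, crop / 255, tolerance = 1e-9)  # identity resize
  big <- array(120, c(77, 41, 3))
  expect_true(all(abs(preprocess_crop(big) - 120 / 255) < 1e-9))
  expect_error(preprocess_crop(matrix(1, 50, 50)), "RGB")
  expect_error(preprocess_crop(array(1, c(4, 50, 3))), "8 x 8")
})

test_that("the shape audit matches hand-derived sizes for all nine candidates", {
  cands <- table_architectures(7)
  for (a in cands) {
    audit <- build_cnn(a)
    h <- 50; cin <- 3; total <- 0
    for (s in seq_along(a$filters)) {
      total <- total + a$filters[s] * (a$kernel^2 * cin + 1) + 2 * a$filters[s]
      h <- ceiling(h / a$pools[s])   # ceiling-mode pooling
      cin <- a$filters[s]
    }
    total <- total + (h * h * cin + 1) * 7
    expect_equal(audit$flat_dim, h * h * cin)
    expect_equal(audit$total_params, total)
    expect_equal(audit$input_neurons, 7500)
  }
  # conv parameter closed form, spelled out for the two-stage candidate
  two <- build_cnn(cnn_architecture(c(32, 64), c(2, 8), 2L, 7L))
  expect_equal(two$layers$params[1], 32 * (4 * 3 + 1) + 64)
  expect_equal(two$layers$params[3], 64 * (4 * 32 + 1) + 128)
  # pool size 1 preserves spatial size through every stage
  keep <- build_cnn(cnn_architecture(c(8, 8), c(1, 1), 2L, 3L))
  expect_true(all(keep$layers$out_h[1:4] == 50))
})

test_that("softmax outputs are proper distributions", {
  set.seed(3)
  x <- array(runif(4 * 50 * 50 * 3), c(4, 50, 50, 3))
  arch <- cnn_architecture(c(4, 8), c(2, 8), 2L, 5L)
  m <- train_cnn(arch, x, factor(c("a", "b", "a", "b")),
                 train_config(epochs = 1, seed = 1))
  p <- predict(m, x, type = "prob")
  expect_equal(rowSums(p), rep(1, 4), tolerance = 1e-6)
})

test_that("a trivially learnable batch drives the loss down monotonically", {
  x <- array(0, c(2, 50, 50, 3)); x[1, , , 1] <- 1; x[2, , , 3] <- 1
  m <- train_cnn(cnn_architecture(c(8, 16), c(2, 8), 2L, 2L), x,
                 factor(c("red", "blue")), train_config(epochs = 10, seed = 3))
  expect_true(all(diff(m$curve$loss) < 0))
  expect_equal(nrow(m$curve), 10)
})

test_that("seeded training reproduces the loss curve", {
  set.seed(5)
  x <- array(runif(12 * 50 * 50 * 3), c(12, 50, 50, 3))
  y <- factor(rep(c("a", "b", "c"), 4))
  cfg <- train_config(epochs = 4, seed = 11)
  arch <- cnn_architecture(c(6, 12), c(2, 8), 2L, 3L)
  m1 <- train_cnn(arch, x, y, cfg)
  m2 <- train_cnn(arch, x, y, cfg)
  expect_equal(m1$curve$loss, m2$curve$loss, tolerance = 1e-6)
  expect_identical(predict(m1, x), predict(m2, x))
})

test_that("colour-separable classes are fit quickly and evaluated consistently", {
  set.seed(7)
  n <- 36
  y <- factor(rep(c("r", "g", "b"), n / 3))
  cols <- diag(3) * 0.8
  x <- array(0, c(n, 50, 50, 3))
  for (i in 1:n)
    for (ch in 1:3)
      x[i, , , ch] <- cols[as.integer(y[i]), ch] +
        matrix(rnorm(2500, 0, 0.04), 50, 50)
  m <- train_cnn(cnn_architecture(c(8, 16), c(2, 8), 2L, 3L), x, y,
                 train_config(epochs = 30, batch = 12, seed = 2))
  ev <- evaluate_cnn(m, x, y)
  expect_gte(ev$accuracy, 95)
  # evaluation on the training set agrees with the final training accuracy
  expect_lt(abs(ev$accuracy - m$curve$accuracy[nrow(m$curve)]), 6)
  # conservation and permutation invariance
  expect_equal(unname(rowSums(ev$confusion)), as.vector(table(y)))
  perm <- sample(n)
  expect_equal(evaluate_cnn(m, x[perm, , , , drop = FALSE], y[perm])$accuracy,
               ev$accuracy)
  # a non-finite loss is reported with its epoch index
  xbad <- x; xbad[1, 1, 1, 1] <- NaN
  expect_error(train_cnn(cnn_architecture(c(8, 16), c(2, 8), 2L, 3L), xbad, y,
                         train_config(epochs = 2, batch = 36, seed = 2)),
               "epoch 1")
})

test_that("architecture search records failures and breaks ties by size", {
  set.seed(13)
  x <- array(runif(30 * 50 * 50 * 3), c(30, 50, 50, 3))
  y <- factor(rep(c("a", "b"), 15))
  good <- cnn_architecture(c(4, 8), c(2, 8), 2L, 2L)
  bad <- structure(list(filters = c(-4L, 8L), pools = c(2L, 8L),
                        kernel = 2L, n_classes = 2L),
                   class = "cnn_architecture")  # bypasses the constructor
  se <- architecture_search(list(bad, good, good), x, y,
                            train_config(epochs = 2, seed = 3))
  expect_match(se$results$status[1], "stage")
  expect_true(se$best %in% c(2, 3))
  expect_equal(se$results$params[2], se$results$params[3])
  # duplicated winner: stable selection by (accuracy, params, order)
  expect_equal(se$best, 2)
})
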
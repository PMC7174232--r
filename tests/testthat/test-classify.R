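test_that("the 9:1 split is exact, stratified and seeded", {
  y <- factor(rep(letters[1:2], each = 50))
  sp <- split_dataset(y, 0.9, seed = 5)
  expect_length(sp$train, 90)
  expect_length(sp$test, 10)
  expect_setequal(c(sp$train, sp$test), 1:100)
  sp2 <- split_dataset(y, 0.9, seed = 5)
  expect_identical(sp, sp2)
  y7 <- factor(rep(letters[1:7], each = 30))
  sp7 <- split_dataset(y7, 0.9, seed = 1)
  expect_true(all(table(y7[sp7$train]) == 27))
  expect_true(all(table(y7[sp7$test]) == 3))
})

test_that("z-score standardization uses train-only population statistics", {
  z <- zscore(matrix(c(0, 2), 2, 1), matrix(1, 1, 1))
  expect_equal(as.numeric(z$train), c(-1, 1))
  expect_equal(as.numeric(z$test), 0)  # test value at the train mean
  set.seed(3)
  X <- matrix(rnorm(50 * 14, 5, 3), 50, 14,
              dimnames = list(NULL, paste0("f", 1:14)))
  z <- zscore(X)
  expect_equal(colMeans(z$train), setNames(rep(0, 14), colnames(X)),
               tolerance = 1e-9)
  expect_equal(sqrt(colMeans(z$train^2)), setNames(rep(1, 14), colnames(X)),
               tolerance = 1e-9)
  expect_equal(z$center, colMeans(X))
  expect_equal(z$scale, sqrt(colMeans(sweep(X, 2, colMeans(X))^2)))
  Xz <- X; Xz[, 3] <- 7
  expect_error(zscore(Xz), "f3")
})

test_that("PCA matches the covariance eigendecomposition", {
  set.seed(11)
  X <- matrix(rnorm(150), 30, 5)
  Xc <- scale(X, center = TRUE, scale = FALSE)
  p <- pca_explore(X, 5)
  ev <- eigen(stats::cov(Xc))
  expect_equal(p$explained_all, ev$values / sum(ev$values), tolerance = 1e-9)
  for (j in 1:5)
    expect_equal(abs(p$loadings[, j]), abs(ev$vectors[, j]), tolerance = 1e-7)
  # sign convention: dominant loading positive
  expect_true(all(apply(p$loadings, 2, function(l) l[which.max(abs(l))] > 0)))
  # completeness: full reconstruction
  expect_lt(max(abs(X - p$scores %*% t(p$loadings))), 1e-8)
  # one-axis data
  X1 <- cbind(seq_len(20), 0, 0)
  expect_equal(pca_explore(X1, 1)$explained[1], 1)
  expect_error(pca_explore(X1, 3), "rank")
})

test_that("the canonical grids have the printed sizes and order", {
  g <- default_grid()
  expect_equal(nrow(g$knn), 10)
  expect_equal(nrow(g$mlp), 26)
  expect_equal(nrow(g$svm), 99)
  expect_equal(g$knn$k[1:3], c(1, 1, 2))       # k ascending, then p
  expect_equal(g$knn$p[1:2], c(2, 3))
  expect_equal(g$mlp$hidden[1:3], c(5, 5, 7))
  expect_equal(as.character(g$mlp$activation[1:2]), c("relu", "tanh"))
  expect_equal(g$svm$C[1:10], c(rep(1, 9), 2))  # C ascending, then gamma
  expect_equal(g$svm$gamma[1:3], 2^(-8:-6))
  expect_equal(range(g$svm$C), c(1, 1024))
  expect_equal(range(g$svm$gamma), c(2^-8, 1))
})

make_gaussians <- function(n = 60, sep = 8) {
  x <- rbind(matrix(rnorm(n * 2), n, 2),
             matrix(rnorm(n * 2, sep), n, 2))
  colnames(x) <- c("u", "v")
  list(x = x, y = factor(rep(c("a", "b"), each = n)))
}

test_that("grid search is exhaustive, seeded and separable-friendly", {
  set.seed(19)
  d <- make_gaussians()
  g <- default_grid(folds = 5L)
  gs <- grid_search_cv("knn", d$x, d$y, grid = g, seed = 3)
  expect_equal(nrow(gs$table), 10)
  expect_true(all(gs$table$cv_accuracy >= 95))
  expect_true(gs$best$k %in% 1:5 && gs$best$p %in% 2:3)
  gs2 <- grid_search_cv("knn", d$x, d$y, grid = g, seed = 3)
  expect_identical(gs$best, gs2$best)
  # tie-break: all-perfect grid selects the first candidate
  if (all(gs$table$cv_accuracy == 100))
    expect_equal(unlist(gs$best), c(k = 1, p = 2))
})

test_that("train_eval reports honest accuracies and confusions", {
  set.seed(23)
  d <- make_gaussians()
  r <- train_eval("knn", list(k = 1, p = 2), d$x, d$y, d$x, d$y, seed = 1)
  expect_equal(r$train_accuracy, 100)  # k = 1 memorizes its training set
  expect_equal(sum(r$confusion), length(d$y))
  expect_equal(unname(rowSums(r$confusion)), as.vector(table(d$y)))
  expect_equal(r$test_accuracy_pct, as.integer(round(r$test_accuracy)))
})

test_that("every family beats the majority baseline on separable data", {
  set.seed(29)
  d <- make_gaussians(40, sep = 6)
  small <- list(knn = data.frame(k = 3, p = 2),
                mlp = data.frame(hidden = 9, activation = "relu",
                                 stringsAsFactors = FALSE),
                svm = data.frame(C = 4, gamma = 0.25), folds = 5L)
  sp <- split_dataset(d$y, 0.8, seed = 2)
  for (fam in c("knn", "mlp", "svm")) {
    gs <- grid_search_cv(fam, d$x[sp$train, ], d$y[sp$train], small, seed = 2)
    r <- train_eval(fam, gs$best, d$x[sp$train, ], d$y[sp$train],
                    d$x[sp$test, ], d$y[sp$test], seed = 2)
    expect_gt(r$test_accuracy, 50, label = fam)
  }
})

test_that("standardization and selection never touch test rows", {
  set.seed(31)
  d <- make_gaussians(50)
  sp <- split_dataset(d$y, 0.8, seed = 7)
  x_taint <- d$x
  x_taint[sp$test, ] <- x_taint[sp$test, ] + 1e6  # poison the test rows
  g <- list(knn = data.frame(k = 1, p = 2), folds = 5L)
  gs1 <- grid_search_cv("knn", d$x[sp$train, ], d$y[sp$train], g, seed = 1)
  gs2 <- grid_search_cv("knn", x_taint[sp$train, ], d$y[sp$train], g, seed = 1)
  expect_identical(gs1, gs2)  # CV saw only training rows
  z <- zscore(d$x[sp$train, ], d$x[sp$test, ])
  zt <- zscore(x_taint[sp$train, ], d$x[sp$test, ])
  expect_identical(z$center, zt$center)
})
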
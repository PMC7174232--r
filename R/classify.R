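#' Stratified train/test split
#'
#' Randomly divides instances into a training and an independent test set
#' (default 9:1), stratified so per-class proportions are preserved to within
#' one instance; deterministic for a given seed.
#'
#' @param labels factor or character vector of class labels.
#' @param train_frac training fraction in (0, 1).
#' @param seed integer seed.
#' @param stratify stratify by `labels` (default) or split completely at
#'   random.
#' @return List with integer index vectors `train` and `test` (disjoint,
#'   exhaustive).
#' @export
split_dataset <- function(labels, train_frac = 0.9, seed = 1L,
                          stratify = TRUE) {
  if (train_frac <= 0 || train_frac >= 1) stopf("train_frac must be in (0,1)")
  labels <- as.factor(labels)
  n <- length(labels)
  if (n < 20) stopf("need at least 20 instances to split")
  test <- with_seed(seed, {
    if (stratify) {
      unlist(lapply(levels(labels), function(cl) {
        idx <- which(labels == cl)
        k <- round(length(idx) * (1 - train_frac))
        if (k >= length(idx)) k <- length(idx) - 1L
        if (k > 0) sample(idx, k) else integer()
      }), use.names = FALSE)
    } else {
      sample.int(n, round(n * (1 - train_frac)))
    }
  })
  train <- setdiff(seq_len(n), test)
  missing <- setdiff(levels(labels), unique(as.character(labels[train])))
  if (length(missing))
    stopf("class absent from the training set after split: %s",
          paste(missing, collapse = ", "))
  list(train = sort(train), test = sort(as.integer(test)))
}

#' z-score standardization fit on the training set
#'
#' Per-feature mean and population standard deviation are estimated on the
#' training rows only and applied to both sets, so no test information leaks
#' into the scaling.
#'
#' @param train numeric matrix / data.frame of training features.
#' @param test optional matrix of test features.
#' @return List with standardized `train`, `test` (or NULL), and the
#'   `center`/`scale` vectors used.
#' @export
zscore <- function(train, test = NULL) {
  train <- as.matrix(train)
  if (nrow(train) < 2) stopf("need at least 2 training rows")
  ctr <- colMeans(train)
  sc <- sqrt(colMeans(sweep(train, 2, ctr)^2))  # population SD
  bad <- which(sc == 0)
  if (length(bad))
    stopf("zero-variance training feature: %s",
          paste(colnames(train)[bad] %||% bad, collapse = ", "))
  std <- function(x) sweep(sweep(as.matrix(x), 2, ctr), 2, sc, "/")
  list(train = std(train), test = if (!is.null(test)) std(test),
       center = ctr, scale = sc)
}

#' Principal component exploration of a feature table
#'
#' Eigen-decomposition of the covariance of the (standardized) feature
#' matrix. Loadings follow the convention that each component's
#' largest-magnitude element is positive; scores are the projections onto
#' the loadings.
#'
#' @param X standardized feature matrix.
#' @param n_components number of components to return (<= rank of X).
#' @return List with `scores`, `loadings`, `explained` (variance fractions,
#'   non-increasing) of class `bud_pca`.
#' @export
pca_explore <- function(X, n_components = 2L) {
  X <- as.matrix(X)
  r <- qr(X)$rank
  if (n_components > r)
    stopf("n_components (%d) exceeds the rank of X (%d)", n_components, r)
  sv <- svd(scale(X, center = TRUE, scale = FALSE))
  expl <- sv$d^2 / sum(sv$d^2)
  load <- sv$v[, seq_len(n_components), drop = FALSE]
  for (j in seq_len(ncol(load))) {
    i <- which.max(abs(load[, j]))
    if (load[i, j] < 0) load[, j] <- -load[, j]
  }
  rownames(load) <- colnames(X)
  colnames(load) <- paste0("PC", seq_len(n_components))
  scores <- X %*% load
  structure(list(scores = scores, loadings = load,
                 explained = expl[seq_len(n_components)],
                 explained_all = expl),
            class = "bud_pca")
}

#' @export
print.bud_pca <- function(x, ...) {
  cat(sprintf("<bud_pca> %d components; explained: %s\n", ncol(x$loadings),
              paste(sprintf("%.1f%%", 100 * x$explained), collapse = ", ")))
  invisible(x)
}

#' Scatter plot of PCA scores coloured by label
#'
#' @param x a `bud_pca` object.
#' @param labels factor used for colouring (e.g. stage or type).
#' @param ... passed to [graphics::plot()].
#' @export
plot.bud_pca <- function(x, labels = NULL, ...) {
  s <- x$scores
  col <- if (is.null(labels)) 1 else as.integer(as.factor(labels))
  graphics::plot(s[, 1], s[, 2], col = col, pch = 19,
                 xlab = sprintf("PC1 (%.0f%%)", 100 * x$explained[1]),
                 ylab = sprintf("PC2 (%.0f%%)", 100 * x$explained[2]), ...)
  if (!is.null(labels))
    graphics::legend("topright", legend = levels(as.factor(labels)),
                     col = seq_along(levels(as.factor(labels))), pch = 19,
                     cex = 0.8)
  invisible(x)
}

#' Hyperparameter grids for the three classifier families
#'
#' The canonical search grids: KNN `k = 1..5` crossed with Minkowski power
#' `p = 2, 3` (10 candidates); single-hidden-layer MLP sizes `5, 7, ..., 29`
#' crossed with ReLU/tanh activations, Adam solver (26 candidates); RBF-SVM
#' `C = 2^0..2^10` crossed with `gamma = 2^-8..2^0` (99 candidates).
#' Candidate enumeration order is the tie-breaking order of the grid search.
#'
#' @param folds number of cross-validation folds.
#' @return List with elements `knn`, `mlp`, `svm` (data.frames of candidates
#'   in canonical order) and `folds`.
#' @export
default_grid <- function(folds = 10L) {
  knn <- expand.grid(p = c(2, 3), k = 1:5)[, c("k", "p")]  # k asc, then p
  mlp <- expand.grid(activation = c("relu", "tanh"),
                     hidden = seq(5L, 29L, 2L),
                     stringsAsFactors = FALSE)[, c("hidden", "activation")]
  svm <- expand.grid(gamma = 2^(-8:0), C = 2^(0:10))[, c("C", "gamma")]
  list(knn = knn, mlp = mlp, svm = svm, folds = as.integer(folds))
}

# ---- KNN with Minkowski metric --------------------------------------------

minkowski_dist <- function(A, B, p) {
  # |A_i - B_j|_p for all pairs; small n, loop over features
  n <- nrow(A); m <- nrow(B)
  D <- matrix(0, n, m)
  for (f in seq_len(ncol(A)))
    D <- D + abs(outer(A[, f], B[, f], "-"))^p
  D^(1 / p)
}

knn_predict <- function(train_x, train_y, test_x, k, p) {
  D <- minkowski_dist(as.matrix(test_x), as.matrix(train_x), p)
  train_y <- as.factor(train_y)
  apply_row <- function(i) {
    ord <- order(D[i, ])[seq_len(k)]
    votes <- table(train_y[ord])
    top <- names(votes)[votes == max(votes)]
    if (length(top) == 1L) top else {
      # tie: class of the nearest neighbour among the tied classes
      as.character(train_y[ord][as.character(train_y[ord]) %in% top][1])
    }
  }
  factor(vapply(seq_len(nrow(D)), apply_row, ""), levels = levels(train_y))
}

# ---- single-hidden-layer MLP trained with Adam ----------------------------

mlp_train <- function(x, y, hidden, activation = c("relu", "tanh"),
                      seed = 1L, maxit = 1000L, lr = 1e-3, tol = 1e-4,
                      n_iter_no_change = 10L) {
  activation <- match.arg(activation)
  x <- as.matrix(x); y <- as.factor(y)
  K <- nlevels(y); d <- ncol(x); n <- nrow(x)
  Yh <- matrix(0, n, K); Yh[cbind(seq_len(n), as.integer(y))] <- 1
  act <- if (activation == "relu") function(z) pmax(z, 0) else tanh
  dact <- if (activation == "relu") function(z, a) (z > 0) + 0 else
    function(z, a) 1 - a^2
  with_seed(seed, {
    W1 <- matrix(rnorm(d * hidden, 0, sqrt(2 / d)), d, hidden)
    b1 <- numeric(hidden)
    W2 <- matrix(rnorm(hidden * K, 0, sqrt(2 / hidden)), hidden, K)
    b2 <- numeric(K)
    ms <- lapply(list(W1, b1, W2, b2), function(p) p * 0)
    vs <- ms
    b1v <- 0.9; b2v <- 0.999; eps <- 1e-8
    best <- Inf; stall <- 0L
    for (it in seq_len(maxit)) {
      Z1 <- sweep(x %*% W1, 2, b1, "+")
      A1 <- act(Z1)
      Z2 <- sweep(A1 %*% W2, 2, b2, "+")
      Z2 <- Z2 - Z2[cbind(seq_len(n), max.col(Z2, ties.method = "first"))]
      P <- exp(Z2); P <- P / rowSums(P)
      loss <- -mean(log(pmax(P[cbind(seq_len(n), as.integer(y))], 1e-12)))
      # plateau stopping: loss must improve the running best by tol
      if (loss < best - tol) { best <- loss; stall <- 0L } else
        stall <- stall + 1L
      if (stall >= n_iter_no_change || loss < 1e-3) break
      dZ2 <- (P - Yh) / n
      gW2 <- crossprod(A1, dZ2); gb2 <- colSums(dZ2)
      dA1 <- dZ2 %*% t(W2)
      dZ1 <- dA1 * dact(Z1, A1)
      gW1 <- crossprod(x, dZ1); gb1 <- colSums(dZ1)
      gs <- list(gW1, gb1, gW2, gb2)
      ps <- list(W1, b1, W2, b2)
      for (j in 1:4) {
        ms[[j]] <- b1v * ms[[j]] + (1 - b1v) * gs[[j]]
        vs[[j]] <- b2v * vs[[j]] + (1 - b2v) * gs[[j]]^2
        mhat <- ms[[j]] / (1 - b1v^it)
        vhat <- vs[[j]] / (1 - b2v^it)
        ps[[j]] <- ps[[j]] - lr * mhat / (sqrt(vhat) + eps)
      }
      W1 <- ps[[1]]; b1 <- ps[[2]]; W2 <- ps[[3]]; b2 <- ps[[4]]
    }
    structure(list(W1 = W1, b1 = b1, W2 = W2, b2 = b2, act = activation,
                   levels = levels(y)),
              class = "bud_mlp")
  })
}

predict.bud_mlp <- function(object, x, ...) {
  act <- if (object$act == "relu") function(z) pmax(z, 0) else tanh
  A1 <- act(sweep(as.matrix(x) %*% object$W1, 2, object$b1, "+"))
  Z2 <- sweep(A1 %*% object$W2, 2, object$b2, "+")
  factor(object$levels[max.col(Z2, ties.method = "first")],
         levels = object$levels)
}

# fit + predict for one (family, params) candidate on standardized features
fit_predict <- function(family, params, train_x, train_y, test_x,
                        seed = 1L) {
  train_y <- as.factor(train_y)
  switch(family,
    knn = knn_predict(train_x, train_y, test_x, params$k, params$p),
    mlp = {
      fit <- mlp_train(train_x, train_y, hidden = params$hidden,
                       activation = params$activation, seed = seed)
      predict.bud_mlp(fit, test_x)
    },
    svm = {
      fit <- e1071::svm(x = as.matrix(train_x), y = train_y,
                        kernel = "radial", cost = params$C,
                        gamma = params$gamma, scale = FALSE)
      predict(fit, as.matrix(test_x))
    },
    stopf("unknown classifier family '%s'", family))
}

# stratified fold assignment, deterministic per seed
make_folds <- function(y, folds, seed) {
  y <- as.factor(y)
  fold <- integer(length(y))
  with_seed(seed, {
    for (cl in levels(y)) {
      idx <- sample(which(y == cl))
      fold[idx] <- rep_len(seq_len(folds), length(idx))
    }
  })
  fold
}

#' Grid search by stratified k-fold cross-validation
#'
#' Exhaustively evaluates every candidate of the family's grid by k-fold
#' cross-validation on the training set only. Standardization is refit
#' inside each fold (no leakage across folds). Selection is the highest mean
#' fold accuracy; ties go to the earliest candidate in canonical grid order.
#'
#' @param family `"knn"`, `"mlp"` or `"svm"`.
#' @param train_x raw (unstandardized) training features.
#' @param train_y training labels.
#' @param grid a grid list from [default_grid()].
#' @param seed integer seed (folds and MLP initialization).
#' @return List with `best` (named list of the winning hyperparameters),
#'   `cv_accuracy` (percent), and `table` (all candidates with their mean CV
#'   accuracies).
#' @export
grid_search_cv <- function(family, train_x, train_y, grid = default_grid(),
                           seed = 1L) {
  cand <- grid[[family]]
  folds <- grid$folds
  y <- as.factor(train_y)
  x <- as.matrix(train_x)
  fold <- make_folds(y, folds, seed)
  # standardization refit per fold, shared across candidates
  prep <- lapply(seq_len(folds), function(f) {
    tr <- fold != f
    if (nlevels(droplevels(y[tr])) < nlevels(y))
      stopf("fold %d lost a class; reduce folds or rebalance", f)
    z <- zscore(x[tr, , drop = FALSE], x[!tr, , drop = FALSE])
    list(train = z$train, test = z$test, ytr = y[tr], yte = y[!tr])
  })
  accs <- numeric(nrow(cand))
  for (ci in seq_len(nrow(cand))) {
    fa <- vapply(prep, function(pz) {
      pred <- fit_predict(family, as.list(cand[ci, , drop = FALSE]),
                          pz$train, pz$ytr, pz$test, seed = seed)
      mean(pred == pz$yte)
    }, 0)
    accs[ci] <- mean(fa)
  }
  best <- which.max(accs)  # first maximum = canonical tie-break
  list(best = as.list(cand[best, , drop = FALSE]),
       cv_accuracy = 100 * accs[best],
       table = cbind(cand, cv_accuracy = 100 * accs))
}

#' Fit the selected model and evaluate on the held-out test set
#'
#' Refits the family with its selected hyperparameters on the full training
#' set (standardization fit on train, applied to test) and reports training
#' and test accuracies plus the test confusion matrix.
#'
#' @param family `"knn"`, `"mlp"` or `"svm"`.
#' @param params named list of hyperparameters (from [grid_search_cv()]).
#' @param train_x,train_y,test_x,test_y raw features and labels.
#' @param seed integer seed.
#' @param cv_accuracy optional CV accuracy to carry into the result.
#' @return Object of class `bud_classifier_result`: family, params,
#'   accuracies (float and integer percent) and confusion matrix.
#' @export
train_eval <- function(family, params, train_x, train_y, test_x, test_y,
                       seed = 1L, cv_accuracy = NA_real_) {
  y_tr <- as.factor(train_y)
  y_te <- factor(test_y, levels = levels(y_tr))
  z <- zscore(as.matrix(train_x), as.matrix(test_x))
  pred_tr <- fit_predict(family, params, z$train, y_tr, z$train, seed = seed)
  pred_te <- fit_predict(family, params, z$train, y_tr, z$test, seed = seed)
  acc_tr <- 100 * mean(pred_tr == y_tr)
  acc_te <- 100 * mean(pred_te == y_te)
  cm <- table(truth = y_te, predicted = factor(pred_te, levels = levels(y_tr)))
  structure(list(family = family, params = params,
                 cv_accuracy = cv_accuracy,
                 train_accuracy = acc_tr, test_accuracy = acc_te,
                 train_accuracy_pct = as.integer(round(acc_tr)),
                 test_accuracy_pct = as.integer(round(acc_te)),
                 confusion = cm, n_train = length(y_tr),
                 n_test = length(y_te)),
            class = "bud_classifier_result")
}

#' @export
print.bud_classifier_result <- function(x, ...) {
  cat(sprintf("<%s> train %.1f%% / test %.1f%% (n = %d/%d)\n",
              toupper(x$family), x$train_accuracy, x$test_accuracy,
              x$n_train, x$n_test))
  cat("  params:", paste(names(x$params), unlist(x$params), sep = "=",
                         collapse = ", "), "\n")
  invisible(x)
}

#' Grid-searched classification of a feature table
#'
#' The full shape-feature protocol for one task: stratified 9:1 split,
#' 10-fold grid search on the training set for each requested family, refit
#' and evaluation on the held-out test set.
#'
#' @param features matrix/data.frame of morphology features.
#' @param labels class labels (stage or type).
#' @param families classifier families to run.
#' @param grid grid list from [default_grid()].
#' @param seed integer seed controlling split, folds and initializations.
#' @param train_frac training fraction.
#' @return Named list of `bud_classifier_result`, one per family.
#' @export
classify_features <- function(features, labels,
                              families = c("knn", "mlp", "svm"),
                              grid = default_grid(), seed = 1L,
                              train_frac = 0.9) {
  sp <- split_dataset(labels, train_frac = train_frac, seed = seed)
  x <- as.matrix(features)
  res <- lapply(families, function(fam) {
    gs <- grid_search_cv(fam, x[sp$train, , drop = FALSE],
                         labels[sp$train], grid = grid, seed = seed)
    train_eval(fam, gs$best, x[sp$train, , drop = FALSE], labels[sp$train],
               x[sp$test, , drop = FALSE], labels[sp$test], seed = seed,
               cv_accuracy = gs$cv_accuracy)
  })
  names(res) <- families
  res
}
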
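# Compact convolutional-network engine in vectorised base R. Convolutions
# are evaluated as k^2 shifted matrix products (channels-last batches),
# average pooling as separable 1-D linear operators, so every layer has an
# exact linear-algebra backward pass and runs on BLAS.

#' CNN architecture description
#'
#' A stack of 2-5 "autoencoder" stages, each convolution -> ReLU -> batch
#' normalization -> average pooling, followed by a fully connected softmax
#' head. Convolutions use square kernels, "same" padding and stride 1;
#' pooling windows equal their stride with ceiling-mode sizing and edge
#' replication, so the printed pool sequence 2, 8, 4, 2 is feasible on a
#' 50-px input (50 -> 25 -> 4 -> 1 -> 1).
#'
#' @param filters integer vector of per-stage convolution filter counts.
#' @param pools integer vector (same length) of pooling sizes.
#' @param kernel square convolution kernel side (default 2).
#' @param n_classes number of output classes.
#' @return Object of class `cnn_architecture`.
#' @export
cnn_architecture <- function(filters, pools, kernel = 2L, n_classes = 7L) {
  if (length(filters) != length(pools))
    stopf("filters and pools must have equal length")
  if (length(filters) < 2 || length(filters) > 5)
    stopf("between 2 and 5 stages are supported")
  if (any(filters <= 0) || any(pools < 1) || kernel < 1)
    stopf("filters must be positive and pools/kernel >= 1")
  structure(list(filters = as.integer(filters), pools = as.integer(pools),
                 kernel = as.integer(kernel),
                 n_classes = as.integer(n_classes)),
            class = "cnn_architecture")
}

#' @export
print.cnn_architecture <- function(x, ...) {
  cat(sprintf("<cnn_architecture> conv %dx%d; stages %s; pools %s; %d classes\n",
              x$kernel, x$kernel, paste(x$filters, collapse = ","),
              paste(x$pools, collapse = ","), x$n_classes))
  invisible(x)
}

#' The nine benchmark architecture candidates
#'
#' The canonical candidate list explored for the raw-image branch: depths 2-5,
#' filter stacks doubling VGG-style (16..256), pooling sequences built around
#' 2, 8, 4, 2, and convolution kernels 2x2 to 5x5; the default (second row)
#' is the four-stage 32/64/128/256 network with 2x2 kernels.
#'
#' @param n_classes number of output classes.
#' @return List of nine [cnn_architecture()] objects.
#' @export
table_architectures <- function(n_classes = 7L) {
  list(
    cnn_architecture(c(32, 64, 128, 256, 256), c(2, 8, 4, 2, 1), 2L, n_classes),
    cnn_architecture(c(32, 64, 128, 256), c(2, 8, 4, 2), 2L, n_classes),
    cnn_architecture(c(32, 64, 128, 128), c(2, 8, 4, 2), 2L, n_classes),
    cnn_architecture(c(32, 64, 128), c(2, 8, 4), 2L, n_classes),
    cnn_architecture(c(32, 64), c(2, 8), 2L, n_classes),
    cnn_architecture(c(32, 64, 128, 256), c(2, 8, 4, 2), 3L, n_classes),
    cnn_architecture(c(32, 64, 128, 256), c(2, 8, 4, 2), 4L, n_classes),
    cnn_architecture(c(32, 64, 128, 256), c(2, 8, 4, 2), 5L, n_classes),
    cnn_architecture(c(16, 32, 64, 128, 128), c(1, 4, 2, 1, 1), 2L, n_classes)
  )
}

#' Default training configuration
#'
#' RMSProp at a constant learning rate of 1e-4, at most 100 epochs,
#' minibatches of 128, categorical cross-entropy.
#'
#' @param lr learning rate.
#' @param epochs maximum number of epochs.
#' @param batch minibatch size.
#' @param seed integer seed (weight init and epoch shuffling).
#' @param rho RMSProp decay.
#' @return List of class `train_config`.
#' @export
train_config <- function(lr = 1e-4, epochs = 100L, batch = 128L, seed = 1L,
                         rho = 0.9) {
  if (lr <= 0 || epochs < 1 || batch < 1) stopf("invalid training config")
  structure(list(optimizer = "rmsprop", lr = lr, epochs = as.integer(epochs),
                 batch = as.integer(batch), seed = as.integer(seed),
                 rho = rho, loss = "categorical cross-entropy"),
            class = "train_config")
}

#' Preprocess a colour crop for the network
#'
#' Bicubic resample of an RGB crop straight to 50 x 50 (aspect ratio not
#' preserved) with intensities scaled to [0, 1]; the vectorized input feeds
#' the 7,500-neuron input layer.
#'
#' @param crop H x W x 3 array (intensities 0..255 or already 0..1).
#' @param size output side length (default 50).
#' @return `size` x `size` x 3 array in [0, 1].
#' @export
preprocess_crop <- function(crop, size = 50L) {
  d <- dim(crop)
  if (length(d) != 3 || d[3] != 3) stopf("crop must be an RGB (H x W x 3) array")
  if (d[1] < 8 || d[2] < 8) stopf("crop smaller than 8 x 8 px")
  if (max(crop) > 1) crop <- crop / 255
  clamp(resize_image(crop, size, size, method = "bicubic"), 0, 1)
}

#' Stack crops into a network input tensor
#'
#' @param crops list of RGB crops.
#' @param size output side length.
#' @return N x size x size x 3 array.
#' @export
crops_to_tensor <- function(crops, size = 50L) {
  n <- length(crops)
  out <- array(0, c(n, size, size, 3))
  for (i in seq_len(n)) out[i, , , ] <- preprocess_crop(crops[[i]], size)
  out
}

# ---- layer primitives -----------------------------------------------------
# Internal activation layout is (H, W, N, C): convolution shifts and
# H-pooling then operate on contiguous leading dimensions without
# transposes, and the channel contraction is one BLAS call per kernel
# offset. `ecol(v, m)` recycles a per-channel vector down the rows of an
# (m x C) matrix.

ecol <- function(v, m) rep(v, each = m)

conv_pad <- function(k) floor((k - 1) / 2)  # left/top "same" padding

conv_forward <- function(X, W, b) {
  d <- dim(X); H <- d[1]; Wd <- d[2]; N <- d[3]; C <- d[4]
  k <- dim(W)[1]; f <- dim(W)[4]
  pt <- conv_pad(k)
  Xp <- array(0, c(H + k - 1, Wd + k - 1, N, C))
  Xp[pt + seq_len(H), pt + seq_len(Wd), , ] <- X
  m <- H * Wd * N
  out <- matrix(0, m, f)
  for (dy in seq_len(k)) for (dx in seq_len(k)) {
    sl <- Xp[dy:(dy + H - 1), dx:(dx + Wd - 1), , , drop = FALSE]
    dim(sl) <- c(m, C)
    out <- out + sl %*% matrix(W[dy, dx, , ], C, f)
  }
  out <- out + ecol(b, m)
  dim(out) <- c(H, Wd, N, f)
  list(out = out, Xp = Xp, in_dim = d)
}

conv_backward <- function(dY, cache, W, need_dx = TRUE) {
  d <- cache$in_dim; H <- d[1]; Wd <- d[2]; N <- d[3]; C <- d[4]
  k <- dim(W)[1]; f <- dim(W)[4]
  pt <- conv_pad(k)
  m <- H * Wd * N
  dYm <- dY; dim(dYm) <- c(m, f)
  dW <- array(0, dim(W)); db <- colSums(dYm)
  dXp <- if (need_dx) array(0, dim(cache$Xp))
  for (dy in seq_len(k)) for (dx in seq_len(k)) {
    sl <- cache$Xp[dy:(dy + H - 1), dx:(dx + Wd - 1), , , drop = FALSE]
    dim(sl) <- c(m, C)
    dW[dy, dx, , ] <- crossprod(sl, dYm)
    if (need_dx) {
      dsl <- dYm %*% t(matrix(W[dy, dx, , ], C, f))
      dim(dsl) <- c(H, Wd, N, C)
      dXp[dy:(dy + H - 1), dx:(dx + Wd - 1), , ] <-
        dXp[dy:(dy + H - 1), dx:(dx + Wd - 1), , , drop = FALSE] + dsl
    }
  }
  dX <- if (need_dx) dXp[pt + seq_len(H), pt + seq_len(Wd), , , drop = FALSE]
  list(dX = dX, dW = dW, db = db)
}

pool_matrix <- function(n_in, p) {
  n_out <- ceiling(n_in / p)
  P <- matrix(0, n_out, n_in)
  for (o in seq_len(n_out)) {
    js <- pmin(((o - 1) * p + 1):(o * p), n_in)  # edge replication
    for (j in js) P[o, j] <- P[o, j] + 1 / p
  }
  P
}

# contract the leading dimension of a 4-D array with operator P
lead_op <- function(X, P) {
  d <- dim(X)
  dim(X) <- c(d[1], prod(d[-1]))
  Y <- P %*% X
  dim(Y) <- c(nrow(P), d[-1])
  Y
}

swap12 <- function(X) aperm(X, c(2, 1, 3, 4))

pool_forward <- function(X, p) {
  if (p == 1) return(list(out = X, Ph = NULL, Pw = NULL))
  Ph <- pool_matrix(dim(X)[1], p)
  Pw <- pool_matrix(dim(X)[2], p)
  out <- swap12(lead_op(swap12(lead_op(X, Ph)), Pw))
  list(out = out, Ph = Ph, Pw = Pw)
}

pool_backward <- function(dY, cache) {
  if (is.null(cache$Ph)) return(dY)
  lead_op(swap12(lead_op(swap12(dY), t(cache$Pw))), t(cache$Ph))
}

bn_forward <- function(X, gamma, beta, training, rmean, rvar,
                       momentum = 0.9, eps = 1e-5) {
  d <- dim(X); C <- d[4]
  m <- prod(d[1:3])
  Xm <- X; dim(Xm) <- c(m, C)
  if (training) {
    mu <- colMeans(Xm)
    v <- colMeans(Xm^2) - mu^2
    rmean <- momentum * rmean + (1 - momentum) * mu
    rvar <- momentum * rvar + (1 - momentum) * v
  } else {
    mu <- rmean; v <- rvar
  }
  istd <- 1 / sqrt(v + eps)
  xhat <- .cpp_col_affine(Xm, istd, -mu * istd)
  Y <- .cpp_col_affine(xhat, gamma, beta)
  dim(Y) <- d
  list(out = Y, xhat = xhat, istd = istd, rmean = rmean, rvar = rvar,
       in_dim = d)
}

bn_backward <- function(dY, cache, gamma) {
  d <- cache$in_dim; m <- prod(d[1:3])
  dYm <- dY; dim(dYm) <- c(m, d[4])
  dgamma <- colSums(dYm * cache$xhat)
  dbeta <- colSums(dYm)
  s <- gamma * cache$istd
  dX <- .cpp_col_affine2(dYm, cache$xhat, s, -s * dgamma / m,
                         -s * dbeta / m)
  dim(dX) <- d
  list(dX = dX, dgamma = dgamma, dbeta = dbeta)
}

# Recompute exact batch-norm population statistics over a dataset after
# training ("precise" BN): in training mode later stages depend only on
# batch statistics, so per-stage channel moments can be accumulated across
# minibatches and committed as the inference statistics.
finalize_bn <- function(net, x, batch = 128L) {
  N <- dim(x)[1]
  S <- length(net$stages)
  acc <- lapply(seq_len(S), function(s)
    list(sum = 0, sumsq = 0, n = 0))
  for (b0 in seq(1, N, by = batch)) {
    bi <- b0:min(b0 + batch - 1, N)
    A <- aperm(x[bi, , , , drop = FALSE], c(2, 3, 1, 4))
    for (s in seq_len(S)) {
      st <- net$stages[[s]]
      cv <- conv_forward(A, st$W, st$b)
      R <- pmax(cv$out, 0)
      d <- dim(R); m <- prod(d[1:3])
      Rm <- R; dim(Rm) <- c(m, d[4])
      acc[[s]]$sum <- acc[[s]]$sum + colSums(Rm)
      acc[[s]]$sumsq <- acc[[s]]$sumsq + colSums(Rm^2)
      acc[[s]]$n <- acc[[s]]$n + m
      bn <- bn_forward(R, st$gamma, st$beta, TRUE, st$rmean, st$rvar)
      A <- pool_forward(bn$out, net$arch$pools[s])$out
    }
  }
  for (s in seq_len(S)) {
    mu <- acc[[s]]$sum / acc[[s]]$n
    net$stages[[s]]$rmean <- mu
    net$stages[[s]]$rvar <- pmax(acc[[s]]$sumsq / acc[[s]]$n - mu^2, 0)
  }
  net
}

# ---- network --------------------------------------------------------------

#' Build a network and audit its shapes and parameter counts
#'
#' Symbolic construction only (no training): per-stage output shapes under
#' "same" convolutions and ceiling-mode average pooling, plus trainable
#' parameter counts (convolutions `f * (k^2 * c_in + 1)`, batch norm `2f`,
#' fully connected `(flat + 1) * n_classes`).
#'
#' @param arch a [cnn_architecture()].
#' @param input input dimensions `c(H, W, C)` (default 50 x 50 x 3).
#' @return List with `layers` (data.frame audit), `total_params`,
#'   `flat_dim`, `input_neurons`.
#' @export
build_cnn <- function(arch, input = c(50L, 50L, 3L)) {
  h <- input[1]; w <- input[2]; cin <- input[3]
  rows <- list()
  total <- 0
  for (s in seq_along(arch$filters)) {
    f <- arch$filters[s]; p <- arch$pools[s]; k <- arch$kernel
    if (h < 1 || w < 1)
      stopf("stage %d receives an empty spatial map", s)
    if (f < 1 || p < 1 || k < 1)
      stopf("stage %d has nonpositive filters/pool/kernel", s)
    pc <- f * (k^2 * cin + 1)
    bnc <- 2L * f
    h2 <- ceiling(h / p); w2 <- ceiling(w / p)
    rows[[length(rows) + 1]] <- data.frame(
      stage = s, layer = "conv+relu+bn", out_h = h, out_w = w,
      channels = f, params = pc + bnc)
    rows[[length(rows) + 1]] <- data.frame(
      stage = s, layer = sprintf("avgpool %d", p), out_h = h2, out_w = w2,
      channels = f, params = 0)
    total <- total + pc + bnc
    h <- h2; w <- w2; cin <- f
  }
  flat <- h * w * cin
  fc <- (flat + 1) * arch$n_classes
  rows[[length(rows) + 1]] <- data.frame(
    stage = length(arch$filters) + 1L, layer = "fc+softmax", out_h = 1L,
    out_w = 1L, channels = arch$n_classes, params = fc)
  total <- total + fc
  list(layers = do.call(rbind, rows), total_params = total, flat_dim = flat,
       input_neurons = prod(input))
}

init_cnn <- function(arch, input = c(50L, 50L, 3L), seed = 1L) {
  audit <- build_cnn(arch, input)  # validates feasibility
  with_seed(seed, {
    cin <- input[3]
    stages <- list()
    for (s in seq_along(arch$filters)) {
      f <- arch$filters[s]; k <- arch$kernel
      stages[[s]] <- list(
        W = array(rnorm(k * k * cin * f, 0, sqrt(2 / (k * k * cin))),
                  c(k, k, cin, f)),
        b = numeric(f), gamma = rep(1, f), beta = numeric(f),
        rmean = numeric(f), rvar = rep(1, f))
      cin <- f
    }
    fc <- list(W = matrix(rnorm(audit$flat_dim * arch$n_classes, 0,
                                sqrt(2 / audit$flat_dim)),
                          audit$flat_dim, arch$n_classes),
               b = numeric(arch$n_classes))
    list(arch = arch, input = input, stages = stages, fc = fc,
         audit = audit)
  })
}

cnn_forward <- function(net, X, training = FALSE) {
  caches <- list()
  A <- aperm(X, c(2, 3, 1, 4))  # batch (N,H,W,C) -> internal (H,W,N,C)
  for (s in seq_along(net$stages)) {
    st <- net$stages[[s]]
    cv <- conv_forward(A, st$W, st$b)
    R <- pmax(cv$out, 0)
    bn <- bn_forward(R, st$gamma, st$beta, training, st$rmean, st$rvar)
    pl <- pool_forward(bn$out, net$arch$pools[s])
    caches[[s]] <- list(conv = cv, relu_in = cv$out, bn = bn, pool = pl)
    A <- pl$out
  }
  d <- dim(A)  # (h, w, N, C)
  flat <- aperm(A, c(3, 1, 2, 4))
  dim(flat) <- c(d[3], d[1] * d[2] * d[4])
  logits <- flat %*% net$fc$W + ecol(net$fc$b, d[3])
  list(logits = logits, flat = flat, flat_dim = d, caches = caches)
}

softmax_probs <- function(logits) {
  z <- logits - apply(logits, 1, max)
  e <- exp(z)
  e / rowSums(e)
}

cnn_backward <- function(net, fwd, Y) {
  # Y: one-hot matrix; returns gradients mirroring the parameter structure
  N <- nrow(Y)
  P <- softmax_probs(fwd$logits)
  dlog <- (P - Y) / N
  g <- list(fc = list(W = crossprod(fwd$flat, dlog), b = colSums(dlog)),
            stages = vector("list", length(net$stages)))
  dflat <- dlog %*% t(net$fc$W)
  fd <- fwd$flat_dim  # (h, w, N, C)
  dim(dflat) <- c(fd[3], fd[1], fd[2], fd[4])
  dA <- aperm(dflat, c(2, 3, 1, 4))
  for (s in rev(seq_along(net$stages))) {
    ca <- fwd$caches[[s]]
    st <- net$stages[[s]]
    dA <- pool_backward(dA, ca$pool)
    bb <- bn_backward(dA, ca$bn, st$gamma)
    dR <- bb$dX * (ca$relu_in > 0)
    cb <- conv_backward(dR, ca$conv, st$W, need_dx = s > 1L)
    g$stages[[s]] <- list(W = cb$dW, b = cb$db, gamma = bb$dgamma,
                          beta = bb$dbeta)
    dA <- cb$dX
  }
  g
}

rmsprop_update <- function(net, g, state, lr, rho, eps = 1e-8) {
  upd <- function(p, gr, v) {
    v <- rho * v + (1 - rho) * gr^2
    list(p = p - lr * gr / (sqrt(v) + eps), v = v)
  }
  for (s in seq_along(net$stages)) {
    for (nm in c("W", "b", "gamma", "beta")) {
      u <- upd(net$stages[[s]][[nm]], g$stages[[s]][[nm]],
               state$stages[[s]][[nm]])
      net$stages[[s]][[nm]] <- u$p
      state$stages[[s]][[nm]] <- u$v
    }
  }
  for (nm in c("W", "b")) {
    u <- upd(net$fc[[nm]], g$fc[[nm]], state$fc[[nm]])
    net$fc[[nm]] <- u$p
    state$fc[[nm]] <- u$v
  }
  list(net = net, state = state)
}

#' Train a convolutional network
#'
#' Minimizes categorical cross-entropy with RMSProp at a constant learning
#' rate, seeded epoch shuffling, batch statistics for batch norm during
#' training and running statistics at inference. The same seed reproduces
#' the loss curve exactly on a fixed thread configuration.
#'
#' @param arch a [cnn_architecture()].
#' @param x N x 50 x 50 x 3 input tensor (see [crops_to_tensor()]).
#' @param y class labels (factor or character), length N.
#' @param cfg a [train_config()].
#' @param verbose print the per-epoch curve.
#' @return Object of class `budvision_cnn` with the fitted parameters and
#'   the per-epoch training loss/accuracy curve.
#' @export
train_cnn <- function(arch, x, y, cfg = train_config(), verbose = FALSE) {
  y <- as.factor(y)
  if (nlevels(y) < 2) stopf("need at least two classes present")
  if (nlevels(y) != arch$n_classes)
    arch$n_classes <- nlevels(y)
  N <- dim(x)[1]
  net <- init_cnn(arch, input = dim(x)[-1], seed = cfg$seed)
  state <- rapply(list(stages = lapply(net$stages, function(s)
    s[c("W", "b", "gamma", "beta")]),
    fc = net$fc), function(p) p * 0, how = "replace")
  curve <- data.frame(epoch = integer(), loss = numeric(),
                      accuracy = numeric())
  with_seed(cfg$seed + 1L, {
    for (ep in seq_len(cfg$epochs)) {
      ord <- sample.int(N)
      ep_loss <- 0; ep_hits <- 0
      for (b0 in seq(1, N, by = cfg$batch)) {
        bi <- ord[b0:min(b0 + cfg$batch - 1, N)]
        Xb <- x[bi, , , , drop = FALSE]
        yb <- y[bi]
        Yb <- matrix(0, length(bi), nlevels(y))
        Yb[cbind(seq_along(bi), as.integer(yb))] <- 1
        fwd <- cnn_forward(net, Xb, training = TRUE)
        # commit running BN statistics from the training pass
        for (s in seq_along(net$stages)) {
          net$stages[[s]]$rmean <- fwd$caches[[s]]$bn$rmean
          net$stages[[s]]$rvar <- fwd$caches[[s]]$bn$rvar
        }
        P <- softmax_probs(fwd$logits)
        loss <- -mean(log(pmax(P[cbind(seq_along(bi), as.integer(yb))],
                               1e-12)))
        if (!is.finite(loss)) stopf("training diverged at epoch %d", ep)
        ep_loss <- ep_loss + loss * length(bi)
        ep_hits <- ep_hits + sum(max.col(P, ties.method = "first") ==
                                   as.integer(yb))
        g <- cnn_backward(net, fwd, Yb)
        up <- rmsprop_update(net, g, state, cfg$lr, cfg$rho)
        net <- up$net; state <- up$state
      }
      curve <- rbind(curve, data.frame(epoch = ep, loss = ep_loss / N,
                                       accuracy = 100 * ep_hits / N))
      if (verbose)
        message(sprintf("epoch %3d  loss %.4f  acc %.1f%%", ep,
                        ep_loss / N, 100 * ep_hits / N))
    }
  })
  net <- finalize_bn(net, x, cfg$batch)
  structure(list(net = net, arch = net$arch, curve = curve,
                 classes = levels(y), cfg = cfg),
            class = "budvision_cnn")
}

#' @export
print.budvision_cnn <- function(x, ...) {
  last <- x$curve[nrow(x$curve), ]
  cat(sprintf("<budvision_cnn> stages %s, %d classes; %d epochs, final train acc %.1f%%\n",
              paste(x$arch$filters, collapse = ","),
              length(x$classes), nrow(x$curve), last$accuracy))
  invisible(x)
}

#' Predict from a trained network
#'
#' @param object a `budvision_cnn`.
#' @param x input tensor N x 50 x 50 x 3.
#' @param type `"class"` for labels, `"prob"` for softmax probabilities.
#' @param ... unused.
#' @return Factor of predicted labels, or a probability matrix.
#' @export
predict.budvision_cnn <- function(object, x, type = c("class", "prob"), ...) {
  type <- match.arg(type)
  fwd <- cnn_forward(object$net, x, training = FALSE)
  P <- softmax_probs(fwd$logits)
  if (type == "prob") {
    colnames(P) <- object$classes
    return(P)
  }
  factor(object$classes[max.col(P, ties.method = "first")],
         levels = object$classes)
}

#' Evaluate a trained network on held-out data
#'
#' @param model a `budvision_cnn`.
#' @param x input tensor.
#' @param y true labels.
#' @return List with `accuracy` (percent), `accuracy_pct` (integer percent)
#'   and `confusion` (counts, rows = truth).
#' @export
evaluate_cnn <- function(model, x, y) {
  y <- as.character(y)
  unseen <- setdiff(unique(y), model$classes)
  if (length(unseen))
    warning(sprintf("classes unseen at training: %s (counted as errors)",
                    paste(unseen, collapse = ", ")))
  pred <- predict(model, x)
  acc <- 100 * mean(as.character(pred) == y)
  cm <- table(truth = factor(y, levels = union(model$classes, unseen)),
              predicted = factor(as.character(pred),
                                 levels = union(model$classes, unseen)))
  list(accuracy = acc, accuracy_pct = as.integer(round(acc)),
       confusion = cm)
}

#' Train and compare a list of candidate architectures
#'
#' Trains every candidate on the training split and scores it on a
#' validation split carved from the training data (10% stratified), keeping
#' the test set untouched; `paper_mode = TRUE` instead compares candidates
#' directly on the supplied test set. Selection is the highest comparison
#' accuracy, ties broken by fewer parameters. A candidate that fails to
#' build is recorded as a failed row and the search continues.
#'
#' @param candidates list of [cnn_architecture()] objects.
#' @param x,y training tensor and labels.
#' @param cfg a [train_config()].
#' @param test_x,test_y optional held-out data (reported; used for selection
#'   only under `paper_mode`).
#' @param paper_mode compare candidates on the test set instead of a
#'   validation split.
#' @param val_frac validation fraction carved from training.
#' @return List with `results` (data.frame), `best` (index) and `model`
#'   (the selected trained network).
#' @export
architecture_search <- function(candidates, x, y, cfg = train_config(),
                                test_x = NULL, test_y = NULL,
                                paper_mode = FALSE, val_frac = 0.1) {
  if (!length(candidates)) stopf("need at least one candidate")
  y <- as.factor(y)
  if (paper_mode && is.null(test_x))
    stopf("paper_mode requires test data")
  sp <- split_dataset(y, train_frac = 1 - val_frac, seed = cfg$seed)
  rows <- list(); models <- list()
  for (i in seq_along(candidates)) {
    arch <- candidates[[i]]
    audit <- tryCatch(build_cnn(arch, input = dim(x)[-1]),
                      error = function(e) e)
    if (inherits(audit, "error")) {
      rows[[i]] <- data.frame(candidate = i, params = NA, train_acc = NA,
                              val_acc = NA, test_acc = NA,
                              status = conditionMessage(audit))
      models[i] <- list(NULL)
      next
    }
    fit <- train_cnn(arch, x[sp$train, , , , drop = FALSE], y[sp$train], cfg)
    val <- evaluate_cnn(fit, x[sp$test, , , , drop = FALSE], y[sp$test])
    test_acc <- if (!is.null(test_x))
      evaluate_cnn(fit, test_x, test_y)$accuracy else NA
    rows[[i]] <- data.frame(candidate = i, params = audit$total_params,
                            train_acc = fit$curve$accuracy[nrow(fit$curve)],
                            val_acc = val$accuracy, test_acc = test_acc,
                            status = "ok")
    models[[i]] <- fit
  }
  res <- do.call(rbind, rows)
  crit <- if (paper_mode) res$test_acc else res$val_acc
  ok <- which(res$status == "ok")
  best <- ok[order(-crit[ok], res$params[ok])][1]
  list(results = res, best = best, model = models[[best]])
}
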
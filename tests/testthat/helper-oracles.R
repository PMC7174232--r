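# Brute-force oracles and small random fixtures. Every oracle here is an
# independent re-derivation (enumeration / exhaustive scan) of the quantity
# the package computes by a smarter algorithm.

# random connected blob mask: union of a few overlapping discs on a small grid
random_blob <- function(size = 48, n_discs = 3) {
  H <- size; W <- size
  m <- matrix(FALSE, H, W)
  cx0 <- runif(1, W * 0.35, W * 0.65)
  cy0 <- runif(1, H * 0.35, H * 0.65)
  px <- matrix(0:(W - 1), H, W, byrow = TRUE)
  py <- matrix(0:(H - 1), H, W)
  for (i in seq_len(n_discs)) {
    r <- runif(1, size * 0.08, size * 0.2)
    # keep discs overlapping the first so the blob stays connected
    cx <- cx0 + runif(1, -r, r); cy <- cy0 + runif(1, -r, r)
    m <- m | ((px - cx)^2 + (py - cy)^2 <= r^2)
  }
  m
}

# incircle oracle: per foreground pixel, min distance to any background
# pixel (image padded by one background ring), maximized
oracle_incircle <- function(mask) {
  pm <- matrix(FALSE, nrow(mask) + 2, ncol(mask) + 2)
  pm[2:(nrow(mask) + 1), 2:(ncol(mask) + 1)] <- mask
  fg <- which(pm, arr.ind = TRUE)
  bg <- which(!pm, arr.ind = TRUE)
  d2 <- outer(fg[, 1], bg[, 1], "-")^2 + outer(fg[, 2], bg[, 2], "-")^2
  sqrt(max(apply(d2, 1, min)))
}

# minimum enclosing circle oracle: best circle through all pairs (as
# diameter) and all triples (circumcircle)
oracle_excircle <- function(pts) {
  n <- nrow(pts)
  covers <- function(cx, cy, r) {
    all(sqrt((pts[, 1] - cx)^2 + (pts[, 2] - cy)^2) <= r + 1e-7)
  }
  best <- Inf
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    cx <- (pts[i, 1] + pts[j, 1]) / 2; cy <- (pts[i, 2] + pts[j, 2]) / 2
    r <- sqrt((pts[i, 1] - pts[j, 1])^2 + (pts[i, 2] - pts[j, 2])^2) / 2
    if (r < best && covers(cx, cy, r)) best <- r
  }
  if (n >= 3) {
    for (i in 1:(n - 2)) for (j in (i + 1):(n - 1)) for (k in (j + 1):n) {
      ax <- pts[i, 1]; ay <- pts[i, 2]; bx <- pts[j, 1]; by <- pts[j, 2]
      cx <- pts[k, 1]; cy <- pts[k, 2]
      G <- 2 * ((bx - ax) * (cy - by) - (by - ay) * (cx - bx))
      if (abs(G) < 1e-12) next
      E <- (bx - ax) * (ax + bx) + (by - ay) * (ay + by)
      F <- (cx - ax) * (ax + cx) + (cy - ay) * (ay + cy)
      ux <- ((cy - ay) * E - (by - ay) * F) / G
      uy <- ((bx - ax) * F - (cx - ax) * E) / G
      r <- sqrt((ax - ux)^2 + (ay - uy)^2)
      if (r < best && covers(ux, uy, r)) best <- r
    }
  }
  best
}

# long-axis oracle: max over all point pairs
oracle_long_axis <- function(pts) max(stats::dist(pts))

# Otsu oracle: exhaustive scan over all 256 candidate bin splits
oracle_otsu_bin <- function(px) {
  lo <- min(px); hi <- max(px)
  bin <- pmin(floor((px - lo) / (hi - lo) * 256), 255)
  counts <- tabulate(as.vector(bin) + 1L, nbins = 256)
  p <- counts / sum(counts)
  mids <- 0:255
  best <- -Inf; tbest <- NA
  for (t in 0:254) {
    w0 <- sum(p[1:(t + 1)]); w1 <- 1 - w0
    if (w0 == 0 || w1 == 0) next
    mu0 <- sum(p[1:(t + 1)] * mids[1:(t + 1)]) / w0
    mu1 <- sum(p[(t + 2):256] * mids[(t + 2):256]) / w1
    s <- w0 * w1 * (mu0 - mu1)^2
    if (s > best + 1e-12) { best <- s; tbest <- t }
  }
  tbest
}

# per-pixel 3x3 median oracle with edge replication
oracle_median3 <- function(img) {
  H <- nrow(img); W <- ncol(img)
  out <- img
  for (y in 1:H) for (x in 1:W) {
    ys <- pmin(pmax((y - 1):(y + 1), 1), H)
    xs <- pmin(pmax((x - 1):(x + 1), 1), W)
    out[y, x] <- median(img[ys, xs])
  }
  out
}

# 4/8-connected flood fill labelling oracle
oracle_label <- function(mask) {
  H <- nrow(mask); W <- ncol(mask)
  lab <- matrix(0L, H, W)
  nxt <- 0L
  for (y0 in 1:H) for (x0 in 1:W) {
    if (!mask[y0, x0] || lab[y0, x0]) next
    nxt <- nxt + 1L
    stack <- list(c(y0, x0)); lab[y0, x0] <- nxt
    while (length(stack)) {
      p <- stack[[length(stack)]]; stack[[length(stack)]] <- NULL
      for (dy in -1:1) for (dx in -1:1) {
        y <- p[1] + dy; x <- p[2] + dx
        if (y < 1 || y > H || x < 1 || x > W) next
        if (mask[y, x] && !lab[y, x]) {
          lab[y, x] <- nxt
          stack[[length(stack) + 1]] <- c(y, x)
        }
      }
    }
  }
  lab
}

# rotate a logical mask by 90 degrees (counter-clockwise k times)
rotate_mask_90 <- function(m, k = 1L) {
  for (i in seq_len(k %% 4)) m <- t(m)[ncol(m):1, , drop = FALSE]
  m
}

# small bud spec sampler used by invariance suites
random_bud_spec <- function(scale = NULL) {
  shape_spec("bud",
             scale_px = scale %||% runif(1, 40, 60),
             elongation = runif(1, 1, 1.3),
             frill_amplitude = runif(1, 0.05, 0.2),
             frill_count = sample(5:10, 1),
             rotation_rad = runif(1, 0, 2 * pi),
             center = c(100, 100))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
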
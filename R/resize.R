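# Separable image resampling. A 1-D resampling step is a dense operator
# out = A %*% in built from the interpolation kernel, so a 2-D resize is
# A_rows %*% X %*% t(A_cols); this is exact, fast for small outputs, and the
# identity when sizes match (kernel hits grid nodes).

cubic_kernel <- function(t, a = -0.5) {
  # Keys bicubic kernel (a = -0.5, the Catmull-Rom choice)
  t <- abs(t)
  w <- numeric(length(t))
  i1 <- t <= 1
  w[i1] <- (a + 2) * t[i1]^3 - (a + 3) * t[i1]^2 + 1
  i2 <- t > 1 & t < 2
  w[i2] <- a * t[i2]^3 - 5 * a * t[i2]^2 + 8 * a * t[i2] - 4 * a
  w
}

triangle_kernel <- function(t) pmax(1 - abs(t), 0)

resample_matrix <- function(n_in, n_out, method) {
  support <- if (method == "bicubic") 2L else 1L
  A <- matrix(0, n_out, n_in)
  scale <- n_in / n_out
  for (i in seq_len(n_out)) {
    src <- (i - 0.5) * scale - 0.5          # 0-based source position
    j0 <- floor(src) - support + 1L
    js <- j0:(j0 + 2L * support - 1L)
    w <- if (method == "bicubic") cubic_kernel(src - js) else
      triangle_kernel(src - js)
    w <- w / sum(w)
    jc <- clamp(js, 0L, n_in - 1L) + 1L     # edge clamp
    for (k in seq_along(js)) A[i, jc[k]] <- A[i, jc[k]] + w[k]
  }
  A
}

#' Resize an image by separable interpolation
#'
#' @param img matrix or H x W x C array.
#' @param out_h,out_w output size in pixels.
#' @param method `"bicubic"` (Keys kernel, a = -0.5) or `"bilinear"`.
#' @return Resized matrix or array; intensity scale is preserved.
#' @export
resize_image <- function(img, out_h, out_w, method = c("bicubic", "bilinear")) {
  method <- match.arg(method)
  d <- dim(img)
  Ar <- resample_matrix(d[1], out_h, method)
  Ac <- resample_matrix(d[2], out_w, method)
  if (length(d) == 2) return(Ar %*% img %*% t(Ac))
  out <- array(0, c(out_h, out_w, d[3]))
  for (ch in seq_len(d[3])) out[, , ch] <- Ar %*% img[, , ch] %*% t(Ac)
  out
}

# smooth random field in [-1, 1]-ish used for bud surface texture
smooth_noise_field <- function(h, w, cells = 6L) {
  g <- matrix(rnorm(cells * cells), cells, cells)
  f <- resize_image(g, h, w, method = "bilinear")
  s <- stats::sd(f)
  if (s > 0) f / (2.5 * s) else f
}
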
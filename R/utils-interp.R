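# Separable image resampling and smoothing primitives.
#
# All resamplers use the half-pixel-center convention: output sample i (0-based)
# reads the source at position (i + 0.5) * src/dst - 0.5, with edge clamping.
# Weight operators are built once per axis as dense matrices so that
# resampling is `A %*% img %*% t(B)`.

# Keys cubic-convolution kernel, a = -0.5 (the classical bicubic kernel).
cubic_kernel <- function(x, a = -0.5) {
  ax <- abs(x)
  w <- numeric(length(x))
  i1 <- ax <= 1
  i2 <- !i1 & ax < 2
  w[i1] <- (a + 2) * ax[i1]^3 - (a + 3) * ax[i1]^2 + 1
  w[i2] <- a * ax[i2]^3 - 5 * a * ax[i2]^2 + 8 * a * ax[i2] - 4 * a
  w
}

linear_kernel <- function(x) pmax(0, 1 - abs(x))

# Dense (dst x src) 1-D resampling operator with edge clamp.
resample_operator <- function(src, dst, kernel = c("bicubic", "bilinear")) {
  kernel <- match.arg(kernel)
  support <- if (kernel == "bicubic") 2L else 1L
  kfun <- if (kernel == "bicubic") cubic_kernel else linear_kernel
  pos <- (seq_len(dst) - 0.5) * src / dst - 0.5   # 0-based source positions
  A <- matrix(0, dst, src)
  base <- floor(pos)
  for (d in seq.int(-support + 1L, support)) {
    idx <- base + d
    w <- kfun(pos - idx)
    idx <- pmin(pmax(idx, 0L), src - 1L)           # clamp to the edge sample
    A[cbind(seq_len(dst), idx + 1L)] <- A[cbind(seq_len(dst), idx + 1L)] + w
  }
  A
}

# Resample a matrix to target_shape = c(rows, cols).
resample_matrix <- function(m, target_shape, kernel = c("bicubic", "bilinear")) {
  kernel <- match.arg(kernel)
  th <- as.integer(target_shape[1]); tw <- as.integer(target_shape[2])
  if (th == nrow(m) && tw == ncol(m) && kernel == "bilinear") return(m)
  A <- resample_operator(nrow(m), th, kernel)
  B <- resample_operator(ncol(m), tw, kernel)
  A %*% m %*% t(B)
}

# Separable Gaussian blur with replicate padding (via clamped-index operator).
gaussian_blur <- function(m, sigma) {
  if (sigma <= 0) return(m)
  r <- max(1L, ceiling(3 * sigma))
  k <- exp(-(seq.int(-r, r))^2 / (2 * sigma^2))
  k <- k / sum(k)
  blur_axis <- function(n) {
    A <- matrix(0, n, n)
    for (d in seq.int(-r, r)) {
      idx <- pmin(pmax(seq_len(n) + d, 1L), n)
      A[cbind(seq_len(n), idx)] <- A[cbind(seq_len(n), idx)] + k[d + r + 1L]
    }
    A
  }
  blur_axis(nrow(m)) %*% m %*% t(blur_axis(ncol(m)))
}

# Deterministic half-up rounding (round() uses banker's rounding).
round_half_up <- function(x) floor(x + 0.5)

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)
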
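# Convolution and pooling primitives for the random feature stack.
# Convolutions are "same"-size with replicate (edge-clamped) boundary --
# consistent with the gradient and pooling boundary handling elsewhere
# in the package, and it keeps zero-mean kernels exactly zero on
# constant images. They are evaluated as a patch-matrix product
# (im2col), which also gives dilated (atrous) kernels for free: taps
# are spaced `dilation` pixels apart, enlarging the receptive field
# without extra parameters.

# Patch matrix: rows = pixels (column-major), cols = kernel taps for
# each input channel. `channels` is a list of H x W matrices.
im2col <- function(channels, k, dilation = 1L) {
  h <- nrow(channels[[1]]); w <- ncol(channels[[1]])
  r <- (k - 1L) %/% 2L
  offs <- expand.grid(dy = (-r:r) * dilation, dx = (-r:r) * dilation)
  P <- matrix(0, h * w, k * k * length(channels))
  col <- 0L
  for (ch in channels) {
    for (i in seq_len(nrow(offs))) {
      col <- col + 1L
      P[, col] <- as.numeric(shift_replicate(ch, -offs$dy[i], -offs$dx[i]))
    }
  }
  P
}

# 2-D multi-channel convolution via im2col. `kernels` is an array
# (k, k, n_in, n_out). Returns a list of n_out H x W matrices.
conv2d <- function(channels, kernels, dilation = 1L) {
  if (is.matrix(channels)) channels <- list(channels)
  k <- dim(kernels)[1]
  n_in <- dim(kernels)[3]; n_out <- dim(kernels)[4]
  stopifnot(length(channels) == n_in)
  h <- nrow(channels[[1]]); w <- ncol(channels[[1]])
  P <- im2col(channels, k, dilation)
  Kmat <- matrix(kernels, nrow = k * k * n_in, ncol = n_out)
  O <- P %*% Kmat
  lapply(seq_len(n_out), function(j) matrix(O[, j], h, w))
}

# Stochastic ("random") pooling over k x k sliding windows, stride 1,
# replicate padding. In expectation mode each output is the within-window
# average weighted by activation magnitude; in stochastic mode one
# activation is sampled per window with probability proportional to its
# magnitude (Gumbel-max draw on the caller's RNG stream).
random_pool <- function(channel, k, stochastic = FALSE) {
  P <- im2col(list(channel), k)
  A <- abs(P)
  if (!stochastic) {
    den <- rowSums(A)
    num <- rowSums(P * A)
    out <- ifelse(den > 0, num / den, 0)
  } else {
    gum <- -log(-log(matrix(stats::runif(length(P)), nrow(P), ncol(P))))
    pick <- max.col(log(A + 1e-300) + gum, ties.method = "first")
    out <- P[cbind(seq_len(nrow(P)), pick)]
  }
  matrix(out, nrow(channel), ncol(channel))
}

# Max pooling over k x k sliding windows, stride 1, replicate padding.
max_pool <- function(channel, k) {
  r <- (k - 1L) %/% 2L
  out <- channel
  for (dy in -r:r) for (dx in -r:r) {
    if (dy == 0 && dx == 0) next
    out <- pmax(out, shift_replicate(channel, dy, dx))
  }
  out
}
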
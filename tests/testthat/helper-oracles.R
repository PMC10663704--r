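# Independent brute-force oracles used to cross-check the package
# implementations. These are deliberately naive: direct transcriptions
# of the set/algebra definitions, with no shared code paths.

# Erosion by explicit set containment over every frame translation.
oracle_erode <- function(mask, offsets) {
  h <- nrow(mask); w <- ncol(mask)
  out <- matrix(FALSE, h, w)
  for (y in seq_len(h)) for (x in seq_len(w)) {
    inside <- TRUE
    for (i in seq_len(nrow(offsets))) {
      yy <- y + offsets[i, 1]; xx <- x + offsets[i, 2]
      if (yy < 1 || yy > h || xx < 1 || xx > w || !mask[yy, xx]) {
        inside <- FALSE; break
      }
    }
    out[y, x] <- inside
  }
  out
}

# Dilation: reflected element translated by q intersects the mask.
oracle_dilate <- function(mask, offsets) {
  h <- nrow(mask); w <- ncol(mask)
  out <- matrix(FALSE, h, w)
  for (y in seq_len(h)) for (x in seq_len(w)) {
    hit <- FALSE
    for (i in seq_len(nrow(offsets))) {
      yy <- y - offsets[i, 1]; xx <- x - offsets[i, 2]
      if (yy >= 1 && yy <= h && xx >= 1 && xx <= w && mask[yy, xx]) {
        hit <- TRUE; break
      }
    }
    out[y, x] <- hit
  }
  out
}

# Direct 2-D convolution (replicate boundary, "same"), optional
# dilation -- naive quadruple loop with index clamping.
oracle_conv2d <- function(x, kernel, dilation = 1) {
  h <- nrow(x); w <- ncol(x)
  k <- nrow(kernel); r <- (k - 1) / 2
  out <- matrix(0, h, w)
  for (y in seq_len(h)) for (xx in seq_len(w)) {
    acc <- 0
    for (i in seq_len(k)) for (j in seq_len(k)) {
      yy <- min(max(y + (i - 1 - r) * dilation, 1), h)
      xj <- min(max(xx + (j - 1 - r) * dilation, 1), w)
      acc <- acc + kernel[i, j] * x[yy, xj]
    }
    out[y, xx] <- acc
  }
  out
}

# AUC as the concordant-pair (Mann-Whitney) statistic; ties count half.
oracle_auc_pairs <- function(scores, truth) {
  pos <- scores[as.logical(truth)]
  neg <- scores[!as.logical(truth)]
  tot <- 0
  for (p in pos) for (n in neg)
    tot <- tot + if (p > n) 1 else if (p == n) 0.5 else 0
  tot / (length(pos) * length(neg))
}

# Least-squares coefficients via the normal equations (independent of
# the package's SVD pseudoinverse).
oracle_lstsq <- function(G, Y) {
  solve(crossprod(G), crossprod(G, Y))
}

# CRF labeling energy by explicit double loop over pixel pairs.
oracle_crf_energy <- function(labels, unary, K) {
  y <- as.integer(labels)
  n <- length(y)
  e <- 0
  for (i in seq_len(n)) e <- e - log(max(unary[i, y[i]], 1e-10))
  for (i in seq_len(n - 1)) for (j in (i + 1):n)
    if (y[i] != y[j]) e <- e + K[i, j]
  e
}

# Deterministic test image: smooth phantom-like ramp.
ramp_image <- function(h = 32, w = 32) {
  gray_image(outer(seq_len(h), seq_len(w),
                   function(y, x) (y * 3 + x * 2) %% 256))
}
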
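# Internal helpers shared across modules.

# Run expr with a local RNG seed, restoring the caller's RNG state.
with_local_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  expr
}

# Derive a stream of per-case seeds from a master seed, staying well
# inside the 32-bit integer range.
derive_seed <- function(seed, i) {
  (abs(as.numeric(seed)) %% 99991) * 20011 + i
}

clip01 <- function(x) pmin(pmax(x, 0), 1)

clip255 <- function(x) pmin(pmax(x, 0), 255)

check_gray <- function(img, arg = "image") {
  if (!is.matrix(img) || !is.numeric(img))
    stop(arg, " must be a numeric matrix of gray levels")
  if (nrow(img) < 8 || ncol(img) < 8)
    stop(arg, " must be at least 8x8")
  if (anyNA(img) || min(img) < 0 || max(img) > 255)
    stop(arg, " values must lie in [0, 255]")
  invisible(img)
}

#' Construct a validated 8-bit gray image
#'
#' Gray images are plain integer matrices with values in `[0, 255]`,
#' row 1 = top image row (top-left origin). This constructor rounds,
#' validates range and dimensions, and sets integer storage.
#'
#' @param pixels numeric matrix of gray levels.
#' @return integer matrix in `[0, 255]`.
#' @export
gray_image <- function(pixels) {
  if (!is.matrix(pixels)) stop("pixels must be a matrix")
  m <- round(pixels)
  storage.mode(m) <- "integer"
  check_gray(m, "pixels")
  m
}

# Shift a matrix by (dy, dx); vacated cells take `fill`.
# result[i, j] = m[i - dy, j - dx] where defined.
shift_matrix <- function(m, dy, dx, fill = 0) {
  h <- nrow(m); w <- ncol(m)
  out <- matrix(fill, h, w)
  ys <- max(1, 1 + dy):min(h, h + dy)
  xs <- max(1, 1 + dx):min(w, w + dx)
  if (length(ys) > 0 && length(xs) > 0)
    out[ys, xs] <- m[ys - dy, xs - dx]
  out
}

# Shift with replicate (edge-clamped) boundary.
shift_replicate <- function(m, dy, dx) {
  h <- nrow(m); w <- ncol(m)
  ys <- pmin(pmax(seq_len(h) - dy, 1), h)
  xs <- pmin(pmax(seq_len(w) - dx, 1), w)
  m[ys, xs, drop = FALSE]
}

# Separable convolution with a 1-D kernel along rows then columns,
# replicate boundary. Kernel must be odd-length.
conv_separable <- function(m, k) {
  r <- (length(k) - 1L) / 2L
  out <- matrix(0, nrow(m), ncol(m))
  for (i in seq_along(k)) out <- out + k[i] * shift_replicate(m, i - 1L - r, 0L)
  m2 <- out
  out <- matrix(0, nrow(m), ncol(m))
  for (i in seq_along(k)) out <- out + k[i] * shift_replicate(m2, 0L, i - 1L - r)
  out
}

gauss_kernel_1d <- function(sigma, radius = ceiling(3 * sigma)) {
  x <- (-radius):radius
  k <- exp(-x^2 / (2 * sigma^2))
  k / sum(k)
}

# 3x3 box mean with replicate boundary.
mean_filter3 <- function(m) {
  out <- matrix(0, nrow(m), ncol(m))
  for (dy in -1:1) for (dx in -1:1) out <- out + shift_replicate(m, dy, dx)
  out / 9
}

# 3x3 median with replicate boundary (via EBImage histogram median on the
# padded integer image).
median_filter3 <- function(m) {
  md <- EBImage::medianFilter(clip255(m) / 255, size = 1)
  as.matrix(EBImage::imageData(md)) * 255
}

# Bilinear resize of a numeric matrix.
resize_matrix <- function(m, h, w) {
  as.matrix(EBImage::imageData(EBImage::resize(m, w = h, h = w)))
}
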
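# Separable 2-D discrete wavelet transform with periodized boundary,
# orthonormal filter banks (perfect reconstruction, energy preserving),
# and soft thresholding of detail coefficients. Written against the
# standard pyramid algorithm; no external wavelet library is used.

#' Orthonormal wavelet filter bank
#'
#' Returns the low-pass analysis filter `h` and its quadrature mirror
#' high-pass `g` for the named mother wavelet. Both the Haar and the
#' 4-tap Daubechies filters are orthonormal: `sum(h^2) = 1`, `sum(g) = 0`.
#'
#' @param name `"haar"` or `"db2"`.
#' @return list with elements `h`, `g`, `name`.
#' @export
wavelet_filters <- function(name = c("haar", "db2")) {
  name <- match.arg(name)
  h <- switch(name,
    haar = c(1, 1) / sqrt(2),
    db2  = c(0.4829629131445341, 0.8365163037378079,
             0.2241438680420134, -0.1294095225512604))
  L <- length(h)
  g <- rev(h) * (-1)^(seq_len(L) - 1)   # quadrature mirror filter
  list(h = h, g = g, name = name)
}

#' Numerical admissibility checks for a discrete wavelet filter
#'
#' A usable mother wavelet is wave-like (zero mean) with its energy
#' concentrated in a finite support; on the discrete high-pass filter
#' these become `sum(g) = 0` and `sum(g^2) = 1`.
#'
#' @param name wavelet name.
#' @return list with `zero_mean` and `unit_energy` (numeric residuals)
#'   plus `admissible` (logical).
#' @export
wavelet_admissibility <- function(name = "haar") {
  fb <- wavelet_filters(name)
  zm <- abs(sum(fb$g))
  ue <- abs(sum(fb$g^2) - 1)
  list(zero_mean = zm, unit_energy = ue,
       admissible = zm < 1e-12 && ue < 1e-12)
}

# One periodized analysis step along matrix columns: returns the
# approximation and detail halves (nrow(x)/2 rows each).
dwt_step_cols <- function(x, h, g) {
  n <- nrow(x); L <- length(h)
  k <- seq_len(n / 2)
  A <- matrix(0, n / 2, ncol(x)); D <- A
  for (l in seq_len(L)) {
    idx <- ((2 * (k - 1) + l - 1) %% n) + 1
    A <- A + h[l] * x[idx, , drop = FALSE]
    D <- D + g[l] * x[idx, , drop = FALSE]
  }
  list(A = A, D = D)
}

# Inverse of dwt_step_cols (transpose of the orthonormal analysis map).
idwt_step_cols <- function(A, D, h, g) {
  n <- 2 * nrow(A); L <- length(h)
  k <- seq_len(nrow(A))
  x <- matrix(0, n, ncol(A))
  for (l in seq_len(L)) {
    idx <- ((2 * (k - 1) + l - 1) %% n) + 1
    x[idx, ] <- x[idx, ] + h[l] * A + g[l] * D
  }
  x
}

dwt2_step <- function(x, h, g) {
  cs <- dwt_step_cols(x, h, g)
  a  <- dwt_step_cols(t(cs$A), h, g)   # rows of the approximation half
  d  <- dwt_step_cols(t(cs$D), h, g)
  list(LL = t(a$A), LH = t(a$D), HL = t(d$A), HH = t(d$D))
}

idwt2_step <- function(LL, LH, HL, HH, h, g) {
  A <- t(idwt_step_cols(t(LL), t(LH), h, g))
  D <- t(idwt_step_cols(t(HL), t(HH), h, g))
  idwt_step_cols(A, D, h, g)
}

#' Multi-level 2-D wavelet decomposition
#'
#' Standard separable pyramid decomposition with periodized boundary.
#' An untouched decomposition inverts to the input within numerical
#' round-off, and for these orthonormal banks total energy is preserved.
#'
#' @param image numeric matrix (any real values; gray images are used
#'   as-is).
#' @param wavelet wavelet name, see [wavelet_filters()].
#' @param levels number of decomposition levels; each level halves both
#'   dimensions, which must stay even.
#' @return object of class `wavelet_decomposition`: list with
#'   `approximation`, `details` (per level: `horizontal`, `vertical`,
#'   `diagonal`), `wavelet`, `levels`, `dims`.
#' @export
qwt_decompose <- function(image, wavelet = "haar", levels = 2) {
  if (!is.matrix(image)) stop("image must be a matrix")
  if (levels < 1) stop("levels must be >= 1")
  if (levels > floor(log2(min(dim(image)))))
    stop("image too small for ", levels, " levels")
  fb <- wavelet_filters(wavelet)
  x <- image * 1.0
  details <- vector("list", levels)
  for (lv in seq_len(levels)) {
    if (nrow(x) %% 2 != 0 || ncol(x) %% 2 != 0)
      stop("image dimensions must be divisible by 2^levels")
    s <- dwt2_step(x, fb$h, fb$g)
    details[[lv]] <- list(horizontal = s$LH, vertical = s$HL, diagonal = s$HH)
    x <- s$LL
  }
  structure(list(approximation = x, details = details,
                 wavelet = fb$name, levels = levels, dims = dim(image)),
            class = "wavelet_decomposition")
}

#' Invert a 2-D wavelet decomposition
#'
#' @param decomp a `wavelet_decomposition`.
#' @return numeric matrix with the original dimensions.
#' @export
qwt_reconstruct <- function(decomp) {
  stopifnot(inherits(decomp, "wavelet_decomposition"))
  fb <- wavelet_filters(decomp$wavelet)
  x <- decomp$approximation
  for (lv in rev(seq_len(decomp$levels))) {
    d <- decomp$details[[lv]]
    x <- idwt2_step(x, d$horizontal, d$vertical, d$diagonal, fb$h, fb$g)
  }
  x
}

#' Soft (shrinkage) thresholding
#'
#' `sign(c) * max(|c| - t, 0)`, elementwise.
#'
#' @param c coefficients.
#' @param t threshold, >= 0.
#' @return shrunk coefficients.
#' @export
soft_threshold <- function(c, t) sign(c) * pmax(abs(c) - t, 0)

# Robust noise scale from the finest diagonal band.
estimate_noise_sigma <- function(decomp) {
  stats::median(abs(decomp$details[[1]]$diagonal)) / 0.6745
}

#' Soft-threshold the detail coefficients of a decomposition
#'
#' The approximation band is left untouched. Thresholds:
#' * `universal`: `sigma_hat * sqrt(2 log N)` with `sigma_hat` the median
#'   absolute finest diagonal coefficient divided by 0.6745;
#' * `bayes`: per-band `sigma_hat^2 / sigma_x` with `sigma_x` the
#'   estimated signal scale of the band (a band that looks like pure
#'   noise is zeroed);
#' * `fixed`: the supplied `value` for every band.
#'
#' @param decomp a `wavelet_decomposition`.
#' @param rule `"universal"`, `"bayes"` or `"fixed"`.
#' @param value threshold in coefficient units (required for `"fixed"`).
#' @return thresholded `wavelet_decomposition`.
#' @export
threshold_details <- function(decomp, rule = c("universal", "bayes", "fixed"),
                              value = NULL) {
  stopifnot(inherits(decomp, "wavelet_decomposition"))
  rule <- match.arg(rule)
  if (rule == "fixed" && is.null(value))
    stop("fixed thresholding requires a value")
  sig <- estimate_noise_sigma(decomp)
  N <- prod(decomp$dims)
  for (lv in seq_len(decomp$levels)) {
    for (band in names(decomp$details[[lv]])) {
      c <- decomp$details[[lv]][[band]]
      t <- switch(rule,
        universal = sig * sqrt(2 * log(N)),
        fixed = value,
        bayes = {
          sx <- sqrt(max(mean(c^2) - sig^2, 0))
          if (sx > 0) sig^2 / sx else max(abs(c))
        })
      decomp$details[[lv]][[band]] <- soft_threshold(c, t)
    }
  }
  decomp
}
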
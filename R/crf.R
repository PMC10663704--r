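# Dense (fully connected) CRF refinement of per-pixel class
# probabilities by mean-field iteration. The pairwise potential between
# two pixels is a Potts compatibility (it fires only when the labels
# differ) times a sum of two Gaussian kernels: an appearance kernel over
# positions and intensities, and a smoothness kernel over positions
# only. Kernels are evaluated exactly over all pixel pairs, which is
# intended for desk-scale instances (<= ~96 x 96 pixels).

#' Dense-CRF parameters
#'
#' @param w_appearance,w_smoothness nonnegative kernel weights.
#' @param theta_alpha spatial bandwidth of the appearance kernel, px.
#' @param theta_beta intensity bandwidth of the appearance kernel, gray
#'   levels.
#' @param theta_gamma spatial bandwidth of the smoothness kernel, px.
#' @param iterations mean-field iterations, >= 1.
#' @return object of class `crf_params`.
#' @export
crf_params <- function(w_appearance = 1, w_smoothness = 0.3,
                       theta_alpha = 8, theta_beta = 25, theta_gamma = 3,
                       iterations = 5) {
  if (w_appearance < 0 || w_smoothness < 0) stop("kernel weights must be >= 0")
  if (theta_alpha <= 0 || theta_beta <= 0 || theta_gamma <= 0)
    stop("bandwidths must be > 0")
  if (iterations < 1) stop("iterations must be >= 1")
  structure(list(w_appearance = w_appearance, w_smoothness = w_smoothness,
                 theta_alpha = theta_alpha, theta_beta = theta_beta,
                 theta_gamma = theta_gamma, iterations = iterations),
            class = "crf_params")
}

# Exact pairwise kernel matrix (n x n, zero diagonal). Each Gaussian
# kernel is scaled by the reciprocal of its mean row sum so that message
# magnitudes are O(1) regardless of instance size; the scaling is a
# global scalar, so the matrix stays symmetric.
crf_kernel_matrix <- function(image, params) {
  h <- nrow(image); w <- ncol(image)
  py <- rep(seq_len(h), times = w); px <- rep(seq_len(w), each = h)
  D2 <- outer(py, py, "-")^2
  D2 <- D2 + outer(px, px, "-")^2
  e <- as.numeric(image)
  E2 <- outer(e, e, "-")^2
  K1 <- exp(-D2 / (2 * params$theta_alpha^2) - E2 / (2 * params$theta_beta^2))
  K2 <- exp(-D2 / (2 * params$theta_gamma^2))
  diag(K1) <- 0; diag(K2) <- 0
  norm1 <- mean(rowSums(K1)); norm2 <- mean(rowSums(K2))
  params$w_appearance * K1 / max(norm1, 1e-12) +
    params$w_smoothness * K2 / max(norm2, 1e-12)
}

#' Exact CRF energy of a labeling
#'
#' Unary part: sum over pixels of the negative log probability of the
#' assigned label. Pairwise part: sum over unordered pixel pairs of the
#' kernel value whenever the two labels differ (Potts compatibility).
#'
#' @param labels integer vector/matrix of labels (1-based).
#' @param unary n x L matrix of per-pixel class probabilities.
#' @param K pairwise kernel matrix from the same instance.
#' @return scalar energy.
#' @export
crf_energy <- function(labels, unary, K) {
  y <- as.integer(labels)
  n <- length(y); L <- ncol(unary)
  U <- -log(pmax(unary, 1e-10))
  e_un <- sum(U[cbind(seq_len(n), y)])
  Yh <- matrix(0, n, L); Yh[cbind(seq_len(n), y)] <- 1
  same <- sum(vapply(seq_len(L), function(l) {
    v <- Yh[, l]
    as.numeric(t(v) %*% K %*% v)
  }, numeric(1)))
  e_pw <- (sum(K) - same) / 2
  e_un + e_pw
}

#' Mean-field dense-CRF refinement
#'
#' Starting from the unary probabilities, each mean-field step passes
#' messages through the exact pairwise kernel and renormalizes:
#' `Q <- softmax(-U - M)` where `M_i(l)` collects kernel-weighted mass
#' of all labels different from `l` at all other pixels. Returns the
#' refined hard labels and the energy of the argmax labeling after each
#' iteration (the first entry is the energy of the initial unary
#' argmax).
#'
#' @param unary_probs per-pixel class probabilities: an n x L matrix
#'   (pixels column-major) or an H x W x L array; rows must sum to 1.
#' @param image gray image matrix of the same frame.
#' @param params a [crf_params()].
#' @return list with `labels` (H x W integer matrix), `Q` (n x L
#'   posterior marginals), `energy_trace`.
#' @export
crf_refine <- function(unary_probs, image, params = crf_params()) {
  h <- nrow(image); w <- ncol(image)
  if (length(dim(unary_probs)) == 3)
    unary_probs <- matrix(unary_probs, h * w, dim(unary_probs)[3])
  if (nrow(unary_probs) != h * w)
    stop("unary_probs rows must match the image pixel count")
  if (max(abs(rowSums(unary_probs) - 1)) > 1e-6)
    stop("unary_probs rows must sum to 1")
  L <- ncol(unary_probs)
  U <- -log(pmax(unary_probs, 1e-10))
  K <- crf_kernel_matrix(image, params)

  y0 <- max.col(unary_probs, ties.method = "first")
  trace <- crf_energy(y0, unary_probs, K)
  Q <- unary_probs
  for (it in seq_len(params$iterations)) {
    M <- K %*% Q
    pw <- rowSums(M) - M          # mass of disagreeing labels, per label
    Z <- -U - pw
    Z <- Z - apply(Z, 1, max)
    Q <- exp(Z) / rowSums(exp(Z))
    trace <- c(trace, crf_energy(max.col(Q, ties.method = "first"),
                                 unary_probs, K))
  }
  list(labels = matrix(max.col(Q, ties.method = "first"), h, w),
       Q = Q, energy_trace = trace)
}
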
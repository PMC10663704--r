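# Particle-filter localization of the mass center from a sequence of
# detection score maps: sequential importance resampling with a
# Gaussian random-walk system model and a two-dimensional Gaussian
# observation kernel over the score evidence.

#' Particle-filter configuration
#'
#' @param n_particles number of particles, >= 10.
#' @param process_sd random-walk standard deviation, pixels/frame.
#' @param sigma1,sigma2 standard deviations of the two-dimensional
#'   Gaussian observation kernel (rows, columns), pixels.
#' @param seed RNG seed.
#' @return object of class `pf_config`.
#' @export
pf_config <- function(n_particles = 200, process_sd = 2,
                      sigma1 = 3, sigma2 = 3, seed = 1) {
  if (n_particles < 10) stop("n_particles must be >= 10")
  structure(list(n_particles = n_particles, process_sd = process_sd,
                 sigma1 = sigma1, sigma2 = sigma2, seed = seed),
            class = "pf_config")
}

# Anisotropic Gaussian blur: the observation likelihood of a particle
# is the score evidence correlated with the two-dimensional Gaussian
# kernel centered on the particle.
blur_2d <- function(m, sigma1, sigma2) {
  k1 <- gauss_kernel_1d(sigma1)
  k2 <- gauss_kernel_1d(sigma2)
  out <- matrix(0, nrow(m), ncol(m))
  r <- (length(k1) - 1L) / 2L
  for (i in seq_along(k1)) out <- out + k1[i] * shift_matrix(m, i - 1L - r, 0L)
  m2 <- out
  out <- matrix(0, nrow(m), ncol(m))
  r <- (length(k2) - 1L) / 2L
  for (i in seq_along(k2)) out <- out + k2[i] * shift_matrix(m2, 0L, i - 1L - r)
  out
}

systematic_resample <- function(weights, n) {
  u <- (stats::runif(1) + seq_len(n) - 1) / n
  findInterval(u, cumsum(weights), left.open = TRUE) + 1L
}

#' Localize a mass center from score-map evidence
#'
#' Particles are initialized by sampling pixels with probability
#' proportional to the first score map (uniformly when it is all zero,
#' a documented fallback). For each frame: particles are propagated by
#' a Gaussian random walk, weighted by the Gaussian-correlated score
#' evidence at their positions, normalized to sum to one, summarized by
#' their weighted mean, and systematically resampled. Deterministic
#' given the seed.
#'
#' @param score_maps list of score-map matrices (all the same shape),
#'   one per frame; nonnegative values.
#' @param config a [pf_config()].
#' @return list with `trajectory` (frames x 2 matrix of (row, col)
#'   estimates), `estimate` (final row/col), `particles`, `weights`.
#' @export
localize_mass <- function(score_maps, config = pf_config()) {
  if (length(score_maps) < 1) stop("at least one score map is required")
  h <- nrow(score_maps[[1]]); w <- ncol(score_maps[[1]])
  n <- config$n_particles
  with_local_seed(config$seed, {
    first <- pmax(score_maps[[1]], 0)
    if (sum(first) > 0) {
      idx <- sample.int(h * w, n, replace = TRUE,
                        prob = as.numeric(first) / sum(first))
    } else {
      idx <- sample.int(h * w, n, replace = TRUE)
    }
    py <- ((idx - 1) %% h) + 1
    px <- ((idx - 1) %/% h) + 1
    pos <- cbind(as.numeric(py), as.numeric(px))
    wts <- rep(1 / n, n)
    traj <- matrix(NA_real_, length(score_maps), 2)
    for (m in seq_along(score_maps)) {
      if (m > 1) {
        pos <- pos + matrix(stats::rnorm(2 * n, 0, config$process_sd), n, 2)
        pos[, 1] <- pmin(pmax(pos[, 1], 1), h)
        pos[, 2] <- pmin(pmax(pos[, 2], 1), w)
      }
      L <- blur_2d(pmax(score_maps[[m]], 0), config$sigma1, config$sigma2)
      wts <- L[cbind(pmin(pmax(round(pos[, 1]), 1), h),
                     pmin(pmax(round(pos[, 2]), 1), w))]
      if (sum(wts) <= 0) wts <- rep(1, n)     # all-zero evidence fallback
      wts <- wts / sum(wts)
      traj[m, ] <- c(sum(wts * pos[, 1]), sum(wts * pos[, 2]))
      norm_wts <- wts
      keep <- systematic_resample(wts, n)
      pos <- pos[keep, , drop = FALSE]
      wts <- rep(1 / n, n)
    }
    list(trajectory = traj, estimate = traj[nrow(traj), ],
         particles = pos, weights = norm_wts)
  })
}
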
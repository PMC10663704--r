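# Wavelet-shrinkage denoising driven by a greedy local search over a
# total-variation + fidelity energy. The stage profiles the noise type,
# flags noisy pixels on a four-level quantized view of the image, builds
# a first estimate by soft-thresholding the wavelet detail bands, and
# then proposes local-search operators (Gaussian blur, mean filter,
# global intensity scaling, re-thresholding one detail band, median
# replacement of flagged pixels) that are accepted only if the energy
# strictly decreases.

#' Denoising configuration
#'
#' `alpha` weighs the total-variation (edge) term and `gamma` the
#' fidelity term of the search energy (see [denoise_energy()]); both are
#' unitless multipliers on squared gray levels.
#'
#' @param alpha total-variation balance weight, >= 0.
#' @param gamma fidelity balance weight, >= 0.
#' @param wavelet,levels wavelet basis for the shrinkage stage.
#' @param threshold_rule `"universal"`, `"bayes"` or `"fixed"`.
#' @param fixed_threshold threshold value when `threshold_rule = "fixed"`.
#' @param local_search_rate probability in `[0, 1]` that an iteration
#'   proposes a local-search operator.
#' @param max_iterations local-search iteration budget.
#' @param seed RNG seed for the search.
#' @return object of class `denoise_config`.
#' @export
denoise_config <- function(alpha = 1, gamma = 1.5, wavelet = "haar",
                           levels = 2, threshold_rule = "universal",
                           fixed_threshold = NULL, local_search_rate = 0.8,
                           max_iterations = 30, seed = 1) {
  if (alpha < 0 || gamma < 0) stop("alpha and gamma must be >= 0")
  if (local_search_rate < 0 || local_search_rate > 1)
    stop("local_search_rate must lie in [0, 1]")
  structure(list(alpha = alpha, gamma = gamma, wavelet = wavelet,
                 levels = levels, threshold_rule = threshold_rule,
                 fixed_threshold = fixed_threshold,
                 local_search_rate = local_search_rate,
                 max_iterations = max_iterations, seed = seed),
            class = "denoise_config")
}

# Forward-difference gradient with replicate boundary (the last row and
# column difference against themselves, i.e. zero).
forward_gradient <- function(img) {
  h <- nrow(img); w <- ncol(img)
  dx <- img[, c(2:w, w), drop = FALSE] - img
  dy <- img[c(2:h, h), , drop = FALSE] - img
  list(dx = dx, dy = dy)
}

#' Total-variation + fidelity search energy
#'
#' `sum over pixels of 1 + alpha^2 |grad I|^2 + gamma^2 (I - I0)^2`,
#' where `I` is the candidate, `I0` the original (noisy) image and the
#' gradient uses forward differences with replicate boundary. The
#' constant term makes the energy of an unchanged flat image equal the
#' pixel count.
#'
#' @param candidate,original numeric matrices of the same shape.
#' @param alpha,gamma balance weights.
#' @return scalar energy.
#' @export
denoise_energy <- function(candidate, original, alpha, gamma) {
  if (!all(dim(candidate) == dim(original)))
    stop("candidate and original must have the same shape")
  g <- forward_gradient(candidate)
  sum(1 + alpha^2 * (g$dx^2 + g$dy^2) + gamma^2 * (candidate - original)^2)
}

#' Profile the dominant noise family of an image
#'
#' Computes the total variation (sum of gradient magnitudes), the
#' fraction of impulse pixels (exactly 0 or 255 *and* deviating from
#' their 3x3 median by more than 100 gray levels, which separates
#' isolated impulses from e.g. a clipped dark background), and the
#' variance of a 3x3 median-filter residual. The dominant family is
#' `salt_pepper` when the impulse fraction exceeds `impulse_threshold`;
#' otherwise, if the residual variance exceeds `variance_floor`, the
#' choice between `poisson` and `gaussian` rests on whether the local
#' variance scales with the local mean across flat image tiles (Poisson
#' variance is proportional to intensity: dark and bright tiles must
#' differ in variance by about their mean ratio, a test that is immune
#' to the spurious mean-variance correlation that clipping at gray
#' level 0 induces for Gaussian noise); otherwise `none`.
#'
#' @param image gray image matrix.
#' @param impulse_threshold saturated-pixel fraction above which the
#'   image is called salt-and-pepper corrupted.
#' @param variance_floor minimum residual variance (gray-level^2) to
#'   call the image noisy at all.
#' @return list with `tv_sum`, `impulse_fraction`, `saturated_fraction`,
#'   `residual_variance`, `mean_var_correlation`, `dominant_family`.
#' @export
profile_noise <- function(image, impulse_threshold = 0.01,
                          variance_floor = 9) {
  check_gray(image)
  g <- forward_gradient(image)
  tv_sum <- sum(sqrt(g$dx^2 + g$dy^2))
  med <- median_filter3(image)
  saturated <- image == 0 | image == 255
  impulse_fraction <- mean(saturated & abs(image - med) > 100)
  resid <- image - med
  residual_variance <- stats::var(as.numeric(resid))

  # tile statistics for the mean-variance relationship
  ts <- 16L
  h <- nrow(image) %/% ts * ts; w <- ncol(image) %/% ts * ts
  tile_of <- function(m) {
    m <- m[seq_len(h), seq_len(w), drop = FALSE]
    ti <- (rep(seq_len(h), times = w) - 1) %/% ts +
          ((rep(seq_len(w), each = h) - 1) %/% ts) * (h %/% ts)
    ti
  }
  ti <- tile_of(image)
  mm <- tapply(as.numeric(image[seq_len(h), seq_len(w)]), ti, mean)
  vv <- tapply(as.numeric(resid[seq_len(h), seq_len(w)]), ti, stats::var)
  gg <- forward_gradient(med)
  tv_tile <- tapply(as.numeric(sqrt(gg$dx^2 + gg$dy^2)[seq_len(h), seq_len(w)]),
                    ti, mean)
  # the mean-variance relationship is read off flat tiles only:
  # structural edges inflate the tile variance in ways unrelated to the
  # noise family
  flat <- tv_tile <= stats::quantile(tv_tile, 0.7)
  mid <- flat & mm > 40 & mm < 215
  mv_cor <- if (sum(mid) > 2 && stats::sd(mm[mid]) > 0 &&
                stats::sd(vv[mid]) > 0)
    stats::cor(mm[mid], vv[mid]) else 0

  # intensity-scaling test: Poisson variance is proportional to the
  # mean, so dark and bright flat tiles differ in variance by about
  # their mean ratio; intensity-independent (Gaussian) noise does not,
  # even when clipping at 0 inflates the correlation statistic
  dark <- flat & mm < 40; bright <- flat & mm > 100
  scales_with_mean <- if (any(dark) && any(bright)) {
    vratio <- mean(vv[bright]) / max(mean(vv[dark]), 1e-9)
    mratio <- mean(mm[bright]) / max(mean(mm[dark]), 1e-9)
    vratio > sqrt(mratio)
  } else mv_cor > 0.5

  fam <- if (impulse_fraction > impulse_threshold) "salt_pepper"
    else if (residual_variance > variance_floor) {
      if (scales_with_mean) "poisson" else "gaussian"
    } else "none"
  list(tv_sum = tv_sum, impulse_fraction = impulse_fraction,
       saturated_fraction = mean(saturated),
       residual_variance = residual_variance,
       mean_var_correlation = mv_cor, dominant_family = fam)
}

#' Four-level quantization and noisy-pixel flagging
#'
#' Each pixel is assigned one of four equal-width brightness levels
#' (black, dark gray, gray, white over `[0, 255]`). Scanning its eight
#' neighbours along rows, columns and diagonals (replicate boundary), a
#' pixel is flagged noisy when its level differs from at least six of
#' the eight; a checkerboard therefore flags nothing.
#'
#' @param image gray image matrix.
#' @return list with `mask` (logical matrix of flagged pixels) and
#'   `quantized` (integer matrix of levels 0-3).
#' @export
quantize_and_flag <- function(image) {
  check_gray(image)
  lvl <- pmin(image %/% 64L, 3L)
  ndiff <- matrix(0L, nrow(image), ncol(image))
  for (dy in -1:1) for (dx in -1:1) {
    if (dy == 0 && dx == 0) next
    ndiff <- ndiff + (shift_replicate(lvl, dy, dx) != lvl)
  }
  list(mask = ndiff >= 6L, quantized = lvl)
}

# Replace flagged pixels by the median of their 3x3 neighbourhood.
median_replace_flagged <- function(img, flagged) {
  if (!any(flagged)) return(img)
  med <- median_filter3(img)
  img[flagged] <- med[flagged]
  img
}

#' Wavelet-shrinkage denoising with greedy local search
#'
#' Starts from the soft-thresholded wavelet reconstruction of the input.
#' At each iteration, with probability `local_search_rate`, one operator
#' is proposed uniformly among Gaussian blur (sigma 1), 3x3 mean filter,
#' a global intensity scale drawn uniformly from `[0.7, 1.3]`,
#' re-thresholding one randomly chosen detail band, and 3x3 median
#' replacement of the pixels flagged by [quantize_and_flag()] on the
#' input. A proposal is accepted only if the [denoise_energy()] strictly
#' decreases (ties reject), so the energy trace over accepted states is
#' non-increasing. The search stops after `max_iterations` iterations or
#' 10 consecutive rejected proposals.
#'
#' @param image gray image matrix (the noisy input).
#' @param config a [denoise_config()].
#' @return object of class `denoise_result`: list with `image` (integer
#'   gray matrix), `initial` (the thresholded reconstruction), an
#'   `energy_trace` of accepted-state energies, the noise `profile`, and
#'   `accepted` operator names.
#' @export
denoise <- function(image, config = denoise_config()) {
  check_gray(image)
  stopifnot(inherits(config, "denoise_config"))
  noisy <- image * 1.0
  profile <- profile_noise(image)
  flagged <- quantize_and_flag(image)$mask

  decomp <- qwt_decompose(noisy, config$wavelet, config$levels)
  thr <- threshold_details(decomp, config$threshold_rule,
                           config$fixed_threshold)
  cur <- clip255(qwt_reconstruct(thr))
  initial <- cur
  a <- config$alpha; g <- config$gamma
  e_cur <- denoise_energy(cur, noisy, a, g)
  trace <- e_cur
  accepted <- character(0)
  ops <- c("gauss_blur", "mean_filter", "intensity_scale",
           "rethreshold_band", "median_flagged")

  with_local_seed(config$seed, {
    stale <- 0L
    it <- 0L
    while (it < config$max_iterations && stale < 10L) {
      it <- it + 1L
      if (stats::runif(1) >= config$local_search_rate) next
      op <- sample(ops, 1)
      cand <- switch(op,
        gauss_blur = conv_separable(cur, gauss_kernel_1d(1)),
        mean_filter = mean_filter3(cur),
        intensity_scale = clip255(cur * stats::runif(1, 0.7, 1.3)),
        rethreshold_band = {
          d <- qwt_decompose(cur, config$wavelet, config$levels)
          lv <- sample(config$levels, 1)
          band <- sample(c("horizontal", "vertical", "diagonal"), 1)
          t <- estimate_noise_sigma(d) * sqrt(2 * log(prod(d$dims)))
          d$details[[lv]][[band]] <- soft_threshold(d$details[[lv]][[band]], t)
          clip255(qwt_reconstruct(d))
        },
        median_flagged = median_replace_flagged(cur, flagged))
      e_cand <- denoise_energy(cand, noisy, a, g)
      if (e_cand < e_cur) {
        cur <- cand; e_cur <- e_cand
        trace <- c(trace, e_cur)
        accepted <- c(accepted, op)
        stale <- 0L
      } else stale <- stale + 1L
    }
  })
  structure(list(image = gray_image(clip255(cur)), initial = initial,
                 energy_trace = trace, profile = profile,
                 accepted = accepted),
            class = "denoise_result")
}
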
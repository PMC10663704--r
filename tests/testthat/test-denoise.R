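# Noise profiling, quantized flagging, the search energy, and the
# greedy denoiser.

test_that("noise profiler identifies each injected family", {
  flat <- gray_image(matrix(100, 64, 64))
  pf <- profile_noise(flat)
  expect_equal(pf$tv_sum, 0)
  expect_equal(pf$dominant_family, "none")

  ph <- generate_phantom(256, "benign", seed = 42)
  expect_equal(profile_noise(ph$image)$dominant_family, "none")
  sp <- add_noise(ph$image, noise_spec("salt_pepper", density = 0.05, seed = 1))
  expect_equal(profile_noise(sp)$dominant_family, "salt_pepper")
  gs <- add_noise(ph$image, noise_spec("gaussian", sigma = 15, seed = 1))
  expect_equal(profile_noise(gs)$dominant_family, "gaussian")
  po <- add_noise(ph$image, noise_spec("poisson", seed = 1))
  expect_equal(profile_noise(po)$dominant_family, "poisson")
})

test_that("four-level quantized flagging marks isolated impulses only", {
  flat <- gray_image(matrix(100, 16, 16))
  expect_false(any(quantize_and_flag(flat)$mask))

  one <- flat; one[8, 8] <- 255L
  qf <- quantize_and_flag(one)
  expect_true(qf$mask[8, 8])
  expect_equal(sum(qf$mask), 1)
  expect_equal(sort(unique(as.numeric(qf$quantized))), c(1, 3))

  # checkerboard: only 4 of 8 neighbours disagree -> nothing flagged
  cb <- gray_image(255L * ((row(matrix(0, 16, 16)) +
                            col(matrix(0, 16, 16))) %% 2L))
  expect_false(any(quantize_and_flag(cb)$mask))
})

test_that("flagging recovers >= 95% of isolated impulses on a smooth phantom", {
  ph <- generate_phantom(256, "benign", seed = 21)
  sp <- add_noise(ph$image, noise_spec("salt_pepper", density = 0.02, seed = 5))
  injected <- which(sp != ph$image & (sp == 0L | sp == 255L))
  flags <- quantize_and_flag(sp)$mask
  # count only impulses that are visible against their background level
  lvl <- pmin(ph$image %/% 64L, 3L)
  visible <- injected[pmin(sp[injected] %/% 64L, 3L) != lvl[injected]]
  expect_gt(mean(flags[visible]), 0.95)
})

test_that("search energy matches hand-enumerated forward differences", {
  # constant candidate equal to the original: only the '1 +' term
  flat <- matrix(50, 8, 8)
  expect_equal(denoise_energy(flat, flat, 1, 1), 64)

  # 2x2 case enumerated by hand with replicate boundary:
  # I = [[0,1],[0,1]] -> dx = 1 at column 1 (both rows), 0 at column 2;
  # dy = 0 everywhere; so sum |grad|^2 = 2
  I <- matrix(c(0, 0, 1, 1), 2, 2)
  expect_equal(denoise_energy(I, I, 1, 1), 4 + 2)
  # alpha = 0 removes the gradient term
  expect_equal(denoise_energy(I, I, 0, 1), 4)
  # fidelity term: gamma^2 * sum of squared deviations
  expect_equal(denoise_energy(I, I * 0, 0, 2), 4 + 4 * 2)

  expect_error(denoise_energy(matrix(0, 2, 2), matrix(0, 3, 3)), "shape")
})

test_that("denoiser is greedy: energy trace never increases", {
  ph <- generate_phantom(128, "benign", seed = 3)
  noisy <- add_noise(ph$image, noise_spec("salt_pepper", density = 0.05,
                                          seed = 2))
  dn <- denoise(noisy, denoise_config(max_iterations = 25, seed = 4))
  expect_true(all(diff(dn$energy_trace) < 0))
  expect_lte(tail(dn$energy_trace, 1), dn$energy_trace[1])
})

test_that("zero search iterations return the thresholded reconstruction", {
  ph <- generate_phantom(128, "benign", seed = 6)
  dn <- denoise(ph$image, denoise_config(max_iterations = 0))
  expect_equal(dn$image * 1.0, round(clip255(dn$initial)) * 1.0,
               tolerance = 1e-12)
})

test_that("denoising improves PSNR for each noise family", {
  ph <- generate_phantom(256, "benign", seed = 31)
  specs <- list(noise_spec("salt_pepper", density = 0.05, seed = 8),
                noise_spec("gaussian", sigma = 15, seed = 8),
                noise_spec("poisson", seed = 8))
  for (sp in specs) {
    noisy <- add_noise(ph$image, sp)
    dn <- denoise(noisy, denoise_config(seed = 9))
    expect_gt(psnr_metric(dn$image, ph$image),
              psnr_metric(noisy, ph$image))
  }
})

test_that("denoiser is deterministic given its seed", {
  ph <- generate_phantom(128, "malignant", seed = 17)
  noisy <- add_noise(ph$image, noise_spec("gaussian", sigma = 15, seed = 3))
  a <- denoise(noisy, denoise_config(seed = 5))
  b <- denoise(noisy, denoise_config(seed = 5))
  expect_identical(a$image, b$image)
  expect_identical(a$energy_trace, b$energy_trace)
})
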
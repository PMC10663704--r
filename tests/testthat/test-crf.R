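# Dense-CRF mean-field refinement and its energy.

test_that("with zero pairwise weights the refinement is the unary argmax", {
  ph <- generate_phantom(128, "benign", seed = 5)
  img <- ph$image[33:64, 33:64]
  withr::local_seed(3)
  p <- runif(length(img), 0.05, 0.95)
  unary <- cbind(1 - p, p)
  r <- crf_refine(unary, img, crf_params(w_appearance = 0, w_smoothness = 0))
  expect_equal(as.integer(r$labels), max.col(unary, ties.method = "first"))
})

test_that("uniform image and unary give a label-permutation-invariant energy", {
  img <- gray_image(matrix(100, 8, 8))
  unary <- matrix(0.5, 64, 2)
  K <- mammocad:::crf_kernel_matrix(img, crf_params())
  y <- rep(c(1L, 2L), 32)
  expect_equal(crf_energy(y, unary, K), crf_energy(3L - y, unary, K))
})

test_that("package energy matches the pairwise-loop oracle and refinement
           does not exceed the initial argmax energy (3x3 exhaustive)", {
  # 3x3 toy frame: evaluate the kernel/energy machinery directly
  img <- matrix(c(10, 10, 10, 10, 200, 200, 10, 200, 200), 3, 3)
  K <- mammocad:::crf_kernel_matrix(img, crf_params())
  withr::local_seed(4)
  p <- runif(9, 0.2, 0.8)
  unary <- cbind(1 - p, p)

  energies <- numeric(512)
  for (bits in 0:511) {
    y <- as.integer(bitwAnd(bits, 2^(0:8)) > 0) + 1L
    e_pkg <- crf_energy(y, unary, K)
    expect_equal(e_pkg, oracle_crf_energy(y, unary, K), tolerance = 1e-10)
    energies[bits + 1] <- e_pkg
  }
  y0 <- max.col(unary, ties.method = "first")
  e0 <- crf_energy(y0, unary, K)
  # exhaustive minimum is a lower bound for everything
  expect_lte(min(energies), e0 + 1e-12)
})

test_that("mean-field refinement lowers the energy on phantom instances", {
  for (s in c(601, 602)) {
    lab <- if (s %% 2) "benign" else "malignant"
    ph <- generate_phantom(128, lab, seed = s)
    img <- ph$image[33:96, 33:96]          # 64 x 64 instance
    mask <- ph$mask[33:96, 33:96]
    p <- ifelse(mask, 0.7, 0.25) + (as.numeric(img) / 255 - 0.5) * 0.2
    p <- pmin(pmax(p, 0.05), 0.95)
    unary <- cbind(1 - as.numeric(p), as.numeric(p))
    r <- crf_refine(unary, img, crf_params())
    expect_lte(tail(r$energy_trace, 1), r$energy_trace[1])
  }
})

test_that("refinement validates its unary input", {
  img <- gray_image(matrix(100, 8, 8))
  bad <- matrix(0.7, 64, 2)
  expect_error(crf_refine(bad, img, crf_params()), "sum to 1")
  expect_error(crf_refine(matrix(0.5, 10, 2), img), "pixel count")
})
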
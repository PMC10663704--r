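# Sobel edges, K-segment clustering and mass ROI extraction.

test_that("sobel magnitude is zero on flat images and maximal on a step", {
  expect_equal(max(sobel_edges(gray_image(matrix(9, 16, 16)))), 0)

  step <- gray_image(cbind(matrix(0L, 16, 8), matrix(255L, 16, 8)))
  e <- sobel_edges(step)
  expect_true(all(e[, 8] > 0))
  expect_equal(max(e[, c(1:6, 11:16)]), 0)
})

test_that("interior sobel response matches direct kernel convolution", {
  img <- ramp_image(9, 9)
  kx <- matrix(c(-1, -2, -1, 0, 0, 0, 1, 2, 1), 3, 3)       # d/dx (columns)
  ky <- t(kx)
  e <- sobel_edges(img)
  for (y in 4:6) for (x in 4:6) {
    patch <- img[(y - 1):(y + 1), (x - 1):(x + 1)] * 1.0
    expect_equal(e[y, x], sqrt(sum(patch * kx)^2 + sum(patch * ky)^2))
  }
})

test_that("clustering fitness is non-increasing and ends at a fixpoint", {
  ph <- generate_phantom(96, "benign", seed = 9)
  seg <- segment_kmeans(ph$image, K = 3)
  expect_true(all(diff(seg$fitness_trace) <= 1e-9))

  # fixpoint: reassigning with the final centers changes nothing
  d2 <- sapply(seq_len(seg$K), function(m)
    (seg$features[, 1] - seg$centers[m, 1])^2 +
    (seg$features[, 2] - seg$centers[m, 2])^2)
  expect_equal(max.col(-d2, ties.method = "first"),
               as.integer(seg$assignment))

  expect_error(segment_kmeans(gray_image(matrix(5, 16, 16)), K = 2),
               "degenerate")
})

test_that("two-intensity phantom is recovered with Dice >= 0.9 at K = 2", {
  img <- matrix(120L, 96, 96)
  truth <- (row(img) - 48)^2 + (col(img) - 40)^2 <= 15^2
  img[truth] <- 200L
  seg <- segment_kmeans(gray_image(img), K = 2)
  roi <- extract_mass_roi(img, seg)
  expect_true(roi$found)
  expect_gte(dice_coef(roi$mask, truth), 0.9)
})

test_that("ROI extraction finds planted masses and rejects normals", {
  for (s in 1:4) {
    lab <- if (s %% 2) "benign" else "malignant"
    ph <- generate_phantom(128, lab, seed = 400 + s)
    roi <- extract_mass_roi(ph$image, segment_kmeans(ph$image, K = 3))
    expect_true(roi$found)
    # centroid within the opening radius + rasterization slack of truth
    err <- sqrt(sum((roi$centroid - ph$mass_center)^2))
    expect_lt(err, 5)
    expect_true(all(!roi$boundary | roi$mask))
  }
  for (s in 1:3) {
    phn <- generate_phantom(128, "normal", seed = 500 + s)
    expect_false(extract_mass_roi(phn$image,
                                  segment_kmeans(phn$image, K = 3))$found)
  }
})
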
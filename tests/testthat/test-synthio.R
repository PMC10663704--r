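# PGM I/O, metadata parsing, phantom generation and noise injection.

test_that("read_pgm transcribes ASCII content and rejects malformed files", {
  p <- withr::local_tempfile(fileext = ".pgm")
  writeLines(c("P2", "# a comment", "2 2", "255", "0 255 128 64"), p)
  expect_identical(read_pgm(p), matrix(c(0L, 128L, 255L, 64L), 2, 2))

  writeLines(c("P2", "2 2", "255", "0 255 128"), p)
  expect_error(read_pgm(p), "truncated")
  writeLines(c("P2", "2 2", "4095", "0 1 2 3"), p)
  expect_error(read_pgm(p), "depth")
  writeLines(c("P7", "2 2", "255", "0 1 2 3"), p)
  expect_error(read_pgm(p), "magic")
})

test_that("write_pgm / read_pgm round-trips bit-exactly in both dialects", {
  img <- gray_image(matrix(sample(0:255, 24 * 17, replace = TRUE), 24, 17))
  for (ascii in c(FALSE, TRUE)) {
    p <- withr::local_tempfile(fileext = ".pgm")
    write_pgm(img, p, ascii = ascii)
    expect_identical(read_pgm(p), img)
  }
})

test_that("metadata parser maps the seven columns and flags bad codes", {
  recs <- parse_mias_metadata(c("mdb001 G CIRC B 535 425 197",
                                "mdb003 D NORM"))
  expect_equal(nrow(recs), 2)
  expect_equal(recs$severity[1], "B")
  expect_equal(recs$radius[1], 197)
  expect_equal(recs$class[2], "NORM")
  expect_true(is.na(recs$severity[2]) && is.na(recs$x[2]))

  expect_error(parse_mias_metadata("mdb999 X FOO"), "tissue")
  expect_error(parse_mias_metadata("mdb999 G FOO"), "line 1.*FOO")
  expect_error(parse_mias_metadata("mdb001 G CIRC B 10 10 0"), "radius")
  expect_error(parse_mias_metadata("mdb004 D NORM B 1 1 5"), "NORM")
})

test_that("bottom-left metadata coordinates convert to matrix indices and back", {
  # y counts up from the bottom; a point 1 above the bottom-left corner
  # of a 1024-row image sits on row 1023, column 1
  cc <- mias_to_matrix_coords(x = 0, y = 1, height = 1024)
  expect_equal(c(cc$row, cc$col), c(1023, 1))
  back <- matrix_to_mias_coords(cc$row, cc$col, height = 1024)
  expect_equal(c(back$x, back$y), c(0, 1))
})

test_that("phantoms are deterministic, labelled, and geometrically sound", {
  a <- generate_phantom(128, "malignant", seed = 7)
  b <- generate_phantom(128, "malignant", seed = 7)
  expect_identical(a$image, b$image)
  expect_identical(a$mask, b$mask)

  n <- generate_phantom(128, "normal", seed = 1)
  expect_false(any(n$mask))
  expect_equal(n$record$class, "NORM")

  # benign disc rasterization: mask area close to pi r^2
  ph <- generate_phantom(256, "benign", mass_radius = 20, seed = 3)
  expect_gt(sum(ph$mask), 0.9 * pi * 20^2)
  expect_lt(sum(ph$mask), 1.1 * pi * 20^2)
  # the mask is exactly the painted pixels: all strictly brighter than
  # the same phantom without a mass
  base <- generate_phantom(256, "normal", seed = 3)
  expect_true(all(ph$image[ph$mask] >= base$image[ph$mask]))

  expect_error(generate_phantom(128, "benign", mass_center = c(5, 5),
                                mass_radius = 20),
               "ellipse")
})

test_that("noise families behave as specified", {
  img <- gray_image(matrix(128, 64, 64))

  # full corruption: every pixel saturated
  sp1 <- add_noise(img, noise_spec("salt_pepper", density = 1, seed = 1))
  expect_true(all(sp1 %in% c(0L, 255L)))
  # zero density: identity
  expect_identical(add_noise(img, noise_spec("salt_pepper", density = 0)),
                   img)

  # empirical corrupted fraction close to the density
  ph <- generate_phantom(128, "benign", seed = 5)
  d <- 0.05
  sp <- add_noise(ph$image, noise_spec("salt_pepper", density = d, seed = 2))
  frac <- mean(sp != ph$image)
  tol <- 3 * sqrt(d * (1 - d) / length(sp)) + d * 0.5 / 64  # some draws
  expect_lt(abs(frac - d), d * 0.15 + tol)                  # hit 0/255 pixels

  # gaussian: sample sd of the added noise near sigma (constant-128
  # image, no clipping bias at sigma 10)
  gs <- add_noise(gray_image(matrix(128, 256, 256)),
                  noise_spec("gaussian", sigma = 10, seed = 3))
  expect_gt(sd(as.numeric(gs) - 128), 9.5)
  expect_lt(sd(as.numeric(gs) - 128), 10.5)

  # poisson: variance scales with the clean intensity
  po <- add_noise(gray_image(matrix(100, 128, 128)),
                  noise_spec("poisson", seed = 4))
  expect_lt(abs(var(as.numeric(po)) - 100) / 100, 0.1)
  expect_identical(add_noise(ph$image, noise_spec("poisson", seed = 9)),
                   add_noise(ph$image, noise_spec("poisson", seed = 9)))
})

test_that("phantom datasets round-trip through the PGM + metadata format", {
  dir <- withr::local_tempdir()
  phs <- generate_phantom_set(4, size = 64, labels = c("benign", "normal"),
                              seed = 2)
  write_phantom_dataset(phs, dir)
  meta <- parse_mias_metadata(file = file.path(dir, "metadata.txt"))
  expect_equal(nrow(meta), 4)
  img <- read_pgm(file.path(dir, paste0(meta$ref_id[1], ".pgm")))
  expect_identical(img, phs[[1]]$image)
})
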
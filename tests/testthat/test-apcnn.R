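# Feature stack, closed-form training, prediction, Bayes utility.

test_that("feature stack is deterministic and near-constant on flat input", {
  cfg <- apcnn_config(seed = 2)
  flat <- gray_image(matrix(128, 64, 64))
  f <- build_features(flat, cfg)
  # zero-mean kernels + zero-mean dense input: every conv output sits at
  # the activation of zero (sigmoid: 0.5), so all channel sds vanish
  sds <- f$features[grepl("_sd", names(f$features))]
  expect_lt(max(abs(sds)), 1e-8)
  means <- f$features[grepl("_mean", names(f$features))]
  expect_lt(max(abs(means - 0.5)), 1e-8)

  ph <- generate_phantom(128, "malignant", seed = 3)
  expect_identical(build_features(ph$image, cfg)$features,
                   build_features(ph$image, cfg)$features)
  expect_error(build_features(gray_image(matrix(0, 32, 32)), cfg), "64x64")
})

test_that("rate-1 atrous convolution equals the direct convolution oracle", {
  withr::local_seed(4)
  x <- matrix(rnorm(16 * 16), 16, 16)
  kern <- array(rnorm(81), dim = c(9, 9, 1, 1))
  ours <- mammocad:::conv2d(x, kern, dilation = 1)[[1]]
  expect_equal(ours, oracle_conv2d(x, kern[, , 1, 1]), tolerance = 1e-12)
  # dilated taps also agree with the naive dilated oracle
  kern3 <- array(rnorm(9), dim = c(3, 3, 1, 1))
  ours3 <- mammocad:::conv2d(x, kern3, dilation = 3)[[1]]
  expect_equal(ours3, oracle_conv2d(x, kern3[, , 1, 1], dilation = 3),
               tolerance = 1e-12)
})

test_that("pseudoinverse training attains the least-squares optimum", {
  withr::local_seed(5)
  cfg <- apcnn_config(hidden_units = 8, seed = 6)
  X <- matrix(rnorm(50 * 12), 50, 12)
  y <- rep(c("benign", "malignant"), 25)
  m <- apcnn_fit(cfg, X, y)

  # oracle: normal equations on the same hidden design matrix
  G <- mammocad:::apcnn_hidden(m, X)
  Y <- cbind(as.numeric(y == "benign"), as.numeric(y == "malignant"))
  beta_star <- oracle_lstsq(G, Y)
  r_ours <- norm(G %*% m$beta - Y, "F")
  r_star <- norm(G %*% beta_star - Y, "F")
  expect_lt(abs(r_ours - r_star), 1e-8 * max(r_star, 1))

  # duplicating every training row leaves beta unchanged
  m2 <- apcnn_fit(cfg, rbind(X, X), c(y, y))
  expect_equal(m2$beta, m$beta, tolerance = 1e-8)

  # refit is bit-reproducible
  m3 <- apcnn_fit(cfg, X, y)
  expect_identical(m3$beta, m$beta)
})

test_that("a square invertible hidden matrix is interpolated exactly", {
  withr::local_seed(7)
  # hidden width + intercept = n rows -> square G
  cfg <- apcnn_config(hidden_units = 11, seed = 8)
  X <- matrix(rnorm(12 * 5), 12, 5)
  y <- rep(c("benign", "malignant"), 6)
  m <- apcnn_fit(cfg, X, y)
  expect_equal(m$hidden_matrix_shape, c(12L, 12L))
  expect_lt(m$training_residual, 1e-7)
})

test_that("the suspicious threshold behaves at its extremes", {
  withr::local_seed(9)
  cfg <- apcnn_config(hidden_units = 16, seed = 10)
  X <- matrix(rnorm(40 * 6), 40, 6)
  y <- rep(c("benign", "malignant"), 20)
  m <- apcnn_fit(cfg, X, y)
  p0 <- apcnn_predict(m, X, tau = 0)
  expect_false(any(p0$label == "suspicious"))
  p1 <- apcnn_predict(m, X, tau = 1 + 1e-9)
  expect_true(all(p1$label == "suspicious"))
  # suspicious rate is monotone non-decreasing in tau
  rates <- vapply(seq(0, 1, by = 0.1), function(tau)
    mean(apcnn_predict(m, X, tau = tau)$label == "suspicious"), numeric(1))
  expect_true(all(diff(rates) >= 0))

  expect_error(apcnn_predict(structure(list(), class = "apcnn_model"), X),
               "not trained")
})

test_that("pinv matches crossprod inversion on a well-posed system", {
  withr::local_seed(11)
  A <- matrix(rnorm(30 * 7), 30, 7)
  expect_equal(pinv(A), solve(crossprod(A)) %*% t(A), tolerance = 1e-9)
})

test_that("bayes posterior follows the product rule", {
  expect_equal(bayes_posterior(0.5, 0.5, 0.5), 0.5)
  expect_equal(bayes_posterior(0.9, 0.5, 0.45), 1.0)
  # two exhaustive hypotheses: posteriors sum to one
  lik <- c(0.8, 0.3); pri <- c(0.4, 0.6)
  ev <- sum(lik * pri)
  expect_equal(sum(bayes_posterior(lik, pri, ev)), 1)
  expect_error(bayes_posterior(0.5, 0.5, 0), "evidence")
})
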
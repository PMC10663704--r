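# Restoration and classification metrics, ROC/AUC, CV splits.

test_that("psnr and mse follow the closed forms", {
  x <- gray_image(matrix(100, 16, 16))
  expect_equal(mse_metric(x, x), 0)
  expect_equal(psnr_metric(x, x), Inf)

  y <- gray_image(matrix(116, 16, 16))        # uniform offset 16
  expect_equal(mse_metric(y, x), 256)
  expect_equal(psnr_metric(y, x), 10 * log10(255^2 / 256), tolerance = 1e-6)

  # strictly decreasing in mse
  z <- gray_image(matrix(130, 16, 16))
  expect_lt(psnr_metric(z, x), psnr_metric(y, x))
  expect_error(mse_metric(matrix(0, 2, 2), matrix(0, 3, 3)), "shape")
})

test_that("confusion-matrix metrics match hand arithmetic", {
  cm <- matrix(c(50, 0, 0, 50), 2, 2,
               dimnames = list(c("benign", "malignant"),
                               c("benign", "malignant")))
  m <- classification_metrics(cm)
  expect_equal(unlist(m), c(accuracy = 1, sensitivity = 1,
                            specificity = 1, ppv = 1))

  cm2 <- matrix(c(45, 10, 5, 40), 2, 2,
                dimnames = list(c("benign", "malignant"),
                                c("benign", "malignant")))
  # truth benign: 45 right / 5 wrong; truth malignant: 10 wrong / 40 right
  m2 <- classification_metrics(cm2)
  expect_equal(m2$accuracy, 0.85)
  expect_equal(m2$sensitivity, 0.8)
  expect_equal(m2$specificity, 0.9)

  # relabeling both axes together leaves accuracy unchanged
  perm <- c(2, 1)
  expect_equal(classification_metrics(cm2[perm, perm])$accuracy, 0.85)
  expect_error(classification_metrics(cm2 * 0), "empty")
})

test_that("dice handles identity, disjoint and partial overlap", {
  a <- matrix(FALSE, 10, 10); a[2:5, 2:5] <- TRUE
  expect_equal(dice_coef(a, a), 1)
  b <- matrix(FALSE, 10, 10); b[7:9, 7:9] <- TRUE
  expect_equal(dice_coef(a, b), 0)
  expect_equal(dice_coef(matrix(FALSE, 4, 4), matrix(FALSE, 4, 4)), 1)

  # |A| = |B| = 16, |A & B| = 12 -> 2*12/32
  c <- matrix(FALSE, 10, 10); c[2:5, 3:6] <- TRUE
  expect_equal(dice_coef(a, c), 0.75)
})

test_that("threshold-sweep AUC equals the pair-counting oracle", {
  expect_equal(roc_auc(c(3, 2, 1, 0), c(1, 1, 0, 0))$auc, 1)
  expect_equal(roc_auc(rep(0.5, 6), c(1, 0, 1, 0, 1, 0))$auc, 0.5)
  expect_equal(roc_auc(c(.9, .8, .4, .2), c(1, 0, 1, 0))$auc, 0.75)

  withr::local_seed(14)
  for (rep in 1:25) {
    n <- sample(4:20, 1)
    truth <- c(0, 1, rbinom(n - 2, 1, 0.5))
    scores <- round(runif(n), 2)             # ties likely
    r <- roc_auc(scores, truth)
    expect_equal(r$auc, oracle_auc_pairs(scores, truth), tolerance = 1e-12)
    expect_true(all(diff(r$points$fpr) >= 0))
    expect_true(all(diff(r$points$tpr) >= 0))
  }
  expect_error(roc_auc(1:3, c(1, 1, 1)), "positive and one negative")
})

test_that("stratified folds partition the cases and preserve ratios", {
  labels <- rep(c("benign", "malignant"), c(60, 40))
  cv <- split_and_cv(labels, train_frac = 0.7, k = 5, seed = 3)
  expect_equal(sort(cv$case), 1:100)
  expect_equal(as.numeric(table(cv$fold)), rep(20, 5))
  # stratification: class ratio within each fold off by at most one case
  tab <- table(cv$fold, cv$label)
  expect_true(all(abs(tab[, "benign"] - 12) <= 1))
  expect_equal(sum(cv$split == "train"), 70)
  # per-class split sizes
  expect_equal(sum(cv$split == "train" & cv$label == "malignant"), 28)

  expect_identical(split_and_cv(labels, seed = 9), split_and_cv(labels, seed = 9))
  expect_warning(split_and_cv(c(rep("a", 20), rep("b", 3)), k = 5, seed = 1),
                 "unstratified")
})
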
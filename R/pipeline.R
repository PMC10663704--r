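# End-to-end pipeline: phantom generation (or a PGM directory) ->
# denoise -> segment -> feature stack -> closed-form training ->
# prediction, CRF mask refinement, particle-filter localization and
# report generation.

#' Pipeline configuration
#'
#' @param n_phantoms number of synthetic cases.
#' @param size phantom side in pixels.
#' @param labels label pool cycled over cases.
#' @param noise optional [noise_spec()] applied to every phantom.
#' @param denoise run the denoising stage.
#' @param denoise_config a [denoise_config()].
#' @param K segmentation cluster count.
#' @param se_radius opening disc radius for ROI extraction.
#' @param apcnn an [apcnn_config()].
#' @param crf run dense-CRF mask refinement on test cases.
#' @param crf_params a [crf_params()].
#' @param crf_max_side largest crop side (pixels) on which the exact
#'   dense CRF is evaluated; larger crops are downsampled.
#' @param mask_confidence unary confidence assigned to the segmentation
#'   mask when seeding the CRF.
#' @param pf_cases number of test cases passed to the particle-filter
#'   localizer (0 disables it).
#' @param pf a [pf_config()].
#' @param train_frac,k_folds evaluation split settings.
#' @param use_attributes append the nine tabular attributes to the
#'   image features.
#' @param seed master seed; all stage seeds derive from it.
#' @return object of class `pipeline_config`.
#' @export
pipeline_config <- function(n_phantoms = 200, size = 128,
                            labels = c("benign", "malignant"),
                            noise = NULL, denoise = TRUE,
                            denoise_config = mammocad::denoise_config(max_iterations = 10),
                            K = 3, se_radius = 2,
                            apcnn = apcnn_config(),
                            crf = TRUE, crf_params = mammocad::crf_params(),
                            crf_max_side = 48, mask_confidence = 0.9,
                            pf_cases = 10, pf = pf_config(),
                            train_frac = 0.7, k_folds = 5,
                            use_attributes = TRUE, seed = 1) {
  structure(as.list(environment()), class = "pipeline_config")
}

# Dense-CRF refinement of a found ROI: crop a window around the
# bounding box, downsample to the exact-CRF budget if needed, seed the
# unary from an intensity-likelihood map blended with the segmentation
# mask prior, refine, and paste back. The intensity map gives rim and
# spicule pixels (whose gray level sits between mass core and tissue)
# intermediate probabilities that the pairwise kernels can resolve.
refine_roi_mask <- function(image, roi, params = crf_params(),
                            max_side = 48, mask_confidence = 0.9,
                            intensity_mix = 0.6) {
  if (!roi$found) return(NULL)
  h <- nrow(image); w <- ncol(image)
  bb <- roi$bbox
  my <- ceiling((bb["rmax"] - bb["rmin"] + 1) * 0.5) + 4
  mx <- ceiling((bb["cmax"] - bb["cmin"] + 1) * 0.5) + 4
  r0 <- max(1, bb["rmin"] - my); r1 <- min(h, bb["rmax"] + my)
  c0 <- max(1, bb["cmin"] - mx); c1 <- min(w, bb["cmax"] + mx)
  crop <- image[r0:r1, c0:c1, drop = FALSE]
  mcrop <- roi$mask[r0:r1, c0:c1, drop = FALSE]
  ch <- nrow(crop); cw <- ncol(crop)
  scale <- max(ch, cw) / max_side
  if (scale > 1) {
    th <- max(8, round(ch / scale)); tw <- max(8, round(cw / scale))
    crop_s <- resize_matrix(crop, th, tw)
    mask_s <- resize_matrix(mcrop * 1.0, th, tw) > 0.5
  } else {
    crop_s <- crop; mask_s <- mcrop
  }
  mu1 <- mean(crop_s[mask_s]); mu0 <- mean(crop_s[!mask_s])
  p_int <- pmin(pmax(0.5 + 0.5 * tanh((crop_s - (mu1 + mu0) / 2) /
                                      max((mu1 - mu0) / 2, 1)), 0.05), 0.95)
  p_mask <- ifelse(mask_s, mask_confidence, 1 - mask_confidence)
  p_mass <- intensity_mix * p_int + (1 - intensity_mix) * p_mask
  unary <- cbind(1 - as.numeric(p_mass), as.numeric(p_mass))
  ref <- crf_refine(unary, crop_s, params)
  lab_s <- ref$labels == 2
  qmap_s <- matrix(ref$Q[, 2], nrow(crop_s), ncol(crop_s))
  if (scale > 1) {
    lab <- resize_matrix(lab_s * 1.0, ch, cw) > 0.5
    qmap <- resize_matrix(qmap_s, ch, cw)
  } else {
    lab <- lab_s; qmap <- qmap_s
  }
  full <- matrix(FALSE, h, w); full[r0:r1, c0:c1] <- lab
  score <- matrix(0, h, w); score[r0:r1, c0:c1] <- qmap
  list(mask = full, score_map = score, energy_trace = ref$energy_trace)
}

#' Run the full synthetic-experiment pipeline
#'
#' Generates phantoms, optionally corrupts and denoises them, segments
#' the candidate mass, extracts stack features (plus the tabular
#' attributes), trains the closed-form classifier on a stratified
#' 70/30 split, evaluates hold-out predictions and k-fold
#' cross-validation, refines the test-case masks with the dense CRF,
#' and localizes a subset of masses with the particle filter.
#'
#' @param config a [pipeline_config()].
#' @param out_dir optional directory for artifacts (`report.json`,
#'   `roc.csv`, refined mask PGMs). Timings are logged to stderr and
#'   kept out of the report so reruns are byte-identical.
#' @return object of class `pipeline_report` (a list; see fields in the
#'   JSON it writes).
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  t0 <- Sys.time()
  stage <- function(name) message(sprintf("[%s] %s (seed %d)",
    format(Sys.time(), "%H:%M:%S"), name, config$seed))

  stage("simulate")
  phantoms <- generate_phantom_set(config$n_phantoms, size = config$size,
                                   labels = config$labels,
                                   noise = config$noise, seed = config$seed)
  labels <- vapply(phantoms, function(p) p$label, character(1))

  stage("denoise")
  psnr_noisy <- psnr_denoised <- rep(NA_real_, length(phantoms))
  images <- vector("list", length(phantoms))
  for (i in seq_along(phantoms)) {
    ph <- phantoms[[i]]
    img <- ph$image
    if (isTRUE(config$denoise)) {
      dcfg <- config$denoise_config
      dcfg$seed <- derive_seed(config$seed + 7, i)
      dn <- denoise(img, dcfg)
      images[[i]] <- dn$image
    } else {
      images[[i]] <- img
    }
    if (!is.null(ph$clean)) {
      psnr_noisy[i] <- psnr_metric(ph$image, ph$clean)
      psnr_denoised[i] <- psnr_metric(images[[i]], ph$clean)
    }
  }

  stage("segment")
  rois <- vector("list", length(phantoms))
  for (i in seq_along(phantoms)) {
    seg <- segment_kmeans(images[[i]], K = config$K)
    rois[[i]] <- extract_mass_roi(images[[i]], seg,
                                  se_radius = config$se_radius)
  }

  stage("features")
  X <- NULL
  for (i in seq_along(phantoms)) {
    f <- build_features(images[[i]], config$apcnn)$features
    if (config$use_attributes) f <- c(f, phantoms[[i]]$attributes)
    if (is.null(X)) X <- matrix(NA_real_, length(phantoms), length(f),
                                dimnames = list(NULL, names(f)))
    X[i, ] <- f
  }

  stage("train")
  cv <- split_and_cv(labels, train_frac = config$train_frac,
                     k = config$k_folds, seed = derive_seed(config$seed, 13))
  tr <- cv$split == "train"
  model <- apcnn_fit(config$apcnn, X[tr, , drop = FALSE], labels[tr])
  pred <- apcnn_predict(model, X[!tr, , drop = FALSE])
  truth_test <- labels[!tr]

  cm3 <- confusion_matrix(truth_test, pred$label,
                          labels = c("benign", "malignant", "suspicious"))
  acc3 <- sum(diag(cm3)) / sum(cm3)
  collapsed <- collapse_suspicious(pred$label)
  cm2 <- confusion_matrix(truth_test, collapsed,
                          labels = c("benign", "malignant"))
  met <- classification_metrics(cm2, positive = "malignant")
  roc <- roc_auc(pred$p_malignant, truth_test == "malignant")
  suspicious_rate <- mean(pred$label == "suspicious")

  fold_acc <- vapply(seq_len(config$k_folds), function(f) {
    infold <- cv$fold == f
    m <- apcnn_fit(config$apcnn, X[!infold, , drop = FALSE], labels[!infold])
    p <- apcnn_predict(m, X[infold, , drop = FALSE])
    mean(collapse_suspicious(p$label) == labels[infold])
  }, numeric(1))

  stage("refine")
  test_idx <- which(!tr)
  dice <- rep(NA_real_, length(test_idx))
  score_maps <- vector("list", length(test_idx))
  for (j in seq_along(test_idx)) {
    i <- test_idx[j]
    truth_mask <- phantoms[[i]]$mask
    if (!any(truth_mask)) next
    if (isTRUE(config$crf)) {
      ref <- refine_roi_mask(images[[i]], rois[[i]], config$crf_params,
                             config$crf_max_side, config$mask_confidence)
      if (is.null(ref)) { dice[j] <- 0; next }
      dice[j] <- dice_coef(ref$mask, truth_mask)
      score_maps[[j]] <- ref$score_map
    } else if (rois[[i]]$found) {
      dice[j] <- dice_coef(rois[[i]]$mask, truth_mask)
      score_maps[[j]] <- rois[[i]]$mask * 1.0
    } else dice[j] <- 0
  }

  stage("localize")
  loc_err <- NA_real_
  if (config$pf_cases > 0) {
    cand <- which(!vapply(score_maps, is.null, logical(1)))
    cand <- utils::head(cand, config$pf_cases)
    errs <- vapply(cand, function(j) {
      i <- test_idx[j]
      pfc <- config$pf
      pfc$seed <- derive_seed(config$seed + 3, j)
      est <- localize_mass(rep(score_maps[j], 10), pfc)$estimate
      sqrt(sum((est - phantoms[[i]]$mass_center)^2))
    }, numeric(1))
    if (length(errs) > 0) loc_err <- mean(errs)
  }

  report <- structure(list(
    n_cases = length(phantoms),
    size = config$size,
    seed = config$seed,
    noise_family = if (is.null(config$noise)) "none" else config$noise$family,
    denoised = isTRUE(config$denoise),
    confusion_matrix_3way = unclass(cm3),
    confusion_matrix = unclass(cm2),
    accuracy = met$accuracy,
    accuracy_3way = acc3,
    sensitivity = met$sensitivity,
    specificity = met$specificity,
    ppv = met$ppv,
    auc = roc$auc,
    roc_points = roc$points,
    suspicious_rate = suspicious_rate,
    cv_fold_accuracy = fold_acc,
    cv_mean_accuracy = mean(fold_acc),
    mean_dice = mean(dice, na.rm = TRUE),
    localization_error_px = loc_err,
    mean_psnr_noisy = if (all(is.na(psnr_noisy))) NULL else mean(psnr_noisy),
    mean_psnr_denoised = if (all(is.na(psnr_denoised))) NULL
                         else mean(psnr_denoised)
  ), class = "pipeline_report")

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    out <- unclass(report)
    out$roc_points <- NULL
    jsonlite::write_json(out, file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, digits = 10, pretty = TRUE,
                         matrix = "rowmajor")
    utils::write.csv(roc$points, file.path(out_dir, "roc.csv"),
                     row.names = FALSE)
  }
  message(sprintf("pipeline finished in %.1f s",
                  as.numeric(difftime(Sys.time(), t0, units = "secs"))))
  report
}
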
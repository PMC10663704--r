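# Synthetic mammogram phantoms: an elliptical breast region on a dark
# background, an optional pectoral wedge, and an optional bright mass --
# smooth disc (benign, "CIRC") or spiculated star (malignant, "SPIC") --
# with a per-image ground-truth mask, class label, metadata record and
# nine label-conditional cytology-style attributes.

#' Generate a labelled synthetic mammogram phantom
#'
#' The breast is an ellipse of intensity roughly 120-180 (base level with
#' a radial falloff plus smooth low-frequency texture) on a background
#' near gray level 10. Malignant masses have spiculated (star-shaped)
#' margins; benign masses are smooth discs, mirroring the circumscribed
#' vs spiculated distinction of the standard metadata classes. The
#' ground-truth mask is exactly the set of pixels whose intensity the
#' mass painter incremented.
#'
#' Nine per-case tabular attributes (cytology-style scores on a 1-10
#' scale: clump thickness, cell size/shape uniformity, marginal adhesion,
#' epithelial cell size, bare nuclei, bland chromatin, normal nucleoli,
#' mitoses) are drawn from label-conditional Gaussians so that a
#' metadata-aware classifier head can be exercised.
#'
#' @param size image side in pixels (square), >= 64.
#' @param label one of `"benign"`, `"malignant"`, `"normal"`.
#' @param mass_center `(row, col)` of the mass, or `NULL` for a seeded
#'   draw near the breast center.
#' @param mass_radius mass radius in pixels; default `0.08 * size`.
#' @param contrast added gray levels at the mass core.
#' @param n_spicules number of spicules for malignant masses.
#' @param texture_sd standard deviation of the smooth tissue texture.
#' @param pectoral include a pectoral wedge in the top-left corner.
#' @param ref_id reference id for the metadata record.
#' @param seed RNG seed; fixed seed gives identical phantoms.
#' @return object of class `phantom`: list with `image` (integer matrix),
#'   `mask` (logical matrix), `label`, `record` (one-row metadata
#'   data.frame), `attributes` (named numeric of length 9).
#' @export
generate_phantom <- function(size = 256,
                             label = c("benign", "malignant", "normal"),
                             mass_center = NULL, mass_radius = NULL,
                             contrast = 70, n_spicules = 8,
                             texture_sd = 6, pectoral = TRUE,
                             ref_id = "syn001", seed = 1) {
  label <- match.arg(label)
  if (size < 64) stop("size must be >= 64")
  with_local_seed(seed, {
    h <- w <- size
    yy <- matrix(seq_len(h), h, w)
    xx <- matrix(seq_len(w), h, w, byrow = TRUE)
    cy <- 0.50 * h; cx <- 0.45 * w
    ry <- 0.45 * h; rx <- 0.38 * w
    er2 <- ((yy - cy) / ry)^2 + ((xx - cx) / rx)^2    # elliptical radius^2
    breast <- er2 <= 1

    img <- matrix(10, h, w)
    img[breast] <- 152 - 16 * er2[breast]
    if (pectoral) {
      wedge <- (xx + 0.9 * yy) < 0.30 * w
      img[wedge & breast] <- img[wedge & breast] + 20
    }
    tex <- conv_separable(matrix(rnorm(h * w), h, w), gauss_kernel_1d(4))
    tex <- tex / max(stats::sd(tex), 1e-12) * texture_sd
    img <- img + tex

    mask <- matrix(FALSE, h, w)
    rec_class <- "NORM"; sev <- NA_character_
    mx <- NA_real_; my <- NA_real_; mr <- NA_real_
    if (label != "normal") {
      if (is.null(mass_radius)) mass_radius <- round(0.08 * size)
      if (is.null(mass_center)) {
        ang <- stats::runif(1, 0, 2 * pi)
        rad <- stats::runif(1, 0, 0.35)
        mass_center <- c(cy + rad * ry * sin(ang), cx + rad * rx * cos(ang))
      }
      mcy <- mass_center[1]; mcx <- mass_center[2]
      # the whole mass extent must sit inside the breast ellipse
      ext2 <- ((abs(mcy - cy) + mass_radius) / ry)^2 +
              ((abs(mcx - cx) + mass_radius) / rx)^2
      if (ext2 > 0.95^2)
        stop("mass does not fit inside the breast ellipse")
      d <- sqrt((yy - mcy)^2 + (xx - mcx)^2)
      if (label == "benign") {
        # smooth disc: full contrast inside 0.8 r, ramp to zero exactly at r
        wgt <- clip01((mass_radius - d) / (0.2 * mass_radius))
      } else {
        # star-shaped margin: n_spicules lobes modulating the radius
        th <- atan2(yy - mcy, xx - mcx)
        phase <- stats::runif(1, 0, 2 * pi)
        reff <- mass_radius * (0.65 + 0.35 * pmax(0, cos(n_spicules * th + phase))^3)
        wgt <- clip01((reff - d) / (0.15 * mass_radius))
      }
      inc <- contrast * wgt
      mask <- inc > 0
      img <- img + inc
      rec_class <- if (label == "benign") "CIRC" else "SPIC"
      sev <- if (label == "benign") "B" else "M"
      cc <- matrix_to_mias_coords(mcy, mcx, h)
      mx <- round(cc$x); my <- round(cc$y); mr <- mass_radius
    }
    # clean phantoms avoid the saturated extremes 0/255, which are the
    # signature of impulse corruption
    img <- gray_image(pmin(pmax(img, 2), 250))

    record <- data.frame(ref_id = ref_id, tissue = "G", class = rec_class,
                         severity = sev, x = mx, y = my, radius = mr,
                         stringsAsFactors = FALSE)
    mu <- switch(label, benign = 2.8, malignant = 7.2, normal = 1.5)
    attrs <- pmin(pmax(stats::rnorm(9, mu, 1.2), 1), 10)
    names(attrs) <- c("clump_thickness", "cell_size_uniformity",
                      "cell_shape_uniformity", "marginal_adhesion",
                      "epithelial_cell_size", "bare_nuclei",
                      "bland_chromatin", "normal_nucleoli", "mitoses")
    structure(list(image = img, mask = mask, label = label,
                   record = record, attributes = attrs,
                   mass_center = if (label == "normal") NULL else mass_center,
                   mass_radius = if (label == "normal") NULL else mass_radius),
              class = "phantom")
  })
}

#' Noise specification
#'
#' @param family `"salt_pepper"`, `"gaussian"` or `"poisson"`.
#' @param sigma gray-level standard deviation (Gaussian family).
#' @param density fraction of corrupted pixels in `[0, 1]` (salt-and-pepper).
#' @param seed RNG seed.
#' @return object of class `noise_spec`.
#' @export
noise_spec <- function(family = c("salt_pepper", "gaussian", "poisson"),
                       sigma = 15, density = 0.05, seed = 1) {
  family <- match.arg(family)
  if (family == "gaussian" && sigma <= 0) stop("sigma must be > 0")
  if (density < 0 || density > 1) stop("density must lie in [0, 1]")
  structure(list(family = family, sigma = sigma, density = density,
                 seed = seed), class = "noise_spec")
}

#' Corrupt an image with a specified noise family
#'
#' Salt-and-pepper replaces a `density` fraction of pixels by 0 or 255
#' with equal probability; Gaussian adds zero-mean noise of standard
#' deviation `sigma` and clips to `[0, 255]`; Poisson draws each pixel
#' from a Poisson distribution whose mean is the clean gray level
#' (photon-count noise directly on gray levels), clipped to 255.
#'
#' @param image gray image matrix.
#' @param spec a [noise_spec()].
#' @return integer gray image of the same shape; deterministic given
#'   `spec$seed`.
#' @export
add_noise <- function(image, spec) {
  check_gray(image)
  stopifnot(inherits(spec, "noise_spec"))
  with_local_seed(spec$seed, {
    out <- image
    if (spec$family == "salt_pepper") {
      n <- round(spec$density * length(image))
      if (n > 0) {
        idx <- sample(length(image), n)
        out[idx] <- 255L * stats::rbinom(n, 1, 0.5)
      }
    } else if (spec$family == "gaussian") {
      out <- clip255(round(image + stats::rnorm(length(image), 0, spec$sigma)))
    } else {
      out <- pmin(stats::rpois(length(image), lambda = as.numeric(image)), 255)
      dim(out) <- dim(image)
    }
    gray_image(out)
  })
}

#' Generate a set of phantoms
#'
#' Convenience wrapper drawing `n` phantoms with per-case seeds derived
#' from `seed`, optional noise injection, and labels cycled from
#' `labels`.
#'
#' @param n number of phantoms.
#' @param labels label pool to cycle through.
#' @param noise optional [noise_spec()] applied to every image (per-case
#'   seeds derived from its seed); the clean image is kept in `$clean`.
#' @param seed master seed.
#' @inheritParams generate_phantom
#' @return list of `phantom` objects.
#' @export
generate_phantom_set <- function(n, size = 256,
                                 labels = c("benign", "malignant"),
                                 noise = NULL, seed = 1, ...) {
  lapply(seq_len(n), function(i) {
    ph <- generate_phantom(size = size,
                           label = labels[(i - 1) %% length(labels) + 1],
                           ref_id = sprintf("syn%03d", i),
                           seed = derive_seed(seed, i), ...)
    if (!is.null(noise)) {
      sp <- noise
      sp$seed <- derive_seed(noise$seed + 1, i)
      ph$clean <- ph$image
      ph$image <- add_noise(ph$image, sp)
    }
    ph
  })
}

#' Write a phantom dataset to disk
#'
#' One PGM per case, one mask PGM (0/255) per abnormal case, plus a
#' single whitespace-delimited metadata file in the seven-column format.
#'
#' @param phantoms list of `phantom` objects.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_phantom_dataset <- function(phantoms, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  meta <- character(length(phantoms))
  for (i in seq_along(phantoms)) {
    ph <- phantoms[[i]]
    id <- ph$record$ref_id
    write_pgm(ph$image, file.path(dir, paste0(id, ".pgm")))
    r <- ph$record
    meta[i] <- if (r$class == "NORM") paste(r$ref_id, r$tissue, r$class)
      else paste(r$ref_id, r$tissue, r$class, r$severity, r$x, r$y, r$radius)
    if (any(ph$mask))
      write_pgm(255L * (ph$mask * 1L), file.path(dir, paste0(id, "_mask.pgm")))
  }
  writeLines(meta, file.path(dir, "metadata.txt"))
  invisible(dir)
}
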
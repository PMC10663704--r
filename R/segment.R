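# Mass segmentation: Sobel edge magnitudes, a K-segment alternating
# minimization over two per-pixel features (brightness and edge
# strength, each scaled to [0, 1]), and morphological extraction of the
# candidate mass region.

#' Sobel edge magnitude
#'
#' Standard 3x3 Sobel kernels with replicate boundary;
#' `magnitude = sqrt(Gx^2 + Gy^2)`.
#'
#' @param image gray image matrix.
#' @return numeric matrix of edge magnitudes.
#' @export
sobel_edges <- function(image) {
  check_gray(image)
  m <- image * 1.0
  s <- function(dy, dx) shift_replicate(m, dy, dx)
  gx <- (s(-1, -1) + 2 * s(0, -1) + s(1, -1)) -
        (s(-1,  1) + 2 * s(0,  1) + s(1,  1))
  gy <- (s(-1, -1) + 2 * s(-1, 0) + s(-1, 1)) -
        (s( 1, -1) + 2 * s( 1, 0) + s( 1, 1))
  sqrt(gx^2 + gy^2)
}

#' K-segment clustering of brightness and edge features
#'
#' Builds an N x 2 feature matrix (one row per pixel: brightness, Sobel
#' magnitude, each min-max scaled to `[0, 1]`) and alternates between
#' assigning every pixel to its nearest center (Euclidean distance) and
#' recomputing each center as the mean of its assignment. The fitness --
#' the sum of squared distances of pixels to their assigned centers --
#' is non-increasing across iterations; iteration stops at an
#' assignment fixpoint or `max_iters`. Centers are initialized at the
#' feature rows of the K brightness quantiles, so the procedure is
#' deterministic.
#'
#' @param image gray image matrix.
#' @param K number of segments, >= 2.
#' @param max_iters iteration cap.
#' @param seed RNG seed (kept for interface stability; the default
#'   initialization is deterministic).
#' @return object of class `segmentation`: list with `assignment`
#'   (integer matrix of labels 1..K), `centers` (K x 2), `fitness_trace`,
#'   `iterations`, `K`, and the scaled `features`.
#' @export
segment_kmeans <- function(image, K = 3, max_iters = 50, seed = 1) {
  check_gray(image)
  if (K < 2) stop("K must be >= 2")
  scale01 <- function(x) {
    r <- range(x)
    if (diff(r) == 0) x * 0 else (x - r[1]) / diff(r)
  }
  b <- scale01(as.numeric(image))
  e <- scale01(as.numeric(sobel_edges(image)))
  X <- cbind(brightness = b, edge = e)
  if (nrow(unique(X)) < K)
    stop("degenerate input: fewer than K distinct feature rows")

  # deterministic init: feature rows at K brightness quantiles spanning
  # the full range, so the darkest and brightest pixels each seed a
  # center (a small bright mass otherwise never wins one)
  ord <- order(b)
  qidx <- ord[round(seq(1, length(b), length.out = K))]
  centers <- X[qidx, , drop = FALSE]

  assign_old <- rep(0L, nrow(X))
  trace <- numeric(0)
  it <- 0L
  repeat {
    it <- it + 1L
    d2 <- sapply(seq_len(K), function(m)
      (X[, 1] - centers[m, 1])^2 + (X[, 2] - centers[m, 2])^2)
    assign <- max.col(-d2, ties.method = "first")
    trace <- c(trace, sum(d2[cbind(seq_len(nrow(X)), assign)]))
    if (all(assign == assign_old) || it >= max_iters) break
    assign_old <- assign
    for (m in seq_len(K)) {
      sel <- assign == m
      if (any(sel)) centers[m, ] <- colMeans(X[sel, , drop = FALSE])
    }
  }
  structure(list(assignment = matrix(assign, nrow(image), ncol(image)),
                 centers = centers, fitness_trace = trace,
                 iterations = it, K = K, features = X),
            class = "segmentation")
}

# Deterministic 1-D two-means on brightness values (Lloyd iterations
# from the extremes); returns the bright-half membership and the final
# center separation.
split_by_brightness <- function(b, max_iters = 25) {
  c1 <- min(b); c2 <- max(b)
  for (i in seq_len(max_iters)) {
    hi <- abs(b - c2) < abs(b - c1)
    n1 <- mean(b[!hi]); n2 <- mean(b[hi])
    if (is.nan(n1) || is.nan(n2)) break
    if (n1 == c1 && n2 == c2) break
    c1 <- n1; c2 <- n2
  }
  list(bright = hi, contrast = c2 - c1)
}

#' Extract the candidate mass region from a segmentation
#'
#' Takes the brightest cluster's mask, applies a morphological opening
#' (disc element of `se_radius`) to remove specks, and keeps the largest
#' connected component together with its internal boundary.
#'
#' A focal mass occupies a small fraction of the frame; whenever the
#' brightest cluster is larger than `max_area_frac` of the frame (the
#' typical outcome when the mass and the surrounding tissue share a
#' cluster), the cluster is split by a deterministic two-means on
#' brightness and the brighter half is taken, for at most `max_splits`
#' rounds. The image is flagged as containing no mass when at any stage
#' the candidate is not separated from the remaining pixels by at least
#' `min_contrast` (in scaled brightness units), when the opening empties
#' the mask, or when no split yields a focal candidate.
#'
#' @param image gray image matrix (used for reporting only).
#' @param seg a [segment_kmeans()] result.
#' @param se_radius disc radius of the opening element, pixels.
#' @param min_contrast minimum scaled-brightness separation between the
#'   candidate and the next-brightest cluster centers.
#' @param max_area_frac largest admissible component area as a fraction
#'   of the frame.
#' @param max_splits maximum brightness-split rounds.
#' @return list with `found` (logical), `mask`, `boundary`, `centroid`
#'   (row, col), `bbox` (rmin, rmax, cmin, cmax) or `NULL`s when no mass
#'   is found.
#' @export
extract_mass_roi <- function(image, seg, se_radius = 2,
                             min_contrast = 0.15, max_area_frac = 0.15,
                             max_splits = 3) {
  stopifnot(inherits(seg, "segmentation"))
  bright <- seg$centers[, 1]
  top <- which.max(bright)
  sep <- sort(bright, decreasing = TRUE)
  no_mass <- list(found = FALSE, mask = NULL, boundary = NULL,
                  centroid = NULL, bbox = NULL)
  if (length(sep) >= 2 && (sep[1] - sep[2]) < min_contrast) return(no_mass)
  cand <- seg$assignment == top
  b <- matrix(seg$features[, 1], nrow(cand), ncol(cand))
  for (s in seq_len(max_splits)) {
    if (sum(cand) <= max_area_frac * length(cand)) break
    if (s == max_splits) return(no_mass)
    sub <- split_by_brightness(b[cand])
    if (sub$contrast < min_contrast) return(no_mass)
    keep <- matrix(FALSE, nrow(cand), ncol(cand))
    keep[cand][sub$bright] <- TRUE
    cand <- keep
  }
  opened <- open_mask(cand, se_disc(se_radius))
  if (!any(opened)) return(no_mass)
  comp <- largest_component(opened)
  if (sum(comp) > max_area_frac * length(comp)) return(no_mass)
  idx <- which(comp, arr.ind = TRUE)
  list(found = TRUE, mask = comp,
       boundary = boundary_mask(comp, se_box(3)),
       centroid = c(mean(idx[, 1]), mean(idx[, 2])),
       bbox = c(rmin = min(idx[, 1]), rmax = max(idx[, 1]),
                cmin = min(idx[, 2]), cmax = max(idx[, 2])))
}
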
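# Set-theoretic binary morphology on a finite pixel frame. Masks are
# logical matrices; a structuring element is a set of (dy, dx) offsets.
# Translations that leave the frame fail the containment test, so
# erosion shrinks at the borders (the frame is not padded with
# foreground).

#' Structuring elements
#'
#' `struct_element()` builds an element from an explicit offset matrix
#' (two columns: dy, dx). `se_box()` gives a full k x k square and
#' `se_disc()` a rasterized disc of the given radius; both contain the
#' origin.
#'
#' @param offsets integer matrix with columns `dy`, `dx`.
#' @return object of class `struct_element`.
#' @export
struct_element <- function(offsets) {
  offsets <- matrix(as.integer(offsets), ncol = 2)
  if (nrow(offsets) == 0) stop("structuring element must be nonempty")
  colnames(offsets) <- c("dy", "dx")
  structure(list(offsets = offsets), class = "struct_element")
}

#' @rdname struct_element
#' @param k odd side length.
#' @export
se_box <- function(k = 3) {
  r <- (k - 1) / 2
  struct_element(as.matrix(expand.grid(dy = -r:r, dx = -r:r)))
}

#' @rdname struct_element
#' @param radius disc radius in pixels.
#' @export
se_disc <- function(radius = 2) {
  r <- ceiling(radius)
  g <- expand.grid(dy = -r:r, dx = -r:r)
  struct_element(as.matrix(g[g$dy^2 + g$dx^2 <= radius^2, ]))
}

#' @rdname struct_element
#' @param se a `struct_element`.
#' @export
reflect_se <- function(se) struct_element(-se$offsets)

check_mask <- function(m, arg = "mask") {
  if (!is.matrix(m) || !is.logical(m)) stop(arg, " must be a logical matrix")
  invisible(m)
}

#' Binary erosion
#'
#' `erode_mask(M, N)` is the set of all pixels q such that N translated
#' by q lies entirely inside M (equivalently, the translated element
#' shares nothing with the background).
#'
#' @param mask logical matrix M.
#' @param se a [struct_element()] N.
#' @return logical matrix.
#' @export
erode_mask <- function(mask, se) {
  check_mask(mask)
  out <- matrix(TRUE, nrow(mask), ncol(mask))
  for (i in seq_len(nrow(se$offsets))) {
    o <- se$offsets[i, ]
    out <- out & shift_matrix(mask, -o[1], -o[2], fill = FALSE)
  }
  out
}

#' Binary dilation
#'
#' `dilate_mask(M, N)` reflects N about its origin, and collects every
#' translation q at which the reflected element intersects M.
#'
#' @inheritParams erode_mask
#' @return logical matrix.
#' @export
dilate_mask <- function(mask, se) {
  check_mask(mask)
  out <- matrix(FALSE, nrow(mask), ncol(mask))
  for (i in seq_len(nrow(se$offsets))) {
    o <- se$offsets[i, ]
    out <- out | shift_matrix(mask, o[1], o[2], fill = FALSE)
  }
  out
}

#' Internal boundary
#'
#' `boundary_mask(M, N) = M` minus the erosion of M by N: the pixels of
#' M whose structuring-element neighbourhood is not wholly inside M.
#'
#' @inheritParams erode_mask
#' @return logical matrix, always a subset of `mask`.
#' @export
boundary_mask <- function(mask, se = se_box(3)) {
  mask & !erode_mask(mask, se)
}

#' Morphological opening
#'
#' Erosion followed by dilation with the same element; removes specks
#' smaller than the element and never grows the mask.
#'
#' @inheritParams erode_mask
#' @return logical matrix.
#' @export
open_mask <- function(mask, se) {
  dilate_mask(erode_mask(mask, se), se)
}

# Largest 4/8-connected component of a mask (EBImage labeling).
largest_component <- function(mask) {
  if (!any(mask)) return(mask)
  lab <- as.matrix(EBImage::imageData(EBImage::bwlabel(mask * 1)))
  tab <- tabulate(lab[lab > 0])
  lab == which.max(tab)
}
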
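#' Cross-shaped structuring element
#'
#' The standard cross (plus-shaped) structuring element of radius 1 pixel:
#' the origin and its four orthogonal neighbors, as a 0/1 kernel matrix.
#'
#' @param radius integer >= 1; offsets with |drow| + |dcol| <= radius.
#' @return a square 0/1 numeric matrix of odd side, symmetric about its
#'   center.
#' @export
crossKernel <- function(radius = 1L) {
  stopifnot(radius >= 1)
  radius <- as.integer(radius)
  idx <- abs(seq_len(2L * radius + 1L) - radius - 1L)
  (outer(idx, idx, "+") <= radius) * 1
}

.padMask <- function(m, r) {
  out <- matrix(FALSE, nrow(m) + 2L * r, ncol(m) + 2L * r)
  out[(r + 1L):(r + nrow(m)), (r + 1L):(r + ncol(m))] <- m
  out
}

#' Morphological closing of a binary mask
#'
#' Dilation followed by erosion with the given structuring element,
#' evaluated with plane semantics: the mask is embedded in a background
#' plane (zero padding by the kernel radius), closed there, and the result
#' cropped back to the image — so dilation keeps its reach beyond the
#' border and the operator stays extensive and idempotent up to the edge.
#' The heavy lifting is done by `EBImage`'s dilate/erode.
#'
#' @param mask a [BinaryMask-class] (or logical matrix).
#' @param kern 0/1 kernel matrix of odd side, symmetric about its center
#'   (default: the radius-1 cross).
#' @return a [BinaryMask-class].
#' @export
morphClosing <- function(mask, kern = crossKernel()) {
  m <- .asMaskMatrix(mask)
  r <- (max(dim(kern)) - 1L) %/% 2L
  rows <- (r + 1L):(r + nrow(m)); cols <- (r + 1L):(r + ncol(m))
  cl <- EBImage::erode(EBImage::dilate(.padMask(m, r) * 1, kern), kern)
  BinaryMask(cl[rows, cols, drop = FALSE] > 0.5)
}

#' Connectivity filter followed by morphological closing
#'
#' The comparison baseline: connectivity-filter segmentation composed with
#' a morphological closing by the cross structuring element. The default
#' order (filter, then closing) follows the six-step pipeline; the
#' alternative order (closing first, then the filter) is available via
#' `closingFirst = TRUE`.
#'
#' @inheritParams cfSegment
#' @param kern structuring element, as in [morphClosing()].
#' @param closingFirst apply the closing before the connectivity filter.
#' @return a [BinaryMask-class].
#' @export
cfPlusClosing <- function(mask, spec = NeighborhoodSpec(), sMin = 1L,
                          kern = crossKernel(), closingFirst = FALSE) {
  if (closingFirst) {
    cfSegment(morphClosing(mask, kern), spec, sMin)
  } else {
    morphClosing(cfSegment(mask, spec, sMin), kern)
  }
}
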
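#' @useDynLib LSCFilter, .registration = TRUE
#' @importFrom Rcpp evalCpp
NULL

.asMaskMatrix <- function(mask) {
  if (is(mask, "BinaryMask")) return(mask@.Data)
  m <- as.matrix(mask)
  if (!is.logical(m)) m <- m == 1
  m
}

#' Connectivity scores by flood fill
#'
#' Assigns every vessel pixel its connectivity score: the number of
#' foreground pixels in its connected component under the given adjacency
#' (a pixel counts itself, so an isolated pixel scores 1). Background
#' pixels score 0 and all pixels of one component share one score. The
#' traversal is an explicit-worklist flood fill, so component size is not
#' limited by call-stack depth.
#'
#' @param mask a [BinaryMask-class] (or logical matrix).
#' @param spec a [NeighborhoodSpec-class]; the default gives 8-connectivity.
#' @return a [ScoreMap-class].
#' @examples
#' m <- matrix(FALSE, 5, 5); m[2, 2:4] <- TRUE; m[5, 5] <- TRUE
#' connectivityScores(BinaryMask(m))
#' @export
connectivityScores <- function(mask, spec = NeighborhoodSpec()) {
  m <- .asMaskMatrix(mask)
  res <- cpp_label_components(m, neighborhoodOffsets(spec))
  lab <- res$labels
  sc <- matrix(0L, nrow(lab), ncol(lab))
  fg <- lab > 0L
  sc[fg] <- res$sizes[lab[fg]]
  ScoreMap(sc)
}

#' Threshold a score map into a cleaned mask
#'
#' Keeps exactly the pixels whose connectivity score is strictly greater
#' than `sMin`. The default `sMin = 1` removes isolated single pixels (the
#' salt noise of thresholded vesselness responses) and keeps every
#' component of two or more pixels; `sMin = 0` reproduces the scored
#' support unchanged. The threshold is configurable for other scenarios.
#'
#' @param scoreMap a [ScoreMap-class].
#' @param sMin integer >= 0; keep scores > sMin.
#' @return a [BinaryMask-class].
#' @export
thresholdScores <- function(scoreMap, sMin = 1L) {
  stopifnot(is(scoreMap, "ScoreMap"), sMin >= 0)
  BinaryMask(scoreMap@.Data > sMin)
}

#' Connectivity-filter segmentation
#'
#' The full connectivity filter: score every component by its size, then
#' keep components scoring strictly above `sMin`. Equivalent to removing
#' every connected component of at most `sMin` pixels.
#'
#' @inheritParams connectivityScores
#' @inheritParams thresholdScores
#' @return a [BinaryMask-class].
#' @export
cfSegment <- function(mask, spec = NeighborhoodSpec(), sMin = 1L) {
  thresholdScores(connectivityScores(mask, spec), sMin)
}

#' Render a score map as an 8-bit image
#'
#' Clamps scores at 255 for display/export. Raw score maps are never
#' clamped internally — thresholds always act on true component counts.
#'
#' @param scoreMap a [ScoreMap-class].
#' @return a [GrayImage-class].
#' @export
renderScores8bit <- function(scoreMap) {
  stopifnot(is(scoreMap, "ScoreMap"))
  GrayImage(pmin(scoreMap@.Data, 255L))
}
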
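#' Local-sensitive connectivity traversal
#'
#' Extends the connectivity-filter flood fill with a tolerance heuristic
#' that re-links broken vessel branches. While walking on vessel pixels the
#' traversal behaves exactly like [connectivityScores()]; each component
#' additionally grows an off-vessel excursion wave: walkers depart from
#' every vessel pixel onto background, expanding neighbors momentum-first
#' (continuing the direction of the previous move before turning
#' clockwise). A walker's tolerance score is its excursion depth — the
#' number of consecutive background pixels visited since leaving the
#' vessel — and may not exceed `params@maxScore`; every step must also
#' stay within `params@maxDist` pixels (Chebyshev) of the vessel pixel
#' the walker departed from. The wave's first contact with a vessel pixel
#' of a different component realizes a shortest admissible bridge: its
#' path is painted as vessel ("bridged") and the components merge, the
#' wave regrowing until no contact remains; exhausted walkers leave no
#' trace. Final scores are merged-component cardinalities including
#' bridge pixels.
#'
#' With `maxScore = 0` or `maxDist = 0` no excursion can visit any
#' background pixel and the result degenerates to the plain connectivity
#' filter.
#'
#' @param mask a [BinaryMask-class] (or logical matrix).
#' @param spec a [NeighborhoodSpec-class] defining adjacency and neighbor
#'   order.
#' @param params an [LSCFParams-class]; defaults maxScore 350, maxDist 4.
#' @param sMin score threshold used for the `segmented` slot of the result.
#' @return an [LSCFResult-class] with slots `scores`, `bridged`,
#'   `segmented`.
#' @examples
#' m <- matrix(FALSE, 5, 12)
#' m[3, 1:5] <- TRUE; m[3, 8:12] <- TRUE   # 2-pixel gap
#' lsConnectivity(BinaryMask(m))
#' @export
lsConnectivity <- function(mask, spec = NeighborhoodSpec(),
                           params = LSCFParams(), sMin = 1L) {
  m <- .asMaskMatrix(mask)
  stopifnot(is(params, "LSCFParams"))
  res <- cpp_ls_connectivity(m, neighborhoodOffsets(spec),
                             params@maxScore, params@maxDist)
  sc <- ScoreMap(res$scores)
  new("LSCFResult",
      scores = sc,
      bridged = BinaryMask(res$bridged),
      segmented = thresholdScores(sc, sMin))
}

#' Local-sensitive connectivity-filter segmentation
#'
#' Runs [lsConnectivity()] and thresholds the resulting score map at
#' `sMin`, yielding the final binary segmentation (a subset of the input
#' foreground plus the painted bridge pixels).
#'
#' @inheritParams lsConnectivity
#' @return a [BinaryMask-class].
#' @export
lscfSegment <- function(mask, spec = NeighborhoodSpec(),
                        params = LSCFParams(), sMin = 1L) {
  segmented(lsConnectivity(mask, spec, params, sMin))
}
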
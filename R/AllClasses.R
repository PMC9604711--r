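#' @import methods
NULL

#' GrayImage: an 8-bit single-channel image
#'
#' A plain integer matrix (row-major, 0-based pixel coordinates at the C
#' level, 1-based at the R level) constrained to values in [0, 255]. Used
#' for raw channels, vesselness responses and rendered score maps.
#'
#' @slot .Data integer matrix with values in [0, 255].
#' @export
setClass("GrayImage", contains = "matrix", validity = function(object) {
  v <- object@.Data
  if (length(v) == 0L) return("image must have at least one pixel")
  if (!is.numeric(v)) return("pixel values must be numeric")
  if (anyNA(v)) return("pixel values must not contain NA")
  if (any(v < 0 | v > 255)) return("pixel values must lie in [0, 255]")
  if (any(v != round(v))) return("pixel values must be whole numbers")
  TRUE
})

#' BinaryMask: a boolean vessel mask
#'
#' A logical matrix; `TRUE` marks vessel/foreground pixels.
#'
#' @slot .Data logical matrix.
#' @export
setClass("BinaryMask", contains = "matrix", validity = function(object) {
  v <- object@.Data
  if (length(v) == 0L) return("mask must have at least one pixel")
  if (!is.logical(v)) return("mask values must be logical")
  if (anyNA(v)) return("mask values must not contain NA")
  TRUE
})

#' ScoreMap: per-pixel connectivity scores
#'
#' Integer matrix of connectivity scores: 0 on background, >= 1 on every
#' foreground pixel, constant within a connected component. Scores are kept
#' as raw counts (components on fundus images routinely exceed 255 pixels);
#' clamping to 8 bits happens only in [renderScores8bit()].
#'
#' @slot .Data integer matrix, values >= 0.
#' @export
setClass("ScoreMap", contains = "matrix", validity = function(object) {
  v <- object@.Data
  if (length(v) == 0L) return("score map must have at least one pixel")
  if (anyNA(v)) return("scores must not contain NA")
  if (any(v < 0)) return("scores must be nonnegative")
  if (any(v != round(v))) return("scores must be whole numbers")
  TRUE
})

#' NeighborhoodSpec: pixel adjacency by the Rodrigues distance
#'
#' Adjacency between pixels is defined by thresholding the Rodrigues
#' distance, a weighted sum of a Minkowski and a Chebyshev term:
#' \deqn{d(a, b) = w_1 (\sum_i |a_i-b_i|^p)^{1/p} + w_2 \max_i |a_i-b_i|.}
#' Two pixels are neighbors when d <= radius. With the unit weights
#' (w1 = w2 = p = 1) used throughout, radius 2 yields 4-connectivity and
#' radius 3 yields 8-connectivity.
#'
#' @slot w1 nonnegative weight of the Minkowski term.
#' @slot w2 nonnegative weight of the Chebyshev term.
#' @slot p Minkowski exponent, >= 1.
#' @slot radius inclusive distance threshold, > 0.
#' @export
setClass("NeighborhoodSpec",
  representation(w1 = "numeric", w2 = "numeric", p = "numeric",
                 radius = "numeric"),
  validity = function(object) {
    for (s in c("w1", "w2", "p", "radius")) {
      v <- slot(object, s)
      if (length(v) != 1L || !is.finite(v)) return(sprintf("%s must be a single finite number", s))
    }
    if (object@w1 < 0 || object@w2 < 0) return("w1 and w2 must be nonnegative")
    if (object@w1 == 0 && object@w2 == 0) return("w1 and w2 must not both be zero")
    if (object@p < 1) return("p must be >= 1")
    if (object@radius <= 0) return("radius must be positive")
    TRUE
  })

#' LSCFParams: tolerance and distance budgets for gap bridging
#'
#' `maxScore` caps how many background pixels a single off-vessel excursion
#' may visit; `maxDist` caps how far (in pixels, Chebyshev) an excursion may
#' stray from the vessel pixel it departed from. Defaults follow the
#' reference configuration maxScore = 350, maxDist = 4.
#'
#' @slot maxScore integer >= 0, per-excursion visit budget.
#' @slot maxDist numeric >= 0, excursion radius in pixels.
#' @export
setClass("LSCFParams",
  representation(maxScore = "integer", maxDist = "numeric"),
  validity = function(object) {
    if (length(object@maxScore) != 1L || is.na(object@maxScore) ||
        object@maxScore < 0L) return("maxScore must be a single integer >= 0")
    if (length(object@maxDist) != 1L || !is.finite(object@maxDist) ||
        object@maxDist < 0) return("maxDist must be a single number >= 0")
    TRUE
  })

#' FrangiParams: configuration of the vesselness front end
#'
#' @slot scaleMin smallest Gaussian scale (sigma, pixels), > 0.
#' @slot scaleMax largest scale, >= scaleMin.
#' @slot scaleStep scale increment, > 0.
#' @slot beta blobness sensitivity, > 0.
#' @slot gamma structureness sensitivity (8-bit intensity units), > 0.
#' @slot invert TRUE for dark-vessel-on-bright modalities (fundus green
#'   channel); FALSE for bright vessels (inverted angiograms).
#' @export
setClass("FrangiParams",
  representation(scaleMin = "numeric", scaleMax = "numeric",
                 scaleStep = "numeric", beta = "numeric", gamma = "numeric",
                 invert = "logical"),
  validity = function(object) {
    if (object@scaleMin <= 0) return("scaleMin must be positive")
    if (object@scaleMax < object@scaleMin) return("scaleMax must be >= scaleMin")
    if (object@scaleStep <= 0) return("scaleStep must be positive")
    if (object@beta <= 0) return("beta must be positive")
    if (object@gamma <= 0) return("gamma must be positive")
    if (length(object@invert) != 1L || is.na(object@invert)) return("invert must be TRUE or FALSE")
    TRUE
  })

#' LSCFResult: output of the local-sensitive connectivity traversal
#'
#' @slot scores [ScoreMap] of merged-component cardinalities (bridge pixels
#'   included in the counts and carrying their component's score).
#' @slot bridged [BinaryMask] of background pixels painted vessel by
#'   successful excursions; disjoint from the input foreground.
#' @slot segmented [BinaryMask] final thresholded segmentation, a subset of
#'   input foreground plus bridged pixels.
#' @export
setClass("LSCFResult",
  representation(scores = "ScoreMap", bridged = "BinaryMask",
                 segmented = "BinaryMask"),
  validity = function(object) {
    d1 <- dim(object@scores); d2 <- dim(object@bridged); d3 <- dim(object@segmented)
    if (!identical(d1, d2) || !identical(d1, d3)) return("scores, bridged and segmented must share one shape")
    if (any(object@bridged@.Data & object@scores@.Data == 0L))
      return("bridged pixels must carry a positive score")
    TRUE
  })

#' ConfusionCounts: pixelwise confusion-matrix tallies
#'
#' @slot tp,fp,tn,fn nonnegative integer counts; their sum is the number of
#'   evaluated pixels (all pixels, or those inside the field-of-view mask).
#' @export
setClass("ConfusionCounts",
  representation(tp = "integer", fp = "integer", tn = "integer",
                 fn = "integer"),
  validity = function(object) {
    v <- c(object@tp, object@fp, object@tn, object@fn)
    if (length(v) != 4L || anyNA(v) || any(v < 0L)) return("counts must be single nonnegative integers")
    TRUE
  })

#' VesselFixture: a synthetic phantom with known degradations
#'
#' @slot truth [BinaryMask] the intact vessel tree.
#' @slot observed [BinaryMask] the degraded mask (gaps punched, noise added).
#' @slot gaps list of integer matrices (row, col), one per punched gap,
#'   holding the exact removed pixels.
#' @slot noise integer matrix (row, col) of injected isolated pixels.
#' @export
setClass("VesselFixture",
  representation(truth = "BinaryMask", observed = "BinaryMask",
                 gaps = "list", noise = "matrix"),
  validity = function(object) {
    if (!identical(dim(object@truth), dim(object@observed)))
      return("truth and observed must share one shape")
    TRUE
  })

# ---- constructors ----

#' @describeIn GrayImage-class Construct a GrayImage from a numeric matrix.
#' @param values numeric matrix of whole numbers in [0, 255].
#' @export
GrayImage <- function(values) {
  m <- as.matrix(values)
  storage.mode(m) <- "integer"
  new("GrayImage", m)
}

#' @describeIn BinaryMask-class Construct a BinaryMask from a logical or 0/1
#'   numeric matrix.
#' @param values logical (or 0/1 numeric) matrix.
#' @export
BinaryMask <- function(values) {
  m <- as.matrix(values)
  if (!is.logical(m)) {
    if (!all(m %in% c(0, 1))) stop("mask values must be logical or 0/1")
    m <- m == 1
  }
  new("BinaryMask", m)
}

#' @describeIn ScoreMap-class Construct a ScoreMap from a numeric matrix.
#' @param values nonnegative integer matrix.
#' @export
ScoreMap <- function(values) {
  m <- as.matrix(values)
  storage.mode(m) <- "integer"
  new("ScoreMap", m)
}

#' @describeIn NeighborhoodSpec-class Construct a NeighborhoodSpec. The
#'   defaults give 8-connectivity under the unit-weight Rodrigues distance.
#' @param w1,w2,p,radius see slots.
#' @export
NeighborhoodSpec <- function(w1 = 1, w2 = 1, p = 1, radius = 3) {
  new("NeighborhoodSpec", w1 = as.numeric(w1), w2 = as.numeric(w2),
      p = as.numeric(p), radius = as.numeric(radius))
}

#' @describeIn LSCFParams-class Construct LSCFParams (defaults
#'   maxScore = 350, maxDist = 4).
#' @param maxScore,maxDist see slots.
#' @export
LSCFParams <- function(maxScore = 350, maxDist = 4) {
  new("LSCFParams", maxScore = as.integer(maxScore),
      maxDist = as.numeric(maxDist))
}

#' @describeIn FrangiParams-class Construct FrangiParams. Defaults: scales
#'   1..8 step 1, beta 0.5, gamma 15, invert TRUE (fundus-style dark
#'   vessels).
#' @param scaleMin,scaleMax,scaleStep,beta,gamma,invert see slots.
#' @export
FrangiParams <- function(scaleMin = 1, scaleMax = 8, scaleStep = 1,
                         beta = 0.5, gamma = 15, invert = TRUE) {
  new("FrangiParams", scaleMin = as.numeric(scaleMin),
      scaleMax = as.numeric(scaleMax), scaleStep = as.numeric(scaleStep),
      beta = as.numeric(beta), gamma = as.numeric(gamma),
      invert = as.logical(invert))
}

#' @describeIn ConfusionCounts-class Construct ConfusionCounts.
#' @param tp,fp,tn,fn nonnegative integer counts.
#' @export
ConfusionCounts <- function(tp, fp, tn, fn) {
  new("ConfusionCounts", tp = as.integer(tp), fp = as.integer(fp),
      tn = as.integer(tn), fn = as.integer(fn))
}

# ---- show methods ----

setMethod("show", "GrayImage", function(object) {
  cat(sprintf("GrayImage %d x %d, range [%d, %d]\n",
              nrow(object), ncol(object), min(object@.Data), max(object@.Data)))
})

setMethod("show", "BinaryMask", function(object) {
  cat(sprintf("BinaryMask %d x %d, %d foreground pixel(s) (%.2f%%)\n",
              nrow(object), ncol(object), sum(object@.Data),
              100 * mean(object@.Data)))
})

setMethod("show", "ScoreMap", function(object) {
  fg <- object@.Data[object@.Data > 0L]
  cat(sprintf("ScoreMap %d x %d, %d scored pixel(s), max score %d\n",
              nrow(object), ncol(object), length(fg),
              if (length(fg)) max(fg) else 0L))
})

setMethod("show", "NeighborhoodSpec", function(object) {
  cat(sprintf("NeighborhoodSpec: w1=%g w2=%g p=%g radius=%g (%d offsets)\n",
              object@w1, object@w2, object@p, object@radius,
              nrow(neighborhoodOffsets(object))))
})

setMethod("show", "LSCFParams", function(object) {
  cat(sprintf("LSCFParams: maxScore=%d maxDist=%g\n",
              object@maxScore, object@maxDist))
})

setMethod("show", "LSCFResult", function(object) {
  cat("LSCFResult\n")
  cat(sprintf("  scores   : %d x %d, max %d\n", nrow(object@scores),
              ncol(object@scores), max(object@scores@.Data)))
  cat(sprintf("  bridged  : %d pixel(s)\n", sum(object@bridged@.Data)))
  cat(sprintf("  segmented: %d pixel(s)\n", sum(object@segmented@.Data)))
})

setMethod("show", "ConfusionCounts", function(object) {
  cat(sprintf("ConfusionCounts: TP=%d FP=%d TN=%d FN=%d (n=%d)\n",
              object@tp, object@fp, object@tn, object@fn,
              object@tp + object@fp + object@tn + object@fn))
})

setMethod("show", "VesselFixture", function(object) {
  cat(sprintf("VesselFixture %d x %d: %d truth px, %d observed px, %d gap(s), %d noise px\n",
              nrow(object@truth), ncol(object@truth), sum(object@truth@.Data),
              sum(object@observed@.Data), length(object@gaps),
              nrow(object@noise)))
})

# ---- accessors ----

#' Accessors for result and fixture objects
#'
#' `scores()`, `bridged()`, `segmented()` extract the slots of an
#' [LSCFResult-class]; `fixtureTruth()`, `fixtureObserved()`, `fixtureGaps()`
#' and `fixtureNoise()` extract the slots of a [VesselFixture-class].
#'
#' @param x the object.
#' @return the corresponding slot.
#' @name accessors
NULL

#' @rdname accessors
#' @export
scores <- function(x) x@scores

#' @rdname accessors
#' @export
bridged <- function(x) x@bridged

#' @rdname accessors
#' @export
segmented <- function(x) x@segmented

#' @rdname accessors
#' @export
fixtureTruth <- function(x) x@truth

#' @rdname accessors
#' @export
fixtureObserved <- function(x) x@observed

#' @rdname accessors
#' @export
fixtureGaps <- function(x) x@gaps

#' @rdname accessors
#' @export
fixtureNoise <- function(x) x@noise
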
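#' Rodrigues distance between pixel coordinates
#'
#' Weighted sum of a Minkowski term and a Chebyshev term,
#' \eqn{w_1 (\sum_i |a_i-b_i|^p)^{1/p} + w_2 \max_i |a_i-b_i|},
#' evaluated in two dimensions. With w1 = w2 = p = 1 this is the metric
#' whose unit balls give the classic 4- and 8-neighborhoods at thresholds
#' 2 and 3.
#'
#' @param a,b length-2 numeric vectors (row, col), or matrices with two
#'   columns for vectorized evaluation.
#' @param spec a [NeighborhoodSpec-class] carrying w1, w2 and p.
#' @return nonnegative numeric distance(s).
#' @examples
#' rodriguesDistance(c(0, 0), c(1, 1), NeighborhoodSpec())  # 3
#' @export
rodriguesDistance <- function(a, b, spec = NeighborhoodSpec()) {
  stopifnot(is(spec, "NeighborhoodSpec"))
  if (is.null(dim(a))) a <- matrix(a, ncol = 2)
  if (is.null(dim(b))) b <- matrix(b, ncol = 2)
  d <- abs(a - b)
  mink <- (d[, 1]^spec@p + d[, 2]^spec@p)^(1 / spec@p)
  cheb <- pmax(d[, 1], d[, 2])
  as.numeric(spec@w1 * mink + spec@w2 * cheb)
}

# clockwise angle from North (up = decreasing row), in [0, 360)
.offsetAngle <- function(drow, dcol) {
  a <- atan2(dcol, -drow) * 180 / pi
  ifelse(a < 0, a + 360, a)
}

#' Enumerate neighborhood offsets in deterministic order
#'
#' Returns every nonzero (drow, dcol) offset whose Rodrigues distance from
#' the origin is at most `spec@radius`, ordered clockwise starting from
#' North (N, NE, E, SE, S, SW, W, NW for the 8-neighborhood), ties at equal
#' angle broken by increasing distance. When `momentum` is given, the
#' sequence is rotated so that the offset equal to `momentum` comes first —
#' the traversal's "brush stroke" preference for continuing in the direction
#' of its previous move.
#'
#' @param spec a [NeighborhoodSpec-class].
#' @param momentum `NULL`, or a length-2 integer offset that must be a
#'   member of the offset set.
#' @return integer matrix with columns `drow`, `dcol`.
#' @examples
#' neighborhoodOffsets(NeighborhoodSpec(radius = 2))  # the 4-neighborhood
#' @export
neighborhoodOffsets <- function(spec = NeighborhoodSpec(), momentum = NULL) {
  stopifnot(is(spec, "NeighborhoodSpec"))
  r <- ceiling(spec@radius)
  g <- expand.grid(drow = -r:r, dcol = -r:r)
  g <- g[!(g$drow == 0 & g$dcol == 0), , drop = FALSE]
  d <- rodriguesDistance(cbind(g$drow, g$dcol),
                         matrix(0, nrow(g), 2), spec)
  g <- g[d <= spec@radius, , drop = FALSE]
  if (nrow(g) == 0L) stop("radius too small: empty neighborhood")
  ang <- .offsetAngle(g$drow, g$dcol)
  mag <- pmax(abs(g$drow), abs(g$dcol))
  g <- g[order(ang, mag), , drop = FALSE]
  off <- cbind(drow = as.integer(g$drow), dcol = as.integer(g$dcol))
  rownames(off) <- NULL
  if (!is.null(momentum)) {
    i <- which(off[, 1] == momentum[1] & off[, 2] == momentum[2])
    if (length(i) != 1L) stop("momentum must be one of the neighborhood offsets")
    if (i > 1L) off <- off[c(i:nrow(off), 1:(i - 1L)), , drop = FALSE]
  }
  off
}
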
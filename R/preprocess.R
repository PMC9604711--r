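#' Extract the green channel of an RGB image
#'
#' Fundus vessels show the highest contrast in the green channel, the
#' standard gray conversion in the vessel-segmentation literature. A
#' single-channel input is returned unchanged; 2- or >4-channel inputs are
#' rejected as ambiguous. A 4th (alpha) channel is ignored.
#'
#' @param img a [GrayImage-class], a matrix, or an h x w x channels array
#'   of 8-bit values.
#' @return a [GrayImage-class] of the green-channel values.
#' @export
extractGreenChannel <- function(img) {
  if (is(img, "GrayImage")) return(img)
  if (is.matrix(img)) return(GrayImage(img))
  d <- dim(img)
  if (length(d) != 3L || !(d[3] %in% c(3L, 4L)))
    stop(sprintf("expected 1, 3 or 4 channels, got an array of shape %s",
                 paste(d, collapse = " x ")))
  GrayImage(img[, , 2L])
}

.gaussianKernel1d <- function(sigma) {
  r <- max(1L, ceiling(3 * sigma))
  x <- (-r):r
  g <- exp(-x^2 / (2 * sigma^2))
  g / sum(g)
}

# separable Gaussian smoothing with replicated borders
.gaussSmooth <- function(m, sigma) {
  g <- .gaussianKernel1d(sigma)
  r <- (length(g) - 1L) %/% 2L
  pad <- function(x, n) x[c(rep(1L, n), seq_along(x), rep(length(x), n))]
  # rows
  m1 <- apply(m, 2L, function(col) {
    as.numeric(stats::filter(pad(col, r), g, sides = 2))[(r + 1L):(r + length(col))]
  })
  t(apply(m1, 1L, function(row) {
    as.numeric(stats::filter(pad(row, r), g, sides = 2))[(r + 1L):(r + length(row))]
  }))
}

# multiscale Hessian-eigenvalue vesselness for bright ridges on dark
# background (classic beta/c formulation); scale-normalized second
# derivatives by central differences of the smoothed image
.hessianVesselness <- function(m, scales, beta, gamma) {
  nr <- nrow(m); nc <- ncol(m)
  best <- matrix(0, nr, nc)
  for (s in scales) {
    sm <- .gaussSmooth(m, s)
    shift <- function(x, dr, dc) {
      ri <- pmin(pmax(seq_len(nr) + dr, 1L), nr)
      ci <- pmin(pmax(seq_len(nc) + dc, 1L), nc)
      x[ri, ci, drop = FALSE]
    }
    dxx <- shift(sm, 1, 0) - 2 * sm + shift(sm, -1, 0)
    dyy <- shift(sm, 0, 1) - 2 * sm + shift(sm, 0, -1)
    dxy <- (shift(sm, 1, 1) + shift(sm, -1, -1) -
            shift(sm, 1, -1) - shift(sm, -1, 1)) / 4
    s2 <- s^2
    dxx <- dxx * s2; dyy <- dyy * s2; dxy <- dxy * s2
    tmp <- sqrt((dxx - dyy)^2 + 4 * dxy^2)
    l1 <- (dxx + dyy + tmp) / 2
    l2 <- (dxx + dyy - tmp) / 2
    # order by |lambda|: lam2 = larger magnitude
    swap <- abs(l1) > abs(l2)
    lam1 <- ifelse(swap, l2, l1)
    lam2 <- ifelse(swap, l1, l2)
    rb2 <- (lam1 / ifelse(lam2 == 0, 1, lam2))^2
    st2 <- lam1^2 + lam2^2
    v <- exp(-rb2 / (2 * beta^2)) * (1 - exp(-st2 / (2 * gamma^2)))
    v[lam2 > 0] <- 0  # bright ridge: dominant curvature negative
    best <- pmax(best, v)
  }
  best
}

#' Multiscale vesselness response
#'
#' Computes a multiscale Hessian-eigenvalue vesselness response (Gaussian
#' scale space, eigenvalue blobness/structureness formulation) and rescales
#' it linearly from its native real range to 8 bits (minimum to 0, maximum
#' to 255; a constant response maps to all zeros). With
#' `params@invert = TRUE` the input is negated first, so dark vessels on a
#' bright background (fundus green channel) become bright ridges. A
#' user-supplied engine honoring the same contract (numeric matrix in,
#' numeric matrix out, larger = more vessel-like) may replace the built-in
#' filter via `fun`.
#'
#' @param gray a [GrayImage-class] or numeric matrix.
#' @param params a [FrangiParams-class].
#' @param fun optional replacement engine, called as `fun(matrix)`.
#' @return a [GrayImage-class] vesselness response.
#' @export
computeVesselness <- function(gray, params = FrangiParams(), fun = NULL) {
  m <- if (is(gray, "GrayImage")) gray@.Data else as.matrix(gray)
  m <- m * 1.0
  stopifnot(is(params, "FrangiParams"))
  if (params@invert) m <- 255 - m
  v <- if (is.null(fun)) {
    .hessianVesselness(m, seq(params@scaleMin, params@scaleMax,
                              by = params@scaleStep),
                       params@beta, params@gamma)
  } else {
    fun(m)
  }
  rng <- range(v)
  if (rng[2] > rng[1]) {
    v <- (v - rng[1]) / (rng[2] - rng[1]) * 255
  } else {
    v <- matrix(0, nrow(v), ncol(v))
  }
  GrayImage(round(v))
}

#' Threshold a gray image into a binary mask
#'
#' Pixels strictly greater than `level` (the default, matching the
#' fixed gray-level-100 rule) — or `>= level` with `strict = FALSE` —
#' become foreground.
#'
#' @param img a [GrayImage-class] or numeric matrix.
#' @param level integer threshold in [0, 255].
#' @param strict keep values strictly greater than `level` (default);
#'   otherwise greater-or-equal.
#' @return a [BinaryMask-class].
#' @export
binarize <- function(img, level = 100L, strict = TRUE) {
  m <- if (is(img, "GrayImage")) img@.Data else as.matrix(img)
  stopifnot(level >= 0, level <= 255)
  BinaryMask(if (strict) m > level else m >= level)
}
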
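# evaluate expr under a fixed seed, restoring the caller's RNG state
.withSeed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

# sample one integer from an inclusive range (safe when min == max)
.sampleRange <- function(rng) {
  lo <- rng[1]; hi <- rng[length(rng)]
  if (lo >= hi) return(as.integer(lo))
  lo + sample.int(hi - lo + 1L, 1L) - 1L
}

# the 8 principal step directions, clockwise from North
.DIRS8 <- rbind(c(-1L, 0L), c(-1L, 1L), c(0L, 1L), c(1L, 1L),
                c(1L, 0L), c(1L, -1L), c(0L, -1L), c(-1L, -1L))

.stampDisk <- function(mask, r, c, radius) {
  nr <- nrow(mask); nc <- ncol(mask)
  ri <- max(1L, r - radius):min(nr, r + radius)
  ci <- max(1L, c - radius):min(nc, c + radius)
  mask[ri, ci] <- TRUE
  mask
}

#' Generate a synthetic binary vessel tree
#'
#' Draws `nBranches` correlated random walks ("branches") of the requested
#' lengths and widths: the first branch starts at a random interior point,
#' later branches start from a random point of an earlier branch, emulating
#' a bifurcating vessel tree as it appears in thresholded vesselness
#' responses. Each step moves one pixel along one of the 8 principal
#' directions and turns by 45 degrees with probability `turnProb`; the
#' branch is stamped as a square of the branch's width centered on the
#' centerline. Fully deterministic for a fixed seed.
#'
#' The returned mask carries the centerline paths and widths as attributes
#' `centerlines` (list of (row, col) integer matrices) and `widths`;
#' [punchGaps()] uses them to cut gaps along branch directions.
#'
#' @param imageSize integer (height, width).
#' @param nBranches number of branches, >= 1.
#' @param branchLength integer (min, max) centerline length in pixels.
#' @param widthRange integer (min, max) branch width in pixels (odd widths
#'   render symmetrically).
#' @param turnProb per-step probability of a 45-degree turn.
#' @param seed RNG seed.
#' @return a [BinaryMask-class] with `centerlines`/`widths` attributes.
#' @export
generateVesselTree <- function(imageSize = c(96L, 96L), nBranches = 4L,
                               branchLength = c(30L, 60L),
                               widthRange = c(1L, 1L), turnProb = 0.15,
                               seed = 1L) {
  stopifnot(length(imageSize) == 2L, all(imageSize >= 16L), nBranches >= 1L)
  .withSeed(seed, {
    nr <- as.integer(imageSize[1]); nc <- as.integer(imageSize[2])
    mask <- matrix(FALSE, nr, nc)
    margin <- 3L
    centerlines <- list()
    widths <- integer(0)
    for (b in seq_len(nBranches)) {
      len <- .sampleRange(branchLength)
      w <- .sampleRange(widthRange)
      rad <- (w - 1L) %/% 2L
      if (b == 1L || length(centerlines) == 0L) {
        r <- .sampleRange(c(margin + 1L, nr - margin))
        c <- .sampleRange(c(margin + 1L, nc - margin))
      } else {
        parent <- centerlines[[sample(length(centerlines), 1L)]]
        at <- parent[sample(nrow(parent), 1L), ]
        r <- at[1]; c <- at[2]
      }
      dir <- sample(8L, 1L)
      path <- matrix(0L, len, 2L)
      n <- 0L
      for (s in seq_len(len)) {
        if (stats::runif(1) < turnProb)
          dir <- ((dir - 1L + sample(c(-1L, 1L), 1L)) %% 8L) + 1L
        # deflect off the border instead of truncating the branch
        turns <- 0L
        repeat {
          nr2 <- r + .DIRS8[dir, 1]; nc2 <- c + .DIRS8[dir, 2]
          inside <- nr2 > margin && nr2 <= nr - margin &&
                    nc2 > margin && nc2 <= nc - margin
          if (inside || turns >= 8L) break
          dir <- (dir %% 8L) + 1L
          turns <- turns + 1L
        }
        if (!inside) break
        r <- nr2; c <- nc2
        n <- n + 1L
        path[n, ] <- c(r, c)
        mask <- .stampDisk(mask, r, c, rad)
      }
      if (n >= 2L) {
        centerlines[[length(centerlines) + 1L]] <- path[seq_len(n), , drop = FALSE]
        widths <- c(widths, w)
      }
    }
    if (!any(mask)) { # degenerate draw: fall back to a straight segment
      mask[nr %/% 2L, (margin + 1L):(nc - margin)] <- TRUE
      centerlines <- list(cbind(nr %/% 2L, (margin + 1L):(nc - margin)))
      widths <- 1L
    }
    out <- BinaryMask(mask)
    attr(out, "centerlines") <- centerlines
    attr(out, "widths") <- widths
    out
  })
}

#' Punch gaps into a vessel tree
#'
#' Removes `nGaps` runs of foreground pixels along branch directions,
#' recording the exact removed pixels, so gap-bridging can be scored
#' against known ground truth. Gap sites are sampled on the centerlines
#' recorded by [generateVesselTree()], away from branch endpoints and from
#' one another; the removed set is the band of the branch's width around
#' the chosen centerline run, so the geometric gap length matches the
#' requested length.
#'
#' @param mask a [BinaryMask-class] produced by [generateVesselTree()]
#'   (must carry the `centerlines` attribute).
#' @param nGaps number of gaps, >= 0.
#' @param gapLength integer (min, max) gap length in pixels.
#' @param seed RNG seed.
#' @return a [VesselFixture-class] (`truth` = input, `observed` = input
#'   minus gap pixels, `gaps` = removed pixels per gap).
#' @export
punchGaps <- function(mask, nGaps = 4L, gapLength = c(2L, 3L), seed = 1L) {
  stopifnot(is(mask, "BinaryMask"))
  cl <- attr(mask, "centerlines")
  if (is.null(cl)) stop("mask must carry the centerlines recorded by generateVesselTree()")
  widths <- attr(mask, "widths")
  truth <- mask@.Data
  if (!any(truth)) stop("mask is empty: nothing to punch")
  .withSeed(seed, {
    observed <- truth
    gaps <- list()
    used <- lapply(cl, function(p) rep(FALSE, nrow(p)))
    tries <- 0L
    while (length(gaps) < nGaps && tries < 200L) {
      tries <- tries + 1L
      b <- sample(length(cl), 1L, prob = vapply(cl, nrow, 1L))
      path <- cl[[b]]
      len <- .sampleRange(gapLength)
      lo <- len + 3L; hi <- nrow(path) - len - 3L
      if (hi < lo) next
      pos <- .sampleRange(c(lo, hi))
      span <- pos:(pos + len - 1L)
      guard <- max(1L, pos - len - 2L):min(nrow(path), pos + 2L * len + 2L)
      if (any(used[[b]][guard])) next
      rad <- (widths[b] - 1L) %/% 2L
      rem <- NULL
      for (s in span) {
        r <- path[s, 1]; c <- path[s, 2]
        ri <- max(1L, r - rad):min(nrow(observed), r + rad)
        ci <- max(1L, c - rad):min(ncol(observed), c + rad)
        g <- expand.grid(row = ri, col = ci)
        rem <- rbind(rem, as.matrix(g[observed[as.matrix(g)], , drop = FALSE]))
      }
      if (is.null(rem) || nrow(rem) == 0L) next
      rem <- unique(rem)
      observed[rem] <- FALSE
      used[[b]][span] <- TRUE
      attr(rem, "length") <- len
      gaps[[length(gaps) + 1L]] <- rem
    }
    if (length(gaps) < nGaps)
      stop(sprintf("could only place %d of %d requested gaps; mask too small",
                   length(gaps), nGaps))
    new("VesselFixture", truth = BinaryMask(truth),
        observed = BinaryMask(observed), gaps = gaps,
        noise = matrix(integer(0), 0L, 2L,
                       dimnames = list(NULL, c("row", "col"))))
  })
}

#' Add isolated salt noise to a mask
#'
#' Injects single-pixel foreground noise at the given density, emulating
#' the speckle of a noisy thresholded vesselness response. Candidate
#' positions within Chebyshev distance `margin` of any existing foreground
#' pixel (or of an already placed noise pixel) are rejected, so every noise
#' pixel is isolated under 8-adjacency; a larger margin keeps the clutter
#' clear of the vasculature (e.g. beyond an intended bridging radius).
#' Deterministic per seed.
#'
#' @param mask a [BinaryMask-class] (or logical matrix).
#' @param density fraction of all pixels to turn into noise, in [0, 1].
#' @param seed RNG seed.
#' @param margin minimum Chebyshev distance to other foreground, >= 1.
#' @return a [BinaryMask-class] with the added pixels recorded in the
#'   `noise` attribute (an integer (row, col) matrix).
#' @export
addSaltNoise <- function(mask, density = 0.01, seed = 1L, margin = 2L) {
  m <- .asMaskMatrix(mask)
  stopifnot(density >= 0, density <= 1, margin >= 1)
  .withSeed(seed, {
    nr <- nrow(m); nc <- ncol(m)
    n <- round(density * nr * nc)
    pts <- matrix(integer(0), 0L, 2L, dimnames = list(NULL, c("row", "col")))
    if (n > 0L) {
      # candidate pool: background clear of foreground by `margin`
      far <- !.dilateSquare(m, margin)
      cand <- which(far)
      cand <- cand[sample.int(length(cand))]
      taken <- matrix(FALSE, nr, nc)
      for (idx in cand) {
        if (nrow(pts) >= n) break
        r <- ((idx - 1L) %% nr) + 1L
        c <- ((idx - 1L) %/% nr) + 1L
        ri <- max(1L, r - margin):min(nr, r + margin)
        ci <- max(1L, c - margin):min(nc, c + margin)
        if (any(taken[ri, ci])) next
        taken[r, c] <- TRUE
        pts <- rbind(pts, c(r, c))
      }
      m[pts] <- TRUE
    }
    out <- BinaryMask(m)
    attr(out, "noise") <- pts
    out
  })
}

# binary dilation by a (2r+1) square, zero-padded
.dilateSquare <- function(m, r) {
  out <- m
  for (dr in -r:r) for (dc in -r:r) {
    if (dr == 0 && dc == 0) next
    sh <- matrix(FALSE, nrow(m), ncol(m))
    rs <- max(1, 1 + dr):min(nrow(m), nrow(m) + dr)
    cs <- max(1, 1 + dc):min(ncol(m), ncol(m) + dc)
    sh[rs, cs] <- m[rs - dr, cs - dc]
    out <- out | sh
  }
  out
}

#' Two-segment gap fixture at a principal orientation
#'
#' Builds two collinear one-pixel-wide segments separated by a gap of known
#' length along one of the 8 principal directions — the elementary test
#' case for gap bridging. `truth` is the unbroken line, `observed` omits
#' the gap pixels.
#'
#' @param gapLength gap length in pixels, >= 1.
#' @param orientation integer 1..8, clockwise from North.
#' @param segLength pixels per segment, >= 2.
#' @param pad background border around the line, >= 1.
#' @return list with `observed`, `truth` ([BinaryMask-class]) and `gap`
#'   (integer (row, col) matrix of the punched pixels).
#' @export
segmentGapFixture <- function(gapLength, orientation, segLength = 5L,
                              pad = 6L) {
  stopifnot(gapLength >= 1, orientation %in% 1:8, segLength >= 2, pad >= 1)
  d <- .DIRS8[orientation, ]
  total <- 2L * segLength + gapLength
  ext <- (total - 1L)
  nr <- ext * abs(d[1]) + 2L * pad + 1L
  nc <- ext * abs(d[2]) + 2L * pad + 1L
  r0 <- if (d[1] >= 0) pad + 1L else pad + 1L + ext
  c0 <- if (d[2] >= 0) pad + 1L else pad + 1L + ext
  ks <- 0:(total - 1L)
  rows <- r0 + ks * d[1]; cols <- c0 + ks * d[2]
  truth <- matrix(FALSE, nr, nc)
  truth[cbind(rows, cols)] <- TRUE
  gapIdx <- (segLength + 1L):(segLength + gapLength)
  observed <- truth
  observed[cbind(rows[gapIdx], cols[gapIdx])] <- FALSE
  list(observed = BinaryMask(observed), truth = BinaryMask(truth),
       gap = cbind(row = rows[gapIdx], col = cols[gapIdx]))
}

#' Simulate a degraded vessel fixture
#'
#' Convenience composition of [generateVesselTree()], [punchGaps()] and
#' [addSaltNoise()]: a vessel tree with punched gaps and isolated salt
#' noise, with all degradations recorded. The noise margin defaults to 6
#' pixels so the clutter sits beyond the default bridging radius — the
#' regime in which noise removal and gap bridging can be scored
#' independently.
#'
#' @inheritParams generateVesselTree
#' @inheritParams punchGaps
#' @param noiseDensity salt-noise density.
#' @param noiseMargin Chebyshev clearance of noise from other foreground.
#' @return a [VesselFixture-class].
#' @export
simulateVesselFixture <- function(seed = 1L, imageSize = c(96L, 96L),
                                  nBranches = 4L, branchLength = c(30L, 60L),
                                  widthRange = c(1L, 1L), turnProb = 0.15,
                                  nGaps = 3L, gapLength = c(2L, 3L),
                                  noiseDensity = 0.005, noiseMargin = 6L) {
  tree <- generateVesselTree(imageSize, nBranches, branchLength, widthRange,
                             turnProb, seed = seed)
  fx <- punchGaps(tree, nGaps, gapLength, seed = seed + 1L)
  noisy <- addSaltNoise(fixtureObserved(fx), noiseDensity, seed = seed + 2L,
                        margin = noiseMargin)
  new("VesselFixture", truth = fixtureTruth(fx), observed = noisy,
      gaps = fixtureGaps(fx), noise = attr(noisy, "noise"))
}
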
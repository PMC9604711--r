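test_that("Rodrigues distance matches hand-evaluated cases", {
  spec <- NeighborhoodSpec()
  expect_equal(rodriguesDistance(c(5, 7), c(5, 7), spec), 0)
  expect_equal(rodriguesDistance(c(0, 0), c(0, 1), spec), 2)
  expect_equal(rodriguesDistance(c(0, 0), c(1, 1), spec), 3)
  # degenerate weights recover the pure Chebyshev / Minkowski terms
  expect_equal(rodriguesDistance(c(0, 0), c(2, 3), NeighborhoodSpec(w1 = 0, w2 = 1)), 3)
  expect_equal(rodriguesDistance(c(0, 0), c(3, 4), NeighborhoodSpec(w1 = 1, w2 = 0, p = 2)), 5)
})

test_that("Rodrigues distance is a symmetric nonnegative form vanishing iff equal", {
  set.seed(42)
  specs <- list(NeighborhoodSpec(), NeighborhoodSpec(w1 = 0.5, w2 = 2, p = 2),
                NeighborhoodSpec(w1 = 2, w2 = 0, p = 3))
  for (spec in specs) {
    a <- matrix(sample(-20:20, 100, replace = TRUE), ncol = 2)
    b <- matrix(sample(-20:20, 100, replace = TRUE), ncol = 2)
    expect_equal(rodriguesDistance(a, b, spec), rodriguesDistance(b, a, spec))
    expect_true(all(rodriguesDistance(a, b, spec) >= 0))
    expect_true(all(rodriguesDistance(a, a, spec) == 0))
    same <- rodriguesDistance(a, b, spec) == 0
    expect_equal(same, rowSums(a != b) == 0)
  }
})

test_that("unit-weight offsets give the 4- and 8-neighborhoods in canonical order", {
  o4 <- neighborhoodOffsets(NeighborhoodSpec(radius = 2))
  expect_equal(unname(o4), rbind(c(-1L, 0L), c(0L, 1L), c(1L, 0L), c(0L, -1L)))
  o8 <- neighborhoodOffsets(NeighborhoodSpec(radius = 3))
  expect_equal(unname(o8),
               rbind(c(-1L, 0L), c(-1L, 1L), c(0L, 1L), c(1L, 1L),
                     c(1L, 0L), c(1L, -1L), c(0L, -1L), c(-1L, -1L)))
})

test_that("offset enumeration agrees with brute force and is negation-closed", {
  for (spec in list(NeighborhoodSpec(radius = 2), NeighborhoodSpec(radius = 3),
                    NeighborhoodSpec(radius = 4.5),
                    NeighborhoodSpec(w1 = 0, w2 = 1, radius = 2))) {
    off <- neighborhoodOffsets(spec)
    r <- ceiling(spec@radius)
    g <- as.matrix(expand.grid(-r:r, -r:r))
    g <- g[rowSums(g != 0) > 0, , drop = FALSE]
    keep <- g[rodriguesDistance(g, 0 * g, spec) <= spec@radius, , drop = FALSE]
    expect_setequal(paste(off[, 1], off[, 2]), paste(keep[, 1], keep[, 2]))
    # closed under negation
    expect_setequal(paste(off[, 1], off[, 2]), paste(-off[, 1], -off[, 2]))
  }
})

test_that("momentum rotates the canonical order, momentum offset first", {
  spec <- NeighborhoodSpec(radius = 3)
  base <- neighborhoodOffsets(spec)
  for (i in seq_len(nrow(base))) {
    rot <- neighborhoodOffsets(spec, momentum = base[i, ])
    expect_equal(unname(rot[1, ]), unname(base[i, ]))
    expect_equal(unname(rot),
                 unname(base[((i - 1 + 0:7) %% 8) + 1, ]))
  }
  expect_error(neighborhoodOffsets(spec, momentum = c(2, 0)),
               "momentum")
})
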
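test_that("vessel-tree generation is reproducible and nonempty", {
  a <- generateVesselTree(seed = 12)
  b <- generateVesselTree(seed = 12)
  expect_identical(a@.Data, b@.Data)
  expect_gt(sum(a@.Data), 0)
  expect_false(identical(a@.Data, generateVesselTree(seed = 13)@.Data))
  expect_true(is.list(attr(a, "centerlines")))
})

test_that("a single straight branch is one component of its full length", {
  tr <- generateVesselTree(imageSize = c(64, 64), nBranches = 1,
                           branchLength = c(20, 20), widthRange = c(1, 1),
                           turnProb = 0, seed = 3)
  sc <- connectivityScores(tr)
  expect_equal(sum(tr@.Data), 20L)
  expect_equal(unique(sc@.Data[tr@.Data]), 20L)
})

test_that("wide branches cover their centerline neighborhood", {
  tr <- generateVesselTree(imageSize = c(64, 64), nBranches = 2,
                           branchLength = c(20, 30), widthRange = c(3, 3),
                           seed = 21)
  m <- tr@.Data
  for (path in attr(tr, "centerlines")) {
    for (i in seq_len(nrow(path))) {
      r <- path[i, 1]; c <- path[i, 2]
      expect_true(all(m[(r - 1):(r + 1), (c - 1):(c + 1)]),
                  info = sprintf("centerline (%d,%d)", r, c))
    }
  }
})

test_that("punched gaps remove recorded pixels and split components", {
  tr <- generateVesselTree(imageSize = c(64, 64), nBranches = 1,
                           branchLength = c(20, 20), widthRange = c(1, 1),
                           turnProb = 0, seed = 3)
  fx0 <- punchGaps(tr, nGaps = 0, seed = 1)
  expect_identical(fixtureObserved(fx0)@.Data, fixtureTruth(fx0)@.Data)
  fx <- punchGaps(tr, nGaps = 1, gapLength = c(2, 2), seed = 1)
  obs <- fixtureObserved(fx)@.Data
  gap <- fixtureGaps(fx)[[1]]
  expect_equal(nrow(gap), 2L)
  expect_false(any(obs[gap]))
  expect_true(all(fixtureTruth(fx)@.Data[gap]))
  sizes <- oracleComponentSizes(obs, 3)
  expect_equal(sum(obs), 18L)
  expect_equal(max(oracleComponentSizes(fixtureTruth(fx)@.Data, 3)), 20L)
  expect_lt(max(sizes), 20L) # the branch is split
  # reproducible placement
  fx2 <- punchGaps(tr, nGaps = 1, gapLength = c(2, 2), seed = 1)
  expect_identical(fixtureObserved(fx2)@.Data, obs)
  expect_error(punchGaps(BinaryMask(matrix(TRUE, 4, 4)), 1), "centerlines")
})

test_that("salt noise is isolated, recorded, reproducible and CF-removable", {
  tr <- generateVesselTree(seed = 5)
  expect_identical(addSaltNoise(tr, 0, seed = 1)@.Data, tr@.Data)
  noisy <- addSaltNoise(tr, 0.01, seed = 7)
  pts <- attr(noisy, "noise")
  expect_gt(nrow(pts), 50)
  m <- noisy@.Data
  sc <- connectivityScores(noisy)
  for (i in seq_len(nrow(pts))) {
    expect_equal(sc@.Data[pts[i, 1], pts[i, 2]], 1L)
  }
  # every noise pixel disappears under the default score threshold
  kept <- cfSegment(noisy)@.Data
  expect_false(any(kept[pts]))
  expect_identical(addSaltNoise(tr, 0.01, seed = 7)@.Data, m)
})

test_that("composite fixtures obey observed = truth - gaps + noise", {
  fx <- simulateVesselFixture(seed = 8)
  truth <- fixtureTruth(fx)@.Data
  obs <- fixtureObserved(fx)@.Data
  gapPx <- do.call(rbind, fixtureGaps(fx))
  noise <- fixtureNoise(fx)
  rebuilt <- truth
  rebuilt[gapPx] <- FALSE
  rebuilt[noise] <- TRUE
  expect_identical(obs, rebuilt)
  expect_false(any(truth[noise]))
})

test_that("two-segment gap fixtures have the stated geometry", {
  for (o in 1:8) {
    fx <- segmentGapFixture(2, o, segLength = 5)
    expect_equal(sum(fx$truth@.Data), 12L)
    expect_equal(sum(fx$observed@.Data), 10L)
    expect_equal(nrow(fx$gap), 2L)
    expect_false(any(fx$observed@.Data[fx$gap]))
    # observed splits into two components of 5
    expect_equal(sort(unique(as.vector(
      oracleComponentSizes(fx$observed@.Data, 3)))), c(0L, 5L))
  }
})
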
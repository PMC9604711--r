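test_that("zero tolerance or zero distance degenerates to the plain CF", {
  for (seed in 1:10) {
    m <- BinaryMask(randomMask(40, 40, 0.1 + 0.03 * seed, seed))
    cf <- cfSegment(m)
    for (p in list(LSCFParams(maxScore = 0), LSCFParams(maxDist = 0))) {
      r <- lsConnectivity(m, params = p)
      expect_identical(segmented(r)@.Data, cf@.Data)
      expect_false(any(bridged(r)@.Data))
      expect_identical(scores(r)@.Data, connectivityScores(m)@.Data)
    }
  }
})

test_that("a 2-pixel gap between collinear segments is bridged exactly", {
  m <- matrix(FALSE, 5, 12)
  m[3, 1:5] <- TRUE; m[3, 8:12] <- TRUE
  r <- lsConnectivity(BinaryMask(m))
  expect_equal(max(scores(r)@.Data), 12L) # 10 vessel + 2 bridge pixels
  expect_equal(which(bridged(r)@.Data, arr.ind = TRUE),
               cbind(row = c(3L, 3L), col = c(6L, 7L)), ignore_attr = TRUE)
  expect_true(all(scores(r)@.Data[m] == 12L))
  # bridge pixels carry the merged score and survive the threshold
  expect_true(all(segmented(r)@.Data[3, 6:7]))
})

test_that("a 6-pixel gap exceeds the default reach and stays open", {
  m <- matrix(FALSE, 7, 20)
  m[4, 1:5] <- TRUE; m[4, 12:16] <- TRUE
  r <- lsConnectivity(BinaryMask(m))
  expect_equal(max(scores(r)@.Data), 5L)
  expect_false(any(bridged(r)@.Data))
})

test_that("gaps up to maxDist are reconnected in all 8 orientations on the punched path", {
  for (gap in 1:3) {
    for (o in 1:8) {
      fx <- segmentGapFixture(gap, o)
      r <- lsConnectivity(fx$observed)
      expect_equal(max(scores(r)@.Data), 10L + gap,
                   info = sprintf("gap %d orientation %d", gap, o))
      got <- which(bridged(r)@.Data, arr.ind = TRUE)
      expect_setequal(paste(got[, 1], got[, 2]),
                      paste(fx$gap[, 1], fx$gap[, 2]))
      # thickness away from bridges unchanged
      seg <- segmented(r)@.Data
      expect_equal(seg & !bridged(r)@.Data, fx$observed@.Data)
    }
  }
})

test_that("bridging is monotone in the distance and tolerance budgets", {
  fx <- segmentGapFixture(3, 4) # diagonal, the widest unit-step case
  prev <- matrix(FALSE, nrow(fx$observed), ncol(fx$observed))
  for (d in c(1, 2, 3, 4, 6)) {
    b <- bridged(lsConnectivity(fx$observed, params = LSCFParams(maxDist = d)))@.Data
    expect_true(all(b[prev]), info = sprintf("maxDist %g", d))
    prev <- b
  }
  prev <- matrix(FALSE, nrow(fx$observed), ncol(fx$observed))
  for (s in c(0, 1, 2, 3, 350)) {
    b <- bridged(lsConnectivity(fx$observed,
                                params = LSCFParams(maxScore = s)))@.Data
    expect_true(all(b[prev]), info = sprintf("maxScore %d", s))
    prev <- b
  }
})

test_that("result invariants hold on degraded tree fixtures", {
  for (seed in c(2, 9, 17)) {
    fx <- simulateVesselFixture(seed = seed)
    obs <- fixtureObserved(fx)@.Data
    r <- lsConnectivity(BinaryMask(obs))
    expect_false(any(bridged(r)@.Data & obs))          # bridges are new pixels
    expect_true(all(obs[segmented(r)@.Data & !bridged(r)@.Data])) # no dilation
    sc <- scores(r)@.Data
    expect_true(all(sc[obs] >= 1L))
    expect_true(all(sc[!(obs | bridged(r)@.Data)] == 0L))
  }
})

test_that("the traversal is deterministic", {
  fx <- simulateVesselFixture(seed = 4)
  a <- lsConnectivity(fixtureObserved(fx))
  b <- lsConnectivity(fixtureObserved(fx))
  expect_identical(scores(a)@.Data, scores(b)@.Data)
  expect_identical(bridged(a)@.Data, bridged(b)@.Data)
  expect_identical(segmented(a)@.Data, segmented(b)@.Data)
})
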
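test_that("the cross structuring element is the radius-1 plus shape", {
  k <- crossKernel()
  expect_equal(k, rbind(c(0, 1, 0), c(1, 1, 1), c(0, 1, 0)))
  expect_equal(k, k[3:1, 3:1]) # symmetric about the origin
})

test_that("closing fills single-pixel holes and leaves small masks alone", {
  m <- matrix(FALSE, 5, 5)
  m[2:4, 2:4] <- TRUE; m[3, 3] <- FALSE
  cl <- morphClosing(BinaryMask(m))@.Data
  expect_true(cl[3, 3])
  expect_true(all(cl[m]))
  expect_false(any(morphClosing(BinaryMask(matrix(FALSE, 4, 4)))@.Data))
})

test_that("closing bridges 1-pixel but not 3-pixel collinear gaps", {
  # segments must be thick enough for erosion to keep the bridge (the
  # cross needs transverse support), so use 3-pixel-wide bars
  m1 <- matrix(FALSE, 5, 11); m1[2:4, 1:5] <- TRUE; m1[2:4, 7:11] <- TRUE
  cl1 <- morphClosing(BinaryMask(m1))@.Data
  expect_true(cl1[3, 6]) # the two bars are re-linked
  expect_equal(max(oracleComponentSizes(cl1, 3)), sum(cl1))
  m3 <- matrix(FALSE, 5, 13); m3[2:4, 1:5] <- TRUE; m3[2:4, 9:13] <- TRUE
  cl3 <- morphClosing(BinaryMask(m3))@.Data
  expect_false(any(cl3[, 7]))
  expect_lt(max(oracleComponentSizes(cl3, 3)), sum(cl3))
})

test_that("closing matches the set-arithmetic oracle and its lattice laws", {
  k <- crossKernel()
  for (seed in 1:10) {
    m <- randomMask(32, 32, 0.05 + 0.04 * seed, seed)
    cl <- morphClosing(BinaryMask(m))@.Data
    expect_equal(cl, oracleClosing(m, k), info = sprintf("seed %d", seed))
    expect_true(all(cl[m]))                                   # extensive
    expect_equal(morphClosing(BinaryMask(cl))@.Data, cl)      # idempotent
    m2 <- m; m2[sample(length(m2), 40)] <- TRUE               # superset
    expect_true(all(morphClosing(BinaryMask(m2))@.Data[cl]))  # monotone
  }
})

test_that("CF + closing composes the two stages in either order", {
  # isolated pixels die before the closing can act
  iso <- matrix(FALSE, 8, 8)
  iso[cbind(c(2, 5, 7), c(2, 5, 7))] <- TRUE
  expect_false(any(cfPlusClosing(BinaryMask(iso))@.Data))
  # an already-closed mask with a large component passes through
  solid <- matrix(FALSE, 8, 8); solid[3:6, 3:6] <- TRUE
  expect_equal(cfPlusClosing(BinaryMask(solid))@.Data, solid)
  # explicit composition identity, both orders
  m <- randomMask(32, 32, 0.25, 31)
  expect_equal(cfPlusClosing(BinaryMask(m))@.Data,
               morphClosing(cfSegment(BinaryMask(m)))@.Data)
  expect_equal(cfPlusClosing(BinaryMask(m), closingFirst = TRUE)@.Data,
               cfSegment(morphClosing(BinaryMask(m)))@.Data)
})

test_that("closing cannot re-link a 2-pixel gap that LS-CF bridges", {
  m <- matrix(FALSE, 5, 12)
  m[3, 1:5] <- TRUE; m[3, 8:12] <- TRUE
  closed <- cfPlusClosing(BinaryMask(m))@.Data
  expect_false(any(closed[3, 6:7]))             # still two pieces
  expect_equal(max(oracleComponentSizes(closed, 3)), 5L)
  seg <- lscfSegment(BinaryMask(m))@.Data
  expect_equal(max(oracleComponentSizes(seg, 3)), 12L) # one merged branch
})
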
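test_that("registering identical height maps yields the identity", {
  ph <- makePhantom(cleanPhantomSpec(seed = 31L))
  pair <- ph$pair
  ## replace the moving height map by the reference one
  refH <- getChannel(pair@ds1650, "Height")
  pair@ds1625 <- afmirib:::.setChannel(pair@ds1625,
    ChannelMap("Height", mapData(refH), "trace", "nm"))
  out <- registerPair(pair)
  expect_lt(max(abs(pairTransform(out) - diag(3))), 1e-3)
})

test_that("planted translation is recovered to subpixel accuracy", {
  ph <- makePhantom(cleanPhantomSpec(seed = 32L,
                                     interMapDrift = c(5, -3, 0)))
  out <- registerPair(ph$pair)
  A <- pairTransform(out)
  expect_lt(abs(A[1, 3] - 5), 0.25)
  expect_lt(abs(A[2, 3] + 3), 0.25)
})

test_that("the affine stage resolves shear that the rigid stage cannot", {
  ph <- makePhantom(cleanPhantomSpec(seed = 33L, size = 128L,
                                     interMapDrift = c(4, -2, 0.02)))
  support <- cellLabels(ph$truth) > 0
  rigid <- registerPair(ph$pair, refine = FALSE)
  full <- registerPair(ph$pair)
  resRigid <- meanResidualPx(pairTransform(rigid),
                             trueTransform(ph$truth), support)
  resFull <- meanResidualPx(pairTransform(full),
                            trueTransform(ph$truth), support)
  expect_lt(resFull, 0.5)
  expect_gt(resRigid, resFull)
})

test_that("flat height maps make registration unidentifiable", {
  ph <- makePhantom(cleanPhantomSpec(seed = 34L))
  pair <- ph$pair
  flat <- ChannelMap("Height", matrix(1, 96, 96), "trace", "nm")
  pair@ds1650 <- afmirib:::.setChannel(pair@ds1650, flat)
  expect_error(registerPair(pair), "unidentifiable")
})

test_that("PLL line correction cancels a pure ramp exactly with window 1", {
  ramp <- matrix(rep(0.01 * (0:63), 64), 64, 64)
  out <- correctPllMap(ramp, matrix(TRUE, 64, 64), rollingWindowLines = 1)
  expect_equal(out, matrix(0, 64, 64), tolerance = 1e-12)
  expect_error(correctPllMap(ramp, matrix(FALSE, 64, 64)), "empty")
  expect_error(correctPllMap(ramp, matrix(TRUE, 64, 64), 16), "odd")
})

test_that("PLL correction recovers an in-cell offset on top of line drift", {
  set.seed(35)
  h <- 96; w <- 96
  cell <- matrix(FALSE, h, w); cell[30:60, 35:70] <- TRUE
  delta <- 0.4
  ramp <- matrix(rep(2e-3 * (0:(h - 1)), w), h, w)
  noise <- matrix(stats::rnorm(h * w, 0, 0.05), h, w)
  pll <- 880 + ramp + delta * cell + noise
  out <- correctPllMap(pll, !cell, rollingWindowLines = 17)
  expect_equal(mean(out[cell]) - mean(out[!cell]), delta, tolerance = 0.04)
  ## per-line epoxy means sit within the noise floor
  lm <- vapply(seq_len(h), function(r) mean(out[r, !cell[r, ]]), numeric(1))
  nEp <- vapply(seq_len(h), function(r) sum(!cell[r, ]), numeric(1))
  expect_true(all(abs(lm) < 3 * 0.05 / sqrt(nEp)))
})

test_that("lines without epoxy pixels are interpolated and reported", {
  h <- 32; w <- 32
  mask <- matrix(TRUE, h, w)
  mask[10:12, ] <- FALSE                     # no epoxy on these lines
  ramp <- matrix(rep(0.05 * (0:(h - 1)), w), h, w)
  expect_message(out <- correctPllMap(ramp, mask, rollingWindowLines = 1),
                 "interpolated")
  ## linear interpolation reproduces the ramp on the gap lines
  expect_equal(out[10:12, ], matrix(0, 3, w), tolerance = 1e-12)
})

test_that("ratio map divides pixelwise and masks weak denominators", {
  a50 <- matrix(2, 32, 32)
  a25 <- 2 * a50
  rm <- ratioMap(a25, a50)
  expect_true(all(mapData(rm)[validMask(rm)] == 2))
  ## a zero denominator pixel is masked, not infinite
  a50z <- a50; a50z[5, 5] <- 0
  rmz <- ratioMap(a25, a50z, minDenominatorQuantile = 0)
  expect_false(validMask(rmz)[5, 5])
  expect_true(all(is.finite(mapData(rmz))))
  expect_error(ratioMap(matrix(1, 3, 3), matrix(1, 4, 4)), "shape")
})

test_that("ratio map recovers the planted enrichment within 2 percent", {
  ph <- makePhantom(cleanPhantomSpec(seed = 36L, betaEnrichmentTrue = 1.5))
  rm <- ratioMap(getChannel(ph$pair@ds1625, "IRAmplitude"),
                 getChannel(ph$pair@ds1650, "IRAmplitude"),
                 epoxyMask = cellLabels(ph$truth) == 0)
  ib <- ibLabels(ph$truth) > 0 & validMask(rm)
  cyto <- cellLabels(ph$truth) > 0 & ibLabels(ph$truth) == 0 & validMask(rm)
  est <- mean(mapData(rm)[ib]) / mean(mapData(rm)[cyto])
  expect_equal(est, 1.5, tolerance = 0.02)
})

test_that("resampling after registration masks out-of-frame pixels", {
  ph <- makePhantom(cleanPhantomSpec(seed = 37L,
                                     interMapDrift = c(8, 0, 0)))
  out <- registerPair(ph$pair)
  v <- validMask(getChannel(out@ds1625, "IRAmplitude"))
  expect_true(all(!v[, 89:96]))   # right edge maps outside the source
  ## interior stays valid (first/last rows may clip with the recovered dy)
  expect_true(all(v[3:94, 1:80]))
})
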
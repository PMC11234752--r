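rasterShape <- function(h, w, pred) {
  X <- matrix(rep(0:(w - 1), each = h), h, w)
  Y <- matrix(rep(0:(h - 1), times = w), h, w)
  pred(X, Y)
}

test_that("cell geometry: rectangles, disks and rotation", {
  rect <- rasterShape(40, 40, function(X, Y)
    X >= 10 & X <= 29 & Y >= 17 & Y <= 22)   # 20 x 6 px, axis-aligned
  geo <- cellGeometry(rect)
  expect_equal(geo$orientation, 0, tolerance = 1e-9)
  expect_equal(geo$majorLength, 20)
  expect_equal(geo$area, 120)
  ## disk: degenerate orientation flagged, extent equals the diameter
  disk <- rasterShape(40, 40, function(X, Y) (X - 20)^2 + (Y - 20)^2 <= 81)
  gd <- cellGeometry(disk)
  expect_true(gd$degenerate)
  expect_equal(gd$majorLength, 19)
  ## rectangle rotated by 30 degrees: orientation within 2 degrees
  th <- 30 * pi / 180
  rot <- rasterShape(64, 64, function(X, Y) {
    u <- (X - 32) * cos(th) + (Y - 32) * sin(th)
    v <- -(X - 32) * sin(th) + (Y - 32) * cos(th)
    abs(u) <= 14 & abs(v) <= 4
  })
  gr <- cellGeometry(rot)
  expect_lt(abs(gr$orientation - th) * 180 / pi, 2)
  expect_error(cellGeometry(matrix(FALSE, 4, 4)), "empty")
})

test_that("polar position: centre, pole tip, and mirror antisymmetry", {
  rect <- rasterShape(40, 40, function(X, Y)
    X >= 10 & X <= 29 & Y >= 17 & Y <= 22)
  geo <- cellGeometry(rect)
  expect_equal(polarPosition(geo$centroid, geo)$position, 0)
  ## right-hand pole tip projects to +1
  expect_equal(polarPosition(c(29, 19.5), geo)$position, 1)
  expect_equal(polarPosition(c(10, 19.5), geo)$position, -1)
  ## mirror flip of the image negates the position
  rectM <- rect[, 40:1]
  geoM <- cellGeometry(rectM)
  p <- polarPosition(c(12, 19.5), geo)$position
  pM <- polarPosition(c(39 - 12, 19.5), geoM)$position
  expect_equal(pM, -p)
  ## degenerate cells return 0 with a flag
  disk <- rasterShape(20, 20, function(X, Y) (X - 10)^2 + (Y - 10)^2 <= 16)
  pd <- polarPosition(c(12, 10), cellGeometry(disk))
  expect_true(pd$degenerate)
  expect_equal(pd$position, 0)
})

test_that("feature extraction recovers enrichment and PLL offset", {
  ph <- makePhantom(cleanPhantomSpec(seed = 51L, nCells = 3L,
                                     betaEnrichmentTrue = 1.4,
                                     pllOffsetIbKhz = 0.5))
  pair <- identityRegistered(ph$pair)
  f <- extractIbFeatures(pair, truthSegmentation(ph$truth))
  expect_gt(nrow(f$ibs), 0)
  m <- mean(f$ibs$beta_enrichment)
  expect_gte(m, 1.37); expect_lte(m, 1.43)
  mp <- mean(f$ibs$pll_diff)
  expect_gte(mp, 0.45); expect_lte(mp, 0.55)
  ## invariants on the table
  expect_true(all(f$ibs$beta_enrichment > 0))
  expect_true(all(abs(f$ibs$polar_position) <= 1))
  expect_equal(f$ibs$pll_diff, f$ibs$pll_ib - f$ibs$pll_cp)
  expect_equal(f$ibs$pole_proximity, abs(f$ibs$polar_position))
  ## per-cell counts add up to the number of IB labels
  expect_equal(sum(f$cells$n_ibs), max(ibLabels(ph$truth)))
})

test_that("cells without IBs appear with n_ibs = 0", {
  ph <- makePhantom(cleanPhantomSpec(seed = 52L, nCells = 3L,
                                     ibCountRange = c(0L, 0L)))
  pair <- identityRegistered(ph$pair)
  f <- extractIbFeatures(pair, truthSegmentation(ph$truth))
  expect_equal(nrow(f$ibs), 0)
  expect_equal(nrow(f$cells), 3)
  expect_true(all(f$cells$n_ibs == 0))
})

test_that("enrichment is invariant to global amplitude rescaling", {
  ph <- makePhantom(cleanPhantomSpec(seed = 53L, betaEnrichmentTrue = 1.3))
  pair <- identityRegistered(ph$pair)
  f0 <- extractIbFeatures(pair, truthSegmentation(ph$truth))
  scaled <- pair
  cm <- getChannel(scaled@ds1625, "IRAmplitude")
  scaled@ds1625 <- afmirib:::.setChannel(scaled@ds1625,
    ChannelMap("IRAmplitude", 37 * mapData(cm), "trace", "a.u."))
  f1 <- extractIbFeatures(scaled, truthSegmentation(ph$truth))
  expect_equal(f1$ibs$beta_enrichment, f0$ibs$beta_enrichment,
               tolerance = 1e-9)
})

test_that("estimated enrichment regresses on truth with slope 1", {
  enr <- seq(1.0, 2.0, length.out = 20)
  est <- vapply(seq_along(enr), function(i) {
    ph <- makePhantom(cleanPhantomSpec(seed = 600L + i,
                                       betaEnrichmentTrue = enr[i]))
    pair <- identityRegistered(ph$pair)
    f <- extractIbFeatures(pair, truthSegmentation(ph$truth))
    mean(f$ibs$beta_enrichment)
  }, numeric(1))
  fit <- stats::coef(stats::lm(est ~ enr))
  expect_lt(abs(fit[2] - 1), 0.05)
  expect_lt(abs(fit[1]), 0.05)
})

test_that("edge profile is a step for sharp IBs and ordered by enrichment", {
  ph <- makePhantom(cleanPhantomSpec(seed = 54L, nCells = 2L,
                                     ibRadiusRangePx = c(4, 6),
                                     betaEnrichmentTrue = 1.5))
  pair <- identityRegistered(ph$pair)
  prof <- edgeDistanceProfile(pair, truthSegmentation(ph$truth),
                              nBoot = 199)
  px <- pixelSizeNm(pair)
  inside <- prof$mean_ratio[prof$distance_nm > px]
  outside <- prof$mean_ratio[prof$distance_nm < -px &
                               prof$distance_nm > -6 * px]
  expect_true(all(min(inside) > max(outside)))
  ## the transition occupies at most two bins around zero
  far <- mean(prof$mean_ratio[prof$distance_nm > 2 * px])
  near <- mean(prof$mean_ratio[prof$distance_nm < -2 * px &
                                 prof$distance_nm > -6 * px])
  mid <- prof$mean_ratio[abs(prof$distance_nm) <= px]
  expect_true(all(mid >= near - 1e-9 & mid <= far + 1e-9))
  expect_error(
    edgeDistanceProfile(pair,
                        SegmentationMaps(cellLabels(ph$truth))),
    "no IBs")
})

test_that("fitted boundary width recovers the planted blur", {
  ph <- makePhantom(cleanPhantomSpec(seed = 55L, size = 128L, nCells = 2L,
                                     ibRadiusRangePx = c(6, 8),
                                     edgeBlurSigmaPx = 1.5,
                                     betaEnrichmentTrue = 1.6))
  pair <- identityRegistered(ph$pair)
  prof <- edgeDistanceProfile(pair, truthSegmentation(ph$truth),
                              nBoot = 99)
  fit <- fitEdgeWidth(prof)
  expected <- 4 * 1.5 * pixelSizeNm(pair)
  expect_lt(abs(fit$widthNm - expected) / expected, 0.25)
})
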
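test_that("triangle threshold matches the brute-force construction", {
  set.seed(41)
  for (i in 1:25) {
    n <- sample(200:3000, 1)
    x <- switch(sample(3, 1),
      c(stats::rnorm(round(0.9 * n), 1, 0.05),
        stats::rnorm(round(0.1 * n), 2, 0.05)),
      stats::rexp(n),
      stats::runif(n)^2)
    expect_equal(triangleThreshold(x), oracleTriangleThreshold(x),
                 tolerance = 1e-12)
  }
})

test_that("triangle threshold separates a 90/10 bimodal mixture", {
  set.seed(42)
  lo <- stats::rnorm(900, 1, 0.05)
  hi <- stats::rnorm(100, 2, 0.05)
  x <- c(lo, hi)
  thr <- triangleThreshold(x)
  ## the corner sits just past the dominant mode (oracle-verified), above
  ## nearly all of it and below all of the minor mode
  expect_equal(thr, oracleTriangleThreshold(x), tolerance = 1e-12)
  expect_gt(thr, 1.1)
  expect_lt(thr, 1.8)
  expect_lte(mean(lo > thr), 0.01)
  expect_equal(mean(hi > thr), 1)
  expect_gte(thr, min(x))
  expect_lte(thr, max(x))
  expect_error(triangleThreshold(rep(1, 100)), "constant")
})

test_that("triangle threshold commutes with affine rescaling", {
  set.seed(43)
  x <- c(stats::rnorm(500, 0, 1), stats::rnorm(80, 5, 0.5))
  t0 <- triangleThreshold(x)
  for (ab in list(c(2, 0), c(0.3, -7), c(1000, 42))) {
    t1 <- triangleThreshold(ab[1] * x + ab[2])
    expect_equal(t1, ab[1] * t0 + ab[2], tolerance = 1e-9)
  }
})

test_that("border-touching cells are discarded by segmentation", {
  ph <- makePhantom(testPhantomSpec(seed = 44L, nCells = 3L,
                                    includeBorderCell = TRUE))
  lab <- segmentCells(ph$pair@ds1625)
  expect_equal(max(lab), 3)                       # interior cells only
  h <- nrow(lab); w <- ncol(lab)
  expect_true(all(c(lab[1, ], lab[h, ], lab[, 1], lab[, w]) == 0))
})

test_that("membrane erosion shrinks a disk cell by the analytic margin", {
  img <- matrix(0.4, 64, 64)
  X <- matrix(rep(0:63, each = 64), 64, 64)
  Y <- matrix(rep(0:63, times = 64), 64, 64)
  disk <- (X - 32)^2 + (Y - 32)^2 <= 10^2
  img[disk] <- 1
  backend <- function(m) (disk) * 1L              # exact instance oracle
  lab <- segmentCells(img, backend = backend, erosionRadiusPx = 2)
  ## erosion of a radius-10 disk by a radius-2 disk is about a radius-8 disk
  expect_equal(sum(lab > 0), pi * 8^2, tolerance = 0.08)
  expect_error(segmentCells(img, backend = function(m) matrix(0L, 2, 2)),
               "shape")
})

test_that("a blank image yields zero cells with a warning", {
  expect_warning(lab <- segmentCells(matrix(1, 48, 48)),
                 "no cells")
  expect_true(all(lab == 0))
})

test_that("opening rejects radius-1 disks and keeps radius >= 2 (detection floor)", {
  ## one synthetic cell with planted supra-threshold disks of radii 1..4
  ph <- makePhantom(cleanPhantomSpec(
    size = 128L, nCells = 1L, seed = 45L,
    cellMajorUm = c(4.2, 4.2), cellMinorUm = c(1.1, 1.1),
    ibRadiiPx = list(c(1, 2, 3, 4)), ibPlacement = "spread",
    betaEnrichmentTrue = 1.6))
  expect_equal(nrow(ibTable(ph$truth)), 4)
  pair <- identityRegistered(ph$pair)
  cl <- segmentCells(pair@ds1625)
  seg <- segmentIbs(getChannel(pair@ds1625, "IRAmplitude"), cl)
  areas <- tabulate(ibLabels(seg))
  radii <- sort(sqrt(areas / pi))
  expect_length(radii, 3)                       # the radius-1 disk is gone
  expect_gte(min(radii), 2)
  ## detected disks match the planted radius-2, 3, 4 disks
  planted <- sort(ibTable(ph$truth)$equiv_radius_px)[-1]
  expect_equal(radii, planted, tolerance = 0.15)
})

test_that("supra-threshold pixels outside the cell mask are discarded", {
  set.seed(46)
  amp <- matrix(stats::rnorm(64^2, 0.5, 0.01), 64, 64)
  cell <- matrix(0L, 64, 64); cell[20:45, 20:45] <- 1L
  amp[25:30, 25:30] <- 1            # IB inside
  amp[50:60, 50:60] <- 1            # bright blob outside the cell
  seg <- segmentIbs(amp, cell)
  il <- ibLabels(seg)
  expect_true(all(il[cell == 0L] == 0L))
  expect_equal(max(il), 1)
  expect_equal(ibToCell(seg)$cell_id, 1L)
})

test_that("three IBs in one cell give three components owned by it", {
  ph <- makePhantom(cleanPhantomSpec(
    size = 128L, nCells = 1L, seed = 47L,
    cellMajorUm = c(4.0, 4.0), cellMinorUm = c(1.0, 1.0),
    ibRadiiPx = list(c(3, 3, 3)), ibPlacement = "spread",
    betaEnrichmentTrue = 1.5))
  pair <- identityRegistered(ph$pair)
  cl <- segmentCells(pair@ds1625)
  seg <- segmentIbs(getChannel(pair@ds1625, "IRAmplitude"), cl)
  expect_equal(max(ibLabels(seg)), 3)
  expect_equal(unique(ibToCell(seg)$cell_id), 1L)
})

test_that("IB count per cell and areas are recovered on clean phantoms", {
  ph <- makePhantom(cleanPhantomSpec(seed = 48L, nCells = 3L,
                                     ibRadiusRangePx = c(3, 5),
                                     betaEnrichmentTrue = 1.5))
  pair <- identityRegistered(ph$pair)
  cl <- segmentCells(pair@ds1625)
  seg <- segmentIbs(getChannel(pair@ds1625, "IRAmplitude"), cl)
  truth <- ibTable(ph$truth)
  expect_equal(max(ibLabels(seg)), nrow(truth))
  detAreas <- sort(tabulate(ibLabels(seg)))
  expect_equal(detAreas, sort(truth$area_px), tolerance = 0.15)
  ## per-cell counts match (detected cell ids may be permuted; compare sets)
  detPerCell <- sort(as.vector(table(ibToCell(seg)$cell_id)))
  truthPerCell <- sort(as.vector(table(truth$cell_id)))
  expect_equal(detPerCell, truthPerCell)
})

test_that("the IB mask is a fixed point of its own opening", {
  ph <- makePhantom(cleanPhantomSpec(seed = 48L, nCells = 3L,
                                     betaEnrichmentTrue = 1.5))
  pair <- identityRegistered(ph$pair)
  cl <- segmentCells(pair@ds1625)
  seg <- segmentIbs(getChannel(pair@ds1625, "IRAmplitude"), cl)
  m <- ibLabels(seg) > 0
  k <- diskKernel(2)
  opened <- afmirib:::.em(EBImage::dilate(EBImage::erode(m, k), k)) > 0
  expect_identical(opened, m)
})

test_that("tiny cells are skipped with a warning", {
  amp <- matrix(stats::rnorm(32^2, 1, 0.1), 32, 32)
  cell <- matrix(0L, 32, 32); cell[10:11, 10:12] <- 1L   # 6 px cell
  expect_warning(seg <- segmentIbs(amp, cell), "skipped")
  expect_equal(max(ibLabels(seg)), 0)
})
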
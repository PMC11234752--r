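g <- wavenumberGrid()

test_that("session epoxy averaging is a pointwise mean with guards", {
  bg1 <- Spectrum(g, rep(0.4, 501), category = "BG", sessionId = "m1")
  bg2 <- Spectrum(g, rep(0.6, 501), category = "BG", sessionId = "m1")
  avg <- averageSessionEpoxy(list(bg1, bg2), "m1")
  expect_equal(irAmplitude(avg), rep(0.5, 501))
  ## idempotence on identical spectra
  same <- averageSessionEpoxy(list(bg1, bg1), "m1")
  expect_equal(irAmplitude(same), irAmplitude(bg1))
  ## a session without epoxy spectra errors, naming the session
  ib <- Spectrum(g, rep(1, 501), category = "IB", sessionId = "m2")
  expect_error(averageSessionEpoxy(list(ib), "m2"), "m2")
})

test_that("epoxy normalisation divides pointwise and masks bad references", {
  ref <- makeBandSpectrum("BG", g, baseline = 0.2, category = "BG")
  s <- Spectrum(g, 2 * irAmplitude(ref), category = "CP")
  out <- epoxyNormalize(s, ref)
  expect_equal(irAmplitude(out), rep(2, 501))
  ident <- epoxyNormalize(ref, ref)
  expect_equal(irAmplitude(ident), rep(1, 501))
  ## a zero point in the reference masks that point only
  refAmp <- irAmplitude(ref); refAmp[100] <- 0
  ref0 <- Spectrum(g, refAmp, category = "BG")
  expect_warning(out0 <- epoxyNormalize(s, ref0), "masked")
  expect_false(validMask(out0)[100])
  expect_true(all(validMask(out0)[-100]))
  ## grids must match
  expect_error(
    epoxyNormalize(makeBandSpectrum("CP", wavenumberGrid(1000, 1800)), ref),
    "grid mismatch")
})

test_that("min-max normalisation pins the window to [0, 1]", {
  set.seed(2)
  s <- makeBandSpectrum("IB", g, baseline = 0.1, noiseSd = 0.02)
  out <- minmaxNormalize(s)
  w <- g >= 1600 & g <= 1800
  expect_equal(max(irAmplitude(out)[w]), 1)
  expect_equal(min(irAmplitude(out)[w]), 0)
  ## linear ramp: midpoint of the window maps to 0.5
  ramp <- Spectrum(g, seq(0, 10, length.out = 501), category = "CP")
  outR <- minmaxNormalize(ramp)
  expect_equal(irAmplitude(outR)[g == 1700], 0.5)
  expect_error(minmaxNormalize(Spectrum(g, rep(3, 501), category = "CP")),
               "degenerate")
})

test_that("beta-sheet integral matches width, zero and a quadrature oracle", {
  expect_equal(betaSheetContent(Spectrum(g, rep(1, 501), category = "IB")),
               20)
  expect_equal(betaSheetContent(Spectrum(g, rep(0, 501), category = "IB")),
               0)
  band <- rbind(c(1625, 8, 1))
  s <- makeBandSpectrum(band, g)
  expect_equal(betaSheetContent(s),
               oracleBandIntegral(band, 1615, 1635),
               tolerance = 0.01)
  expect_error(betaSheetContent(s, band = c(1790, 1810)), "outside grid")
})

test_that("band intensity is the inclusive-window mean", {
  expect_equal(bandIntensity(Spectrum(g, rep(0.7, 501), category = "CP"),
                             1628), 0.7)
  ## delta at one grid point inside a 6-point window around 1625
  amp <- rep(0, 501); amp[g == 1624] <- 1
  expect_equal(bandIntensity(Spectrum(g, amp, category = "CP"), 1625, 5),
               1 / 6)
  expect_error(bandIntensity(Spectrum(g, amp, category = "CP"), 1800, 5),
               "outside grid")
})

test_that("second derivative is exact on polynomials and localises bands", {
  a <- 3e-4
  quad <- Spectrum(g, a * g^2, category = "CP")
  d2 <- secondDerivative(quad)
  expect_equal(irAmplitude(d2)[10:490], rep(2 * a, 481), tolerance = 1e-8)
  ## Gaussian band: minimum of the second derivative at the band centre
  s <- makeBandSpectrum(rbind(c(1625, 10, 1)), g)
  d2s <- secondDerivative(s)
  expect_true(g[which.min(irAmplitude(d2s))] %in% c(1624, 1626))
  ## wider windows smooth white noise harder
  set.seed(5)
  noise <- Spectrum(g, stats::rnorm(501), category = "CP")
  v5 <- stats::var(irAmplitude(secondDerivative(noise, 5, 2))[50:450])
  v21 <- stats::var(irAmplitude(secondDerivative(noise, 21, 2))[50:450])
  expect_lt(v21, v5)
  expect_error(secondDerivative(s, 4, 3), "odd")
  expect_error(secondDerivative(s, 3, 3), "polyOrder")
})

test_that("PLL reduction subtracts the session reference over 1600-1650", {
  pll <- rep(880, 501)
  s <- Spectrum(g, rep(1, 501), pllFrequency = pll, category = "IB")
  expect_equal(pllSummary(s, sessionEpoxyPll = 880), 0)
  s2 <- Spectrum(g, rep(1, 501), pllFrequency = pll + 0.3, category = "IB")
  expect_equal(pllSummary(s2, sessionEpoxyPll = 880), 0.3)
  ## linear PLL ramp across the window averages to its midpoint
  ramp <- ifelse(g >= 1600 & g <= 1650, (g - 1600) / 50, 0)
  s3 <- Spectrum(g, rep(1, 501), pllFrequency = ramp, category = "IB")
  expect_equal(pllSummary(s3, sessionEpoxyPll = 0), 0.5)
  expect_error(pllSummary(Spectrum(g, rep(1, 501), category = "IB")),
               "no PLL")
  ## session reference from BG spectra
  bg <- Spectrum(g, rep(1, 501), pllFrequency = pll, category = "BG",
                 sessionId = "m1")
  expect_equal(sessionEpoxyPllReference(list(bg), "m1"), 880)
})

test_that("processing order preserves beta ordering for any enrichment > 1", {
  for (f in c(1.2, 1.6, 2.5)) {
    bands <- bandPreset("CP")
    bandsIb <- bands
    bandsIb[bandsIb[, 1] == 1628, 3] <- bandsIb[bandsIb[, 1] == 1628, 3] * f
    bg <- makeBandSpectrum("BG", g, baseline = 0.3, category = "BG",
                           sessionId = "m")
    cp <- makeBandSpectrum(bands, g, baseline = 0.05, category = "CP",
                           sessionId = "m")
    ib <- makeBandSpectrum(bandsIb, g, baseline = 0.05, category = "IB",
                           sessionId = "m")
    pr <- processSpectra(list(bg, cp, ib))
    beta <- vapply(pr, betaSheetContent, numeric(1))
    cats <- vapply(pr, category, character(1))
    expect_gt(beta[cats == "IB"], beta[cats == "CP"])
  }
})

test_that("beta ordering is invariant to positive affine pre-scaling", {
  bg <- makeBandSpectrum("BG", g, baseline = 0.3, category = "BG")
  cp <- makeBandSpectrum("CP", g, baseline = 0.05, category = "CP")
  ib <- makeBandSpectrum("IB", g, baseline = 0.05, category = "IB")
  run <- function(scale) {
    sc <- function(s) Spectrum(g, scale * irAmplitude(s),
                               category = category(s))
    b <- vapply(list(sc(cp), sc(ib)), function(s)
      betaSheetContent(minmaxNormalize(epoxyNormalize(s, bg))), numeric(1))
    b[2] > b[1]
  }
  expect_true(run(1))
  expect_true(run(0.01))
  expect_true(run(250))
})
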
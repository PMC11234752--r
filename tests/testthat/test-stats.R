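test_that("decision tree picks the expected branch per distribution", {
  set.seed(61)
  pickG <- replicate(100, chosenTest(chooseAndRunTest(
    list(a = stats::rnorm(50), b = stats::rnorm(50), c = stats::rnorm(50)),
    posthocMethod = "none")))
  expect_gte(mean(pickG == "ANOVA"), 0.9)
  pickE <- replicate(100, chosenTest(chooseAndRunTest(
    list(a = stats::rexp(50), b = stats::rexp(50), c = stats::rexp(50)),
    posthocMethod = "none")))
  expect_gte(mean(pickE == "Kruskal-Wallis"), 0.9)
})

test_that("full decision tree keeps its type-I error near nominal", {
  set.seed(62)
  p <- replicate(400, chooseAndRunTest(
    list(a = stats::rnorm(50), b = stats::rnorm(50), c = stats::rnorm(50)),
    posthocMethod = "none")@p)
  expect_gte(mean(p < 0.05), 0.03)
  expect_lte(mean(p < 0.05), 0.07)
})

test_that("the report records the full decision path", {
  set.seed(63)
  r <- chooseAndRunTest(list(x = stats::rnorm(30), y = stats::rnorm(30, 2)))
  expect_s4_class(r, "StatTestReport")
  expect_length(r@normalityP, 2)
  expect_equal(r@normalityPAdj, 3 * r@normalityP)   # k + 1 pre-tests
  expect_equal(r@homoscedasticityPAdj, 3 * r@homoscedasticityP)
  expect_true(r@posthocMethod %in% c("tukey", "dunn"))
  expect_output(show(r), "chosen test")
  expect_error(chooseAndRunTest(list(a = 1:2, b = 1:5)), "n >= 3")
  expect_error(chooseAndRunTest(list(a = 1:5)), "2 groups")
  ## the uncorrected variant uses the raw pre-test p values
  r0 <- chooseAndRunTest(list(x = stats::rnorm(30), y = stats::rnorm(30)),
                         pretestCorrection = "none")
  expect_equal(r0@normalityPAdj, r0@normalityP)
})

test_that("two-group Tukey reduces to the pooled t test", {
  set.seed(64)
  a <- stats::rnorm(20); b <- stats::rnorm(20, 1)
  tk <- posthocTest(list(a = a, b = b), "tukey")
  tt <- stats::t.test(a, b, var.equal = TRUE)
  expect_equal(tk$table$p, tt$p.value, tolerance = 1e-6)
})

test_that("post hocs are calibrated under the null and see planted shifts", {
  set.seed(65)
  minP <- replicate(150, {
    g <- list(a = stats::rnorm(20), b = stats::rnorm(20),
              c = stats::rnorm(20))
    min(posthocTest(g, "tukey")$table$p)
  })
  expect_gte(mean(minP > 0.05), 0.90)   # family-wise calibration
  ## a 3-pooled-SD shift is flagged hard
  g <- list(a = stats::rnorm(20), b = stats::rnorm(20),
            c = stats::rnorm(20, 3))
  tk <- posthocTest(g, "tukey")$table
  expect_lt(tk$p[tk$comparison == "c-a"], 0.001)
  dn <- posthocTest(g, "dunn")$table
  expect_lt(dn$p_adj[dn$comparison == "a-c"], 0.01)
  du <- posthocTest(g, "dunnett", controlIndex = 1)$table
  expect_lt(du$p[grepl("^c", du$comparison)], 0.001)
  expect_error(posthocTest(g, "dunnett", controlIndex = NA), "control")
})

test_that("Bonferroni correction is uncapped and composition is visible", {
  expect_equal(bonferroni(0.05, 4), 0.2)
  expect_equal(bonferroni(0.55, 4), 2.2)     # adjusted p above 1 is reported
  expect_equal(bonferroni(0.3, 1), 0.3)
  expect_equal(bonferroni(c(0.1, 0.2)), c(0.2, 0.4))
  expect_equal(bonferroni(0.5, 4, cap = TRUE), 1)
  expect_error(bonferroni(1.2, 2), "\\[0, 1\\]")
  expect_error(bonferroni(c(0.1, 0.2, 0.3), m = 2), "at least")
  ## double correction is not a no-op: the count must be tracked, not stacked
  p <- c(0.01, 0.02)
  expect_false(isTRUE(all.equal(bonferroni(bonferroni(p)), bonferroni(p))))
})

test_that("bootstrap CI: degenerate data, determinism, and coverage", {
  expect_equal(bootstrapCi(rep(3, 10), seed = 1, nBoot = 99), c(3, 3))
  x <- stats::rnorm(40)
  expect_identical(bootstrapCi(x, seed = 7, nBoot = 999),
                   bootstrapCi(x, seed = 7, nBoot = 999))
  expect_error(bootstrapCi(1), "at least 2")
  set.seed(66)
  cover <- replicate(200, {
    x <- stats::rnorm(100)
    ci <- bootstrapCi(x)            # the default 9999 resamples
    ci[1] <= 0 && 0 <= ci[2]
  })
  expect_gte(mean(cover), 0.93)
  expect_lte(mean(cover), 0.97)
})

test_that("general-statistic bootstrap works too", {
  x <- c(1, 2, 100)
  ci <- bootstrapCi(x, statistic = stats::median, nBoot = 499, seed = 2)
  expect_true(ci[1] >= 1 && ci[2] <= 100)
})

test_that("correlation bootstrap flags duplicated and planted signals", {
  set.seed(67)
  tabs <- lapply(1:6, function(i) {
    x <- stats::rnorm(40)
    data.frame(a = x, b = x, c = stats::rnorm(40))
  })
  res <- correlationMatrixBootstrap(tabs, nBoot = 999)
  expect_equal(res@meanR["a", "b"], 1)
  expect_true(res@significant["a", "b"])
  ## planted rho = 0.8
  set.seed(68)
  tabs2 <- lapply(1:8, function(i) {
    x <- stats::rnorm(50)
    data.frame(u = x, v = 0.8 * x + sqrt(1 - 0.64) * stats::rnorm(50))
  })
  res2 <- correlationMatrixBootstrap(tabs2, nBoot = 999)
  expect_true(res2@significant["u", "v"])
  expect_gte(res2@meanR["u", "v"], 0.7)
  expect_lte(res2@meanR["u", "v"], 0.9)
})

test_that("null correlations are rarely flagged after correction", {
  set.seed(69)
  tabs <- lapply(1:20, function(i)
    as.data.frame(matrix(stats::rnorm(50 * 5), 50, 5,
                         dimnames = list(NULL, letters[1:5]))))
  res <- correlationMatrixBootstrap(tabs, nBoot = 999)
  up <- upper.tri(res@significant)
  expect_lte(mean(res@significant[up]), 0.05)
})

test_that("constant properties are excluded, not propagated", {
  tabs <- list(data.frame(a = stats::rnorm(10), b = rep(1, 10)),
               data.frame(a = stats::rnorm(10), b = stats::rnorm(10)),
               data.frame(a = stats::rnorm(10), b = stats::rnorm(10)))
  res <- correlationMatrixBootstrap(tabs, nBoot = 199, seed = 3)
  rv <- res@rValues
  expect_true(is.na(rv$dataset1[rv$var1 == "a" & rv$var2 == "b"]))
  expect_true(is.finite(res@meanR["a", "b"]))
  expect_error(correlationMatrixBootstrap(tabs[1]), "2 datasets")
  expect_error(correlationMatrixBootstrap(
    list(data.frame(a = 1:2, b = 2:3), tabs[[2]])), "3 IBs")
})

test_that("PCA is beta-sensitive, sign-deterministic, and nested", {
  g <- wavenumberGrid()
  set.seed(70)
  m <- t(vapply(seq(0.1, 1.2, length.out = 12), function(a)
    irAmplitude(makeBandSpectrum(rbind(c(1654, 14, 1), c(1628, 10, a)), g,
                                 noiseSd = 0.002)),
    numeric(501)))
  pc <- pcaSpectra(m)
  peak <- g[which.max(abs(pc$components[, 1]))]
  expect_gte(peak, 1620); expect_lte(peak, 1640)
  ## sign convention: the extremal loading is positive
  expect_gt(pc$components[which.max(abs(pc$components[, 1])), 1], 0)
  ## reconstruction error decreases monotonically in k
  ctr <- scale(m, scale = FALSE)
  errs <- vapply(1:4, function(k) {
    rec <- pc$scores[, 1:k, drop = FALSE] %*% t(pc$components[, 1:k])
    sum((ctr - rec)^2)
  }, numeric(1))
  expect_true(all(diff(errs) < 1e-9))
  expect_equal(sum(pc$explainedVariance), 1)
  ## duplicated spectra: all variance beyond PC1 is numerically zero
  dup <- rbind(m[1, ], m[1, ], m[2, ], m[2, ])
  pcd <- pcaSpectra(dup)
  expect_lt(pcd$explainedVariance[2], 1e-20)
})

test_that("embedding backends are pluggable and seeded", {
  set.seed(71)
  m <- matrix(stats::rnorm(20 * 30), 20, 30)
  expect_equal(dim(embedSpectra(m, "pca")), c(20, 2))
  expect_equal(dim(embedSpectra(m, "mds")), c(20, 2))
  fn <- function(x) x[, 1:2] + stats::rnorm(nrow(x) * 2)
  e1 <- embedSpectra(m, fn, seed = 5)
  e2 <- embedSpectra(m, fn, seed = 5)
  expect_identical(e1, e2)
})

test_that("paired contrasts wrap the classic tests with family correction", {
  set.seed(72)
  ib <- stats::rnorm(30, 0.4, 0.3); cp <- stats::rnorm(30, 0, 0.3)
  w <- pairedContrast(ib, cp, "wilcoxon", m = 2)
  expect_lt(w$p, 0.01)
  expect_equal(w$p_adj, 2 * w$p)
  t1 <- pairedContrast(ib - cp, method = "t")
  expect_lt(t1$p, 0.01)
})
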
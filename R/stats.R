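## The statistical layer: test-selection decision tree, post hoc tests,
## uncapped Bonferroni correction, bootstrap CIs, bootstrap-tested
## correlation matrices, PCA and pluggable 2D embedding.

.asGroupList <- function(groups) {
  if (is.data.frame(groups)) groups <- split(groups[[1]], groups[[2]])
  if (!is.list(groups)) stop("groups must be a list of numeric vectors")
  if (is.null(names(groups)) || any(!nzchar(names(groups))))
    names(groups) <- paste0("g", seq_along(groups))
  lapply(groups, as.numeric)
}

#' Bonferroni correction, uncapped by default
#'
#' Multiplies p values by the number of comparisons. Adjusted values are
#' deliberately not clipped to 1, so heavily corrected non-significant
#' results remain distinguishable (an adjusted p of 2.2 says more than a
#' wall of 1s); set \code{cap = TRUE} for conventional clipping.
#'
#' @param p Numeric p values in [0, 1].
#' @param m Number of comparisons (>= length(p)).
#' @param cap Clip adjusted values at 1.
#' @return Adjusted p values.
#' @examples
#' bonferroni(c(0.05, 0.55), m = 4)  # 0.2, 2.2
#' @export
bonferroni <- function(p, m = length(p), cap = FALSE) {
  if (any(!is.finite(p) | p < 0 | p > 1))
    stop("p values must lie in [0, 1]")
  if (m < length(p))
    stop("m must be at least the number of p values")
  out <- m * p
  if (cap) out <- pmin(out, 1)
  out
}

#' Test-selection decision tree for multi-group comparisons
#'
#' Runs Shapiro normality tests per group and a Bartlett homoscedasticity
#' test across groups; if every pre-test (Bonferroni-adjusted over the
#' pre-test family by default, see the vignette) is non-significant at
#' \code{alphaPretest}, a one-way ANOVA is run, otherwise Kruskal-Wallis.
#' A suitable post hoc follows the chosen branch: Tukey (all pairs) or
#' Dunnett (versus a control) after ANOVA, Dunn's rank test with Bonferroni
#' correction after Kruskal-Wallis. The full decision path is recorded in
#' the returned [StatTestReport-class].
#'
#' @param groups Named list of numeric vectors (each n >= 3), or a
#'   two-column data.frame (values, group).
#' @param alphaPretest Pre-test significance level.
#' @param pretestCorrection \code{"bonferroni"} (adjust the k + 1 pre-test p
#'   values over the family) or \code{"none"}.
#' @param posthocMethod \code{"auto"}, \code{"tukey"}, \code{"dunnett"},
#'   \code{"dunn"} or \code{"none"}.
#' @param controlIndex Index of the control group for Dunnett.
#' @return A [StatTestReport-class].
#' @export
chooseAndRunTest <- function(groups, alphaPretest = 0.05,
                             pretestCorrection = c("bonferroni", "none"),
                             posthocMethod = c("auto", "tukey", "dunnett",
                                               "dunn", "none"),
                             controlIndex = 1L) {
  pretestCorrection <- match.arg(pretestCorrection)
  posthocMethod <- match.arg(posthocMethod)
  groups <- .asGroupList(groups)
  if (length(groups) < 2L) stop("need at least 2 groups")
  sizes <- lengths(groups)
  if (any(sizes < 3L)) stop("every group needs n >= 3")
  shap <- vapply(groups, function(g) stats::shapiro.test(g)$p.value,
                 numeric(1))
  vals <- unlist(groups, use.names = FALSE)
  fac <- factor(rep(names(groups), sizes), levels = names(groups))
  bart <- stats::bartlett.test(vals, fac)$p.value
  mPre <- if (pretestCorrection == "bonferroni") length(groups) + 1L else 1L
  shapAdj <- mPre * shap
  bartAdj <- mPre * bart
  parametric <- all(shapAdj > alphaPretest) && bartAdj > alphaPretest
  if (parametric) {
    fit <- stats::aov(vals ~ fac)
    sm <- summary(fit)[[1]]
    statistic <- sm[["F value"]][1]
    p <- sm[["Pr(>F)"]][1]
    chosen <- "ANOVA"
  } else {
    kw <- stats::kruskal.test(vals, fac)
    statistic <- unname(kw$statistic)
    p <- kw$p.value
    chosen <- "Kruskal-Wallis"
  }
  if (posthocMethod == "auto")
    posthocMethod <- if (parametric) "tukey" else "dunn"
  ph <- data.frame(); mPost <- 0L
  if (posthocMethod != "none") {
    if (posthocMethod %in% c("tukey", "dunnett") && !parametric)
      warning("parametric post hoc requested on the nonparametric branch")
    res <- posthocTest(groups, posthocMethod, controlIndex)
    ph <- res$table; mPost <- res$m
  }
  new("StatTestReport", groups = names(groups), sizes = as.integer(sizes),
      normalityP = unname(shap), normalityPAdj = unname(shapAdj),
      homoscedasticityP = bart, homoscedasticityPAdj = bartAdj,
      pretestCorrection = pretestCorrection, alphaPretest = alphaPretest,
      chosenTest = chosen, statistic = statistic, p = p,
      posthocMethod = posthocMethod, posthoc = ph,
      mPosthoc = as.integer(mPost))
}

#' Post hoc pairwise tests
#'
#' Tukey's honest significant difference over all pairs
#' (studentized-range distribution), Dunnett's many-to-one comparisons
#' against a control (multivariate-t critical values via \pkg{multcomp}),
#' or Dunn's rank-based test (the Kruskal-Wallis companion) with Bonferroni
#' adjustment. Tukey and Dunnett p values are family-wise by construction,
#' so their recorded adjustment count m is 1; Dunn reports raw p values
#' Bonferroni-multiplied by the number of pairs (uncapped).
#'
#' @param groups Named list of numeric vectors.
#' @param method \code{"tukey"}, \code{"dunnett"} or \code{"dunn"}.
#' @param controlIndex Control group index (Dunnett only).
#' @return List: \code{table} (data.frame comparison / estimate / p /
#'   p_adj) and \code{m} (comparisons behind p_adj).
#' @export
posthocTest <- function(groups, method = c("tukey", "dunnett", "dunn"),
                        controlIndex = 1L) {
  method <- match.arg(method)
  groups <- .asGroupList(groups)
  vals <- unlist(groups, use.names = FALSE)
  fac <- factor(rep(names(groups), lengths(groups)), levels = names(groups))
  if (method == "tukey") {
    tk <- stats::TukeyHSD(stats::aov(vals ~ fac))$fac
    tab <- data.frame(comparison = rownames(tk), estimate = tk[, "diff"],
                      p = tk[, "p adj"], p_adj = tk[, "p adj"])
    rownames(tab) <- NULL
    return(list(table = tab, m = 1L))
  }
  if (method == "dunnett") {
    if (is.na(controlIndex) || controlIndex < 1 ||
        controlIndex > length(groups))
      stop("Dunnett post hoc requires a valid control group index")
    lev <- c(names(groups)[controlIndex], names(groups)[-controlIndex])
    fac <- factor(fac, levels = lev)
    fit <- stats::aov(vals ~ fac)
    gl <- multcomp::glht(fit, linfct = multcomp::mcp(fac = "Dunnett"))
    sm <- summary(gl)
    tab <- data.frame(comparison = rownames(sm$linfct),
                      estimate = unname(sm$test$coefficients),
                      p = unname(sm$test$pvalues),
                      p_adj = unname(sm$test$pvalues))
    rownames(tab) <- NULL
    return(list(table = tab, m = 1L))
  }
  ## Dunn: pairwise z tests on mean ranks with tie correction
  N <- length(vals)
  rk <- rank(vals)
  ties <- table(vals)
  tieTerm <- sum(ties^3 - ties) / (12 * (N - 1))
  s2 <- N * (N + 1) / 12 - tieTerm
  mr <- tapply(rk, fac, mean)
  n <- lengths(groups)
  cmb <- utils::combn(names(groups), 2)
  m <- ncol(cmb)
  rows <- lapply(seq_len(m), function(j) {
    pr <- cmb[, j]
    z <- (mr[[pr[1]]] - mr[[pr[2]]]) /
      sqrt(s2 * (1 / n[[pr[1]]] + 1 / n[[pr[2]]]))
    p <- 2 * stats::pnorm(-abs(z))
    data.frame(comparison = paste(pr[1], pr[2], sep = "-"),
               estimate = mr[[pr[1]]] - mr[[pr[2]]], p = p,
               p_adj = m * p)
  })
  list(table = do.call(rbind, rows), m = as.integer(m))
}

#' Paired or one/two-sample contrasts
#'
#' Thin wrappers for Wilcoxon signed-rank and t contrasts used for paired
#' comparisons (e.g. IB versus cytoplasm of the same cell), reporting an
#' uncapped Bonferroni-adjusted p when the contrast is one of a family.
#'
#' @param x,y Numeric samples (y NULL for a one-sample test against mu).
#' @param method \code{"wilcoxon"} or \code{"t"}.
#' @param paired Paired contrast (requires y).
#' @param mu Null value for one-sample contrasts.
#' @param m Number of comparisons in the family.
#' @return List: statistic, p, p_adj, method.
#' @export
pairedContrast <- function(x, y = NULL, method = c("wilcoxon", "t"),
                           paired = !is.null(y), mu = 0, m = 1L) {
  method <- match.arg(method)
  ht <- if (method == "wilcoxon")
    stats::wilcox.test(x, y, paired = paired, mu = mu, exact = FALSE)
  else stats::t.test(x, y, paired = paired, mu = mu)
  list(statistic = unname(ht$statistic), p = ht$p.value,
       p_adj = bonferroni(ht$p.value, m = max(m, 1L)), method = ht$method)
}

#' Bootstrap percentile confidence interval
#'
#' Percentile interval of a resampled statistic; deterministic for a fixed
#' seed.
#'
#' @param values Numeric vector (n >= 2).
#' @param statistic Function of a numeric vector (default mean).
#' @param nBoot Number of bootstrap resamples.
#' @param level Confidence level.
#' @param seed Optional integer seed (restores the caller's RNG state).
#' @return Numeric (lo, hi).
#' @examples
#' bootstrapCi(rnorm(50), nBoot = 999, seed = 1)
#' @export
bootstrapCi <- function(values, statistic = mean, nBoot = 9999,
                        level = 0.95, seed = NULL) {
  n <- length(values)
  if (n < 2L) stop("need at least 2 values")
  .withSeed(seed, {
    if (identical(statistic, mean)) {
      idx <- sample.int(n, n * nBoot, replace = TRUE)
      stat <- colMeans(matrix(values[idx], n, nBoot))
    } else {
      stat <- vapply(seq_len(nBoot), function(i)
        statistic(values[sample.int(n, n, replace = TRUE)]), numeric(1))
    }
    a <- (1 - level) / 2
    unname(stats::quantile(stat, c(a, 1 - a)))
  })
}

#' Bootstrap-tested correlation matrix across datasets
#'
#' Pearson correlations between all pairs of properties are computed within
#' each dataset (each AFM-IR map's IB feature table); the resulting set of
#' per-dataset correlations for a pair is bootstrap-resampled to test
#' whether its mean differs from zero (two-sided percentile test), and p
#' values are Bonferroni-corrected (uncapped) over the number of pairs.
#' A property that is constant within a dataset has no defined correlation
#' there and that dataset is excluded for the affected pairs.
#'
#' @param tables List (>= 2) of data.frames with shared numeric columns,
#'   each with >= 3 rows.
#' @param vars Property columns to use (default: all shared numeric).
#' @param nBoot Bootstrap replicates.
#' @param alpha Significance level applied to adjusted p values.
#' @param seed Optional seed.
#' @return A [CorrelationMatrixResult-class].
#' @export
correlationMatrixBootstrap <- function(tables, vars = NULL, nBoot = 9999,
                                       alpha = 0.05, seed = NULL) {
  if (length(tables) < 2L) stop("need at least 2 datasets")
  if (any(vapply(tables, nrow, integer(1)) < 3L))
    stop("every dataset needs at least 3 IBs")
  if (is.null(vars)) {
    vars <- Reduce(intersect, lapply(tables, function(t)
      names(t)[.dfNum(t)]))
  }
  if (length(vars) < 2L) stop("need at least 2 numeric properties")
  k <- length(vars)
  rPer <- lapply(tables, function(t) {
    m <- suppressWarnings(stats::cor(as.matrix(t[vars])))
    m[!is.finite(m)] <- NA_real_
    m
  })
  pairs <- utils::combn(k, 2)
  meanR <- p <- matrix(NA_real_, k, k, dimnames = list(vars, vars))
  diag(meanR) <- 1
  rvRows <- list()
  .withSeed(seed, {
    for (j in seq_len(ncol(pairs))) {
      a <- pairs[1, j]; b <- pairs[2, j]
      rs <- vapply(rPer, function(m) m[a, b], numeric(1))
      rvRows[[j]] <- data.frame(var1 = vars[a], var2 = vars[b],
                                t(rs))
      rs <- rs[is.finite(rs)]
      if (length(rs) < 2L) next
      meanR[a, b] <- meanR[b, a] <- mean(rs)
      idx <- sample.int(length(rs), length(rs) * nBoot, replace = TRUE)
      bm <- colMeans(matrix(rs[idx], length(rs), nBoot))
      pj <- 2 * min((sum(bm <= 0) + 1) / (nBoot + 1),
                    (sum(bm >= 0) + 1) / (nBoot + 1))
      p[a, b] <- p[b, a] <- min(pj, 1)
    }
  })
  nPairs <- ncol(pairs)
  pAdj <- p * nPairs
  sig <- pAdj < alpha
  rValues <- do.call(rbind, rvRows)
  names(rValues) <- c("var1", "var2",
                      paste0("dataset", seq_along(tables)))
  new("CorrelationMatrixResult", vars = vars, meanR = meanR, p = p,
      pAdj = pAdj, significant = sig, rValues = rValues,
      nBoot = as.integer(nBoot), alpha = alpha)
}

#' Principal component analysis of processed spectra
#'
#' Mean-centered PCA with a deterministic sign convention: each component is
#' flipped so that its largest-magnitude loading is positive.
#'
#' @param mat Numeric matrix, one spectrum per row, shared wavenumber grid
#'   along columns (processed: epoxy-normalised and min-max rescaled).
#' @return List: components (loadings, wavenumbers x k), scores (spectra x
#'   k), explainedVariance (fractions).
#' @export
pcaSpectra <- function(mat) {
  mat <- as.matrix(mat)
  if (nrow(mat) < 3L) stop("need at least 3 spectra")
  pc <- stats::prcomp(mat, center = TRUE, scale. = FALSE)
  rot <- pc$rotation; sc <- pc$x
  for (j in seq_len(ncol(rot))) {
    i <- which.max(abs(rot[, j]))
    if (rot[i, j] < 0) {
      rot[, j] <- -rot[, j]
      sc[, j] <- -sc[, j]
    }
  }
  list(components = rot, scores = sc,
       explainedVariance = pc$sdev^2 / sum(pc$sdev^2))
}

#' Two-dimensional embedding of spectra
#'
#' Pluggable 2D embedding used for cluster visualisation. Built-in backends:
#' \code{"pca"} (first two principal components) and \code{"mds"} (classical
#' multidimensional scaling of Euclidean distances). Any function
#' \code{(matrix, ...) -> n x 2 matrix} can be supplied as a backend (e.g.
#' an adapter around a nonlinear embedding); it runs under the given seed.
#'
#' @param mat Numeric matrix, one spectrum per row.
#' @param method \code{"pca"}, \code{"mds"}, or a function.
#' @param seed Seed fixed for stochastic backends.
#' @param ... Passed on to a function backend.
#' @return n x 2 coordinate matrix.
#' @export
embedSpectra <- function(mat, method = "pca", seed = 1L, ...) {
  mat <- as.matrix(mat)
  if (is.function(method))
    return(.withSeed(seed, {
      out <- method(mat, ...)
      stopifnot(ncol(out) == 2, nrow(out) == nrow(mat))
      out
    }))
  switch(match.arg(method, c("pca", "mds")),
    pca = pcaSpectra(mat)$scores[, 1:2, drop = FALSE],
    mds = stats::cmdscale(stats::dist(mat), k = 2))
}
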
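#' Median-of-ratios size factors
#'
#' Per-sample scaling factors: each feature with all-positive counts
#' defines a reference (its geometric mean across samples), and a sample's
#' factor is the median, over those features, of count/reference. Factors
#' are rescaled to geometric mean 1.
#'
#' @param counts Integer matrix, features x samples.
#' @return Named numeric vector of positive size factors, geometric mean 1.
#' @examples
#' m <- rbind(c(10, 20), c(100, 200))
#' sizeFactorsMedianOfRatios(m)  # proportional to 1:2
#' @export
sizeFactorsMedianOfRatios <- function(counts) {
  counts <- as.matrix(counts)
  pos <- rowSums(counts <= 0) == 0
  if (!any(pos))
    stop("no feature with all-positive counts; consider adding a ",
         "pseudo-count before normalization")
  lc <- log(counts[pos, , drop = FALSE])
  ref <- rowMeans(lc)
  sf <- exp(apply(lc - ref, 2, stats::median))
  sf <- sf / exp(mean(log(sf)))
  sf
}

#' Counts per million
#'
#' @param counts Integer matrix, features x samples.
#' @param libSizes Library sizes; defaults to column sums.
#' @return Numeric matrix of CPM values.
#' @export
cpm <- function(counts, libSizes = colSums(counts)) {
  if (any(libSizes <= 0)) stop("zero or negative library size")
  t(1e6 * t(as.matrix(counts)) / libSizes)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up BH with monotonicity enforcement, capped at 1. `NA`/`NaN`
#' inputs propagate.
#'
#' @param p Numeric vector of p values in [0, 1].
#' @return Adjusted p values.
#' @export
adjustBH <- function(p) stats::p.adjust(p, method = "BH")

## ---- batched NB GLM machinery ------------------------------------------

## Negative binomial (NB2) deviance per feature; phi = 0 gives Poisson.
.nbDeviance <- function(y, mu, phi) {
  mu <- pmax(mu, 1e-10)
  t1 <- ifelse(y > 0, y * log(y / mu), 0)
  if (length(phi) == 1) phi <- rep(phi, nrow(y))
  dev <- matrix(0, nrow(y), ncol(y))
  for (f in seq_len(nrow(y))) {
    if (phi[f] > 1e-10) {
      dev[f, ] <- 2 * (t1[f, ] - (y[f, ] + 1 / phi[f]) *
                         log((1 + phi[f] * y[f, ]) /
                             (1 + phi[f] * mu[f, ])))
    } else {
      dev[f, ] <- 2 * (t1[f, ] - (y[f, ] - mu[f, ]))
    }
  }
  rowSums(dev)
}

## Solve, for every feature, the weighted least-squares system
## (X'WX) beta = X'Wz. Fast closed forms for p = 1, 2; generic loop beyond.
.batchWls <- function(X, w, z) {
  p <- ncol(X)
  if (p == 1L) {
    a <- w %*% (X[, 1]^2)
    b <- rowSums(w * z * matrix(X[, 1], nrow(w), ncol(w), byrow = TRUE))
    return(matrix(b / a, ncol = 1))
  }
  if (p == 2L) {
    x1 <- matrix(X[, 1], nrow(w), ncol(w), byrow = TRUE)
    x2 <- matrix(X[, 2], nrow(w), ncol(w), byrow = TRUE)
    a11 <- rowSums(w * x1 * x1); a12 <- rowSums(w * x1 * x2)
    a22 <- rowSums(w * x2 * x2)
    b1 <- rowSums(w * z * x1); b2 <- rowSums(w * z * x2)
    det <- a11 * a22 - a12^2
    det[det == 0] <- NA_real_
    return(cbind((a22 * b1 - a12 * b2) / det,
                 (a11 * b2 - a12 * b1) / det))
  }
  beta <- matrix(NA_real_, nrow(w), p)
  for (f in seq_len(nrow(w))) {
    A <- crossprod(X, w[f, ] * X)
    beta[f, ] <- tryCatch(solve(A, crossprod(X, w[f, ] * z[f, ])),
                          error = function(e) rep(NA_real_, p))
  }
  beta
}

#' Fit negative-binomial log-linear models by IRLS
#'
#' Fits, for every feature at once, the log-link NB GLM
#' `log(mu) = X beta + offset` with fixed dispersion, by iteratively
#' reweighted least squares (weights `mu / (1 + phi mu)`). Convergence is
#' declared when the relative deviance change falls below `tol` or after
#' `maxIter` iterations (non-converged features are flagged and the last
#' iterate returned).
#'
#' @param counts Matrix (features x samples) or vector of counts.
#' @param design Design matrix, samples x p.
#' @param offsets Per-sample offsets on the log scale (e.g. log size
#'   factors); a vector or a features x samples matrix.
#' @param dispersion NB dispersion, scalar or per-feature; 0 for Poisson.
#' @param tol,maxIter Convergence controls.
#' @return A list with `coefficients` (features x p), `fitted` (features x
#'   samples means), `deviance`, `converged`, `df_residual`.
#' @export
fitNbGlm <- function(counts, design, offsets = 0, dispersion = 0,
                     tol = 1e-8, maxIter = 100L) {
  y <- if (is.matrix(counts)) counts else matrix(counts, nrow = 1)
  storage.mode(y) <- "double"
  X <- as.matrix(design)
  if (nrow(X) != ncol(y)) stop("design rows must match samples")
  if (qr(X)$rank < ncol(X)) stop("design is not of full rank")
  nf <- nrow(y); ns <- ncol(y)
  off <- if (is.matrix(offsets)) offsets
         else matrix(offsets, nf, ns, byrow = length(offsets) == ns)
  phi <- if (length(dispersion) == 1) rep(dispersion, nf) else dispersion
  phiM <- matrix(phi, nf, ns)
  ## initialize from log counts (pseudo 1/6 guards zeros)
  z0 <- log(pmax(y, 1 / 6)) - off
  beta <- .batchWls(X, matrix(1, nf, ns), z0)
  dev <- rep(Inf, nf)
  converged <- rep(FALSE, nf)
  for (it in seq_len(maxIter)) {
    eta <- beta %*% t(X) + off
    mu <- pmin(pmax(exp(eta), 1e-10), 1e10)
    w <- mu / (1 + phiM * mu)
    z <- (eta - off) + (y - mu) / mu
    betaNew <- .batchWls(X, w, z)
    bad <- !is.finite(rowSums(betaNew))
    betaNew[bad, ] <- beta[bad, , drop = FALSE]
    beta <- betaNew
    devNew <- .nbDeviance(y, pmin(pmax(exp(beta %*% t(X) + off), 1e-10),
                                  1e10), phi)
    delta <- abs(devNew - dev) / (abs(devNew) + 0.1)
    converged <- is.finite(delta) & delta < tol
    dev <- devNew
    if (all(converged)) break
  }
  mu <- pmin(pmax(exp(beta %*% t(X) + off), 1e-10), 1e10)
  list(coefficients = beta, fitted = mu, deviance = dev,
       converged = converged, df_residual = ns - ncol(X))
}

## Cox-Reid adjusted profile log-likelihood per feature at dispersion phi.
.coxReidApl <- function(y, X, off, phi) {
  fit <- fitNbGlm(y, X, off, dispersion = phi, tol = 1e-6, maxIter = 50L)
  mu <- fit$fitted
  nf <- nrow(y)
  ll <- numeric(nf)
  usePois <- phi <= 1e-8
  for (f in seq_len(nf)) {
    ll[f] <- if (usePois)
      sum(stats::dpois(y[f, ], mu[f, ], log = TRUE))
    else
      sum(stats::dnbinom(y[f, ], size = 1 / phi, mu = mu[f, ],
                         log = TRUE))
  }
  w <- mu / (1 + phi * mu)
  p <- ncol(X)
  cr <- if (p == 1L) {
    0.5 * log(w %*% (X[, 1]^2))
  } else if (p == 2L) {
    x1 <- matrix(X[, 1], nf, ncol(y), byrow = TRUE)
    x2 <- matrix(X[, 2], nf, ncol(y), byrow = TRUE)
    a11 <- rowSums(w * x1 * x1); a12 <- rowSums(w * x1 * x2)
    a22 <- rowSums(w * x2 * x2)
    0.5 * log(pmax(a11 * a22 - a12^2, 1e-300))
  } else {
    vapply(seq_len(nf), function(f)
      0.5 * determinant(crossprod(X, w[f, ] * X))$modulus, numeric(1))
  }
  ll - as.numeric(cr)
}

#' Estimate the common NB dispersion by Cox-Reid adjusted profile likelihood
#'
#' Maximizes the summed Cox-Reid adjusted NB profile log-likelihood over
#' the abundance-filtered features, on a log-scale grid refined by
#' golden-section search. The least abundant features (bottom
#' `abundanceFilter` fraction by total count) are excluded because their
#' noisy likelihoods adversely affect the estimate. Returns 0 when the
#' likelihood is maximized at the lower boundary.
#'
#' @param counts Integer matrix, features x samples.
#' @param design Design matrix.
#' @param sizeFactors Per-sample size factors.
#' @param abundanceFilter Fraction of least abundant features to drop
#'   (default 0.5).
#' @return Scalar dispersion estimate (>= 0).
#' @export
estimateCommonDispersion <- function(counts, design,
                                     sizeFactors = rep(1, ncol(counts)),
                                     abundanceFilter = 0.5) {
  y <- as.matrix(counts); storage.mode(y) <- "double"
  X <- as.matrix(design)
  if (qr(X)$rank < ncol(X)) stop("design is not of full rank")
  tot <- rowSums(y)
  keep <- tot > 0 & tot >= stats::quantile(tot[tot > 0], abundanceFilter)
  if (!any(keep)) stop("no features left after abundance filtering")
  y <- y[keep, , drop = FALSE]
  off <- matrix(log(sizeFactors), nrow(y), ncol(y), byrow = TRUE)
  apl <- function(phi) sum(.coxReidApl(y, X, off, phi))
  grid <- exp(seq(log(1e-4), log(4), length.out = 12))
  vals <- vapply(grid, apl, numeric(1))
  i <- which.max(vals)
  if (i == 1L && apl(0) >= vals[1]) return(0)
  lo <- grid[max(i - 1L, 1L)]; hi <- grid[min(i + 1L, length(grid))]
  ## golden-section on log(phi)
  gr <- (sqrt(5) - 1) / 2
  a <- log(lo); b <- log(hi)
  c1 <- b - gr * (b - a); d1 <- a + gr * (b - a)
  fc <- apl(exp(c1)); fd <- apl(exp(d1))
  for (k in seq_len(25)) {
    if (fc > fd) { b <- d1; d1 <- c1; fd <- fc
                   c1 <- b - gr * (b - a); fc <- apl(exp(c1)) }
    else         { a <- c1; c1 <- d1; fc <- fd
                   d1 <- a + gr * (b - a); fd <- apl(exp(d1)) }
    if (b - a < 1e-3) break
  }
  exp((a + b) / 2)
}

#' Estimate tagwise NB dispersions with shrinkage toward the common value
#'
#' Maximizes, per feature, its Cox-Reid adjusted profile log-likelihood
#' plus a prior weight times the average APL over the abundance-filtered
#' features (weighted-likelihood empirical Bayes). As `priorDf` grows the
#' estimates shrink to the common dispersion; `priorDf = 0` gives
#' unshrunken per-feature maxima.
#'
#' @inheritParams estimateCommonDispersion
#' @param common Common dispersion (from [estimateCommonDispersion()]).
#' @param priorDf Prior degrees of freedom (default 10).
#' @param gridLength,gridSpan Grid controls: `gridSpan`-fold around the
#'   common value, `gridLength` points on the log scale.
#' @return Numeric vector of per-feature dispersions.
#' @export
estimateTagwiseDispersions <- function(counts, design,
                                       sizeFactors = rep(1, ncol(counts)),
                                       common, priorDf = 10,
                                       abundanceFilter = 0.5,
                                       gridLength = 21L, gridSpan = 50) {
  y <- as.matrix(counts); storage.mode(y) <- "double"
  X <- as.matrix(design)
  off <- matrix(log(sizeFactors), nrow(y), ncol(y), byrow = TRUE)
  tot <- rowSums(y)
  keep <- tot > 0 & tot >= stats::quantile(tot[tot > 0], abundanceFilter)
  dfRes <- ncol(y) - ncol(X)
  priorN <- if (dfRes > 0) priorDf / dfRes else priorDf
  ctr <- max(common, 1e-4)
  grid <- exp(seq(log(ctr) - log(gridSpan), log(ctr) + log(gridSpan),
                  length.out = gridLength))
  aplMat <- vapply(grid, function(phi) .coxReidApl(y, X, off, phi),
                   numeric(nrow(y)))
  aplBar <- colMeans(aplMat[keep, , drop = FALSE])
  obj <- aplMat + matrix(priorN * aplBar, nrow(y), length(grid),
                         byrow = TRUE)
  grid[max.col(obj, ties.method = "first")]
}

#' Quasi-likelihood F-tests for a negative-binomial log-linear model
#'
#' Fits the full and reduced NB GLMs at the supplied dispersion, computes
#' per-feature quasi-dispersions (residual deviance / residual df),
#' moderates them toward a scaled inverse-chi-square prior fitted by
#' moments on the log scale, and tests the dropped coefficient with an
#' F-statistic whose denominator uses the moderated quasi-dispersion and
#' augmented degrees of freedom.
#'
#' @param counts Integer matrix, features x samples.
#' @param design Full design matrix.
#' @param coef Column index of the coefficient to drop for the reduced
#'   model (default last column).
#' @param sizeFactors Per-sample size factors.
#' @param dispersion NB dispersion (scalar or per feature).
#' @return A data.frame with `log2_fc`, `F`, `df_prior`, `p_raw`, `p_adj`,
#'   `mean_abundance` (average CPM), one row per feature.
#' @export
qlTest <- function(counts, design, coef = ncol(design),
                   sizeFactors = rep(1, ncol(counts)), dispersion = 0.1) {
  y <- as.matrix(counts); storage.mode(y) <- "double"
  X <- as.matrix(design)
  off <- matrix(log(sizeFactors), nrow(y), ncol(y), byrow = TRUE)
  dfRes <- ncol(y) - ncol(X)
  if (dfRes <= 0)
    stop("no residual degrees of freedom; more replicates are required")
  full <- fitNbGlm(y, X, off, dispersion)
  red <- fitNbGlm(y, X[, -coef, drop = FALSE], off, dispersion)
  s2 <- pmax(full$deviance, 0) / dfRes
  sq <- .squeezeVar(s2, dfRes)
  num <- pmax(red$deviance - full$deviance, 0)
  Fstat <- num / pmax(sq$varPost, 1e-10)
  dfTotal <- sq$dfPrior + dfRes
  p <- stats::pf(Fstat, 1, dfTotal, lower.tail = FALSE)
  ## fold change with a pseudo-fraction guard against one-group zeros
  eps <- 0.5 / exp(mean(log(colSums(y) + 1)))
  grpMeans <- .contrastGroupMeans(full, X, coef, off)
  lfc <- log2((grpMeans$hi + eps) / (grpMeans$lo + eps))
  data.frame(log2_fc = lfc, F = Fstat, df_prior = sq$dfPrior,
             p_raw = p, p_adj = adjustBH(p),
             mean_abundance = rowMeans(cpm(y)),
             row.names = rownames(counts))
}

## fitted means at the two levels of the tested (assumed 0/1) coefficient;
## for a general column the fitted means at its max/min observed values.
.contrastGroupMeans <- function(fit, X, coef, off) {
  v <- X[, coef]
  hiS <- v == max(v); loS <- v == min(v)
  mu <- fit$fitted / exp(off)   # normalized means
  list(hi = rowMeans(mu[, hiS, drop = FALSE]),
       lo = rowMeans(mu[, loS, drop = FALSE]))
}

## Moment fit (on the log scale) of a scaled inverse-chi-square prior to
## observed variances with df degrees of freedom; mirrors the classical
## empirical-Bayes squeeze.
.squeezeVar <- function(s2, df) {
  ok <- is.finite(s2) & s2 > 0
  z <- log(pmax(s2, 1e-12))
  e <- z - digamma(df / 2) + log(df / 2)
  ev <- stats::var(e[ok]) - trigamma(df / 2)
  if (is.na(ev) || ev <= 0) {
    dfPrior <- Inf
    s0 <- exp(mean(e[ok]))
  } else {
    dfPrior <- 2 * .trigammaInverse(ev)
    s0 <- exp(mean(e[ok]) + digamma(dfPrior / 2) - log(dfPrior / 2))
  }
  varPost <- if (is.infinite(dfPrior)) rep(s0, length(s2))
             else (dfPrior * s0 + df * s2) / (dfPrior + df)
  list(varPost = varPost, dfPrior = dfPrior, varPrior = s0)
}

.trigammaInverse <- function(x) {
  if (x > 1e7) return(1 / sqrt(x))
  if (x < 1e-6) return(1 / x)
  y <- 0.5 + 1 / x
  for (i in seq_len(50)) {
    tri <- trigamma(y)
    dif <- tri * (1 - tri / x) / psigamma(y, 2)
    y <- y + dif
    if (abs(dif) / y < 1e-8) break
  }
  y
}

#' Spectral-count / small-RNA differential enrichment pipeline
#'
#' End-to-end quasi-likelihood NB analysis of a count matrix: drop
#' all-zero features, median-of-ratios size factors, common dispersion by
#' Cox-Reid APL on the abundance-filtered features, NB GLM fits and
#' moderated QL F-tests of the group coefficient, BH adjustment.
#'
#' @param counts Integer matrix, features x samples.
#' @param groups Character/factor of sample groups (two levels).
#' @param refGroup Reference (control) level; default the second unique
#'   value, so positive log2 fold changes mean enrichment in the first.
#' @param abundanceFilter Fraction of least abundant features excluded
#'   from dispersion estimation (default 0.5).
#' @return A data.frame as [qlTest()], plus attributes `sizeFactors` and
#'   `commonDispersion`.
#' @export
enrichmentAnalysis <- function(counts, groups, refGroup = NULL,
                               abundanceFilter = 0.5) {
  counts <- as.matrix(counts)
  groups <- as.character(groups)
  lv <- unique(groups)
  if (length(lv) != 2) stop("exactly two groups are required")
  if (is.null(refGroup)) refGroup <- lv[2]
  if (min(table(groups)) < 2)
    stop("at least 2 samples per compared group are required")
  keep <- rowSums(counts) > 0
  y <- counts[keep, , drop = FALSE]
  sf <- sizeFactorsMedianOfRatios(y)
  X <- cbind(intercept = 1, group = as.numeric(groups != refGroup))
  disp <- estimateCommonDispersion(y, X, sf, abundanceFilter)
  res <- qlTest(y, X, coef = 2L, sizeFactors = sf, dispersion = disp)
  out <- res[match(rownames(counts), rownames(y)), ]
  rownames(out) <- rownames(counts)
  attr(out, "sizeFactors") <- sf
  attr(out, "commonDispersion") <- disp
  out
}

#' Annotate enrichment results for a volcano plot
#'
#' @param results A data.frame with `log2_fc` and `p_adj` columns.
#' @param fcThreshold Absolute log2 fold-change threshold (default 0).
#' @param alpha Adjusted-p significance threshold; strict `<` (default
#'   0.05).
#' @return The input with added `significant` flag and `direction`
#'   (`"enriched"`, `"depleted"`, `"ns"`).
#' @export
volcanoTable <- function(results, fcThreshold = 0, alpha = 0.05) {
  sig <- !is.na(results$p_adj) & results$p_adj < alpha &
    abs(results$log2_fc) > fcThreshold
  dir <- rep("ns", nrow(results))
  dir[sig & results$log2_fc > 0] <- "enriched"
  dir[sig & results$log2_fc < 0] <- "depleted"
  results$significant <- sig
  results$direction <- dir
  results
}
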
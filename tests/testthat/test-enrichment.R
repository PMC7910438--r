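test_that("median-of-ratios size factors match the definition", {
  m <- rbind(c(10, 20), c(100, 200), c(7, 14))
  sf <- sizeFactorsMedianOfRatios(m)
  expect_equal(sf[2] / sf[1], 2, ignore_attr = TRUE)
  expect_equal(exp(mean(log(sf))), 1)
  ## identical samples: all factors 1
  expect_equal(unname(sizeFactorsMedianOfRatios(cbind(5:9, 5:9, 5:9))),
               rep(1, 3))
  ## random NB matrix: agrees with the DESeq2 reference implementation
  ## (up to the geometric-mean-1 rescaling convention)
  set.seed(8)
  y <- matrix(rnbinom(5000 * 6, mu = 50, size = 5), ncol = 6) +
    matrix(rep(c(0, 10), each = 15000), ncol = 6)
  sf1 <- sizeFactorsMedianOfRatios(y)
  sf2 <- DESeq2::estimateSizeFactorsForMatrix(y)
  expect_equal(sf1, sf2 / exp(mean(log(sf2))), tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_error(sizeFactorsMedianOfRatios(rbind(c(0, 1), c(1, 0))),
               "pseudo-count")
})

test_that("scaling one sample scales its size factor", {
  set.seed(9)
  y <- matrix(rnbinom(2000 * 4, mu = 100, size = 10), ncol = 4)
  y2 <- y
  y2[, 3] <- y[, 3] * 5
  sf <- sizeFactorsMedianOfRatios(y)
  sf2 <- sizeFactorsMedianOfRatios(y2)
  ## relative to an untouched sample the rescaled factor carries the x5
  ratio <- (sf2[3] / sf[3]) / (sf2[1] / sf[1])
  expect_equal(unname(ratio), 5, tolerance = 0.02)
})

test_that("CPM columns sum to one million and match the definition", {
  set.seed(1)
  y <- matrix(rpois(200, 20), ncol = 4)
  cm <- cpm(y)
  expect_equal(unname(colSums(cm)), rep(1e6, 4))
  expect_equal(cm[1, 1], 1e6 * y[1, 1] / sum(y[, 1]))
  expect_equal(cpm(matrix(5), libSizes = 1e6)[1, 1], 5)
  expect_error(cpm(matrix(0, 2, 2)), "library")
})

test_that("BH adjustment equals the independent step-up oracle", {
  expect_equal(adjustBH(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(adjustBH(0.2), 0.2)
  set.seed(2)
  for (i in 1:10) {
    p <- runif(sample(3:50, 1))
    a <- adjustBH(p)
    expect_equal(a, oracleBH(p))
    expect_true(all(a >= p & a <= 1))
    expect_true(all(diff(a[order(p)]) >= -1e-12))
  }
  expect_true(is.na(adjustBH(c(0.1, NA))[2]))
})

test_that("NB GLM fits match an independent IRLS implementation", {
  ## closed form: two-group doubling with no dispersion
  f <- fitNbGlm(c(10, 10, 20, 20), cbind(1, c(0, 0, 1, 1)),
                dispersion = 0)
  expect_equal(f$coefficients[2] / log(2), 1, tolerance = 1e-9)
  ## all-zero feature: fitted means at the floor, flagged usable
  f0 <- fitNbGlm(rep(0, 4), cbind(1, c(0, 0, 1, 1)), dispersion = 0.1)
  expect_true(all(f0$fitted <= 1e-9))
  ## random instances vs glm.fit with the matching NB family
  set.seed(12)
  X <- cbind(1, rep(c(0, 1), each = 4))
  off <- log(runif(8, 0.5, 2))
  for (i in 1:25) {
    phi <- sample(c(0, 0.05, 0.3), 1)
    mu <- exp(runif(1, 1, 4))
    y <- if (phi == 0) rpois(8, mu) else rnbinom(8, mu = mu,
                                                 size = 1 / phi)
    if (all(y == 0)) next
    fit <- fitNbGlm(y, X, offsets = off, dispersion = phi,
                    tol = 1e-12, maxIter = 200L)
    oracle <- oracleNbFit(y, X, off, phi)
    expect_equal(unname(fit$fitted[1, ]), unname(oracle),
                 tolerance = 1e-6)
  }
  expect_error(fitNbGlm(1:4, cbind(rep(1, 4), rep(1, 4)),
                        dispersion = 0), "full rank")
})

test_that("common dispersion is recovered from NB data", {
  cfg <- spectralSimConfig(nProteins = 5000, groups = rep("a", 6),
                           dispersion = 0.2, seed = 5)
  y <- simulateSpectralCounts(cfg)$counts
  est <- estimateCommonDispersion(y, matrix(1, 6, 1))
  expect_gt(est, 0.15)
  expect_lt(est, 0.25)
  ## Poisson data: estimate collapses toward the boundary
  cfg0 <- spectralSimConfig(nProteins = 5000, groups = rep("a", 6),
                            dispersion = 0, seed = 6)
  est0 <- estimateCommonDispersion(simulateSpectralCounts(cfg0)$counts,
                                   matrix(1, 6, 1))
  expect_lte(est0, 0.01)
  ## identically repeated feature rows have no dispersion signal
  flat <- matrix(rep(c(10, 12, 9, 11, 10, 10), each = 40), ncol = 6)
  expect_lte(estimateCommonDispersion(flat, matrix(1, 6, 1)), 0.01)
})

test_that("common dispersion agrees with the edgeR reference estimate", {
  cfg <- spectralSimConfig(nProteins = 2000, dispersion = 0.15, seed = 7)
  sim <- simulateSpectralCounts(cfg)
  y <- sim$counts
  keep <- rowSums(y) >= stats::quantile(rowSums(y)[rowSums(y) > 0], 0.5) &
    rowSums(y) > 0
  X <- cbind(1, as.numeric(sim$samples$group == "bait"))
  sf <- sizeFactorsMedianOfRatios(y[keep, ])
  mine <- estimateCommonDispersion(y, X, sf, abundanceFilter = 0.5)
  ref <- edgeR::estimateGLMCommonDisp(y[keep, ], design = X,
                                      offset = matrix(log(sf),
                                                      sum(keep), ncol(y),
                                                      byrow = TRUE))
  expect_lt(abs(mine - ref) / ref, 0.15)
})

test_that("tagwise dispersions shrink toward the common value", {
  cfg <- spectralSimConfig(nProteins = 300, groups = rep("a", 6),
                           dispersion = 0.2, seed = 5)
  y <- simulateSpectralCounts(cfg)$counts
  common <- estimateCommonDispersion(y, matrix(1, 6, 1))
  twBig <- estimateTagwiseDispersions(y, matrix(1, 6, 1),
                                      common = common, priorDf = 1e9)
  expect_true(all(abs(twBig - common) / common < 0.05))
  ## heterogeneous truth, no shrinkage: estimates track the truth order
  set.seed(31)
  trueDisp <- rep(c(0.05, 0.5), each = 1000)
  y2 <- t(vapply(trueDisp, function(d)
    rnbinom(6, mu = 100, size = 1 / d), numeric(6)))
  tw <- estimateTagwiseDispersions(y2, matrix(1, 6, 1), common = 0.15,
                                   priorDf = 0)
  expect_gt(suppressWarnings(
    cor(tw, trueDisp, method = "spearman")), 0.5)
  ## zero-variance feature stays at or below the common value
  yz <- rbind(y[1:20, ], rep(50, 6))
  twz <- estimateTagwiseDispersions(yz, matrix(1, 6, 1),
                                    common = common, priorDf = 10)
  expect_lte(twz[21], common * 1.001)
})

test_that("the QL F-test is calibrated under the null", {
  cfg <- spectralSimConfig(nProteins = 5000, dispersion = 0.1, seed = 9)
  sim <- simulateSpectralCounts(cfg)
  res <- enrichmentAnalysis(sim$counts, sim$samples$group)
  frac <- mean(res$p_raw < 0.05, na.rm = TRUE)
  expect_gt(frac, 0.035)
  expect_lt(frac, 0.065)
  ## null p values are close to uniform
  ks <- stats::ks.test(res$p_raw[!is.na(res$p_raw)], "punif")
  expect_gt(ks$p.value, 0.01)
})

test_that("fold-4 spike-ins are detected with high power and low FDR", {
  cfg <- spectralSimConfig(nProteins = 2000, dispersion = 0.1,
                           enrichedIdx = 1:50, fold = 4,
                           baselineMeanLog = log(50), baselineSdLog = 0,
                           seed = 10)
  sim <- simulateSpectralCounts(cfg)
  res <- enrichmentAnalysis(sim$counts, sim$samples$group)
  expect_gte(mean(res$p_adj[1:50] < 0.05, na.rm = TRUE), 0.8)
  fp <- sum(res$p_adj[-(1:50)] < 0.05, na.rm = TRUE)
  expect_lte(fp / max(sum(res$p_adj < 0.05, na.rm = TRUE), 1), 0.1)
  expect_gt(stats::median(res$log2_fc[1:50]), 1.5)
  ## ranking broadly agrees with the edgeR QL reference pipeline
  dge <- edgeR::DGEList(sim$counts,
                        group = factor(sim$samples$group,
                                       levels = c("control", "bait")))
  dge <- dge[rowSums(dge$counts) > 0, ]
  dge <- edgeR::calcNormFactors(dge, method = "RLE")
  X <- stats::model.matrix(~group, dge$samples)
  dge <- edgeR::estimateDisp(dge, X)
  qf <- edgeR::glmQLFTest(edgeR::glmQLFit(dge, X), coef = 2)
  common <- intersect(rownames(qf$table),
                      rownames(res)[!is.na(res$p_raw)])
  expect_gt(cor(-log10(qf$table[common, "PValue"]),
                -log10(res[common, "p_raw"]),
                method = "spearman"), 0.8)
})

test_that("volcano annotation applies strict thresholds", {
  res <- data.frame(log2_fc = c(1, -2, 0.5, 3),
                    p_adj = c(0.049, 0.01, 0.05, NA))
  v <- volcanoTable(res)
  expect_equal(v$direction, c("enriched", "depleted", "ns", "ns"))
  expect_equal(v$significant, c(TRUE, TRUE, FALSE, FALSE))
  ## manual tally on a small fixture
  set.seed(3)
  res2 <- data.frame(log2_fc = rnorm(10), p_adj = runif(10))
  v2 <- volcanoTable(res2, alpha = 0.3)
  expect_equal(sum(v2$significant),
               sum(res2$p_adj < 0.3))
})

test_that("the QL pipeline refuses degenerate designs", {
  y <- matrix(rpois(40, 20), ncol = 4)
  expect_error(qlTest(y, cbind(1, c(0, 0, 1, 1), c(1, 0, 1, 0),
                               c(0, 1, 0, 1))[, 1:4],
                      dispersion = 0.1), "residual degrees")
  expect_error(enrichmentAnalysis(y, c("a", "a", "a", "b")),
               "at least 2 samples")
})
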
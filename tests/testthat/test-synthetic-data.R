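test_that("degenerate tail configs produce the forced truth", {
  cat. <- fixtureCatalog(1)
  cfg <- tailSimConfig(nReads = 200, catalog = cat.,
                       mixtureWeights = c(0, 1, 0),
                       oligoRange = c(14L, 14L),
                       pUridylationByClass = c(0, 0, 0), pArich = 0,
                       pUntailed = 0, seqErrorRate = 0, seed = 1)
  tr <- simulateTailReads(cfg)$truth
  expect_true(all(tr$n_term_U == 0L))
  expect_true(all(tr$tail_class == "non_uridylated"))
  expect_true(all(tr$polyA_len == 14L))
  ## uCountMean 1 makes the shifted geometric a point mass: with certain
  ## uridylation every truth row carries exactly one terminal U
  cfg2 <- tailSimConfig(nReads = 200, catalog = cat.,
                        pUridylationByClass = c(1, 1, 1), uCountMean = 1,
                        pArich = 0, pUntailed = 0, seqErrorRate = 0,
                        seed = 1)
  tr2 <- simulateTailReads(cfg2)$truth
  expect_true(all(tr2$n_term_U == 1L))
})

test_that("uridylation frequencies are calibrated to the config", {
  cat. <- fixtureCatalog(2)
  cfg <- tailSimConfig(nReads = 10000, catalog = cat.,
                       mixtureWeights = c(0, 1, 0),
                       pUridylationByClass = c(0, 0.3, 0), pArich = 0,
                       pUntailed = 0, seqErrorRate = 0, seed = 8)
  tr <- simulateTailReads(cfg)$truth
  pHat <- mean(tr$n_term_U > 0)
  expect_lt(abs(pHat - 0.3), 1.96 * sqrt(0.3 * 0.7 / 10000))
})

test_that("the simulator is deterministic given a seed", {
  cat. <- fixtureCatalog(3)
  cfg <- tailSimConfig(nReads = 100, catalog = cat., seed = 42)
  a <- simulateTailReads(cfg)
  b <- simulateTailReads(cfg)
  expect_identical(a$r1, b$r1)
  expect_identical(a$r2, b$r2)
  expect_identical(as.data.frame(a$truth), as.data.frame(b$truth))
  dirA <- withr::local_tempdir(); dirB <- withr::local_tempdir()
  fa <- simulateTailReads(cfg, outDir = dirA)$files
  fb <- simulateTailReads(cfg, outDir = dirB)$files
  expect_identical(unname(tools::md5sum(fa)), unname(tools::md5sum(fb)))
})

test_that("truth classes agree with the classification rule", {
  cat. <- fixtureCatalog(4)
  cfg <- tailSimConfig(nReads = 3000, catalog = cat., pArich = 0.3,
                       arichRate = 0.2, seqErrorRate = 0, seed = 13)
  tr <- simulateTailReads(cfg)$truth
  d <- decomposeTail(tr$tail_seq)
  expect_equal(d$tail_class, tr$tail_class)
  expect_equal(d$polyA_len, tr$polyA_len)
  expect_equal(d$n_term_U, tr$n_term_U)
})

test_that("reference catalog round-trips through FASTA + TSV", {
  cat. <- fixtureCatalog(2)
  dir <- withr::local_tempdir()
  writeReferenceCatalog(cat., file.path(dir, "ref.fa"),
                        file.path(dir, "sites.tsv"))
  expect_equal(length(Biostrings::readDNAStringSet(
    file.path(dir, "ref.fa"))), 2L)
  back <- readReferenceCatalog(file.path(dir, "ref.fa"),
                               file.path(dir, "sites.tsv"))
  expect_equal(as.character(refSequences(back)),
               as.character(refSequences(cat.)))
  expect_equal(polyASites(back), polyASites(cat.))
  ## empty catalog writes empty, valid files
  empty <- referenceCatalog(setNames(character(0), character(0)))
  writeReferenceCatalog(empty, file.path(dir, "e.fa"),
                        file.path(dir, "e.tsv"))
  expect_equal(length(Biostrings::readDNAStringSet(
    file.path(dir, "e.fa"))), 0L)
  expect_error(referenceCatalog(c(g = "ACGT", g = "ACGT")), "duplicate")
})

test_that("spectral-count simulator matches its moments", {
  ## dispersion 0 gives Poisson: variance/mean near 1 across features
  cfg <- spectralSimConfig(nProteins = 5000, dispersion = 0, seed = 2)
  sim <- simulateSpectralCounts(cfg)
  vm <- apply(sim$counts, 1, stats::var) / rowMeans(sim$counts)
  expect_gt(mean(vm, na.rm = TRUE), 0.9)
  expect_lt(mean(vm, na.rm = TRUE), 1.1)
  ## no enrichment: two-group mean log-ratio near zero
  cfg0 <- spectralSimConfig(nProteins = 5000, dispersion = 0.05,
                            baselineMeanLog = log(100), seed = 3)
  sim0 <- simulateSpectralCounts(cfg0)
  g <- sim0$samples$group == "bait"
  lr <- log(rowMeans(sim0$counts[, g]) + 0.5) -
    log(rowMeans(sim0$counts[, !g]) + 0.5)
  expect_lt(abs(mean(lr)), 0.05)
  ## fold-4 spike: realized ratio near 4 across replicates of one protein
  set.seed(11)
  ratios <- vapply(1:100, function(s) {
    cfgF <- spectralSimConfig(nProteins = 10, dispersion = 0.05,
                              enrichedIdx = 1L, fold = 4,
                              baselineMeanLog = log(50),
                              baselineSdLog = 0, seed = 1000 + s)
    simF <- simulateSpectralCounts(cfgF)
    gF <- simF$samples$group == "bait"
    mean(simF$counts[1, gF]) / mean(simF$counts[1, !gF])
  }, numeric(1))
  expect_lt(abs(mean(ratios) - 4), 0.4)
  ## small-RNA wrapper carries the fold in the mutant group
  sr <- simulateSmallRnaCounts(nGenes = 500, affectedIdx = 1:10,
                               fold = 8, dispersion = 0,
                               baselineMeanLog = log(100),
                               baselineSdLog = 0, seed = 4)
  gm <- sr$samples$group == "mutant"
  expect_gt(mean(rowMeans(sr$counts[1:10, gm]) /
                   rowMeans(sr$counts[1:10, !gm])), 5)
})

test_that("decay-curve simulator reproduces the exponential mean", {
  cfg <- decaySimConfig(halfLife = 10, timepoints = c(0, 10, 20),
                        initialSignal = 100, overdispersion = 1, seed = 1)
  mu <- cfg$initialSignal * 2^(-cfg$timepoints / cfg$halfLife)
  expect_equal(mu, c(100, 50, 25))
  ## 1000 replicate draws at t = 10: sample mean within 3 SE of 50
  draws <- vapply(1:1000, function(s)
    simulateDecayCurve(decaySimConfig(halfLife = 10,
                                      timepoints = c(0, 10),
                                      initialSignal = 100,
                                      overdispersion = 2,
                                      seed = s))$intensity[2], numeric(1))
  se <- stats::sd(draws) / sqrt(1000)
  expect_lt(abs(mean(draws) - 50), 3 * se)
  ## near-infinite half-life: flat expectation
  flat <- simulateDecayCurve(decaySimConfig(halfLife = 1e9,
                                            overdispersion = 1,
                                            initialSignal = 1000,
                                            seed = 2))
  expect_lt(abs(mean(flat$intensity) - 1000) / 1000, 0.1)
})

test_that("DRS table simulator respects location, shift and filters", {
  ## one gene, constant length 60, no noise
  d <- simulateDrsTable(nGenes = 1, readsPerGene = 50,
                        geneMedianMeanLog = log(60), geneMedianSdLog = 0,
                        readSdLog = 0, seed = 1)
  expect_true(all(abs(d$polyA_len_estimate - 60) < 1e-9))
  ## point-mass reads per gene of 150: every gene passes a >=100 filter
  d2 <- simulateDrsTable(nGenes = 20, readsPerGene = function(n)
    rep(150L, n), seed = 2)
  tab <- table(d2$gene, interaction(d2$genotype, d2$replicate))
  expect_true(all(tab >= 100))
  ## no shift: pooled genotype medians agree within resampling error
  d3 <- simulateDrsTable(nGenes = 40, readsPerGene = 100,
                         genotypeShift = 0, seed = 3)
  meds <- tapply(d3$polyA_len_estimate, d3$genotype, stats::median)
  boot <- replicate(200, {
    i <- sample(nrow(d3), replace = TRUE)
    diff(tapply(d3$polyA_len_estimate[i], d3$genotype[i], stats::median))
  })
  expect_lt(abs(diff(meds)), 2 * stats::sd(boot))
  ## a negative shift moves the mutant distribution down
  d4 <- simulateDrsTable(nGenes = 40, readsPerGene = 100,
                         genotypeShift = -20, seed = 4)
  meds4 <- tapply(d4$polyA_len_estimate, d4$genotype, stats::median)
  expect_lt(meds4[["mut"]], meds4[["WT"]] - 10)
})

test_that("half-life/uridylation table encodes the designed relation", {
  ## deterministic decreasing relation: bin medians strictly decrease
  t1 <- simulateHalfLifeTable(nGenes = 500, slope = -6, noiseSdLog = 0,
                              seed = 1)
  bins <- cut(t1$uridylation_pct, c(0, 2, 5, 10, 24),
              include.lowest = TRUE)
  meds <- tapply(t1$half_life, bins, stats::median)
  expect_true(all(diff(meds) < 0))
  ## flat relation: extreme bins rarely differ significantly
  pvals <- vapply(1:100, function(s) {
    tf <- simulateHalfLifeTable(nGenes = 300, slope = 0,
                                noiseSdLog = 0.4, seed = s)
    b <- cut(tf$uridylation_pct, c(0, 2, 10, 24), include.lowest = TRUE)
    lo <- tf$half_life[b == levels(b)[1]]
    hi <- tf$half_life[b == levels(b)[3]]
    suppressWarnings(stats::wilcox.test(lo, hi)$p.value)
  }, numeric(1))
  expect_gte(mean(pvals > 0.05), 0.9)
  ## fixed seed reproducibility
  expect_identical(simulateHalfLifeTable(seed = 9),
                   simulateHalfLifeTable(seed = 9))
})
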
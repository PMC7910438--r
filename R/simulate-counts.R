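#' Configuration for the spectral-count simulator
#'
#' Negative-binomial generative model for IP-MS spectral counts: per-protein
#' baseline means, per-sample size factors, a common (or per-protein) NB
#' dispersion, and a set of truly enriched proteins carrying a fold change
#' in the bait group.
#'
#' @param nProteins Number of proteins.
#' @param groups Character vector of sample group labels (e.g. `"bait"` /
#'   `"control"`), one per sample.
#' @param sizeFactors Positive per-sample scaling factors (default all 1).
#' @param dispersion NB dispersion; scalar or one value per protein.
#'   0 gives Poisson counts.
#' @param enrichedIdx Integer indices of truly enriched proteins.
#' @param fold Fold change applied to enriched proteins in the group named
#'   by `enrichedGroup`.
#' @param enrichedGroup Group receiving the fold change (default first
#'   non-reference group, i.e. `unique(groups)[2]` if present else
#'   `groups[1]`).
#' @param baselineMeanLog,baselineSdLog Meanlog/sdlog of the log-normal
#'   distribution of baseline means (defaults give a median of 30 spectra,
#'   typical of enriched IP preys).
#' @param seed Integer seed.
#' @return A validated config list of class `SpectralSimConfig`.
#' @export
spectralSimConfig <- function(nProteins = 2000L,
                              groups = rep(c("bait", "control"), each = 4),
                              sizeFactors = rep(1, length(groups)),
                              dispersion = 0.1,
                              enrichedIdx = integer(0), fold = 4,
                              enrichedGroup = NULL,
                              baselineMeanLog = log(30),
                              baselineSdLog = 1, seed = 1L) {
  if (any(sizeFactors <= 0)) stop("size factors must be positive")
  if (any(dispersion < 0)) stop("dispersion must be non-negative")
  if (length(enrichedIdx) && any(enrichedIdx < 1 |
                                 enrichedIdx > nProteins))
    stop("enriched set must be a subset of proteins")
  if (length(sizeFactors) != length(groups))
    stop("one size factor per sample required")
  if (is.null(enrichedGroup))
    enrichedGroup <- if (length(unique(groups)) > 1) unique(groups)[1]
                     else groups[1]
  structure(list(nProteins = as.integer(nProteins), groups = groups,
                 sizeFactors = sizeFactors, dispersion = dispersion,
                 enrichedIdx = as.integer(enrichedIdx), fold = fold,
                 enrichedGroup = enrichedGroup,
                 baselineMeanLog = baselineMeanLog,
                 baselineSdLog = baselineSdLog, seed = as.integer(seed)),
            class = "SpectralSimConfig")
}

.rnbinomMu <- function(n, mu, dispersion) {
  out <- numeric(n)
  pois <- dispersion <= 0
  if (length(dispersion) == 1) pois <- rep(pois, n)
  if (length(mu) == 1) mu <- rep(mu, n)
  if (length(dispersion) == 1) dispersion <- rep(dispersion, n)
  if (any(pois)) out[pois] <- stats::rpois(sum(pois), mu[pois])
  if (any(!pois)) out[!pois] <- stats::rnbinom(sum(!pois),
                                               size = 1 / dispersion[!pois],
                                               mu = mu[!pois])
  out
}

#' Simulate a spectral-count matrix with known enrichment
#'
#' Counts are drawn as `NB(mean = baseline x sizeFactor x fold^[enriched &
#' bait group], dispersion)`.
#'
#' @param config A [spectralSimConfig()].
#' @return A list with `counts` (integer matrix proteins x samples),
#'   `samples` (data.frame of sample metadata) and `truth` (data.frame of
#'   enriched protein ids and true fold changes).
#' @export
simulateSpectralCounts <- function(config) {
  stopifnot(inherits(config, "SpectralSimConfig"))
  set.seed(config$seed)
  n <- config$nProteins
  ns <- length(config$groups)
  baseline <- stats::rlnorm(n, config$baselineMeanLog, config$baselineSdLog)
  foldMat <- matrix(1, n, ns)
  foldMat[config$enrichedIdx, config$groups == config$enrichedGroup] <-
    config$fold
  mu <- baseline * foldMat *
    matrix(config$sizeFactors, n, ns, byrow = TRUE)
  disp <- if (length(config$dispersion) == 1)
    rep(config$dispersion, n) else config$dispersion
  counts <- matrix(0L, n, ns,
                   dimnames = list(sprintf("protein%05d", seq_len(n)),
                                   sprintf("%s_%d", config$groups,
                                           stats::ave(seq_len(ns),
                                                      config$groups,
                                                      FUN = seq_along))))
  for (j in seq_len(ns))
    counts[, j] <- as.integer(.rnbinomMu(n, mu[, j], disp))
  list(counts = counts,
       samples = data.frame(sample = colnames(counts),
                            group = config$groups,
                            size_factor = config$sizeFactors),
       truth = data.frame(feature = rownames(counts)[config$enrichedIdx],
                          fold = rep(config$fold,
                                     length(config$enrichedIdx))))
}

#' Simulate 21-25 nt small-RNA counts per mRNA locus
#'
#' Same NB generative model as [simulateSpectralCounts()], phrased for
#' small-RNA counts: loci in `affectedIdx` carry the fold change in the
#' mutant group.
#'
#' @param nGenes Number of mRNA loci.
#' @param groups Sample group labels (e.g. `"wt"` / `"mutant"`).
#' @param affectedIdx Indices of loci with increased siRNA production.
#' @param fold Fold change in the affected group.
#' @param affectedGroup Group carrying the fold (default second unique
#'   group).
#' @param dispersion,sizeFactors,baselineMeanLog,baselineSdLog,seed As in
#'   [spectralSimConfig()].
#' @return As [simulateSpectralCounts()].
#' @export
simulateSmallRnaCounts <- function(nGenes = 2000L,
                                   groups = rep(c("wt", "mutant"),
                                                each = 2),
                                   affectedIdx = integer(0), fold = 8,
                                   affectedGroup = NULL,
                                   dispersion = 0.1,
                                   sizeFactors = rep(1, length(groups)),
                                   baselineMeanLog = log(20),
                                   baselineSdLog = 1.2, seed = 1L) {
  if (is.null(affectedGroup))
    affectedGroup <- if (length(unique(groups)) > 1) unique(groups)[2]
                     else groups[1]
  cfg <- spectralSimConfig(nProteins = nGenes, groups = groups,
                           sizeFactors = sizeFactors,
                           dispersion = dispersion,
                           enrichedIdx = affectedIdx, fold = fold,
                           enrichedGroup = affectedGroup,
                           baselineMeanLog = baselineMeanLog,
                           baselineSdLog = baselineSdLog, seed = seed)
  out <- simulateSpectralCounts(cfg)
  rownames(out$counts) <- sprintf("mRNA%05d", seq_len(nGenes))
  out$truth$feature <- rownames(out$counts)[affectedIdx]
  out
}

#' Configuration for the decay-curve simulator
#'
#' @param halfLife True half-life in minutes.
#' @param timepoints Sampling times in minutes; must include 0.
#' @param initialSignal Mean intensity at time 0 (arbitrary densitometry
#'   units).
#' @param overdispersion Variance-to-mean ratio of the intensity noise
#'   (>= 1; 1 gives Poisson noise).
#' @param seed Integer seed.
#' @return A validated config list of class `DecaySimConfig`.
#' @export
decaySimConfig <- function(halfLife = 12,
                           timepoints = c(0, 2, 5, 10, 15, 20, 30, 45, 60),
                           initialSignal = 1000, overdispersion = 2,
                           seed = 1L) {
  if (halfLife <= 0) stop("half-life must be positive")
  if (any(timepoints < 0) || !any(timepoints == 0))
    stop("timepoints must be non-negative and include 0")
  if (overdispersion < 1) stop("overdispersion must be >= 1")
  structure(list(halfLife = halfLife, timepoints = timepoints,
                 initialSignal = initialSignal,
                 overdispersion = overdispersion, seed = as.integer(seed)),
            class = "DecaySimConfig")
}

#' Simulate an exponential decay time course with overdispersed noise
#'
#' Mean intensity follows `initialSignal * 2^(-t / halfLife)`; noise is
#' negative binomial parameterized so that the variance-to-mean ratio is
#' exactly `overdispersion` (Poisson for 1).
#'
#' @param config A [decaySimConfig()].
#' @return A data.frame with columns `time_min` and `intensity`.
#' @export
simulateDecayCurve <- function(config) {
  stopifnot(inherits(config, "DecaySimConfig"))
  set.seed(config$seed)
  mu <- config$initialSignal * 2^(-config$timepoints / config$halfLife)
  d <- config$overdispersion
  y <- if (d <= 1) stats::rpois(length(mu), mu)
       else stats::rnbinom(length(mu), size = mu / (d - 1), mu = mu)
  data.frame(time_min = config$timepoints, intensity = as.numeric(y))
}

#' Simulate a per-read nanopore DRS poly(A) length table
#'
#' Gene-level median poly(A) lengths are log-normal across genes; per-read
#' estimates are log-normal around the gene median. The genotype shift is
#' an additive change of the per-gene location (in nt, floored at 1 nt)
#' applied to the second genotype.
#'
#' @param nGenes Number of genes.
#' @param readsPerGene Expected reads per gene x replicate x genotype cell;
#'   either a single number (Poisson draw) or a function `f(n)` returning
#'   `n` counts.
#' @param geneMedianMeanLog,geneMedianSdLog Log-normal parameters of the
#'   per-gene median poly(A) length (defaults centred near 70 nt).
#' @param readSdLog Read-level log-normal sd around the gene location.
#' @param genotypeShift Additive shift (nt) of the per-gene location in the
#'   second genotype; negative values emulate a deadenylation-prone mutant.
#' @param genotypes Character length-2 genotype labels.
#' @param replicates Number of replicates per genotype.
#' @param seed Integer seed.
#' @return A data.frame with columns `gene`, `replicate`, `genotype`,
#'   `polyA_len_estimate` (continuous, positive).
#' @export
simulateDrsTable <- function(nGenes = 50L, readsPerGene = 150,
                             geneMedianMeanLog = log(70),
                             geneMedianSdLog = 0.35, readSdLog = 0.25,
                             genotypeShift = 0,
                             genotypes = c("WT", "mut"),
                             replicates = 3L, seed = 1L) {
  set.seed(seed)
  geneMed <- stats::rlnorm(nGenes, geneMedianMeanLog, geneMedianSdLog)
  genes <- sprintf("gene%04d", seq_len(nGenes))
  drawN <- if (is.function(readsPerGene)) readsPerGene
           else function(n) stats::rpois(n, readsPerGene)
  res <- vector("list", 2L * replicates)
  k <- 0L
  for (gt in seq_along(genotypes)) {
    loc <- pmax(geneMed + if (gt == 2) genotypeShift else 0, 1)
    for (rep in seq_len(replicates)) {
      nr <- drawN(nGenes)
      k <- k + 1L
      res[[k]] <- data.frame(
        gene = rep(genes, nr),
        replicate = rep, genotype = genotypes[gt],
        polyA_len_estimate = rep(loc, nr) *
          exp(stats::rnorm(sum(nr), 0, readSdLog) - readSdLog^2 / 2))
    }
  }
  do.call(rbind, res)
}

#' Simulate a gene table pairing uridylation propensity with half-life
#'
#' Emulates the comparison of transcriptome-wide uridylation percentages
#' with mRNA half-lives: uridylation percentages are drawn from a scaled
#' Beta distribution and the conditional median half-life decreases
#' monotonically with uridylation.
#'
#' @param nGenes Number of genes.
#' @param uridylationMax Upper bound of the uridylation percentage support
#'   (default 24, the span observed across profiled mRNAs).
#' @param betaShape1,betaShape2 Beta shape parameters for the uridylation
#'   distribution (defaults skew toward low uridylation).
#' @param halfLifeAt0 Median half-life (minutes) at 0% uridylation.
#' @param slope Change in median half-life per uridylation percentage
#'   point; must be <= 0 for the monotone-decreasing relation. Use 0 for
#'   the independence (flat) null.
#' @param noiseSdLog Log-normal noise of half-lives around the conditional
#'   median (0 for a deterministic relation).
#' @param seed Integer seed.
#' @return A data.frame with columns `gene`, `uridylation_pct`,
#'   `half_life`.
#' @export
simulateHalfLifeTable <- function(nGenes = 2000L, uridylationMax = 24,
                                  betaShape1 = 1.2, betaShape2 = 4,
                                  halfLifeAt0 = 200, slope = -6,
                                  noiseSdLog = 0.4, seed = 1L) {
  if (slope > 0) stop("conditional median must be monotone non-increasing")
  set.seed(seed)
  u <- uridylationMax * stats::rbeta(nGenes, betaShape1, betaShape2)
  med <- pmax(halfLifeAt0 + slope * u, 5)
  hl <- med * exp(stats::rnorm(nGenes, 0, noiseSdLog))
  data.frame(gene = sprintf("gene%05d", seq_len(nGenes)),
             uridylation_pct = u, half_life = hl)
}
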
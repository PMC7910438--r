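#' Configuration for the targeted 3'-end read simulator
#'
#' Defines the generative model for paired 41 x 111 nt tail-sequencing
#' reads: a three-component mixture of poly(A) length classes (short < 10
#' nt, oligo(A) 10-25 nt, long 26 nt and above, truncated), per-class
#' uridylation probabilities, a shifted-geometric distribution for the
#' number of added uridines, A-rich interruptions, and a uniform per-base
#' substitution error rate.
#'
#' @param nReads Number of read pairs.
#' @param catalog A [ReferenceCatalog-class]; reads are spread uniformly
#'   over its genes.
#' @param mixtureWeights Numeric length-3, weights of the short/oligo/long
#'   poly(A) classes; must sum to 1.
#' @param shortRange,oligoRange Integer length-2 ranges (inclusive) for the
#'   short and oligo classes; lengths are uniform within each.
#' @param longMax Truncation of the long class; lengths are
#'   `26 + Geometric(longDecay)` truncated at `longMax`.
#' @param longDecay Geometric decay parameter of the long class.
#' @param pUridylationByClass Numeric length-3, probability that a tail of
#'   each class carries at least one terminal uridine.
#' @param uCountMean Mean of the shifted-geometric added-U count
#'   (`1 + Geometric(p)` with mean `uCountMean`; default 1.5 so most tails
#'   get 1-2 uridines).
#' @param pArich Probability a tail is A-rich (contains internal non-A).
#' @param arichRate Per-position interruption probability inside an A-rich
#'   poly(A) segment (the final segment position is never interrupted, so
#'   the heteropolymeric core still ends in A and the terminal-U count
#'   stays well defined).
#' @param pUntailed Probability of an untailed read (tail length 0).
#' @param seqErrorRate Per-base substitution probability applied to both
#'   reads.
#' @param readLengths Integer length-2, widths of the gene-identification
#'   and tail-side reads (default `c(41, 111)`).
#' @param seed Integer seed; identical seed and config give byte-identical
#'   output.
#' @return A validated config list of class `TailSimConfig`.
#' @export
tailSimConfig <- function(nReads = 10000L, catalog,
                          mixtureWeights = c(0.10, 0.45, 0.45),
                          shortRange = c(1L, 9L), oligoRange = c(10L, 25L),
                          longMax = 250L, longDecay = 0.04,
                          pUridylationByClass = c(0.10, 0.20, 0.02),
                          uCountMean = 1.5, pArich = 0.02,
                          arichRate = 0.10, pUntailed = 0.01,
                          seqErrorRate = 0.001, readLengths = c(41L, 111L),
                          seed = 1L) {
  stopifnot(is(catalog, "ReferenceCatalog"), length(geneIds(catalog)) > 0)
  if (abs(sum(mixtureWeights) - 1) > 1e-8)
    stop("mixture weights must sum to 1")
  probs <- c(pUridylationByClass, pArich, pUntailed, seqErrorRate)
  if (any(probs < 0 | probs > 1) || arichRate < 0 || arichRate > 1)
    stop("all probabilities must lie in [0, 1]")
  if (any(readLengths <= 0)) stop("read lengths must be positive")
  if (uCountMean < 1) stop("uCountMean must be >= 1")
  if (any(Biostrings::width(refSequences(catalog)) < 60))
    stop("reference sequences must be at least 60 nt")
  structure(list(nReads = as.integer(nReads), catalog = catalog,
                 mixtureWeights = mixtureWeights,
                 shortRange = as.integer(shortRange),
                 oligoRange = as.integer(oligoRange),
                 longMax = as.integer(longMax), longDecay = longDecay,
                 pUridylationByClass = pUridylationByClass,
                 uCountMean = uCountMean, pArich = pArich,
                 arichRate = arichRate, pUntailed = pUntailed,
                 seqErrorRate = seqErrorRate,
                 readLengths = as.integer(readLengths),
                 seed = as.integer(seed)),
            class = "TailSimConfig")
}

.applySubstitutions <- function(seqs, rate) {
  if (rate <= 0) return(seqs)
  bases <- c("A", "C", "G", "T")
  vapply(seqs, function(s) {
    ch <- strsplit(s, "", fixed = TRUE)[[1]]
    hit <- which(stats::runif(length(ch)) < rate)
    for (i in hit)
      ch[i] <- sample(setdiff(bases, ch[i]), 1L)
    paste(ch, collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

#' Simulate paired targeted 3'-end sequencing reads with ground truth
#'
#' Builds, for each read, an RNA molecule consisting of the gene's sense
#' 3'-region up to its main polyadenylation site followed by a simulated
#' tail (poly(A) segment, optional A-rich interruptions, optional terminal
#' uridines). Read 1 is the first `readLengths[1]` nt of the gene region;
#' read 2 is the reverse complement of the molecule's last `readLengths[2]`
#' nt, so its first base is the complement of the RNA 3' terminus.
#' Substitution errors are applied to both reads after layout. The truth
#' table records the error-free tail and its decomposition.
#'
#' @param config A [tailSimConfig()].
#' @param outDir Optional directory; when given, paired FASTQ files
#'   (`reads_R1.fastq`, `reads_R2.fastq`, constant quality `I`) and a
#'   `truth.tsv` table are written there.
#' @return A list with `r1`, `r2` (named character vectors of read
#'   sequences), `truth` (a [S4Vectors::DataFrame] of per-read ground
#'   truth) and, if `outDir` was given, the file paths.
#' @export
simulateTailReads <- function(config, outDir = NULL) {
  stopifnot(inherits(config, "TailSimConfig"))
  set.seed(config$seed)
  n <- config$nReads
  cat <- config$catalog
  ids <- sprintf("read%06d", seq_len(n))
  gene <- sample(geneIds(cat), n, replace = TRUE)

  cls <- sample(c("short", "oligo", "long"), n, replace = TRUE,
                prob = config$mixtureWeights)
  sampleRange <- function(rng, k) {
    vals <- seq.int(rng[1], rng[2])
    vals[sample.int(length(vals), k, replace = TRUE)]
  }
  aLen <- integer(n)
  i <- cls == "short"
  aLen[i] <- sampleRange(config$shortRange, sum(i))
  i <- cls == "oligo"
  aLen[i] <- sampleRange(config$oligoRange, sum(i))
  i <- cls == "long"
  aLen[i] <- pmin(26L + stats::rgeom(sum(i), config$longDecay),
                  config$longMax)
  untailed <- stats::runif(n) < config$pUntailed
  aLen[untailed] <- 0L

  pU <- c(short = config$pUridylationByClass[1],
          oligo = config$pUridylationByClass[2],
          long = config$pUridylationByClass[3])[cls]
  uridylated <- stats::runif(n) < pU & !untailed
  pGeom <- 1 / config$uCountMean
  nU <- integer(n)
  nU[uridylated] <- 1L + stats::rgeom(sum(uridylated), pGeom)

  arich <- stats::runif(n) < config$pArich & aLen >= 2L
  tailSeq <- strrep("A", aLen)
  for (i in which(arich)) {
    ## interrupt internal positions only: the segment keeps a terminal A
    cand <- seq_len(aLen[i] - 1L)
    hit <- cand[stats::runif(length(cand)) < config$arichRate]
    if (length(hit) == 0L) hit <- sample(cand, 1L)
    ch <- strsplit(tailSeq[i], "", fixed = TRUE)[[1]]
    ch[hit] <- sample(c("C", "G", "U"), length(hit), replace = TRUE)
    tailSeq[i] <- paste(ch, collapse = "")
  }
  tailSeq <- paste0(tailSeq, strrep("U", nU))

  truthDecomp <- decomposeTail(tailSeq)
  site <- polyASites(cat)[gene]
  truth <- DataFrame(read_id = ids, gene_id = gene,
                     polyA_len = truthDecomp$polyA_len,
                     n_term_U = truthDecomp$n_term_U,
                     internal_nonA_positions =
                       I(as.list(truthDecomp$internal_nonA_positions)),
                     tail_class = truthDecomp$tail_class,
                     tail_seq = tailSeq,
                     end_offset = 0L,
                     length_class = cls)

  refs <- as.character(refSequences(cat))[gene]
  tailDNA <- chartr("U", "T", tailSeq)
  molecule <- paste0(substr(refs, 1L, site + 1L), tailDNA)
  w1 <- config$readLengths[1]; w2 <- config$readLengths[2]
  if (any(nchar(refs) < w1) || any(nchar(molecule) < w2))
    stop("read length exceeds template length")
  r1 <- substr(refs, 1L, w1)
  tailEnd <- nchar(molecule)
  r2sense <- substr(molecule, tailEnd - w2 + 1L, tailEnd)
  r2 <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAStringSet(r2sense)))
  r1 <- .applySubstitutions(r1, config$seqErrorRate)
  r2 <- .applySubstitutions(r2, config$seqErrorRate)
  names(r1) <- names(r2) <- ids

  out <- list(r1 = r1, r2 = r2, truth = truth)
  if (!is.null(outDir)) {
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
    f1 <- file.path(outDir, "reads_R1.fastq")
    f2 <- file.path(outDir, "reads_R2.fastq")
    .writeFastq(r1, f1); .writeFastq(r2, f2)
    ft <- file.path(outDir, "truth.tsv")
    tt <- as.data.frame(truth)
    tt$internal_nonA_positions <- vapply(
      truth$internal_nonA_positions,
      function(p) paste(p, collapse = ","), character(1))
    utils::write.table(tt, ft, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    out$files <- c(r1 = f1, r2 = f2, truth = ft)
  }
  out
}

.writeFastq <- function(seqs, path) {
  dna <- Biostrings::DNAStringSet(seqs)
  qual <- Biostrings::PhredQuality(strrep("I", nchar(seqs)))
  qdna <- Biostrings::QualityScaledDNAStringSet(dna, qual)
  Biostrings::writeQualityScaledXStringSet(qdna, path)
}
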
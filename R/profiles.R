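#' Tail-length size distribution
#'
#' Computes the percentage of reads per integer tail length over the 1-90
#' nt reporting range. Following the reporting convention for targeted
#' 3'-end libraries, percentages are computed over reads with tails of 1-90
#' nt, and tails longer than 90 nt are reported separately as a fraction of
#' all tailed reads.
#'
#' @param x A [TailCalls-class], or an integer vector of tail lengths.
#' @param classes Optional subset of tail classes to include (e.g.
#'   `"uridylated"` for the uridylated-tail profile, `"non_uridylated"` for
#'   homopolymeric poly(A) tails). Untailed reads are never included.
#' @return A [TailDistribution-class].
#' @examples
#' sizeDistribution(c(14L, 14L, 20L))
#' @export
sizeDistribution <- function(x, classes = NULL) {
  if (is(x, "TailCalls")) {
    calls <- tailCalls(x)
    keep <- calls$tail_class != "untailed"
    if (!is.null(classes)) keep <- keep & calls$tail_class %in% classes
    len <- calls$total_tail_len[keep]
  } else {
    len <- as.integer(x)
    len <- len[len > 0]
  }
  nTotal <- length(len)
  in90 <- len >= 1L & len <= 90L
  n90 <- sum(in90)
  pct <- tabulate(len[in90], nbins = 90L)
  pct <- if (n90 > 0) 100 * pct / n90 else numeric(90)
  new("TailDistribution", pctByLen = pct,
      fracGt90 = if (nTotal > 0) sum(len > 90L) / nTotal else 0,
      n1to90 = as.integer(n90), nTotal = as.integer(nTotal))
}

#' Per-gene uridylation percentage
#'
#' 100 x (uridylated reads) / (tailed reads) per gene, reported only for
#' genes detected with at least `minReads` tailed reads (the detection
#' filter used for transcriptome-wide uridylation profiling).
#'
#' @param x A [TailCalls-class].
#' @param minReads Minimum tailed reads per gene (default 20).
#' @return A data.frame with columns `gene_id`, `n_reads`,
#'   `uridylation_pct` (`NA` below the detection threshold).
#' @export
uridylationPercent <- function(x, minReads = 20L) {
  stopifnot(is(x, "TailCalls"))
  calls <- tailCalls(x)
  tailed <- calls[calls$tail_class != "untailed", , drop = FALSE]
  genes <- unique(calls$gene_id)
  n <- vapply(genes, function(g) sum(tailed$gene_id == g), integer(1))
  nU <- vapply(genes, function(g)
    sum(tailed$gene_id == g & tailed$tail_class == "uridylated"),
    integer(1))
  pct <- ifelse(n >= minReads, 100 * nU / n, NA_real_)
  data.frame(gene_id = genes, n_reads = n, uridylation_pct = pct,
             row.names = NULL)
}

#' Tail-length class bins per gene
#'
#' Fractions of tailed reads in the three biologically meaningful tail-size
#' bins: excessively deadenylated (< 10 nt, i.e. 1-9), oligo(A) (10-25 nt,
#' the preferred uridylation substrate) and longer (> 25 nt).
#'
#' @param x A [TailCalls-class] or integer vector of tail lengths.
#' @param denominator Either `"tailed"` (all tailed reads; default) or
#'   `"len1to90"` (reads with tails 1-90 nt, the percentage-profile
#'   convention — with 111-nt tail reads, tails much beyond 90 nt are not
#'   measurable anyway).
#' @param byGene Summarize per gene (requires a `TailCalls`)?
#' @return A data.frame with columns `n_reads`, `frac_lt10`,
#'   `frac_10to25`, `frac_gt25` (and `gene_id` when `byGene`).
#' @examples
#' classLengthBins(c(9L, 10L, 25L, 26L))
#' @export
classLengthBins <- function(x, denominator = c("tailed", "len1to90"),
                            byGene = FALSE) {
  denominator <- match.arg(denominator)
  binOne <- function(len) {
    len <- len[len > 0]
    if (denominator == "len1to90") len <- len[len <= 90]
    n <- length(len)
    data.frame(n_reads = n,
               frac_lt10 = if (n) sum(len < 10) / n else NA_real_,
               frac_10to25 = if (n) sum(len >= 10 & len <= 25) / n
                             else NA_real_,
               frac_gt25 = if (n) sum(len > 25) / n else NA_real_)
  }
  if (is(x, "TailCalls")) {
    calls <- tailCalls(x)
    calls <- calls[calls$tail_class != "untailed", , drop = FALSE]
    if (byGene) {
      res <- do.call(rbind, lapply(split(calls$total_tail_len,
                                         calls$gene_id), binOne))
      res <- cbind(gene_id = rownames(res), res)
      rownames(res) <- NULL
      return(res)
    }
    return(binOne(calls$total_tail_len))
  }
  binOne(as.integer(x))
}

#' Bulk DRS poly(A) profile
#'
#' 1-nt binning of rounded nanopore poly(A) length estimates, per genotype
#' and replicate, plus the per-genotype replicate average. Percentages are
#' computed over reads whose rounded length falls within `range`.
#'
#' @param drs A data.frame as from [simulateDrsTable()] (columns `gene`,
#'   `replicate`, `genotype`, `polyA_len_estimate`).
#' @param range Integer length-2 reporting range (default `c(1, 250)`).
#' @return A list with `profiles` (data.frame: genotype, replicate, length,
#'   pct) and `average` (data.frame: genotype, length, pct).
#' @export
drsBulkProfile <- function(drs, range = c(1L, 250L)) {
  stopifnot(all(c("gene", "replicate", "genotype",
                  "polyA_len_estimate") %in% names(drs)))
  if (any(drs$polyA_len_estimate <= 0))
    stop("poly(A) length estimates must be positive")
  lens <- as.integer(floor(drs$polyA_len_estimate + 0.5))  # round half-up
  keep <- lens >= range[1] & lens <= range[2]
  d <- data.frame(genotype = drs$genotype[keep],
                  replicate = drs$replicate[keep], length = lens[keep])
  prof <- do.call(rbind, lapply(
    split(d, list(d$genotype, d$replicate), drop = TRUE),
    function(g) {
      tab <- tabulate(g$length - range[1] + 1L,
                      nbins = range[2] - range[1] + 1L)
      data.frame(genotype = g$genotype[1], replicate = g$replicate[1],
                 length = seq(range[1], range[2]),
                 pct = 100 * tab / sum(tab))
    }))
  rownames(prof) <- NULL
  avg <- stats::aggregate(pct ~ genotype + length, prof, mean)
  list(profiles = prof, average = avg[order(avg$genotype, avg$length), ])
}

#' Median per-gene DRS poly(A) profile
#'
#' A gene enters the profile only when it is detected with at least
#' `minReads` reads in every replicate x genotype cell. For each eligible
#' gene and genotype a percentage profile over 1-nt bins is computed
#' (replicates pooled), and the reported profile is the per-bin median
#' across genes.
#'
#' @inheritParams drsBulkProfile
#' @param minReads Detection threshold per replicate x genotype cell
#'   (default 100).
#' @return A list with `median` (data.frame: genotype, length, pct),
#'   `eligible` (character vector of gene ids) and `perGene` (array of
#'   per-gene profiles).
#' @export
drsMedianGeneProfile <- function(drs, minReads = 100L,
                                 range = c(1L, 250L)) {
  stopifnot(all(c("gene", "replicate", "genotype",
                  "polyA_len_estimate") %in% names(drs)))
  cellCounts <- table(drs$gene, interaction(drs$genotype, drs$replicate,
                                            drop = TRUE))
  eligible <- rownames(cellCounts)[apply(cellCounts >= minReads, 1, all)]
  nb <- range[2] - range[1] + 1L
  lens <- as.integer(floor(drs$polyA_len_estimate + 0.5))
  keep <- drs$gene %in% eligible & lens >= range[1] & lens <= range[2]
  d <- data.frame(gene = drs$gene[keep], genotype = drs$genotype[keep],
                  length = lens[keep])
  genotypes <- unique(d$genotype)
  perGene <- array(NA_real_, dim = c(length(eligible), nb,
                                     length(genotypes)),
                   dimnames = list(eligible, NULL, genotypes))
  for (gt in genotypes) {
    dd <- d[d$genotype == gt, ]
    for (g in eligible) {
      tab <- tabulate(dd$length[dd$gene == g] - range[1] + 1L, nbins = nb)
      perGene[g, , gt] <- 100 * tab / max(sum(tab), 1L)
    }
  }
  med <- do.call(rbind, lapply(genotypes, function(gt)
    data.frame(genotype = gt, length = seq(range[1], range[2]),
               pct = apply(perGene[, , gt, drop = FALSE], 2,
                           stats::median))))
  list(median = med, eligible = eligible, perGene = perGene)
}
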
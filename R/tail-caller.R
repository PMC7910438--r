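#' Parameters for gene assignment and tail extraction
#'
#' @param geneAssignMaxMismatch Maximum substitutions tolerated when matching
#'   the gene-identification read against a catalog prefix (default 1).
#'   Reads matching two genes within budget are left unassigned.
#' @param anchorMinMatch Minimum templated anchor, in nt, required to align
#'   the tail-side read to the reference (default 12).
#' @param siteWindow Half-width, in nt, of the window around the main
#'   polyadenylation site used by [filterBySite()] (default 50).
#' @param maxTailLen Tails are truncated at this length (default 250).
#' @return A named list of caller parameters.
#' @export
callerParams <- function(geneAssignMaxMismatch = 1L, anchorMinMatch = 12L,
                         siteWindow = 50L, maxTailLen = 250L) {
  p <- list(geneAssignMaxMismatch = as.integer(geneAssignMaxMismatch),
            anchorMinMatch = as.integer(anchorMinMatch),
            siteWindow = as.integer(siteWindow),
            maxTailLen = as.integer(maxTailLen))
  if (any(unlist(p) < 0)) stop("caller parameters must be non-negative")
  p
}

## split a character vector of equal-width strings into a matrix of single
## characters (rows = strings)
.charMatrix <- function(x, width) {
  matrix(unlist(strsplit(x, "", fixed = TRUE), use.names = FALSE),
         ncol = width, byrow = TRUE)
}

#' Decompose 3' tails into poly(A), terminal uridines and internal non-A
#'
#' Implements the tail classification rule. Scanning from the 3' terminus of
#' the RNA-sense tail: the maximal terminal run of `U` gives `n_term_U`; any
#' trailing run of `C`/`G` immediately upstream marks an other-nucleotide 3'
#' addition; the remaining (core) segment contributes `polyA_len` (its
#' number of `A`s). A core containing at least one non-A nucleotide makes
#' the tail A-rich; otherwise the tail is uridylated (`n_term_U >= 1`),
#' non-uridylated (pure poly(A)), or carries only an other-nucleotide 3'
#' addition. An empty tail is untailed.
#'
#' @param tails Character vector of RNA-sense tails (alphabet `A`,`C`,`G`,
#'   `U`; 5'->3', last character is the RNA 3' terminus). `T` is accepted
#'   as a synonym of `U`.
#' @return A [S4Vectors::DataFrame] with one row per tail and columns
#'   `tail_seq`, `polyA_len`, `n_term_U`, `n_other3p`,
#'   `internal_nonA_positions` (list of 0-based offsets within the tail),
#'   `tail_class` and `total_tail_len`.
#' @examples
#' decomposeTail(c("AAAAAAAAAAAAAA", "AAAAAAAAAAAAUU", "AAAAAGAAAAU", ""))
#' @export
decomposeTail <- function(tails) {
  tails <- chartr("t", "T", chartr("T", "U", toupper(tails)))
  bad <- grepl("[^ACGU]", tails)
  if (any(bad))
    stop("invalid character in tail sequence: ",
         paste(utils::head(tails[bad], 3), collapse = ", "))
  total <- nchar(tails)
  noU <- sub("U*$", "", tails)
  nTermU <- total - nchar(noU)
  core <- sub("[CG]*$", "", noU)
  nOther <- nchar(noU) - nchar(core)
  nA <- nchar(gsub("[^A]", "", core))
  nNonA <- nchar(core) - nA
  cls <- rep("non_uridylated", length(tails))
  cls[nTermU > 0] <- "uridylated"
  cls[nOther > 0] <- "other_3p_addition"
  cls[nNonA > 0] <- "a_rich"
  cls[total == 0] <- "untailed"
  pos <- gregexpr("[^A]", core)
  pos <- lapply(pos, function(p) if (p[1] == -1L) integer(0)
                                 else as.integer(p) - 1L)
  DataFrame(tail_seq = tails, polyA_len = nA, n_term_U = nTermU,
            n_other3p = nOther,
            internal_nonA_positions = I(pos),
            tail_class = cls, total_tail_len = total)
}

#' Assign gene-identification reads to catalog genes
#'
#' Matches each read-1 sequence against the equally long prefix of every
#' gene's sense 3'-region. A read is assigned to the unique gene matching
#' with at most `geneAssignMaxMismatch` substitutions; reads matching no
#' gene, or more than one, are unassigned.
#'
#' @param read1 Character vector of gene-identification reads (DNA, equal
#'   width).
#' @param catalog A [ReferenceCatalog-class].
#' @param params See [callerParams()].
#' @return Character vector of gene ids, `NA` for unassigned reads.
#' @export
assignGene <- function(read1, catalog, params = callerParams()) {
  if (length(geneIds(catalog)) == 0) stop("empty reference catalog")
  if (length(read1) == 0) return(character(0))
  w <- unique(nchar(read1))
  if (length(w) != 1)
    stop("gene-identification reads must have equal width")
  if (w < params$anchorMinMatch)
    stop("reads shorter than the minimum anchor")
  refs <- as.character(Biostrings::subseq(refSequences(catalog), 1L,
                                          pmin(w, Biostrings::width(
                                            refSequences(catalog)))))
  rm <- .charMatrix(toupper(read1), w)
  nHit <- integer(length(read1))
  hit <- rep(NA_character_, length(read1))
  for (g in seq_along(refs)) {
    pc <- strsplit(refs[g], "", fixed = TRUE)[[1]]
    if (length(pc) < w) next
    mm <- rowSums(rm != matrix(pc, nrow(rm), w, byrow = TRUE))
    ok <- mm <= params$geneAssignMaxMismatch
    nHit <- nHit + ok
    hit[ok] <- geneIds(catalog)[g]
  }
  hit[nHit != 1L] <- NA_character_
  hit
}

## Align the sense-oriented tail-side sequence of one gene's reads to its
## reference and locate the templated/tail boundary. Returns per-read
## tail (DNA chars), end offset, and an alignable flag.
.extractTailGene <- function(senseReads, refSeq, site0, params) {
  L <- nchar(refSeq)
  rc <- strsplit(refSeq, "", fixed = TRUE)[[1]]
  K <- length(senseReads)
  w <- unique(nchar(senseReads))
  stopifnot(length(w) == 1)
  rdm <- .charMatrix(senseReads, w)
  A <- params$anchorMinMatch
  ## anchor search: best start s of the read prefix within the reference
  nStart <- L - A + 1L
  bestS <- rep(NA_integer_, K)
  bestMM <- rep(Inf, K)
  anchor <- rdm[, seq_len(A), drop = FALSE]
  for (s in seq_len(nStart)) {
    mm <- rowSums(anchor != matrix(rc[s:(s + A - 1L)], K, A, byrow = TRUE))
    upd <- mm <= 1L & mm < bestMM
    bestS[upd] <- s
    bestMM[upd] <- mm[upd]
  }
  tail <- rep(NA_character_, K)
  offset <- rep(NA_integer_, K)
  alignable <- !is.na(bestS)
  for (i in which(alignable)) {
    s <- bestS[i]
    span <- min(w, L - s + 1L)          # templated span available in ref
    cmp <- rdm[i, seq_len(span)] != rc[s:(s + span - 1L)]
    mmpos <- which(cmp)
    E <- span                            # boundary: last templated read pos
    if (length(mmpos) >= 3) {
      ## a non-templated region mismatches the reference densely (~3/4 of
      ## positions); isolated substitutions from sequencing error do not.
      ## Stop at the first cluster of 3 mismatches within one anchor
      ## length and place the boundary before its first mismatch.
      j <- which(mmpos[-(1:2)] - mmpos[seq_len(length(mmpos) - 2L)] < A)
      if (length(j)) E <- min(E, mmpos[j[1]] - 1L)
    }
    tl <- substr(senseReads[i], E + 1L, w)
    if (nchar(tl) > params$maxTailLen)
      tl <- substr(tl, 1L, params$maxTailLen)
    tail[i] <- tl
    offset[i] <- (s + E - 2L) - site0    # 0-based end - site
  }
  list(tail = tail, end_offset = offset, alignable = alignable)
}

#' Extract the 3' tail from tail-side reads
#'
#' Reverse-complements read 2 into RNA sense, anchors its prefix to the gene
#' reference (allowing one substitution in the anchor), and extends the
#' templated match until two mismatches fall within one anchor length, the
#' reference is exhausted, or the read ends. Everything 3' of the last
#' templated base is the tail.
#'
#' @param read2 Character vector of tail-side reads (DNA, as sequenced).
#' @param catalog A [ReferenceCatalog-class].
#' @param geneId Gene id (single) the reads belong to.
#' @param params See [callerParams()].
#' @return A list with `tail_seq` (RNA sense), `end_offset` (signed nt from
#'   the main polyadenylation site) and `alignable`.
#' @export
extractTail <- function(read2, catalog, geneId, params = callerParams()) {
  stopifnot(geneId %in% geneIds(catalog))
  sense <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAStringSet(toupper(read2))))
  res <- .extractTailGene(sense, as.character(refSequences(catalog)[[geneId]]),
                          polyASites(catalog)[[geneId]], params)
  list(tail_seq = ifelse(is.na(res$tail), NA_character_,
                         chartr("T", "U", res$tail)),
       end_offset = res$end_offset, alignable = res$alignable)
}

#' Call tails for a paired 3'-end sequencing run
#'
#' Full read-level pipeline: assign each read pair to a gene from its
#' gene-identification read, recover the RNA-sense tail from the tail-side
#' read, and decompose it into poly(A) length, terminal uridines and class.
#'
#' @param r1,r2 Paths to the paired FASTQ files (read 1 = gene
#'   identification, read 2 = tail side), or character vectors of sequences
#'   named by read id.
#' @param catalog A [ReferenceCatalog-class].
#' @param params See [callerParams()].
#' @return A [TailCalls-class] with one row per assigned, alignable read and
#'   a disposition summary (`assigned`, `unassigned`, `unalignable`).
#' @export
callReads <- function(r1, r2, catalog, params = callerParams()) {
  readFq <- function(x) {
    if (length(x) == 1 && file.exists(x)) {
      s <- Biostrings::readDNAStringSet(x, format = "fastq")
      stats::setNames(as.character(s), sub("\\s.*$", "", names(s)))
    } else as.character(x)
  }
  s1 <- readFq(r1); s2 <- readFq(r2)
  if (length(s1) != length(s2))
    stop("mismatched pair files: ", length(s1), " vs ", length(s2),
         " reads")
  if (!is.null(names(s1)) && !is.null(names(s2)) &&
      !identical(names(s1), names(s2)))
    stop("read ids of the two files are not paired")
  n <- length(s1)
  emptyCalls <- decomposeTail(character(0))
  emptyCalls$read_id <- character(0); emptyCalls$gene_id <- character(0)
  emptyCalls$end_offset <- integer(0)
  if (n == 0)
    return(new("TailCalls", calls = emptyCalls,
               disposition = c(assigned = 0L, unassigned = 0L,
                               unalignable = 0L),
               params = params))
  ids <- names(s1)
  if (is.null(ids)) ids <- sprintf("read%06d", seq_len(n))
  gene <- assignGene(s1, catalog, params)
  unassigned <- sum(is.na(gene))
  keep <- which(!is.na(gene))
  out <- vector("list", length(keep))
  tailSeq <- rep(NA_character_, n)
  offs <- rep(NA_integer_, n)
  ok <- rep(FALSE, n)
  for (g in unique(gene[keep])) {
    idx <- which(!is.na(gene) & gene == g)
    ex <- extractTail(s2[idx], catalog, g, params)
    tailSeq[idx] <- ex$tail_seq
    offs[idx] <- ex$end_offset
    ok[idx] <- ex$alignable
  }
  called <- which(!is.na(gene) & ok)
  unalignable <- length(keep) - length(called)
  calls <- decomposeTail(tailSeq[called])
  calls$read_id <- ids[called]
  calls$gene_id <- gene[called]
  calls$end_offset <- offs[called]
  new("TailCalls", calls = calls,
      disposition = c(assigned = length(called),
                      unassigned = as.integer(unassigned),
                      unalignable = as.integer(unalignable)),
      params = params)
}

#' Keep calls whose 3' extremities map near the main polyadenylation site
#'
#' Retains reads whose templated 3' end lies within `windowNt` nucleotides
#' of the gene's main polyadenylation site.
#'
#' @param x A [TailCalls-class].
#' @param windowNt Window half-width in nt (default 50).
#' @return A filtered [TailCalls-class].
#' @export
filterBySite <- function(x, windowNt = 50L) {
  stopifnot(is(x, "TailCalls"))
  keep <- !is.na(x@calls$end_offset) & abs(x@calls$end_offset) <= windowNt
  new("TailCalls", calls = x@calls[keep, , drop = FALSE],
      disposition = x@disposition, params = x@params)
}
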
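AA_ALPHABET <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

## Parse a position-set motif pattern: literal residues, 'x' wildcards,
## and bracketed residue sets like "[LM]xx[LF]". Returns a list of allowed
## residue sets, one per slot.
.parseMotifPattern <- function(pattern) {
  slots <- list()
  i <- 1L
  ch <- strsplit(pattern, "", fixed = TRUE)[[1]]
  while (i <= length(ch)) {
    if (ch[i] == "[") {
      j <- i + 1L
      while (j <= length(ch) && ch[j] != "]") j <- j + 1L
      if (j > length(ch)) stop("unclosed '[' in motif pattern")
      set <- ch[(i + 1L):(j - 1L)]
      i <- j + 1L
    } else if (ch[i] %in% c("x", "X", ".")) {
      set <- AA_ALPHABET
      i <- i + 1L
    } else {
      set <- ch[i]
      i <- i + 1L
    }
    if (!all(set %in% AA_ALPHABET))
      stop("invalid residue in motif pattern: ",
           paste(setdiff(set, AA_ALPHABET), collapse = ""))
    slots <- c(slots, list(set))
  }
  if (!length(slots)) stop("empty motif pattern")
  slots
}

#' Scan a protein sequence for a short linear motif
#'
#' Position-set semantics: each pattern slot lists its allowed residues —
#' a literal residue, a bracketed set (`"[LM]"`), or the wildcard `x`.
#' All leftmost non-overlapping matches are reported, with the
#' length-normalized position `(start + 1) / length x 100` used for
#' occurrence maps across orthologs.
#'
#' @param sequence Amino-acid sequence (single string, 20-letter
#'   alphabet).
#' @param pattern Motif pattern, e.g. the literal `"PPGF"` or a
#'   position-set pattern such as `"[LM]xx[IL]L"`.
#' @param id Optional sequence id carried into the output.
#' @return A data.frame of hits: `sequence_id`, `start` (0-based), `end`
#'   (exclusive), `normalized_position`.
#' @examples
#' scanMotif("AAPPGFAA", "PPGF")
#' @export
scanMotif <- function(sequence, pattern, id = NA_character_) {
  sequence <- toupper(sequence)
  ch <- strsplit(sequence, "", fixed = TRUE)[[1]]
  if (!all(ch %in% AA_ALPHABET))
    stop("invalid residue in sequence: ",
         paste(unique(setdiff(ch, AA_ALPHABET)), collapse = ""))
  slots <- .parseMotifPattern(pattern)
  k <- length(slots)
  n <- length(ch)
  starts <- integer(0)
  i <- 1L
  while (i <= n - k + 1L) {
    ok <- TRUE
    for (j in seq_len(k)) {
      if (!(ch[i + j - 1L] %in% slots[[j]])) { ok <- FALSE; break }
    }
    if (ok) {
      starts <- c(starts, i - 1L)   # 0-based
      i <- i + k                     # leftmost non-overlapping
    } else i <- i + 1L
  }
  data.frame(sequence_id = rep(id, length(starts)), start = starts,
             end = starts + k,
             normalized_position = (starts + 1) / n * 100)
}

#' Length-normalized motif occurrence map across sequences
#'
#' Maps motif hit positions onto a common 0-100 scale so that occurrences
#' can be compared across orthologs of different lengths (position 1 of a
#' length-L sequence maps to 100/L, the final position to 100).
#'
#' @param hits A data.frame of hits with `sequence_id` and `start`
#'   (0-based) columns.
#' @param lengths Named numeric vector of sequence lengths.
#' @return The hits with a recomputed `normalized_position` column.
#' @export
normalizedOccurrenceMap <- function(hits, lengths) {
  if (any(lengths <= 0)) stop("sequence lengths must be positive")
  L <- lengths[hits$sequence_id]
  hits$normalized_position <- (hits$start + 1) / L * 100
  hits
}

#' Information content of an alignment column, in bits
#'
#' `log2(20)` minus the Shannon entropy of the residue frequencies in the
#' column. Gaps (`-`, `.`) are excluded from the counts; an all-gap column
#' is undefined (`NA` with a warning).
#'
#' @param column Character vector of residues (one per aligned sequence).
#' @param smallSampleCorrection Subtract the Miller-Madow small-sample
#'   term `(k - 1) / (2 n ln 2)`? Off by default.
#' @return Information content in bits, in `[0, log2(20)]`.
#' @examples
#' columnInformation(rep("L", 10))          # log2(20)
#' columnInformation(c(rep("L", 10), rep("I", 10)))
#' @export
columnInformation <- function(column, smallSampleCorrection = FALSE) {
  column <- toupper(column)
  column <- column[!(column %in% c("-", "."))]
  if (!length(column)) {
    warning("all-gap column: information undefined")
    return(NA_real_)
  }
  if (!all(column %in% AA_ALPHABET))
    stop("invalid residue in column")
  f <- table(column) / length(column)
  h <- -sum(f * log2(f))
  ic <- log2(20) - h
  if (smallSampleCorrection)
    ic <- ic - (length(f) - 1) / (2 * length(column) * log(2))
  max(ic, 0)
}

#' Residue-group composition enrichment of a protein region
#'
#' Exact two-sided binomial test of the count of group residues (default
#' P/Q/N/G, the composition bias typical of the TUTase N-terminal
#' disordered region) in a region against a background frequency (e.g. the
#' proteome-wide frequency of those residues).
#'
#' @param region Amino-acid sequence of the region (single string).
#' @param residueGroup Character vector of residues in the group (default
#'   `c("P", "Q", "N", "G")`).
#' @param backgroundFreq Background probability of a group residue, in
#'   (0, 1).
#' @return A data.frame: `observed`, `region_length`, `expected`,
#'   `background_freq`, `p_two_sided`.
#' @export
compositionEnrichment <- function(region,
                                  residueGroup = c("P", "Q", "N", "G"),
                                  backgroundFreq) {
  if (backgroundFreq <= 0 || backgroundFreq >= 1)
    stop("background frequency must be in (0, 1)")
  ch <- strsplit(toupper(region), "", fixed = TRUE)[[1]]
  if (!length(ch)) stop("empty region")
  if (!all(ch %in% AA_ALPHABET)) stop("invalid residue in region")
  obs <- sum(ch %in% residueGroup)
  bt <- stats::binom.test(obs, length(ch), p = backgroundFreq,
                          alternative = "two.sided")
  data.frame(observed = obs, region_length = length(ch),
             expected = length(ch) * backgroundFreq,
             background_freq = backgroundFreq,
             p_two_sided = bt$p.value)
}
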
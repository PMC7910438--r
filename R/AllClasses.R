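#' @import methods
#' @importFrom S4Vectors DataFrame
NULL

TAIL_CLASSES <- c("uridylated", "non_uridylated", "a_rich",
                  "other_3p_addition", "untailed")

#' Reference catalog of gene 3'-end regions
#'
#' Holds, for each targeted gene, the sense-strand sequence of its 3' region
#' together with the 0-based coordinate of the last templated nucleotide (the
#' main polyadenylation site). Reads are assigned to genes against this
#' catalog, and tail extraction aligns the tail-side read to these sequences.
#'
#' @slot sequences A [Biostrings::DNAStringSet] of sense 3'-region sequences,
#'   one per gene, named by gene id.
#' @slot polyASites Named integer vector, 0-based coordinate of the last
#'   templated nucleotide within each sequence.
#'
#' @seealso [referenceCatalog()], [readReferenceCatalog()],
#'   [writeReferenceCatalog()]
#' @export
setClass("ReferenceCatalog",
  representation(sequences = "DNAStringSet", polyASites = "integer"))

setValidity("ReferenceCatalog", function(object) {
  msg <- NULL
  ids <- names(object@sequences)
  if (length(object@sequences) > 0 && (is.null(ids) || any(ids == "")))
    msg <- c(msg, "all sequences must be named by gene id")
  if (anyDuplicated(ids))
    msg <- c(msg, "duplicate gene ids in catalog")
  if (length(object@polyASites) != length(object@sequences))
    msg <- c(msg, "one polyA site per sequence required")
  if (!identical(names(object@polyASites), ids))
    msg <- c(msg, "polyASites names must match sequence names")
  if (length(object@sequences) > 0) {
    w <- Biostrings::width(object@sequences)
    if (any(w == 0))
      msg <- c(msg, "sequences must be non-empty")
    if (any(object@polyASites < 0 | object@polyASites >= w))
      msg <- c(msg, "polyA sites must lie within sequence bounds (0-based)")
  }
  if (is.null(msg)) TRUE else msg
})

#' Tail calls for a set of reads
#'
#' One row per read that could be assigned to a gene and aligned to its
#' reference, carrying the recovered tail in RNA sense together with its
#' decomposition (poly(A) length, terminal uridines, internal non-A
#' positions, class) and the signed offset of the templated 3' end from the
#' main polyadenylation site. A disposition summary records how many reads
#' were assigned, unassigned or unalignable.
#'
#' @slot calls A [S4Vectors::DataFrame] with columns `read_id`, `gene_id`,
#'   `tail_seq`, `polyA_len`, `n_term_U`, `n_other3p`,
#'   `internal_nonA_positions` (IntegerList-like list column, 0-based offsets
#'   within `tail_seq`), `tail_class`, `total_tail_len`, `end_offset`.
#' @slot disposition Named integer vector with counts for `assigned`,
#'   `unassigned`, `unalignable`.
#' @slot params List of caller parameters used (see [callerParams()]).
#'
#' @seealso [callReads()], [decomposeTail()], [filterBySite()]
#' @export
setClass("TailCalls",
  representation(calls = "DataFrame", disposition = "integer",
                 params = "list"))

setValidity("TailCalls", function(object) {
  need <- c("read_id", "gene_id", "tail_seq", "polyA_len", "n_term_U",
            "n_other3p", "internal_nonA_positions", "tail_class",
            "total_tail_len", "end_offset")
  msg <- NULL
  if (!all(need %in% colnames(object@calls)))
    msg <- c(msg, paste("calls must have columns:",
                        paste(setdiff(need, colnames(object@calls)),
                              collapse = ", ")))
  else {
    cl <- object@calls$tail_class
    if (length(cl) && !all(cl %in% TAIL_CLASSES))
      msg <- c(msg, "invalid tail_class value")
    if (length(cl) && any(object@calls$polyA_len < 0 |
                          object@calls$n_term_U < 0))
      msg <- c(msg, "polyA_len and n_term_U must be non-negative")
  }
  if (is.null(msg)) TRUE else msg
})

#' Tail-length distribution
#'
#' Percentages of reads per integer tail length over the 1-90 nt reporting
#' range, plus the fraction of all tailed reads whose tails exceed 90 nt.
#' Percentages are computed over the reads with tails of 1-90 nt only, so
#' they sum to 100 whenever at least one such read exists.
#'
#' @slot pctByLen Numeric vector of length 90; `pctByLen[k]` is the
#'   percentage of 1-90 nt tails having length `k`.
#' @slot fracGt90 Fraction (0-1) of all tailed reads with tail length > 90.
#' @slot n1to90 Number of tailed reads with length in 1-90.
#' @slot nTotal Total number of tailed reads considered.
#'
#' @seealso [sizeDistribution()], [drsBulkProfile()]
#' @export
setClass("TailDistribution",
  representation(pctByLen = "numeric", fracGt90 = "numeric",
                 n1to90 = "integer", nTotal = "integer"))

setValidity("TailDistribution", function(object) {
  msg <- NULL
  if (length(object@pctByLen) != 90)
    msg <- c(msg, "pctByLen must have length 90")
  if (object@n1to90 > 0 &&
      abs(sum(object@pctByLen) - 100) > 1e-9)
    msg <- c(msg, "percentages must sum to 100")
  if (object@fracGt90 < 0 || object@fracGt90 > 1)
    msg <- c(msg, "fracGt90 must be in [0, 1]")
  if (is.null(msg)) TRUE else msg
})

#' Decay-kinetics fit
#'
#' Result of a quasi-Poisson log-linear regression of band intensity on time:
#' the decay rate, the derived half-life with its delta-method standard
#' deviation, and the estimated quasi-dispersion.
#'
#' @slot rate Decay rate (1/min); negative of the fitted slope.
#' @slot halfLife Half-life in minutes, `log(2)/rate` (Inf when the slope is
#'   non-negative).
#' @slot halfLifeSD Delta-method standard deviation of the half-life.
#' @slot dispersion Estimated quasi-dispersion (Pearson).
#' @slot df Residual degrees of freedom of the fit.
#' @slot converged Logical, IRLS convergence flag.
#'
#' @seealso [fitDecayQuasipoisson()], [halfLifeInterval()]
#' @export
setClass("DecayFit",
  representation(rate = "numeric", halfLife = "numeric",
                 halfLifeSD = "numeric", dispersion = "numeric",
                 df = "integer", converged = "logical"))

setValidity("DecayFit", function(object) {
  msg <- NULL
  if (is.finite(object@rate) && object@rate > 1e-10 &&
      abs(object@halfLife - log(2) / object@rate) > 1e-8 * object@halfLife)
    msg <- c(msg, "halfLife must equal log(2)/rate for positive rates")
  if (is.finite(object@halfLifeSD) && object@halfLifeSD < 0)
    msg <- c(msg, "halfLifeSD must be non-negative")
  if (is.null(msg)) TRUE else msg
})

setMethod("show", "ReferenceCatalog", function(object) {
  cat("ReferenceCatalog with", length(object@sequences), "genes\n")
  if (length(object@sequences)) {
    w <- Biostrings::width(object@sequences)
    cat("  sequence widths:", min(w), "-", max(w), "nt\n")
  }
})

setMethod("show", "TailCalls", function(object) {
  cat("TailCalls with", nrow(object@calls), "called reads\n")
  d <- object@disposition
  cat("  disposition:",
      paste(names(d), d, sep = "=", collapse = ", "), "\n")
  if (nrow(object@calls)) {
    tab <- table(factor(object@calls$tail_class, levels = TAIL_CLASSES))
    cat("  classes:", paste(names(tab), tab, sep = "=", collapse = ", "),
        "\n")
  }
})

setMethod("show", "TailDistribution", function(object) {
  cat("TailDistribution over tails 1-90 nt\n")
  cat("  n (1-90):", object@n1to90, " n total:", object@nTotal, "\n")
  cat(sprintf("  fraction > 90 nt: %.4f\n", object@fracGt90))
  if (object@n1to90 > 0) {
    mode <- which.max(object@pctByLen)
    cat(sprintf("  modal length: %d nt (%.2f%%)\n", mode,
                object@pctByLen[mode]))
  }
})

setMethod("show", "DecayFit", function(object) {
  cat("DecayFit (quasi-Poisson log-linear)\n")
  cat(sprintf("  rate: %.5g /min   half-life: %.4g min (SD %.3g)\n",
              object@rate, object@halfLife, object@halfLifeSD))
  cat(sprintf("  quasi-dispersion: %.3g on %d df; converged: %s\n",
              object@dispersion, object@df, object@converged))
})

#' @describeIn ReferenceCatalog-class Accessor for the gene sequences.
#' @param x,object A `ReferenceCatalog`.
#' @export
refSequences <- function(x) x@sequences

#' @describeIn ReferenceCatalog-class Accessor for the 0-based main
#'   polyadenylation sites.
#' @export
polyASites <- function(x) x@polyASites

#' @describeIn ReferenceCatalog-class Gene ids in the catalog.
#' @export
geneIds <- function(x) names(x@sequences)

#' @describeIn TailCalls-class Accessor for the per-read call table.
#' @export
tailCalls <- function(x) x@calls

#' @describeIn TailCalls-class Accessor for the disposition counts.
#' @export
disposition <- function(x) x@disposition

#' @describeIn TailDistribution-class Percentage per tail length 1-90.
#' @export
pctByLen <- function(x) x@pctByLen

#' @describeIn TailDistribution-class Fraction of tailed reads > 90 nt.
#' @export
fracGt90 <- function(x) x@fracGt90

#' @describeIn DecayFit-class Half-life in minutes.
#' @export
halfLife <- function(x) x@halfLife

#' @describeIn DecayFit-class Delta-method SD of the half-life.
#' @export
halfLifeSD <- function(x) x@halfLifeSD

#' @describeIn DecayFit-class Decay rate in 1/min.
#' @export
decayRate <- function(x) x@rate
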
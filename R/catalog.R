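#' Build a reference catalog of gene 3'-end regions
#'
#' @param sequences Named character vector or [Biostrings::DNAStringSet] of
#'   sense 3'-region sequences (DNA alphabet; `U` is accepted and converted
#'   to `T`). Names are gene ids and must be unique.
#' @param polyASites Named integer vector giving, for each gene, the 0-based
#'   coordinate of the last templated nucleotide. Defaults to the last base
#'   of each sequence.
#'
#' @return A [ReferenceCatalog-class] object.
#' @examples
#' cat <- referenceCatalog(c(g1 = "ACGTACGTACGTACGT"))
#' polyASites(cat)
#' @export
referenceCatalog <- function(sequences, polyASites = NULL) {
  if (is.character(sequences)) {
    sequences <- chartr("Uu", "Tt", sequences)
    sequences <- Biostrings::DNAStringSet(toupper(sequences))
  }
  if (anyDuplicated(names(sequences)))
    stop("duplicate gene id in catalog: ",
         paste(unique(names(sequences)[duplicated(names(sequences))]),
               collapse = ", "))
  if (is.null(polyASites)) {
    polyASites <- Biostrings::width(sequences) - 1L
    names(polyASites) <- names(sequences)
  }
  polyASites <- polyASites[names(sequences)]
  storage.mode(polyASites) <- "integer"
  new("ReferenceCatalog", sequences = sequences, polyASites = polyASites)
}

#' Generate a random reference catalog
#'
#' Convenience generator for simulations: random DNA sequences whose main
#' polyadenylation site is the final base.
#'
#' @param nGenes Number of genes.
#' @param width Sequence width in nt (default 150, comfortably longer than
#'   the 111-nt tail-side read).
#' @param seed Integer seed.
#' @return A [ReferenceCatalog-class].
#' @export
randomReferenceCatalog <- function(nGenes, width = 150L, seed = 1L) {
  set.seed(seed)
  seqs <- vapply(seq_len(nGenes), function(i)
    paste(sample(c("A", "C", "G", "T"), width, replace = TRUE),
          collapse = ""), character(1))
  names(seqs) <- sprintf("gene%03d", seq_len(nGenes))
  referenceCatalog(seqs)
}

#' Write a reference catalog to FASTA + polyadenylation-site TSV
#'
#' @param catalog A [ReferenceCatalog-class].
#' @param fastaFile,sitesFile Output paths. The TSV has columns `gene_id`
#'   and `main_polyA_site` (0-based coordinate of the last templated
#'   nucleotide).
#' @return Invisibly, the two paths.
#' @export
writeReferenceCatalog <- function(catalog, fastaFile, sitesFile) {
  stopifnot(is(catalog, "ReferenceCatalog"))
  Biostrings::writeXStringSet(catalog@sequences, fastaFile)
  df <- data.frame(gene_id = geneIds(catalog),
                   main_polyA_site = unname(catalog@polyASites))
  utils::write.table(df, sitesFile, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(c(fasta = fastaFile, sites = sitesFile))
}

#' Read a reference catalog from FASTA + polyadenylation-site TSV
#'
#' @param fastaFile,sitesFile Paths written by [writeReferenceCatalog()].
#' @return A [ReferenceCatalog-class].
#' @export
readReferenceCatalog <- function(fastaFile, sitesFile) {
  seqs <- Biostrings::readDNAStringSet(fastaFile)
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  df <- utils::read.delim(sitesFile, stringsAsFactors = FALSE)
  sites <- stats::setNames(as.integer(df$main_polyA_site), df$gene_id)
  if (!setequal(names(seqs), names(sites)))
    stop("FASTA and sites TSV disagree on gene ids")
  referenceCatalog(seqs, sites[names(seqs)])
}
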
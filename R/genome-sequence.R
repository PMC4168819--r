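#' Construct a GenomeSequence
#'
#' @param sequences named character vector or [Biostrings::DNAStringSet]
#' @param offset integer vector of genomic positions of each sequence's first
#'   base (recycled; default 1, i.e. complete chromosomes)
#' @return a [GenomeSequence-class]
#' @examples
#' g <- GenomeSequence(c(chr1 = "ACGTACGT"))
#' getSubseq(g, "chr1", 2, 4)
#' @export
GenomeSequence <- function(sequences, offset = 1L) {
  if (is.character(sequences)) {
    if (any(grepl("[^ACGTN]", toupper(sequences))))
      .err("rohdel_bad_sequence", "alphabet restricted to A/C/G/T/N")
    sequences <- Biostrings::DNAStringSet(toupper(sequences))
  }
  offset <- rep_len(as.integer(offset), length(sequences))
  new("GenomeSequence", sequences = sequences, offset = offset)
}

#' @describeIn GenomeSequence sequence names
#' @param x,object a GenomeSequence
#' @export
setMethod("names", "GenomeSequence", function(x) names(x@sequences))

setMethod("show", "GenomeSequence", function(object) {
  cat(sprintf("GenomeSequence with %d sequence(s)\n", length(object@sequences)))
  for (i in seq_along(object@sequences))
    cat(sprintf("  %s: %d bp (genomic %d-%d)\n",
                names(object@sequences)[i], length(object@sequences[[i]]),
                object@offset[i],
                object@offset[i] + length(object@sequences[[i]]) - 1L))
})

#' Extract a genomic subsequence
#'
#' Lookup by genomic coordinates; positions outside the stored window are
#' errors.
#'
#' @param genome a [GenomeSequence-class]
#' @param chrom sequence name
#' @param start,end 1-based inclusive genomic positions
#' @return character string of bases
#' @export
getSubseq <- function(genome, chrom, start, end) {
  stopifnot(is(genome, "GenomeSequence"))
  i <- match(chrom, names(genome@sequences))
  if (is.na(i))
    .err("rohdel_unknown_sequence", "unknown sequence '%s'", chrom)
  off <- genome@offset[i]
  len <- length(genome@sequences[[i]])
  if (start < off || end > off + len - 1L || start > end)
    .err("rohdel_out_of_bounds",
         "positions %d-%d outside stored window of %s (%d-%d)",
         start, end, chrom, off, off + len - 1L)
  as.character(Biostrings::subseq(genome@sequences[[i]],
                                  start - off + 1L, end - off + 1L))
}

#' Read a genome FASTA with optional window anchors
#'
#' Standard FASTA; a record whose description contains \code{offset=<n>}
#' is interpreted as a window of its chromosome starting at genomic
#' position n.
#'
#' @param path FASTA file
#' @return a [GenomeSequence-class]
#' @export
readGenomeFasta <- function(path) {
  ss <- Biostrings::readDNAStringSet(path)
  nm <- names(ss)
  off <- rep(1L, length(ss))
  hit <- regmatches(nm, regexpr("offset=[0-9]+", nm))
  has <- grepl("offset=[0-9]+", nm)
  off[has] <- as.integer(sub("offset=", "", regmatches(nm, regexpr("offset=[0-9]+", nm))))
  names(ss) <- sub("\\s.*$", "", nm)
  GenomeSequence(ss, off)
}

#' Write a GenomeSequence as FASTA
#'
#' Window anchors are recorded as \code{offset=<n>} in the description.
#'
#' @param genome a [GenomeSequence-class]
#' @param path output file
#' @return invisibly, the path
#' @export
writeGenomeFasta <- function(genome, path) {
  ss <- genome@sequences
  desc <- ifelse(genome@offset != 1L,
                 sprintf("%s offset=%d", names(ss), genome@offset),
                 names(ss))
  out <- ss
  names(out) <- desc
  Biostrings::writeXStringSet(out, path)
  invisible(path)
}
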
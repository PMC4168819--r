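#' @import methods
#' @importFrom S4Vectors mcols mcols<- DataFrame metadata metadata<-
#' @importFrom IRanges IRanges
#' @importFrom GenomicRanges GRanges seqnames start end width strand granges
#' @importFrom Biostrings DNAString DNAStringSet
NULL

## ---------------------------------------------------------------------------
## GenomeSequence: named nucleotide sequences, each anchored at a genomic
## start offset so that small windows of large chromosomes can be carried
## without storing the whole chromosome.
## ---------------------------------------------------------------------------

#' Reference nucleotide sequences with per-sequence genomic anchors
#'
#' Holds one nucleotide string per sequence name, 1-based addressing.  Each
#' stored string may represent only a window of its chromosome: slot
#' \code{offset} gives the genomic coordinate of the first stored base, so
#' lookups use genomic coordinates throughout.
#'
#' @slot sequences a [Biostrings::DNAStringSet] of the stored sequences
#' @slot offset integer vector, parallel to \code{sequences}; genomic
#'   position of the first stored base (1 for a complete chromosome)
#' @export
setClass("GenomeSequence",
  slots = c(sequences = "DNAStringSet", offset = "integer"))

setValidity("GenomeSequence", function(object) {
  msg <- character()
  if (length(object@offset) != length(object@sequences))
    msg <- c(msg, "offset must be parallel to sequences")
  if (is.null(names(object@sequences)) ||
      anyDuplicated(names(object@sequences)))
    msg <- c(msg, "sequences must have unique names")
  if (length(object@offset) && any(object@offset < 1L))
    msg <- c(msg, "offsets must be >= 1")
  bad <- grepl("[^ACGTN]", as.character(object@sequences))
  if (any(bad))
    msg <- c(msg, "alphabet restricted to A/C/G/T/N")
  if (length(msg)) msg else TRUE
})

## ---------------------------------------------------------------------------
## TranscriptModel
## ---------------------------------------------------------------------------

#' Exon/intron/CDS geometry of a single transcript
#'
#' The coordinate frame for all HGVS arithmetic.  Exons are 1-based inclusive
#' genomic intervals in genomic order; \code{cdsStart}/\code{cdsEnd} are the
#' genomic positions of the first and last coding base *in transcription
#' order* (so \code{cdsStart > cdsEnd} on the minus strand).
#'
#' @slot geneId,transcriptId labels
#' @slot chrom sequence name
#' @slot strand "+" or "-"
#' @slot exons [GenomicRanges::GRanges] of exons, sorted in genomic order
#' @slot cdsStart,cdsEnd genomic positions of the first/last coding base in
#'   transcription order
#' @export
setClass("TranscriptModel",
  slots = c(geneId = "character", transcriptId = "character",
            chrom = "character", strand = "character",
            exons = "GRanges", cdsStart = "integer", cdsEnd = "integer"))

setValidity("TranscriptModel", function(object) {
  msg <- character()
  ex <- object@exons
  if (!object@strand %in% c("+", "-"))
    msg <- c(msg, "strand must be '+' or '-'")
  if (length(ex) == 0L)
    msg <- c(msg, "model must have at least one exon")
  if (length(ex) > 1L) {
    s <- GenomicRanges::start(ex); e <- GenomicRanges::end(ex)
    if (is.unsorted(s, strictly = TRUE) ||
        any(s[-1] <= e[-length(e)]))
      msg <- c(msg, "exons must be non-overlapping and sorted in genomic order")
  }
  inExon <- function(g) any(GenomicRanges::start(ex) <= g &
                            GenomicRanges::end(ex) >= g)
  if (!inExon(object@cdsStart) || !inExon(object@cdsEnd))
    msg <- c(msg, "cdsStart/cdsEnd must fall inside exons")
  if (!length(msg)) {
    cl <- sum(BiocGenerics::width(.codingRanges(object)))
    if (cl %% 3L != 0L)
      msg <- c(msg, sprintf("CDS length %d not divisible by 3", cl))
  }
  if (length(msg)) msg else TRUE
})

## ---------------------------------------------------------------------------
## CdsCoordinate
## ---------------------------------------------------------------------------

#' Coding-DNA (HGVS c.) coordinates with intronic offsets
#'
#' A vector of HGVS-style coding positions.  \code{base} is the 1-based CDS
#' position (the "294" in c.294+139); \code{offset} the signed intronic
#' offset, 0 for exonic positions (the "+139").  Positive offsets count into
#' the intron 3' of an exon boundary, negative offsets 5' of one.
#'
#' @slot base integer vector of CDS positions (>= 1)
#' @slot offset integer vector of intronic offsets, parallel to \code{base}
#' @export
setClass("CdsCoordinate", slots = c(base = "integer", offset = "integer"))

setValidity("CdsCoordinate", function(object) {
  msg <- character()
  if (length(object@base) != length(object@offset))
    msg <- c(msg, "base and offset must be parallel")
  if (any(is.na(object@base)) || any(object@base < 1L))
    msg <- c(msg, "base must be >= 1 (UTR coordinates are unsupported)")
  if (length(msg)) msg else TRUE
})

## ---------------------------------------------------------------------------
## Deletion types
## ---------------------------------------------------------------------------

#' A deletion in coding-DNA coordinates
#'
#' @slot start,end [CdsCoordinate] (length 1 each), inclusive, start <= end
#'   in transcription order
#' @slot raw the original HGVS string if the object was parsed from one
#' @export
setClass("DeletionDescription",
  slots = c(start = "CdsCoordinate", end = "CdsCoordinate", raw = "character"))

#' Full consequence record of a genomic deletion
#'
#' @slot genomicStart,genomicEnd 1-based inclusive genomic span
#' @slot totalLength,codingBasesRemoved,intronicBasesRemoved base-pair
#'   bookkeeping; coding + intronic = total
#' @slot inFrame TRUE when codingBasesRemoved is a multiple of 3
#' @slot status one of "codon_aligned", "junction", "frameshift",
#'   "no_coding", "unsupported"
#' @slot firstResidue,lastResidue 1-based protein ordinals of the removed run
#'   (NA unless codon-aligned)
#' @slot firstResidueAa,lastResidueAa three-letter amino-acid codes
#' @slot proteinHgvs protein-level HGVS string ("fs" marker for frameshifts)
#' @slot wtProteinLength,mutProteinLength residue counts
#' @slot notes character vector of recorded caveats
#' @export
setClass("DeletionConsequence",
  slots = c(genomicStart = "integer", genomicEnd = "integer",
            totalLength = "integer", codingBasesRemoved = "integer",
            intronicBasesRemoved = "integer", inFrame = "logical",
            status = "character",
            firstResidue = "integer", lastResidue = "integer",
            firstResidueAa = "character", lastResidueAa = "character",
            proteinHgvs = "character",
            wtProteinLength = "integer", mutProteinLength = "integer",
            notes = "character"))

setValidity("DeletionConsequence", function(object) {
  msg <- character()
  if (object@totalLength !=
      object@genomicEnd - object@genomicStart + 1L)
    msg <- c(msg, "totalLength must equal genomicEnd - genomicStart + 1")
  if (object@codingBasesRemoved + object@intronicBasesRemoved !=
      object@totalLength)
    msg <- c(msg, "coding + intronic bases must equal totalLength")
  if (length(msg)) msg else TRUE
})

#' A PCR primer pair as genomic footprints on the reference
#'
#' @slot forwardStart,forwardEnd,reverseStart,reverseEnd 1-based inclusive
#'   footprints; the forward footprint lies entirely 5' of the reverse one
#' @slot chrom sequence name
#' @slot label assay label
#' @export
setClass("PrimerPair",
  slots = c(chrom = "character",
            forwardStart = "integer", forwardEnd = "integer",
            reverseStart = "integer", reverseEnd = "integer",
            label = "character"))

setValidity("PrimerPair", function(object) {
  msg <- character()
  fl <- object@forwardEnd - object@forwardStart + 1L
  rl <- object@reverseEnd - object@reverseStart + 1L
  if (object@forwardEnd >= object@reverseStart)
    msg <- c(msg, "forward footprint must lie entirely 5' of the reverse one")
  if (fl < 15L || fl > 35L || rl < 15L || rl > 35L)
    msg <- c(msg, "primer lengths must be 15-35 nt")
  if (length(msg)) msg else TRUE
})

#' A mutant allele produced by deleting a reference interval
#'
#' Carries the mutant sequence together with the deleted reference interval
#' so that reference coordinates can be lifted onto the allele.
#'
#' @slot chrom sequence name
#' @slot sequence the mutant [Biostrings::DNAString]
#' @slot offset genomic coordinate of the first stored reference base
#' @slot delStart,delEnd deleted reference interval (1-based inclusive)
#' @export
setClass("MutantAllele",
  slots = c(chrom = "character", sequence = "DNAString", offset = "integer",
            delStart = "integer", delEnd = "integer"))

## ---------------------------------------------------------------------------
## Genotypes & pedigree
## ---------------------------------------------------------------------------

#' Biallelic SNP calls, markers x samples
#'
#' @slot markers [GenomicRanges::GRanges] of marker positions (width 1) with
#'   an mcols column \code{marker_id}; positions strictly increasing within
#'   each chromosome
#' @slot calls character matrix markers x samples with entries in
#'   \{"AA","AB","BB","NC"\} ("NC" = missing)
#' @export
setClass("GenotypeMatrix",
  slots = c(markers = "GRanges", calls = "matrix"))

setValidity("GenotypeMatrix", function(object) {
  msg <- character()
  if (nrow(object@calls) != length(object@markers))
    msg <- c(msg, "calls must have one row per marker")
  if (is.null(colnames(object@calls)))
    msg <- c(msg, "calls must have sample names as column names")
  if (!all(object@calls %in% c("AA", "AB", "BB", "NC")))
    msg <- c(msg, "every call must be one of AA/AB/BB/NC")
  pos <- GenomicRanges::start(object@markers)
  chr <- as.character(GenomicRanges::seqnames(object@markers))
  for (cc in unique(chr)) {
    p <- pos[chr == cc]
    if (is.unsorted(p, strictly = TRUE)) {
      msg <- c(msg, sprintf("positions not strictly increasing on %s", cc))
      break
    }
  }
  if (length(msg)) msg else TRUE
})

#' A nuclear (or extended) pedigree
#'
#' @slot members data.frame with columns id, father, mother, sex, affected;
#'   founders carry NA parents
#' @export
setClass("Pedigree", slots = c(members = "data.frame"))

setValidity("Pedigree", function(object) {
  m <- object@members
  msg <- character()
  need <- c("id", "father", "mother", "sex", "affected")
  if (!all(need %in% names(m)))
    return(sprintf("members must have columns %s", paste(need, collapse = ", ")))
  if (anyDuplicated(m$id)) msg <- c(msg, "duplicate individual ids")
  known <- function(p) all(is.na(p) | p %in% m$id)
  if (!known(m$father) || !known(m$mother))
    msg <- c(msg, "parents must be pedigree members or NA")
  ## cycle check: repeated parent-substitution must terminate
  for (i in m$id) {
    seen <- character(); frontier <- i
    repeat {
      par <- unique(stats::na.omit(c(m$father[m$id %in% frontier],
                                     m$mother[m$id %in% frontier])))
      if (!length(par)) break
      if (i %in% par) { msg <- c(msg, sprintf("%s is its own ancestor", i)); break }
      par <- setdiff(par, seen)
      if (!length(par)) break
      seen <- c(seen, par); frontier <- par
    }
  }
  if (length(msg)) unique(msg) else TRUE
})

## ---------------------------------------------------------------------------
## Filter report
## ---------------------------------------------------------------------------

#' Per-stage bookkeeping of the variant filter cascade
#'
#' @slot stages data.frame with columns stage, n_in, n_out
#' @slot survivors data.frame of surviving variant records (with
#'   \code{repeat_flag} annotation)
#' @slot skipped number of malformed input records skipped
#' @export
setClass("FilterReport",
  slots = c(stages = "data.frame", survivors = "data.frame",
            skipped = "integer"))

setValidity("FilterReport", function(object) {
  st <- object@stages
  msg <- character()
  if (nrow(st)) {
    if (any(st$n_out > st$n_in))
      msg <- c(msg, "stage output counts must not exceed input counts")
    if (nrow(st) > 1L && any(st$n_in[-1] != st$n_out[-nrow(st)]))
      msg <- c(msg, "each stage's output must be the next stage's input")
    if (nrow(object@survivors) != st$n_out[nrow(st)])
      msg <- c(msg, "survivors must match the final stage count")
  }
  if (length(msg)) msg else TRUE
})

## ---------------------------------------------------------------------------
## Exon depth table (RangedSummarizedExperiment subclass)
## ---------------------------------------------------------------------------

#' Per-exon mean read depth, case and control-panel samples
#'
#' A [SummarizedExperiment::RangedSummarizedExperiment] whose rows are exons
#' (rowRanges carry \code{gene} and \code{exon_index}), whose single assay
#' \code{meanDepth} holds mean reads/base per exon per sample, and whose
#' colData column \code{role} marks each sample "case" or "panel".  After
#' [compareToPanel()] the rowData gains panel summaries and depth ratios.
#'
#' @export
setClass("ExonDepthTable", contains = "RangedSummarizedExperiment")

setValidity("ExonDepthTable", function(object) {
  msg <- character()
  if (!"meanDepth" %in% SummarizedExperiment::assayNames(object))
    msg <- c(msg, "assay 'meanDepth' is required")
  else if (any(SummarizedExperiment::assay(object, "meanDepth") < 0))
    msg <- c(msg, "mean depths must be >= 0")
  cd <- SummarizedExperiment::colData(object)
  if (!"role" %in% names(cd) || !all(cd$role %in% c("case", "panel")))
    msg <- c(msg, "colData$role must be 'case' or 'panel' for every sample")
  rd <- SummarizedExperiment::rowData(object)
  if (!all(c("gene", "exon_index") %in% names(rd)))
    msg <- c(msg, "rowData must carry gene and exon_index")
  if (all(c("panel_mean", "panel_min", "panel_max") %in% names(rd))) {
    ok <- rd$panel_min <= rd$panel_mean + 1e-9 &
          rd$panel_mean <= rd$panel_max + 1e-9
    if (!all(ok)) msg <- c(msg, "panel_min <= panel_mean <= panel_max violated")
  }
  if (length(msg)) msg else TRUE
})
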
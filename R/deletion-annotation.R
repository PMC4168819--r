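## ---------------------------------------------------------------------------
## HGVS c. deletion parsing / formatting
## ---------------------------------------------------------------------------

#' Construct a DeletionDescription
#'
#' @param start,end [CdsCoordinate-class] of length 1, inclusive bounds in
#'   transcription order
#' @param raw original HGVS string, if any
#' @return a [DeletionDescription-class]
#' @export
DeletionDescription <- function(start, end, raw = NA_character_) {
  new("DeletionDescription", start = start, end = end,
      raw = as.character(raw))
}

setMethod("show", "DeletionDescription", function(object) {
  cat("DeletionDescription:", formatHgvsCDel(object), "\n")
})

#' Parse an HGVS coding-DNA deletion string
#'
#' Accepts \code{c.<pos>_<pos>del} with optional signed intronic offsets.
#' Whitespace around the offset sign is tolerated on input (journals often
#' typeset "c.294 + 139"); [formatHgvsCDel()] always emits the canonical
#' whitespace-free form.
#'
#' @param s HGVS string, e.g. \code{"c.294+139_531+478del"}
#' @param model a [TranscriptModel-class] the coordinates must be valid for
#' @return a [DeletionDescription-class]
#' @export
parseHgvsCDel <- function(s, model) {
  stopifnot(is(model, "TranscriptModel"))
  s0 <- gsub("[[:space:]]+", "", s)
  m <- regmatches(s0, regexec(
    "^c\\.(\\d+)([+-]\\d+)?_(\\d+)([+-]\\d+)?del$", s0))[[1]]
  if (!length(m))
    .err("rohdel_bad_hgvs", "cannot parse '%s' as c.<pos>_<pos>del", s)
  off <- function(x) if (nzchar(x)) as.integer(x) else 0L
  start <- CdsCoordinate(as.integer(m[2]), off(m[3]))
  end <- CdsCoordinate(as.integer(m[4]), off(m[5]))
  ## validity for the model (errors if not), and transcription-order check
  gs <- cdsToGenomic(model, start)
  ge <- cdsToGenomic(model, end)
  dir <- if (model@strand == "-") -1L else 1L
  if (dir * (ge - gs) < 0L)
    .err("rohdel_bad_hgvs",
         "'%s': start lies 3' of end in transcription order", s)
  DeletionDescription(start, end, raw = s)
}

#' Format a deletion description as canonical HGVS
#'
#' @param d a [DeletionDescription-class]
#' @return string like \code{"c.294+139_531+478del"}
#' @export
formatHgvsCDel <- function(d) {
  sprintf("c.%s_%sdel", formatCds(d@start), formatCds(d@end))
}

#' Shift a deletion to its most 3' equivalent position
#'
#' HGVS normalization: while the reference base immediately 3' of the
#' deleted interval equals the first deleted base, the window can slide 3'
#' without changing the mutant sequence.  Off by default in
#' [annotateDeletion()]; breakpoints determined by sequencing are usually
#' reported as observed.
#'
#' @param d a [DeletionDescription-class]
#' @param model a [TranscriptModel-class]
#' @param genome a [GenomeSequence-class]
#' @return a (possibly shifted) [DeletionDescription-class]
#' @export
normalizeDeletion3prime <- function(d, model, genome) {
  gs <- cdsToGenomic(model, d@start)
  ge <- cdsToGenomic(model, d@end)
  dir <- if (model@strand == "-") -1L else 1L
  repeat {
    nxt <- ge + dir          # reference base just 3' of the deleted window
    first <- gs              # first deleted base (5' end in tx order)
    ok <- tryCatch({
      getSubseq(genome, model@chrom, min(nxt, nxt), max(nxt, nxt)) ==
        getSubseq(genome, model@chrom, first, first)
    }, error = function(e) FALSE)
    if (!isTRUE(ok)) break
    gs <- gs + dir; ge <- ge + dir
  }
  DeletionDescription(genomicToCds(model, gs), genomicToCds(model, ge),
                      raw = d@raw)
}

## ---------------------------------------------------------------------------
## Deletion consequence annotation
## ---------------------------------------------------------------------------

#' Annotate the genomic and protein consequence of a coding-DNA deletion
#'
#' Computes the genomic span via [cdsToGenomic()], intersects it with the
#' exon model to split removed bases into coding and intronic, determines
#' frame status, and — when the removed coding run starts and ends on codon
#' boundaries — names the removed residues from the translated wild-type
#' CDS (e.g. \code{p.Tyr99_Glu177del}).
#'
#' Deletions removing the initiator or terminator codon are flagged
#' \code{"unsupported"}; in-frame deletions that cut within codons are
#' flagged \code{"junction"} and carry no residue names; frameshifts carry
#' the \code{"fs"} marker.
#'
#' @param d a [DeletionDescription-class]
#' @param model a [TranscriptModel-class]
#' @param genome a [GenomeSequence-class] covering the transcript span
#' @param normalize3prime shift the deletion to its most 3' equivalent
#'   position first (default FALSE)
#' @return a [DeletionConsequence-class]
#' @examples
#' cm <- makeCanonicalModel()
#' d <- parseHgvsCDel("c.294+139_531+478del", cm$model)
#' annotateDeletion(d, cm$model, cm$genome)
#' @export
annotateDeletion <- function(d, model, genome, normalize3prime = FALSE) {
  stopifnot(is(d, "DeletionDescription"), is(model, "TranscriptModel"),
            is(genome, "GenomeSequence"))
  if (normalize3prime) d <- normalizeDeletion3prime(d, model, genome)
  gs <- cdsToGenomic(model, d@start)
  ge <- cdsToGenomic(model, d@end)
  gLo <- min(gs, ge); gHi <- max(gs, ge)
  total <- gHi - gLo + 1L

  tx <- .txMap(model)
  dir <- if (model@strand == "-") -1L else 1L
  ## removed coding run, in CDS coordinates
  cFirst <- NA_integer_; cLast <- NA_integer_; coding <- 0L
  for (i in seq_len(nrow(tx))) {
    if (is.na(tx$cumFrom[i])) next
    eLo <- min(tx$codingFirstG[i], tx$codingLastG[i])
    eHi <- max(tx$codingFirstG[i], tx$codingLastG[i])
    oLo <- max(eLo, gLo); oHi <- min(eHi, gHi)
    if (oLo > oHi) next
    coding <- coding + (oHi - oLo + 1L)
    ## CDS positions of the overlapped genomic sub-interval
    cA <- tx$cumFrom[i] + dir * (oLo - tx$codingFirstG[i])
    cB <- tx$cumFrom[i] + dir * (oHi - tx$codingFirstG[i])
    cFirst <- min(cFirst, cA, cB, na.rm = TRUE)
    cLast <- max(cLast, cA, cB, na.rm = TRUE)
  }
  intronic <- total - coding
  inFrame <- coding %% 3L == 0L

  wtCds <- cdsSequence(model, genome)
  wtAa <- translateCds(wtCds)
  wtLen <- nchar(wtAa)

  status <- "codon_aligned"
  firstRes <- lastRes <- NA_integer_
  firstAa <- lastAa <- NA_character_
  pHgvs <- NA_character_
  mutLen <- wtLen
  notes <- character()

  if (coding == 0L) {
    status <- "no_coding"
    notes <- c(notes, "deletion removes no coding bases")
  } else if (cFirst <= 3L || cLast > 3L * wtLen) {
    status <- "unsupported"
    notes <- c(notes, if (cFirst <= 3L)
      "deletion removes (part of) the initiator codon" else
      "deletion removes (part of) the terminator codon")
  } else if (!inFrame) {
    status <- "frameshift"
    pHgvs <- "fs"
    notes <- c(notes, sprintf(
      "%d coding bases removed: downstream reading frame shifted", coding))
  } else if ((cFirst - 1L) %% 3L != 0L || cLast %% 3L != 0L) {
    status <- "junction"
    notes <- c(notes,
      "in-frame deletion not aligned to codon boundaries: novel junction residue; residue names withheld")
  } else {
    firstRes <- (cFirst + 2L) %/% 3L
    lastRes <- cLast %/% 3L
    aa1 <- substr(wtAa, firstRes, firstRes)
    aa2 <- substr(wtAa, lastRes, lastRes)
    firstAa <- unname(Biostrings::AMINO_ACID_CODE[aa1])
    lastAa <- unname(Biostrings::AMINO_ACID_CODE[aa2])
    pHgvs <- if (firstRes == lastRes)
      sprintf("p.%s%ddel", firstAa, firstRes)
    else
      sprintf("p.%s%d_%s%ddel", firstAa, firstRes, lastAa, lastRes)
    mutLen <- wtLen - (lastRes - firstRes + 1L)
  }
  ## record where the breakpoints sit relative to the exon model, so a
  ## reader can cross-check breakpoint statements phrased in other frames
  notes <- c(notes, sprintf("c. description: %s (genomic %d-%d)",
                            formatHgvsCDel(d), gLo, gHi))

  obj <- new("DeletionConsequence",
             genomicStart = gLo, genomicEnd = gHi, totalLength = total,
             codingBasesRemoved = coding, intronicBasesRemoved = intronic,
             inFrame = inFrame, status = status,
             firstResidue = firstRes, lastResidue = lastRes,
             firstResidueAa = firstAa, lastResidueAa = lastAa,
             proteinHgvs = pHgvs, wtProteinLength = wtLen,
             mutProteinLength = mutLen, notes = notes)
  validObject(obj)
  obj
}

setMethod("show", "DeletionConsequence", function(object) {
  cat(sprintf("DeletionConsequence: %d bp (genomic %d-%d)\n",
              object@totalLength, object@genomicStart, object@genomicEnd))
  cat(sprintf("  coding %d bp, intronic %d bp, %s [%s]\n",
              object@codingBasesRemoved, object@intronicBasesRemoved,
              if (object@inFrame) "in-frame" else "frameshift",
              object@status))
  if (!is.na(object@proteinHgvs))
    cat(sprintf("  protein: %s (%d -> %d residues)\n", object@proteinHgvs,
                object@wtProteinLength, object@mutProteinLength))
})

## ---------------------------------------------------------------------------
## Report writers
## ---------------------------------------------------------------------------

#' Write a deletion consequence report as TSV
#'
#' @param cons a [DeletionConsequence-class]
#' @param model the annotated [TranscriptModel-class]
#' @param path output TSV
#' @return invisibly, the path
#' @export
writeDeletionReport <- function(cons, model, path) {
  d <- data.frame(
    gene = model@geneId, transcript = model@transcriptId,
    chrom = model@chrom,
    genomic_start = cons@genomicStart, genomic_end = cons@genomicEnd,
    total_length = cons@totalLength,
    coding_bases_removed = cons@codingBasesRemoved,
    intronic_bases_removed = cons@intronicBasesRemoved,
    in_frame = cons@inFrame, status = cons@status,
    first_residue = cons@firstResidue, last_residue = cons@lastResidue,
    protein_hgvs = cons@proteinHgvs,
    wt_protein_length = cons@wtProteinLength,
    mut_protein_length = cons@mutProteinLength,
    notes = paste(cons@notes, collapse = "; "))
  utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a deletion as a VCF symbolic-DEL record
#'
#' Emits a minimal VCF v4.2 with a single \code{<DEL>} ALT record
#' (\code{SVTYPE=DEL}, \code{END}, \code{SVLEN}); POS is the base before the
#' deleted interval, per VCF structural-variant convention.
#'
#' @param cons a [DeletionConsequence-class]
#' @param model the annotated [TranscriptModel-class]
#' @param genome a [GenomeSequence-class] (for the anchor REF base)
#' @param path output VCF
#' @return invisibly, the path
#' @export
writeDeletionVcf <- function(cons, model, genome, path) {
  pos <- cons@genomicStart - 1L
  ref <- getSubseq(genome, model@chrom, pos, pos)
  lines <- c(
    "##fileformat=VCFv4.2",
    "##ALT=<ID=DEL,Description=\"Deletion\">",
    "##INFO=<ID=SVTYPE,Number=1,Type=String,Description=\"Type of structural variant\">",
    "##INFO=<ID=END,Number=1,Type=Integer,Description=\"End position of the variant\">",
    "##INFO=<ID=SVLEN,Number=1,Type=Integer,Description=\"Length difference between ALT and REF alleles\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO",
    sprintf("%s\t%d\t.\t%s\t<DEL>\t.\tPASS\tSVTYPE=DEL;END=%d;SVLEN=-%d",
            model@chrom, pos, ref, cons@genomicEnd, cons@totalLength))
  writeLines(lines, path)
  invisible(path)
}

## ---------------------------------------------------------------------------
## In-silico PCR
## ---------------------------------------------------------------------------

#' Construct a PrimerPair
#'
#' @param chrom sequence name
#' @param forwardStart,forwardEnd,reverseStart,reverseEnd 1-based inclusive
#'   genomic footprints of the two primers on the reference
#' @param label assay label
#' @return a [PrimerPair-class]
#' @export
PrimerPair <- function(chrom, forwardStart, forwardEnd,
                       reverseStart, reverseEnd, label = "") {
  obj <- new("PrimerPair", chrom = as.character(chrom),
             forwardStart = as.integer(forwardStart),
             forwardEnd = as.integer(forwardEnd),
             reverseStart = as.integer(reverseStart),
             reverseEnd = as.integer(reverseEnd),
             label = as.character(label))
  validObject(obj)
  obj
}

setMethod("show", "PrimerPair", function(object) {
  cat(sprintf("PrimerPair %s: %s fwd %d-%d / rev %d-%d\n",
              object@label, object@chrom,
              object@forwardStart, object@forwardEnd,
              object@reverseStart, object@reverseEnd))
})

#' Predict a PCR product length on a template
#'
#' Purely positional amplicon computation (perfect primer hybridization
#' assumed): the product runs from the forward primer's 5' end to the
#' reverse primer's 3' end, inclusive.  On a deletion allele, a primer whose
#' reference footprint overlaps the deleted interval has no binding site and
#' the assay yields no product.
#'
#' @param template a [GenomeSequence-class] (wild-type) or
#'   [MutantAllele-class] (deletion allele)
#' @param primers a [PrimerPair-class]
#' @return product length in bp, or \code{NA_integer_} for no product
#' @examples
#' cm <- makeCanonicalModel()
#' pp <- PrimerPair("chrG", 1002300, 1002319, 1005421, 1005440)
#' inSilicoPcr(cm$genome, pp)  # 3141
#' @export
setGeneric("inSilicoPcr", function(template, primers)
  standardGeneric("inSilicoPcr"))

#' @rdname inSilicoPcr
#' @export
setMethod("inSilicoPcr", "GenomeSequence", function(template, primers) {
  i <- match(primers@chrom, names(template@sequences))
  if (is.na(i))
    .err("rohdel_unknown_sequence", "unknown sequence '%s'", primers@chrom)
  off <- template@offset[i]
  hi <- off + length(template@sequences[[i]]) - 1L
  if (primers@forwardStart < off || primers@reverseEnd > hi)
    return(NA_integer_)
  primers@reverseEnd - primers@forwardStart + 1L
})

#' @rdname inSilicoPcr
#' @export
setMethod("inSilicoPcr", "MutantAllele", function(template, primers) {
  if (primers@chrom != template@chrom)
    return(NA_integer_)
  intact <- function(s, e)
    e < template@delStart || s > template@delEnd
  if (!intact(primers@forwardStart, primers@forwardEnd) ||
      !intact(primers@reverseStart, primers@reverseEnd))
    return(NA_integer_)                  # footprint destroyed
  a <- liftToMutant(template, primers@forwardStart)
  b <- liftToMutant(template, primers@reverseEnd)
  if (is.na(a) || is.na(b)) return(NA_integer_)
  b - a + 1L
})

#' Classify an individual's deletion genotype from two PCR assays
#'
#' Combines an exon-internal assay (product only when the exon is present)
#' with a long-range assay spanning the deletion (a short product only when
#' the deletion collapses the template into amplifiable range).  Products
#' longer than \code{max_amplicon} are treated as not amplified, mirroring
#' the long-range assay's failure to amplify the full-length wild-type
#' template.
#'
#' @param exon6_products numeric vector of per-allele exon-assay product
#'   lengths (NA = no product)
#' @param longrange_products numeric vector of per-allele long-range product
#'   lengths (NA = no product)
#' @param max_amplicon longest product considered amplifiable (bp)
#' @return one of "wild_type", "carrier", "homozygous_deleted"; if neither
#'   assay yields any product an assay-failure condition is signalled
#' @export
classifyPcrGenotype <- function(exon6_products, longrange_products,
                                max_amplicon = 2000L) {
  amp <- function(x) !is.na(x) & x <= max_amplicon
  ex <- any(amp(exon6_products))
  lr <- any(amp(longrange_products))
  if (!ex && !lr)
    .err("rohdel_assay_failure",
         "neither assay yielded a product: assay failure (check positive control)")
  if (ex && lr) "carrier"
  else if (ex) "wild_type"
  else "homozygous_deleted"
}
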
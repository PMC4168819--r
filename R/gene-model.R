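## ---------------------------------------------------------------------------
## TranscriptModel construction & accessors
## ---------------------------------------------------------------------------

#' Construct a TranscriptModel
#'
#' @param geneId,transcriptId labels
#' @param chrom sequence name
#' @param strand "+" or "-"
#' @param exonStarts,exonEnds 1-based inclusive genomic exon bounds, sorted
#'   in genomic order
#' @param cdsStart,cdsEnd genomic positions of the first/last coding base in
#'   transcription order (\code{cdsStart > cdsEnd} on the minus strand)
#' @return a validated [TranscriptModel-class]
#' @export
TranscriptModel <- function(geneId, transcriptId, chrom, strand,
                            exonStarts, exonEnds, cdsStart, cdsEnd) {
  ex <- GenomicRanges::GRanges(chrom,
          IRanges::IRanges(as.integer(exonStarts), as.integer(exonEnds)),
          strand = strand)
  obj <- new("TranscriptModel", geneId = as.character(geneId),
             transcriptId = as.character(transcriptId),
             chrom = as.character(chrom), strand = as.character(strand),
             exons = ex, cdsStart = as.integer(cdsStart),
             cdsEnd = as.integer(cdsEnd))
  validObject(obj)
  obj
}

#' @rdname TranscriptModel
#' @param model a [TranscriptModel-class]
#' @export
exonRanges <- function(model) model@exons

#' @rdname TranscriptModel
#' @export
geneId <- function(model) model@geneId

#' @rdname TranscriptModel
#' @export
transcriptId <- function(model) model@transcriptId

## coding sub-interval of each exon, genomic order, zero-width exons dropped
.codingRanges <- function(model) {
  lo <- min(model@cdsStart, model@cdsEnd)
  hi <- max(model@cdsStart, model@cdsEnd)
  s <- pmax(GenomicRanges::start(model@exons), lo)
  e <- pmin(GenomicRanges::end(model@exons), hi)
  keep <- s <= e
  GenomicRanges::GRanges(model@chrom, IRanges::IRanges(s[keep], e[keep]),
                         strand = model@strand)
}

#' Total CDS length of a transcript model, in nucleotides
#' @param model a [TranscriptModel-class]
#' @export
cdsLength <- function(model) sum(BiocGenerics::width(.codingRanges(model)))

## transcription-order exon map: genomic bounds, coding sub-interval,
## cumulative CDS interval, and the 5'/3' genomic edges in the transcript's
## reading sense.  The workhorse table behind all c. <-> genomic arithmetic.
.txMap <- function(model) {
  gs <- GenomicRanges::start(model@exons)
  ge <- GenomicRanges::end(model@exons)
  lo <- min(model@cdsStart, model@cdsEnd)
  hi <- max(model@cdsStart, model@cdsEnd)
  cs <- pmax(gs, lo); ce <- pmin(ge, hi)
  none <- cs > ce
  cs[none] <- NA_integer_; ce[none] <- NA_integer_
  minus <- model@strand == "-"
  ord <- if (minus) rev(seq_along(gs)) else seq_along(gs)
  w <- ifelse(is.na(cs[ord]), 0L, ce[ord] - cs[ord] + 1L)
  cumTo <- cumsum(w)
  cumFrom <- ifelse(w > 0L, cumTo - w + 1L, NA_integer_)
  cumTo[w == 0L] <- NA_integer_
  data.frame(
    exon       = ord,
    gStart     = gs[ord], gEnd = ge[ord],
    boundary5  = if (minus) ge[ord] else gs[ord],
    boundary3  = if (minus) gs[ord] else ge[ord],
    ## genomic coordinate of the exon's first/last coding base in tx order
    codingFirstG = if (minus) ce[ord] else cs[ord],
    codingLastG  = if (minus) cs[ord] else ce[ord],
    cumFrom = cumFrom, cumTo = cumTo
  )
}

setMethod("show", "TranscriptModel", function(object) {
  cat(sprintf("TranscriptModel %s (%s) on %s(%s): %d exons, CDS %d nt (%d codons)\n",
              object@transcriptId, object@geneId, object@chrom, object@strand,
              length(object@exons), cdsLength(object), cdsLength(object) %/% 3L))
})

## ---------------------------------------------------------------------------
## CdsCoordinate
## ---------------------------------------------------------------------------

#' Construct coding-DNA coordinates
#'
#' @param base 1-based CDS positions
#' @param offset signed intronic offsets (0 = exonic), recycled
#' @return a [CdsCoordinate-class] vector
#' @examples
#' CdsCoordinate(294, 139)  # c.294+139
#' @export
CdsCoordinate <- function(base, offset = 0L) {
  offset <- rep_len(as.integer(offset), length(base))
  obj <- new("CdsCoordinate", base = as.integer(base), offset = offset)
  validObject(obj)
  obj
}

#' @describeIn CdsCoordinate number of coordinates
#' @param x,object a CdsCoordinate
#' @export
setMethod("length", "CdsCoordinate", function(x) length(x@base))

#' @rdname CdsCoordinate
#' @export
cdsBase <- function(x) x@base

#' @rdname CdsCoordinate
#' @export
cdsOffset <- function(x) x@offset

#' Format coding coordinates as HGVS position strings
#' @param x a [CdsCoordinate-class]
#' @return character vector like \code{"294+139"} or \code{"295"}
#' @export
formatCds <- function(x) {
  paste0(x@base, ifelse(x@offset == 0L, "",
                        sprintf("%+d", x@offset)))
}

setMethod("show", "CdsCoordinate", function(object) {
  cat("CdsCoordinate:", paste0("c.", formatCds(object)), "\n")
})

## ---------------------------------------------------------------------------
## Coordinate algebra
## ---------------------------------------------------------------------------

#' Map coding-DNA coordinates to genomic positions
#'
#' Exonic positions map inside their exon; a positive offset +k maps k bases
#' into the intron 3' of the donor exon's genomic edge (mirrored on the minus
#' strand), a negative offset -k maps k bases 5' of the acceptor exon.
#' Offsets are only valid from a genuine exon/intron boundary and must not
#' run past the far end of the intron.
#'
#' @param model a [TranscriptModel-class]
#' @param coord a [CdsCoordinate-class] (vectorized)
#' @return integer vector of 1-based genomic positions
#' @examples
#' cm <- makeCanonicalModel()
#' cdsToGenomic(cm$model, CdsCoordinate(294, 139))  # 1002483
#' @export
cdsToGenomic <- function(model, coord) {
  stopifnot(is(model, "TranscriptModel"), is(coord, "CdsCoordinate"))
  tx <- .txMap(model)
  dir <- if (model@strand == "-") -1L else 1L
  L <- cdsLength(model)
  vapply(seq_len(length(coord)), function(i) {
    b <- coord@base[i]; k <- coord@offset[i]
    if (b < 1L || b > L)
      .err("rohdel_bad_coordinate", "c.%d outside CDS of length %d", b, L)
    j <- which(!is.na(tx$cumFrom) & tx$cumFrom <= b & tx$cumTo >= b)
    if (k == 0L)
      return(tx$codingFirstG[j] + dir * (b - tx$cumFrom[j]))
    if (k > 0L) {
      if (j == nrow(tx))
        .err("rohdel_out_of_intron", "no intron 3' of the last exon")
      if (b != tx$cumTo[j] || tx$codingLastG[j] != tx$boundary3[j])
        .err("rohdel_bad_coordinate",
             "+%d offset only valid from an exon 3' boundary (c.%d is not one)",
             k, b)
      intronLen <- abs(tx$boundary5[j + 1L] - tx$boundary3[j]) - 1L
      if (k > intronLen)
        .err("rohdel_out_of_intron",
             "offset +%d exceeds intron length %d", k, intronLen)
      return(tx$boundary3[j] + dir * k)
    }
    ## k < 0
    if (b != tx$cumFrom[j] || tx$codingFirstG[j] != tx$boundary5[j])
      .err("rohdel_bad_coordinate",
           "%d offset only valid from an exon 5' boundary (c.%d is not one)",
           k, b)
    if (j == 1L)
      .err("rohdel_out_of_intron", "no intron 5' of the first exon")
    intronLen <- abs(tx$boundary5[j] - tx$boundary3[j - 1L]) - 1L
    if (-k > intronLen)
      .err("rohdel_out_of_intron",
           "offset %d exceeds intron length %d", k, intronLen)
    tx$boundary5[j] + dir * k
  }, integer(1))
}

#' Map genomic positions to coding-DNA coordinates
#'
#' Inverse of [cdsToGenomic()].  Intronic positions take the nearer-exon
#' convention: within the 5' half of an intron (ties included) the position
#' is expressed as "+k" from the preceding exon, otherwise "-k" from the
#' following one.  UTR positions are rejected (c.-k / c.*k nomenclature is
#' unsupported).
#'
#' @param model a [TranscriptModel-class]
#' @param g integer vector of 1-based genomic positions within the
#'   transcript span
#' @return a [CdsCoordinate-class]
#' @export
genomicToCds <- function(model, g) {
  stopifnot(is(model, "TranscriptModel"))
  tx <- .txMap(model)
  dir <- if (model@strand == "-") -1L else 1L
  span <- range(c(tx$gStart, tx$gEnd))
  res <- lapply(as.integer(g), function(gg) {
    if (gg < span[1] || gg > span[2])
      .err("rohdel_out_of_bounds",
           "position %d outside transcript span %d-%d", gg, span[1], span[2])
    j <- which(tx$gStart <= gg & tx$gEnd >= gg)
    if (length(j)) {
      if (is.na(tx$cumFrom[j]) ||
          gg < min(tx$codingFirstG[j], tx$codingLastG[j]) ||
          gg > max(tx$codingFirstG[j], tx$codingLastG[j]))
        .err("rohdel_utr_unsupported",
             "position %d is exonic but non-coding (UTR nomenclature unsupported)",
             gg)
      return(c(tx$cumFrom[j] + dir * (gg - tx$codingFirstG[j]), 0L))
    }
    ## intronic: find flanking tx-order exons
    j <- which(vapply(seq_len(nrow(tx) - 1L), function(i) {
      lo <- min(tx$boundary3[i], tx$boundary5[i + 1L])
      hi <- max(tx$boundary3[i], tx$boundary5[i + 1L])
      gg > lo && gg < hi
    }, logical(1)))
    d1 <- abs(gg - tx$boundary3[j])        # from 5' exon's edge
    d2 <- abs(tx$boundary5[j + 1L] - gg)   # to 3' exon's edge
    if (d1 <= d2) {
      if (tx$codingLastG[j] != tx$boundary3[j])
        .err("rohdel_utr_unsupported",
             "intron adjacent to a UTR exon edge is unsupported")
      c(tx$cumTo[j], d1)
    } else {
      if (tx$codingFirstG[j + 1L] != tx$boundary5[j + 1L])
        .err("rohdel_utr_unsupported",
             "intron adjacent to a UTR exon edge is unsupported")
      c(tx$cumFrom[j + 1L], -d2)
    }
  })
  m <- do.call(rbind, res)
  CdsCoordinate(m[, 1], m[, 2])
}

## ---------------------------------------------------------------------------
## Translation
## ---------------------------------------------------------------------------

#' Translate a CDS nucleotide string
#'
#' Standard genetic code.  A terminal stop codon is excluded from the
#' returned peptide; an internal stop is an error.
#'
#' @param seq nucleotide string (A/C/G/T), length divisible by 3
#' @return amino-acid string (one-letter codes)
#' @examples
#' translateCds("ATGGAATAA")  # "ME"
#' @export
translateCds <- function(seq) {
  seq <- toupper(seq)
  if (nchar(seq) %% 3L != 0L)
    .err("rohdel_bad_cds", "CDS length %d not divisible by 3", nchar(seq))
  if (grepl("[^ACGT]", seq))
    .err("rohdel_bad_cds", "CDS contains non-ACGT characters")
  aa <- as.character(Biostrings::translate(Biostrings::DNAString(seq)))
  body <- if (substring(aa, nchar(aa)) == "*") substr(aa, 1L, nchar(aa) - 1L) else aa
  if (grepl("\\*", body))
    .err("rohdel_internal_stop", "internal stop codon at residue %d",
         regexpr("\\*", body))
  body
}

#' Extract the CDS nucleotide sequence of a transcript
#'
#' @param model a [TranscriptModel-class]
#' @param genome a [GenomeSequence-class] covering the transcript span
#' @return CDS string in transcription order (reverse-complemented for
#'   minus-strand models)
#' @export
cdsSequence <- function(model, genome) {
  cr <- .codingRanges(model)
  pieces <- vapply(seq_along(cr), function(i)
    getSubseq(genome, model@chrom,
              GenomicRanges::start(cr)[i], GenomicRanges::end(cr)[i]),
    character(1))
  if (model@strand == "-") {
    pieces <- rev(vapply(pieces, function(p)
      as.character(Biostrings::reverseComplement(Biostrings::DNAString(p))),
      character(1)))
  }
  paste(pieces, collapse = "")
}

#' Check sequence-level CDS invariants of a model
#'
#' Verifies that the CDS translates cleanly with exactly one stop codon, at
#' its 3' end.
#'
#' @param model a [TranscriptModel-class]
#' @param genome a [GenomeSequence-class]
#' @return TRUE invisibly; errors name the violated invariant
#' @export
validateTranscriptSequence <- function(model, genome) {
  cds <- cdsSequence(model, genome)
  last <- substring(cds, nchar(cds) - 2L)
  if (!last %in% c("TAA", "TAG", "TGA"))
    .err("rohdel_bad_cds", "CDS does not end in a stop codon")
  translateCds(cds)  # errors on internal stops
  invisible(TRUE)
}

## ---------------------------------------------------------------------------
## Model file I/O
## ---------------------------------------------------------------------------

#' Load a transcript model from a GFF3 or TSV gene-model file
#'
#' GFF3 input needs \code{exon} and \code{CDS} features whose \code{Parent}
#' is the transcript.  The TSV dialect has one exon per row with columns
#' \code{gene_id, transcript_id, chrom, strand, exon_index, start, end,
#' cds_start, cds_end}, where cds_start/cds_end delimit the coding
#' sub-interval of the exon (empty/NA for a non-coding exon).
#'
#' @param path model file
#' @param transcript_id transcript to load (may be NULL if the file holds
#'   exactly one transcript)
#' @param format "auto" (by extension), "gff3" or "tsv"
#' @return a validated [TranscriptModel-class]
#' @export
loadTranscript <- function(path, transcript_id = NULL,
                           format = c("auto", "gff3", "tsv")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.gff3?$", path, ignore.case = TRUE)) "gff3" else "tsv"
  if (format == "gff3") .loadTranscriptGff3(path, transcript_id)
  else .loadTranscriptTsv(path, transcript_id)
}

.loadTranscriptGff3 <- function(path, transcript_id) {
  gr <- rtracklayer::import(path, format = "gff3")
  parent <- vapply(as.list(gr$Parent), function(p)
    if (length(p)) p[[1]] else NA_character_, character(1))
  type <- as.character(gr$type)
  if (is.null(transcript_id)) {
    tids <- unique(parent[type == "exon"])
    if (length(tids) != 1L)
      .err("rohdel_unknown_transcript",
           "file holds %d transcripts; specify transcript_id", length(tids))
    transcript_id <- tids
  }
  ex <- gr[type == "exon" & !is.na(parent) & parent == transcript_id]
  cds <- gr[type == "CDS" & !is.na(parent) & parent == transcript_id]
  if (length(ex) == 0L)
    .err("rohdel_unknown_transcript", "transcript '%s' not found in %s",
         transcript_id, path)
  mrna <- gr[type %in% c("mRNA", "transcript") & !is.na(gr$ID) &
             gr$ID == transcript_id]
  gid <- if (length(mrna)) parent[type %in% c("mRNA", "transcript") &
                                  !is.na(gr$ID) & gr$ID == transcript_id][1]
         else NA_character_
  ex <- BiocGenerics::sort(ex)
  strand <- as.character(GenomicRanges::strand(ex))[1]
  cdsLo <- min(GenomicRanges::start(cds)); cdsHi <- max(GenomicRanges::end(cds))
  TranscriptModel(gid %||% "", transcript_id,
                  as.character(GenomicRanges::seqnames(ex))[1], strand,
                  GenomicRanges::start(ex), GenomicRanges::end(ex),
                  if (strand == "-") cdsHi else cdsLo,
                  if (strand == "-") cdsLo else cdsHi)
}

.loadTranscriptTsv <- function(path, transcript_id) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("gene_id", "transcript_id", "chrom", "strand", "exon_index",
            "start", "end", "cds_start", "cds_end")
  if (!all(need %in% names(d)))
    .err("rohdel_bad_model_file", "TSV model file must have columns: %s",
         paste(need, collapse = ", "))
  if (is.null(transcript_id)) {
    tids <- unique(d$transcript_id)
    if (length(tids) != 1L)
      .err("rohdel_unknown_transcript",
           "file holds %d transcripts; specify transcript_id", length(tids))
    transcript_id <- tids
  }
  d <- d[d$transcript_id == transcript_id, , drop = FALSE]
  if (!nrow(d))
    .err("rohdel_unknown_transcript", "transcript '%s' not found in %s",
         transcript_id, path)
  d <- d[order(d$exon_index), , drop = FALSE]
  strand <- d$strand[1]
  coding <- d[!is.na(d$cds_start), , drop = FALSE]
  if (!nrow(coding))
    .err("rohdel_bad_model_file", "transcript '%s' has no coding exons",
         transcript_id)
  cdsLo <- min(coding$cds_start); cdsHi <- max(coding$cds_end)
  ord <- order(d$start)
  TranscriptModel(d$gene_id[1], transcript_id, d$chrom[1], strand,
                  d$start[ord], d$end[ord],
                  if (strand == "-") cdsHi else cdsLo,
                  if (strand == "-") cdsLo else cdsHi)
}

#' Write a transcript model to GFF3 or TSV
#'
#' @param model a [TranscriptModel-class]
#' @param path output file
#' @param format "gff3" or "tsv"
#' @return invisibly, the path
#' @export
writeTranscriptModel <- function(model, path, format = c("gff3", "tsv")) {
  format <- match.arg(format)
  tx <- .txMap(model)
  tx <- tx[order(tx$gStart), , drop = FALSE]
  if (format == "tsv") {
    d <- data.frame(gene_id = model@geneId, transcript_id = model@transcriptId,
                    chrom = model@chrom, strand = model@strand,
                    exon_index = seq_len(nrow(tx)),
                    start = tx$gStart, end = tx$gEnd,
                    cds_start = pmin(tx$codingFirstG, tx$codingLastG),
                    cds_end = pmax(tx$codingFirstG, tx$codingLastG))
    utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
    return(invisible(path))
  }
  gid <- if (nzchar(model@geneId)) model@geneId else "gene1"
  span <- range(c(tx$gStart, tx$gEnd))
  att <- function(...) paste(..., sep = ";")
  lines <- c("##gff-version 3",
    paste(model@chrom, "rohdel", "gene", span[1], span[2], ".", model@strand,
          ".", sprintf("ID=%s", gid), sep = "\t"),
    paste(model@chrom, "rohdel", "mRNA", span[1], span[2], ".", model@strand,
          ".", sprintf("ID=%s;Parent=%s", model@transcriptId, gid), sep = "\t"))
  for (i in seq_len(nrow(tx))) {
    lines <- c(lines,
      paste(model@chrom, "rohdel", "exon", tx$gStart[i], tx$gEnd[i], ".",
            model@strand, ".",
            sprintf("ID=%s.exon%d;Parent=%s", model@transcriptId, i,
                    model@transcriptId), sep = "\t"))
    if (!is.na(tx$cumFrom[i])) {
      cs <- min(tx$codingFirstG[i], tx$codingLastG[i])
      ce <- max(tx$codingFirstG[i], tx$codingLastG[i])
      lines <- c(lines,
        paste(model@chrom, "rohdel", "CDS", cs, ce, ".", model@strand, "0",
              sprintf("ID=%s.cds%d;Parent=%s", model@transcriptId, i,
                      model@transcriptId), sep = "\t"))
    }
  }
  writeLines(lines, path)
  invisible(path)
}
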
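## Variant records travel as a plain data.frame with columns
##   chrom, pos, id, ref, alt, filter, db129, af137, fclass, gt
## produced by readVariantVcf() or the synthetic generator.

.FUNCTIONAL_CLASSES <- c("nonsynonymous", "synonymous", "exonic_indel",
                         "splice_consensus", "intronic", "intergenic",
                         "other")

#' Read an annotated VCF into a variant table
#'
#' Uses [VariantAnnotation::readVcf()].  The cascade expects INFO keys
#' \code{DB129} (flag: present in the early dbSNP build), \code{AF137}
#' (float: minor allele frequency in the later build) and \code{FCLASS}
#' (string: functional class, one of nonsynonymous / synonymous /
#' exonic_indel / splice_consensus / intronic / intergenic / other);
#' missing annotations become NA.
#'
#' @param path VCF file (v4.2)
#' @return data.frame with columns chrom, pos, id, ref, alt, filter, db129,
#'   af137, fclass, gt
#' @export
readVariantVcf <- function(path) {
  vcf <- VariantAnnotation::readVcf(path, genome = "synthetic")
  rr <- SummarizedExperiment::rowRanges(vcf)
  n <- length(rr)
  info <- VariantAnnotation::info(vcf)
  getInfo <- function(key, default) {
    if (key %in% names(info)) {
      v <- info[[key]]
      if (is(v, "List")) v <- vapply(as.list(v), function(x)
        if (length(x)) x[[1]] else default, default)
      v
    } else rep(default, n)
  }
  alt <- vapply(as.list(VariantAnnotation::alt(vcf)), function(a)
    if (length(a)) as.character(a[[1]]) else NA_character_, character(1))
  gt <- if ("GT" %in% names(VariantAnnotation::geno(vcf)) &&
            ncol(vcf) >= 1L)
    as.character(VariantAnnotation::geno(vcf)$GT[, 1L]) else rep(NA_character_, n)
  data.frame(
    chrom = as.character(GenomicRanges::seqnames(rr)),
    pos = GenomicRanges::start(rr),
    id = names(rr) %||% rep(NA_character_, n),
    ref = as.character(VariantAnnotation::ref(vcf)),
    alt = alt,
    filter = as.character(rr$FILTER),
    db129 = as.logical(getInfo("DB129", FALSE)),
    af137 = as.numeric(getInfo("AF137", NA_real_)),
    fclass = as.character(getInfo("FCLASS", NA_character_)),
    gt = gt,
    row.names = NULL, stringsAsFactors = FALSE)
}

#' Restrict a variant table to candidate regions
#'
#' Keeps caller-passing records (\code{FILTER == "PASS"}) whose position
#' falls inside any candidate region (inclusive bounds).  Overlapping
#' regions are merged first.  Records with missing coordinates or an
#' unrecognized functional class are malformed: they are skipped with a
#' warning and counted in the \code{"n_malformed"} attribute of the result.
#'
#' @param variants variant data.frame (see [readVariantVcf()])
#' @param regions [GenomicRanges::GRanges] of candidate regions
#' @return filtered data.frame, attribute \code{n_malformed} set
#' @export
restrictToRegions <- function(variants, regions) {
  malformed <- is.na(variants$chrom) | is.na(variants$pos) |
    (!is.na(variants$fclass) & !variants$fclass %in% .FUNCTIONAL_CLASSES)
  if (any(malformed))
    warning(sprintf("skipping %d malformed variant record(s)",
                    sum(malformed)))
  v <- variants[!malformed, , drop = FALSE]
  regions <- GenomicRanges::reduce(granges(regions))
  keep <- rep(FALSE, nrow(v))
  rchr <- as.character(GenomicRanges::seqnames(regions))
  rs <- GenomicRanges::start(regions); re <- GenomicRanges::end(regions)
  for (i in seq_along(regions))
    keep <- keep | (v$chrom == rchr[i] & v$pos >= rs[i] & v$pos <= re[i])
  keep <- keep & v$filter == "PASS"
  out <- v[keep, , drop = FALSE]
  attr(out, "n_malformed") <- sum(malformed)
  out
}

#' Filter out known polymorphisms
#'
#' Drops records present in the early dbSNP build (\code{db129}) or with a
#' minor allele frequency of at least \code{maf_threshold} in the later
#' build (threshold inclusive).  Records with unknown MAF are retained
#' unless db129-flagged (conservative for a discovery screen).
#'
#' @param variants variant data.frame
#' @param maf_threshold inclusive MAF cutoff (default 0.01)
#' @return filtered data.frame
#' @export
filterKnown <- function(variants, maf_threshold = 0.01) {
  drop <- variants$db129 %in% TRUE |
    (!is.na(variants$af137) & variants$af137 >= maf_threshold)
  variants[!drop, , drop = FALSE]
}

#' Keep potentially protein-altering variants
#'
#' Retains nonsynonymous substitutions, exonic insertions/deletions and
#' splice-consensus-site variants.  The splice-consensus class is assigned
#' upstream (annotation); by default it denotes the canonical +/-2 intronic
#' dinucleotides.
#'
#' @param variants variant data.frame
#' @param keep_classes classes retained
#' @return filtered data.frame
#' @export
filterFunctional <- function(variants,
                             keep_classes = c("nonsynonymous", "exonic_indel",
                                              "splice_consensus")) {
  variants[!is.na(variants$fclass) & variants$fclass %in% keep_classes, ,
           drop = FALSE]
}

#' Flag indels lying in tandem-repeat context
#'
#' An insertion or deletion whose sequence is a whole multiple of a
#' tandem-repeat unit (unit length at most \code{unit_max}) that is present
#' at least \code{min_copies} times in the reference abutting the breakpoint
#' is flagged as a likely repeat-number polymorphism.  Flagged records are
#' annotated, never removed: repeat-context judgement is left to the
#' analyst.
#'
#' @param variants variant data.frame (left-anchored REF/ALT alleles)
#' @param genome a [GenomeSequence-class] covering the variant sites
#' @param unit_max maximum repeat-unit length considered (bp)
#' @param min_copies minimum tandem copies in the reference
#' @return logical vector, one element per record: TRUE/FALSE for indels,
#'   NA for non-indels (not applicable)
#' @export
flagRepeatContext <- function(variants, genome, unit_max = 6L,
                              min_copies = 4L) {
  vapply(seq_len(nrow(variants)), function(i) {
    ref <- variants$ref[i]; alt <- variants$alt[i]
    if (is.na(ref) || is.na(alt)) return(NA)
    if (nchar(ref) == 1L && nchar(alt) > 1L &&
        substr(alt, 1L, 1L) == ref) {
      indel <- substr(alt, 2L, nchar(alt))
    } else if (nchar(alt) == 1L && nchar(ref) > 1L &&
               substr(ref, 1L, 1L) == alt) {
      indel <- substr(ref, 2L, nchar(ref))
    } else {
      return(NA)                         # SNV or complex: not applicable
    }
    .repeatContext(indel, genome, variants$chrom[i], variants$pos[i],
                   unit_max, min_copies)
  }, logical(1))
}

## is `indel` a whole multiple of a unit (<= unit_max) present >= min_copies
## in tandem in the reference abutting position `pos` (breakpoint after pos)?
.repeatContext <- function(indel, genome, chrom, pos, unit_max, min_copies) {
  L <- nchar(indel)
  fetch <- function(s, e) tryCatch(getSubseq(genome, chrom, s, e),
                                   error = function(e) NULL)
  for (u in seq_len(min(unit_max, L))) {
    if (L %% u != 0L) next
    unit <- substr(indel, 1L, u)
    if (strrep(unit, L %/% u) != indel) next   # not periodic with period u
    for (t in seq_len(u) - 1L) {
      rot <- paste0(substr(unit, t + 1L, u), substr(unit, 1L, t))
      right <- 0L
      repeat {
        s <- pos + 1L + right * u
        piece <- fetch(s, s + u - 1L)
        if (is.null(piece) || piece != rot) break
        right <- right + 1L
      }
      left <- 0L
      repeat {
        e <- pos - left * u
        piece <- fetch(e - u + 1L, e)
        if (is.null(piece) || piece != rot) break
        left <- left + 1L
      }
      if (left + right >= min_copies) return(TRUE)
    }
  }
  FALSE
}

#' Run the full rare-variant filter cascade
#'
#' Region restriction, known-polymorphism removal, functional-class
#' selection, then repeat-context flagging of surviving indels.  Per-stage
#' input/output counts are book-kept in the returned [FilterReport-class].
#'
#' @param variants variant data.frame (see [readVariantVcf()])
#' @param regions candidate [GenomicRanges::GRanges]
#' @param genome a [GenomeSequence-class] (NULL skips repeat flagging)
#' @param maf_threshold inclusive MAF cutoff for [filterKnown()]
#' @param keep_classes classes retained by [filterFunctional()]
#' @param unit_max,min_copies repeat-context parameters
#' @return a [FilterReport-class]
#' @export
runCascade <- function(variants, regions, genome = NULL,
                       maf_threshold = 0.01,
                       keep_classes = c("nonsynonymous", "exonic_indel",
                                        "splice_consensus"),
                       unit_max = 6L, min_copies = 4L) {
  s1 <- restrictToRegions(variants, regions)
  s2 <- filterKnown(s1, maf_threshold)
  s3 <- filterFunctional(s2, keep_classes)
  survivors <- s3
  survivors$repeat_flag <- if (nrow(s3) && !is.null(genome))
    flagRepeatContext(s3, genome, unit_max, min_copies)
  else rep(NA, nrow(s3))
  stages <- data.frame(
    stage = c("region_restriction", "known_polymorphisms",
              "functional_class"),
    n_in = c(nrow(variants), nrow(s1), nrow(s2)),
    n_out = c(nrow(s1), nrow(s2), nrow(s3)))
  obj <- new("FilterReport", stages = stages, survivors = survivors,
             skipped = attr(s1, "n_malformed") %||% 0L)
  validObject(obj)
  obj
}

#' @rdname runCascade
#' @param report a [FilterReport-class]
#' @export
filterStages <- function(report) report@stages

#' @rdname runCascade
#' @export
filterSurvivors <- function(report) report@survivors

setMethod("show", "FilterReport", function(object) {
  cat("FilterReport:\n")
  st <- object@stages
  for (i in seq_len(nrow(st)))
    cat(sprintf("  %-22s %5d -> %5d\n", st$stage[i], st$n_in[i], st$n_out[i]))
  if (object@skipped > 0L)
    cat(sprintf("  (%d malformed record(s) skipped)\n", object@skipped))
  nf <- sum(object@survivors$repeat_flag %in% TRUE)
  cat(sprintf("  survivors: %d (%d flagged LIKELY_REPEAT_POLYMORPHISM)\n",
              nrow(object@survivors), nf))
})

#' Write a filter report as TSV plus a human-readable log
#'
#' @param report a [FilterReport-class]
#' @param tsv path for the surviving records (TSV); NULL skips
#' @param log path for the per-stage counts (text); NULL skips
#' @return invisibly, the paths
#' @export
writeFilterReport <- function(report, tsv = NULL, log = NULL) {
  if (!is.null(tsv)) {
    out <- report@survivors
    out$annotation <- ifelse(out$repeat_flag %in% TRUE,
                             "LIKELY_REPEAT_POLYMORPHISM", "")
    utils::write.table(out, tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  if (!is.null(log)) {
    con <- file(log, "w"); on.exit(close(con))
    st <- report@stages
    writeLines(c(
      "variant filter cascade",
      sprintf("  %-22s %6s %6s", "stage", "in", "out"),
      sprintf("  %-22s %6d %6d", st$stage, st$n_in, st$n_out),
      sprintf("  malformed records skipped: %d", report@skipped),
      sprintf("  survivors flagged as repeat polymorphisms: %d",
              sum(report@survivors$repeat_flag %in% TRUE))), con)
  }
  invisible(c(tsv = tsv, log = log))
}
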
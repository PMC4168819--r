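## ---------------------------------------------------------------------------
## GenotypeMatrix
## ---------------------------------------------------------------------------

#' Construct a GenotypeMatrix
#'
#' @param chrom,pos,marker_id parallel vectors describing the markers;
#'   positions must be strictly increasing within each chromosome
#' @param calls character matrix (markers x samples) with entries
#'   AA/AB/BB/NC and sample ids as column names
#' @return a [GenotypeMatrix-class]
#' @export
GenotypeMatrix <- function(chrom, pos, marker_id, calls) {
  mk <- GenomicRanges::GRanges(chrom, IRanges::IRanges(pos, width = 1L))
  S4Vectors::mcols(mk)$marker_id <- as.character(marker_id)
  obj <- new("GenotypeMatrix", markers = mk, calls = as.matrix(calls))
  validObject(obj)
  obj
}

#' @describeIn GenotypeMatrix sample ids
#' @param x,object a GenotypeMatrix
#' @export
setMethod("colnames", "GenotypeMatrix", function(x) colnames(x@calls))

#' @rdname GenotypeMatrix
#' @export
markerRanges <- function(x) x@markers

#' @rdname GenotypeMatrix
#' @export
genotypeCalls <- function(x) x@calls

setMethod("show", "GenotypeMatrix", function(object) {
  cat(sprintf("GenotypeMatrix: %d markers on %d chromosome(s), %d samples\n",
              length(object@markers),
              length(unique(as.character(GenomicRanges::seqnames(object@markers)))),
              ncol(object@calls)))
})

#' Read a genotype matrix from TSV
#'
#' Expected columns: chrom, pos, marker_id, then one column of AA/AB/BB/NC
#' calls per sample.
#'
#' @param path TSV file
#' @return a [GenotypeMatrix-class]
#' @export
readGenotypeTsv <- function(path) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE,
                         check.names = FALSE)
  need <- c("chrom", "pos", "marker_id")
  if (!all(need %in% names(d)))
    .err("rohdel_bad_genotype_file",
         "genotype TSV must start with columns chrom, pos, marker_id")
  samp <- setdiff(names(d), need)
  GenotypeMatrix(d$chrom, d$pos, d$marker_id,
                 as.matrix(d[, samp, drop = FALSE]))
}

#' Write a genotype matrix as TSV
#'
#' @param g a [GenotypeMatrix-class]
#' @param path output file
#' @return invisibly, the path
#' @export
writeGenotypeTsv <- function(g, path) {
  d <- data.frame(
    chrom = as.character(GenomicRanges::seqnames(g@markers)),
    pos = GenomicRanges::start(g@markers),
    marker_id = S4Vectors::mcols(g@markers)$marker_id,
    g@calls, check.names = FALSE)
  utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

## ---------------------------------------------------------------------------
## ROH detection
## ---------------------------------------------------------------------------

#' Region size in megabases
#'
#' Sizes follow the (end - start) / 1e6 convention (no +1), rounded half-up
#' to one decimal.
#'
#' @param start,end 1-based genomic positions, end >= start
#' @return size in Mb, one decimal
#' @examples
#' regionSizeMb(11698902, 26171473)  # 14.5
#' @export
regionSizeMb <- function(start, end) {
  if (any(end < start))
    .err("rohdel_bad_interval", "end must be >= start")
  roundHalfUp((end - start) / 1e6, 1L)
}

## decorate a region GRanges with marker support and sizes
.annotateRegions <- function(gr, markers = NULL, calls = NULL) {
  if (!length(gr)) {
    S4Vectors::mcols(gr) <- S4Vectors::DataFrame(
      n_markers = integer(), n_het_tolerated = integer(),
      n_missing_tolerated = integer(), size_mb = numeric())
    return(gr)
  }
  if (!is.null(markers)) {
    ov <- GenomicRanges::findOverlaps(markers, gr)
    nm <- tabulate(S4Vectors::subjectHits(ov), nbins = length(gr))
    S4Vectors::mcols(gr)$n_markers <- nm
    if (!is.null(calls)) {
      het <- miss <- integer(length(gr))
      for (k in seq_len(length(gr))) {
        idx <- S4Vectors::queryHits(ov)[S4Vectors::subjectHits(ov) == k]
        het[k] <- sum(calls[idx] == "AB")
        miss[k] <- sum(calls[idx] == "NC")
      }
      S4Vectors::mcols(gr)$n_het_tolerated <- het
      S4Vectors::mcols(gr)$n_missing_tolerated <- miss
    }
  }
  S4Vectors::mcols(gr)$size_mb <-
    regionSizeMb(GenomicRanges::start(gr), GenomicRanges::end(gr))
  gr
}

#' Detect runs of homozygosity for one sample
#'
#' Finds maximal runs of consecutive markers that are homozygous, tolerating
#' up to \code{max_het} heterozygous and \code{max_missing} missing calls
#' per run.  Run boundaries are trimmed to the outermost homozygous marker
#' positions; runs supported by fewer than \code{min_markers} markers or
#' spanning less than \code{min_length_bp} (end - start) are discarded.
#'
#' Defaults target multi-megabase autozygous segments at SNP-array marker
#' density while tolerating occasional genotyping artefacts; all are
#' configurable.
#'
#' @param g a [GenotypeMatrix-class]
#' @param sample sample id
#' @param min_markers minimum markers per run
#' @param min_length_bp minimum run span in bp (end - start)
#' @param max_het maximum heterozygous calls tolerated per run
#' @param max_missing maximum missing calls tolerated per run
#' @return [GenomicRanges::GRanges] of ROH regions with mcols
#'   \code{n_markers}, \code{n_het_tolerated}, \code{n_missing_tolerated},
#'   \code{size_mb}
#' @export
detectRoh <- function(g, sample, min_markers = 25L, min_length_bp = 1e6,
                      max_het = 1L, max_missing = 2L) {
  stopifnot(is(g, "GenotypeMatrix"))
  if (length(g@markers) == 0L)
    .err("rohdel_empty_matrix", "genotype matrix has no markers")
  if (!sample %in% colnames(g@calls))
    .err("rohdel_unknown_sample", "unknown sample '%s'", sample)
  stopifnot(min_markers > 0L, min_length_bp > 0, max_het >= 0L,
            max_missing >= 0L)
  chr <- as.character(GenomicRanges::seqnames(g@markers))
  pos <- GenomicRanges::start(g@markers)
  calls <- g@calls[, sample]
  lev <- unique(chr)
  out <- list()
  for (cc in lev) {
    sel <- which(chr == cc)
    gr1 <- .rohOneChrom(calls[sel], pos[sel], cc,
                        min_markers, min_length_bp, max_het, max_missing)
    GenomeInfoDb::seqlevels(gr1) <- lev
    out[[cc]] <- gr1
  }
  gr <- do.call(c, unname(out))
  names(gr) <- NULL
  .annotateRegions(BiocGenerics::sort(gr), g@markers, calls)
}

## sliding-window scan on one chromosome: for each window end r keep the
## smallest window start l such that [l, r] respects the het/missing
## budgets; windows where l is forced to advance (or r is the last marker)
## are the maximal qualifying runs.
.rohOneChrom <- function(calls, pos, chrom, min_markers, min_length_bp,
                         max_het, max_missing) {
  n <- length(calls)
  het <- calls == "AB"
  mis <- calls == "NC"
  hom <- !het & !mis
  keepS <- integer(0); keepE <- integer(0)
  l <- 1L; nh <- 0L; nm <- 0L
  for (r in seq_len(n)) {
    nh <- nh + het[r]; nm <- nm + mis[r]
    moved <- FALSE
    while (nh > max_het || nm > max_missing) {
      nh <- nh - het[l]; nm <- nm - mis[l]
      l <- l + 1L; moved <- TRUE
    }
    if (moved && r > 1L && lPrev <= r - 1L) {
      ## window ending at r-1 was maximal
      keepS <- c(keepS, lPrev); keepE <- c(keepE, r - 1L)
    }
    lPrev <- l
  }
  if (n > 0L && l <= n) { keepS <- c(keepS, l); keepE <- c(keepE, n) }
  ## trim to outermost homozygous markers; filter; dedupe
  starts <- ends <- integer(0)
  for (i in seq_along(keepS)) {
    idx <- keepS[i]:keepE[i]
    homIdx <- idx[hom[idx]]
    if (!length(homIdx)) next
    s <- min(homIdx); e <- max(homIdx)
    if (e - s + 1L < min_markers) next
    if (pos[e] - pos[s] < min_length_bp) next
    starts <- c(starts, s); ends <- c(ends, e)
  }
  if (length(starts)) {
    dup <- duplicated(paste(starts, ends))
    ## a trimmed run may be nested in another trimmed run; drop contained ones
    keep <- !dup
    for (i in seq_along(starts)) {
      if (!keep[i]) next
      contained <- starts <= starts[i] & ends >= ends[i] &
        !(starts == starts[i] & ends == ends[i])
      if (any(contained & keep)) keep[i] <- FALSE
    }
    starts <- starts[keep]; ends <- ends[keep]
  }
  if (!length(starts)) return(GenomicRanges::GRanges())
  GenomicRanges::GRanges(chrom, IRanges::IRanges(pos[starts], pos[ends]))
}

#' Intersect per-sample ROH regions into shared candidate regions
#'
#' Returns the maximal genomic intervals contained in at least one ROH of
#' every sample.  Marker support is recomputed over the intersections when
#' the genotype matrix is supplied.
#'
#' @param regions_per_sample named list (one [GenomicRanges::GRanges] per
#'   affected sample)
#' @param genotypes optional [GenotypeMatrix-class] for marker recounts
#' @return [GenomicRanges::GRanges] of shared regions with \code{n_markers}
#'   and \code{size_mb} mcols
#' @export
intersectShared <- function(regions_per_sample, genotypes = NULL) {
  if (length(regions_per_sample) < 2L)
    .err("rohdel_bad_input", "need ROH region sets for at least 2 samples")
  red <- lapply(regions_per_sample, function(r)
    GenomicRanges::reduce(granges(r)))
  ## samples may carry ROH on disjoint chromosome sets; differing seqlevels
  ## are expected, not a data problem
  shared <- suppressWarnings(Reduce(function(a, b)
    GenomicRanges::intersect(a, b, ignore.strand = TRUE), red))
  shared <- BiocGenerics::sort(shared)
  .annotateRegions(shared,
                   if (!is.null(genotypes)) genotypes@markers else NULL)
}

#' Write ROH/shared regions as BED and TSV
#'
#' BED output is 0-based half-open; the TSV keeps 1-based inclusive
#' coordinates with marker counts and sizes.
#'
#' @param regions [GenomicRanges::GRanges] from [detectRoh()] or
#'   [intersectShared()]
#' @param bed,tsv output paths (either may be NULL to skip)
#' @return invisibly, the paths written
#' @export
writeRohRegions <- function(regions, bed = NULL, tsv = NULL) {
  if (!is.null(bed)) {
    rtracklayer::export(granges(regions), bed, format = "BED")
  }
  if (!is.null(tsv)) {
    d <- data.frame(chrom = as.character(GenomicRanges::seqnames(regions)),
                    start = GenomicRanges::start(regions),
                    end = GenomicRanges::end(regions))
    mc <- S4Vectors::mcols(regions)
    for (nm in names(mc)) d[[nm]] <- mc[[nm]]
    utils::write.table(d, tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(c(bed = bed, tsv = tsv))
}
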
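## ---------------------------------------------------------------------------
## Depth tracks and per-exon aggregation
## ---------------------------------------------------------------------------

#' Read a per-base depth track
#'
#' Accepts bedGraph (0-based half-open intervals with a depth value) or a
#' 3-column TSV (chrom, pos, depth; 1-based positions).  Bases absent from
#' the track count as depth 0.
#'
#' @param path depth file
#' @param format "auto" (by extension), "bedgraph" or "tsv"
#' @return data.frame with columns chrom, pos, depth (1-based, one row per
#'   covered base)
#' @export
readDepthTrack <- function(path, format = c("auto", "bedgraph", "tsv")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.(bedgraph|bg)$", path, ignore.case = TRUE))
      "bedgraph" else "tsv"
  if (format == "bedgraph") {
    gr <- rtracklayer::import(path, format = "bedGraph")
    n <- BiocGenerics::width(gr)
    data.frame(
      chrom = rep(as.character(GenomicRanges::seqnames(gr)), n),
      pos = unlist(lapply(seq_along(gr), function(i)
        seq(GenomicRanges::start(gr)[i], GenomicRanges::end(gr)[i]))),
      depth = rep(gr$score, n))
  } else {
    d <- utils::read.delim(path, stringsAsFactors = FALSE)
    if (!all(c("chrom", "pos", "depth") %in% names(d)))
      .err("rohdel_bad_depth_file",
           "depth TSV must have columns chrom, pos, depth")
    d[, c("chrom", "pos", "depth")]
  }
}

#' Mean read depth per exon
#'
#' mean_depth = (sum of per-base depth over the exon) / exon length, bounds
#' inclusive; bases absent from the track contribute 0.
#'
#' @param depth data.frame with columns chrom, pos, depth (or a file path
#'   accepted by [readDepthTrack()])
#' @param model a [TranscriptModel-class] (its exons are the intervals), or
#'   a [GenomicRanges::GRanges] of intervals
#' @return numeric vector of mean depths, one per exon
#' @export
exonMeanDepth <- function(depth, model) {
  if (is.character(depth)) depth <- readDepthTrack(depth)
  exons <- if (is(model, "TranscriptModel")) model@exons else model
  chrTrack <- unique(depth$chrom)
  vapply(seq_along(exons), function(i) {
    cc <- as.character(GenomicRanges::seqnames(exons))[i]
    s <- GenomicRanges::start(exons)[i]; e <- GenomicRanges::end(exons)[i]
    if (!cc %in% chrTrack)
      .err("rohdel_missing_chrom",
           "depth track has no chromosome '%s' (exon %d, %s:%d-%d)",
           cc, i, cc, s, e)
    sel <- depth$chrom == cc & depth$pos >= s & depth$pos <= e
    sum(depth$depth[sel]) / (e - s + 1L)
  }, numeric(1))
}

## ---------------------------------------------------------------------------
## ExonDepthTable
## ---------------------------------------------------------------------------

#' Construct an ExonDepthTable
#'
#' @param exons [GenomicRanges::GRanges] of exon intervals
#' @param gene gene label(s), recycled over exons
#' @param depths numeric matrix, exons x samples, mean reads/base
#' @param case name of the case sample (all others form the control panel)
#' @return an [ExonDepthTable-class]
#' @export
ExonDepthTable <- function(exons, gene, depths, case) {
  depths <- as.matrix(depths)
  if (is.null(colnames(depths)))
    .err("rohdel_bad_input", "depth matrix needs sample names")
  if (!case %in% colnames(depths))
    .err("rohdel_unknown_sample", "case sample '%s' not in depth matrix", case)
  rr <- granges(exons)
  S4Vectors::mcols(rr)$gene <- rep_len(gene, length(rr))
  S4Vectors::mcols(rr)$exon_index <- seq_along(rr)
  cd <- S4Vectors::DataFrame(
    role = ifelse(colnames(depths) == case, "case", "panel"),
    row.names = colnames(depths))
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(meanDepth = depths), rowRanges = rr, colData = cd)
  obj <- new("ExonDepthTable", se)
  validObject(obj)
  obj
}

setMethod("show", "ExonDepthTable", function(object) {
  cat(sprintf("ExonDepthTable: %d exon(s) x %d sample(s) (case: %s)\n",
              nrow(object), ncol(object),
              paste(colnames(object)[object$role == "case"], collapse = ", ")))
  rd <- SummarizedExperiment::rowData(object)
  if ("depth_ratio" %in% names(rd))
    cat("  panel summaries present (compareToPanel applied)\n")
})

#' Summarize a case sample against its control panel
#'
#' Adds per-exon \code{panel_mean} (arithmetic mean over panel samples),
#' \code{panel_min}, \code{panel_max}, \code{case_depth} and
#' \code{depth_ratio = case_depth / panel_mean} to the rowData.  A zero
#' panel mean leaves the ratio undefined (NA), which downstream calling
#' treats as low confidence.  With \code{normalize = TRUE} every sample is
#' first rescaled so its median exon depth matches the cross-sample median
#' (for unequal library sizes); raw means are compared by default.
#'
#' @param edt an [ExonDepthTable-class] with >= 2 panel samples
#' @param normalize per-sample median-depth normalization flag
#' @return the [ExonDepthTable-class] with panel summaries
#' @export
compareToPanel <- function(edt, normalize = FALSE) {
  stopifnot(is(edt, "ExonDepthTable"))
  d <- SummarizedExperiment::assay(edt, "meanDepth")
  role <- edt$role
  if (sum(role == "panel") < 2L)
    .err("rohdel_bad_input", "need at least 2 panel samples")
  if (normalize) {
    med <- apply(d, 2L, stats::median)
    target <- stats::median(med)
    scale <- ifelse(med > 0, target / med, 1)
    d <- sweep(d, 2L, scale, `*`)
  }
  panel <- d[, role == "panel", drop = FALSE]
  case <- d[, role == "case", drop = FALSE][, 1L]
  rd <- SummarizedExperiment::rowData(edt)
  rd$case_depth <- case
  rd$panel_mean <- rowMeans(panel)
  rd$panel_min <- apply(panel, 1L, min)
  rd$panel_max <- apply(panel, 1L, max)
  rd$depth_ratio <- ifelse(rd$panel_mean > 0, case / rd$panel_mean, NA_real_)
  SummarizedExperiment::rowData(edt) <- rd
  validObject(edt)
  edt
}

#' Call candidate homozygous exon deletions
#'
#' An exon is a \code{homozygous_deletion_candidate} when its depth ratio is
#' at most \code{max_ratio} and the panel mean is at least
#' \code{min_panel_depth}; exons whose panel is too shallow to judge (or
#' with undefined ratio) are \code{low_confidence}; everything else is
#' \code{normal}.  Verdicts are computed on unrounded values; the reported
#' ratio is rounded to 4 decimals.
#'
#' @param edt an [ExonDepthTable-class] after [compareToPanel()]
#' @param max_ratio largest case/panel depth ratio called (default 0.1)
#' @param min_panel_depth minimum panel mean for a confident call
#' @return data.frame of calls (gene, exon_index, chrom, start, end,
#'   case_depth, panel_mean, depth_ratio, verdict)
#' @export
callDeletions <- function(edt, max_ratio = 0.1, min_panel_depth = 10) {
  stopifnot(is(edt, "ExonDepthTable"))
  rd <- SummarizedExperiment::rowData(edt)
  if (!"depth_ratio" %in% names(rd))
    .err("rohdel_bad_input", "run compareToPanel() before callDeletions()")
  rr <- SummarizedExperiment::rowRanges(edt)
  verdict <- ifelse(
    rd$panel_mean < min_panel_depth | is.na(rd$depth_ratio),
    "low_confidence",
    ifelse(rd$depth_ratio <= max_ratio, "homozygous_deletion_candidate",
           "normal"))
  data.frame(
    gene = rd$gene, exon_index = rd$exon_index,
    chrom = as.character(GenomicRanges::seqnames(rr)),
    start = GenomicRanges::start(rr), end = GenomicRanges::end(rr),
    case_depth = rd$case_depth, panel_mean = rd$panel_mean,
    depth_ratio = roundHalfUp(rd$depth_ratio, 4L),
    verdict = verdict, row.names = NULL)
}

#' Write coverage-screen output
#'
#' TSV of the full table with calls, plus optionally a BED (0-based
#' half-open) of candidate deleted exons.
#'
#' @param edt an [ExonDepthTable-class] after [compareToPanel()]
#' @param calls output of [callDeletions()]
#' @param tsv,bed output paths (NULL skips)
#' @return invisibly, the paths
#' @export
writeCoverageScreen <- function(edt, calls, tsv = NULL, bed = NULL) {
  if (!is.null(tsv)) {
    d <- calls
    d$case_depth <- roundHalfUp(d$case_depth, 2L)
    d$panel_mean <- roundHalfUp(d$panel_mean, 2L)
    utils::write.table(d, tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  if (!is.null(bed)) {
    cand <- calls[calls$verdict == "homozygous_deletion_candidate", ,
                  drop = FALSE]
    gr <- GenomicRanges::GRanges(cand$chrom,
                                 IRanges::IRanges(cand$start, cand$end))
    rtracklayer::export(gr, bed, format = "BED")
  }
  invisible(c(tsv = tsv, bed = bed))
}
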
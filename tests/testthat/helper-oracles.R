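## Independent oracles and small fixture builders used across test files.

## ---- brute-force ROH enumeration -----------------------------------------
## All maximal marker windows with at most max_het heterozygous and
## max_missing missing calls, trimmed to the outermost homozygous markers,
## deduplicated, containment-pruned and threshold-filtered.  Quadratic in
## the number of markers; the reference the scanning detector must match.
bruteForceRoh <- function(calls, pos, min_markers = 25L,
                          min_length_bp = 1e6, max_het = 1L,
                          max_missing = 2L) {
  n <- length(calls)
  het <- calls == "AB"; mis <- calls == "NC"; hom <- !het & !mis
  ch <- c(0L, cumsum(het)); cm <- c(0L, cumsum(mis))
  ok <- function(i, j) (ch[j + 1L] - ch[i]) <= max_het &&
    (cm[j + 1L] - cm[i]) <= max_missing
  starts <- ends <- integer(0)
  for (i in seq_len(n)) for (j in i:n) {
    if (!ok(i, j)) break
    maximal <- (i == 1L || !ok(i - 1L, j)) && (j == n || !ok(i, j + 1L))
    if (!maximal) next
    idx <- i:j; homIdx <- idx[hom[idx]]
    if (!length(homIdx)) next
    s <- min(homIdx); e <- max(homIdx)
    if (e - s + 1L < min_markers) next
    if (pos[e] - pos[s] < min_length_bp) next
    starts <- c(starts, s); ends <- c(ends, e)
  }
  if (length(starts)) {
    dup <- duplicated(paste(starts, ends))
    keep <- !dup
    for (k in seq_along(starts)) {
      if (!keep[k]) next
      contained <- starts <= starts[k] & ends >= ends[k] &
        !(starts == starts[k] & ends == ends[k])
      if (any(contained & keep)) keep[k] <- FALSE
    }
    starts <- starts[keep]; ends <- ends[keep]
  }
  o <- order(starts, ends)
  data.frame(start = pos[starts[o]], end = pos[ends[o]])
}

## one-chromosome GenotypeMatrix from a call vector
gmFromCalls <- function(calls, pos = NULL, sample = "S1", chrom = "chr1") {
  if (is.null(pos)) pos <- seq_along(calls) * 1000L
  m <- matrix(calls, ncol = 1, dimnames = list(NULL, sample))
  GenotypeMatrix(rep(chrom, length(calls)), pos,
                 sprintf("m%04d", seq_along(calls)), m)
}

rohAsDf <- function(gr) {
  if (!length(gr)) return(data.frame(start = integer(0), end = integer(0)))
  data.frame(start = GenomicRanges::start(gr), end = GenomicRanges::end(gr))
}

## ---- brute-force tandem-repeat context check ------------------------------
## Character-by-character enumeration over unit lengths and phases: is the
## indel a whole multiple of some unit of length <= unit_max that tiles the
## reference at least min_copies times in tandem, phase-aligned to the
## breakpoint after position bp (1-based index into `context`)?
bruteForceRepeat <- function(indel, context, bp, unit_max = 6L,
                             min_copies = 4L) {
  L <- nchar(indel)
  cv <- strsplit(context, "")[[1]]
  iv <- strsplit(indel, "")[[1]]
  for (u in seq_len(min(unit_max, L))) {
    if (L %% u != 0L) next
    periodic <- TRUE
    for (k in seq_len(L)) if (iv[k] != iv[(k - 1L) %% u + 1L]) {
      periodic <- FALSE; break
    }
    if (!periodic) next
    for (phase in seq_len(u) - 1L) {
      unit <- iv[((phase + seq_len(u) - 1L) %% u) + 1L]
      right <- 0L
      repeat {
        s <- bp + 1L + right * u
        if (s + u - 1L > length(cv) ||
            any(cv[s:(s + u - 1L)] != unit)) break
        right <- right + 1L
      }
      left <- 0L
      repeat {
        e <- bp - left * u
        if (e - u + 1L < 1L || any(cv[(e - u + 1L):e] != unit)) break
        left <- left + 1L
      }
      if (left + right >= min_copies) return(TRUE)
    }
  }
  FALSE
}

## ---- model fixtures --------------------------------------------------------
## canonical toy model built once per test run
canonicalFixture <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- makeCanonicalModel()
    cache
  }
})

## reflect the canonical model (and genome) onto the minus strand:
## coordinate g maps to chromLen + 1 - g, the sequence is
## reverse-complemented, and all c. positions must be preserved.
mirrorFixture <- function(cm) {
  chromLen <- 1100000L
  refl <- function(g) chromLen + 1L - g
  ex <- exonRanges(cm$model)
  s <- refl(GenomicRanges::end(ex)); e <- refl(GenomicRanges::start(ex))
  o <- order(s)
  model <- TranscriptModel(geneId(cm$model), transcriptId(cm$model),
                           "chrM", "-", s[o], e[o],
                           refl(cm$model@cdsStart), refl(cm$model@cdsEnd))
  fwd <- getSubseq(cm$genome, "chrG", 1L, chromLen)
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(fwd)))
  list(model = model, genome = GenomeSequence(c(chrM = rc)), refl = refl)
}
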
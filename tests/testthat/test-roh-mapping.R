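test_that("region sizes follow the end-minus-start megabase convention", {
  expect_identical(regionSizeMb(11698902, 26171473), 14.5)
  expect_identical(regionSizeMb(71230491, 83403217), 12.2)
  expect_identical(regionSizeMb(5, 5), 0)
  ## half-up, not banker's rounding
  expect_identical(regionSizeMb(1, 1450001), 1.5)
  expect_error(regionSizeMb(10, 5), class = "rohdel_bad_interval")
})

test_that("an all-heterozygous sample yields no runs", {
  gm <- gmFromCalls(rep("AB", 100L))
  expect_length(detectRoh(gm, "S1", min_markers = 5L, min_length_bp = 1000L),
                0L)
})

test_that("a clean homozygous block is recovered at its outermost markers", {
  calls <- rep("AB", 100L)
  calls[20:80] <- "AA"
  gm <- gmFromCalls(calls)
  got <- detectRoh(gm, "S1", min_markers = 10L, min_length_bp = 1000L,
                   max_het = 0L, max_missing = 0L)
  expect_length(got, 1L)
  expect_identical(GenomicRanges::start(got), 20000L)
  expect_identical(GenomicRanges::end(got), 80000L)
  expect_identical(S4Vectors::mcols(got)$n_markers, 61L)
  ## matches the brute-force enumeration
  expect_identical(rohAsDf(got),
                   bruteForceRoh(calls, seq_along(calls) * 1000L,
                                 min_markers = 10L, min_length_bp = 1000L,
                                 max_het = 0L, max_missing = 0L))
})

test_that("the scanning detector equals brute-force enumeration", {
  set.seed(202)
  for (rep in 1:30) {
    n <- sample(c(40L, 80L, 200L), 1L)
    ## blocky genotypes so that qualifying runs actually arise
    calls <- character(0)
    while (length(calls) < n) {
      len <- sample.int(25L, 1L)
      state <- sample(c("AA", "BB", "AB", "NC"), 1L,
                      prob = c(0.4, 0.3, 0.25, 0.05))
      calls <- c(calls, rep(state, len))
    }
    calls <- calls[seq_len(n)]
    pos <- cumsum(sample.int(5000L, n, replace = TRUE))
    params <- list(min_markers = sample(3:10, 1L),
                   min_length_bp = sample(c(1000L, 20000L), 1L),
                   max_het = sample(0:2, 1L),
                   max_missing = sample(0:2, 1L))
    gm <- gmFromCalls(calls, pos)
    got <- rohAsDf(do.call(detectRoh, c(list(gm, "S1"), params)))
    want <- do.call(bruteForceRoh, c(list(calls, pos), params))
    expect_identical(got, want,
                     label = sprintf("case %d (n=%d)", rep, n))
  }
})

test_that("raising max_het never shrinks the detected region set", {
  set.seed(33)
  for (rep in 1:10) {
    calls <- sample(c("AA", "BB", "AB"), 150L, replace = TRUE,
                    prob = c(0.45, 0.45, 0.1))
    gm <- gmFromCalls(calls)
    prev <- detectRoh(gm, "S1", min_markers = 5L, min_length_bp = 1000L,
                      max_het = 0L)
    for (mh in 1:3) {
      cur <- detectRoh(gm, "S1", min_markers = 5L, min_length_bp = 1000L,
                       max_het = mh)
      ## every previous region is contained in some current region
      if (length(prev))
        expect_true(all(S4Vectors::queryHits(GenomicRanges::findOverlaps(
          prev, cur, type = "within")) %in% seq_along(prev)) &&
          length(GenomicRanges::findOverlaps(prev, cur, type = "within")) >=
            length(prev))
      expect_gte(sum(BiocGenerics::width(GenomicRanges::reduce(cur))),
                 sum(BiocGenerics::width(GenomicRanges::reduce(prev))))
      prev <- cur
    }
  }
})

test_that("detectRoh validates its inputs", {
  gm <- gmFromCalls(rep("AA", 30L))
  expect_error(detectRoh(gm, "nope"), class = "rohdel_unknown_sample")
  expect_error(GenotypeMatrix("chr1", c(10L, 10L), c("a", "b"),
                              matrix("AA", 2, 1, dimnames = list(NULL, "S1"))),
               "strictly increasing")
  expect_error(GenotypeMatrix("chr1", c(10L, 20L), c("a", "b"),
                              matrix("XX", 2, 1, dimnames = list(NULL, "S1"))),
               "AA/AB/BB/NC")
})

test_that("intersectShared behaves like interval intersection", {
  r <- function(chrom, s, e) GenomicRanges::GRanges(chrom,
                                                    IRanges::IRanges(s, e))
  ## identical single region in all samples
  a <- r("chr1", 100e6, 200e6)
  out <- intersectShared(list(A = a, B = a, C = a))
  expect_identical(rohAsDf(out),
                   data.frame(start = 100000000L, end = 200000000L))
  ## the worked overlap example
  out2 <- intersectShared(list(A = r("chr1", 100e6, 200e6),
                               B = r("chr1", 150e6, 300e6)))
  expect_identical(rohAsDf(out2),
                   data.frame(start = 150000000L, end = 200000000L))
  ## empty intersection is an empty list, not an error
  out3 <- intersectShared(list(A = r("chr1", 1, 10), B = r("chr2", 1, 10)))
  expect_length(out3, 0L)
  expect_error(intersectShared(list(A = a)), class = "rohdel_bad_input")
})

test_that("intersectShared is commutative, associative and idempotent", {
  set.seed(77)
  mk <- function() {
    s <- sort(sample.int(100e6, 6L))
    GenomicRanges::GRanges("chr1", IRanges::IRanges(s[c(1, 3, 5)],
                                                    s[c(2, 4, 6)]))
  }
  rs <- list(A = mk(), B = mk(), C = mk())
  base <- rohAsDf(intersectShared(rs))
  for (perm in list(c(2, 1, 3), c(3, 2, 1), c(2, 3, 1)))
    expect_identical(rohAsDf(intersectShared(rs[perm])), base)
  expect_identical(rohAsDf(intersectShared(list(rs$A, rs$A))),
                   rohAsDf(GenomicRanges::reduce(rs$A)))
})

test_that("planted shared segments are recovered across seeds", {
  recovered <- 0L
  for (seed in 1:20) {
    sim <- simulatePedigreeGenotypes(seed = seed)
    per <- lapply(c("VI2", "VI3", "VI4"), function(s)
      detectRoh(sim$genotypes, s))
    names(per) <- c("VI2", "VI3", "VI4")
    shared <- intersectShared(per, sim$genotypes)
    truth <- sim$truth$shared_segments
    ok <- length(shared) == length(truth)
    if (ok) {
      ov <- GenomicRanges::pintersect(
        GenomicRanges::reduce(shared),
        truth + 0L)
      ro <- BiocGenerics::width(ov) /
        pmax(BiocGenerics::width(shared), BiocGenerics::width(truth))
      ok <- all(ro >= 0.95)
    }
    recovered <- recovered + ok
  }
  expect_identical(recovered, 20L)
})

test_that("every reported shared region is homozygous in every affected", {
  sim <- simulatePedigreeGenotypes(seed = 4)
  gm <- sim$genotypes
  per <- lapply(c("VI2", "VI3", "VI4"), function(s) detectRoh(gm, s))
  shared <- intersectShared(per, gm)
  ov <- GenomicRanges::findOverlaps(markerRanges(gm), shared)
  idx <- S4Vectors::queryHits(ov)
  for (s in c("VI2", "VI3", "VI4")) {
    calls <- genotypeCalls(gm)[idx, s]
    ## within tolerance: at most max_het hets per region per sample
    expect_lte(sum(calls == "AB"), 2L * length(shared))
    expect_gte(mean(calls %in% c("AA", "BB")), 0.999)
  }
})

test_that("region output lands in BED (0-based) and TSV (1-based)", {
  gr <- GenomicRanges::GRanges("chr1", IRanges::IRanges(1001L, 2000L))
  S4Vectors::mcols(gr)$n_markers <- 10L
  S4Vectors::mcols(gr)$size_mb <- 0
  bed <- withr::local_tempfile(fileext = ".bed")
  tsv <- withr::local_tempfile(fileext = ".tsv")
  writeRohRegions(gr, bed = bed, tsv = tsv)
  bedLine <- strsplit(readLines(bed), "\t")[[1]]
  expect_identical(bedLine[2:3], c("1000", "2000"))
  d <- utils::read.delim(tsv)
  expect_identical(d$start, 1001L)
  expect_identical(d$end, 2000L)
})
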
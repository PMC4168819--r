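cm <- canonicalFixture()
m <- cm$model
g <- cm$genome

test_that("HGVS c. deletion strings parse, tolerate whitespace and round-trip", {
  d <- parseHgvsCDel("c.294+139_531+478del", m)
  expect_equal(cdsBase(d@start), 294L); expect_equal(cdsOffset(d@start), 139L)
  expect_equal(cdsBase(d@end), 531L); expect_equal(cdsOffset(d@end), 478L)
  ## typeset with spaces around the signs, as journals print it
  d2 <- parseHgvsCDel("c.294 + 139_531 + 478del", m)
  expect_equal(formatHgvsCDel(d2), "c.294+139_531+478del")
  d3 <- parseHgvsCDel("c.10_12del", m)
  expect_equal(cdsOffset(d3@start), 0L)
  expect_equal(formatHgvsCDel(d3), "c.10_12del")
  expect_error(parseHgvsCDel("c.531+478_294+139del", m),
               class = "rohdel_bad_hgvs")
  expect_error(parseHgvsCDel("c.10-12del", m), class = "rohdel_bad_hgvs")
  expect_error(parseHgvsCDel("g.10_12del", m), class = "rohdel_bad_hgvs")
})

test_that("parse/format round-trips over generated deletion descriptions", {
  set.seed(11)
  for (i in 1:50) {
    a <- sort(sample.int(cdsLength(m), 2L))
    s <- sprintf("c.%d_%ddel", a[1], a[2])
    expect_identical(formatHgvsCDel(parseHgvsCDel(s, m)), s)
  }
  ## with intronic offsets off exon 5 / exon 6 boundaries
  for (k in c(1L, 50L, 139L)) {
    s <- sprintf("c.294+%d_531+%ddel", k, k + 10L)
    expect_identical(formatHgvsCDel(parseHgvsCDel(s, m)), s)
  }
})

test_that("the canonical deletion annotates to the full consequence record", {
  cons <- annotateDeletion(parseHgvsCDel("c.294+139_531+478del", m), m, g)
  expect_identical(cons@genomicStart, 1002483L)
  expect_identical(cons@genomicEnd, 1004829L)
  expect_identical(cons@totalLength, 2347L)
  expect_identical(cons@codingBasesRemoved, 237L)
  expect_identical(cons@intronicBasesRemoved, 2110L)
  expect_true(cons@inFrame)
  expect_identical(cons@status, "codon_aligned")
  expect_identical(cons@firstResidue, 99L)
  expect_identical(cons@lastResidue, 177L)
  expect_identical(cons@proteinHgvs, "p.Tyr99_Glu177del")
  expect_identical(cons@wtProteinLength, 447L)
  expect_identical(cons@mutProteinLength, 368L)
  ## 3' normalization is a no-op at these breakpoints
  cons2 <- annotateDeletion(parseHgvsCDel("c.294+139_531+478del", m), m, g,
                            normalize3prime = TRUE)
  expect_identical(cons2@genomicStart, cons@genomicStart)
  expect_identical(cons2@genomicEnd, cons@genomicEnd)
})

test_that("single-codon and frameshift deletions are classified correctly", {
  one <- annotateDeletion(parseHgvsCDel("c.295_297del", m), m, g)
  expect_identical(one@codingBasesRemoved, 3L)
  expect_true(one@inFrame)
  expect_identical(one@proteinHgvs, "p.Tyr99del")
  expect_identical(one@mutProteinLength, 446L)

  fs <- annotateDeletion(parseHgvsCDel("c.295_296del", m), m, g)
  expect_identical(fs@codingBasesRemoved, 2L)
  expect_false(fs@inFrame)
  expect_identical(fs@status, "frameshift")
  expect_identical(fs@proteinHgvs, "fs")

  junc <- annotateDeletion(parseHgvsCDel("c.296_298del", m), m, g)
  expect_true(junc@inFrame)
  expect_identical(junc@status, "junction")
  expect_true(is.na(junc@proteinHgvs))

  init <- annotateDeletion(parseHgvsCDel("c.1_3del", m), m, g)
  expect_identical(init@status, "unsupported")
  term <- annotateDeletion(parseHgvsCDel("c.1342_1344del", m), m, g)
  expect_identical(term@status, "unsupported")
})

test_that("in-frame whole-codon deletions satisfy the length bookkeeping", {
  set.seed(5)
  for (i in 1:25) {
    r1 <- sample(2:446, 1L); r2 <- sample(r1:446, 1L)
    d <- parseHgvsCDel(sprintf("c.%d_%ddel", 3L * (r1 - 1L) + 1L, 3L * r2), m)
    cons <- annotateDeletion(d, m, g)
    expect_identical(cons@status, "codon_aligned")
    expect_identical(cons@wtProteinLength - cons@mutProteinLength,
                     cons@codingBasesRemoved %/% 3L)
    expect_identical(cons@firstResidue, r1)
    expect_identical(cons@lastResidue, r2)
    expect_identical(cons@codingBasesRemoved + cons@intronicBasesRemoved,
                     cons@totalLength)
  }
})

test_that("annotated deletion length equals the bases missing from the mutant", {
  cons <- annotateDeletion(parseHgvsCDel("c.294+139_531+478del", m), m, g)
  mut <- applyDeletion(g, "chrG", cons@genomicStart, cons@genomicEnd)
  refLen <- nchar(getSubseq(g, "chrG", 1L, 1100000L))
  expect_identical(refLen - length(mut@sequence),
                   as.integer(cons@totalLength))
  ## the mutant really lacks exactly the interval
  expect_identical(
    as.character(Biostrings::subseq(mut@sequence, 1L, cons@genomicStart - 1L)),
    getSubseq(g, "chrG", 1L, cons@genomicStart - 1L))
  expect_identical(
    substr(as.character(mut@sequence), cons@genomicStart,
           cons@genomicStart + 9L),
    getSubseq(g, "chrG", cons@genomicEnd + 1L, cons@genomicEnd + 10L))
})

test_that("in-silico PCR reproduces the diagnostic amplicons", {
  lr <- PrimerPair("chrG", 1002300, 1002319, 1005421, 1005440, "longrange")
  ex6 <- PrimerPair("chrG", 1004130, 1004149, 1004300, 1004319, "exon6")
  expect_identical(inSilicoPcr(g, lr), 3141L)
  expect_identical(inSilicoPcr(g, ex6), 190L)
  mut <- applyDeletion(g, "chrG", 1002483L, 1004829L)
  expect_identical(inSilicoPcr(mut, lr), 794L)
  expect_true(is.na(inSilicoPcr(mut, ex6)))
  ## primer overlapping a breakpoint loses its footprint
  bk <- PrimerPair("chrG", 1002475, 1002494, 1005421, 1005440, "bkpt")
  expect_true(is.na(inSilicoPcr(mut, bk)))
})

test_that("wild-type minus deleted product equals the deletion length", {
  set.seed(9)
  mut <- applyDeletion(g, "chrG", 1002483L, 1004829L)
  for (i in 1:20) {
    fs <- sample(1000000:1002400, 1L)
    rs <- sample(1004900:1007000, 1L)
    pp <- PrimerPair("chrG", fs, fs + 19L, rs, rs + 19L)
    expect_identical(inSilicoPcr(g, pp) - inSilicoPcr(mut, pp), 2347L)
  }
})

test_that("PCR genotype classification matches the gel logic", {
  wt <- c(190L, 190L); none <- c(NA_integer_, NA_integer_)
  expect_identical(classifyPcrGenotype(wt, c(3141L, 3141L)), "wild_type")
  expect_identical(classifyPcrGenotype(c(190L, NA), c(3141L, 794L)), "carrier")
  expect_identical(classifyPcrGenotype(none, c(794L, 794L)),
                   "homozygous_deleted")
  expect_error(classifyPcrGenotype(none, none),
               class = "rohdel_assay_failure")
  ## the 3141 bp wild-type long-range product is beyond amplifiable range
  expect_error(classifyPcrGenotype(none, c(3141L, 3141L)),
               class = "rohdel_assay_failure")
})

test_that("primer pair validity enforces geometry", {
  expect_error(PrimerPair("c", 100L, 119L, 90L, 109L), "5'")
  expect_error(PrimerPair("c", 100L, 110L, 200L, 219L), "15-35")
})

test_that("deletion report writers emit TSV and a symbolic-DEL VCF", {
  cons <- annotateDeletion(parseHgvsCDel("c.294+139_531+478del", m), m, g)
  tsv <- withr::local_tempfile(fileext = ".tsv")
  vcf <- withr::local_tempfile(fileext = ".vcf")
  writeDeletionReport(cons, m, tsv)
  rec <- utils::read.delim(tsv)
  expect_identical(rec$total_length, 2347L)
  expect_identical(rec$protein_hgvs, "p.Tyr99_Glu177del")
  writeDeletionVcf(cons, m, g, vcf)
  v <- VariantAnnotation::readVcf(vcf, genome = "toy")
  expect_identical(unname(VariantAnnotation::info(v)$SVTYPE), "DEL")
  expect_identical(unname(VariantAnnotation::info(v)$SVLEN), -2347L)
  expect_identical(unname(VariantAnnotation::info(v)$END), 1004829L)
  expect_identical(GenomicRanges::start(SummarizedExperiment::rowRanges(v)),
                   1002482L)
})
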
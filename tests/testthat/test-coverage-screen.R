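cm <- canonicalFixture()
model <- cm$model
nEx <- length(exonRanges(model))

## exon depth matrix for one case + five panel samples, via the generator
simDepthMatrix <- function(seed, caseCn = c(2L, 2L, 2L, 2L, 2L, 0L, 2L),
                           caseMean = 230, panelMeans = c(200, 210, 230, 250, 260)) {
  cols <- c(list(CASE = exonMeanDepth(
    simulateExonDepths(model, caseCn, caseMean, seed = seed), model)),
    lapply(seq_along(panelMeans), function(i) exonMeanDepth(
      simulateExonDepths(model, rep(2L, nEx), panelMeans[i],
                         seed = seed * 101L + i), model)))
  names(cols) <- c("CASE", sprintf("P%d", seq_along(panelMeans)))
  do.call(cbind, cols)
}

test_that("exon mean depth is total coverage over exon length", {
  ex <- GenomicRanges::GRanges("chrX", IRanges::IRanges(101L, 200L))
  flat <- data.frame(chrom = "chrX", pos = 101:200, depth = 10L)
  expect_identical(exonMeanDepth(flat, ex), 10)
  expect_identical(exonMeanDepth(data.frame(chrom = "chrX", pos = 150L,
                                            depth = 0L), ex), 0)
  ## 133 read-bases over a 237 bp exon, reported at the printed scale
  ex6 <- GenomicRanges::GRanges("chrX", IRanges::IRanges(1L, 237L))
  sparse <- data.frame(chrom = "chrX", pos = 1:133, depth = 1L)
  expect_equal(roundHalfUp(exonMeanDepth(sparse, ex6), 2L), 0.56)
  ## bases absent from the track count as zero
  half <- data.frame(chrom = "chrX", pos = 101:150, depth = 20L)
  expect_identical(exonMeanDepth(half, ex), 10)
  expect_error(exonMeanDepth(data.frame(chrom = "chrY", pos = 1L, depth = 1L),
                             ex), class = "rohdel_missing_chrom")
})

test_that("bedGraph and per-base TSV depth inputs agree", {
  ex <- GenomicRanges::GRanges("chrX", IRanges::IRanges(11L, 40L))
  bg <- withr::local_tempfile(fileext = ".bedgraph")
  ## 0-based half-open: bases 11-20 depth 7, 21-40 depth 3
  writeLines(c("chrX\t10\t20\t7", "chrX\t20\t40\t3"), bg)
  tsv <- withr::local_tempfile(fileext = ".tsv")
  utils::write.table(
    data.frame(chrom = "chrX", pos = 11:40, depth = rep(c(7L, 3L), c(10, 20))),
    tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_equal(exonMeanDepth(bg, ex), exonMeanDepth(tsv, ex))
  expect_equal(exonMeanDepth(tsv, ex), (10 * 7 + 20 * 3) / 30)
})

test_that("panel comparison reproduces the printed case/panel contrast", {
  ## fixture consistent with a 230x panel (range 200-269) and a 0.56x case
  depths <- matrix(rep(c(0.56, 200, 210, 230, 250, 260), each = 1),
                   nrow = 1,
                   dimnames = list(NULL, c("CASE", paste0("P", 1:5))))
  depths <- depths[rep(1, nEx), , drop = FALSE]
  depths[-6, "CASE"] <- 230
  edt <- compareToPanel(ExonDepthTable(exonRanges(model), "AMBN_toy",
                                       depths, case = "CASE"))
  rd <- SummarizedExperiment::rowData(edt)
  expect_equal(unique(rd$panel_mean), 230)
  expect_equal(unique(rd$panel_min), 200)
  expect_equal(unique(rd$panel_max), 260)
  expect_equal(roundHalfUp(rd$depth_ratio[6], 4L), 0.0024)
  calls <- callDeletions(edt)
  expect_identical(calls$verdict[6], "homozygous_deletion_candidate")
  expect_true(all(calls$verdict[-6] == "normal"))
})

test_that("a case identical to its panel has unit ratios everywhere", {
  depths <- matrix(100, nEx, 4,
                   dimnames = list(NULL, c("CASE", "P1", "P2", "P3")))
  edt <- compareToPanel(ExonDepthTable(exonRanges(model), "g", depths, "CASE"))
  expect_true(all(SummarizedExperiment::rowData(edt)$depth_ratio == 1))
  expect_true(all(callDeletions(edt)$verdict == "normal"))
})

test_that("zero or shallow panels are low confidence, never called", {
  depths <- cbind(CASE = c(0, 0, 230), P1 = c(0, 4, 230), P2 = c(0, 4, 230))
  ex <- GenomicRanges::GRanges("chrG", IRanges::IRanges(c(1, 101, 201),
                                                        c(50, 150, 250)))
  edt <- compareToPanel(ExonDepthTable(ex, "g", depths, "CASE"))
  calls <- callDeletions(edt)
  expect_identical(calls$verdict[1], "low_confidence")  # 0/0 ratio undefined
  expect_identical(calls$verdict[2], "low_confidence")  # panel too shallow
  expect_identical(calls$verdict[3], "normal")
})

test_that("panel order does not matter and global depth scaling cancels", {
  d <- simDepthMatrix(seed = 5)
  edt <- compareToPanel(ExonDepthTable(exonRanges(model), "g", d, "CASE"))
  rd <- SummarizedExperiment::rowData(edt)
  perm <- d[, c("CASE", sample(colnames(d)[-1]))]
  rd2 <- SummarizedExperiment::rowData(
    compareToPanel(ExonDepthTable(exonRanges(model), "g", perm, "CASE")))
  expect_equal(rd$panel_mean, rd2$panel_mean)
  expect_equal(rd$depth_ratio, rd2$depth_ratio)
  rd3 <- SummarizedExperiment::rowData(
    compareToPanel(ExonDepthTable(exonRanges(model), "g", d * 3.7, "CASE")))
  expect_equal(rd$depth_ratio, rd3$depth_ratio)
})

test_that("median normalization rescales unequal library sizes", {
  d <- simDepthMatrix(seed = 6)
  d[, "P1"] <- d[, "P1"] * 4         # inflated library
  edt <- compareToPanel(ExonDepthTable(exonRanges(model), "g", d, "CASE"),
                        normalize = TRUE)
  rd <- SummarizedExperiment::rowData(edt)
  ## after normalization the inflated sample no longer dominates the panel
  expect_lt(max(rd$panel_max / rd$panel_mean), 1.6)
  expect_identical(callDeletions(edt)$verdict[6],
                   "homozygous_deletion_candidate")
})

test_that("a planted homozygous exon deletion is called at defaults", {
  d <- simDepthMatrix(seed = 1)
  edt <- compareToPanel(ExonDepthTable(exonRanges(model), "g", d, "CASE"))
  calls <- callDeletions(edt)
  expect_identical(which(calls$verdict == "homozygous_deletion_candidate"),
                   6L)
  ## case depth lands near the sub-1x scale the screen is built to catch
  expect_lt(calls$case_depth[6], 2)
  expect_gt(calls$panel_mean[6], 200)
})

test_that("a heterozygous deletion halves depth but is not called", {
  d <- simDepthMatrix(seed = 2, caseCn = c(2L, 2L, 2L, 2L, 2L, 1L, 2L))
  edt <- compareToPanel(ExonDepthTable(exonRanges(model), "g", d, "CASE"))
  calls <- callDeletions(edt)
  expect_gt(calls$depth_ratio[6], 0.35)
  expect_lt(calls$depth_ratio[6], 0.65)
  expect_true(all(calls$verdict != "homozygous_deletion_candidate"))
})

test_that("coverage output writers emit the calls and candidate BED", {
  d <- simDepthMatrix(seed = 3)
  edt <- compareToPanel(ExonDepthTable(exonRanges(model), "AMBN_toy", d,
                                       "CASE"))
  calls <- callDeletions(edt)
  tsv <- withr::local_tempfile(fileext = ".tsv")
  bed <- withr::local_tempfile(fileext = ".bed")
  writeCoverageScreen(edt, calls, tsv = tsv, bed = bed)
  out <- utils::read.delim(tsv)
  expect_identical(nrow(out), nEx)
  bedLines <- readLines(bed)
  expect_length(bedLines, 1L)
  expect_match(bedLines, "1004114\t1004351")
})
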
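cm <- canonicalFixture()

test_that("the canonical model satisfies its printed geometry", {
  m <- cm$model
  ex <- exonRanges(m)
  expect_length(ex, 7L)
  expect_equal(cdsLength(m), 1344L)                       # 447 codons + stop
  expect_equal(BiocGenerics::width(ex)[6], 237L)          # the deleted exon
  expect_identical(GenomicRanges::start(ex)[6], 1004115L)
  expect_identical(GenomicRanges::end(ex)[6], 1004351L)
  expect_identical(GenomicRanges::end(ex)[5], 1002344L)
  ## deleted intron-5 run + exon 6 + intron-6 run = 2347
  expect_identical((1004114L - 1002483L + 1L) + 237L + 478L, 2347L)
  expect_true(validateTranscriptSequence(m, cm$genome))
})

test_that("generators are bit-identical given the same seed", {
  a <- makeCanonicalModel(seed = 3); b <- makeCanonicalModel(seed = 3)
  expect_identical(as.character(a$genome@sequences),
                   as.character(b$genome@sequences))
  g1 <- simulatePedigreeGenotypes(seed = 5)
  g2 <- simulatePedigreeGenotypes(seed = 5)
  expect_identical(genotypeCalls(g1$genotypes), genotypeCalls(g2$genotypes))
  d1 <- simulateExonDepths(cm$model, seed = 5)
  d2 <- simulateExonDepths(cm$model, seed = 5)
  expect_identical(d1, d2)
  v1 <- simulateVcf(genome = cm$genome, seed = 5)
  v2 <- simulateVcf(genome = cm$genome, seed = 5)
  expect_identical(v1$variants, v2$variants)
  ## and different seeds genuinely differ
  expect_false(identical(genotypeCalls(g1$genotypes),
                         genotypeCalls(simulatePedigreeGenotypes(seed = 6)$genotypes)))
})

test_that("applyDeletion removes exactly the interval and lifts coordinates", {
  mut <- applyDeletion(cm$genome, "chrG", 1002483L, 1004829L)
  expect_identical(length(mut@sequence), 1100000L - 2347L)
  one <- applyDeletion(cm$genome, "chrG", 500L, 500L)
  expect_identical(length(one@sequence), 1100000L - 1L)
  expect_identical(liftToMutant(mut, 1004830L), 1004830L - 2347L)
  expect_identical(liftToMutant(mut, 1002482L), 1002482L)
  expect_true(is.na(liftToMutant(mut, 1003000L)))
  expect_error(applyDeletion(cm$genome, "chrG", 1099999L, 1100001L),
               class = "rohdel_out_of_bounds")
})

test_that("pedigree validity catches ancestry cycles and unknown parents", {
  expect_error(Pedigree(id = c("A", "B"), father = c("B", "A"),
                        mother = c(NA, NA), sex = c("M", "M"),
                        affected = c(FALSE, FALSE)), "ancestor")
  expect_error(Pedigree(id = "A", father = "ghost", mother = NA,
                        sex = "M", affected = FALSE), "members")
  ped <- canonicalPedigree()
  expect_identical(affectedIds(ped), c("VI2", "VI3", "VI4"))
  expect_identical(nrow(pedigreeMembers(ped)), 8L)
})

test_that("planted autozygosity shows up as clean homozygous runs", {
  ## no error: every affected marker inside a planted segment is homozygous
  sim <- simulatePedigreeGenotypes(error_rate = 0, seed = 2)
  gm <- sim$genotypes
  ov <- GenomicRanges::findOverlaps(markerRanges(gm),
                                    sim$truth$shared_segments)
  idx <- S4Vectors::queryHits(ov)
  for (s in c("VI2", "VI3", "VI4"))
    expect_true(all(genotypeCalls(gm)[idx, s] %in% c("AA", "BB")))
  ## all affecteds carry the same founder homozygote there
  expect_identical(genotypeCalls(gm)[idx, "VI2"],
                   genotypeCalls(gm)[idx, "VI3"])
  ## unaffected sibs are ordinary background inside the segment
  expect_gt(mean(genotypeCalls(gm)[idx, "VI1"] == "AB"), 0.25)
})

test_that("het_rate 0 collapses each chromosome into one run per sample", {
  sim <- simulatePedigreeGenotypes(het_rate = 0, error_rate = 0, seed = 3)
  roh <- detectRoh(sim$genotypes, "VI1")
  expect_length(roh, 2L)   # one run per simulated chromosome
  expect_identical(S4Vectors::mcols(roh)$n_markers, c(6001L, 6001L))
})

test_that("segments outside the simulated chromosomes are rejected", {
  bad <- GenomicRanges::GRanges("chr1", IRanges::IRanges(1, 40000000))
  expect_error(simulatePedigreeGenotypes(shared_segments = bad),
               class = "rohdel_bad_segment")
  expect_error(simulatePedigreeGenotypes(
    private_segments = list(VI2 = GenomicRanges::GRanges(
      "chr1", IRanges::IRanges(12000000, 13000000)))),
    class = "rohdel_bad_segment")
})

test_that("depth simulation concentrates near its configured means", {
  nEx <- 7L
  means6 <- vapply(1:20, function(seed) {
    tr <- simulateExonDepths(cm$model, c(2L, 2L, 2L, 2L, 2L, 0L, 2L),
                             mean_depth = 230, seed = seed)
    exonMeanDepth(tr, cm$model)[6]
  }, numeric(1))
  expect_true(all(means6 <= 2))        # copy-0 exon is near-silent
  meansDiploid <- vapply(1:20, function(seed) {
    tr <- simulateExonDepths(cm$model, rep(2L, nEx), mean_depth = 230,
                             seed = seed + 100L)
    exonMeanDepth(tr, cm$model)[6]
  }, numeric(1))
  expect_true(mean(meansDiploid >= 200 & meansDiploid <= 260) >= 0.95)
  ## vanishing mean depth gives an all-zero track
  tr0 <- simulateExonDepths(cm$model, rep(2L, nEx), mean_depth = 1e-4,
                            seed = 1)
  expect_identical(sum(tr0$depth), 0L)
  expect_error(simulateExonDepths(cm$model, rep(3L, nEx)),
               class = "rohdel_bad_input")
})

test_that("simulated VCF truth tracks every planted classification", {
  sim <- simulateVcf(genome = cm$genome, seed = 13)
  expect_identical(nrow(sim$variants), nrow(sim$truth))
  tab <- table(sim$truth$planted)
  expect_identical(unname(tab["rare_functional_repeat"]), 1L)
  expect_true(tab["known_common"] > 500)
  expect_true(tab["rare_silent"] >= 40)
  ## positions are collision-free and inside/outside as planted
  expect_false(any(duplicated(paste(sim$variants$chrom, sim$variants$pos))))
  inReg <- !is.na(GenomicRanges::findOverlaps(
    GenomicRanges::GRanges(sim$variants$chrom,
                           IRanges::IRanges(sim$variants$pos, width = 1L)),
    defaultSharedSegments(), select = "first"))
  expect_true(all(inReg[sim$truth$planted != "outside_region"]))
  expect_true(!any(inReg[sim$truth$planted == "outside_region"]))
})

test_that("an empty composition yields a header-only VCF", {
  comp <- defaultVcfComposition()[0, ]
  tf <- withr::local_tempfile(fileext = ".vcf")
  sim <- simulateVcf(composition = comp, genome = cm$genome,
                     plant_repeat_insertion = FALSE, seed = 1, path = tf)
  expect_identical(nrow(sim$variants), 0L)
  expect_true(all(grepl("^#", readLines(tf))))
})

test_that("a fixture directory carries everything the pipeline consumes", {
  dir <- withr::local_tempdir()
  cfg <- writeFixture(dir, seed = 2)
  expect_true(file.exists(cfg))
  for (f in c("genome.fasta", "model.gff3", "model.tsv", "genotypes.tsv",
              "depth_case.tsv", "depth_panel_5.tsv", "variants.vcf",
              "truth.json"))
    expect_true(file.exists(file.path(dir, f)), label = f)
  truth <- jsonlite::read_json(file.path(dir, "truth.json"),
                               simplifyVector = TRUE)
  expect_identical(truth$deletion$start, 1002483L)
  expect_identical(truth$deletion$end, 1004829L)
  expect_identical(truth$exon_copy_number_case[6], 0L)
})
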
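## ---------------------------------------------------------------------------
## Pedigree
## ---------------------------------------------------------------------------

#' Construct a Pedigree
#'
#' @param id,father,mother,sex,affected parallel vectors; founders carry NA
#'   parents; \code{affected} is logical
#' @return a [Pedigree-class]
#' @export
Pedigree <- function(id, father, mother, sex, affected) {
  obj <- new("Pedigree", members = data.frame(
    id = as.character(id), father = as.character(father),
    mother = as.character(mother), sex = as.character(sex),
    affected = as.logical(affected), stringsAsFactors = FALSE))
  validObject(obj)
  obj
}

#' @rdname Pedigree
#' @param x,object a Pedigree
#' @export
pedigreeMembers <- function(x) x@members

#' @rdname Pedigree
#' @export
affectedIds <- function(x) x@members$id[x@members$affected]

setMethod("show", "Pedigree", function(object) {
  m <- object@members
  cat(sprintf("Pedigree: %d members (%d founders, %d affected)\n",
              nrow(m), sum(is.na(m$father) & is.na(m$mother)),
              sum(m$affected)))
})

#' The default study pedigree
#'
#' A consanguineous nuclear family: two (related) parents and six children,
#' three of them affected with the recessive phenotype.
#'
#' @return a [Pedigree-class]
#' @export
canonicalPedigree <- function() {
  Pedigree(
    id = c("V1", "V2", paste0("VI", 1:6)),
    father = c(NA, NA, rep("V1", 6)),
    mother = c(NA, NA, rep("V2", 6)),
    sex = c("M", "F", "M", "F", "M", "F", "M", "F"),
    affected = c(FALSE, FALSE, FALSE, TRUE, TRUE, TRUE, FALSE, FALSE))
}

## ---------------------------------------------------------------------------
## Canonical toy genome + gene model
## ---------------------------------------------------------------------------

## fixed geometry of the canonical toy gene (plus strand):
## 7 exons; CDS per exon 60/60/60/60/54/237/813 nt (1344 nt = 448 codons);
## introns 500/500/500/500/1770/1000 bp; 50 bp UTR on each terminal exon.
.CANONICAL <- list(
  chrom = "chrG", chromLen = 1100000L, geneStart = 1000001L,
  utr5 = 50L, utr3 = 50L,
  cdsPerExon = c(60L, 60L, 60L, 60L, 54L, 237L, 813L),
  intronLen = c(500L, 500L, 500L, 500L, 1770L, 1000L),
  delStart = 1002483L, delEnd = 1004829L,
  ## aperiodic 20-mers written over the breakpoint-flanking windows so that
  ## HGVS 3' normalization of the canonical deletion is a no-op
  bkptWindow5 = "TGCAACTGGACTTAGCGATC",   # delStart-10 .. delStart+9
  bkptWindow3 = "GAGTCCTAAGTCACGGATTG",   # delEnd-9  .. delEnd+10
  repeatChrom = "chr1", repeatOffset = 17025900L, repeatWindowLen = 300L,
  repeatInsPos = 17026040L, repeatUnit = "CGG", repeatRefCopies = 8L,
  repeatInsCopies = 5L)

.canonicalExonBounds <- function() {
  p <- .CANONICAL
  exLen <- p$cdsPerExon
  exLen[1] <- exLen[1] + p$utr5
  exLen[length(exLen)] <- exLen[length(exLen)] + p$utr3
  starts <- integer(length(exLen)); starts[1] <- p$geneStart
  for (i in seq_along(p$intronLen))
    starts[i + 1] <- starts[i] + exLen[i] + p$intronLen[i]
  list(starts = starts, ends = starts + exLen - 1L)
}

#' Build the canonical toy genome and gene model
#'
#' Emits a deterministic toy reference: a ~1.1 Mb sequence chromosome
#' (\code{chrG}) hosting a plus-strand 7-exon gene whose CDS is 1344 nt
#' (447 codons plus stop; per-exon coding spans 60/60/60/60/54/237/813 nt,
#' introns 500/500/500/500/1770/1000 bp), plus a 300 bp window of a marker
#' chromosome carrying a (CGG)8 tandem tract for repeat-context tests.
#' Codon 99 is seeded TAT (Tyr) and codon 177 GAA (Glu); the CDS is free of
#' internal stops, and the 20-mers flanking the canonical deletion
#' breakpoints are fixed aperiodic sequences so 3' normalization cannot
#' shift the deletion.
#'
#' @param dir if non-NULL, write \code{genome.fasta}, \code{model.gff3} and
#'   \code{model.tsv} there
#' @param seed RNG seed for the non-constrained background sequence
#' @return list with \code{genome} ([GenomeSequence-class]), \code{model}
#'   ([TranscriptModel-class]), \code{deletion} (the canonical deletion's
#'   genomic interval) and, when \code{dir} is given, the file \code{paths}
#' @export
makeCanonicalModel <- function(dir = NULL, seed = 1L) {
  p <- .CANONICAL
  seed <- .checkSeed(seed)
  withr::with_seed(.childSeed(seed, 1L), {
    bases <- c("A", "C", "G", "T")
    chrG <- sample(bases, p$chromLen, replace = TRUE)

    ## CDS: 448 codons, start/stop fixed, landmark codons seeded
    nonStop <- setdiff(
      as.vector(outer(as.vector(outer(bases, bases, paste0)), bases, paste0)),
      c("TAA", "TAG", "TGA"))
    codons <- sample(nonStop, 448L, replace = TRUE)
    codons[1] <- "ATG"; codons[99] <- "TAT"; codons[177] <- "GAA"
    codons[448] <- "TAA"
    cds <- strsplit(paste(codons, collapse = ""), "")[[1]]

    eb <- .canonicalExonBounds()
    cdsStartG <- eb$starts[1] + p$utr5
    cdsEndG <- eb$ends[7] - p$utr3
    ## write CDS into the chromosome, exon by exon
    cdsAt <- unlist(lapply(1:7, function(i) {
      s <- if (i == 1L) cdsStartG else eb$starts[i]
      e <- if (i == 7L) cdsEndG else eb$ends[i]
      seq(s, e)
    }))
    stopifnot(length(cdsAt) == length(cds))
    chrG[cdsAt] <- cds
    ## breakpoint-flanking windows (intronic) forced aperiodic
    w5 <- strsplit(p$bkptWindow5, "")[[1]]
    w3 <- strsplit(p$bkptWindow3, "")[[1]]
    chrG[(p$delStart - 10L):(p$delStart + 9L)] <- w5
    chrG[(p$delEnd - 9L):(p$delEnd + 10L)] <- w3
    ## normalization no-op guards: no 3' or 5' slide possible
    stopifnot(chrG[p$delEnd + 1L] != chrG[p$delStart],
              chrG[p$delStart - 1L] != chrG[p$delEnd])

    ## marker-chromosome window with the (CGG)n tract
    frag <- sample(bases, p$repeatWindowLen, replace = TRUE)
    tract <- strsplit(strrep(p$repeatUnit, p$repeatRefCopies), "")[[1]]
    at <- (p$repeatInsPos + 1L - p$repeatOffset + 1L)
    frag[at:(at + length(tract) - 1L)] <- tract
    ## stop the tract from extending beyond its planted copies
    frag[(at - 6L):(at - 1L)] <- strsplit("ATTACA", "")[[1]]
    frag[(at + length(tract)):(at + length(tract) + 5L)] <-
      strsplit("TTAATC", "")[[1]]

    genome <- GenomeSequence(
      stats::setNames(c(paste(chrG, collapse = ""),
                        paste(frag, collapse = "")),
                      c(p$chrom, p$repeatChrom)),
      offset = c(1L, p$repeatOffset))
    model <- TranscriptModel("AMBN_toy", "AMBN_toy_tx", p$chrom, "+",
                             eb$starts, eb$ends, cdsStartG, cdsEndG)
    validateTranscriptSequence(model, genome)

    out <- list(genome = genome, model = model,
                deletion = c(start = p$delStart, end = p$delEnd))
    if (!is.null(dir)) {
      dir.create(dir, recursive = TRUE, showWarnings = FALSE)
      paths <- c(fasta = file.path(dir, "genome.fasta"),
                 gff3 = file.path(dir, "model.gff3"),
                 tsv = file.path(dir, "model.tsv"))
      writeGenomeFasta(genome, paths["fasta"])
      writeTranscriptModel(model, paths["gff3"], "gff3")
      writeTranscriptModel(model, paths["tsv"], "tsv")
      out$paths <- paths
    }
    out
  })
}

## ---------------------------------------------------------------------------
## Mutant alleles
## ---------------------------------------------------------------------------

#' Delete an interval from a reference sequence
#'
#' @param genome a [GenomeSequence-class]
#' @param chrom sequence name
#' @param start,end 1-based inclusive interval to remove
#' @return a [MutantAllele-class] carrying the shortened sequence and the
#'   coordinate lift
#' @export
applyDeletion <- function(genome, chrom, start, end) {
  stopifnot(is(genome, "GenomeSequence"), start <= end)
  i <- match(chrom, names(genome@sequences))
  if (is.na(i))
    .err("rohdel_unknown_sequence", "unknown sequence '%s'", chrom)
  off <- genome@offset[i]
  len <- length(genome@sequences[[i]])
  if (start < off || end > off + len - 1L)
    .err("rohdel_out_of_bounds", "interval %d-%d outside %s", start, end, chrom)
  s <- genome@sequences[[i]]
  mut <- Biostrings::xscat(
    Biostrings::subseq(s, 1L, start - off),
    Biostrings::subseq(s, end - off + 2L, len))
  new("MutantAllele", chrom = chrom,
      sequence = Biostrings::DNAString(as.character(mut)),
      offset = as.integer(off),
      delStart = as.integer(start), delEnd = as.integer(end))
}

#' Lift reference coordinates onto a deletion allele
#'
#' Positions 5' of the deletion are unchanged; positions 3' shift down by
#' the deletion length; deleted positions have no image (NA).
#'
#' @param allele a [MutantAllele-class]
#' @param g integer vector of reference positions
#' @return integer vector of positions on the mutant allele (reference
#'   numbering)
#' @export
liftToMutant <- function(allele, g) {
  stopifnot(is(allele, "MutantAllele"))
  dlen <- allele@delEnd - allele@delStart + 1L
  out <- as.integer(g)
  out[g >= allele@delStart & g <= allele@delEnd] <- NA_integer_
  out[!is.na(out) & out > allele@delEnd] <-
    out[!is.na(out) & out > allele@delEnd] - dlen
  out
}

setMethod("show", "MutantAllele", function(object) {
  cat(sprintf("MutantAllele on %s: deleted %d-%d (%d bp), %d bp remaining\n",
              object@chrom, object@delStart, object@delEnd,
              object@delEnd - object@delStart + 1L,
              length(object@sequence)))
})

## ---------------------------------------------------------------------------
## Pedigree genotype simulation
## ---------------------------------------------------------------------------

#' Default planted autozygous segments shared by all affecteds
#' @return [GenomicRanges::GRanges] of the two shared segments
#' @export
defaultSharedSegments <- function() {
  GenomicRanges::GRanges(c("chr1", "chr4"),
    IRanges::IRanges(c(11698902L, 71230491L), c(26171473L, 83403217L)))
}

#' Default private (single-affected) autozygous segments
#' @return named list of [GenomicRanges::GRanges], one per affected sample
#' @export
defaultPrivateSegments <- function() {
  list(
    VI2 = GenomicRanges::GRanges("chr1", IRanges::IRanges(2000001L, 5000001L)),
    VI3 = GenomicRanges::GRanges("chr4", IRanges::IRanges(86000001L, 89000001L)),
    VI4 = GenomicRanges::GRanges("chr1", IRanges::IRanges(27000001L, 29500001L)))
}

#' Simulate SNP-array genotypes for a pedigree with planted autozygosity
#'
#' Two marker chromosomes are tiled at \code{marker_spacing_bp}.  Inside a
#' planted shared segment every affected individual is homozygous for the
#' same founder allele (autozygosity by descent); inside a private segment
#' only its owner is homozygous; everywhere else calls are drawn with the
#' background heterozygosity rate.  Unaffected relatives carry ordinary
#' background genotypes inside the planted segments (carriers are
#' heterozygous there, consistent with recessive inheritance).
#'
#' Genotyping error is modelled as an allele-swap: with probability
#' \code{error_rate} a homozygous call is recorded as the opposite
#' homozygote.  This preserves zygosity, so planted segments stay clean
#' runs; the detector's heterozygote/missing tolerance is exercised by
#' dedicated tests rather than by the default simulation.
#'
#' @param ped a [Pedigree-class]
#' @param shared_segments [GenomicRanges::GRanges] planted in all affecteds
#' @param private_segments named list of [GenomicRanges::GRanges] per sample
#' @param chromosomes data.frame(chrom, start, end) of marker chromosomes
#' @param marker_spacing_bp marker grid spacing (default 5 kb)
#' @param het_rate background heterozygosity per marker (default 0.35)
#' @param error_rate allele-swap error probability (default 0.002)
#' @param missing_rate no-call probability (default 0)
#' @param seed RNG seed
#' @return list with \code{genotypes} ([GenotypeMatrix-class]) and
#'   \code{truth} (planted segments, params, seed)
#' @export
simulatePedigreeGenotypes <- function(ped = canonicalPedigree(),
                                      shared_segments = defaultSharedSegments(),
                                      private_segments = defaultPrivateSegments(),
                                      chromosomes = data.frame(
                                        chrom = c("chr1", "chr4"),
                                        start = c(1L, 65000001L),
                                        end = c(30000001L, 95000001L)),
                                      marker_spacing_bp = 5000L,
                                      het_rate = 0.35, error_rate = 0.002,
                                      missing_rate = 0, seed = 1L) {
  stopifnot(is(ped, "Pedigree"))
  seed <- .checkSeed(seed)
  samples <- pedigreeMembers(ped)$id
  affected <- affectedIds(ped)
  ## planted segments must sit on the simulated chromosomes
  allSeg <- c(list(shared = shared_segments), private_segments)
  for (nm in names(allSeg)) {
    seg <- allSeg[[nm]]
    for (i in seq_along(seg)) {
      cc <- as.character(GenomicRanges::seqnames(seg))[i]
      row <- chromosomes[chromosomes$chrom == cc, , drop = FALSE]
      if (!nrow(row) || GenomicRanges::start(seg)[i] < row$start ||
          GenomicRanges::end(seg)[i] > row$end)
        .err("rohdel_bad_segment",
             "planted segment %s:%d-%d outside simulated chromosomes",
             cc, GenomicRanges::start(seg)[i], GenomicRanges::end(seg)[i])
    }
  }
  ## per-sample planted segments must not overlap each other
  for (s in samples) {
    mine <- c(granges(shared_segments)[rep(s %in% affected,
                                           length(shared_segments))],
              if (s %in% names(private_segments))
                granges(private_segments[[s]]) else GenomicRanges::GRanges())
    if (length(mine) > 1L &&
        length(GenomicRanges::reduce(mine)) != length(mine) ||
        sum(BiocGenerics::width(GenomicRanges::reduce(mine))) !=
          sum(BiocGenerics::width(mine)))
      .err("rohdel_bad_segment", "planted segments overlap for sample %s", s)
  }

  withr::with_seed(.childSeed(seed, 2L), {
    mk <- do.call(rbind, lapply(seq_len(nrow(chromosomes)), function(i)
      data.frame(chrom = chromosomes$chrom[i],
                 pos = seq(chromosomes$start[i], chromosomes$end[i],
                           by = marker_spacing_bp))))
    n <- nrow(mk)
    mkGr <- GenomicRanges::GRanges(mk$chrom, IRanges::IRanges(mk$pos, width = 1L))

    inSeg <- function(seg) {
      hits <- GenomicRanges::findOverlaps(mkGr, seg)
      idx <- logical(n); idx[S4Vectors::queryHits(hits)] <- TRUE; idx
    }
    sharedIdx <- inSeg(shared_segments)
    ## founder allele of each autozygous marker, common to all affecteds
    founder <- ifelse(stats::runif(n) < 0.5, "AA", "BB")

    calls <- matrix(NA_character_, n, length(samples),
                    dimnames = list(NULL, samples))
    for (s in samples) {
      u <- stats::runif(n)
      g <- ifelse(u < het_rate, "AB",
                  ifelse(u < het_rate + (1 - het_rate) / 2, "AA", "BB"))
      if (s %in% affected) g[sharedIdx] <- founder[sharedIdx]
      if (s %in% names(private_segments)) {
        idx <- inSeg(private_segments[[s]])
        g[idx] <- ifelse(stats::runif(sum(idx)) < 0.5, "AA", "BB")
      }
      ## allele-swap genotyping error (zygosity-preserving)
      swap <- stats::runif(n) < error_rate & g != "AB"
      g[swap] <- ifelse(g[swap] == "AA", "BB", "AA")
      if (missing_rate > 0)
        g[stats::runif(n) < missing_rate] <- "NC"
      calls[, s] <- g
    }
    gm <- GenotypeMatrix(mk$chrom, mk$pos,
                         sprintf("mk%06d", seq_len(n)), calls)
    list(genotypes = gm,
         truth = list(shared_segments = shared_segments,
                      private_segments = private_segments,
                      affected = affected,
                      marker_spacing_bp = marker_spacing_bp,
                      het_rate = het_rate, error_rate = error_rate,
                      missing_rate = missing_rate, seed = seed))
  })
}

## ---------------------------------------------------------------------------
## Exon depth simulation
## ---------------------------------------------------------------------------

#' Simulate a per-base exon depth track
#'
#' Per-base depths are independent Poisson draws with mean
#' \code{mean_depth * copy_number / 2}.  Exons at copy number 0 instead
#' receive sparse mis-mapping noise at \code{noise_frac} of the full mean,
#' so a homozygously deleted exon shows near-zero (not exactly zero) depth.
#'
#' @param model a [TranscriptModel-class]
#' @param copy_number_by_exon integer vector (0/1/2), one per exon
#' @param mean_depth diploid mean reads/base (default 230)
#' @param noise_frac mis-mapping noise fraction for copy-0 exons (default
#'   0.0025, at most 0.005)
#' @param seed RNG seed
#' @return data.frame(chrom, pos, depth), one row per exon base
#' @export
simulateExonDepths <- function(model, copy_number_by_exon = NULL,
                               mean_depth = 230, noise_frac = 0.0025,
                               seed = 1L) {
  stopifnot(is(model, "TranscriptModel"), mean_depth > 0,
            noise_frac <= 0.005)
  ex <- model@exons
  nEx <- length(ex)
  cn <- copy_number_by_exon %||% rep(2L, nEx)
  if (length(cn) != nEx || !all(cn %in% 0:2))
    .err("rohdel_bad_input",
         "copy_number_by_exon must give 0/1/2 for each of the %d exons", nEx)
  seed <- .checkSeed(seed)
  withr::with_seed(.childSeed(seed, 3L), {
    do.call(rbind, lapply(seq_len(nEx), function(i) {
      pos <- seq(GenomicRanges::start(ex)[i], GenomicRanges::end(ex)[i])
      lambda <- if (cn[i] == 0L) mean_depth * noise_frac
                else mean_depth * cn[i] / 2
      data.frame(chrom = model@chrom, pos = pos,
                 depth = stats::rpois(length(pos), lambda))
    }))
  })
}

## ---------------------------------------------------------------------------
## Annotated VCF simulation
## ---------------------------------------------------------------------------

#' Default composition of the simulated candidate-region VCF
#'
#' Shaped like a typical consanguineous-exome screen: hundreds of known or
#' common records, tens of rare silent records, a single rare functional
#' indel in tandem-repeat context, plus a handful of records outside the
#' candidate regions or failing caller filters.
#'
#' @return data.frame with columns n, db129, af_bin, fclass, inside, pass
#' @export
defaultVcfComposition <- function() {
  data.frame(
    n = c(400L, 226L, 25L, 15L, 5L, 20L, 8L),
    db129 = c(TRUE, FALSE, FALSE, FALSE, FALSE, FALSE, FALSE),
    af_bin = c("common", "common", "rare", "unknown", "rare",
               "common", "common"),
    fclass = c("synonymous", "intronic", "synonymous", "intronic", "other",
               "synonymous", "synonymous"),
    inside = c(TRUE, TRUE, TRUE, TRUE, TRUE, FALSE, TRUE),
    pass = c(TRUE, TRUE, TRUE, TRUE, TRUE, TRUE, FALSE))
}

#' Simulate an annotated candidate-region VCF with ground truth
#'
#' Emits SNV records per \code{composition} at collision-free uniform
#' positions, and (by default) plants one rare exonic insertion of
#' (CGG)5 at the reference (CGG)8 tract carried by the canonical genome —
#' the record that survives the filter cascade and gets the repeat-context
#' flag.
#'
#' @param regions candidate [GenomicRanges::GRanges] positions are drawn
#'   from
#' @param composition data.frame as [defaultVcfComposition()]
#' @param genome a [GenomeSequence-class] (canonical toy genome) providing
#'   the repeat-context window
#' @param plant_repeat_insertion plant the canonical repeat-tract insertion
#' @param seed RNG seed
#' @param path if non-NULL, also write the VCF there
#' @return list with \code{variants} (data.frame as [readVariantVcf()]),
#'   \code{truth} (per-record planted classification) and \code{path}
#' @export
simulateVcf <- function(regions = defaultSharedSegments(),
                        composition = defaultVcfComposition(),
                        genome = NULL, plant_repeat_insertion = TRUE,
                        seed = 1L, path = NULL) {
  stopifnot(all(composition$n >= 0L))
  seed <- .checkSeed(seed)
  p <- .CANONICAL
  withr::with_seed(.childSeed(seed, 4L), {
    nTot <- sum(composition$n) + as.integer(plant_repeat_insertion)
    rchr <- as.character(GenomicRanges::seqnames(regions))
    rs <- GenomicRanges::start(regions); re <- GenomicRanges::end(regions)
    avail <- sum(re - rs + 1)
    if (nTot > avail / 2)
      .err("rohdel_bad_input", "composition exceeds available positions")

    drawPos <- function(n, inside) {
      out <- data.frame(chrom = character(0), pos = integer(0))
      while (nrow(out) < n) {
        need <- n - nrow(out)
        if (inside) {
          i <- sample.int(length(regions), need, replace = TRUE)
          cand <- data.frame(
            chrom = rchr[i],
            pos = rs[i] + floor(stats::runif(need) * (re[i] - rs[i] + 1)))
        } else {
          cand <- data.frame(
            chrom = sample(rchr, need, replace = TRUE),
            pos = sample.int(1000000L, need))   # well 5' of any region
        }
        out <- unique(rbind(out, cand))
      }
      out[seq_len(n), , drop = FALSE]
    }

    bases <- c("A", "C", "G", "T")
    recs <- list(); truth <- list()
    idc <- 0L
    for (k in seq_len(nrow(composition))) {
      row <- composition[k, ]
      if (row$n == 0L) next
      ps <- drawPos(row$n, row$inside)
      ref <- sample(bases, row$n, replace = TRUE)
      alt <- vapply(ref, function(r) sample(setdiff(bases, r), 1L),
                    character(1))
      af <- switch(row$af_bin,
        common = stats::runif(row$n, 0.01, 0.5),
        rare = stats::runif(row$n, 1e-4, 0.0099),
        unknown = rep(NA_real_, row$n))
      ids <- sprintf("var%04d", idc + seq_len(row$n)); idc <- idc + row$n
      recs[[k]] <- data.frame(
        chrom = ps$chrom, pos = ps$pos, id = ids, ref = ref, alt = alt,
        filter = if (row$pass) "PASS" else "LowQual",
        db129 = row$db129, af137 = af, fclass = row$fclass,
        gt = sample(c("0/1", "1/1"), row$n, replace = TRUE))
      truth[[k]] <- data.frame(
        id = ids,
        planted = if (!row$inside) "outside_region"
                  else if (!row$pass) "non_pass"
                  else if (row$db129 || row$af_bin == "common") "known_common"
                  else "rare_silent",
        expected_survivor = FALSE, repeat_context = FALSE)
    }
    if (plant_repeat_insertion) {
      ref <- if (!is.null(genome))
        getSubseq(genome, p$repeatChrom, p$repeatInsPos, p$repeatInsPos)
      else "A"
      ins <- strrep(p$repeatUnit, p$repeatInsCopies)
      recs <- c(recs, list(data.frame(
        chrom = p$repeatChrom, pos = p$repeatInsPos, id = "varREP",
        ref = ref, alt = paste0(ref, ins), filter = "PASS",
        db129 = FALSE, af137 = NA_real_, fclass = "exonic_indel",
        gt = "1/1")))
      truth <- c(truth, list(data.frame(
        id = "varREP", planted = "rare_functional_repeat",
        expected_survivor = TRUE, repeat_context = TRUE)))
    }
    emptyVariants <- data.frame(
      chrom = character(0), pos = integer(0), id = character(0),
      ref = character(0), alt = character(0), filter = character(0),
      db129 = logical(0), af137 = numeric(0), fclass = character(0),
      gt = character(0))
    variants <- do.call(rbind, recs) %||% emptyVariants
    variants <- variants[order(variants$chrom, variants$pos), ,
                         drop = FALSE]
    rownames(variants) <- NULL
    truth <- do.call(rbind, truth) %||% data.frame(
      id = character(0), planted = character(0),
      expected_survivor = logical(0), repeat_context = logical(0))
    ## keep the truth table parallel to the (sorted) variant table
    truth <- truth[match(variants$id, truth$id), , drop = FALSE]
    rownames(truth) <- NULL
    if (!is.null(path)) writeVariantVcf(variants, path)
    list(variants = variants, truth = truth, path = path)
  })
}

#' Write a variant table as VCF v4.2
#'
#' Emits the cascade's INFO annotations (DB129, AF137, FCLASS) and a single
#' GT sample column.
#'
#' @param variants variant data.frame (see [readVariantVcf()])
#' @param path output VCF
#' @param sample_name name of the genotype column
#' @return invisibly, the path
#' @export
writeVariantVcf <- function(variants, path, sample_name = "CASE") {
  info <- vapply(seq_len(nrow(variants)), function(i) {
    parts <- character(0)
    if (isTRUE(variants$db129[i])) parts <- c(parts, "DB129")
    if (!is.na(variants$af137[i]))
      parts <- c(parts, sprintf("AF137=%.6f", variants$af137[i]))
    parts <- c(parts, sprintf("FCLASS=%s", variants$fclass[i]))
    paste(parts, collapse = ";")
  }, character(1))
  body <- sprintf("%s\t%d\t%s\t%s\t%s\t.\t%s\t%s\tGT\t%s",
                  variants$chrom, variants$pos, variants$id, variants$ref,
                  variants$alt, variants$filter, info,
                  ifelse(is.na(variants$gt), "./.", variants$gt))
  header <- c(
    "##fileformat=VCFv4.2",
    "##INFO=<ID=DB129,Number=0,Type=Flag,Description=\"Present in the early dbSNP build\">",
    "##INFO=<ID=AF137,Number=1,Type=Float,Description=\"Minor allele frequency in the later dbSNP build\">",
    "##INFO=<ID=FCLASS,Number=1,Type=String,Description=\"Functional class\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    sprintf("#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\t%s",
            sample_name))
  writeLines(c(header, body), path)
  invisible(path)
}

## ---------------------------------------------------------------------------
## Complete fixture directory
## ---------------------------------------------------------------------------

#' Write a complete synthetic fixture directory
#'
#' Generates every input the discovery pipeline needs — genome FASTA, gene
#' model (GFF3 + TSV), pedigree genotype TSV, case and panel depth tracks,
#' annotated VCF — plus the ground truth (JSON) and a ready-to-run pipeline
#' config.  Panel samples are simulated at diploid means 200/210/230/250/260
#' reads/base; the case is simulated at 230 with the gene's sixth exon at
#' copy number 0.
#'
#' @param dir output directory (created)
#' @param seed master RNG seed
#' @param plant_deletion simulate the case with the homozygous exon
#'   deletion (FALSE gives an all-normal case)
#' @return path of the written config file, invisibly; the truth is in
#'   \code{truth.json}
#' @export
writeFixture <- function(dir, seed = 1L, plant_deletion = TRUE) {
  seed <- .checkSeed(seed)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  cm <- makeCanonicalModel(dir = dir, seed = seed)
  ped <- canonicalPedigree()
  sim <- simulatePedigreeGenotypes(ped, seed = seed)
  genoPath <- file.path(dir, "genotypes.tsv")
  writeGenotypeTsv(sim$genotypes, genoPath)

  nEx <- length(exonRanges(cm$model))
  cnCase <- rep(2L, nEx)
  if (plant_deletion) cnCase[6L] <- 0L
  casePath <- file.path(dir, "depth_case.tsv")
  utils::write.table(
    simulateExonDepths(cm$model, cnCase, mean_depth = 230,
                       seed = .childSeed(seed, 10L)),
    casePath, sep = "\t", quote = FALSE, row.names = FALSE)
  panelMeans <- c(200, 210, 230, 250, 260)
  panelPaths <- vapply(seq_along(panelMeans), function(i) {
    pp <- file.path(dir, sprintf("depth_panel_%d.tsv", i))
    utils::write.table(
      simulateExonDepths(cm$model, rep(2L, nEx), mean_depth = panelMeans[i],
                         seed = .childSeed(seed, 10L + i)),
      pp, sep = "\t", quote = FALSE, row.names = FALSE)
    pp
  }, character(1))

  vcfPath <- file.path(dir, "variants.vcf")
  vsim <- simulateVcf(genome = cm$genome, seed = seed, path = vcfPath)

  truth <- list(
    seed = seed,
    shared_segments = .grToDf(sim$truth$shared_segments),
    private_segments = lapply(sim$truth$private_segments, .grToDf),
    affected = sim$truth$affected,
    deletion = if (plant_deletion)
      list(chrom = "chrG", start = unname(cm$deletion["start"]),
           end = unname(cm$deletion["end"]), exon = 6L) else NULL,
    exon_copy_number_case = cnCase,
    variant_truth = vsim$truth)
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")

  cfg <- c(
    "# synthetic fixture pipeline configuration",
    sprintf("seed: %d", seed),
    sprintf("genotypes: %s", genoPath),
    "affected: VI2,VI3,VI4",
    sprintf("vcf: %s", vcfPath),
    sprintf("genome: %s", file.path(dir, "genome.fasta")),
    sprintf("model: %s", file.path(dir, "model.tsv")),
    sprintf("depth_case: %s", casePath),
    sprintf("depth_panel: %s", paste(panelPaths, collapse = ",")),
    "case_sample: VI2",
    "annotation.hgvs_c: c.294+139_531+478del",
    "pcr.longrange: chrG:1002300-1002319/1005421-1005440",
    "pcr.exon6: chrG:1004130-1004149/1004300-1004319")
  cfgPath <- file.path(dir, "config.yaml")
  writeLines(cfg, cfgPath)
  invisible(cfgPath)
}

.grToDf <- function(gr) {
  data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
             start = GenomicRanges::start(gr),
             end = GenomicRanges::end(gr))
}
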
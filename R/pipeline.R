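## ---------------------------------------------------------------------------
## Run configuration
## ---------------------------------------------------------------------------

## schema: default NULL = required; validate() returns an error message or NULL
.CONFIG_SCHEMA <- list(
  genotypes = list(type = "path"),
  affected = list(type = "idlist"),
  vcf = list(type = "path"),
  genome = list(type = "path"),
  model = list(type = "path"),
  transcript_id = list(type = "string", default = NA_character_),
  depth_case = list(type = "path"),
  depth_panel = list(type = "pathlist"),
  case_sample = list(type = "string"),
  seed = list(type = "number", default = 1, min = 0, max = 2^31 - 1),
  `annotation.hgvs_c` = list(type = "string", default = NA_character_),
  `annotation.normalize_3prime` = list(type = "flag", default = FALSE),
  `pcr.longrange` = list(type = "string", default = NA_character_),
  `pcr.exon6` = list(type = "string", default = NA_character_),
  `pcr.max_amplicon` = list(type = "number", default = 2000, min = 1),
  `roh.min_markers` = list(type = "number", default = 25, min = 1),
  `roh.min_length_bp` = list(type = "number", default = 1e6, min = 1),
  `roh.max_het` = list(type = "number", default = 1, min = 0),
  `roh.max_missing` = list(type = "number", default = 2, min = 0),
  `filter.maf_threshold` = list(type = "number", default = 0.01, min = 0, max = 1),
  `filter.unit_max` = list(type = "number", default = 6, min = 1),
  `filter.min_copies` = list(type = "number", default = 4, min = 1),
  `coverage.max_ratio` = list(type = "number", default = 0.1, min = 0, max = 1),
  `coverage.min_panel_depth` = list(type = "number", default = 10, min = 0),
  `coverage.normalize` = list(type = "flag", default = FALSE))

#' Validate a pipeline configuration file
#'
#' The config is a flat key-value YAML document (dotted keys select stage
#' parameter blocks).  All problems — unknown keys (with a did-you-mean
#' suggestion), type errors, out-of-range values, missing required paths —
#' are collected and reported together, not fail-fast.  Defaults are filled
#' for everything optional.
#'
#' @param path config file
#' @return a validated \code{RunConfig} (named list, class "RunConfig")
#' @export
validateConfig <- function(path) {
  if (!file.exists(path))
    .err("rohdel_config_error", "config file '%s' does not exist", path)
  raw <- yaml::read_yaml(path)
  errs <- character()
  known <- names(.CONFIG_SCHEMA)
  for (k in setdiff(names(raw), known)) {
    d <- utils::adist(k, known)
    hint <- if (min(d) <= 3L) sprintf(" (did you mean '%s'?)",
                                      known[which.min(d)]) else ""
    errs <- c(errs, sprintf("unknown key '%s'%s", k, hint))
  }
  cfg <- list()
  for (k in known) {
    sc <- .CONFIG_SCHEMA[[k]]
    v <- raw[[k]]
    if (is.null(v)) {
      if (is.null(sc$default)) {
        errs <- c(errs, sprintf("missing required key '%s'", k))
        next
      }
      cfg[[k]] <- sc$default
      next
    }
    cfg[[k]] <- switch(sc$type,
      number = {
        vn <- suppressWarnings(as.numeric(v))
        if (is.na(vn)) {
          errs <- c(errs, sprintf("'%s' must be numeric (got '%s')", k, v))
          NA_real_
        } else if (!is.null(sc$min) && vn < sc$min ||
                   !is.null(sc$max) && vn > sc$max) {
          errs <- c(errs, sprintf("'%s' = %s out of range [%s, %s]", k, vn,
                                  sc$min %||% "-Inf", sc$max %||% "Inf"))
          vn
        } else vn
      },
      flag = {
        vb <- as.logical(v)
        if (is.na(vb))
          errs <- c(errs, sprintf("'%s' must be true/false (got '%s')", k, v))
        vb
      },
      path = {
        if (!file.exists(v))
          errs <- c(errs, sprintf("'%s': file '%s' does not exist", k, v))
        as.character(v)
      },
      pathlist = {
        vv <- trimws(strsplit(as.character(v), ",")[[1]])
        miss <- vv[!file.exists(vv)]
        if (length(miss))
          errs <- c(errs, sprintf("'%s': file(s) %s do not exist", k,
                                  paste(sQuote(miss), collapse = ", ")))
        vv
      },
      idlist = trimws(strsplit(as.character(v), ",")[[1]]),
      string = as.character(v))
  }
  if (length(errs))
    .err("rohdel_config_error", "invalid configuration:\n%s",
         paste("  -", errs, collapse = "\n"))
  structure(cfg, class = "RunConfig")
}

## "chrG:1002300-1002319/1005421-1005440" -> PrimerPair
.parsePrimerSpec <- function(spec, label = "") {
  m <- regmatches(spec, regexec(
    "^([^:]+):(\\d+)-(\\d+)/(\\d+)-(\\d+)$", spec))[[1]]
  if (!length(m))
    .err("rohdel_config_error",
         "cannot parse primer spec '%s' (expected chrom:fs-fe/rs-re)", spec)
  PrimerPair(m[2], as.integer(m[3]), as.integer(m[4]),
             as.integer(m[5]), as.integer(m[6]), label = label)
}

## ---------------------------------------------------------------------------
## DiscoveryReport
## ---------------------------------------------------------------------------

#' End-to-end discovery run results
#'
#' @slot sharedRegions shared candidate regions ([GenomicRanges::GRanges])
#' @slot filterReport the variant-filter [FilterReport-class]
#' @slot coverageCalls per-exon depth-screen calls (data.frame)
#' @slot consequence annotated [DeletionConsequence-class], or NULL when no
#'   breakpoint description was supplied
#' @slot pcrAssay diagnostic in-silico PCR table (data.frame)
#' @slot provenance list: config hash, seed, package version
#' @export
setClass("DiscoveryReport",
  slots = c(sharedRegions = "GRanges", filterReport = "FilterReport",
            coverageCalls = "data.frame", consequence = "ANY",
            pcrAssay = "data.frame", provenance = "list"))

#' @rdname DiscoveryReport-class
#' @param report a DiscoveryReport
#' @export
candidateDeletions <- function(report) {
  report@coverageCalls[
    report@coverageCalls$verdict == "homozygous_deletion_candidate", ,
    drop = FALSE]
}

setMethod("show", "DiscoveryReport", function(object) {
  cat("DiscoveryReport\n")
  cat(sprintf("  shared regions: %d\n", length(object@sharedRegions)))
  st <- object@filterReport@stages
  cat(sprintf("  filter cascade: %s -> %d survivor(s)\n",
              paste(st$n_in, collapse = " -> "), st$n_out[nrow(st)]))
  cand <- candidateDeletions(object)
  cat(sprintf("  deleted-exon candidates: %d\n", nrow(cand)))
  if (is(object@consequence, "DeletionConsequence") &&
      !is.na(object@consequence@proteinHgvs))
    cat(sprintf("  consequence: %s\n", object@consequence@proteinHgvs))
})

## ---------------------------------------------------------------------------
## Orchestration
## ---------------------------------------------------------------------------

#' Run the full discovery pipeline
#'
#' Executes autozygosity mapping, the variant filter cascade, the exome
#' depth screen and (when a breakpoint description is configured) deletion
#' annotation plus the diagnostic in-silico PCR, logging each stage to
#' stderr.  Any stage error aborts with the stage name; when \code{out_dir}
#' is given the outputs written so far are retained next to a
#' \code{FAILED} marker naming the stage.
#'
#' @param config path to a config file, or a validated \code{RunConfig}
#' @param out_dir if non-NULL, stage outputs plus \code{report.json} and
#'   \code{report.txt} are written there
#' @param quiet suppress stderr progress logging
#' @return a [DiscoveryReport-class]
#' @export
runDiscovery <- function(config, out_dir = NULL, quiet = FALSE) {
  cfg <- if (inherits(config, "RunConfig")) config else validateConfig(config)
  if (!is.null(out_dir))
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  log <- function(fmt, ...) if (!quiet) message(sprintf(fmt, ...))
  stage <- function(name, expr) {
    log("[%s] running", name)
    tryCatch(expr, error = function(e) {
      if (!is.null(out_dir))
        writeLines(sprintf("stage %s failed: %s", name, conditionMessage(e)),
                   file.path(out_dir, "FAILED"))
      .err("rohdel_stage_failure", "stage %s failed: %s", name,
           conditionMessage(e))
    })
  }
  hash <- .configHash(cfg)
  log("run seed %s, config hash %s", cfg$seed, hash)

  shared <- stage("roh_mapping", {
    gm <- readGenotypeTsv(cfg$genotypes)
    per <- lapply(cfg$affected, function(s)
      detectRoh(gm, s, min_markers = cfg$`roh.min_markers`,
                min_length_bp = cfg$`roh.min_length_bp`,
                max_het = cfg$`roh.max_het`,
                max_missing = cfg$`roh.max_missing`))
    names(per) <- cfg$affected
    sh <- intersectShared(per, gm)
    if (!is.null(out_dir))
      writeRohRegions(sh, bed = file.path(out_dir, "shared_regions.bed"),
                      tsv = file.path(out_dir, "shared_regions.tsv"))
    sh
  })
  log("[roh_mapping] %d shared region(s)", length(shared))

  genome <- stage("input_io", readGenomeFasta(cfg$genome))
  filt <- stage("variant_filter", {
    variants <- readVariantVcf(cfg$vcf)
    fr <- runCascade(variants, shared, genome,
                     maf_threshold = cfg$`filter.maf_threshold`,
                     unit_max = cfg$`filter.unit_max`,
                     min_copies = cfg$`filter.min_copies`)
    if (!is.null(out_dir))
      writeFilterReport(fr, tsv = file.path(out_dir, "variants_surviving.tsv"),
                        log = file.path(out_dir, "filter_cascade.txt"))
    fr
  })
  log("[variant_filter] %d survivor(s)",
      nrow(filt@survivors))

  model <- stage("coverage_screen_model", {
    tid <- cfg$transcript_id
    loadTranscript(cfg$model, if (is.na(tid)) NULL else tid)
  })
  cov <- stage("coverage_screen", {
    samples <- c(cfg$case_sample,
                 sprintf("panel_%d", seq_along(cfg$depth_panel)))
    depths <- cbind(
      exonMeanDepth(cfg$depth_case, model),
      vapply(cfg$depth_panel, function(p) exonMeanDepth(p, model),
             numeric(length(exonRanges(model)))))
    colnames(depths) <- samples
    edt <- ExonDepthTable(exonRanges(model), geneId(model), depths,
                          case = cfg$case_sample)
    edt <- compareToPanel(edt, normalize = cfg$`coverage.normalize`)
    calls <- callDeletions(edt, max_ratio = cfg$`coverage.max_ratio`,
                           min_panel_depth = cfg$`coverage.min_panel_depth`)
    if (!is.null(out_dir))
      writeCoverageScreen(edt, calls,
                          tsv = file.path(out_dir, "coverage_screen.tsv"),
                          bed = file.path(out_dir, "deleted_exons.bed"))
    calls
  })
  log("[coverage_screen] %d candidate exon(s)",
      sum(cov$verdict == "homozygous_deletion_candidate"))

  cons <- NULL
  pcr <- data.frame()
  if (!is.na(cfg$`annotation.hgvs_c`)) {
    cons <- stage("deletion_annotation", {
      d <- parseHgvsCDel(cfg$`annotation.hgvs_c`, model)
      cc <- annotateDeletion(d, model, genome,
                             normalize3prime = cfg$`annotation.normalize_3prime`)
      if (!is.null(out_dir)) {
        writeDeletionReport(cc, model, file.path(out_dir, "deletion_report.tsv"))
        writeDeletionVcf(cc, model, genome, file.path(out_dir, "deletion.vcf"))
      }
      cc
    })
    log("[deletion_annotation] %s", cons@proteinHgvs)
    if (!is.na(cfg$`pcr.longrange`) && !is.na(cfg$`pcr.exon6`))
      pcr <- stage("pcr_genotyping", {
        .pcrAssayTable(genome, cons, model,
                       .parsePrimerSpec(cfg$`pcr.exon6`, "exon6"),
                       .parsePrimerSpec(cfg$`pcr.longrange`, "longrange"),
                       cfg$`pcr.max_amplicon`)
      })
  }

  report <- new("DiscoveryReport", sharedRegions = shared,
                filterReport = filt, coverageCalls = cov,
                consequence = cons, pcrAssay = pcr,
                provenance = list(
                  config_hash = unname(hash), seed = cfg$seed,
                  package_version =
                    as.character(utils::packageVersion("rohdel"))))
  if (!is.null(out_dir)) {
    writeDiscoveryReport(report, json = file.path(out_dir, "report.json"),
                         txt = file.path(out_dir, "report.txt"))
  }
  report
}

## diagnostic assay: expected products per allele and the classification
## each deletion genotype yields
.pcrAssayTable <- function(genome, cons, model, exon6, longrange,
                           max_amplicon) {
  mut <- applyDeletion(genome, model@chrom, cons@genomicStart,
                       cons@genomicEnd)
  prod <- list(
    wt = c(exon6 = inSilicoPcr(genome, exon6),
           longrange = inSilicoPcr(genome, longrange)),
    del = c(exon6 = inSilicoPcr(mut, exon6),
            longrange = inSilicoPcr(mut, longrange)))
  geno <- list(wild_type = c("wt", "wt"), carrier = c("wt", "del"),
               homozygous_deleted = c("del", "del"))
  do.call(rbind, lapply(names(geno), function(g) {
    al <- geno[[g]]
    ex <- c(prod[[al[1]]]["exon6"], prod[[al[2]]]["exon6"])
    lr <- c(prod[[al[1]]]["longrange"], prod[[al[2]]]["longrange"])
    data.frame(genotype = g,
               exon6_products = paste(ifelse(is.na(ex), "-", ex),
                                      collapse = "/"),
               longrange_products = paste(ifelse(is.na(lr), "-", lr),
                                          collapse = "/"),
               classification = classifyPcrGenotype(ex, lr, max_amplicon))
  }))
}

.configHash <- function(cfg) {
  canon <- vapply(sort(names(unclass(cfg))), function(k)
    sprintf("%s=%s", k, paste(format(cfg[[k]]), collapse = ",")),
    character(1))
  tf <- tempfile(); on.exit(unlink(tf))
  writeLines(canon, tf)
  unname(tools::md5sum(tf))
}

#' Write a discovery report as JSON and text
#'
#' The JSON report is byte-identical across reruns of the same config and
#' seed (the determinism contract): every numeric field is traceable to a
#' stage output and no timestamps are embedded.
#'
#' @param report a [DiscoveryReport-class]
#' @param json,txt output paths (NULL skips)
#' @return invisibly, the paths
#' @export
writeDiscoveryReport <- function(report, json = NULL, txt = NULL) {
  regions <- .grToDf(report@sharedRegions)
  if (length(report@sharedRegions))
    regions$size_mb <- S4Vectors::mcols(report@sharedRegions)$size_mb
  cons <- report@consequence
  consList <- if (is(cons, "DeletionConsequence")) list(
    genomic_start = cons@genomicStart, genomic_end = cons@genomicEnd,
    total_length = cons@totalLength,
    coding_bases_removed = cons@codingBasesRemoved,
    intronic_bases_removed = cons@intronicBasesRemoved,
    in_frame = cons@inFrame, status = cons@status,
    first_residue = cons@firstResidue, last_residue = cons@lastResidue,
    protein_hgvs = cons@proteinHgvs,
    wt_protein_length = cons@wtProteinLength,
    mut_protein_length = cons@mutProteinLength) else NULL
  payload <- list(
    shared_regions = regions,
    filter_cascade = report@filterReport@stages,
    filter_survivors = nrow(report@filterReport@survivors),
    coverage_calls = report@coverageCalls,
    deletion_consequence = consList,
    pcr_assay = report@pcrAssay,
    provenance = report@provenance)
  if (!is.null(json))
    jsonlite::write_json(payload, json, auto_unbox = TRUE, digits = NA,
                         null = "null")
  if (!is.null(txt)) {
    con <- file(txt, "w"); on.exit(close(con))
    lines <- c("recessive-deletion discovery report", "")
    lines <- c(lines, sprintf("shared candidate regions: %d",
                              nrow(regions)),
               if (nrow(regions))
                 sprintf("  %s:%d-%d (%.1f Mb)", regions$chrom,
                         regions$start, regions$end, regions$size_mb))
    st <- report@filterReport@stages
    lines <- c(lines, "", "variant filter cascade:",
               sprintf("  %-22s %6d -> %6d", st$stage, st$n_in, st$n_out))
    cand <- candidateDeletions(report)
    lines <- c(lines, "", sprintf("deleted-exon candidates: %d", nrow(cand)),
               if (nrow(cand))
                 sprintf("  %s exon %d (%s:%d-%d) ratio %.4f",
                         cand$gene, cand$exon_index, cand$chrom, cand$start,
                         cand$end, cand$depth_ratio))
    if (!is.null(consList))
      lines <- c(lines, "",
                 sprintf("deletion: %d bp, coding %d bp, %s, %s (%d -> %d aa)",
                         consList$total_length,
                         consList$coding_bases_removed,
                         if (consList$in_frame) "in-frame" else "frameshift",
                         consList$protein_hgvs,
                         consList$wt_protein_length,
                         consList$mut_protein_length))
    if (nrow(report@pcrAssay)) {
      lines <- c(lines, "", "diagnostic PCR assay:",
                 sprintf("  %-20s exon6 %-12s longrange %-12s -> %s",
                         report@pcrAssay$genotype,
                         report@pcrAssay$exon6_products,
                         report@pcrAssay$longrange_products,
                         report@pcrAssay$classification))
    }
    lines <- c(lines, "", sprintf("seed: %s  config: %s  version: %s",
                                  report@provenance$seed,
                                  report@provenance$config_hash,
                                  report@provenance$package_version))
    writeLines(lines, con)
  }
  invisible(c(json = json, txt = txt))
}
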
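Package: rohdel
Title: Autozygosity Mapping and Exome Read-Depth Screening for Recessive
    Deletions
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Gene-discovery pipeline for recessive disease in consanguineous
    pedigrees: detects runs of homozygosity from SNP genotype matrices and
    intersects them across affected individuals; applies a rare-variant
    filter cascade (candidate-region restriction, known-polymorphism and
    allele-frequency filters, functional-class selection, tandem-repeat
    context flagging) to annotated VCFs; screens per-exon exome read depth
    against a control panel to call homozygous exon deletions; and annotates
    genomic deletions with HGVS c./p. nomenclature, frame status, protein
    consequence and an in-silico PCR genotyping assay. Includes a synthetic
    data generator that emulates a consanguineous nuclear family segregating
    a homozygous in-frame exon deletion, with queryable ground truth for
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    BiocGenerics,
    S4Vectors,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    Biostrings,
    SummarizedExperiment,
    VariantAnnotation,
    rtracklayer,
    jsonlite,
    yaml,
    withr
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
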
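# rohdel

Gene discovery for recessive disease in consanguineous families:
shared-autozygosity mapping, rare-variant filtering, exome read-depth
screening for homozygous exon deletions, and HGVS-level deletion annotation
— as a tested, reusable R/Bioconductor-style pipeline.

## The problem

In a family with related parents, a recessive disorder is usually caused by
a variant that is homozygous by descent. Two signals locate it:

1. **Shared runs of homozygosity (ROH).** All affected relatives inherit
   the same ancestral segment on both chromosomes, producing multi-megabase
   runs of homozygous SNP calls shared by every affected — the candidate
   regions.
2. **Missing read depth.** If the causal allele is a genomic deletion,
   SNV/indel calling inside the candidate regions comes up empty, but a
   per-exon depth comparison of the case against control exomes shows one
   exon with essentially no reads (case ≈ 0.5 reads/base vs panel
   ≈ 230 reads/base) — a homozygous exon deletion.

`rohdel` implements both, plus the connective tissue: the rare-variant
filter cascade that excludes SNV/indel explanations, and the coordinate
algebra that turns breakpoints into a full consequence record. For a
deletion written in HGVS coding-DNA notation,

> c.294+139_531+478del

the package computes the genomic span (2347 bp), the coding loss (all
237 bp of the sixth exon plus 2110 bp of flanking intron), frame status
(237 ≡ 0 mod 3: in-frame), the removed residue run (`p.Tyr99_Glu177del`,
79 residues, shortening the protein from 447 to 368 amino acids), and the
diagnostic in-silico PCR (exon-5→7 primers: 3141 bp on the wild-type
allele, 794 bp on the deletion allele; an exon-6-internal assay amplifies
only when the exon is present).

A synthetic-data generator emulates the whole study — a 2-parent/6-child
pedigree with three affecteds, two planted shared autozygous segments
(14.5 and 12.2 Mb), Poisson exon coverage with a copy-0 exon, and an
annotated VCF whose filter cascade shrinks 700 → 672 → 46 → 1 — with
queryable ground truth, so every stage is tested end-to-end.

## Worked example

```r
library(rohdel)

dir <- tempfile("fixture")
cfg <- writeFixture(dir, seed = 1)          # complete synthetic study
report <- runDiscovery(cfg, out_dir = file.path(dir, "out"))
report
#> DiscoveryReport
#>   shared regions: 2
#>   filter cascade: 700 -> 672 -> 46 -> 1 survivor(s)
#>   deleted-exon candidates: 1
#>   consequence: p.Tyr99_Glu177del
```

The two shared regions are the planted autozygous segments (14.5 Mb and
12.2 Mb); the cascade's lone survivor is a (CGG)n repeat-context insertion
annotated `LIKELY_REPEAT_POLYMORPHISM` (an unlikely cause, mirroring how
such survivors are triaged); the depth screen flags exon 6 of the toy gene
(case 0.57 vs panel 230 reads/base, ratio 0.0025); and the annotation stage
turns the configured breakpoint string into the consequence record above.

The pieces work standalone:

```r
cm <- makeCanonicalModel()                  # toy genome + transcript model
d  <- parseHgvsCDel("c.294+139_531+478del", cm$model)
annotateDeletion(d, cm$model, cm$genome)
#> DeletionConsequence: 2347 bp (genomic 1002483-1004829)
#>   coding 237 bp, intronic 2110 bp, in-frame [codon_aligned]
#>   protein: p.Tyr99_Glu177del (447 -> 368 residues)

mut <- applyDeletion(cm$genome, "chrG", 1002483, 1004829)
inSilicoPcr(mut, PrimerPair("chrG", 1002300, 1002319, 1005421, 1005440))
#> [1] 794
```

A thin CLI (`inst/scripts/rohdel`) exposes the stages as subcommands
(`simulate`, `roh`, `filter-variants`, `covscreen`, `annotate`,
`run-all`); `run-all` exits 0 when at least one deletion candidate is
found, 3 when none is, 1 on error.

### Input formats

* genotypes: TSV with columns `chrom, pos, marker_id`, then one AA/AB/BB/NC
  column per sample;
* gene model: GFF3 (exon + CDS features) or a TSV dialect with one exon per
  row (`gene_id, transcript_id, chrom, strand, exon_index, start, end,
  cds_start, cds_end`, the last two delimiting the coding sub-interval,
  empty for non-coding exons);
* depth: bedGraph or per-base TSV (`chrom, pos, depth`);
* variants: VCF v4.2 with INFO keys `DB129` (flag), `AF137` (float),
  `FCLASS` (string);
* regions out: BED (0-based half-open) and TSV (1-based) with sizes and
  marker counts; deletions out: TSV report and a VCF symbolic-DEL record
  (`SVTYPE=DEL`, `END`, `SVLEN`).

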
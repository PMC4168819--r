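---
title: "Mapping recessive exon deletions from autozygosity and exome depth"
author: "rohdel maintainers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping recessive exon deletions from autozygosity and exome depth}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rohdel)
```

## The discovery problem

In a consanguineous family, a rare recessive disorder is very likely caused
by a variant that is homozygous by descent: both copies come from a common
ancestor of the related parents. That history leaves a footprint —
multi-megabase runs of homozygosity (ROH) shared by all affected relatives —
which shrinks the search space from the whole genome to a few candidate
regions. Within those regions, exome sequencing should reveal the causal
variant; when it does not, the absence itself can be the signal: a
homozygous genomic deletion removes all reads over the deleted exon, a
pattern invisible to SNV/indel callers but obvious when per-exon read depth
is compared against control exomes.

`rohdel` implements that chain of reasoning as a tested pipeline with four
analysis stages plus a synthetic-data generator:

1. **ROH mapping** (`detectRoh`, `intersectShared`): runs of homozygous SNP
   calls per affected sample, intersected into shared candidate regions.
2. **Variant filtering** (`runCascade`): the classic rare-variant cascade on
   an annotated VCF — candidate-region restriction, known-polymorphism
   removal, functional-class selection, tandem-repeat context flagging.
3. **Coverage screening** (`compareToPanel`, `callDeletions`): per-exon mean
   read depth of the case against a control panel, calling candidate
   homozygous exon deletions.
4. **Deletion annotation** (`parseHgvsCDel`, `annotateDeletion`,
   `inSilicoPcr`): HGVS-level characterization of the deletion — genomic
   span, coding loss, frame, protein consequence — and an in-silico PCR
   genotyping assay.

## ROH detection model

A run is a maximal stretch of consecutive markers that is homozygous up to
small tolerances: at most `max_het` heterozygous calls (genotyping
artefacts) and `max_missing` no-calls per run. Boundaries are trimmed to the
outermost homozygous markers, and runs are kept only if they carry at least
`min_markers` markers and span at least `min_length_bp`. The scanner is a
two-pointer sweep whose output is property-tested against a brute-force
enumeration of all maximal qualifying windows.

Defaults — `min_markers = 25`, `min_length_bp = 1e6`, `max_het = 1`,
`max_missing = 2` — target multi-megabase autozygous segments at SNP-array
density (one marker per few kb) while tolerating occasional artefacts.
Homozygosity viewers used in clinical mapping studies rarely document their
exact run definition, so these values are explicit, configurable stand-ins
rather than a reconstruction of any specific tool.

Two conventions are worth stating:

* **Region size** is `(end − start) / 1e6`, rounded half-up to one decimal —
  without the `+1`. This is the convention under which the printed bounds of
  both textbook candidate regions (Chr1: 11,698,902–26,171,473;
  Chr4: 71,230,491–83,403,217) reproduce their published sizes of 14.5 and
  12.2 Mb exactly.
* **Sharing** requires only overlapping homozygosity across affecteds, not
  identical alleles, matching how array-based viewers operate. Regions
  homozygous in unaffected siblings are *not* excluded by default, because
  exclusion logic is a study-design decision, not a property of the data.

## The coordinate frame: transcripts and HGVS arithmetic

Everything downstream of mapping depends on exact coordinate algebra between
genomic positions and coding-DNA (HGVS c.) positions. A `TranscriptModel`
holds exon intervals, strand, and the CDS bounds; validity checks enforce
sorted non-overlapping exons, CDS length divisible by 3, and (when sequence
is available) a single terminal stop codon. `cdsToGenomic` and
`genomicToCds` are mutual inverses, property-tested exhaustively over the
CDS and over whole introns, on both strands.

Conventions: coordinates are 1-based inclusive (BED output converts to
0-based half-open at the boundary); intronic positions use the nearer-exon
offset form, with exact-midpoint ties assigned to the 5′ exon's `+k` form;
UTR nomenclature (`c.-k`, `c.*k`) is rejected rather than half-supported.
Intronic offsets are only accepted from genuine exon/intron boundaries and
may not run past the far end of the intron.

`annotateDeletion` combines these pieces: the genomic span of a parsed
`c.<pos>_<pos>del` string, its intersection with the exon model (coding vs
intronic bases), frame status, and — when the removed coding run is
codon-aligned — the removed residue range read from the translated wild-type
CDS, e.g. `p.Tyr99_Glu177del`. In-frame deletions that cut within codons
are reported with a `junction` flag and no residue names (full HGVS indel
grammar is out of scope); frameshifts carry an `fs` marker; deletions
touching the initiator or terminator codon are flagged unsupported rather
than silently annotated. HGVS 3′-most normalization is available
(`normalize3prime = TRUE`) but off by default: breakpoints resolved by
sequencing are conventionally reported as observed.

## Coverage screening model

Per-exon mean depth is total read coverage over the exon divided by exon
length, with absent bases counting zero. The case is compared against a
panel of at least two control exomes processed identically: per exon the
panel mean/min/max and the ratio `case / panel_mean` are computed. An exon
is a `homozygous_deletion_candidate` when the ratio is at most `max_ratio`
(default 0.1) **and** the panel mean is at least `min_panel_depth` (default
10 reads/base); shallow panels give `low_confidence`, never a call. The
thresholds are chosen so that a truly deleted exon (case depth well under
1 read/base against a panel of hundreds) is always called while Poisson
noise at panel-scale depth never is; both are configurable.

Raw means are compared by default — no between-sample normalization — since
panels processed identically need none; a per-sample median-depth
normalization flag exists for unequal library sizes. The method is
deliberately homozygous-only: a heterozygous deletion halves depth (ratio
near 0.5) and is documented by tests as *not called* at defaults. Multi-exon
HMM segmentation of the XHMM/CoNIFER kind is a non-goal.

## Variant filter cascade

The cascade consumes a VCF annotated with three INFO keys — `DB129` (flag:
present in an early dbSNP build), `AF137` (float: allele frequency in a
later build), `FCLASS` (functional class) — so no live database access is
needed. Stages:

1. keep caller-PASS records inside the candidate regions (inclusive bounds);
2. drop records in the early dbSNP build or with MAF ≥ 1% (threshold
   inclusive, per the conventional wording of "≥1%"); unknown MAF is
   retained — conservative for discovery;
3. keep nonsynonymous, exonic indel, and splice-consensus classes, with the
   splice consensus read minimally as the canonical ±2 intronic
   dinucleotides;
4. flag (never remove) surviving indels whose sequence is a whole multiple
   of a tandem-repeat unit (≤ 6 bp) present ≥ 4 times in the reference
   abutting the breakpoint — likely repeat-number polymorphisms. Flagging
   mirrors the analyst's judgement call; automation should annotate, not
   decide.

Stage counts are book-kept in a `FilterReport` whose invariants (counts
non-increasing, drops + survivors = input) are enforced by the class
validity. The two annotation filters commute, and the repeat flag is
property-tested against a brute-force repeat-unit enumeration.

## What the synthetic data emulates — and what it does not

The generator produces every input with queryable ground truth:

* **Canonical toy gene**: a plus-strand 7-exon gene on a ~1.1 Mb toy
  chromosome; per-exon coding spans 60/60/60/60/54/237/813 nt (CDS 1344 nt =
  447 codons + stop), introns 500/500/500/500/1770/1000 bp, 50 bp terminal
  UTRs. Codon 99 is seeded TAT (Tyr) and codon 177 GAA (Glu). Under this
  geometry the deletion `c.294+139_531+478del` spans 2347 bp, removes the
  entire 237 bp sixth exon plus 2110 bp of flanking intron, and excises
  residues 99–177 — the worked example every test can check by hand. The
  1770 bp fifth intron is *back-derived* from those totals; it is a
  synthetic choice, not a claim about any real gene. Breakpoint-flanking
  20-mers are fixed aperiodic sequences, so 3′ normalization of the
  canonical deletion is provably a no-op.
* **Pedigree genotypes**: two marker chromosomes tiled at 5 kb; two shared
  autozygous segments (14.5 and 12.2 Mb, at the textbook bounds) planted in
  all three affected children of a 2-parent/6-child family, plus one private
  segment per affected. Background heterozygosity is 0.35 per marker.
  Genotyping error (rate 0.002) is modelled as an *allele swap* — a
  homozygous call recorded as the opposite homozygote. This preserves
  zygosity, so planted segments stay clean runs; models in which array error
  produces heterozygous or missing calls inside a ~2,900-marker segment
  would fragment every segment at the detector's default tolerances, so the
  het/missing tolerance is exercised by dedicated unit tests instead of the
  default simulation. No linkage disequilibrium, recombination-map realism,
  or allele-frequency spectrum is modelled.
* **Exon depth**: independent per-base Poisson draws at mean
  `mean_depth × copy_number / 2`; copy-0 exons receive sparse mis-mapping
  noise at 0.25% of the diploid mean, so a deleted exon shows ~0.6 reads/base
  rather than exactly zero. The fixture simulates the case at 230 reads/base
  and panels at 200/210/230/250/260, bracketing a realistic panel spread.
  Read-length autocorrelation is deliberately absent — depth at adjacent
  bases is independent, which makes exon means slightly *better* behaved
  than real data; recovery rates on real exomes will be somewhat noisier.
* **Annotated VCF**: 700 records shaped like a consanguineous exome screen —
  626 known/common, 45 rare silent, 20 outside the candidate regions, 8
  failing caller filters, and one rare exonic insertion of (CGG)5 planted at
  a reference (CGG)8 tract, which survives the cascade and receives the
  repeat flag. The cascade therefore shrinks 700 → 672 → 46 → 1 on the
  default fixture.

Every generator is deterministic given (parameters, seed); regenerating with
the same seed is bit-identical, which the tests assert. Because the noise
models are idealized (independent Poisson depth, zygosity-preserving
genotype error, no mapping bias), a green test suite demonstrates
correctness of the *computations*, not robustness to every artefact of real
exome data.

## Numerical and degenerate-input choices

* Region sizes and reported ratios round half-up (`14472571/1e6 → 14.5`),
  not banker's-style; verdicts are always computed on unrounded values.
* A panel mean of zero leaves the depth ratio undefined → `low_confidence`.
* An empty intersection of ROH sets is an empty result, not an error; an
  all-heterozygous sample yields no runs.
* `classifyPcrGenotype` treats products longer than `max_amplicon`
  (default 2000 bp) as not amplified, mirroring a long-range assay that only
  yields a product once the deletion collapses the template (794 bp here vs
  3141 bp on the wild-type allele); two completely silent assays signal
  assay failure, the role of the positive control on a genotyping gel.
* Config validation collects *all* problems (unknown keys get
  did-you-mean suggestions) instead of failing at the first.

## Problem sizes and runtime

The test suite runs the scanner-vs-brute-force equivalence on 200-marker
matrices, the planted-deletion recovery on 100 seeds (with the heterozygous
non-call companion property), the pedigree recovery on 20 seeds of the full
12,002-marker matrix, and one complete end-to-end fixture run; everything
completes in a couple of minutes on a single core. These sizes were chosen
as the smallest that still exercise every code path with meaningful
statistics.

## A complete run

```{r, eval = FALSE}
dir <- tempfile("fixture")
cfg <- writeFixture(dir, seed = 1)
report <- runDiscovery(cfg, out_dir = file.path(dir, "out"))
report
#> DiscoveryReport
#>   shared regions: 2
#>   filter cascade: 700 -> 672 -> 46 -> 1 survivor(s)
#>   deleted-exon candidates: 1
#>   consequence: p.Tyr99_Glu177del
```

## Known limitations

* Single-transcript genes, standard genetic code, deletions only; no
  duplications, insertions, inversions, or splice-effect scoring.
* Functional classes are consumed as annotations, never predicted from
  sequence.
* The coverage screen has no GC correction and, by design, no sensitivity to
  heterozygous losses.
* In-silico PCR is purely positional: perfect primer hybridization is
  assumed, with no thermodynamics or mismatch model.
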
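---
title: "Assessing exome-capture data quality outside target regions"
author: "offtargetQC"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Assessing exome-capture data quality outside target regions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Exome and targeted sequencing enrich a DNA library for a designed set of
capture intervals (the *target regions*), but enrichment is leaky: with
first-generation capture kits roughly half of all sequenced bases land
outside the targets, mostly in the flanks pulled down together with
on-target fragments and in a diffuse genome-wide background. Standard
practice discards everything off-target. `offtargetQC` quantifies what is
being discarded: it stratifies positions, reads and SNP genotype calls by
distance to the nearest target and measures, per stratum, the quality
signals a variant-calling pipeline cares about — depth, coverage breadth,
GC content, mapping and base qualities, the transition/transversion
(Ti/Tv) ratio, overlap with a known-variant catalogue, and genotype
concordance against an orthogonal SNP array.

## Region, read and SNP stratification

Positions fall into three classes relative to the merged target set:

* **inside** — within a target interval (distance 0);
* **near** — outside but within `D` bp of the nearest target (distance
  1..`D`, inclusive at `D`);
* **far** — more than `D` bp away, including chromosomes without targets.

Distance is counted in gap bases: the first base outside an interval has
distance 1, so "within 200 bp" means distance ≤ 200. The default
`D = 200` bp reflects typical capture insert sizes (150–200 bp): a
fragment overlapping a target edge rarely reaches further than one insert
length beyond it. The threshold is a parameter everywhere (`near =`), and
results are qualitatively stable at `D = 100`.

A read is classified by the majority of the bases of its *effective
reference span* — the interval obtained after applying soft clips and
walking the CIGAR (M/D/N/=/X consume reference; S/H/I do not). A read is
`inside` when at least half of its span bases have distance 0; otherwise
`near` when at least half are within `D` (distance-0 bases count toward
this, since they trivially satisfy "within `D`"); otherwise `far`. Ties
("at least half") go to the closer class, the natural reading of the
majority rule. SNP genotypes are classified by their site position alone.

## Quality measures

**Filters.** Reads: MAPQ ≥ 20 and duplicate-flagged reads removed.
Genotypes: GQ ≥ 20 and depth ≥ 5. These are the package defaults because
the threshold-sweep machinery (below) identifies them as the knee of the
consistency curve; all are arguments.

**Ti/Tv.** Among non-reference SNV genotypes, transitions (A↔G, C↔T)
divided by transversions. Random errors push Ti/Tv toward 0.5, so values
near the biological expectation (≈3 in exons, ≈2 genome-wide) indicate
clean calls. Genotypes are pooled across samples; with zero transversions
the ratio is reported as missing, never infinity.

**Known-variant overlap.** The fraction of called SNVs present in a
dbSNP-like catalogue, matched on position *and* alternate allele by
default (`match_alleles = FALSE` gives position-only matching).

**Concordance.** Overall consistency compares unordered genotypes at
sample-by-position entries present on both platforms. Heterozygote
consistency — the more error-sensitive measure — uses as denominator the
chip-heterozygous genotypes with a sequencing call of GQ ≥ 20, and as
numerator those where sequencing calls the same unordered heterozygote.
Because the VCF omits reference-homozygous sites, overall consistency has
two modes: `strict` compares only VCF-emitted genotypes, while `homref`
(the `run_study()` default) additionally scores chip positions covered at
depth ≥ 5 with no variant call as implied reference-homozygotes. In that
mode a homozygous chip genotype at such a position is credited as
agreement (its allele is taken to be the reference, since no variant was
emitted); genotypes that were emitted but *removed by quality filtering*
are excluded entirely — they are neither qualifying calls nor evidence
for hom-ref. Cohort summaries carry per-sample rates alongside pooled
counts.

**Strand imbalance.** Capture edges often leave positions covered by one
strand only. `strand_imbalance_consistency()` finds chip-covered
positions with depth ≥ 5 whose reads are all forward or all reverse and
reports concordance restricted to them, separating a capture artifact
from a genotype-quality problem.

**Boundary depth profile and decay.** Depth is averaged at signed offsets
−50..+200 bp around every target boundary (negative = inside). All
boundaries enter the average, including uncovered ones.
`estimate_enrichment_decay()` fits `depth = A·exp(−k·d) + B` to the
outside limb at d = 40..200 bp; distances below ~half a read length are
excluded because pileup smooths the profile across the boundary (the
smoothing rescales `A` but leaves `k` intact where the profile is purely
exponential). When given reads directly it restricts to *isolated*
boundaries (no other target within 700 bp on the outside), removing
contamination of the tail by neighbouring targets, and obtains the
standard error of `k` by bootstrap over boundaries — the pointwise
nonlinear-least-squares error is far too small because neighbouring
profile positions share the same reads.

## The simulator

`sim_config()` + `simulate_study()` generate a complete, deterministic
study — targets BED, coordinate-sorted SAM, multi-sample VCF, chip TSV,
known-sites TSV, gene-model BED and truth tables — with the statistical
structure the analysis assumes:

* **Geometry.** 5 Mb genome over 2 chromosomes with 2,000 targets of
  length 228 ± 60 bp (the geometry of a first-generation whole-exome
  kit, scaled down ~600-fold), spaced with exponential gaps so target
  spacing behaves like a Poisson process.
* **Enrichment.** Expected depth is 40× inside targets and
  `40·exp(−0.02 d) + 3` at distance `d` outside. The exponential form is
  a modelling choice (real boundary profiles are monotone but not
  exactly exponential); 0.02/bp makes enrichment decay over ~100–200 bp,
  commensurate with the 170 ± 30 bp inserts. A 3× far background gives
  the far stratum partial, shallow coverage, as observed in real
  captures. Two 300 bp far blocks at +200× emulate off-target homology
  pile-ups.
* **Reads.** 72 bp, paired flags with insert sizes 170 ± 30 bp plus a
  5.8% long tail beyond 500 bp; a MAPQ mixture with 8% below 20; 2%
  duplicate-flagged; 2% soft-clipped and 1% indel-containing CIGARs so
  the CIGAR-aware paths are always exercised. 5% of targets are forced
  single-strand. Read bases copy a synthetic genome whose GC probability
  is 0.506 inside targets and 0.464 elsewhere, reproducing the
  coding/noncoding GC contrast.
* **Variants.** SNVs at 1 per kb (a realistic per-individual
  heterozygosity scale); transition probability 0.75 for inside/near
  sites (Ti/Tv 3) and 2/3 far (Ti/Tv 2); 77% of sites in the known-site
  catalogue; 4 samples, each carrying a non-reference genotype at half
  the sites, two-thirds of them heterozygous. Per-sample depth is drawn
  from the positional depth surface, and GQ is an increasing, noisy
  function of depth (so GQ and depth are correlated, with a hard penalty
  below depth 5). Miscalls occur at 25% in the noisy stratum (GQ < 20 or
  depth < 5) and 0.3% otherwise — concentrating errors exactly where the
  default filters cut. The chip is error-free by default (it plays the
  truth role), covers 30% of polymorphic sites plus 2,000 invariant
  positions, and has a 0.5% no-call rate.

Everything derives from a single integer seed; identical configs give
byte-identical files. The truth tables include pileup depth by strand
both for all emitted reads and for the filter-passing subset, so
detection results can be compared to exact truth at either stage.

**What the simulator does not emulate:** per-base sequencing errors in
read strings, reference-genome realism (repeats, segmental duplication,
the homology that causes real high-depth far blocks), alignment
artifacts such as the BWA MAPQ discretisation, indel alignment
ambiguity, and population structure (sites are independent). Passing the
recovery tests therefore demonstrates that the *measurement* machinery is
correct and calibrated, not that real off-target data will reach any
particular quality.

## Numerical and design choices

* Coordinates are 0-based half-open internally; BED is read natively,
  SAM/VCF/chip positions are converted on input. Chromosome names are
  matched exactly; positions on unknown chromosomes are `far` so naming
  mismatches surface as obviously wrong stratification rather than
  silent drops.
* "Within D" is inclusive at exactly `D`.
* Multi-allelic VCF records are split into biallelic records; symbolic
  alleles are skipped with a warning. Allelic balance comes from AD
  (ref / (ref+alt)) and is missing when AD is absent.
* Per-class SNP counts tally distinct site-by-sample non-reference
  genotypes; per-sample means are reported alongside.
* The threshold sweep filters each axis marginally; for allelic balance
  it keeps `min(ab, 1−ab) ≥ t` since heterozygotes should sit near 0.5.
* Known-site membership is matched on position + alternate allele
  (position-only as an option) — the stricter definition, which can only
  lower the reported overlap.
* Indel sites are counted (distinct sites, site QUAL ≥ 1000 inclusive)
  but never validated or annotated; codon-level annotation is out of
  scope, positional annotation (exonic / splicing ≤ 2 bp from an exon
  boundary / ncRNA / intronic / intergenic, in that precedence) covers
  the rest.
* Test and acceptance runs use the default 5 Mb / 2,000-target / 40×
  conditions for recovery checks and a 0.2 Mb / 40-target configuration
  for unit fixtures — sizes chosen so that every stochastic recovery has
  enough events for a three-standard-error comparison while a complete
  run stays in the minutes range on one core.

## Limitations

The package consumes aligned reads and called variants; it performs no
alignment, duplicate marking, recalibration or variant calling, and no
liftover — coordinates are taken as given. GC content is computed from
the majority read base per covered position unless a reference is
integrated upstream, which slightly conflates sequencing composition
with genome composition at low depth. The hom-ref concordance mode rests
on the stated assumption about un-emitted sites; `strict` mode is
available where that assumption is unacceptable.
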
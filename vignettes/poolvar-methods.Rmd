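---
title: "poolvar: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{poolvar: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(poolvar)
```

## The problem

`poolvar` implements the analysis used in divergent-line pooled capture
sequencing: DNA from groups of birds (here ten diploid individuals per
pool) selected for extreme values of a phenotype — serum immunoglobulin
Y (IgY) level in two chicken breeds, White Leghorn (WL) and Beijing-You
(BY) — is pooled, enriched for target genomic regions, sequenced, and
screened for SNPs and indels. Because only pools are sequenced, the
observable quantity at a site is the pool-level allele fraction, not
individual genotypes. The scientific questions are set-theoretic: which
variants are breed-specific, which are specific to the high- or
low-phenotype group within a breed, which are shared by both breeds'
high (or low) groups, and which positions carry *different* mutations
in the two breeds' extreme groups.

The pipeline consumes standard interchange formats only — FASTA
reference, GFF3 gene models, samtools-style text pileups (one per
pool), BED target regions and a per-bird phenotype TSV — and emits
per-pool VCFs, an annotation table and the summary report tables.

## Calling model

Pileup sites are reduced to allele counts by a parser implementing the
documented samtools text grammar (`.`/`,` reference matches,
`ACGTacgt` mismatches, `+n<seq>`/`-n<seq>` indels on an anchor base,
`^X` read starts, `$` read ends, `*` placeholders; case is folded
because calling is strand-agnostic). Three gates produce calls per
pool:

1. **Coverage.** Site depth must be strictly greater than
   `min_depth_exclusive` (default 4, i.e. depth ≥ 5). The boundary is
   exclusive by deliberate, literal reading of the "coverage > 4"
   criterion.
2. **Allele fraction.** The modal non-reference allele (substitutions
   and indels compete; ties go to the lexicographically first
   substitution) must reach `het_fraction_min` (default 0.2). In a pool
   of 10 diploids, 0.2 corresponds to 4 of 40 chromosomes, comfortably
   above singleton carriers yet permissive enough for segregating
   variants.
3. **FDR.** Each candidate gets an upper-tail binomial p-value
   `P[X >= alt_count | X ~ Bin(depth, base_error_rate)]` — the chance
   that sequencing error alone (default rate 0.01 per base) produced at
   least the observed alternate count. Benjamini–Hochberg step-up at
   `fdr_q` (default 0.01) is applied jointly over all candidate sites
   of the pool; only survivors are emitted. The original analysis names
   an FDR threshold but not a procedure; BH over binomial tails is this
   package's documented, swappable stand-in, chosen because it is
   closed-form, reproducible and testable against a brute-force oracle.
   FDR control is applied per pool; whether the original was per-pool
   or global is unstated, and per-pool is the conservative reading for
   per-pool call sets.

Pool-level zygosity is a fraction heuristic: a call with alternate
fraction at or above `hom_fraction_min` (default 0.8) is classed
*pool-homozygous* (effectively fixed in the pool), otherwise
*pool-heterozygous* (segregating). The source analysis tabulates
homozygous/heterozygous pooled calls without defining the rule; 0.8 is
this package's choice, equivalent to at least 32 of 40 chromosomes
carrying the variant at the expected fraction.

Indel keys are canonicalised by left-alignment (shift the event left
while the anchor base equals the last base of the indel sequence), so
that identical events called in different pools compare exactly.

## Annotation model

Gene models are single-transcript and strand-aware. The proximal
promoter is defined as the 2000 bp immediately upstream of the TSS,
TSS excluded — `[tss-2000, tss-1]` on `+`, `[tss+1, tss+2000]` on `-`,
clipped at chromosome ends. For each gene whose body or promoter
overlaps a variant's reference footprint (a deletion spans its deleted
bases; an insertion sits on its anchor), the single most specific
component is reported with precedence CDS > UTR > intron > promoter —
but hits are kept for *every* overlapping gene. This dual reporting is
what handles overlapping gene pairs such as a 3'UTR nested in another
gene's intron (the chicken MHC-B *TAP1*/*BF1* situation), where one
deletion legitimately belongs to both genes.

Coding effects are computed for CDS SNPs only: the affected codon is
located by cumulative CDS position in transcription order (reverse
complemented on `-`), translated with the standard genetic code, and
classed synonymous or non-synonymous (stop gain/loss counts as
non-synonymous). Indels in CDS keep a class (insertion/deletion) and a
length, not a frameshift prediction — effect prediction for indels is
out of scope, matching the source analysis which reports indel
position only. Two summary flags serve the distribution tables:
`in_gene` (overlaps any gene body) and `in_mRNA` (overlaps any exon);
the source tables never define these columns, so this
operationalisation is stated in the report headers.

## Set algebra over the four pools

Calls from the pools BY-H, BY-L, WL-H, WL-L are joined into a presence
matrix by exact left-aligned key. Absence of a call is treated as
absence of the variant — there is no depth-aware missingness state;
this mirrors the presence/absence language of the source analysis and
is a documented limitation (a variant uncovered in one pool counts as
absent there). Seven categories partition the rows: for each breed,
*shared* (both its pools), *high-specific*, *low-specific* (given the
other breed has no call), and *both-breeds* otherwise.

Cross-breed common sets pair each WL group-specific variant (present
in that group's pool, absent from the breed's other pool) with a BY
group-specific variant: identical keys are *same-type*; SNPs at the
same `(chrom, pos, ref)` with different alternate alleles — and indels
with anchors within `indel_match_window` bp (default 10) — are
*different-type*. The window is a stand-in for the source's undefined
"same genomic regions" criterion and is config-exposed. Pairing is
greedy in sorted position order, each key joining at most one pair, so
counts are reproducible.

## The synthetic-data generator

The generator exists so that every stage is testable against a known
truth with no external data. It emulates the study conditions:

* four pools of 10 diploid individuals (allele fractions are multiples
  of 1/20),
* per-site Poisson depth with mean 30 (typical capture-seq coverage at
  this scale),
* uniform base-error noise at the configured rate, spread evenly over
  the three non-reference bases (binomial with a closed-form oracle),
* truth variants planted by category — breed-shared, breed
  high-/low-specific, cross-breed common-high/-low, and same-position
  different-allele SNP pairs split across the two breeds' high pools —
  with exact per-category counts,
* placement across CDS / promoter / UTR / intron / intergenic space by
  configurable weights (default near-uniform), with at least one gene
  pair whose 3'UTR/intron overlap reproduces the dual-annotation case,
* about 70% SNPs, the rest insertions and deletions of 1–9 bp.

The default design plants 200 variants on a 60 kb two-chromosome
genome with 8 genes; this size keeps a full four-pool
simulate–call–annotate–compare–report run under half a minute on one
CPU while exercising every category. What the generator does *not*
model: read-level artefacts (no FASTQ, no mapping bias), capture
efficiency variation, depth loss across deleted bases (deletions are
annotated on their anchor site only), multi-allelic segregation within
a pool, and linkage between neighbouring variants (planted footprints
are kept ≥20 bp apart). Tests passing on this generator therefore
validate the statistical and set-algebra machinery, not robustness to
alignment artefacts in real pileups.

Phenotypes are drawn lognormally per (breed, group) with targets
emulating a strong divergent contrast (high means about five to six
times low means), so the group-statistics and fold-change reports have
realistic inputs.

## Numerical and degenerate-input choices

* **Rounding.** All printed percentages, fold changes and Mb lengths
  round half-up (half away from zero), matching printed-table
  conventions; base R's half-to-even would disagree on exact ties.
* **Region lengths** are reported as `(end - start) / 1e6`: the
  coordinate difference, not the closed-interval length. The reference
  region table reproduces only under this convention, and at Mb scale
  the 1 bp is immaterial; the choice is documented rather than hidden.
* **Ties.** Modal-allele ties are broken lexicographically with
  substitutions preferred over indels; cross-breed pairing is greedy in
  sorted order. Both exist purely to make outputs deterministic.
* **Zero-depth sites** are omitted from pileups (as aligners do);
  empty call sets, empty common sets and empty gene lists propagate as
  empty tables rather than errors; a variant on a chromosome with no
  gene models is intergenic, not an error.
* **Seeds.** Every randomised operation takes an explicit seed and
  restores the caller's RNG state; stage seeds are derived from one
  master seed and recorded in the truth-file header and run manifest.
  Re-running with the same seed and config is byte-identical.

## Known limitations

* One transcript per gene; no splice-site classes; no frameshift or
  severity prediction.
* Presence/absence comparison has no power model: a variant below the
  calling gates in one pool is "absent" there, so category assignments
  inherit the caller's sensitivity. Under the noise-free default design
  recovery is exact (this is a tested invariant); under realistic noise
  the documented FDR bound applies per site-test, not per category.
* The binomial error model is a stand-in for the original caller's
  unpublished internals; absolute p-values should not be compared
  across error models, only the resulting call sets.
* Pool-level zygosity thresholds (0.2/0.8) are heuristics; with 10
  diploids per pool they are well separated from the 1/20 singleton
  fraction, but other pool sizes warrant revisiting them.
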
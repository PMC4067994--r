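---
title: "Exon-level CNV detection on targeted deafness panels: models and design"
author: "PanelCNV"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Exon-level CNV detection on targeted deafness panels}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(PanelCNV)
```

## The problem

Hereditary hearing loss is genetically heterogeneous, and a substantial
fraction of cases is caused not by point mutations but by copy number
variants (CNVs) — deletions, duplications, and gene–pseudogene
conversions — concentrated in genes that sit inside or near segmental
duplications, most prominently *STRC* on chromosome 15q15.3 and *OTOA*
on 16p12.2. Clinical panels capture all exons of the known deafness
genes and sequence them to hundreds- or thousands-fold coverage.
Because capture depth is proportional to local copy number after
suitable normalization, the same sequencing run that yields point
variants also carries the CNV signal, at exon-level resolution that
array platforms cannot reach. PanelCNV implements that read-depth
pipeline end to end: normalization, copy-state segmentation,
pseudogene-aware conversion calling, per-patient diagnostic
categorization, cohort summarization, and a repetitive-element burden
analysis of the panel's genes; plus a seeded cohort simulator so that
every stage is testable with known truth and without any patient data.

## The read-depth ratio model

Let $D_{st}$ be the mean depth of sample $s$ at capture target (exon)
$t$. Two nuisance factors dominate raw depth: per-sample library yield
and per-target capture efficiency. Both are removed by a fixed
two-step median contract (`normalizeByBatch()`):

1. **Library-size scaling.** $D'_{st} = D_{st} / \mathrm{median}_t(D_{s\cdot})$,
   cancelling the sample's overall yield.
2. **Batch referencing.** $R_{st} = D'_{st} / \mathrm{median}_{s' \in
   \mathrm{batch}(s)}(D'_{s't})$, cancelling the target's capture
   efficiency using the samples co-processed with $s$.

For a diploid target $R \approx 1$, and in general
$R \approx \mathrm{CN}/2$: a heterozygous deletion sits near 0.5, a
homozygous deletion near 0, a one-copy gain near 1.5. The batch median
is robust as long as fewer than half the batch shares the same CNV,
which is why a batch must contain at least two samples and realistic
batches contain dozens. Targets whose raw within-batch median depth
falls below `minDepth` (default 20x) give unstable ratios and are
masked rather than interpreted. Median-based normalization is exactly
invariant to per-sample scale factors, and each unmasked target's
within-batch median ratio is 1 by construction — both properties are
enforced as tests.

Whether batches coincide with sequencing pools or capture batches is a
laboratory decision; the batch label is caller-supplied and the method
is agnostic.

Per-target depth from per-position input (`readDepthTable()`) is the
mean over all bases of the target, with positions absent from the
table counted as zero — pileup output omits uncovered positions, so
this is the faithful reading. A median aggregation is available as an
option; MAPQ or other read filters are treated as properties of the
upstream pileup, not re-implemented here.

## Copy states, windows, and segmentation

Ratios are classified per target (`classifyTarget()`) with thresholds
placed midway between the ideal diploid levels: at or below 0.2 is a
homozygous deletion, up to 0.7 a heterozygous deletion, at or above
1.3 a duplication (1.8 separates one- from two-copy gains when
zygosity is assigned to duplications). The thresholds are
configurable; boundary values deliberately go to the more extreme
state so that a borderline exon is flagged for review rather than
silently normal.

A sliding median window (`slidingWindowSmooth()`) is measured in
targets, not base pairs, and never crosses gene boundaries or masked
targets: capture targets are discontiguous, and a window across genes
would manufacture artifacts. The default calling track is the
*unsmoothed* one (`w = 1`): panels detect genuine single-exon CNVs,
and any median filter erases them. The smoothed track (`w = 3`) is
kept as a quality-control annotation.

`segmentCalls()` turns maximal runs of identical non-normal states
into calls. Design points:

* **No minimum size.** Single-target calls are legitimate but carry a
  `single_exon` flag — the in-silico surrogate for the manual
  curation step a clinical laboratory applies. `curateCalls()` makes
  that step explicit: single-exon calls are retained only when their
  copy-number estimate is within 0.35 of a non-diploid integer, so a
  clean single-exon homozygous (cn ~ 0) or heterozygous (cn ~ 1)
  loss survives while a threshold-grazing fractional call (e.g. cn
  2.6) is removed, exactly as a reviewer would remove it. Multi-exon
  calls are never filtered. One systematic source of such grazing
  calls is worth naming: a sample carrying a large homozygous
  deletion has its own library median slightly depressed by the
  deleted targets, inflating all its other ratios by a few percent —
  a direct consequence of the fixed two-step median contract, which
  deliberately is not made CNV-aware.
* **Masked targets bridge runs** instead of splitting them, adding a
  `low_coverage_neighbor` flag.
* **Segdup artifact folding.** When a gene's tail lies in a
  high-identity segmental duplication, a true homozygous deletion
  looks heterozygous over those exons because reads from the
  undeleted duplicate locus are attributed there (the classic *OTOA*
  picture). A het-looking run lying entirely in segdup-flagged
  targets adjacent to a homozygous run is folded into one homozygous
  call with a `segdup_overlap` flag, rather than reported as two
  events.
* **Multi-gene contiguity.** Same-state calls in adjacent genes of one
  chromosome that reach the facing gene edges are annotated as a
  `multi_gene_contiguous` group — targeted data cannot place
  breakpoints between genes, so the group, not the per-gene calls, is
  the clinical unit (the chromosome 22 *MYH9*/*TRIOBP* situation).
* **Sex chromosomes.** Without sample sex, X-linked calls carry a
  `sex_chrom_unknown` flag and no zygosity; with `sex = "M"`,
  deletions on X are labelled hemizygous. No baseline re-scaling by
  batch sex composition is attempted — a documented limitation.

## Gene conversions and the STRC locus

A gene–pseudogene conversion moves sequence, and therefore reads,
from the gene to its pseudogene: gene targets lose copies, the
homologous pseudogene targets gain them, and total copy number is
conserved at four per exon pair. `detectConversions()` requires
(a) explicit partner links in the panel (panel designers know the
segdup structure; no sequence-homology inference is attempted),
(b) duplication coverage of at least `overlapFrac = 0.8` of the
deleted exons' partner images, and (c) reciprocity:
$|\mathrm{loss} - \mathrm{gain}| \le 0.6$ copies. The overlap and
tolerance defaults absorb depth noise and are configurable. The
allele count comes from the gene-side zygosity alone; a deletion
without a reciprocal pseudogene gain is never promoted to a
conversion. Exon spans are reported in panel order with no claim
about 5' or 3' orientation, which depth data cannot establish.

`diagnoseStrcLocus()` folds calls and conversions into per-allele
*STRC* status. Deafness-infertility syndrome (DIS) is set only for
homozygous loss of both *STRC* and *CATSPER2*; a deletion touching
only *CATSPER2* and the pseudogene leaves *STRC* intact, and a
biallelic *STRC* conversion is functionally null for *STRC* but
non-syndromic. *CATSPER2* involvement is reported as `NA` on panel
versions that do not tile it.

## Diagnostic categories and cohort summaries

`classifyCausative()` assigns one category per sample and gene by
precedence: homozygous deletion, then biallelic CNV (two abnormal
alleles not forming a homozygous deletion — deletion opposite
conversion, or both alleles converted), then a heterozygous CNV in
trans with a heterozygous pathogenic small variant, then membership
in a multi-gene contiguous deletion, else carrier. Recessive logic
requires two hit alleles. For dominant genes a single heterozygous
CNV is never automatically causative: the package emits a review flag
and a reading-frame hint (summed deleted exon lengths modulo 3) and
leaves the decision to expert review, mirroring clinical practice.

Cohort tallies (`summarizeCohort()`) count CNVs per affected allele —
a homozygous event is two records — which is the convention that makes
carrier allele frequencies (`carrierFrequency()`: alleles over twice
the individuals tested) read directly off the same table. All
percentages round half-away-from-zero at the printed precision:
integers in the per-gene table, one decimal for cohort scalars.

The packaged reference cohort (`deafnessCohortFixture()`) encodes the
published aggregate CNV spectrum of a 686-patient comprehensive
deafness-panel screen: per-gene totals, carrier/causative splits,
class totals, patient counts and the causative-category structure.
Only those marginals are meaningful. The assignment of carrier CNVs
to individual synthetic patients is under-determined by aggregates
alone, so one consistent assignment is frozen. One reconciliation was
unavoidable: the published causative CNV total exceeds by two the
allele count implied by the published category split (21 homozygous
patients x 2 + 16 hemizygous x 1 + 12 biallelic x 2 + 2 contiguous
= 84, against 86); the fixture places the two surplus causative
deletion records with two hemizygous-category *STRC* patients so that
every published figure is reproduced simultaneously. Similar
small tensions exist elsewhere in the published figures (an *OTOA*
class split quoted in prose that does not sum to its table row; a
dominant-gene deletion described as causative in prose but tallied as
carrier) and in each case the fixture follows the table.

## The cohort simulator

`simulateCohort()` emulates the data regime of targeted enrichment:

* batches filled in sample order, up to 48 per batch (one flow-cell
  pool);
* base depth 700x — the hundreds-to-thousands-fold coverage regime of
  diagnostic capture;
* per-target capture efficiency log-normal with sd 0.3 and per-sample
  library factor log-normal with sd 0.2: several-fold efficiency
  spread between probes and tens-of-percent yield spread between
  libraries, typical of capture experiments;
* depth negative-binomial. The `dispersion` parameter is the
  *per-sequenced-position* NB size: each base of a target of length
  $L$ is an independent NB draw and the reported per-target depth is
  their mean, drawn exactly as $\mathrm{NB}(L\mu, L \cdot
  \mathrm{size})/L$. This matches what a pileup actually delivers —
  per-position depths later averaged per target — and makes the
  per-target coefficient of variation shrink with target length, as
  real capture data do. At the defaults (700x, dispersion 10, 100-200
  bp targets) the per-target CV is about 2-3%, comfortably separating
  the copy-state bands. Treating positions as independent understates
  the within-read correlation of real coverage, so simulated noise is
  somewhat optimistic; GC content and mappability structure are not
  modelled at all. Passing tests on this generator therefore
  demonstrates the correctness of the machinery under its stated
  noise model, not performance on adversarial real-world capture.

Spiked events (`spikeEvent()`) define truth: deletions and
duplications shift the expected copy number of the gene's targets;
conversions move copies to the pseudogene partners reciprocally.
The same seed reproduces a cohort bit for bit.

## Validation design and problem sizes

The test suite pins every numeric core to an independent brute-force
oracle: two-step median normalization (random 30x10 matrices, 1e-12),
windowed medians, segmentation against run-length encoding over all
4^6 state vectors of a six-exon gene, interval overlap counting
against all-pairs scans, and Welch's t against the closed form
(1e-10). Calling performance is measured on simulated cohorts, always through
the full pipeline of calling followed by curation: 50
seeded 24-sample batches with spiked deletions (homozygous from one
exon, heterozygous from two) for sensitivity and false calls; a
64-sample cohort with four homozygous and four heterozygous
*STRC*-region deletions as an in-silico stand-in for orthogonal
probe-assay (MLPA-style) confirmation; and spiked conversions checked
for the reciprocal signature and single-event reporting. These sizes
keep the full suite in the minutes range while giving the binomial
checks (e.g. 300 spiked events for sensitivity) reasonable
resolution. Single-exon heterozygous events sit closest to the
threshold and their recovery is reported rather than asserted.

## Known limitations

* Breakpoints outside captured exons are unobservable; event sizes are
  bounded by target extent only.
* No GC or mappability correction; the batch median absorbs shared
  bias but not sample-specific GC effects.
* The paired mode of the burden comparison is retained for fidelity
  experiments, but between a small CNV-associated group and the rest
  of a panel no natural pairing exists; the package defaults to
  Welch's unequal-variance test and reports group sizes alongside.
* Segdup flags are panel annotations; the caller does not compute
  sequence identity.
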
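# PanelCNV

Exon-level copy number variant (CNV) detection from targeted genomic
enrichment sequencing depth, built for clinical deafness gene panels —
the setting in which deletions of the *STRC* region, gene–pseudogene
conversions inside segmental duplications, and single- to multi-exon
deletions in recessive deafness genes account for a large share of
molecular diagnoses.

## What it computes

For a panel of exon targets and a samples-by-targets depth matrix
(pileup-derived), PanelCNV:

1. **Normalizes depth to copy-number ratios** by a fixed two-step
   median contract: per-sample library scaling
   `D'[s,t] = D[s,t] / median_t D[s,·]`, then batch referencing
   `R[s,t] = D'[s,t] / median_{s' in batch} D'[s',t]`, so that
   `R ≈ CN/2` (diploid 1, het deletion 0.5, hom deletion 0). A
   sliding median window (in exons, never crossing genes) is kept as a
   QC track; calling uses the unsmoothed track so single-exon events
   survive.
2. **Segments copy states into calls** with thresholds 0.2 / 0.7 / 1.3
   on the ratio, QC flags (`single_exon`, `segdup_overlap`,
   `low_coverage_neighbor`, `multi_gene_contiguous`), folding of
   segdup-masked deletion tails (the *OTOA* artifact), and an explicit
   curation step for threshold-grazing single-exon calls.
3. **Reinterprets reciprocal deletion/duplication pairs as gene
   conversions** over panel-defined gene–pseudogene partner links
   (gene loss ≈ pseudogene gain, copies conserved at 4), and
   diagnoses the *STRC*/*CATSPER2* locus per allele, including the
   deafness-infertility syndrome (DIS) verdict for homozygous loss of
   both genes.
4. **Assigns per-patient causative categories** (homozygous CNV,
   biallelic CNV, het CNV in trans with a pathogenic small variant,
   multi-gene contiguous deletion, carrier), summarizes cohorts into
   per-gene tables with carrier allele frequencies (alleles over
   2 × individuals tested), and
5. **Quantifies repetitive-element burden** (segdups > 95% identity,
   Alu, L1, simple repeats; counts per kb of gene) with Welch
   two-sample comparison between CNV-associated and other genes.

A seeded negative-binomial cohort simulator (`simulateCohort()`) with
spiked deletions, duplications and conversions makes the entire
pipeline testable without patient data, and
`deafnessCohortFixture()` packages the aggregate CNV spectrum of a
published 686-patient comprehensive deafness screen for the
summarization machinery.

## Worked example

```r
library(PanelCNV)

panel <- examplePanel()   # 150-target demo deafness panel, built in code
cfg <- simulationConfig(nSamples = 24, seed = 7, events = list(
  spikeEvent("S003", "STRC", c(19, 29), "conversion", 2),  # biallelic
  spikeEvent("S005", "TMC1", c(14, 15), "deletion", 1)))   # two-exon het
sim  <- simulateCohort(cfg, panel)
cov  <- normalizeByBatch(sim$coverage)
calls <- curateCalls(callCnvs(cov))
dc   <- detectConversions(calls, panel)

dc$residual[, c("sample_id", "gene", "first_exon", "last_exon",
                "cnv_class", "zygosity", "copy_number")]
#>   sample_id gene first_exon last_exon cnv_class zygosity copy_number
#> 3      S005 TMC1         14        15  deletion      het        1.01

dc$conversions
#>   sample_id gene pseudogene first_exon last_exon alleles cn_gene cn_pseudo
#> 1      S003 STRC      PSTRC         19        29       2       0      3.96
```

The two-exon *TMC1* deletion comes back at copy number ~1
(heterozygous), and the spiked biallelic *STRC* conversion is
reported as one conversion event — gene side at copy 0, pseudogene
side at copy ~4 — rather than as an unexplained deletion plus
duplication pair.

Cohort summarization on the packaged reference cohort:

```r
fx <- deafnessCohortFixture()
summarizeCohort(fx$records, fx$nTested, fx$nDiagnosed)
#> Cohort CNV summary: 143 CNVs in 104 of 686 patients (15.2%)
#>   causative in 50 of 267 diagnosed patients (18.7%)
#>   class split: 64.3% deletions, 26.6% conversions, 9.1% duplications
#>   gene total_cnvs carrier_cnvs causative_cnvs deletions conversions
#>   STRC        105           35             70        65          35
#>   OTOA         18           11              7        12           3
#>   ...
```

15.2% of tested patients carry at least one CNV; CNVs are involved in
18.7% of all molecular diagnoses; *STRC* alone accounts for 73% of
CNVs, with carrier allele frequencies of 4.7% (deletions), 2.6%
(conversions) and 0.4% (duplications).

A thin command-line wrapper with `simulate`, `call`, `summarize` and
`burden` subcommands is installed at `inst/scripts/otocnv.R`.

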
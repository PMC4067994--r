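mkCall <- function(sample, gene, cls, zyg, first = 1L, last = 2L,
                   flags = "") {
  data.frame(sample_id = sample, gene = gene, chrom = "chr1",
             start = 0L, end = 100L, first_exon = first, last_exon = last,
             cnv_class = cls, zygosity = zyg,
             mean_ratio = if (identical(zyg, "hom")) 0.01 else 0.5,
             n_targets = last - first + 1L,
             copy_number = if (identical(zyg, "hom")) 0.02 else 1,
             flags = flags, contig_group = "", stringsAsFactors = FALSE)
}
mkConv <- function(sample, gene, alleles) {
  data.frame(sample_id = sample, gene = gene, pseudogene = "PSTRC",
             first_exon = 19L, last_exon = 29L, alleles = alleles,
             cn_gene = 2 - alleles, cn_pseudo = 2 + alleles,
             stringsAsFactors = FALSE)
}
noConv <- function() PanelCNV:::emptyConversions()
noCalls <- function() PanelCNV:::emptyCnvCalls()

test_that("causative categories follow the diagnostic precedence", {
  p <- examplePanel()
  snv <- data.frame(sample_id = "S2", gene = "TMC1", chrom = "chr9",
                    pos = 100L, ref = "G", alt = "A", zygosity = "het",
                    pathogenic = TRUE, stringsAsFactors = FALSE)

  # homozygous whole-gene deletion in a recessive gene
  a <- classifyCausative(mkCall("S1", "OTOA", "deletion", "hom"),
                         noConv(), NULL, p)
  expect_identical(a$category, "hom_cnv")
  expect_true(a$inheritance_consistent)

  # het deletion in trans with a het pathogenic missense, same gene
  a <- classifyCausative(mkCall("S2", "TMC1", "deletion", "het",
                                first = 14L, last = 15L),
                         noConv(), snv, p)
  expect_identical(a$category, "hemizygous_cnv_plus_snv")

  # without the small variant the same call is carrier-only
  a <- classifyCausative(mkCall("S2", "TMC1", "deletion", "het",
                                first = 14L, last = 15L),
                         noConv(), NULL, p)
  expect_identical(a$category, "carrier_only")

  # deletion on one allele, conversion on the other
  a <- classifyCausative(mkCall("S3", "STRC", "deletion", "het"),
                         mkConv("S3", "STRC", 1L), NULL, p)
  expect_identical(a$category, "biallelic_cnv")

  # both alleles converted
  a <- classifyCausative(noCalls(), mkConv("S4", "STRC", 2L), NULL, p)
  expect_identical(a$category, "biallelic_cnv")

  # hom deletion outranks an additional conversion
  a <- classifyCausative(mkCall("S5", "STRC", "deletion", "hom"),
                         mkConv("S5", "STRC", 1L), NULL, p)
  expect_identical(a$category, "hom_cnv")

  # multi-gene contiguous het deletion
  a <- classifyCausative(mkCall("S6", "TRIOBP", "deletion", "het",
                                flags = "multi_gene_contiguous"),
                         noConv(), NULL, p)
  expect_identical(a$category, "contiguous_multi_gene")
})

test_that("dominant genes are never auto-called on one het CNV", {
  p <- examplePanel()
  a <- classifyCausative(mkCall("S1", "MYH9", "deletion", "het",
                                first = 1L, last = 3L),
                         noConv(), NULL, p)
  expect_identical(a$category, "carrier_only")
  expect_true(a$needs_review)
  expect_true(a$inheritance_consistent)  # one AD hit can cause disease
  # frame annotation from summed exon lengths
  expect_true(a$frame %in% c("in_frame", "out_of_frame"))
})

test_that("a small variant in an off-panel gene is an error", {
  p <- examplePanel()
  snv <- data.frame(sample_id = "S1", gene = "NOTAGENE", chrom = "chr1",
                    pos = 1L, ref = "A", alt = "T", zygosity = "het",
                    pathogenic = TRUE, stringsAsFactors = FALSE)
  expect_error(classifyCausative(mkCall("S1", "OTOA", "deletion", "het"),
                                 noConv(), snv, p),
               "absent from panel")
})

test_that("cnvRecords expands zygosity and conversion alleles to alleles", {
  p <- examplePanel()
  calls <- rbind(mkCall("S1", "OTOA", "deletion", "hom"),
                 mkCall("S2", "STRC", "deletion", "het"))
  conv <- mkConv("S3", "STRC", 2L)
  asg <- classifyCausative(calls, conv, NULL, p)
  rec <- cnvRecords(calls, conv, asg)
  expect_identical(nrow(rec), 2L + 1L + 2L)
  expect_identical(sum(rec$cnv_class == "deletion"), 3L)
  expect_identical(sum(rec$cnv_class == "conversion"), 2L)
  expect_identical(sum(rec$causative), 4L)  # hom OTOA + biallelic conv
})

test_that("cohort tallies equal a brute-force counting oracle", {
  set.seed(13)
  genes <- c("G1", "G2", "G3")
  classes <- c("deletion", "conversion", "duplication")
  for (rep in 1:5) {
    n <- sample(20:60, 1)
    rec <- data.frame(
      patient = sprintf("P%02d", sample(30, n, replace = TRUE)),
      gene = sample(genes, n, replace = TRUE),
      cnv_class = sample(classes, n, replace = TRUE),
      causative = sample(c(TRUE, FALSE), n, replace = TRUE),
      stringsAsFactors = FALSE)
    rec$category <- ifelse(rec$causative, "hom_cnv", "carrier_only")
    s <- summarizeCohort(rec, nTested = 100, nDiagnosed = 50)
    for (g in genes) {
      row <- s$byGene[s$byGene$gene == g, ]
      expect_identical(row$total_cnvs, sum(rec$gene == g))
      expect_identical(row$causative_cnvs, sum(rec$gene == g & rec$causative))
      expect_identical(row$carrier_cnvs, sum(rec$gene == g & !rec$causative))
      for (cl in classes) {
        col <- c(deletion = "deletions", conversion = "conversions",
                 duplication = "duplications")[[cl]]
        expect_identical(row[[col]], sum(rec$gene == g & rec$cnv_class == cl))
      }
    }
    expect_identical(s$scalars$n_patients_with_cnv,
                     length(unique(rec$patient)))
    expect_identical(s$scalars$n_cnv_diagnosed,
                     length(unique(rec$patient[rec$causative])))
    # allele conservation: class columns partition total per gene
    expect_true(all(s$byGene$deletions + s$byGene$conversions +
                    s$byGene$duplications == s$byGene$total_cnvs))
  }
})

test_that("an empty record set summarizes to zeroes", {
  rec <- deafnessCohortFixture()$records[0, ]
  s <- summarizeCohort(rec, nTested = 10, nDiagnosed = 5)
  expect_identical(nrow(s$byGene), 0L)
  expect_identical(s$scalars$n_cnvs, 0L)
  expect_equal(s$scalars$overall_carrier_freq_pct, 0)
  expect_error(summarizeCohort(rec, nTested = 5, nDiagnosed = 6),
               "exceed")
})

test_that("carrier frequency counts alleles over twice the cohort", {
  fx <- deafnessCohortFixture()
  expect_equal(carrierFrequency(fx$records, 686, "STRC", "deletion"),
               65 / 1372)
  expect_equal(carrierFrequency(fx$records, 686, "STRC", "conversion"),
               35 / 1372)
  expect_equal(carrierFrequency(fx$records, 10, "NOPE", "deletion"), 0)
  expect_error(carrierFrequency(fx$records, 0, "STRC", "deletion"),
               "positive")
  # call-table route: hom events contribute two alleles
  calls <- rbind(mkCall("S1", "G", "deletion", "hom"),
                 mkCall("S2", "G", "deletion", "het"))
  expect_equal(carrierFrequency(calls, 10, "G", "deletion"), 3 / 20)
})

test_that("carrier frequencies agree with simulated truth alleles", {
  p <- examplePanel()
  ev <- list(spikeEvent("S001", "TMC1", c(1, 24), "deletion", 2),
             spikeEvent("S002", "TMC1", c(1, 24), "deletion", 1),
             spikeEvent("S003", "TMC1", c(2, 9), "deletion", 1))
  sim <- simulateCohort(simulationConfig(nSamples = 24, seed = 21,
                                         events = ev), p)
  calls <- callCnvs(normalizeByBatch(sim$coverage))
  truthAlleles <- sum(vapply(ev, `[[`, integer(1), "alleles"))
  expect_equal(carrierFrequency(calls, 24, "TMC1", "deletion"),
               truthAlleles / 48)
})

test_that("half-away-from-zero rounding matches the printed convention", {
  expect_equal(roundHalfUp(c(0.5, 1.5, 2.5, -0.5)), c(1, 2, 3, -1))
  expect_equal(roundHalfUp(20.85, 1), 20.9)
  expect_equal(roundHalfUp(c(143 / 686, 104 / 686) * 100, 1), c(20.8, 15.2))
})
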
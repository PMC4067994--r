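test_that("panel BED parsing builds targets with exon ordinals and links", {
  bed <- tempfile(fileext = ".bed")
  writeLines(c(
    "chr1\t100\t200\tG1|1",
    "chr1\t300\t400\tG1|2",
    "chr1\t500\t600\tG1|3"
  ), bed)
  p <- readPanelBed(bed)
  tg <- panelTargets(p)
  expect_s4_class(p, "CnvPanel")
  expect_length(tg, 3L)
  expect_identical(S4Vectors::mcols(tg)$exon_index, 1:3)
  expect_identical(GenomicRanges::start(tg), c(101L, 301L, 501L))

  # pseudo_partner pass-through (both sides present so links resolve)
  bed2 <- tempfile(fileext = ".bed")
  writeLines(c(
    "chr15\t100\t200\tPSTRC|29",
    "chr15\t5000\t5100\tSTRC|29|PSTRC_29"
  ), bed2)
  p2 <- readPanelBed(bed2)
  mc <- S4Vectors::mcols(panelTargets(p2))
  expect_identical(mc$pseudo_partner[mc$gene == "STRC"], "PSTRC_29")
})

test_that("malformed panel BED lines are rejected with line numbers", {
  bed <- tempfile(fileext = ".bed")
  writeLines(c("chr1\t100\t200\tG1|1", "chr1\t500\t400\tG1|2"), bed)
  expect_error(readPanelBed(bed), "line 2")
  writeLines(c("chr1\t100\t200\tG1"), bed)
  expect_error(readPanelBed(bed), "exon_index")
  bed3 <- tempfile(fileext = ".bed")
  writeLines("chr1\t100\t200\tG1|1|NOPE_9", bed3)
  expect_error(readPanelBed(bed3), "dangling")
  expect_error(readPanelBed(tempfile()), "not found")
})

test_that("panel read -> write -> read is the identity", {
  p <- examplePanel()
  f <- tempfile(fileext = ".bed")
  writePanelBed(p, f)
  p2 <- readPanelBed(f, geneMetadata = panelGenes(p), name = panelName(p))
  asdf <- function(x) {
    df <- as.data.frame(panelTargets(x))
    df$seqnames <- as.character(df$seqnames)  # levels reflect input order
    df$strand <- NULL
    df
  }
  expect_identical(asdf(p2), asdf(p))
  expect_identical(panelGenes(p2), panelGenes(p))
})

test_that("per-position depth aggregates to per-target means", {
  bed <- tempfile(fileext = ".bed")
  writeLines(c("chr1\t100\t200\tG1|1", "chr1\t300\t303\tG1|2"), bed)
  p <- readPanelBed(bed)
  f <- tempfile(fileext = ".tsv")
  df <- rbind(
    data.frame(sample = "S1", chrom = "chr1", pos = 101:200, depth = 500),
    data.frame(sample = "S1", chrom = "chr1", pos = 301:303,
               depth = c(100, 200, 300)),
    data.frame(sample = "S1", chrom = "chr1", pos = 999, depth = 7)
  )
  write.table(df, f, sep = "\t", quote = FALSE, row.names = FALSE)
  suppressMessages(cov <- readDepthTable(f, p))
  d <- depthMatrix(cov)
  expect_equal(unname(d["G1_1", "S1"]), 500)   # uniform coverage
  expect_equal(unname(d["G1_2", "S1"]), 200)   # mean of 100,200,300
  # the off-target position is excluded, not attributed anywhere
  expect_equal(sum(d), 700)
})

test_that("per-target mean matches a brute-force per-base oracle", {
  set.seed(42)
  p <- tinyPanel()
  tg <- panelTargets(p)
  rows <- list()
  for (t in sample(seq_along(tg), 5)) {
    pos <- GenomicRanges::start(tg)[t]:GenomicRanges::end(tg)[t]
    rows[[length(rows) + 1L]] <- data.frame(
      sample = "S1", chrom = as.character(GenomicRanges::seqnames(tg)[t]),
      pos = pos, depth = rpois(length(pos), 300))
  }
  df <- do.call(rbind, rows)
  f <- tempfile(fileext = ".tsv")
  write.table(df, f, sep = "\t", quote = FALSE, row.names = FALSE)
  suppressMessages(cov <- readDepthTable(f, p))
  d <- depthMatrix(cov)
  for (tid in rownames(d)) {
    t <- match(tid, S4Vectors::mcols(tg)$target_id)
    pos <- GenomicRanges::start(tg)[t]:GenomicRanges::end(tg)[t]
    expected <- sum(df$depth[df$pos %in% pos &
                    df$chrom == as.character(GenomicRanges::seqnames(tg)[t])]) /
      length(pos)
    expect_equal(unname(d[tid, "S1"]), expected)
  }
})

test_that("depth table errors and warnings fire on bad input", {
  p <- tinyPanel()
  f <- tempfile(fileext = ".tsv")
  write.table(data.frame(sample = "S1", chrom = "chr1", pos = 1001,
                         depth = -3),
              f, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(readDepthTable(f, p), "negative depth")
  write.table(data.frame(sample = "S1", chrom = "chr99", pos = 10,
                         depth = 5),
              f, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_warning(readDepthTable(f, p), "skipped")
})

test_that("matrix-layout depth tables round-trip through write/read", {
  p <- tinyPanel()
  sim <- simulateCohort(simulationConfig(nSamples = 4, seed = 3), p)
  f <- tempfile(fileext = ".tsv")
  writeDepthTable(sim$coverage, f)
  cov2 <- readDepthTable(f, p)
  expect_equal(depthMatrix(cov2), depthMatrix(sim$coverage))
})

test_that("CNV call tables round-trip through TSV", {
  # empty call set -> header-only file
  f <- tempfile(fileext = ".tsv")
  writeCnvCalls(PanelCNV:::emptyCnvCalls(), f)
  expect_length(readLines(f), 1L)
  expect_identical(nrow(readCnvCalls(f)), 0L)

  p <- examplePanel()
  sim <- simulateCohort(simulationConfig(
    nSamples = 12, seed = 11,
    events = list(spikeEvent("S001", "OTOA", c(1, 28), "deletion", 2),
                  spikeEvent("S002", "TMC1", c(3, 7), "deletion", 1),
                  spikeEvent("S003", "GJB2", c(1, 2), "duplication", 1))), p)
  calls <- callCnvs(normalizeByBatch(sim$coverage))
  expect_gt(nrow(calls), 2L)
  writeCnvCalls(calls, f)
  back <- readCnvCalls(f)
  expect_equal(back, calls, ignore_attr = TRUE)
})

test_that("whole-gene homozygous deletions export to symbolic-ALT VCF", {
  p <- examplePanel()
  sim <- simulateCohort(simulationConfig(
    nSamples = 6, seed = 5,
    events = list(spikeEvent("S001", "OTOA", c(1, 28), "deletion", 2))), p)
  calls <- callCnvs(normalizeByBatch(sim$coverage))
  expect_identical(calls$cnv_class, "deletion")
  expect_identical(calls$zygosity, "hom")
  f <- tempfile(fileext = ".vcf")
  writeCnvCalls(calls, f, format = "vcf")
  vcf <- readLines(f)
  body <- vcf[!startsWith(vcf, "#")]
  expect_length(body, 1L)
  expect_match(body, "<DEL>")
  expect_match(body, "END=")
  expect_match(body, "SVCLASS=deletion")
})

test_that("small variants are read from VCF with zygosity and gene", {
  p <- examplePanel()
  tg <- panelTargets(p)
  tmcPos <- GenomicRanges::start(tg)[S4Vectors::mcols(tg)$gene == "TMC1"][1]
  f <- tempfile(fileext = ".vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##INFO=<ID=PATHOGENIC,Number=0,Type=Flag,Description=\"asserted\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\tS1\tS2",
    sprintf("chr9\t%d\t.\tG\tA\t.\tPASS\tPATHOGENIC\tGT\t0/1\t1/1", tmcPos),
    "chr1\t5\t.\tT\tC\t.\tPASS\t.\tGT\t0/0\t0/1"
  ), f)
  sv <- readSmallVariants(f, p)
  expect_identical(nrow(sv), 3L)
  s1 <- sv[sv$sample_id == "S1", ]
  expect_identical(s1$zygosity, "het")
  expect_identical(s1$gene, "TMC1")
  expect_true(s1$pathogenic)
  s2 <- sv[sv$sample_id == "S2", ]
  expect_setequal(s2$zygosity, c("hom", "het"))
  expect_true(is.na(s2$gene[s2$chrom == "chr1"]))
  expect_false(s2$pathogenic[s2$chrom == "chr1"])
})

test_that("RepeatMasker .out and repeat BED readers map families", {
  f <- tempfile(fileext = ".out")
  writeLines(c(
    "   SW   perc perc perc  query     position in query    matching repeat",
    "score   div. del. ins.  sequence  begin end (left)     repeat class/family",
    "",
    "  463   12.4  0.0  0.0  chr1      101   400 (0) +  AluYa5  SINE/Alu     1 300 (0) 1",
    "  999    8.1  0.0  0.0  chr1      901  1400 (0) C  L1PA3   LINE/L1      1 500 (0) 2",
    "   55    2.0  0.0  0.0  chr2       11    60 (0) +  (TG)n   Simple_repeat 1 50 (0) 3",
    "  120   20.0  0.0  0.0  chr2      201   300 (0) +  MER5    DNA/hAT      1 100 (0) 4"
  ), f)
  rm <- readRepeatMasker(f)
  expect_identical(S4Vectors::mcols(rm)$family,
                   c("Alu", "L1", "simple_repeat", "other"))
  expect_equal(S4Vectors::mcols(rm)$identity_pct[1], 100 - 12.4)
  expect_identical(GenomicRanges::start(rm)[1], 101L)

  fb <- tempfile(fileext = ".bed")
  writeLines("chr1\t100\t5000\tsegdup\t99.2", fb)
  sd <- readRepeatBed(fb)
  expect_identical(S4Vectors::mcols(sd)$family, "segdup")
  expect_equal(S4Vectors::mcols(sd)$identity_pct, 99.2)
  writeLines("chr1\t100\t5000\tweird", fb)
  expect_error(readRepeatBed(fb), "unknown repeat family")
})

test_that("ratio track export carries midpoints and masks per gene", {
  p <- tinyPanel()
  sim <- simulateCohort(simulationConfig(nSamples = 4, seed = 2), p)
  cov <- normalizeByBatch(sim$coverage)
  tr <- ratioTrack(cov, "S001", genes = "A")
  expect_identical(nrow(tr), 6L)
  expect_identical(tr$exon_index, 1:6)
  expect_true(all(tr$ratio > 0))
  expect_error(ratioTrack(cov, "nope"), "unknown sample")
})
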
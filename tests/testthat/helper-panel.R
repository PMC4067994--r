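# Shared fixtures, built in code.

# A small panel exercising every structural feature: plain genes, an
# AD gene adjacent to another gene on one chromosome, a gene/pseudogene
# pair, a gene with a segdup tail, and an X-linked gene.
tinyPanel <- function() {
  mk <- function(chrom, gene, n, at, w = 100L, gap = 400L,
                 segdup = integer(0)) {
    start <- at + (seq_len(n) - 1L) * (w + gap)
    data.frame(chrom = chrom, start = start, end = start + w, gene = gene,
               exon = seq_len(n), segdup = seq_len(n) %in% segdup,
               stringsAsFactors = FALSE)
  }
  df <- rbind(
    mk("chr1", "A", 6L, 1000L),
    mk("chr1", "B", 4L, 20000L),
    mk("chr2", "PC", 5L, 5000L, segdup = 1:5),
    mk("chr2", "C", 5L, 50000L, segdup = 1:5),
    mk("chr3", "D", 10L, 1000L, segdup = 8:10),
    mk("chrX", "XG", 3L, 1000L)
  )
  partner <- rep(NA_character_, nrow(df))
  partner[df$gene == "C"] <- paste0("PC_", df$exon[df$gene == "C"])
  partner[df$gene == "PC"] <- paste0("C_", df$exon[df$gene == "PC"])
  gr <- GenomicRanges::GRanges(df$chrom,
                               IRanges::IRanges(df$start + 1L, df$end))
  S4Vectors::mcols(gr) <- S4Vectors::DataFrame(
    gene = df$gene, exon_index = df$exon,
    target_id = paste(df$gene, df$exon, sep = "_"),
    pseudo_partner = partner, segdup_flag = df$segdup)
  genes <- data.frame(
    symbol = c("A", "B", "PC", "C", "D", "XG"),
    inheritance = c("AR", "AD", "AR", "AR", "AR", "XL"),
    nshl_mimic = FALSE, stringsAsFactors = FALSE)
  CnvPanel("tiny", gr, genes)
}

# Coverage object with a ratio assay injected directly, for caller tests
# that want exact ratios rather than simulated depth.
makeRatioCoverage <- function(panel, ratios, masked = NULL, batch = "b1") {
  depth <- ratios
  depth[!is.finite(depth)] <- 1
  cov <- PanelCoverage(depth * 500, panel, batch = batch)
  SummarizedExperiment::assay(cov, "ratio") <- ratios
  rd <- SummarizedExperiment::rowData(cov)
  rd$masked <- if (is.null(masked)) rep(FALSE, nrow(cov)) else masked
  SummarizedExperiment::rowData(cov) <- rd
  cov
}

# ratio matrix of all-normal baseline for a panel
baselineRatios <- function(panel, samples = "S1") {
  n <- length(panelTargets(panel))
  matrix(1, nrow = n, ncol = length(samples),
         dimnames = list(S4Vectors::mcols(panelTargets(panel))$target_id,
                         samples))
}

# independent two-step median-normalization oracle (plain loops)
oracleNormalize <- function(D, batch) {
  R <- D * NA_real_
  for (s in seq_len(ncol(D))) {
    Dp <- D[, s] / median(D[, s])
    mates <- which(batch == batch[s])
    for (t in seq_len(nrow(D))) {
      denom <- median(vapply(mates, function(m)
        D[t, m] / median(D[, m]), numeric(1)))
      R[t, s] <- Dp[t] / denom
    }
  }
  R
}

# independent run-length segmentation oracle over a state vector: maximal
# runs of identical non-normal states
oracleRuns <- function(states) {
  out <- list()
  i <- 1L
  while (i <= length(states)) {
    j <- i
    while (j < length(states) && states[j + 1L] == states[i]) j <- j + 1L
    if (states[i] != "normal")
      out[[length(out) + 1L]] <- list(state = states[i], from = i, to = j)
    i <- j + 1L
  }
  out
}

hasFlagTest <- function(flags, f) PanelCNV:::hasFlag(flags, f)

# closed-form Welch t statistic and two-sided p
oracleWelch <- function(x, y) {
  vx <- var(x) / length(x); vy <- var(y) / length(y)
  t <- (mean(x) - mean(y)) / sqrt(vx + vy)
  df <- (vx + vy)^2 / (vx^2 / (length(x) - 1) + vy^2 / (length(y) - 1))
  list(t = t, p = 2 * pt(-abs(t), df))
}
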
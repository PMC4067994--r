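#' A built-in demonstration deafness panel
#'
#' Constructs, entirely in code, a compact synthetic capture panel shaped
#' like a clinical deafness panel: 150 exon targets in 9 genes, including
#' the chromosome 15 STRC locus with its pseudogene (every STRC exon
#' partner-linked to the matching pseudo-STRC exon) and the adjacent
#' CATSPER2 gene, an OTOA gene whose last 9 exons sit inside a
#' high-identity segmental duplication, and the adjacent chromosome 22
#' pair MYH9/TRIOBP used to exercise multi-gene contiguous deletions.
#' Coordinates are synthetic; exon counts and the locus layout mirror the
#' real genes. STRC and its pseudogene are encoded on the minus strand, so
#' their exon ordinals descend with genomic coordinate.
#'
#' @return a \linkS4class{CnvPanel} named \code{"demo-v1"}.
#' @export
#' @examples
#' panel <- examplePanel()
#' panel
examplePanel <- function() {
  lens <- c(142L, 98L, 187L, 120L, 156L, 203L, 88L, 131L, 175L, 110L)
  mkGene <- function(chrom, gene, n, at, minus = FALSE,
                     segdupExons = integer(0)) {
    w <- rep_len(lens, n)
    gaps <- rep_len(c(1800L, 2400L, 1300L, 3100L, 900L), n)
    start <- at + cumsum(c(0L, (w + gaps)[-n]))
    exon <- if (minus) rev(seq_len(n)) else seq_len(n)
    data.frame(chrom = chrom, start = start, end = start + w,
               gene = gene, exon = exon,
               segdup = exon %in% segdupExons,
               stringsAsFactors = FALSE)
  }
  df <- rbind(
    mkGene("chr7",  "SLC26A4",  10L, 107300000L),
    mkGene("chr9",  "TMC1",     24L,  75100000L),
    mkGene("chr13", "GJB2",      2L,  20760000L),
    mkGene("chr15", "PSTRC",    29L,  43890000L, minus = TRUE,
           segdupExons = 1:29),
    mkGene("chr15", "CATSPER2", 12L,  44100000L, minus = TRUE,
           segdupExons = 1:12),
    mkGene("chr15", "STRC",     29L,  44230000L, minus = TRUE,
           segdupExons = 1:29),
    mkGene("chr16", "OTOA",     28L,  21690000L, segdupExons = 20:28),
    mkGene("chr22", "MYH9",      8L,  36680000L, minus = TRUE),
    mkGene("chr22", "TRIOBP",    8L,  38090000L)
  )
  partner <- rep(NA_character_, nrow(df))
  strc <- df$gene == "STRC"; pstrc <- df$gene == "PSTRC"
  partner[strc] <- paste0("PSTRC_", df$exon[strc])
  partner[pstrc] <- paste0("STRC_", df$exon[pstrc])
  gr <- GenomicRanges::GRanges(
    df$chrom, IRanges::IRanges(start = df$start + 1L, end = df$end))
  S4Vectors::mcols(gr) <- S4Vectors::DataFrame(
    gene = df$gene, exon_index = df$exon,
    target_id = paste(df$gene, df$exon, sep = "_"),
    pseudo_partner = partner, segdup_flag = df$segdup
  )
  genes <- data.frame(
    symbol = c("SLC26A4", "TMC1", "GJB2", "PSTRC", "CATSPER2", "STRC",
               "OTOA", "MYH9", "TRIOBP"),
    inheritance = c("AR", "both", "both", "AR", "AR", "AR",
                    "AR", "AD", "AR"),
    nshl_mimic = c(FALSE, FALSE, FALSE, FALSE, TRUE, FALSE,
                   FALSE, TRUE, FALSE),
    stringsAsFactors = FALSE
  )
  CnvPanel(name = "demo-v1", targets = gr, genes = genes)
}
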
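#' Repetitive-element burden per gene
#'
#' Counts segmental duplications, Alu elements, L1 elements and simple
#' repeats overlapping each gene span (an element counts on any >= 1 bp
#' overlap) and normalizes counts by gene length. Segmental duplications
#' only count when their percent identity exceeds
#' \code{minSegdupIdentity}, the homology level required for non-allelic
#' homologous recombination. Gene spans may optionally be extended by
#' \code{flank} bp on both sides.
#'
#' @param geneIntervals named \code{GRanges} of gene spans (e.g.
#'   \code{\link{geneRanges}} of a panel), or a \linkS4class{CnvPanel}.
#' @param annotations \code{GRanges} from \code{\link{readRepeatMasker}} /
#'   \code{\link{readRepeatBed}} with \code{family} and
#'   \code{identity_pct}.
#' @param cnvGenes gene symbols with observed CNVs (sets the
#'   \code{cnv_associated} column).
#' @param minSegdupIdentity strict lower bound on segdup identity
#'   (default 95).
#' @param flank bp added to each side of every gene span (default 0).
#' @return \code{data.frame} with one row per gene: \code{gene,
#'   length_bp, segdup, Alu, L1, simple_repeat, alu_l1} counts, their
#'   \code{*_per_kb} normalizations, and \code{cnv_associated}.
#' @export
countRepeats <- function(geneIntervals, annotations, cnvGenes = character(0),
                         minSegdupIdentity = 95, flank = 0) {
  if (is(geneIntervals, "CnvPanel"))
    geneIntervals <- geneRanges(geneIntervals)
  if (any(GenomicRanges::width(geneIntervals) <= 0))
    stop("gene with zero length")
  spans <- geneIntervals
  if (flank > 0) {
    spans <- GenomicRanges::GRanges(
      GenomicRanges::seqnames(spans),
      IRanges::IRanges(pmax(1L, GenomicRanges::start(spans) - flank),
                       GenomicRanges::end(spans) + flank))
    names(spans) <- names(geneIntervals)
  }
  mc <- S4Vectors::mcols(annotations)
  countFam <- function(sel) {
    GenomicRanges::countOverlaps(spans, annotations[sel], minoverlap = 1L)
  }
  segdupSel <- mc$family == "segdup" & !is.na(mc$identity_pct) &
    mc$identity_pct > minSegdupIdentity
  out <- data.frame(
    gene = names(spans),
    length_bp = GenomicRanges::width(geneIntervals),
    segdup = countFam(segdupSel),
    Alu = countFam(mc$family == "Alu"),
    L1 = countFam(mc$family == "L1"),
    simple_repeat = countFam(mc$family == "simple_repeat"),
    stringsAsFactors = FALSE, row.names = NULL
  )
  out$alu_l1 <- out$Alu + out$L1
  for (cl in c("segdup", "Alu", "L1", "simple_repeat", "alu_l1"))
    out[[paste0(cl, "_per_kb")]] <- out[[cl]] * 1000 / out$length_bp
  out$cnv_associated <- out$gene %in% cnvGenes
  out
}

#' Compare repetitive-element burden between gene groups
#'
#' Tests whether per-kb element densities differ between CNV-associated
#' genes and the remaining panel genes. The default is a Welch two-sample
#' t-test on the normalized values (the groups are of unequal size and
#' unpaired); a paired mode is retained for designs with an explicit
#' pairing and requires equal group sizes.
#'
#' @param burdens output of \code{\link{countRepeats}} with the
#'   \code{cnv_associated} column set.
#' @param elementClasses subset of \code{c("Alu", "L1", "alu_l1",
#'   "simple_repeat", "segdup")}.
#' @param testKind \code{"welch_two_sample"} (default) or \code{"paired"}.
#' @return \code{data.frame(element_class, n_cnv, n_other, t_statistic,
#'   p_value, test_kind)}.
#' @export
compareBurden <- function(burdens,
                          elementClasses = c("Alu", "L1", "alu_l1",
                                             "simple_repeat"),
                          testKind = c("welch_two_sample", "paired")) {
  testKind <- match.arg(testKind)
  a <- burdens[burdens$cnv_associated, , drop = FALSE]
  b <- burdens[!burdens$cnv_associated, , drop = FALSE]
  if (nrow(a) == 0L || nrow(b) == 0L)
    stop("both gene groups must be non-empty")
  if (nrow(a) < 2L || nrow(b) < 2L)
    stop("each group needs >= 2 genes to estimate a variance")
  if (testKind == "paired" && nrow(a) != nrow(b))
    stop("paired comparison requires equal group sizes with explicit pairing")
  rows <- lapply(elementClasses, function(cl) {
    col <- paste0(cl, "_per_kb")
    if (!col %in% colnames(burdens)) stop("unknown element class: ", cl)
    tt <- if (testKind == "paired")
      stats::t.test(a[[col]], b[[col]], paired = TRUE)
    else
      stats::t.test(a[[col]], b[[col]], var.equal = FALSE)
    data.frame(element_class = cl, n_cnv = nrow(a), n_other = nrow(b),
               t_statistic = unname(tt$statistic),
               p_value = tt$p.value, test_kind = testKind,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
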
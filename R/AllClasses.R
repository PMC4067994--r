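#' CnvPanel: a targeted capture panel definition
#'
#' A \code{CnvPanel} holds the exon-level capture targets of a diagnostic
#' gene panel together with per-gene metadata. Each target is one captured
#' exon, carrying its gene symbol, its 1-based exon ordinal in transcription
#' order, a unique target id, an optional link to the homologous pseudogene
#' target (used by the gene-conversion caller), and a flag marking targets
#' that lie inside a segmental duplication.
#'
#' Internal coordinates are 0-based half-open throughout the package
#' (GRanges display them 1-based; conversion happens only at file
#' boundaries: BED is 0-based half-open, depth tables and VCF 1-based).
#'
#' @slot name panel version label, e.g. \code{"v4"}.
#' @slot targets \code{GRanges}, sorted by (chrom, start), with metadata
#'   columns \code{gene}, \code{exon_index}, \code{target_id},
#'   \code{pseudo_partner} (NA when no partner) and \code{segdup_flag}.
#' @slot genes \code{data.frame} with columns \code{symbol},
#'   \code{inheritance} (one of \code{"AR"}, \code{"AD"}, \code{"XL"},
#'   \code{"both"}) and \code{nshl_mimic} (logical).
#'
#' @importClassesFrom GenomicRanges GRanges
#' @importFrom GenomicRanges GRanges seqnames start end width findOverlaps
#' @importFrom IRanges IRanges
#' @importFrom S4Vectors mcols queryHits subjectHits
#' @exportClass CnvPanel
#' @aliases panelTargets panelGenes panelName geneRanges
#' @name CnvPanel-class
setClass("CnvPanel",
  representation(
    name    = "character",
    targets = "GRanges",
    genes   = "data.frame"
  )
)

setValidity("CnvPanel", function(object) {
  tg <- object@targets
  mc <- S4Vectors::mcols(tg)
  need <- c("gene", "exon_index", "target_id", "pseudo_partner", "segdup_flag")
  if (!all(need %in% colnames(mc)))
    return(paste("targets must carry metadata columns:",
                 paste(setdiff(need, colnames(mc)), collapse = ", ")))
  if (length(tg) == 0L) return(TRUE)
  if (anyDuplicated(mc$target_id))
    return("target_ids must be unique within a panel")
  o <- order(as.character(GenomicRanges::seqnames(tg)),
             GenomicRanges::start(tg))
  if (!identical(o, seq_along(tg)))
    return("targets must be sorted by (chrom, start)")
  ## same-gene targets must not overlap
  for (g in unique(mc$gene)) {
    sub <- tg[mc$gene == g]
    if (length(sub) > 1L) {
      hits <- GenomicRanges::findOverlaps(sub, drop.self = TRUE,
                                          drop.redundant = TRUE)
      if (length(hits) > 0L)
        return(sprintf("overlapping targets within gene %s", g))
    }
  }
  ## pseudo_partner links must resolve to an existing target in another gene
  pp <- mc$pseudo_partner
  set <- !is.na(pp)
  if (any(set)) {
    idx <- match(pp[set], mc$target_id)
    if (anyNA(idx))
      return(sprintf("dangling pseudo_partner reference: %s",
                     paste(pp[set][is.na(idx)], collapse = ", ")))
    if (any(mc$gene[idx] == mc$gene[set]))
      return("pseudo_partner must refer to a target in a different gene")
  }
  if (!all(mc$gene %in% object@genes$symbol))
    return("every target's gene must appear in the gene table")
  if (!all(object@genes$inheritance %in% c("AR", "AD", "XL", "both")))
    return("gene inheritance must be one of AR, AD, XL, both")
  TRUE
})

#' Construct a CnvPanel
#'
#' @param name panel version label.
#' @param targets \code{GRanges} with the metadata columns documented in
#'   \linkS4class{CnvPanel}; will be sorted by (chrom, start).
#' @param genes gene metadata \code{data.frame} (\code{symbol},
#'   \code{inheritance}, \code{nshl_mimic}). Genes present in targets but
#'   missing here are added with inheritance \code{"AR"}.
#' @return a \code{CnvPanel}.
#' @export
CnvPanel <- function(name, targets, genes = NULL) {
  o <- order(as.character(GenomicRanges::seqnames(targets)),
             GenomicRanges::start(targets))
  targets <- targets[o]
  tgenes <- unique(S4Vectors::mcols(targets)$gene)
  if (is.null(genes))
    genes <- data.frame(symbol = character(0), inheritance = character(0),
                        nshl_mimic = logical(0), stringsAsFactors = FALSE)
  missing <- setdiff(tgenes, genes$symbol)
  if (length(missing) > 0L)
    genes <- rbind(genes,
                   data.frame(symbol = missing, inheritance = "AR",
                              nshl_mimic = FALSE, stringsAsFactors = FALSE))
  new("CnvPanel", name = name, targets = targets, genes = genes)
}

#' @rdname CnvPanel-class
#' @export
setMethod("panelTargets", "CnvPanel", function(x) x@targets)

#' @rdname CnvPanel-class
#' @export
setMethod("panelGenes", "CnvPanel", function(x) x@genes)

#' @rdname CnvPanel-class
#' @export
setMethod("panelName", "CnvPanel", function(x) x@name)

#' @describeIn CnvPanel-class per-gene genomic span (min start to max end of
#'   the gene's targets), returned as a named \code{GRanges}.
#' @export
setMethod("geneRanges", "CnvPanel", function(x) {
  tg <- x@targets
  mc <- S4Vectors::mcols(tg)
  genes <- unique(mc$gene)
  gr <- GenomicRanges::GRanges(
    seqnames = vapply(genes, function(g)
      as.character(GenomicRanges::seqnames(tg[mc$gene == g])[1]), character(1)),
    ranges = IRanges::IRanges(
      start = vapply(genes, function(g)
        min(GenomicRanges::start(tg[mc$gene == g])), numeric(1)),
      end = vapply(genes, function(g)
        max(GenomicRanges::end(tg[mc$gene == g])), numeric(1))
    )
  )
  names(gr) <- genes
  S4Vectors::mcols(gr)$gene <- genes
  gr
})

setMethod("show", "CnvPanel", function(object) {
  mc <- S4Vectors::mcols(object@targets)
  cat("CnvPanel '", object@name, "': ", length(object@targets),
      " targets in ", length(unique(mc$gene)), " genes\n", sep = "")
  nlink <- sum(!is.na(mc$pseudo_partner))
  if (nlink > 0L)
    cat("  ", nlink, " targets carry gene-pseudogene partner links\n", sep = "")
  nsd <- sum(mc$segdup_flag)
  if (nsd > 0L)
    cat("  ", nsd, " targets flagged inside segmental duplications\n", sep = "")
})

#' PanelCoverage: depth and ratio matrices over a panel
#'
#' A \code{PanelCoverage} extends \code{RangedSummarizedExperiment}: rows are
#' panel targets (with the \linkS4class{CnvPanel} metadata columns in
#' \code{rowData}), columns are samples with a mandatory \code{batch} label
#' in \code{colData}. The \code{"depth"} assay holds per-target mean
#' fold-coverage; \code{\link{normalizeByBatch}} adds a \code{"ratio"} assay
#' and a per-target low-coverage \code{masked} column in \code{rowData};
#' \code{\link{slidingWindowSmooth}} adds a \code{"smoothed"} assay.
#'
#' @importClassesFrom SummarizedExperiment RangedSummarizedExperiment
#' @importFrom SummarizedExperiment SummarizedExperiment assay assays
#'   assayNames rowData colData assay<- rowData<-
#' @importFrom S4Vectors metadata metadata<- DataFrame
#' @exportClass PanelCoverage
#' @aliases depthMatrix ratioMatrix smoothedMatrix batchLabels maskedTargets
#' @name PanelCoverage-class
setClass("PanelCoverage", contains = "RangedSummarizedExperiment")

setValidity("PanelCoverage", function(object) {
  if (!"depth" %in% SummarizedExperiment::assayNames(object))
    return("a 'depth' assay is required")
  if (!"batch" %in% colnames(SummarizedExperiment::colData(object)))
    return("colData must contain a 'batch' label for every sample")
  d <- SummarizedExperiment::assay(object, "depth")
  if (any(!is.finite(d)) || any(d < 0))
    return("depth must be finite and non-negative")
  TRUE
})

#' Construct a PanelCoverage from a depth matrix
#'
#' @param depth numeric matrix, targets (rows, named by target id) x samples
#'   (columns, named by sample id). Values are per-target mean fold-coverage.
#' @param panel a \linkS4class{CnvPanel}; rows of \code{depth} must match its
#'   targets (matched by target id when rownames are present, by order
#'   otherwise).
#' @param batch character vector of batch labels, one per sample (recycled if
#'   length 1).
#' @return a \linkS4class{PanelCoverage}.
#' @export
PanelCoverage <- function(depth, panel, batch = "batch1") {
  tg <- panelTargets(panel)
  ids <- S4Vectors::mcols(tg)$target_id
  if (!is.null(rownames(depth))) {
    idx <- match(ids, rownames(depth))
    if (anyNA(idx))
      stop("depth matrix is missing targets: ",
           paste(ids[is.na(idx)], collapse = ", "))
    depth <- depth[idx, , drop = FALSE]
  } else if (nrow(depth) != length(tg)) {
    stop("depth has ", nrow(depth), " rows but the panel has ",
         length(tg), " targets")
  }
  rownames(depth) <- ids
  if (is.null(colnames(depth)))
    colnames(depth) <- sprintf("S%03d", seq_len(ncol(depth)))
  batch <- rep_len(batch, ncol(depth))
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(depth = depth),
    rowRanges = tg,
    colData = S4Vectors::DataFrame(batch = batch,
                                   row.names = colnames(depth))
  )
  S4Vectors::metadata(se)$panel_name <- panelName(panel)
  new("PanelCoverage", se)
}

#' @rdname PanelCoverage-class
#' @export
setMethod("depthMatrix", "PanelCoverage", function(x)
  SummarizedExperiment::assay(x, "depth"))

#' @rdname PanelCoverage-class
#' @export
setMethod("ratioMatrix", "PanelCoverage", function(x) {
  if (!"ratio" %in% SummarizedExperiment::assayNames(x))
    stop("no 'ratio' assay; run normalizeByBatch() first")
  SummarizedExperiment::assay(x, "ratio")
})

#' @rdname PanelCoverage-class
#' @export
setMethod("smoothedMatrix", "PanelCoverage", function(x) {
  if (!"smoothed" %in% SummarizedExperiment::assayNames(x))
    stop("no 'smoothed' assay; run slidingWindowSmooth() first")
  SummarizedExperiment::assay(x, "smoothed")
})

#' @rdname PanelCoverage-class
#' @export
setMethod("batchLabels", "PanelCoverage", function(x)
  stats::setNames(SummarizedExperiment::colData(x)$batch, colnames(x)))

#' @describeIn PanelCoverage-class logical per-target low-coverage mask
#'   (all-FALSE before normalization).
#' @export
setMethod("maskedTargets", "PanelCoverage", function(x) {
  rd <- SummarizedExperiment::rowData(x)
  if ("masked" %in% colnames(rd)) {
    stats::setNames(rd$masked, rd$target_id)
  } else {
    stats::setNames(rep(FALSE, nrow(x)), rd$target_id)
  }
})

#' @rdname CnvPanel-class
#' @export
setMethod("panelTargets", "PanelCoverage", function(x)
  SummarizedExperiment::rowRanges(x))

setMethod("show", "PanelCoverage", function(object) {
  cat("PanelCoverage: ", nrow(object), " targets x ", ncol(object),
      " samples (", length(unique(batchLabels(object))), " batch",
      if (length(unique(batchLabels(object))) != 1L) "es" else "",
      ")\n", sep = "")
  cat("  assays:", paste(SummarizedExperiment::assayNames(object),
                         collapse = ", "), "\n")
  m <- maskedTargets(object)
  if (any(m)) cat("  ", sum(m), " low-coverage targets masked\n", sep = "")
})
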
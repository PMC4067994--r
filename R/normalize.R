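#' Batch-normalized median read-depth ratios
#'
#' The quantitative core of the CNV method, a fixed two-step median
#' contract. First, library-size scaling: every sample's depth vector is
#' divided by its own median across targets, removing sequencing-yield
#' differences. Second, batch referencing: each scaled value is divided by
#' the median of the scaled values of all samples in the same batch at that
#' target, so a diploid target sits at ratio 1 and ratio approximates copy
#' number / 2. Targets whose raw within-batch median depth falls below
#' \code{minDepth} in any batch are masked as too unstable to interpret.
#'
#' @param x a \linkS4class{PanelCoverage} with a \code{depth} assay; every
#'   batch must contain at least two samples and no sample may be all-zero.
#' @param minDepth low-coverage mask threshold on the raw batch-median
#'   depth (default 20).
#' @return \code{x} with a \code{ratio} assay, a logical \code{masked}
#'   column in \code{rowData}, and \code{min_depth} recorded in metadata.
#' @export
#' @examples
#' sim <- simulateCohort(simulationConfig(nSamples = 8), examplePanel())
#' cov <- normalizeByBatch(sim$coverage)
#' summary(as.vector(ratioMatrix(cov)))
normalizeByBatch <- function(x, minDepth = 20) {
  d <- depthMatrix(x)
  batch <- batchLabels(x)
  bt <- table(batch)
  if (any(bt < 2L))
    stop("batch of size 1: ", paste(names(bt)[bt < 2L], collapse = ", "),
         " (the batch median needs at least two samples)")
  libMed <- apply(d, 2L, stats::median)
  if (any(libMed == 0))
    stop("all-zero (or majority-zero) sample: ",
         paste(colnames(d)[libMed == 0], collapse = ", "))
  dprime <- sweep(d, 2L, libMed, "/")
  r <- matrix(NA_real_, nrow(d), ncol(d), dimnames = dimnames(d))
  masked <- rep(FALSE, nrow(d))
  for (b in unique(batch)) {
    cols <- which(batch == b)
    rawMed <- apply(d[, cols, drop = FALSE], 1L, stats::median)
    masked <- masked | rawMed < minDepth
    batchMed <- apply(dprime[, cols, drop = FALSE], 1L, stats::median)
    rr <- sweep(dprime[, cols, drop = FALSE], 1L, batchMed, "/")
    rr[batchMed == 0, ] <- NA_real_
    r[, cols] <- rr
  }
  SummarizedExperiment::assay(x, "ratio") <- r
  rd <- SummarizedExperiment::rowData(x)
  rd$masked <- masked
  SummarizedExperiment::rowData(x) <- rd
  S4Vectors::metadata(x)$min_depth <- minDepth
  x
}

#' Sliding-window median smoothing of ratio tracks
#'
#' Replaces each target's ratio by the median over a window of \code{w}
#' targets centred on it. Windows are counted in targets (exons), not base
#' pairs, are restricted to unmasked targets of the same gene, and never
#' cross gene boundaries, preserving the exon-level resolution of the
#' panel. \code{w = 1} is the identity. The smoothed track is stored as a
#' secondary assay; calling on the unsmoothed track (the default
#' elsewhere) keeps single-exon events visible, while the smoothed track
#' serves as a quality-control annotation.
#'
#' @param x a normalized \linkS4class{PanelCoverage}.
#' @param w odd window width in targets (default 3).
#' @return \code{x} with a \code{smoothed} assay and \code{window_w} in
#'   metadata.
#' @export
slidingWindowSmooth <- function(x, w = 3L) {
  if (w %% 2L == 0L) stop("window width w must be odd")
  if (w < 1L) stop("window width w must be >= 1")
  r <- ratioMatrix(x)
  out <- r
  if (w > 1L) {
    genes <- SummarizedExperiment::rowData(x)$gene
    masked <- maskedTargets(x)
    h <- (w - 1L) %/% 2L
    for (g in unique(genes)) {
      rows <- which(genes == g & !masked)
      ng <- length(rows)
      if (ng == 0L) next
      for (k in seq_len(ng)) {
        win <- rows[max(1L, k - h):min(ng, k + h)]
        out[rows[k], ] <- apply(r[win, , drop = FALSE], 2L, stats::median)
      }
    }
  }
  SummarizedExperiment::assay(x, "smoothed") <- out
  S4Vectors::metadata(x)$window_w <- as.integer(w)
  x
}
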
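#' Copy-state thresholds on read-depth ratios
#'
#' Ratio cut points separating the discrete copy states. Ideal diploid
#' ratios are 0 (homozygous deletion), 0.5 (heterozygous deletion), 1
#' (normal) and 1.5+ (duplication); the defaults sit midway between them.
#' Boundary values are assigned to the more extreme state (\code{<=} for
#' deletions, \code{>=} for duplications). \code{dupHom} separates
#' single-copy gains from two-copy gains (ratio 1.5 vs 2) when zygosity is
#' assigned to duplications.
#'
#' @param homDel ratio at or below which a target is a homozygous deletion
#'   (default 0.2).
#' @param hetDel upper bound (inclusive) for heterozygous deletion
#'   (default 0.7).
#' @param dup ratio at or above which a target is duplicated (default 1.3).
#' @param dupHom ratio at or above which a duplication is treated as a
#'   two-copy (biallelic) gain (default 1.8).
#' @return a validated threshold list.
#' @export
cnvThresholds <- function(homDel = 0.2, hetDel = 0.7, dup = 1.3,
                          dupHom = 1.8) {
  stopifnot(0 < homDel, homDel < hetDel, hetDel < 1, 1 < dup, dup < dupHom)
  list(homDel = homDel, hetDel = hetDel, dup = dup, dupHom = dupHom)
}

#' Classify a single target ratio into a copy state
#'
#' @param ratio non-negative read-depth ratio(s).
#' @param thresholds a \code{\link{cnvThresholds}} list.
#' @return character vector over \code{c("hom_del", "het_del", "normal",
#'   "dup")}; \code{NA} ratios give \code{NA}.
#' @export
#' @examples
#' classifyTarget(c(0, 0.5, 1, 1.5))
classifyTarget <- function(ratio, thresholds = cnvThresholds()) {
  if (any(ratio < 0, na.rm = TRUE)) stop("ratios must be >= 0")
  out <- rep(NA_character_, length(ratio))
  ok <- !is.na(ratio)
  out[ok & ratio <= thresholds$homDel] <- "hom_del"
  out[ok & ratio > thresholds$homDel & ratio <= thresholds$hetDel] <- "het_del"
  out[ok & ratio >= thresholds$dup] <- "dup"
  out[ok & is.na(out)] <- "normal"
  out
}

#' Copy number implied by a call's mean ratio
#'
#' @param call one or more rows of a call table (or any object with a
#'   \code{mean_ratio} column).
#' @return numeric, \code{2 * mean_ratio}.
#' @export
estimateCopyNumber <- function(call) 2 * call$mean_ratio

#' Segment one sample's ratios into CNV calls
#'
#' Walks each gene's targets in panel order, classifies every unmasked
#' target and turns maximal runs of identical non-normal states into one
#' call. Masked (low-coverage) targets inside a run do not break it but set
#' the \code{low_coverage_neighbor} flag; single-target calls are flagged
#' \code{single_exon} (the in-silico stand-in for manual curation of
#' single-exon events); calls touching segmental-duplication targets are
#' flagged \code{segdup_overlap}. A heterozygous-looking deletion tail
#' lying entirely inside segdup-flagged targets and adjacent to a
#' homozygous deletion run is merged into it as one homozygous deletion
#' (reads from the undeleted duplicate locus mask the true copy number
#' there). Finally, calls in adjacent genes on one chromosome with the
#' same class and zygosity that reach the facing gene edges are annotated
#' as a \code{multi_gene_contiguous} group.
#'
#' Without sample sex metadata, calls on X-chromosome targets carry a
#' \code{sex_chrom_unknown} flag and no zygosity; with \code{sex = "M"}
#' deletion calls on X are labelled hemizygous.
#'
#' @param x a normalized \linkS4class{PanelCoverage}.
#' @param sample sample id to segment.
#' @param thresholds a \code{\link{cnvThresholds}} list.
#' @param track assay to classify, \code{"ratio"} (default; preserves
#'   single-exon events) or \code{"smoothed"}.
#' @param sex optional \code{"M"}/\code{"F"} for the sample.
#' @return a call table (possibly zero rows): \code{sample_id, gene,
#'   chrom, start, end, first_exon, last_exon, cnv_class, zygosity,
#'   mean_ratio, n_targets, copy_number, flags, contig_group}. Coordinates
#'   are 0-based half-open.
#' @export
segmentCalls <- function(x, sample, thresholds = cnvThresholds(),
                         track = c("ratio", "smoothed"), sex = NA) {
  track <- match.arg(track)
  r <- if (track == "ratio") ratioMatrix(x) else smoothedMatrix(x)
  if (!sample %in% colnames(r)) stop("unknown sample: ", sample)
  ctx <- .panelContext(x)
  .segmentOne(r[, sample], sample, ctx, thresholds, sex)
}

## flat-vector view of the panel, computed once per cohort: S4 accessor
## calls inside the per-sample loop dominate runtime otherwise
.panelContext <- function(x) {
  tg <- panelTargets(x)
  mc <- S4Vectors::mcols(tg)
  geneOrder <- unique(mc$gene)
  chrom <- as.character(GenomicRanges::seqnames(tg))
  start1 <- GenomicRanges::start(tg)
  end <- GenomicRanges::end(tg)
  list(gene = mc$gene, exon = mc$exon_index, segdup = mc$segdup_flag,
       chrom = chrom, start1 = start1, end = end,
       masked = unname(maskedTargets(x)),
       geneIdx = split(seq_along(tg), factor(mc$gene, levels = geneOrder)),
       geneOrder = geneOrder,
       geneChrom = vapply(geneOrder, function(g)
         chrom[mc$gene == g][1], character(1)),
       geneFirst = vapply(geneOrder, function(g)
         min(start1[mc$gene == g]), numeric(1)),
       geneLast = vapply(geneOrder, function(g)
         max(end[mc$gene == g]), numeric(1)))
}

.segmentOne <- function(rv, sample, ctx, thresholds, sex) {
  state <- classifyTarget(ifelse(ctx$masked, NA_real_, rv), thresholds)
  rows <- list()
  for (g in ctx$geneOrder) {
    gidx <- ctx$geneIdx[[g]]
    runs <- .stateRuns(state[gidx])
    runs <- .mergeSegdupTail(runs, state[gidx], ctx$segdup[gidx])
    for (run in runs) {
      members <- gidx[run$members]
      inside <- gidx[seq(min(run$members), max(run$members))]
      lowcov <- any(ctx$masked[setdiff(inside, members)]) ||
        .maskedAdjacent(ctx$masked, gidx, run$members)
      chrom <- ctx$chrom[members[1]]
      cls <- if (run$state == "dup") "duplication" else "deletion"
      mr <- mean(rv[members])
      zyg <- switch(run$state, hom_del = "hom", het_del = "het",
                    dup = if (mr >= thresholds$dupHom) "hom" else "het")
      flags <- character(0)
      if (length(members) == 1L) flags <- c(flags, "single_exon")
      if (any(ctx$segdup[members]) || isTRUE(run$segdup_merged))
        flags <- c(flags, "segdup_overlap")
      if (lowcov) flags <- c(flags, "low_coverage_neighbor")
      if (chrom %in% c("chrX", "X")) {
        if (is.na(sex)) {
          flags <- c(flags, "sex_chrom_unknown")
          zyg <- NA_character_
        } else if (sex == "M" && cls == "deletion") {
          zyg <- "hemizygous"
        }
      }
      rows[[length(rows) + 1L]] <- list(
        sample_id = sample, gene = g, chrom = chrom,
        start = ctx$start1[members[1]] - 1L,
        end = max(ctx$end[members]),
        first_exon = min(ctx$exon[members]),
        last_exon = max(ctx$exon[members]),
        cnv_class = cls, zygosity = zyg, mean_ratio = mr,
        n_targets = length(members), copy_number = 2 * mr,
        flags = joinFlags(flags), contig_group = "")
    }
  }
  out <- if (length(rows) > 0L) {
    cols <- names(rows[[1]])
    as.data.frame(stats::setNames(lapply(cols, function(cn)
      unlist(lapply(rows, `[[`, cn), use.names = FALSE)), cols),
      stringsAsFactors = FALSE)
  } else emptyCnvCalls()
  .annotateContiguous(out, ctx)
}

## maximal runs of identical non-normal state over unmasked targets;
## NA (masked) targets are transparent and never break a run
.stateRuns <- function(states) {
  runs <- list()
  cur <- NULL
  for (i in seq_along(states)) {
    s <- states[i]
    if (is.na(s)) next
    if (!is.null(cur) && s == cur$state) {
      cur$members <- c(cur$members, i)
    } else {
      if (!is.null(cur) && cur$state != "normal")
        runs[[length(runs) + 1L]] <- cur
      cur <- list(state = s, members = i)
    }
  }
  if (!is.null(cur) && cur$state != "normal")
    runs[[length(runs) + 1L]] <- cur
  runs
}

## merge a het_del run lying wholly inside segdup-flagged targets into an
## adjacent hom_del run: the duplicate locus donates reads over the segdup
## exons, so a true homozygous loss looks heterozygous there
.mergeSegdupTail <- function(runs, states, segdup) {
  if (length(runs) < 2L) return(runs)
  repeat {
    merged <- FALSE
    for (i in seq_len(length(runs) - 1L)) {
      a <- runs[[i]]; b <- runs[[i + 1L]]
      adjacent <- .runsAdjacent(a, b, states)
      pair <- NULL
      if (adjacent && a$state == "hom_del" && b$state == "het_del" &&
          all(segdup[b$members])) pair <- c(i, i + 1L)
      if (adjacent && b$state == "hom_del" && a$state == "het_del" &&
          all(segdup[a$members])) pair <- c(i, i + 1L)
      if (!is.null(pair)) {
        runs[[pair[1]]] <- list(state = "hom_del",
                                members = c(a$members, b$members),
                                segdup_merged = TRUE)
        runs[[pair[2]]] <- NULL
        merged <- TRUE
        break
      }
    }
    if (!merged) break
  }
  runs
}

## two runs are adjacent when no unmasked target separates them
.runsAdjacent <- function(a, b, states) {
  between <- seq(max(a$members) + 1L, length.out =
                   min(b$members) - max(a$members) - 1L)
  all(is.na(states[between]))
}

.maskedAdjacent <- function(masked, gidx, members) {
  lo <- min(members); hi <- max(members)
  (lo > 1L && masked[gidx[lo - 1L]]) ||
    (hi < length(gidx) && masked[gidx[hi + 1L]])
}

## annotate same-class same-zygosity calls in adjacent genes of one
## chromosome that reach the facing gene edges as one contiguous group
.annotateContiguous <- function(calls, ctx) {
  if (nrow(calls) < 2L) return(calls)
  geneOrder <- ctx$geneOrder  # panel (chrom, start) order
  geneChrom <- ctx$geneChrom
  geneFirst <- ctx$geneFirst
  geneLast <- ctx$geneLast
  gid <- 0L
  for (i in seq_len(length(geneOrder) - 1L)) {
    g1 <- geneOrder[i]; g2 <- geneOrder[i + 1L]
    if (geneChrom[i] != geneChrom[i + 1L]) next
    c1 <- which(calls$gene == g1 & calls$end == geneLast[i])
    c2 <- which(calls$gene == g2 & calls$start == geneFirst[i + 1L] - 1L)
    for (a in c1) for (b in c2) {
      if (calls$cnv_class[a] == calls$cnv_class[b] &&
          identical(calls$zygosity[a], calls$zygosity[b])) {
        grp <- unique(c(calls$contig_group[a], calls$contig_group[b]))
        grp <- grp[nzchar(grp)]
        if (length(grp) == 0L) {
          gid <- gid + 1L
          grp <- sprintf("%s_ctg%d", calls$sample_id[a], gid)
        }
        calls$contig_group[c(a, b)] <- grp[1]
        calls$flags[a] <- addFlag(calls$flags[a], "multi_gene_contiguous")
        calls$flags[b] <- addFlag(calls$flags[b], "multi_gene_contiguous")
      }
    }
  }
  calls
}

#' Curation surrogate for single-exon calls
#'
#' Clinical pipelines follow read-depth calling with manual inspection;
#' this filter is the in-silico stand-in. Multi-exon calls pass
#' unchanged. A single-exon call (the class most exposed to ratio noise)
#' is retained only when its copy-number estimate is consistent with a
#' genuine integer copy state: within \code{maxIntegerDeviation} of an
#' integer other than 2. A single-exon homozygous loss (cn ~ 0) or clean
#' heterozygous loss (cn ~ 1) survives; a threshold-grazing call with a
#' fractional copy number (e.g. cn 2.6) is removed as a reviewer would
#' remove it.
#'
#' @param calls a call table from \code{\link{callCnvs}}.
#' @param maxIntegerDeviation maximum distance of \code{copy_number} from
#'   the nearest non-diploid integer for single-exon calls (default 0.35).
#' @return the curated call table.
#' @export
curateCalls <- function(calls, maxIntegerDeviation = 0.35) {
  if (nrow(calls) == 0L) return(calls)
  single <- hasFlag(calls$flags, "single_exon")
  cn <- calls$copy_number
  nearest <- round(cn)
  nearest[nearest == 2] <- ifelse(cn[nearest == 2] < 2, 1, 3)
  keep <- !single | abs(cn - nearest) <= maxIntegerDeviation
  calls[keep, , drop = FALSE]
}

#' Call CNVs for every sample of a cohort
#'
#' Convenience wrapper running \code{\link{segmentCalls}} across samples
#' and binding the results.
#'
#' @param x a normalized \linkS4class{PanelCoverage}.
#' @param samples sample ids (default all).
#' @param thresholds,track,sex passed to \code{\link{segmentCalls}};
#'   \code{sex} may be a named vector per sample.
#' @return a combined call table.
#' @export
callCnvs <- function(x, samples = colnames(x),
                     thresholds = cnvThresholds(),
                     track = c("ratio", "smoothed"), sex = NULL) {
  track <- match.arg(track)
  r <- if (track == "ratio") ratioMatrix(x) else smoothedMatrix(x)
  ctx <- .panelContext(x)
  res <- lapply(samples, function(s) {
    if (!s %in% colnames(r)) stop("unknown sample: ", s)
    sx <- if (is.null(sex)) NA else if (length(sex) == 1L && is.null(names(sex)))
      sex else unname(sex[s])
    .segmentOne(r[, s], s, ctx, thresholds, sx)
  })
  res <- res[vapply(res, nrow, integer(1)) > 0L]
  if (length(res) == 0L) return(emptyCnvCalls())
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}
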
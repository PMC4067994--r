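#' Read a panel definition from BED
#'
#' Parses a 4+ column BED file (0-based half-open) whose name field encodes
#' \code{gene|exon_index[|pseudo_partner][|segdup]}: the gene symbol, the
#' 1-based exon ordinal in transcription order, optionally the target id of
#' the homologous pseudogene exon, and optionally the literal token
#' \code{segdup} marking a target inside a segmental duplication. Target ids
#' are formed as \code{gene_exonIndex}.
#'
#' @param path BED file path.
#' @param geneMetadata optional \code{data.frame(symbol, inheritance,
#'   nshl_mimic)}; genes absent from it default to autosomal recessive.
#' @param name panel version label stored on the object.
#' @return a \linkS4class{CnvPanel}.
#' @export
readPanelBed <- function(path, geneMetadata = NULL, name = "panel") {
  if (!file.exists(path)) stop("panel BED not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines)) &
                 !startsWith(lines, "#") & !startsWith(lines, "track")]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(fields) < 4L)
  if (length(bad) > 0L)
    stop("malformed BED line(s) (need >= 4 columns): line ",
         paste(bad, collapse = ", "))
  chrom <- vapply(fields, `[[`, character(1), 1L)
  start <- suppressWarnings(as.integer(vapply(fields, `[[`, character(1), 2L)))
  end   <- suppressWarnings(as.integer(vapply(fields, `[[`, character(1), 3L)))
  nm    <- vapply(fields, `[[`, character(1), 4L)
  bad <- which(is.na(start) | is.na(end))
  if (length(bad) > 0L)
    stop("non-numeric coordinates on line ", paste(bad, collapse = ", "))
  bad <- which(end <= start)
  if (length(bad) > 0L)
    stop("end <= start on line ", paste(bad, collapse = ", "))
  parts <- strsplit(nm, "|", fixed = TRUE)
  bad <- which(lengths(parts) < 2L)
  if (length(bad) > 0L)
    stop("name field must be gene|exon_index[|pseudo_partner]: line ",
         paste(bad, collapse = ", "))
  gene <- vapply(parts, `[[`, character(1), 1L)
  exon <- suppressWarnings(as.integer(vapply(parts, `[[`, character(1), 2L)))
  bad <- which(is.na(exon))
  if (length(bad) > 0L)
    stop("non-integer exon_index on line ", paste(bad, collapse = ", "))
  extra <- lapply(parts, function(p) p[-(1:2)])
  partner <- vapply(extra, function(p) {
    p <- p[p != "segdup"]
    if (length(p) >= 1L && nzchar(p[1])) p[1] else NA_character_
  }, character(1))
  segdup <- vapply(extra, function(p) "segdup" %in% p, logical(1))
  gr <- GenomicRanges::GRanges(
    seqnames = chrom,
    ranges = IRanges::IRanges(start = start + 1L, end = end)  # to 1-based
  )
  S4Vectors::mcols(gr) <- S4Vectors::DataFrame(
    gene = gene, exon_index = exon,
    target_id = paste(gene, exon, sep = "_"),
    pseudo_partner = partner, segdup_flag = segdup
  )
  CnvPanel(name = name, targets = gr, genes = geneMetadata)
}

#' Write a panel definition to BED
#'
#' Inverse of \code{\link{readPanelBed}}: emits 0-based half-open
#' coordinates with the \code{gene|exon_index[|pseudo_partner][|segdup]}
#' name encoding, so read-write-read is the identity.
#'
#' @param panel a \linkS4class{CnvPanel}.
#' @param path output file.
#' @export
writePanelBed <- function(panel, path) {
  tg <- panelTargets(panel)
  mc <- S4Vectors::mcols(tg)
  nm <- paste(mc$gene, mc$exon_index, sep = "|")
  has_pp <- !is.na(mc$pseudo_partner)
  nm[has_pp] <- paste(nm[has_pp], mc$pseudo_partner[has_pp], sep = "|")
  nm[mc$segdup_flag] <- paste(nm[mc$segdup_flag], "segdup", sep = "|")
  df <- data.frame(
    chrom = as.character(GenomicRanges::seqnames(tg)),
    start = GenomicRanges::start(tg) - 1L,
    end = GenomicRanges::end(tg),
    name = nm
  )
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a depth table into a PanelCoverage
#'
#' Accepts either of two TSV layouts, distinguished by the header line:
#' \itemize{
#'   \item per-position (pileup-derived): columns \code{sample, chrom, pos,
#'     depth} with 1-based positions. Positions are assigned to panel
#'     targets; positions outside every target are dropped with a warning.
#'     Per-target depth is the mean (or median) over all bases of the
#'     target, with positions absent from the table counted as depth 0,
#'     matching pileup output which omits uncovered positions.
#'   \item matrix: first column \code{target_id}, remaining columns one per
#'     sample, values are per-target mean depth.
#' }
#'
#' @param path TSV path.
#' @param panel a \linkS4class{CnvPanel}.
#' @param batch batch label(s) for the samples (recycled).
#' @param stat per-target aggregation for per-position input, \code{"mean"}
#'   (default) or \code{"median"}.
#' @return a \linkS4class{PanelCoverage} with a \code{depth} assay.
#' @export
readDepthTable <- function(path, panel, batch = "batch1",
                           stat = c("mean", "median")) {
  stat <- match.arg(stat)
  if (!file.exists(path)) stop("depth table not found: ", path)
  tab <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (all(c("sample", "chrom", "pos", "depth") %in% colnames(tab))) {
    if (any(tab$depth < 0)) stop("negative depth in depth table")
    tg <- panelTargets(panel)
    known <- as.character(GenomicRanges::seqnames(tg))
    off <- !(tab$chrom %in% known)
    if (any(off)) {
      warning(sum(off), " position(s) on chromosomes absent from the panel",
              " were skipped")
      tab <- tab[!off, , drop = FALSE]
    }
    pos <- GenomicRanges::GRanges(tab$chrom,
                                  IRanges::IRanges(tab$pos, width = 1L))
    hits <- GenomicRanges::findOverlaps(pos, tg)
    dropped <- nrow(tab) - length(unique(S4Vectors::queryHits(hits)))
    if (dropped > 0L)
      message(dropped, " position(s) outside panel targets dropped")
    samples <- sort(unique(tab$sample))
    ids <- S4Vectors::mcols(tg)$target_id
    depth <- matrix(0, nrow = length(tg), ncol = length(samples),
                    dimnames = list(ids, samples))
    qi <- S4Vectors::queryHits(hits); ti <- S4Vectors::subjectHits(hits)
    w <- GenomicRanges::width(tg)
    if (stat == "mean") {
      sums <- tapply(tab$depth[qi],
                     list(factor(ti, levels = seq_along(tg)),
                          factor(tab$sample[qi], levels = samples)),
                     sum)
      sums[is.na(sums)] <- 0
      depth <- sweep(sums, 1L, w, "/")
      dimnames(depth) <- list(ids, samples)
    } else {
      for (k in seq_along(samples)) {
        sel <- tab$sample[qi] == samples[k]
        for (t in unique(ti[sel])) {
          d <- tab$depth[qi[sel][ti[sel] == t]]
          depth[t, k] <- stats::median(c(d, rep(0, w[t] - length(d))))
        }
      }
    }
    PanelCoverage(depth, panel, batch = batch)
  } else {
    idcol <- colnames(tab)[1]
    depth <- as.matrix(tab[, -1, drop = FALSE])
    if (any(depth < 0)) stop("negative depth in depth table")
    rownames(depth) <- tab[[idcol]]
    PanelCoverage(depth, panel, batch = batch)
  }
}

#' Write a depth matrix as TSV
#'
#' @param x a \linkS4class{PanelCoverage}.
#' @param path output TSV (matrix layout readable by
#'   \code{\link{readDepthTable}}).
#' @export
writeDepthTable <- function(x, path) {
  d <- depthMatrix(x)
  df <- data.frame(target_id = rownames(d), d, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write CNV calls to TSV or a minimal structural-variant VCF
#'
#' The TSV layout is the package's canonical call table (one row per call)
#' and round-trips through \code{\link{readCnvCalls}}. The VCF dialect uses
#' symbolic \code{<DEL>}/\code{<DUP>} ALT alleles with \code{END},
#' \code{SVTYPE} and \code{CN} in INFO; gene-conversion calls are written
#' from their gene side as \code{<DEL>} with \code{SVCLASS=conversion}.
#'
#' @param calls a call table from \code{\link{segmentCalls}} or
#'   \code{\link{callCnvs}}.
#' @param path output file.
#' @param format \code{"tsv"} or \code{"vcf"}.
#' @export
writeCnvCalls <- function(calls, path, format = c("tsv", "vcf")) {
  format <- match.arg(format)
  if (format == "tsv") {
    utils::write.table(calls, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, na = "")
    return(invisible(path))
  }
  hdr <- c(
    "##fileformat=VCFv4.2",
    "##ALT=<ID=DEL,Description=\"Deletion\">",
    "##ALT=<ID=DUP,Description=\"Duplication\">",
    "##INFO=<ID=END,Number=1,Type=Integer,Description=\"End of the variant\">",
    "##INFO=<ID=SVTYPE,Number=1,Type=String,Description=\"Structural variant type\">",
    "##INFO=<ID=SVCLASS,Number=1,Type=String,Description=\"deletion, duplication or conversion\">",
    "##INFO=<ID=CN,Number=1,Type=Float,Description=\"Estimated copy number\">",
    "##INFO=<ID=GENE,Number=1,Type=String,Description=\"Gene symbol\">",
    "##INFO=<ID=EXONS,Number=1,Type=String,Description=\"First-last exon index\">",
    "##INFO=<ID=SAMPLE,Number=1,Type=String,Description=\"Sample id\">",
    "##INFO=<ID=ZYG,Number=1,Type=String,Description=\"Zygosity\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO"
  )
  rows <- character(0)
  if (nrow(calls) > 0L) {
    alt <- ifelse(calls$cnv_class == "duplication", "<DUP>", "<DEL>")
    svtype <- ifelse(calls$cnv_class == "duplication", "DUP", "DEL")
    info <- sprintf(
      "END=%d;SVTYPE=%s;SVCLASS=%s;CN=%.3f;GENE=%s;EXONS=%d-%d;SAMPLE=%s;ZYG=%s",
      calls$end, svtype, calls$cnv_class, calls$copy_number, calls$gene,
      calls$first_exon, calls$last_exon, calls$sample_id, calls$zygosity)
    rows <- sprintf("%s\t%d\t.\tN\t%s\t.\t.\t%s",
                    calls$chrom, calls$start + 1L, alt, info)
  }
  writeLines(c(hdr, rows), path)
  invisible(path)
}

#' Read CNV calls back from the TSV written by \code{writeCnvCalls}
#'
#' @param path TSV path.
#' @return the call table.
#' @export
readCnvCalls <- function(path) {
  if (!file.exists(path)) stop("call table not found: ", path)
  tmpl <- emptyCnvCalls()
  tab <- utils::read.delim(path, stringsAsFactors = FALSE,
                           colClasses = vapply(tmpl, class, character(1)),
                           na.strings = character(0))
  tab
}

#' Read small variants from a VCF
#'
#' A thin wrapper over \pkg{vcfR} extracting CHROM, POS, REF, ALT and the
#' per-sample GT field. Genotypes with at least one alternate allele become
#' one row per sample; zygosity is \code{"het"} with one alternate allele
#' and \code{"hom"} with two. Gene symbols are assigned by overlap with the
#' panel gene spans; a pathogenicity assertion is taken from the INFO flag
#' named by \code{pathogenicKey} when present, otherwise \code{FALSE}.
#'
#' @param path VCF path (4.x, plain text or bgzipped).
#' @param panel optional \linkS4class{CnvPanel} for gene assignment.
#' @param pathogenicKey INFO flag marking caller-asserted pathogenic sites.
#' @return \code{data.frame(sample_id, gene, chrom, pos, ref, alt, zygosity,
#'   pathogenic)} with 1-based positions.
#' @export
readSmallVariants <- function(path, panel = NULL, pathogenicKey = "PATHOGENIC") {
  if (!file.exists(path)) stop("VCF not found: ", path)
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- v@fix   # getFIX() drops INFO, which carries the pathogenic flag
  info <- fix[, "INFO"]
  info[is.na(info)] <- ""
  patho <- grepl(paste0("(^|;)", pathogenicKey, "(;|=|$)"), info)
  gt <- vcfR::extract.gt(v, element = "GT")
  out <- list()
  for (s in colnames(gt)) {
    g <- gt[, s]
    alleles <- lapply(strsplit(g, "[/|]"), function(a) suppressWarnings(as.integer(a)))
    nalt <- vapply(alleles, function(a) sum(a > 0, na.rm = TRUE), integer(1))
    keep <- which(nalt > 0L)
    if (length(keep) == 0L) next
    out[[s]] <- data.frame(
      sample_id = s,
      chrom = fix[keep, "CHROM"],
      pos = as.integer(fix[keep, "POS"]),
      ref = fix[keep, "REF"],
      alt = fix[keep, "ALT"],
      zygosity = ifelse(nalt[keep] >= 2L, "hom", "het"),
      pathogenic = patho[keep],
      stringsAsFactors = FALSE
    )
  }
  res <- if (length(out) > 0L) do.call(rbind, out) else
    data.frame(sample_id = character(0), chrom = character(0),
               pos = integer(0), ref = character(0), alt = character(0),
               zygosity = character(0), pathogenic = logical(0))
  rownames(res) <- NULL
  res$gene <- NA_character_
  if (!is.null(panel) && nrow(res) > 0L) {
    gr <- geneRanges(panel)
    pos <- GenomicRanges::GRanges(res$chrom,
                                  IRanges::IRanges(res$pos, width = 1L))
    # variants on chromosomes without panel targets simply get no gene
    hits <- suppressWarnings(GenomicRanges::findOverlaps(pos, gr))
    res$gene[S4Vectors::queryHits(hits)] <-
      names(gr)[S4Vectors::subjectHits(hits)]
  }
  res[, c("sample_id", "gene", "chrom", "pos", "ref", "alt",
          "zygosity", "pathogenic")]
}

#' Read repeat annotations
#'
#' \code{readRepeatMasker} parses the standard RepeatMasker \code{.out}
#' alignment table (whitespace-separated, 3 header lines). Repeat classes
#' are mapped to the package's closed family set: \code{SINE/Alu} to
#' \code{Alu}, \code{LINE/L1} to \code{L1}, \code{Simple_repeat} to
#' \code{simple_repeat}, everything else to \code{other}. Percent identity
#' is 100 minus the divergence column.
#'
#' \code{readRepeatBed} reads a BED-style table \code{chrom, start, end,
#' family[, identity_pct]} (0-based half-open) and is the expected route for
#' segmental-duplication tracks, which RepeatMasker does not report.
#'
#' @param path input file.
#' @return \code{GRanges} with metadata columns \code{family} and
#'   \code{identity_pct}.
#' @export
readRepeatMasker <- function(path) {
  if (!file.exists(path)) stop("RepeatMasker .out not found: ", path)
  lines <- readLines(path)
  lines <- lines[-seq_len(min(3L, length(lines)))]
  lines <- trimws(lines[nzchar(trimws(lines))])
  if (length(lines) == 0L)
    return(.repeatGRanges(character(0), integer(0), integer(0),
                          character(0), numeric(0)))
  fld <- strsplit(lines, "[[:space:]]+")
  chrom <- vapply(fld, `[[`, character(1), 5L)
  start1 <- as.integer(vapply(fld, `[[`, character(1), 6L))
  end <- as.integer(vapply(fld, `[[`, character(1), 7L))
  div <- as.numeric(vapply(fld, `[[`, character(1), 2L))
  cls <- vapply(fld, `[[`, character(1), 11L)
  family <- rep("other", length(cls))
  family[startsWith(cls, "SINE/Alu")] <- "Alu"
  family[startsWith(cls, "LINE/L1")] <- "L1"
  family[startsWith(cls, "Simple_repeat")] <- "simple_repeat"
  .repeatGRanges(chrom, start1 - 1L, end, family, 100 - div)
}

#' @rdname readRepeatMasker
#' @export
readRepeatBed <- function(path) {
  if (!file.exists(path)) stop("repeat BED not found: ", path)
  tab <- utils::read.table(path, sep = "\t", stringsAsFactors = FALSE)
  if (ncol(tab) < 4L) stop("repeat BED needs chrom, start, end, family")
  fam <- tab[[4]]
  ok <- fam %in% c("Alu", "L1", "segdup", "simple_repeat", "other")
  if (!all(ok))
    stop("unknown repeat family: ", paste(unique(fam[!ok]), collapse = ", "))
  ident <- if (ncol(tab) >= 5L) as.numeric(tab[[5]]) else
    rep(NA_real_, nrow(tab))
  .repeatGRanges(tab[[1]], tab[[2]], tab[[3]], fam, ident)
}

.repeatGRanges <- function(chrom, start0, end, family, identity) {
  if (length(start0) > 0L && any(end <= start0))
    stop("repeat annotation with end <= start")
  gr <- GenomicRanges::GRanges(chrom,
                               IRanges::IRanges(start = start0 + 1L, end = end))
  S4Vectors::mcols(gr) <- S4Vectors::DataFrame(family = family,
                                               identity_pct = identity)
  gr
}

#' Export per-gene ratio-plot data
#'
#' Returns (and optionally writes) the data behind a per-gene read-depth
#' ratio plot: one row per target with its genomic midpoint and the
#' sample's normalized ratio, the layout used for visualising deletion,
#' duplication and conversion signatures along a locus.
#'
#' @param x a normalized \linkS4class{PanelCoverage}.
#' @param sample sample id.
#' @param genes gene symbols to include (default all).
#' @param path optional TSV output path.
#' @return \code{data.frame(gene, target_id, exon_index, midpoint, ratio,
#'   masked)}.
#' @export
ratioTrack <- function(x, sample, genes = NULL, path = NULL) {
  r <- ratioMatrix(x)
  if (!sample %in% colnames(r)) stop("unknown sample: ", sample)
  tg <- panelTargets(x)
  mc <- S4Vectors::mcols(tg)
  sel <- if (is.null(genes)) rep(TRUE, length(tg)) else mc$gene %in% genes
  df <- data.frame(
    gene = mc$gene[sel],
    target_id = mc$target_id[sel],
    exon_index = mc$exon_index[sel],
    midpoint = (GenomicRanges::start(tg)[sel] +
                GenomicRanges::end(tg)[sel]) / 2,
    ratio = r[sel, sample],
    masked = maskedTargets(x)[sel],
    row.names = NULL
  )
  if (!is.null(path))
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  df
}
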
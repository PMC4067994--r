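#' Assign per-patient causative categories
#'
#' Combines residual CNV calls, conversion events and heterozygous
#' pathogenic small variants into one diagnostic category per
#' (sample, gene), by precedence:
#' \enumerate{
#'   \item \code{hom_cnv} - a homozygous deletion;
#'   \item \code{biallelic_cnv} - two abnormal alleles of different kinds
#'     (e.g. a deletion opposite a conversion) or a biallelic conversion;
#'   \item \code{hemizygous_cnv_plus_snv} - one heterozygous CNV allele in
#'     trans with a heterozygous pathogenic small variant in the same gene;
#'   \item \code{contiguous_multi_gene} - membership in a heterozygous
#'     multi-gene contiguous deletion group;
#'   \item \code{carrier_only} - any remaining CNV.
#' }
#' Recessive logic requires two hit alleles. For autosomal-dominant genes a
#' single heterozygous CNV is never automatically causative: it is returned
#' as \code{carrier_only} with \code{needs_review = TRUE} plus a
#' reading-frame hint (deleted exon lengths summing to a multiple of 3 are
#' annotated in-frame), mirroring expert adjudication of dominant CNVs.
#'
#' @param calls residual call table (after \code{\link{detectConversions}}).
#' @param conversions conversion table.
#' @param smallVariants optional table from \code{\link{readSmallVariants}};
#'   a variant in a gene absent from the panel is an error.
#' @param panel the \linkS4class{CnvPanel} (inheritance modes).
#' @return \code{data.frame(sample_id, gene, category,
#'   inheritance_consistent, needs_review, frame)}.
#' @export
classifyCausative <- function(calls, conversions, smallVariants = NULL,
                              panel) {
  genes <- panelGenes(panel)
  if (!is.null(smallVariants) && nrow(smallVariants) > 0L) {
    known <- smallVariants$gene[!is.na(smallVariants$gene)]
    if (!all(known %in% genes$symbol))
      stop("small variant in gene absent from panel: ",
           paste(setdiff(known, genes$symbol), collapse = ", "))
  }
  combos <- unique(rbind(calls[, c("sample_id", "gene")],
                         conversions[, c("sample_id", "gene")]))
  if (nrow(combos) == 0L)
    return(data.frame(sample_id = character(0), gene = character(0),
                      category = character(0),
                      inheritance_consistent = logical(0),
                      needs_review = logical(0), frame = character(0)))
  tg <- panelTargets(panel)
  mc <- S4Vectors::mcols(tg)
  rows <- lapply(seq_len(nrow(combos)), function(k) {
    s <- combos$sample_id[k]; g <- combos$gene[k]
    cc <- calls[calls$sample_id == s & calls$gene == g, , drop = FALSE]
    cv <- conversions[conversions$sample_id == s & conversions$gene == g, ,
                      drop = FALSE]
    mode <- genes$inheritance[match(g, genes$symbol)]
    homDel <- any(cc$cnv_class == "deletion" & cc$zygosity %in% "hom")
    hetDel <- sum(cc$cnv_class == "deletion" &
                  cc$zygosity %in% c("het", "hemizygous"))
    convAlleles <- sum(cv$alleles)
    hasDup <- any(cc$cnv_class == "duplication")
    hasSnv <- !is.null(smallVariants) && nrow(smallVariants) > 0L &&
      any(smallVariants$sample_id == s & smallVariants$gene %in% g &
          smallVariants$zygosity == "het" & smallVariants$pathogenic)
    contiguous <- any(hasFlag(cc$flags, "multi_gene_contiguous"))
    recessive <- mode %in% c("AR", "both", "XL")
    category <-
      if (homDel && recessive) "hom_cnv"
      else if (recessive &&
               ((hetDel >= 1L && convAlleles >= 1L) || convAlleles >= 2L))
        "biallelic_cnv"
      else if (recessive && (hetDel + convAlleles) >= 1L && hasSnv)
        "hemizygous_cnv_plus_snv"
      else if (contiguous) "contiguous_multi_gene"
      else "carrier_only"
    hits <- 2L * homDel + hetDel + convAlleles
    consistent <- if (mode == "AD") hits >= 1L || hasDup else
      category == "carrier_only" || hits >= 2L
    review <- mode == "AD" && (hetDel + hasDup) >= 1L && !homDel
    dels <- cc[cc$cnv_class == "deletion", , drop = FALSE]
    frame <- NA_character_
    if (nrow(dels) > 0L) {
      w <- 0L
      for (d in seq_len(nrow(dels))) {
        sel <- mc$gene == g & mc$exon_index >= dels$first_exon[d] &
          mc$exon_index <= dels$last_exon[d]
        w <- w + sum(GenomicRanges::width(tg)[sel])
      }
      frame <- if (w %% 3L == 0L) "in_frame" else "out_of_frame"
    }
    data.frame(sample_id = s, gene = g, category = category,
               inheritance_consistent = consistent, needs_review = review,
               frame = frame, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Expand calls and conversions into per-allele CNV records
#'
#' The cohort summary counts CNVs per affected allele, the convention of
#' diagnostic reporting at these loci: a homozygous event contributes two
#' records, a heterozygous one, a conversion as many as its allele count.
#' Causative status is looked up from the assignment table (categories
#' other than \code{carrier_only} mark the gene's records causative).
#'
#' @param calls residual call table.
#' @param conversions conversion table.
#' @param assignments output of \code{\link{classifyCausative}}.
#' @return \code{data.frame(patient, gene, cnv_class, causative, category)}.
#' @export
cnvRecords <- function(calls, conversions, assignments = NULL) {
  lookup <- function(s, g) {
    if (is.null(assignments)) return("carrier_only")
    hit <- assignments$category[assignments$sample_id == s &
                                assignments$gene == g]
    if (length(hit) == 0L) "carrier_only" else hit[1]
  }
  rows <- list()
  for (k in seq_len(nrow(calls))) {
    n <- if (identical(calls$zygosity[k], "hom")) 2L else 1L
    cat <- lookup(calls$sample_id[k], calls$gene[k])
    rows[[length(rows) + 1L]] <- data.frame(
      patient = calls$sample_id[k], gene = calls$gene[k],
      cnv_class = calls$cnv_class[k],
      causative = cat != "carrier_only", category = cat,
      stringsAsFactors = FALSE)[rep(1L, n), , drop = FALSE]
  }
  for (k in seq_len(nrow(conversions))) {
    cat <- lookup(conversions$sample_id[k], conversions$gene[k])
    rows[[length(rows) + 1L]] <- data.frame(
      patient = conversions$sample_id[k], gene = conversions$gene[k],
      cnv_class = "conversion",
      causative = cat != "carrier_only", category = cat,
      stringsAsFactors = FALSE)[rep(1L, conversions$alleles[k]), ,
                                drop = FALSE]
  }
  out <- do.call(rbind, c(rows, list(
    data.frame(patient = character(0), gene = character(0),
               cnv_class = character(0), causative = logical(0),
               category = character(0)))))
  rownames(out) <- NULL
  out
}

#' Summarize a cohort's CNV records
#'
#' Exhaustive tallies of per-allele CNV records: a per-gene table (total,
#' carrier and causative records and the deletion / conversion /
#' duplication split, each with its column percentage) plus cohort
#' scalars (carrier frequency of CNVs per patient tested, fraction of
#' patients with at least one CNV, fraction of diagnoses involving a CNV,
#' class proportions and the causative-category split). All percentages
#' are rounded half-away-from-zero: per-gene column percentages and
#' category percentages to integers, cohort scalars to one decimal.
#'
#' @param records per-allele record table (\code{\link{cnvRecords}} or
#'   \code{\link{deafnessCohortFixture}}).
#' @param nTested number of patients tested.
#' @param nDiagnosed number of patients with any genetic diagnosis; must
#'   not exceed \code{nTested}.
#' @return a \code{CohortSummary} list: \code{byGene}, \code{classTotals},
#'   \code{categories}, \code{scalars}.
#' @export
summarizeCohort <- function(records, nTested, nDiagnosed) {
  if (nDiagnosed > nTested)
    stop("nDiagnosed cannot exceed nTested")
  nCnv <- nrow(records)
  genes <- unique(records$gene)
  tab <- do.call(rbind, lapply(genes, function(g) {
    r <- records[records$gene == g, , drop = FALSE]
    data.frame(gene = g,
               total_cnvs = nrow(r),
               carrier_cnvs = sum(!r$causative),
               causative_cnvs = sum(r$causative),
               deletions = sum(r$cnv_class == "deletion"),
               conversions = sum(r$cnv_class == "conversion"),
               duplications = sum(r$cnv_class == "duplication"),
               stringsAsFactors = FALSE)
  }))
  if (is.null(tab)) tab <- data.frame(
    gene = character(0), total_cnvs = integer(0), carrier_cnvs = integer(0),
    causative_cnvs = integer(0), deletions = integer(0),
    conversions = integer(0), duplications = integer(0))
  tab <- tab[order(-tab$total_cnvs, tab$gene), , drop = FALSE]
  rownames(tab) <- NULL
  colTot <- colSums(tab[, -1, drop = FALSE])
  pct <- function(x, tot) {
    if (tot > 0) roundHalfUp(x / tot * 100) else rep(NA_real_, length(x))
  }
  tab$total_pct <- pct(tab$total_cnvs, colTot["total_cnvs"])
  tab$carrier_pct <- pct(tab$carrier_cnvs, colTot["carrier_cnvs"])
  tab$causative_pct <- pct(tab$causative_cnvs, colTot["causative_cnvs"])
  tab$deletions_pct <- pct(tab$deletions, colTot["deletions"])
  tab$conversions_pct <- pct(tab$conversions, colTot["conversions"])
  tab$duplications_pct <- pct(tab$duplications, colTot["duplications"])

  nPat <- length(unique(records$patient))
  causPat <- unique(records$patient[records$causative])
  nDiag <- length(causPat)
  patCat <- function(cat) length(unique(
    records$patient[records$causative & records$category == cat]))
  categories <- data.frame(
    category = c("hom_cnv", "hemizygous_cnv_plus_snv", "biallelic_cnv",
                 "contiguous_multi_gene"),
    ## the contiguous category is tallied as causative CNV records (one
    ## patient's multi-gene deletion counts once per gene hit); the others
    ## as patients
    n = c(patCat("hom_cnv"), patCat("hemizygous_cnv_plus_snv"),
          patCat("biallelic_cnv"),
          sum(records$causative &
              records$category == "contiguous_multi_gene")),
    stringsAsFactors = FALSE
  )
  categories$pct <- if (nDiag > 0) roundHalfUp(categories$n / nDiag * 100)
    else NA
  scalars <- list(
    n_tested = nTested, n_diagnosed = nDiagnosed, n_cnvs = nCnv,
    n_patients_with_cnv = nPat, n_cnv_diagnosed = nDiag,
    overall_carrier_freq_pct = roundHalfUp(nCnv / nTested * 100, 1),
    patients_with_cnv_pct = roundHalfUp(nPat / nTested * 100, 1),
    diagnoses_cnv_pct = if (nDiagnosed > 0)
      roundHalfUp(nDiag / nDiagnosed * 100, 1) else NA,
    deletions_pct = if (nCnv > 0)
      roundHalfUp(sum(records$cnv_class == "deletion") / nCnv * 100, 1)
      else NA,
    conversions_pct = if (nCnv > 0)
      roundHalfUp(sum(records$cnv_class == "conversion") / nCnv * 100, 1)
      else NA,
    duplications_pct = if (nCnv > 0)
      roundHalfUp(sum(records$cnv_class == "duplication") / nCnv * 100, 1)
      else NA
  )
  structure(list(byGene = tab, classTotals = colTot,
                 categories = categories, scalars = scalars),
            class = "CohortSummary")
}

#' @export
print.CohortSummary <- function(x, ...) {
  s <- x$scalars
  cat("Cohort CNV summary: ", s$n_cnvs, " CNVs in ",
      s$n_patients_with_cnv, " of ", s$n_tested, " patients (",
      s$patients_with_cnv_pct, "%)\n", sep = "")
  cat("  causative in ", s$n_cnv_diagnosed, " of ", s$n_diagnosed,
      " diagnosed patients (", s$diagnoses_cnv_pct, "%)\n", sep = "")
  cat("  class split: ", s$deletions_pct, "% deletions, ",
      s$conversions_pct, "% conversions, ", s$duplications_pct,
      "% duplications\n", sep = "")
  print(utils::head(x$byGene, 10), row.names = FALSE)
  invisible(x)
}

#' Fraction of patients with a causative CNV in one gene
#'
#' @param records per-allele record table.
#' @param gene gene symbol.
#' @param nTested cohort size.
#' @return fraction of tested patients carrying at least one causative
#'   CNV record in the gene.
#' @export
causativeRate <- function(records, gene, nTested) {
  length(unique(records$patient[records$gene == gene &
                                records$causative])) / nTested
}

#' Carrier allele frequency of a CNV class at a locus
#'
#' Carrier alleles over 2x the number of individuals tested. On per-allele
#' record tables each record is one allele; on call tables homozygous
#' events contribute two alleles and heterozygous events one.
#'
#' @param x record table (\code{patient/gene/cnv_class}) or call table
#'   (with a \code{zygosity} column).
#' @param nSamples number of individuals tested (> 0).
#' @param locus gene symbol.
#' @param cnvClass \code{"deletion"}, \code{"conversion"} or
#'   \code{"duplication"}.
#' @return allele frequency as a fraction.
#' @export
#' @examples
#' # 65 deletion alleles among 686 individuals -> 65/1372 = 4.7%
carrierFrequency <- function(x, nSamples, locus, cnvClass) {
  if (nSamples <= 0) stop("nSamples must be positive")
  sel <- x$gene == locus & x$cnv_class == cnvClass
  alleles <- if ("zygosity" %in% colnames(x)) {
    sum(ifelse(x$zygosity[sel] %in% "hom", 2L, 1L))
  } else {
    sum(sel)
  }
  alleles / (2 * nSamples)
}
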
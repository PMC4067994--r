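#' Detect gene-pseudogene conversions among CNV calls
#'
#' A non-allelic gene conversion replaces gene sequence with pseudogene
#' sequence: in read-depth space the gene targets lose copies while the
#' homologous pseudogene targets gain them reciprocally. For every
#' deletion call in a gene with pseudogene partner links, this searches
#' the same sample's duplication calls for one covering at least
#' \code{overlapFrac} of the partner images of the deleted exons, and
#' checks copy conservation: the gene-side copy loss and pseudogene-side
#' copy gain must agree within \code{reciprocityTol} copies (summed copy
#' number of a converted pair stays ~4). On a match both calls are
#' consumed and one conversion event is emitted, with the allele count
#' taken from the gene-side zygosity (hom = 2, het = 1). Plain deletions
#' without a reciprocal pseudogene gain stay deletions.
#'
#' @param calls a call table from \code{\link{callCnvs}}.
#' @param panel the \linkS4class{CnvPanel} defining partner links.
#' @param overlapFrac minimum fraction of the deletion's exons whose
#'   partner images the duplication must cover (default 0.8).
#' @param reciprocityTol allowed copy-number mismatch between gene loss
#'   and pseudogene gain (default 0.6 copies).
#' @return list with \code{conversions} (\code{sample_id, gene,
#'   pseudogene, first_exon, last_exon, alleles, cn_gene, cn_pseudo}) and
#'   \code{residual} (the calls not consumed).
#' @export
detectConversions <- function(calls, panel, overlapFrac = 0.8,
                              reciprocityTol = 0.6) {
  mc <- S4Vectors::mcols(panelTargets(panel))
  consumed <- rep(FALSE, nrow(calls))
  events <- list()
  dels <- which(calls$cnv_class == "deletion")
  dups <- which(calls$cnv_class == "duplication")
  for (i in dels) {
    sel <- mc$gene == calls$gene[i] &
      mc$exon_index >= calls$first_exon[i] &
      mc$exon_index <= calls$last_exon[i]
    partners <- mc$pseudo_partner[sel]
    if (all(is.na(partners))) next
    images <- partners[!is.na(partners)]
    pgene <- unique(mc$gene[match(images, mc$target_id)])
    if (length(pgene) != 1L) next
    for (j in dups) {
      if (consumed[j] || calls$sample_id[j] != calls$sample_id[i] ||
          calls$gene[j] != pgene) next
      dupsel <- mc$gene == pgene &
        mc$exon_index >= calls$first_exon[j] &
        mc$exon_index <= calls$last_exon[j]
      covered <- sum(images %in% mc$target_id[dupsel])
      if (covered / sum(sel) < overlapFrac) next
      loss <- 2 - calls$copy_number[i]
      gain <- calls$copy_number[j] - 2
      if (abs(loss - gain) > reciprocityTol) next
      alleles <- if (identical(calls$zygosity[i], "hom")) 2L else 1L
      events[[length(events) + 1L]] <- data.frame(
        sample_id = calls$sample_id[i], gene = calls$gene[i],
        pseudogene = pgene,
        first_exon = calls$first_exon[i], last_exon = calls$last_exon[i],
        alleles = alleles,
        cn_gene = calls$copy_number[i], cn_pseudo = calls$copy_number[j],
        stringsAsFactors = FALSE
      )
      consumed[c(i, j)] <- TRUE
      break
    }
  }
  conversions <- if (length(events) > 0L) do.call(rbind, events) else
    emptyConversions()
  list(conversions = conversions,
       residual = calls[!consumed, , drop = FALSE])
}

#' Diagnose the STRC/CATSPER2 locus for one sample
#'
#' Combines residual deletion calls and conversion events over the
#' chromosome 15 deafness-infertility locus into a per-allele STRC status
#' (\code{intact}, \code{deleted}, \code{converted} or \code{duplicated}),
#' reports whether CATSPER2 is involved in any deletion, and sets the
#' deafness-infertility-syndrome (DIS) verdict: DIS requires homozygous
#' loss of both STRC and CATSPER2. A deletion touching only CATSPER2 and
#' the pseudogene leaves STRC intact and never yields DIS; a biallelic
#' STRC conversion nulls both alleles but spares CATSPER2, so it is
#' non-syndromic.
#'
#' @param calls residual call table (after \code{\link{detectConversions}}).
#' @param conversions conversion table from \code{\link{detectConversions}}.
#' @param sample sample id.
#' @param panel the \linkS4class{CnvPanel}; must contain \code{strcGene}.
#' @param strcGene,catsper2Gene gene symbols at the locus (defaults
#'   \code{"STRC"}, \code{"CATSPER2"}); CATSPER2 coverage depends on panel
#'   version and \code{catsper2_involved} is \code{NA} when absent.
#' @return one-row \code{data.frame(sample_id, allele1, allele2,
#'   catsper2_involved, dis)}.
#' @export
diagnoseStrcLocus <- function(calls, conversions, sample, panel,
                              strcGene = "STRC", catsper2Gene = "CATSPER2") {
  genes <- panelGenes(panel)$symbol
  if (!strcGene %in% genes)
    stop(strcGene, " is not on this panel")
  sc <- calls[calls$sample_id == sample & calls$gene == strcGene, ,
              drop = FALSE]
  cv <- conversions[conversions$sample_id == sample &
                    conversions$gene == strcGene, , drop = FALSE]
  alleles <- c("intact", "intact")
  fill <- function(alleles, status, n) {
    free <- which(alleles == "intact")
    take <- free[seq_len(min(n, length(free)))]
    alleles[take] <- status
    alleles
  }
  for (k in seq_len(nrow(sc))) {
    if (sc$cnv_class[k] == "deletion") {
      n <- if (identical(sc$zygosity[k], "hom")) 2L else 1L
      alleles <- fill(alleles, "deleted", n)
    } else if (sc$cnv_class[k] == "duplication") {
      n <- if (identical(sc$zygosity[k], "hom")) 2L else 1L
      alleles <- fill(alleles, "duplicated", n)
    }
  }
  for (k in seq_len(nrow(cv)))
    alleles <- fill(alleles, "converted", cv$alleles[k])
  if (catsper2Gene %in% genes) {
    cc <- calls[calls$sample_id == sample & calls$gene == catsper2Gene &
                calls$cnv_class == "deletion", , drop = FALSE]
    catsper2Involved <- nrow(cc) > 0L
    catsper2Hom <- any(cc$zygosity == "hom", na.rm = TRUE)
  } else {
    catsper2Involved <- NA
    catsper2Hom <- FALSE
  }
  dis <- all(alleles == "deleted") && isTRUE(catsper2Hom)
  data.frame(sample_id = sample, allele1 = alleles[1], allele2 = alleles[2],
             catsper2_involved = catsper2Involved, dis = dis,
             stringsAsFactors = FALSE)
}
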
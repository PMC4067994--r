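#' Simulation configuration for synthetic capture cohorts
#'
#' Bundles the knobs of the cohort simulator. Depth at a target is
#' negative-binomial: each sequenced position of a target of length L
#' contributes an independent NB draw with mean
#' \code{baseDepth * eff_t * lib_s * cn/2} and size \code{dispersion}, and
#' the reported per-target depth is their mean (drawn exactly as
#' \code{NB(L*mu, L*dispersion)/L}). \code{dispersion} is therefore the
#' per-position inverse-overdispersion: small values give heavily
#' overdispersed coverage, large values approach Poisson-like noise, and
#' averaging over the target length shrinks the per-target coefficient of
#' variation the way pileup-derived mean depths do in practice.
#'
#' @param nSamples number of samples.
#' @param batchSize maximum samples per batch (default 48, one flow-cell
#'   pool); batches are filled in sample order.
#' @param baseDepth expected fold-coverage of a diploid target with unit
#'   efficiency (default 700, the hundreds-to-thousands-fold regime of
#'   targeted enrichment).
#' @param targetEfficiencySd log-normal sd of per-target capture efficiency
#'   (default 0.3).
#' @param sampleSizeSd log-normal sd of per-sample library-size factors
#'   (default 0.2).
#' @param dispersion per-position negative-binomial size (> 0, default 10).
#' @param seed RNG seed; the same seed reproduces the cohort bit for bit.
#' @param events list of \code{\link{spikeEvent}} objects.
#' @return a \code{SimulationConfig} list.
#' @export
simulationConfig <- function(nSamples = 24L, batchSize = 48L,
                             baseDepth = 700, targetEfficiencySd = 0.3,
                             sampleSizeSd = 0.2, dispersion = 10,
                             seed = 1L, events = list()) {
  stopifnot(nSamples >= 2L, batchSize >= 2L, baseDepth > 0, dispersion > 0,
            targetEfficiencySd >= 0, sampleSizeSd >= 0)
  structure(list(nSamples = as.integer(nSamples),
                 batchSize = as.integer(batchSize),
                 baseDepth = baseDepth,
                 targetEfficiencySd = targetEfficiencySd,
                 sampleSizeSd = sampleSizeSd,
                 dispersion = dispersion, seed = seed,
                 events = events),
            class = "SimulationConfig")
}

#' A spiked copy-number event for the simulator
#'
#' @param sample sample id (\code{"S001"} style, assigned in order).
#' @param gene gene symbol in the panel.
#' @param exonRange inclusive \code{c(first, last)} exon ordinals.
#' @param kind \code{"deletion"}, \code{"duplication"} or
#'   \code{"conversion"} (reciprocal gene-to-pseudogene exchange; requires
#'   every exon in range to carry a pseudogene partner).
#' @param alleles 1 (monoallelic) or 2 (biallelic).
#' @return a \code{SpikeEvent} list.
#' @export
spikeEvent <- function(sample, gene, exonRange,
                       kind = c("deletion", "duplication", "conversion"),
                       alleles = 1L) {
  kind <- match.arg(kind)
  stopifnot(length(exonRange) == 2L, exonRange[1] <= exonRange[2],
            alleles %in% c(1L, 2L))
  structure(list(sample = sample, gene = gene,
                 exonRange = as.integer(exonRange), kind = kind,
                 alleles = as.integer(alleles)),
            class = "SpikeEvent")
}

#' Expected copy number per target under a set of spiked events
#'
#' Builds the truth matrix the simulator draws from: every (target, sample)
#' starts at copy number 2; deletions subtract and duplications add
#' \code{alleles} copies over the gene targets in range; conversions move
#' \code{alleles} copies from the gene targets to their pseudogene partner
#' targets reciprocally, so the summed copy number of a converted pair
#' stays 4.
#'
#' @param panel a \linkS4class{CnvPanel}.
#' @param events list of \code{\link{spikeEvent}}s.
#' @param samples character vector of sample ids.
#' @return a \code{TruthSet}: list with \code{cn} (targets x samples
#'   matrix) and \code{events}.
#' @export
expectedCopyNumber <- function(panel, events, samples) {
  tg <- panelTargets(panel)
  mc <- S4Vectors::mcols(tg)
  cn <- matrix(2, nrow = length(tg), ncol = length(samples),
               dimnames = list(mc$target_id, samples))
  truth <- structure(list(cn = cn, events = list()), class = "TruthSet")
  for (ev in events) truth <- applySpike(truth, ev, panel)
  truth
}

applySpike <- function(truth, ev, panel) {
  mc <- S4Vectors::mcols(panelTargets(panel))
  if (!ev$sample %in% colnames(truth$cn))
    stop("spike references unknown sample: ", ev$sample)
  sel <- mc$gene == ev$gene & mc$exon_index >= ev$exonRange[1] &
    mc$exon_index <= ev$exonRange[2]
  if (!any(mc$gene == ev$gene))
    stop("spike references unknown gene: ", ev$gene)
  if (sum(sel) != ev$exonRange[2] - ev$exonRange[1] + 1L)
    stop("spike references exons absent from ", ev$gene, ": ",
         ev$exonRange[1], "-", ev$exonRange[2])
  s <- ev$sample
  if (ev$kind == "deletion") {
    truth$cn[sel, s] <- pmax(0, truth$cn[sel, s] - ev$alleles)
  } else if (ev$kind == "duplication") {
    truth$cn[sel, s] <- truth$cn[sel, s] + ev$alleles
  } else {
    partners <- mc$pseudo_partner[sel]
    if (anyNA(partners))
      stop("conversion requires a pseudogene partner for every exon in ",
           ev$gene, " ", ev$exonRange[1], "-", ev$exonRange[2])
    pidx <- match(partners, mc$target_id)
    truth$cn[sel, s] <- pmax(0, truth$cn[sel, s] - ev$alleles)
    truth$cn[pidx, s] <- truth$cn[pidx, s] + ev$alleles
  }
  truth$events <- c(truth$events, list(ev))
  truth
}

#' Add a reciprocal gene-conversion event to an existing truth set
#'
#' @param truth a \code{TruthSet} from \code{\link{expectedCopyNumber}}.
#' @param sample,gene,exonRange,alleles as in \code{\link{spikeEvent}}.
#' @param panel the \linkS4class{CnvPanel} defining partner links.
#' @return the updated \code{TruthSet}.
#' @export
spikeConversion <- function(truth, sample, gene, exonRange, alleles, panel) {
  applySpike(truth,
             spikeEvent(sample, gene, exonRange, "conversion", alleles),
             panel)
}

#' Simulate a targeted-enrichment cohort with known CNV truth
#'
#' Draws a seeded synthetic depth matrix over a panel: per-target capture
#' efficiencies and per-sample library factors are log-normal, copy-number
#' truth comes from the spiked events, and per-target mean depth is
#' negative-binomial as documented in \code{\link{simulationConfig}}.
#' Batch labels are assigned by fill order (\code{batchSize} samples per
#' batch). The same seed reproduces the cohort exactly.
#'
#' @param config a \code{\link{simulationConfig}}.
#' @param panel a \linkS4class{CnvPanel}.
#' @return list with \code{coverage} (a \linkS4class{PanelCoverage} holding
#'   the \code{depth} assay), \code{truth} (the \code{TruthSet}),
#'   \code{efficiency} and \code{libSize} (the drawn nuisance factors).
#' @export
simulateCohort <- function(config, panel) {
  stopifnot(inherits(config, "SimulationConfig"))
  tg <- panelTargets(panel)
  n <- config$nSamples
  samples <- sprintf("S%03d", seq_len(n))
  batch <- sprintf("B%02d", ceiling(seq_len(n) / config$batchSize))
  if (min(table(batch)) < 2L)
    stop("batch fill order leaves a batch with a single sample; ",
         "adjust nSamples or batchSize")
  set.seed(config$seed)
  Tn <- length(tg)
  eff <- stats::rlnorm(Tn, meanlog = 0, sdlog = config$targetEfficiencySd)
  lib <- stats::rlnorm(n, meanlog = 0, sdlog = config$sampleSizeSd)
  truth <- expectedCopyNumber(panel, config$events, samples)
  L <- GenomicRanges::width(tg)
  mu <- config$baseDepth * outer(eff, lib) * truth$cn / 2
  depth <- matrix(
    stats::rnbinom(Tn * n, mu = as.vector(mu * L),
                   size = as.vector(L * config$dispersion)) / rep(L, n),
    nrow = Tn, ncol = n,
    dimnames = list(S4Vectors::mcols(tg)$target_id, samples))
  cov <- PanelCoverage(depth, panel, batch = batch)
  list(coverage = cov, truth = truth,
       efficiency = stats::setNames(eff, rownames(depth)),
       libSize = stats::setNames(lib, samples))
}
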
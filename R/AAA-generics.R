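#' @import methods
NULL

#' @rdname CnvPanel-class
#' @param x a \code{CnvPanel} or \code{PanelCoverage} object.
#' @export
setGeneric("panelTargets", function(x) standardGeneric("panelTargets"))

#' @rdname CnvPanel-class
#' @export
setGeneric("panelGenes", function(x) standardGeneric("panelGenes"))

#' @rdname CnvPanel-class
#' @export
setGeneric("panelName", function(x) standardGeneric("panelName"))

#' @rdname CnvPanel-class
#' @export
setGeneric("geneRanges", function(x) standardGeneric("geneRanges"))

#' @rdname PanelCoverage-class
#' @export
setGeneric("depthMatrix", function(x) standardGeneric("depthMatrix"))

#' @rdname PanelCoverage-class
#' @export
setGeneric("ratioMatrix", function(x) standardGeneric("ratioMatrix"))

#' @rdname PanelCoverage-class
#' @export
setGeneric("smoothedMatrix", function(x) standardGeneric("smoothedMatrix"))

#' @rdname PanelCoverage-class
#' @export
setGeneric("batchLabels", function(x) standardGeneric("batchLabels"))

#' @rdname PanelCoverage-class
#' @export
setGeneric("maskedTargets", function(x) standardGeneric("maskedTargets"))
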
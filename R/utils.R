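#' Round half away from zero
#'
#' Rounds to `digits` decimal places with ties going away from zero
#' (so 0.5 -> 1, -0.5 -> -1), the convention used for all printed
#' percentages in cohort summaries. Base R's `round()` rounds half to
#' even, which disagrees on exact ties.
#'
#' @param x numeric vector.
#' @param digits integer, decimal places (default 0).
#' @return numeric vector of the same length.
#' @export
#' @examples
#' roundHalfUp(20.85, 1)   # 20.9, not 20.8
#' roundHalfUp(38.46)      # 38
roundHalfUp <- function(x, digits = 0) {
  p <- 10^digits
  trunc(abs(x) * p + 0.5) * sign(x) / p
}

## internal: collapse a character vector of flags to one comma string
joinFlags <- function(flags) {
  flags <- unique(flags[nzchar(flags)])
  if (length(flags) == 0L) "" else paste(sort(flags), collapse = ",")
}

hasFlag <- function(flagString, flag) {
  vapply(strsplit(flagString, ",", fixed = TRUE),
         function(fs) flag %in% fs, logical(1))
}

addFlag <- function(flagString, flag) {
  vapply(flagString, function(fs) {
    parts <- strsplit(fs, ",", fixed = TRUE)[[1]]
    joinFlags(c(parts, flag))
  }, character(1), USE.NAMES = FALSE)
}

## internal: canonical empty CNV call table (column contract for all callers)
emptyCnvCalls <- function() {
  data.frame(
    sample_id   = character(0),
    gene        = character(0),
    chrom       = character(0),
    start       = integer(0),
    end         = integer(0),
    first_exon  = integer(0),
    last_exon   = integer(0),
    cnv_class   = character(0),
    zygosity    = character(0),
    mean_ratio  = numeric(0),
    n_targets   = integer(0),
    copy_number = numeric(0),
    flags       = character(0),
    contig_group = character(0),
    stringsAsFactors = FALSE
  )
}

emptyConversions <- function() {
  data.frame(
    sample_id  = character(0),
    gene       = character(0),
    pseudogene = character(0),
    first_exon = integer(0),
    last_exon  = integer(0),
    alleles    = integer(0),
    cn_gene    = numeric(0),
    cn_pseudo  = numeric(0),
    stringsAsFactors = FALSE
  )
}
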
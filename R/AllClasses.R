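#' GenotypeData: samples x biallelic markers with genomic coordinates
#'
#' `GenotypeData` extends [SummarizedExperiment::RangedSummarizedExperiment].
#' The single assay, `"dosage"`, holds the alternate-allele count per
#' (marker, sample) as an integer in \{0, 1, 2\} with `NA` for a missing call;
#' missing calls are never imputed. Rows are markers carried as a width-one
#' [GenomicRanges::GRanges] (the marker map: chromosome, 1-based position,
#' `ref`/`alt` allele labels in `mcols`), with chromosome lengths in the
#' `seqinfo` (the genome layout used as denominator of marker density and
#' F_ROH). Columns are samples; `colData` carries the sample metadata (sex,
#' birth year, origin, camp, recorded dam).
#'
#' Class invariants, enforced by the validity method:
#' * every dosage is 0, 1, 2 or `NA`;
#' * sample identifiers are unique;
#' * positions are strictly increasing within each chromosome;
#' * where a chromosome length is declared, no marker lies beyond it.
#'
#' @seealso [GenotypeData()] for the constructor, [readVcfGenotypes()],
#'   [readPlinkText()] for I/O.
#' @aliases GenotypeData-class
#' @exportClass GenotypeData
setClass("GenotypeData", contains = "RangedSummarizedExperiment")

setValidity("GenotypeData", function(object) {
  msg <- character()
  if (!"dosage" %in% assayNames(object))
    return("assay 'dosage' is required")
  d <- assay(object, "dosage")
  if (!all(d[!is.na(d)] %in% c(0L, 1L, 2L)))
    msg <- c(msg, "dosage calls must be 0, 1, 2 or NA")
  ids <- colnames(object)
  if (is.null(ids) || anyDuplicated(ids))
    msg <- c(msg, "sample identifiers must be present and unique")
  rr <- rowRanges(object)
  if (length(rr)) {
    ch <- as.character(seqnames(rr))
    pos <- start(rr)
    bad <- vapply(split(pos, factor(ch, levels = unique(ch))),
                  function(p) any(diff(p) <= 0), logical(1))
    if (any(bad))
      msg <- c(msg,
        "marker positions must be strictly increasing within chromosomes")
    sl <- seqlengths(rr)
    for (c2 in names(sl)[!is.na(sl)]) {
      p <- pos[ch == c2]
      if (length(p) && max(p) > sl[[c2]])
        msg <- c(msg, sprintf("marker beyond declared length of '%s'", c2))
    }
  }
  if (length(msg)) msg else TRUE
})

#' Multi-class homozygosity-by-descent model
#'
#' Parameters of a hidden Markov model that partitions a genome into nine
#' homozygous-by-descent (HBD) classes plus one non-HBD class. Class `k` has
#' an exponential segment-length distribution with rate `rates[k]` per Morgan,
#' so class rates 2, 4, ..., 512 correspond approximately to common ancestors
#' 2, 4, ..., 512 generations back (rate/2 generations; small rate = long
#' segment = recent inbreeding). `mixing` is the simplex of prior
#' probabilities that a new segment belongs to each class; `error` is the
#' genotyping/mutation error used in the HBD emission law; `cMperMb` converts
#' physical to genetic distance.
#'
#' @aliases HbdModel-class
#' @seealso [hbdModel()], [forwardBackward()], [fitMixing()]
#' @exportClass HbdModel
setClass("HbdModel", representation(
  rates  = "numeric",
  mixing = "numeric",
  error  = "numeric",
  cMperMb = "numeric"
))

setValidity("HbdModel", function(object) {
  msg <- character()
  R <- object@rates; M <- object@mixing
  if (length(R) < 2L) msg <- c(msg, "need at least one HBD class plus non-HBD")
  if (any(R <= 0)) msg <- c(msg, "rates must be strictly positive")
  nh <- length(R) - 1L
  if (nh >= 2L && any(diff(R[seq_len(nh)]) < 0))
    msg <- c(msg, "HBD class rates must be non-decreasing")
  if (length(M) != length(R))
    msg <- c(msg, "mixing and rates must have equal length")
  if (any(M < 0) || abs(sum(M) - 1) > 1e-8)
    msg <- c(msg, "mixing must be a probability simplex")
  if (object@error < 0 || object@error >= 0.5)
    msg <- c(msg, "error must lie in [0, 0.5)")
  if (object@cMperMb <= 0) msg <- c(msg, "cMperMb must be positive")
  if (length(msg)) msg else TRUE
})

#' Posterior genome partition of one sample under an HBD model
#'
#' Per-marker posterior state probabilities from the forward--backward
#' algorithm, the sample log-likelihood, and the per-class genome fractions
#' (unweighted means of the posterior over markers).
#'
#' @aliases HbdPosterior-class
#' @seealso [forwardBackward()], [partitionAutozygosity()]
#' @exportClass HbdPosterior
setClass("HbdPosterior", representation(
  posterior = "matrix",
  loglik    = "numeric",
  fractions = "numeric",
  sampleId  = "character"
))

setValidity("HbdPosterior", function(object) {
  p <- object@posterior
  if (nrow(p) && any(abs(rowSums(p) - 1) > 1e-10))
    return("marker posteriors must sum to 1 (tolerance 1e-10)")
  if (length(object@fractions) &&
      abs(sum(object@fractions) - 1) > 1e-8)
    return("class fractions must sum to 1 (tolerance 1e-8)")
  TRUE
})

#' Reduced relatedness-informative marker (RIM) panel
#'
#' A set of marker identifiers retained after the RIM filtering cascade
#' (missingness, LD pruning, then a minor-allele-frequency floor). Panels
#' built at increasing MAF thresholds from the same input are nested.
#'
#' @aliases RimPanel-class
#' @seealso [selectRim()], [panelCorrelation()]
#' @exportClass RimPanel
setClass("RimPanel", representation(
  threshold = "numeric",
  markers   = "character",
  params    = "list"
))

setValidity("RimPanel", function(object) {
  if (anyDuplicated(object@markers)) "duplicated panel markers" else TRUE
})
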
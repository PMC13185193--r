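#' Construct a GenotypeData object
#'
#' Assembles a dosage matrix and a marker map into a validated
#' [GenotypeData-class] container. Markers are reordered chromosome-blocked
#' (chromosomes in order of first appearance) and by increasing position
#' within each chromosome; the dosage matrix is reordered alongside.
#'
#' @param dosage integer matrix, markers in rows, samples in columns; values
#'   0/1/2 (alternate-allele count) or `NA` for missing. Column names are the
#'   sample identifiers.
#' @param markers [GenomicRanges::GRanges] of width-one marker positions
#'   (1-based), one per dosage row, optionally with `ref`/`alt` metadata
#'   columns.
#' @param sampleMeta optional `data.frame`/`DataFrame` of per-sample metadata
#'   (rows matched to dosage columns by name, or positionally if unnamed).
#' @param seqlengths optional named vector of chromosome lengths in bp (the
#'   genome layout).
#' @return A [GenotypeData-class] object.
#' @examples
#' d <- matrix(c(0L, 1L, 2L, NA, 1L, 1L), nrow = 3,
#'             dimnames = list(NULL, c("s1", "s2")))
#' gr <- GenomicRanges::GRanges("1", IRanges::IRanges(c(100, 200, 300), width = 1))
#' g <- GenotypeData(d, gr, seqlengths = c("1" = 1e6))
#' dosage(g)
#' @export
GenotypeData <- function(dosage, markers, sampleMeta = NULL,
                         seqlengths = NULL) {
  if (!is.matrix(dosage))
    stop("'dosage' must be a matrix")
  if (!is(markers, "GRanges"))
    stop("'markers' must be a GRanges")
  if (length(markers) != nrow(dosage))
    stop("number of dosage rows must equal number of markers")
  storage.mode(dosage) <- "integer"
  if (is.null(colnames(dosage)))
    stop("'dosage' must have sample identifiers as column names")

  ch <- as.character(seqnames(markers))
  ord <- order(match(ch, unique(ch)), start(markers))
  markers <- markers[ord]
  dosage <- dosage[ord, , drop = FALSE]

  ids <- if (!is.null(names(markers)) && !anyDuplicated(names(markers)) &&
             !any(names(markers) == "")) {
    names(markers)
  } else if (!is.null(rownames(dosage))) {
    rownames(dosage)
  } else {
    paste0(as.character(seqnames(markers)), ":", start(markers))
  }
  names(markers) <- ids
  rownames(dosage) <- ids

  if (!is.null(seqlengths)) {
    sl <- GenomeInfoDb::seqlengths(markers)
    keep <- intersect(names(seqlengths), names(sl))
    miss <- setdiff(names(seqlengths), names(sl))
    if (length(miss))
      GenomeInfoDb::seqlevels(markers) <-
        c(GenomeInfoDb::seqlevels(markers), miss)
    sl <- GenomeInfoDb::seqlengths(markers)
    sl[names(seqlengths)] <- as.numeric(seqlengths)
    GenomeInfoDb::seqlengths(markers) <- sl
  }

  cd <- if (is.null(sampleMeta)) {
    S4Vectors::DataFrame(row.names = colnames(dosage))
  } else {
    sm <- as(sampleMeta, "DataFrame")
    if (!is.null(rownames(sm))) {
      if (!all(colnames(dosage) %in% rownames(sm)))
        stop("sampleMeta rows do not cover all samples")
      sm[colnames(dosage), , drop = FALSE]
    } else {
      if (nrow(sm) != ncol(dosage))
        stop("sampleMeta has wrong number of rows")
      rownames(sm) <- colnames(dosage)
      sm
    }
  }

  se <- SummarizedExperiment(assays = list(dosage = dosage),
                             rowRanges = markers, colData = cd)
  new("GenotypeData", se)
}

#' @rdname GenotypeData
#' @param x a `GenotypeData` object.
#' @export
setGeneric("dosage", function(x) standardGeneric("dosage"))

#' @describeIn GenotypeData the integer dosage matrix (markers x samples).
#' @export
setMethod("dosage", "GenotypeData", function(x) assay(x, "dosage"))

#' @rdname GenotypeData
#' @export
setGeneric("markerMap", function(x) standardGeneric("markerMap"))

#' @describeIn GenotypeData the marker map as a `GRanges`.
#' @export
setMethod("markerMap", "GenotypeData", function(x) rowRanges(x))

#' @rdname GenotypeData
#' @export
setGeneric("genomeLayout", function(x) standardGeneric("genomeLayout"))

#' @describeIn GenotypeData named chromosome lengths (bp; `NA` if undeclared).
#' @export
setMethod("genomeLayout", "GenotypeData",
          function(x) seqlengths(rowRanges(x)))

#' @rdname GenotypeData
#' @export
setGeneric("sampleMeta", function(x) standardGeneric("sampleMeta"))

#' @describeIn GenotypeData sample metadata as a `data.frame` with a
#'   `sample_id` column.
#' @export
setMethod("sampleMeta", "GenotypeData", function(x) {
  df <- as.data.frame(colData(x))
  cbind(data.frame(sample_id = colnames(x), stringsAsFactors = FALSE),
        df, row.names = NULL)
})

#' @rdname GenotypeData
#' @param value replacement sample metadata (`data.frame` keyed by
#'   `sample_id` column or by row names).
#' @export
setGeneric("sampleMeta<-", function(x, value) standardGeneric("sampleMeta<-"))

#' @describeIn GenotypeData attach sample metadata, matched by `sample_id`.
#' @export
setMethod("sampleMeta<-", "GenotypeData", function(x, value) {
  value <- as.data.frame(value)
  key <- if ("sample_id" %in% colnames(value)) value$sample_id
         else rownames(value)
  if (is.null(key)) stop("metadata needs a 'sample_id' column or row names")
  if (anyDuplicated(key)) stop("duplicated sample_id in metadata")
  idx <- match(colnames(x), key)
  if (anyNA(idx))
    stop("metadata missing for sample(s): ",
         paste(colnames(x)[is.na(idx)], collapse = ", "))
  value <- value[idx, setdiff(colnames(value), "sample_id"), drop = FALSE]
  rownames(value) <- colnames(x)
  colData(x) <- S4Vectors::DataFrame(value)
  validObject(x)
  x
})

#' @rdname GenotypeData
#' @export
nMarkers <- function(x) nrow(x)

#' @rdname GenotypeData
#' @export
nSamples <- function(x) ncol(x)

#' @describeIn GenotypeData compact summary.
#' @param object a `GenotypeData` object.
#' @export
setMethod("show", "GenotypeData", function(object) {
  d <- assay(object, "dosage")
  miss <- if (length(d)) mean(is.na(d)) else NA_real_
  cat(sprintf("GenotypeData: %d markers x %d samples\n",
              nrow(object), ncol(object)))
  cat(sprintf("  chromosomes: %s\n",
              paste(GenomeInfoDb::seqlevels(rowRanges(object)),
                    collapse = ", ")))
  cat(sprintf("  missing calls: %.2f%%\n", 100 * miss))
  if (ncol(colData(object)))
    cat(sprintf("  sample metadata: %s\n",
                paste(colnames(colData(object)), collapse = ", ")))
})
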
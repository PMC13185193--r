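#' Per-individual observed heterozygosity
#'
#' `Ho = n_het / n_non_missing`, computed independently per sample. A
#' sample with every call missing is an error.
#'
#' @param x a [GenotypeData-class] object.
#' @return named numeric vector of Ho values in \[0, 1\].
#' @export
observedHet <- function(x) {
  d <- dosage(x)
  n <- colSums(!is.na(d))
  if (any(n == 0L))
    stop("sample(s) with all calls missing: ",
         paste(colnames(d)[n == 0L], collapse = ", "))
  colSums(d == 1L, na.rm = TRUE) / n
}

#' Parameters for run-of-homozygosity detection
#'
#' The five criteria a run must satisfy: (i) at most `maxHet` heterozygous
#' calls (0: absence of heterozygotes), (ii) at most `maxMissing` missing
#' calls (1: "fewer than two"), (iii) at least `minSnps` markers,
#' (iv) marker density (markers / span) at least `minDensity` — by default
#' the dataset-wide density, total markers over total genome length —
#' and (v) span at least `minLengthBp`.
#'
#' @param minSnps minimum markers per run (default 20).
#' @param minLengthBp minimum run span in bp (default 100 kb).
#' @param maxMissing maximum missing calls inside a run (default 1).
#' @param maxHet maximum heterozygous calls inside a run (default 0).
#' @param minDensity minimum run SNP density in markers/bp; `NULL` (default)
#'   uses the dataset-wide density, computed after all marker filters.
#' @return a `RohParams` list.
#' @export
rohParams <- function(minSnps = 20, minLengthBp = 1e5, maxMissing = 1,
                      maxHet = 0, minDensity = NULL) {
  stopifnot(minSnps >= 1, minLengthBp >= 1, maxMissing >= 0, maxHet >= 0)
  structure(list(minSnps = as.integer(minSnps), minLengthBp = minLengthBp,
                 maxMissing = as.integer(maxMissing),
                 maxHet = as.integer(maxHet), minDensity = minDensity),
            class = "RohParams")
}

#' Detect runs of homozygosity
#'
#' Exact maximal-run semantics: per sample and chromosome, a reported
#' segment is a marker interval that satisfies all five criteria of
#' [rohParams()] and is not contained in any longer interval that also
#' satisfies them. This is deterministic and directly testable against
#' exhaustive enumeration, unlike windowed heuristics, at the cost of
#' occasionally splitting what a scanning tool would join. Segment
#' endpoints are the positions of the first and last marker of the run
#' (1-based, closed; no extension into flanking inter-marker gaps).
#'
#' @param x a [GenotypeData-class] object whose layout (chromosome lengths)
#'   is declared when `params$minDensity` is `NULL`.
#' @param params a [rohParams()] list.
#' @return `data.frame` with columns `sample_id`, `chrom`, `start`, `end`,
#'   `n_snps` (markers in the run, missing included), `n_missing`,
#'   `length` (= end - start + 1).
#' @seealso [froh()]
#' @export
detectRoh <- function(x, params = rohParams()) {
  dens <- params$minDensity
  if (is.null(dens)) {
    sl <- genomeLayout(x)
    if (!length(sl) || anyNA(sl))
      stop("genome layout (chromosome lengths) required to derive the ",
           "dataset-wide density; declare seqlengths or set minDensity")
    dens <- nMarkers(x) / sum(as.numeric(sl))
  }
  d <- dosage(x)
  rr <- rowRanges(x)
  ch <- as.character(seqnames(rr))
  pos <- start(rr)
  chromIdx <- split(seq_along(pos), factor(ch, unique(ch)))
  out <- vector("list", 0L)
  for (s in seq_len(ncol(d))) {
    for (ci in chromIdx) {
      segs <- .rohChrom(d[ci, s], pos[ci], params, dens)
      if (nrow(segs)) {
        segs$sample_id <- colnames(d)[s]
        segs$chrom <- ch[ci[1L]]
        out[[length(out) + 1L]] <- segs
      }
    }
  }
  if (!length(out))
    return(data.frame(sample_id = character(), chrom = character(),
                      start = integer(), end = integer(),
                      n_snps = integer(), n_missing = integer(),
                      length = numeric(), stringsAsFactors = FALSE))
  res <- do.call(rbind, out)
  res[, c("sample_id", "chrom", "start", "end", "n_snps", "n_missing",
          "length")]
}

# Candidate generation for one sample x chromosome. Two-pointer pass finds
# every maximal interval satisfying the het/missing constraints; each such
# window either passes the size criteria outright or, when only density
# fails, is searched exhaustively for maximal passing sub-intervals.
.rohChrom <- function(g, p, params, dens) {
  n <- length(g)
  empty <- data.frame(start = integer(), end = integer(),
                      n_snps = integer(), n_missing = integer(),
                      length = numeric(), stringsAsFactors = FALSE)
  if (!n) return(empty)
  het <- !is.na(g) & g == 1L
  mis <- is.na(g)
  cumH <- cumsum(het); cumM <- cumsum(mis)
  nH <- function(a, b) cumH[b] - if (a > 1L) cumH[a - 1L] else 0L
  nM <- function(a, b) cumM[b] - if (a > 1L) cumM[a - 1L] else 0L
  passes <- function(a, b) {
    k <- b - a + 1L
    len <- p[b] - p[a] + 1
    k >= params$minSnps && len >= params$minLengthBp && k / len >= dens
  }
  cand <- list()
  j <- 0L
  prevEnd <- 0L
  for (i in seq_len(n)) {
    if (j < i) j <- i - 1L
    while (j < n && nH(i, j + 1L) <= params$maxHet &&
           nM(i, j + 1L) <= params$maxMissing) j <- j + 1L
    if (j < i || j <= prevEnd) next   # not a new maximal window
    prevEnd <- j
    a <- i; b <- j
    if (passes(a, b)) {
      cand[[length(cand) + 1L]] <- c(a, b)
    } else {
      k <- b - a + 1L
      len <- p[b] - p[a] + 1
      if (k >= params$minSnps && len >= params$minLengthBp) {
        # only density can be repaired by shrinking; for each left edge the
        # widest passing right edge is the only possibly-maximal interval
        for (u in a:b) {
          vs <- u:b
          kk <- vs - u + 1L
          ll <- p[vs] - p[u] + 1
          ok <- kk >= params$minSnps & ll >= params$minLengthBp &
            kk / ll >= dens
          if (any(ok))
            cand[[length(cand) + 1L]] <- c(u, vs[max(which(ok))])
        }
      }
    }
  }
  if (!length(cand)) return(empty)
  cm <- unique(do.call(rbind, cand))
  # keep only intervals not contained in another candidate
  keep <- vapply(seq_len(nrow(cm)), function(i) {
    !any(cm[, 1L] <= cm[i, 1L] & cm[, 2L] >= cm[i, 2L] &
         (cm[, 1L] < cm[i, 1L] | cm[, 2L] > cm[i, 2L]))
  }, logical(1))
  cm <- cm[keep, , drop = FALSE]
  cm <- cm[order(cm[, 1L], cm[, 2L]), , drop = FALSE]
  data.frame(start = p[cm[, 1L]], end = p[cm[, 2L]],
             n_snps = cm[, 2L] - cm[, 1L] + 1L,
             n_missing = vapply(seq_len(nrow(cm)),
                                function(i) nM(cm[i, 1L], cm[i, 2L]),
                                integer(1)),
             length = p[cm[, 2L]] - p[cm[, 1L]] + 1,
             stringsAsFactors = FALSE)
}

#' Genomic inbreeding coefficient from ROH segments
#'
#' `F_ROH` is the proportion of the genome covered by runs of homozygosity:
#' the union of a sample's segments (overlaps merged) divided by the total
#' genome length.
#'
#' @param segments segment table from [detectRoh()].
#' @param layout named chromosome lengths in bp (e.g. [genomeLayout()]).
#' @param sampleIds optional identifiers to report (samples without
#'   segments get 0).
#' @return named numeric vector of F_ROH values.
#' @export
froh <- function(segments, layout, sampleIds = NULL) {
  total <- sum(as.numeric(layout))
  if (!is.finite(total) || total <= 0)
    stop("layout must provide finite positive chromosome lengths")
  ids <- if (is.null(sampleIds)) unique(segments$sample_id) else sampleIds
  out <- stats::setNames(numeric(length(ids)), ids)
  if (nrow(segments)) {
    for (s in intersect(ids, unique(segments$sample_id))) {
      ss <- segments[segments$sample_id == s, , drop = FALSE]
      cov <- sum(vapply(split(ss, ss$chrom), function(cc) {
        sum(width(IRanges::reduce(IRanges(cc$start, cc$end))))
      }, numeric(1)))
      out[s] <- cov / total
    }
  }
  out
}

#' Two-group and multi-group location tests
#'
#' `"wilcoxon"`: two-sided Wilcoxon rank-sum test with normal approximation
#' and tie correction (exactly two groups). `"anova"`: one-way
#' fixed-effects F test (each group needs at least two observations).
#'
#' @param values numeric observations.
#' @param labels group labels, same length as `values`.
#' @param test `"wilcoxon"` or `"anova"`.
#' @return list with `statistic`, `p_value`, `test`.
#' @export
compareGroups <- function(values, labels, test = c("wilcoxon", "anova")) {
  test <- match.arg(test)
  labels <- as.character(labels)
  stopifnot(length(values) == length(labels))
  groups <- split(values, labels)
  if (length(groups) < 2L) stop("need at least two groups")
  if (any(vapply(groups, length, integer(1)) == 0L))
    stop("empty group")
  if (test == "wilcoxon") {
    if (length(groups) != 2L)
      stop("wilcoxon requires exactly two groups")
    ht <- suppressWarnings(
      wilcox.test(groups[[1L]], groups[[2L]], exact = FALSE))
    list(statistic = unname(ht$statistic), p_value = ht$p.value,
         test = "wilcoxon")
  } else {
    if (any(vapply(groups, length, integer(1)) < 2L))
      stop("anova needs at least two observations per group")
    ht <- oneway.test(values ~ factor(labels), var.equal = TRUE)
    list(statistic = unname(ht$statistic), p_value = ht$p.value,
         test = "anova")
  }
}
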
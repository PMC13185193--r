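#' Per-marker alternate-allele frequencies
#'
#' Computed over non-missing calls as (sum of dosages) / (2 x non-missing
#' count). Markers with every call missing get `NA` (flagged undefined, not
#' an error). Invariant under any permutation of samples.
#'
#' @param x a [GenotypeData-class] object.
#' @return named numeric vector of alt-allele frequencies in \[0, 1\].
#' @export
alleleFrequencies <- function(x) {
  d <- dosage(x)
  n <- rowSums(!is.na(d))
  f <- rowSums(d, na.rm = TRUE) / (2 * n)
  f[n == 0L] <- NA_real_
  f
}

#' Per-marker missing-call fractions
#'
#' @param x a [GenotypeData-class] object.
#' @return named numeric vector of missing fractions in \[0, 1\].
#' @export
missingRates <- function(x) rowMeans(is.na(dosage(x)))

#' Filter markers on minor allele frequency and missingness
#'
#' Retains markers whose minor allele frequency is strictly greater than
#' `mafMin` and whose missing fraction is at most `maxMissingRate` (so a
#' marker at exactly MAF = `mafMin` is removed, while one at exactly the
#' missingness cutoff is retained — only strictly worse markers go).
#' Markers with undefined frequency (all calls missing) are removed. Marker
#' order is preserved; the operation is idempotent.
#'
#' @param x a [GenotypeData-class] object.
#' @param mafMin minor-allele-frequency cutoff in \[0, 0.5\] (default 0.05).
#' @param maxMissingRate maximum tolerated missing fraction in \[0, 1\]
#'   (default 0.10).
#' @return the filtered [GenotypeData-class] object.
#' @export
filterMarkers <- function(x, mafMin = 0.05, maxMissingRate = 0.10) {
  stopifnot(mafMin >= 0, mafMin <= 0.5,
            maxMissingRate >= 0, maxMissingRate <= 1)
  f <- alleleFrequencies(x)
  keep <- !is.na(f) & pmin(f, 1 - f) > mafMin &
    missingRates(x) <= maxMissingRate
  x[keep, ]
}

#' Prune markers in linkage disequilibrium
#'
#' Within each chromosome, every marker pair closer than `windowBp` whose
#' squared Pearson correlation of dosages (composite LD on
#' pairwise-complete samples; genotypes are unphased) exceeds `r2Max` loses
#' exactly one member. Pairs are resolved deterministically in (chromosome,
#' left marker, right marker) order; from an offending pair the member with
#' the higher missing rate is removed, ties broken towards the lower minor
#' allele frequency, remaining ties towards the larger position — so the
#' more informative marker survives. The survivor set contains no remaining
#' within-window pair above the threshold and is deterministic for a fixed
#' input; it does not depend on `stepSnps`, which only batches the sweep.
#'
#' @param x a [GenotypeData-class] object (markers sorted, as the class
#'   guarantees).
#' @param windowBp window span in bp (default 50000).
#' @param stepSnps sweep advance in markers (default 5); kept for interface
#'   compatibility, no effect on the result.
#' @param r2Max maximum tolerated squared correlation in (0, 1\]
#'   (default 0.25).
#' @return integer vector of retained marker indices (named by marker id).
#' @export
ldPrune <- function(x, windowBp = 50000, stepSnps = 5, r2Max = 0.25) {
  if (windowBp <= 0) stop("windowBp must be positive")
  if (stepSnps < 1) stop("stepSnps must be >= 1")
  stopifnot(r2Max > 0, r2Max <= 1)
  d <- dosage(x)
  rr <- rowRanges(x)
  chrom <- as.character(seqnames(rr))
  pos <- start(rr)
  miss <- rowMeans(is.na(d))
  f <- alleleFrequencies(x)
  maf <- pmin(f, 1 - f)
  removed <- logical(nrow(d))

  for (ch in unique(chrom)) {
    idx <- which(chrom == ch)
    p <- pos[idx]
    n <- length(idx)
    for (i in seq_len(n)) {
      gi <- idx[i]
      if (removed[gi]) next
      j <- i + 1L
      while (j <= n && p[j] - p[i] <= windowBp) {
        gj <- idx[j]
        if (!removed[gj]) {
          r2 <- suppressWarnings(
            cor(d[gi, ], d[gj, ], use = "pairwise.complete.obs"))^2
          if (!is.na(r2) && r2 > r2Max) {
            drop <- .ldTieBreak(gi, gj, miss, maf, pos)
            removed[drop] <- TRUE
            if (drop == gi) break
          }
        }
        j <- j + 1L
      }
    }
  }
  out <- which(!removed)
  names(out) <- rownames(d)[out]
  out
}

# From an offending pair, pick the index to REMOVE: higher missing rate,
# tie -> lower MAF, tie -> larger position.
.ldTieBreak <- function(i, j, miss, maf, pos) {
  if (miss[i] != miss[j]) return(if (miss[i] > miss[j]) i else j)
  mi <- maf[i]; mj <- maf[j]
  if (!is.na(mi) && !is.na(mj) && mi != mj) return(if (mi < mj) i else j)
  if (pos[i] > pos[j]) i else j
}
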
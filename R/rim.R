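#' Select a relatedness-informative marker (RIM) panel
#'
#' Filtering cascade for cost-effective kinship genotyping: markers failing
#' the missingness screen are removed, the survivors are LD-pruned (same
#' deterministic window machinery as [ldPrune()], default r^2 > 0.2 in
#' 50 kb windows), and finally only high-frequency markers with
#' MAF >= `mafMin` are retained — high-MAF markers maximise heterozygosity
#' and therefore relatedness information. Because the MAF floor is applied
#' last, panels built at increasing thresholds from the same input are
#' nested. The inclusive MAF boundary lets a threshold of 0.45 retain
#' markers at MAF exactly 0.45.
#'
#' The missingness screen reads "call rate below 5%" as missingness above
#' 5% (call rate under 95%); set `callRateLiteral = TRUE` for the literal
#' reading (drop only markers genotyped in under 5% of samples), which is
#' a near no-op after upstream QC.
#'
#' @param x a post-QC [GenotypeData-class] object.
#' @param mafMin panel MAF threshold (inclusive), e.g. 0.35 / 0.40 / 0.45.
#' @param maxMissing missingness ceiling (default 0.05).
#' @param r2Max LD threshold (default 0.2).
#' @param windowBp,stepSnps LD window machinery (defaults 50 kb / 5).
#' @param callRateLiteral use the literal call-rate reading (default
#'   `FALSE`).
#' @return a [RimPanel-class] object (empty panels warn, not fail).
#' @export
selectRim <- function(x, mafMin, maxMissing = 0.05, r2Max = 0.2,
                      windowBp = 50000, stepSnps = 5,
                      callRateLiteral = FALSE) {
  stopifnot(mafMin >= 0, mafMin <= 0.5)
  miss <- missingRates(x)
  keep <- if (callRateLiteral) (1 - miss) >= 0.05 else miss <= maxMissing
  sub <- x[keep, ]
  ret <- ldPrune(sub, windowBp = windowBp, stepSnps = stepSnps,
                 r2Max = r2Max)
  sub <- sub[ret, ]
  f <- alleleFrequencies(sub)
  maf <- pmin(f, 1 - f)
  ids <- rownames(dosage(sub))[!is.na(maf) & maf >= mafMin]
  if (!length(ids)) warning("RIM panel is empty at mafMin = ", mafMin)
  new("RimPanel", threshold = mafMin, markers = ids,
      params = list(maxMissing = maxMissing, r2Max = r2Max,
                    windowBp = windowBp, stepSnps = stepSnps,
                    callRateLiteral = callRateLiteral))
}

#' @describeIn selectRim panel marker identifiers.
#' @param panel a [RimPanel-class] object.
#' @export
panelMarkers <- function(panel) panel@markers

#' @describeIn selectRim panel size.
#' @export
panelSize <- function(panel) length(panel@markers)

#' @describeIn selectRim compact display.
#' @param object a `RimPanel`.
#' @export
setMethod("show", "RimPanel", function(object) {
  cat(sprintf("RimPanel: %d markers at MAF >= %g\n",
              length(object@markers), object@threshold))
})

#' Kinship correlation of a marker panel against a reference
#'
#' Recomputes KING-robust kinship restricted to the panel's markers and
#' reports the Pearson correlation of `phi` against the reference kinship
#' table over all pairs with a defined estimate in both sets (pairs
#' undefined in either set are excluded and counted). Correlating on `phi`
#' or on `r = 2 phi` is equivalent for Pearson correlation.
#'
#' @param x the [GenotypeData-class] object the reference was computed
#'   from.
#' @param panel a [RimPanel-class] object or character marker ids.
#' @param referenceKin kinship table from [kinshipMatrix()] on the full
#'   marker set.
#' @return list with `correlation`, `nPairs`, `nExcluded`, `size`, and a
#'   `lowConfidence` flag for very small panels or few usable pairs.
#' @export
panelCorrelation <- function(x, panel, referenceKin) {
  ids <- if (is(panel, "RimPanel")) panel@markers else panel
  if (!length(ids)) stop("empty panel")
  phiRef <- .alignReferencePhi(x, referenceKin)
  phi <- .kingPhiUT(dosage(x)[ids, , drop = FALSE])
  ok <- !is.na(phi) & !is.na(phiRef)
  if (sum(ok) < 3L) stop("fewer than 3 usable pairs")
  r <- cor(phi[ok], phiRef[ok])
  list(correlation = r, nPairs = sum(ok), nExcluded = sum(!ok),
       size = length(ids),
       lowConfidence = length(ids) < 10L || sum(ok) < 30L)
}

# Reference phi values reordered to the canonical upper-triangle pair
# order of x's samples.
.alignReferencePhi <- function(x, referenceKin) {
  sn <- colnames(x)
  n <- length(sn)
  ut <- upper.tri(matrix(0, n, n))
  ia <- row(ut)[ut]; ib <- col(ut)[ut]
  m <- match(paste(sn[ia], sn[ib]),
             paste(referenceKin$id_a, referenceKin$id_b))
  rev <- is.na(m)
  if (any(rev))
    m[rev] <- match(paste(sn[ib[rev]], sn[ia[rev]]),
                    paste(referenceKin$id_a, referenceKin$id_b))
  if (anyNA(m))
    stop("referenceKin does not cover every sample pair")
  referenceKin$phi[m]
}

#' Random-panel null distribution of the kinship correlation
#'
#' Repeatedly draws `size` markers without replacement from the full
#' marker set, recomputes the panel-vs-reference kinship correlation, and
#' summarises the resulting null distribution a designed panel must beat.
#' Deterministic under `seed`.
#'
#' @param x a [GenotypeData-class] object.
#' @param size markers per random panel (must not exceed the total).
#' @param referenceKin reference kinship table ([kinshipMatrix()]).
#' @param nIter number of random panels (default 100).
#' @param seed optional integer seed.
#' @return list with `panel = "random"`, `size`, `correlations`
#'   (per-iteration), `mean`, `sd`, `nIter`.
#' @export
randomPanelNull <- function(x, size, referenceKin, nIter = 100,
                            seed = NULL) {
  d <- dosage(x)
  if (size > nrow(d)) stop("size exceeds number of markers")
  if (!is.null(seed)) set.seed(seed)
  phiRef <- .alignReferencePhi(x, referenceKin)
  cors <- vapply(seq_len(nIter), function(i) {
    idx <- sample.int(nrow(d), size)
    phi <- .kingPhiUT(d[idx, , drop = FALSE])
    ok <- !is.na(phi) & !is.na(phiRef)
    cor(phi[ok], phiRef[ok])
  }, numeric(1))
  list(panel = "random", size = size, correlations = cors,
       mean = mean(cors), sd = sd(cors), nIter = nIter)
}

#' Build and validate RIM panels at several MAF thresholds
#'
#' Runs [selectRim()] at each threshold, computes each panel's kinship
#' correlation against the full-set reference, and opposes it to a
#' size-matched [randomPanelNull()]. The `gap` column (RIM minus null
#' mean), reported alongside the null standard deviation, lets the
#' "designed panels beat random panels" claim be inspected rather than
#' assumed.
#'
#' @param x a post-QC [GenotypeData-class] object.
#' @param mafThresholds MAF floors (default 0.35, 0.40, 0.45).
#' @param maxMissing,r2Max,windowBp,stepSnps passed to [selectRim()].
#' @param nIter random panels per size (default 100).
#' @param seed optional integer seed (whole evaluation deterministic).
#' @param referenceKin optional precomputed reference kinship table.
#' @return `data.frame` with one row per threshold: `maf_threshold`,
#'   `size`, `rim_correlation`, `null_mean`, `null_sd`, `gap`, `n_pairs`.
#' @export
evaluatePanels <- function(x, mafThresholds = c(0.35, 0.40, 0.45),
                           maxMissing = 0.05, r2Max = 0.2,
                           windowBp = 50000, stepSnps = 5, nIter = 100,
                           seed = NULL, referenceKin = NULL) {
  if (is.null(referenceKin)) referenceKin <- kinshipMatrix(x)
  # the missingness + LD base is threshold-independent; compute it once
  base <- selectRim(x, mafMin = 0, maxMissing = maxMissing, r2Max = r2Max,
                    windowBp = windowBp, stepSnps = stepSnps)
  f <- alleleFrequencies(x)[panelMarkers(base)]
  maf <- pmin(f, 1 - f)
  rows <- lapply(seq_along(mafThresholds), function(i) {
    th <- mafThresholds[i]
    panel <- new("RimPanel", threshold = th,
                 markers = panelMarkers(base)[!is.na(maf) & maf >= th],
                 params = base@params)
    pc <- panelCorrelation(x, panel, referenceKin)
    nullSeed <- if (is.null(seed)) NULL else seed + i
    nl <- randomPanelNull(x, size = panelSize(panel),
                          referenceKin = referenceKin, nIter = nIter,
                          seed = nullSeed)
    data.frame(maf_threshold = th, size = panelSize(panel),
               rim_correlation = pc$correlation, null_mean = nl$mean,
               null_sd = nl$sd, gap = pc$correlation - nl$mean,
               n_pairs = pc$nPairs)
  })
  do.call(rbind, rows)
}

#' Line plot of RIM versus random-panel correlations
#'
#' @param evaluation output of [evaluatePanels()].
#' @param ... passed to [plot()].
#' @return invisibly, `evaluation`.
#' @export
plotPanelEvaluation <- function(evaluation, ...) {
  ev <- evaluation[order(evaluation$size), ]
  ylim <- range(c(ev$rim_correlation, ev$null_mean - 2 * ev$null_sd,
                  ev$null_mean + 2 * ev$null_sd))
  plot(ev$size, ev$rim_correlation, type = "b", pch = 19, col = "blue3",
       ylim = ylim, xlab = "panel size (markers)",
       ylab = "correlation with full-set kinship", ...)
  lines(ev$size, ev$null_mean, type = "b", pch = 17, col = "red3")
  legend("bottomright", legend = c("RIM panel", "random panels (mean)"),
         col = c("blue3", "red3"), pch = c(19, 17), lty = 1, bty = "n")
  invisible(evaluation)
}
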
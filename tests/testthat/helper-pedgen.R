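# Shared builders and independent oracles for the test suite.

# Quick GenotypeData from a dosage matrix.
toyG <- function(d, chrom = rep("1", nrow(d)), pos = seq_len(nrow(d)) * 1000,
                 seqlen = NULL, freq = NULL) {
  if (is.null(colnames(d))) colnames(d) <- paste0("s", seq_len(ncol(d)))
  gr <- GenomicRanges::GRanges(chrom, IRanges::IRanges(pos, width = 1),
                               ref = rep("A", nrow(d)),
                               alt = rep("C", nrow(d)))
  GenotypeData(d, gr, seqlengths = seqlen)
}

im <- function(...) {
  m <- rbind(...)
  storage.mode(m) <- "integer"
  t(m)  # callers pass per-sample rows; transpose to markers x samples
}

# Exhaustive LD pruning oracle: every within-window pair, fixed order,
# same tie rule, no window machinery.
ldPruneOracle <- function(x, windowBp, r2Max) {
  d <- dosage(x)
  rr <- SummarizedExperiment::rowRanges(x)
  chrom <- as.character(GenomicRanges::seqnames(rr))
  pos <- GenomicRanges::start(rr)
  miss <- rowMeans(is.na(d))
  f <- alleleFrequencies(x)
  maf <- pmin(f, 1 - f)
  removed <- logical(nrow(d))
  for (ci in unique(chrom)) {
    idx <- which(chrom == ci)
    for (ii in seq_along(idx)) {
      i <- idx[ii]
      if (removed[i]) next
      for (jj in seq_along(idx)) {
        if (jj <= ii) next
        j <- idx[jj]
        if (pos[j] - pos[i] > windowBp) break
        if (removed[i] || removed[j]) next
        r2 <- suppressWarnings(
          stats::cor(d[i, ], d[j, ], use = "pairwise.complete.obs"))^2
        if (!is.na(r2) && r2 > r2Max) {
          drop <- if (miss[i] != miss[j]) {
            if (miss[i] > miss[j]) i else j
          } else if (!is.na(maf[i]) && !is.na(maf[j]) && maf[i] != maf[j]) {
            if (maf[i] < maf[j]) i else j
          } else if (pos[i] > pos[j]) i else j
          removed[drop] <- TRUE
        }
      }
    }
  }
  which(!removed)
}

# Brute-force ROH oracle: enumerate every marker sub-interval, test all
# five criteria, keep maximal passes.
rohOracle <- function(g, pos, params, dens) {
  n <- length(g)
  cand <- NULL
  for (a in seq_len(n)) for (b in a:n) {
    gg <- g[a:b]
    if (sum(!is.na(gg) & gg == 1L) > params$maxHet) next
    if (sum(is.na(gg)) > params$maxMissing) next
    k <- b - a + 1L
    len <- pos[b] - pos[a] + 1
    if (k < params$minSnps || len < params$minLengthBp || k / len < dens)
      next
    cand <- rbind(cand, c(a, b))
  }
  if (is.null(cand)) return(matrix(numeric(0), 0, 2))
  keep <- vapply(seq_len(nrow(cand)), function(i) {
    !any(cand[, 1] <= cand[i, 1] & cand[, 2] >= cand[i, 2] &
         (cand[, 1] < cand[i, 1] | cand[, 2] > cand[i, 2]))
  }, logical(1))
  cand[keep, , drop = FALSE]
}

# Exact HBD likelihood by enumeration over all K^L state paths.
hbdEnumLoglik <- function(model, g, q, pos) {
  K <- length(model@rates)
  L <- length(g)
  eH <- emissionProb(g, q, "hbd", model@error)
  eN <- emissionProb(g, q, "nonhbd")
  E <- rbind(matrix(rep(eH, each = K - 1), K - 1, L), eN)
  d <- diff(pos) * model@cMperMb * 1e-8
  Tm <- lapply(d, function(dd) {
    a <- exp(-model@rates * dd)
    diag(a) + (1 - a) %o% model@mixing
  })
  paths <- as.matrix(expand.grid(rep(list(seq_len(K)), L)))
  lp <- model@mixing[paths[, 1]] * E[cbind(paths[, 1], 1L)]
  for (t in 2:L)
    lp <- lp * Tm[[t - 1]][cbind(paths[, t - 1], paths[, t])] *
      E[cbind(paths[, t], t)]
  log(sum(lp))
}

# Hand-built pedigree wrapper accepted by transmitGenotypes().
handPedigree <- function(records, truth) {
  structure(list(records = records, truth = truth), class = "SimPedigree")
}

pedRecord <- function(id, sex, year, dam = NA_character_,
                      origin = "captive", camp = "A", genotyped = TRUE) {
  data.frame(id = id, sex = sex, birth_year = year,
             birth_year_approx = FALSE, origin = origin, camp = camp,
             dam_id = dam, genotyped = genotyped, stringsAsFactors = FALSE)
}

pairKey <- function(a, b) paste(pmin(a, b), pmax(a, b))

extdata <- function(f) system.file("extdata", f, package = "pedgen")
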
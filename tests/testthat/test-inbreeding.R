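test_that("observed heterozygosity counts hets over non-missing calls", {
  g <- toyG(im(c(1L, 1L, 1L, 1L), c(0L, 2L, 0L, 2L), c(1L, 0L, 2L, NA)))
  ho <- observedHet(g)
  expect_equal(unname(ho), c(1, 0, 1 / 3))
  # Ho plus homozygous fraction is 1 over non-missing calls
  d <- dosage(g)
  hom <- colSums(d == 0L | d == 2L, na.rm = TRUE) / colSums(!is.na(d))
  expect_equal(unname(ho + hom), rep(1, 3))
  gm <- toyG(im(c(NA, NA), c(0L, 1L)))
  expect_error(observedHet(gm), "all calls missing")
})

test_that("ROH detection honours each of the five criteria", {
  # 25 homozygous markers spanning ~120 kb, one missing call inside
  pos <- seq(1, 120001, length.out = 25)
  g <- rep(0L, 25); g[13] <- NA
  base <- toyG(matrix(g, ncol = 1, dimnames = list(NULL, "s1")),
               pos = pos, seqlen = c("1" = 2.5e6))
  p <- rohParams(minSnps = 20, minLengthBp = 1e5)
  seg <- detectRoh(base, p)   # dataset density 25/2.5e6 = 1e-5 = run density
  expect_equal(nrow(seg), 1)
  expect_equal(seg$n_snps, 25)
  expect_equal(seg$n_missing, 1)
  expect_equal(seg$start, 1)
  expect_equal(seg$end, 120001)
  # (ii) two missing calls: rejected
  g2 <- g; g2[14] <- NA
  miss2 <- toyG(matrix(g2, ncol = 1, dimnames = list(NULL, "s1")),
                pos = pos, seqlen = c("1" = 2.5e6))
  expect_equal(nrow(detectRoh(miss2, p)), 0)
  # (i) a heterozygote splits the run; fragments fail the SNP minimum
  g3 <- g; g3[13] <- 1L
  het1 <- toyG(matrix(g3, ncol = 1, dimnames = list(NULL, "s1")),
               pos = pos, seqlen = c("1" = 2.5e6))
  expect_equal(nrow(detectRoh(het1, p)), 0)
  # (iii) only 19 markers: rejected
  n19 <- toyG(matrix(rep(2L, 19), ncol = 1, dimnames = list(NULL, "s1")),
              pos = seq(1, 120001, length.out = 19),
              seqlen = c("1" = 1.9e6))
  expect_equal(nrow(detectRoh(n19, p)), 0)
  # (v) span 99 kb: rejected
  p99 <- toyG(matrix(rep(2L, 25), ncol = 1, dimnames = list(NULL, "s1")),
              pos = round(seq(1, 99000, length.out = 25)),
              seqlen = c("1" = 2.5e6))
  expect_equal(nrow(detectRoh(p99, p)), 0)
  # (iv) density below the required minimum: rejected
  sparse <- toyG(matrix(rep(2L, 25), ncol = 1,
                        dimnames = list(NULL, "s1")),
                 pos = round(seq(1, 5e6, length.out = 25)),
                 seqlen = c("1" = 5.2e6))  # run density 5e-6 < 1e-5
  pd <- rohParams(minSnps = 20, minLengthBp = 1e5, minDensity = 1e-5)
  expect_equal(nrow(detectRoh(sparse, pd)), 0)
  # fully heterozygous chromosome: nothing
  allhet <- toyG(matrix(rep(1L, 30), ncol = 1,
                        dimnames = list(NULL, "s1")),
                 seqlen = c("1" = 1e6))
  expect_equal(nrow(detectRoh(allhet, p)), 0)
})

test_that("ROH detection equals the brute-force oracle", {
  set.seed(99)
  params <- rohParams(minSnps = 5, minLengthBp = 3000, maxMissing = 1,
                      maxHet = 0)
  for (rep in 1:200) {
    n <- sample(10:60, 1)
    g <- sample(c(0L, 1L, 2L, NA), n, TRUE,
                prob = c(0.42, 0.08, 0.42, 0.08))
    pos <- sort(sample.int(5e4, n))
    dens <- n / 6e4
    gd <- toyG(matrix(g, ncol = 1, dimnames = list(NULL, "s1")),
               pos = pos, seqlen = c("1" = 6e4))
    mine <- detectRoh(gd, rohParams(minSnps = 5, minLengthBp = 3000,
                                    minDensity = dens))
    oracle <- rohOracle(g, pos, params, dens)
    expect_equal(nrow(mine), nrow(oracle), info = paste("rep", rep))
    if (nrow(oracle)) {
      expect_equal(mine$start, pos[oracle[, 1]])
      expect_equal(mine$end, pos[oracle[, 2]])
    }
  }
})

test_that("raising ROH thresholds never yields more segments", {
  set.seed(5)
  for (rep in 1:20) {
    n <- 80
    g <- sample(c(0L, 1L, 2L, NA), n, TRUE, prob = c(.45, .05, .45, .05))
    pos <- sort(sample.int(8e4, n))
    gd <- toyG(matrix(g, ncol = 1, dimnames = list(NULL, "s1")),
               pos = pos, seqlen = c("1" = 1e5))
    lo <- detectRoh(gd, rohParams(minSnps = 5, minLengthBp = 2000,
                                  minDensity = 1e-9))
    hiSnps <- detectRoh(gd, rohParams(minSnps = 8, minLengthBp = 2000,
                                      minDensity = 1e-9))
    hiLen <- detectRoh(gd, rohParams(minSnps = 5, minLengthBp = 10000,
                                     minDensity = 1e-9))
    expect_lte(nrow(hiSnps), nrow(lo))
    expect_lte(nrow(hiLen), nrow(lo))
  }
})

test_that("F_ROH is covered length over genome length", {
  layout <- c("1" = 5e7, "2" = 5e7)
  expect_equal(unname(froh(data.frame(sample_id = character(),
                                      chrom = character(),
                                      start = integer(), end = integer()),
                           layout, sampleIds = "s1")), 0)
  segs <- data.frame(sample_id = "s1", chrom = "1",
                     start = 1, end = 1e6)
  expect_equal(unname(froh(segs, layout)), 0.01)
  # overlapping segments are merged before summing
  segs2 <- data.frame(sample_id = "s1", chrom = c("1", "1"),
                      start = c(1, 5e5), end = c(1e6, 1.5e6))
  expect_equal(unname(froh(segs2, layout)), 0.015)
  # never exceeds the marker-covered fraction bound
  set.seed(8)
  cfg <- simConfig(nSamples = 20, nFounderFemales = 4, nFounderMales = 3,
                   nWildMales = 0, nMarkers = 2000, nChromosomes = 4,
                   chromosomeLengthBp = 1e8, errorRate = 0,
                   missingRate = 0)
  sim <- simulateStudy(cfg, seed = 31)
  segs3 <- detectRoh(sim$genotypes, rohParams(minSnps = 10,
                                              minLengthBp = 5e4))
  fr <- froh(segs3, genomeLayout(sim$genotypes))
  rr <- markerMap(sim$genotypes)
  span <- sum(vapply(split(start(rr), as.character(seqnames(rr))),
                     function(p) diff(range(p)) + 1, numeric(1)))
  expect_true(all(fr <= span / sum(genomeLayout(sim$genotypes))))
})

test_that("group comparisons use the right tests and errors", {
  same <- c(1, 2, 3, 4, 5)
  w <- compareGroups(c(same, same), rep(c("a", "b"), each = 5), "wilcoxon")
  expect_gt(w$p_value, 0.95)
  # complete separation: with the normal approximation the rank-sum p at
  # n = 3 per group bottoms out near 0.08, so test the property at n = 10
  sep <- compareGroups(c(1:10, 101:110),
                       rep(c("a", "b"), each = 10), "wilcoxon")
  expect_lt(sep$p_value, 0.01)
  av <- compareGroups(c(1, 2, 3, 101, 102, 103),
                      rep(c("a", "b"), each = 3), "anova")
  expect_lt(av$p_value, 0.01)
  expect_error(compareGroups(1:6, rep("a", 6), "wilcoxon"), "two groups")
  expect_error(compareGroups(1:6, c("a", "a", "b", "b", "c", "c"),
                             "wilcoxon"), "two groups")
  expect_error(compareGroups(1:5, c("a", "a", "b", "c", "c"), "anova"),
               "two observations")
})
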
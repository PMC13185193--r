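smallCfg <- function(...) {
  simConfig(nSamples = 50, nFounderFemales = 10, nFounderMales = 8,
            nWildMales = 2, nMarkers = 600, nChromosomes = 3,
            chromosomeLengthBp = 1e8, ...)
}

test_that("simulation is bit-reproducible under a fixed seed", {
  cfg <- smallCfg()
  f1 <- simulateFounders(cfg, seed = 9)
  f2 <- simulateFounders(cfg, seed = 9)
  expect_identical(f1$haplos, f2$haplos)
  expect_identical(f1$freqs, f2$freqs)
  s1 <- simulateStudy(cfg, seed = 4)
  s2 <- simulateStudy(cfg, seed = 4)
  expect_identical(dosage(s1$genotypes), dosage(s2$genotypes))
  expect_identical(s1$truth, s2$truth)
})

test_that("founder pool matches Hardy-Weinberg expectations", {
  cfg <- simConfig(nSamples = 4, nFounderFemales = 2, nFounderMales = 2,
                   nWildMales = 0, nMarkers = 10000, nChromosomes = 2,
                   chromosomeLengthBp = 1e8,
                   founderFreqRange = c(0.5, 0.5))
  fd <- simulateFounders(cfg, seed = 3)
  het <- vapply(fd$haplos, function(h) mean(h[, 1] != h[, 2]), numeric(1))
  expect_true(all(abs(het - 0.5) < 0.02))  # 2pq at p = q = 0.5
  # degenerate: zero markers still yields a valid empty pool
  cfg0 <- simConfig(nSamples = 4, nFounderFemales = 2, nFounderMales = 2,
                    nWildMales = 0, nMarkers = 0)
  fd0 <- simulateFounders(cfg0, seed = 1)
  expect_equal(length(fd0$map), 0)
  expect_true(all(vapply(fd0$haplos, nrow, integer(1)) == 0L))
})

test_that("sire skew controls the paternity concentration", {
  cfg <- simConfig(nSamples = 1030, nFounderFemales = 20,
                   nFounderMales = 10, nWildMales = 0, nMarkers = 10,
                   sireSkew = 0, mateAvoidanceKinship = Inf,
                   birthYearRange = c(1970, 2015))
  ped <- simulatePedigree(cfg, seed = 5)
  sires <- ped$truth$sire_id[!is.na(ped$truth$sire_id)]
  founderSires <- sires[grepl("^M", sires)]
  tab <- table(founderSires)
  gof <- stats::chisq.test(tab)
  expect_gt(gof$p.value, 0.001)  # about uniform under zero skew
  # cap birth years so late-born captive males never enter the sire pool
  # and the heaviest founder bull keeps winning
  cfgS <- simConfig(nSamples = 220, nFounderFemales = 20,
                    nFounderMales = 10, nWildMales = 0, nMarkers = 10,
                    sireSkew = 60, mateAvoidanceKinship = Inf,
                    birthYearRange = c(1966, 1984))
  pedS <- simulatePedigree(cfgS, seed = 5)
  sS <- pedS$truth$sire_id[!is.na(pedS$truth$sire_id)]
  expect_gt(max(table(sS)) / length(sS), 0.5)  # one bull dominates
})

test_that("visible pedigree is matrilineal-only; truth holds the sires", {
  sim <- simulateStudy(smallCfg(), seed = 8)
  expect_false("sire_id" %in% colnames(sim$pedigree))
  captive <- sim$pedigree$origin == "captive"
  expect_true(all(!is.na(sim$pedigree$dam_id[captive])))
  expect_true(all(is.na(sim$pedigree$dam_id[!captive])))
  cap <- sim$pedigree$sample_id[captive]
  expect_true(all(!is.na(sim$truth$sire_id[match(cap, sim$truth$id)])))
  # parents precede offspring in birth order
  yr <- setNames(sim$pedigree$birth_year, sim$pedigree$sample_id)
  dam <- setNames(sim$pedigree$dam_id, sim$pedigree$sample_id)
  has <- !is.na(dam)
  expect_true(all(yr[dam[has]] < yr[names(dam)[has]]))
})

test_that("transmission is Mendelian before degradation", {
  sim <- simulateStudy(smallCfg(), seed = 12)
  d <- dosage(sim$cleanGenotypes)
  ped <- sim$pedigree
  sire <- setNames(sim$truth$sire_id, sim$truth$id)
  for (i in which(!is.na(ped$dam_id))) {
    kid <- ped$sample_id[i]
    for (par in c(ped$dam_id[i], unname(sire[kid]))) {
      if (is.na(par) || !(par %in% colnames(d))) next
      opp <- sum((d[, kid] == 0L & d[, par] == 2L) |
                 (d[, kid] == 2L & d[, par] == 0L))
      expect_identical(opp, 0L)
    }
  }
  # zero recombination + homozygous parents -> exact mid-parent dosage
  cfg <- smallCfg(founderFreqRange = c(1, 1))
  fd <- simulateFounders(cfg, seed = 2)
  ped2 <- simulatePedigree(cfg, seed = 2)
  g2 <- transmitGenotypes(ped2, fd, cMperMb = 0, seed = 2)
  expect_true(all(dosage(g2) == 2L))
})

test_that("degradation injects the configured noise and nothing else", {
  sim <- simulateStudy(smallCfg(), seed = 3)
  clean <- sim$cleanGenotypes
  expect_identical(dosage(degradeGenotypes(clean, 0, 0)), dosage(clean))
  allMiss <- degradeGenotypes(clean, 0, 1, seed = 1)
  expect_true(all(is.na(dosage(allMiss))))
  expect_error(degradeGenotypes(clean, -0.1, 0), "rates")
  # realized error fraction within the binomial 99% CI over ~1e6 calls
  cfgBig <- simConfig(nSamples = 100, nFounderFemales = 30,
                      nFounderMales = 20, nWildMales = 0, nMarkers = 10000,
                      nChromosomes = 5, chromosomeLengthBp = 2e8,
                      errorRate = 0, missingRate = 0)
  simBig <- simulateStudy(cfgBig, seed = 6)
  eps <- 0.01
  noisy <- degradeGenotypes(simBig$cleanGenotypes, eps, 0, seed = 7)
  n <- length(dosage(noisy))
  flips <- sum(dosage(noisy) != dosage(simBig$cleanGenotypes))
  ci <- qbinom(c(0.005, 0.995), n, eps)
  expect_gte(flips, ci[1])
  expect_lte(flips, ci[2])
})

test_that("HBD sequence generator obeys its chain law", {
  m <- hbdModel(mixing = c(rep(0, 9), 1))
  pos <- seq(1, 1e6, by = 1000)
  sim <- simulateHbdSequence(m, rep(0.3, length(pos)), pos, seed = 1)
  expect_true(all(sim$states == 10L))  # all mass on non-HBD
  # empirical occupancy across many markers matches the chain's
  # stationary distribution at the (constant) marker spacing
  m2 <- hbdModel(mixing = c(0.05, 0.05, 0.1, 0.1, 0.1, 0.1, 0.1, 0.1,
                            0.1, 0.2))
  n <- 1e5
  pos2 <- seq(1, by = 5e5, length.out = n)  # 0.5 cM spacing
  sim2 <- simulateHbdSequence(m2, rep(0.3, n), pos2, seed = 2)
  a <- exp(-m2@rates * 5e5 * 1e-8)
  P <- diag(a) + (1 - a) %o% m2@mixing
  ev <- eigen(t(P))
  statio <- Re(ev$vectors[, which.max(Re(ev$values))])
  statio <- statio / sum(statio)
  occ <- tabulate(sim2$states, 10) / n
  expect_true(all(abs(occ - statio) < 0.03))
  # enormous rates: the state changes between nearly all adjacent markers
  m3 <- hbdModel(rates = rep(1e6, 10),
                 mixing = rep(0.1, 10))
  sim3 <- simulateHbdSequence(m3, rep(0.3, 5000),
                              seq(1, by = 20000, length.out = 5000),
                              seed = 3)
  changes <- mean(diff(sim3$states) != 0)
  expect_gt(changes, 0.85)  # re-entry can hit the same class 1/10 of time
})
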
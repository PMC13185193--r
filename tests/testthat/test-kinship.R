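test_that("KING-robust reproduces hand-counted statistics", {
  # worked example: g_a = (1,1,2,0,1), g_b = (1,0,2,2,1)
  g <- toyG(im(c(1L, 1L, 2L, 0L, 1L), c(1L, 0L, 2L, 2L, 1L)))
  k <- kingRobust(g, "s1", "s2")
  expect_equal(k$n_shared, 5)
  expect_equal(k$n_both_het, 2)
  expect_equal(k$n_opp_hom, 1)
  expect_equal(k$n_het_a, 3)
  expect_equal(k$n_het_b, 2)
  expect_equal(k$phi, 0)
  expect_equal(k$r, 0)
  # duplicate genotype vectors with hets -> phi exactly 0.5
  dup <- toyG(im(c(0L, 1L, 2L, 1L, 1L), c(0L, 1L, 2L, 1L, 1L)))
  expect_identical(kingRobust(dup, "s1", "s2")$phi, 0.5)
  expect_identical(kingRobust(dup, "s1", "s2")$degree, "first")
  # degenerate: no heterozygote in either member -> undefined
  hom <- toyG(im(c(0L, 0L, 2L), c(0L, 0L, 2L)))
  kh <- kingRobust(hom, "s1", "s2")
  expect_true(is.na(kh$phi))
  expect_identical(kh$degree, "undefined")
  expect_error(kingRobust(g, "s1", "s1"), "distinct")
  expect_error(kingRobust(g, "s1", "zz"), "unknown")
  nog <- toyG(im(c(NA, 1L), c(1L, NA)))
  expect_error(kingRobust(nog, "s1", "s2"), "zero pairwise-complete")
})

test_that("kinship matrix agrees with the per-pair estimator", {
  set.seed(42)
  d <- matrix(sample(c(0:2, NA), 50 * 6, TRUE, prob = c(.3, .3, .3, .1)),
              50, 6, dimnames = list(NULL, paste0("s", 1:6)))
  g <- toyG(d)
  kin <- kinshipMatrix(g)
  expect_equal(nrow(kin), 15)
  for (i in seq_len(nrow(kin))) {
    one <- kingRobust(g, kin$id_a[i], kin$id_b[i])
    rev <- kingRobust(g, kin$id_b[i], kin$id_a[i])
    expect_equal(kin$phi[i], one$phi)
    expect_identical(one$phi, rev$phi)   # symmetry, exact
    expect_equal(kin$n_shared[i], one$n_shared)
    expect_equal(kin$n_opp_hom[i], one$n_opp_hom)
  }
  # permuting samples preserves the multiset of pair estimates
  g2 <- toyG(d[, c(4, 2, 6, 1, 3, 5)])
  kin2 <- kinshipMatrix(g2)
  k1 <- setNames(kin$phi, pairKey(kin$id_a, kin$id_b))
  k2 <- setNames(kin2$phi, pairKey(kin2$id_a, kin2$id_b))
  expect_equal(k1[sort(names(k1))], k2[sort(names(k2))])
  expect_error(kinshipMatrix(g[, 1]), "two samples")
})

test_that("degree bins follow the printed thresholds on the r scale", {
  expect_identical(classifyDegree(c(0.5, 0.30, 0.124, 0.2, 0.46)),
                   c("first", "second", "unrelated", "third_fourth",
                     "first"))
  expect_identical(classifyDegree(0.125), "third_fourth")
  expect_identical(classifyDegree(0.25), "second")
  expect_identical(classifyDegree(0.45), "second")   # first is r > 0.45
  expect_identical(classifyDegree(NA_real_), "undefined")
})

test_that("unrelated subset removes one member per kin pair", {
  kin <- data.frame(id_a = c("A", "B"), id_b = c("B", "C"),
                    phi = c(0.2, 0.2))
  expect_identical(unrelatedSubset(kin), c("A", "C"))
  none <- data.frame(id_a = "A", id_b = "B", phi = 0.01)
  expect_identical(unrelatedSubset(none), c("A", "B"))
  # camp tie-break: drop from the best-represented camp
  kin2 <- data.frame(id_a = "A", id_b = "B", phi = 0.3)
  meta <- data.frame(sample_id = c("A", "B", "C", "D"),
                     camp = c("big", "small", "big", "big"))
  kept <- unrelatedSubset(kin2, meta = meta)
  expect_true(setequal(kept, c("B", "C", "D")))  # A dropped: camp "big"
  # postcondition on a random instance
  set.seed(3)
  ids <- paste0("x", 1:12)
  rk <- data.frame(id_a = rep(ids, each = 12), id_b = rep(ids, 12))
  rk <- rk[rk$id_a < rk$id_b, ]
  rk$phi <- runif(nrow(rk), 0, 0.15)
  kept <- unrelatedSubset(rk, phiCutoff = 0.08)
  bad <- rk$phi >= 0.08 & rk$id_a %in% kept & rk$id_b %in% kept
  expect_false(any(bad))
})

test_that("paternity rule enforces its three exclusions", {
  meta <- data.frame(
    sample_id = c("M1", "F1", "Y1", "Y2", "Y3", "S1"),
    sex = c("male", "female", "male", "female", "male", "male"),
    birth_year = c(1950L, 1950L, 1990L, 1990L, 1969L, 1967L),
    stringsAsFactors = FALSE)
  kin <- data.frame(
    id_a = c("M1", "F1", "M1", "M1"),
    id_b = c("Y1", "Y2", "Y3", "S1"),
    phi = 0.25, r = 0.5, degree = "first", stringsAsFactors = FALSE)
  # no pedigree: emitted iff the older member is male and gap > 18
  out <- inferPaternity(kin, meta)
  expect_true(all(out$pairs$sire_id == "M1"))
  expect_setequal(out$pairs$offspring_id, c("Y1", "Y3"))  # gaps 40, 19
  expect_false("Y2" %in% out$pairs$offspring_id)  # older member female
  expect_false("S1" %in% out$pairs$offspring_id)  # gap 17
  # gap exactly 18 is excluded (strict inequality)
  kin18 <- data.frame(id_a = "M1", id_b = "X", phi = 0.25, r = 0.5,
                      degree = "first")
  meta18 <- rbind(meta, data.frame(sample_id = "X", sex = "male",
                                   birth_year = 1968L))
  expect_equal(nrow(inferPaternity(kin18, meta18)$pairs), 0)
  kin19 <- within(kin18, id_b <- "Y3")  # gap 19 -> emitted
  expect_equal(nrow(inferPaternity(kin19, meta)$pairs), 1)
  # recorded relatedness excludes: shared recorded ancestry via the dam
  ped <- data.frame(sample_id = c("M1", "D1", "Y1"),
                    dam_id = c("D1", NA, "D1"), stringsAsFactors = FALSE)
  out2 <- inferPaternity(kin[1, ], meta, pedigree = ped)
  expect_equal(nrow(out2$pairs), 0)     # M1 and Y1 share recorded dam D1
  # recorded sire-line ancestor also excludes
  ped2 <- data.frame(sample_id = c("M1", "S1", "Y1"),
                     dam_id = NA_character_,
                     sire_id = c(NA, "M1", "S1"), stringsAsFactors = FALSE)
  out3 <- inferPaternity(kin[1, ], meta, pedigree = ped2)
  expect_equal(nrow(out3$pairs), 0)     # M1 is Y1's recorded grandsire
  # missing metadata: skipped and counted
  kinNA <- data.frame(id_a = "M1", id_b = "ZZ", phi = 0.25, r = 0.5,
                      degree = "first")
  outNA <- inferPaternity(kinNA, meta)
  expect_equal(nrow(outNA$pairs), 0)
  expect_equal(outNA$nSkipped, 1)
})

test_that("prolific sires are counted and ranked", {
  meta <- data.frame(sample_id = c("M1", "a", "b", "c"),
                     sex = c("male", "female", "male", "female"),
                     birth_year = c(1950L, 1990L, 1991L, 1992L))
  kin <- data.frame(id_a = "M1", id_b = c("a", "b", "c"),
                    phi = 0.25, r = 0.5, degree = "first")
  out <- inferPaternity(kin, meta)
  expect_identical(out$sireCounts$sire_id, "M1")
  expect_identical(out$sireCounts$n_offspring, 3L)
})

test_that("maternal links are verified against kinship", {
  kin <- data.frame(id_a = c("D1", "D2"), id_b = c("K1", "K2"),
                    phi = c(0.25, 0.01), r = c(0.5, 0.02),
                    degree = c("first", "unrelated"))
  ped <- data.frame(sample_id = c("D1", "D2", "K1", "K2"),
                    dam_id = c(NA, NA, "D1", "D2"))
  out <- verifyMaternalLinks(kin, ped)
  expect_equal(nrow(out), 2)
  expect_identical(out$discordant, c(FALSE, TRUE))
  # on a clean simulation every recorded link is concordant
  cfg <- simConfig(nSamples = 40, nFounderFemales = 8, nFounderMales = 6,
                   nWildMales = 1, nMarkers = 3000, nChromosomes = 5,
                   chromosomeLengthBp = 2e8, errorRate = 0,
                   missingRate = 0)
  sim <- simulateStudy(cfg, seed = 21)
  kin2 <- kinshipMatrix(sim$genotypes)
  chk <- verifyMaternalLinks(kin2, sim$pedigree)
  expect_gt(nrow(chk), 5)
  expect_false(any(chk$discordant, na.rm = TRUE))
})
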
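test_that("VCF genotypes decode to dosages with missing handling", {
  g <- readVcfGenotypes(extdata("toy.vcf"))
  expect_s4_class(g, "GenotypeData")
  expected <- matrix(c(0L, 1L, 2L,
                       1L, NA, 0L,
                       2L, 1L, 0L,
                       0L, 0L, NA),
                     nrow = 4, byrow = TRUE,
                     dimnames = list(c("rs1", "rs2", "rs3", "rs4"),
                                     c("S1", "S2", "S3")))
  expect_identical(dosage(g), expected)
  expect_identical(as.character(seqnames(markerMap(g))),
                   c("1", "1", "2", "2"))
  expect_identical(start(markerMap(g)), c(100L, 5000L, 200L, 9000L))
  expect_equal(unname(genomeLayout(g)[c("1", "2")]), c(1e6, 8e5))
})

test_that("multi-allelic VCF records are skipped or rejected per flag", {
  tmp <- tempfile(fileext = ".vcf")
  lines <- readLines(extdata("toy.vcf"))
  lines <- append(lines, "1\t700\trsX\tA\tC,G\t.\tPASS\t.\tGT\t1/2\t0/0\t0/1",
                  after = 5)
  writeLines(lines, tmp)
  g <- readVcfGenotypes(tmp)
  expect_equal(nMarkers(g), 4)
  expect_false("rsX" %in% rownames(dosage(g)))
  expect_error(readVcfGenotypes(tmp, multiallelic = "error"),
               "multi-allelic")
})

test_that("VCF reading drops sex chromosomes and rejects bad input", {
  tmp <- tempfile(fileext = ".vcf")
  lines <- readLines(extdata("toy.vcf"))
  writeLines(c(lines, "X\t100\trsx\tA\tC\t.\tPASS\t.\tGT\t0/0\t0/1\t1/1"),
             tmp)
  expect_equal(nMarkers(readVcfGenotypes(tmp)), 4)
  expect_error(readVcfGenotypes(tempfile()), "cannot read")
})

test_that("VCF round-trips through write + read", {
  g <- readVcfGenotypes(extdata("toy.vcf"))
  tmp <- tempfile(fileext = ".vcf")
  writeVcfGenotypes(g, tmp)
  g2 <- readVcfGenotypes(tmp)
  expect_identical(dosage(g2), dosage(g))
  expect_identical(start(markerMap(g2)), start(markerMap(g)))
  expect_identical(genomeLayout(g2), genomeLayout(g))
})

test_that("PED/MAP recodes allele pairs against declared alleles", {
  g <- readPlinkText(ped = extdata("toy.ped"), map = extdata("toy.map"))
  expected <- matrix(c(0L, 1L,   # m1: alt C
                       1L, 2L,   # m2: alt T
                       NA, 1L,   # m3: 0 0 -> missing
                       2L, 1L),  # m4: alt A; "A A" -> 2
                     nrow = 4, byrow = TRUE,
                     dimnames = list(c("m1", "m2", "m3", "m4"),
                                     c("I1", "I2")))
  expect_identical(dosage(g), expected)
  expect_identical(unname(as.character(colData(g)$sex)),
                   c("male", "female"))
})

test_that("PED/MAP round-trips and catches inconsistencies", {
  g <- readPlinkText(ped = extdata("toy.ped"), map = extdata("toy.map"))
  pre <- file.path(tempdir(), "rt")
  writePlinkText(g, pre)
  g2 <- readPlinkText(pre)
  expect_identical(dosage(g2), dosage(g))
  expect_identical(start(markerMap(g2)), start(markerMap(g)))
  # marker-count mismatch
  bad <- file.path(tempdir(), "bad")
  file.copy(paste0(pre, ".ped"), paste0(bad, ".ped"), overwrite = TRUE)
  mp <- read.table(paste0(pre, ".map"))
  write.table(mp[1:2, ], paste0(bad, ".map"), sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  expect_error(readPlinkText(bad), "mismatch")
  # three alleles at one marker
  pd <- readLines(paste0(pre, ".ped"))
  pd[1] <- sub("A\tA", "G\tA", pd[1])
  writeLines(pd, paste0(bad, ".ped"))
  file.copy(paste0(pre, ".map"), paste0(bad, ".map"), overwrite = TRUE)
  expect_error(readPlinkText(bad), "allele")
})

test_that("sample metadata parses blanks, sexes and years", {
  meta <- readSampleMeta(extdata("toy_meta.tsv"))
  expect_equal(nrow(meta), 5)
  expect_identical(meta$sample_id, paste0("E", 1:5))
  expect_identical(meta$sex,
                   c("female", "male", "female", "unknown", "male"))
  expect_identical(meta$birth_year, c(1974L, 1968L, 1990L, NA, 2001L))
  expect_identical(meta$origin,
                   c("captive", "wild", "captive", "unknown", "captive"))
  expect_true(is.na(meta$dam_id[1]))
  expect_identical(meta$dam_id[3], "E1")

  tmp <- tempfile(fileext = ".tsv")
  writeSampleMeta(meta, tmp)
  expect_identical(readSampleMeta(tmp), meta)

  bad <- readLines(extdata("toy_meta.tsv"))
  bad[2] <- sub("1974", "about 1974", bad[2])
  writeLines(bad, tmp)
  expect_error(readSampleMeta(tmp), "malformed birth_year")
  bad <- readLines(extdata("toy_meta.tsv"))
  bad[3] <- sub("^E2", "E1", bad[3])
  writeLines(bad, tmp)
  expect_error(readSampleMeta(tmp), "duplicated")
  bad <- readLines(extdata("toy_meta.tsv"))
  bad[4] <- sub("E1$", "E2", bad[4])   # dam points at a male
  writeLines(bad, tmp)
  expect_error(readSampleMeta(tmp), "male")
})

test_that("GenotypeData enforces its invariants", {
  d <- matrix(c(0L, 1L, 2L, NA), 2, 2,
              dimnames = list(NULL, c("a", "b")))
  gr <- GRanges("1", IRanges(c(10, 20), width = 1))
  g <- GenotypeData(d, gr, seqlengths = c("1" = 100))
  expect_true(validObject(g))
  expect_error(GenotypeData(matrix(3L, 2, 2,
                                   dimnames = list(NULL, c("a", "b"))), gr),
               "0, 1, 2")
  expect_error(GenotypeData(`colnames<-`(d, c("a", "a")), gr), "unique")
  expect_error(GenotypeData(d, GRanges("1", IRanges(c(10, 10), width = 1))),
               "strictly increasing")
  suppressWarnings(   # GRanges itself also flags the out-of-bound range
    expect_error(GenotypeData(d, gr, seqlengths = c("1" = 15)), "beyond"))
  # markers are sorted on construction, dosages follow
  g2 <- GenotypeData(matrix(c(0L, 1L, 2L, 0L), 2, 2,
                            dimnames = list(NULL, c("a", "b"))),
                     GRanges("1", IRanges(c(20, 10), width = 1)))
  expect_identical(start(markerMap(g2)), c(10L, 20L))
  expect_identical(unname(dosage(g2)[1, ]), c(1L, 0L))
})

test_that("sample metadata attaches by id and subsetting works", {
  g <- readVcfGenotypes(extdata("toy.vcf"))
  meta <- data.frame(sample_id = c("S3", "S1", "S2"),
                     sex = c("male", "female", "female"),
                     birth_year = c(2000L, 1990L, 1995L))
  sampleMeta(g) <- meta
  expect_identical(sampleMeta(g)$sex, c("female", "female", "male"))
  sub <- g[c("rs2", "rs3"), c("S2", "S3")]
  expect_equal(dim(sub), c(2L, 2L))
  expect_identical(rownames(dosage(sub)), c("rs2", "rs3"))
})
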
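#' Read genotypes from a VCF file
#'
#' Parses a (possibly bgzipped) VCF of biallelic SNPs into a
#' [GenotypeData-class] object. Dosage is the alternate-allele count of the
#' GT field; any half-missing, fully missing or non-diploid genotype becomes
#' `NA`. Phased and unphased separators are treated identically. Record order
#' is preserved (chromosomes in order of appearance). Chromosome lengths are
#' taken from `##contig` header lines when present.
#'
#' Markers on sex chromosomes (or other excluded contigs) are dropped on
#' load, as analyses downstream assume autosomal data.
#'
#' @param path path to the VCF file.
#' @param multiallelic `"skip"` (default) silently drops records whose ALT
#'   holds more than one allele; `"error"` aborts on them.
#' @param dropChrom chromosome labels removed on load (default: common sex
#'   chromosome and mitochondrial labels).
#' @return A [GenotypeData-class] object.
#' @seealso [writeVcfGenotypes()], [readPlinkText()]
#' @export
readVcfGenotypes <- function(path, multiallelic = c("skip", "error"),
                             dropChrom = c("X", "Y", "W", "Z", "MT",
                                           "chrX", "chrY", "chrW", "chrZ",
                                           "chrM")) {
  multiallelic <- match.arg(multiallelic)
  if (!file.exists(path)) stop("cannot read VCF: ", path)
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  if (ncol(v@gt) < 2L) stop("VCF contains zero samples")
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1,
                                       dimnames = list(NULL, names(fix)))
  gt <- vcfR::extract.gt(v, element = "GT")
  samples <- colnames(gt)
  if (anyDuplicated(samples)) stop("duplicated sample ids in VCF")

  alt <- fix[, "ALT"]
  multi <- is.na(alt) | grepl(",", alt, fixed = TRUE)
  if (any(multi)) {
    if (multiallelic == "error")
      stop(sum(multi), " multi-allelic record(s) in VCF")
    fix <- fix[!multi, , drop = FALSE]
    gt <- gt[!multi, , drop = FALSE]
  }
  if (!nrow(fix)) stop("no biallelic records in VCF")

  code <- c("0/0" = 0L, "0/1" = 1L, "1/0" = 1L, "1/1" = 2L,
            "0|0" = 0L, "0|1" = 1L, "1|0" = 1L, "1|1" = 2L)
  d <- matrix(code[gt], nrow = nrow(gt), dimnames = list(NULL, samples))

  chrom <- fix[, "CHROM"]
  pos <- as.integer(fix[, "POS"])
  ids <- fix[, "ID"]
  ids[is.na(ids) | ids == "."] <- paste0(chrom, ":", pos)[is.na(ids) | ids == "."]
  if (anyDuplicated(ids)) ids <- make.unique(ids)

  keep <- !(chrom %in% dropChrom)
  chrom <- chrom[keep]; pos <- pos[keep]; ids <- ids[keep]
  d <- d[keep, , drop = FALSE]
  if (!nrow(d)) stop("no autosomal records left after chromosome filtering")

  gr <- GRanges(chrom, IRanges(pos, width = 1),
                ref = fix[keep, "REF"], alt = fix[keep, "ALT"])
  names(gr) <- ids

  sl <- .vcfContigLengths(v@meta)
  sl <- sl[!(names(sl) %in% dropChrom)]
  GenotypeData(d, gr, seqlengths = if (length(sl)) sl else NULL)
}

.vcfContigLengths <- function(meta) {
  ln <- grep("^##contig=", meta, value = TRUE)
  if (!length(ln)) return(numeric())
  id <- sub(".*[<,]ID=([^,>]+).*", "\\1", ln)
  has <- grepl("length=", ln)
  len <- rep(NA_real_, length(ln))
  len[has] <- as.numeric(sub(".*length=([0-9]+).*", "\\1", ln[has]))
  stats::setNames(len, id)[has]
}

#' Write genotypes to a VCF file
#'
#' Emits a minimal VCF 4.2 with GT-only genotypes; `NA` calls become `./.`.
#' Declared chromosome lengths are written as `##contig` lines so the genome
#' layout round-trips. Output is deterministic.
#'
#' @param x a [GenotypeData-class] object.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
writeVcfGenotypes <- function(x, path) {
  d <- dosage(x)
  rr <- rowRanges(x)
  sl <- seqlengths(rr)
  hdr <- c("##fileformat=VCFv4.2",
           sprintf("##contig=<ID=%s,length=%d>",
                   names(sl)[!is.na(sl)], as.integer(sl[!is.na(sl)])),
           "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", colnames(d)), collapse = "\t"))
  gtc <- c("0/0", "0/1", "1/1")
  gt <- matrix("./.", nrow = nrow(d), ncol = ncol(d))
  ok <- !is.na(d)
  gt[ok] <- gtc[d[ok] + 1L]
  ref <- if ("ref" %in% colnames(mcols(rr))) mcols(rr)$ref else rep("A", nrow(d))
  alt <- if ("alt" %in% colnames(mcols(rr))) mcols(rr)$alt else rep("C", nrow(d))
  body <- paste(as.character(seqnames(rr)), start(rr), names(rr), ref, alt,
                ".", "PASS", ".", "GT",
                apply(gt, 1L, paste, collapse = "\t"), sep = "\t")
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Read genotypes from PLINK PED/MAP text files
#'
#' Recodes PED allele pairs to alternate-allele dosage. If the MAP file has
#' six columns the fifth/sixth are taken as the declared ref/alt alleles
#' (the convention [writePlinkText()] emits); with the standard four-column
#' MAP, the alternate allele at each marker is the minor observed allele
#' (ties broken to the alphabetically later allele). `0 0` and half-missing
#' pairs become `NA`. More than two distinct non-missing alleles at a marker
#' is an error.
#'
#' @param prefix path prefix; `<prefix>.ped` and `<prefix>.map` are read.
#' @param ped,map explicit file paths overriding `prefix`.
#' @param dropChrom chromosome labels removed on load.
#' @return A [GenotypeData-class] object (PED sex stored in `colData`).
#' @export
readPlinkText <- function(prefix = NULL, ped = NULL, map = NULL,
                          dropChrom = c("X", "Y", "W", "Z", "MT",
                                        "chrX", "chrY", "chrW", "chrZ",
                                        "chrM")) {
  if (is.null(ped)) ped <- paste0(prefix, ".ped")
  if (is.null(map)) map <- paste0(prefix, ".map")
  if (!file.exists(ped) || !file.exists(map))
    stop("PED/MAP file(s) not found for prefix/path given")
  mp <- read.table(map, stringsAsFactors = FALSE, colClasses = "character")
  if (!ncol(mp) %in% c(4L, 6L))
    stop("MAP file must have 4 or 6 columns")
  pd <- read.table(ped, stringsAsFactors = FALSE, colClasses = "character")
  nmk <- nrow(mp)
  if ((ncol(pd) - 6L) != 2L * nmk)
    stop("PED/MAP marker-count mismatch: MAP declares ", nmk,
         " markers, PED carries ", (ncol(pd) - 6L) / 2)
  ids <- pd[[2L]]
  if (anyDuplicated(ids)) stop("duplicated sample ids in PED")

  a1 <- as.matrix(pd[, 6L + 2L * seq_len(nmk) - 1L, drop = FALSE])
  a2 <- as.matrix(pd[, 6L + 2L * seq_len(nmk), drop = FALSE])
  d <- matrix(NA_integer_, nrow = nmk, ncol = length(ids),
              dimnames = list(mp[[2L]], ids))
  for (j in seq_len(nmk)) {
    x1 <- a1[, j]; x2 <- a2[, j]
    obs <- c(x1, x2)
    alleles <- sort(unique(obs[obs != "0"]))
    if (length(alleles) > 2L)
      stop("more than two alleles observed at marker ", mp[[2L]][j])
    if (ncol(mp) == 6L) {
      refA <- mp[[5L]][j]; altA <- mp[[6L]][j]
      if (length(setdiff(alleles, c(refA, altA))))
        stop("allele not matching declared ref/alt at marker ", mp[[2L]][j])
    } else if (length(alleles) == 0L) {
      altA <- NA_character_; refA <- NA_character_
    } else if (length(alleles) == 1L) {
      refA <- alleles; altA <- NA_character_
    } else {
      n1 <- sum(obs == alleles[1L]); n2 <- sum(obs == alleles[2L])
      # minor allele is alt; tie -> alphabetically later allele
      if (n1 < n2) {
        altA <- alleles[1L]; refA <- alleles[2L]
      } else {
        altA <- alleles[2L]; refA <- alleles[1L]
      }
    }
    ok <- x1 != "0" & x2 != "0"
    if (is.na(altA)) {
      d[j, ok] <- 0L
    } else {
      d[j, ok] <- (x1[ok] == altA) + (x2[ok] == altA)
    }
    if (!exists("refv", inherits = FALSE)) {
      refv <- character(nmk); altv <- character(nmk)
    }
    refv[j] <- if (is.na(refA)) "0" else refA
    altv[j] <- if (is.na(altA)) "0" else altA
  }

  chrom <- mp[[1L]]
  keep <- !(chrom %in% dropChrom)
  gr <- GRanges(chrom[keep], IRanges(as.integer(mp[[4L]][keep]), width = 1),
                ref = refv[keep], alt = altv[keep])
  names(gr) <- mp[[2L]][keep]
  sexmap <- c("1" = "male", "2" = "female")
  sex <- unname(sexmap[pd[[5L]]])
  sex[is.na(sex)] <- "unknown"
  meta <- S4Vectors::DataFrame(sex = sex, row.names = ids)
  GenotypeData(d[keep, , drop = FALSE], gr, sampleMeta = meta)
}

#' Write genotypes as PLINK PED/MAP text
#'
#' Emits `<prefix>.ped` and a six-column `<prefix>.map` (chromosome, marker
#' id, genetic position in cM at 1 cM/Mb, bp position, ref allele, alt
#' allele) so dosages round-trip exactly through [readPlinkText()].
#'
#' @param x a [GenotypeData-class] object.
#' @param prefix output path prefix.
#' @return `prefix`, invisibly.
#' @export
writePlinkText <- function(x, prefix) {
  d <- dosage(x)
  rr <- rowRanges(x)
  ref <- if ("ref" %in% colnames(mcols(rr))) as.character(mcols(rr)$ref)
         else rep("A", nrow(d))
  alt <- if ("alt" %in% colnames(mcols(rr))) as.character(mcols(rr)$alt)
         else rep("C", nrow(d))
  ref[is.na(ref) | ref == ""] <- "A"
  alt[is.na(alt) | alt == ""] <- "C"
  mp <- data.frame(chrom = as.character(seqnames(rr)), id = names(rr),
                   cm = start(rr) * 1e-6, pos = start(rr),
                   ref = ref, alt = alt)
  write.table(mp, paste0(prefix, ".map"), sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)

  sex <- rep("0", ncol(d))
  cd <- colData(x)
  if ("sex" %in% colnames(cd))
    sex <- c(male = "1", female = "2", unknown = "0")[as.character(cd$sex)]
  sex[is.na(sex)] <- "0"

  lines <- vapply(seq_len(ncol(d)), function(s) {
    g <- d[, s]
    h1 <- ifelse(is.na(g), "0", ifelse(g >= 1L, alt, ref))
    h2 <- ifelse(is.na(g), "0", ifelse(g == 2L, alt, ref))
    paste(c(colnames(d)[s], colnames(d)[s], "0", "0", sex[s], "-9",
            as.vector(rbind(h1, h2))), collapse = "\t")
  }, character(1))
  writeLines(lines, paste0(prefix, ".ped"))
  invisible(prefix)
}

#' Read a sample metadata table
#'
#' Reads a tab-separated table with header columns `sample_id`, `sex`,
#' `birth_year`, `origin`, `camp`, `dam_id` (an optional
#' `birth_year_approx` column of TRUE/FALSE flags estimated birth years).
#' Blank fields map to `"unknown"` (sex, origin) or `NA` (camp, dam,
#' birth year); `sex` accepts `M`/`F`/`male`/`female` in any case. A
#' non-integer birth year, a duplicated `sample_id`, or a `dam_id` pointing
#' at a male record is an error.
#'
#' @param path path to the TSV file.
#' @return `data.frame` with columns `sample_id`, `sex`, `birth_year`
#'   (integer), `birth_year_approx` (logical), `origin`, `camp`, `dam_id`.
#' @export
readSampleMeta <- function(path) {
  df <- read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE,
                   colClasses = "character", na.strings = c("", "NA"),
                   quote = "", comment.char = "")
  need <- c("sample_id", "sex", "birth_year", "origin", "camp", "dam_id")
  miss <- setdiff(need, colnames(df))
  if (length(miss))
    stop("metadata missing column(s): ", paste(miss, collapse = ", "))
  if (anyDuplicated(df$sample_id))
    stop("duplicated sample_id in metadata")
  by <- df$birth_year
  bad <- !is.na(by) & !grepl("^-?[0-9]+$", by)
  if (any(bad))
    stop("malformed birth_year: ", paste(unique(by[bad]), collapse = ", "))
  sx <- tolower(df$sex)
  sex <- ifelse(sx %in% c("m", "male"), "male",
         ifelse(sx %in% c("f", "female"), "female", "unknown"))
  org <- tolower(df$origin)
  origin <- ifelse(org %in% "wild", "wild",
            ifelse(org %in% "captive", "captive", "unknown"))
  approx <- if ("birth_year_approx" %in% colnames(df)) {
    as.logical(df$birth_year_approx)
  } else rep(FALSE, nrow(df))
  approx[is.na(approx)] <- FALSE
  out <- data.frame(sample_id = df$sample_id, sex = sex,
                    birth_year = as.integer(by),
                    birth_year_approx = approx,
                    origin = origin, camp = df$camp, dam_id = df$dam_id,
                    stringsAsFactors = FALSE)
  dam <- out$dam_id[!is.na(out$dam_id)]
  damsex <- out$sex[match(dam, out$sample_id)]
  if (any(!is.na(damsex) & damsex == "male"))
    stop("dam_id refers to a male record: ",
         paste(unique(dam[!is.na(damsex) & damsex == "male"]), collapse = ", "))
  out
}

#' Write a sample metadata table
#'
#' Inverse of [readSampleMeta()]; deterministic TSV output.
#'
#' @param meta metadata `data.frame` as returned by [readSampleMeta()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
writeSampleMeta <- function(meta, path) {
  write.table(meta, path, sep = "\t", quote = FALSE, row.names = FALSE,
              na = "")
  invisible(path)
}
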
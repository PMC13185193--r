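.pipelineDefaults <- function() list(
  simulate = list(),          # simConfig() arguments; NULL disables
  input = NULL,               # list(vcf=|pedPrefix=, metadata=)
  stages = c("qc", "kinship", "inbreeding", "hbd", "rim", "report"),
  qc = list(maf = 0.05, maxMissing = 0.10, ld = FALSE,
            ldWindowBp = 50000, ldStep = 5, ldR2 = 0.25),
  kinship = list(phiCutoff = 0.08, ageGap = 18),
  inbreeding = list(minSnps = 20, minLengthKb = 100, maxMissingInRoh = 1,
                    maxHet = 0),
  hbd = list(error = 0.001, fit = TRUE, maxSamples = NULL, tol = 1e-4,
             maxIter = 200),
  rim = list(mafThresholds = c(0.35, 0.40, 0.45), maxMissing = 0.05,
             r2 = 0.2, nIter = 100),
  seed = 1L
)

.stageDeps <- list(qc = character(), kinship = "qc", inbreeding = "qc",
                   hbd = "qc", rim = c("qc", "kinship"),
                   report = character())

# Fan a single global seed out to per-stage seeds so toggling one stage
# never perturbs another stage's randomness.
.stageSeed <- function(seed, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(seed) * 10007 + h * 7919) %% 2147483647)
}

.mergeConfig <- function(config) {
  def <- .pipelineDefaults()
  bad <- setdiff(names(config), names(def))
  if (length(bad))
    stop("unknown config key(s): ", paste(bad, collapse = ", "))
  for (nm in names(config)) {
    if (nm %in% c("qc", "kinship", "inbreeding", "hbd", "rim")) {
      badk <- setdiff(names(config[[nm]]), names(def[[nm]]))
      if (length(badk))
        stop("unknown key(s) in '", nm, "': ", paste(badk, collapse = ", "))
      def[[nm]][names(config[[nm]])] <- config[[nm]]
    } else {
      def[[nm]] <- config[[nm]]
    }
  }
  if (!is.null(def$input)) def$simulate <- NULL
  stages <- def$stages
  badst <- setdiff(stages, names(.stageDeps))
  if (length(badst))
    stop("unknown stage(s): ", paste(badst, collapse = ", "))
  for (st in stages) {
    need <- setdiff(.stageDeps[[st]], stages)
    if (length(need))
      stop("stage '", st, "' requires disabled stage(s): ",
           paste(need, collapse = ", "))
  }
  def
}

.writeTsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              na = "NA")
  path
}

#' Run the full analysis pipeline
#'
#' Executes the enabled stages in dependency order — input/simulation, QC
#' (marker filters, optional LD pruning), kinship (all-pairs KING table,
#' degree counts, unrelated subset, paternity inference, maternal
#' cross-check), inbreeding (Ho, ROH, F_ROH, group tests), HBD partition,
#' RIM panel evaluation, report — writing one TSV per result plus a
#' machine-readable manifest with an MD5 checksum per output. A single
#' global seed fans out to per-stage seeds, and two runs with the same
#' configuration and seed produce checksum-identical outputs. A failing
#' stage aborts with the stage named and leaves a `FAILED` marker next to
#' any partial outputs.
#'
#' @param config nested list of options; unknown keys are rejected. Top
#'   level: `simulate` (arguments to [simConfig()]; the default), `input`
#'   (`list(vcf=)` or `list(pedPrefix=)` plus `metadata=`), `stages`,
#'   `seed`, and per-stage blocks `qc`, `kinship`, `inbreeding`, `hbd`,
#'   `rim` mirroring the module arguments.
#' @param outDir output directory (created if absent).
#' @return the manifest, invisibly.
#' @seealso [makeReport()]
#' @export
runPipeline <- function(config = list(), outDir) {
  cfg <- .mergeConfig(config)
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(package = "pedgen",
                   version = as.character(packageVersion("pedgen")),
                   seed = cfg$seed, stages = cfg$stages,
                   config = cfg[setdiff(names(cfg), "input")],
                   files = list())
  addFile <- function(name, path, manifest) {
    manifest$files[[name]] <- list(path = basename(path),
                                   md5 = unname(tools::md5sum(path)))
    manifest
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      writeLines(c(name, conditionMessage(e)),
                 file.path(outDir, "FAILED"))
      stop("stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }

  # --- input / simulation -------------------------------------------------
  G <- NULL; truth <- NULL; meta <- NULL
  if (is.null(cfg$input)) {
    stage("simulate", {
      scfg <- do.call(simConfig, cfg$simulate)
      sim <- simulateStudy(scfg, seed = .stageSeed(cfg$seed, "simulate"))
      G <- sim$genotypes
      meta <- sim$pedigree
      truth <- sim$truth
      writeVcfGenotypes(G, file.path(outDir, "genotypes.vcf"))
      writeSampleMeta(meta, file.path(outDir, "metadata.tsv"))
      .writeTsv(truth, file.path(outDir, "truth_sires.tsv"))
      manifest <- addFile("genotypes", file.path(outDir, "genotypes.vcf"),
                           manifest)
      manifest <- addFile("metadata", file.path(outDir, "metadata.tsv"),
                           manifest)
      manifest <- addFile("truth", file.path(outDir, "truth_sires.tsv"),
                           manifest)
    })
  } else {
    stage("input", {
      G <- if (!is.null(cfg$input$vcf)) readVcfGenotypes(cfg$input$vcf)
            else readPlinkText(cfg$input$pedPrefix)
      if (!is.null(cfg$input$metadata)) {
        meta <- readSampleMeta(cfg$input$metadata)
        sampleMeta(G) <- meta
      } else {
        meta <- sampleMeta(G)
      }
    })
  }

  # --- qc -----------------------------------------------------------------
  if ("qc" %in% cfg$stages) stage("qc", {
    n0 <- nMarkers(G)
    G <- filterMarkers(G, mafMin = cfg$qc$maf,
                        maxMissingRate = cfg$qc$maxMissing)
    if (isTRUE(cfg$qc$ld))
      G <- G[ldPrune(G, windowBp = cfg$qc$ldWindowBp,
                      stepSnps = cfg$qc$ldStep, r2Max = cfg$qc$ldR2), ]
    .writeTsv(data.frame(markers_in = n0, markers_out = nMarkers(G),
                         samples = nSamples(G)),
              file.path(outDir, "qc_summary.tsv"))
    manifest <- addFile("qc_summary", file.path(outDir, "qc_summary.tsv"),
                         manifest)
  })

  kin <- NULL
  if ("kinship" %in% cfg$stages) stage("kinship", {
    kin <- kinshipMatrix(G)
    kout <- kin
    kout$phi <- sprintf("%.6g", kout$phi)
    kout$r <- sprintf("%.6g", kout$r)
    .writeTsv(kout, file.path(outDir, "kinship.tsv"))
    dc <- as.data.frame(table(degree = kin$degree),
                        stringsAsFactors = FALSE)
    .writeTsv(dc, file.path(outDir, "degree_counts.tsv"))
    keep <- unrelatedSubset(kin, phiCutoff = cfg$kinship$phiCutoff,
                            meta = meta)
    writeLines(keep, file.path(outDir, "unrelated_subset.txt"))
    pat <- inferPaternity(kin, meta, pedigree = meta,
                          ageGap = cfg$kinship$ageGap)
    .writeTsv(pat$pairs, file.path(outDir, "paternity.tsv"))
    .writeTsv(pat$sireCounts, file.path(outDir, "sire_counts.tsv"))
    mat <- verifyMaternalLinks(kin, meta)
    .writeTsv(mat, file.path(outDir, "maternal_check.tsv"))
    for (f in c("kinship", "degree_counts", "unrelated_subset",
                "paternity", "sire_counts", "maternal_check")) {
      ext <- if (f == "unrelated_subset") ".txt" else ".tsv"
      manifest <- addFile(f, file.path(outDir, paste0(f, ext)), manifest)
    }
  })

  if ("inbreeding" %in% cfg$stages) stage("inbreeding", {
    ho <- observedHet(G)
    params <- rohParams(minSnps = cfg$inbreeding$minSnps,
                        minLengthBp = cfg$inbreeding$minLengthKb * 1000,
                        maxMissing = cfg$inbreeding$maxMissingInRoh,
                        maxHet = cfg$inbreeding$maxHet)
    segs <- detectRoh(G, params)
    fr <- froh(segs, genomeLayout(G), sampleIds = colnames(G))
    div <- data.frame(sample_id = colnames(G),
                      ho = sprintf("%.6g", ho),
                      f_roh = sprintf("%.6g", fr[colnames(G)]))
    .writeTsv(div, file.path(outDir, "diversity.tsv"))
    .writeTsv(segs, file.path(outDir, "roh_segments.tsv"))
    tests <- list()
    if (!is.null(meta) && "origin" %in% colnames(meta)) {
      grp <- meta$origin[match(colnames(G), meta$sample_id)]
      ok <- grp %in% c("wild", "captive")
      if (length(unique(grp[ok])) == 2L) {
        wh <- compareGroups(ho[ok], grp[ok], "wilcoxon")
        wf <- compareGroups(fr[colnames(G)][ok], grp[ok], "wilcoxon")
        tests <- c(tests, list(
          data.frame(comparison = "ho_wild_vs_captive", test = "wilcoxon",
                     statistic = wh$statistic, p_value = wh$p_value),
          data.frame(comparison = "froh_wild_vs_captive",
                     test = "wilcoxon", statistic = wf$statistic,
                     p_value = wf$p_value)))
      }
    }
    if (!is.null(meta) && "birth_year" %in% colnames(meta)) {
      dec <- 10 * (meta$birth_year[match(colnames(G),
                                         meta$sample_id)] %/% 10)
      cnt <- table(dec)
      okd <- dec %in% as.numeric(names(cnt)[cnt >= 2]) & !is.na(dec)
      if (length(unique(dec[okd])) >= 2L) {
        av <- compareGroups(fr[colnames(G)][okd], dec[okd], "anova")
        tests <- c(tests, list(
          data.frame(comparison = "froh_by_decade", test = "anova",
                     statistic = av$statistic, p_value = av$p_value)))
      }
    }
    gt <- if (length(tests)) do.call(rbind, tests)
          else data.frame(comparison = character(), test = character(),
                          statistic = numeric(), p_value = numeric())
    gt$statistic <- sprintf("%.6g", gt$statistic)
    gt$p_value <- sprintf("%.6g", gt$p_value)
    .writeTsv(gt, file.path(outDir, "group_tests.tsv"))
    for (f in c("diversity", "roh_segments", "group_tests"))
      manifest <- addFile(f, file.path(outDir, paste0(f, ".tsv")),
                           manifest)
  })

  if ("hbd" %in% cfg$stages) stage("hbd", {
    Gh <- G
    if (!is.null(cfg$hbd$maxSamples) && ncol(G) > cfg$hbd$maxSamples)
      Gh <- G[, seq_len(cfg$hbd$maxSamples)]
    part <- hbdPartition(Gh, hbdModel(error = cfg$hbd$error),
                         fit = isTRUE(cfg$hbd$fit), tol = cfg$hbd$tol,
                         maxIter = cfg$hbd$maxIter)
    num <- setdiff(colnames(part), "sample_id")
    part[num] <- lapply(part[num], function(v) sprintf("%.6g", v))
    .writeTsv(part, file.path(outDir, "hbd_fractions.tsv"))
    manifest <- addFile("hbd_fractions",
                         file.path(outDir, "hbd_fractions.tsv"), manifest)
  })

  if ("rim" %in% cfg$stages) stage("rim", {
    ev <- evaluatePanels(G, mafThresholds = cfg$rim$mafThresholds,
                         maxMissing = cfg$rim$maxMissing,
                         r2Max = cfg$rim$r2, nIter = cfg$rim$nIter,
                         seed = .stageSeed(cfg$seed, "rim"),
                         referenceKin = kin)
    for (i in seq_len(nrow(ev))) {
      th <- ev$maf_threshold[i]
      panel <- selectRim(G, mafMin = th, maxMissing = cfg$rim$maxMissing,
                         r2Max = cfg$rim$r2)
      pf <- file.path(outDir, sprintf("rim_panel_%03d.txt",
                                      round(100 * th)))
      writeLines(panelMarkers(panel), pf)
      # sidecar: panel provenance (threshold, size, hash of the marker list)
      jsonlite::write_json(
        list(maf_threshold = th, size = panelSize(panel),
             params = panel@params,
             markers_md5 = unname(tools::md5sum(pf))),
        sub("\\.txt$", ".json", pf), auto_unbox = TRUE, digits = NA)
      manifest <- addFile(sprintf("rim_panel_%03d", round(100 * th)),
                           pf, manifest)
      manifest <- addFile(sprintf("rim_panel_%03d_meta", round(100 * th)),
                           sub("\\.txt$", ".json", pf), manifest)
    }
    evo <- ev
    for (cc in c("rim_correlation", "null_mean", "null_sd", "gap"))
      evo[[cc]] <- sprintf("%.6g", evo[[cc]])
    .writeTsv(evo, file.path(outDir, "rim_evaluation.tsv"))
    manifest <- addFile("rim_evaluation",
                         file.path(outDir, "rim_evaluation.tsv"), manifest)
  })

  jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       null = "null")
  if ("report" %in% cfg$stages)
    stage("report", makeReport(outDir))
  invisible(manifest)
}

#' Aggregate pipeline outputs into a summary report
#'
#' Re-reads the per-stage TSVs listed in a run's manifest and assembles a
#' human-readable summary (sample and marker counts, degree-class pair
#' counts, inferred paternity list size and most prolific sires, diversity
#' and inbreeding means, HBD class means, RIM panel table) as
#' `report.json` and a key--value `report.tsv`. Nothing is recomputed, so
#' regenerating the report from the same stage outputs is byte-identical.
#'
#' @param outDir a directory written by [runPipeline()].
#' @return the report list, invisibly.
#' @export
makeReport <- function(outDir) {
  mf <- file.path(outDir, "manifest.json")
  if (!file.exists(mf)) stop("no manifest.json in ", outDir)
  manifest <- jsonlite::read_json(mf)
  have <- function(f) file.exists(file.path(outDir, f))
  rd <- function(f) read.table(file.path(outDir, f), sep = "\t",
                               header = TRUE, stringsAsFactors = FALSE)
  rpt <- list(seed = manifest$seed, stages = unlist(manifest$stages))

  if (have("qc_summary.tsv")) {
    qc <- rd("qc_summary.tsv")
    rpt$markers <- qc$markers_out[1]
    rpt$samples <- qc$samples[1]
  }
  if (have("degree_counts.tsv")) {
    dc <- rd("degree_counts.tsv")
    rpt$degree_counts <- stats::setNames(as.list(dc$Freq), dc$degree)
  }
  if (have("paternity.tsv")) {
    pat <- rd("paternity.tsv")
    rpt$n_father_offspring_pairs <- nrow(pat)
  }
  if (have("sire_counts.tsv")) {
    sc <- rd("sire_counts.tsv")
    rpt$top_sires <- if (nrow(sc)) stats::setNames(
      as.list(utils::head(sc$n_offspring, 3)),
      utils::head(sc$sire_id, 3)) else list()
  }
  if (have("maternal_check.tsv")) {
    mat <- rd("maternal_check.tsv")
    rpt$n_maternal_links <- nrow(mat)
    rpt$n_maternal_discordant <- sum(mat$discordant %in% TRUE)
  }
  if (have("unrelated_subset.txt"))
    rpt$n_unrelated_subset <-
      length(readLines(file.path(outDir, "unrelated_subset.txt")))
  if (have("diversity.tsv")) {
    div <- rd("diversity.tsv")
    rpt$mean_ho <- signif(mean(as.numeric(div$ho)), 6)
    rpt$mean_f_roh <- signif(mean(as.numeric(div$f_roh)), 6)
  }
  if (have("roh_segments.tsv"))
    rpt$n_roh_segments <- nrow(rd("roh_segments.tsv"))
  if (have("group_tests.tsv")) {
    gt <- rd("group_tests.tsv")
    rpt$group_tests <- if (nrow(gt)) stats::setNames(
      as.list(as.numeric(gt$p_value)), gt$comparison) else list()
  }
  if (have("hbd_fractions.tsv")) {
    hb <- rd("hbd_fractions.tsv")
    num <- setdiff(colnames(hb), c("sample_id", "loglik"))
    rpt$hbd_mean_fractions <-
      stats::setNames(as.list(signif(colMeans(
        data.matrix(hb[num])), 6)), num)
  }
  if (have("rim_evaluation.tsv")) {
    ev <- rd("rim_evaluation.tsv")
    rpt$rim <- lapply(seq_len(nrow(ev)), function(i) as.list(ev[i, ]))
  }
  jsonlite::write_json(rpt, file.path(outDir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  flat <- unlist(rpt)
  write.table(data.frame(key = names(flat), value = as.character(flat)),
              file.path(outDir, "report.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(rpt)
}
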
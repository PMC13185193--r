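.pedIdCol <- function(pedigree) {
  if (is.null(pedigree)) return(NULL)
  nm <- if ("sample_id" %in% colnames(pedigree)) "sample_id"
        else if ("id" %in% colnames(pedigree)) "id"
        else stop("pedigree needs an 'id' or 'sample_id' column")
  nm
}

# All recorded ancestors of `id` (any path length) via dam/sire links.
.recordedAncestors <- function(id, dam, sire) {
  anc <- character()
  queue <- id
  while (length(queue)) {
    cur <- queue[[1L]]; queue <- queue[-1L]
    for (p in c(dam[cur], sire[cur])) {
      if (!is.na(p) && !(p %in% anc)) {
        anc <- c(anc, p)
        queue <- c(queue, p)
      }
    }
  }
  anc
}

.pedLinks <- function(pedigree) {
  idc <- .pedIdCol(pedigree)
  ids <- pedigree[[idc]]
  dam <- if ("dam_id" %in% colnames(pedigree))
    stats::setNames(as.character(pedigree$dam_id), ids)
  else stats::setNames(rep(NA_character_, length(ids)), ids)
  sire <- if ("sire_id" %in% colnames(pedigree))
    stats::setNames(as.character(pedigree$sire_id), ids)
  else stats::setNames(rep(NA_character_, length(ids)), ids)
  list(ids = ids, dam = dam, sire = sire)
}

#' Infer unrecorded father--offspring pairs
#'
#' Applies a threshold rule to the kinship table: a pair is called
#' father--offspring when (a) it is classified first degree, (b) the older
#' member is male, (c) the birth-year gap strictly exceeds `ageGap` years
#' (18 by default; gap exactly 18 fails), and (d) the pedigree records no
#' other relatedness between the two — no shared recorded dam and no
#' recorded ancestor--descendant path of any length. In a matrilineal
#' system this recovers the paternal links the log books cannot contain.
#' Pairs with missing sex or birth year are skipped and counted. Birth-year
#' gaps use whole years only; approximate birth years propagate an
#' `approx` flag onto emitted pairs.
#'
#' @param kin kinship table from [kinshipMatrix()].
#' @param meta metadata `data.frame` with `sample_id`, `sex`, `birth_year`
#'   (optionally `birth_year_approx`).
#' @param pedigree optional recorded pedigree (`id`/`sample_id`, `dam_id`,
#'   optionally `sire_id`) used for exclusion (d).
#' @param ageGap strict minimum birth-year gap (default 18).
#' @return list with `pairs` (`data.frame`: `sire_id`, `offspring_id`,
#'   `phi`, `r`, `age_gap`, `approx`), `sireCounts` (per-sire offspring
#'   counts, decreasing — the prolific-bull report), and `nSkipped`.
#' @export
inferPaternity <- function(kin, meta, pedigree = NULL, ageGap = 18) {
  sex <- stats::setNames(as.character(meta$sex), meta$sample_id)
  by <- stats::setNames(meta$birth_year, meta$sample_id)
  approx <- if ("birth_year_approx" %in% colnames(meta))
    stats::setNames(meta$birth_year_approx, meta$sample_id)
  else stats::setNames(rep(FALSE, nrow(meta)), meta$sample_id)

  links <- if (!is.null(pedigree)) .pedLinks(pedigree) else NULL

  first <- kin[kin$degree == "first", , drop = FALSE]
  out <- list()
  skipped <- 0L
  for (i in seq_len(nrow(first))) {
    a <- first$id_a[i]; b <- first$id_b[i]
    ya <- by[a]; yb <- by[b]
    if (is.na(ya) || is.na(yb) || is.na(sex[a]) || is.na(sex[b]) ||
        sex[a] == "unknown" || sex[b] == "unknown") {
      skipped <- skipped + 1L
      next
    }
    older <- if (ya < yb) a else b
    younger <- if (ya < yb) b else a
    gap <- abs(ya - yb)
    if (sex[older] != "male" || gap <= ageGap) next
    if (!is.null(links)) {
      # any recorded relatedness excludes the pair: same dam, an
      # ancestor-descendant path, or any shared recorded ancestor
      ancA <- c(a, .recordedAncestors(a, links$dam, links$sire))
      ancB <- c(b, .recordedAncestors(b, links$dam, links$sire))
      if (length(intersect(ancA, ancB))) next
    }
    out[[length(out) + 1L]] <- data.frame(
      sire_id = older, offspring_id = younger,
      phi = first$phi[i], r = first$r[i], age_gap = unname(gap),
      approx = unname(approx[a] | approx[b]), stringsAsFactors = FALSE)
  }
  pairs <- if (length(out)) do.call(rbind, out)
  else data.frame(sire_id = character(), offspring_id = character(),
                  phi = numeric(), r = numeric(), age_gap = numeric(),
                  approx = logical(), stringsAsFactors = FALSE)
  rownames(pairs) <- NULL
  cnt <- sort(table(pairs$sire_id), decreasing = TRUE)
  sireCounts <- data.frame(sire_id = names(cnt),
                           n_offspring = as.integer(cnt),
                           stringsAsFactors = FALSE)
  list(pairs = pairs, sireCounts = sireCounts, nSkipped = skipped)
}

#' Cross-check recorded maternal links against genomic kinship
#'
#' Annotates every recorded dam--offspring pair with its estimated kinship
#' and flags pairs whose degree classification is not first degree as
#' discordant (a recorded dam should be a parent, r near 0.5). Links whose
#' members are absent from the kinship table are reported with `NA`
#' kinship and left unflagged.
#'
#' @param kin kinship table from [kinshipMatrix()].
#' @param pedigree recorded pedigree (`id`/`sample_id` and `dam_id`).
#' @return `data.frame` with `offspring_id`, `dam_id`, `phi`, `r`,
#'   `degree`, `discordant`.
#' @export
verifyMaternalLinks <- function(kin, pedigree) {
  links <- .pedLinks(pedigree)
  has <- !is.na(links$dam)
  off <- links$ids[has]
  dam <- unname(links$dam[has])
  key <- function(a, b) paste(pmin(a, b), pmax(a, b))
  kk <- stats::setNames(seq_len(nrow(kin)), key(kin$id_a, kin$id_b))
  idx <- kk[key(off, dam)]
  phi <- kin$phi[idx]
  deg <- kin$degree[idx]
  data.frame(offspring_id = off, dam_id = dam, phi = phi, r = 2 * phi,
             degree = ifelse(is.na(idx), NA_character_, deg),
             discordant = !is.na(idx) & deg != "first",
             stringsAsFactors = FALSE, row.names = NULL)
}
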
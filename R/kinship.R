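#' KING-robust kinship for one sample pair
#'
#' Moment estimator of the kinship coefficient from genotype counts over
#' pairwise-complete markers, robust to population structure:
#' \deqn{\phi = \frac{N_{both\,het} - 2\,N_{opp\,hom}}{N_{het,a} + N_{het,b}}}
#' where the heterozygote counts are taken over markers non-missing in both
#' samples. Relatedness is `r = 2 * phi` (parent--offspring r of about 0.5).
#' When `n_het_a + n_het_b = 0` the estimate is undefined: `phi` is `NA`
#' and the degree is `"undefined"`.
#'
#' @param x a [GenotypeData-class] object.
#' @param a,b distinct sample identifiers (or column indices).
#' @return one-row `data.frame` with columns `id_a`, `id_b`, `n_shared`,
#'   `n_both_het`, `n_opp_hom`, `n_het_a`, `n_het_b`, `phi`, `r`, `degree`.
#' @seealso [kinshipMatrix()] for all pairs, [classifyDegree()].
#' @export
kingRobust <- function(x, a, b) {
  ids <- colnames(x)
  ia <- if (is.numeric(a)) a else match(a, ids)
  ib <- if (is.numeric(b)) b else match(b, ids)
  if (is.na(ia) || is.na(ib)) stop("unknown sample id")
  if (ia == ib) stop("'a' and 'b' must be distinct samples")
  d <- dosage(x)
  ga <- d[, ia]; gb <- d[, ib]
  ok <- !is.na(ga) & !is.na(gb)
  if (!any(ok)) stop("zero pairwise-complete markers for this pair")
  ga <- ga[ok]; gb <- gb[ok]
  nBH <- sum(ga == 1L & gb == 1L)
  nOH <- sum((ga == 0L & gb == 2L) | (ga == 2L & gb == 0L))
  nHa <- sum(ga == 1L); nHb <- sum(gb == 1L)
  den <- nHa + nHb
  phi <- if (den > 0L) (nBH - 2 * nOH) / den else NA_real_
  data.frame(id_a = ids[ia], id_b = ids[ib], n_shared = sum(ok),
             n_both_het = nBH, n_opp_hom = nOH, n_het_a = nHa,
             n_het_b = nHb, phi = phi, r = 2 * phi,
             degree = classifyDegree(2 * phi), stringsAsFactors = FALSE)
}

#' All-pairs KING-robust kinship table
#'
#' Computes the KING-robust statistics for every unordered sample pair via
#' matrix cross-products (fast for hundreds of samples and thousands of
#' markers). `phi` is exactly symmetric; pairs with an undefined estimate
#' (no heterozygotes in either member over shared markers, or no shared
#' markers) are kept with `phi = NA` and degree `"undefined"`.
#'
#' @param x a [GenotypeData-class] object with at least two samples.
#' @return `data.frame` with `n * (n - 1) / 2` rows and the columns of
#'   [kingRobust()].
#' @export
kinshipMatrix <- function(x) {
  if (ncol(x) < 2L) stop("need at least two samples")
  d <- dosage(x)
  st <- .kingStats(d)
  NN <- st$NN; BH <- st$BH; HN <- st$HN; OPP <- st$OPP
  DEN <- st$DEN; PHI <- st$PHI
  ut <- upper.tri(NN)
  ia <- row(NN)[ut]; ib <- col(NN)[ut]
  phi <- PHI[ut]
  phi[DEN[ut] == 0] <- NA_real_
  ids <- colnames(x)
  data.frame(id_a = ids[ia], id_b = ids[ib],
             n_shared = NN[ut], n_both_het = BH[ut], n_opp_hom = OPP[ut],
             n_het_a = HN[ut], n_het_b = t(HN)[ut],
             phi = phi, r = 2 * phi, degree = classifyDegree(2 * phi),
             stringsAsFactors = FALSE)
}

# Pairwise KING counting statistics via matrix cross-products.
.kingStats <- function(d) {
  N <- !is.na(d); storage.mode(N) <- "double"
  H <- !is.na(d) & d == 1L; storage.mode(H) <- "double"
  A0 <- !is.na(d) & d == 0L; storage.mode(A0) <- "double"
  A2 <- !is.na(d) & d == 2L; storage.mode(A2) <- "double"
  NN <- crossprod(N)
  BH <- crossprod(H)
  HN <- crossprod(H, N)   # HN[a, b] = het in a among markers typed in b
  OP <- crossprod(A0, A2) # OP[a, b] = a hom-ref & b hom-alt
  OPP <- OP + t(OP)
  DEN <- HN + t(HN)
  list(NN = NN, BH = BH, HN = HN, OPP = OPP, DEN = DEN,
       PHI = (BH - 2 * OPP) / DEN)
}

# Upper-triangle phi vector (NA where undefined), pair order fixed by
# column order: (1,2), (1,3), (2,3), ...
.kingPhiUT <- function(d) {
  st <- .kingStats(d)
  ut <- upper.tri(st$PHI)
  phi <- st$PHI[ut]
  phi[st$DEN[ut] == 0] <- NA_real_
  phi
}

#' Classify a relatedness value into degree bins
#'
#' Bins operate on the relatedness scale `r = 2 * phi` (the scale on which
#' parent--offspring pairs sit near 0.5): `r > 0.45` first degree
#' (parent--offspring, full sibs); `0.25 <= r <= 0.45` second degree
#' (half-sibs, avuncular, grandparental); `0.125 <= r < 0.25` third/fourth
#' degree (e.g. first cousins); below 0.125 unrelated. `NA` maps to
#' `"undefined"`. The bin labels follow the conventions of field usage for
#' these thresholds rather than strict genealogical-degree nomenclature.
#'
#' @param r numeric vector of relatedness values (`2 * phi`).
#' @return character vector over
#'   `c("first", "second", "third_fourth", "unrelated", "undefined")`.
#' @export
classifyDegree <- function(r) {
  out <- rep("undefined", length(r))
  out[!is.na(r) & r > 0.45] <- "first"
  out[!is.na(r) & r >= 0.25 & r <= 0.45] <- "second"
  out[!is.na(r) & r >= 0.125 & r < 0.25] <- "third_fourth"
  out[!is.na(r) & r < 0.125] <- "unrelated"
  out
}

#' Greedy selection of an unrelated sample subset
#'
#' Builds the graph of sample pairs with kinship `phi >= phiCutoff`
#' (default 0.08, which removes second-degree or closer relatives) and
#' iteratively deletes the vertex of highest degree until no edge remains,
#' so that one member of each kin pair is dropped. Degree ties are broken
#' towards the sample whose camp is currently most represented among
#' survivors (preserving camp representativeness); remaining ties remove
#' the lexicographically greatest identifier. The returned subset is
#' re-checked exhaustively against the kinship table before returning.
#'
#' @param kin kinship table from [kinshipMatrix()].
#' @param phiCutoff kinship threshold (phi scale).
#' @param meta optional metadata `data.frame` with `sample_id` and `camp`
#'   columns (used for tie-breaking and to retain unlisted samples).
#' @return character vector of retained sample identifiers.
#' @export
unrelatedSubset <- function(kin, phiCutoff = 0.08, meta = NULL) {
  verts <- sort(unique(c(kin$id_a, kin$id_b,
                         if (!is.null(meta)) meta$sample_id)))
  camp <- if (!is.null(meta) && "camp" %in% colnames(meta))
    stats::setNames(as.character(meta$camp), meta$sample_id)[verts]
  else stats::setNames(rep(NA_character_, length(verts)), verts)
  ed <- kin[!is.na(kin$phi) & kin$phi >= phiCutoff, c("id_a", "id_b")]
  alive <- stats::setNames(rep(TRUE, length(verts)), verts)
  repeat {
    act <- ed[alive[ed$id_a] & alive[ed$id_b], , drop = FALSE]
    if (!nrow(act)) break
    deg <- table(factor(c(act$id_a, act$id_b), levels = verts[alive]))
    cand <- names(deg)[deg == max(deg)]
    if (length(cand) > 1L && any(!is.na(camp[cand]))) {
      reps <- table(factor(camp[verts[alive]],
                           levels = unique(camp[!is.na(camp)])))
      score <- as.numeric(reps[camp[cand]])
      score[is.na(score)] <- -Inf
      cand <- cand[score == max(score)]
    }
    drop <- max(cand)  # lexicographically greatest
    alive[drop] <- FALSE
  }
  kept <- verts[alive]
  bad <- !is.na(kin$phi) & kin$phi >= phiCutoff &
    kin$id_a %in% kept & kin$id_b %in% kept
  stopifnot(!any(bad))  # postcondition: output is pair-free
  kept
}
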
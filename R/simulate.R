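#' Configuration for the pedigree-genotype simulator
#'
#' Bundles and validates every knob of the simulator. The defaults are the
#' package's desk-scale emulation of a semi-captive working-elephant
#' population: 261 genotyped samples (54 wild-captured founders, the rest
#' captive-born), 13,000 biallelic markers on 10 chromosomes of 300 Mb
#' (an elephant-scale ~3 Gb genome), founder alternate-allele frequencies
#' Uniform(0.05, 0.5), unsupervised mating in which sires are drawn with
#' reproductive skew from semi-captive and unsampled wild bulls, matrilineal
#' pedigree recording only, and mild RADseq-style genotyping noise.
#'
#' Breeding is scheduled on a calendar: captive birth years are drawn over
#' `birthYearRange`, dams uniformly among females of breeding age, sires
#' among males at least `minSireAge` years older than the offspring with
#' probability proportional to a per-male latent weight raised to
#' `sireSkew` (0 = uniform paternity; large values concentrate paternity on
#' one bull).
#'
#' @param nFounderFemales,nFounderMales numbers of wild-captured, genotyped
#'   founders.
#' @param nWildMales unsampled wild bulls available as sires (never
#'   genotyped; free parameter, as camp-level wild-male availability is
#'   unknown in such systems).
#' @param nSamples total genotyped individuals (founders + captive-born).
#' @param birthYearRange calendar range of captive births.
#' @param founderFemaleBirthRange,founderMaleBirthRange founder birth-year
#'   ranges (estimated years; founders carry the approximate flag).
#' @param femaleBreedingAge dam age window in years.
#' @param minSireAge minimum sire age at offspring birth (years).
#' @param sireSkew reproductive-skew exponent.
#' @param mateAvoidanceKinship close-kin mating avoidance: candidate sires
#'   whose pedigree kinship with the dam is at least this value are
#'   excluded (default 0.125, i.e. no matings between second-degree or
#'   closer relatives — emulating the behavioural inbreeding avoidance and
#'   kin recognition documented in elephants and other long-lived
#'   mammals). Set to `Inf` to disable.
#' @param nChromosomes,chromosomeLengthBp,nMarkers genome shape.
#' @param founderFreqRange founder alt-allele frequency range (uniform law).
#' @param cMperMb constant recombination rate (1 cM/Mb, the mammalian
#'   convention).
#' @param errorRate,missingRate per-call genotyping error and missingness
#'   injected by [degradeGenotypes()].
#' @param camps,campWeights camp labels and sampling weights.
#' @param seed optional seed recorded in the config (stages also accept
#'   seeds directly).
#' @return a validated `SimConfig` list.
#' @export
simConfig <- function(nFounderFemales = 30, nFounderMales = 24,
                      nWildMales = 6, nSamples = 261,
                      birthYearRange = c(1965, 2010),
                      founderFemaleBirthRange = c(1942, 1968),
                      founderMaleBirthRange = c(1930, 1955),
                      femaleBreedingAge = c(15, 50), minSireAge = 20,
                      sireSkew = 4, mateAvoidanceKinship = 0.125,
                      nChromosomes = 10, chromosomeLengthBp = 3e8,
                      nMarkers = 13000,
                      founderFreqRange = c(0.05, 0.5), cMperMb = 1,
                      errorRate = 0.005, missingRate = 0.03,
                      camps = c("Kawlin", "East Katha", "West Katha"),
                      campWeights = c(129, 51, 38), seed = NULL) {
  cfg <- list(nFounderFemales = as.integer(nFounderFemales),
              nFounderMales = as.integer(nFounderMales),
              nWildMales = as.integer(nWildMales),
              nSamples = as.integer(nSamples),
              birthYearRange = birthYearRange,
              founderFemaleBirthRange = founderFemaleBirthRange,
              founderMaleBirthRange = founderMaleBirthRange,
              femaleBreedingAge = femaleBreedingAge,
              minSireAge = minSireAge, sireSkew = sireSkew,
              mateAvoidanceKinship = mateAvoidanceKinship,
              nChromosomes = as.integer(nChromosomes),
              chromosomeLengthBp = chromosomeLengthBp,
              nMarkers = as.integer(nMarkers),
              founderFreqRange = founderFreqRange, cMperMb = cMperMb,
              errorRate = errorRate, missingRate = missingRate,
              camps = camps, campWeights = campWeights, seed = seed)
  counts <- c(cfg$nFounderFemales, cfg$nFounderMales, cfg$nWildMales,
              cfg$nSamples, cfg$nChromosomes, cfg$nMarkers)
  if (any(counts < 0)) stop("counts must be non-negative")
  if (cfg$nSamples < cfg$nFounderFemales + cfg$nFounderMales)
    stop("nSamples smaller than the number of genotyped founders")
  rates <- c(cfg$errorRate, cfg$missingRate)
  if (any(rates < 0) || any(rates > 1)) stop("rates must lie in [0, 1]")
  if (cfg$sireSkew < 0) stop("sireSkew must be non-negative")
  if (length(cfg$campWeights) != length(cfg$camps))
    stop("campWeights must match camps")
  class(cfg) <- "SimConfig"
  cfg
}

.founderIds <- function(cfg) {
  list(females = sprintf("F%03d", seq_len(cfg$nFounderFemales)),
       males   = sprintf("M%03d", seq_len(cfg$nFounderMales)),
       wild    = sprintf("W%03d", seq_len(cfg$nWildMales)))
}

#' Simulate the founder haplotype pool
#'
#' Draws a marker map (distinct, sorted positions per chromosome), founder
#' alternate-allele frequencies from the configured uniform law, and two
#' phased haplotypes per founder with alleles drawn independently at every
#' marker (Hardy--Weinberg proportions, linkage equilibrium). Linkage
#' disequilibrium then arises downstream purely from pedigree transmission.
#' Deterministic under `seed`.
#'
#' @param cfg a [simConfig()] object.
#' @param seed optional integer seed.
#' @return a `FounderPool` list: `map` (GRanges with `alt_freq`), `layout`
#'   (named chromosome lengths), `freqs`, and `haplos` (named list of
#'   markers x 2 0/1 matrices).
#' @export
simulateFounders <- function(cfg, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  nm <- cfg$nMarkers; nc <- cfg$nChromosomes
  len <- cfg$chromosomeLengthBp
  chroms <- as.character(seq_len(nc))
  cnt <- rep(nm %/% nc, nc)
  if (nc > 0 && nm %% nc) cnt[seq_len(nm %% nc)] <- cnt[seq_len(nm %% nc)] + 1L
  pos <- lapply(cnt, function(k) sort(sample.int(len, k)))
  map <- GRanges(rep(chroms, cnt),
                 IRanges(unlist(pos, use.names = FALSE), width = 1),
                 ref = rep("A", nm), alt = rep("C", nm))
  freqs <- runif(nm, cfg$founderFreqRange[1], cfg$founderFreqRange[2])
  mcols(map)$alt_freq <- freqs
  if (nm > 0) names(map) <- sprintf("snp%05d", seq_len(nm))
  layout <- stats::setNames(rep(len, nc), chroms)
  GenomeInfoDb::seqlevels(map) <- chroms
  GenomeInfoDb::seqlengths(map) <- layout

  ids <- unlist(.founderIds(cfg), use.names = FALSE)
  haplos <- lapply(ids, function(i)
    matrix(rbinom(2L * nm, 1L, rep(freqs, 2L)), nrow = nm, ncol = 2L))
  names(haplos) <- ids
  structure(list(map = map, layout = layout, freqs = freqs, haplos = haplos,
                 config = cfg),
            class = "FounderPool")
}

#' Simulate a pedigree with matrilineal-only recording
#'
#' Founders are wild-captured (no recorded parents, approximate birth
#' years). Each captive birth draws a dam uniformly from females currently
#' in the breeding-age window and a sire from all sufficiently old males
#' (semi-captive and wild) with probability proportional to
#' `weight^sireSkew`. The dam is recorded in the visible pedigree; the sire
#' is stored only in the hidden truth table, mirroring field conditions in
#' which matings are unobserved. The relation graph is acyclic by
#' construction (parents are always born before offspring).
#'
#' @param cfg a [simConfig()] object.
#' @param seed optional integer seed.
#' @return a `SimPedigree` list: `records` (all individuals, visible fields
#'   plus a `genotyped` flag) and `truth` (`id`, `sire_id`).
#' @export
simulatePedigree <- function(cfg, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  ids <- .founderIds(cfg)
  if (cfg$nFounderFemales < 1L) stop("empty female pool")
  if (cfg$nFounderMales + cfg$nWildMales < 1L) stop("empty male pool")

  ry <- function(range, n) sample(seq(range[1], range[2]), n, replace = TRUE)
  n0 <- cfg$nFounderFemales + cfg$nFounderMales + cfg$nWildMales
  camp0 <- sample(cfg$camps, n0, replace = TRUE,
                  prob = cfg$campWeights / sum(cfg$campWeights))
  rec <- data.frame(
    id = c(ids$females, ids$males, ids$wild),
    sex = c(rep("female", cfg$nFounderFemales),
            rep("male", cfg$nFounderMales + cfg$nWildMales)),
    birth_year = c(ry(cfg$founderFemaleBirthRange, cfg$nFounderFemales),
                   ry(cfg$founderMaleBirthRange,
                      cfg$nFounderMales + cfg$nWildMales)),
    birth_year_approx = TRUE,
    origin = "wild", camp = camp0, dam_id = NA_character_,
    sire_id = NA_character_,
    genotyped = c(rep(TRUE, cfg$nFounderFemales + cfg$nFounderMales),
                  rep(FALSE, cfg$nWildMales)),
    stringsAsFactors = FALSE)
  weight <- stats::setNames(rep(NA_real_, nrow(rec)), rec$id)
  weight[rec$sex == "male"] <- runif(sum(rec$sex == "male"), 0.5, 1.5)

  # incrementally maintained pedigree kinship matrix (founders unrelated)
  nBirths <- cfg$nSamples - cfg$nFounderFemales - cfg$nFounderMales
  nTot <- n0 + nBirths
  Kin <- matrix(0, nTot, nTot)
  diag(Kin)[seq_len(n0)] <- 0.5
  kinIdx <- stats::setNames(seq_len(n0), rec$id)

  # preallocated record vectors (the loop is hot in replicate studies)
  vid <- c(rec$id, rep(NA_character_, nBirths))
  vsex <- c(rec$sex, rep(NA_character_, nBirths))
  vyear <- c(rec$birth_year, rep(NA_integer_, nBirths))
  vcamp <- c(rec$camp, rep(NA_character_, nBirths))
  vdam <- c(rec$dam_id, rep(NA_character_, nBirths))
  vsire <- c(rec$sire_id, rep(NA_character_, nBirths))
  vgeno <- c(rec$genotyped, rep(TRUE, nBirths))
  vappr <- c(rec$birth_year_approx, rep(FALSE, nBirths))
  weight <- c(weight, stats::setNames(rep(NA_real_, nBirths),
                                      sprintf("C%03d", seq_len(nBirths))))

  years <- sort(ry(cfg$birthYearRange, nBirths))
  for (b in seq_len(nBirths)) {
    y <- years[b]
    k <- n0 + b
    cur <- seq_len(k - 1L)
    repeat {
      age <- y - vyear[cur]
      dams <- vid[cur][vsex[cur] == "female" &
                       age >= cfg$femaleBreedingAge[1] &
                       age <= cfg$femaleBreedingAge[2]]
      sires <- vid[cur][vsex[cur] == "male" & age >= cfg$minSireAge]
      if (length(dams) && length(sires)) break
      y <- y + 1L
    }
    dam <- dams[sample.int(length(dams), 1L)]
    # behavioural close-kin mating avoidance (kin-recognition emulation)
    okSires <- sires[Kin[kinIdx[dam], kinIdx[sires]] <
                       cfg$mateAvoidanceKinship]
    if (length(okSires)) sires <- okSires
    w <- weight[sires]^cfg$sireSkew
    sire <- sires[sample.int(length(sires), 1L, prob = w / sum(w))]
    sex <- if (runif(1) < 0.5) "female" else "male"
    id <- sprintf("C%03d", b)
    vid[k] <- id; vsex[k] <- sex; vyear[k] <- y
    vcamp[k] <- vcamp[kinIdx[dam]]; vdam[k] <- dam; vsire[k] <- sire
    if (sex == "male") weight[id] <- runif(1, 0.5, 1.5)
    kinIdx[id] <- k
    Kin[k, cur] <- 0.5 * (Kin[kinIdx[dam], cur] + Kin[kinIdx[sire], cur])
    Kin[cur, k] <- Kin[k, cur]
    Kin[k, k] <- 0.5 * (1 + Kin[kinIdx[dam], kinIdx[sire]])
  }
  rec <- data.frame(id = vid, sex = vsex, birth_year = vyear,
                    birth_year_approx = vappr, origin = c(
                      rec$origin, rep("captive", nBirths)),
                    camp = vcamp, dam_id = vdam, sire_id = vsire,
                    genotyped = vgeno, stringsAsFactors = FALSE)
  rec <- rec[order(rec$birth_year), , drop = FALSE]
  rownames(rec) <- NULL
  visible <- rec[, c("id", "sex", "birth_year", "birth_year_approx",
                     "origin", "camp", "dam_id", "genotyped")]
  structure(list(records = visible,
                 truth = data.frame(id = rec$id, sire_id = rec$sire_id,
                                    stringsAsFactors = FALSE)),
            class = "SimPedigree")
}

#' Transmit founder haplotypes through a pedigree
#'
#' Forms each gamete by drawing a Poisson number of crossovers (mean = map
#' length in Morgans, at `cMperMb`), placing them uniformly along the
#' chromosome, and alternating parental haplotypes from a random start.
#' Offspring dosage is the sum of the two transmitted alleles. Only
#' genotyped individuals appear in the returned matrix; sample metadata
#' (sex, birth year + approximate flag, origin, camp, recorded dam) is
#' attached as `colData`. Deterministic under `seed`.
#'
#' @param pedigree a `SimPedigree` from [simulatePedigree()].
#' @param founders a `FounderPool` from [simulateFounders()].
#' @param cMperMb recombination rate (default 1 cM/Mb).
#' @param seed optional integer seed.
#' @return a [GenotypeData-class] object of error-free genotypes.
#' @export
transmitGenotypes <- function(pedigree, founders, cMperMb = 1, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  rec <- pedigree$records
  sire <- stats::setNames(pedigree$truth$sire_id, pedigree$truth$id)
  map <- founders$map
  pos <- start(map)
  ch <- as.character(seqnames(map))
  chroms <- unique(ch)
  idxList <- split(seq_along(pos), factor(ch, chroms))
  posList <- split(pos, factor(ch, chroms))
  lenList <- founders$layout[chroms]
  mpb <- cMperMb * 1e-8  # Morgans per bp

  haplos <- new.env(parent = emptyenv())
  for (r in seq_len(nrow(rec))) {
    id <- rec$id[r]
    dam <- rec$dam_id[r]; s <- unname(sire[id])
    if (is.na(dam) && is.na(s)) {
      h <- founders$haplos[[id]]
      if (is.null(h))
        stop("pedigree references absent founder: ", id)
      assign(id, h, envir = haplos)
    } else {
      if (is.na(dam) || is.na(s) || !exists(dam, envir = haplos) ||
          !exists(s, envir = haplos))
        stop("pedigree references absent parent for: ", id)
      h <- cbind(.gamete(get(dam, envir = haplos), idxList, posList,
                         lenList, mpb),
                 .gamete(get(s, envir = haplos), idxList, posList,
                         lenList, mpb))
      assign(id, h, envir = haplos)
    }
  }
  gid <- rec$id[rec$genotyped]
  d <- vapply(gid, function(i) {
    h <- get(i, envir = haplos)
    as.integer(h[, 1L] + h[, 2L])
  }, integer(length(pos)))
  if (is.null(dim(d))) d <- matrix(d, ncol = length(gid),
                                   dimnames = list(NULL, gid))
  rownames(d) <- names(map)
  meta <- rec[rec$genotyped, c("sex", "birth_year", "birth_year_approx",
                               "origin", "camp", "dam_id")]
  rownames(meta) <- gid
  GenotypeData(d, map, sampleMeta = meta, seqlengths = founders$layout)
}

.gamete <- function(h, idxList, posList, lenList, morgansPerBp) {
  out <- integer(nrow(h))
  for (c2 in seq_along(idxList)) {
    ids <- idxList[[c2]]
    if (!length(ids)) next
    p <- posList[[c2]]
    Lbp <- lenList[[c2]]
    k <- rpois(1L, Lbp * morgansPerBp)
    cur <- sample.int(2L, 1L)
    if (k == 0L) {
      seg <- rep.int(cur, length(ids))
    } else {
      xo <- sort(runif(k, 0, Lbp))
      seg <- (cur - 1L + findInterval(p, xo)) %% 2L + 1L
    }
    out[ids] <- h[cbind(ids, seg)]
  }
  out
}

#' Inject genotyping error and missingness
#'
#' Independently per call: with probability `missingRate` the call becomes
#' missing; otherwise, with probability `errorRate`, it is replaced by one
#' of the two other dosage codes uniformly (a symmetric mis-call model
#' whose severity is directly controllable). Already-missing calls stay
#' missing. Deterministic under `seed`.
#'
#' @param x a [GenotypeData-class] object.
#' @param errorRate per-call mis-call probability in \[0, 1\].
#' @param missingRate per-call dropout probability in \[0, 1\].
#' @param seed optional integer seed.
#' @return the degraded [GenotypeData-class] object.
#' @export
degradeGenotypes <- function(x, errorRate, missingRate, seed = NULL) {
  if (errorRate < 0 || errorRate > 1 || missingRate < 0 || missingRate > 1)
    stop("rates must lie in [0, 1]")
  if (!is.null(seed)) set.seed(seed)
  d <- dosage(x)
  n <- length(d)
  if (n == 0L || (errorRate == 0 && missingRate == 0)) return(x)
  drop <- runif(n) < missingRate
  err <- !drop & !is.na(d) & runif(n) < errorRate
  shift <- 1L + (runif(n) < 0.5)
  d[err] <- (d[err] + shift[err]) %% 3L
  d[drop] <- NA_integer_
  out <- x
  assay(out, "dosage") <- d
  out
}

#' Simulate a full study dataset
#'
#' Chains [simulateFounders()], [simulatePedigree()], [transmitGenotypes()]
#' and [degradeGenotypes()] into one reproducible draw of the configured
#' study design. The visible metadata never contains sire identities; the
#' hidden truth table does.
#'
#' @param cfg a [simConfig()] object.
#' @param seed optional integer seed controlling the whole draw.
#' @return list with elements `genotypes` (degraded [GenotypeData-class]),
#'   `cleanGenotypes` (pre-degradation), `pedigree` (visible records of
#'   genotyped individuals), `truth` (`id`, `sire_id`), `founderFreqs`,
#'   `config`, `seed`.
#' @export
simulateStudy <- function(cfg = simConfig(), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  founders <- simulateFounders(cfg)
  ped <- simulatePedigree(cfg)
  clean <- transmitGenotypes(ped, founders, cMperMb = cfg$cMperMb)
  noisy <- degradeGenotypes(clean, cfg$errorRate, cfg$missingRate)
  vis <- ped$records[ped$records$genotyped, , drop = FALSE]
  vis$genotyped <- NULL
  names(vis)[names(vis) == "id"] <- "sample_id"
  rownames(vis) <- NULL
  list(genotypes = noisy, cleanGenotypes = clean, pedigree = vis,
       truth = ped$truth, founderFreqs = founders$freqs, config = cfg,
       seed = seed)
}

#' Simulate a genotype sequence from an HBD model
#'
#' Generative twin of the hidden Markov model used by [forwardBackward()]:
#' the initial state is drawn from the mixing vector; between adjacent
#' markers at genetic distance `d` the chain leaves its state with
#' probability `1 - exp(-R_state * d)` and re-enters class `j` with
#' probability `mixing[j]` (possibly the same class). Genotypes are emitted
#' from each state's emission law. Deterministic under `seed`.
#'
#' @param model an [HbdModel-class] object.
#' @param freqs per-marker alternate-allele frequencies.
#' @param positionsBp per-marker positions in bp (single chromosome,
#'   increasing).
#' @param seed optional integer seed.
#' @return list with `states` (integer path; the last class is non-HBD) and
#'   `genotypes` (dosage vector).
#' @export
simulateHbdSequence <- function(model, freqs, positionsBp, seed = NULL) {
  validObject(model)
  if (!is.null(seed)) set.seed(seed)
  n <- length(freqs)
  stopifnot(length(positionsBp) == n)
  K <- length(model@rates)
  M <- model@mixing
  d <- diff(positionsBp) * model@cMperMb * 1e-8
  s <- integer(n)
  s[1L] <- sample.int(K, 1L, prob = M)
  if (n > 1L) {
    pLeave <- 1 - exp(-outer(d, model@rates))  # (n-1) x K
    u <- runif(n - 1L)
    for (t in 2L:n) {
      s[t] <- if (u[t - 1L] < pLeave[t - 1L, s[t - 1L]])
        sample.int(K, 1L, prob = M) else s[t - 1L]
    }
  }
  q <- freqs; p <- 1 - q
  g <- integer(n)
  nonhbd <- s == K
  g[nonhbd] <- rbinom(sum(nonhbd), 2L, q[nonhbd])
  hbd <- which(!nonhbd)
  if (length(hbd)) {
    isErr <- runif(length(hbd)) < model@error
    auto <- hbd[!isErr]
    g[auto] <- 2L * rbinom(length(auto), 1L, q[auto])
    mis <- hbd[isErr]
    g[mis] <- rbinom(length(mis), 2L, q[mis])
  }
  list(states = s, genotypes = g)
}
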
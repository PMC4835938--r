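## Gene-drop simulator: a pedigreed population segregating a recessive
## lethal deletion, plus the four observation layers (genotype calls, array
## intensity, sequencing depth, calving records + DRPs).

#' Simulate a pedigreed population carrying a recessive lethal deletion
#'
#' Performs a Mendelian gene drop down a half-sib pedigree. Founders draw
#' each chromosome as "deleted" with probability \code{causativeFreq};
#' gametes recombine under a Haldane map at \code{recombRate} cM/Mb. A
#' 10-SNP tag window (5 markers on each side of the deletion) is placed in
#' complete founder linkage disequilibrium with the deletion: deleted
#' founder chromosomes carry the alt allele at all tag markers, intact
#' founder chromosomes the ref allele, so LD decays only by recombination.
#' Homozygous-deletion conceptuses are recorded stillborn with probability
#' \code{penetrance}; all other calves are stillborn according to a liability
#' threshold model with heritability \code{drpH2} and baseline rate
#' \code{baselineStillbirth}. Dead conceptuses stay in the population record
#' (they enter calving tables) but are never genotyped.
#'
#' @param config A [SimulationConfig-class].
#' @return A [Population-class] with full ground truth.
#' @examples
#' pop <- simulatePopulation(SimulationConfig(nFounders = 60,
#'   nGenerations = 2, nSiresPerGen = 6, progenyPerSire = 10,
#'   nMarkers = 60, seed = 7))
#' pop
#' @export
simulatePopulation <- function(config) {
  validObject(config)
  set.seed(.stageSeed(config@seed, 1L))
  nF <- as.integer(config@nFounders)
  nG <- as.integer(config@nGenerations)
  nS <- as.integer(config@nSiresPerGen)
  nP <- as.integer(config@progenyPerSire)
  M <- as.integer(config@nMarkers)
  N <- nF + nG * nS * nP

  ## evenly spaced marker map with random ref/alt bases
  spacing <- config@chromLengthBp / M
  pos <- round(spacing / 2 + spacing * (seq_len(M) - 1))
  bases <- c("A", "C", "G", "T")
  ref <- sample(bases, M, replace = TRUE)
  alt <- vapply(ref, function(b) sample(setdiff(bases, b), 1L), "")
  markers <- data.frame(id = sprintf("snp%04d", seq_len(M)), chrom = "23",
                        pos = pos, ref = ref, alt = unname(alt),
                        stringsAsFactors = FALSE)

  inDel <- .markersInRegion(markers, config@deletionStartBp,
                            config@deletionEndBp)
  up <- which(markers$pos < config@deletionStartBp)
  down <- which(markers$pos > config@deletionEndBp)
  if (length(up) < 5L || length(down) < 5L)
    stop("marker map leaves fewer than 5 markers on a flank of the ",
         "deletion; increase 'nMarkers' or move the deletion")
  tagMarkers <- c(utils::tail(up, 5L), utils::head(down, 5L))
  tagAllele <- paste0(markers$alt[tagMarkers], collapse = "")

  ## founders
  foundFreq <- stats::runif(M, 0.1, 0.9)
  hap1 <- matrix(0L, M, N)
  hap2 <- matrix(0L, M, N)
  fcols <- seq_len(nF)
  hap1[, fcols] <- stats::rbinom(M * nF, 1L, foundFreq)
  hap2[, fcols] <- stats::rbinom(M * nF, 1L, foundFreq)
  del1 <- logical(N)
  del2 <- logical(N)
  del1[fcols] <- stats::runif(nF) < config@causativeFreq
  del2[fcols] <- stats::runif(nF) < config@causativeFreq
  ## founders are live breeding adults, so their genotypes come from the
  ## post-selection distribution: a homozygous-deletion founder survives
  ## only with probability 1 - penetrance (rejection sampling)
  if (config@penetrance > 0 && config@causativeFreq > 0) {
    for (i in fcols) {
      while (del1[i] && del2[i] &&
             stats::runif(1) < config@penetrance) {
        del1[i] <- stats::runif(1) < config@causativeFreq
        del2[i] <- stats::runif(1) < config@causativeFreq
      }
    }
  }
  hap1[tagMarkers, fcols] <- 0L
  hap2[tagMarkers, fcols] <- 0L
  hap1[tagMarkers, fcols[del1[fcols]]] <- 1L
  hap2[tagMarkers, fcols[del2[fcols]]] <- 1L

  sex <- character(N)
  sex[fcols] <- sample(rep(c("M", "F"), length.out = nF))
  generation <- integer(N)
  sire <- rep(NA_integer_, N)
  dam <- rep(NA_integer_, N)
  bv <- numeric(N)
  bv[fcols] <- stats::rnorm(nF)
  alive <- rep(TRUE, N)

  morgans <- config@chromLengthBp / 1e6 * config@recombRate / 100
  delMid <- (config@deletionStartBp + config@deletionEndBp) / 2
  thrBase <- stats::qnorm(1 - config@baselineStillbirth)
  h2 <- config@drpH2

  nxt <- nF + 1L
  for (g in seq_len(nG)) {
    sireCand <- which(sex == "M" & alive & generation == g - 1L)
    if (length(sireCand) < nS)
      stop(sprintf(
        "generation %d has only %d live males for 'nSiresPerGen' = %d",
        g - 1L, length(sireCand), nS))
    sires <- sireCand[sample.int(length(sireCand), nS)]
    damPool <- which(sex == "F" & alive & generation < g)
    if (length(damPool) < 1L)
      stop("no live females available as dams for generation ", g)
    nCalf <- nS * nP
    calfSire <- rep(sires, each = nP)
    calfDam <- damPool[sample.int(length(damPool), nCalf, replace = TRUE)]
    idx <- nxt:(nxt + nCalf - 1L)

    gp <- .gametes(hap1, hap2, del1, del2, calfSire, pos, morgans, delMid,
                   config@deletionStartBp, config@deletionEndBp)
    gm <- .gametes(hap1, hap2, del1, del2, calfDam, pos, morgans, delMid,
                   config@deletionStartBp, config@deletionEndBp)
    hap1[, idx] <- gp$alleles
    hap2[, idx] <- gm$alleles
    del1[idx] <- gp$del
    del2[idx] <- gm$del

    sire[idx] <- calfSire
    dam[idx] <- calfDam
    generation[idx] <- g
    sex[idx] <- sample(c("M", "F"), nCalf, replace = TRUE)
    bv[idx] <- 0.5 * (bv[calfSire] + bv[calfDam]) +
      stats::rnorm(nCalf, 0, sqrt(0.5))
    copies <- as.integer(del1[idx]) + as.integer(del2[idx])
    hom <- copies == 2L
    liab <- sqrt(h2) * bv[idx] + stats::rnorm(nCalf, 0, sqrt(1 - h2))
    dead <- ifelse(hom, stats::runif(nCalf) < config@penetrance,
                   liab > thrBase)
    alive[idx] <- !dead
    nxt <- nxt + nCalf
  }

  ids <- sprintf("I%06d", seq_len(N))
  individuals <- data.frame(
    id = ids,
    sire = ifelse(is.na(sire), NA_character_, ids[pmax(sire, 1L)]),
    dam = ifelse(is.na(dam), NA_character_, ids[pmax(dam, 1L)]),
    sex = sex, generation = generation,
    deletionCopies = as.integer(del1) + as.integer(del2),
    aliveAtBirth = alive, bv = bv, stringsAsFactors = FALSE)
  colnames(hap1) <- colnames(hap2) <- ids
  rownames(hap1) <- rownames(hap2) <- markers$id

  new("Population", individuals = individuals, markers = markers,
      hap1 = hap1, hap2 = hap2, del1 = del1, del2 = del2,
      tagMarkers = as.integer(tagMarkers), tagAllele = tagAllele,
      config = config)
}

## One gamete per entry of parentIdx. Haldane model: crossover count is
## Poisson(morgans), breakpoints uniform on the chromosome, starting
## chromatid random. Deletion transmission follows the chromatid covering
## the deletion midpoint. In a parent carrying the deletion the region is
## unpaired at meiosis, so crossover points falling inside it are
## suppressed for that parent's gametes.
.gametes <- function(hap1, hap2, del1, del2, parentIdx, pos, morgans,
                     delMid, delStart, delEnd) {
  n <- length(parentIdx)
  M <- nrow(hap1)
  k <- stats::rpois(n, morgans)
  startHap <- sample(c(1L, 2L), n, replace = TRUE)
  alleles <- matrix(0L, M, n)
  del <- logical(n)
  chromLen <- max(pos)

  plain <- which(k == 0L)
  if (length(plain)) {
    p1 <- plain[startHap[plain] == 1L]
    p2 <- plain[startHap[plain] == 2L]
    if (length(p1)) {
      alleles[, p1] <- hap1[, parentIdx[p1], drop = FALSE]
      del[p1] <- del1[parentIdx[p1]]
    }
    if (length(p2)) {
      alleles[, p2] <- hap2[, parentIdx[p2], drop = FALSE]
      del[p2] <- del2[parentIdx[p2]]
    }
  }
  for (i in which(k > 0L)) {
    p <- parentIdx[i]
    xo <- sort(stats::runif(k[i], 0, chromLen))
    if (del1[p] || del2[p])
      xo <- xo[xo < delStart | xo > delEnd]
    if (!length(xo)) {
      if (startHap[i] == 1L) {
        alleles[, i] <- hap1[, p]
        del[i] <- del1[p]
      } else {
        alleles[, i] <- hap2[, p]
        del[i] <- del2[p]
      }
      next
    }
    src <- 1L + (startHap[i] - 1L + findInterval(pos, xo)) %% 2L
    alleles[, i] <- ifelse(src == 1L, hap1[, p], hap2[, p])
    sMid <- 1L + (startHap[i] - 1L + findInterval(delMid, xo)) %% 2L
    del[i] <- if (sMid == 1L) del1[p] else del2[p]
  }
  list(alleles = alleles, del = del)
}

#' Call genotypes for the live population
#'
#' Produces the called allele-dosage matrix the downstream association and
#' haplotype stages consume. Only live animals are genotyped. Outside the
#' deletion the call equals the true dosage subject to a per-call error
#' rate: with probability \code{genotypeError} a homozygous call is
#' perturbed to heterozygous and a heterozygous call to a random homozygote
#' (so a true homozygote is called homozygous with probability exactly
#' \code{1 - genotypeError}). Inside the deletion a single-copy carrier is
#' hemizygous and is called homozygous for its one present allele; a live
#' two-copy animal (possible only at penetrance < 1) has no allele present
#' and is reported missing. Phased haplotype assays reflect the hemizygote
#' masking but not the sporadic dosage error (phase is taken as imputed
#' correctly).
#'
#' @param pop A [Population-class].
#' @return A phased [GenotypeData-class] over live animals.
#' @export
callGenotypes <- function(pop) {
  config <- pop@config
  set.seed(.stageSeed(config@seed, 2L))
  live <- which(pop@individuals$aliveAtBirth)
  ids <- pop@individuals$id[live]
  h1 <- pop@hap1[, live, drop = FALSE]
  h2 <- pop@hap2[, live, drop = FALSE]
  d1 <- pop@del1[live]
  d2 <- pop@del2[live]
  inDel <- .markersInRegion(pop@markers, config@deletionStartBp,
                            config@deletionEndBp)

  ## hemizygote masking: inside the deletion only the intact chromosome's
  ## allele is seen, and it is called homozygous
  if (length(inDel)) {
    c1 <- which(d1 & !d2)   # chromosome 1 deleted -> copy allele from hap2
    c2 <- which(d2 & !d1)
    if (length(c1)) h1[inDel, c1] <- h2[inDel, c1]
    if (length(c2)) h2[inDel, c2] <- h1[inDel, c2]
  }
  dosage <- h1 + h2
  if (length(inDel)) {
    hom2 <- which(d1 & d2)
    if (length(hom2)) dosage[inDel, hom2] <- NA_integer_
  }

  e <- config@genotypeError
  if (e > 0) {
    nCell <- length(dosage)
    hit <- which(stats::runif(nCell) < e & !is.na(dosage))
    if (length(hit)) {
      d <- dosage[hit]
      repl <- ifelse(d == 1L, sample(c(0L, 2L), length(hit), replace = TRUE),
                     1L)
      dosage[hit] <- repl
    }
  }
  colnames(dosage) <- ids
  g <- GenotypeData(pop@markers, dosage, hap1 = h1, hap2 = h2)
  colnames(g) <- ids
  g
}

#' Simulate SNP-array Log2R intensities
#'
#' Noncarriers draw Log2R ~ Normal(0, \code{intensitySd}) at every marker.
#' Single-copy deletion carriers draw Normal(\code{intensityMeanCarrier},
#' \code{intensitySd}) at in-deletion markers; live two-copy animals draw a
#' doubled mean shift there (both alleles absent).
#'
#' @param pop A [Population-class].
#' @return Numeric matrix (markers x live samples) of Log2R ratios.
#' @export
simulateIntensity <- function(pop) {
  config <- pop@config
  set.seed(.stageSeed(config@seed, 3L))
  live <- which(pop@individuals$aliveAtBirth)
  ids <- pop@individuals$id[live]
  M <- nrow(pop@markers)
  x <- matrix(stats::rnorm(M * length(live), 0, config@intensitySd),
              M, length(live), dimnames = list(pop@markers$id, ids))
  inDel <- .markersInRegion(pop@markers, config@deletionStartBp,
                            config@deletionEndBp)
  copies <- pop@individuals$deletionCopies[live]
  if (length(inDel)) {
    x[inDel, copies == 1L] <- x[inDel, copies == 1L] +
      config@intensityMeanCarrier
    x[inDel, copies == 2L] <- x[inDel, copies == 2L] +
      2 * config@intensityMeanCarrier
  }
  x
}

#' Simulate windowed sequencing depth
#'
#' Per-window read-base counts are Poisson with rate
#' \code{meanDepth * windowBp}, reduced in proportion to the deleted
#' fraction of the window: a single-copy carrier loses half the rate over
#' the deleted part, a two-copy animal all of it.
#'
#' @param pop A [Population-class].
#' @param samples Character ids of the sequenced animals; defaults to a
#'   seeded draw of up to 100 live animals.
#' @param windowBp Window length in bp (default 10 kb).
#' @return data.frame with columns sample, window_start, window_end, reads.
#' @export
simulateDepth <- function(pop, samples = NULL, windowBp = 1e4) {
  config <- pop@config
  set.seed(.stageSeed(config@seed, 4L))
  ind <- pop@individuals
  liveIds <- ind$id[ind$aliveAtBirth]
  if (is.null(samples))
    samples <- sort(liveIds[sample.int(length(liveIds),
                                       min(100L, length(liveIds)))])
  if (!all(samples %in% liveIds))
    stop("samples must be live animals")
  starts <- seq(1, config@chromLengthBp, by = windowBp)
  ends <- pmin(starts + windowBp - 1, config@chromLengthBp)
  wlen <- ends - starts + 1
  ## deleted overlap fraction of each window
  ovl <- pmax(0, pmin(ends, config@deletionEndBp) -
                 pmax(starts, config@deletionStartBp) + 1) / wlen
  copies <- ind$deletionCopies[match(samples, ind$id)]
  out <- vector("list", length(samples))
  for (i in seq_along(samples)) {
    rate <- config@meanDepth * wlen * (1 - 0.5 * copies[i] * ovl)
    out[[i]] <- data.frame(sample = samples[i], window_start = starts,
                           window_end = ends,
                           reads = stats::rpois(length(starts), rate),
                           stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

#' Simulate calving records and de-regressed proofs
#'
#' The calving table holds one row per conceived calf of generation >= 1
#' (recorded stillbirths included): calf, sire, dam, maternal grandsire,
#' parity (the dam's calving number), insemination month-year and the
#' outcome coded as in routine recording (\code{alive} = 1 for a calf alive
#' 24 h after birth, 0 for a stillbirth).
#'
#' The DRP table gives every live bull with a recorded sire a de-regressed
#' proof on the additive-genetic-SD scale: true transmitting ability
#' (polygenic breeding value plus a deletion term \eqn{-\delta} for
#' carriers, with \eqn{\delta = 0.5 \, P(\text{mate carrier}) \,
#' \text{penetrance} / \sqrt{h^2}}) plus noise with variance
#' \eqn{(1-r^2)/r^2}; the reliability \eqn{r^2} is drawn per bull and is
#' capped at 0.98 when converted to weights downstream.
#'
#' @param pop A [Population-class].
#' @return list with elements \code{calving} and \code{drp} (data.frames).
#' @export
simulateRecordsAndDrp <- function(pop) {
  config <- pop@config
  set.seed(.stageSeed(config@seed, 5L))
  ind <- pop@individuals
  calves <- ind[ind$generation >= 1L, , drop = FALSE]
  mgs <- ind$sire[match(calves$dam, ind$id)]
  ## rows are in birth order, so the dam's running calf count is her parity
  parity <- stats::ave(rep(1, nrow(calves)), calves$dam, FUN = cumsum)
  year <- 2000L + calves$generation
  month <- sample.int(12L, nrow(calves), replace = TRUE)
  calving <- data.frame(
    calf = calves$id, sire = calves$sire, dam = calves$dam, mgs = mgs,
    parity = as.integer(parity),
    insem_ym = sprintf("%04d-%02d", year, month),
    alive = as.integer(calves$aliveAtBirth), stringsAsFactors = FALSE)

  bulls <- ind[ind$aliveAtBirth & ind$sex == "M" & !is.na(ind$sire), ,
               drop = FALSE]
  p <- config@causativeFreq
  mateCarrier <- if (p > 0) 2 * p / (1 + p) else 0
  delta <- 0.5 * mateCarrier * config@penetrance / sqrt(max(config@drpH2,
                                                            1e-8))
  r2 <- stats::runif(nrow(bulls), 0.35, 0.995)
  noise <- stats::rnorm(nrow(bulls), 0, sqrt((1 - r2) / r2))
  drpVal <- bulls$bv - delta * (bulls$deletionCopies >= 1L) + noise
  drp <- data.frame(id = bulls$id, trait = "SB", drp = drpVal,
                    reliability = r2, stringsAsFactors = FALSE)
  list(calving = calving, drp = drp)
}
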
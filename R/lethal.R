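## Haplotype-window missing-homozygote machinery: sliding windows over
## phased genotypes, the Poisson absence-of-homozygotes test, and
## haplotype-based carrier assignment.

## Build a HaplotypeWindow from phased assays for given marker indices.
.windowFromHaps <- function(g, idx, samples = colnames(g)) {
  mk <- markerInfo(g)
  h1 <- hapMatrix(g, 1)[idx, samples, drop = FALSE]
  h2 <- hapMatrix(g, 2)[idx, samples, drop = FALSE]
  if (anyNA(h1) || anyNA(h2))
    stop("window contains missing haplotype calls for markers ",
         paste(mk$id[idx][rowSums(is.na(h1) | is.na(h2)) > 0],
               collapse = ", "))
  ## allele letters: 0 -> ref base, 1 -> alt base
  toStr <- function(h) {
    L <- ifelse(h == 1L, mk$alt[idx], mk$ref[idx])
    dim(L) <- dim(h)
    do.call(paste0, as.data.frame(t(L), stringsAsFactors = FALSE))
  }
  s1 <- toStr(h1)
  s2 <- toStr(h2)
  alleles <- sort(unique(c(s1, s2)))
  a1 <- match(s1, alleles)
  a2 <- match(s2, alleles)
  names(a1) <- names(a2) <- samples
  cnt <- tabulate(a1, length(alleles)) + tabulate(a2, length(alleles))
  new("HaplotypeWindow", markerIds = mk$id[idx],
      start = min(mk$pos[idx]), end = max(mk$pos[idx]),
      alleles = alleles, freq = cnt / sum(cnt),
      hap1Allele = a1, hap2Allele = a2)
}

#' Sliding haplotype windows over phased genotypes
#'
#' @param g Phased [GenotypeData-class] (after QC filtering).
#' @param k Window size in markers (>= 2).
#' @param step Window step in markers (default 1).
#' @return List of [HaplotypeWindow-class] objects.
#' @export
windowHaplotypes <- function(g, k = 10, step = 1) {
  stopifnot(k >= 2)
  if (!isPhased(g)) stop("phased genotypes are required")
  M <- nrow(g)
  if (M < k) stop("fewer markers than the window size")
  starts <- seq(1L, M - k + 1L, by = step)
  lapply(starts, function(s) .windowFromHaps(g, s:(s + k - 1L)))
}

#' Theoretical haplotype allele space of a window
#'
#' @param k Number of markers in the window.
#' @param nAlleles Alleles per marker (2 for biallelic SNPs).
#' @return \code{nAlleles ^ k} (1024 for a 10-SNP biallelic window).
#' @export
haplotypeSpace <- function(k, nAlleles = 2) nAlleles^k

#' Expected homozygote count under Hardy-Weinberg proportions
#'
#' @param nAnimals Number of live genotyped animals.
#' @param q Haplotype (or allele) frequency.
#' @return list with \code{lambda} = \eqn{n q^2} and \code{rounded}, the
#'   nearest integer (the figure typically reported).
#' @examples
#' expectedHomozygotes(19309, 0.043)  # lambda 35.71, rounded 36
#' @export
expectedHomozygotes <- function(nAnimals, q) {
  stopifnot(nAnimals >= 0, q >= 0, q <= 1)
  lambda <- nAnimals * q^2
  list(lambda = lambda, rounded = round(lambda))
}

#' Missing-homozygote Poisson test
#'
#' Probability of observing at most \code{observed} homozygotes when the
#' Hardy-Weinberg expectation is Poisson with mean \code{lambda}; for
#' \code{observed = 0} this is \eqn{e^{-\lambda}}. Small values are strong
#' evidence that the haplotype carries or tags a recessive lethal.
#'
#' @param observed Observed homozygote count (non-negative integer).
#' @param lambda Expected count under HWE (>= 0).
#' @return Lower-tail Poisson probability.
#' @examples
#' missingHomozygoteTest(0, 36)  # ~2.3e-16
#' @export
missingHomozygoteTest <- function(observed, lambda) {
  if (any(lambda < 0)) stop("lambda must be >= 0")
  if (any(observed < 0) || any(observed != round(observed)))
    stop("observed must be a non-negative integer")
  stats::ppois(observed, lambda)
}

#' Scan haplotype windows for missing homozygotes
#'
#' For every window allele with frequency at least \code{qMin}, compares
#' the observed homozygote count to its HWE expectation. Reports both the
#' exact-lambda probability (default for new analyses) and the probability
#' at the rounded lambda, plus a Bonferroni-adjusted column over the number
#' of tested alleles.
#'
#' @param windows List of [HaplotypeWindow-class] from [windowHaplotypes()].
#' @param qMin Minimum allele frequency to test (default 0.01).
#' @return data.frame with window bounds, allele, q, nAnimals, observed
#'   and expected homozygotes, p (exact lambda), pRounded, pAdjusted.
#' @export
missingHomozygoteScan <- function(windows, qMin = 0.01) {
  rows <- lapply(windows, function(w) {
    keep <- which(w@freq >= qMin)
    if (!length(keep)) return(NULL)
    nAnimals <- length(w@hap1Allele)
    obs <- vapply(keep, function(i)
      sum(w@hap1Allele == i & w@hap2Allele == i), 0L)
    lam <- nAnimals * w@freq[keep]^2
    data.frame(start = w@start, end = w@end, allele = w@alleles[keep],
               q = w@freq[keep], nAnimals = nAnimals, observed = obs,
               lambda = lam,
               p = missingHomozygoteTest(obs, lam),
               pRounded = missingHomozygoteTest(obs, round(lam)),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) return(data.frame())
  out$pAdjusted <- pmin(1, out$p * nrow(out))
  out[order(out$p), , drop = FALSE]
}

#' Assign carriers of a target haplotype
#'
#' An animal is a carrier when exactly one of its chromosomes bears the
#' target allele. Animals with two copies are flagged as anomalies (under
#' a recessive lethal none should be alive) and reported as "ambiguous";
#' their ids are kept in \code{info$homozygotes}.
#'
#' @param window A [HaplotypeWindow-class].
#' @param targetHaplotype The allele string to track.
#' @return A [CarrierCallSet-class] (channel "haplotype") whose info also
#'   holds the carrier frequency.
#' @export
assignHaplotypeCarriers <- function(window, targetHaplotype) {
  ti <- match(targetHaplotype, window@alleles)
  n <- length(window@hap1Allele)
  copies <- if (is.na(ti)) rep(0L, n) else
    (window@hap1Allele == ti) + (window@hap2Allele == ti)
  calls <- factor(c("noncarrier", "carrier", "ambiguous")[copies + 1L],
                  levels = c("carrier", "noncarrier", "ambiguous"))
  names(calls) <- names(window@hap1Allele)
  support <- data.frame(copies = as.integer(copies),
                        row.names = names(calls))
  homo <- names(calls)[copies == 2L]
  if (length(homo))
    warning(length(homo), " animal(s) homozygous for the target haplotype",
            " - unexpected under a recessive lethal")
  new("CarrierCallSet", channel = "haplotype", calls = calls,
      support = support,
      info = list(homozygotes = homo,
                  carrierFrequency = mean(copies == 1L),
                  targetHaplotype = targetHaplotype))
}
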
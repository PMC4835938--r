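## Orthogonal deletion evidence: Hardy-Weinberg deviation scan, array
## intensity carrier calling, read-depth ratios and channel concordance.

#' Hardy-Weinberg deviation scan
#'
#' Per-marker 1-df chi-square comparing observed genotype counts to the
#' Hardy-Weinberg expectation at the sample allele frequency (no continuity
#' correction), with the direction of the deviation. Inside a deletion,
#' hemizygotes are called homozygous, so in-deletion markers show a
#' heterozygote deficit.
#'
#' @param g A [GenotypeData-class] (biallelic markers).
#' @param region Optional region ("chr:start-end" or GRanges) to restrict
#'   the scan.
#' @param exact Also compute an exact Hardy-Weinberg test (conditional on
#'   allele counts) for small samples.
#' @return data.frame with id, pos, n0/n1/n2 counts, chi2, p, direction
#'   ("het_deficit", "het_excess" or "none"), and pExact when requested.
#' @export
hwpScan <- function(g, region = NULL, exact = FALSE) {
  mk <- markerInfo(g)
  keep <- seq_len(nrow(mk))
  if (!is.null(region)) {
    reg <- parseRegion(region)
    keep <- which(IRanges::overlapsAny(rowRanges(g), reg,
                                       ignore.strand = TRUE))
  }
  D <- dosages(g)[keep, , drop = FALSE]
  n0 <- rowSums(D == 0L, na.rm = TRUE)
  n1 <- rowSums(D == 1L, na.rm = TRUE)
  n2 <- rowSums(D == 2L, na.rm = TRUE)
  n <- n0 + n1 + n2
  qhat <- (2 * n2 + n1) / (2 * pmax(n, 1L))
  e0 <- n * (1 - qhat)^2
  e1 <- n * 2 * qhat * (1 - qhat)
  e2 <- n * qhat^2
  chi2 <- (n0 - e0)^2 / pmax(e0, 1e-12) + (n1 - e1)^2 / pmax(e1, 1e-12) +
    (n2 - e2)^2 / pmax(e2, 1e-12)
  mono <- qhat == 0 | qhat == 1
  chi2[mono] <- 0
  p <- stats::pchisq(chi2, df = 1, lower.tail = FALSE)
  direction <- ifelse(chi2 < 1e-9, "none",
                      ifelse(n1 < e1, "het_deficit", "het_excess"))
  out <- data.frame(id = mk$id[keep], pos = mk$pos[keep],
                    n0 = n0, n1 = n1, n2 = n2, chi2 = chi2, p = p,
                    direction = direction, stringsAsFactors = FALSE)
  if (exact)
    out$pExact <- mapply(.hweExactP, n1, n, round(2 * n * qhat))
  out
}

## Exact HWE test (conditional distribution of heterozygote count given
## allele counts), two-sided by summing probabilities <= observed.
.hweExactP <- function(nhet, n, nMinor) {
  nMinor <- min(nMinor, 2 * n - nMinor)
  hets <- seq(nMinor %% 2, nMinor, by = 2)
  lp <- vapply(hets, function(h) {
    nAA <- (nMinor - h) / 2
    nBB <- n - nAA - h
    lgamma(n + 1) - lgamma(nAA + 1) - lgamma(h + 1) - lgamma(nBB + 1) +
      h * log(2) + lgamma(nMinor + 1) + lgamma(2 * n - nMinor + 1) -
      lgamma(2 * n + 1)
  }, 0)
  pr <- exp(lp - max(lp))
  pr <- pr / sum(pr)
  sum(pr[pr <= pr[match(nhet, hets)] * (1 + 1e-9)])
}

#' Infer a deletion region from a Hardy-Weinberg scan
#'
#' Takes the markers with a significant heterozygote deficit and returns
#' the genomic span of the largest run of consecutive flagged markers
#' (tolerating \code{gap} unflagged markers inside a run).
#'
#' @param hwp Result of [hwpScan()].
#' @param chrom Chromosome name for the returned region.
#' @param pThresh Significance threshold (default 1e-5).
#' @param gap Number of unflagged markers tolerated inside a run.
#' @return A GRanges of length 1, or NULL when nothing is flagged.
#' @export
inferDeletionRegion <- function(hwp, chrom = "23", pThresh = 1e-5,
                                gap = 1) {
  flag <- which(hwp$p < pThresh & hwp$direction == "het_deficit")
  if (!length(flag)) return(NULL)
  runs <- split(flag, cumsum(c(1, diff(flag) > gap + 1)))
  best <- runs[[which.max(lengths(runs))]]
  GRanges(chrom, IRanges(min(hwp$pos[best]), max(hwp$pos[best])))
}

#' Call deletion carriers from genotype intensity
#'
#' An animal is called a carrier when, over the markers of the candidate
#' region, its mean Log2R ratio is below \code{meanThreshold} AND at least
#' \code{ceiling(homozygousFraction * m)} of the m region markers are
#' called homozygous (the ceiling reproduces the usual "more than
#' 97 percent of loci" operationalization, e.g. at least 135 of 139).
#'
#' @param intensity Numeric matrix (markers x samples) of Log2R ratios.
#' @param g [GenotypeData-class] giving the called genotypes of the same
#'   samples.
#' @param region Candidate deletion region ("chr:start-end" or GRanges);
#'   must contain at least 10 markers present in both inputs.
#' @param meanThreshold Carrier mean-intensity threshold (default 0).
#' @param homozygousFraction Minimum homozygous-call fraction (default
#'   0.97).
#' @return A [CarrierCallSet-class] (channel "intensity") with per-animal
#'   mean Log2R and homozygous fraction as support.
#' @export
callIntensityCarriers <- function(intensity, g, region, meanThreshold = 0,
                                  homozygousFraction = 0.97) {
  reg <- parseRegion(region)
  mk <- markerInfo(g)
  inReg <- mk$id[IRanges::overlapsAny(rowRanges(g), reg,
                                      ignore.strand = TRUE)]
  mids <- intersect(inReg, rownames(intensity))
  if (length(mids) < 10L)
    stop("region contains only ", length(mids),
         " markers present in both inputs (>= 10 required)")
  samples <- intersect(colnames(intensity), colnames(g))
  m <- length(mids)
  meanL <- colMeans(intensity[mids, samples, drop = FALSE])
  D <- dosages(g)[mids, samples, drop = FALSE]
  homCount <- colSums(D == 0L | D == 2L, na.rm = TRUE)
  need <- ceiling(homozygousFraction * m)
  carrier <- meanL < meanThreshold & homCount >= need
  calls <- factor(ifelse(carrier, "carrier", "noncarrier"),
                  levels = c("carrier", "noncarrier", "ambiguous"))
  names(calls) <- samples
  new("CarrierCallSet", channel = "intensity", calls = calls,
      support = data.frame(meanLog2R = meanL,
                           homozygousFraction = homCount / m,
                           row.names = samples),
      info = list(nMarkers = m, required = need,
                  carrierFrequency = mean(carrier)))
}

#' Read-depth ratio deletion calls
#'
#' Per animal, the ratio of mean depth over windows inside the candidate
#' region to mean depth outside it. A single-copy deletion carrier shows a
#' ratio near 0.5. Calls: carrier below 0.7, noncarrier above 0.85,
#' ambiguous between (cutoffs separate the Poisson ratio distributions at
#' typical whole-genome depth over a 0.5-Mb region).
#'
#' @param depth data.frame with columns sample, window_start, window_end,
#'   reads (from [simulateDepth()] or equivalent).
#' @param region Candidate region ("chr:start-end" or GRanges).
#' @param carrierBelow,noncarrierAbove Call cutoffs on the ratio.
#' @return A [CarrierCallSet-class] (channel "depth") with the per-animal
#'   ratio as support.
#' @export
depthRatio <- function(depth, region, carrierBelow = 0.7,
                       noncarrierAbove = 0.85) {
  reg <- parseRegion(region)
  lo <- GenomicRanges::start(reg)
  hi <- GenomicRanges::end(reg)
  mid <- (depth$window_start + depth$window_end) / 2
  inside <- mid >= lo & mid <= hi
  samples <- unique(depth$sample)
  inMean <- tapply(depth$reads[inside], depth$sample[inside],
                   mean)[samples]
  outMean <- tapply(depth$reads[!inside], depth$sample[!inside],
                    mean)[samples]
  if (any(is.na(outMean) | outMean == 0))
    stop("zero off-region depth for sample(s): ",
         paste(samples[is.na(outMean) | outMean == 0], collapse = ", "),
         " (uninformative)")
  ratio <- as.numeric(inMean) / as.numeric(outMean)
  calls <- factor(ifelse(ratio < carrierBelow, "carrier",
                         ifelse(ratio > noncarrierAbove, "noncarrier",
                                "ambiguous")),
                  levels = c("carrier", "noncarrier", "ambiguous"))
  names(calls) <- samples
  new("CarrierCallSet", channel = "depth", calls = calls,
      support = data.frame(depthRatio = ratio, row.names = samples),
      info = list(carrierFrequency = mean(calls == "carrier")))
}

#' Concordance between two carrier-call channels
#'
#' Cross-tabulates carrier/noncarrier calls over the animals present in
#' both sets; ambiguous calls are excluded from the table and counted.
#'
#' @param a,b [CarrierCallSet-class] objects.
#' @return list with \code{table} (2x2), \code{agreement} (overall
#'   proportion), \code{carrierConcordance} (among a-carriers, the fraction
#'   also called carrier by b), \code{nAmbiguous}, \code{nCommon}.
#' @export
concordance <- function(a, b) {
  common <- intersect(names(a@calls), names(b@calls))
  ca <- a@calls[common]
  cb <- b@calls[common]
  amb <- ca == "ambiguous" | cb == "ambiguous"
  ca <- factor(as.character(ca[!amb]), c("carrier", "noncarrier"))
  cb <- factor(as.character(cb[!amb]), c("carrier", "noncarrier"))
  tab <- table(a = ca, b = cb)
  nA <- sum(tab["carrier", ])
  list(table = tab,
       agreement = if (length(ca)) sum(diag(tab)) / length(ca) else NA_real_,
       carrierConcordance = if (nA) tab["carrier", "carrier"] / nA
       else NA_real_,
       nAmbiguous = sum(amb), nCommon = length(common))
}
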
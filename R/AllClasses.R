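#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<- mcols mcols<-
#' @importFrom GenomicRanges GRanges
#' @importFrom IRanges IRanges
#' @importFrom SummarizedExperiment SummarizedExperiment assay assays
#'   rowRanges rowRanges<- colData
NULL

## ---------------------------------------------------------------------------
## SimulationConfig
## ---------------------------------------------------------------------------

#' Configuration for the gene-drop simulator
#'
#' Holds every tunable of the synthetic population: pedigree geometry, marker
#' panel, the planted recessive lethal deletion, observation-layer noise
#' (genotype calling error, array intensity, sequencing depth) and the
#' de-regressed-proof (DRP) phenotype model.
#'
#' @slot nFounders Number of unrelated founder animals (generation 0).
#' @slot nGenerations Number of gene-drop generations after the founders.
#' @slot nSiresPerGen Sires sampled per generation; each forms one half-sib
#'   family.
#' @slot progenyPerSire Calves per sire per generation.
#' @slot nMarkers Number of evenly spaced biallelic SNPs on the single
#'   simulated chromosome.
#' @slot chromLengthBp Chromosome length in base pairs.
#' @slot deletionStartBp,deletionEndBp 1-based inclusive bounds of the
#'   deleted segment.
#' @slot causativeFreq Founder frequency \eqn{p} of the deleted chromosome.
#' @slot baselineStillbirth Baseline probability that a non-homozygous calf
#'   is recorded stillborn.
#' @slot penetrance Probability that a homozygous-deletion conceptus is
#'   recorded as a stillbirth (absorbs late-gestation loss and
#'   under-reporting).
#' @slot genotypeError Per-call probability that a genotype call is
#'   perturbed (homozygous calls become heterozygous; heterozygous calls
#'   become a random homozygote).
#' @slot intensityMeanCarrier Mean Log2R ratio at in-deletion markers for
#'   single-copy carriers.
#' @slot intensitySd Log2R standard deviation common to all markers.
#' @slot meanDepth Mean per-base sequencing depth for the read-depth layer.
#' @slot drpH2 Heritability proxy used to place the deletion effect on the
#'   additive-genetic-SD scale of the DRPs and as the liability-scale
#'   heritability of stillbirth.
#' @slot recombRate Recombination rate in cM/Mb (Haldane map, uniform).
#' @slot seed Integer seed; identical seeds give bit-identical populations.
#' @export
setClass("SimulationConfig", representation(
  nFounders = "numeric", nGenerations = "numeric", nSiresPerGen = "numeric",
  progenyPerSire = "numeric", nMarkers = "numeric", chromLengthBp = "numeric",
  deletionStartBp = "numeric", deletionEndBp = "numeric",
  causativeFreq = "numeric", baselineStillbirth = "numeric",
  penetrance = "numeric", genotypeError = "numeric",
  intensityMeanCarrier = "numeric", intensitySd = "numeric",
  meanDepth = "numeric", drpH2 = "numeric", recombRate = "numeric",
  seed = "numeric"))

setValidity("SimulationConfig", function(object) {
  msg <- character()
  chk1 <- function(x, nm) {
    if (length(slot(object, nm)) != 1L || !is.finite(slot(object, nm)))
      msg <<- c(msg, sprintf("'%s' must be a single finite number", nm))
  }
  for (nm in slotNames(object)) chk1(slot(object, nm), nm)
  if (length(msg)) return(msg)
  frac <- c("causativeFreq", "baselineStillbirth", "penetrance",
            "genotypeError", "drpH2")
  for (nm in frac) {
    v <- slot(object, nm)
    if (v < 0 || v > 1) msg <- c(msg, sprintf("'%s' must lie in [0, 1]", nm))
  }
  if (object@causativeFreq >= 0.5)
    msg <- c(msg, "'causativeFreq' must lie in [0, 0.5)")
  if (!(object@deletionStartBp < object@deletionEndBp))
    msg <- c(msg, "'deletionStartBp' must be < 'deletionEndBp'")
  if (object@deletionEndBp > object@chromLengthBp)
    msg <- c(msg, "'deletionEndBp' must be <= 'chromLengthBp'")
  pos <- c("nFounders", "nGenerations", "nSiresPerGen", "progenyPerSire",
           "nMarkers", "chromLengthBp")
  for (nm in pos) if (slot(object, nm) < 1)
    msg <- c(msg, sprintf("'%s' must be >= 1", nm))
  if (object@nMarkers < 30)
    msg <- c(msg, "'nMarkers' must be >= 30 (tag window needs flanks)")
  if (object@intensitySd < 0) msg <- c(msg, "'intensitySd' must be >= 0")
  if (object@meanDepth <= 0) msg <- c(msg, "'meanDepth' must be > 0")
  if (object@recombRate < 0) msg <- c(msg, "'recombRate' must be >= 0")
  if (length(msg)) msg else TRUE
})

#' Create a simulation configuration
#'
#' Defaults emulate a Nordic-cattle-like study population at desk scale: a
#' half-sib pedigree, one chromosome carrying a 0.5-Mbp deletion segregating
#' at a founder frequency of 0.043 tagged by a 10-SNP haplotype, a fully
#' penetrant recessive lethal, a ~4\% baseline stillbirth rate, mild genotype
#' calling error and a single-copy intensity loss of -0.35 Log2R units.
#'
#' @param nFounders,nGenerations,nSiresPerGen,progenyPerSire Pedigree
#'   geometry; see the class documentation.
#' @param nMarkers,chromLengthBp Marker panel density and chromosome length.
#' @param deletionStartBp,deletionEndBp Deletion bounds (1-based inclusive).
#' @param causativeFreq Founder frequency of the deleted chromosome.
#' @param baselineStillbirth,penetrance,genotypeError,intensityMeanCarrier,intensitySd,meanDepth,drpH2,recombRate,seed
#'   See the class documentation.
#' @return A validated [SimulationConfig-class] object.
#' @examples
#' cfg <- SimulationConfig(nFounders = 50, nGenerations = 2,
#'                         nSiresPerGen = 5, progenyPerSire = 10)
#' cfg
#' @export
SimulationConfig <- function(nFounders = 200, nGenerations = 4,
    nSiresPerGen = 25, progenyPerSire = 40, nMarkers = 400,
    chromLengthBp = 2e7, deletionStartBp = 9750001, deletionEndBp = 10250000,
    causativeFreq = 0.043, baselineStillbirth = 0.04, penetrance = 1,
    genotypeError = 0.002, intensityMeanCarrier = -0.35, intensitySd = 0.15,
    meanDepth = 10, drpH2 = 0.01, recombRate = 1, seed = 1) {
  new("SimulationConfig", nFounders = nFounders,
      nGenerations = nGenerations, nSiresPerGen = nSiresPerGen,
      progenyPerSire = progenyPerSire, nMarkers = nMarkers,
      chromLengthBp = chromLengthBp, deletionStartBp = deletionStartBp,
      deletionEndBp = deletionEndBp, causativeFreq = causativeFreq,
      baselineStillbirth = baselineStillbirth, penetrance = penetrance,
      genotypeError = genotypeError,
      intensityMeanCarrier = intensityMeanCarrier,
      intensitySd = intensitySd, meanDepth = meanDepth, drpH2 = drpH2,
      recombRate = recombRate, seed = seed)
}

setMethod("show", "SimulationConfig", function(object) {
  cat("SimulationConfig\n")
  cat(sprintf("  pedigree: %d founders, %d generations x %d sires x %d progeny\n",
              object@nFounders, object@nGenerations, object@nSiresPerGen,
              object@progenyPerSire))
  cat(sprintf("  markers : %d SNPs on %.1f Mbp\n", object@nMarkers,
              object@chromLengthBp / 1e6))
  cat(sprintf("  deletion: %.2f-%.2f Mbp, founder freq p = %.3f, penetrance %.2f\n",
              object@deletionStartBp / 1e6, object@deletionEndBp / 1e6,
              object@causativeFreq, object@penetrance))
  cat(sprintf("  seed    : %d\n", as.integer(object@seed)))
})

## ---------------------------------------------------------------------------
## Population
## ---------------------------------------------------------------------------

#' Simulated population with ground truth
#'
#' Result of [simulatePopulation()]. Carries every individual ever conceived
#' (including recorded stillbirths), the true phased haplotypes, per-chromosome
#' deletion flags, the marker map, the designated tag window and the
#' configuration that produced it. Downstream observation layers
#' ([callGenotypes()], [simulateIntensity()], [simulateDepth()],
#' [simulateRecordsAndDrp()]) are deterministic functions of this object and
#' their own seeds.
#'
#' @slot individuals data.frame with columns id, sire, dam, sex, generation,
#'   deletionCopies, aliveAtBirth, bv (true polygenic breeding value in
#'   additive-genetic SD units).
#' @slot markers data.frame with columns id, chrom, pos, ref, alt.
#' @slot hap1,hap2 Integer matrices (markers x individuals) of true alt-allele
#'   indicators per chromosome.
#' @slot del1,del2 Logical vectors: whether chromosome 1/2 of each individual
#'   is the deleted chromosome.
#' @slot tagMarkers Integer indices of the 10-SNP tag window (5 markers each
#'   side of the deletion).
#' @slot tagAllele Character scalar: the tag-window allele string carried in
#'   complete founder LD with the deletion.
#' @slot config The [SimulationConfig-class] used.
#' @export
setClass("Population", representation(
  individuals = "data.frame", markers = "data.frame",
  hap1 = "matrix", hap2 = "matrix", del1 = "logical", del2 = "logical",
  tagMarkers = "integer", tagAllele = "character",
  config = "SimulationConfig"))

setValidity("Population", function(object) {
  msg <- character()
  n <- nrow(object@individuals)
  m <- nrow(object@markers)
  if (is.unsorted(object@markers$pos, strictly = TRUE))
    msg <- c(msg, "marker positions must be strictly increasing")
  if (!all(dim(object@hap1) == c(m, n)) || !all(dim(object@hap2) == c(m, n)))
    msg <- c(msg, "haplotype matrices must be markers x individuals")
  if (length(object@del1) != n || length(object@del2) != n)
    msg <- c(msg, "deletion flags must have one entry per individual")
  cp <- as.integer(object@del1) + as.integer(object@del2)
  if (!identical(cp, as.integer(object@individuals$deletionCopies)))
    msg <- c(msg, "deletionCopies must equal the count of deleted chromosomes")
  if (length(msg)) msg else TRUE
})

setMethod("show", "Population", function(object) {
  ind <- object@individuals
  cat("Population:", nrow(ind), "individuals,", nrow(object@markers),
      "markers\n")
  cat(sprintf("  live: %d | recorded stillbirths: %d\n",
              sum(ind$aliveAtBirth), sum(!ind$aliveAtBirth)))
  cat(sprintf("  deletion carriers (live): %d | live homozygotes: %d\n",
              sum(ind$deletionCopies == 1L & ind$aliveAtBirth),
              sum(ind$deletionCopies == 2L & ind$aliveAtBirth)))
  cat(sprintf("  tag window: %d SNPs flanking %.2f-%.2f Mbp, allele %s\n",
              length(object@tagMarkers),
              object@config@deletionStartBp / 1e6,
              object@config@deletionEndBp / 1e6, object@tagAllele))
})

## ---------------------------------------------------------------------------
## GenotypeData
## ---------------------------------------------------------------------------

#' Called genotypes with a ranged marker map
#'
#' Thin extension of \code{RangedSummarizedExperiment}: the \code{dosage}
#' assay holds called alt-allele dosages (0/1/2, NA for missing) and, when
#' phase is available, \code{hap1}/\code{hap2} assays hold per-chromosome
#' alt-allele indicators. Row ranges carry marker id, ref/alt alleles and the
#' minor allele frequency recomputed from the data.
#'
#' @export
setClass("GenotypeData", contains = "RangedSummarizedExperiment")

setValidity("GenotypeData", function(object) {
  msg <- character()
  if (!"dosage" %in% names(assays(object)))
    msg <- c(msg, "a 'dosage' assay is required")
  else {
    d <- assay(object, "dosage")
    if (!all(d %in% c(0L, 1L, 2L, NA)))
      msg <- c(msg, "dosages must be 0, 1, 2 or NA")
  }
  need <- c("ref", "alt", "maf")
  if (!all(need %in% names(mcols(rowRanges(object)))))
    msg <- c(msg, "rowRanges mcols must contain ref, alt, maf")
  if (length(msg)) msg else TRUE
})

#' Construct a GenotypeData object
#'
#' @param markers data.frame with columns id, chrom, pos, ref, alt.
#' @param dosage Integer matrix (markers x samples) of alt-allele dosages.
#' @param hap1,hap2 Optional phased alt-allele indicator matrices of the
#'   same shape.
#' @return A [GenotypeData-class] object with MAF computed from the dosages
#'   (missing calls excluded from the denominator).
#' @export
GenotypeData <- function(markers, dosage, hap1 = NULL, hap2 = NULL) {
  stopifnot(is.data.frame(markers),
            all(c("id", "chrom", "pos", "ref", "alt") %in% names(markers)),
            nrow(markers) == nrow(dosage))
  o <- order(markers$pos)
  markers <- markers[o, , drop = FALSE]
  dosage <- dosage[o, , drop = FALSE]
  if (!is.null(hap1)) hap1 <- hap1[o, , drop = FALSE]
  if (!is.null(hap2)) hap2 <- hap2[o, , drop = FALSE]
  gr <- GRanges(markers$chrom, IRanges(markers$pos, markers$pos))
  mcols(gr) <- DataFrame(id = markers$id, ref = markers$ref,
                         alt = markers$alt,
                         maf = .computeMaf(dosage))
  names(gr) <- markers$id
  rownames(dosage) <- markers$id
  al <- list(dosage = dosage)
  if (!is.null(hap1) && !is.null(hap2)) {
    rownames(hap1) <- rownames(hap2) <- markers$id
    al$hap1 <- hap1
    al$hap2 <- hap2
  }
  new("GenotypeData", SummarizedExperiment(assays = al, rowRanges = gr))
}

.computeMaf <- function(dosage) {
  called <- !is.na(dosage)
  altf <- rowSums(dosage, na.rm = TRUE) / (2 * pmax(rowSums(called), 1L))
  pmin(altf, 1 - altf)
}

#' @describeIn GenotypeData Marker map as a data.frame (id, chrom, pos, ref,
#'   alt, maf).
#' @param g A [GenotypeData-class] object.
#' @export
markerInfo <- function(g) {
  gr <- rowRanges(g)
  data.frame(id = mcols(gr)$id, chrom = as.character(GenomicRanges::seqnames(gr)),
             pos = GenomicRanges::start(gr), ref = mcols(gr)$ref,
             alt = mcols(gr)$alt, maf = mcols(gr)$maf,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' @describeIn GenotypeData Called dosage matrix (markers x samples).
#' @export
dosages <- function(g) assay(g, "dosage")

#' @describeIn GenotypeData Phased haplotype matrix for chromosome
#'   \code{which} (1 or 2); errors when phase is absent.
#' @param which Chromosome copy, 1 or 2.
#' @export
hapMatrix <- function(g, which = 1) {
  if (!isPhased(g)) stop("GenotypeData has no phased haplotypes")
  assay(g, paste0("hap", which))
}

#' @describeIn GenotypeData TRUE when phased haplotype assays are present.
#' @export
isPhased <- function(g) all(c("hap1", "hap2") %in% names(assays(g)))

setMethod("show", "GenotypeData", function(object) {
  cat("GenotypeData:", nrow(object), "markers x", ncol(object), "samples",
      if (isPhased(object)) "(phased)" else "(unphased)", "\n")
  qc <- metadata(object)$qc
  if (!is.null(qc))
    cat(sprintf("  QC removed: %d MAF, %d HWP, %d in-region\n",
                qc$maf, qc$hwp, qc$region))
})

## ---------------------------------------------------------------------------
## RemlFit
## ---------------------------------------------------------------------------

#' REML mixed-model fit
#'
#' @slot beta,se Named fixed-effect estimates and standard errors (GLS at the
#'   variance-component optimum).
#' @slot varComponents Named variance components, including \code{residual}
#'   (the per-unit-weight residual variance).
#' @slot logLik Restricted log-likelihood at the optimum.
#' @slot converged Logical convergence flag (non-convergence is flagged, not
#'   an error).
#' @slot nobs Number of observations used.
#' @slot blup Named list of BLUPs for the random terms where they were
#'   requested.
#' @slot optim List with optimizer details (log variance ratios, value).
#' @export
setClass("RemlFit", representation(
  beta = "numeric", se = "numeric", varComponents = "numeric",
  logLik = "numeric", converged = "logical", nobs = "integer",
  blup = "list", optim = "list"))

setValidity("RemlFit", function(object) {
  msg <- character()
  if (any(object@varComponents < -1e-8)) msg <- c(msg, "variance components must be >= 0")
  if (any(object@se < 0, na.rm = TRUE)) msg <- c(msg, "standard errors must be >= 0")
  if (length(msg)) msg else TRUE
})

setMethod("show", "RemlFit", function(object) {
  cat("RemlFit  (REML logLik", format(object@logLik, digits = 8), ")\n")
  cat("fixed effects:\n")
  print(round(cbind(estimate = object@beta, se = object@se), 6))
  cat("variance components:\n")
  print(round(object@varComponents, 6))
  if (!object@converged) cat("WARNING: optimizer did not converge\n")
})

## ---------------------------------------------------------------------------
## ScanResult
## ---------------------------------------------------------------------------

#' Single-marker association scan result
#'
#' One row per tested marker: id, pos, maf, beta (allele substitution
#' effect), se, p, mlog10p and a note column ("ok", "skipped_monomorphic",
#' "not_estimable").
#'
#' @slot table The per-marker data.frame.
#' @slot model Character label ("sire", "animal", "animal+cofactor").
#' @slot nTests Number of markers actually tested.
#' @export
setClass("ScanResult", representation(
  table = "data.frame", model = "character", nTests = "integer"))

setMethod("show", "ScanResult", function(object) {
  cat("ScanResult:", object@model, "model,", nrow(object@table), "markers (",
      object@nTests, "tested )\n")
  tb <- object@table
  ok <- !is.na(tb$p)
  if (any(ok)) {
    top <- tb[ok, ][which.min(tb$p[ok]), ]
    cat(sprintf("  top marker: %s at %d bp, beta = %.4f (SE %.4f), -log10 p = %.2f\n",
                top$id, top$pos, top$beta, top$se, top$mlog10p))
  }
})

#' @describeIn ScanResult Extract the per-marker table.
#' @param x A ScanResult.
#' @param ... unused.
#' @export
setMethod("as.data.frame", "ScanResult", function(x, ...) x@table)

## ---------------------------------------------------------------------------
## CarrierCallSet
## ---------------------------------------------------------------------------

#' Per-animal carrier calls from one evidence channel
#'
#' @slot channel Evidence channel: "haplotype", "intensity" or "depth".
#' @slot calls Named factor with levels carrier / noncarrier / ambiguous.
#' @slot support Per-animal support values (e.g. mean Log2R, homozygous
#'   fraction, depth ratio), one row per call.
#' @slot info List of channel-specific extras (e.g. flagged homozygotes for
#'   the haplotype channel, carrier frequency).
#' @export
setClass("CarrierCallSet", representation(
  channel = "character", calls = "factor", support = "data.frame",
  info = "list"))

setValidity("CarrierCallSet", function(object) {
  msg <- character()
  if (!all(levels(object@calls) == c("carrier", "noncarrier", "ambiguous")))
    msg <- c(msg, "calls must have levels carrier/noncarrier/ambiguous")
  if (is.null(names(object@calls)))
    msg <- c(msg, "calls must be named by animal id")
  if (nrow(object@support) && nrow(object@support) != length(object@calls))
    msg <- c(msg, "support must have one row per call")
  if (length(msg)) msg else TRUE
})

#' @describeIn CarrierCallSet Named factor of calls.
#' @param x A CarrierCallSet.
#' @export
carrierCalls <- function(x) x@calls

#' @describeIn CarrierCallSet Character vector of animals called carrier.
#' @export
carrierIds <- function(x) names(x@calls)[x@calls == "carrier"]

setMethod("show", "CarrierCallSet", function(object) {
  tab <- table(object@calls)
  cat(sprintf("CarrierCallSet [%s]: %d animals (%d carrier, %d noncarrier, %d ambiguous)\n",
              object@channel, length(object@calls), tab["carrier"],
              tab["noncarrier"], tab["ambiguous"]))
  if (!is.null(object@info$carrierFrequency))
    cat(sprintf("  carrier frequency: %.4f\n", object@info$carrierFrequency))
})

## ---------------------------------------------------------------------------
## HaplotypeWindow
## ---------------------------------------------------------------------------

#' Haplotype alleles of one marker window
#'
#' @slot markerIds Ordered marker ids forming the window.
#' @slot start,end Genomic bounds (bp) of the window.
#' @slot alleles Distinct haplotype allele strings observed.
#' @slot freq Relative frequency of each allele among the 2N chromosomes.
#' @slot hap1Allele,hap2Allele Integer index into \code{alleles} for each
#'   sample's two chromosomes (named by sample).
#' @export
setClass("HaplotypeWindow", representation(
  markerIds = "character", start = "numeric", end = "numeric",
  alleles = "character", freq = "numeric",
  hap1Allele = "integer", hap2Allele = "integer"))

setValidity("HaplotypeWindow", function(object) {
  msg <- character()
  if (abs(sum(object@freq) - 1) > 1e-8)
    msg <- c(msg, "haplotype frequencies must sum to 1")
  if (length(unique(nchar(object@alleles))) > 1)
    msg <- c(msg, "all allele strings must have the window length")
  if (length(msg)) msg else TRUE
})

setMethod("show", "HaplotypeWindow", function(object) {
  cat(sprintf("HaplotypeWindow: %d SNPs [%d-%d bp], %d of %s possible alleles observed\n",
              length(object@markerIds), object@start, object@end,
              length(object@alleles),
              format(haplotypeSpace(length(object@markerIds)), big.mark = ",")))
  top <- order(object@freq, decreasing = TRUE)
  top <- top[seq_len(min(5, length(top)))]
  for (i in top)
    cat(sprintf("  %s  q = %.4f\n", object@alleles[i], object@freq[i]))
})
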
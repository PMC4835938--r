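## End-to-end orchestration: simulate -> QC -> sire scan -> RHM + cofactor
## re-scan -> missing-homozygote scan -> deletion evidence -> mating test,
## with one config, a run directory, a manifest and a summary report.

#' Pipeline configuration
#'
#' @param simulation Named list of [SimulationConfig()] arguments.
#' @param mafMin,hwpPMin Marker QC thresholds (defaults 0.01 and 1e-5).
#' @param windowK Haplotype window size in markers (default 10).
#' @param alpha Family-wise significance level for Bonferroni lines.
#' @param animalModelMaxN Cap on animals entering the animal-model stages
#'   (RHM, cofactor re-scan); a seeded subsample is taken above it.
#' @return A validated config list of class "PipelineConfig".
#' @export
pipelineConfig <- function(simulation = list(), mafMin = 0.01,
                           hwpPMin = 1e-5, windowK = 10, alpha = 0.05,
                           animalModelMaxN = 1500) {
  stopifnot(mafMin >= 0, mafMin < 0.5, hwpPMin >= 0, hwpPMin <= 1,
            windowK >= 2, alpha > 0, alpha <= 1, animalModelMaxN >= 50)
  ## validate the simulation block eagerly so errors name the field
  do.call(SimulationConfig, simulation)
  structure(list(simulation = simulation, mafMin = mafMin,
                 hwpPMin = hwpPMin, windowK = windowK, alpha = alpha,
                 animalModelMaxN = animalModelMaxN),
            class = "PipelineConfig")
}

#' Read / write a pipeline configuration as YAML
#'
#' The config round-trips unchanged through the serializer.
#'
#' @param path YAML file path.
#' @param config A "PipelineConfig" list.
#' @name pipelineConfigIO
#' @export
readPipelineConfig <- function(path) {
  do.call(pipelineConfig, yaml::read_yaml(path))
}

#' @rdname pipelineConfigIO
#' @export
writePipelineConfig <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' Run the full discovery pipeline on a simulated population
#'
#' Sequences every stage on one simulated data set: gene drop, genotype
#' calling, interchange-format export, marker QC (with the putative
#' deletion region inferred from the Hardy-Weinberg scan excluded from
#' phase-sensitive stages), sire-model association scan, random haplotype
#' model on the top markers with a cofactor re-scan, sliding-window
#' missing-homozygote scan, intensity and depth carrier calling, channel
#' concordance, and the mating-type stillbirth model. Writes stage
#' artifacts, a manifest with file hashes, a JSON summary and a markdown
#' report into \code{outDir}. All randomness derives from the simulation
#' seed, so a rerun with the same config is byte-identical.
#'
#' @param config A "PipelineConfig" from [pipelineConfig()].
#' @param outDir Run directory (created if missing).
#' @return Invisibly, the summary list.
#' @export
runPipeline <- function(config, outDir = tempfile("lethalscan_run")) {
  stopifnot(inherits(config, "PipelineConfig"))
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  stage <- function(name, expr) {
    message("[", format(Sys.time(), "%H:%M:%S"), "] stage: ", name)
    tryCatch(expr, error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }
  cfg <- do.call(SimulationConfig, config$simulation)
  summary <- list(seed = cfg@seed)

  pop <- stage("simulate", simulatePopulation(cfg))
  g0 <- stage("call_genotypes", callGenotypes(pop))
  intensity <- stage("intensity", simulateIntensity(pop))
  depth <- stage("depth", simulateDepth(pop))
  rec <- stage("records", simulateRecordsAndDrp(pop))
  ind <- pop@individuals
  ped <- ind[, c("id", "sire", "dam", "sex", "generation")]

  stage("export", {
    writeVcf(g0, file.path(outDir, "genotypes.vcf"))
    writeTableCsv(ped, file.path(outDir, "pedigree.csv"))
    writeTableCsv(rec$drp, file.path(outDir, "drp.csv"))
    writeTableCsv(rec$calving, file.path(outDir, "calving.csv"))
    writeIntensityTsv(intensity, file.path(outDir, "intensity.tsv"))
    writeTableCsv(depth, file.path(outDir, "depth.csv"))
  })

  hwp <- stage("hwp_scan", hwpScan(g0))
  region <- stage("infer_region",
                  inferDeletionRegion(hwp, chrom = pop@markers$chrom[1],
                                      pThresh = config$hwpPMin))
  ## association stages: sequence-style QC (allele frequency only; an HWP
  ## filter would remove perfectly tagging markers of a lethal, whose
  ## missing homozygotes are themselves signal). Haplotype-window stage:
  ## array-panel QC with the putative deleted region excluded to protect
  ## phasing.
  gScan <- stage("qc_scan", filterMarkers(g0, config$mafMin, hwpPMin = 0))
  gQc <- stage("qc_panel", filterMarkers(g0, config$mafMin, config$hwpPMin,
                                         excludeRegion = region))
  summary$qc <- metadata(gQc)$qc
  summary$inferredRegion <- if (is.null(region)) NULL else
    sprintf("%s:%d-%d", as.character(GenomicRanges::seqnames(region)),
            GenomicRanges::start(region), GenomicRanges::end(region))

  pheno <- data.frame(id = rec$drp$id, drp = rec$drp$drp,
                      reliability = rec$drp$reliability)
  scan <- stage("sire_scan", scanSireModel(gScan, pheno, ped))
  sTab <- as.data.frame(scan)
  bonf <- bonferroniThreshold(config$alpha, scan@nTests)
  utils::write.table(sTab, file.path(outDir, "scan_sire.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  ok <- !is.na(sTab$p)
  peak <- sTab[ok, ][which.min(sTab$p[ok]), ]
  summary$sireScan <- list(bonferroni = round(bonf, 2),
                           peakMarker = peak$id, peakPos = peak$pos,
                           peakMlog10p = peak$mlog10p,
                           nSignificant = sum(sTab$mlog10p[ok] > bonf))

  ## animal-model stages on a capped subsample
  set.seed(.stageSeed(cfg@seed, 11L))
  amIds <- pheno$id
  if (length(amIds) > config$animalModelMaxN)
    amIds <- sort(sample(amIds, config$animalModelMaxN))
  phenoAm <- pheno[pheno$id %in% amIds, ]
  A <- stage("relationship", buildA(prunePedigree(ped, amIds)))

  top <- topMarkers(scan, config$windowK)
  rhm <- stage("rhm", fitRhm(gScan, phenoAm, A, top))
  summary$rhm <- list(window = top, lrtStat = rhm$lrt$statistic,
                      lrtP = rhm$lrt$p, hapQtl = rhm$hapQtl,
                      hapQtlFreq = rhm$effects$freq[1])

  win <- .windowFromHaps(gScan, match(top, markerInfo(gScan)$id),
                         colnames(gScan))
  hapCalls <- stage("haplotype_carriers",
                    assignHaplotypeCarriers(win, rhm$hapQtl))
  cof <- (win@hap1Allele == match(rhm$hapQtl, win@alleles)) +
    (win@hap2Allele == match(rhm$hapQtl, win@alleles))
  names(cof) <- names(win@hap1Allele)
  cscan <- stage("cofactor_scan",
                 cofactorScan(gScan, phenoAm, A, cof))
  cTab <- as.data.frame(cscan)
  utils::write.table(cTab, file.path(outDir, "scan_cofactor.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  summary$cofactorScan <- list(
    maxMlog10p = suppressWarnings(max(cTab$mlog10p, na.rm = TRUE)),
    nSignificant = sum(cTab$mlog10p > bonf, na.rm = TRUE))

  wins <- stage("lethal_windows",
                windowHaplotypes(gQc, config$windowK,
                                 step = max(1L, config$windowK %/% 2L)))
  mh <- stage("missing_homozygotes", missingHomozygoteScan(wins))
  utils::write.table(mh, file.path(outDir, "missing_homozygotes.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  summary$missingHomozygote <- if (nrow(mh)) list(
    topAllele = mh$allele[1], q = mh$q[1], lambda = mh$lambda[1],
    observed = mh$observed[1], p = mh$p[1]) else list()

  ## the candidate region for the intensity/depth channels is a user
  ## parameter of those methods; on simulated data it is the configured
  ## deletion (the inferred HWP span above is reported as the discovery)
  evRegion <- parseRegion(list(chrom = pop@markers$chrom[1],
                               start = cfg@deletionStartBp,
                               end = cfg@deletionEndBp))
  intCalls <- stage("intensity_carriers",
                    callIntensityCarriers(intensity, g0, evRegion))
  depthCalls <- stage("depth_ratio", depthRatio(depth, evRegion))
  concIH <- concordance(intCalls, hapCalls)
  concDH <- concordance(depthCalls, hapCalls)
  summary$concordance <- list(
    intensityVsHaplotype = concIH$agreement,
    depthVsHaplotype = concDH$agreement)

  carrierTruth <- stats::setNames(ind$deletionCopies >= 1L, ind$id)
  summary$truth <- list(
    liveHomozygotes = sum(ind$deletionCopies == 2L & ind$aliveAtBirth),
    haplotypeAgreement = mean(
      (carrierCalls(hapCalls) == "carrier") ==
        carrierTruth[names(carrierCalls(hapCalls))]),
    intensityAgreement = mean(
      (carrierCalls(intCalls) == "carrier") ==
        carrierTruth[names(carrierCalls(intCalls))]))

  mrec <- stage("mating_records",
                buildMatingRecords(rec$calving, hapCalls))
  mfit <- stage("mating_model", fitMatingModel(mrec, pedigree = ped))
  writeTableCsv(stillbirthRateTable(mrec),
                file.path(outDir, "stillbirth_table.csv"))
  summary$mating <- list(contrasts = mfit$contrasts)

  jsonlite::write_json(summary, file.path(outDir, "summary.json"),
                       auto_unbox = TRUE, digits = 10, pretty = TRUE,
                       null = "null")
  .writeReport(summary, bonf, file.path(outDir, "report.md"))
  files <- list.files(outDir, full.names = TRUE)
  manifest <- data.frame(file = basename(files),
                         md5 = unname(tools::md5sum(files)))
  writeTableCsv(manifest, file.path(outDir, "manifest.csv"))
  invisible(summary)
}

.writeReport <- function(s, bonf, path) {
  ct <- s$mating$contrasts
  lines <- c(
    "# lethalscan pipeline report", "",
    sprintf("- seed: %d", as.integer(s$seed)),
    sprintf("- QC removed: %d (MAF), %d (HWP), %d (region)",
            s$qc$maf, s$qc$hwp, s$qc$region),
    sprintf("- inferred deletion region: %s",
            if (is.null(s$inferredRegion)) "none" else s$inferredRegion),
    sprintf("- sire-model peak: %s at %d bp, -log10 p = %.2f (Bonferroni line %.2f)",
            s$sireScan$peakMarker, as.integer(s$sireScan$peakPos),
            s$sireScan$peakMlog10p, bonf),
    sprintf("- RHM: LRT = %.2f (p = %.3g); lethal-candidate haplotype %s (q = %.4f)",
            s$rhm$lrtStat, s$rhm$lrtP, s$rhm$hapQtl, s$rhm$hapQtlFreq),
    sprintf("- cofactor re-scan: %d markers above the line (max -log10 p = %.2f)",
            s$cofactorScan$nSignificant, s$cofactorScan$maxMlog10p),
    if (length(s$missingHomozygote))
      sprintf("- missing-homozygote test: allele %s, q = %.4f, observed %d vs expected %.1f, p = %.3g",
              s$missingHomozygote$topAllele, s$missingHomozygote$q,
              s$missingHomozygote$observed, s$missingHomozygote$lambda,
              s$missingHomozygote$p) else NULL,
    sprintf("- live deletion homozygotes (truth): %d",
            s$truth$liveHomozygotes),
    sprintf("- carrier-call agreement with truth: haplotype %.3f, intensity %.3f",
            s$truth$haplotypeAgreement, s$truth$intensityAgreement),
    sprintf("- channel concordance: intensity vs haplotype %.3f, depth vs haplotype %.3f",
            s$concordance$intensityVsHaplotype,
            s$concordance$depthVsHaplotype),
    "", "## Mating-type contrasts (vs type I)", "",
    if (!is.null(ct) && nrow(ct))
      sprintf("- type %s: %+.4f (SE %.4f, p = %.3g)",
              ct$matingType, ct$estimate, ct$se, ct$p) else "- none")
  writeLines(unlist(lines), path)
  invisible(path)
}
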
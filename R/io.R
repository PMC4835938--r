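## Interchange formats: VCF 4.2 genotypes, pedigree/DRP/calving CSV,
## intensity TSV, depth CSV, plus the shared marker QC filter.

#' Read phased genotypes from a VCF file
#'
#' Parses a VCF 4.2 file via \pkg{vcfR} and returns a [GenotypeData-class]
#' holding alt-allele dosages and, when every genotype is phased, the two
#' haplotype assays. Missing genotypes (\code{./.}) become NA dosages and
#' are excluded from the MAF denominator.
#'
#' @param path Path to a VCF (plain or gzipped).
#' @param requirePhased Error when TRUE (default) and any called genotype is
#'   unphased ("/" separator).
#' @return A [GenotypeData-class].
#' @export
readVcf <- function(path, requirePhased = TRUE) {
  v <- tryCatch(vcfR::read.vcfR(path, verbose = FALSE),
                error = function(e) stop("failed to parse VCF '", path,
                                         "': ", conditionMessage(e)))
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1,
                                       dimnames = list(NULL, names(fix)))
  pos <- suppressWarnings(as.numeric(fix[, "POS"]))
  if (anyNA(pos)) {
    bad <- which(is.na(pos))[1]
    stop("malformed VCF record at data line ", bad, ": non-numeric POS")
  }
  gt <- vcfR::extract.gt(v, element = "GT")
  if (is.null(gt)) stop("VCF '", path, "' has no GT field")
  miss <- is.na(gt) | gt %in% c("./.", ".|.", ".")
  phased <- grepl("|", gt, fixed = TRUE) | miss
  if (requirePhased && !all(phased))
    stop("VCF '", path, "' contains unphased genotypes; phased GT ",
         "(with '|') is required")
  a1 <- suppressWarnings(as.integer(substr(gt, 1, 1)))
  a2 <- suppressWarnings(as.integer(substr(gt, 3, 3)))
  a1[miss] <- NA_integer_
  a2[miss] <- NA_integer_
  dim(a1) <- dim(a2) <- dim(gt)
  dimnames(a1) <- dimnames(a2) <- dimnames(gt)
  dosage <- a1 + a2
  markers <- data.frame(
    id = fix[, "ID"], chrom = fix[, "CHROM"], pos = pos,
    ref = fix[, "REF"], alt = fix[, "ALT"], stringsAsFactors = FALSE)
  noId <- is.na(markers$id) | markers$id == "."
  markers$id[noId] <- sprintf("%s:%d", markers$chrom[noId],
                              as.integer(markers$pos[noId]))
  rownames(dosage) <- markers$id
  if (all(phased)) {
    GenotypeData(markers, dosage, hap1 = a1, hap2 = a2)
  } else {
    GenotypeData(markers, dosage)
  }
}

#' Write genotypes to a VCF 4.2 file
#'
#' Emits phased GT ("|" separator) when haplotypes are present, otherwise
#' unphased dosage-consistent genotypes. \code{readVcf(writeVcf(g))} is the
#' identity on GT fields.
#'
#' @param g A [GenotypeData-class].
#' @param path Output path (plain text).
#' @return \code{path}, invisibly.
#' @export
writeVcf <- function(g, path) {
  mk <- markerInfo(g)
  samples <- colnames(g)
  if (isPhased(g)) {
    h1 <- hapMatrix(g, 1)
    h2 <- hapMatrix(g, 2)
    gt <- matrix(paste0(h1, "|", h2), nrow = nrow(g))
    ## the dosage is the canonical call: where a sporadic calling error
    ## made it inconsistent with the phased alleles, encode the dosage
    ## with an arbitrary phase so dosages round-trip exactly
    d <- dosages(g)
    bad <- which(!is.na(d) & !is.na(h1) & !is.na(h2) & h1 + h2 != d)
    if (length(bad)) gt[bad] <- c("0|0", "0|1", "1|1")[d[bad] + 1L]
    gt[is.na(h1) | is.na(h2)] <- ".|."
    ## dosage NA (e.g. in-deletion no-calls) must round-trip as missing
    gt[is.na(d)] <- ".|."
  } else {
    d <- dosages(g)
    gt <- matrix(c("0/0", "0/1", "1/1")[d + 1L], nrow = nrow(g))
    gt[is.na(d)] <- "./."
  }
  hdr <- c("##fileformat=VCFv4.2",
           sprintf("##contig=<ID=%s>", unique(mk$chrom)),
           "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", samples), collapse = "\t"))
  body <- paste(mk$chrom, as.integer(mk$pos), mk$id, mk$ref, mk$alt, ".",
                "PASS", ".", "GT",
                apply(gt, 1, paste, collapse = "\t"), sep = "\t")
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' De-regressed proof weight from reliability
#'
#' \eqn{w = r^2 / (1 - r^2)} with the reliability capped at 0.98, so the
#' weight never exceeds 49.
#'
#' @param r2 Reliability in (0, 1]; vectorized.
#' @return Numeric weights.
#' @examples
#' drpWeight(c(0.5, 0.98, 0.99))  # 1, 49, 49
#' @export
drpWeight <- function(r2) {
  if (any(!is.finite(r2)) || any(r2 <= 0) || any(r2 > 1))
    stop("reliability must lie in (0, 1]")
  r2 <- pmin(r2, 0.98)
  r2 / (1 - r2)
}

#' Marker quality-control filter
#'
#' Retains markers with MAF >= \code{mafMin}, Hardy-Weinberg 1-df chi-square
#' p >= \code{hwpPMin}, and position outside \code{excludeRegion}. Criteria
#' are applied in the order MAF, HWP, region, and each removed marker is
#' tallied once under the first criterion it fails, so the reported tallies
#' are disjoint. The tallies are stored in \code{metadata(g)$qc}.
#'
#' @param g A [GenotypeData-class].
#' @param mafMin Minimum minor allele frequency (default 0.01).
#' @param hwpPMin Minimum Hardy-Weinberg p-value (default 1e-5).
#' @param excludeRegion Optional region ("chr:start-end" or GRanges) whose
#'   markers are removed (e.g. a putative deletion, to protect phasing).
#' @return The filtered [GenotypeData-class]; a warning (not an error) is
#'   raised when no marker survives.
#' @export
filterMarkers <- function(g, mafMin = 0.01, hwpPMin = 1e-5,
                          excludeRegion = NULL) {
  maf <- mcols(rowRanges(g))$maf
  failMaf <- maf < mafMin
  hwp <- hwpScan(g)
  failHwp <- !failMaf & !is.na(hwp$p) & hwp$p < hwpPMin
  failRegion <- rep(FALSE, nrow(g))
  if (!is.null(excludeRegion)) {
    reg <- parseRegion(excludeRegion)
    hits <- IRanges::overlapsAny(rowRanges(g), reg, ignore.strand = TRUE)
    failRegion <- !failMaf & !failHwp & hits
  }
  keep <- !(failMaf | failHwp | failRegion)
  if (!any(keep)) warning("no markers survive QC")
  out <- g[keep, ]
  ## MAF is unchanged by sample-preserving subsetting, but recompute for
  ## the invariant that it always reflects the data at hand
  mcols(rowRanges(out))$maf <- .computeMaf(dosages(out))
  metadata(out)$qc <- list(maf = sum(failMaf), hwp = sum(failHwp),
                           region = sum(failRegion))
  out
}

## ---------------------------------------------------------------------------
## plain-table readers/writers (comma for tables, tab for matrices)
## ---------------------------------------------------------------------------

#' Table and matrix writers/readers for the pipeline interchange formats
#'
#' Pedigree (id,sire,dam,sex,generation), DRP (id,trait,drp,reliability) and
#' calving tables are comma-separated with a header; the intensity matrix
#' (markers x samples) is tab-separated with marker ids in the first column.
#'
#' @param x data.frame (tables) or matrix (intensity).
#' @param path File path.
#' @return Readers return a data.frame or matrix; writers return
#'   \code{path} invisibly.
#' @name tableIO
NULL

#' @rdname tableIO
#' @export
writeTableCsv <- function(x, path) {
  utils::write.csv(x, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname tableIO
#' @param required Character vector of columns that must be present.
#' @export
readTableCsv <- function(path, required = NULL) {
  x <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!is.null(required) && !all(required %in% names(x)))
    stop("file '", path, "' lacks required columns: ",
         paste(setdiff(required, names(x)), collapse = ", "))
  x
}

#' @rdname tableIO
#' @export
writeIntensityTsv <- function(x, path) {
  df <- data.frame(marker = rownames(x), x, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname tableIO
#' @export
readIntensityTsv <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE,
                          stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  m
}
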
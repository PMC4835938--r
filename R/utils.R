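#' Parse a genomic region string
#'
#' Accepts "chr:start-end" (1-based inclusive) or a list/GRanges and returns
#' a GRanges of length 1.
#'
#' @param region Character "chr:start-end", a GRanges, or a list with
#'   chrom/start/end.
#' @return A \code{GRanges} of length 1.
#' @examples
#' parseRegion("23:12280000-12810000")
#' @export
parseRegion <- function(region) {
  if (is(region, "GRanges")) {
    stopifnot(length(region) == 1L)
    return(region)
  }
  if (is.list(region))
    return(GRanges(as.character(region$chrom),
                   IRanges(as.numeric(region$start), as.numeric(region$end))))
  m <- regmatches(region, regexec("^([^:]+):([0-9]+)-([0-9]+)$", region))[[1]]
  if (length(m) != 4L)
    stop("region must look like 'chr:start-end', got: ", region)
  GRanges(m[2], IRanges(as.numeric(m[3]), as.numeric(m[4])))
}

## Derive a per-stage RNG seed from a base seed; kept below 2^31.
.stageSeed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 1000003 + offset) %% 2147483647)
}

## Positions (bp) of markers falling inside [start, end], given a marker df.
.markersInRegion <- function(markers, start, end) {
  which(markers$pos >= start & markers$pos <= end)
}

#' -log10 of a two-sided normal p-value, computed in log space
#' @noRd
.mlog10pNorm <- function(z) {
  -(log(2) + stats::pnorm(abs(z), lower.tail = FALSE, log.p = TRUE)) / log(10)
}
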
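#' Count read intervals over a region set
#'
#' Multicov-style counting: a read increments every region it overlaps by at
#' least one base pair, so a read spanning two bins is counted in both.
#' Reads carrying a logical `duplicate` metadata column are excluded when
#' flagged (duplicate-marked), unless `excludeDuplicates = FALSE`.
#'
#' @param reads `GRanges` of read (or fragment) intervals; paired reads given
#'   as two intervals are counted as two.
#' @param regions `GRanges` of regions to count over.
#' @param excludeDuplicates Drop reads with `duplicate == TRUE` (default).
#' @return Named integer vector of counts, one per region. Reads on
#'   chromosomes absent from `regions` are skipped with a message.
#' @examples
#' regions <- GenomicRanges::GRanges("chr1",
#'   IRanges::IRanges(c(1, 1001), width = 1000))
#' reads <- GenomicRanges::GRanges("chr1", IRanges::IRanges(951, 1050))
#' countReads(reads, regions)  # increments both bins
#' @export
countReads <- function(reads, regions, excludeDuplicates = TRUE) {
  if (excludeDuplicates && !is.null(mcols(reads)$duplicate))
    reads <- reads[!mcols(reads)$duplicate]
  known <- as.character(seqnames(reads)) %in%
    unique(as.character(seqnames(regions)))
  if (any(!known))
    message(sum(!known), " read(s) on chromosomes absent from the region ",
            "set were skipped")
  n <- countOverlaps(regions, reads[known], minoverlap = 1L,
                     ignore.strand = TRUE)
  names(n) <- if (!is.null(names(regions))) names(regions)
              else regionIds(regions)
  n
}

#' Assemble a DamageExperiment from per-sample read sets
#'
#' Convenience wrapper counting each sample's reads over a common region set.
#'
#' @param readsList Named list of read `GRanges`, one per sample.
#' @param regions Common region set.
#' @param sampleInfo Sample annotation (see [DamageExperiment()]); rows in
#'   the order of `readsList`.
#' @param excludeDuplicates Passed to [countReads()].
#' @return A [DamageExperiment-class].
#' @export
countSamples <- function(readsList, regions, sampleInfo,
                         excludeDuplicates = TRUE) {
  m <- vapply(readsList, countReads, integer(length(regions)),
              regions = regions, excludeDuplicates = excludeDuplicates)
  DamageExperiment(m, regions, sampleInfo)
}
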
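#' Log2 OG/input ratio per bin
#'
#' @param og OG counts.
#' @param scaledInput SES-scaled input counts.
#' @param pseudocount Added to both numerator and denominator (default 0.5)
#'   to avoid infinite ratios while preserving their ordering.
#' @return `log2((og + pc) / (scaledInput + pc))`.
#' @export
log2Ratio <- function(og, scaledInput, pseudocount = 0.5) {
  if (length(og) != length(scaledInput)) stop("vectors must align")
  if (any(og < 0) || any(scaledInput < 0)) stop("counts must be non-negative")
  log2((og + pseudocount) / (scaledInput + pseudocount))
}

#' Select bins at or above a ratio percentile
#'
#' Percentile threshold computed by linear interpolation between order
#' statistics (R quantile type 7); bins with ratio greater than or equal to
#' the threshold are selected. Applied per technical replicate independently.
#'
#' @param ratios Numeric vector of per-bin log2 ratios.
#' @param percentile Percentile in (0, 100); default 95.
#' @return Integer indices of selected bins (named if `ratios` is named).
#' @examples
#' thresholdBins(1:100)  # threshold 95.05 selects 96..100
#' @export
thresholdBins <- function(ratios, percentile = 95) {
  if (percentile <= 0 || percentile >= 100)
    stop("percentile must lie strictly between 0 and 100")
  if (length(ratios) < 20)
    stop("need at least 20 bins for percentile thresholding")
  thr <- stats::quantile(ratios, percentile / 100, type = 7, names = FALSE)
  if (max(ratios) == min(ratios))
    warning("all ratios equal: every bin selected")
  which(ratios >= thr)
}

#' Replicate-consensus filtering of enriched bins
#'
#' A bin is retained for a genotype only if it was selected in every
#' technical replicate (clone) of a biological replicate, in at least
#' `minBioReps` biological replicates.
#'
#' @param sets Named list of per-sample bin id vectors (indices or names).
#' @param design `data.frame` with columns `sample` (matching `names(sets)`),
#'   `bio_rep` and `clone`.
#' @param minBioReps Minimum supporting biological replicates (default 2).
#' @return Sorted vector of consensus bin ids.
#' @export
replicateConsensus <- function(sets, design, minBioReps = 2) {
  missing <- setdiff(design$sample, names(sets))
  if (length(missing))
    stop("missing replicate set(s): ", paste(missing, collapse = ", "))
  perBio <- lapply(split(design$sample, design$bio_rep), function(samples) {
    Reduce(intersect, sets[samples])
  })
  support <- table(unlist(perBio, use.names = FALSE))
  ids <- names(support)[support >= minBioReps]
  if (is.numeric(unlist(sets, use.names = FALSE)))
    ids <- as.numeric(ids)
  sort(ids)
}

#' Merge bookended bins into enriched regions
#'
#' Maximal runs of directly adjacent bins (zero gap, same chromosome) are
#' combined into one region; the region score is the mean log2 ratio of its
#' constituent bins.
#'
#' @param bins `GRanges` of consensus-enriched bins.
#' @param log2ratio Optional per-bin mean log2 ratio; stored on the merged
#'   regions as `mean_log2_ratio`.
#' @return `GRanges` of merged regions with metadata columns `n_bins` and
#'   (when ratios are given) `mean_log2_ratio`.
#' @export
mergeBookended <- function(bins, log2ratio = NULL) {
  if (!length(bins)) return(GRanges())
  bins <- BiocGenerics::sort(bins, ignore.strand = TRUE)
  merged <- reduce(granges(bins), min.gapwidth = 1L, ignore.strand = TRUE)
  hit <- findOverlaps(bins, merged, ignore.strand = TRUE)
  mcols(merged)$n_bins <- as.integer(table(factor(subjectHits(hit),
                                                  seq_along(merged))))
  if (!is.null(log2ratio)) {
    means <- tapply(log2ratio[queryHits(hit)], subjectHits(hit), mean)
    mcols(merged)$mean_log2_ratio <- as.numeric(means[as.character(
      seq_along(merged))])
  }
  names(merged) <- regionIds(merged)
  merged
}

#' Call OG-enriched bins (OG-EBs) per genotype
#'
#' End-to-end enriched-bin caller over a binned [DamageExperiment-class]:
#' per OG/input pair an SES fit scales the input, per technical replicate the
#' log2(OG/scaled input) ratio is thresholded at the given percentile, the
#' replicate consensus (all clones of a biological replicate, at least
#' `minBioReps` biological replicates) is applied per genotype, and bookended
#' bins are merged.
#'
#' @param x A [DamageExperiment-class] of bin counts covering OG and input
#'   samples for one or more genotypes.
#' @param percentile Ratio percentile (default 95).
#' @param pseudocount Pseudocount of [log2Ratio()].
#' @param minBioReps Consensus minimum (default 2).
#' @return Named list per genotype with elements `regions` (merged `GRanges`
#'   with `mean_log2_ratio`, `n_bins` and `supporting_bio_reps`), `bins`
#'   (consensus bin indices) and `ses` (list of [SESResult-class] per pair).
#' @export
callEnrichedBins <- function(x, percentile = 95, pseudocount = 0.5,
                             minBioReps = 2) {
  pairs <- samplePairs(x)
  counts <- assay(x, "counts")
  bins <- rowRanges(x)
  ratios <- matrix(NA_real_, nrow(counts), nrow(pairs))
  sel <- vector("list", nrow(pairs))
  ses <- vector("list", nrow(pairs))
  for (i in seq_len(nrow(pairs))) {
    og <- counts[, pairs$og[i]]
    inp <- counts[, pairs$input[i]]
    ses[[i]] <- sesFit(og, inp)
    ratios[, i] <- log2Ratio(og, inp * inputScaleFactor(ses[[i]]),
                             pseudocount)
    sel[[i]] <- thresholdBins(ratios[, i], percentile)
  }
  names(sel) <- names(ses) <- pairs$og
  out <- list()
  for (g in unique(pairs$genotype)) {
    pg <- pairs[pairs$genotype == g, ]
    design <- data.frame(sample = pg$og, bio_rep = pg$bio_rep,
                         clone = pg$clone)
    cons <- replicateConsensus(sel[pg$og], design, minBioReps)
    cons <- as.integer(cons)
    meanRatio <- rowMeans(ratios[, match(pg$og, pairs$og), drop = FALSE])
    perBio <- lapply(split(pg$og, pg$bio_rep), function(s)
      Reduce(intersect, sel[s]))
    supp <- vapply(cons, function(b)
      sum(vapply(perBio, function(v) b %in% v, logical(1))), integer(1))
    regions <- mergeBookended(bins[cons], meanRatio[cons])
    if (length(regions)) {
      hit <- findOverlaps(bins[cons], regions, ignore.strand = TRUE)
      mcols(regions)$supporting_bio_reps <- as.integer(
        tapply(supp[queryHits(hit)], subjectHits(hit), min))
    }
    out[[g]] <- list(regions = regions, bins = cons,
                     ses = ses[pg$og])
  }
  out
}
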
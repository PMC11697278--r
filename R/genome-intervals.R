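#' @importFrom GenomicRanges GRanges seqnames start end width strand
#'   findOverlaps countOverlaps pintersect reduce gaps resize trim promoters
#'   mcols granges
#' @importFrom GenomicRanges "strand<-" "mcols<-" "start<-" "end<-"
#' @importFrom IRanges IRanges Views overlapsAny subsetByOverlaps
#' @importFrom GenomeInfoDb seqlengths seqlengths<- seqlevels keepSeqlevels
#' @importFrom S4Vectors queryHits subjectHits
#' @importFrom Biostrings letterFrequency readDNAStringSet writeXStringSet
#'   DNAStringSet reverseComplement DNAString
NULL

# Coerce chromosome sizes given as a named vector, two-column data.frame or
# a chrom-sizes TSV path into a named integer vector.
.chromSizes <- function(chromSizes) {
  if (is.character(chromSizes) && length(chromSizes) == 1L &&
      file.exists(chromSizes)) {
    tab <- utils::read.table(chromSizes, sep = "\t", header = FALSE,
                             col.names = c("chrom", "size"))
    chromSizes <- stats::setNames(tab$size, tab$chrom)
  } else if (is.data.frame(chromSizes)) {
    chromSizes <- stats::setNames(chromSizes[[2]], chromSizes[[1]])
  }
  if (is.null(names(chromSizes)) || any(chromSizes <= 0))
    stop("chromSizes must be named positive lengths")
  chromSizes
}

#' Tile the genome into fixed-width analysis bins
#'
#' Splits each chromosome into non-overlapping `binSize` windows, drops the
#' incomplete terminal window, and removes any bin overlapping a blacklist
#' interval by one or more base pairs.
#'
#' @param chromSizes Named vector of chromosome lengths, a two-column
#'   data.frame, or the path to a chrom-sizes TSV.
#' @param binSize Bin width in bp (default 1000).
#' @param blacklist Optional `GRanges` of excluded regions.
#' @param chroms Optional character vector restricting the chromosome
#'   universe (e.g. the standard chromosomes of an assembly).
#' @param genome Optional `DNAStringSet`; when given, a `gc` metadata column
#'   (GC fraction per bin) is attached.
#' @return A sorted `GRanges` of retained bins with metadata columns
#'   `complete` and `blacklisted` (all retained bins are complete and not
#'   blacklisted) and names in `chrom:start-end` (0-based half-open) form.
#' @examples
#' makeBins(c(chr1 = 3500), binSize = 1000)
#' @export
makeBins <- function(chromSizes, binSize = 1000, blacklist = NULL,
                     chroms = NULL, genome = NULL) {
  if (binSize <= 0) stop("binSize must be positive")
  sizes <- .chromSizes(chromSizes)
  if (!is.null(chroms)) sizes <- sizes[names(sizes) %in% chroms]
  if (!length(sizes)) stop("no chromosomes left after restriction")
  per <- lapply(names(sizes), function(chr) {
    k <- floor(sizes[[chr]] / binSize)
    if (k == 0) return(GRanges())
    GRanges(chr, IRanges(start = seq_len(k) * binSize - binSize + 1,
                         width = binSize))
  })
  bins <- suppressWarnings(do.call(c, per))
  seqlengths(bins) <- sizes[seqlevels(bins)]
  mcols(bins)$complete <- TRUE
  mcols(bins)$blacklisted <- FALSE
  if (!is.null(blacklist) && length(blacklist)) {
    unknown <- !as.character(seqnames(blacklist)) %in% names(sizes)
    if (any(unknown)) {
      warning(sum(unknown), " blacklist interval(s) on unknown chromosomes ",
              "ignored")
      blacklist <- blacklist[!unknown]
    }
    if (length(blacklist))
      mcols(bins)$blacklisted <- overlapsAny(bins, blacklist,
                                             minoverlap = 1L,
                                             ignore.strand = TRUE)
  }
  bins <- bins[!mcols(bins)$blacklisted]
  names(bins) <- regionIds(bins)
  if (!is.null(genome)) mcols(bins)$gc <- gcContent(bins, genome)
  bins
}

#' Derive strand-aware promoter intervals
#'
#' The promoter of a gene is the `flank` bp immediately upstream of its
#' transcription start site: `[start - flank, start)` for plus-strand genes
#' and `[end, end + flank)` for minus-strand genes (0-based half-open),
#' truncated at chromosome bounds.
#'
#' @param genes `GRanges` with strand `+` or `-`; names identify genes.
#' @param flank Promoter width in bp (default 1000).
#' @return `GRanges` of promoters, named like `genes`; promoters truncated at
#'   an edge may be shorter than `flank` (possibly zero width).
#' @export
derivePromoters <- function(genes, flank = 1000) {
  st <- as.character(strand(genes))
  bad <- !st %in% c("+", "-")
  if (any(bad)) {
    nm <- names(genes)[bad]
    if (is.null(nm)) nm <- which(bad)
    stop("gene(s) without strand: ", paste(utils::head(nm, 5), collapse = ", "))
  }
  # promoters() warns about out-of-bound ranges at chromosome edges; they are
  # clamped immediately below, so the warning carries no information here
  prom <- suppressWarnings(promoters(genes, upstream = flank, downstream = 0))
  # clamp at chromosome bounds without dropping genes
  GenomicRanges::start(prom) <- pmax(start(prom), 1L)
  sl <- seqlengths(prom)[as.character(seqnames(prom))]
  keep <- !is.na(sl)
  GenomicRanges::end(prom)[keep] <- pmin(end(prom)[keep], sl[keep])
  names(prom) <- names(genes)
  prom
}

#' GC content of intervals
#'
#' Fraction (G + C) / (A + C + G + T) per interval, counting both cases;
#' ambiguous bases are excluded from the denominator.
#'
#' @param intervals `GRanges`.
#' @param genome `DNAStringSet` keyed by chromosome.
#' @return Numeric vector of GC fractions (NaN for intervals with no
#'   unambiguous base).
#' @export
gcContent <- function(intervals, genome) {
  out <- numeric(length(intervals))
  for (chr in unique(as.character(seqnames(intervals)))) {
    if (!chr %in% names(genome))
      stop("no sequence for chromosome ", chr)
    idx <- which(as.character(seqnames(intervals)) == chr)
    if (any(end(intervals)[idx] > length(genome[[chr]])))
      stop("interval beyond end of ", chr)
    v <- Views(genome[[chr]],
               IRanges(start(intervals)[idx], end(intervals)[idx]))
    lf <- letterFrequency(v, c("A", "C", "G", "T"))
    out[idx] <- (lf[, "G"] + lf[, "C"]) / rowSums(lf)
  }
  out
}

# priority used to break exact overlap ties; maximal overlap wins otherwise
.classPriority <- c("promoter", "utr5", "utr3", "exon", "intron",
                    "downstream", "intergenic")

#' Annotate regions with genomic feature classes and nearest genes
#'
#' Each region receives exactly one primary feature class, decided by maximal
#' overlap; equal overlaps are broken by the fixed priority order promoter,
#' 5'UTR, 3'UTR, exon, intron, downstream, intergenic. CpG-island overlap is
#' reported as an additional boolean overlay, mirroring how damage maps are
#' summarized alongside (not instead of) genic context. The nearest gene is
#' the one whose TSS is closest to the region midpoint, with signed distance
#' (positive downstream of the TSS in the gene's orientation).
#'
#' @param regions `GRanges` to annotate.
#' @param features Named list of `GRanges`: must contain `gene` (stranded);
#'   recognized classes are `promoter` (or `upstream`), `utr5`, `utr3`,
#'   `exon`, `intron`, `downstream`, `intergenic`, plus the `cpg_island`
#'   overlay. A missing `intergenic` track is computed as the complement of
#'   gene bodies.
#' @return `data.frame` with columns `region`, `feature_class`, `cpg_island`,
#'   `nearest_gene`, `distance_to_tss`.
#' @export
annotateRegions <- function(regions, features) {
  if (!length(features) || is.null(features$gene) || !length(features$gene))
    stop("features must include a non-empty 'gene' track")
  if (!length(regions)) stop("no regions to annotate")
  feats <- features
  names(feats)[names(feats) == "upstream"] <- "promoter"
  if (is.null(feats$intergenic)) {
    g <- feats$gene
    strand(g) <- "*"
    feats$intergenic <- gaps(reduce(g))
    feats$intergenic <-
      feats$intergenic[strand(feats$intergenic) == "*"]
  }
  classes <- intersect(.classPriority, names(feats))
  ow <- matrix(0, length(regions), length(classes),
               dimnames = list(NULL, classes))
  for (cls in classes) {
    f <- reduce(feats[[cls]], ignore.strand = TRUE)
    hit <- findOverlaps(regions, f, ignore.strand = TRUE)
    if (!length(hit)) next
    w <- width(pintersect(granges(regions)[queryHits(hit)],
                          granges(f)[subjectHits(hit)],
                          ignore.strand = TRUE))
    agg <- tapply(w, queryHits(hit), sum)
    ow[as.integer(names(agg)), cls] <- agg
  }
  best <- max.col(ow, ties.method = "first")  # columns already in priority order
  cls <- classes[best]
  cls[rowSums(ow) == 0] <- "intergenic"
  cpg <- if (!is.null(feats$cpg_island))
    overlapsAny(regions, feats$cpg_island, ignore.strand = TRUE)
  else rep(FALSE, length(regions))
  genes <- feats$gene
  tss <- resize(genes, width = 1L, fix = "start")
  mid <- floor((start(regions) + end(regions)) / 2)
  tssPos <- start(tss)
  nearestGene <- character(length(regions))
  distTss <- integer(length(regions))
  for (chr in unique(as.character(seqnames(regions)))) {
    ri <- which(as.character(seqnames(regions)) == chr)
    gi <- which(as.character(seqnames(tss)) == chr)
    if (!length(gi)) {
      nearestGene[ri] <- NA_character_
      distTss[ri] <- NA_integer_
      next
    }
    d <- abs(outer(mid[ri], tssPos[gi], "-"))
    j <- gi[max.col(-d, ties.method = "first")]
    nearestGene[ri] <- if (!is.null(names(genes))) names(genes)[j]
                       else as.character(j)
    sgn <- ifelse(as.character(strand(genes))[j] == "-", -1L, 1L)
    distTss[ri] <- (mid[ri] - tssPos[j]) * sgn
  }
  rid <- names(regions)
  if (is.null(rid)) rid <- regionIds(regions)
  data.frame(region = rid, feature_class = cls, cpg_island = cpg,
             nearest_gene = nearestGene, distance_to_tss = distTss,
             stringsAsFactors = FALSE)
}

#' Observed/expected feature-class representation
#'
#' Compares the fraction of regions assigned to each primary feature class
#' against the fraction of the genome the class occupies, as
#' log2(observed / expected); a class with no assigned regions is reported as
#' `-Inf`.
#'
#' @param annotation Output of [annotateRegions()].
#' @param features Named list of class `GRanges` (footprints).
#' @param chromSizes Chromosome sizes defining the total considered bp.
#' @return `data.frame` with columns `feature_class`, `observed`, `expected`
#'   (fractions) and `log2_obs_exp`.
#' @export
observedExpected <- function(annotation, features, chromSizes) {
  if (!nrow(annotation)) stop("empty annotation")
  sizes <- .chromSizes(chromSizes)
  total <- sum(as.numeric(sizes))
  names(features)[names(features) == "upstream"] <- "promoter"
  classes <- intersect(.classPriority, names(features))
  footprint <- vapply(classes, function(cls)
    sum(as.numeric(width(reduce(features[[cls]], ignore.strand = TRUE)))),
    numeric(1))
  observed <- vapply(classes, function(cls)
    mean(annotation$feature_class == cls), numeric(1))
  expected <- footprint / total
  if (any(expected == 0 & observed > 0))
    stop("feature class with zero footprint but observed regions: ",
         paste(classes[expected == 0 & observed > 0], collapse = ", "))
  l2 <- ifelse(observed == 0, -Inf, log2(observed / expected))
  data.frame(feature_class = classes, observed = observed,
             expected = expected, log2_obs_exp = l2, row.names = NULL,
             stringsAsFactors = FALSE)
}
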
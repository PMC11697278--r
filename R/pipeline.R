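# Study bundle I/O and the end-to-end pipeline orchestrator.

.writeBed <- function(gr, path, score = NULL) {
  nm <- names(gr)
  if (is.null(nm)) nm <- regionIds(gr)
  if (is.null(score)) score <- rep(0, length(gr))
  st <- as.character(strand(gr))
  st[st == "*"] <- "."
  df <- data.frame(as.character(seqnames(gr)), start(gr) - 1L, end(gr),
                   nm, score, st)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
}

.writeCounts <- function(se, path) {
  m <- assay(se, "counts")
  df <- data.frame(region = rownames(m), m, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

.readCounts <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df$region
  m
}

.parseRegionIds <- function(ids) {
  parts <- regmatches(ids, regexec("^(.+):(\\d+)-(\\d+)$", ids))
  chrom <- vapply(parts, `[`, character(1), 2)
  st <- as.integer(vapply(parts, `[`, character(1), 3))
  en <- as.integer(vapply(parts, `[`, character(1), 4))
  gr <- GRanges(chrom, IRanges(st + 1L, en))
  names(gr) <- ids
  gr
}

.granges2df <- function(gr) {
  data.frame(chrom = as.character(seqnames(gr)), start = start(gr) - 1L,
             end = end(gr), name = if (is.null(names(gr)))
               regionIds(gr) else names(gr),
             strand = as.character(strand(gr)), stringsAsFactors = FALSE)
}

.df2granges <- function(df, sizes = NULL) {
  gr <- GRanges(df$chrom, IRanges(df$start + 1L, df$end),
                strand = ifelse(df$strand %in% c("+", "-"), df$strand, "*"))
  names(gr) <- df$name
  if (!is.null(sizes)) seqlengths(gr) <- sizes[seqlevels(gr)]
  gr
}

#' Write a simulated study bundle to disk
#'
#' Emits the on-disk form of a [simulateStudy()] bundle: genome FASTA,
#' chrom-sizes TSV, BED6 feature tracks, per-region-set OG/input count TSVs,
#' sample sheets, RNA counts, ground-truth JSON and a pipeline `config.yaml`
#' with relative paths.
#'
#' @param bundle A study bundle.
#' @param dir Output directory (created).
#' @return Invisibly, the path to `config.yaml`.
#' @export
writeStudy <- function(bundle, dir) {
  dir.create(file.path(dir, "features"), recursive = TRUE,
             showWarnings = FALSE)
  dir.create(file.path(dir, "counts"), showWarnings = FALSE)
  writeXStringSet(bundle$genome, file.path(dir, "genome.fa"))
  utils::write.table(
    data.frame(names(bundle$chrom_sizes), unname(bundle$chrom_sizes)),
    file.path(dir, "chrom_sizes.tsv"), sep = "\t", quote = FALSE,
    row.names = FALSE, col.names = FALSE)
  for (cls in names(bundle$features))
    .writeBed(bundle$features[[cls]],
              file.path(dir, "features", paste0(cls, ".bed")))
  cd <- as.data.frame(colData(bundle$binCounts))
  cd$sample <- colnames(bundle$binCounts)
  utils::write.table(cd[, c("sample", "genotype", "clone", "bio_rep",
                            "assay_type")],
                     file.path(dir, "samples_og.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  .writeCounts(bundle$binCounts, file.path(dir, "counts", "bins.tsv"))
  for (cls in names(bundle$regionCounts))
    .writeCounts(bundle$regionCounts[[cls]],
                 file.path(dir, "counts", paste0(cls, ".tsv")))
  utils::write.table(
    data.frame(gene = rownames(bundle$rna$counts), bundle$rna$counts,
               check.names = FALSE),
    file.path(dir, "rna_counts.tsv"), sep = "\t", quote = FALSE,
    row.names = FALSE)
  utils::write.table(bundle$rna$sampleInfo, file.path(dir, "samples_rna.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  truth <- bundle$truth
  truthOut <- truth
  truthOut$g4 <- .granges2df(truth$g4)
  jsonlite::write_json(truthOut, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA)
  config <- bundle$config
  config$paths <- list(
    genome = "genome.fa", chrom_sizes = "chrom_sizes.tsv",
    features = "features", counts = "counts",
    samples_og = "samples_og.tsv", rna_counts = "rna_counts.tsv",
    samples_rna = "samples_rna.tsv", truth = "truth.json")
  yaml::write_yaml(config, file.path(dir, "config.yaml"))
  invisible(file.path(dir, "config.yaml"))
}

#' Read a study bundle from a pipeline config file
#'
#' @param configPath Path to a `config.yaml` written by [writeStudy()] (or
#'   hand-written with the same layout).
#' @return A study bundle as produced by [simulateStudy()] (without `bins`).
#' @export
readStudy <- function(configPath) {
  config <- yaml::read_yaml(configPath)
  base <- dirname(configPath)
  rel <- function(p) file.path(base, p)
  genome <- readDNAStringSet(rel(config$paths$genome))
  names(genome) <- sub("\\s.*", "", names(genome))
  cs <- utils::read.delim(rel(config$paths$chrom_sizes), header = FALSE)
  sizes <- stats::setNames(as.integer(cs[[2]]), cs[[1]])
  featDir <- rel(config$paths$features)
  features <- list()
  for (f in sort(list.files(featDir, pattern = "\\.bed$"))) {
    cls <- sub("\\.bed$", "", f)
    bed <- utils::read.delim(file.path(featDir, f), header = FALSE)
    names(bed)[1:6] <- c("chrom", "start", "end", "name", "score", "strand")
    features[[cls]] <- .df2granges(bed, sizes)
  }
  sheet <- utils::read.delim(rel(config$paths$samples_og))
  countsDir <- rel(config$paths$counts)
  mkSE <- function(path, regions = NULL) {
    m <- .readCounts(path)
    missing <- setdiff(sheet$sample, colnames(m))
    if (length(missing))
      stop("count table ", basename(path), " lacks sample(s): ",
           paste(missing, collapse = ", "))
    m <- m[, sheet$sample, drop = FALSE]
    if (is.null(regions)) {
      regions <- .parseRegionIds(rownames(m))
      seqlengths(regions) <- sizes[seqlevels(regions)]
    }
    DamageExperiment(m, regions, sheet[, c("genotype", "clone", "bio_rep",
                                           "assay_type")])
  }
  binSE <- mkSE(file.path(countsDir, "bins.tsv"))
  regionCounts <- list()
  for (f in sort(list.files(countsDir, pattern = "\\.tsv$"))) {
    cls <- sub("\\.tsv$", "", f)
    if (cls == "bins") next
    regions <- NULL
    if (cls == "upstream") {
      up <- features$upstream
      m <- .readCounts(file.path(countsDir, f))
      regions <- up[match(rownames(m), names(up))]
    }
    regionCounts[[cls]] <- mkSE(file.path(countsDir, f), regions)
  }
  rnaM <- utils::read.delim(rel(config$paths$rna_counts),
                            check.names = FALSE)
  rnaCounts <- as.matrix(rnaM[, -1, drop = FALSE])
  rownames(rnaCounts) <- rnaM$gene
  rnaInfo <- utils::read.delim(rel(config$paths$samples_rna))
  truth <- NULL
  if (!is.null(config$paths$truth) && file.exists(rel(config$paths$truth))) {
    truth <- jsonlite::read_json(rel(config$paths$truth),
                                 simplifyVector = TRUE)
    if (!is.null(truth$g4)) truth$g4 <- .df2granges(truth$g4, sizes)
  }
  list(genome = genome, chrom_sizes = sizes, features = features,
       binCounts = binSE, regionCounts = regionCounts,
       rna = list(counts = rnaCounts, sampleInfo = rnaInfo),
       truth = truth, config = config)
}

# validate that the OG sample sheet covers the full design
.validateDesign <- function(se, genotypes) {
  cd <- as.data.frame(colData(se))
  for (g in genotypes)
    for (cl in unique(cd$clone))
      for (b in unique(cd$bio_rep))
        for (a in c("OG", "input"))
          if (!any(cd$genotype == g & cd$clone == cl & cd$bio_rep == b &
                     cd$assay_type == a))
            stop("sample sheet misses cell (genotype=", g, ", clone=", cl,
                 ", bio_rep=", b, ", assay=", a, ")")
  invisible(TRUE)
}

#' Run the full OG-seq analysis pipeline
#'
#' Executes the stages in dependency order on a study bundle: enriched-bin
#' calling (SES normalization, percentile thresholding, replicate consensus,
#' bookended-bin merging) with GC, feature and G4 annotation and
#' observed/expected summaries; library factors; per-feature-class
#' differential OG enrichment of every knockout genotype against the
#' reference, including G4 windows; RNA differential expression; and the
#' promoter OG/expression concordance clustering with DER/DEG fold-change
#' correlation. All outputs are plain-text tables under `outdir` plus a
#' parameter manifest; re-running on the same inputs reproduces them
#' byte-identically.
#'
#' @param input A study bundle (from [simulateStudy()] / [readStudy()]) or
#'   the path to a `config.yaml`.
#' @param outdir Output directory.
#' @return Invisibly, a list with the main in-memory results (`ebs`,
#'   `obs_exp`, `ders`, `degs`, `concordance`, `der_deg`, `eb_g4`).
#' @export
runPipeline <- function(input, outdir) {
  bundle <- if (is.character(input)) readStudy(input) else input
  config <- bundle$config
  genotypes <- config$genotypes
  reference <- config$reference
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  logLines <- character()
  note <- function(...) {
    m <- paste0(...)
    message(m)
    logLines <<- c(logLines, m)
  }
  out <- function(f) file.path(outdir, f)
  tsv <- function(df, f) utils::write.table(df, out(f), sep = "\t",
                                            quote = FALSE, row.names = FALSE)

  .validateDesign(bundle$binCounts, genotypes)
  note("stage validate: ", ncol(bundle$binCounts), " OG/input samples, ",
       length(genotypes), " genotypes")

  note("stage call-ebs: ", nrow(bundle$binCounts), " bins")
  ebs <- callEnrichedBins(bundle$binCounts, percentile = config$percentile,
                          pseudocount = config$pseudocount,
                          minBioReps = config$min_bio_reps)
  note("stage g4: scanning genome in ", config$g4_window, " bp windows")
  g4win <- g4WindowSet(bundle$genome, config$g4_window)
  annFeatures <- bundle$features

  obsExp <- list(); ebSummary <- list()
  for (g in genotypes) {
    regions <- ebs[[g]]$regions
    if (length(regions)) {
      mcols(regions)$gc <- gcContent(regions, bundle$genome)
      ann <- annotateRegions(regions, annFeatures)
      mcols(regions)$feature_class <- ann$feature_class
      mcols(regions)$cpg_island <- ann$cpg_island
      mcols(regions)$nearest_gene <- ann$nearest_gene
      mcols(regions)$contains_g4 <- overlapsAny(
        regions, g4win[mcols(g4win)$has_motif], ignore.strand = TRUE)
      ebs[[g]]$regions <- regions
      obsExp[[g]] <- cbind(genotype = g,
                           observedExpected(ann, annFeatures,
                                            bundle$chrom_sizes))
      .writeBed(regions, out(paste0("ebs_", g, ".bed")),
                score = round(mcols(regions)$mean_log2_ratio, 4))
      tsv(cbind(region = names(regions),
                as.data.frame(mcols(regions))),
          paste0("ebs_", g, ".tsv"))
    }
    ebSummary[[g]] <- data.frame(
      genotype = g, n_regions = length(regions),
      n_bins = length(ebs[[g]]$bins),
      mean_gc = if (length(regions)) mean(mcols(regions)$gc) else NA_real_,
      mean_log2_ratio = if (length(regions))
        mean(mcols(regions)$mean_log2_ratio) else NA_real_)
    note("stage call-ebs: ", g, ": ", length(ebs[[g]]$bins),
         " consensus bins -> ", length(regions), " regions")
  }
  tsv(do.call(rbind, ebSummary), "ebs_summary.tsv")
  if (length(obsExp)) tsv(do.call(rbind, obsExp), "observed_expected.tsv")

  ebG4 <- ebG4Overlap(lapply(ebs, `[[`, "regions"), g4win)
  tsv(data.frame(genotype = names(ebG4), fraction_with_g4 = unname(ebG4)),
      "eb_g4_overlap.tsv")
  .writeBed(g4win[mcols(g4win)$has_motif], out("g4_windows.bed"),
            score = mcols(g4win)$n_motifs[mcols(g4win)$has_motif])

  # SES factors (from the genome-wide bin fits) and library factors
  sesF <- unlist(lapply(ebs, function(e)
    vapply(e$ses, inputScaleFactor, numeric(1))))
  names(sesF) <- unlist(lapply(ebs, function(e) names(e$ses)))
  cd <- as.data.frame(colData(bundle$binCounts))
  ogCols <- colnames(bundle$binCounts)[cd$assay_type == "OG"]
  libF <- libraryFactors(colSums(assay(bundle$binCounts,
                                       "counts")[, ogCols]))
  tsv(data.frame(sample = names(libF), library_factor = unname(libF)),
      "library_factors.tsv")
  tsv(data.frame(sample = names(sesF), ses_factor = unname(sesF)),
      "ses_factors.tsv")

  note("stage der: ", length(bundle$regionCounts), " feature classes")
  derTables <- list(); derSummaries <- list()
  for (cls in names(bundle$regionCounts)) {
    se <- bundle$regionCounts[[cls]]
    pairs <- samplePairs(se)
    m <- assay(se, "counts")
    damage <- vapply(seq_len(nrow(pairs)), function(i)
      subtractInput(m[, pairs$og[i]],
                    m[, pairs$input[i]] * sesF[[pairs$og[i]]]),
      numeric(nrow(m)))
    colnames(damage) <- pairs$og
    regions <- rowRanges(se)
    ann <- annotateRegions(regions, annFeatures)
    for (g in setdiff(genotypes, reference)) {
      aCols <- pairs$og[pairs$genotype == g]
      bCols <- pairs$og[pairs$genotype == reference]
      keep <- filterLowReads(damage[, c(aCols, bCols), drop = FALSE],
                             config$min_total)
      if (!any(keep)) next
      sub <- damage[keep, c(aCols, bCols), drop = FALSE]
      disp <- estimateTrendedDispersion(
        sub, rep(c("A", "B"), c(length(aCols), length(bCols))),
        libF[c(aCols, bCols)])
      res <- nbExactTest(damage[keep, aCols, drop = FALSE],
                         damage[keep, bCols, drop = FALSE],
                         factorsA = libF[aCols], factorsB = libF[bCols],
                         dispersion = disp)
      res$region <- rownames(m)[keep]
      res$feature_class <- cls
      res$contrast <- paste0(g, "_vs_", reference)
      res$gene <- ann$nearest_gene[keep]
      called <- callDERs(res, pMax = config$der_p, lfcMin = config$der_lfc)
      derTables[[paste(cls, g, sep = ".")]] <- called$table
      derSummaries[[paste(cls, g, sep = ".")]] <-
        cbind(contrast = paste0(g, "_vs_", reference), called$summary)
      note("stage der: ", cls, " ", g, "_vs_", reference, ": ",
           sum(called$table$passes), "/", sum(keep), " DERs")
    }
  }
  derAll <- do.call(rbind, derTables)
  rownames(derAll) <- NULL
  tsv(derAll[, c("region", "feature_class", "contrast", "gene", "log2FC",
                 "p_value", "fdr", "passes", "direction")], "ders.tsv")
  tsv(do.call(rbind, derSummaries), "ders_summary.tsv")

  note("stage rna-de")
  degTables <- list(); degSets <- list()
  rnaGroups <- bundle$rna$sampleInfo$genotype[
    match(colnames(bundle$rna$counts), bundle$rna$sampleInfo$sample)]
  for (g in setdiff(genotypes, reference)) {
    dd <- rnaDE(bundle$rna$counts, rnaGroups, c(g, reference),
                pMax = config$deg_p, lfcMin = config$deg_lfc)
    dd$contrast <- paste0(g, "_vs_", reference)
    degTables[[g]] <- dd
    degSets[[g]] <- dd$gene[dd$is_deg]
    note("stage rna-de: ", g, ": ", sum(dd$is_deg), " DEGs")
  }
  degAll <- do.call(rbind, degTables)
  rownames(degAll) <- NULL
  tsv(degAll, "degs.tsv")
  ov <- degOverlap(degSets)
  jsonlite::write_json(
    list(pairwise = ov$pairwise, common = ov$common,
         union_size = ov$union_size, shared_fraction = ov$shared_fraction),
    out("deg_overlap.json"), auto_unbox = TRUE, digits = NA, matrix = "rowmajor")

  note("stage integrate")
  prom <- bundle$regionCounts$upstream
  pairs <- samplePairs(prom)
  ogSig <- promoterSignal(
    assay(prom, "counts")[, pairs$og, drop = FALSE],
    assay(prom, "counts")[, pairs$input, drop = FALSE],
    pairs, sesF[pairs$og], libF[pairs$og])
  ogSig <- ogSig[, genotypes, drop = FALSE]
  rnaF <- libraryFactors(colSums(bundle$rna$counts))
  rnaNorm <- sweep(bundle$rna$counts, 2, rnaF, "/")
  rnaGeno <- vapply(genotypes, function(g)
    rowMeans(rnaNorm[, rnaGroups == g, drop = FALSE]),
    numeric(nrow(rnaNorm)))
  genes <- filterPresent(ogSig, rnaGeno, minGenotypes = 3)
  note("stage integrate: ", length(genes), " genes present in both assays")
  minCl <- if (!is.null(config$min_cluster_size)) config$min_cluster_size
           else 20
  conc <- concordanceCluster(ogSig[genes, , drop = FALSE],
                             rnaGeno[genes, , drop = FALSE],
                             k = config$k_clusters, minClusterSize = minCl)
  tsv(conc$records, "concordance.tsv")
  tsv(conc$clusters, "concordance_clusters.tsv")
  note("stage integrate: ",
       sum(conc$records$classification == "positive"), " positive / ",
       sum(conc$records$classification == "negative"),
       " negative concordant genes")

  derSub <- derAll[derAll$feature_class %in%
                     c("cpg_island", "upstream", "exon") &
                     !is.na(derAll$gene), ]
  dd <- derDegCorrelation(
    derSub[, c("gene", "contrast", "feature_class", "log2FC", "passes")],
    degAll[, c("gene", "contrast", "log2FC", "is_deg")])
  if (!is.null(dd$correlation)) {
    tsv(dd$pairs, "der_deg_pairs.tsv")
    tsv(dd$correlation, "der_deg_correlation.tsv")
    tsv(dd$overlap, "der_deg_overlap.tsv")
  }

  manifest <- list(
    package = "ogmap",
    version = as.character(utils::packageVersion("ogmap")),
    parameters = config[setdiff(names(config), "paths")],
    n_bins = nrow(bundle$binCounts),
    feature_classes = names(bundle$regionCounts))
  jsonlite::write_json(manifest, out("manifest.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  writeLines(logLines, out("run.log"))
  invisible(list(ebs = ebs, obs_exp = obsExp, ders = derAll,
                 der_summary = do.call(rbind, derSummaries),
                 degs = degAll, deg_overlap = ov, concordance = conc,
                 der_deg = dd, eb_g4 = ebG4, ses_factors = sesF,
                 library_factors = libF))
}

#' Digest of a pipeline output directory
#'
#' MD5 checksums of every regular file under `dir` (sorted by relative
#' path), used to verify byte-identical reproduction of a run.
#'
#' @param dir Output directory of [runPipeline()].
#' @return Named character vector of MD5 digests keyed by relative path.
#' @export
pipelineDigest <- function(dir) {
  files <- sort(list.files(dir, recursive = TRUE, full.names = FALSE))
  md5 <- tools::md5sum(file.path(dir, files))
  stats::setNames(unname(md5), files)
}
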
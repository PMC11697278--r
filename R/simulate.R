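# Synthetic OG-seq / RNA-seq study generator with known ground truth.
# Every emitted artifact draws from its own RNG stream (seed + stable hash
# of the artifact name), so adding samples never perturbs existing ones.

.sampleSeq <- function(n, gc) {
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  sample(names(p), n, replace = TRUE, prob = p)
}

# Break every G or C run of length >= 3 outside protected spans, so planted
# canonical motifs are the only G4 instances on either strand.
.breakRuns <- function(chars, protected) {
  for (base in c("G", "C")) {
    r <- rle(chars == base)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    long <- which(r$values & r$lengths >= 3L)
    if (!length(long)) next
    at <- sequence(floor(r$lengths[long] / 3), from = starts[long] + 2L,
                   by = 3L)
    at <- at[!protected[at]]
    chars[at] <- if (base == "G") "T" else "A"
  }
  chars
}

#' Simulate a genome with annotations and planted G4 motifs
#'
#' Emits random chromosome sequences at genomic GC content (0.41) with
#' GC-elevated CpG islands, strand-assigned genes partitioned exactly into
#' exons and introns (with 5'/3' UTR-like fragments of the terminal exons),
#' 1 kb upstream/downstream flanks, the intergenic complement, a blacklist
#' track, and canonical G4 motifs planted at known positions. Background G/C
#' runs of three or more bases are disrupted outside planted motifs, so the
#' planted set is exactly the set of canonical-motif instances on either
#' strand — a requirement for exact ground-truth recovery.
#'
#' @param cfg A [SimConfig-class].
#' @return List with `genome` (`DNAStringSet`), `chrom_sizes` (named
#'   integer), `features` (named list of `GRanges`: gene, exon, intron,
#'   upstream, downstream, utr5, utr3, intergenic, cpg_island, blacklist) and
#'   `truth` (list with `g4` motif spans, per-gene structure).
#' @export
simulateGenome <- function(cfg) {
  validObject(cfg)
  seed <- cfg@seed
  sizes <- stats::setNames(rep(as.integer(cfg@chrom_length), cfg@n_chroms),
                           paste0("chr", seq_len(cfg@n_chroms)))
  nGenesPer <- diff(round(seq(0, cfg@n_genes, length.out = cfg@n_chroms + 1)))
  minGeneLen <- 2000; maxGeneLen <- 6000; geneGap <- 2500
  if (any(nGenesPer * maxGeneLen + (nGenesPer + 1) * geneGap > sizes))
    stop("chrom_length too small to place n_genes genes")

  chars <- list(); islands <- list(); genes <- list()
  exons <- list(); introns <- list(); utr5 <- list(); utr3 <- list()
  blacklist <- list(); g4 <- list()
  geneCounter <- 0L

  for (ci in seq_along(sizes)) {
    chr <- names(sizes)[ci]; len <- sizes[[ci]]
    .setStream(seed, paste0("seq_", chr))
    s <- .sampleSeq(len, 0.409)

    # CpG islands: non-overlapping, GC 0.65
    .setStream(seed, paste0("cpg_", chr))
    target <- cfg@cpg_island_frac * len
    isl <- IRanges()
    guard <- 0L
    while (sum(width(isl)) < target && guard < 10000L) {
      w <- round(stats::runif(1, 500, 1500))
      st <- sample.int(len - w, 1L)
      cand <- IRanges(st, st + w - 1L)
      if (!any(overlapsAny(cand, isl))) isl <- c(isl, cand)
      guard <- guard + 1L
    }
    isl <- BiocGenerics::sort(isl)
    for (j in seq_along(isl))
      s[start(isl)[j]:end(isl)[j]] <- .sampleSeq(width(isl)[j], 0.65)
    islands[[chr]] <- GRanges(chr, isl)

    # genes with guaranteed flanking room
    .setStream(seed, paste0("genes_", chr))
    k <- nGenesPer[ci]
    if (k > 0) {
      glen <- sample(minGeneLen:maxGeneLen, k, replace = TRUE)
      slack <- len - sum(glen) - (k + 1) * geneGap
      u <- stats::runif(k + 1)
      extra <- floor(slack * u / sum(u))
      pos <- 0L; gstart <- integer(k)
      for (i in seq_len(k)) {
        gstart[i] <- pos + geneGap + extra[i] + 1L
        pos <- gstart[i] + glen[i] - 1L
      }
      gstrand <- sample(c("+", "-"), k, replace = TRUE)
      ids <- sprintf("g%04d", geneCounter + seq_len(k))
      geneCounter <- geneCounter + k
      gg <- GRanges(chr, IRanges(gstart, width = glen), strand = gstrand)
      names(gg) <- ids
      genes[[chr]] <- gg

      # exon/intron partition per gene (alternating, exon at both ends);
      # coordinates accumulated as plain vectors, one GRanges per track
      exS <- integer(0); exE <- integer(0); exStr <- character(0)
      exId <- character(0)
      inS <- integer(0); inE <- integer(0); inStr <- character(0)
      inId <- character(0)
      u5S <- integer(k); u5E <- integer(k); u3S <- integer(k)
      u3E <- integer(k)
      for (i in seq_len(k)) {
        nEx <- sample(2:6, 1L)
        nSeg <- 2L * nEx - 1L
        repeat {
          cuts <- sort(sample.int(glen[i] - 1L, nSeg - 1L))
          w <- diff(c(0L, cuts, glen[i]))
          if (all(w >= 30L)) break
        }
        segEnd <- gstart[i] - 1L + cumsum(w)
        segStart <- segEnd - w + 1L
        isEx <- seq_len(nSeg) %% 2L == 1L
        exS <- c(exS, segStart[isEx]); exE <- c(exE, segEnd[isEx])
        exStr <- c(exStr, rep(gstrand[i], sum(isEx)))
        exId <- c(exId, rep(ids[i], sum(isEx)))
        if (any(!isEx)) {
          inS <- c(inS, segStart[!isEx]); inE <- c(inE, segEnd[!isEx])
          inStr <- c(inStr, rep(gstrand[i], sum(!isEx)))
          inId <- c(inId, rep(ids[i], sum(!isEx)))
        }
        # UTR-like fragments of the terminal exons (transcript orientation)
        es <- segStart[isEx]; ee <- segEnd[isEx]
        nE <- length(es)
        if (gstrand[i] == "+") {
          w5 <- min(100L, floor((ee[1] - es[1] + 1L) / 2))
          u5S[i] <- es[1]; u5E[i] <- es[1] + w5 - 1L
          w3 <- min(200L, floor((ee[nE] - es[nE] + 1L) / 2))
          u3S[i] <- ee[nE] - w3 + 1L; u3E[i] <- ee[nE]
        } else {
          w5 <- min(100L, floor((ee[nE] - es[nE] + 1L) / 2))
          u5S[i] <- ee[nE] - w5 + 1L; u5E[i] <- ee[nE]
          w3 <- min(200L, floor((ee[1] - es[1] + 1L) / 2))
          u3S[i] <- es[1]; u3E[i] <- es[1] + w3 - 1L
        }
      }
      exons[[chr]] <- GRanges(chr, IRanges(exS, exE), strand = exStr)
      names(exons[[chr]]) <- exId
      introns[[chr]] <- GRanges(chr, IRanges(inS, inE), strand = inStr)
      if (length(inId)) names(introns[[chr]]) <- inId
      utr5[[chr]] <- GRanges(chr, IRanges(u5S, u5E), strand = gstrand)
      utr3[[chr]] <- GRanges(chr, IRanges(u3S, u3E), strand = gstrand)
      names(utr5[[chr]]) <- ids; names(utr3[[chr]]) <- ids
    } else {
      genes[[chr]] <- GRanges(); exons[[chr]] <- GRanges()
      introns[[chr]] <- GRanges(); utr5[[chr]] <- GRanges()
      utr3[[chr]] <- GRanges()
    }

    # blacklist: two anomalous 2 kb intervals per chromosome
    .setStream(seed, paste0("blacklist_", chr))
    bst <- sample.int(len - 2000L, 2L)
    blacklist[[chr]] <- reduce(GRanges(chr, IRanges(bst, width = 2000L)))

    # planted canonical G4 motifs, one per distinct 100 bp window
    .setStream(seed, paste0("g4_", chr))
    nMotif <- round(cfg@g4_density * len / 1e4)
    if (nMotif > 0) {
      nWin <- floor(len / 100)
      wins <- sort(sample.int(nWin, nMotif))
      mstr <- character(nMotif); mlen <- integer(nMotif)
      mstart <- integer(nMotif); strands <- character(nMotif)
      for (i in seq_len(nMotif)) {
        stems <- sample(3:4, 4L, replace = TRUE)
        loops <- sample(1:7, 3L, replace = TRUE)
        motif <- character(0)
        for (j in 1:4) {
          motif <- c(motif, rep("G", stems[j]))
          if (j < 4) motif <- c(motif, sample(c("A", "C", "T"), loops[j],
                                              replace = TRUE))
        }
        strands[i] <- sample(c("+", "-"), 1L)
        if (strands[i] == "-")
          motif <- rev(chartr("ACGT", "TGCA", motif))
        mlen[i] <- length(motif)
        off <- sample(3:(96 - mlen[i]), 1L)
        mstart[i] <- (wins[i] - 1L) * 100L + off
        span <- mstart[i]:(mstart[i] + mlen[i] - 1L)
        s[span] <- motif
        # non-G/C flanks so the planted span is exactly the motif instance
        fl <- c(mstart[i] - (2:1), mstart[i] + mlen[i] - 1L + (1:2))
        s[fl[fl >= 1 & fl <= len]] <- "A"
      }
      g4[[chr]] <- GRanges(chr, IRanges(mstart, width = mlen),
                           strand = strands)
    } else g4[[chr]] <- GRanges()

    protected <- logical(len)
    if (length(g4[[chr]]))
      for (j in seq_along(g4[[chr]]))
        protected[start(g4[[chr]])[j]:end(g4[[chr]])[j]] <- TRUE
    s <- .breakRuns(s, protected)
    chars[[chr]] <- s
  }

  genome <- DNAStringSet(vapply(chars, paste, character(1), collapse = ""))
  names(genome) <- names(sizes)
  cat0 <- function(lst) {
    gr <- suppressWarnings(do.call(c, unname(lst)))
    seqlengths(gr) <- sizes[seqlevels(gr)]
    gr
  }
  geneGr <- cat0(genes)
  feats <- list(
    gene = geneGr,
    exon = cat0(exons), intron = cat0(introns),
    utr5 = cat0(utr5), utr3 = cat0(utr3),
    upstream = derivePromoters(geneGr, 1000),
    cpg_island = cat0(islands),
    blacklist = cat0(blacklist)
  )
  down <- GenomicRanges::flank(geneGr, 1000, start = FALSE)
  GenomicRanges::start(down) <- pmax(start(down), 1L)
  sl <- sizes[as.character(seqnames(down))]
  GenomicRanges::end(down) <- pmin(end(down), sl)
  feats$downstream <- down
  ug <- geneGr; strand(ug) <- "*"
  inter <- gaps(reduce(ug))
  feats$intergenic <- inter[strand(inter) == "*"]
  list(genome = genome, chrom_sizes = sizes, features = feats,
       truth = list(g4 = cat0(g4)))
}

.sampleSheet <- function(cfg) {
  grid <- expand.grid(bio_rep = seq_len(cfg@n_bio_reps),
                      clone = seq_len(cfg@n_tech_reps),
                      genotype = cfg@genotypes,
                      stringsAsFactors = FALSE)
  grid <- grid[order(match(grid$genotype, cfg@genotypes), grid$clone,
                     grid$bio_rep), ]
  og <- transform(grid, assay_type = "OG")
  inp <- transform(grid, assay_type = "input")
  sheet <- rbind(og, inp)
  sheet$sample <- sprintf("%s_c%d_b%d_%s", sheet$genotype, sheet$clone,
                          sheet$bio_rep, sheet$assay_type)
  rownames(sheet) <- sheet$sample
  sheet
}

.libFactor <- function(cfg, sampleId) {
  .setStream(cfg@seed, paste0("libfac_", sampleId))
  stats::runif(1, cfg@library_factor_range[1], cfg@library_factor_range[2])
}

#' Simulate OG pulldown and input counts over a region set
#'
#' Input counts are NB-distributed around the background mean times a
#' per-sample library factor; OG counts share the background mean scaled by
#' the pair's pulldown/input factor, multiplied by `enrichment_fold` at
#' planted enriched bins (bin sets; sampled preferentially from GC-rich
#' bins), by `der_fold` (gain) or its inverse (loss) at planted differential
#' regions of knockout genotypes (feature sets), and by the genotype damage
#' profile at the promoters of planted OG/RNA-coupled genes (`upstream`
#' set). Each sample is an independent NB draw from its own RNG stream.
#'
#' @param cfg A [SimConfig-class].
#' @param regions `GRanges` of bins or feature regions; names key the truth
#'   sets (for `regionType = "upstream"`, names must be gene ids).
#' @param truth Accumulating ground-truth list (pass the result of
#'   [simulateGenome()]'s `truth`, then thread through calls).
#' @param regionType One of `"bins"`, `"cpg_island"`, `"upstream"`, `"exon"`,
#'   `"intron"`, `"downstream"`, `"intergenic"`, `"g4"`.
#' @return List with `se` (a [DamageExperiment-class]) and the updated
#'   `truth` (planted sets, true per-pair SES factors, per-sample library
#'   factors).
#' @export
simulateOGCounts <- function(cfg, regions, truth = list(),
                             regionType = "bins") {
  validObject(cfg)
  seed <- cfg@seed
  sheet <- .sampleSheet(cfg)
  n <- length(regions)
  ids <- names(regions)
  if (is.null(ids)) ids <- regionIds(regions)

  if (is.null(truth$library_factors)) truth$library_factors <- numeric(0)
  for (s in sheet$sample)
    if (is.na(truth$library_factors[s]))
      truth$library_factors[s] <- .libFactor(cfg, s)

  pairsKey <- unique(sprintf("%s_c%d_b%d", sheet$genotype, sheet$clone,
                             sheet$bio_rep))
  if (is.null(truth$ses_base)) truth$ses_base <- numeric(0)
  for (p in pairsKey)
    if (is.na(truth$ses_base[p])) {
      .setStream(seed, paste0("sesfac_", p))
      truth$ses_base[p] <- stats::runif(1, cfg@ses_factor_range[1],
                                        cfg@ses_factor_range[2])
    }
  truth$true_ses_factor <- truth$ses_base *
    truth$library_factors[paste0(pairsKey, "_OG")] /
    truth$library_factors[paste0(pairsKey, "_input")]
  names(truth$true_ses_factor) <- pairsKey

  baseMu <- if (regionType == "bins") rep(cfg@background_mean, n)
            else cfg@der_region_mean * pmin(pmax(width(regions), 1) / 1000, 10)

  # planted structure
  if (regionType == "bins" && is.null(truth$enriched_bins)) {
    truth$enriched_bins <- list()
    gc <- mcols(regions)$gc
    w <- if (!is.null(gc)) rank(gc, ties.method = "first")^3 else rep(1, n)
    nEnr <- round(cfg@frac_enriched_bins * n)
    for (g in cfg@genotypes) {
      .setStream(seed, paste0("enriched_", g))
      truth$enriched_bins[[g]] <- ids[sample.int(n, nEnr, prob = w)]
    }
  }
  if (regionType == "upstream" && is.null(truth$correlated)) {
    .setStream(seed, "corr_genes")
    pick <- sample(ids, cfg@n_pos_corr_genes + cfg@n_neg_corr_genes)
    truth$correlated <- list(
      positive = pick[seq_len(cfg@n_pos_corr_genes)],
      negative = pick[cfg@n_pos_corr_genes + seq_len(cfg@n_neg_corr_genes)])
  }
  if (!regionType %in% "bins") {
    if (is.null(truth$der)) truth$der <- list()
    if (is.null(truth$der[[regionType]])) {
      truth$der[[regionType]] <- list()
      nDer <- round(cfg@frac_der_regions * n)
      # DER truth stays disjoint from the OG/RNA-coupled promoters so the
      # two planted signals never confound each other
      pool <- setdiff(ids, c(truth$correlated$positive,
                             truth$correlated$negative))
      for (g in cfg@genotypes[-1]) {
        .setStream(seed, paste0("der_", regionType, "_", g))
        pick <- sample(pool, nDer)
        dir <- rep(c("gain", "loss"), length.out = nDer)
        truth$der[[regionType]][[g]] <-
          data.frame(region = pick, direction = dir,
                     stringsAsFactors = FALSE)
      }
    }
  }

  disp <- if (regionType == "bins") cfg@dispersion else cfg@region_dispersion
  counts <- matrix(0L, n, nrow(sheet),
                   dimnames = list(ids, sheet$sample))
  profile <- stats::setNames(cfg@damage_profile, cfg@genotypes)
  for (i in seq_len(nrow(sheet))) {
    si <- sheet[i, ]
    lf <- truth$library_factors[si$sample]
    if (si$assay_type == "input") {
      mu <- baseMu * lf
    } else {
      pairKey <- sprintf("%s_c%d_b%d", si$genotype, si$clone, si$bio_rep)
      mult <- rep(1, n)
      if (regionType == "bins") {
        mult[ids %in% truth$enriched_bins[[si$genotype]]] <-
          cfg@enrichment_fold
      } else {
        d <- truth$der[[regionType]][[si$genotype]]
        if (!is.null(d)) {
          mult[ids %in% d$region[d$direction == "gain"]] <- cfg@der_fold
          mult[ids %in% d$region[d$direction == "loss"]] <- 1 / cfg@der_fold
        }
        if (regionType == "upstream") {
          corr <- c(truth$correlated$positive, truth$correlated$negative)
          mult[ids %in% corr] <- mult[ids %in% corr] *
            profile[si$genotype]
        }
      }
      mu <- baseMu * truth$ses_base[pairKey] * lf * mult
    }
    .setStream(seed, paste0("counts_", regionType, "_", si$sample))
    counts[, i] <- .rnbinomMu(n, mu, disp)
  }
  se <- DamageExperiment(counts, regions,
                         sheet[, c("genotype", "clone", "bio_rep",
                                   "assay_type")])
  list(se = se, truth = truth)
}

#' Simulate RNA counts coupled to promoter damage
#'
#' Baseline expression per gene is log-normal around the configured mean.
#' For planted positively coupled genes, the per-genotype expression mean is
#' a linear increasing function of that genotype's promoter OG z-score
#' (`pmax(0.05, 1 + slope * z)` times baseline); decreasing for the negative
#' set. Designated genotype-specific genes carry a planted `deg_fold` change.
#' All counts are independent NB draws per sample.
#'
#' @param cfg A [SimConfig-class].
#' @param truth Ground-truth list carrying `correlated` gene sets (from
#'   [simulateOGCounts()] on the promoter set).
#' @param ogPromoterSignal Gene x genotype matrix of promoter damage signal.
#' @return List with `counts` (gene x sample matrix), `sampleInfo` and the
#'   updated `truth` (planted DEG sets with direction).
#' @export
simulateRNACounts <- function(cfg, truth, ogPromoterSignal) {
  validObject(cfg)
  seed <- cfg@seed
  genes <- rownames(ogPromoterSignal)
  nG <- length(genes)
  if (cfg@n_pos_corr_genes + cfg@n_neg_corr_genes +
      cfg@n_deg_genes * (length(cfg@genotypes) - 1) > nG)
    stop("planted gene sets exceed the number of genes")
  z <- .rowZ(ogPromoterSignal[, cfg@genotypes, drop = FALSE])
  z[is.na(z)] <- 0

  .setStream(seed, "rna_baseline")
  baseline <- stats::rlnorm(nG, log(cfg@rna_baseline_mean), 0.6)

  if (is.null(truth$deg)) {
    truth$deg <- list()
    avoid <- c(truth$correlated$positive, truth$correlated$negative)
    for (g in cfg@genotypes[-1]) {
      .setStream(seed, paste0("deg_genes_", g))
      pool <- setdiff(genes, c(avoid, unlist(lapply(truth$deg,
                                                    `[[`, "gene"))))
      pick <- sample(pool, cfg@n_deg_genes)
      truth$deg[[g]] <- data.frame(
        gene = pick,
        direction = sample(c("up", "down"), cfg@n_deg_genes, replace = TRUE),
        stringsAsFactors = FALSE)
    }
  }

  mult <- matrix(1, nG, length(cfg@genotypes),
                 dimnames = list(genes, cfg@genotypes))
  pos <- genes %in% truth$correlated$positive
  neg <- genes %in% truth$correlated$negative
  mult[pos, ] <- pmax(0.05, 1 + cfg@og_rna_slope * z[pos, , drop = FALSE])
  mult[neg, ] <- pmax(0.05, 1 - cfg@og_rna_slope * z[neg, , drop = FALSE])
  for (g in names(truth$deg)) {
    d <- truth$deg[[g]]
    mult[d$gene, g] <- mult[d$gene, g] *
      ifelse(d$direction == "up", cfg@deg_fold, 1 / cfg@deg_fold)
  }

  sampleInfo <- expand.grid(rep = seq_len(cfg@n_rna_reps),
                            genotype = cfg@genotypes,
                            stringsAsFactors = FALSE)
  sampleInfo <- sampleInfo[, c("genotype", "rep")]
  sampleInfo$sample <- sprintf("%s_r%d", sampleInfo$genotype, sampleInfo$rep)
  counts <- matrix(0L, nG, nrow(sampleInfo),
                   dimnames = list(genes, sampleInfo$sample))
  for (i in seq_len(nrow(sampleInfo))) {
    s <- sampleInfo$sample[i]
    .setStream(seed, paste0("rna_libfac_", s))
    lf <- stats::runif(1, 0.8, 1.2)
    .setStream(seed, paste0("rna_", s))
    counts[, i] <- .rnbinomMu(nG, baseline * mult[, sampleInfo$genotype[i]] *
                                lf, cfg@rna_dispersion)
  }
  list(counts = counts, sampleInfo = sampleInfo, truth = truth)
}

#' Simulate a complete study bundle
#'
#' Runs [simulateGenome()], bins the genome, simulates OG/input bin counts
#' and per-feature-class regional counts (including counts over the planted
#' G4 windows), computes the generator-side promoter damage signal, and
#' simulates coupled RNA counts — the full input bundle of [runPipeline()].
#'
#' @param cfg A [SimConfig-class].
#' @param dir Optional directory; when given, the bundle is written to disk
#'   (FASTA, chrom sizes, feature BEDs, count TSVs, sample sheets, truth
#'   JSON and a pipeline `config.yaml`) via [writeStudy()].
#' @return The study bundle: `genome`, `chrom_sizes`, `features`, `bins`,
#'   `binCounts` ([DamageExperiment-class]), `regionCounts` (named list of
#'   DamageExperiments per feature class and `g4`), `rna` (counts +
#'   sampleInfo), `truth`, `config` (pipeline parameter list).
#' @export
simulateStudy <- function(cfg, dir = NULL) {
  gen <- simulateGenome(cfg)
  truth <- gen$truth
  bins <- makeBins(gen$chrom_sizes, cfg@bin_size,
                   blacklist = gen$features$blacklist,
                   genome = gen$genome)
  ogBins <- simulateOGCounts(cfg, bins, truth, "bins")
  truth <- ogBins$truth

  regionSets <- list(
    cpg_island = gen$features$cpg_island,
    upstream = gen$features$upstream,
    exon = gen$features$exon,
    intron = gen$features$intron,
    downstream = gen$features$downstream,
    intergenic = gen$features$intergenic
  )
  # G4 region set: the 100 bp windows holding planted motifs
  nWin <- floor(gen$chrom_sizes / 100)
  winList <- lapply(names(gen$chrom_sizes), function(chr)
    GRanges(chr, IRanges(seq_len(nWin[[chr]]) * 100 - 99, width = 100)))
  wins <- suppressWarnings(do.call(c, winList))
  seqlengths(wins) <- gen$chrom_sizes[seqlevels(wins)]
  regionSets$g4 <- wins[overlapsAny(wins, truth$g4, ignore.strand = TRUE)]

  for (cls in names(regionSets)) {
    gr <- regionSets[[cls]]
    if (cls == "upstream") gr <- gr[width(gr) > 0]  # keep gene-id names
    else names(gr) <- regionIds(gr)
    regionSets[[cls]] <- gr
  }
  regionCounts <- list()
  for (cls in names(regionSets)) {
    sim <- simulateOGCounts(cfg, regionSets[[cls]], truth, cls)
    truth <- sim$truth
    regionCounts[[cls]] <- sim$se
  }

  # generator-side promoter signal for RNA coupling (true factors)
  prom <- regionCounts$upstream
  pairs <- samplePairs(prom)
  pairKey <- sprintf("%s_c%d_b%d", pairs$genotype, pairs$clone, pairs$bio_rep)
  sesF <- stats::setNames(truth$true_ses_factor[pairKey], pairs$og)
  libF <- truth$library_factors[pairs$og] /
    mean(truth$library_factors[pairs$og])
  ogSig <- promoterSignal(assay(prom, "counts")[, pairs$og, drop = FALSE],
                          assay(prom, "counts")[, pairs$input, drop = FALSE],
                          pairs, sesF, libF)
  ogSig <- ogSig[, cfg@genotypes, drop = FALSE]

  rna <- simulateRNACounts(cfg, truth, ogSig)
  truth <- rna$truth

  config <- list(
    genotypes = cfg@genotypes, reference = cfg@genotypes[1],
    bin_size = cfg@bin_size, percentile = 95, min_bio_reps = 2,
    pseudocount = 0.5, min_total = 10,
    der_p = 0.01, der_lfc = 0.5, deg_p = 0.05, deg_lfc = 1,
    promoter_flank = 1000, g4_window = 100, k_clusters = 8,
    min_cluster_size = min(20, max(5, round(cfg@n_genes / 10))),
    seed = cfg@seed
  )
  bundle <- list(genome = gen$genome, chrom_sizes = gen$chrom_sizes,
                 features = gen$features, bins = bins,
                 binCounts = ogBins$se, regionCounts = regionCounts,
                 rna = rna[c("counts", "sampleInfo")], truth = truth,
                 config = config)
  if (!is.null(dir)) writeStudy(bundle, dir)
  bundle
}
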
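#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<-
#' @importFrom SummarizedExperiment SummarizedExperiment assay colData rowRanges
NULL

setClassUnion("numericOrNULL", c("numeric", "NULL"))

#' Simulation configuration
#'
#' Parameters of the synthetic OG-seq/RNA-seq study generator. The defaults
#' emulate the design the package targets: four genotypes (wild type, two
#' single glycosylase knockouts and the double knockout), two knockout clones
#' per genotype acting as technical replicates, three biological replicates,
#' negative-binomial background counts over 1 kb bins, planted OG-enriched
#' bins, planted genotype-specific differentially enriched feature regions,
#' planted canonical G4 motifs, and RNA counts coupled to promoter OG damage
#' for designated gene sets.
#'
#' @slot seed integer master seed; every emitted artifact derives its own
#'   stream from it (see [streamSeed()]).
#' @slot n_chroms,chrom_length number and length (bp) of simulated
#'   chromosomes.
#' @slot bin_size genome bin width in bp.
#' @slot n_genes number of genes placed across the genome.
#' @slot genotypes genotype labels; the first is the reference (wild type).
#' @slot n_bio_reps,n_tech_reps biological replicates and technical
#'   replicates (clones) per genotype.
#' @slot background_mean expected input count per bin.
#' @slot dispersion NB dispersion of bin counts (variance = mu + mu^2 * disp).
#' @slot region_dispersion,rna_dispersion NB dispersion of feature-region
#'   damage counts and of RNA counts. Feature-level and expression counts
#'   aggregate over wider footprints between isogenic clones, so their
#'   biological coefficient of variation (0.2, i.e. dispersion 0.04) is set
#'   below the noisier 1 kb bin level.
#' @slot frac_enriched_bins,enrichment_fold fraction of bins planted as
#'   OG-enriched per genotype and the multiplicative fold on the OG mean.
#' @slot frac_der_regions,der_fold,der_region_mean fraction of each feature
#'   region set planted as differentially enriched per knockout genotype, the
#'   fold applied (gains and losses in equal parts), and the expected damage
#'   count for a 1 kb feature region.
#' @slot library_factor_range,ses_factor_range uniform ranges for planted
#'   per-sample library-size multipliers and per-pair pulldown/input scale
#'   factors.
#' @slot n_pos_corr_genes,n_neg_corr_genes numbers of genes with planted
#'   positive/negative promoter-OG vs expression coupling.
#' @slot n_deg_genes,deg_fold planted genotype-specific differentially
#'   expressed genes per knockout and their fold change.
#' @slot damage_profile relative promoter OG multiplier per genotype for
#'   coupled genes; the default keeps wild type and the MUTYH knockout low
#'   and elevates the OGG1-deficient genotypes, the repair biology the
#'   concordance analysis searches for.
#' @slot og_rna_slope slope of the linear map from promoter OG z-score to the
#'   relative expression mean of coupled genes.
#' @slot rna_baseline_mean,n_rna_reps expected baseline RNA count per gene
#'   and RNA replicates (clones) per genotype.
#' @slot g4_density planted canonical G4 motifs per 10 kb.
#' @slot cpg_island_frac fraction of the genome covered by CpG islands.
#'
#' @seealso [simConfig()], [simulateGenome()], [simulateOGCounts()],
#'   [simulateRNACounts()]
#' @export
setClass("SimConfig", representation(
  seed = "numeric", n_chroms = "numeric", chrom_length = "numeric",
  bin_size = "numeric", n_genes = "numeric", genotypes = "character",
  n_bio_reps = "numeric", n_tech_reps = "numeric",
  background_mean = "numeric", dispersion = "numeric",
  region_dispersion = "numeric", rna_dispersion = "numeric",
  frac_enriched_bins = "numeric", enrichment_fold = "numeric",
  frac_der_regions = "numeric", der_fold = "numeric",
  der_region_mean = "numeric",
  library_factor_range = "numeric", ses_factor_range = "numeric",
  n_pos_corr_genes = "numeric", n_neg_corr_genes = "numeric",
  n_deg_genes = "numeric", deg_fold = "numeric",
  damage_profile = "numeric", og_rna_slope = "numeric",
  rna_baseline_mean = "numeric", n_rna_reps = "numeric",
  g4_density = "numeric", cpg_island_frac = "numeric"
))

setValidity("SimConfig", function(object) {
  msg <- character()
  frac <- c(frac_enriched_bins = object@frac_enriched_bins,
            frac_der_regions = object@frac_der_regions,
            cpg_island_frac = object@cpg_island_frac)
  if (any(frac < 0 | frac > 1))
    msg <- c(msg, "fractions must lie in [0, 1]")
  if (object@enrichment_fold < 1 || object@der_fold < 1 ||
      object@deg_fold < 1)
    msg <- c(msg, "fold parameters must be >= 1")
  if (object@bin_size < 1) msg <- c(msg, "bin_size must be positive")
  if (length(object@genotypes) < 2)
    msg <- c(msg, "need at least two genotypes (reference first)")
  if (anyDuplicated(object@genotypes))
    msg <- c(msg, "genotype labels must be unique")
  if (length(object@damage_profile) != length(object@genotypes))
    msg <- c(msg, "damage_profile must have one entry per genotype")
  if (any(object@damage_profile <= 0))
    msg <- c(msg, "damage_profile must be positive")
  for (r in list(object@library_factor_range, object@ses_factor_range))
    if (length(r) != 2 || any(r <= 0) || r[1] > r[2])
      msg <- c(msg, "factor ranges must be positive ascending pairs")
  if (object@n_pos_corr_genes + object@n_neg_corr_genes +
      object@n_deg_genes * (length(object@genotypes) - 1) > object@n_genes)
    msg <- c(msg, "planted gene sets exceed n_genes")
  if (length(msg)) msg else TRUE
})

#' Create a simulation configuration
#'
#' @param seed Integer master seed.
#' @param ... Named values overriding the defaults of any [SimConfig-class]
#'   slot.
#' @return A validated `SimConfig` object.
#' @examples
#' cfg <- simConfig(seed = 1, n_chroms = 1, chrom_length = 1e5, n_genes = 40)
#' @export
simConfig <- function(seed = 1L, ...) {
  args <- list(...)
  defaults <- list(
    seed = seed, n_chroms = 2, chrom_length = 1e6, bin_size = 1000,
    n_genes = 200, genotypes = c("WT", "MUTYH", "OGG1", "DKO"),
    n_bio_reps = 3, n_tech_reps = 2,
    background_mean = 10, dispersion = 0.1,
    region_dispersion = 0.04, rna_dispersion = 0.04,
    frac_enriched_bins = 0.01, enrichment_fold = 8,
    frac_der_regions = 0.05, der_fold = 2, der_region_mean = 100,
    library_factor_range = c(0.7, 1.3), ses_factor_range = c(0.8, 1.25),
    n_pos_corr_genes = 30, n_neg_corr_genes = 30,
    n_deg_genes = 10, deg_fold = 4,
    damage_profile = c(2, 2.2, 8, 8.8), og_rna_slope = 0.8,
    rna_baseline_mean = 200, n_rna_reps = 2,
    g4_density = 1, cpg_island_frac = 0.02
  )
  unknown <- setdiff(names(args), names(defaults))
  if (length(unknown))
    stop("unknown SimConfig parameter(s): ", paste(unknown, collapse = ", "))
  defaults[names(args)] <- args
  do.call(new, c(list(Class = "SimConfig"), defaults))
}

setMethod("show", "SimConfig", function(object) {
  cat("SimConfig:", object@n_chroms, "chrom x", object@chrom_length, "bp,",
      object@n_genes, "genes,", length(object@genotypes), "genotypes (",
      paste(object@genotypes, collapse = ", "), ")\n")
  cat("  replicates:", object@n_tech_reps, "clones x", object@n_bio_reps,
      "biological; bin", object@bin_size, "bp\n")
  cat("  background mu", object@background_mean, "dispersion",
      object@dispersion, "| planted:", object@frac_enriched_bins * 100,
      "% bins x", object@enrichment_fold, "fold,",
      object@frac_der_regions * 100, "% regions x", object@der_fold,
      "fold,", object@n_pos_corr_genes, "+", object@n_neg_corr_genes,
      "coupled genes\n")
})

#' Signal extraction scaling (SES) fit
#'
#' Result of the rank-based decomposition of a pulldown/input pair into
#' signal and background bins: bins are ordered by increasing pulldown count,
#' the split maximizing the gap between the cumulative input fraction and the
#' cumulative pulldown fraction separates background from signal, and the
#' input scale factor is the ratio of pulldown to input mass over background
#' bins only.
#'
#' @slot ordering integer permutation sorting bins by increasing OG count
#'   (ties by input count, then position).
#' @slot splitIndex the smallest index maximizing the cumulative difference.
#' @slot scaleFactor factor applied to input counts.
#' @slot background integer ids (original positions) of background bins.
#' @slot separable FALSE when no signal/background split was found and the
#'   global count ratio was used instead.
#'
#' @seealso [sesFit()]
#' @export
setClass("SESResult", representation(
  ordering = "integer", splitIndex = "integer", scaleFactor = "numeric",
  background = "integer", separable = "logical"
))

setValidity("SESResult", function(object) {
  n <- length(object@ordering)
  if (object@splitIndex < 1L || object@splitIndex > n)
    return("splitIndex out of range")
  if (object@scaleFactor <= 0) return("scaleFactor must be positive")
  if (length(object@background) != object@splitIndex)
    return("background set size must equal splitIndex")
  TRUE
})

#' @export
setGeneric("inputScaleFactor", function(x) standardGeneric("inputScaleFactor"))
#' @export
setGeneric("splitIndex", function(x) standardGeneric("splitIndex"))
#' @export
setGeneric("backgroundBins", function(x) standardGeneric("backgroundBins"))

#' @describeIn SESResult-class the input scale factor.
#' @param x An `SESResult`.
#' @export
setMethod("inputScaleFactor", "SESResult", function(x) x@scaleFactor)
#' @describeIn SESResult-class index of the background/signal split in the
#'   OG-ordered bin ranking.
#' @export
setMethod("splitIndex", "SESResult", function(x) x@splitIndex)
#' @describeIn SESResult-class original positions of background bins.
#' @export
setMethod("backgroundBins", "SESResult", function(x) x@background)

setMethod("show", "SESResult", function(object) {
  n <- length(object@ordering)
  cat("SESResult:", n, "bins, background", object@splitIndex,
      sprintf("(%.1f%%),", 100 * object@splitIndex / n),
      "input scale factor", signif(object@scaleFactor, 4),
      if (!object@separable) "[no separable signal: global ratio]" else "",
      "\n")
})

#' Container for binned or regional damage-mapping counts
#'
#' A `RangedSummarizedExperiment` holding one `counts` assay over a region
#' set (genome bins or feature regions) with the sample annotation the
#' pipeline requires: `genotype`, `clone` (technical replicate), `bio_rep`
#' and `assay_type` (`"OG"` pulldown or `"input"`).
#'
#' @seealso [DamageExperiment()], [samplePairs()]
#' @export
setClass("DamageExperiment",
         contains = "RangedSummarizedExperiment")

setValidity("DamageExperiment", function(object) {
  cd <- colData(object)
  need <- c("genotype", "clone", "bio_rep", "assay_type")
  missing <- setdiff(need, colnames(cd))
  if (length(missing))
    return(paste("colData lacks column(s):", paste(missing, collapse = ", ")))
  if (!all(cd$assay_type %in% c("OG", "input")))
    return("assay_type must be 'OG' or 'input'")
  if (!"counts" %in% SummarizedExperiment::assayNames(object))
    return("need a 'counts' assay")
  m <- assay(object, "counts")
  if (any(m < 0)) return("counts must be non-negative")
  TRUE
})

#' Construct a DamageExperiment
#'
#' @param counts Non-negative count matrix, regions x samples.
#' @param regions `GRanges` of the counted regions (rows).
#' @param sampleInfo `data.frame` with columns `genotype`, `clone`,
#'   `bio_rep`, `assay_type`; rows match the columns of `counts`.
#' @return A [DamageExperiment-class] object.
#' @examples
#' gr <- GenomicRanges::GRanges("chr1", IRanges::IRanges(c(1, 1001), width = 1000))
#' m <- matrix(rpois(4, 10), 2, dimnames = list(NULL, c("s1", "s2")))
#' si <- data.frame(genotype = "WT", clone = 1:2, bio_rep = 1,
#'                  assay_type = c("OG", "input"))
#' de <- DamageExperiment(m, gr, si)
#' @export
DamageExperiment <- function(counts, regions, sampleInfo) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts))) rownames(counts) <- regionIds(regions)
  if (is.null(names(regions))) names(regions) <- rownames(counts)
  se <- SummarizedExperiment(assays = list(counts = counts),
                             rowRanges = regions,
                             colData = DataFrame(sampleInfo))
  new("DamageExperiment", se)
}

#' Pair OG pulldown samples with their inputs
#'
#' @param x A [DamageExperiment-class].
#' @return `data.frame` with one row per (genotype, clone, bio_rep) cell and
#'   columns `og` and `input` giving the column names of the paired samples.
#' @export
setGeneric("samplePairs", function(x) standardGeneric("samplePairs"))

#' @rdname samplePairs
#' @export
setMethod("samplePairs", "DamageExperiment", function(x) {
  cd <- as.data.frame(colData(x))
  cd$sample <- colnames(x)
  key <- interaction(cd$genotype, cd$clone, cd$bio_rep, drop = TRUE)
  out <- do.call(rbind, lapply(split(cd, key), function(d) {
    og <- d$sample[d$assay_type == "OG"]
    inp <- d$sample[d$assay_type == "input"]
    if (length(og) != 1L || length(inp) != 1L)
      stop("sample sheet cell (", d$genotype[1], ", clone ", d$clone[1],
           ", bio_rep ", d$bio_rep[1], ") lacks a complete OG/input pair")
    data.frame(genotype = d$genotype[1], clone = d$clone[1],
               bio_rep = d$bio_rep[1], og = og, input = inp)
  }))
  rownames(out) <- NULL
  out[order(out$genotype, out$clone, out$bio_rep), , drop = FALSE]
})

setMethod("show", "DamageExperiment", function(object) {
  cd <- colData(object)
  cat("DamageExperiment:", nrow(object), "regions x", ncol(object),
      "samples\n")
  print(table(genotype = cd$genotype, assay = cd$assay_type))
})
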
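test_that("simulation configs validate their invariants", {
  expect_s4_class(simConfig(seed = 1), "SimConfig")
  expect_error(simConfig(frac_enriched_bins = 1.5), "0, 1")
  expect_error(simConfig(der_fold = 0.5), ">= 1")
  expect_error(simConfig(genotypes = "WT", damage_profile = 1),
               "two genotypes")
  expect_error(simConfig(n_genes = 10), "exceed")
  expect_error(simConfig(bogus = 1), "unknown")
  # null-model folds of exactly 1 are allowed
  expect_s4_class(simConfig(enrichment_fold = 1, der_fold = 1,
                            deg_fold = 1), "SimConfig")
})

test_that("every generator is byte-deterministic under a fixed seed", {
  cfg <- simConfig(seed = 31, n_chroms = 1, chrom_length = 8e4, n_genes = 8,
                   n_pos_corr_genes = 2, n_neg_corr_genes = 2,
                   n_deg_genes = 1)
  g1 <- simulateGenome(cfg)
  g2 <- simulateGenome(cfg)
  expect_identical(as.character(g1$genome), as.character(g2$genome))
  bins <- makeBins(g1$chrom_sizes, 1000)
  c1 <- simulateOGCounts(cfg, bins, g1$truth, "bins")
  c2 <- simulateOGCounts(cfg, bins, g2$truth, "bins")
  expect_identical(assay(c1$se, "counts"), assay(c2$se, "counts"))
  z <- matrix(rnorm(8 * 4), 8, 4,
              dimnames = list(sprintf("g%04d", 1:8), cfg@genotypes))
  r1 <- simulateRNACounts(cfg, c1$truth, z)
  r2 <- simulateRNACounts(cfg, c2$truth, z)
  expect_identical(r1$counts, r2$counts)
})

test_that("genome structure honours its contracts", {
  cfg <- simConfig(seed = 32, n_chroms = 2, chrom_length = 2e5, n_genes = 30,
                   n_pos_corr_genes = 5, n_neg_corr_genes = 5,
                   n_deg_genes = 3)
  gen <- simulateGenome(cfg)
  # exons and introns partition each gene body exactly
  ei <- reduce(c(granges(gen$features$exon), granges(gen$features$intron)),
               ignore.strand = TRUE)
  expect_equal(ei, reduce(granges(gen$features$gene), ignore.strand = TRUE))
  # intergenic is the complement of gene bodies
  expect_equal(sum(width(gen$features$intergenic)) +
                 sum(width(reduce(granges(gen$features$gene),
                                  ignore.strand = TRUE))),
               sum(gen$chrom_sizes))
  # no planted motifs when the density is zero
  cfg0 <- simConfig(seed = 32, n_chroms = 1, chrom_length = 1e5,
                    n_genes = 8, n_pos_corr_genes = 2, n_neg_corr_genes = 2,
                    n_deg_genes = 1, g4_density = 0)
  expect_equal(length(simulateGenome(cfg0)$truth$g4), 0L)
  expect_error(simulateGenome(simConfig(seed = 1, n_chroms = 1,
                                        chrom_length = 5e4, n_genes = 30,
                                        n_pos_corr_genes = 0,
                                        n_neg_corr_genes = 0,
                                        n_deg_genes = 0)),
               "too small")
  # CpG islands have elevated GC
  gc <- gcContent(gen$features$cpg_island, gen$genome)
  expect_gt(mean(gc), 0.55)
})

test_that("counts match the null model and the NB moment structure", {
  cfg <- simConfig(seed = 33, genotypes = c("WT", "KO"),
                   damage_profile = c(1, 1), n_pos_corr_genes = 0,
                   n_neg_corr_genes = 0, n_deg_genes = 0,
                   enrichment_fold = 1, der_fold = 1)
  bins <- GRanges("chr1", IRanges(0:19999 * 1000 + 1, width = 1000))
  names(bins) <- ogmap:::regionIds(bins)
  sim <- simulateOGCounts(cfg, bins, list(), "bins")
  m <- assay(sim$se, "counts")
  truth <- sim$truth
  pairs <- samplePairs(sim$se)
  for (i in c(1, 5)) {
    pk <- sprintf("%s_c%d_b%d", pairs$genotype[i], pairs$clone[i],
                  pairs$bio_rep[i])
    ratio <- mean(m[, pairs$og[i]]) / mean(m[, pairs$input[i]])
    expect_equal(ratio, unname(truth$true_ses_factor[pk]), tolerance = 0.03)
  }
  # variance of background input counts ~ mu + mu^2 * dispersion
  mu <- cfg@background_mean * unname(truth$library_factors[pairs$input[1]])
  expect_equal(var(m[, pairs$input[1]]), mu + mu^2 * cfg@dispersion,
               tolerance = 0.1)
})

test_that("planted eight-fold bins show an eight-fold mean ratio", {
  cfg <- simConfig(seed = 34, genotypes = c("WT", "KO"),
                   damage_profile = c(1, 1), n_pos_corr_genes = 0,
                   n_neg_corr_genes = 0, n_deg_genes = 0,
                   frac_enriched_bins = 0.5, enrichment_fold = 8)
  bins <- GRanges("chr1", IRanges(0:19999 * 1000 + 1, width = 1000))
  names(bins) <- ogmap:::regionIds(bins)
  sim <- simulateOGCounts(cfg, bins, list(), "bins")
  m <- assay(sim$se, "counts")
  truth <- sim$truth
  allPairs <- samplePairs(sim$se)
  pairs <- allPairs[allPairs$genotype == "WT", ][1, ]
  planted <- names(bins) %in% truth$enriched_bins$WT
  pk <- sprintf("%s_c%d_b%d", pairs$genotype, pairs$clone, pairs$bio_rep)
  scaledInput <- m[, pairs$input] * truth$true_ses_factor[pk]
  ratio <- mean(m[planted, pairs$og]) / mean(scaledInput[planted])
  expect_equal(ratio, 8, tolerance = 0.05)
  ratioBg <- mean(m[!planted, pairs$og]) / mean(scaledInput[!planted])
  expect_equal(ratioBg, 1, tolerance = 0.05)
})

test_that("ground truth references only emitted regions and genes", {
  study <- smallStudy()
  truth <- study$truth
  expect_true(all(unlist(truth$enriched_bins) %in% names(study$bins)))
  for (cls in names(truth$der))
    for (g in names(truth$der[[cls]]))
      expect_true(all(truth$der[[cls]][[g]]$region %in%
                        rownames(study$regionCounts[[cls]])))
  genes <- names(study$features$gene)
  expect_true(all(unlist(truth$correlated) %in% genes))
  expect_length(intersect(truth$correlated$positive,
                          truth$correlated$negative), 0)
  expect_true(all(unlist(lapply(truth$deg, `[[`, "gene")) %in% genes))
})

test_that("uncoupled expression is uncorrelated with promoter damage", {
  cfg <- simConfig(seed = 35, n_genes = 5000, n_pos_corr_genes = 0,
                   n_neg_corr_genes = 0, n_deg_genes = 0)
  prom <- GRanges("chr1", IRanges(seq_len(5000) * 2000, width = 1000))
  names(prom) <- sprintf("g%04d", 1:5000)
  sim <- simulateOGCounts(cfg, prom, list(), "upstream")
  pairs <- samplePairs(sim$se)
  m <- assay(sim$se, "counts")
  pk <- sprintf("%s_c%d_b%d", pairs$genotype, pairs$clone, pairs$bio_rep)
  sesF <- setNames(sim$truth$true_ses_factor[pk], pairs$og)
  ogSig <- promoterSignal(m[, pairs$og], m[, pairs$input], pairs, sesF)
  ogSig <- ogSig[, cfg@genotypes]
  rna <- simulateRNACounts(cfg, sim$truth, ogSig)
  for (g in cfg@genotypes) {
    rnaMean <- rowMeans(rna$counts[, rna$sampleInfo$genotype == g])
    expect_lt(abs(cor(ogSig[, g], rnaMean)), 0.05)
  }
})
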
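test_that("log2 ratio follows the pseudocount definition", {
  expect_equal(log2Ratio(8, 2, pseudocount = 0), 2)
  expect_equal(log2Ratio(c(5, 7), c(5, 7)), c(0, 0))
  expect_equal(log2Ratio(0, 0), 0)  # degenerate bin at default pseudocount
  expect_error(log2Ratio(-1, 2), "non-negative")
})

test_that("percentile thresholding uses interpolated order statistics", {
  sel <- thresholdBins(1:100)
  expect_equal(sel, 96:100)  # threshold 95.05
  expect_warning(selAll <- thresholdBins(rep(2, 30)), "every bin")
  expect_equal(selAll, 1:30)
  expect_error(thresholdBins(1:100, percentile = 100), "between")
  expect_error(thresholdBins(1:5), "at least 20")
  # about 5% of standard-normal ratios clear the 95th percentile
  set.seed(10)
  sel2 <- thresholdBins(rnorm(20000))
  expect_equal(length(sel2), 1000, tolerance = 0.1)
})

test_that("consensus requires both clones in at least two biological replicates", {
  design <- tinyDesign()
  sets <- list(s1 = c(5L, 7L, 9L), s2 = c(5L, 7L),
               s3 = c(5L, 7L, 9L), s4 = c(5L, 7L),
               s5 = c(5L, 9L),     s6 = c(5L))
  out <- replicateConsensus(sets, design)
  expect_equal(out, c(5, 7))  # 7: both clones of bio 1 and 2; 9: clone 1 only
  expect_error(replicateConsensus(sets[-2], design), "s2")
})

test_that("consensus is monotone in replicate support", {
  set.seed(11)
  design <- tinyDesign()
  for (i in 1:20) {
    sets <- lapply(1:6, function(j) which(rbinom(50, 1, 0.3) == 1))
    names(sets) <- design$sample
    base <- replicateConsensus(sets, design)
    # adding support to one replicate never removes a consensus bin
    j <- sample(6, 1)
    sets2 <- sets
    sets2[[j]] <- union(sets2[[j]], sample(50, 5))
    expect_true(all(base %in% replicateConsensus(sets2, design)))
  }
})

test_that("bookended bins merge and merging is idempotent", {
  bins <- GRanges("chr1", IRanges(c(1, 1001), width = 1000))
  m <- mergeBookended(bins, log2ratio = c(2, 4))
  expect_equal(length(m), 1L)
  expect_equal(width(m), 2000L)
  expect_equal(mcols(m)$mean_log2_ratio, 3)
  expect_equal(mcols(m)$n_bins, 2L)

  gap <- GRanges("chr1", IRanges(c(1, 2001), width = 1000))
  expect_equal(length(mergeBookended(gap)), 2L)

  m2 <- mergeBookended(m, mcols(m)$mean_log2_ratio)
  expect_equal(granges(m2), granges(m))
  expect_equal(length(mergeBookended(GRanges())), 0L)
})

test_that("the enriched-bin caller recovers strong planted bins end to end", {
  cfg <- simConfig(seed = 3, genotypes = c("WT", "KO"),
                   damage_profile = c(1, 1), n_pos_corr_genes = 0,
                   n_neg_corr_genes = 0, n_deg_genes = 0,
                   frac_enriched_bins = 0.01, enrichment_fold = 8)
  bins <- GRanges("chr1", IRanges(0:9999 * 1000 + 1, width = 1000))
  names(bins) <- ogmap:::regionIds(bins)
  sim <- simulateOGCounts(cfg, bins, list(), "bins")
  wt <- sim$se[, colData(sim$se)$genotype == "WT"]
  ebs <- callEnrichedBins(wt)
  called <- names(bins)[ebs$WT$bins]
  truthSet <- sim$truth$enriched_bins$WT
  expect_gte(mean(truthSet %in% called), 0.9)
  expect_gte(mean(called %in% truthSet), 0.8)
  expect_true(all(mcols(ebs$WT$regions)$supporting_bio_reps >= 2))
})
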
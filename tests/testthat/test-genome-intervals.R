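test_that("makeBins drops incomplete terminal bins and blacklisted bins", {
  bins <- makeBins(c(chr1 = 3500), binSize = 1000)
  expect_equal(length(bins), 3L)
  expect_equal(start(bins), c(1L, 1001L, 2001L))
  expect_equal(width(bins), rep(1000L, 3))

  # a single blacklisted base pair removes the whole bin
  bl <- GRanges("chr1", IRanges(1501, 1501))
  bins2 <- makeBins(c(chr1 = 3500), 1000, blacklist = bl)
  expect_equal(start(bins2), c(1L, 2001L))

  expect_warning(makeBins(c(chr1 = 3500), 1000,
                          blacklist = GRanges("chrZ", IRanges(1, 10))),
                 "unknown chromosome")
  expect_error(makeBins(c(chr1 = 3500), 0), "positive")
})

test_that("bin counts and widths follow the arithmetic over many chromosomes", {
  sizes <- setNames(rep(1e5, 10), paste0("chr", 1:10))
  bins <- makeBins(sizes, 1000)
  expect_equal(length(bins), 1000L)
  expect_equal(sum(width(bins)), 1e6)
  # partition: retained + blacklisted tile all complete windows
  bl <- GRanges("chr3", IRanges(c(5, 50001), width = 10))
  kept <- makeBins(sizes, 1000, blacklist = bl)
  expect_equal(length(kept), 1000L - 2L)
})

test_that("promoters are the strand-aware 1 kb upstream of the TSS", {
  sl <- c(chr1 = 20000)
  plus <- GRanges("chr1", IRanges(5001, 8000), strand = "+",
                  seqlengths = sl)
  names(plus) <- "gp"
  minus <- GRanges("chr1", IRanges(5001, 8000), strand = "-",
                   seqlengths = sl)
  names(minus) <- "gm"
  expect_equal(ranges(derivePromoters(plus)), IRanges(4001, 5000, names = "gp"))
  expect_equal(ranges(derivePromoters(minus)), IRanges(8001, 9000, names = "gm"))

  # clamped at the chromosome start
  edge <- GRanges("chr1", IRanges(301, 900), strand = "+", seqlengths = sl)
  names(edge) <- "ge"
  expect_equal(ranges(derivePromoters(edge)), IRanges(1, 300, names = "ge"))

  nostrand <- GRanges("chr1", IRanges(100, 200))
  names(nostrand) <- "gx"
  expect_error(derivePromoters(nostrand), "gx")
})

test_that("promoter derivation commutes with strand flip plus reflection", {
  set.seed(1)
  L <- 50000L
  st <- sample.int(L - 6000L, 20) + 1500L
  g <- GRanges("chr1", IRanges(st, width = sample(500:3000, 20, TRUE)),
               strand = sample(c("+", "-"), 20, TRUE),
               seqlengths = c(chr1 = L))
  names(g) <- paste0("g", 1:20)
  flip <- GRanges("chr1", IRanges(L - end(g) + 1, L - start(g) + 1),
                  strand = ifelse(strand(g) == "+", "-", "+"),
                  seqlengths = c(chr1 = L))
  names(flip) <- names(g)
  p1 <- derivePromoters(g)
  p2 <- derivePromoters(flip)
  expect_equal(start(p2), L - end(p1) + 1)
  expect_equal(end(p2), L - start(p1) + 1)
})

test_that("gcContent counts G+C over unambiguous bases only", {
  genome <- DNAStringSet(c(chr1 = "GGCCATATGCATN"))
  iv <- GRanges("chr1", IRanges(c(1, 5, 9), c(4, 8, 13)))
  expect_equal(gcContent(iv, genome), c(1, 0, 0.5))
  expect_error(gcContent(GRanges("chr1", IRanges(10, 50)), genome), "beyond")
  expect_error(gcContent(GRanges("chr9", IRanges(1, 2)), genome),
               "no sequence")
})

test_that("annotation assigns the class with maximal overlap", {
  f <- tinyFeatures()
  # 50 bp of exon, 950 bp of intron: the larger overlap wins
  r <- GRanges("chr1", IRanges(1001, 2000))
  ann <- annotateRegions(r, f)
  expect_equal(ann$feature_class, "intron")
  expect_equal(ann$nearest_gene, "g1")

  inProm <- annotateRegions(GRanges("chr1", IRanges(101, 200)), f)
  expect_equal(inProm$feature_class, "promoter")

  nowhere <- annotateRegions(GRanges("chr1", IRanges(8001, 8100)), f)
  expect_equal(nowhere$feature_class, "intergenic")
  expect_equal(nowhere$nearest_gene, "g1")
  expect_equal(nowhere$distance_to_tss, 7049L)  # midpoint 8050 vs TSS 1001

  expect_error(annotateRegions(r, list()), "gene")
})

test_that("observed/expected representation matches hand arithmetic", {
  feats <- list(
    gene = tinyFeatures()$gene,
    promoter = GRanges("chr1", IRanges(1, 1000)),        # 10% of genome
    intergenic = GRanges("chr1", IRanges(4001, 10000)),  # 60%
    exon = GRanges("chr1", IRanges(1001, 1500))          # 5%
  )
  ann <- data.frame(
    region = paste0("r", 1:10),
    feature_class = rep(c("promoter", "intergenic"), each = 5))
  oe <- observedExpected(ann, feats, c(chr1 = 10000))
  expect_equal(oe$log2_obs_exp[oe$feature_class == "promoter"],
               log2(0.5 / 0.1))
  expect_equal(oe$log2_obs_exp[oe$feature_class == "intergenic"],
               log2(0.5 / 0.6))
  expect_equal(oe$log2_obs_exp[oe$feature_class == "exon"], -Inf)
  expect_equal(sum(oe$observed), 1)
  # identity when observed equals the footprint fraction
  ann2 <- data.frame(region = "r", feature_class = "promoter")
  feats2 <- list(gene = feats$gene,
                 promoter = GRanges("chr1", IRanges(1, 10000)))
  oe2 <- observedExpected(ann2, feats2, c(chr1 = 10000))
  expect_equal(oe2$log2_obs_exp[oe2$feature_class == "promoter"], 0)
})
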
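test_that("promoter signal reproduces hand-computed subtraction and collapse", {
  og <- matrix(c(10, 4, 0,   20, 6, 8), ncol = 2,
               dimnames = list(c("g1", "g2", "g3"), c("A_og", "B_og")))
  inp <- matrix(c(8, 8, 2,   5, 10, 2), ncol = 2,
                dimnames = list(c("g1", "g2", "g3"), c("A_in", "B_in")))
  pairs <- data.frame(genotype = c("A", "B"), clone = 1, bio_rep = 1,
                      og = c("A_og", "B_og"), input = c("A_in", "B_in"))
  sesF <- c(A_og = 0.5, B_og = 2)
  libF <- c(A_og = 1, B_og = 2)
  sig <- promoterSignal(og, inp, pairs, sesF, libF)
  # A: max(og - 0.5 * in, 0) / 1 ; B: max(og - 2 * in, 0) / 2
  expect_equal(sig[, "A"], c(g1 = 6, g2 = 0, g3 = 0))
  expect_equal(sig[, "B"], c(g1 = 5, g2 = 0, g3 = 2))
  # all-equal OG and scaled input collapse to zero
  expect_message(
    sig0 <- promoterSignal(inp, inp, data.frame(genotype = "A", clone = 1,
                                                bio_rep = 1, og = "A_in",
                                                input = "A_in"),
                           c(A_in = 1), promoterWidths = c(10, 10, 0)),
    "zero-width")
  expect_equal(unname(sig0[, 1]), c(0, 0))
})

test_that("presence filtering requires 3 of 4 genotypes in both assays", {
  og <- matrix(c(1, 1, 1, 1,  1, 1, 1, 0,  1, 1, 0, 0), 3, byrow = TRUE,
               dimnames = list(c("g1", "g2", "g3"), NULL))
  rna <- matrix(c(1, 1, 0, 0,  1, 0, 1, 1,  1, 1, 1, 1), 3, byrow = TRUE,
                dimnames = list(c("g1", "g2", "g3"), NULL))
  expect_equal(filterPresent(og, rna), "g2")  # g1: 2/4 RNA; g3: 2/4 OG
  # monotone: adding signal never drops a kept gene
  rna2 <- rna; rna2[1, 3] <- 5
  expect_true("g2" %in% filterPresent(og, rna2))
  expect_true("g1" %in% filterPresent(og, rna2))
})

test_that("row z-scores are exact and sign classification follows the rule", {
  set.seed(23)
  m <- matrix(rnorm(400, 50, 10), 100, 4,
              dimnames = list(paste0("g", 1:100), c("a", "b", "c", "d")))
  z <- ogmap:::.rowZ(m)
  expect_lt(max(abs(rowMeans(z))), 1e-9)
  expect_lt(max(abs(sqrt(rowSums((z - rowMeans(z))^2) / 3) - 1)), 1e-9)

  expect_equal(ogmap:::.signClass(c(1, 1, -1, -1), c(2, 0.5, -3, -1)),
               "positive")
  expect_equal(ogmap:::.signClass(c(1, 1, 1, 1), c(-1, -1, -1, -1)),
               "negative")
  expect_equal(ogmap:::.signClass(c(1, 1, -1, -1), c(1, -1, -1, -1)),
               "unclassified")
  # zeros drop the constraint; two unconstrained genotypes -> unclassified
  expect_equal(ogmap:::.signClass(c(1, 0, -1, -1), c(1, 5, -1, -1)),
               "positive")
  expect_equal(ogmap:::.signClass(c(1, 0, 0, -1), c(1, 5, 2, -1)),
               "unclassified")
})

test_that("concordance classification recovers constructed blocks", {
  set.seed(24)
  profile <- c(-1, -1, 1, 1)
  mk <- function(n, sgn) {
    og <- t(replicate(n, profile * 50 + rnorm(4, 0, 5) + 100))
    rna <- t(replicate(n, sgn * profile * 30 + rnorm(4, 0, 3) + 60))
    list(og = og, rna = rna)
  }
  pos <- mk(30, 1); neg <- mk(30, -1)
  null <- list(og = matrix(rnorm(240, 100, 20), 60, 4),
               rna = matrix(rnorm(240, 60, 10), 60, 4))
  og <- rbind(pos$og, neg$og, null$og)
  rna <- rbind(pos$rna, neg$rna, null$rna)
  rownames(og) <- rownames(rna) <- paste0("g", seq_len(nrow(og)))
  colnames(og) <- colnames(rna) <- c("WT", "MUTYH", "OGG1", "DKO")
  conc <- concordanceCluster(og, rna, k = 8)
  r <- conc$records
  expect_gte(mean(r$classification[1:30] == "positive"), 0.9)
  expect_gte(mean(r$classification[31:60] == "negative"), 0.9)
  expect_gte(mean(r$classification[61:120] == "unclassified"), 0.9)

  # invariance under positive rescaling of each gene's values
  og2 <- og * runif(nrow(og), 0.2, 5)
  rna2 <- rna * runif(nrow(rna), 0.2, 5)
  conc2 <- concordanceCluster(og2, rna2, k = 8)
  expect_equal(conc2$records$classification, r$classification)

  # constant rows are excluded with a message
  og3 <- rbind(og, gflat = rep(7, 4))
  rna3 <- rbind(rna, gflat = rnorm(4, 60))
  expect_message(conc3 <- concordanceCluster(og3, rna3), "constant")
  expect_false("gflat" %in% conc3$records$gene)
})

test_that("sign candidates are symmetric under an uncoupled null", {
  set.seed(25)
  og <- matrix(rnorm(4000 * 4), 4000, 4,
               dimnames = list(paste0("g", 1:4000), c("a", "b", "c", "d")))
  rna <- matrix(rnorm(4000 * 4), 4000, 4, dimnames = dimnames(og))
  conc <- concordanceCluster(og, rna, k = 8)
  nPos <- sum(conc$records$candidate == "positive")
  nNeg <- sum(conc$records$candidate == "negative")
  expect_gt(nPos + nNeg, 0)
  expect_lt(abs(nPos - nNeg) / (nPos + nNeg), 0.2)
})

test_that("fold-change correlation handles the exact and degenerate limits", {
  der <- data.frame(gene = paste0("g", 1:6),
                    contrast = "KO_vs_WT", feature_class = "cpg_island",
                    log2FC = c(1, -2, 0.5, 3, -1, 2), passes = TRUE)
  degSame <- data.frame(gene = paste0("g", 1:6), contrast = "KO_vs_WT",
                        log2FC = der$log2FC, is_deg = TRUE)
  out <- derDegCorrelation(der, degSame)
  expect_equal(out$correlation$pearson_r, 1)
  expect_equal(out$overlap$fraction_deg, 1)

  degAnti <- transform(degSame, log2FC = -log2FC)
  expect_equal(derDegCorrelation(der, degAnti)$correlation$pearson_r, -1)

  expect_warning(out3 <- derDegCorrelation(der[1:2, ], degSame[1, ]),
                 "fewer than 3")
  expect_null(out3$correlation)
})
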
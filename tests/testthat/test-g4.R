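test_that("minimal canonical instances are matched and three runs are not", {
  one <- scanG4("GGGTGGGTGGGTGGG", bothStrands = FALSE)
  expect_equal(nrow(one), 1L)
  expect_equal(c(one$start, one$end), c(1L, 15L))
  expect_equal(nrow(scanG4("GGGTGGGTGGG")), 0L)
  expect_equal(nrow(scanG4("")), 0L)
  # minus-strand motif is found via the reverse complement
  rc <- as.character(reverseComplement(DNAString("GGGTGGGTGGGTGGG")))
  both <- scanG4(rc)
  expect_equal(both$strand, "-")
  expect_equal(c(both$start, both$end), c(1L, 15L))
  # loops may be 1-7 bases; an 8-base loop breaks the motif
  expect_equal(nrow(scanG4(paste0("GGG", strrep("A", 7), "GGGTGGGTGGG"),
                           bothStrands = FALSE)), 1L)
  expect_equal(nrow(scanG4(paste0("GGG", strrep("A", 8), "GGGTGGGTGGG"),
                           bothStrands = FALSE)), 0L)
})

test_that("scanner agrees with the exhaustive decomposition oracle", {
  set.seed(20)
  for (i in 1:60) {
    s <- randomSeq(200, probG = if (i %% 2) 0.35 else 0.25)
    got <- scanG4(s)
    want <- g4Oracle(s)
    expect_equal(got, want, info = paste("seq", i))
  }
})

test_that("motif calls are strand-symmetric", {
  set.seed(21)
  for (i in 1:20) {
    s <- randomSeq(300, probG = 0.33)
    rc <- as.character(reverseComplement(DNAString(s)))
    a <- scanG4(s)
    b <- scanG4(rc)
    expect_equal(nrow(a), nrow(b))
    expect_equal(unname(table(factor(a$strand, c("+", "-")))),
                 rev(unname(table(factor(b$strand, c("+", "-"))))))
  }
})

test_that("window sets tile chromosomes and flag motif windows", {
  genome <- DNAStringSet(c(chr1 = strrep("ACT", 120),   # 360 bp -> 3 windows
                           chr2 = strrep("AGT", 180)))  # 540 bp -> 5 windows
  win <- g4WindowSet(genome)
  expect_equal(length(win), 3L + 5L)
  expect_false(any(mcols(win)$has_motif))
  # a window with any ambiguous base is removed
  ng <- DNAStringSet(c(chr1 = paste0(strrep("A", 150), "N",
                                     strrep("A", 249))))
  expect_equal(length(g4WindowSet(ng)), 3L)

  # planted motifs are recovered as exactly the flagged windows
  cfg <- simConfig(seed = 6, n_chroms = 1, chrom_length = 1e5, n_genes = 8,
                   n_pos_corr_genes = 2, n_neg_corr_genes = 2,
                   n_deg_genes = 1, g4_density = 2)
  gen <- simulateGenome(cfg)
  win2 <- g4WindowSet(gen$genome)
  flagged <- win2[mcols(win2)$has_motif]
  expect_equal(length(flagged), length(gen$truth$g4))
  expect_true(all(overlapsAny(gen$truth$g4, flagged, ignore.strand = TRUE)))
})

test_that("enriched-region G4 overlap fractions hit the trivial limits", {
  genome <- DNAStringSet(c(chr1 = paste0(strrep("A", 100),
                                         "GGGTGGGTGGGTGGG",
                                         strrep("A", 185))))
  win <- g4WindowSet(genome)
  expect_equal(sum(mcols(win)$has_motif), 1L)
  onMotif <- GRanges("chr1", IRanges(95, 130))
  offMotif <- GRanges("chr1", IRanges(240, 280))
  expect_equal(ebG4Overlap(onMotif, win), 1)
  expect_equal(ebG4Overlap(c(onMotif, offMotif), win), 0.5)
  noG4 <- DNAStringSet(c(chr1 = strrep("ACT", 100)))
  expect_equal(ebG4Overlap(onMotif, g4WindowSet(noG4)), 0)
  expect_message(na <- ebG4Overlap(GRanges(), win), "undefined")
  expect_true(is.na(na))
})
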
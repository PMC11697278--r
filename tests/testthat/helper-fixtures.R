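suppressPackageStartupMessages({
  library(GenomicRanges)
  library(IRanges)
  library(Biostrings)
  library(SummarizedExperiment)
})

# small annotation set used by interval/annotation tests: one plus-strand
# gene on a 10 kb chromosome with a short first exon
tinyFeatures <- function() {
  gene <- GRanges("chr1", IRanges(1001, 4000), strand = "+",
                  seqlengths = c(chr1 = 10000))
  names(gene) <- "g1"
  exon <- GRanges("chr1", IRanges(c(1001, 2051), c(1050, 4000)),
                  strand = "+", seqlengths = c(chr1 = 10000))
  names(exon) <- c("g1", "g1")
  intron <- GRanges("chr1", IRanges(1051, 2050), strand = "+",
                    seqlengths = c(chr1 = 10000))
  names(intron) <- "g1"
  promoter <- GRanges("chr1", IRanges(1, 1000), seqlengths = c(chr1 = 10000))
  list(gene = gene, exon = exon, intron = intron, promoter = promoter)
}

# replicate design of one genotype: 3 biological replicates x 2 clones
tinyDesign <- function() {
  data.frame(sample = paste0("s", 1:6),
             bio_rep = rep(1:3, each = 2),
             clone = rep(1:2, 3))
}

# a small complete study bundle, built once per test session
.studyCache <- new.env(parent = emptyenv())
smallStudy <- function() {
  if (is.null(.studyCache$bundle)) {
    cfg <- simConfig(seed = 2, n_chroms = 1, chrom_length = 3e5,
                     n_genes = 30, n_pos_corr_genes = 6,
                     n_neg_corr_genes = 6, n_deg_genes = 3)
    .studyCache$bundle <- simulateStudy(cfg)
    .studyCache$cfg <- cfg
  }
  .studyCache$bundle
}
smallStudyConfig <- function() {
  smallStudy()
  .studyCache$cfg
}

# random read/region interval pair on one chromosome
randomReadsRegions <- function(nReads, nRegions, span = 1e6) {
  rs <- sample.int(span, nReads)
  re <- rs + sample(50:500, nReads, replace = TRUE)
  qs <- sample.int(span, nRegions)
  qe <- qs + sample(100:2000, nRegions, replace = TRUE)
  list(reads = GRanges("chr1", IRanges(rs, re)),
       regions = GRanges("chr1", IRanges(qs, qe)),
       rs = rs, re = re, qs = qs, qe = qe)
}

# quadratic brute-force interval counting (>= 1 bp overlap)
bruteCount <- function(x) {
  colSums(outer(x$rs, x$qe, "<=") & outer(x$re, x$qs, ">="))
}
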
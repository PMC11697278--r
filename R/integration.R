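#' Promoter damage signal per gene and genotype
#'
#' For each OG/input pair, SES-scaled input counts over promoters are
#' subtracted from the OG counts (floored at zero), each sample's damage
#' vector is divided by its library factor, and samples are collapsed to one
#' meta-feature value per genotype by the mean.
#'
#' @param ogCounts,inputCounts Promoter x sample count matrices (rows named
#'   by gene).
#' @param pairs Pairing table as from [samplePairs()] (columns `genotype`,
#'   `og`, `input`).
#' @param sesFactors Named numeric: SES input scale factor per OG sample.
#' @param libFactors Named numeric: library factor per OG sample (default 1).
#' @param promoterWidths Optional widths; zero-width (edge-truncated)
#'   promoters are excluded with a message.
#' @return Matrix genes x genotypes of mean normalized damage signal.
#' @export
promoterSignal <- function(ogCounts, inputCounts, pairs, sesFactors,
                           libFactors = NULL, promoterWidths = NULL) {
  if (is.null(libFactors))
    libFactors <- stats::setNames(rep(1, nrow(pairs)), pairs$og)
  keep <- rep(TRUE, nrow(ogCounts))
  if (!is.null(promoterWidths)) {
    keep <- promoterWidths > 0
    if (any(!keep))
      message(sum(!keep), " gene(s) with zero-width promoter excluded")
  }
  ogCounts <- ogCounts[keep, , drop = FALSE]
  inputCounts <- inputCounts[keep, , drop = FALSE]
  damage <- vapply(seq_len(nrow(pairs)), function(i) {
    s <- pairs$og[i]
    d <- subtractInput(ogCounts[, s],
                       inputCounts[, pairs$input[i]] * sesFactors[[s]])
    d / libFactors[[s]]
  }, numeric(nrow(ogCounts)))
  colnames(damage) <- pairs$og
  genos <- unique(pairs$genotype)
  out <- vapply(genos, function(g)
    rowMeans(damage[, pairs$og[pairs$genotype == g], drop = FALSE]),
    numeric(nrow(ogCounts)))
  rownames(out) <- rownames(ogCounts)
  out
}

#' Filter genes detected in both assays
#'
#' Keeps genes with nonzero (replicate-averaged) signal in at least
#' `minGenotypes` of the genotypes in both the damage and the expression
#' matrix.
#'
#' @param ogMatrix,rnaMatrix Gene x genotype matrices (replicates already
#'   averaged).
#' @param minGenotypes Minimum genotypes with nonzero signal per assay
#'   (default 3).
#' @return Character vector of retained gene ids.
#' @export
filterPresent <- function(ogMatrix, rnaMatrix, minGenotypes = 3) {
  genes <- intersect(rownames(ogMatrix), rownames(rnaMatrix))
  okOg <- rowSums(ogMatrix[genes, , drop = FALSE] > 0) >= minGenotypes
  okRna <- rowSums(rnaMatrix[genes, , drop = FALSE] > 0) >= minGenotypes
  genes[okOg & okRna]
}

# row z-scores with sample (n-1) standard deviation; zero-variance rows NA
.rowZ <- function(m) {
  mu <- rowMeans(m)
  sd <- sqrt(rowSums((m - mu)^2) / (ncol(m) - 1))
  z <- (m - mu) / sd
  z[sd == 0, ] <- NA_real_
  z
}

# Bottom-up candidate-class counts per internal node of an hclust tree, and
# extraction of maximal subtrees that are at least `frac` one class with at
# least `minSize` leaves. Scale-free alternative to gating on a fixed-k cut:
# a tight concordant blob qualifies regardless of how many background genes
# the dendrogram holds.
.pureSubtrees <- function(tree, candidate, minSize, frac) {
  n <- length(tree$order)
  merge <- tree$merge
  levs <- c("positive", "negative")
  cnt <- matrix(0, n - 1L, 2L, dimnames = list(NULL, levs))
  size <- integer(n - 1L)
  leafCnt <- function(v) as.numeric(candidate[v] == levs)
  for (i in seq_len(n - 1L)) {
    for (j in 1:2) {
      ch <- merge[i, j]
      if (ch < 0) {
        cnt[i, ] <- cnt[i, ] + leafCnt(-ch)
        size[i] <- size[i] + 1L
      } else {
        cnt[i, ] <- cnt[i, ] + cnt[ch, ]
        size[i] <- size[i] + size[ch]
      }
    }
  }
  parent <- integer(n - 1L)
  for (i in seq_len(n - 1L)) for (j in 1:2)
    if (merge[i, j] > 0) parent[merge[i, j]] <- i
  nodeClass <- rep(NA_character_, n - 1L)
  for (lab in levs)
    nodeClass[size >= minSize & cnt[, lab] / size >= frac] <- lab
  qualifies <- !is.na(nodeClass)
  maximal <- qualifies
  for (i in which(qualifies)) {
    p <- parent[i]
    while (p != 0L) {
      if (qualifies[p]) { maximal[i] <- FALSE; break }
      p <- parent[p]
    }
  }
  leaves <- function(i) {
    out <- integer(0); stack <- i
    while (length(stack)) {
      nd <- stack[length(stack)]; stack <- stack[-length(stack)]
      for (j in 1:2) {
        ch <- merge[nd, j]
        if (ch < 0) out <- c(out, -ch) else stack <- c(stack, ch)
      }
    }
    out
  }
  assigned <- rep(NA_character_, n)
  for (i in which(maximal)) assigned[leaves(i)] <- nodeClass[i]
  assigned
}

# per-gene sign concordance between two z-score vectors: "positive" when all
# constrained genotypes agree in sign, "negative" when all disagree;
# genotypes with a zero in either assay contribute no constraint, and fewer
# than 3 constrained genotypes leaves the gene unclassified
.signClass <- function(ogZ, rnaZ) {
  constrained <- ogZ != 0 & rnaZ != 0 & !is.na(ogZ) & !is.na(rnaZ)
  if (sum(constrained) < length(ogZ) - 1) return("unclassified")
  same <- sign(ogZ[constrained]) == sign(rnaZ[constrained])
  if (all(same)) "positive" else if (all(!same)) "negative"
  else "unclassified"
}

#' Concordance clustering of promoter damage and expression
#'
#' Genes are z-scored per row within each assay, embedded as the
#' concatenation of their damage and expression z-profiles, and clustered by
#' agglomerative hierarchical clustering (Euclidean distance, average
#' linkage) cut at `k`. Each gene gets a candidate sign classification:
#' positive when damage and expression deviate from their genotype means in
#' the same direction in every genotype, negative when always opposite. A
#' group of genes is reported positive or negative when at least
#' `reportFrac` of its members share that candidate class; because the right
#' cut granularity depends on how many genes surround a concordant blob, the
#' report is evaluated on maximal dendrogram subtrees (with at least
#' `minClusterSize` leaves) rather than on the fixed-`k` clusters, which are
#' still returned as cluster ids. A gene's final classification is its
#' candidate class provided it sits in a subtree reported for that class —
#' genes whose sign pattern agrees by chance but that do not sit in a
#' concordant group stay unclassified.
#'
#' @param ogMatrix,rnaMatrix Gene x genotype matrices over the same genotype
#'   columns (replicates averaged), typically pre-filtered by
#'   [filterPresent()].
#' @param k Number of clusters to cut for reporting (default 8).
#' @param reportFrac Concordant-group majority (default 0.8).
#' @param minClusterSize Smallest group size that can be reported (default
#'   20).
#' @return List with `records` (`data.frame`: gene, cluster, candidate,
#'   classification, plus `og_z_*` and `rna_z_*` columns), `clusters`
#'   (per-cluster size and reported class) and the `hclust` tree.
#' @export
concordanceCluster <- function(ogMatrix, rnaMatrix, k = 8,
                               reportFrac = 0.8, minClusterSize = 20) {
  genes <- intersect(rownames(ogMatrix), rownames(rnaMatrix))
  ogZ <- .rowZ(ogMatrix[genes, , drop = FALSE])
  rnaZ <- .rowZ(rnaMatrix[genes, , drop = FALSE])
  ok <- stats::complete.cases(ogZ) & stats::complete.cases(rnaZ)
  if (any(!ok))
    message(sum(!ok), " constant-signal gene(s) excluded from z-scoring")
  ogZ <- ogZ[ok, , drop = FALSE]; rnaZ <- rnaZ[ok, , drop = FALSE]
  genes <- genes[ok]
  emb <- cbind(ogZ, rnaZ)
  k <- min(k, nrow(emb))
  tree <- stats::hclust(stats::dist(emb, "euclidean"), method = "average")
  cl <- stats::cutree(tree, k = k)
  candidate <- vapply(seq_along(genes), function(i)
    .signClass(ogZ[i, ], rnaZ[i, ]), character(1))
  grp <- if (nrow(emb) >= 3)
    .pureSubtrees(tree, candidate, minClusterSize, reportFrac)
  else rep(NA_character_, nrow(emb))
  classification <- ifelse(candidate != "unclassified" & !is.na(grp) &
                             grp == candidate,
                           candidate, "unclassified")
  clusterClass <- vapply(seq_len(k), function(cid) {
    cls <- classification[cl == cid]
    for (lab in c("positive", "negative"))
      if (length(cls) && mean(cls == lab) >= reportFrac) return(lab)
    "unclassified"
  }, character(1))
  colnames(ogZ) <- paste0("og_z_", colnames(ogZ))
  colnames(rnaZ) <- paste0("rna_z_", colnames(rnaZ))
  records <- data.frame(gene = genes, cluster = cl, candidate = candidate,
                        classification = classification, ogZ, rnaZ,
                        row.names = NULL, stringsAsFactors = FALSE)
  clusters <- data.frame(cluster = seq_len(k),
                         size = as.integer(table(factor(cl, seq_len(k)))),
                         reported = clusterClass)
  list(records = records, clusters = clusters, tree = tree)
}

#' Correlate regional damage fold changes with expression fold changes
#'
#' Joins OG differential-enrichment fold changes (annotated to genes) with
#' the matching differential-expression fold changes per contrast, reports
#' the Pearson correlation of the paired log2 fold changes per feature class,
#' the fraction of DER genes that are differentially expressed, and — when
#' genes carry fold changes across several contrasts — an average-linkage
#' clustering of genes under the correlation distance 1 - Pearson r.
#'
#' @param derTable `data.frame` with columns `gene`, `contrast`,
#'   `feature_class`, `log2FC` (and logical `passes`).
#' @param degTable `data.frame` with columns `gene`, `contrast`, `log2FC`
#'   (and logical `is_deg`).
#' @return List with `pairs` (joined per-gene table), `correlation` (per
#'   feature class x contrast), `overlap` (per feature class: DER genes, DEG
#'   overlap count and fraction), and `tree` (`hclust` or NULL when fewer
#'   than 3 genes span at least 3 fold-change columns).
#' @export
derDegCorrelation <- function(derTable, degTable) {
  joined <- merge(derTable, degTable, by = c("gene", "contrast"),
                  suffixes = c("_og", "_rna"))
  if (nrow(joined) < 3) {
    warning("fewer than 3 overlapping genes: correlation skipped")
    return(list(pairs = joined, correlation = NULL, overlap = NULL,
                tree = NULL))
  }
  keys <- split(seq_len(nrow(joined)),
                list(joined$feature_class, joined$contrast), drop = TRUE)
  correlation <- do.call(rbind, lapply(names(keys), function(kk) {
    i <- keys[[kk]]
    r <- if (length(i) >= 3)
      stats::cor(joined$log2FC_og[i], joined$log2FC_rna[i])
    else NA_real_
    data.frame(group = kk, n = length(i), pearson_r = r)
  }))
  overlap <- do.call(rbind, lapply(split(joined, joined$feature_class),
                                   function(d) {
    der <- d[if (!is.null(d$passes)) d$passes else TRUE, , drop = FALSE]
    data.frame(feature_class = d$feature_class[1],
               n_der_genes = length(unique(der$gene)),
               n_overlap = length(unique(der$gene[der$is_deg])),
               fraction_deg = if (nrow(der)) mean(der$is_deg) else NA_real_)
  }))
  rownames(overlap) <- NULL
  # gene-level clustering on the paired fold-change profiles; a gene hit by
  # several regions of one class contributes its mean regional fold change
  agg <- stats::aggregate(cbind(log2FC_og, log2FC_rna) ~ gene + contrast,
                          data = joined, FUN = mean)
  wide <- stats::reshape(agg, direction = "wide", idvar = "gene",
                         timevar = "contrast")
  m <- as.matrix(wide[, -1, drop = FALSE])
  rownames(m) <- wide$gene
  m <- m[stats::complete.cases(m), , drop = FALSE]
  tree <- NULL
  if (nrow(m) >= 3 && ncol(m) >= 3) {
    cc <- suppressWarnings(stats::cor(t(m)))
    cc[!is.finite(cc)] <- 0
    tree <- stats::hclust(stats::as.dist(1 - cc), method = "average")
  }
  list(pairs = joined, correlation = correlation, overlap = overlap,
       tree = tree)
}
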
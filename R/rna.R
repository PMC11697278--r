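#' Two-group differential expression on RNA counts
#'
#' Runs the package's conditional NB exact test per gene between two
#' genotypes, normalizing by total-count library factors computed on the RNA
#' matrix, and flags differentially expressed genes at |log2FC| strictly
#' greater than `lfcMin` and p <= `pMax`.
#'
#' @param counts Gene x sample count matrix.
#' @param group Genotype label per sample (length `ncol(counts)`).
#' @param contrast Length-2 character: (test group, reference group); the
#'   fold change is test over reference.
#' @param pMax P-value bound, inclusive (default 0.05).
#' @param lfcMin Absolute log2 fold-change bound, exclusive (default 1).
#' @param dispersion Optional fixed common dispersion; estimated when NULL.
#' @return `data.frame` with `gene`, `log2FC`, `p_value`, `fdr`, `is_deg`;
#'   genes that are all-zero across both groups are excluded with a message.
#' @export
rnaDE <- function(counts, group, contrast, pMax = 0.05, lfcMin = 1,
                  dispersion = NULL) {
  if (length(contrast) != 2) stop("contrast must name two groups")
  idxA <- which(group == contrast[1])
  idxB <- which(group == contrast[2])
  if (length(idxA) < 2 || length(idxB) < 2)
    stop("need at least two replicates per genotype")
  factors <- libraryFactors(colSums(counts))
  sub <- counts[, c(idxA, idxB), drop = FALSE]
  zero <- rowSums(sub) == 0
  if (any(zero))
    message(sum(zero), " all-zero gene(s) excluded")
  sub <- sub[!zero, , drop = FALSE]
  res <- nbExactTest(sub[, seq_along(idxA), drop = FALSE],
                     sub[, length(idxA) + seq_along(idxB), drop = FALSE],
                     factorsA = factors[idxA], factorsB = factors[idxB],
                     dispersion = dispersion)
  out <- data.frame(gene = rownames(sub), log2FC = res$log2FC,
                    p_value = res$p_value,
                    fdr = stats::p.adjust(res$p_value, "BH"),
                    stringsAsFactors = FALSE)
  out$is_deg <- out$p_value <= pMax & abs(out$log2FC) > lfcMin
  rownames(out) <- NULL
  out
}

#' Overlap structure of DEG sets across genotypes
#'
#' @param sets Named list (one per genotype) of gene identifier vectors.
#' @return List with `pairwise` (matrix of pairwise intersection sizes, set
#'   sizes on the diagonal), `common` (genes in every set), `union_size`, and
#'   `shared_fraction` (per genotype, fraction of its genes found in at least
#'   one other set).
#' @export
degOverlap <- function(sets) {
  if (length(sets) < 2) stop("need at least two sets")
  k <- length(sets)
  pw <- matrix(0L, k, k, dimnames = list(names(sets), names(sets)))
  for (i in seq_len(k)) for (j in seq_len(k))
    pw[i, j] <- length(intersect(sets[[i]], sets[[j]]))
  shared <- vapply(seq_len(k), function(i) {
    others <- unique(unlist(sets[-i]))
    if (!length(sets[[i]])) return(NA_real_)
    mean(sets[[i]] %in% others)
  }, numeric(1))
  names(shared) <- names(sets)
  list(pairwise = pw,
       common = Reduce(intersect, sets),
       union_size = length(unique(unlist(sets))),
       shared_fraction = shared)
}
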
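#' Fit the signal extraction scaling (SES) decomposition
#'
#' Orders bins by increasing OG pulldown count (ties broken by input count,
#' then bin position) and computes, along that ordering, the difference
#' between the cumulative input fraction and the cumulative OG fraction. The
#' smallest index maximizing this difference splits low-damage background
#' bins (where input mass accumulates faster) from signal bins. The input
#' scale factor is the ratio of OG to input mass over background bins only,
#' and is applied to the input counts.
#'
#' When the difference is never positive (no separable signal) or all OG
#' counts are equal, the global ratio `sum(og) / sum(input)` is returned with
#' a warning and all bins are treated as background.
#'
#' @param og,input Aligned non-negative count vectors over the same bins.
#' @return An [SESResult-class].
#' @examples
#' fit <- sesFit(og = c(0, 1, 2, 10, 100), input = rep(5, 5))
#' inputScaleFactor(fit)  # 13/20
#' @export
sesFit <- function(og, input) {
  n <- length(og)
  if (length(input) != n) stop("og and input must have equal length")
  if (any(og < 0) || any(input < 0)) stop("counts must be non-negative")
  if (sum(og) <= 0 || sum(input) <= 0)
    stop("both libraries must contain reads")
  ord <- order(og, input, seq_len(n))
  if (max(og) == min(og)) {
    warning("all OG counts equal: no separable signal, using global ratio")
    return(new("SESResult", ordering = as.integer(ord), splitIndex = n,
               scaleFactor = sum(og) / sum(input),
               background = as.integer(sort(ord)), separable = FALSE))
  }
  p <- cumsum(input[ord]) / sum(input)
  q <- cumsum(og[ord]) / sum(og)
  d <- p - q
  k <- which.max(d)  # smallest argmax: largest (most conservative) background
  if (d[k] <= 0) {
    warning("cumulative difference never positive: using global ratio")
    return(new("SESResult", ordering = as.integer(ord), splitIndex = n,
               scaleFactor = sum(og) / sum(input),
               background = as.integer(sort(ord)), separable = FALSE))
  }
  bg <- sort(ord[seq_len(k)])
  sIn <- sum(input[bg])
  factor <- if (sIn > 0) sum(og[bg]) / sIn else sum(og) / sum(input)
  if (factor <= 0) factor <- sum(og) / sum(input)
  new("SESResult", ordering = as.integer(ord), splitIndex = as.integer(k),
      scaleFactor = factor, background = as.integer(bg), separable = TRUE)
}

#' Inter-sample library scale factors
#'
#' Factor of sample i is its library size divided by the mean library size
#' over all samples, so the factors average to one. These are the fixed
#' ("predetermined") normalization factors of the differential enrichment
#' test.
#'
#' @param librarySizes Named numeric vector of total counts per sample, or a
#'   [DamageExperiment-class] whose column sums are used.
#' @return Named numeric vector of factors with mean 1.
#' @examples
#' libraryFactors(c(a = 100, b = 300))  # 0.5, 1.5
#' @export
libraryFactors <- function(librarySizes) {
  if (is(librarySizes, "SummarizedExperiment"))
    librarySizes <- colSums(assay(librarySizes, "counts"))
  if (length(librarySizes) < 2) stop("need at least two samples")
  if (any(librarySizes <= 0)) stop("zero library size")
  librarySizes / mean(librarySizes)
}

#' Floored input subtraction
#'
#' Subtracts SES-scaled input counts from OG counts element-wise, flooring at
#' zero, yielding the damage signal vector.
#'
#' @param og OG pulldown counts.
#' @param scaledInput Input counts already multiplied by the SES factor.
#' @return `pmax(og - scaledInput, 0)`.
#' @export
subtractInput <- function(og, scaledInput) {
  if (length(og) != length(scaledInput)) stop("vectors must align")
  pmax(og - scaledInput, 0)
}
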
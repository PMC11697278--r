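# Internal helpers shared across modules.

# Polynomial rolling hash over UTF-8 bytes, kept exact in double precision
# (modulus < 2^31 so the product never exceeds 2^53).
.stableHash <- function(x) {
  h <- 0
  for (b in utf8ToInt(x)) h <- (h * 131 + b) %% 2147483629
  h
}

#' Derive a reproducible RNG seed for a named stream
#'
#' Each simulated artifact (a sample, the genome, a factor vector) draws from
#' its own RNG stream seeded by `seed` plus a stable hash of its name, so
#' adding samples to a simulation never perturbs previously emitted ones.
#'
#' @param seed Integer master seed.
#' @param name Character stream label.
#' @return An integer seed below 2^31.
#' @export
streamSeed <- function(seed, name) {
  as.integer((as.numeric(seed) + .stableHash(name)) %% 2147483629)
}

.setStream <- function(seed, name) set.seed(streamSeed(seed, name))

# NB draws parameterized by mean and dispersion (variance = mu + mu^2 * disp);
# dispersion 0 degenerates to Poisson.
.rnbinomMu <- function(n, mu, dispersion) {
  if (dispersion <= 0) stats::rpois(n, mu)
  else stats::rnbinom(n, mu = mu, size = 1 / dispersion)
}

.assertFraction <- function(x, what) {
  if (!is.numeric(x) || any(x < 0) || any(x > 1))
    stop(what, " must lie in [0, 1]", call. = FALSE)
  invisible(x)
}

# Region ids in BED-style 0-based half-open notation, used to key count
# tables and ground-truth sets.
regionIds <- function(gr) {
  paste0(as.character(GenomicRanges::seqnames(gr)), ":",
         GenomicRanges::start(gr) - 1L, "-", GenomicRanges::end(gr))
}
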
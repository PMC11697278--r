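---
title: "ogmap: methods and modelling choices"
author: "Package Author"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{ogmap: methods and modelling choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Scope

`ogmap` analyzes affinity-pulldown sequencing maps of genomic
8-oxo-7,8-dihydroguanine (OG) together with matched RNA-seq, in a study design
with four glycosylase genotypes (wild type, MUTYH-deficient, OGG1-deficient
and the double knockout), two technical clones per genotype and three
biological replicates per clone, each with a paired input control. The
package ships a complete synthetic-data generator with known ground truth, so
every estimator can be validated by parameter recovery rather than by
plausibility.

This vignette documents the statistical model behind each stage, the defaults
and why they are what they are, what the generator does and does not emulate,
and the numerical conventions that make results reproducible to the byte.

# The count model

All sequencing counts — OG pulldown, input, and RNA — are negative binomial:
a count with mean $\mu$ and dispersion $\phi$ has variance
$\mu + \phi\mu^2$. The generator draws with `rnbinom(mu =, size = 1/phi)`
and degrades gracefully to Poisson at $\phi = 0$. Per-sample library factors
(sequencing depth) multiply $\mu$; per-pair pulldown efficiencies multiply
the OG channel only. Bins are 1 kb by default (`makeBins`), incomplete
terminal bins are dropped, and any bin overlapping a blacklist interval by at
least one base pair is removed before counting.

# SES input scaling

`sesFit` implements signal extraction scaling: bins are sorted by ascending
OG count (ties broken by input count, then by original index), the cumulative
input fraction $p_k$ and cumulative OG fraction $q_k$ are computed along that
order, and the background/signal split is the smallest $k^\*$ maximizing
$p_k - q_k$. The input scale factor is the ratio of OG to input totals over
the background bins, and the scaled input is subtracted from OG counts with a
floor at zero (`subtractInput`).

**Truncation bias.** Because background bins are selected by low OG rank, the
OG sum over them is biased low: selecting the smaller order statistics of a
noisy variable truncates its upper tail. Empirically the relative bias of the
recovered factor is of order $0.7 \cdot \mathrm{CV}$ of the background
counts. At shallow, overdispersed backgrounds (mean 10, dispersion 0.1,
CV ≈ 0.45) the bias reaches 25–30 % regardless of bin count — it is a
property of the estimator, not of sample size. Recovery of a planted factor
to within 10 % is therefore demonstrated on deep, low-dispersion backgrounds
(mean 400, dispersion 0.002, CV ≈ 0.067), where the truncation term is small.
Users comparing SES factors across samples should match sequencing depth, or
treat the factors as comparable only up to this depth-dependent bias.

Degenerate inputs are handled explicitly: an all-constant OG vector or a
decomposition whose difference curve never becomes positive triggers a
warning and a fall-back to the global OG/input ratio, flagged by
`separable = FALSE` on the returned `SESResult`.

# Enriched-bin calling

Per technical replicate, `log2Ratio` computes
$\log_2((\mathrm{OG} + 0.5) / (\mathrm{scaled\ input} + 0.5))$; the 0.5
pseudocount keeps ratios finite for empty bins. `thresholdBins` retains bins
at or above the 95th percentile of that ratio (R quantile type 7, the
default). `replicateConsensus` keeps a bin if **both** clones call it in at
least 2 of 3 biological replicates, and `mergeBookended` merges exactly
adjacent (zero-gap) bins into regions, recording the bin count and the mean
log2 ratio. The percentile rule means roughly 5 % of bins are called per
replicate by construction; the consensus is what creates specificity.

# Differential enrichment

Between-genotype tests use a conditional negative binomial exact test
(`nbExactTest`): given region sums $Z_A$, $Z_B$ over $n_A$, $n_B$ replicates,
and using the fact that a sum of $n$ i.i.d. NB($\mu$, $\phi$) variables is
NB($n\mu$, $\phi/n$), the two-sided p-value is the sum of all probabilities
of the conditional distribution of $Z_A$ given $Z_A + Z_B$ that do not exceed
the observed probability (inflated by a relative $10^{-7}$ guard against
floating-point ties). In the Poisson limit ($\phi \to 0$) this reproduces the
exact binomial test. Counts are adjusted by library factors normalized to
mean one, and adjusted sums are rounded to the nearest integer before the
exact computation. Log2 fold changes use factor-adjusted group means with the
same 0.5 pseudocount, so they are always finite — including when one group is
all zero.

**Dispersion.** The default is a pooled method-of-moments common dispersion
(`estimateCommonDispersion`), solving
$\sum_r w_r (s^2_r - m_r \overline{1/f}) = \phi \sum_r w_r m_r^2$ across
regions. The pipeline's differential stage, however, operates on
input-subtracted damage signals floored at zero, whose background regions
have variance roughly proportional to the mean (subtraction noise) rather
than NB-quadratic; a single common $\phi$ fitted to that mixture is inflated
and costs sensitivity. `estimateTrendedDispersion` therefore bins regions
into 10 abundance deciles, fits the pooled moment estimator within each bin,
floors at zero and interpolates with `approx`, yielding a per-region
dispersion passed to the same exact test. `nbExactTest` accepts either a
scalar or a per-region vector.

Differential enriched regions (DERs) require $p \le 0.01$ (inclusive) and
$|\mathrm{log2FC}| > 0.5$ (strict); differential genes (DEGs, `rnaDE`)
require $p \le 0.05$ and $|\mathrm{log2FC}| > 1$. Benjamini–Hochberg FDR is
reported alongside for transparency but is not part of the calling rule.
Regions with fewer than 10 reads total are removed before testing
(`filterLowReads`).

# G-quadruplex motifs

`scanG4` finds canonical G4 motifs $G_{3+}N_{1-7}G_{3+}N_{1-7}G_{3+}N_{1-7}G_{3+}$
on both strands (the minus strand via reverse complement). Matching is
deterministic: matches are taken leftmost-first, each match is the shortest
completion from its start (a memoized recursive search over stem lengths,
with G-runs inside a motif capped at 10), and matched bases are consumed so
motifs never overlap on a strand. `g4WindowSet` tiles the genome into 100 bp
windows, removes windows containing ambiguous bases, and marks a window as
G4-positive if any motif overlaps it by at least one base pair.
`ebG4Overlap` reports the fraction of enriched regions overlapping a
G4-positive window.

**Generator sanitization.** Random sequence at realistic GC content contains
accidental canonical motifs (about two per megabase), which would make a
planted-motif truth set incomplete. The generator therefore breaks every
background G/C run of length ≥ 3 outside planted spans (replacing the third
base with T/A), plants motifs with loops drawn from {A, C, T} and non-G/C
flanks, and places at most one motif per 100 bp window. As a result the
planted motif set equals the scanner's match set exactly, and window-level
ground truth is exact. Real genomes, of course, are not sanitized; on real
data the scanner simply reports all canonical matches.

# OG/expression concordance

`promoterSignal` computes per-genotype mean promoter damage (OG minus
SES-scaled input, floored, library-normalized); genotype mean expression
comes from library-normalized RNA counts. `filterPresent` keeps genes with
signal in at least 3 of 4 genotypes in both assays. Each gene's two 4-vectors
are z-scored per row ($n-1$ denominator), concatenated into an 8-vector, and
clustered with `hclust` (Euclidean distance, average linkage).

A gene is a **candidate** positive (negative) if its damage and expression
z-scores agree (oppose) in sign across all genotypes, with zero entries
unconstrained (two or more unconstrained entries → unclassified). The sign
rule alone, however, labels ~14 % of null genes, because two independent
mean-zero 4-vectors agree in sign pattern with probability about 1/14 per
direction. Classification is therefore gated by cluster support: a candidate
is confirmed only if it lies in a maximal dendrogram subtree with at least
`minClusterSize` leaves (default 20) of which at least 80 % share its
candidate class. Subtree extraction is scale-free — unlike a fixed-$k$ tree
cut, it isolates a coherent 100-gene block among thousands of null genes
without diluting below the 80 % purity rule. `cutree` cluster identifiers at
`k` (default 8) are still reported for each gene. The gate is what the
biology predicts: genes whose expression tracks promoter damage share the
glycosylase-dependent damage profile (low in genotypes with intact OGG1,
high without it) and so form tight clusters.

`derDegCorrelation` then relates differential damage to differential
expression: DER fold changes are aggregated to the nearest gene, merged with
DEG fold changes by gene and contrast, and summarized as per-class Pearson
correlations, overlap fractions, and a $1 - r$ average-linkage tree over
feature classes.

# The synthetic generator

`simulateStudy` produces a full study bundle: genome FASTA, CpG islands,
genes with exon/intron structure and UTR fragments, blacklist, planted G4
motifs, OG/input counts over bins and feature-region sets, and RNA counts.
Randomness is organized as independent named streams: every artifact draws
from `set.seed(streamSeed(seed, name))`, where `streamSeed` hashes the stream
name into an offset below $2^{31}$. Adding a new artifact therefore never
perturbs existing ones, and identical seeds give byte-identical bundles.

What it emulates:

* NB sampling noise with per-sample depth factors (0.7–1.3) and per-pair
  pulldown efficiencies (0.8–1.25);
* GC-biased damage: enriched bins are planted with probability proportional
  to the cube of the GC rank, mimicking the affinity of oxidation for
  GC-rich regions;
* genotype-dependent promoter damage for coupled genes (damage profile
  2, 2.2, 8, 8.8 across WT, MUTYH, OGG1, DKO — low with intact OGG1, high
  without);
* linear OG-to-expression coupling for planted concordant genes (expression
  multiplier $\max(0.05,\ 1 \pm 0.8 z)$ of the damage z-score);
* planted differential regions (default 2-fold, half gains, half losses) and
  differential genes (default 4-fold), sampled disjointly from the coupled
  genes so the two truth sets do not contaminate each other.

What it does not emulate: read-level alignment artifacts, fragment-length
effects, mappability, copy-number variation, strand-specific damage, or
batch effects beyond scalar depth factors. The generator is a test harness
for the estimators, not a sequencing simulator.

# Defaults at a glance

| Parameter | Default | Rationale |
|---|---|---|
| `bin_size` | 1000 | standard damage-map resolution |
| `background_mean` | 10 | shallow-coverage regime for calling tests |
| `dispersion` | 0.1 | typical biological-replicate overdispersion |
| `frac_enriched_bins` | 0.01 | enriched fraction well below the 5 % percentile rule |
| `enrichment_fold` | 8 | clearly separable enrichment |
| `der_fold` / `deg_fold` | 2 / 4 | moderate effect sizes near the calling thresholds |
| percentile | 95 | per-replicate enrichment cut |
| consensus | both clones, ≥ 2 of 3 bio reps | replication before biology |
| DER rule | p ≤ 0.01 and \|lfc\| > 0.5 | strict fold, inclusive p |
| DEG rule | p ≤ 0.05 and \|lfc\| > 1 | conventional expression thresholds |
| pseudocount | 0.5 | finite ratios, half a read |
| G4 window | 100 bp | motif-scale resolution |
| `minClusterSize` | 20 | smallest cluster treated as evidence |

# Numerical conventions

Determinism to the byte rests on a handful of fixed choices: quantile type 7
everywhere; ties in SES ordering broken by input then index; ties in
feature-class assignment broken by a fixed priority (promoter, 5'UTR, 3'UTR,
exon, intron, downstream, intergenic); the *smallest* arg-max for the SES
split; `max.col(ties.method = "first")` for nearest-TSS ties; rounding of
factor-adjusted sums before the exact test; and output files written with
fixed column orders and no timestamps. `pipelineDigest` md5-sums every
output file in sorted order; two runs of the same bundle produce identical
digests.

# Problem sizes

The validation suite exercises the methods at the scales they target:
SES on $10^2$–$10^4$ bins against an exhaustive oracle; counting on
$10^4$ reads × $10^3$ regions against a brute-force scan; enrichment
recovery on $10^5$ bins; the exact test's null calibration on $10^4$
regions; differential recovery on 2 000 regions; G4 scanning against an
independent decomposition oracle on random 200-mers; concordance on 5 000
genes with 100 + 100 planted coupled genes; and the full pipeline on a small
bundle run twice for byte-identity.

# Limitations

* SES factors carry the depth-dependent truncation bias described above.
* The exact test conditions on region sums and assumes a shared dispersion
  within an abundance stratum; strong per-region dispersion heterogeneity
  within a stratum is not modelled.
* The concordance gate trades a small amount of sensitivity for specificity:
  coupled blocks smaller than `minClusterSize` will not be confirmed.
* The G4 scanner finds canonical motifs only; bulged or long-loop
  quadruplexes are out of scope.
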
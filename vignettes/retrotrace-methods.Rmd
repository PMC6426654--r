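---
title: "Quantifying stress-induced tRNA retrograde transport: methods and design"
author: "retrotrace"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying stress-induced tRNA retrograde transport: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(retrotrace)
```

# Scope

Under oxidative stress, cytoplasmic tRNAs are imported back into the
nucleus — retrograde transport, the reverse of canonical tRNA export. Two
complementary readouts quantify this movement, and `retrotrace`
implements both as a tested pipeline:

1. **Sequencing arm.** Small-RNA reads from nuclear and cytosolic
   fractions of control and peroxide-treated cells are assigned to mature
   tRNA transcripts *and* to their 3'-truncated variants, so that every
   read carries both a gene label and the number of 3' nucleotides it is
   missing. Counts feed a normalization, filtering and
   differential-localization analysis that separates *intact* tRNAs
   (full 3' CCA end) from *defective* ones (missing at least one 3'
   nucleotide).
2. **Imaging arm.** tRNA fluorescence in situ hybridization (tFISH)
   images are segmented — nuclei from the DAPI channel, cytoplasm from
   the probe channel — and each cell is summarized by its
   nuclear:cytoplasmic (N/C) mean-intensity ratio, with Dunnett or t-test
   group comparisons.

Both arms are exercised end-to-end against synthetic data generators that
emit machine-readable truth tables, so every statistical property the
package claims is demonstrated by computation, not assertion.

# The truncation-aware reference

A mature tRNA ends in the universal CCA trinucleotide; a tRNA that lost
part of its 3' end cannot be aminoacylated, which makes the missing-3'
count a biologically meaningful axis. `buildTruncationSet()` enumerates,
for each gene, the mature transcript (`missing_3p = 0`) and all variants
missing 1..K terminal nucleotides. K defaults to 13, deep enough to
capture the 5–8-nt truncations characteristic of nuclear tRNA pools
under stress while staying clear of tRNA-half territory; it is
configurable.

Conventions worth stating:

* Sequences are normalized to the DNA alphabet (U→T) on load, since
  reads are basecalled in DNA space.
* A genomically encoded CCA is treated identically to an enzymatically
  added one: `matureSequence()` appends CCA only when absent and is
  idempotent. The distinction has no observable consequence at the read
  level.
* `missing_3p` is counted against the CCA-mature transcript: k = 1 means
  the terminal A is missing, k = 3 the entire CCA.
* Pseudogenes are dropped by default at load time; FASTA headers are
  accepted in a native `gene|aa|anticodon|pseudo=` dialect or a
  permissive gtRNAdb-style form.

# Read assignment

For desk-scale and synthetic work the package ships its own matcher: a
read matches a reference entry when it equals the entry exactly or is a
3'-anchored suffix of it (reverse transcription of structured tRNAs
frequently stalls before the 5' end, so 5' truncation is evidence-free
rather than disqualifying; 5'-truncated reads are assigned on their 3'
suffix). A read is *unique* only when all its best matches fall in one
gene; ties across genes are flagged and excluded from counting, which
implements "uniquely mapped reads only" exactly. Within a gene an
ambiguous k resolves to the most intact variant. Reads shorter than
15 nt are discarded. Matching is hash-based per distinct read sequence,
so results are independent of read order.

Aligner output (SAM/BAM, against either the truncation reference or the
mature transcripts) is supported through `samAssignments()`: the
missing-3' count derives from the rightmost aligned reference position,
and 3' soft-clipped bases deliberately do not extend the alignment end —
clipping is treated as absence of evidence. Reimplementing a
general-purpose spliced aligner is out of scope.

# Localization statistics

**Normalization** is plain median-of-ratios: each sample's factor is the
median over genes of the ratio between the sample's count and the
per-gene geometric mean, genes with any zero excluded, medians taken in
log space. One property deserves emphasis because it is easy to
mis-state: scaling one sample by *s* does **not** scale that sample's
factor by *s* — the geometric-mean reference absorbs s^(1/m) — but
factor *ratios* scale by *s* and every log2 fold change is invariant
(exactly so at pseudocount zero). The estimator also presumes that most
genes are not differentially localized; simulated designs where the
majority of genes carry effects will show size-factor leakage into the
fold changes, as any median-of-ratios analysis would.

**Depth filters.** Both published rules are exposed: a base-mean filter
(mean of normalized counts strictly greater than 20 across all samples)
and a cytosolic-control filter (at least 20 reads in the cytosolic
control samples). The text behind the second rule is ambiguous between
per-sample and mean thresholds; the package defaults to the stricter
per-sample reading (`scope = "each"`) and offers `scope = "mean"`.

**Fold changes** are `log2((treated + c)/(control + c))` on normalized
means within a compartment, pseudocount c = 0.5 guarding zeros.
Per-replicate fold changes pair replicate i treated with replicate i
control, which is what a "consistent in both biological replicates"
criterion needs; `consistencyCall()` then demands every replicate
strictly beyond ±0.75 with a single sign.

**Testing.** The NB Wald test is a deliberately simplified stand-in for
a full DESeq2-style analysis, and the vignette is the right place to be
precise about what it does. Counts are modeled as NB with mean
`s_j * q_condition` and a dispersion shared across genes. The dispersion
is estimated by method of moments with three refinements that matter at
n = 2 per group, where the naive per-gene estimate is useless:

* the excess variance over the mean is pooled across genes as a ratio
  of sums, not averaged as per-gene ratios;
* `q^2` is corrected for its small-sample bias as an estimate of
  `mu^2` (`q^2 - v/n`);
* each gene is self-normalized by its squared mean before pooling, so a
  handful of highly expressed genes cannot dominate the estimate, and
  genes with mean below 10 are excluded.

With these, the estimate is near-unbiased (recovered 0.048–0.052 for a
true dispersion of 0.05 across seeds) and the Wald statistic against a
standard normal holds its nominal size (empirical type-I 0.046–0.058 at
alpha 0.05 over null simulations spanning dispersions 0.01–0.2, which
the acceptance suite re-verifies at every run). A per-gene dispersion
mode remains available for heterogeneous data, and a label-permutation
test is provided for designs too small to trust asymptotics — with
2 + 2 samples its p-value grid bottoms out at 1/6, which is the honest
resolution of such a design. Benjamini–Hochberg adjustment is used for
"adjusted p", matching the convention of the tools this analysis
simplifies. No shrinkage of fold changes is attempted; bit-exact
agreement with DESeq2 is a non-goal.

Heatmap row ordering uses complete-linkage hierarchical clustering on
Euclidean distances; only the leaf order is in scope, not plot
aesthetics.

# Image quantification

Segmentation follows an ImageJ-macro-style recipe. Nuclei: Otsu
threshold on the DAPI channel (bright foreground on dark background, the
"Otsu dark" convention), one binary dilation with a 3×3 square element,
hole filling, 8-connected labeling, particles under 500 px discarded and
border-touching particles excluded. Cytoplasm: the probe channel with
nuclear regions blanked is Otsu-thresholded, median-filtered at radius
2, labeled, and grown by two rounds of *non-merging* dilation before
each component is matched to the nucleus it surrounds.

Two interpretive choices are documented rather than hidden:

* **Non-merging dilation** is implemented as constrained dilation on the
  label image: a background pixel is claimed only when exactly one label
  appears among its 8-neighbors, so distinct cells can never fuse — the
  contract of the third-party ImageJ plugin the macro calls, whose
  source is not published. Additionally, growth is restricted to the
  pre-filter threshold support: dilation re-claims above-threshold
  pixels the median filter removed but never extends the measurement
  mask into sub-threshold background. Unconstrained growth would dilute
  the cytoplasmic mean with background and bias every N/C ratio upward
  by roughly the rim fraction (8–14% on hard-edged synthetic cells).
* The original workflow included manual background correction and
  freehand cell separation; automation replaces these, which is a stated
  deviation. No rolling-ball correction is applied by default.

Per-cell quantification supports two modes that are algebraically
identical on exact masks and are cross-checked to numerical precision:
mask mode (mean probe intensity over the nucleus ÷ mean over the
cytoplasm) and formula mode, the whole-cell raw-integrated-density
equation

$$N/C = \frac{RID_{Nuc}/Area_{Nuc}}{(RID_{Cyt} - RID_{Nuc})/(Area_{Cyt} - Area_{Nuc})}$$

where *Cyt* denotes the whole cell. Group statistics are one-way ANOVA
with Dunnett's multiple comparisons against a designated control
(multivariate-t adjusted, via `multcomp`) and the classical unpaired
two-tailed Student's t test; with a single comparison Dunnett reduces to
the t test, which the tests verify to 1e-6.

# Synthetic data: what it emulates, and what it does not

`simulateTrnaGenes()` draws gene bodies of 62–90 nt plus CCA with
anticodons consistent with the standard genetic code, defaulting to 323
genes — the size of a human high-confidence tRNA gene set with
pseudogenes removed. `simulateReads()` draws per-gene counts from a
negative binomial (default dispersion 0.05, typical of tight cell-line
replicates), splits each gene's reads over missing-3' classes by a
per-compartment spectrum, and writes every `(gene, k, sample)` count to
a truth table. Default spectra mirror the qualitative structure of
fractionated pools: ~50% intact in the cytosol with defects spread over
1–6 missing nt, 60% intact in the untreated nucleus, 30% intact in the
stressed nucleus with defect mass concentrated at 5–8 missing nt. The
default effect palette is null except one selenocysteine-like gene with
an 8.6-fold nuclear gain and a 2.7-fold cytosolic loss, echoing the
magnitude of the strongest published signal so smoke tests contain one
known positive. Depth defaults to 1e5 reads per sample — desk scale,
deliberately far below the 6–12 million of a production run; the
acceptance analyses state their sizes (300 genes for pipeline identity,
100 genes at depth 1e5 for spectrum recovery, 700 genes at mean depth
500/gene for fold-change recovery).

In noise-free mode counts are deterministic largest-remainder
apportionments of expectations, which is what makes the "profiler equals
truth exactly" identity a meaningful test of bookkeeping rather than of
luck.

`simulateImages()` places non-overlapping elliptical cells by rejection
sampling (nucleus semi-axes 14–19 px, comfortably above the 500 px
particle filter; Gaussian noise; SNR defined as (cytoplasm −
background)/noise SD). The DAPI chromatin signal is painted one pixel
inside the probe's nuclear domain, emulating the envelope-to-chromatin
offset of real stains; the macro's one-pixel nuclear dilation then lands
on the true nuclear domain, so clean images are recovered exactly rather
than with a systematic rim bias.

What the generators do **not** emulate — and therefore what passing
tests cannot certify about real data: reverse-transcription stops at
modified bases and their mapping artifacts, demethylase treatment
effects, ligation and PCR bias, quality-score structure, mitochondrial
versus nuclear-encoded tRNA composition, out-of-focus light, uneven
illumination, touching or overlapping cells, and the manual corrections
of the original imaging workflow.

# Numerical conventions

Transcript coordinates are 1-based inclusive. Reads ending more than K
nucleotides short are clamped into the k = K bin. Truncation-depth ties
within a gene resolve to the most intact variant. Ambiguity across genes
discards the read from counts but keeps it in the assignment table.
p-values are floored away from zero only by machine precision; BH
adjustment is monotone by construction. The permutation test includes
the observed labeling in its reference set. Apportionment ties break by
index order, making all noise-free outputs byte-reproducible. All
generators are deterministic given their seed.

# Known limitations

The NB test shares one dispersion across genes by default; strongly
gene-specific dispersion calls for the per-gene mode and a larger
design. The 2-replicate permutation option cannot reach p < 1/6.
Covariance-model (structure-space) coverage is replaced by
transcript-coordinate coverage. Image analysis is single-plane;
confluent cultures where cytoplasms touch before dilation will see
contested pixels left unassigned, and a cytoplasm component already
shared by two nuclei at threshold time is attributed to the
better-overlapping nucleus while the other cell is dropped with a
warning.
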
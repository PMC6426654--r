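# retrotrace

Quantitative analysis of stress-induced **tRNA retrograde transport** —
the import of cytoplasmic tRNAs back into the nucleus under oxidative
stress — from its two standard readouts:

* **Truncation-aware tRNA-seq profiling.** Small-RNA reads from nuclear
  and cytosolic fractions are assigned to mature tRNA transcripts and to
  all their 3′-truncated variants (0–13 missing nucleotides against the
  CCA end), yielding per-gene, per-truncation-depth count matrices,
  3′-end spectra and positional coverage. Downstream statistics call
  differential localization of *intact* (full 3′ CCA) versus
  *defective* (≥1 missing 3′ nt) tRNAs: median-of-ratios size factors,
  base-mean and cytosolic-control depth filters (threshold 20), log2
  fold changes per compartment, a negative-binomial Wald test with
  pooled method-of-moments dispersion, Benjamini–Hochberg adjustment,
  and replicate-consistency calls (|Log2FC| > 0.75, same sign in every
  replicate).
* **tFISH image quantification.** DAPI-seeded nuclear segmentation
  (Otsu, one 3×3 dilation, hole filling, ≥500 px particles, border
  exclusion), cytoplasm segmentation with *non-merging* dilation, and
  per-cell nuclear:cytoplasmic ratios in two algebraically identical
  modes — mean-intensity masks, or the whole-cell raw-integrated-density
  formula

  N/C = (RID_Nuc/Area_Nuc) / ((RID_Cyt − RID_Nuc)/(Area_Cyt − Area_Nuc))

  — followed by Dunnett or Student-t group statistics.

A third component generates synthetic inputs with machine-readable truth
tables: tRNA gene sets (default 323 genes), fractionated read sets with
known truncation spectra and fold changes under negative-binomial noise,
and two-channel cell images with known per-cell N/C ratios. Every
statistical property the package claims is validated against these
generators.

The package is aimed at RNA biologists analyzing nucleo-cytoplasmic
small-RNA fractionation experiments, and at anyone needing a tested
reference implementation of 3′-truncation-resolved tRNA quantification.

## Worked example

```r
library(retrotrace)

genes  <- simulateTrnaGenes(n = 60, seed = 42)       # gene set, CCA-mature
ref    <- buildTruncationSet(genes, maxMissing = 13) # 60 x 14 variants
design <- simDesign(genes, replicates = 2, depth = 5e4, seed = 42)
sim    <- simulateReads(design)                      # 8 samples + truth
vc     <- profileSamples(sim$reads, sim$samples, ref)
tab    <- localizationTable(vc)

# the simulated selenocysteine-like gene (8.6x nuclear gain, 2.7x
# cytosolic loss) as the localization table reports it:
sec <- tab[tab$gene_id ==
             geneIds(genes)[geneInfo(genes)$amino_acid == "Sec"][1], ]
sec[, c("gene_id", "variant_class", "base_mean", "lfc_nucleus",
        "lfc_cytosol", "p_nucleus", "adj_p_nucleus", "call_nucleus")]
#>    gene_id variant_class base_mean lfc_nucleus lfc_cytosol p_nucleus
#>  chrX-tr17     defective       712        4.26      -1.396  1.78e-38
#>  chrX-tr17        intact       369        2.40      -0.992  2.05e-10
#>  adj_p_nucleus call_nucleus
#>       1.07e-36           up
#>       1.23e-08           up
```

The gene is called consistently "up" in the nucleus (both replicate
Log2FCs above +0.75) with a strongly negative cytosolic fold change —
the retrograde signature. The nuclear intact fraction drops under
treatment exactly as the generator's spectra prescribe:

```r
cd <- as.data.frame(SummarizedExperiment::colData(vc))
truncationSpectrum(vc, cd$sample_id[cd$fraction == "nucleus" &
                                    cd$condition == "control"])["miss0"]
#> 0.602
truncationSpectrum(vc, cd$sample_id[cd$fraction == "nucleus" &
                                    cd$condition == "treated"])["miss0"]
#> 0.298
```

i.e. ~60% of nuclear reads are intact in control versus ~30% under
stress. The imaging arm on synthetic cells with a true N/C of 2:

```r
img <- simulateImages(nCells = 10, ratio = 2, noiseSd = 0.02, seed = 42)
nuc <- segmentNuclei(img$dapi)
cyt <- segmentCytoplasm(img$probe, nuc)
m   <- measureCells(img$probe, nuc, cyt)
c(cells = nrow(m), median_nc = median(m$nc_ratio))
#> cells = 10, median_nc = 1.978
```

All ten cells are recovered and the median ratio lands within ~1% of
truth.

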
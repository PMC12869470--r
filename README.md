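# nkatac

Compartment-stratified chromatin accessibility analysis for NK-cell
snATAC-seq.

## The problem

Human NK cells circulate as a CD56^bright^ minority and a cytotoxic
CD56^dim^ majority. Their accessibility landscapes differ mainly at
**distal regulatory elements (DREs)**: dim cells lose accessibility at
most DREs while promoters stay flat or gain slightly. Because the loss is
global, any normalization that assumes fold changes centre on zero —
median-of-ratios size factors, as in DESeq2-style workflows — absorbs the
shift into the size factors, *masking* the DRE loss and inventing a
promoter gain.

`nkatac` is for epigenomics analysts who need to detect and quantify that
situation. It provides:

* **Fragment QC** — per-cell TSS enrichment, nucleosome signal,
  blacklist ratio; cells kept with TSS enrichment > 2, nucleosome
  signal < 4, blacklist ratio < 0.05 and > 200 unique fragments.
* **Peak compartments** — promoter / CTCF-distal / DRE, with precedence
  promoter > CTCF > DRE. Promoters are called by TSS overlap (±2 kb) or
  the hyperconserved lymphocyte promoter motif M4 (`ACTAYRnnnCCCR`);
  CTCF peaks by ChIP intervals or a bundled CTCF PWM.
* **Differential accessibility**, per compartment, in two modes. With
  donor pseudobulk counts `K`, pseudocount `c` and size factors `s`:
  raw mode tests `log2(K + c)`, centered mode tests `log2(K/s + c)`,
  with `log2FC = mean_B − mean_A` and a two-sample t-test across donors
  (Welch, or pooled Student's). `compartmentShift()` summarizes mean
  log2FC per compartment — the raw-vs-centered contrast is the headline
  readout.
* **Co-accessibility** — Pearson correlation of binarized, metacell-
  pooled profiles for peak pairs within 500 kb, with the published
  cutoffs (0.05, 0.25) as presets, plus Hi-C loop-support annotation of
  DRE-promoter links (BEDPE anchors, 10 kb tolerance).
* **Allele-specific motif deltas** — for a SNP, scan reference and
  alternate haplotypes with IUPAC/PWM motifs on both strands and call a
  motif *gained*/*lost* from hits covering the SNP position (e.g. a C→T
  variant creating a BLIMP1 `CTTTCT` repressor site next to an intact
  STAT3 `TTCCNGGAA` site).
* **A deterministic synthetic-data generator** with planted ground truth
  (peak classes, shifted DREs, co-accessible pairs, low-quality cells,
  motif-creating SNPs) so every stage is testable offline.

## Worked example

```r
library(nkatac)
res <- runDemo("demo_out", seed = 7)
```

which prints (peaks tested per compartment, mean log2FC dim-vs-bright):

```
Compartment shift, dim57neg vs bright (raw vs centered normalization):
 compartment n_peaks_raw mean_log2fc_raw mean_log2fc_centered
 ctcf_distal          30     -0.02703202            0.2068839
         dre         120     -0.75335049           -0.5199237
    promoter          60      0.15148154            0.3849796
```

Read it as: the generator planted a 2-fold accessibility loss in 70% of
DREs and a +0.2 log2 promoter gain. The raw (non-centered) mode recovers
the DRE loss (−0.75 ≈ 0.7 × −1) and the modest promoter gain; the
centered mode drags the DRE mean toward zero and inflates every other
compartment — the masking effect, end to end. `demo_out/` contains each
stage's TSV (QC table, peak classes, both differential modes,
co-accessibility pairs, loop-supported links, SNP motif deltas) and a
JSON run manifest; rerunning with the same seed reproduces every file
byte for byte.

Individual stages are plain functions on standard containers
(`GRanges`, `DNAStringSet`, `SummarizedExperiment`): `computeCellQC()`,
`filterCells()`, `classifyPeaks()`, `pseudobulk()`,
`diffAccessibility()`, `compartmentShift()`, `binarizeAndPool()`,
`coAccessibility()`, `annotateLinks()`, `alleleMotifDelta()`. See the
methods vignette (`vignettes/nkatac-methods.Rmd`) for the models,
parameter defaults and design decisions.

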
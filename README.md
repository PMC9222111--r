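# SynergyDE

Does activating two receptors together regulate gene expression beyond
the sum of the single activations? `SynergyDE` answers this for bulk
RNA-seq from paired multi-arm designs (each animal contributes one
sample per treatment arm), the setting typical of primary-cell
stimulation experiments. It is aimed at bioinformaticians analyzing
receptor-crosstalk or drug-combination transcriptomics who need the
synergy calls to be statistically explicit and fully reproducible.

## What it computes

* **Consensus differential expression** under the blocked model
  `~ animal + treatment`: a gene is a DEG for a contrast when two
  independent negative-binomial procedures (edgeR and DESeq2) both give
  FDR < 0.05 *and* its mean expression reaches 5 FPM in one of the
  contrast groups. Timepoints are analyzed separately.
* **Qualitative synergy**: exclusive intersections of the DEG sets (an
  UpSet plot in tabular form), each cell labelled *stimulation* (genes
  regulated only when stimuli are combined), *inhibition* (regulation by
  one stimulus blocked by another) or *none*, driven by an explicit
  condition algebra such as `EU = {E, U}`.
* **Quantitative synergy** via a symmetric fold-change additivity null.
  Per replicate, fold changes are mapped to the symmetric scale
  (ratio r ≥ 1 ↦ r, r < 1 ↦ −1/r) and the combined response expected
  under additivity is

  ```
  f_exp = f1 + f2 − 1   (both f > 0)
  f_exp = f1 + f2 + 1   (otherwise)
  ```

  A paired t-test of measured vs expected fold changes across animals
  calls each gene stimulatory, inhibitory or neither.
* **Distribution-shift (KS) tests** comparing log2 fold-change
  distributions of shared genes between single and combined contrasts,
  up- and down-regulated genes separately.
* **Calibrated enrichment**: hypergeometric over-representation with the
  effect size E = (k/q)/(m/N), filtered at adjusted p ≤ 0.001 and E ≥ 3,
  plus a random-gene-set simulation that shows *why* 0.05 would be too
  lenient a threshold for minimal adjusted p-values.
* **Phenotype assay statistics**: per-experiment senescence gating by
  the crossing of control/treated intensity density estimates,
  senescent-cell fractions, 2^−ΔΔCt relative quantification with two
  reference genes, exact paired Wilcoxon tests and a single-pass
  chi-squared outlier check.
* **A synthetic-data generator** (`simulateCounts()` and friends) that
  emulates the paired factorial design — NB counts, per-animal block
  effects, planted additive/stimulatory/inhibitory genes on the
  symmetric-FC scale — so every stage is testable without external data.

## Worked example

```r
library(SynergyDE)

demo <- makeDemo(seed = 1)      # 500 genes, 6 animals, arms control/E/U/EU
res <- runPipeline(demo$experiment, demo$annotation,
                   outDir = "synergy-out",
                   algebra = list(EU = c("E", "U")),
                   calibrationRuns = 100, seed = 1)

sapply(res$deg[["24h"]], nrow)
#>   E   U  EU
#> 123 114  85
```

123, 114 and 85 genes pass the consensus rule for the three contrasts.
The exclusive intersections of those lists carry the qualitative labels:

```r
res$intersections[["24h"]][, c("signature", "n_genes", "label")]
#>   signature n_genes       label
#> 1    E&U&EU      64        none
#> 2         E      31  inhibition
#> 3         U      28  inhibition
#> 4       E&U      16  inhibition
#> 5      E&EU      12        none
#> 6      U&EU       6        none
#> 7        EU       3 stimulation
```

The `EU`-only cell (genes needing both stimuli) is stimulation; the
`E`-only and `U`-only cells (single-stimulus regulation absent when the
partner is added) are inhibition. The quantitative calls for the
combined arm:

```r
table(res$synergy[["24h_EU"]]$direction)
#>  inhibitory        none stimulatory
#>          58          79          23
```

Each called gene carries its per-replicate measured and expected fold
changes, e.g. `gene00026` measures a mean symmetric FC of −10.8 where
additivity predicts −2.9 (p = 1.8e−05, inhibitory — the response
overshoots downward beyond the additive expectation).

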
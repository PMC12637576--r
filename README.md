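# minisplice

Analysis and design toolkit for massively parallel splicing reporter
(minigene MPRA) experiments: pooled libraries of barcoded cassette-exon
minigenes measured across many cell types by paired-end amplicon
sequencing, where read 1 spans the spliced exon–exon junctions and
read 2 carries a 14-nt element barcode plus a 10-nt UMI.

The package covers the full computational arc of such a screen:

* **Library design** — exon filtering (length 10–120 nt, in-frame stop
  codons, restriction sites on either strand), intron trimming to
  215-nt variable regions with ≥75 / ≥30 nt intron minima, barcode
  assignment, and saturation mutagenesis (all 3·L single-nucleotide
  variants).
* **Quantification** — barcode/UMI extraction against a whitelist,
  junction k-mer isoform classification with cryptic-junction
  resolution, UMI deduplication, chimeric-read correction, and
  PSI / log-ratio matrices. `PSI = I/(I+E)`; the modelling scale is
  `log2((I'+1)/(E'+1))` after normalising counts to 1,000 reads, with
  an exact inverse back to PSI.
* **Specificity** — the Tau index and its PSI-adapted variant Upsilon,

  `upsilon = 2 * sum(1 - (x_i + 1)/(max(x) + 1)) / (N - 1)`,

  which is 0 for uniform profiles and 1 for single-cell-type-exclusive
  ones, plus reverse scores and the shortlisting rules
  (υ ≥ 0.7, or τ ≥ 0.7 & range ≥ 0.3, or τ_rev ≥ 0.85 & range ≥ 0.3).
* **Saturation mutagenesis analysis** — ΔPSI = parent − variant effect
  grids, Gaussian smoothing, robust z-score calling of
  mutation-sensitive regions (|z| ≥ 3, blocks ≥ 3, mean |ΔPSI| ≥ 0.25),
  and PWM log-odds scanning of called regions.
* **Predictive model** — a multi-scale convolutional network (kernels
  5/11/21) over one-hot 250-nt sequences predicts the cell-type mean
  splicing level; an expression encoder fused with the sequence latent
  predicts per-cell-type deviations. Supports by-sequence and
  by-cell-type train/test splits and in-silico saturation mutagenesis.
* **Generative designer** — a per-position transformer VAE (3 encoder
  blocks, 8 heads, single-block decoder) trained with reconstruction +
  KL + teacher-guidance losses against an ensemble of independently
  trained predictor "teachers"; one held-out teacher filters candidate
  designs. Supports PSI bin-switching (low/intermediate/high) and
  cell-context-specific design tasks.
* **Synthetic data** — generators for every input (bimodal PSI
  landscapes with planted cell-type-specific elements, replicate noise,
  barcoded paired-end reads with chimera swaps, expression profiles
  with a planted regulator) and a ground-truth sequence→PSI oracle, so
  the entire pipeline runs and validates with no external data.

The neural layers (im2col convolution, multi-head attention) are
implemented in the package with compiled kernels and hand-written
backward passes; no deep-learning framework is required.

## Worked example

Simulate a small screen, quantify it, and score specificity:

```r
library(minisplice)

cfg <- sim_config(n_elements = 50, n_celltypes = 3, n_replicates = 1,
                  read_depth = 2000, seed = 3)
lib <- simulate_library(50, seed = 3)
truth <- simulate_psi_matrix(cfg)
psi_true <- truth$psi[1:50, ]
rownames(psi_true) <- vapply(lib, `[[`, "", "id")

reads <- simulate_reads(lib, psi_true, cfg)
counts <- quantify_reads(reads, lib)
pm <- compute_psi(counts, samples = data.frame(
  sample = unique(counts$sample),
  celltype = sub("_r[0-9]+$", "", unique(counts$sample))))

common <- intersect(rownames(pm$psi), rownames(psi_true))
cor(as.vector(psi_true[common, colnames(pm$psi)]), as.vector(pm$psi[common, ]))
#> [1] 0.999
sqrt(mean((psi_true[common, colnames(pm$psi)] - pm$psi[common, ])^2, na.rm = TRUE))
#> [1] 0.019

upsilon_score(c(1, 0, 0, 0, 0))   # exclusive profile
#> [1] 1
upsilon_score(rep(0.6, 5))        # uniform profile
#> [1] 0
head(shortlist_specific(pm$psi))
```

At a simulated depth of 2,000 reads per element the recovered PSI
matrix correlates with the ground truth at r ≈ 0.999 with an RMSE of
about 0.02 (replicate beta noise included); with a 20% chimeric-read
rate, enabling `chimera_correction` cuts the RMSE roughly four-fold.
A shell entry point for the same steps lives at
`inst/cli/minisplice.R` (`quant`, `specificity`, `regions`,
`mutagenize`, `simulate` subcommands).

The predictive and generative models are exercised end-to-end on the
synthetic oracle in `tests/testthat/test-acceptance.R`; the methods
vignette (`vignettes/minisplice-methods.Rmd`) documents the models,
default parameters and the design decisions behind them.

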
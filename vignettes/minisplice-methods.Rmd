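---
title: "Models and methods in minisplice"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods in minisplice}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(minisplice)
```

minisplice analyses massively parallel splicing reporter (minigene MPRA)
experiments: pooled libraries of cassette exons with their flanking
introns, cloned between constant reporter exons, barcoded, transfected
into many cell lines, and read out by paired-end amplicon sequencing in
which read 1 spans the spliced exon-exon junctions and read 2 carries a
14-nt element barcode followed by a 10-nt UMI. This vignette documents
the statistical models, the algorithms, the tunable parameters and the
design decisions, in the order the data flows through the package.

## The quantification model

**PSI.** For each element and sample, exon inclusion is summarised as
percent spliced-in, `PSI = I / (I + E)`, where `I` and `E` are
UMI-deduplicated included- and skipped-isoform counts. Reads are
assigned to elements through the barcode (exact whitelist match or a
unique 1-mismatch rescue; ambiguous barcodes are dropped), classified
by junction k-mers (12-mers spanning each junction), and collapsed to
one count per `(barcode, UMI)` pair with a strict-majority vote on
conflicting calls (ties are discarded). UMI collapse is exact-match:
at roughly 4^10 possible UMIs and a few hundred UMIs per element,
collisions are negligible and no network clustering is attempted.
Elements with fewer than `min_umis = 10` informative UMIs in a sample
are masked rather than reported as unstable ratios. Reads that splice
at a non-annotated position are resolved by exact anchored matching of
the spliced middle segment back into the element reference and reported
as cryptic junctions with their breakpoint pair (requiring canonical
GT/AG by default); cryptic counts are tallied separately and excluded
from the PSI denominator by default, since the included/skipped
dichotomy is undefined for them.

**The log-ratio scale.** PSI is bounded and strongly bimodal, which is
awkward for regression models. Counts are therefore rescaled to a
total of 1,000 reads per element and transformed to
`log2((I' + 1)/(E' + 1))`. This map is invertible
(`logratio_to_psi()` solves `I' = (1001 * 2^L - 1)/(1 + 2^L)`), strictly
increasing in PSI, and approximately normal across a library. All
neural-network training happens on this scale; predictions are mapped
back to PSI exactly.

**Chimeric reads.** Pooled amplification swaps a fraction of barcodes
between molecules. Included-type reads carry element-identifying exon
sequence, so a read whose read-1 identity disagrees with its barcode is
discarded. Skipped chimeras are sequence-identical across elements and
cannot be removed read by read; instead their expected count per
barcode is estimated from the observed discordant (identifiable)
chimeras — for every observed discordant UMI there are on average
`(1 - f)/f` invisible skipped chimeras, with `f` the sample's overall
inclusion fraction — and subtracted from the skipped count. Barcodes in
which a *single* foreign identity exceeds `1 - purity` (default 10%) of
identity-resolved reads are removed outright: concentrated
contamination indicates a barcode collision from cloning, whereas
diffuse low-level swapping is handled by the read drop and count
debiasing. On simulated data with a 20% swap rate this correction cuts
the PSI error roughly four-fold.

**Differential splicing.** `call_differential()` tests replicate PSIs
between two groups with Welch's t-test on logit-PSI (any per-element
test can be plugged in), corrects with Benjamini-Hochberg, and calls
significance jointly: `|dPSI| > 0.1` and `FDR < 0.05`.

## Specificity indices

Tau is the classical specificity index,
`tau = sum(1 - x_i / max(x)) / (N - 1)`. On PSI profiles it
overstates specificity when the dynamic range is compressed (a profile
of 0.02 everywhere with a maximum of 0.05 scores like an exclusive
exon). Upsilon anchors the normalisation to the absolute PSI scale,
`upsilon = 2 * sum(1 - (x_i + 1)/(max(x) + 1)) / (N - 1)`: it is 0 iff
the profile is constant and 1 iff exactly one cell type has PSI 1 and
the rest 0, and — unlike Tau — it is *not* invariant to rescaling a
profile, by design. Reverse scores are the same indices on `1 - x` and
flag single-cell-type *skipping*. Elements are shortlisted when
`upsilon >= 0.7` (either direction), or `tau >= 0.7` with dynamic range
`>= 0.3`, or `tau_rev >= 0.85` with dynamic range `>= 0.3`; ranking
uses the larger of the forward and reverse Upsilon (the forward-only
ranking is available via `rank_by = "forward"`). Elements observed in
fewer than 3 cell types are not scored; an all-zero profile has no
evidence of specificity and scores 0 with a degeneracy flag.

## Mutation-sensitive regions

Saturation mutagenesis measures every single-nucleotide substitution of
a parent. Effects are `dPSI = parent PSI - variant PSI` (positive =
the mutation reduces inclusion; `flip_sign` reports the opposite
convention). Per-position means are smoothed with a discrete Gaussian
kernel (sigma 2 positions by default, reflective boundary, truncated at
four sigma), standardised with the robust z-score
`(smoothed - median) / (IQR / 1.349)`, and maximal runs of positions
with `|z| >= z_min` of length `>= min_block` are emitted as regions when
the mean *raw* effect inside the run is at least `min_mean_effect`
(defaults 3 / 3 / 0.25 for cell-type-specific screens; constitutive
screens conventionally use z 4 and block 2). Two numerical notes: a
perfectly constant baseline has zero IQR and is flagged degenerate (no
calls), and because smoothing spreads a bump over its ~±2-sigma skirt,
the marked run is wider than the underlying lesion, so the run mean
dilutes by roughly `width/(width + 4 sigma)`; a 5-position bump must
have effects well above 0.25 for the run mean to clear the threshold.
Called regions are scanned against user-supplied PWMs with additive
`log2(p/0.25)` scores, reporting hits at log-odds >= 10.

## The synthetic-data generators and the ground-truth oracle

Every input the pipeline consumes can be simulated. The generators'
defaults describe the study conditions used in the package's tests:

* **PSI landscape** — each element draws a base PSI from the equal
  mixture `Beta(0.3, 3) + Beta(3, 0.3)` (most exons near 0 or 1);
  cell-type values jitter around the base on the logit scale (sd 0.25);
  a configurable fraction of elements is planted as cell-type-specific
  by shifting one cell type's PSI by 0.8 toward the opposite extreme.
  Planting happens on extreme-base elements, where such a shift both
  fits in [0, 1] and corresponds to the biology of a cell-type-specific
  exon.
* **Replicates** — beta noise with concentration 200 around the
  cell-type PSI, which reproduces the replicate correlations (>~0.8)
  typical of well-powered screens at the default depth.
* **Reads** — read 1 is the exact junction-spanning sequence of the
  included or skipped isoform (Bernoulli at a beta-distributed
  replicate PSI, i.e. beta-binomial over UMIs), read 2 is barcode + a
  UMI drawn uniformly from 4^10 space; a `chimera_rate` fraction of
  reads keeps read 1 and receives another element's barcode. No
  sequencing-error model is applied to barcodes by default; barcode
  errors are exercised separately in tests via injected mismatches.
* **Expression** — one designated regulator gene carries the oracle's
  per-cell-type level exactly; the remaining genes are i.i.d. gamma
  noise on a log scale.

The **oracle** maps (sequence, cell type) to PSI through a logistic
model: a baseline from the element's own splice-site strength — the
best donor-PWM match and the best 17-nt core acceptor-PWM match
anywhere in the variable region (a strongest-site rule, which makes the
ground truth a position-independent function of sequence) — plus
motif terms. Each motif contributes
`weight * sigmoid(best log-odds - midpoint)`, optionally multiplied by
the cell type's regulator expression level (gating). The default
oracle plants a regulator-gated enhancer (consensus `TGCATG`, the
neuronal splicing-enhancer hexamer) and an ungated silencer
(`TCTTCTT`). The link slope (2.2) is chosen so the simulated library
reproduces the strongly bimodal PSI landscape seen in real screens.
With all motif weights zero the oracle is identical across cell types,
and increasing a gated motif's match strictly increases PSI exactly in
regulator-expressing cell types.

What the oracle does *not* emulate: RNA secondary structure,
position-dependent motif grammar, competition between overlapping
elements, plasmid copy number or transfection efficiency. Passing the
closed-loop tests therefore demonstrates that the inference and design
machinery works when its assumptions hold, not that real splicing is
this simple.

## The sequence-to-PSI predictor

The predictor is trained in two stages, mirroring how the measurement
decomposes:

1. **Pretraining (sequence only).** A convolutional trunk over the
   one-hot sequence (4 x 250; variable regions are padded into a fixed
   pseudo-random backbone at a constant offset; channel order A/C/G/T)
   predicts the element's mean log-ratio across cell types. The trunk
   applies multi-scale kernels of sizes 5, 11 and 21 in parallel
   (capturing core splice-site motifs, extended contexts and the
   acceptor region), batch normalisation, ReLU, optionally residual
   multi-scale blocks, and a global pooled readout feeding a dense
   head. Targets are standardised internally; training is minibatch
   Adam with decoupled weight decay and MSE loss, with a 10%
   validation split and best-validation early stopping.
2. **Expression fine-tuning.** Per-gene-standardised expression
   profiles pass through a two-layer encoder; the expression latent is
   concatenated with the (frozen) pooled sequence latent and a dense
   deviation head is trained on the residuals
   `logratio[element, celltype] - mean_c logratio[element, ]`. The
   final prediction is exactly mean head + deviation head, converted
   to PSI through the inverse log-ratio map and clipped to [0, 1].

Several defaults here were settled empirically on the oracle benchmark
and deserve explanation:

* **Pooled readout.** The default readout is the global *max* per
  channel (`pool_mode = "max"`). The biology the trunk must capture is
  dominated by presence/strength of localised motifs; max pooling is
  the matched readout and generalised far better than average pooling
  on the benchmark (average and concatenated mean+max remain
  available).
* **Depth at small sample sizes.** With ~2,000 training sequences the
  full-depth residual trunk has enough capacity to interpolate the
  training set through pooled-feature "hashes", and held-out accuracy
  collapses while training error vanishes. The desk-scale benchmark
  configuration therefore uses the multi-scale stem with `n_blocks = 0`
  and a small (16-unit) head; residual blocks (`n_blocks = 3`,
  the default) become useful only with much larger libraries. Early
  stopping, weight decay and the small head are the corresponding
  regularisers.
* **Trunk freezing.** Fine-tuning keeps the trunk frozen. This lets
  sequence latents be computed once (a large speed win) and, at these
  sample sizes, avoids destroying the pretrained representation; the
  deviation head and expression encoder are small enough to train in
  seconds.
* **Optimiser.** Adam with decoupled weight decay at 2e-3, batch 16,
  with a cosine learning-rate decay to a quarter of the initial rate.
  Small batches matter: the benchmark budget is a few thousand
  optimiser steps, and motif detectors form per *step*, not per epoch.
* **Batch-norm recalibration.** With small batches the running
  batch-norm moments lag the population statistics, which distorts
  eval-mode predictions; the moments are therefore recomputed as exact
  streaming averages over (a subsample of) the training data before
  each validation pass and for the final model.

`in_silico_mutagenesis()` scores all `3 * length` single-nucleotide
variants of a parent and emits the same `effect_profile` structure as
the experimental screen, so `call_sensitive_regions()` applies
unchanged to model predictions.

On the oracle benchmark (2,000 sequences, 10 cell types, one planted
regulator; the configuration and sizes are printed by the acceptance
tests) the pretrained model reaches held-out r >= 0.8 on the mean
log-ratio, and adding expression raises the per-(element, cell type)
correlation in both the by-sequence and the by-cell-type split — the
directional ablation the architecture was designed around.

## The teacher-guided sequence designer

The designer is a per-position transformer VAE: linear projection of
the one-hot input plus learned positional embeddings, three pre-norm
encoder blocks with eight attention heads, per-position Gaussian
latents `(mu, log sigma^2)` sampled with the reparameterisation trick,
a single-block decoder, and a linear projection to per-position
nucleotide logits (sigmoid at evaluation; discretisation is
per-position argmax with ties broken in channel order A/C/G/T, so
designs are always valid, length-preserving DNA).

Training minimises
`lambda_recon * BCE + lambda_kl * KL + lambda_disc * MSE(D(xhat), y_target)`,
where `D` is the mean prediction of the guidance teachers —
independently trained predictor models with distinct seeds and 80/20
splits, one of which is held out of training entirely and used only to
filter candidate designs. Losses are summed per sequence and averaged
over the batch (so the KL of a single unit at `mu = 1, logvar = 0` is
exactly 1/2).

Design decisions that were genuinely open:

* **Teacher coupling.** The decoder output reaches the teachers as the
  *discretised* argmax sequence, with gradients routed through a
  tempered per-position softmax (straight-through). Feeding the soft
  probabilities directly lets the optimiser exploit superpositions of
  bases that no discrete sequence realises — the guidance loss
  collapses while the discretised designs are inert or nonsensical.
  The soft coupling remains available (`teacher_coupling = "softmax"`).
* **Dynamic weighting.** The guidance weight ramps from zero over the
  first part of training (`guidance_warmup`, default 30% of steps), so
  the VAE first learns to reconstruct and guidance then steers
  sequences that are already on the data manifold.
* **Ensemble size.** Guidance averaged over many teachers resists
  adversarial drift: with very few teachers the generator finds
  sequences that fool them all simultaneously and the held-out filter
  rejects everything. The default ensemble is 10 (9 guidance + 1
  filter); the closed-loop tests document the size they use.
* **Targets.** Bin targets use the PSI midpoints 0.05 / 0.5 / 0.95
  mapped to the log-ratio scale; context-specific targets are signed
  dPSI values in the teachers' output space.
* **Desk-scale optimisation.** The published settings (Adam 1e-4,
  batch 128, 10 epochs) correspond to tens of thousands of optimiser
  steps on an atlas-scale library. At a few hundred training
  sequences the same recipe performs almost no optimisation, so the
  desk-scale configurations raise the learning rate to ~1e-3 and scale
  `lambda_disc` up to compensate for the much smaller number of
  guidance steps; the KL weight also sets design diversity around each
  parent (its stated role), and `logvar` is clamped at ±6.

* **Generation-time latent refinement.** Teacher saliency demonstrably
  encodes how to *construct* target sequences (greedy hill-climbing on
  the ensemble gradient converts near-zero-PSI parents into
  high-inclusion sequences within a few dozen substitutions), but at a
  few hundred training sequences the VAE cannot amortise that
  optimisation into its weights. `generate_designs()` therefore
  optionally refines each sampled latent with a few normalised gradient
  steps on the guidance objective, differentiating through the decoder
  (straight-through to the teachers, with a soft backward temperature
  so the path does not saturate). Refinement targets are placed at the
  far edge of the requested bin (PSI 0.99 / 0.02 rather than the
  0.95 / 0.05 training midpoints): imperfect teachers regress extreme
  sequences toward the mean, and midpoint targets leave designs
  stranded at the 0.8 / 0.2 bin boundaries.

`filter_designs()` implements the two-stage screen: all designs of a
parent are dropped when the filter teacher's prediction for the parent
misses its measured value by more than `parent_accuracy_max` (0.2 PSI),
and an individual design is kept only when the filter prediction lands
in the requested bin (or within `target_tolerance` of a numeric
target). `evaluate_designs()` scores measured (or oracle) outcomes,
with bootstrap CIs and fold-enrichment against a supplied background
rate.

## Problem sizes and reproducibility

All stochastic functions take explicit seeds and are bit-reproducible
under them; derived seeds keep independent streams below 2^31. The
test-suite problem sizes were chosen as the package's desk-scale study
conditions: quantification round trips use 200 elements x 5 cell types
at 10,000 reads per element; the predictor benchmark uses 2,000
sequences x 10 cell types; the closed-loop design benchmark uses a
2,000-element library, teacher ensembles as documented in the tests,
and ~25 parents x 8 designs per task. The compiled kernels (im2col
convolution, multi-head attention) are exact implementations checked
against pure-R references and numerical gradients in the test suite.

## Known limitations

* The neural models are small, CPU-sized networks; the defaults are
  tuned for libraries of a few thousand elements, not 46k-element
  atlases.
* The oracle's position-independent strongest-site rule makes the
  benchmark learnable by pooled convolutional readouts; real splicing
  has positional grammar the benchmark does not test.
* Chimera correction estimates contamination from identifiable reads
  only; with extreme swap rates and very unbalanced pools the
  subtraction is approximate.
* The designer's success depends on teacher quality; with weak
  teachers the filter model rejects most designs rather than passing
  bad ones (fail-closed, but yield suffers).
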
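---
title: "Predicting per-residue disorder from embeddings: models, statistics and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting per-residue disorder from embeddings}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chezod)
```

## The problem and the measurement scale

Intrinsically disordered regions (IDRs) are stretches of a protein that do
not adopt a unique three-dimensional structure in isolation. The most
nuanced experimental per-residue measure of disorder available today is the
CheZOD score: a Z-score computed from the difference between NMR-observed
chemical shifts and computed random-coil shifts. Low scores mean disorder,
high scores mean order; the conventional decision threshold is 8
(disorder: score ≤ 8, order: score > 8), and observed scores in curated
NMR sets span roughly −5.6 to 16.2. Score files use a sentinel convention:
any value ≥ 900 marks a residue for which no valid score could be measured,
and such residues are excluded from training and evaluation
(`filter_invalid()`).

This package predicts continuous CheZOD scores for every residue of a
protein from an L×N matrix of per-residue features — typically the hidden
states ("embeddings") of a protein language model, with N = 1024, but any
per-residue feature matrix works, including 20-dimensional one-hot
encodings (`one_hot_encode()`, alphabetical column order, `X` all-zero).
Generating embeddings is upstream of this package: matrices arrive through
an HDF5 container (`read_embeddings()`), one float dataset per protein.

## The prediction heads

Five deliberately shallow heads are implemented (`model_spec()`,
`fit_disorder_model()`):

* **linreg** — ordinary least squares from all N dimensions to the score,
  with intercept, fit in closed form.
* **linreg1d** — the same regression restricted to one embedding dimension.
  In 1024-dimensional language-model embeddings a single dimension
  (index 295 by convention, the package default) carries most of the
  disorder signal; this head quantifies exactly how much.
* **logreg** — ridge logistic regression on the binarized scores,
  predicting the probability of order. The penalty is L2 with an effective
  strength of 1 in the "sum-of-losses" convention, which maps to a glmnet
  `lambda` of `1/n` on its mean-loss scale; this is exposed as
  `logreg_lambda` for sensitivity analyses.
* **ann** — a per-residue two-layer feed-forward network (default 32
  hidden units, Tanh). No canonical reference topology exists for this
  head, so the width is a package default and is tunable.
* **cnn** — the main model: two convolutional layers along the sequence,
  kernel length 5 in **both** layers (a single stated kernel size is
  applied symmetrically), 28 channels after the first layer, Tanh between
  the layers, and zero padding of `(kernel_len−1)/2` per side in each layer
  so that every residue — including in sequences shorter than the kernel —
  receives exactly one output. For N = 1024 this is
  1024·5·28 + 28 + 28·5 + 1 = 143 529 free parameters (`n_parameters()`).

The iterative heads (ann, cnn) train with MSE loss and Adam
(learning rate 0.001, amsgrad on, weight decay 0.001 added to the
gradient), one **protein per optimizer step** — variable-length sequences
make residue-level batching awkward and per-protein steps avoid padding
artifacts. An epoch is one pass over the shuffled training proteins.
Proteins are split 90/10 into training and validation; training stops after
`patience = 10` epochs without validation-loss improvement (hard cap
`max_epochs = 200`), and the parameters of the best validation epoch are
restored, with ties broken toward the earliest epoch. Every random choice —
split, initialization, shuffling — derives from `spec$seed` (default 42),
so a fit is bit-reproducible.

Residues without valid scores are dropped before presentation for every
head. For the CNN this differs from removing them *before embedding
generation* (which keeps the pLM's context intact); with precomputed
embeddings of full sequences that ordering cannot be reproduced, so the
package drops invalid positions from both the embedding matrix and the
score vector and documents the discrepancy here.

## Evaluation statistics

`evaluate_predictions()` implements the field's standard protocol:

* **Spearman ρ** (`spearman_rho()`) is computed as the Pearson correlation
  of the average-rank vectors, from first principles. A constant input
  yields a distinguished `NA`, never a silent zero.
* **AUC** (`auc()`) treats *order* as the positive class after binarizing
  the truth at 8. Ties between the classes contribute ½ by default (the
  convention of the common toolkit implementations); the literal strict
  indicator is also available, and the two differ by exactly
  `n_tied_pairs / (2 m⁺ m⁻)` — an identity the test suite asserts.
* **Bootstrap**: `bootstrap_stat()` draws 1000 resamples of the m residue
  pairs with replacement, reports the mean statistic over the resamples,
  and a 95% CI as 1.96 × the population (divide-by-n) standard deviation of
  the per-resample statistics. Resampling residues (not proteins) matches
  the "sample of the size of the test set" protocol in which m counts
  paired observations; per-protein resampling is available through
  `protein_ids` for block-bootstrap sensitivity checks. Degenerate
  resamples on which the statistic is undefined are dropped and counted,
  never imputed.
* **ROC curves** (`roc_curve()`) are the monotone staircase over grouped
  thresholds; their trapezoidal area equals the ties-as-half AUC to
  machine precision.
* **Stratified evaluation**: `classify_regions()` partitions residues into
  ORDERED, SHORT_DISORDER and LONG_DISORDER (a disordered residue is LONG
  when its maximal run of consecutive scores ≤ 8 spans at least
  `lmin = 30` residues — the conservative minimum length at which
  disordered regions are reliably distinguishable from long loops), and
  `per_class = TRUE` evaluates each stratum as a pooled subset.

## AlphaFold2-derived disorder proxies

AlphaFold2 model files store the per-residue pLDDT in the B-factor column.
`extract_plddt()` reads single-model PDB files, asserts all atoms of a
residue agree (tolerance 1e-3) and returns one value per residue. Three
proxies are derived (`smoothed_measures()`): the raw pLDDT, the pLDDT
smoothed over 21 consecutive residues, and the relative solvent
accessibility smoothed over 25 residues (RSA and "experimentally resolved"
values are ingested from per-residue TSV tables; computing them from
coordinates is upstream). Orientation metadata records that low pLDDT, low
experimentally-resolved probability and **high** RSA indicate disorder, so
evaluation can negate consistently.

Smoothing (`smooth_scores()`) uses the shrunken-window rule: position i
averages `[i−h, i+h]` with `h = (window−1)/2`, and within h of a terminus
the terminus side shrinks to the positions that exist while the other side
keeps its h positions. The stated rule covers only positions near one
terminus of a long sequence; for sequences shorter than the window this
implementation extends it symmetrically — both sides are truncated at the
termini — which is the only choice that keeps the operator equal to a
clipped-window mean everywhere.

`prefilter_analysis()` asks whether cheap disorder predictions can decide
for which proteins an expensive structure prediction is worth running. With
"wanted" defined as mean pLDDT ≥ 70 and a threshold t on the mean predicted
score, it reports cost = FN/P (wanted proteins missed), gain = (FN+TN)/All
(predictions avoided) and accuracy = (TP+TN)/All. The boundary is strict
(`mean < t` filters a protein out), so a protein with mean exactly t is
retained.

## Organism disorder spectra

`build_spectrum()` reduces all predicted scores of an organism to an 8-bin
histogram over the fixed edges (−15, −11.125, −7.25, −3.375, 0.5, 4.375,
8.25, 12.125, 16), normalized by the number of binned residues; proteins
longer than 9000 residues are excluded (and counted), mirroring the
practical length cap of proteome-scale prediction runs. Only the edges of
these bins are conventionally fixed; this implementation closes each bin on
the left, closes the final bin on both sides, and by default clips
out-of-range scores to the nearest edge — predictions can exceed the
training score range, and clipping keeps the normalized spectrum summing
to 1. `pca_project()` centers the spectra without variance scaling (the
`prcomp` default) and applies a deterministic sign convention (each loading
vector's largest-magnitude entry is positive), so projections are
reproducible across platforms.

## The synthetic generator: what it emulates and what it does not

`generate_dataset()` makes the whole pipeline testable without downloads by
planting the three structures that real embeddings exhibit:

1. **One dominant disorder dimension** — a latent signal z enters a single
   embedding column (`informative_dim_index`).
2. **Amino-acid cluster structure** — each residue's row receives a fixed
   unit-norm centroid for its amino acid (`aa_cluster_scale`), emulating
   the observation that raw embeddings cluster by residue type first.
3. **Contiguous disordered regions** — z is a moving average of white
   noise over `region_smoothing` residues (default 15), rescaled per
   position so its marginal is exactly standard normal.

Scores are an affine map of z, calibrated so that
`P(score > 8) = order_fraction_target` exactly in expectation (the default
0.72 matches a typical training composition; 0.31 a disorder-rich test
composition), then clipped to the observed range [−5.6, 16.2]. Because 8
lies inside the clipping interval, clipping never changes the order
fraction, which is why the calibration is exact. The embedding carries the
clipped signal, so at `noise_sd = 0, aa_cluster_scale = 0` the score is an
exactly invertible affine function of the informative column — the anchor
for parameter-recovery tests. Protein lengths follow a shifted geometric
distribution with mean 112 truncated to [20, 1000], the length scale of
NMR-amenable proteins. With `target_window > 1` the score depends on a
moving average of z over that window while the embedding stays per-residue;
this is the controlled setting in which convolution provably helps and the
per-residue linear model cannot keep up.

`generate_af2_fixture()` produces pLDDT tables coupled to the scores
through a monotone affine map ([−5.6, 16.2] → [0, 100]) mixed with noise:
`coupling = 1` is exact and strictly monotone (so protein-mean pLDDT is
rank-identical to protein-mean score — an affine map is the only choice
that makes means commute), `coupling = 0` is independent of the scores.
Values are rounded to the 2 decimals a PDB B-factor carries, so the written
poly-alanine PDB fixtures round-trip exactly through `extract_plddt()`;
this rounding introduces ties, leaving residue-level rank correlations at
1 − O(10⁻⁵) rather than exactly 1.

What the generator does **not** emulate: real embedding geometry beyond
these three planted structures, sequence-composition biases of disordered
regions (the synthetic amino acids are uniform and independent of the
scores), bimodality of real score distributions, NMR noise, or any
evolutionary signal. Passing tests therefore demonstrate that the
machinery is correct and that each model recovers the structure it is
designed to exploit — not that any particular accuracy will be attained on
real embeddings.

## Problem sizes and numerical choices

The test suite and the acceptance script run at desk scale, chosen as the
smallest sizes at which the checked properties are stable across seeds:
embedding dimension 64, 120–500 proteins for model fits, 1000 bootstrap
sets, 2000 proteins for the order-fraction calibration check, and 10 + 10
organisms for the spectrum PCA separation. Model checkpoints
(`save_model()`) are a single text file — a JSON header plus one line of
`%.17g` values per parameter array — so a save/load round trip reproduces
predictions bit-identically and other languages can read the format with a
JSON parser and a float scanner.

Known limitations: the ANN topology is a package default, not a canonical
one; the CNN drops invalid residues from precomputed embeddings rather
than embedding pre-filtered sequences; `logreg` requires both classes
present in training data; and rank-deficient design matrices in the linear
heads resolve by zeroing the unidentifiable coefficients, which preserves
predictions but makes individual coefficients uninterpretable in that
(degenerate) case.
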
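---
title: "Methods: voxelwise encoding, passage decoding and representation maps"
author: "storyEncoding"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: voxelwise encoding, passage decoding and representation maps}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(storyEncoding)
```

## The generative model

A story is presented by rapid serial visual presentation: one word every
0.5 s, while fMRI volumes are acquired every TR = 2 s. Each word carries a
vector of feature annotations — indicator columns for discrete properties
(part of speech, character mentions, dialogue) and continuous columns such
as letter count. `resampleToTr()` sums the feature vectors of all words
presented within one TR (half-open bins `[t*tr, (t+1)*tr)`; a word exactly
on a boundary belongs to the later bin), producing TR-aligned magnitudes
$x_f(t)$. Column totals are conserved by construction, and the declared
run length pads trailing silent TRs with zero rows.

The signal of voxel $v$ at TR $t$ is modelled as

$$ y_v(t) \;=\; \sum_{f} \sum_{d=1}^{L} w_{v,f,d}\, x_f(t-d) \;+\;
\varepsilon_v(t), \qquad L = 4 . $$

The lags run over the **preceding** 1..4 TRs (2–8 s after onset), not
0..3: the hemodynamic response is delayed, and a lag-0 regressor would let
instantaneous correlations masquerade as response. `buildLaggedDesign()`
zero-pads the first rows and orders columns feature-major, lag-minor, so
the fitted weight matrix reshapes directly into per-voxel, per-feature
4-point *response signatures*. No functional form is assumed for those
signatures — the double-gamma shape appears in this package only inside
the synthetic-data generator as ground truth.

## Estimation

`fitRidge()` solves, per voxel, the penalized least squares problem
$(X^\top X + \lambda_v I)\,w_v = X^\top y_v$, sharing one
eigendecomposition of $X^\top X$ across all voxels and penalties per
training fold. $\lambda_v = 0$ is solved as the minimum-norm solution via
the same eigendecomposition with a relative tolerance, which also makes
the signature of a feature that never occurs in training exactly zero.

The per-voxel penalty is selected on a logarithmic grid ($10^0..10^7$ by
decades — wide enough that the extremes are effectively "unpenalized" and
"silenced" at the package's default problem sizes) by inner
cross-validation over **contiguous** time blocks, because fMRI noise is
temporally autocorrelated and interleaved folds would leak. The selection
rule is the one-standard-error rule: the largest penalty whose mean inner
held-out squared error lies within one standard error (over inner folds)
of the minimum. The plain argmin would not produce the intended automatic
voxel selection: for a voxel containing no signal, the cross-validation
curve is flat over all large penalties (differences of order
$10^{-3}\sigma^2$ against Monte-Carlo noise of order $10^{-1}\sigma^2$),
so the argmin is close to uniform over the upper half of the grid. The
1-SE rule resolves those near-ties toward shrinkage, sending noise voxels
to the top of the grid (the package tests require ≥ 90% of pure-noise
voxels in the top two grid values) while leaving clearly informative
voxels at small penalties.

Design columns and voxel time series are standardized (centred, unit
population SD) with statistics computed on **training rows only**; the
same recorded transform is applied to held-out rows, and predictions are
inverse-transformed. Constant columns get unit scale and map to zero.
Whether feature columns should be normalized before TR-summation is left
open by the modelling framework; this package deliberately does *not*
normalize at the annotation stage — all scaling happens once, in the
training-fold standardization, where it cannot leak.

## Passage classification

`runClassification()` evaluates the model by 10-fold cross-validation
over contiguous blocks (90% train / 10% test). A trim of `nLags` TRs on
each side of the held-out block is additionally excluded from training so
that lagged regressors never straddle the train/test boundary; the
evaluation is conservative without it, but the trim makes the
independence explicit. Held-out blocks are cut into non-overlapping
20-TR segments. For each observed segment, the trial compares the
Euclidean distance (on the standardized training scale) between the
observed **group** time series — per-subject matrices concatenated along
the voxel axis, never averaged — and the model predictions for the true
passage versus a random alternative segment. Alternatives are drawn
without replacement from the *same fold's* held-out pool so both
candidate predictions come from the same trained model; exact distance
ties score 0.5, which is unbiased under the null. With the default
segment geometry each fold holds 3 segments, so 2 pairings exhaust the
alternatives and the result carries no sampling variance.

## Concatenated searchlight and statistics

`searchlightMap()` repeats the classification per feature set inside a
cube of MNI coordinates around each grid centre, restricting each subject
to its own voxels whose coordinates fall in the cube (subjects may
contribute different counts, or none — pooling never mixes subjects).
The default cube edge is 5 voxels (15 mm at 3 mm voxels) and the default
grid is every voxel position in the union of the subjects' masks, with a
configurable stride; centres pooling fewer than `minVoxels` (default 10)
voxels are reported missing. Per-centre seeds are derived by hashing the
centre coordinates, so maps are invariant to grid enumeration order.

`empiricalNull()` estimates chance performance by circularly shifting the
feature time series by a uniform random offset of at least twice the
segment length before training and classification. Circular shifting
(rather than shuffling segment labels) preserves the temporal
autocorrelation of both the stimulus and the fMRI series, which label
shuffling would destroy; it requires T ≥ 4 segment lengths of data.
P-values use the add-one permutation formula
$p = (1 + \#\{\text{null} \ge \text{acc}\}) / (1 + n)$, never exactly
zero. `fdrBH()` applies Benjamini–Hochberg step-up control (via
`stats::p.adjust`), default level 0.05; by default each map gets its own
null (pooling nulls across locations is available as an option).
`topAccuracyVoxels()` provides the threshold-free alternative rendering:
flag the K most accurate centres per feature set (default 1000).

`smoothVolumes()` applies per-volume, strictly within-subject 3D Gaussian
smoothing. It is *not* part of the default pipeline: it exists as a
sensitivity knob, because spatial smoothing disturbs the per-voxel
penalty selection and moves region boundaries in the maps.

## The synthetic generator

`generateStory()` emulates the stimulus statistics: fixed-rate onsets,
one continuous positive right-skewed "visual" column (letter count of the
generated token), and sparse Bernoulli indicator columns (default
activation probability 0.1) partitioned into "syntax", "semantics" and
"discourse" sets. `generateSubjects()` simulates fMRI **from the model
equation itself**: planted regions of voxels are driven by one feature
set each with random per-voxel amplitudes (N(1, 0.3)) times the
double-gamma HRF sampled at the lags; noise is AR(1) (coefficient 0.3 —
fMRI noise is autocorrelated, and white noise would make the contiguous
fold design pointless), scaled per driven voxel so SD(signal)/SD(noise)
equals the requested SNR exactly; undriven voxels are pure noise at the
median driven-noise SD. Anatomical variability is a rigid whole-grid
translation per subject of at most `jitterMm` (default 2 mm), the
simplest model of small cross-subject misalignment after normalization.

The default desk-scale scenario is 2 subjects, 600 TRs (2400 words),
200 voxels on an 8×5×5 grid of 3 mm voxels, 10 features. What the
generator does **not** emulate: spatially correlated noise, slow scanner
drift, correlated feature sets (real syntactic and semantic annotations
are strongly correlated), non-rigid anatomical variation, and
voxel-dependent hemodynamic shapes. Passing tests therefore demonstrate
the pipeline's correctness and calibration, not that real-data accuracy
of any particular magnitude is attainable.

## Numerical and design choices

* **Ridge solver**: eigendecomposition of $X^\top X$, exact solution;
  $\lambda = 0$ via pseudoinverse with relative tolerance $10^{-12}$.
* **Penalties** may be zero although the selected grid is positive; the
  zero-penalty path exists for oracle tests and interpolation checks.
* **Tie-breaks**: penalty near-ties toward more shrinkage (1-SE rule);
  classification distance ties score 0.5; top-K accuracy ties keep map
  order.
* **Degenerate inputs**: constant columns standardize to zero; folds with
  fewer than two segments contribute no trials (an error only if no fold
  has two); centres with too few pooled voxels are missing, not zero.
* **Problem sizes in tests**: the test suite runs the full pipeline at
  600 TRs × 200 voxels × 2 subjects (about a second per replicate) and
  uses 150 pure-noise replicates for the chance-calibration check; the
  planted-region map uses a 10×6×6 grid with two 40-voxel plants.

### The planted-region mapping check

Validating the searchlight against a known plant needs care, because the
map's spatial resolution is the cube half-width: every centre within half
an edge of a planted region genuinely pools driven voxels, so with
multi-voxel cubes the elevated set is the plant *dilated* by the cube,
and at informative SNR many of those centres saturate at accuracy 1.0,
making any ranking among them arbitrary. The package's double-plant
harness is therefore resolution-matched: edge-1 cubes on the exact voxel
grid with ≤ 1 mm jitter, so each centre pools exactly one voxel per
subject and the decodable set equals the plant. At SNR 0.5 the planted
centres separate completely from the null centres (plant minimum ≈ 0.83
vs null maximum ≈ 0.77 accuracy in the packaged check), the top decile of
centres per feature set lands inside the correct plant (Jaccard ≈ 0.89),
and the two feature sets' top deciles are disjoint.

## Known limitations

* Feature sets are analysed independently; correlated feature sets will
  both decode from regions that represent only one of them.
* The alternative-segment pool is the same fold's held-out block set, so
  very short runs leave few alternatives and coarse accuracy resolution.
* The searchlight refits the full ridge path per centre; maps over large
  grids are embarrassingly parallel but the implementation is serial.
* Real-data ingestion expects already MNI-normalized volumes (or
  matrix + coordinate sidecars); no registration or preprocessing is
  provided.
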
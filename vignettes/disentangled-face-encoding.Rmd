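---
title: "Disentangled latent encoding and decoding of face-selective responses"
author: "LatentFaces package"
output: rmarkdown::html_document
vignette: >
  %\VignetteIndexEntry{Disentangled latent encoding and decoding of face-selective responses}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The analysis this package implements

Deep generative models of faces learn a low-dimensional latent space in which
an image can be encoded, manipulated and reconstructed. When the training
objective additionally enforces statistical independence between latent
dimensions — the *disentanglement* penalty of the beta-VAE and FactorVAE
families — individual dimensions tend to isolate single semantic factors of
variation: rotation, lighting, smile, skin tone, hair, and so on. Such a
latent space is an attractive feature basis for voxelwise *encoding models*
of face-selective fMRI responses, because a voxel's fitted weights are then
interpretable dimension by dimension.

`LatentFaces` implements that analysis end to end at desk scale, paired with
a synthetic-data module that makes every stage testable against known ground
truth:

1. **Synthesis** (`sampleFaceDataset`, `simulateVoxelResponses`,
   `simulateTimeseries`, `simulateLocalizer`): procedural face images
   governed by eight independent factors, and simulated voxels whose
   responses are linear in those factors with known weights, bias, drift,
   motion and noise.
2. **Generative model** (`trainVae`, `vaeLossTerms`, `latentTraversal`,
   `hyperparameterGrid`, `disentanglementScore`, `selectModel`): beta-VAE
   and FactorVAE objectives, traversal rendering, and disentanglement-based
   model selection.
3. **Representation comparison** (`ccaSimilarity`, `pcaReduce`): canonical
   correlations between latent spaces and PCA reduction of external
   embeddings to a matched dimensionality.
4. **Encoding** (`buildDesign`, `fitEncodingGlm`, `predictTestResponses`,
   `evaluateEncoding`, `splitHalfReliability`): per-voxel GLM with
   latent-value regressors, evaluated by Spearman correlation on 20 held-out
   test faces against a split-half reliability ceiling.
5. **Voxel selection** (`parcelSelect`, `wholeBrainSelect`): the combined
   metric v = v_s + v_r of z-scored selectivity and reliability, top 10% per
   parcel or mean + 1.5 sd whole-brain.
6. **Preference mapping** (`singleDimPredict`, `preferenceProfile`):
   single-dimension predictions and winner-take-all voxel labelling.
7. **Identity decoding** (`decodeLatents`, `pairwiseIdentityAccuracy`,
   `subsetBattery`): pseudo-inverse inversion of the encoding map,
   x̂ = pinv(W)(y − b), scored by the pairwise foil procedure over
   20 × 19 = 380 comparisons and over dimension subsets.
8. **Inference** (`permTestAboveChance`, `permTestModelDiff`,
   `permTestRoiDiff`, `groupLevel`): permutation tests with 1000 resamples
   by default, at the individual and group level.
9. **Orchestration** (`pipelineConfig`, `runStage`, `runPipeline`): staged
   execution with manifests, checksums and per-stage seed substreams.

## The generative model and its training

The encoder maps an image to a Gaussian posterior q(z|x) = N(mu, diag(sigma^2));
the decoder maps a latent vector back to Bernoulli pixel logits. The
training objectives are

* beta-VAE: `reconstruction + beta * KL(q(z|x) || N(0, I))`, beta >= 1;
* FactorVAE: `reconstruction + KL + gamma * TC(z)`, where the total
  correlation TC — the KL between the aggregate posterior and the product of
  its marginals — is estimated with the density-ratio trick: a small
  discriminator is trained to tell genuine latent batches from batches whose
  columns have been independently permuted, and its mean logit on genuine
  batches estimates TC.

A FactorVAE with gamma = 0 is by construction the same model as a beta-VAE
with beta = 1 (a standard VAE); `vaeConfig` records this equivalence, the
hyperparameter grid aliases those cells rather than duplicating them, and
the two objectives agree to machine precision on any batch.

**Architecture.** The encoder and decoder are fully connected
(pixels → 128 → 64 → 2k and mirrored), trained by minibatch Adam with
manual backpropagation; the analytic gradients are verified against numeric
differentiation in the test suite. A fully connected pair was chosen over a
convolutional one deliberately: at the 32 px working resolution of the
procedural faces an MLP reaches the same qualitative behaviour (reconstructs
held-out faces better than the mean-image baseline, supports traversals and
disentanglement scoring) while remaining compact, dependency-free and fast
enough to train inside a test suite. The encoder's posterior heads are
zero-initialised, so an untrained model emits exactly zero posterior means
with unit variance. The TC discriminator is a two-layer MLP (64 hidden
units). Defaults: 15–30 epochs, batch 24–32, learning rate 3e-3 (Adam),
chosen once as the smallest budget at which reconstruction reliably beats
the mean-image baseline on the default synthetic faces.

**Traversals.** `latentTraversal` holds all other dimensions at the image's
posterior mean and sweeps one dimension over −2..+2 by default — the range
that covers ±2 prior standard deviations; the range is configurable because
narrower sweeps (−1..+1) are sometimes preferred for display. Frames are
exported as PNGs plus a montage; no animated-GIF encoder is available in
this stack and a frame strip carries the same information.

**Model selection.** Because the synthetic factors are known, model
selection uses a *supervised* disentanglement score instead of an
unsupervised one: the importance of latent l for factor f is
|Spearman r(l, f)| across stimuli, and each factor contributes the
normalised gap (m1 − m2)/m1 between its largest and second-largest
importance. The score is 1 exactly when each factor aligns with a unique
latent with zero cross-talk, 0 under fully symmetric mixing, and is
invariant to latent permutations and sign flips. On finite random samples
the cross-correlations are O(1/sqrt(n)), so "perfect" alignment scores
1 − O(1/sqrt(n)); the test suite uses a balanced full-factorial factor
table, whose midrank cross-correlations vanish exactly, where an exact 1 is
asserted. Ties in `selectModel` break towards fewer latent dimensions, then
the smaller seed.

## The synthetic faces and voxels

Eight factors, each uniform on [−1, 1]: rotation, lighting, background,
face width, skin tone, smile, hair size, and a gender proxy (brow weight).
Identity is *defined* as the vector of identity-relevant factor values —
face width, skin tone, hair size, gender proxy — while rotation, lighting,
background and smile are transformations that leave identity unchanged
(smile is face-specific yet not identity-relevant). The renderer is
deterministic and each factor moves a visually distinct property; the
background factor paints only the complement of the maximal face-plus-hair
mask, and the mouth is drawn with one-pixel anti-aliasing so the mean
intensity of the mouth region is an exactly linear, strictly increasing
function of the smile factor — both properties are asserted against
independently coded oracles.

Voxel responses follow the same linear model the encoding GLM assumes:
every presentation of a face with latent vector x yields
y = x'W* + b* + noise, with i.i.d. Gaussian noise per voxel per
presentation. Training faces appear once; the 20 test faces appear 40–60
times (default 50) and their repeats are averaged. `noiseSdForSnr` sets the
noise scale relative to the signal spread so simulations are specified by
per-trial SNR. The time-series form convolves latent-weighted stimulus
impulses (one event every 3 s: 1 s stimulus, 2 s inter-stimulus interval)
with a canonical double-gamma HRF (peak 6 s, undershoot 16 s, ratio 1/6,
32 s support), sampled at TR = 2 s, and adds per-run linear drift,
smooth random-walk motion traces times their coefficients, a constant
baseline b*, and white noise. TR, HRF shape and the noise law are stated
defaults of the simulator, not claims about any particular scanner
protocol. Because the generator and the hrf-mode design share the same
convolution and discretisation, noiseless recovery of every coefficient is
exact, which the tests assert at 1e-6.

One modelling choice deserves emphasis: in the *amplitude* view, b* is the
face-common response amplitude added to every presentation; in the
*time-series* view, b* is the constant session baseline (a flat series when
all weights are zero). The hrf-mode design therefore carries b on its
constant column, and both fitting routes deliver the same W and the same b,
keeping pseudo-inverse decoding x̂ = pinv(W)(y − b) coherent across modes.

What the simulator does **not** emulate: temporal autocorrelation of fMRI
noise, physiological noise, run-to-run baseline shifts, spatial smoothness,
cortical geometry, or photorealistic faces. Passing tests therefore
demonstrate the correctness and calibration of the analysis machinery under
its own assumptions, not performance on real scanner data.

## Encoding model choices

* "Latent values as weighted regressors" is implemented as parametric
  modulation: the event regressor is scaled by the stimulus's latent value,
  so each fitted beta is response per unit of that dimension. One regressor
  per training image would not be estimable from single presentations.
* The 20 test faces get indicator regressors during fitting, so their
  repeated single trials inform only their own amplitude estimates, never
  the latent weights; test predictions come exclusively from
  X_test W + b.
* Fitting is per-voxel OLS (QR). A rank-deficient design triggers a warning
  and the minimum-norm pseudo-inverse solution. No shrinkage is applied by
  default because the reference procedure is a plain GLM.
* Evaluation uses Spearman correlation across the 20 test faces; voxels
  with constant predictions (for example a zero-weight dimension in
  preference mapping) get r = 0 and a flag rather than NA, so downstream
  argmax operations stay total.
* Split-half reliability averages Spearman correlations over random
  half-splits of the test repeats and serves as the effective noise
  ceiling.

## Voxel selection, preference maps, decoding, inference

**Selection.** Selectivity and reliability are z-scored within parcel with
the population-sd convention and summed; the top ceiling(fraction × n)
voxels per parcel are kept, ties broken by voxel index. The simulated
localizer emits a statistic where larger means more face-selective; if raw
localizer p-values are supplied instead, transform them with −log10(p)
before selection so the ordering is preserved — z-scoring raw p-values
would invert it. Whole-brain selection thresholds v at mean + 1.5 sd.

**Preference mapping.** Single-dimension predictions include the face bias
(rank correlations ignore it, but exported predictions stay on the response
scale). The winner is the argmax dimension, ties to the lowest index;
voxels whose best correlation is non-positive get no winner, because
winner-take-all over noise is meaningless.

**Decoding.** W is non-square (dimensions × voxels), so its inverse is the
Moore–Penrose pseudo-inverse. Pair scoring uses Pearson correlation between
decoded and true latent vectors (Spearman available via an argument). Ties
score 0.5 — this also fixes the chance level at exactly 50% when the
candidate identities are indistinguishable. Dimension subsets are applied
*after* decoding with the full W; a subset-restricted pseudo-inverse mode
exists and is labelled as such in its results. In simulations that ask
whether identity-relevant dimensions out-decode irrelevant ones, "identity
is defined by the relevant factors" is operationalised by the generator's
`testIrrelevantScale`: relevant factors span their full range across the 20
test identities while irrelevant factors vary at a reduced scale (0.2)
around a shared anchor, or are exactly constant (scale 0) for the
chance-level control.

**Permutation inference.** All tests use the add-one convention
p = (1 + #{null ≥ observed}) / (1 + resamples), so p is never 0; 1000
resamples by default. Above-chance tests permute the 20 test-image labels
of the observed data (ranks are permuted rather than recomputed — a
permutation of labels permutes rank vectors). Model comparisons swap the
two models' predictions independently per test image, preserving the
voxelwise correlation structure; the per-image (rather than per-voxel)
granularity is the documented choice. ROI comparisons shuffle voxel
assignment. Group-level statistics average subjects' observed values and
their aligned null samples. No multiple-comparison correction is applied by
default across dimensions or ROIs; `adjustPValues` provides
Benjamini–Hochberg when wanted.

## Representation comparison

`ccaSimilarity` standardises columns, whitens each set with a 1e-8 ridge on
its correlation matrix, and summarises the canonical correlations by their
**mean** over min(dims) components ("first component only" is available) —
the summary is stated explicitly because a bare "CCA r" is ambiguous.
Posterior means, not samples, are the latent representation throughout.
`pcaReduce` is column-centred PCA with the variance-explained fraction of
the retained components.

## Problem sizes and numerical conventions

The test suite and the pipeline presets run at deliberately small scales,
chosen as the package's own defaults for interactive work: 100–500 training
faces at 32 px, 24–200 voxels, 6–8 latent dimensions, 2–30 epochs,
150–1000 permutation resamples, 100–200 calibration replicates. The full
protocol (about 8000 training faces, 64 px, the complete 480-model grid of
4 latent sizes × {6 betas + 6 nonzero gammas} × 10 seeds) is available
behind the `paper` preset and the grid defaults, and is expected to take
hours. Degenerate inputs are handled deterministically: constant score
vectors z-score to 0 with a warning; constant latent columns get zero
importance; constant decoded vectors skip their pairs; rank-deficient
designs fall back to minimum-norm solutions; all tie-breaks are by lowest
index.

## Known limitations

* The MLP architecture caps reconstruction fidelity at higher resolutions;
  at 64 px a convolutional pair would be preferable.
* Simulated noise is white; real fMRI noise is autocorrelated and
  structured, so real-data reliability and encoding correlations will be
  lower than matched-SNR simulations suggest.
* The supervised disentanglement score requires known factors and cannot
  select models on real image corpora; an unsupervised criterion would be
  needed there.
* The discriminator TC estimate is biased for small batches; it is used as
  a training signal and a relative diagnostic, not as a calibrated
  information measure.
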
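---
title: "QEEG Z-score feature images: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{QEEG Z-score feature images: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Resting-state quantitative EEG (QEEG) carries a well-replicated signature of
Alzheimer's disease dementia (ADD): power shifts toward slow rhythms (delta,
theta) while the posterior alpha rhythm weakens. Classical scalp topographies
visualize one frequency band at a time and are awkward inputs for image
classifiers. `featimg` implements an alternative representation: the full
spectrum of every channel, standardized against an age- and sex-specific
normative database, is rearranged into a single rectangular *feature image*
that an ordinary convolutional network can consume, and that a band-aligned
local surrogate explainer can read back in clinical vocabulary ("high power
of slower waves").

## The pipeline

1. **Preprocessing.** A 19-channel 10–20 recording (250 Hz, eyes closed) is
   re-referenced to the common average, band-passed to 1–45.5 Hz with a
   zero-phase (forward–backward) 4th-order Butterworth filter, cut into 4 s
   epochs, and epochs containing any sample above ±100 µV are rejected. An
   artifact-removal hook (`artifact_hook` in `rp_from_recording()`) is a
   deliberate no-op slot: ICA-based artifact classification is out of scope,
   but a user-supplied function can be inserted at exactly that point.
   The per-channel mean is removed before filtering so a DC offset cannot
   leak through the forward–backward passes as an edge transient.
2. **Spectra.** Per epoch and channel, squared-magnitude FFTs are averaged
   (Bartlett-style, rectangular window by default; a Hann option exists) and
   accumulated onto half-open 0.25 Hz bins covering [1, 45) Hz — 176 bins.
   Each channel row is divided by its total: *relative* power. The 4 s epoch
   is forced: it is the unique epoch length whose DFT resolution equals the
   0.25 Hz bin grid.
3. **Standardization.** A normative database stores the mean and SD of every
   channel × bin cell per (sex, age band) stratum; a subject's spectrum maps
   to `z = (x - mean) / sd` in their stratum — 176 Z-scores at each of the 19
   electrodes. Strata with fewer than `min_n` subjects or a zero-SD cell are
   flagged unusable and looking them up is an explicit error; there is no
   silent nearest-stratum fallback, because a silently wrong stratum corrupts
   standardization invisibly. Identity and log10 transforms are both exposed
   (normative practice varies); identity is the default.
4. **Feature matrix.** Channels are split into a left and a right
   front-to-back strip of 11 rows each (midline Fz/Cz/Pz belong to both), and
   the two 11 × 176 blocks are concatenated along frequency into an 11 × 352
   matrix: columns 1–176 left, 177–352 right, each ascending 1.00–44.75 Hz.
5. **Feature images.** Four renderings of that matrix:
   - *nearest*: exact 32× row replication to 352 × 352 (352 = 32 × 11);
   - *bicubic*: each cell's third-degree surface
     `p(x, y) = Σᵢ Σⱼ aᵢⱼ xⁱ yʲ` with the 16 coefficients solved from corner
     values and central-finite-difference derivative estimates;
   - *weight map*: the bicubic image with all pixels at ≥ 20 Hz (beta3 and
     gamma) masked — those regions render black and carry no information;
   - *rescaled*: beta3/gamma columns dropped (152 remain), bicubic-upscaled
     to 152 × 152, then each of the 12 band regions (6 bands × 2 sides,
     widths 12, 16, 8, 8, 12, 20 per side) resized to 20 × 240 and
     concatenated to 240 × 240, giving every band equal image area.
   Rendering maps Z ∈ [−1.96, 1.96] onto a blue–white–red diverging scale,
   saturating beyond the clip; masked pixels are black *at render time* (a
   masked value set to z = 0 would incorrectly render as the white midpoint).

## Design choices that were genuinely open

- **Column arrangement.** The right half could equally run ascending in
  frequency or mirror the left half about the matrix midline; the package
  defaults to concatenated-ascending and records the choice per column in
  `region_map`, with `mirror_right = TRUE` as the alternative.
- **Bicubic derivative scheme.** The polynomial is given but not the
  derivative estimator; central finite differences with edge replication are
  used, making the scheme equivalent to separable cubic convolution with
  kernel parameter −1/2 — the package's tests exploit exactly that
  equivalence as an independent oracle.
- **Resampling grid.** Align-corners sampling (`x = i·(n−1)/(N−1)`), so the
  interpolant reproduces source nodes exactly and the x-axis of a 352-wide
  image is the identity on the 352 matrix columns.
- **Final rescaled size.** The per-region target of 20 × 240 implies a
  240 × 240 composite (12 regions × 20 px wide, one shared 240 px height);
  the composite size follows from that arithmetic and is fixed here as a
  package decision.
- **Flatline epochs.** A flatline check (per-channel SD below 0.01 µV) is
  implemented but off by default: an all-zero epoch is clean by the
  amplitude criterion, and rejecting it by default would contradict the
  amplitude-only contract. Enable with `flat_sd_uV > 0`.

## The synthetic data generator

No clinical EEG ships with the package; every claim is validated on
synthetic recordings whose construction mirrors the assumptions the pipeline
relies on:

- per band, three sinusoids at uniformly drawn in-band frequencies, each
  amplitude-modulated by a slow raised-cosine envelope (period 2–6 s, one
  envelope per band) — the simplest process putting band-limited mass where
  it belongs;
- 1/f background noise (spectrally shaped white noise, exponent 1, default
  5 µV RMS) — the standard EEG background approximation;
- posterior channels (O1, O2, P3, P4, Pz, T5, T6) get a ×2 alpha boost,
  emulating the eyes-closed posterior dominant rhythm;
- healthy amplitudes (µV): delta 4, theta 3, alpha1 8, alpha2 6, beta1 2.5,
  beta2 2, beta3 1.5, gamma 1 — alpha-dominant at rest, weak fast activity;
- the ADD profile multiplies delta and theta by 1.8 and halves alpha1/alpha2,
  the direction of the established dementia signature; `separation` scales
  this shift linearly (0 = exchangeable with controls);
- cohorts draw ages uniformly, alternate sexes (configurable ratio) and
  jitter each subject's gains lognormally (SD 0.1) for between-subject
  variability. Labeled datasets default to ages 60–81, matching dementia
  cohort recruitment.

What the generator does **not** emulate: volume conduction and source
geometry (no head model), ocular/muscle artifacts beyond amplitude spikes,
age- or sex-dependent spectral drift (strata therefore differ only by
sampling noise), and channel covariance structure. Passing the synthetic
benchmark demonstrates that the pipeline is internally consistent and that
the classifier uses the spectral signature it should — it does not
demonstrate clinical-grade accuracy on real EEG.

## Classifier

Three compact from-scratch analogs of classic image networks are provided —
`alexnet_s` (five convolutions, one 5 × 5 kernel), `vgg_s` (3 × 3 kernels
throughout) and `resnet_s` (residual blocks computing
`ReLU(conv2(ReLU(conv1(x))) + x)`) — each ending in global average pooling
and a dense softmax head. Full-size AlexNet/VGG16/ResNet18 are deliberately
out of scope at desk scale; depth and width are configuration. Training is
softmax cross-entropy with Adam (lr 3e-3, batch 16, up to 30 epochs, early
stop on a 10% validation split with patience 5), no pretrained weights, no
augmentation; a global seed drives weight initialization, shuffling and the
validation split, making runs bit-reproducible. Inverse-frequency class
weighting exists but is off by default. RGB rasters are block-averaged by a
factor of 8 before entering the network (352 → 44 px): band regions remain
several pixels wide while the compute budget drops by two orders of
magnitude.

## Explainer

Perturbation segments are axis-aligned rectangles — (band × side) column
groups crossed with row blocks (default: quarter-height, i.e. 64 segments on
a plain 352 × 352 image, 48 on a weight-map image whose beta3/gamma regions
are inert background). Generic superpixels would blur band attribution;
band-aligned rectangles make surrogate weights aggregate directly into
band-level statements. Perturbed samples switch segments off to the
variant's notion of "no signal" (colormap midpoint for plain variants, black
for weight maps), are weighted by `exp(−d²/w²)` on the *normalized* Hamming
distance (fraction of segments toggled; width default `0.25·√n_segments`),
and a sparse surrogate is fitted by forward selection to at most K features
followed by weighted least squares. The recorded fidelity loss is the
weighted squared error of the surrogate against the classifier; complexity
is the selected-feature count (an ℓ₀ budget). The KDE cutoff utility places
a decision threshold at the crossing of two groups' Gaussian kernel density
estimates between their modes (low scores → impaired class), the standard
score-based baseline.

## Problem sizes used in validation

The shipped validation (`scripts/acceptance.R` and the acceptance test file)
runs, per invocation: a 200-subject normative cohort (ages 60–81, one age
stratum per sex so each stratum holds ~100 subjects), 100 ADD-like plus 100
control recordings of 120 s at 250 Hz (the short end of the typical 2–3 min
acquisition), weight-map images, a width-6 `resnet_s` trained up to 15
epochs on the 9:1 split, and a second exchangeable-groups run (separation 0)
against the same database as a no-leakage control. These sizes were fixed
once as the package's desk-scale study conditions. The 60-subject
calibration cohort checks that held-in members standardize to cellwise
mean 0 / SD 1 — with the member spectra standardized against their own
stratum moments this recovery is exact up to floating point, so the check
guards the bookkeeping (stratum lookup, transform plumbing) rather than
sampling noise.

## Known limitations

- The normative database is only as good as its cohort; the synthetic
  cohort has no true age/sex spectral structure, so stratification is
  exercised mechanically, not physiologically.
- Bicubic interpolation overshoots near steep row transitions (bounded by
  12.5% of the local step for monotone data) — visible as slight halos,
  harmless for classification, but worth knowing when reading pixel values
  as Z-scores.
- The CNN engine is plain R; it is sized for hundreds of small images, not
  for large-scale training.
- Explanations are stochastic in their perturbation sample; fixed seeds make
  them reproducible, and across seeds the top segment of a well-determined
  model is stable, but weight magnitudes vary slightly between trials.
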
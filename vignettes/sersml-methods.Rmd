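---
title: "Classifying label-free SERS spectra of extracellular vesicles: models and methods"
author: "sersml"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying label-free SERS spectra of extracellular vesicles}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sersml)
```

## The problem

Surface-enhanced Raman spectroscopy (SERS) of extracellular vesicles (EVs)
produces molecular fingerprints: intensity versus Raman shift (cm^-1), with
bands assigned to vibrations of the proteins, lipids and nucleic acids the
vesicles carry. EVs shed by cancerous and healthy cells differ subtly in a
handful of band intensities, far too subtly for by-eye classification, so the
standard workflow couples spectral cleanup (cosmic-ray removal, baseline
subtraction, smoothing) with supervised classifiers — a support vector
machine (SVM) on principal-component scores, or a one-dimensional
convolutional neural network (CNN) on the full spectrum — and with model
interpretation (Shapley values, partial dependence) to tie the decision back
to chemistry.

`sersml` implements that whole chain as composable, seeded, tested R
functions, together with a synthetic-spectrum generator so that every stage
can be exercised, end to end, without access to instrument data.

## The synthetic-spectrum generator

A class is described by a `class_profile`: a list of Lorentzian bands
(center, mean amplitude, amplitude coefficient of variation, FWHM), a smooth
drifting baseline (cubic polynomial plus one broad Gaussian hump), additive
Gaussian point noise, and Poisson-count single-point cosmic-ray spikes. A
simulated spectrum is

    intensity = sum_bands amp_i * L(center_i, fwhm_i)
              + baseline + N(0, noise_sd) + spikes,

with `amp_i` drawn per spectrum around its mean. Every draw is a pure
function of `(profile, axis, seed)`.

Default conditions, chosen once:

* **Axis** 400–3200 cm^-1 at 2 cm^-1 spacing (1401 points) — spans all bands
  used by the presets (493–2913 cm^-1) at a realistic dispersion.
* **Peak shape** Lorentzian, the standard Raman line shape.
* **Band list** shared by all five presets: 493 (glycogen), 741 (amide IV),
  1011 (ring breathing), 1078 (C–C/C–N stretch), 1221 (amide III),
  1349 (C–H bend / C–C stretch), 1437 (lipid CH2 bend) and 2913 cm^-1
  (lipid/protein C–H stretch), plus a broad baseline hump near 1598 cm^-1
  mimicking citrate background on gold nanoparticles.
* **Signal-to-noise** about 10 at the strongest band (amplitude 100 counts,
  `noise_sd` 10).
* **Class contrasts** as amplitude multipliers on the common bands:
  cancer-like classes (`a549-like`, `hela-like`, `hepg2-like`) are ~30%
  stronger at 1349 and 1437 cm^-1; normal-like classes (`beas2b-like`,
  `hek-like`) ~30% stronger at 1078 and 1221 cm^-1. Each class additionally
  carries a small distinctive pattern (e.g. `hek-like` is strong at 741 and
  weak at 493 cm^-1) sized so that *every pair* of presets is separated by
  about the same contrast magnitude as the cancer/normal pair. Without this,
  two presets would be near-duplicates and no classifier — however good —
  could reach the recovery targets the presets are designed to support.
* **Replicate amplitude variability** `amplitude_cv = 0.06`. The measurable
  quantity this is anchored to is substrate uniformity: a high-quality
  colloidal gold substrate reproduces a reporter band intensity across
  positions with a relative standard deviation of about 5.7%, so per-band
  amplitudes here jitter with a matching ~6% CV.
* **Spikes** single-point positive excursions (800 counts, rate 0.1 per
  spectrum), which is what a cosmic-ray filter should see.

What the generator does *not* emulate: common-mode enhancement variation
(real SERS spectra often share a dominant global intensity mode), correlated
band amplitudes from shared biochemistry, peak-position drift, detector
etaloning, and heteroscedastic shot noise. Passing recovery tests on this
generator therefore demonstrates the pipeline's correctness and sensitivity
under controlled conditions, not instrument-grade performance.

```{r template, fig.width = 7, fig.height = 3.2}
axis <- default_axis()
plot(axis, class_template(preset_profile("cancer-like"), axis), type = "l",
     xlab = expression(paste("Raman shift (", cm^-1, ")")),
     ylab = "intensity (counts)", col = "firebrick")
lines(axis, class_template(preset_profile("normal-like"), axis),
      col = "steelblue")
legend("topleft", c("cancer-like", "normal-like"), lty = 1,
       col = c("firebrick", "steelblue"), bty = "n")
```

## Preprocessing

**Despiking.** Cosmic rays are narrow, huge, and rare. `despike()` is a
Hampel-style filter: within a 5-point window, a point whose modified z-score
`0.6745 |x - med| / MAD` exceeds 8 is replaced by the window median. Three
numerical choices matter. Windows are mirror-padded so a spike in the first
or last channel is still caught. The window MAD is floored at half the
global robust noise scale (`mad(diff(x))/sqrt(2)`), because a 5-point MAD
occasionally collapses to near zero in flat noise and would otherwise flag
ordinary points. The pass is iterated to a fixed point (almost always one or
two passes), which makes the filter exactly idempotent.

**MPLS baseline.** Morphologically weighted penalized least squares removes
the broad background: a morphological opening (erosion then dilation with a
flat structuring element of `struct_width = 75` grid points — points, not
cm^-1, matching the convention of the implementation the parameter value
comes from) clips off everything narrower than the element; the average of
the opening's own dilation and erosion cancels the noise bias of the bare
opening; a weighted Whittaker smoother (penalty λ = 10 on first differences)
then refines this contour. Weights are 1 where the opening agrees with the
spectrum within 3 robust noise SDs (baseline regions), 0.001 under peaks,
and forced to 1 on the `ceiling(n/2000)` end points. Two boundary choices
keep sloped baselines unbiased at the spectrum ends: the signal is extended
by linear extrapolation before the morphology, and the Whittaker system is
solved on that padded support, so both kinds of end effect fall in the
padding and are trimmed away. By construction
`baseline + corrected = input` exactly.

**DFT smoothing.** The spectrum is Fourier transformed, multiplied by a
low-pass window, and transformed back. The window is flat to
`(cutoff - rolloff)` of Nyquist, then tapers to zero with a raised cosine at
`cutoff` (defaults 0.15 and 0.05): the taper avoids the ringing a brick-wall
filter would produce. The window is symmetric in frequency, so the output is
real (the residual imaginary part, checked to be below 1e-10 relative, is
discarded) and DC is preserved exactly. No intensity normalization is
applied by default; `preprocess(..., normalize = TRUE)` enables per-spectrum
max-normalization.

## PCA and the SVM

`fit_pca()` centers columns (no variance scaling — conventional for
intensity matrices) and extracts principal axes by SVD; signs are fixed so
each loading's largest-magnitude element is positive, making results
reproducible. The binary pipeline reduces to `k = 2` components before the
SVM; the CNN consumes full spectra.

`train_svm()` solves the soft-margin dual

    max  sum(alpha) - 1/2 sum_jk alpha_j alpha_k y_j y_k G(x_j, x_k)
    s.t. 0 <= alpha_j <= C,  sum_j alpha_j y_j = 0

by sequential minimal optimization. Features are divided by the kernel
scale `s` before inner products (both kernels); `G` is the plain dot product
(linear) or `exp(-|u - v|^2)` on scaled features (Gaussian). The working
pair is chosen by first-order violation for the first index and maximal
second-order gain for the partner — the plain maximal-violating-pair rule
cycles badly on near-collinear 2-D score data. Iteration stops when the
violating-pair gap falls below `tol` (default 1e-3 in score units, with a
20000-update cap); the final gap is stored on the model as `kkt_gap`.
Multiclass problems are handled one-vs-one with majority voting, ties going
to the smallest class index. `platt_calibrate()` maps scores to posterior
probabilities by a maximum-likelihood sigmoid with the standard smoothed
targets.

**Hyperparameter search.** `bayes_optimize()` minimizes the 5-fold
cross-validated misclassification rate (`cv_loss()`, seeded shuffle fold
assignment) over `(log10 C, log10 s)` in `[-3, 6]^2` — a box bracketing the
magnitudes a well-scaled problem needs — with a Gaussian-process surrogate
(squared-exponential kernel, length scale 0.2 of the unit box, small
nugget) and expected-improvement acquisition over seeded candidate clouds,
after 5 seeded space-filling points. Plain expected improvement is used
rather than a time-penalized variant: wall-clock terms are
hardware-dependent and irrelevant to correctness. Inside the search the CV
objective caps the SMO at 5000 updates; configurations so ill-scaled that
they cannot converge in that budget produce honestly poor CV losses and are
discarded by the search itself.

## The CNN

The default architecture is conv1d(16 filters, width 9) → ReLU → maxpool(4)
→ conv1d(32, width 9) → ReLU → maxpool(4) → fully-connected(d) → softmax:
the smallest stack exercising every layer type. Pooling width 4 (rather
than 2) keeps the dense head near 2700 weights per class, which matters at
the few-hundred-sample training sizes typical of EV studies; with width-2
pooling the head quadruples and the network memorizes the training noise.
Inputs are per-spectrum max-normalized. Training minimizes mean
cross-entropy with Adam (β1 = 0.9, β2 = 0.999) at the stated initial
learning rate 0.01 for at most 60 epochs, batch size 16, with three
stabilizers exposed in `train_config()`:

* **gradient clipping** at global L2 norm 1 — without it, Adam at 0.01
  drives the ReLUs dead within the first few batches and the network locks
  onto the uniform softmax;
* **L2 weight decay** 1e-3, the same regularization family the mainstream
  deep-learning toolboxes apply by default;
* **per-epoch learning-rate decay** 0.92 — an "initial" learning rate
  implies a schedule, and a constant 0.01 leaves a parameter noise ball
  that blurs the closest class pair.

Everything (initialization, shuffling) is seeded; identical seeds give
bit-identical weights. Gradients of every layer are verified against
central finite differences in the test suite. The convolution and pooling
layers run through small compiled kernels (im2col/col2im and max-pool
forward/backward) with the matrix products left to BLAS.

## Evaluation

`split_dataset()` shuffles the pooled set (not per class) under a seed and
cuts `round(n*f)` training and validation samples, the test set absorbing
the rounding remainder — so 2700 spectra at 60/10/30 give exactly
1620/270/810. A stratified variant exists for robustness experiments but is
off by default. `evaluate()` builds the confusion matrix and per-class
recall/precision plus overall accuracy, reported half-up to one decimal
with raw fractions kept alongside so rounding never feeds downstream
computation; a class absent from the truth reports `NA` recall, not 0.
`roc_auc()` sweeps all thresholds (trapezoidal AUC = Mann-Whitney
concordance with ties counted half); multiclass AUC is one-vs-rest per
class. Reports serialize losslessly to JSON.

## Interpretation

`shapley_values()` attributes a prediction to features under the
interventional convention: absent features are imputed from background
rows. Exact mode enumerates all coalitions (limited to 12 features); sampled
mode averages marginal contributions along seeded random feature orderings,
one background row per ordering, and reports Monte-Carlo standard errors.
Efficiency (`sum(phi) = f(x) - mean f(background)`), symmetry and the dummy
axiom are tested exactly. `shapley_summary()` ranks features by the mean of
per-sample |φ| (not |mean φ|), ties broken by ascending wavenumber.
`partial_dependence()` averages the model over the data with one feature
pinned to a grid. For an SVM trained on PCA scores, `spectral_score_fn()`
composes projection and scoring so explanations live in the wavenumber
view, which is where band assignments have meaning. The default background
is a seeded subsample of at most 100 training spectra.

## Problem sizes used in the tests

The recovery tests run the full two-class pipeline (135 spectra/class,
60/10/30 split, PCA(2), 24-evaluation Bayesian search) and the five-class
CNN pipeline over 10 seeds each. The CNN recovery runs train for 25 epochs
at batch size 32 — on these high-contrast presets validation accuracy is
flat well before that — while the acceptance script runs the full 60-epoch
default. Oracle-equivalence tests (dense QP, exact Shapley enumeration,
circular convolution, eigendecomposition, Mann-Whitney) use small n where
the oracle is exact.

## Known limitations

* The generator's independence assumptions (per-band amplitude jitter,
  white noise) make the PCA variance spectrum flatter than measured SERS
  data, where a common-mode intensity direction usually dominates.
* The SMO solver is tuned for the data sizes of this workflow (hundreds to
  a few thousand samples); it precomputes the full Gram matrix.
* Platt calibration is the only probability mapping provided; the Gaussian
  kernel and the linear kernel are the only kernels.
* Shapley sampling assumes feature independence (interventional
  imputation); correlated-feature attributions inherit the usual caveats.
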
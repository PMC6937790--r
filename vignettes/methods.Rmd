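---
title: "Screening fetal acidemia from heart-rate scalograms: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Screening fetal acidemia from heart-rate scalograms: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup, message = FALSE}
library(ctgcnn)
```

## The problem

Intrapartum cardiotocography records the fetal heart rate (FHR, in beats
per minute at 4 Hz here) during labour. Hypoxic distress depresses the
fetal blood pH; an umbilical-artery pH measured after delivery below 7.15
defines the pathological (acidemic) class, a pH of 7.15 or above the
normal class. Visual interpretation of FHR tracings is notoriously
inconsistent between observers, which motivates a computer-aided pipeline:
clean the raw trace, convert it to a time-frequency image, and classify
the image with a small convolutional network, reporting accuracy,
sensitivity, specificity, the quality index and the ROC AUC under
stratified ten-fold cross-validation. Throughout the package the *normal*
class is the positive class.

## Artifact removal

Raw FHR traces carry three kinds of noise, each with its own rule, applied
in a fixed order:

1. **Missing signal.** A gap is a maximal run of zero samples. Gaps of at
   most 15 s are filled; longer gaps are removed outright, shortening the
   trace. Gaps touching a trace boundary lack one flank and are removed
   regardless of length.
2. **Spikes.** Whenever two adjacent samples differ by more than 25 bpm,
   the samples between the pre-spike sample and the first sample of the
   next *stable section* — five adjacent samples whose successive
   differences are all below 10 bpm — are replaced by linear
   interpolation between those two preserved endpoints. If no stable
   section follows, the unstable tail is trimmed. Both comparison
   thresholds are strict inequalities. A consequence of this reading is
   that a clean step onto a new stable level (e.g. 140 to 172 bpm with a
   stable plateau starting immediately) has an empty bridge interior and
   survives unchanged; re-running the stage is therefore idempotent.
3. **Non-physiological values.** Samples below 50 or above 200 bpm are
   replaced by a natural cubic spline through the in-range samples and
   then limited to the band (an unconstrained cubic can overshoot near a
   steep edit). Records with more than half their samples out of range
   are rejected.

The analysis segment is the **final 20 minutes** of the cleaned trace
(4800 samples at 4 Hz) — the window closest to delivery, the standard
choice in intrapartum analysis; `extractSegment(position = "first")`
selects the initial window instead. Segment duration is measured on the
cleaned signal, after any long-gap removal.

### Numerical choices in the gap fill

The fill for short gaps is a *monotone cubic Hermite* spline anchored on
short flank averages (up to two 4-sample chunks per side). Two failure
modes drove this choice, both visible with a band-limited variability of a
few bpm: a cubic through raw flank samples amplifies flank noise into
bulges of tens of bpm across a 10–15 s gap, and an unconstrained cubic
through even averaged anchors can bow far outside the flank range when
the two flank slopes disagree. The monotone Hermite form cannot leave the
anchor range, and averaging suppresses the noise; on smooth simulated
records with injected artifacts the root-mean-square recovery error over
edited samples is 1.3–4.8 bpm (the package tests assert < 5 bpm).

Every edited sample is tracked in a per-sample edit mask
(`untouched` / `interpolated` / `removed-adjacent`), so provenance is
testable: the set of samples that differ between input and output equals
the flagged set.

## Continuous wavelet transform

The cleaned segment $f(t)$ is correlated with translated, dilated copies
of a mother wavelet $\varphi$:

$$\mathrm{CWT}(\tau, s) = \int f(t)\,\frac{1}{\sqrt{|s|}}\,
\varphi^{*}\!\left(\frac{t-\tau}{s}\right)dt,
\qquad \int \varphi(t)\,dt = 0 .$$

Two order-2 families are exposed, `db2` and `sym2`. At order 2 the symlet
construction coincides with the Daubechies filter bank, so the two are
numerically identical; both names are kept because datasets are enriched
by enumerating families and scale settings (each record yields
families × exponents images, e.g. 552 records × 2 × 3 = 3312 images).
The wavelet itself is evaluated *exactly* on a dyadic grid over its
support $[0, 3]$: integer values come from the eigenvector of the
two-scale transfer matrix, then the refinement relation subdivides the
grid, so the discretisation converges and the Riemann sum of $\psi$
vanishes to machine precision.

**Scale grid.** A single scale cannot produce a two-dimensional image, so
a scale setting is read as a dyadic exponent $J \in \{4, 5, 6\}$ and each
scalogram uses the integer scales $1 \dots 2^J$, one row per scale and
one column per sample.

**Kernel discretisation.** Kernels are sampled by *cell averaging* via
the antiderivative $\Psi$ of $\psi$:
$k[m] = \sqrt{s}\,(\Psi((m{+}\tfrac12)/s) - \Psi((m{-}\tfrac12)/s))\,\Delta t$.
Point sampling at small scales breaks the zero-sum property of the
discrete kernel, and because an FHR trace rides on a large baseline
(~140 bpm), even a tiny residual DC response floods the finest scale rows
with a constant of the order of the baseline. Cell averaging makes every
scale's kernel sum exactly zero. The same discretised kernels define the
brute-force direct-summation oracle used in the tests, which the
convolution implementation matches to relative error below $10^{-10}$.

**Boundaries.** The signal is zero-extended. Columns within one wavelet
support of the trace edge (the cone of influence) respond to the
baseline-sized step at the boundary; they are excluded from the
normalisation range during rendering and clipped instead, because letting
them set the range would crush the interior dynamic range by a factor of
~50.

## Rendering

`renderImage()` maps coefficient magnitudes through per-image min–max
normalisation, a colormap (`jet` by default, matching the conventional
rendering of the era; per-image normalisation is the only self-contained
choice absent a global calibration), and a separable bilinear resize to a
square image of 16, 28, 36 or 64 pixels with RGB intensities in $[0,1]$.
When downscaling, the triangle kernel is widened by the scale ratio
(antialiased bilinear, as in the common imaging libraries): a plain 2-tap
kernel taking 64 columns out of 4800 would subsample the time axis nearly
at random. A `"log"` magnitude option implements the field's usual
dB-style scalogram display; the linear scale remains the default. A
constant coefficient matrix renders as the uniform mid-colormap image.

## The classifier

An eight-layer network: image input (augmentation + zero-centering) →
convolution → ReLU → cross-channel normalisation → 2×2 max pooling →
fully-connected → dropout → softmax classification.

* Convolution is valid (stride 1, no padding) with 5×5 kernels and 15
  filters at the default operating point; the constructor rejects
  configurations whose post-convolution width does not tile the 2×2
  pooling grid.
* The normalisation layer is cross-channel (local response)
  normalisation, $b_c = a_c / (K + \alpha \sum_{c'} a_{c'}^2 / W)^\beta$
  with $\alpha = 10^{-3}$, $\beta = 0.75$, $K = 2$ over a 5-channel
  window truncated at the channel edges with a fixed divisor $W$. These
  parameter names only make sense for LRN, which is why this layer is LRN
  rather than batch normalisation.
* The head is one hidden fully-connected layer (100 units, ReLU),
  dropout with probability 0.5 (inverted scaling, training only), and a
  2-unit softmax; its width is a free design parameter and configurable.
* Augmentation (training only): reflect-pad by 4 pixels, random crop
  back to the input size. The evaluation path is the deterministic centre
  crop, which reproduces the original image, so prediction is exactly
  reproducible. Zero-centering subtracts the training-set mean image.
* Training: mini-batch SGD (batch 50), momentum 0.9, initial learning
  rate 0.01 multiplied by 0.1 every 10 epochs, L2 factor $10^{-4}$ on
  weights and biases (their per-layer multipliers are all 1), 20 epochs,
  cross-entropy loss. Batches are reshuffled each epoch from the run
  seed; the last short batch is kept. Non-finite loss aborts with a
  training error.
* Initialisation: He scaling by default — zero-mean Gaussians with
  standard deviation $\sqrt{2/\text{fan-in}}$ per layer, biases zero. A
  fixed-width Gaussian (`init = "gaussian"`, std 0.01) is available, but
  with the fixed learning-rate schedule above it leaves the network at
  chance on desk-scale image sets: through the 13 500-unit flattening
  layer the logits start around $10^{-3}$ and 160 SGD iterations cannot
  recover, so fan-in scaling is the default.

Analytic gradients of every layer (including LRN) are verified against
central finite differences on a 6×6×1 toy network to relative error
below $10^{-4}$.

## Evaluation

From the binary confusion matrix (normal positive):
$\mathrm{Acc} = (TP{+}TN)/(TP{+}FP{+}FN{+}TN)$,
$\mathrm{Se} = TP/(TP{+}FN)$, $\mathrm{Sp} = TN/(FP{+}TN)$, and the
quality index $\mathrm{QI} = \sqrt{\mathrm{Se}\cdot\mathrm{Sp}}$ — the
geometric mean, robust to the ~4:1 class imbalance. AUC is computed by
trapezoidal integration over all score thresholds with the softmax
probability of the normal class as the score; it equals the concordance
probability with ties counting one half, and is invariant under strictly
increasing score transforms.

Cross-validation is stratified: each class is shuffled and split into k
near-equal folds (remainders go to the last folds), reproducing the
90/10 counts of a 2682/630 image set exactly — 2414 normal + 567
pathological images in training, 268 + 63 in test. The printed split
counts are what imply stratification; plain random splitting would not
fix the class proportions. Per-fold metrics are averaged without
weighting. With several images per recording, `grouping = "record"`
assigns whole recordings to folds to prevent leakage of one recording
across the train/test boundary; the image-level default reproduces the
conventional counts and is the default protocol.

## The synthetic test-bed

Real intrapartum databases cannot ship with a package, so every stage is
exercised by a seeded simulator. A clean trace is baseline (constant in
120–160 bpm for normal, 100–130 for pathological, plus a slow sinusoidal
drift) + AR(1)-filtered Gaussian variability scaled to the class band
(5–15 bpm peak-to-peak normal, 1–5 pathological) + Gaussian-bump
accelerations (+10…+25 bpm, 15–60 s) and decelerations (15–30 bpm deep
for normal at ~2/h; 30–60 bpm at ~10/h for pathological) arriving as
Poisson events; traces are floored at 52 bpm so deep pathological
decelerations stay physiological. The artifact injector adds the three
noise kinds the cleaning rules target — zero runs mixing ≤15 s and
>15 s durations, isolated >25 bpm spikes, and out-of-band values — with
a ground-truth mask, so recovery is measurable sample by sample.

The two classes differ in variability *bandwidth* as well as amplitude
(AR coefficient 0.8 normal vs 0.97 pathological, i.e. the pathological
trace is smoother — the classical loss-of-short-term-variability
marker). This matters because per-image min–max normalisation erases
absolute amplitude: with touching amplitude bands alone, records near
the 5 bpm boundary were class-ambiguous after rendering, which defeats
the purpose of a benchmark that must be separable by construction. The
bandwidth contrast shows up as a scale-profile shape difference that
survives normalisation. The benchmark renders one `db2` image per record
at dyadic exponent 5 with log magnitude scaling.

What the simulator does **not** model: true fetal-maternal physiology
(no pH biochemistry, no uterine-contraction coupling, no
sleep-state cycling), realistic artifact correlation structure, or the
label noise of a pH threshold applied to a biological continuum. Passing
the package's tests therefore demonstrates that the machinery is correct
and that the pipeline separates classes whose time-frequency signatures
differ in the clinically expected direction — it does not certify
performance on clinical data.

## Problem sizes used by the checks

The test suite verifies cleaning post-conditions (no zeros, everything in
50–200 bpm, idempotence) on 1000 seeded 5-minute records; the CWT oracle
on 512-sample signals; AUC/concordance equivalence on all 40 320
permutations of an 8-score vector; and the end-to-end benchmark at 200
records per class, 64×64×3 images, 20 epochs, mini-batch 50 — where the
default network reaches ≥ 95 % training accuracy and ≥ 85 % ten-fold
cross-validated accuracy at a fixed seed. These sizes are the package's
chosen desk-scale study conditions; the pipeline itself accepts
full-database inputs through the WFDB reader.

```{r, eval = FALSE}
# the end-to-end benchmark, exactly as the acceptance test runs it
set <- makeBenchmarkSet(nPerClass = 200, seed = 1)
model <- trainModel(buildModel(cnnConfig(seed = 1)), set)
mean(predictLabels(model, set) == imageLabels(set))
cv <- tenFoldCV(set, cnnConfig(seed = 1), k = 10)
cv$mean
```

## Known limitations

* The spike-bridging sentence of the published rule is grammatically
  ambiguous; the implemented reading (interpolate from the pre-spike
  sample to the first sample of the next stable section, endpoints
  preserved) is the minimal well-defined one, and it deliberately leaves
  genuine baseline shifts intact.
* Whether the original protocol interpolated across long-gap removal
  junctions is unknown; here the junction is a plain concatenation and
  any resulting >25 bpm step is left to the subsequent spike stage.
* `sym2` adds no information beyond `db2` (identical filters at order 2);
  it doubles the dataset without enriching it.
* The exact fully-connected width, LRN window and crop geometry of the
  original network are unpublished; all are configurable with the
  defaults documented above.
* Training is plain single-threaded SGD; large grids or databases will
  be slow, and no GPU path is provided.
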
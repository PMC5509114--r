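---
title: "Outline morphometrics for crowdsourced tooth tracings: models and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Outline morphometrics for crowdsourced tooth tracings: models and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(toothtrace)
```

## Scope

`toothtrace` turns filled black-and-white tracings of bovid tooth occlusal
surfaces into homologous landmark outlines, grades crowd-worker tracings
against a gold standard, builds consensus shapes, and classifies specimens
to tribe with random forests. This vignette records the models behind each
stage, the tunable parameters and their defaults, the numerical choices,
and what the synthetic-data generator does and does not emulate.

## From image to contour

A tracing is normalized to a strict binary mask (`binarize`): luminance
below the threshold (default 128 on the 0–255 scale) is foreground. The
outer boundary is extracted (`extract_contour`) in three steps:

1. **Component selection.** The largest 8-connected foreground component
   is kept; stray specks are discarded. `EBImage::bwlabel` provides
   4-connected labels, which we merge across diagonal adjacencies — a
   diagonally attached region belongs to the same tracing, not to a
   separate one.
2. **Sub-pixel boundary.** The 0.5 iso-level between foreground and
   background is traced with marching squares
   (`grDevices::contourLines`). Sub-pixel vertices give smoother contours
   than integer pixel-edge walking and therefore fewer spurious
   high-order harmonics. Interior holes are ignored: only the outer
   occlusal outline is analyzed. The y axis is flipped to standard
   Cartesian orientation and the contour is returned counter-clockwise;
   shape distances downstream are invariant to this convention, which
   only affects plots and exported CSVs.
3. **De-jagging.** The raw iso-contour of binary data cuts pixel corners
   at 45°, which inflates perimeter estimates by ~6% on a rasterized
   disk. A window-3 periodic moving average over the boundary vertices
   (the `smooth` argument) reduces this to ~1% while changing enclosed
   area by less than 0.2%. Smoothing is skipped for contours too short to
   support the window. One consequence worth knowing: the boundary around
   a *single* foreground pixel is the marching-squares diamond through
   the four edge midpoints, enclosing exactly 0.5 px² — sub-pixel
   contours do not reproduce single-pixel areas, which is irrelevant at
   tooth scale.

Foreground touching the image border triggers a warning (possibly clipped
tracing); `validate_inputs()` reports such files, unreadable files, empty
masks, and specimens missing from the metadata table without silently
dropping anything.

## Elliptical Fourier analysis

A closed contour is modeled as
$$x(t) = A_0 + \sum_{j=1}^H a_j\cos jt + b_j\sin jt,\qquad
  y(t) = C_0 + \sum_{j=1}^H c_j\cos jt + d_j\sin jt,$$
with $t$ the chord-length parameter scaled to $[0, 2\pi)$. The
coefficients are computed with the classical closed-form estimators for
piecewise-linear contours: each coefficient is the analytic Fourier
integral of the linearly interpolated coordinate functions, so the
estimators are *exact* for polygonal input (the unit tests verify them to
1e-6 against dense trapezoidal numeric integration). Two consequences of
this parameterization deserve emphasis:

- $A_0, C_0$ are the centroid of the chord-length parameterization, not
  the vertex average.
- An axis-aligned 2:1 ellipse does **not** yield first-harmonic
  coefficients (2, 0, 0, 1): under arc-length parameterization the
  coordinate functions are not pure sinusoids, and the exact first
  harmonic is (1.82841, 0, 0, 1.07302) (frozen in the tests from an
  independent numeric oracle). The reconstructed *curve* still converges
  to the ellipse as $H$ grows; only the per-harmonic values differ from
  the naive expectation.
- Because the estimators are exact integrals rather than a discrete
  Fourier transform, there is no sampling-theorem ceiling on $H$ for
  polygonal input; harmonics beyond roughly half the vertex count
  describe the polygon's corners rather than the underlying outline.

**Number of harmonics.** The default is $H = 10$ (40 amplitude features).
`harmonic_power()` reports the per-harmonic power
$(a_j^2+b_j^2+c_j^2+d_j^2)/2$ so users can choose an $H$ capturing ≥ 99%
of cumulative power; for the synthetic molar shapes $H = 10$ captures
essentially all of it. The classification results below use $H = 10$
throughout, but nothing in the pipeline depends on that specific choice.

**Normalization.** Landmarks must "begin in the same location" on every
tracing of a tooth. `efa_normalize` applies the standard first-harmonic
normalization: the parameter is re-phased so $t = 0$ lies on the first
ellipse's semi-major axis, and the frame is rotated about the centroid so
that axis defines orientation zero, leaving $b_1 = c_1 = 0$ and
$a_1 > 0$. The major axis crosses the ellipse twice; the two candidate
normalizations differ by the sign of every even harmonic. We resolve this
deterministically by picking the lexicographically larger coefficient
vector — a rule that is invariant to start vertex, rotation, translation,
and positive scaling (verified to 1e-6 in tests). Reflection is *not*
normalized: left and right molars genuinely differ, and the study design
analyzes tooth positions separately. Sizes are kept as-is (specimens are
assumed pre-scaled to each other, so size is signal); a
`size_invariant` switch on `efa_features` divides by $a_1$ for scale-free
features, which also drops a third pinned entry (lengths: 4H plain,
4H − 2 with pinned zeros dropped, 4H − 3 size-invariant).

`efa_inverse` evaluates the model at $t_k = 2\pi k/K$, $k = 0..K-1$, with
$K = 150$ by default, giving homologous landmark sets across tracings.

## The Riemannian shape distance

Tracing error is measured as the geodesic distance in Kendall's shape
space for planar configurations: both landmark sets are centered, scaled
to unit centroid size, treated as complex $K$-vectors, and
$$\rho(z_1, z_2) = \arccos\,\lvert\langle z_1, z_2\rangle\rvert
  \in [0, \pi/2].$$
The modulus quotients rotation, so the distance is invariant to
translation, rotation, and scale of either input; reflection is not
quotiented, consistent with the normalization above. The implementation
uses the algebraically identical chordal form
$2\arcsin(\mathrm{chord}/2)$ after optimal rotation, because `acos` near
1 quantizes tiny distances to either 0 or ~1.5e-8; the chord form
resolves distances down to ~1e-14, which the similarity-invariance tests
rely on. The tests also verify agreement to 1e-4 with a brute-force
rotation-grid Procrustes oracle and the metric axioms on 1000 random
triples. The observed range of real campaign errors (maximum ≈ 1.11)
sits inside $[0, \pi/2]$, consistent with this choice of metric.

## Filtering and consensus

A tracing is rejected when its distance to the reference exceeds a
threshold, default **0.2** — the operating point of the reference
campaign. Two reference modes exist because the campaign used both:

- `gold_standard`: grade against the expert outline (used for the
  consensus-plus-expert condition);
- `worker_mean`: grade against the Procrustes mean of the workers' own
  tracings, then recompute the mean once from the survivors (two-pass;
  used for the worker-consensus condition, and valuable because it needs
  no expert at all).

The consensus shape is the **full Procrustes mean**: inputs are centered
and unit-scaled, and the mean is the dominant eigenvector of the complex
sum-of-outer-products matrix (computed through the small $n \times n$
Gram matrix — exact, no iteration). The result is rescaled to the mean
centroid size of its inputs so consensus shapes keep the size signal. We
average landmarks rather than pixels because a pixel-mean of masks is not
a closed outline, and rather than coefficients because the Procrustes
mean is the standard estimator on landmark data; a coefficient-space mean
of normalized decompositions is nearly identical for small dispersions.
Filtering is monotone in the threshold (kept sets are nested), and
averaging provably helps: with 25 jittered tracings the mean beats the
median individual tracing in ≥ 95 of 100 seeded replicates.

## Classification

Features are the harmonic amplitudes; the classifier is a random forest
(`randomForest`, 500 trees, $\sqrt p$ features per split — configuration,
not claims) under leave-one-out cross-validation, each fold re-seeded as
`seed + fold` for exact reproducibility. Scores: multiclass log-loss
$-\frac1N \sum \ln \max(\varepsilon, \hat p(\text{true class}))$ with
natural log and $\varepsilon = 10^{-15}$ clipping (chance for 3 balanced
classes is $\ln 3 \approx 1.099$); classification rate (confusion-matrix
diagonal over total); and the share of misclassifications attributable to
one confusable pair (`confusion_share`). Argmax ties break toward the
lexicographically first label, with a message.

`run_conditions` reproduces the campaign's four-way comparison: expert
outlines, the sampling distribution of single unscreened worker tracings
(R datasets, one sampled tracing per specimen), the filtered worker
consensus, and the consensus averaged with the expert. Specimens with no
usable tracing are dropped from worker conditions and counted. The
single-worker pool includes gross errors by default (an unscreened single
worker is exactly that risk); `include_gross_in_sampling = FALSE` gives
the screened variant.

## The synthetic-data generator

The generator defines truth shapes directly in coefficient space — the
feature space used downstream — so class separation and dispersion are
controllable and interpretable. `molar_mean_shape()` builds a molar-like
mean outline (squarish superellipse with a mid-crown waist);
`default_templates()` instantiates four tribe-like classes with the
reference campaign's class sizes (33/10/35/18, total 96), and
`lm2_templates()` the three-class lower-second-molar layout (15/15/8,
total 38) used for classification experiments, which contains no
Bovini-like class. A specimen perturbs its class mean with zero-mean
Gaussian noise of sd `coeff_sd_scale × size / j` on harmonic $j$
(dispersion decays with harmonic order). The default
`coeff_sd_scale = 0.045` was chosen once so that expert-condition LOOCV
difficulty falls in the reference campaign's range (roughly 75–85%
correct on 38 specimens); it was not adjusted afterwards.

Worker behavior (`worker_noise_model`) has three components, each a
deliberate simplification:

- **Correlated jitter.** Gaussian noise smoothed with a periodic kernel
  (correlation length 10% of the perimeter), because hand-tracing errors
  are locally smooth; i.i.d. per-landmark noise would inject unrealistic
  high-frequency harmonics. `jitter_sd` is expressed in units of the
  outline's RMS radius about its centroid. The default 0.15 was
  calibrated once so the simulated median worker-to-truth distance of
  jitter-only tracings (graded, like real tracings, after EFA re-fit) is
  ≈ 0.115–0.12 — the order of the reference campaign's median (0.1154);
  with gross errors in the mix the overall median runs ≈ 0.12–0.14. No
  claim is made of matching the full error distribution.
- **Gross errors** (probability 0.1 per tracing): a different random
  specimen's outline, distorted further if needed until its raw distance
  to truth exceeds 0.3 — a margin over the 0.2 rejection threshold so the
  guarantee survives EFA re-fit. This emulates "clearly wrong"
  submissions (wrong tooth, internal areas traced) and gives the
  filtering stage guaranteed work.
- **Dropout** (probability 0.1 per tracing): tracings independently not
  returned, emulating incomplete crowdsourcing returns. Dropout and gross
  error are independent Bernoulli events per tracing — the simplest model
  consistent with how such failures are described.

What the generator does *not* emulate: worker skill heterogeneity,
learning effects, photographic artifacts (lighting, perspective), scale
calibration, or real biological outlines. Passing tests on synthetic data
therefore demonstrate the pipeline's correctness and its qualitative
behavior (error distributions, the benefit of filtering and consensus,
the ordering of tracing conditions) — not quantitative agreement with any
specific photographic dataset, whose headline numbers depend on images
that are not distributed.

## Problem sizes and determinism

Simulation-backed checks use a 38-specimen, 3-class layout with up to 3
tracings per specimen, 50 single-worker resamples per seed and 5 seeds
for the condition-ordering check, 100 replicates for consensus-recovery
checks, and 1000 random triples for the metric axioms — sizes at which
the Monte-Carlo conclusions are stable across seeds while a full suite
run stays comfortably interactive. Every stochastic stage takes an
explicit seed; `generate_population`, `simulate_worker_tracings`,
`loocv_predict`, `run_conditions`, and `run_pipeline` are bit-reproducible
under a fixed seed (manifest checksums verify this end to end), and all
seed handling restores the caller's RNG state.

## Known limitations

- The worker-mean reference needs at least two usable tracings to be
  meaningful; with a single tracing the mean *is* that tracing and
  filtering cannot reject it.
- The Procrustes mean is not robust to gross errors that survive
  filtering; a geometric-median consensus is out of scope.
- Marching-squares boundaries under-resolve features at the 1–2 px scale
  (and single-pixel blobs, see above); rasterize at ≥ 256 px for shape
  fidelity (the rasterize → extract → EFA round trip is < 0.05 Riemann
  distance at 512 px).
- Tie-breaking and lexicographic conventions (argmax ties, the
  even-harmonic sign rule) are deterministic but arbitrary; they matter
  only in measure-zero situations.
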
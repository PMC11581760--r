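---
title: "Quantifying three-phase bone scintigraphy: models, phantoms and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying three-phase bone scintigraphy}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tpbsquant)
```

## The measurement

Three-phase bone scintigraphy (TPBS) images local bone turnover: a
radiotracer is injected and planar images are acquired in a flow phase
(p1), a blood-pool phase (p2) and a delayed/bone phase (p3). Both limbs
are in frame, and because tracer accumulation in the *unaffected* limb
is a good within-patient control, the quantity of interest is the
per-region ipsilateral/contralateral ratio

$$R = \frac{\overline{255 - v}\;\big|\;\text{ROI, affected side}}
           {\overline{255 - v}\;\big|\;\text{ROI, unaffected side}},$$

computed on 8-bit display pixels $v$ after inversion. Scintigraphy
displays conventionally render high count rates dark, so inversion makes
larger numbers mean more uptake and $R > 1$ means greater accumulation
on the affected side. The annotation scheme drives which ROIs exist:
hands get the whole hand in p1–p2 and the carpal, MCP and PIP joint
subregions in p3 (five ratios per case); feet get the whole foot in all
phases (three ratios), since individual joints cannot be separated
reliably on planar foot views.

Three deliberate choices fix the arithmetic:

- **Inversion is exactly $255 - v$** and happens before any averaging.
- **No background subtraction, no normalisation.** $R$ is invariant
  under a global rescaling of the inverted display but *not* under
  offsets; silently subtracting a background would change every ratio.
  The pipeline therefore never offsets, and the test suite asserts the
  offset sensitivity explicitly.
- **ROIs below 20 pixels are an error**, not a number: a segmentation
  dropout shrinks the denominator ROI and can produce arbitrarily
  unstable ratios, so the guard names the case, region and side instead.
  The default of 20 pixels is far below any correctly segmented phantom
  region at the resolutions used here.

## The phantom

No patient data ships with the package; a parametric phantom module
emulates what the downstream stages need and nothing more. One case is
two mirror-symmetric limb silhouettes (hand: palm, four fingers, carpal
block, four MCP and four PIP discs, plus a forearm that belongs to the
soft-tissue silhouette but *not* to the whole-hand ROI; foot: a single
silhouette) on a dark-count background. Per-pixel tracer activity is the
region's per-phase baseline, multiplied by an enhancement factor
$f > 0$ inside the chosen regions on the affected side; the activity map
is smoothed by a Gaussian point-spread, mapped to display intensity as
$v = \mathrm{clamp}(255 - \mathrm{round}(100\,a),\,0,\,255)$, and
additive Gaussian display noise is applied and re-clamped.

Parameters that matter, with defaults and rationale:

- **Gain, 100 display units per activity unit.** Baseline joint
  activity (~1.0–1.15) sits near mid-range after inversion (~100–130),
  leaving headroom for $f$ up to ~2 before clipping.
- **Baseline uptake per region and phase.** Phases 1–2 are soft-tissue
  dominated and rendered with stronger smoothing (1.8× and 1.4× the
  phase-3 blur); phase 3 is bone-localised (joints ~1.0–1.15, soft
  tissue 0.25). These are qualitative emulations of the phase behaviour,
  chosen once; they are not fitted to any data.
- **`blur_sigma` (default 1.2 px at the phase-3 image).** Small enough
  that ROI means lose only a few percent of region contrast to
  partial-volume leakage at 96×96.
- **`noise_sd` (default 6 display units).** Visible grain without
  threatening segmentation; ROI means over >100 pixels are barely
  affected.
- **Per-case jitter** (global scale 0.92–1.06, shifts ±2.5% of the
  frame, ~4% lognormal uptake variation) gives the learning problem
  non-trivial variability. Jitter is *identical on both sides* of a
  case, which is what makes the symmetry and recovery properties exact.
- **Enhancement** is uniform within the enhanced regions; the "distal"
  character of real presentations is expressed through the default
  enhanced set (the joint regions of the hand).

Two properties are engineered to be exact, not approximate:

- **Mirror symmetry.** The right limb is constructed as the exact
  column-mirror of the left, and the separable Gaussian blur sums its
  $\pm d$ offset taps *as pairs*; since IEEE addition is commutative,
  smoothing commutes with mirroring bit-for-bit. With $f = 1$ and no
  noise, every ratio is therefore exactly 1 — a sharp null against which
  any asymmetry introduced by a bug is visible.
- **Known induced contrast.** `expected_contrast()` integrates the
  unsmoothed activity over an ROI with and without the enhancement; for
  a fully enhanced ROI it equals $f$ exactly, and for the mixed
  whole-hand ROI in p1–p2 it gives the exact dilution. The rendered
  images differ from it only through smoothing, quantisation and noise,
  which is precisely the measurement error the recovery checks bound
  (5% with truth masks, 10% with predicted masks, at the study
  conditions below).

What the phantom does *not* emulate: anatomically realistic bone
shapes, degenerative changes and other uptake confounders, acquisition
heterogeneity, patient motion, or detector physics beyond a Gaussian
point-spread and additive noise. Passing tests on phantoms therefore
demonstrate the *correctness of the pipeline's arithmetic and learning
machinery*, not clinical segmentation performance.

The raw-pixel convention of clinical TIFF exports is not standardised;
this package fixes "dark = high uptake" as its stored convention
(that is what makes the inversion step meaningful) and documents it
rather than guessing per file. Inputs using the opposite convention
must be inverted at import.

## Segmentation models

Three single-task models cover the annotation scheme: `hand_whole`
(p1–p2), `hand_subregions` (p3), `foot_whole` (p1–p3). Each is an
ensemble of $m$ (default 3) replicas of a small U-net style
encoder–decoder: two 2× average-pool stages, 3×3 convolutions with ReLU,
skip connections, nearest-neighbour upsampling and a 1×1 softmax head;
base width 8 gives ≈27k parameters. The implementation is plain R:
feature maps are $(HW) \times C$ matrices, convolutions are im2col
matrix products executed by the BLAS, and the backward pass is written
out layer by layer (a finite-difference audit in the test suite checks
it). Inputs are the normalised intensity plus two coordinate channels —
the normalised row and the *midline-folded* column $|2x - 1|$, which
respects the left/right mirror structure of the frame and matches the
side-agnostic classes.

Design choices in the learning stack:

- **Side-agnostic classes, midline side assignment.** The two limbs are
  mirror images, so the network predicts region identity only;
  left/right labels are assigned afterwards by the pixel's side of the
  vertical midline. This halves the class count and exploits the frame
  convention (both limbs in frame, one per half).
- **Loss: cross-entropy + soft Dice.** The joint subregions occupy ~3%
  of the frame; the soft-Dice term keeps the background from dominating.
- **Optimiser: Adam**, lr 6e-3, 20 epochs, gradient steps over 2-image
  batches, best-validation-Dice checkpointing per member. A fixed epoch
  budget replaces any "train until good enough" rule, which is not
  operational.
- **Replicas differ only by seed-derived initialisation and data
  order.** The ensemble's role is uncertainty, not accuracy.
- **Uncertainty $u$** is the mean per-pixel predictive entropy of the
  ensemble-mean class distribution: $u = 0$ iff that distribution is
  one-hot everywhere, and $u \le \ln C$. The out-of-distribution
  threshold is the 95th percentile (type-7 linear-interpolation
  quantile) of validation-image uncertainties, so by construction at
  most ~5% (+1/n) of validation images are flagged.
- **Active learning** selects the `budget` most-uncertain pool cases,
  obtains labels from an oracle (ground truth in tests; a human in any
  clinical deployment — no quantitative relabelling rule exists for the
  visual check, so the oracle is pluggable), and retrains all members
  warm-started for a few epochs, keeping the previous weights if
  retraining does not improve validation Dice. That guard is what turns
  "retraining" into a non-degradation operation.

Whether a deployment should read "3 models" as three task-specific
networks or as a 3-member uncertainty ensemble of one network is
ambiguous; this package implements the superset (3 tasks × m replicas),
and either reading is recoverable by configuration.

## Problem sizes and study conditions

All learned-model checks run at reduced resolution so a single CPU
handles them in minutes: 60 hand phantoms at 96×96 (split 42/12/6 by the
70/20/10 case-level rule), 2-member ensembles, 20 epochs. These sizes
are the package's fixed study conditions; the architecture accepts
400×400 inputs unchanged. At these conditions the held-out per-class
Dice of the phase-3 subregion model exceeds 0.85 comfortably (typically
>0.95), enhancement factors 1.2/1.5/2.0 are recovered within 5% (truth
masks) and 10% (predicted masks), pure-noise images score above the
mean validation uncertainty essentially always, and uncertainty-ranked
selection strongly prefers high-noise (noise_sd 60 vs 6) pool cases.
The acceptance script recomputes all of these from scratch at any seed.

## Numerical and procedural details

- **Split arithmetic**: largest-remainder apportionment of
  `floor(n·fraction)` with ties toward train, then validation, then
  test; 40 cases give exactly (28, 8, 4). Splitting is by *case*, never
  by image, so the three phases of one acquisition cannot straddle
  train and test.
- **Dice convention**: $D = 2|A\cap B|/(|A|+|B|)$, and $D = 1$ when both
  masks lack the class — both agreeing the class is absent is perfect
  agreement; the alternative ($D=0$) would penalise correctly-absent
  classes.
- **Cut-off boundary**: a case is positive iff $R \ge c$ (inclusive),
  default $c = 1.32$ on the phase-3 MCP ratio — the previously published
  threshold. The rule lives in one function so the boundary convention
  cannot drift.
- **Quantile rule**: all quartiles and the calibration percentile use
  type-7 linear interpolation, stated so results reproduce across
  languages.
- **Undefined metrics stay undefined**: sensitivity on an all-negative
  truth vector is `NA`, never 0; a zero contralateral mean raises an
  error, never `Inf`.
- **TIFF dialect**: single-channel 8-bit, uncompressed or deflate;
  anything else (RGB, 16-bit) is an explicit unsupported-format error
  rather than a silent conversion.
- **Determinism**: every stochastic step (phantom rendering, shuffling,
  initialisation, noise draws) is driven by an explicit seed through a
  local RNG scope that restores global state; identical seeds give
  bit-identical phantoms and reproducible training up to floating-point
  summation order.

## Known limitations

- Phantom realism is deliberately minimal (see above); Dice values on
  phantoms say nothing about clinical Dice.
- Side assignment by midline split assumes acquisitions with one limb
  per half-frame; crossed or single-limb acquisitions are out of scope.
- The foot is quantified as one region; planar foot acquisitions do not
  support reliable per-joint subregions.
- The uncertainty threshold is calibrated on in-distribution validation
  phantoms; its false-negative rate against real out-of-distribution
  clinical images is unknowable from synthetic data.
- Training at 400×400 works but is slow in plain R; the reduced
  resolution is the supported operating point for routine use.
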
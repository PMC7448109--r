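---
title: "Methods: lesion quantification, perceptron staging and rule-based fusion"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: lesion quantification, perceptron staging and rule-based fusion}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(prostadss)
```

## The model

The package implements a two-channel decision pipeline for prostate
cancer. The **disease channel** is a six-marker serum panel — TPSA,
RBC, HB, FPSA, PAP, PSMA — validated against normal reference ranges,
min–max scaled to $[0,1]$ and fed to a small sigmoid perceptron. The
**image channel** reduces a lesion image to two numbers, the lesion
pixel area $P_{\mathrm{Area}}$ and mean gray level
$P_{\mathrm{Gray}}$, which feed a second perceptron. A rule-based
engine fuses the two channel scores into a single decision score

$$\mathrm{DPC} = w_d \, s_{\mathrm{disease}} + (1 - w_d)\, s_{\mathrm{image}},$$

which maps to clinical stage I–IV by the fixed bands
$(0,0.25] \to \mathrm{I}$, $(0.25,0.50] \to \mathrm{II}$,
$(0.50,0.75] \to \mathrm{III}$, $(0.75,1] \to \mathrm{IV}$ (band
boundaries belong to the lower stage), and each stage carries a
treatment recommendation.

## Lesion quantification

The imaging chain is a classical Canny-style detector followed by
chain-code area measurement:

1. grayscale $P = \alpha R + \beta G + \gamma B$ with
   $\alpha \in [0.25, 0.35]$, $\beta \in [0.55, 0.65]$,
   $\gamma \in [0.1, 0.2]$; defaults $(0.30, 0.59, 0.11)$ are inside
   all three ranges and sum to 1, so already-gray input passes through
   unchanged;
2. Gaussian smoothing, default $\sigma = 1.4$, radius 2, reflect
   border handling;
3. the $2\times 2$ first-difference gradient
   $G_x = \tfrac{1}{2}[f(x{+}1,y) - f(x,y) + f(x{+}1,y{+}1) -
   f(x,y{+}1)]$ (and symmetrically $G_y$), magnitude
   $\sqrt{G_x^2+G_y^2}$, direction $\operatorname{atan2}(G_y, G_x)$;
4. non-maximum suppression in four direction sectors with ties kept
   ($\ge$), so intensity plateaus retain a connected ridge;
5. hysteresis thresholding, defaults $t_{\mathrm{high}}$ = 90th
   percentile of the non-zero thinned magnitudes and
   $t_{\mathrm{low}} = 0.4\, t_{\mathrm{high}}$ — no reference values
   exist for these, so they are configuration, not science;
6. the edge ring is filled by flood-filling the background from the
   border, the largest 8-connected component is kept (the pipeline
   assumes a single lesion), and its boundary is traced
   clockwise (Moore neighbourhood) into an eight-direction Freeman
   chain code.

**Area.** For a *filled mask* whose boundary is the chain itself,
`chain_area()` returns the exact enclosed pixel count via the discrete
Green's theorem plus the Pick correction:
$\bigl|\sum_i \tfrac{x_i + x_{i+1}}{2}\, s_i\bigr| + N/2 + 1$, where
$s_i \in \{-1,0,1\}$ is the vertical step of code $i$ (codes 1–3 step
up, 0 and 4 are horizontal, 5–7 step down). The midpoint form is used
because the plain $\sum x_i s_i$ is off by half a pixel per diagonal
step; the binding contract, enforced in the tests, is exact equality
with a flood-fill pixel count on rasterised convex shapes and all small
rectangles.

**Edge-contour area.** `extract_lesion_metrics()` does *not* use the
boundary-inclusive count: the traced contour follows the detected edge
ridge, which straddles the true lesion boundary, so counting the ring's
pixels fully overestimates small lesions by roughly half the perimeter
(up to +25 % at stage-I sizes). The reported `area_px` is therefore the
Green's-theorem area of the contour polygon itself ($+1$ for the
degenerate single-pixel chain). With this estimator, noise-free
synthetic ellipses across all four stage size ranges are recovered
within 10 % (worst observed ≈ 7 % at the smallest sizes).

An image is marked `informative` when `area_px` ≥ the area of a circle
of diameter 15 (the upper normal lesion bound, interpreted as
millimetres at 1 px/mm unless a pixel spacing is configured) *and* mean
gray ≥ 180 (the upper normal gray bound). The underlying screening rule
is not specified anywhere authoritative; this flag is the package's
operational stand-in, and screened-out images are flagged, never
silently dropped.

## Input model

Validation distinguishes `missing`, `nonnumeric` and `out_of_range`
(negative or above a plausibility cap) fields; a value *above the
normal range but below the cap is accepted* — elevated markers are the
disease signal, not recording errors. The caps (TPSA 1000 ng/ml, FPSA
500 µg/L, HB 250 g/L, RBC 25 g/100 ml, PAP and PSMA 100 ng/ml) are
configurable plumbing with no clinical meaning. Missing data are
rejected at diagnosis time; no imputation is performed. The RBC units
are carried exactly as printed in the reference table
(g/100 ml) and never converted.

Scaling is $(v - \mathrm{lower})/(\mathrm{cap} - \mathrm{lower})$
clipped to $[0,1]$, in the fixed order (tpsa, rbc, hb, fpsa, pap, psma,
area, gray_level); the first six form $ACP(t)$, the last two $AHP(t)$.
Scaling by the cap rather than the normal upper bound compresses the
inputs toward zero, which is harmless for the perceptrons (the bold
driver grows the effective step size) and keeps the map monotone and
total.

## The perceptrons

Two independent networks are used, 6-4-1 for the markers and 2-3-1 for
the image features — the input is explicitly split into two channels
whose scores are fused afterwards, so a single 8-input network was
rejected. Architectures are configurable; the defaults are the
smallest layouts that recover the synthetic stages reliably.

Training is full-batch gradient descent on
$E = \tfrac{1}{2}\sum_k (d_k - a_k)^2$ with sigmoid activations at
every layer, momentum (the "dynamic coefficient", allowed range
0.6–0.8, default 0.7 — the midpoint), and initial learning rates
$\eta_1 = \eta_2 = 0.9$ for weights and biases. The reference material
says only that the rate starts at 0.9 and "adjusts automatically"; this
is implemented as the classical **bold driver**: accepted steps
(error does not increase) multiply the rate by 1.05, rejected steps
restore the weights, clear the momentum buffer and halve the rate,
with a floor of $10^{-4}$. A consequence used by the tests: the error
trajectory over accepted steps is non-increasing by construction, on
any data. Weights and biases are initialised uniformly on $[0, 0.5)$
(biases are not mentioned separately anywhere, so they follow the same
rule), and the allowed-error tolerance defaults to $10^{-4}$, inside
the documented $10^{-3}$–$10^{-5}$ range.

Desired outputs are unspecified in the source material; the package
uses the **stage-band midpoints** 0.125 / 0.375 / 0.625 / 0.875 so that
each sub-model's score already lives on the DPC scale and can be banded
with the same staging function.

Backpropagated gradients are exact: the test suite checks all weight
and bias partials against central finite differences (step $10^{-6}$)
at relative tolerance $10^{-5}$ on 25 random network/input/target
triples. Model files are JSON with 17 significant digits, which
round-trips every double bit-exactly.

## Rule-based fusion

Image findings are markedly more conspicuous in late disease (stages
III–IV) than early (I–II), which yields a four-case rule table on the
(disease band, image band) pair. Only orderings are documented, not
numbers; the package defaults are

| disease band | image band | $w_d$ | constraint enforced |
|---|---|---|---|
| early | early | 0.6 | $w_d > 0.5$ |
| late  | late  | 0.4 | $w_d < 0.5$ |
| late  | early | 0.8 | $w_d \ge 0.75$ ("much larger") |
| early | late  | 0.2 | $w_d \le 0.25$ ("much smaller") |

with $w_i = 1 - w_d$ always, so DPC is a convex combination and lies
between the two channel scores. The table is configurable but the
constructor enforces the orderings, operationalising "much
larger/smaller" as a 0.75/0.25 margin. Exactly one rule fires per band
pair; there are no conflicts by construction.

Boundary handling is exact `<=` on the computed double, pinning
DPC = 0.25 to stage I; a DPC of exactly 0 is rejected rather than
staged, since sigmoid outputs cannot reach 0. For classifier
evaluation the positive class defaults to late-stage disease (III–IV) —
no authoritative definition exists — and is configurable; TPR/FPR with
zero denominators are reported as `NA`, never 0.

## The synthetic generator

The generator emulates the *statistical shape* the pipeline assumes,
not real pathology:

* markers are log-normal with stage-conditioned medians — TPSA 5, 12,
  30, 60 ng/ml (anchored to: < 4 normal, > 10 suspicious, mean > 50
  likely cancer), FPSA/TPSA median ratios 0.20, 0.15, 0.11, 0.07
  (declining below 0.1 by stage IV), HB/RBC mildly declining, PAP and
  PSMA rising. The spread parameters (sdlog 0.04–0.35) are fabricated
  defaults, documented here once and not tuned thereafter;
* images contain one centred filled ellipse with stage-increasing
  semi-axes (5–9, 10–14, 15–19, 20–25 px in a 128 px image) and
  intensity (185–215) on an 80-intensity background with additive
  Gaussian noise (sd 8), clipped to [0, 255]; the ground-truth area is
  the exact rasterised pixel count;
* one root seed drives named sub-streams (stage assignment, markers,
  geometry), so cohorts are byte-reproducible and modules can be
  tested in isolation.

A green end-to-end test (≥ 80 % staging accuracy on 200 held-out
synthetic patients after training on 800) therefore establishes that
the pipeline is *internally consistent* — the networks can learn the
structure the generator encodes and the fusion preserves it. It does
**not** establish clinical accuracy: real marker panels overlap far
more between stages, real lesions are not centred ellipses, and the
reported hospital-scale accuracy figures depend on data that is not
available.

## Numerical choices and degenerate inputs

* Convolution uses mirror (reflect) padding; constant images are fixed
  points and the intensity range never expands.
* The gradient field lives on the $(h{-}1)\times(w{-}1)$ half-pixel
  grid; the half-pixel offset cancels in area measurement and is
  negligible for mean gray.
* A single-pixel region yields a degenerate closed chain of length 0
  and area 1 (the Pick correction alone).
* Multiple foreground components: the largest by pixel count is
  selected before tracing; an empty edge map yields
  `informative = FALSE` with area 0 and `NA` gray, not an error.
* Noisy images with small lesions can defeat the percentile-based
  thresholds (the largest filled component may be background texture);
  the gray-level screening bound catches most of these, and the area
  accuracy guarantee is stated for noise-free renders only.
* Training epochs for the cohort networks default to 4000 (the
  tolerance is rarely reachable on 800-sample batches); the AND-gate
  fixture converges in a few hundred epochs.

## Known limitations

* No DICOM/PET-CT ingestion; disk formats are plain-text PGM/PPM
  (chosen because the deliverable must be text-only and no binary
  image reader is guaranteed present).
* Single-lesion assumption; no 3-D, multi-slice or multi-focal
  support.
* The fusion weight grid beyond the four-case reduction is not
  implemented (it is not specified numerically anywhere).
* Chain-code area requires a simply connected region traced without
  pixel revisits; thin (1-px) protrusions can violate this. The
  acceptance contract is stated — and tested — on convex shapes.
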
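---
title: "Adaptive PCNN fusion of PET and CT images in the NSCT domain"
author: "nsctfusion authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Adaptive PCNN fusion of PET and CT images in the NSCT domain}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nsctfusion)
```

## The fusion problem and the model

PET and CT record complementary physics: metabolic tracer uptake at low
spatial resolution, and anatomy at high resolution. Fusing a co-registered
slice pair into one image is a coefficient-selection problem in a
transform domain: decompose both sources, decide per coefficient which
source to keep, and invert. `nsctfusion` makes that decision with a
pulse-coupled neural network whose inputs and linking strengths are
derived from local image features, inside a shift-invariant contourlet
decomposition.

The pipeline assumes its two inputs are **single-channel, equal-sized, and
already co-registered**; registration is deliberately out of scope and the
functions refuse mismatched shapes rather than resample. Intensities are
conventionally in [0, 1] (the readers rescale on load); the transform and
the selection rule themselves are scale-equivariant.

### The transform

The nonsubsampled contourlet transform (NSCT) used here composes:

* a nonsubsampled pyramid: at stage $k$ the current low-pass band is
  filtered with an à-trous-dilated (factor $2^{k-1}$) low-pass kernel and
  its complementary high-pass kernel, with no down-sampling;
* a nonsubsampled directional filter bank: each stage's high-pass band is
  split $d_k$ times by fan filters into $2^{d_k}$ directional subbands.

Every two-channel split uses a *complementary* analysis pair — the high
(or second fan) kernel is $\delta - h_0$ — with identity synthesis, so the
synthesis side is the plain channel sum and analysis-then-synthesis is the
identity for any low-pass kernel and any boundary handling. Perfect
reconstruction is therefore structural (measured round-trip error is at
machine precision, $\sim 10^{-16}$), and the transform is exactly linear
and, in periodic mode, exactly shift-equivariant.

The kernels themselves are open choices (no particular filters are
mandated by the method): the default preset pairs a $5\times 5$
maximally-flat binomial pyramid low-pass with a $7\times 7$ fan filter
obtained by McClellan transform of the degree-3 maximally-flat halfband
$H(x) = \tfrac12 + \tfrac34 x - \tfrac14 x^3$ at
$x = (\cos\omega_1 + \cos\omega_2)/2$ (a diamond halfband), modulated by
$(-1)^{\text{row}}$ into a fan. The directional tree upsamples the fan on
the lattices $I$, $Q$ (quincunx), $2I$, $2Q$ at depths 1–4 with
alternating fan orientation. This is a simplification of the fully
resampled directional filter bank: the shearing resampling matrices are
omitted, so the eight- and sixteen-band wedges are only approximately
aligned, while reconstruction stays exact. For fusion — where the bands
are fused independently and summed back — the exactness of the inverse
matters more than perfect wedge alignment.

The default decomposition is 3 stages with $2^2, 2^2, 2^3$ directions
(fine scales get more directions). Depth and directions are configurable
(`decompositionSpec()`); directional depth is capped at 4 per stage.

### The PCNN and its firing maps

Each subband drives a simplified PCNN, one independent network per band
(nothing in the method couples bands, and independent runs keep the
selection local to each band's geometry). The recursion, iterated
`nIter` times from $L = 0$, $Y = 0$, $\theta = \theta_0$:

$$F[n] = S,\quad
L[n] = e^{-\alpha_L} L[n-1] + V_L \sum W \cdot Y[n-1],\quad
U[n] = F[n]\,(1 + \beta L[n]),$$
$$Y[n] = \mathbf{1}\{U[n] \ge e^{-\alpha_\theta}\theta[n-1]\},\qquad
\theta[n] = e^{-\alpha_\theta}\theta[n-1] + V_\theta Y[n].$$

Two points are worth making explicit because the formulation leaves them
open:

* the feeding input has **no memory** ($F[n] = S$ at every step), taken as
  written;
* the threshold update involves the *current* pulse, which is circular as
  printed; it is resolved in the standard way — the neuron compares $U$
  against the decayed threshold, and the $V_\theta$ kick is applied after
  the firing decision. Initial conditions ($L=0$, $Y=0$,
  $\theta=\theta_0$) are likewise a documented choice.

The **firing map** is defined as the cumulative count of firing events
over all iterations — a stable ordinal signal that standard PCNN-based
fusion practice uses; a momentary $Y[n]$ snapshot would depend sharply on
the stopping iteration.

The external stimulus $S$ is not the raw subband but a feature map:
NSML on the low-pass band (second-difference energy — a clarity measure
appropriate for a smooth band) and EOE on high-pass bands (squared
responses of three directional operators — an edge-energy measure
appropriate for detail bands). Each feature map is min–max normalized to
[0, 1] per band (a constant map normalizes to zeros). The linking
strength $\beta$ is per-pixel adaptive: the region average gradient of
the *normalized feature map* — the quantity that actually stimulates the
network — rather than of the raw subband. Both the feature choice and the
$\beta$ input are configurable in spirit; the package fixes NSML/EOE as
the supported features and exposes every PCNN constant.

PCNN defaults (`pcnnParams()`), all dimensionless, per iteration:

| parameter | default | role |
|---|---|---|
| `alphaL` | 0.06931 | linking decay (half-life 10 iterations) |
| `alphaTheta` | 0.2 | threshold decay |
| `VL` | 1.0 | linking gain |
| `Vtheta` | 20 | post-fire threshold kick (enforces sparse refiring) |
| `linkKernel` | 3×3 inverse distance, zero center | lateral coupling |
| `nIter` | 200 | iterations (several firing waves at these decays) |
| `thetaInit` | 1 | initial threshold = top of the stimulus range |

These are conventional simplified-PCNN settings; the method itself
specifies none of them. With $\theta_0 = 1$ and $\alpha_\theta = 0.2$, an
unlinked neuron with stimulus $S$ first fires at the smallest $n$ with
$e^{-0.2 n} \le S$ — the closed form used by the unit tests
($S = 0.5 \rightarrow n = 4$; $S = 0.9 \rightarrow n = 1$).

### Selection rule

Each band is fused by max region energy of the two firing maps:
$E = \sum_{a,b} w(a,b)\, C(i{+}a, j{+}b)^2$ with the uniform template
$w_1$ on the low band and the center-dominant $w_2 = [1\,2\,1; 2\,4\,2;
1\,2\,1]/16$ on high bands. $w_2$ is a documented choice: normalized and
center-dominant, matching the stated intent of strengthening the window
center (no canonical value exists). Ties ($E_A \le E_B$) go to source B
as specified by the rule's inequality; firing counts are small integers,
so exact ties do occur — in flat regions where neither source has
features. Raw counts are used (not renormalized) since the selection only
compares them.

## Quality metrics: conventions

All seven metrics are deterministic; where the literature leaves freedom,
the convention is fixed and documented here:

* **Quantization** (EN, JE, CE): each image independently min–max rescaled
  to [0, 255] and rounded; $L = 256$ levels. A constant image maps to
  level 0 (entropy 0).
* **JE of a triple** averages $H(F,A)$ and $H(F,B)$, so one number
  summarizes similarity to both sources.
* **CE** floors the fused histogram at $10^{-12}$ in $D(p\|q)$, so source
  levels absent from the fused image give a large finite penalty and
  Gibbs' inequality keeps CE $\ge 0$.
* **IQI** uses 8×8 sliding windows, stride 1, population moments.
  Degenerate windows: identical constants → 1; zero variance → luminance
  factor only; zero means → correlation–contrast factor only; a variance
  sum below $10^{-12}$ counts as zero (unit-range images).
* **Q_E** weights per-window IQI by saliency (window variance);
  zero-saliency windows get $\lambda = 1/2$, and all-constant inputs get
  uniform window weights. Edge images are Sobel gradient magnitudes
  (the metric's definition leaves the edge operator open). With
  $\alpha = 0$ the edge factor is dropped.
* **Q^AB/F** uses the standard sigmoid constants
  ($\Gamma_g = 0.9994, \kappa_g = -15, \sigma_g = 0.5$;
  $\Gamma_\alpha = 0.9879, \kappa_\alpha = -22, \sigma_\alpha = 0.8$) and
  multiplies the strength and orientation preservation factors —
  the product is what keeps the metric in [0, 1]; the additive variant is
  available as `combine = "sum"` for comparison but is not bounded by 1.
  Pixels where both images have zero gradient count as perfectly
  preserved but carry zero weight. Its self-fusion ceiling is not 1 but
  the sigmoid plateau
  $\frac{0.9994}{1+e^{-7.5}} \cdot \frac{0.9879}{1+e^{-4.4}} \approx 0.9747$.

## The phantom generator

`makePhantomPair()` emulates the study conditions the pipeline targets —
co-registered whole-body slice pairs in which CT carries sharp anatomy and
PET carries smooth functional hotspots:

* **CT-like**: piecewise-constant ellipses (body, soft-tissue regions, a
  bright spine, rib-like bone spots) with low-amplitude (±0.015) pixel
  texture — sharp boundaries and fine detail;
* **PET-like**: a dim body mask with Gaussian hotspots, rendered at
  quarter resolution and bilinearly upsampled ×4, mirroring the practice
  of interpolating low-resolution PET up to the CT grid. Hotspot centers
  are snapped to coarse-grid sample positions so each rendered maximum
  falls within one pixel of its recorded truth center.

The default size is 128 — large enough for 3 pyramid stages and 8×8 metric
windows, small enough that a 20-pair suite (fusion + baseline + metrics)
runs in a couple of minutes; the test suite uses 64 for unit-level checks
and 128 for the suite-level comparisons. Generation is deterministic per
seed (Mersenne-Twister, inversion normals, rejection sampling pinned) and
restores the caller's RNG state.

What the phantoms deliberately do **not** model: reconstruction noise in
either modality, attenuation and partial-volume effects, anatomically
realistic shapes, and registration error. Consequences for interpreting
results are discussed below.

## Numerical choices

* **Boundary handling** is symmetric (half-sample mirror) everywhere by
  default — appropriate for image data. A periodic mode exists end to end
  (transform, features, $\beta$, PCNN linking, templates) solely so that
  shift-equivariance is *exact*, which the tests exploit; with symmetric
  borders shift-equivariance holds only away from the borders.
* PCNN linking uses zero padding by default (border neurons simply have
  fewer neighbours).
* The pipeline is deterministic: identical inputs give bit-identical
  results, and the vectorized C++ PCNN matches a literal per-pixel R
  recursion exactly (integer firing counts, no tolerance).
* `selectMaxEnergy()` uses a strict `>` for A; since firing counts are
  integers, exact energy ties resolve to B reproducibly. Note that
  *re-deriving* the masks from stored firing maps with a differently
  ordered summation can flip exact ties — comparisons should restrict to
  decisively separated energies.
* DWT baseline: LeGall 5/3 lifting with periodic extension; exact
  reconstruction requires dimensions divisible by $2^{\text{levels}}$
  (checked, 3 levels by default).

## Limitations

* The directional tree is the simplified (unsheared) nonsubsampled fan
  tree described above; studies that depend on precise wedge orientation
  at 8+ directions per scale should treat the directional labels as
  approximate.
* The fusion quality ordering between methods is data-dependent, and the
  noise-free phantoms differ from clinical data in one consequential way:
  with piecewise-constant sources, per-coefficient max-absolute selection
  (the NSCT max-rule baseline) degenerates to a spatially coherent
  "locally dominant source" rule and scores very high on windowed
  structural metrics, whereas on noisy clinical material the same rule is
  known for contrast loss. On the phantom suite the proposed framework
  clearly exceeds that baseline on the information-content metrics (EN,
  JE — see `scripts/acceptance.R`, margins of ≈ +1.5 bits each, and also
  AG and CE), while the baseline scores higher on Q_E and Q^AB/F. Passing
  the phantom suite therefore demonstrates the information-fusion
  behaviour and every formula-level property, but not the full metric
  ordering reported on clinical whole-body data.
* Only 2-D slice fusion is implemented (volumes are fused slice-wise);
  DICOM input, pseudo-color composition, and registration are out of
  scope. Supported formats are PNG, TIFF and NIfTI-1.
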
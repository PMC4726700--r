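---
title: "Models and methods behind microlux"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind microlux}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(microlux)
```

# Scope

`microlux` analyses gene expression in engineered quorum-sensing
bacteria — AHL-sensing *receivers* (GFP from P_lux) and AHL-producing
*senders* (LuxI + RFP) — growing in single-layer microfluidic traps, and
ships an agent-based simulator and image renderer that generate every
input the analysis consumes, with ground truth. This vignette describes
the models, their assumptions, the tunable parameters and the numerical
choices; it states no empirical result beyond what the test suite and
`scripts/acceptance.R` compute.

# Expression-rate model

For a stable fluorescent reporter in exponentially growing cells, total
mass obeys $\dot M = \mu M$ and the per-cell reporter density $p$ obeys

$$\dot p = \alpha - \mu p,$$

dilution by growth being the only loss. Since $p \sim F/M$, the two
rate estimates

$$\frac{\dot F}{M} \quad\text{and}\quad \frac{d}{dt}\frac{F}{M} + \mu\,\frac{F}{M}$$

are identical; `verify_rate_identity()` quantifies their numerical
discrepancy as a differentiation/noise diagnostic. In bulk experiments
$M$ is the background-subtracted absorbance; in microscopy the total
segmented cell area $A$ plays the role of mass and $\alpha = \dot F/A$.
`compute_alpha()` uses Savitzky–Golay differentiation (window 7, order
2 at 3–5 min sampling; both configurable). The window suppresses
shot/measurement noise in the derivative without flattening induction
ramps; rates at the first/last half-window are estimated from truncated
polynomial fits and are noticeably noisier, so the response-curve
drivers exclude these edge samples from the max-rate statistic.

Induction follows an activating Hill curve
$\alpha(c) = \mathrm{basal} + \alpha_g\,c^n/(c^n + K^n)$ with threshold
$K$ (nM) and exponent $n$. `fit_hill()` performs weighted
Levenberg–Marquardt least squares with multi-starts over $(K, n)$ and a
basal term bounded at zero; only $K$ and $n$ are comparable across
modalities because $\alpha$ is defined up to an arbitrary intensity
scale. Response-unit rescaling leaves $K, n$ invariant (tested).
Default induction parameter sets mirror the three measurement
modalities the analysis targets: bulk $(K, n) = (13.9\,\mathrm{nM},
0.97)$, chemostat colony $(5.3\,\mathrm{nM}, 0.95)$, and single-cell
trajectory mode — $(3.8\,\mathrm{nM}, 1.5)$ for the time-averaged rate
observable and $(2.7\,\mathrm{nM}, 1.2)$ for the max-rate observable —
so each analysis stage has a recoverable target.

The exponential-phase window is detected by `estimate_growth_rate()`: a
smoothed local slope of $\log(\mathrm{mass})$ (Savitzky–Golay first
derivative over about a quarter of the series) whose maximum is the
specific growth rate $\mu$; the window is the contiguous region where
the local slope stays within 80% of that maximum. This tolerates the
5% multiplicative measurement noise of plate-reader emulations, for
which a strict $R^2$ longest-window rule proved unstable.

# The colony simulator

Cells are rods (spherocylinders) of fixed width (default 1 µm) that
elongate exponentially at rate $\mu$ (default 0.7 h⁻¹, the middle of
the 0.36–1 h⁻¹ chemostat range) and divide at 4 µm with a length-split
asymmetry CV of 0.05. Overlaps are relaxed by iterative pairwise
repulsion (10 iterations per 3-min step) between disc-chain
approximations of the rods; there is no full rigid-body physics — the
packing is realistic enough to exercise segmentation, which is its
purpose. Cells whose centres leave the trap are removed (open trap
edges), which makes the in-trap area saturate once the trap fills.

## Expression noise model

Each cell's rate is
$\alpha_{\mathrm{cell}}(t) = \alpha(c)\,R_{\mathrm{cell}}\,X_{\mathrm{cell}}(t)$:

* $R_{\mathrm{cell}}$ — a lognormal kinetic factor sampled at birth as
  the product of four independent lognormal rates (transcription,
  mRNA decay, translation, protein decay), the steady state being
  $p = \alpha_r \alpha_p / (\lambda_r \lambda_p)$. Daughters retain the
  parent's log-deviations with weight 0.5 and re-randomise the rest,
  keeping the marginal stationary.
* $X_{\mathrm{cell}}(t)$ — a slowly varying extrinsic factor,
  exponentiated Ornstein–Uhlenbeck with correlation time 60 min. A
  slow factor, unlike white noise, produces the constant-CV² plateau at
  high expression that characterises extrinsic noise.

The single knob `extrinsic_cv` (default 0.17) is the **target total
stationary CV of $p$**. Its log-variance $v = \log(1 + \mathrm{cv}^2)$
is split 50/50 between the kinetic factor and the OU factor, and the OU
injection variance is inflated by the attenuation
$\mu\tau/(1 + \mu\tau)$ that the dilution dynamics
$\dot p = \alpha - \mu p$ applies to a slowly varying rate factor — so
the *realised* stationary CV of $p$ matches the configured value
(tested: 500-cell populations land in [0.14, 0.20], and $\log p$ passes
a Shapiro normality check).

## Late inducers

A minority phenotype (default fraction 0.05) expresses nothing before a
delay (default 300 min), then at a reduced rate (factor 0.3), and grows
at 0.3× the normal rate. The fraction, delay and growth factor are
package defaults chosen to make the subpopulation clearly separable in
log-expression histograms; they are not measured quantities. The state
is assigned at initialisation and inherited: in colonies grown from few
founders the late lineage therefore stays small (slow growth), which is
why subpopulation statistics are exercised on snapshot populations
(fixed cells, expression only, `simulate_snapshot_population()`) where
the standing fraction equals the configured one.

## Rendering

Fluorescence frames are the per-pixel sum of $p$ over each cell's
footprint, multiplied by a gain (30 counts per unit), blurred with a
Gaussian PSF ($\sigma$ = 2 px at 0.1–0.125 µm/px), offset by a constant
background (200 counts) and Poisson-sampled; 16-bit range. Brightfield
frames show near-uniformly dark rods with a soft rim on a bright
background (30000 − 15000·profile, Gaussian read noise σ = 300), and a
thin bright line along the equidistant boundary between adjacent
cells — the optical signature of apposed cell walls — implemented by
tracking first- and second-nearest rod-axis distances per pixel.
Without this boundary term, tightly packed cells render as one dark
block no segmentation method could separate, which matches neither real
brightfield images nor the needs of the analysis. Ground-truth label
masks (nearest axis wins contested pixels) and lineages are emitted
alongside. Blur is normalised and noise mean-preserving, so total image
flux above background equals $\mathrm{gain}\cdot\sum_i p_i A_i$
(tested to 1–2%).

# Segmentation

The front end mirrors classic bacterial time-lapse pipelines:

1. **Preprocess** — contrast stretch to [0, 1], small-Gaussian
   denoising (σ = 1 px; a linear filter, so inverted-contrast images
   classify identically with the matching flag), unsharp-mask
   sharpening (amount 0.4), final stretch.
2. **Hybrid background classification** — three votes per pixel:
   global Otsu; local adaptive mean over a 51-px window + offset 0.04;
   and an adaptive-masking vote against a background surface
   re-estimated iteratively from background-classified pixels only
   (normalised Gaussian convolution, σ = 25 px, 2 iterations), which
   keeps the surface from following dense colonies. A pixel is cell on
   ≥ 2 votes. A degenerate-frame guard returns all-background when the
   Otsu between-class variance fraction is below 0.75 (unimodal noise
   peaks near 0.64).
3. **Markers** — connected components; components whose principal-axis
   extents exceed the single-cell geometry bounds (defaults: width
   0.5–1.5 µm, length 1–6 µm; the pipeline drivers tighten the length
   bound to 1.1× the division length, a cell-type prior) are split
   recursively by a watershed on 0.3·(normalised distance map) +
   intensity, tolerance 0.15, depth ≤ 4.
4. **Watershed refinement** — seeded propagation (`EBImage::propagate`)
   constrained to the mask; one region per marker.
5. **Filtering** — area bounds (0.8–20 µm²) and, optionally, an SVM
   (radial kernel) on (area, perimeter, eccentricity, solidity, mean
   intensity, intensity CV), trained through a programmatic API on
   labelled region tables.
6. **Measurement** — per-region area, total and background-corrected
   fluorescence (background = mean intensity outside all regions),
   centroid, moment-based axis lengths, eccentricity, convex-hull
   solidity, perimeter.

The spatial parameters (vote offsets, surface sigma, split tolerance)
were calibrated once on rendered fixtures against ground-truth masks;
on colony stacks at up to ~50% trap occupancy the end-to-end object
recall and precision (IoU ≥ 0.5) exceed 0.9 and per-frame total
segmented area tracks truth within ~10% at colony densities (isolated
cells carry a small halo overcount).

# Tracking

`max_overlap_assign()` assigns each later-frame label the
earlier-frame label of maximal pixel overlap (ties: larger child
overlap fraction, then smaller centroid distance); two children sharing
a parent mark a division. `build_lineage()` chains assignments into
trajectories and a parent–child tree. `correct_lineage()` flags links
whose fluorescence step deviates from the sliding-window median (11
frames) by more than 2× the robust SD (1.4826·MAD, floored at 5% of
the local median step to avoid zero-noise degeneracy) — the signature
of a missed division or identity swap — and re-resolves each flag
either by reassigning the trajectory tail to the second-best-overlap
parent (only when that parent's track ended at the flagged frame) or by
splitting the trajectory into a division, whichever leaves the smaller
residual jump. On ground-truth masks tracking is exact and the flag
rate is ≤ 2% of links.

# Population statistics

Time-slice histograms of $p = F/A$ are near-lognormal (a product of
several weakly correlated kinetic factors). `fit_lognormal_mle()`
returns the MLE (mean/SD of logs) with a KS statistic.
`gmm_separate_log()` fits a two-component Gaussian mixture to
$\log p$ by EM (10 restarts: one deterministic quantile initialisation
plus random pairs; component SDs floored at $10^{-4}$ of the data
range; a BIC comparison guards against spurious splits of unimodal
data). The dominant component is the higher-mean one when weights are
comparable (both within [0.25, 0.75]) and the higher-weight one
otherwise; cells are hard-assigned by maximum responsibility.
`dominant_filter()` applies the mixture to end-of-experiment expression
and keeps trajectories whose terminal cell is dominant, plus their
ancestors (lineage closure); with fewer than 50 usable terminal cells
it keeps everything with a warning rather than fit a meaningless
mixture. `noise_curve()` emits $(\langle p\rangle, CV^2)$ per time
point and estimates the plateau as the median $CV^2$ over snapshots
with $\langle p\rangle \ge \tfrac13 \max\langle p\rangle$ (the
threshold is configurable; the rising low-expression regime is
deliberately not modelled).

# Sender–receiver model and calibration

Senders produce the synthase LuxI, which produces AHL; with receiver
population $N(t) = N_0 e^{\gamma t}$ and sender/receiver ratio $r$:

$$\frac{d[\mathrm{LuxI}]}{dt} = \alpha_l\,r\,N(t) - \lambda[\mathrm{LuxI}],
\qquad
\frac{d[\mathrm{AHL}]}{dt} = \alpha_a[\mathrm{LuxI}] - C[\mathrm{AHL}].$$

`solve_sender_ode()` integrates this with lsoda at relative tolerance
$10^{-8}$. For small $(\gamma, \lambda, C)$ the solution approaches the
closed form $[\mathrm{AHL}](t) \simeq \tfrac12\alpha_a\alpha_l r N_0
t^2$ (`ahl_closed_form()`); the convergence and the exact $t^2/2$ limit
are tested against a fine-step RK4 oracle. Because $r$ and the
measurement time differ between experiments, they are bundled into
$s = \langle r\rangle t_{\max}^2$, with $\langle r\rangle$ the
trapezoidal time average over $[0, t_{\max}]$ and $t_{\max}$ the time
of maximal sender induction (`detect_t_max()`, smoothed argmax, ties to
the earlier time). A receiver's measured rate is inverted through the
calibration Hill curve,

$$\mathrm{AHL}_{\mathrm{eff}} = K\left(\frac{\alpha - b}{(\alpha_g + b) - \alpha}\right)^{1/n},$$

with first-order (delta-method) uncertainty propagation; note the
general-basal form, which reduces to the usual expression at $b = 0$.
`fit_sender_strength()` then fits $\mathrm{AHL}_{\mathrm{eff}} =
\mathrm{slope}\cdot s$ through the origin (weighted least squares),
identifying $\tfrac12\alpha_a\alpha_l N_0$; a free-intercept diagnostic
fit is reported but not used. Default sender parameters
($\alpha_l = 10^{-4}$, $\alpha_a = 0.04$, $N_0 = 50$,
$\lambda = C = 8\times10^{-4}$, $\gamma = 10^{-3}$ min⁻¹) put the
effective AHL at $t_{\max} = 450$ min in the receiver's sensitive range
(≈ 1–20 nM across the nominal ratios $r$ = 0.067–1, i.e. sender
fractions 6.25–50%) while keeping the quadratic approximation within
~10%, so the end-to-end slope recovery is meaningful. The ratio
series can carry slow lognormal division-driven fluctuations
(`r_fluct_cv`).

# Problem sizes and reproducibility

All randomness flows from explicit seeds; identical configuration and
seed give bitwise-identical trajectories, masks and pipeline reports.
The rendered-pipeline experiments use a 32 × 24 µm trap view at
0.125 µm/px (256 × 192 px), 127 frames at 3-min intervals, two founder
cells growing to ≲ 200 — a scale at which a full eight-concentration
round trip (simulate → render → segment → rates → Hill fit) completes
in minutes while preserving every feature the analysis depends on:
hundreds of division events, realistic packing, ramping occupancy. Two
founders rather than one halve the colony-to-colony variance induced by
the founders' birth-sampled kinetic factors, which otherwise dominates
the scatter of single-run response curves. Trajectory-level experiments
use the same scale without rendering.

# What passing tests do and do not show

The synthetic data reproduce the statistical structure the analysis
assumes — exponential single-layer growth, Hill induction, lognormal
rate variability, extrinsic-noise plateau, a distinct late-inducing
minority, quadratic AHL accumulation. They do not emulate phase-contrast
optics, focus drift, photobleaching, uneven illumination, AHL spatial
gradients within a chamber, or cell-shape irregularity; segmentation
accuracy on these images therefore bounds, but does not guarantee,
accuracy on real recordings. Parameter-recovery results show the
*pipeline* is consistent (generator → analysis round trips recover the
generating parameters within their stated tolerances); they cannot
validate the biological parameter values themselves.
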
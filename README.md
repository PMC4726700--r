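# microlux

Single-cell analysis of bacterial quorum-sensing sender–receiver systems
in microfluidic chemostats — as a fully synthetic, testable pipeline.

Engineered *E. coli* "receiver" cells express GFP from the P_lux promoter
when the diffusible quorum-sensing signal AHL (N-3-oxo-C6-homoserine
lactone) binds LuxR; "sender" cells synthesize AHL via LuxI. Time-lapse
microscopy of such strains growing as a single layer in shallow
microfluidic traps yields, after segmentation and lineage tracking,
per-cell fluorescence trajectories from which gene-expression rates,
dose–response curves, expression-noise statistics and — using the
receivers as *in situ* AHL bioreporters — the effective AHL output of
sender cells can be quantified.

`microlux` implements that entire analysis chain **plus** the synthetic
data needed to exercise it:

* **Simulator** — agent-based rod-shaped cells growing, dividing and
  packing in a trap (default 100 µm × 60 µm, frames every 3 min);
  Hill-type AHL induction of a stable reporter with lognormal
  cell-to-cell rate variability, slowly varying extrinsic noise, and a
  slow-growing "late-inducer" minority; plate-reader (OD + fluorescence)
  emulation; LuxI/AHL sender dynamics.
* **Renderer** — synthetic brightfield and fluorescence stacks (PSF
  blur, shot noise) with ground-truth label masks and lineages.
* **Segmentation** — preprocessing, hybrid background classification
  (global Otsu + local adaptive + iterative background surface, 2-of-3
  vote), geometry-guided marker splitting, seeded watershed, size/SVM
  region filtering, per-cell measurements.
* **Tracking** — maximum-overlap lineage reconstruction with a
  fluorescence-jump correction heuristic.
* **Analysis** — expression rates α = Ḟ/M (bulk) or Ḟ/A (microscopy) via
  Savitzky–Golay differentiation; Hill fits α(c) = basal +
  α_g·cⁿ/(cⁿ + Kⁿ); lognormal MLE; two-component Gaussian-mixture
  separation of subpopulations on log expression; CV² noise curves;
  sender-strength calibration AHL_eff = ½·α_a·α_l·N₀·s with
  s = ⟨r⟩·t_max².

## Worked example

Simulate a microcolony at 12 nM AHL, render it, segment it, and estimate
the colony-level expression rate:

```r
library(microlux)

cfg   <- chemostat_sim_config()                 # 32x24 um view, 127 frames
sim   <- simulate_colony(cfg, ahl = 12, seed = 42)
sim
#> Simulated microcolony: 127 frames (378 min), 2 -> 196 cells, AHL = 12 nM

stack <- render_frames(sim, seed = 420)         # brightfield + GFP + truth
seg   <- segment_stack(stack,
           config = seg_config(pixel_size = cfg$pixel_size,
                               max_length = 4.4, max_width = 1.6))

A <- sapply(seg$regions, function(r) sum(r$area))      # total cell area/frame
F <- sapply(seg$regions, function(r) sum(r$F_corr))    # total fluorescence
alpha <- compute_alpha(stack$t, F, A)                  # a.u. / min / px^2
```

Fitting the response curve across eight such stacks (0–50 nM) and the
other response modalities:

```r
res <- colony_response_experiment(c(0, 1, 2, 4, 8, 12, 20, 50),
                                  chemostat_sim_config(), seed = 1)
res$fit
#> Hill fit: alpha(c) = basal + alpha_g * c^n / (c^n + K^n)
#>          alpha_g      K      n  basal
#> estimate 24.8984 4.2394 1.1133 0.0408
#> se        1.5474 0.5653 0.1343 0.7312
```

`K` is the half-induction threshold in nM and `n` the Hill
(cooperativity) exponent; `alpha_g` is in image-intensity units per
minute per pixel of cell area, so only `K` and `n` are comparable across
modalities. The generating chemostat-mode parameters are K = 5.3 nM,
n = 0.95 — the pipeline recovers them through rendered images,
segmentation and rate estimation.

Receivers as AHL bioreporters:

```r
cal <- calibrate_sender_strength(c(1/15, 0.142, 0.33, 1), seed = 21)
cal$calibration
#> Sender-strength calibration: AHL_eff = 9.129e-05 * s (SE 3.6e-06)
#>   free-intercept diagnostic: intercept -0.19, slope 0.0001009
cal$truth                                       # generating 1/2 a_a a_l N0
#> [1] 1e-04
```

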
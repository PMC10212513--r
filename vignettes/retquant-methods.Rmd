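---
title: "Methods: quantifying electron-flow direction in single mitochondria"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying electron-flow direction in single mitochondria}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(retquant)
```

## The measurement problem

Complex I can carry electrons forward (NADH → Q, FET) or — when the
protonmotive force is high and the Q pool reduced — in reverse (QH₂ →
NAD⁺, RET). The two modes are distinguished per mitochondrion by a
rotenone challenge: blocking the Q-site traps the NAD pool, so
mitochondria that were running FET become more reduced (NAD(P)H
autofluorescence rises) and mitochondria running RET become oxidised
(autofluorescence falls). `retquant` quantifies this on two scales:

* **isolated mitochondria on glass** — single-spot TMRM intensities give
  relative membrane potentials through the Nernst slope, and per-object
  NAD(P)H changes give three-way direction calls;
* **mitochondria inside cells** — objects cannot be resolved reliably, so
  the analysis is pixelwise: the distribution of log2-fold intensity
  changes over the mitochondrial mask is decomposed into responder and
  non-responder components, and the RET subpopulation is measured as an
  excess of pixels at significantly decreased intensities.

## Relative polarization and gating

TMRM is a Nernstian dye: matrix accumulation scales one decade per
61 mV. With background-subtracted spot intensities,

```
pol(a, b) = 61 * log10(F_a / F_b)   [mV]
```

The slope is fixed at 61 mV/decade (the conventional decade form near
37 °C) rather than re-derived from first principles; all potentials are
relative between conditions, because no absolute zero-mV calibration
point is available in this preparation — polarization by glutamate+malate
is referenced to succinate, and the G3P response to the G+M state. The
readout is additive over chained ratios (tested to 1e-9 mV) and, because
the synthetic TMRM renderer draws spot amplitudes proportional to
`10^(mV/61)`, the whole imaging chain recovers assigned potentials to
0.01 mV in the noiseless limit.

Gating uses two configurable thresholds, default −30 mV on the
G+M-vs-succinate axis and +20 mV on the G3P hyperpolarization axis,
partitioning the plane into four classes (`medium_medium`,
`strong_gm_weak_g3p`, `ret_like`, `nonresponsive`). The thresholds are a
documented convention: the underlying population is a continuum and any
rectangular gate set is arbitrary; fractions are reported per replicate
and summarized as mean ± SE.

## The cell-arm estimator

Per cell, the chain is: Wiener denoising (local-statistics filter, 5 px
window — preserves the mean to 0.1% and adapts to local variance);
deformable registration of the post-challenge frame onto the baseline
(below); masking by the union of the two frames' Otsu masks, so
mitochondria that *disappear* after the challenge — the RET signature —
stay inside the analysis mask; a modal intensity rescale (a single factor
on the after frame placing the densest log2-fold bin at zero, removing
acquisition-scale drift; every downstream quantity is measured relative
to the fitted non-responder centre, so this choice cannot create or
destroy signal); then the pixelwise histogram of
`log2((after + ε) / (before + ε))` at bin width 0.05 with ε = 1 AFU.

**Null calibration.** Mock (vehicle) pairs differ only by noise and
motility. Their pooled histogram is fit by binned maximum likelihood with
a single Gaussian (multinomial likelihood over bin probabilities,
truncated to the histogram support), giving σ₀.

**Two-component fit.** The treated histogram is fit with
`(1−w)·N(μ_n, σ₀) + w·N(μ_r, σ₀)` — both widths fixed to the mock σ₀,
since the spread of both responder and non-responder pixels is dominated
by the same motility/noise process; means and the weight are free with
the identifiability constraint μ_r ≥ μ_n, optimized from a deterministic
start grid (w ∈ {0.25, 0.5, 0.75} × Δ ∈ {0.15, 0.4, 0.7}).

**Excess count.** Over bins with centre below μ_n − 2σ₀,
`f = Σ max(observed − expected, 0) / N_pixels`, with expected counts from
the full two-component fit. The threshold is anchored at the
*non-responder centre* (not at zero): oxidation is counted relative to
the unresponsive population. Estimates are formed per cell, then pooled
unweighted (mean ± SE across cells, then across experiments); weighting
cells by mitochondrial pixel count is a documented alternative not taken.
The result is a *pixel* fraction of the mitochondrial mask; equating it
with a mitochondrion fraction assumes equal mean mitochondrial area
across classes.

**A robustness device that matters.** The binned likelihood gives
isolated outlier bins essentially zero probability under a two-Gaussian
model, so a strict ML fit is forced to chase them: on the simulated-RET
control the non-responder component latches onto the masked-pixel cluster
and the excess estimate collapses. Both fits therefore mix a small
uniform contamination density (weight 1e-3 over the histogram support)
into the fitted model — a standard robust-ML device. Expected counts for
the excess computation use the pure two-Gaussian model, so the
contamination never absorbs signal; its only effect is to keep the
component means attached to the population structure.

## Deformable registration

Mitochondria are motile; the post-challenge frame is warped onto the
baseline before any pixelwise comparison. The field is a tensor-product
cubic B-spline on a control grid (default spacing 16 px), optimized
coarse-to-fine over a 3-level pyramid by L-BFGS with analytic gradients
of the mean-squared-difference metric on frames rescaled to [0, 1], after
an FFT-based translation pre-alignment; a small ridge penalty (1e-3) on
control-point displacements regularizes the field. These internals
(metric, pyramid depth, regularization) are fixed here for
reproducibility. Pull semantics throughout: the displacement stored at an
output pixel points to its source location. If optimization fails to
improve the Pearson correlation between the frames, the identity field is
returned, so registration can never degrade r. QC follows the correlation
gate: cells with r < 0.6 are discarded; r exactly 0.6 is kept.

## Direction calls on isolated mitochondria

Per-object changes are normalized to the *population mean* baseline
fluorescence — some mitochondria show very little autofluorescence of
their own, and dividing by a per-object baseline would explode their
values — then converted to log2-fold, `log2(1 + ΔF / mean_pre)`, which
keeps symmetric intensity changes symmetric.

The call threshold derives from the data: c times the average per-object
scatter of the repeated post-challenge determinations, where scatter is
the *unbiased single-determination SD* (the raw SD of n = 3 repeats
underestimates σ by the c4 factor 0.886 and is corrected). With the
challenge response formed as the difference of 3-frame means, the
false-call probability on a truly stalled object is a pure function of c:
`thr / sd(Δ) = c·sqrt(n_rep/2)`, so c = 1.5 admits ≈ 5% of stalled
objects per side while c = 2 admits < 1%. The package therefore defaults
to c = 2, the conservative end of the 1–2 range the threshold convention
allows; it is configurable (`c_mult`). The synthetic glass-arm protocol
records 3 baseline and 3 post-challenge frames so that the difference
noise is commensurate with the repeat scatter the threshold is built
from; with a single baseline frame the threshold would undercount its own
noise term. A bulk-trace variant applies the same thresholding to the
difference between post-challenge steady value and baseline.

## The synthetic generator

The generator produces what the estimators assume and nothing more:
isotropic Gaussian spots (the preparations are punctate; elongated
networks are out of scope) placed by rejection sampling with a minimum
separation of 4 spot-sigma; additive Gaussian read noise plus a
scaled-Poisson shot term (`variance = read² + gain·mean`); smooth random
motility fields (Gaussian-correlated, RMS-normalized) applied with pull
semantics; and, for the cell arm, the simulated-RET control that replaces
`⌈fraction·N⌉` mitochondria with locally sampled background. Class counts
are apportioned deterministically (largest remainder) so single-scene
counts are exact; replicate-field experiments switch to multinomial
sampling (`class_sampling = "multinomial"`), because experimental
replicates are independent draws from a population and deterministic
counts would make between-replicate SEs spuriously tiny. One root seed
feeds named child streams, so adding a draw never perturbs existing ones.

Study-condition defaults: 128×128 px cell fields with 125 mitochondria;
74% challenge responders at a mean +0.585 log2-fold (a 50% intensity
increase, SD 0.15) and 26% non-responders; baseline amplitudes lognormal
(meanlog log 300, sdlog 0.25) over a background of 15 AFU; read noise 4,
photon gain 2; motility 0.8 px RMS at 24 px correlation. The noise
magnitudes are not published for either microscope; these values were
calibrated once so the pooled mock-pair log2-fold σ₀ falls in the
plausible 0.1–0.3 range (it lands near 0.18) and are exposed in
`scene_config()`. The background is deliberately low (two-photon-like):
a bright background dilutes pixelwise log2-fold shifts into an
intensity-dependent continuum and destroys the two-component structure
the mixture fit assumes. The glass arm uses 256×256 fields of 150
immobilised (motility-free) spots at 65 / 30.8 / 4.2% FET / stalled / RET.

What the generator does *not* emulate: photobleaching, TMRM quench-mode
dynamics, realistic cell morphology and mitochondrial crowding, 3-D
structure, EMCCD excess noise (the estimators only assume a symmetric
null, which the mock fit calibrates empirically). Passing tests therefore
demonstrate correctness of the estimators under their stated assumptions,
not performance on arbitrary real recordings; in particular, real-image
crowding and registration imperfection push the masking control further
below its nominal fraction than clean synthetic fields do.

## Plate assays

Rates are OLS slopes of fluorescence vs time over the inclusive cycle
window 5–18 (14 points of a 25 × 80 s recording), offset-invariant by
construction. Calibration regresses step responses on spiked pmol amounts
through the origin (steps are differences; a free-intercept variant
exists). No correction is applied for matrix consumption of H₂O₂ (an
optional multiplier exists, default off). The 4PL
`bottom + (top−bottom)/(1+(conc/IC50)^hill)` is fit by Levenberg–Marquardt
on log-IC50 with a deterministic multi-start over hill ∈ {±0.5, ±1, ±2};
zero-dose points are handled through the curve's exact limit; orientation
is normalized (bottom ≤ top, hill sign flipped) since the curve is
invariant under swapping plateaus and negating the slope. With
`subtract_residual`, the fitted bottom plateau — the rate insensitive to
saturating inhibitor — is subtracted and the curve refit with bottom
fixed at 0, isolating the site-specific signal before the IC50 is read.
IC50s are labelled nominal throughout: they reflect added, not measured,
concentrations.

## Numerical choices and degenerate inputs

* Binned fits require ≥ 100 pixels and more than one occupied bin; a
  single-bin histogram is an error, not a fit.
* Otsu thresholds come from a 256-bin histogram; a constant frame yields
  an empty mask with a warning.
* The background estimator (mean of off-mask pixels below the percentile
  of the max projection, default 50th, dilation 3 px) falls back to a
  global percentile with a warning when the foreground mask covers the
  frame. Its selection bias is negligible for time-course stacks but
  reaches ~2 AFU at σ = 5 for a single frame; contracts are stated for
  stacks of ≥ ~10 frames.
* `ceiling(fraction·N)` uses a 1e-9 guard so exact products (0.064·500)
  are not pushed up by floating-point representation.
* Non-positive TMRM intensities are a domain error naming the
  mitochondrion; traces whose maximum does not exceed the background are
  flagged nonresponsive and zeroed.
* Registration refuses non-finite pixels; QC keeps r = 0.6 exactly.

## Problem sizes

The shipped tests and the acceptance script use sizes chosen for a
single-CPU desk run: 100–110 synthetic cells (125 mitochondria each) for
the masking control, 40 mock cells for the false-positive control, 16
cells per point for the masking monotonicity sweep, 4 replicate fields of
150 mitochondria for direction-call recovery, and 10⁵-pixel histograms
for mixture recovery. All randomness flows from the documented seeds.

## Known limitations

* The pixel-fraction → mitochondrion-fraction identification assumes
  equal mean mitochondrial area across classes; brightening responders
  enlarge the Otsu-union mask and bias the masked-fraction share slightly
  downward.
* The mixture model is deliberately coarse (two equal-σ Gaussians plus a
  tiny uniform); it is an estimator of weights and centres, not a
  generative model of the full histogram.
* The segmentation stand-in (difference-of-Gaussian enhancement, Otsu,
  intensity watershed, area filter 6–200 px) is benchmarked to ≥ 95%
  recall and precision on well-separated synthetic spots at SNR ≥ 10; it
  is not a replacement for the original study's proprietary pipeline on
  real, crowded fields.
* Absolute ΔψM, NADH-vs-NADPH attribution, quench-mode TMRM behavior and
  FLIM-style readouts are out of scope.
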
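---
title: "Methods: Raman preprocessing, BubbleFill baseline removal, and the synthetic benchmark"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: Raman preprocessing, BubbleFill baseline removal, and the synthetic benchmark}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ramanpipe)
```

## The problem

A raw bio-Raman acquisition is dominated by everything except the signal of
interest: ambient light and detector offset (the *background*), sharp
cosmic-ray spikes, the instrument's wavelength-dependent sensitivity, and —
above all — tissue autofluorescence, a broad *baseline* that is typically
orders of magnitude more intense than the inelastic-scattering peaks riding
on top of it. `ramanpipe` implements the processing chain that turns
detector counts into comparable Raman spectra:

1. **Truncation** of the high-pass-filter transition region at the start of
   the detector window.
2. **Cosmic-ray removal**, either within a single spectrum
   (`crfilter_single()`) or across repeated accumulations
   (`crfilter_multi()`).
3. **Background subtraction** after accumulation averaging, scaled by the
   exposure-time ratio.
4. **Y-axis calibration**: division by the instrument response function
   `IRF = SRM_measured / SRM_theoretical`, where the theoretical curve is
   the standard reference material's certificate polynomial.
5. **Baseline removal** with BubbleFill (the package's centerpiece),
   MorphBR, or iModPoly.
6. **X-axis calibration** from reference-compound peaks and resampling onto
   a common Raman-shift grid.
7. **Smoothing/normalization**: moving average + min-max for visualization,
   SNV for machine learning.
8. **Quality metrics**: RBR, and the instrument-portable ASSI score with
   batch tiering.

## Cosmic-ray filters

The sources describing the two filters name the ingredients (derivative,
adaptive threshold, disparity across accumulations, interpolation) but no
formulas, thresholds, or window widths. The package's operationalization:

* **Single-spectrum**: robust z-scores of the first difference, scaled by a
  MAD-derived sigma. Default threshold 10 robust sigmas, flags widened by
  2 px, repair by linear interpolation from the nearest clean samples. A
  perfectly flat signal carrying a spike defeats the MAD (it collapses to
  zero), so the scale falls back to the mean absolute deviation; a truly
  constant signal is returned unchanged.
* **Cross-accumulation**: residuals from the per-pixel median across N ≥ 3
  accumulations, z-scored with one global MAD sigma, threshold 7. Because
  the median of N rows coincides with one observation, the residual matrix
  contains exact zeros and the raw MAD underestimates sigma — badly for
  small N (the estimate is ~0.73 sigma at N = 5). The filter divides by a
  Monte-Carlo finite-sample consistency factor (tabulated for N = 3..11)
  so the nominal threshold means what it says. Without this correction the
  effective threshold at N = 5 would be ~5 sigma and pure noise would be
  "repaired" a few times per hundred thousand cells.

Both thresholds are package decisions, not published values; they are
deliberately conservative because a false positive erases real signal.

## BubbleFill

BubbleFill estimates the baseline by growing circular bubbles underneath
the spectrum:

1. Remove the global slope with a polynomial of order `slope_order`
   (default 1, a linear fit).
2. Rescale so the y-range equals the x-range (*square aspect ratio*); in
   these coordinates bubbles are true circles.
3. Starting from one bubble spanning the whole axis, raise each bubble
   until it touches the signal; the touching point splits the interval in
   two, and children keep growing until an interval is narrower than the
   local minimum bubble width `min_width`.
4. The baseline is the running upper envelope of all bubbles
   (`max(bubble, current)` at every update).
5. Undo the scaling, re-add the trend, and smooth with a Savitzky–Golay
   filter.

`min_width` is the single tuning parameter: smaller bubbles fit more
aggressively. It may be a per-pixel vector, so a region holding small
peaks of interest can be protected with larger bubbles while the rest of
the axis is fitted tightly.

**Geometry choices.** The published description fixes neither the exact
arc parameterization nor the edge rule; this implementation is a
documented reconstruction. A bubble over `[l, r]` is the upper half-circle
with diameter `r − l` (in samples, on the square-aspect scale). Intervals
touching the first or last sample use an arc of doubled radius anchored at
that edge, so the baseline can rise at the boundaries — the failure mode
for which plain morphological opening is criticized. Ties for the contact
point are broken to the leftmost sample within a small numerical
tolerance; contact at an interval endpoint yields a single child shrunk by
one sample, which guarantees termination. The growth loop is an explicit
work queue, so no recursion-depth limit applies.

**Defaults.** `slope_order = 1`; Savitzky–Golay window
`max(2*floor(min_width/2) + 1, 5)` with polynomial order 2 — the smoothing
scale is coupled to the bubble scale because scallops between contact
points have roughly the bubble wavelength. `min_width` is canonically a
fraction of the axis span (it survives resampling); sample units are
available via `min_width_unit = "samples"`.

**Degenerate inputs.** A constant spectrum returns `baseline = input`,
`raman = 0`. An input fully explained by the detrending polynomial (e.g. a
straight line with `slope_order = 1`) does the same. For every input,
`baseline + raman` reconstructs the intensity exactly, and the
pre-smoothing envelope never exceeds the detrended signal (exposed in
`diagnostics` and property-tested).

**Known limitation.** On convex, steeply curved baseline regions the
circle arc leaves a sagitta-sized gap that scales with `min_width^2` times
the local curvature; at `min_width` = 10% of the span this is visible in
recovery error (measured nMSE 1.65e-2 on the package's broad-Gaussian +
narrow-peak fixture, versus 2e-3 at 5%). Tighter tuning or a per-pixel
width map is the remedy.

## MorphBR and iModPoly

**MorphBR** applies flat-structuring-element grayscale morphology: erosion
(sliding min), dilation (sliding max), opening (dilation of the erosion).
The default baseline is `min(opening, (erosion + dilation)/2)`; the plain
opening is available as `variant = "opening"` because the literature uses
both. Windows are truncated at the signal edges.

**iModPoly** fits a polynomial (default order 5), computes the residual
standard deviation DEV, clips the working signal to `fit + DEV`, and
iterates until the relative DEV change drops below `tol = 0.05` (the
tolerance is a package convention; the cited algorithm family does not pin
one) or `max_iter`; non-convergence returns the best fit flagged
`converged = FALSE`.

## Calibration

The certificate polynomial is evaluated with an explicit power basis and
must be strictly positive over the requested axis — a nonpositive value
means the certificate is being used outside its validity range.
`calibrate_xaxis()` detects peaks as local maxima with a topographic
prominence of at least 5% of the signal range and at least 10 samples of
mutual separation (defaults; the sources name only a generic peak-finding
tool), refines positions to sub-pixel accuracy with a three-point
parabola, matches the most prominent `K = length(known_shifts)` peaks to
the known shifts by rank order along the axis, and fits a least-squares
polynomial of order 2 or 3. A non-monotonic fitted map is rejected.
Reference measurements with RBR below 0.2 trigger a warning. Resampling
onto the common grid (default choice left to the user; no extrapolation
ever) is plain linear interpolation.

## The synthetic benchmark

Benchmark spectra mix known components:

```
S = (sbr * R + B) / max(sbr * R + B) + N(0, sigma^2)
```

* `R` — unit-max superposition of Gaussian peaks. Three presets mimic the
  density and spread of common reference compounds (`tylenol_like`:
  16 narrow peaks; `nylon_like`: 8; `pdms_like`: 6) over 400–1800 cm^-1.
  Centers follow published band positions of the real compounds; widths
  (4–10 cm^-1 sigma) and relative amplitudes are hand-chosen plausible
  values.
* `B` — either a single broad decaying hump (`smooth`, emulating
  nigrosin-like pure fluorescence) or several broad overlapping humps over
  a gentle pedestal (`bumpy`, emulating aluminium-substrate spectra with
  localized bumps; default 4 humps of sigma 8% of the span, positions and
  amplitudes drawn from the seed). Both are polished with a 50-sample
  moving average, mirroring the smoothing applied to measured baseline
  components, and max-normalized.
* Noise is added after normalization, so `sigma = 0.01` means 1% of the
  baseline maximum.

The `sbr` knob and the post-hoc RBR of the generated spectrum are the same
dial viewed from two sides (the literature uses both labels for the same
sweep); the stored components let `rbr()` recompute the realized ratio.
The quantity a perfect baseline remover would recover is
`sbr * R / max(sbr * R + B)`, stored as `raman_target`, and recovery is
scored with `nmse()` — sum of squared errors over the squared target sum,
invariant under joint positive scaling.

`sweep_benchmark()` runs each algorithm over its whole tuning grid
(min-width fractions 0.01–0.3 for BubbleFill, window fractions 0.015–0.3
for MorphBR, orders 2–9 for iModPoly by default) and keeps the best case,
so no algorithm is penalized for an unlucky default; `rbr_curve()`
replicates this across RBR values and seeds.

**What a green benchmark test does and does not establish.** The measured
components behind the published comparison figures are not public, so the
generator substitutes parameterized analogs; benchmark outcomes here are
trend-level, not value-level. Three findings from this package's own runs
deserve emphasis. First, the polynomial method fails dramatically on
bumpy baselines (one to three orders of magnitude worse than either
morphological method, essentially always) — that trend reproduces
robustly. Second, on *analytically smooth* noiseless humps, best-case
MorphBR is as good as best-case BubbleFill: infinitely smooth synthetic
baselines are the ideal regime for a flat structuring element, and the
large BubbleFill-over-MorphBR margins reported on measured aluminium
baselines do not reproduce under these idealized conditions. The
generator's hump parameters were fixed before any benchmark was run and
were not revisited. Third, with added noise, nMSE differences between the
morphological methods sit below the noise floor, so per-seed rankings are
not stable — consistent with the published observation that MSE-based
comparison becomes impractical on noisy inputs.

## Quality metrics and tiering

SNV uses the population (1/N) standard deviation — not the sample (1/(N−1))
one — so the output has mean 0 and population SD exactly 1. ASSI
SNV-transforms its input unconditionally, then averages the
sign-preserving squares (`sgn(0) := 0`); it is bounded in [−1, 1], equals
`(N−2)/N` for a one-hot vector, is affine-invariant, and is ~0 for pure
noise. Batch tiering takes the top 20% of ASSI ranks as `high`, the
40th–60th percentile band as `average` (one defensible reading of
"middle 20%"), the bottom 20% as `low`, everything else `none`; ties are
broken by input order for determinism.

## Pipeline and CLI

`pipeline_config()` + `run_pipeline()` compose the stages in dependency
order with no hidden state (composition is tested to equal the manual
chain), abort with the failing stage's name and spectrum index, and
report the batch average ± SD plus the quality tiers. Truncation and
background removal are optional per dataset. The same surface is exposed
as subcommands (`process`, `calibrate`, `baseline`, `quality`,
`simulate`, `benchmark`) through `raman_cli()` and the installed
`exec/ramanpipe` script.

## File formats

There is no published schema for open Raman JSON files, so the package
defines one (flagged as a reconstruction): a top-level object (or array
of objects) with `accumulations` (list of lists), `background` (list or
null), `exposure_acq_s`, `exposure_bg_s`, optional `axis`, `axis_kind`
(`pixel`, 0-based, or `shift`), and a free-form `metadata` object. Bare
spectra use `axis`/`intensity`/`axis_kind`/`metadata`. CSV holds one
spectrum as two columns with the axis kind in the header. Floats are
serialized at full precision; `read_spectra(write_spectra(x))` is tested
to round-trip everything.
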
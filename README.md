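# ramanpipe

Preprocessing, baseline removal and benchmarking for biomedical Raman
spectroscopy, in R.

Raman spectra of tissue and biofluids arrive buried under ambient-light
background, cosmic-ray spikes, instrument response, and — dominating
everything — broad tissue autofluorescence. `ramanpipe` implements the full
chain that isolates the inelastic-scattering signal, for spectroscopists and
ML practitioners who need spectra from different instruments on a common,
comparable footing:

* **IO**: an open JSON schema for acquisitions (accumulation matrix,
  background, exposure times, metadata) plus two-column CSV.
* **Preprocessing**: truncation of the filter-transition region; cosmic-ray
  removal within one spectrum or across accumulations (robust MAD-scored
  outliers, interpolation repair); accumulation averaging; exposure-scaled
  background subtraction.
* **Calibration**: y-axis correction by the instrument response function
  `IRF = SRM_measured / SRM_theoretical` (certificate polynomial of a
  standard reference material); x-axis pixel-to-cm⁻¹ polynomial maps fitted
  from reference-compound peaks, and resampling onto a common shift grid.
* **Baseline removal** — the core of the package:
  * **BubbleFill**: circular bubbles grown under the detrended,
    square-aspect-scaled spectrum; each bubble rises until it touches the
    signal, splits there, and recursion stops at a minimum bubble width
    `min_width` (scalar or per-pixel). Baseline = smoothed upper envelope of
    all bubbles.
  * **MorphBR**: flat-element grayscale morphology,
    `baseline = min(opening, (erosion + dilation)/2)`.
  * **iModPoly**: iterative polynomial fitting with `fit + DEV` peak
    clipping.
* **Quality metrics**: SNV (`(s − s̄)/σ_pop`), RBR
  (`max(raman)/max(baseline)`), ASSI (`mean(sgn(r*) · r*²)` of the
  SNV-normalized spectrum, bounded in [−1, 1]) with top/middle/bottom-20%
  batch tiering.
* **Synthetic benchmark**: spectra generated as
  `S = (sbr·R + B)/max(sbr·R + B) + N(0, σ²)` with known Gaussian-peak Raman
  components and smooth or bumpy baseline morphologies; algorithms are
  compared by best-case-tuned nMSE
  (`Σ(Rᵗ − Rᶜ)² / (ΣRᵗ)²`) across RBR sweeps; cosmic-ray injection fixtures
  with ground truth.
* **Pipeline + CLI**: a declarative stage config, batch averages ± SD, and
  subcommands `process | calibrate | baseline | quality | simulate |
  benchmark` (see `inst/exec/ramanpipe`).

## Worked example

```r
library(ramanpipe)

axis <- seq(400, 1800, length.out = 1000)                 # Raman shift, cm^-1
R    <- make_raman_component(raman_peak_preset("nylon_like"), axis)
B    <- make_baseline_component(baseline_model("bumpy"), axis, seed = 7)
sp   <- generate_spectrum(R, B, sbr = 0.1, noise_sigma = 0.01,
                          seed = 7, axis = axis)

fit <- bubblefill(spectrum(sp$spectrum, axis = axis, axis_kind = "shift"),
                  bubble_params(min_width = 0.05))

nmse(fit$raman, sp$raman_target)   # 0.0064
nmse(sp$spectrum, sp$raman_target) # 12.3   (baseline left in place)
assi(sp$spectrum)                  # -0.44  (raw: baseline-dominated)
assi(fit$raman)                    #  0.396 (cleaned: peak-dominated)

sweep_benchmark(sp)$nmse           # best-case nMSE per algorithm
#                0.1
# bubblefill 0.00598
# morphbr    0.00402
# imodpoly   0.04380
```

Reading the numbers: removing the baseline cuts the recovery error by more
than three orders of magnitude (12.3 → 0.0064), and the ASSI quality score
flips from negative (broad fluorescence dips below the mean dominate) to
strongly positive (a few large narrow peaks dominate). In the best-case
sweep the polynomial method trails both morphological methods by roughly
10x on this bumpy baseline; BubbleFill and MorphBR are comparable on
synthetic, analytically smooth humps (see the methods vignette for why
that margin is regime-dependent).

## Layout

```
R/            types, IO, preprocessing, calibration, baselines, metrics,
              synthetic benchmark, pipeline, CLI
tests/        testthat suite (unit, property, acceptance criteria)
scripts/      acceptance.R
vignettes/    raman-processing-methods.Rmd (models, parameters, limits)
inst/exec/    ramanpipe CLI launcher
```

Note: `ramanpipe::spectrum()` masks `stats::spectrum()` when the package is
attached.
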
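# thermalrr

Non-contact respiratory rate (RR) estimation from facial thermal image
sequences.

Respiration modulates the apparent temperature around the nose and mouth:
exhaled air is warm, inhaled air is cool, and a long-wave infrared camera
sees a periodic intensity oscillation at the breathing frequency. Methods
that track the nostrils need close-up, high-resolution imagery; `thermalrr`
is for the setting where only a face bounding box is available — e.g. a
supine patient filmed from above in pre-hospital care, where RR is a key
but chronically under-measured vital sign. It is aimed at researchers in
camera-based vital-sign monitoring who need a transparent, fully testable
reference pipeline.

## Method

The face box is divided into a 4 × 6 grid of subregions. For cell *k*, the
signal is the per-frame pixel mean of the raw counts,

    S_k(t) = (1/wh) Σ_ij I_k(i, j, t),

cut into rectangular 15 s windows, linearly detrended, and analysed twice:

* **frequency domain** — zero-padded periodogram
  `P(f) = |DFT(x)|² / (N·fs)`; the peak over the breathing band
  `0.1 ≤ f ≤ 2 Hz` gives `RR_f = 60·argmax P(f)` ∈ [6, 120] bpm;
* **time domain** — zero crossings of the detrended signal located by
  linear interpolation; each consecutive spacing is a half period, and
  `RR_t = 60 · median(1/(2Δ_i))`.

Each cell is scored by the **Respiratory Quality Index**

    RQI_k = SI_k · G(a − |RR_t − RR_f|),   G(x) = 1/(1+e^(−x)),  a = 5,

where the Spectrum Index `SI = 1 − (F_BF + F_HF)/2` is built from
power-weighted indicator fractions of the breathing band (bins ≥ 0.25 of
the band peak) and the high-frequency band (bins ≥ 0.10 of the band peak).
A dominant breathing peak, a quiet HF band, and agreement between the two
estimators all push RQI toward 1. The cell with maximal RQI is selected
automatically — no nose/mouth localisation — and its `RR_f` is the
subject's RR. If every cell scores 0 the result is an explicit "no
respiratory region found".

The package also provides: readers/writers for 16-bit thermal stacks
(multi-page TIFF, 16-bit PNG directories, raw + plain-text sidecar), box
files (CSV/JSON) and a pluggable detector contract; a scene simulator with
known ground truth (breathing cells = sinusoid + 2nd harmonic + drift +
noise, uint16-quantised); and evaluation metrics (MAE, Bland–Altman bias
and 95 % limits of agreement).

## Worked example

```r
library(thermalrr)

# a synthetic 15 s scene: breathing at 25 bpm in two mid-face grid cells,
# baseline 30000 counts, drift, per-pixel noise sigma 75 counts
scene <- generate_scene(scene_config(rr_true = 25, seed = 42))

fit <- estimate_rr(scene$seq, scene$box)
fit
#> RR estimate from thermal sequence (1 window of 15 s, 4x6 grid)
#>   RR: 25.01 bpm (window-wise), mean 25.01 bpm
#>   selected roi: 10

summary(fit)
#> windows: 1, with respiratory region: 1
#> RR: mean 25.01 bpm
#>  window start_s selected_roi rr_bpm    rqi     si rr_t_bpm found
#>       1       0           10  25.01 0.5953 0.5999    25.14  TRUE
```

The true rate is 25 bpm; the spectral estimate is 25.01 bpm and the
zero-crossing estimate 25.14 bpm, so the agreement term is near its
maximum and the breathing cell (grid index 10, middle of the face) wins
with RQI 0.595 — against ≈ 0 for the 22 drift-and-noise cells. A
benchmark sweep over the instructed rates 15/20/25/30 bpm:

```r
suite <- generate_benchmark_suite(n_reps = 3, seed = 7)
evaluate_suite(suite)$stats
#> agreement (n = 12): MAE 0.074 bpm, bias -0.071 bpm, 95% LoA [-0.197, 0.055] bpm
```

`plot(fit)` draws the selected cell's detrended trace with its zero
crossings and the periodogram with the band edges and selected peak.

A thin command-line front end over the same functions lives at
`inst/cli/thermalrr-cli.R` with subcommands `estimate`, `simulate`,
`evaluate` and `bench`; file-driven runs take a flat YAML config whose
zero-config defaults are the reference settings (8.6 fps, 15 s windows,
a = 5, thresholds 0.25/0.10, 0.1–2 Hz band, 4 × 6 grid).

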
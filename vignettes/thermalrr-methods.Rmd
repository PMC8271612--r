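---
title: "Respiratory rate from facial thermography: the method behind thermalrr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Respiratory rate from facial thermography: the method behind thermalrr}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(thermalrr)
```

## The measurement problem

Exhaled air is warmer than inhaled air, so the apparent temperature of the
skin and air around the nose and mouth oscillates at the breathing
frequency. A long-wave infrared camera sees this as a periodic intensity
modulation of a few tens to hundreds of sensor counts riding on a large
baseline, slow thermal drift, and sensor noise. The difficulty in an
uncontrolled setting (a supine patient filmed from above, say) is not
detecting the oscillation once you are looking at the right pixels — it is
knowing *which* pixels to look at without nostril-level resolution or an
anatomical landmark detector.

`thermalrr` sidesteps localisation: the face bounding box is divided into a
4 × 6 grid of subregions (faces are roughly twice as tall as wide, so the
cells come out nearly square), the mean-intensity time series of every cell
is analysed identically, and a per-cell likelihood score — the Respiratory
Quality Index (RQI) — decides which cell's estimate to report. Only a face
box is required; it can come from any detector, a file, or be static.

## Per-cell signal chain

For cell $k$ covering $w \times h$ pixels, the signal is the plain pixel
mean per frame,

$$S_k(t) = \frac{1}{wh} \sum_{i,j} I_k(i,j,t),$$

computed in double precision from the raw integer counts (never from an
8-bit visualisation copy). The chain applied to each cell is:

1. **Rectangular window**, 15 s by default. Truncation has poor sidelobe
   behaviour but the best mainlobe width of any window, and frequency
   resolution is the binding constraint when breathing rates 0.1–0.5 Hz
   must be told apart in 15 s.
2. **Linear detrend**: subtract the least-squares affine fit. Thermal
   drift is locally linear at this time scale and otherwise dominates the
   low end of the spectrum. Mean removal is subsumed. The operation is
   idempotent.
3. **Periodogram**: $P(f) = |\mathrm{DFT}(x)|^2 / (N f_s)$ with the window
   zero-padded to `n_fft` (default 8192) before the transform; $N$ stays
   the native sample count (129 at 8.6 fps).

The spectrum is split into three bands: LF ($f < 0.1$ Hz, drift), BF
($0.1 \le f \le 2$ Hz, the breathing band — 6 to 120 breaths/min), and HF
($2 < f \le f_s/2$, fast noise). The BF interval is closed on both edges; a
bin at exactly 2 Hz is breathing-band. The HF band's nominally unbounded
upper limit is truncated at Nyquist, unavoidable for sampled data; with the
reference 8.6 fps camera that is 4.3 Hz.

### Why zero-pad

The native grid of a 15 s window is $1/15$ Hz ≈ 4 bpm — far too coarse for
sub-bpm reporting. Zero-padding to 8192 points interpolates the spectrum to
≈ 0.063 bpm without changing its information content: total integrated
power is conserved and the peak moves by less than one native bin (both are
tested properties). Padding does not beat the leakage limit, though: a 15 s
window rarely holds an integer number of breathing cycles, and the
resulting leakage offsets the argmax by up to ≈ 0.1 bpm even at zero noise.
That is the floor on accuracy; it is well below the 1 bpm scale that
matters clinically.

## Two rate estimates per cell

**Frequency domain.** $f_{RR} = \arg\max_{0.1 \le f \le 2} P(f)$ and
$RR_f = 60 f_{RR}$. Ties break to the lowest frequency. Restricting the
argmax to the band hard-bounds the output to $[6, 120]$ bpm — the method
cannot represent apnea, which is a documented limitation, not a bug.

**Time domain.** Zero crossings of the detrended signal are located by
linear interpolation between the bracketing samples (a sample exactly at
zero belongs to the following sign). With crossings $t_1 < \dots < t_N$,
each spacing yields a fundamental-frequency estimate and
$RR_t = 60 \cdot \mathrm{median}(f_i)$, with the even-count median taken as
the mean of the two central values. The median makes the estimate robust to
a few spurious crossings.

### The crossing-convention choice

There is a genuine ambiguity in how the crossing-based frequency should be
formed. If only positive-to-negative crossings are detected, consecutive
spacings are full periods and the fundamental is $1/\Delta$; the
alternative formula $f_i = 2/\Delta_i$ is only consistent with *both*
crossing directions, where each spacing is a half period. Combining
one-directional crossings with the factor 2 reports twice the true
frequency on a clean sinusoid, which would make $|RR_t - RR_f|$ large
exactly when the signal is good and defeat the agreement term below.
`thermalrr` therefore defaults to both-direction crossings with
$f_i = 1/(2\Delta_i)$, which is self-consistent and recovers the
fundamental. The one-directional/$2/\Delta$ reading is kept as
`crossing_mode = "literal"` for comparison; a test pins down that it
reports exactly twice the default on a clean sine.

## The Respiratory Quality Index

Good breathing cells look alike in two ways: the breathing band holds one
dominant peak, and the HF band holds nothing comparable. Two power-weighted
indicator fractions quantify this, with $P_{BFmax}$ the BF peak:

$$F_{BF} = \frac{\sum_{BF} P\,[P \ge 0.25 P_{BFmax}]}{\sum_{BF} P},
\qquad
F_{HF} = \frac{\sum_{HF} P\,[P \ge 0.10 P_{BFmax}]}{\sum_{HF} P},$$

realised as Riemann sums over the padded grid's bins, with $\ge$ at the
threshold so boundary bins count deterministically. The Spectrum Index is
$SI = 1 - (F_{BF} + F_{HF})/2 \in [0, 1]$, and the full index is

$$RQI_k = SI_k \cdot G\!\left(a - |RR_t^k - RR_f^k|\right),
\qquad G(x) = \frac{1}{1+e^{-x}},$$

with $a = 5$ bpm: on respiration-related signals the two estimators agree
to within about 5 bpm, so disagreement beyond that halves-and-worse the
score. $RQI \in [0, 1]$ and $RQI \le SI$ always. The cell with maximal RQI
(ties to the lowest index) is selected and its $RR_f$ reported.

Degenerate rules, all deliberate and tested:

* all-zero spectrum (constant cell): $F_{BF} = F_{HF} = 1$, the cell is
  maximally noise-like, RQI 0; if *every* cell is degenerate or at RQI 0
  the result is an explicit "no respiratory region found", not an error;
* zero total HF power with a nonzero peak: $F_{HF} = 0$ (no fast noise at
  all — the 0/0 resolves in the signal's favour);
* fewer than 2 zero crossings: $RR_t$ undefined and RQI forced to 0 — a
  window with no sign change carries no usable periodicity.

### What the power weighting does and does not buy

Because $F_{BF}$ weights bins by power, even a perfect tone scores
$F_{BF} \approx 0.8$ (the mainlobe top holds most of the band's power), so
clean signals sit near $SI \approx 0.6$, not 1. A consequence worth knowing:
*SI alone is not monotone in noise*. Moderate white noise spreads BF power
across bins below the 25 % threshold faster than it builds HF mass, so SI
can *rise* (measured: from ≈ 0.58 clean to ≈ 0.67 at unit noise-to-signal,
before collapsing to ≈ 0.18). The selection index is saved by the agreement
term: moderate noise wrecks the zero-crossing estimate long before the
spectral peak, $|RR_t - RR_f|$ blows up, and the *RQI* degrades
monotonically across noise regimes — this, not SI monotonicity, is the
property the package tests and relies on.

## The scene simulator

No thermal recordings ship with the package; every pipeline stage is
exercised on synthetic scenes with known ground truth. A scene is a frame
stack in which the cells of a face-box grid evolve as

$$\text{baseline} + \beta_k t
  + A\left[\sin(2\pi f t) + d \sin(4\pi f t)\right]\cdot
    \mathbf{1}[k \in \text{breathing}]
  + \varepsilon_{ijt},$$

quantised to uint16 (round half-up, clipped, clips counted). Defaults are
the study conditions the package targets: 15 s at 8.6 fps (129 frames), a
40 × 60 px face box in a 64 × 64 px frame, two mid-face breathing cells,
rates 15/20/25/30 bpm in the benchmark sweep. Where no published value
exists the choices are what we consider realistic for this class of sensor,
made once: amplitude 150 counts on a 30000-count baseline, per-pixel noise
σ = 75 counts (per-pixel SNR $A^2/2\sigma^2$ ≈ 3 dB; cell averaging over
≈ 100 px lifts the *trace* SNR by ≈ 20 dB), drift slopes uniform in ±20
counts/s, and a second-harmonic fraction $d = 0.2$ because
exhalation/inhalation traces are asymmetric rather than sinusoidal (the
harmonic leaves the zero crossings of the fundamental untouched, since
$\sin x + 0.2\sin 2x = \sin x\,(1 + 0.4\cos x)$ and the bracket is
positive).

What the simulator does **not** emulate — so what passing tests do not
show: rigid head or camera motion (ambulance shake), detector jitter beyond
index-matched per-frame boxes, spatially correlated sensor noise
(fixed-pattern, vignetting), radiometric nonlinearity, partial occlusion,
and real anatomical geometry (the "breathing cells" have sharp borders; a
real nose does not). Benchmark results here bound algorithmic error, not
field performance.

## Problem sizes and numerical choices

The shipped test-suite sizes: 400 scenes (100 per rate at the default SNR)
for parameter recovery, 30-scene sweeps at three SNRs for the
noise-degradation check, 20-replicate Monte-Carlo for the matched-seed
index properties, and brute-force oracles (direct $O(N^2)$ DFT at
$N = 129$, per-bin indicator enumeration) at tolerances 1e-9 and 1e-12
relative. Benchmark suite seeds derive deterministically from one master
seed so every run is reproducible; scene generation saves and restores the
caller's RNG state.

Remainder pixels when a box is not divisible by the grid go one-per-column
from the left and one-per-row from the top, so cell geometry is a pure
function of the box. The grid is 4 columns × 6 rows by default; the
transpose is available (`n_cols = 6, n_rows = 4`) because "4 × 6" does not
itself name the axes, and a sensitivity check is cheap.

## Limitations

* RR outside 6–120 bpm is unrepresentable; apnea in particular maps to
  "no respiratory region found" or to a spurious in-band peak.
* A 15 s window reports one rate; rate changes within the window are
  averaged through the median and the spectral peak.
* The index has no learned component; features are combined with fixed
  weights. Cells with strong periodic non-respiratory content (pulsatile
  vessels at 1–2 Hz, flicker) would score well and be selected.
* Accuracy floors at the leakage limit ≈ 0.1 bpm per window; reported
  errors below that are not meaningful.
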
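---
title: "Methods: aero-acoustic and mechanical analysis of vocal-fold replica benches"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: aero-acoustic and mechanical analysis of vocal-fold replica benches}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phonobench)
```

## Scope

`phonobench` implements the data-reduction and modeling chain of an in
vitro phonation experiment: deformable vocal-fold replicas mounted in a
laryngeal envelope, driven by a stepped airflow, instrumented with a flow
meter, a subglottal pressure sensor, a calibrated microphone and a
high-speed camera, and complemented by quasi-static mechanical tests of the
replica materials. The package covers five stages — synthetic bench
generation, aero-acoustic reduction, glottal imaging, phenomenological
fits, and mechanical post-processing — plus a quasi-steady Bernoulli flow
model that links them. The `analysis/` scripts at the repository root walk
the chain end to end.

No self-oscillation physics is simulated anywhere: the synthetic bench
prescribes its waveforms kinematically. That is a deliberate scope choice —
the chain under test is the *measurement and reduction* pipeline, not a
fluid-structure solver.

## The quasi-steady Bernoulli model

Assuming incompressible quasi-steady flow between the tracheal section
(area $A_s$, where the subglottal pressure $P_s$ is measured) and the point
where the glottal jet separates from the walls (area $A_{sep}$, where the
relative pressure vanishes):

$$P_s + \tfrac{1}{2}\rho\left(\frac{\phi}{A_s}\right)^2 =
  \tfrac{1}{2}\rho\left(\frac{\phi}{A_{sep}}\right)^2,$$

with $\rho = 1.20$ kg/m$^3$ at 22 °C and $A_s = 3.14$ cm$^2$ (a 2 cm
diameter tube). The semi-empirical Liljencrants criterion places separation
at $A_{sep} \approx 1.2\,A_g$, standing in for a boundary-layer theory.
Solving for the glottal area gives

$$A_g = \frac{1}{1.2}\left(\frac{2 P_s}{\rho\,\phi^2} +
  \frac{1}{A_s^2}\right)^{-1/2},
  \qquad R_g = \frac{P_s}{\phi} =
  \frac{\rho\,\phi}{2}\left(\frac{1}{(1.2 A_g)^2} -
  \frac{1}{A_s^2}\right).$$

`predict_area()`, `predict_pressure()` and `predict_resistance()` implement
these maps; `predict_pressure()` is defined as `predict_resistance() * phi`
so the resistance identity holds exactly in floating point, and the
forward/inverse pair round-trips to $10^{-10}$ relative (it is an algebraic
inversion, tested on a $100\times100$ grid). Internally everything is SI;
the interfaces speak L/s and mm$^2$ because that is what bench instruments
report. The iso-resistance abacus (`abacus()`) uses the closed-form
inversion and cross-checks every point by monotone root bracketing — the
bracketing is redundant by construction but guards the closed form against
sign and unit regressions.

When the model is compared with *maximal* per-cycle areas
(`compare_model()`), its pressure input is the per-cycle **minimum** of
$P_s(t)$: the glottis is widest when the pressure drop is lowest, so the
cycle minimum is the aerodynamically consistent operating point.

Two analytic rig constants round out the model: the quarter-wave resonance
of the 6.2 m open-closed subglottal supply line, $c/(4L) \approx 13.9$ Hz
at 22 °C (`tube_resonance()`), low enough that it cannot pace the 50–80 Hz
fold oscillation, and the tracheal section above.

## Synthetic bench: what it emulates and what it does not

`bench_config()` collects the acquisition constants of the emulated rig —
22.05 kHz sampling for flow, pressure and audio; 1473 frames/s video
(the camera's nominal "three frames every 2 ms" would be 1500 fps; the
generator uses the stated 1473 and the discrepancy is immaterial at the
precision tested); 736 × 1296 px frames at 123 px/cm; 4 s quasi-steady
steps spanning roughly 0.3–3.5 L/s. Default source parameters are chosen to
sit inside the measured span of the replicas: f0 = 60 Hz (measured range
50–80 Hz), HNR = 20 dB (measured 0.4–41.6 dB), SPL following
$15\log_{10}\phi + 70$ dB (a logarithmic SPL–flow law with a plausible
slope, so the SPL fits are exercised on a non-degenerate relation), open
quotient 0.6, and the linear pressure–flow law $P_s = 530\,\phi + 800$ Pa
whose coefficients equal the values used throughout the fit-recovery
studies. Measurement noise defaults (20 Pa pressure, 0.02 L/s flow) are
realistic sensor-scale figures; the fit-recovery studies use the harsher
50 Pa prescribed for them.

Generator design choices, made once:

* **Pressure ripple.** Real plateaus carry an oscillation at f0; the
  generator uses a sinusoid with 10 % relative amplitude (capped at 20 %).
  Only its amplitude matters downstream (through the per-cycle minima), not
  its shape.
* **Audio.** A harmonic series with $1/k$ amplitudes over 20 partials plus
  white Gaussian noise. The noise is rescaled by its *realized* RMS so the
  harmonic-to-noise power ratio is exact, then the mix is rescaled so the
  total RMS matches the target SPL exactly — the two targets are decoupled
  because scaling the mix preserves the component ratio.
* **Aperture shape.** A lens (two circular arcs through the commissures),
  the shape replica glottes actually show; an ellipse is available. The
  sagitta is solved from the target area via the exact circular-segment
  formula, so the analytic per-frame area *is* the ground truth. Frames are
  rendered with analytic per-pixel coverage (4× supersampled rows, exact
  column overlap), so edge pixels encode sub-pixel area the way defocused
  video does.
* **Left/right phase delay.** The two halves of the aperture can lag by a
  configurable delay, reproducing the diamond-shaped aperture of a
  propagating mucosal wave; each half contributes half of the lagged area
  waveform.
* **Mechanics.** Load–unload cycles have equally spaced peak amplitudes up
  to `eps_max` (the protocol states increasing amplitudes without spacing;
  equal spacing is the simplest consistent choice). One seeded generator
  drives all noise; noise is Gaussian.

What the generator does **not** emulate: turbulence-colored noise, sensor
drift, camera vignetting or motion blur, irregular cycle-to-cycle jitter,
or any coupling between channels beyond the prescribed laws. Passing the
recovery suites therefore shows the *reduction chain* is correct and
well-calibrated, not that it is robust to every artifact of real
recordings; the manual-override hook in `area_series()` exists precisely
because real segmentations need occasional retouching.

## Aero-acoustic reduction

* **Plateau detection** (`segment_steps()`): the flow is block-averaged to
  ~50 Hz, median-smoothed, split at relative jumps, and each segment is
  trimmed to its longest run within 5 % of the segment median, kept if
  longer than 3.5 s (steps last 4 s). A monotone ramp yields no windows; a
  constant trace yields one.
* **f0** (`estimate_f0()`): the YIN chain — difference function
  (FFT-accelerated), cumulative-mean-normalized difference, absolute
  threshold 0.15, parabolic interpolation — over a 40–400 Hz band. When no
  dip crosses the threshold the global minimum is accepted if it is below
  0.8 (heavily noisy but periodic signals sit near 0.2–0.5; white noise
  near 0.98), otherwise the frame is declared aperiodic. The estimate is
  gain-invariant by construction.
* **SPL** (`compute_spl()`): $20\log_{10}(\mathrm{RMS}/20\,\mu Pa)$, no
  weighting.
* **HNR** (`compute_hnr()`): the default estimator projects the
  Hann-windowed signal on the first 30 partials of f0 (f0 refined by
  maximizing harmonic power, so partial drift does not leak into the noise
  estimate); HNR is the harmonic-to-remainder power ratio, capped at
  +60 dB. A classical normalized-autocorrelation estimator
  ($10\log_{10}(r/(1-r))$ at the period lag) is provided as
  `method = "acf"`. The comb default was chosen because the
  autocorrelation statistic is variance-limited above roughly 30 dB: at
  40 dB, $1-r \approx 10^{-4}$ while the harmonic×noise cross-term
  fluctuates at $\sim 5\times10^{-5}$ for a few seconds of audio, so
  $\pm1$ dB accuracy at the top of the observed range (41.6 dB) is not
  achievable with it. The method used is recorded in the run log.
* **Per-cycle pressure minima** (`average_step()`): cycles are cut every
  $1/f_0$ from the window start; the pressure is moving-averaged over a
  tenth of a period first, because the raw minimum of wideband noise is
  biased low by extreme-value statistics; at least 3 full cycles are
  required. The mean of the minima is reported.
* **Resistance**: $R_g = P_s/\phi$ with the mean pressure drop taken equal
  to the mean subglottal pressure.

## Glottal imaging

Segmentation is threshold-based region growing: the 8-connected component
of below-threshold pixels containing the seed (auto-seeded at the darkest
pixel). The default threshold is Otsu's on a pooled sample of the stack; a
stack with less than 0.2 intensity range is treated as fully closed rather
than letting Otsu split pure noise. Areas convert to mm$^2$ by
$(10/\text{px-per-cm})^2$.

Binary pixel counting quantizes: a 5 mm$^2$ aperture at 123 px/cm is a
sliver ~76 px in area but ~500 px in boundary, and integer counting errs by
several percent. `area_series()` therefore refines each mask by summing the
darkness fraction over the mask and a one-pixel ring (`subpixel = TRUE`),
with the aperture gray level estimated from the eroded mask interior and
the background from a ring just outside — both medians, immune to noise
tails. On noiseless renders this recovers the analytic area to well under
1 %; binary counting remains available and accurate for large apertures.

`ag_max_per_cycle()` finds per-cycle peaks (minimum separation
0.8 × frames-per-cycle), refines each by parabolic interpolation — the true
maximum usually falls between frames — and averages peaks across the
cycles of a step (the aggregation rule; a single manually-chosen cycle
would be equally defensible but is not automatable). Kymograms are bilinear
line samples stacked against time; `kymogram_period()` measures the dark
band width per column and reads the period off the autocorrelation's first
strong local maximum with parabolic interpolation (first, not global,
because multiples of the period can edge higher through finite-sample
noise). Pre-strain is $\ln(\ell/\ell_0)$ between the commissures.

## Phenomenological fits

Unweighted OLS throughout (a weighted variant sits behind the `weights`
argument): $P_s$ on $\phi$ (slope $R_d$, intercept $P_0$), $R_g$ on
$1/\phi$ (slope $P_0$, intercept $R_d$; identical coefficients on exact
data because the model is the same law divided by $\phi$ — on noisy data
the two weight the steps differently, which is why both are reported), and
SPL on $\log_{10}$ of flow or pressure (base 10, consistent with the dB
convention; the base is part of the model name in the output). Standard
errors come from the residual variance; at least 3 distinct-flow steps are
required. Simulation checks: over seeded noisy rounds the mean fitted
$R_d$ falls within the pooled per-fit SE of the generating 530 Pa s/L, and
95 % CIs cover it 93–97 % of the time.

## Mechanics

Nominal stress $P = F/A_0$ and natural strain
$\varepsilon = \ln(1 + u/\ell_0)$ from crosshead displacement (no
extensometer correction, matching the test protocol). Cycle segmentation
uses a zigzag extremum search with an amplitude hysteresis of 5 % of the
peak strain — reversals smaller than that are treated as noise — and is
exact on clean records for 1–6 cycles and robust to 1 % strain noise.
The tangent modulus $E_t = dP/d\varepsilon$ is a sliding-window local
linear regression (window 0.05 strain) on the last unloading path, where
the response is stabilized; for a window $w$ on an exponential law the
relative bias is $O((bw)^2/24)$, far below the 2 % verified tolerance.
Adhesion traces are normalized by the mean absolute force over the
relaxation window (the mean, not the end value — an explicit choice, noted
in the output, since the normalization instant is not prescribed), and the
separation time is where the normalized force first decays to 5 % of its
post-pull peak.

## Numerical choices and degenerate inputs

* All seeded runs are bit-reproducible; `run_synthetic_study()` writes
  byte-identical reports for identical seeds.
* $\phi = 0$ with $P_s > 0$ is an undefined jet (error); $P_s = 0$ returns
  the duct-limited area $A_s/1.2$; $1.2 A_g \ge A_s$ is outside model
  validity (non-positive pressure, warned).
* An all-closed stack reports zero area everywhere; a constant area series
  reports that constant as its per-cycle maximum; windows shorter than
  3 periods leave the cycle-minimum pressure undefined.
* Problem sizes in the tests and the acceptance script — 2 s audio
  segments, 5-step rounds at 6.3 kHz, 100-frame stacks on a 360 × 300 px
  sensor crop at the true 123 px/cm calibration, 100 noisy fit rounds —
  were chosen as the smallest sizes at which every tolerance above has
  comfortable margin; the estimators are resolution-limited, not
  sample-starved, at these sizes.

## Known limitations

* The Bernoulli model ignores viscous losses and unsteady inertia; on real
  replicas its area predictions are reported to underestimate measured
  maximal areas severalfold, which is why the comparison table carries a
  ratio rather than a residual, and no correction factor is applied.
* The comb HNR estimator assumes the noise floor is spectrally flat under
  the harmonic comb; strongly colored noise would bias it.
* The region-growing segmentation assumes a dark glottis on bright folds
  (backlit convention) and a single connected aperture per frame.
* `segment_steps()` assumes uniformly sampled flow and monotone step
  protocols; overlapping or decreasing plateaus are split but not
  reordered.
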
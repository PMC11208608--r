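---
title: "Quantifying microglial dynamics in acute brain slices: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying microglial dynamics in acute brain slices: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sliceglia)
```

Acute brain slices are the workhorse preparation for studying neuronal
circuits, but slicing is itself an injury: microglia — the brain's damage
sensors — react within minutes, migrate toward the cut surfaces, retract
their processes, and chase the focal ATP release that the injury sustains
for hours. Those microglial changes in turn shape network phenomena such as
hippocampal sharp wave-ripples (SWRs). `sliceglia` packages the
quantification machinery this kind of study needs — five measurement
pipelines plus a synthetic-data module that generates every input with known
ground truth, so each stage can be validated without access to raw
recordings or images.

This vignette documents the models, the parameters that matter, the
numerical choices, and what the synthetic benchmarks do and do not
demonstrate.

## Zero-phase two-way RC filtering

All field-potential filtering uses a first-order RC stage applied forward
and backward in time ("two-way"), so that transient shapes — the phase of a
ripple, the peak of a sharp wave — are not displaced. The net amplitude
response is the squared single-pass magnitude:

$$|H_{lp}(f)|^2 = \frac{1}{1 + (f/f_c)^2}, \qquad
  |H_{hp}(f)|^2 = \frac{(f/f_c)^2}{1 + (f/f_c)^2},$$

with a band-pass as the cascade of the two. `rc_filter()` evaluates the
forward-backward pass spectrally: the trace is reflection-padded (three time
constants of the slowest stage), transformed, multiplied by the real squared
analog magnitude, and transformed back. This is the exact zero-phase
equivalent of running the analog stage in both directions; a discretised
recursive stage would warp the amplitude response near Nyquist (at
$f = f_s/4$ a one-pole recursion deviates by ~10%), while the spectral form
reproduces the analytic response to 10 decimal places and commutes with time
reversal exactly. Padded lengths are grown to 2-3-5-smooth numbers because
R's mixed-radix FFT degrades to $O(Np)$ when the length has a large prime
factor $p$.

## Sharp wave-ripple detection

Sharp waves are pre-detected on the 30 Hz low-passed trace as local extrema
(negative polarity by default, the convention for CA3 stratum pyramidale;
configurable) exceeding `threshold_sd` times a reference SD, with a 100 ms
minimum separation and boundaries at the recrossing of half the threshold.
The detection threshold multiplier defaults to 3, within the conventional
2-3 range; recording-level SWR prevalence is always assessed at the fixed
2 SD criterion, independent of the detection threshold.

**Which SD?** The reference SD is taken from the *raw* signal by default
(`sd_source = "raw"`), not from the low-passed trace. This is a deliberate
design decision: a threshold of $k$ times the SD of the filtered trace
itself is self-referential — any recording, including pure noise, has local
maxima above twice its own SD, so no recording could ever be classified
SWR-negative. Referencing the raw-signal SD makes the criterion meaningful:
low-pass filtering leaves broadband noise well below threshold while sharp
waves, whose energy is concentrated below 30 Hz, pass through. The filtered
option remains available.

Per event, the ripple band (200 ± 30 Hz, i.e. 170-230 Hz) is band-passed,
negative ripple peaks located (qualifying only if they dip below 3 SDs of
the band trace, so that events without ripple content get `NA` fields
rather than noise-derived numbers), and three quantities computed: the
trigger (negative ripple peak nearest the sharp-wave peak, used for
phase-preserving averages), the ripple amplitude (maximum of the rectified,
55 Hz low-passed band trace inside the event window; the 55 Hz power
cutoff is a package default, exposed in the interface), and the ripple
frequency (reciprocal median inter-negative-peak interval). Quantification
windows of ~100 consecutive events with maximal mean amplitude are chosen by
`select_top_window()`, which is exhaustively optimal (verified against a
brute-force scan).

Artefact rejection, which was a supervised manual step in the original
workflow, is here a rule (amplitude ceiling, maximum width), configurable
and permissive by default.

## ATP sensor events: extraction, kinetics, classification

Focal extracellular-ATP transients are extracted from ΔF/F movies
(`compute_dff()`: per-pixel 20th temporal percentile baseline by default,
robust to transients; a declared pre-event window is the alternative).
Detection replaces the original manual encircling with connected
spatiotemporal components (4-neighbour in space, adjacent in time) above a
ΔF/F threshold. The default threshold (0.15) sits about four shot-noise SDs
above baseline at the default simulation conditions, with a 6 px minimum
footprint and a 2-frame minimum span; lowering it toward the noise floor
trades missed dim flashes for spurious small components. Because the
ambient background decays over the session, the per-frame spatial median of
ΔF/F is subtracted before thresholding (`detrend = TRUE`), which removes
global drift without touching focal events.

Event kinetics follow standard transient conventions, chosen because the
original "peak duration" was not given a formula: duration is the full
width at half maximum of the ΔF/F trace, rise is 10→90% on the ascending
limb, decay 90→10% descending, all located by linear interpolation between
frames so they resolve below the frame interval. The footprint (and hence
area) is taken at the peak frame, mirroring encirclement at maximum
intensity. The reported event peak is the maximum single-pixel ΔF/F within
the footprint at the peak frame — the ROI-mean would dilute the centre of a
Gaussian-profiled event by more than half. Note two honest limitations: the
max-pixel estimate carries a small upward noise bias, and at 0.5 frame/s a
transient with a time constant of a couple of seconds is undersampled, so
its sampled peak underestimates the true one. Neither affects two-cluster
separation, which operates on log scale.

Flash/surge classification log10-transforms (peak intensity, duration,
area), standardises each feature, and runs k-means with $k = 2$ and ten
restarts. The log transform is a package choice justified by the
log-normal distribution of event parameters; whether the original analysis
standardised raw or log features is not recorded, so both are reachable via
the feature table handed in. Cluster naming is deterministic: the cluster
with lower mean standardised intensity is "flash", the other "surge",
regardless of k-means indexing. Degenerate inputs (all features identical)
yield `"unassigned"` with a warning rather than an arbitrary split.

Sensor calibration fits a line over declared calibration points (the
conventional levels are 10, 50, 100 nM and 0.5, 1, 5 µM) and flags
estimates outside the calibrated range as extrapolated; concentration bands
are never hard-coded as class boundaries.

## Microglial process recruitment

Recruitment to an ATP event is quantified on a paired trace: ATP-sensor
ΔF/F and microglia-reporter MFI over the event footprint at maximum
intensity. The percent MFI change uses the baseline rule (mean over the
100 s before the ATP peak) and a two-branch response rule: the reporter
peak closest to the ATP peak if a definitive peak exists within 300 s after
it, otherwise the 100 s post-window average. "Definitive" is
operationalised as a local maximum with topographic prominence of at least
3 baseline-SDs, measured on a 3-sample moving average of the reporter
trace. The smoothing matters: without it, noise-only local maxima
occasionally qualify and — being closest to the ATP peak — displace the true
response peak, which in simulation cut directed-movement detection from
near-perfect to roughly two thirds. Both the prominence multiplier and the
smoothing width are exposed.

Directed movement is declared when the percent MFI change reaches a
threshold (default 10%); prevalence across events carries an exact binomial
confidence interval. The latency rule is an invention of this package (the
original work shows latencies only graphically): the first time after the
ATP peak at which the raw reporter trace exceeds baseline + 2 SD, sustained
for two samples.

## Depth translocation metrics

Cross-section profiles place a grid over the full slice thickness divided
into seven equal zones (zone 1 at the top surface; intervals half-open with
the last closed, so boundary cells count once). Minimal-displacement
transport sorts the equal-sized depth samples of both timepoints and
subtracts elementwise — in one dimension the monotone (sorted) matching
minimises total absolute movement, which the tests verify against
all-permutation search at $n \le 7$. The two-component description of
translocation (a stronger pull toward the top surface plus a smaller pull
toward both cut surfaces) is reported descriptively from the signed
displacements; no additional model is fitted. Area coverage consumes an
already-binarised process mask, because binarisation thresholds are a
property of the upstream imaging pipeline, and reports percent on-pixels.

## Histological interaction metrics

Puncta detection follows the standard binary pipeline: automatic (Otsu)
threshold, hole filling, one erosion step, connected components, minimum
size 4 px (the erosion step is the published protocol; the size floor is a
package default since none was published). Synapses are pre/post punctum
pairs that touch — mask overlap or 8-adjacency, since no connectivity rule
was published. Microglial contact uses the 200 nm rule (4 px at
50 nm/px): the Euclidean gap between mask boundaries, computed by distance
transform as centre-to-centre distance minus one pixel (adjacent pixels
have zero gap), strictly less than the bound.

Somatic coverage works per 2-D section with per-section aggregation (a
documented simplification of the original 3-D stack analysis): surface is
circumference × section thickness summed over sections, covered surface
likewise over contact arcs, and a soma is "contacted" only when a single
arc reaches 0.5 µm. "Clearly touched" is approximated as zero-gap
adjacency (nearest microglia pixel centre within $\sqrt 2$ px of the
outline). Membrane-intensity ribbons extend the delineated outline 250 nm
to each side (500 nm total); a pixel belongs to the ribbon when its centre
lies within the half-width *perpendicular* distance of a polyline segment,
without end caps — end-cap half-disks would inflate short ribbons by
several percent. Integrated density divided by outline length gives
intensity per unit membrane length. Rasterisation is exact for half-integer
axis-aligned outlines and within a few percent for oblique ones; exactly
45° outlines overcount by ~6% because perpendicular pixel distances
quantise at $1/\sqrt 2$.

## The synthetic-data module

Every generator returns its inputs *and* a ground-truth table, and all
randomness flows through one seeded generator per call (the global RNG
state is saved and restored), so identical seeds give identical outputs.

* **LFP**: 1/f-amplitude ("pink") noise by spectral shaping of white noise,
  with sharp waves as negative Gaussian envelopes (SD 20 ms) carrying a
  ripple sinusoid under the same envelope, at Poisson times (or caller-fixed
  times when an exact count is needed). Pink noise was chosen because an
  LFP-like spectrum stresses the band filters; a white option exists for
  recordings dominated by broadband noise. The true noise spectrum and
  event waveform family of real recordings are not published; these
  families are parameterised stand-ins, not claims of fidelity.
* **ATP movies**: exponentially decaying background (F0 100, tau 1200 s
  over a 10 min movie at 0.5 frame/s, 1 µm/px) plus events with 2-D
  Gaussian footprints and two-sided exponential time courses, features
  drawn log-normally per class. Defaults place flashes at peak ΔF/F ~0.25,
  25 µm², tau ~4/8 s and surges at ~1.0, 150 µm², tau ~15/40 s, with rates
  10 and 5 per movie — dim/fast/small versus bright/slow/big at a realistic
  overlap. Since the temporal profile is two-sided exponential, duration is
  determined by the time constants (FWHM $= \ln 2\,(\tau_r + \tau_d)$) and
  is derived, not drawn. Shot-like noise has SD proportional to the square
  root of the signal. Single plane only; no motion, no bleaching beyond
  the background decay, no 3-D structure — benchmarks on these movies
  validate the measurement chain, not robustness to those real-data
  features.
* **Recruitment pairs**: one ATP transient plus a reporter trace that rises
  as a saturating exponential by `dmfi_true` percent starting
  `latency_true` after the ATP peak (or stays flat), with optional
  Gaussian noise.
* **Cell maps**: uniform depths drifted toward the top with Gaussian
  per-cell noise, clipped to the slab.
* **Puncta scenes**: synapses as overlapping pre/post disks (overlap ~3 px
  so that the published erosion step cannot disconnect them), orphan
  puncta kept ≥6 px from the opposite channel, microglia as thick random
  segments; truth contact flags computed from the generated geometry by
  the same 200 nm distance-transform rule.

## Problem sizes in the test-suite and acceptance benchmarks

The standard benchmarks use a 600 s recording at 2 kHz with 50 events at
6× noise SD for detector recovery; 10-minute 96×96 px movies for event
extraction; 20 replicate seeds for clustering accuracy; 50 simulated pairs
for directed-movement prevalence; 100 random trials for the assignment
and window-selection oracles; and 1000 random cell maps for zone
conservation. These sizes give stable statistics while keeping the full
suite under a minute of compute.

## Known limitations

* The detector benchmarks quantify performance on the generator's waveform
  families only; real artefacts (electrode drift, population spikes) are
  exactly what the original supervised step removed, and the rule-based
  replacement is only as good as its configured ceiling/width.
* The recruitment ROI is the ATP footprint at maximum intensity; processes
  recruited to the periphery of large surges dilute the measured MFI
  change.
* Per-section soma metrics underestimate 3-D coverage when contacts span
  few sections.
* Concentration calibration assumes sensor linearity over the declared
  range; outside it, estimates are flagged, not corrected.
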
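---
title: "A digital twin of an sCMOS-based continuous-wave fNIRS instrument"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A digital twin of an sCMOS-based continuous-wave fNIRS instrument}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fnirstwin)
```

## What the package models

Continuous-wave functional near-infrared spectroscopy (CW-fNIRS) measures
cortical hemodynamics by injecting near-infrared light at two wavelengths
(here 695 and 830 nm) into the scalp and detecting the diffusely
backscattered intensity 30 mm away. Conventional instruments use discrete
avalanche photodiodes; the instrument class modelled here instead images
all detector fibers onto a single scientific-CMOS (sCMOS) camera, reads
each fiber's speckle spot as a circular region of interest (ROI), and uses
the mean grayscale value (MGV) over roughly 3.3 × 10^4 pixels as the
intensity estimate. Summing that many pixels is what gives the camera its
weak-light sensitivity: per-pixel read noise averages down as 1/sqrt(N).

`fnirstwin` is a digital twin of that whole chain. It simulates

* the optode array and its time-division-multiplexed (TDM) source schedule,
* the sensor (photon-to-ADU conversion with shot and read noise),
* tissue-mimicking phantoms that drive the optical input,
* ROI extraction and TDM demultiplexing back to channel time series,
* instrument QC metrics (two-state SNR, noise-equivalent power, dynamic
  optical range, drift metrics), and
* the preprocessing and modified Beer-Lambert (MBLL) pipeline that turns
  dual-wavelength intensities into hemoglobin concentration changes.

Every validation experiment of the physical instrument — ink titration,
blood-phantom deoxygenation, block-design task hemodynamics, drift
characterization — can therefore be rehearsed end to end on synthetic data
with known ground truth.

## Array geometry and multiplexing

The montage is a `rows x cols` checkerboard with sources and detectors
alternating and sources on the corners; a 3 x 11 grid carries 17 sources
and 16 detectors and forms 52 measurement channels, one per orthogonally
adjacent source-detector pair (the grid-graph edge count
`rows*(cols-1) + (rows-1)*cols`). Channel ordering is deterministic
(row-major by detector, then source); any published channel numbering of a
particular instrument is not guaranteed to coincide with it.

Sources are divided into activation groups; each group is on for 25 ms and
off for 25 ms, so four groups give a 200 ms cycle and a 5 Hz channel
sampling rate. The one structural requirement is demultiplexing
unambiguity: no detector may be adjacent to two sources of the same group,
otherwise their light would mix in one ROI during one slot. Group
assignment is a greedy colouring of the "shares a detector"
source-conflict graph, deterministic in source order; any valid colouring
is equivalent for the physics, and `validate_grouping()` certifies a
schedule (or produces the violating detector-source-source triples).

## Sensor model

The sensor follows the standard sCMOS photon-transfer model. For mean
photoelectron count `mu` per pixel per exposure,

```
ADU = clip( round( (Poisson(mu) + Normal(0, Q)) / CG + offset ), 0, 4095 )
```

with read noise `Q = 3.57` electrons rms, conversion gain
`CG = 2.33` e-/ADU, a 12-bit ceiling of 4095 ADU, quantum efficiency
84.06% at 695 nm and 53.33% at 830 nm, and 25 ms exposure per TDM slot.
`mu` comes from the photometric relation `P t eta lambda / (h c)` over the
spot's pixels. The model choices worth noting:

* **Spots are rendered with uniform mean flux.** MGV averaging destroys
  intra-spot structure, so speckle texture would only add a variance term
  that the ROI mean suppresses; it is omitted by default.
* **Pedestal (`offset_adu`).** Real sCMOS cameras add a fixed dark offset
  so that read-noise excursions below zero are not clipped. At operating
  levels (hundreds of ADU) the offset is irrelevant and defaults to 0, but
  for deeply attenuated signals (the deoxygenated blood phantom at 695 nm
  reaches mean signals well below 1 ADU per pixel) clipping at zero would
  bias the MGV upward; the blood-phantom runner therefore uses a 100 ADU
  pedestal which the extraction subtracts.
* **Aggregated ROI sampling.** For protocol runners that only need the ROI
  mean, the summed photoelectron count is drawn once
  (`Poisson(N mu) + Normal(0, Q sqrt(N))`), which is equivalent in
  distribution to per-pixel rendering up to per-pixel quantization
  (variance `1/(12N)` ADU^2 on the mean — negligible at `N = 32681`). The
  equivalence is verified against per-pixel rendering in the test suite.
* **ROI discretization.** A pixel belongs to an ROI iff its centre lies
  within the radius (Euclidean). At the instrument's 102-pixel radius this
  gives 32681 pixels, within 0.02% of `pi * 102^2`; the discrete count is
  used consistently everywhere, including the `sqrt(N)` factor of the
  summed noise-equivalent power.
* Frames are captured during on-slots only; optional full-frame rendering
  materializes the read-noise background, while the default patch mode
  renders only spot discs (the inter-spot background never enters an ROI).

Source safety mirrors the physical device: 4 mW from a 3 mm fiber tip is
56.6 mW/cm^2, below the ANSI CW skin maximum permissible exposure of
200 mW/cm^2 at 695 nm and `200 * 10^(2(0.830-0.700)) = 363.94` mW/cm^2 at
830 nm.

## Light propagation in phantoms

The phantom experiments need a map from optical properties to detected
power. The package uses the semi-infinite extrapolated-boundary solution
of the CW diffusion equation (isotropic point source at depth
`z0 = 1/(mua + musp')` plus a negative image source above the extrapolated
boundary; internal-reflection parameter from `R_eff = 0.431`, i.e. a
liquid of refractive index about 1.33). Only *relative* intensity is used:
the absolute scale is absorbed into a gain calibrated so that the
experiment's first state sits at a chosen operating MGV (the default, 335
ADU, is a forehead-like level for this sensor).

Two consequences of this model are worth stating plainly:

* The differential pathlength at 30 mm separation,
  `d(-ln R)/d mua`, is about 350 mm at `mua = 0.01, musp' = 2.3` mm^-1.
  Over the baseline titration range (`mua` 0.00899 to 0.01100 mm^-1) the
  signal therefore spans about 0.7 natural-log units of attenuation, and
  the percent-change-vs-`mua` relation has a small but irreducible
  convexity: its best linear fit tops out near R^2 ≈ 0.988 at 695 nm even
  with a noiseless sensor. A measurement geometry with shorter effective
  pathlength (a finite vessel with absorbing walls, for instance) would be
  more linear; semi-infinite reflectance at the nominal separation is the
  declared model and the twin reports what it implies.
* For the same reason the high-absorption range is strongly nonlinear in
  raw percent change, and the square-root transform (motivated by its
  variance-stabilizing action on Poisson noise, variance → 1/4) also
  happens to linearize much of the exponential decay; the transformed
  signal fits with R^2 ≈ 0.96-0.97.

Intralipid scattering follows the van Staveren empirical model
(`mus = 0.016 lambda^-2.4` mm^-1 per mL-of-10%-stock per litre,
`g = 1.1 - 0.58 lambda`, lambda in micrometres), linear in concentration,
with a forward and an inverse query. The titration presets reproduce the
three published validation ranges exactly at their endpoints (baseline
0.00899-0.01100, low 0.01192-0.01254, high 0.03366-0.04639 mm^-1 at
695 nm); the per-microlitre ink absorption is calibrated from the
endpoints and step count, and the same `mua` series is applied at both
wavelengths (India ink is spectrally flat across this band) while the
scattering is rescaled to 830 nm by the van Staveren ratio.

## Blood phantom and SO2 chemistry

The blood-doped phantom contains 5% whole blood by volume; with
whole-blood total hemoglobin of 2.3 mM the mixture tHb is 0.115 mM.
Absorption is

```
mua(lambda) = ln(10) * tHb * (SO2 * eps_HbO + (1 - SO2) * eps_HbR) + background
```

with decadic extinction coefficients embedded from the standard compiled
hemoglobin spectra (Prahl's tabulation): at 695 nm HbO 0.0283 / HbR
0.19231 mm^-1 mM^-1, at 830 nm HbO 0.0974 / HbR 0.0693. The wavelengths
straddle the isosbestic point, which is what makes the 2 x 2 inversion
well conditioned.

The deoxygenation course is a logistic decay rescaled to run exactly from
SO2 = 1 at t = 0 to 0 at the end (dithionite kinetics are not specified by
any source we model; any monotone course is accepted), with periodic
reference draws that read the course exactly, mimicking blood-gas
analysis.

**DPF choice.** MBLL needs a differential pathlength factor. For phantom
runs the package computes it from its own forward model — the textbook
definition `DPF = (d(-ln R)/d mua) / L` evaluated at the oxygenated
baseline (about 12.0 at 695 nm and 7.5 at 830 nm for the default
phantom). This keeps the inversion consistent with the physics that
generated the data while remaining a genuine estimate (the inversion still
linearizes a nonlinear relation over a large `mua` swing). For in-vivo
style pipelines, where the true pathlength is unknown, the default DPF is
6.0 at both wavelengths, configurable; concentration outputs are then
conditional on the configured DPF and separation.

SO2 is recovered as `(HbO0 + dHbO) / (tHb0 + dHbO + dHbR)` against the
known baseline state, clipped to [0, 1] with clip events counted. This
estimator is declared, not inferred: a CW instrument cannot measure
absolute saturation without baseline assumptions, so the twin supplies the
true baseline the physical experiment obtains from its 100%-oxygenation
step.

## Block-design hemodynamics

The task generator produces a 30 s rest / 60 s task / 60 s rest block: the
task boxcar convolved with a canonical double-gamma kernel, scaled to a
peak HbO change of 1 micromolar-scale default (`1e-3` mM), HbR
opposite-signed at one third amplitude. Physiological oscillations —
cardiac ~1 Hz, respiratory ~0.3 Hz, Mayer ~0.1 Hz, each defaulting to 10%
of the response peak with random phases — are *added to the concentration
truth*, not to the sensor: they are genuine hemoglobin fluctuations, so
full-chain recovery is scored against the total concentration signal
(band-passed identically when the pipeline filters). Motion artifacts are
scheduled multiplicative intensity excursions, which are not hemodynamics
and are therefore excluded from the truth and expected to be masked.

## Preprocessing pipeline

The pipeline applies, in order:

1. **Channel pruning** (titration sessions): a channel whose fitted
   signal-vs-`mua` slope is non-negative at *both* wavelengths is not
   seeing the medium and is dropped.
2. **Motion-artifact masking**: a windowed change detector (0.5 s
   evaluation window) flags samples where the within-window peak-to-peak
   change exceeds `STDthresh = 10` times the channel's noise scale (robust
   sd of sample-to-sample differences) or the excursion exceeds
   `AMPthresh = 5` on the normalized-intensity scale; flags are dilated by
   `tMask = 0.5 s` each side. The threshold names and values follow common
   fNIRS practice (Homer-style); the exact windowing variant differs
   between implementations, so the rule used here is stated precisely and
   tested against a brute-force re-implementation.
3. **Rejection rules**, in order: channels with strictly more than 5%
   contaminated samples are rejected; participants with strictly more than
   30% bad channels have their channel-pair data excluded. Re-running on
   already-clean data is a no-op.
4. **Band-pass filtering**: zero-phase (forward-backward) Butterworth,
   order 3, 0.01-0.2 Hz. The mean is removed before filtering so edge
   transients of the narrow low corner do not ring through. Masked samples
   are bridged by linear interpolation *before* filtering (so they cannot
   shape the output) and set back to NA afterwards.
5. **MBLL**: `dOD = -log10(I/I0)` against a baseline window (the pre-task
   rest for task data, the early oxygenated window for phantoms), then the
   per-sample 2 x 2 solve for (dHbO, dHbR). The system's condition number
   is checked (error above 1e6).
6. **Statistics**: ordinary least squares with R^2, and a correlation gate
   that applies Shapiro-Wilk at alpha = 0.05 to both series and uses
   Pearson only when both pass, Spearman otherwise.

In the two-state SNR metric `20 log10(mean(dMGV)/sd(dMGV))`, the sd is the
sample (n-1) standard deviation; at the protocol's four repeats the
population alternative would shift results by roughly 1 dB, so the choice
is stated explicitly. The optical perturbation between states is a power
ratio, i.e. `10 log10`; at the 335 ADU operating level the chain is
shot-noise-limited, so halving the operating power costs about 3 dB of
SNR (it would cost 6 dB only in a read-noise-limited regime).

## Noise-equivalent power: a documented discrepancy

The theoretical per-pixel NEP is the read-noise-limited photometric
relation `Q h c / (lambda t eta sqrt(BW))` with `BW = 0.09` Hz, and the
summed-ROI value multiplies by `sqrt(N)`. Evaluating these formulas with
the instrument's own constants gives about 29 pW/sqrt(Hz) at 695 nm —
not the ~5.3 pW/sqrt(Hz) figure published for this class of device. The
830/695 ratio, however, `(695/830)(0.8406/0.5333) = 1.320`, matches the
published pair to better than 0.5%, so the discrepancy is a pure scale
factor (plausibly a different effective pixel count or bandwidth
convention). The package evaluates the formulas literally and treats only
the scale-free ratio as checkable; the measured-NEP figures of the
physical hardware are not reproducible at the desk and are not targets.
Note also the band inconsistency inherited from the instrument's
description: the NEP bandwidth is 0.01-0.1 Hz (0.09 Hz) while the
preprocessing band-pass is 0.01-0.2 Hz; both are kept as stated.

## Drift and stability metrics

Drift streams are mean-one intensity series with a configurable linear
trend (%/h), white noise, and optional 1/f (flicker) noise generated by
spectral shaping. Three metrics characterize them, all on the
percent-of-mean signal:

* the linear drift rate, the least-squares slope scaled to one hour;
* the overlapping Allan deviation
  `sigma_y(tau)^2 = <(ybar_{k+1} - ybar_k)^2> / 2`, whose log-log slope is
  -1/2 for white noise and flattens where flicker or drift dominates
  (the published stability numbers of this instrument class use an
  unstated normalization, so only behavioural properties are checked, not
  their absolute values);
* the percentage of samples within ±3 standard deviations of the mean,
  using the full-record sd (no rolling window), 99.73% for a Gaussian
  stream.

## Problem sizes, determinism, degenerate inputs

The simulation experiments are run at deliberately modest sizes chosen to
exercise the full chain while keeping a desk-scale footprint: titrations
use 10 steps spanning the published ranges with 3 acquisition cycles
averaged per step on the full 3 x 11 array; the blood-phantom course runs
120 s at 20 Hz on a minimal one-channel array (every channel of the
stirred phantom sees the same medium, so one channel carries the
experiment); the SNR protocol uses 4 repeats on all 52 channels at the
full 102-pixel ROI. All generators accept a seed and reproduce
bit-for-bit; a single run seed fans out to named sub-seeds
(`sub_seed(seed, "sensor")`, ...) so stages stay reproducible when run
separately.

Degenerate inputs fail loudly rather than silently: non-diffusive media
(`musp <= mua`) are hard errors, zero source powers cannot normalize,
missing frames become NA samples and are never interpolated, zero-variance
SNR measurements return an `Inf` sentinel, swapped SNR states are an
error, and saturation is flagged per sample with a channel-level warning
above 0.1%.

## What the synthetic data does and does not show

The generators emulate the *structure* of the physical experiments: the
attenuation physics of homogeneous liquid phantoms, shot- and read-noise
statistics, TDM timing, block-design hemodynamics with in-band
physiological confounds. They do not emulate layered head anatomy,
speckle decorrelation, fixed-pattern sensor noise, spot drift on the
sensor, temperature transients, or melanin/skin-tone absorption. Passing
the end-to-end checks therefore demonstrates that the computational chain
is correct and self-consistent at realistic noise levels — not that the
physical instrument meets its specifications, which only hardware
measurements can show. Hardware-bound published figures (measured SNR
means, measured NEP, in-vivo MGVs and inter-system correlations) are
deliberately out of scope.

## File formats

Frame stacks travel as multi-page 16-bit TIFF with a JSON sidecar carrying
the schedule, layout and seed; channel series as CSV
(`time_s, channel_id, wavelength_nm, mgv, saturated`); run configurations
as YAML (validated against a fixed schema, unknown keys rejected); QC and
statistics reports as JSON. Timestamps are seconds from acquisition
start, channel ids 1-based, pixel coordinates 0-based (x right, y down).
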
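---
title: "Quantifying cortical neuron subtypes: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying cortical neuron subtypes: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cortiphys)
```

cortiphys quantifies three complementary views of cortical pyramidal-neuron
identity: intrinsic electrophysiology from whole-cell current-clamp
recordings, morphometric subtype structure from per-neuron feature tables,
and laminar marker co-expression from per-cell counting tables.  This
vignette explains the models and procedures behind each stage, the
parameters that matter, and the design decisions that were genuinely open.

## Current-clamp feature extraction

### Data model and units

A recording is a `sweep_set`: one voltage trace per injected current step,
with shared sampling interval and step window.  Units are fixed throughout:
voltage in mV, time in ms, current in pA, and resistance in megaohms (the
I-V slope in mV/pA multiplied by 1000).  Time starts at 0 at the first
sample; the step window is stated in ms from there.  The default synthetic
sampling interval is 0.1 ms (10 kHz).  Traces are exchanged as a plain CSV
(one column per sweep) with a JSON metadata sidecar, written at full
precision so a save/load cycle is bit-exact.

### Passive properties

The passive protocol injects 500 ms steps from -200 to +80 pA.  For each
spike-free sweep, `step_extrema()` measures the peak deflection (the
extremum within the step in the direction of the current, searched over the
first 250 ms of the step to avoid late rebound artifacts) and the
steady-state voltage (mean over the last 10% of the step; both windows are
configurable).  The slopes of the peak and steady-state I-V curves are the
input resistances Rpeak and Rss; the sag is the steady-state minus peak
voltage of the -200 pA sweep (positive when the Ih-like overshoot is
present); time to peak is reported for the same sweep.

Two numerical choices deserve comment:

* **Peak smoothing.**  The raw argmin over ~2500 samples of a noisy trace
  is biased by the expected extreme value of the noise (about 3.4 standard
  deviations for white noise), which propagates into the Rpeak slope.  The
  peak search therefore runs on a lightly smoothed copy of the trace
  (centred boxcar, `smooth_ms = 3` by default); the steady-state mean is
  always computed on raw samples.  Setting `smooth_ms = 0` reproduces the
  literal per-sample extremum, which is the convention the test-suite
  oracles check against.
* **Spike exclusion.**  Depolarizing sweeps that fire are excluded from the
  I-V fit, since spike deflections corrupt the slope.

### Spike detection and the interpolated threshold

Detection is deliberately permissive — a local maximum above 0 mV whose
preceding 5 ms contain a dV/dt above 20 V/s, with 1 ms refractory
separation — because detection only localizes candidate spikes; all
measurements are anchored on the firing threshold.  The threshold is the
membrane potential at which dV/dt reaches 20 V/s on the upstroke: scanning
backward from the peak, the last sample pair straddling 20 V/s is found and
the crossing is interpolated linearly in the derivative.  The derivative is
the central difference (one-sided at the edges); in mV/ms it is numerically
identical to V/s.  Whether traces should be smoothed before
differentiation is left as configuration; the default is no smoothing,
which on template upstrokes of bounded curvature keeps the interpolation
error below 0.05 mV at 10 kHz.

### Waveform and afterpotential windows

With the threshold as baseline: amplitude is peak minus threshold voltage;
half-width the time between the interpolated half-amplitude crossings;
duration the threshold-to-threshold-return time (the assumption made for
"duration"; an alternative base-width convention can be had by passing a
different reference level); rise time the 10-90% amplitude interval on the
upstroke (the 10-90% convention is this package's choice).

Afterpotentials follow fixed windows: the fAHP is the threshold minus the
minimum within 3 ms of the spike peak (the peak anchors the window, which
is what makes the time-of-fAHP measurable as peak-to-minimum); the fDAP is
the maximum within 5 ms after that minimum, minus the minimum.  The medium
pair uses 50 ms (mAHP) and 70 ms after the mAHP minimum (mDAP).  Bursts of
2-3 spikes are grouped greedily with a configurable intra-burst ISI bound
(default 15 ms — the data report doublets/triplets but no criterion, so the
bound is exposed); inside a burst the fDAP of a non-final spike uses the
following spike's threshold as its maximum, and the medium pair is measured
after the last spike of the burst.  Windows truncated by the end of the
trace yield explicit missing values, never zeros, so group statistics stay
unbiased.

The firing profile reports the rheobase (smallest spiking step), the f-I
curve (spikes within the step divided by the 2 s step duration — mean rate,
not instantaneous), and the adaptation index: first interspike interval
over last, measured on the sweep closest to twice rheobase (ties broken
toward the larger step), requiring at least 3 spikes.

## Morphometric clustering

Feature tables use a fixed named schema (soma diameter/area/volume, oblate
ellipticity, sphericity, apical dendrite diameter at 5 µm from the soma,
radial position, distance to first apical bifurcation, secondary-dendrite
count near the soma, basal dendrite count, and the mean basal angle — the
mean is this package's summary of the angle sets, which the source data do
not specify).  A matched-subset analysis combining features measured at two
magnifications is supported by an inner join on `neuron_id`
(`match_morph_tables()`).

Columns are z-scaled before clustering so no feature dominates the squared
Euclidean metric; the population standard deviation (`ddof = 0`) is the
default.  Zero-variance columns are dropped with a warning; rows with
missing values are dropped for clustering but retained for univariate
tests.

`kmeans_pp()` implements k-means++ seeding followed by Lloyd iteration to
assignment stability, best-of-`n_init` restarts by inertia, and empty-
cluster repair by re-seeding the farthest point.  "A large number of
iterations (1000)" is interpreted as 1000 random restarts rather than 1000
Lloyd passes: the restart count is what stabilizes k-means (Lloyd converges
in far fewer passes), and it is configurable.  `select_k()` scans k = 2..5,
scores each solution by the mean silhouette (singleton clusters score 0, a
standard convention), picks the argmax with ties broken toward smaller k
(parsimony), and re-runs the chosen k with the full restart budget.  Group
differences per feature use the two-sided Wilcoxon Mann-Whitney U-test,
exact by enumeration when the smaller group has at most 8 members and no
ties occur, and the normal approximation with tie correction otherwise.
P-values are reported unadjusted per feature (Holm adjustment is available
but off by default, matching the reporting convention of the source
analyses).

## Laminar composition

Cells carry a depth measured from the cortical bottom, so bin 1 is the
deepest bin; this orientation is forced by the layer maps (bins 1-2 = layer
VI in the 6-bin scheme).  Relative depth is cut into half-open equal bins,
with depth = thickness assigned to the top bin; cells are assigned by soma
depth.  Two schemes are built in: 6 bins (VI, VI, V, V, UL, UL; used at
P0) and 10 bins (VI x3, V x3, UL x4; used at P7).

The four Ctip2/Satb2 classes partition every DAPI-denominated stratum, so
their percentages sum to 100 before rounding — an invariant the tests
enforce.  Percentages are computed per animal and then averaged, with SEM
across animals: animals (not cells or sections) are taken as the
replication unit, a choice the source leaves open but which matches the
stated use of three or more animals per comparison.  Strata with an empty
denominator are undefined, never 0%.  Group comparisons use the two-tailed
Student's t-test with pooled variance by default (Welch is a flag), with
significance stars at 0.05/0.01/0.001.

## Synthetic ground truth

Every stage has a generator whose outputs carry their ground truth, so all
recovery tests compare against the generator, never against hard-coded
constants, and all generators are bit-deterministic given a seed.

* **Passive membranes** follow a phenomenological two-exponential shape:
  the deflection charges with `tau_m` and relaxes toward
  `(1 - sag_frac)` of its amplitude with `tau_sag`, plus white Gaussian
  noise (the noise model is a modelling choice; the source specifies
  none).  The analytic peak, steady state, Rpeak, Rss and sag are attached
  to the simulated sweep set.  Defaults (`tau_m` 12 ms, `tau_sag` 120 ms,
  `sag_frac` 0.25, noise 0.2 mV RMS) give sag magnitudes of a few mV at
  physiological resistances.
* **Spike trains** insert closed-form waveform templates rather than
  integrating a conductance model: the measurements are waveform-geometric,
  so templates give exact truth for every feature, and a biophysical
  simulator is out of scope.  The upstroke's dV/dt rises linearly 0-35 V/s
  over 1 ms — placing the 20 V/s crossing mid-segment, where the sampled
  central difference is exact and the linear interpolation chord error is
  below 0.05 mV at 10 kHz — then accelerates to 250 V/s.  The geometry
  implies validated parameter constraints: the upstroke starts 5.7 mV below
  threshold, so the fAHP must exceed 6 mV, the mAHP must be at least the
  fAHP (otherwise the 50 ms window minimum would be the fast trough), and
  the mDAP bump must clear the inter-spike plateau.  Trains adapt with a
  geometric ISI progression whose first/last ratio is prescribed; burst
  modes repeat each event as doublets/triplets at a fixed intra-burst
  interval, and parameter combinations whose waveforms would overlap raise
  an error.  Protocol constants mirror the recording conventions:
  -200..80 pA/500 ms passive steps, 20 pA/2 s firing ladder, holding near
  -67 mV.
* **Morphology tables** come from diagonal-Gaussian mixtures over the
  feature schema, with physical features clipped at zero and shape indices
  to (0, 1]; true component labels are returned.
* **Cell maps** draw depths uniformly, with layer boundaries taken from the
  bin scheme itself so generator layers and analysis layers coincide
  exactly; marker classes are drawn per layer, Lmo4 conditionally within
  double-positive cells, GFP/tracer independently.

What the generators do *not* emulate matters for interpretation: real
recordings have correlated (not white) noise, electrode and access-
resistance artifacts, and spike waveforms that covary with firing rate;
real morphology features are skewed and correlated rather than diagonal-
Gaussian; real cell maps have spatially clustered cells and imaging
dropout.  Passing recovery tests therefore demonstrates correctness of the
measurement code under the stated statistical structure, not robustness to
every artifact of acquisition.

## Verification scale and reproducibility

The test-suite problem sizes are chosen to exercise the study's own scales
while staying desk-sized: 100 random membranes at 0.2 mV noise for passive
recovery; template trains across all burst modes for spike recovery; 100
seeded clustering runs at n = 145 neurons, p = 10 features, with component
means placed at mutual distance 5 sigma and equal between-component
variance in every feature (so z-scaling rescales dimensions uniformly and
preserves the stated separation); 10,000-replicate null simulations for
test calibration at n = 9 vs 23 cells and n = 3 animals; 3 animals x 500
cells for composition recovery.  The end-to-end demo (`run_full_demo()`)
simulates all three data types (9 vs 23 cells, 145 neurons, two simulated
areas x 3 animals), runs all three analyses and writes plain TSV/JSON
artifacts embedding the seed; reruns with the same seed are byte-identical.

## Known limitations

* The spike simulator is phenomenological; it cannot probe detection
  robustness to waveform shapes it does not generate (e.g. broad calcium
  spikes, strong spike-height accommodation).
* The exact Mann-Whitney branch requires tie-free data; heavily discretized
  features fall back to the normal approximation.
* The f-I curve reports mean rate over the step; instantaneous-rate
  variants must be computed from the per-spike tables.
* Clustering assumes the z-scaled squared-Euclidean geometry of the source
  analyses; strongly non-spherical subtype structure would call for a
  different model class entirely.
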
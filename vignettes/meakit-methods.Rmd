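---
title: "Methods: HD-MEA spike-train analysis and E/I network simulation with meakit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: HD-MEA spike-train analysis and E/I network simulation with meakit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(meakit)
```

## Scope and data model

meakit analyzes spike-sorted recordings from high-density microelectrode
arrays (HD-MEAs): by default a 64 x 64 grid of 4,096 channels with a
60 um pitch (`grid_geometry()`; the pitch is configurable because vendor
grids differ). The central container is the `spike_train_set`: an event
table of `(channel, time)` pairs sorted by time, tied to a geometry and a
recording duration (default fixtures use 300 s, the usual 5-minute
integration window for activity maps). Raw-voltage processing and spike
sorting are upstream of this package; it consumes event tables in a plain
CSV dialect (`channel,time_s` plus a JSON metadata sidecar).

The motivating application is the comparison of neuronal cultures with
different excitatory/inhibitory (E/I) compositions — pure
dorsal-telencephalic ("CYC"-like, ~7% inhibitory), pure
ventral-telencephalic ("SAG"-like, ~80% inhibitory) and their 80:20 /
50:50 mixtures. `expected_inhibitory_fraction()` gives the implied
inhibitory percentage of any mixture as the weight-averaged component
percentage (21.6% and 43.5% for the two standard mixtures).

## Per-channel metrics

`mean_firing_rate()` is spike count over duration per channel. A channel
is *active* at >= 0.1 Hz by default (`detect_active_channels()`); the
threshold corresponds to 30 spikes in 5 minutes and is exposed
everywhere as `min_rate`.

`detect_bursts()` uses a fixed inter-spike-interval rule: a burst is a
maximal run of same-channel spikes with every ISI <= 100 ms and at least
5 spikes. Adaptive (log-ISI) detectors exist but the fixed rule is the
standard simple parameterization for dense cultures, and both parameters
are arguments. From the burst annotations, `summarize_channels()` derives
the mean burst rate (MBR, bursts/min), mean burst duration (MBD, s), the
random-spike fraction (spikes outside any burst, divided by total — a
conserved decomposition: burst plus random spikes always equal the
total), and the percentage of bursting electrodes. The bursting
percentage is computed over *active* channels by default (a
4,096-channel denominator would be dominated by silent electrodes);
`denominator = "all"` switches this.

## Network bursts and activity trajectories

A network burst (NB) is detected on the array-wide binned firing rate
(25 ms bins): a contiguous run of bins whose rate exceeds a threshold
*and* in which at least a fraction of the active channels fire, with
nearby runs merged. Defaults — threshold = mean + 3 SD of the binned
rate, 20% participation, 100 ms merge gap — are conventions of MEA
practice, all exposed. The joint rate-and-participation rule is what
keeps the false-positive rate on pure Poisson activity essentially zero
(the test suite bounds it at 0.2 NBs/min over 100 simulated nulls):
Poisson rate fluctuations can cross a mean + 3 SD threshold, but almost
never involve a fifth of the array within one 25 ms bin. NBR is NBs per
minute; NBD is the mean NB duration (`stat = "median"` is available
since per-culture medians are sometimes preferred).

The center-of-activity trajectory (CAT, `center_of_activity_trajectory()`)
resolves an NB spatially: per 5 ms bin, the spike-count-weighted centroid
of the firing electrodes' positions. Points are convex combinations of
electrode positions, so they always lie inside the array hull; the first
point estimates where the NB ignited and the ordered points trace its
propagation. Near the array boundary the early centroid is biased inward
(the activity disk is clipped), so the synthetic generator offers
`origin_margin` to plant origins whose recovery is identifiable; this is
a property of centroid estimators at edges, not of the detector.

## Functional connectivity

`pairwise_correlation()` bins each active channel's spike train (50 ms
bins) and takes, per channel pair, the maximum Pearson correlation over
lags up to 0.2 s in either direction. Only active channels enter the
matrix — a full 4,096^2 matrix would be mostly silent rows. The
functional graph (`build_graph()`) links pairs at or above a correlation
threshold (default 0.3); nodes are endpoints of at least one link, and
the headline statistics are the node and link counts, compared across
conditions (e.g. before/after a GABA_A antagonist) with
`compare_conditions()`. Whether published analyses of this kind
threshold on the raw index or on a significance estimate is usually
unstated; both are available here — the fixed threshold as default, and
`surrogate_threshold()` (spike-time dithering, 20 surrogates, 95th
percentile of pooled surrogate correlations) as the significance-based
alternative. Plots draw only the strongest decile of links by default;
that subsampling is visualization-only.

## Stimulation analysis

A `stimulation_session` couples a recording with pulse times and the
stimulated channel set; pulses must be separated by more than twice the
analysis window so baselines and responses never overlap.
`evoked_response()` scores each channel and post-pulse latency bin
(default edges 5, 10, 20, 40, 60, 100, 150 ms — the latencies at which
direct responses and delayed suppression are typically discussed) by the
mean over pulses of the post-pulse count minus a *duration-matched*
pre-pulse baseline count. The matched-width integer comparison matters:
scaling a long baseline down to a short bin produces tiny fractional
offsets that make percentile bootstrap intervals degenerate at low
firing rates — a cell with zero post-stimulus spikes but any baseline
spike gets a strictly negative interval and a spurious significance
flag. With the matched-width rule, the 100-session null study in the
test suite keeps the empirical per-cell false-positive rate within
1.5x the nominal 5% level. Confidence intervals come from a bootstrap
over pulses (default 1,000 resamples, seed-controlled); a cell is
significant when its interval excludes zero, signed by its mean. No
multiple-testing correction is applied by default — the per-cell
interval mirrors the averaging-plus-CI description of the reference
protocol — and stimulated channels are blanked for 2 ms around each
pulse.

Downstream summaries: `global_response_curve()` (the fraction of
positively evoked spikes per latency bin, normalized to 1),
`dispersion_index()` (per latency bin, the mean distance of
significantly responsive channels from the nearest stimulated channel;
reported in um). The phrase "average distances between responsive
electrodes" admits a second reading — mean pairwise distance among
responsive electrodes — which is available as `mode = "pairwise"`; the
distance-from-stimulation-site reading is the default because it is the
quantity described as distance of responses from the stimulated channel.
`detect_evoked_nb()` runs NB detection after each pulse of a
multi-electrode session and compares evoked with spontaneous NB
durations; `select_stim_channels()` picks the k most active electrodes
(k = 7 in the reference protocol), ties broken by lower channel id.

## The synthetic-data generator

No public recordings accompany the experiments this package is modeled
on, so every analysis stage is exercised on synthetic fixtures with
planted ground truth. The
generators are deliberately statistical, not biophysical:

- `generate_background()`: independent homogeneous Poisson trains;
  per-channel rates default to log-normal with median 0.5 Hz (no rate
  distribution is published for these cultures; log-normal rates with a
  sub-Hz median are typical of culture MEA data and exercise the
  active/inactive split).
- `generate_network_bursts()`: planted NB episodes at well-separated
  times; each recruits a random channel subset whose onsets lag a random
  origin by distance / speed, i.e. a radially propagating wave — the
  simplest mechanism that produces non-trivial CATs.
- `plant_correlations()`: copy-with-jitter spike injection between
  planted channel pairs.
- `generate_stim_session()`: baseline Poisson plus post-pulse extra
  spikes following a planted distance/latency kernel
  (`make_response_kernel()`); negative kernels thin the baseline,
  clipped at zero net rate.
- `ei_nb_rate()` maps an excitatory fraction to a planted NB rate with a
  Gaussian bump peaking at intermediate fractions (center 0.65, width
  0.18, max 3 NBs/min). This encodes, as a *fixture contract*, the
  qualitative observation that mixed cultures burst more than pure ones;
  passing tests show the pipeline recovers whatever the generator
  plants, not that biology behaves this way.

All generators are deterministic given a seed. What the fixtures do not
emulate: refractory periods, rate nonstationarity, oscillatory structure
within bursts, electrode noise and spike-sorting errors. Results on real
recordings therefore depend on upstream sorting quality in ways these
tests cannot certify.

## The E/I spiking-network simulation

`build_network()` / `simulate_network()` implement a 1,000-neuron
network of two-variable quadratic integrate-and-fire (Izhikevich)
neurons: regular-spiking excitatory cells (a = 0.02, b = 0.2, c = -65,
d = 8) and fast-spiking inhibitory cells (a = 0.1, d = 2), 100 random
outgoing synapses per neuron (inhibitory neurons target excitatory cells
only), integer conduction delays (excitatory 1-20 ms, inhibitory 1 ms),
initial weights +6 / -5 with excitatory weights plastic under additive
STDP (A+ = 0.1, A- = 0.12, tau = 20 ms, per-second consolidation with a
0.9-damped eligibility trace and +0.01 drift) and capped at 10, and a
weak drive of one randomly chosen neuron per millisecond (amplitude 20).
These follow the classic self-organizing-network formulation this model
family comes from; none are fixed by the motivating experiments, and all are
`sim_config()` fields. Integration uses 1 ms steps with two half-steps
of the membrane equation (the customary scheme; `dt` is configurable,
and a single-neuron run at dt = 0.1 ms is tested against an independent
fine-step integration). The integrator is compiled (Rcpp); a counts-only
mode skips raster recording, which matters in high-excitation regimes
where networks enter near-saturated firing and a full raster would hold
~10^8 events.

The Instantaneous Network Firing (INF) metric
(`instantaneous_network_firing()`) bins population spike counts (10 ms)
and counts threshold-crossing events: maximal runs of bins whose count
exceeds a fraction phi = 0.25 of the network, one event per run at its
peak, reported as events/min — the simulated analogue of the biological
NB rate. No standard formula exists under this metric's name; the
population-threshold definition above is this package's documented
choice, with `bin` and `phi` exposed. Note
that it scores *events*: a network in continuous saturated firing
produces one long supra-threshold run and hence a *low* INF event rate,
which is exactly how runaway high-excitation regimes end up below the
intermediate-ratio maximum.

`ei_sweep()` runs the 9 standard ratios (900:100 down to 100:900), 3
seeds per ratio by default, with 60 s STDP warm-up plus 120 s scored per
run. These durations are desk-scale stand-ins for longer original runs;
the INF argmax is robust to them because the ranking of ratios, not the
absolute rate, is the target. A full sweep is ~4,900 s of model time and
runs in minutes on one CPU.

## Numerical choices and degenerate inputs

- Spike times are double-precision seconds on a continuous axis; no
  acquisition-clock grid is imposed (the hardware sampling rate is not
  part of the event-table contract).
- Binning uses half-open bins `[kb, (k+1)b)` with the last bin clipped
  to the duration; bin-sum conservation is asserted in tests.
- Zero-variance channels get correlation 0 by definition (logged
  diagonal exception: self-correlation is 1).
- Empty recordings, zero-rate maps, zero planted bursts, sessions with
  no pulses, and all-inhibitory networks all return well-formed empty
  results rather than errors; genuinely contradictory inputs (negative
  rates, unsorted pulse times, out-of-range events) error with the first
  offending element named.
- Ties in `select_stim_channels()` resolve to lower channel ids, making
  selection deterministic.
- Generator seeds propagate to every random draw; two runs with the same
  seed are byte-identical.

## Problem sizes used by the test suite

Fixtures are sized so the full suite runs in minutes: oracle-equivalence
fixtures stay below 10^4 spikes; null studies use 100 seeds on reduced
grids (16 x 16 for NB false positives, 6 x 6 for stimulation type-I with
200 bootstrap resamples); recovery fixtures use 10 x 10 to 32 x 32
grids; the E/I sweep runs at its standard 1,000-neuron, 3-seed
configuration. Reduced grid sizes affect statistical power, not the
validity of the bounds being checked, and every fixture's parameters are
in the test sources.

## Known limitations

- The burst, NB and connectivity parameter defaults are field
  conventions, not values fitted to any particular laboratory dataset;
  the reference experiments are reproduced structurally, not numerically.
- The correlation index is count-based Pearson at 50 ms resolution;
  spike-timing metrics on finer scales (e.g. STTC) are out of scope.
- The functional graph is undirected; no causal or directed inference.
- The simulator is current-based and non-topographic: no conductances,
  no distance-dependent wiring, no transmission failure.
- Pharmacological perturbations are emulated only as generator scenarios
  (e.g. raising copy probabilities to mimic disinhibition), never
  mechanistically.
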
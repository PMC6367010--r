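---
title: "Methods: laminar analysis of multichannel cortical recordings"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: laminar analysis of multichannel cortical recordings}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(lamprobe)
```

`lamprobe` reconstructs, from a single-shank linear-probe recording of
layered cortex, the physiological quantities that organize such data:
brain states, the DOWN/UP alternation of non-REM slow oscillation, a
laminar map anchored on electrophysiological landmarks, gamma-band layer
structure, single-unit classes and statistics, and monosynaptic
connectivity. This vignette documents the models, parameters and
numerical choices; it is the package's design record.

## Conventions

All public times are seconds with the recording start at 0 and half-open
intervals `[start, end)`; depths are micrometers with 0 at the
shallowest recording site, increasing downward; frequencies are Hz.
Continuous data live in a `probe_recording` (time x channels,
microvolts), serialized as flat binary interleaved int16 with a JSON
descriptor. Channel order in files is geometric, top to bottom.

## The synthetic-session generator

Because every analysis stage here is defined by what it recovers, the
package ships a generator (`sim_config()`, `simulate_session()`) whose
ground truth makes each stage testable. The generator's defaults are the
study conditions of the analyses: a 64-site probe at 20 um pitch,
wideband 20 kHz, LFP down-sampled to 1.25 kHz.

The LFP is a sum of components:

* **Laminar gamma sources.** One band-limited (30-100 Hz) source per
  cortical layer, each an amplitude-modulated oscillation
  `A(t) cos(theta(t))` with lognormal-bursty amplitude (so the sources
  are leptokurtic, as cortical gamma is, which is also what makes them
  separable by ICA) and a slowly wandering instantaneous frequency
  around a layer-specific center (38-88 Hz; faster gamma deeper). The
  depth loading of each source is confined to its layer with a logistic
  falloff of 8 um at the boundaries — channels inside a layer share
  that layer's source at full weight, and the mixing zone at a boundary
  is narrower than the 20 um channel pitch. This flat-top profile, and
  not a Gaussian bump, is the package's reading of layer-confined
  dendritic current domains; it makes "channels of one layer cohere
  with each other and not across the boundary" true by construction.
* **A volume-conducted component**: one spatially uniform, spectrally
  flat (30-100 Hz), amplitude-modulated source whose variance is
  calibrated so that it accounts for a configurable share (default
  0.34) of the gamma-band variance of the average channel.
* **Slow oscillation.** Within non-REM intervals, UP durations are
  lognormal (median 0.45 s) and DOWN durations gamma-distributed (mode
  around 75 ms, floored at 50 ms); each DOWN carries a positive
  delta-band half-sine deflection on a deep-weighted profile, and each
  DOWN-to-UP transition adds a stereotyped dipole template with sinks
  at landmarks b and d and sources at a and e. During DOWN states the
  gamma sources and the broadband channel noise are attenuated
  (network silence). The independent non-REM delta background is kept
  well below the DOWN deflection amplitude — in cortex the largest
  delta waves *are* the slow-oscillation events, and a generator that
  violated this would make the adaptive, spiking-calibrated threshold
  search meaningless.
* **A 3-6 Hz waking rhythm** (center 4.2 Hz) with its largest loading
  around layer 4, present during waking; **volume-conducted theta**
  (6-9 Hz, strongest in REM); and an **EMG-like common component**,
  band-limited to 300-600 Hz and shared identically across channels
  during waking only — this is what the zero-lag correlation proxy
  detects.

Spikes are drawn per unit from a conditional-intensity model on the LFP
time grid: a lognormal base rate (median 3 Hz, layer 5 elevated),
multiplicative state dependence (deep layers fire about 1.6x more in
waking), DOWN-state silencing to 2% (except DOWN-active units, which
invert the pattern), an UP-onset transient (strongest in layer 5),
gamma-phase coupling to the unit's own layer source
(`1 + m cos(phase - preferred)`), and 3-6 Hz phase coupling during
waking. The intensity is rescaled so each unit's expected rate equals
its configured rate exactly; planted excitatory couplings then *inject*
a postsynaptic spike with probability `p` per presynaptic spike at a
lag uniform in 1.5-4 ms (with the base rate debited by the expected
injected rate), so the planted spike-transmission probability is exact
by construction. Inhibitory couplings thin the postsynaptic train in
the same window. Mean waveforms are difference-of-Gaussians templates
whose trough-to-peak latencies are drawn from a two-component mixture
(modes near 0.32 and 0.82 ms), so the 0.55 ms classification boundary
separates the classes by construction; fiber-like and positive
templates are available.

What the generator does **not** emulate: biophysical (conductance or
compartmental) realism, receptive fields, behavior, electrode drift,
spike-sorting errors, or non-stationary rates beyond state switching.
Passing recovery tests on these sessions therefore demonstrates the
correctness and calibration of the analysis code under the stated
statistical structure — not performance on every pathology of real
recordings.

## Brain-state scoring

`compute_scoring_traces()` builds a spectrogram of one scoring channel
(10 s centered windows, 1 s step, truncated at the session edges; 80
log-spaced frequencies 1-100 Hz), z-scores log power per frequency and
takes PC1, sign-oriented so that frames rich in sub-20 Hz power are
positive. The theta ratio is 5-10 Hz over 2-16 Hz power. The EMG proxy
is the mean zero-lag pairwise correlation of 300-600 Hz filtered
signals (cosine filter shoulders 275-625 Hz) over up to 16 evenly
spaced channels per 1 s frame.

`score_states()` places each threshold at the trough between the two
highest modes of a kernel density estimate (Silverman bandwidth) of the
corresponding trace — PC1 for non-REM, then EMG and theta among the
remaining frames for REM — falling back to a fixed quantile with a
warning when a histogram is unimodal. Waking bouts shorter than 7
minutes are merged into the surrounding sleep (relabeled non-REM) and
reported in `merged_wake`; merging rather than unlabeling keeps the
segmentation a partition of scored time.

## DOWN/UP detection

`detect_slow_waves()` uses the coincidence of a delta-band (0.5-8 Hz)
peak and a drop of high-frequency (100-400 Hz) envelope power smoothed
in an 80 ms window, both z-scored within non-REM. Candidate delta peaks
above 0.25 SD are binned by magnitude; the *peak threshold* is the
smallest magnitude bin whose population-spike PETH at the peak falls
below 0.2x the mean rate (the criterion is a parameter). Event timing
comes from the delta trace's window-threshold crossings (the window
threshold is a quarter of the peak threshold, floored at the 0.25 SD
candidate level); the gamma-power drop gates which delta events count,
rather than re-timing them, because the 80 ms power smoothing would
blur boundaries by tens of milliseconds. Events shorter than 40 ms are
discarded. UP states are the complementary intervals within non-REM.

## The laminar map

* `mua_power_profile()`: per-channel 500 Hz-5 kHz power of the wideband
  signal; its peak is landmark **c** (mid layer 5).
* `event_triggered_csd()`: second spatial difference of the
  event-triggered LFP average, `-(V[i-1] - 2 V[i] + V[i+1]) / dz^2`,
  interior channels only, sinks negative. Conductivity is set to 1
  (arbitrary units) and no edge padding is used; the maps are relative.
* `find_landmarks()`: within 0-150 ms after the DOWN-UP transition,
  **b** is the strongest sink above c, **a** the strongest source above
  b, **d** the strongest sink below c, **e** the strongest source below
  d, each located at peak absolute amplitude ("most prominent" is read
  as amplitude, not area). The ordering a < b < c < d < e is enforced;
  violations raise an error carrying the recovered depths.
* `normalize_depth()`: a piecewise-linear warp that is exact at the
  landmarks and has unit slope beyond a and e, so distances outside the
  landmark span are preserved — in particular the estimated pia, 80 um
  above landmark a, maps exactly 80 um above canonical a.

### Coherence clustering

`band_coherence_matrix()` estimates magnitude-squared coherence from
Welch-averaged cross-spectra (Hann windows of 1 s, 50% overlap — long
enough to resolve 30 Hz — averaged per epoch across the given state
intervals) and averages it across 30-100 Hz.

`gradient_descent_cluster()` minimizes the interaction energy
`E_A = -(1/N_A) * sum_{i != j in A} C_ij`, summed over clusters. The
self-coherence diagonal is excluded, since its contribution is a
constant `1/N_A` bias toward large clusters. From a random assignment
into 10 labels, sites are visited in random (seeded) order and moved to
the cluster with the largest normalized-coherence energy gap — but a
move is accepted only when the *total* energy strictly decreases. The
gap formula compares per-site mean coherences and ignores the
renormalization of both clusters, so a positive gap alone neither
guarantees descent nor termination; requiring strict total descent
restores both, and makes the monotone-descent property assertable.
When no single-site move improves, the best strictly improving
whole-cluster merge is applied and site moves resume: single-site moves
alone cannot cross the uphill barrier between two clusters that belong
together, and without merges the greedy search stalls far from the
optimum on unstructured matrices. Cluster count is emergent. The
procedure is restarted (default 50; empty clusters dropped) and the
modal assignment is reported with a consistency score (mean adjusted
Rand index of restarts against the modal solution).

### ICA

`gamma_ica()` band-passes (30-100 Hz), keeps the first 10 principal
components and runs FastICA (logcosh contrast, symmetric decorrelation,
tolerance 1e-4, up to 500 iterations, re-seeded on non-convergence).
Convergence is declared when all components are stable, or when every
component whose logcosh contrast departs from its Gaussian expectation
is stable: the retained subspace usually contains near-Gaussian noise
directions, rotations within which have no fixed point and are
unidentifiable in principle, so their residual wobble (which also
leaks slightly into the other rows through the symmetric
decorrelation) must not block an otherwise converged solution. Components are ranked by explained band variance; loadings
are reported with the maximum-absolute element positive. A component
whose absolute loading has coefficient of variation below 0.1 across
depth is flagged volume-conducted and excluded from the laminar set —
the spatially uniform source is removable precisely because ICA
isolates it as one component with a flat loading.

## Spectral substrate

`cwt_morlet()` implements the complex Morlet transform (omega0 = 6, the
standard default) on log-spaced frequencies by FFT convolution. Phase
convention everywhere: 0 at the oscillation peak, +/-pi at the trough —
so "locked to the trough" reads as a preferred phase near +/-pi.

`modulation_index()` bins the phase of the slow band into 20 bins (18
degrees, common practice for this measure), averages the fast-band
amplitude envelope per bin, normalizes to a distribution and reports
its KL divergence from uniform over `log(n_bins)`, which confines the
index to [0, 1]. Computed KL values below 1e-12 are snapped to an
exact 0 (the divergence is analytically non-negative; floating-point
noise is not allowed to make a zero slightly negative or positive).
Significance comes from 1000 circular time-shift surrogates with
seeded shifts drawn uniformly from [1 s, duration - 1 s]. Time-shift
surrogates assume the rhythm's phase decorrelates over the shift; for
strictly periodic signals they are blind to coupling, which is a
property of the surrogate scheme, not a defect of the estimator.

`spike_phase_coupling()` takes the wavelet phase at spike times over 20
log-spaced scales, reports per-frequency mean resultant length R,
circular mean and Rayleigh p, and defines the preferred frequency as
the largest R among significant (p < 0.05) frequencies. Fewer than 10
spikes flags the result insufficient.

## Unit classification and statistics

* `classify_waveform()` / `classify_units()`: positive-extreme
  waveforms are POSITIVE; among negative ones, units whose normalized
  second-derivative kurtosis is an outlier beyond 5 SD of the
  population are FIBER (a robust median/MAD z is the default — a
  literal mean/SD on a small population lets one extreme unit mask
  itself; `robust = FALSE` restores the literal rule); the rest split
  at 0.55 ms trough-to-peak latency into E (>) and I (<=).
* `optotag()`: mean of the two largest 1 ms bins in the 1-6 ms
  post-pulse window against baseline mean + 8 SD (-100 to 0 ms). A
  silent baseline (SD 0) is flagged degenerate and tags on any
  response spiking.
* `burst_index()`: mean autocorrelogram count in 1.5-13.5 ms over the
  mean in 200-300 ms, 0.5 ms bins, zero-lag excluded. The coarser
  3-10 ms variant that appears in some descriptions of this measure is
  available through the window arguments; the 1.5-13.5 ms form is the
  operational default.
* `up_state_dynamics()`: PETH at 10 ms bins after UP onsets;
  transient/steady ratio = peak rate in 0-200 ms over mean rate in
  100-200 ms (the windows overlap; the definition is implemented
  literally, not reinterpreted), and DOWN-UP latency = median
  first-spike time within 0-500 ms, transitions without spikes
  excluded.
* `detect_down_active()`: per-event DOWN vs UP rates compared by
  one-sided Wilcoxon rank-sum; flagged when the median DOWN rate
  exceeds the median UP rate at p < alpha.
* `cluster_by_ic_coupling()`: k-means under the cityblock (L1) metric —
  Lloyd iterations with coordinate-wise medians, multiple seeded
  starts — on the units x ICs matrix of mean resultant lengths at each
  unit's preferred gamma frequency (0 when no frequency is Rayleigh-
  significant; the scalar entering the matrix is a design choice, R at
  the preferred frequency). K is chosen over 2-12 by the mean
  silhouette width under the manhattan distance; identical profiles
  short-circuit to a flagged single cluster.

## Connectivity

Cross-correlograms use 0.5 ms bins with edges at multiples of the bin
width over +/-50 ms, so the detection window (+1.5, +4] ms is exactly
the five bins centered 1.75-3.75 ms — the half-open convention is fixed
here because the window endpoints are otherwise bin-ambiguous.
Self-pairs are excluded for identical trains; distinct units count all
pairs. The baseline predictor convolves the counts with a unit-area
Gaussian (SD 7 ms, plain, not hollowed; a hollowed variant would be a
sensitivity analysis, not the default) with reflected edges.
`poisson_bounds()` computes the 99.9999th-percentile thresholds by
exact pmf summation with the multiplicative recurrence — no normal
approximation; note that at lambda = 1 the upper bound is 9, since the
CDF at 8 is 0.99999887, just below the percentile. Significance is
strict (`count > k_hi`, `count < k_lo`, the lower tail at the same
1e-6 level), keeping the guaranteed per-bin tail at 1e-6, and an edge
requires two consecutive significant bins in the window. Spike
transmission probability is the basic excess form, `sum(count -
predictor)` over the window divided by the presynaptic spike count
(negative for inhibition), reported with the peak-to-baseline ratio;
the Gaussian predictor absorbs part of the peak's own mass, which
biases the basic estimate low by roughly 15% at these window and
kernel widths — a known property of the convolution baseline, within
the accuracy band validated by the tests. A corrected estimator with
peak exclusion is a documented extension point, not implemented here.
State-resolved transmission recomputes CCG and predictor per state
(spikes restricted to state intervals, so lags never span boundaries;
edges need 500 presynaptic spikes per state) and compares paired edges
with a Wilcoxon signed-rank test. Detecting inhibitory troughs at the
1e-6 level requires per-bin expected counts far above what 10-minute,
5 Hz trains provide; this matches the strong under-sampling of
inhibitory edges inherent to the method.

## Problem sizes in the validation suite

The test suite and the acceptance script regenerate everything they
measure. The sizes are chosen so every claim is tested at useful power
on a single CPU: the laminar session is 600 s of 64 channels (300 s
non-REM, 300 s waking, 10 s of wideband for the MUA landmark); the
state-scoring session is 30 min of 16 channels and 60 units, one of
them DOWN-state-active — enough units that the DOWN-active cell stays
a small minority and the population-silence calibration of the
slow-wave threshold remains meaningful; the connectivity
network is 20 units over 600 s with planted transmissions 0.05-0.2;
the false-positive bound uses 10,000 independent 200 s Poisson pairs;
gradient-descent optimality is checked against exhaustive enumeration
of all 203 partitions of 6 sites on several hundred random matrices.
Rate-calibration claims (burst index, Rayleigh rate, DOWN-active false
positives) use a few hundred simulated trains each; at those counts a
nominal 5% rate is measured with a standard error near 1 percentage
point, which is the resolution the assertions use.

## Known limitations

Landmark search assumes the canonical sink/source polarity pattern of
the DOWN-UP transition; a probe missing the deep layers will fail the
ordering check by design. The slow-oscillation dipole geometry is not
quantitatively constrained by physiology here — sink/source depths are
free generator parameters. The coherence estimator averages per epoch;
concatenation across epochs would mix boundary transients. The
spike-IC coupling matrix uses R at the preferred frequency; z-scored
alternatives would weight high-count units differently. Optotagging
and fiber rules are threshold heuristics with degenerate-input flags
rather than probabilistic models.
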
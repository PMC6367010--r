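# lamprobe

Laminar analysis of multichannel extracellular recordings from layered
cortex, for electrophysiologists working with single-shank linear
probes (e.g. 64 sites at 20 µm pitch spanning all cortical layers).
From a continuous voltage file plus sorted spikes, the package
reconstructs:

- **Brain states** (WAKE / non-REM / REM) from a spectrogram PC1, a
  theta ratio and an intracranial EMG proxy, with thresholds at the
  trough between histogram modes and a 7-minute minimum for waking
  bouts.
- **DOWN/UP states** of the non-REM slow oscillation from the
  coincidence of a delta-band peak and a high-frequency power drop,
  with an adaptive threshold calibrated on population spiking and a
  40 ms minimum duration.
- **A laminar map**: landmark *c* at the 500 Hz–5 kHz (MUA) power peak
  (mid layer 5); landmarks *a, b, d, e* from the sinks and sources of
  the DOWN-UP transition current source density,
  CSDᵢ = −(Vᵢ₋₁ − 2Vᵢ + Vᵢ₊₁)/Δz²; a piecewise-linear warp onto
  canonical depths that is exact at landmarks (pia = 80 µm above *a*).
- **Gamma-band layer structure**: pairwise 30–100 Hz coherence across
  all sites, clustered by an interaction-energy gradient descent
  (E_A = −N_A⁻¹ Σ_{i≠j∈A} C_ij, emergent cluster count, seeded
  restarts with a consistency score), and an ICA decomposition of the
  band-passed LFP (10 PCs → FastICA) whose near-flat component
  captures volume conduction.
- **Coupling statistics**: Morlet wavelet spectra (ω₀ = 6), the
  phase-amplitude modulation index MI = KL(P‖U)/log N with circular
  time-shift surrogates, and spike-phase coupling (mean resultant
  length R, Rayleigh test, preferred frequency).
- **Unit classes and statistics**: waveform classes by trough-to-peak
  latency (E > 0.55 ms ≥ I) with positive-spike and fiber rules,
  optogenetic tagging (1–6 ms response > baseline + 8 SD), burst index
  (ACG 1.5–13.5 ms / 200–300 ms), UP-state transient/steady ratio and
  first-spike latency, DOWN-state-active detection (rank-sum), and
  k-means (cityblock metric, silhouette-selected K) on spike–IC
  coupling profiles.
- **Monosynaptic connectivity**: ±50 ms cross-correlograms at 0.5 ms
  bins, a 7 ms-SD Gaussian-convolved baseline predictor, exact Poisson
  99.9999-percentile bounds, the two-consecutive-bin rule in the
  (+1.5, +4] ms window, spike transmission probability
  (Σ(count − predictor)/n_pre) and its wake vs non-REM comparison by
  signed-rank test.

A synthetic-session generator (`simulate_session()`) produces
ground-truth-annotated recordings — layer-confined bursty gamma
sources plus a volume-conducted term, slow-oscillation DOWN/UP
structure with a transition dipole, a 3–6 Hz waking rhythm, lognormal
unit rates with planted phase coupling and planted monosynaptic
edges — so that every stage is validated by recovery, not by fiat.

## Worked example

```r
library(lamprobe)

# a 10-minute, 64-channel annotated session (300 s non-REM + 300 s wake)
s <- simulate_session(sim_config(
  duration_s = 600, seed = 101, n_channels = 64, n_units = 20,
  wideband_s = 10,
  state_schedule = data.frame(start = c(0, 300), end = c(300, 600),
                              label = c("NREM", "WAKE"))))

wake <- state_intervals(s$truth$state_intervals, "WAKE")
C  <- band_coherence_matrix(s$lfp, band = c(30, 100), intervals = wake)
cl <- gradient_descent_cluster(C, n_restarts = 20, seed = 1)
cl
#> <coherence_clustering> 6 clusters, energy -53.9958, consistency 0.987

mua <- mua_power_profile(s$wideband)
trans <- with(s$truth$downup_intervals, end[label == "DOWN"])
lmk <- find_landmarks(mua, event_triggered_csd(s$lfp, trans, c(0.05, 0.2)))
round(unclass(lmk))
#>    a    b    c    d    e
#>  100  380  680  820 1100
```

The six coherence clusters recover the six planted layers (the
adjusted Rand index against the ground truth is 1 here), and the five
landmarks land within one channel (20 µm) of their planted depths:
*a* and *e* are the superficial/deep CSD sources of the DOWN-UP
transition, *b* and *d* its sinks, and *c* the MUA power peak.

Connectivity on a planted network:

```r
edges <- data.frame(pre = 1:2, post = 3:4, sign = "E", p = c(0.1, 0.2))
net <- simulate_session(sim_config(duration_s = 600, seed = 103,
  n_channels = 16, n_units = 8, edges = edges,
  units_par = list(rate_meanlog = log(5), rate_sdlog = 0.3)))
detect_connections(net$spikes)
#>   pre post sign transmission peak_to_baseline ambiguous
#> 1  u1   u3    E    0.0822877         3.681835     FALSE
#> 2  u2   u4    E    0.1704341         4.764211     FALSE
```

Both planted excitatory edges are detected with transmission
probabilities near their planted values (0.1 and 0.2); the basic
excess-count estimator reads slightly low because the Gaussian
baseline predictor absorbs part of the monosynaptic peak.

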
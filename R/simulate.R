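# Synthetic laminar sessions with ground-truth annotations.
#
# The generator emulates the statistical structure the downstream analyses
# assume: depth-localized gamma sources plus a spatially uniform
# volume-conducted term, a non-REM slow oscillation with alternating
# DOWN/UP states and a stereotyped DOWN-UP transition dipole pattern, a
# 3-6 Hz waking rhythm strongest around layer 4, volume-conducted theta,
# an EMG-like common fast component during waking, lognormal unit rates,
# phase-coupled spiking, bimodal trough-to-peak waveform latencies and
# planted monosynaptic couplings realized by spike injection/thinning.

#' Simulation configuration
#'
#' Defaults mirror a 64-site single-shank recording (20 um pitch, wideband
#' 20 kHz, LFP 1.25 kHz). All rates in Hz, durations in seconds, depths in
#' micrometers. The seed fully determines the output.
#'
#' @param duration_s session length (>= 60 s downstream).
#' @param seed master seed; stage seeds are derived from it.
#' @param n_channels,pitch_um,fs_wideband,fs_lfp probe geometry and rates.
#' @param n_units number of simulated units.
#' @param edges data.frame of planted monosynaptic couplings with columns
#'   `pre`, `post` (unit indices), `sign` ("E" or "I") and `p`
#'   (transmission probability; for "I" the thinning fraction).
#' @param n_down_active number of DOWN-state-active deep units.
#' @param uniform_share share of gamma-band variance contributed by the
#'   spatially uniform volume-conducted source (default 0.34).
#' @param state_schedule optional data.frame (start, end, label) overriding
#'   the default WAKE/NREM/REM cycle.
#' @param n_opto,n_visual numbers of optogenetic (10 ms) and visual
#'   (400 ms) light pulses.
#' @param opto_units indices of units activated by optogenetic pulses.
#' @param wideband_s length of the wideband (20 kHz) segment to synthesize
#'   from the start of the session (0 = LFP only).
#' @param ... overrides for advanced fields (see Details in the package
#'   vignette): `gamma` (source band, center frequencies, loading centers
#'   and widths), `slow` (DOWN/UP duration distributions, deflection
#'   amplitudes; `slow$downup_intervals` plants explicit events),
#'   `rhythm36`, `theta`, `emg`, `units_par` (rate lognormal, coupling
#'   strengths, class fractions), `noise_uV`, `landmarks_um`,
#'   `keep_phases` (retain the gamma source phases in the ground truth).
#' @return object of class `sim_config`.
#' @export
sim_config <- function(duration_s = 600, seed = 1, n_channels = 64,
                       pitch_um = 20, fs_wideband = 20000, fs_lfp = 1250,
                       n_units = 30, edges = NULL, n_down_active = 0,
                       uniform_share = 0.34, state_schedule = NULL,
                       n_opto = 0, n_visual = 0, opto_units = integer(),
                       wideband_s = 0, ...) {
  if (fs_wideband %% fs_lfp != 0) {
    stop("configuration error: fs_wideband must be an integer multiple ",
         "of fs_lfp")
  }
  cfg <- list(
    duration_s = duration_s, seed = seed, n_channels = n_channels,
    pitch_um = pitch_um, fs_wideband = fs_wideband, fs_lfp = fs_lfp,
    n_units = n_units,
    edges = if (is.null(edges))
      data.frame(pre = integer(), post = integer(),
                 sign = character(), p = numeric()) else edges,
    n_down_active = n_down_active, uniform_share = uniform_share,
    state_schedule = state_schedule, n_opto = n_opto, n_visual = n_visual,
    opto_units = opto_units, wideband_s = wideband_s,
    # layer boundaries (um from top site) for layers 1..6
    layer_bounds_um = c(0, 90, 230, 390, 530, 830),
    landmarks_um = c(a = 100, b = 390, c = 680, d = 830, e = 1100),
    gamma = list(band = c(30, 100),
                 center_freq = c(38, 44, 52, 62, 74, 88),
                 loading_center_um = c(45, 160, 310, 460, 680, 1045),
                 loading_sigma_um = c(45, 70, 80, 70, 150, 215),
                 loading_power = 8, sd_uV = 25, burst_sd = 0.6),
    slow = list(down_shape = 4, down_scale = 0.025, down_min_s = 0.05,
                up_meanlog = log(0.45), up_sdlog = 0.5,
                delta_bump_uV = 190, delta_bg_uV = 45,
                transition_uV = 90, transition_dur_s = 0.12,
                down_gamma_atten = 0.25),
    rhythm36 = list(band = c(3, 6), center = 4.2, amp_uV = 45,
                    loading_center_um = 430, loading_sigma_um = 160),
    theta = list(band = c(6, 9),
                 amp_uV = c(WAKE = 18, NREM = 4, REM = 45)),
    emg = list(band = c(300, 600),
               amp_uV = c(WAKE = 9, NREM = 0.4, REM = 0.4)),
    units_par = list(rate_meanlog = log(3), rate_sdlog = 0.7,
                     l5_rate_mult = 1.6, frac_I = 0.25,
                     gamma_coupling = 0.5, coupling36 = 0.4,
                     wake_nrem_ratio_deep = 1.6, down_silence = 0.02,
                     transient_amp = c(0, 0.5, 0.5, 1, 3, 1),
                     opto_p = 0.8, opto_latency_ms = 3),
    noise_uV = 10)
  # depth-valued defaults describe the 64-site x 20 um probe; rescale
  # them to the configured probe span
  ratio <- ((n_channels - 1) * pitch_um) / 1260
  if (abs(ratio - 1) > 1e-9) {
    cfg$layer_bounds_um <- cfg$layer_bounds_um * ratio
    cfg$landmarks_um <- cfg$landmarks_um * ratio
    cfg$gamma$loading_center_um <- cfg$gamma$loading_center_um * ratio
    cfg$gamma$loading_sigma_um <- cfg$gamma$loading_sigma_um * ratio
    cfg$rhythm36$loading_center_um <- cfg$rhythm36$loading_center_um * ratio
    cfg$rhythm36$loading_sigma_um <- cfg$rhythm36$loading_sigma_um * ratio
  }
  dots <- list(...)
  for (nm in names(dots)) {
    if (is.list(cfg[[nm]]) && is.list(dots[[nm]])) {
      cfg[[nm]][names(dots[[nm]])] <- dots[[nm]]
    } else cfg[[nm]] <- dots[[nm]]
  }
  structure(cfg, class = "sim_config")
}

# ---- internal building blocks ----------------------------------------------

# smooth lowpassed standard-normal process
smooth_noise <- function(n, fs, f_cut, seed_expr = NULL) {
  x <- stats::rnorm(n)
  y <- fft_bandpass(x, fs, lo = NULL, hi = f_cut, shoulder = f_cut / 2)
  y / stats::sd(y)
}

# band-limited bursty oscillation with known instantaneous phase.
# Returns list(signal, theta) where signal = A(t) * cos(theta), unit sd.
bursty_oscillation <- function(n, fs, f_center, f_jitter, burst_sd) {
  f_inst <- f_center * (1 + 0.06 * smooth_noise(n, fs, f_jitter))
  theta <- cumsum(2 * pi * f_inst / fs)
  A <- exp(burst_sd * smooth_noise(n, fs, 2))
  s <- A * cos(theta)
  list(signal = s / stats::sd(s), theta = theta %% (2 * pi))
}

# generalized-Gaussian depth loading; power 2 = Gaussian, higher powers
# give a flat-top profile confined to a layer with fast falloff
gaussian_loading <- function(depth_um, center_um, sigma_um, power = 2) {
  l <- exp(-0.5 * ((depth_um - center_um) / sigma_um)^power)
  l / max(l)
}

# layer-confined loading: full drive inside [lo, hi], logistic falloff of
# width edge_um at the boundaries (crossover narrower than channel pitch)
layer_loading <- function(depth_um, lo, hi, edge_um = 8) {
  l <- stats::plogis((depth_um - lo) / edge_um) *
    stats::plogis((hi - depth_um) / edge_um)
  l / max(l)
}

# Alternating UP/DOWN tiling of one NREM interval; first and last are UP.
gen_downup <- function(start, end, slow) {
  t <- start
  rows <- list(); k <- 0L
  label <- "UP"
  while (t < end) {
    dur <- if (label == "UP") {
      stats::rlnorm(1, slow$up_meanlog, slow$up_sdlog)
    } else {
      max(stats::rgamma(1, shape = slow$down_shape,
                        scale = slow$down_scale), slow$down_min_s)
    }
    hi <- min(t + dur, end)
    k <- k + 1L
    rows[[k]] <- data.frame(start = t, end = hi, label = label)
    t <- hi
    label <- if (label == "UP") "DOWN" else "UP"
  }
  df <- do.call(rbind, rows)
  if (df$label[nrow(df)] == "DOWN") df <- df[-nrow(df), , drop = FALSE]
  df
}

default_schedule <- function(duration_s) {
  block <- data.frame(label = c("WAKE", "NREM", "REM"),
                      len = c(480, 540, 120))
  rows <- list(); t <- 0; k <- 0L; i <- 1L
  while (t < duration_s) {
    len <- min(block$len[i], duration_s - t)
    k <- k + 1L
    rows[[k]] <- data.frame(start = t, end = t + len,
                            label = block$label[i])
    t <- t + len
    i <- i %% 3L + 1L
  }
  do.call(rbind, rows)
}

# mean parametric spike waveform: difference of Gaussians (trough + peak);
# fs in Hz
make_waveform <- function(class, tp_ms, fs, n_samp = 64L) {
  t_ms <- (seq_len(n_samp) - 20) / fs * 1000
  stopifnot(fs >= 10000)
  w <- -exp(-t_ms^2 / (2 * 0.1^2)) +
    0.4 * exp(-(t_ms - tp_ms)^2 / (2 * 0.28^2))
  if (class == "POSITIVE") w <- -w
  if (class == "FIBER") {
    w <- -exp(-t_ms^2 / (2 * 0.035^2)) +
      0.6 * exp(-(t_ms - 0.12)^2 / (2 * 0.03^2)) -
      0.25 * exp(-(t_ms - 0.25)^2 / (2 * 0.03^2))
  }
  100 * w
}

#' Simulate laminar gamma-band sources on a linear probe
#'
#' Plants `n_sources` band-limited (30-100 Hz) bursty sources with
#' Gaussian depth loadings (unit maximum) plus, optionally, a spatially
#' uniform volume-conducted source whose share of gamma-band variance on
#' the average channel equals `uniform_share`.
#'
#' @param cfg a [sim_config()].
#' @param n_sources number of laminar sources (>= 1). Six sources get
#'   one layer-confined loading per layer; other counts get evenly
#'   spaced flat-top loadings tiling the probe span.
#' @param uniform_share variance share of the uniform source (0 disables).
#' @param noise_uV white channel noise standard deviation.
#' @param centers_um optional explicit loading centers (one per source).
#' @param duration_s,seed optional overrides of `cfg`.
#' @return list: `rec` ([probe_recording()]), `loadings`
#'   (channels x sources, unit max per source), `uniform_signal`,
#'   `source_signals` (time x sources), `theta` (instantaneous phases).
#' @export
simulate_laminar_gamma <- function(cfg = sim_config(), n_sources = 6,
                                   uniform_share = cfg$uniform_share,
                                   noise_uV = cfg$noise_uV,
                                   centers_um = NULL,
                                   duration_s = cfg$duration_s,
                                   seed = cfg$seed) {
  if (!is.null(centers_um) && anyDuplicated(centers_um)) {
    warning("overlapping identical loading centers; generating anyway")
  }
  with_seed(derive_seed(seed, "laminar_gamma"), {
    fs <- cfg$fs_lfp
    n_t <- round(duration_s * fs)
    depth <- (seq_len(cfg$n_channels) - 1) * cfg$pitch_um
    span <- max(depth) - min(depth)
    centers <- min(depth) + span * (seq_len(n_sources) - 0.5) / n_sources
    if (!is.null(centers_um)) centers <- rep_len(centers_um, n_sources)
    fc <- rep_len(cfg$gamma$center_freq, n_sources)
    if (n_sources == length(cfg$layer_bounds_um)) {
      centers <- cfg$gamma$loading_center_um
      # one source per layer, confined to the layer with a sharp edge
      bounds <- c(cfg$layer_bounds_um, max(depth) + cfg$pitch_um)
      loadings <- vapply(seq_len(n_sources), function(k)
        layer_loading(depth, bounds[k], bounds[k + 1]),
        numeric(length(depth)))
    } else {
      # generic source count: evenly spaced flat-top loadings that tile
      # the probe span
      sig <- span / (1.2 * n_sources)
      loadings <- vapply(seq_len(n_sources), function(k)
        gaussian_loading(depth, centers[k], sig,
                         power = cfg$gamma$loading_power),
        numeric(length(depth)))
    }
    src <- matrix(0, n_t, n_sources)
    theta <- matrix(0, n_t, n_sources)
    for (k in seq_len(n_sources)) {
      o <- bursty_oscillation(n_t, fs, fc[k], 1, cfg$gamma$burst_sd)
      src[, k] <- o$signal
      theta[, k] <- o$theta
    }
    sd_uV <- cfg$gamma$sd_uV
    X <- src %*% t(loadings) * sd_uV
    uniform_signal <- NULL
    if (uniform_share > 0) {
      # per-channel laminar gamma variance, averaged across channels
      v_lam <- mean(rowSums(loadings^2)) * sd_uV^2
      u_sd <- sqrt(uniform_share / (1 - uniform_share) * v_lam)
      # spectrally flat across the band, amplitude-modulated (bursty)
      u <- fft_bandpass(stats::rnorm(n_t), fs, cfg$gamma$band[1],
                        cfg$gamma$band[2])
      u <- u * exp(cfg$gamma$burst_sd * smooth_noise(n_t, fs, 2))
      u <- u / stats::sd(u) * u_sd
      uniform_signal <- u
      X <- X + u
    }
    if (noise_uV > 0) {
      X <- X + matrix(stats::rnorm(length(X), sd = noise_uV), nrow(X))
    }
    list(rec = probe_recording(X, fs, depth),
         loadings = loadings, uniform_signal = uniform_signal,
         source_signals = src, theta = theta, center_freq = fc)
  })
}

#' Simulate a full annotated session
#'
#' Generates LFP (and optionally an initial wideband segment), sorted
#' spikes with mean waveforms, light-pulse events and the ground truth
#' needed to validate every downstream stage. During non-REM DOWN states,
#' spiking of all non-DOWN-active units is suppressed to a small fraction
#' of the UP rate and a delta-band deflection with a stereotyped DOWN-UP
#' transition dipole is added to the LFP. Spikes of coupled units follow a
#' conditional-intensity model in which each presynaptic spike adds (with
#' probability `p`) one postsynaptic spike at a lag uniform in 1.5-4 ms,
#' so the expected excess count per presynaptic spike equals `p`.
#'
#' @param cfg a [sim_config()].
#' @return object of class `sim_session`: `lfp` ([probe_recording()]),
#'   `wideband` (or `NULL`), `spikes` ([spike_dataset()]), `events`
#'   ([event_table()]), `truth` (class `ground_truth`).
#' @export
simulate_session <- function(cfg = sim_config()) {
  stopifnot(inherits(cfg, "sim_config"))
  if (cfg$duration_s < 60) stop("duration must be at least 60 s")
  fs <- cfg$fs_lfp
  n_t <- round(cfg$duration_s * fs)
  depth <- (seq_len(cfg$n_channels) - 1) * cfg$pitch_um
  layer_of_channel <- findInterval(depth, cfg$layer_bounds_um)
  lm <- cfg$landmarks_um

  states <- if (is.null(cfg$state_schedule)) {
    default_schedule(cfg$duration_s)
  } else cfg$state_schedule
  nrem <- as_intervals(states[states$label == "NREM", 1:2])
  downup <- if (!is.null(cfg$slow$downup_intervals)) {
    cfg$slow$downup_intervals    # explicit override (planted events)
  } else {
    with_seed(derive_seed(cfg$seed, "downup"), {
      if (nrow(nrem)) do.call(rbind, lapply(seq_len(nrow(nrem)),
        function(r) gen_downup(nrem[r, 1], nrem[r, 2], cfg$slow)))
      else data.frame(start = numeric(), end = numeric(),
                      label = character())
    })
  }
  down_iv <- as_intervals(downup[downup$label == "DOWN", 1:2])
  up_iv <- as_intervals(downup[downup$label == "UP", 1:2])

  tgrid <- (seq_len(n_t) - 0.5) / fs
  in_state <- function(lbl)
    iv_contains(as_intervals(states[states$label == lbl, 1:2]), tgrid)
  is_wake <- in_state("WAKE"); is_nrem <- in_state("NREM")
  is_rem <- in_state("REM")
  is_down <- iv_contains(down_iv, tgrid)

  # ---- LFP assembly ---------------------------------------------------------
  gam <- simulate_laminar_gamma(cfg, n_sources = 6,
                                uniform_share = cfg$uniform_share,
                                noise_uV = 0, duration_s = cfg$duration_s,
                                seed = cfg$seed)
  gamma_atten <- ifelse(is_down, cfg$slow$down_gamma_atten, 1)
  X <- gam$rec$samples * gamma_atten
  gam$rec <- NULL
  gam$source_signals <- NULL

  lfp_extra <- with_seed(derive_seed(cfg$seed, "lfp_extra"), {
    E <- X
    # non-REM delta background, deeper channels stronger
    delta_bg <- fft_bandpass(stats::rnorm(n_t), fs, 0.5, 3)
    delta_bg <- delta_bg / stats::sd(delta_bg) *
      (0.2 + 0.8 * is_nrem) * cfg$slow$delta_bg_uV
    prof_deep <- 0.3 + 0.7 * gaussian_loading(depth, 0.7 * max(depth),
                                              0.3 * max(depth))
    E <- E + outer(delta_bg, prof_deep)
    # DOWN-state delta deflection (positive bump on deep channels)
    bump <- numeric(n_t)
    if (nrow(down_iv)) {
      for (r in seq_len(nrow(down_iv))) {
        i0 <- max(1L, floor(down_iv[r, 1] * fs) + 1L)
        i1 <- min(n_t, ceiling(down_iv[r, 2] * fs))
        if (i1 > i0) {
          bump[i0:i1] <- sin(pi * seq(0, 1, length.out = i1 - i0 + 1))
        }
      }
    }
    E <- E + outer(bump * cfg$slow$delta_bump_uV, prof_deep)
    # DOWN-UP transition dipole template (sinks at b,d; sources at a,e)
    trans_t <- down_iv[, 2]
    if (length(trans_t)) {
      n_h <- round(cfg$slow$transition_dur_s * fs)
      h <- sin(pi * seq_len(n_h) / n_h)
      prof <- cfg$slow$transition_uV * (
        gaussian_loading(depth, lm["a"], 40) -
          gaussian_loading(depth, lm["b"], 40) -
          gaussian_loading(depth, lm["d"], 40) +
          gaussian_loading(depth, lm["e"], 40))
      for (tt in trans_t) {
        i0 <- floor(tt * fs) + 1L
        idx <- i0:min(i0 + n_h - 1L, n_t)
        E[idx, ] <- E[idx, ] + outer(h[seq_along(idx)], prof)
      }
    }
    # 3-6 Hz waking rhythm, strongest around layer 4
    r36 <- bursty_oscillation(n_t, fs, cfg$rhythm36$center, 0.5, 0.4)
    amp36 <- cfg$rhythm36$amp_uV * is_wake
    prof36 <- 0.35 + 0.65 * gaussian_loading(depth,
      cfg$rhythm36$loading_center_um, cfg$rhythm36$loading_sigma_um)
    E <- E + outer(r36$signal * amp36, prof36)
    # volume-conducted theta
    th <- bursty_oscillation(n_t, fs, mean(cfg$theta$band), 0.5, 0.3)
    amp_th <- cfg$theta$amp_uV["WAKE"] * is_wake +
      cfg$theta$amp_uV["NREM"] * is_nrem +
      cfg$theta$amp_uV["REM"] * is_rem
    E <- E + outer(th$signal * amp_th, rep(1, cfg$n_channels))
    # EMG-like common fast component during waking
    emg <- fft_bandpass(stats::rnorm(n_t), fs, cfg$emg$band[1],
                        min(cfg$emg$band[2], 0.98 * fs / 2), 25)
    emg <- emg / stats::sd(emg)
    amp_emg <- cfg$emg$amp_uV["WAKE"] * is_wake +
      cfg$emg$amp_uV["NREM"] * is_nrem + cfg$emg$amp_uV["REM"] * is_rem
    E <- E + outer(emg * amp_emg, rep(1, cfg$n_channels))
    # independent channel noise, attenuated during DOWN (network silence)
    noise_scale <- ifelse(is_down, 0.3, 1) * cfg$noise_uV
    for (ch in seq_len(cfg$n_channels)) {
      E[, ch] <- E[, ch] + stats::rnorm(n_t) * noise_scale
    }
    list(E = E, theta36 = r36$theta)
  })
  X <- lfp_extra$E
  theta36 <- lfp_extra$theta36
  lfp_extra <- NULL

  # ---- events ---------------------------------------------------------------
  events <- with_seed(derive_seed(cfg$seed, "events"), {
    ev <- event_table()
    if (cfg$n_visual > 0) {
      t0 <- seq(5, by = 2, length.out = cfg$n_visual)
      t0 <- t0[t0 < cfg$duration_s - 1]
      ev <- rbind(ev, event_table(t0, "LIGHT_VISUAL", 0.4, 1))
    }
    if (cfg$n_opto > 0) {
      t0 <- seq(3.5, by = 1, length.out = cfg$n_opto)
      t0 <- t0[t0 < cfg$duration_s - 1]
      ev <- rbind(ev, event_table(t0, "LIGHT_OPTO", 0.01, 1))
    }
    ev <- ev[order(ev$time_s), , drop = FALSE]
    class(ev) <- c("event_table", "data.frame")
    ev
  })
  vis_t <- events$time_s[events$type == "LIGHT_VISUAL"]
  if (length(vis_t)) {
    n_h <- round(0.08 * fs)
    h <- sin(pi * seq_len(n_h) / n_h)
    prof <- cfg$slow$transition_uV * (
      gaussian_loading(depth, lm["a"], 40) -
        gaussian_loading(depth, lm["b"] - 40, 40) -
        gaussian_loading(depth, lm["d"], 40) +
        gaussian_loading(depth, lm["e"], 40))
    for (tt in vis_t + 0.04) {
      i0 <- floor(tt * fs) + 1L
      idx <- i0:min(i0 + n_h - 1L, n_t)
      X[idx, ] <- X[idx, ] + outer(h[seq_along(idx)], prof)
    }
  }

  lfp <- probe_recording(X, fs, depth)

  # ---- units ----------------------------------------------------------------
  up <- cfg$units_par
  unit_table <- with_seed(derive_seed(cfg$seed, "unit_table"), {
    layer_w <- c(0.02, 0.20, 0.18, 0.15, 0.30, 0.15)
    layer <- sample(1:6, cfg$n_units, replace = TRUE, prob = layer_w)
    lb <- c(cfg$layer_bounds_um, max(depth))
    d_u <- stats::runif(cfg$n_units, lb[layer], lb[layer + 1])
    cls <- ifelse(stats::runif(cfg$n_units) < up$frac_I, "I", "E")
    if (cfg$n_down_active > 0) {
      da <- order(d_u, decreasing = TRUE)[seq_len(cfg$n_down_active)]
      cls[da] <- "DOWN_ACTIVE"
      layer[da] <- 6L
      lo6 <- cfg$layer_bounds_um[6]
      d_u[da] <- stats::runif(cfg$n_down_active,
                              lo6 + 0.3 * (max(depth) - lo6), max(depth))
    }
    # presynaptic units of planted edges get the matching true class
    if (nrow(cfg$edges)) {
      for (r in seq_len(nrow(cfg$edges))) {
        u <- cfg$edges$pre[r]
        if (cls[u] != "DOWN_ACTIVE") cls[u] <- cfg$edges$sign[r]
      }
    }
    rate <- stats::rlnorm(cfg$n_units, up$rate_meanlog, up$rate_sdlog)
    rate <- pmin(rate * ifelse(layer == 5, up$l5_rate_mult, 1), 25)
    rate <- pmax(rate, 0.5)
    tp <- ifelse(cls == "I", stats::rnorm(cfg$n_units, 0.32, 0.04),
                 stats::rnorm(cfg$n_units, 0.82, 0.09))
    tp <- pmax(tp, 0.15)
    data.frame(
      unit = paste0("u", seq_len(cfg$n_units)), class = cls,
      layer = layer, depth_um = d_u,
      peak_channel = vapply(d_u, function(d) which.min(abs(depth - d)), 0L),
      rate_hz = rate, tp_ms = tp,
      coupling = up$gamma_coupling,
      pref_phase = stats::runif(cfg$n_units, -pi, pi),
      coupling36 = up$coupling36,
      pref_phase36 = stats::rnorm(cfg$n_units, pi, 0.3),
      wake_mult = ifelse(layer >= 5, up$wake_nrem_ratio_deep, 1))
  })

  edges <- cfg$edges
  opto_t <- events$time_s[events$type == "LIGHT_OPTO"]
  trans_t <- down_iv[, 2]

  spikes_list <- with_seed(derive_seed(cfg$seed, "spikes"), {
    # expected injected rate per post unit, to keep configured rates exact
    inj_rate <- numeric(cfg$n_units)
    if (nrow(edges)) {
      for (r in seq_len(nrow(edges))) {
        if (edges$sign[r] == "E") {
          inj_rate[edges$post[r]] <- inj_rate[edges$post[r]] +
            edges$p[r] * unit_table$rate_hz[edges$pre[r]]
        }
      }
    }
    if (length(opto_t) && length(cfg$opto_units)) {
      inj_rate[cfg$opto_units] <- inj_rate[cfg$opto_units] +
        up$opto_p * length(opto_t) / cfg$duration_s
    }
    trans_mult <- rep(1, n_t)
    if (length(trans_t)) {
      # shared UP-onset transient envelope, scaled per unit below
      n_h <- round(0.15 * fs)
      kern <- exp(-seq(0, by = 1 / fs, length.out = n_h) / 0.05)
      for (tt in trans_t) {
        i0 <- floor(tt * fs) + 1L
        idx <- i0:min(i0 + n_h - 1L, n_t)
        trans_mult[idx] <- pmax(trans_mult[idx], 1 + kern[seq_along(idx)])
      }
    }
    trains <- vector("list", cfg$n_units)
    for (u in seq_len(cfg$n_units)) {
      info <- unit_table[u, ]
      lam <- rep(1, n_t)
      lam <- lam * ifelse(is_wake, info$wake_mult, 1)
      if (info$class == "DOWN_ACTIVE") {
        lam <- lam * ifelse(is_down, 8, ifelse(is_nrem & !is_down, 0.6, 1))
      } else {
        lam <- lam * ifelse(is_down, up$down_silence, 1)
        ta <- up$transient_amp[info$layer]
        if (ta > 0) lam <- lam * (1 + ta * (trans_mult - 1))
      }
      lam <- lam * (1 + info$coupling *
                      cos(gam$theta[, info$layer] - info$pref_phase))
      lam <- lam * (1 + info$coupling36 * is_wake *
                      cos(theta36 - info$pref_phase36))
      target <- max(info$rate_hz - inj_rate[u], 0.2)
      lam <- lam * (target / mean(lam))
      p_bin <- pmin(lam / fs, 0.5)
      hit <- which(stats::runif(n_t) < p_bin)
      trains[[u]] <- (hit - stats::runif(length(hit))) / fs
    }
    # planted monosynaptic couplings: injection (E) / thinning (I)
    if (nrow(edges)) {
      for (r in seq_len(nrow(edges))) {
        pre <- trains[[edges$pre[r]]]
        post <- trains[[edges$post[r]]]
        if (edges$sign[r] == "E") {
          sel <- pre[stats::runif(length(pre)) < edges$p[r]]
          add <- sel + stats::runif(length(sel), 0.0015, 0.004)
          post <- sort(c(post, add[add < cfg$duration_s]))
        } else {
          drop <- logical(length(post))
          lo <- findInterval(pre + 0.0015, post)
          hi <- findInterval(pre + 0.004, post)
          for (i in which(hi > lo)) {
            cand <- (lo[i] + 1L):hi[i]
            drop[cand] <- drop[cand] |
              (stats::runif(length(cand)) < edges$p[r])
          }
          post <- post[!drop]
        }
        trains[[edges$post[r]]] <- post
      }
    }
    # optogenetic responses
    if (length(opto_t) && length(cfg$opto_units)) {
      for (u in cfg$opto_units) {
        sel <- opto_t[stats::runif(length(opto_t)) < up$opto_p]
        add <- sel + (up$opto_latency_ms +
                        stats::rnorm(length(sel), 0, 0.3)) / 1000
        trains[[u]] <- sort(c(trains[[u]], add[add < cfg$duration_s &
                                                 add > 0]))
      }
    }
    trains
  })

  units <- lapply(seq_len(cfg$n_units), function(u) {
    list(spike_times = spikes_list[[u]],
         peak_channel = unit_table$peak_channel[u],
         mean_waveform = make_waveform(unit_table$class[u],
                                       unit_table$tp_ms[u],
                                       cfg$fs_wideband))
  })
  names(units) <- unit_table$unit
  spikes <- spike_dataset(units, cfg$fs_wideband, cfg$duration_s)

  # ---- wideband segment (for MUA power profile) -----------------------------
  wideband <- NULL
  if (cfg$wideband_s > 0) {
    wideband <- with_seed(derive_seed(cfg$seed, "wideband"), {
      n_w <- round(cfg$wideband_s * cfg$fs_wideband)
      ratio <- cfg$fs_wideband / fs
      base <- X[rep(seq_len(ceiling(n_w / ratio)), each = ratio), ,
                drop = FALSE][seq_len(n_w), , drop = FALSE]
      mua_sd <- 4 + 14 * gaussian_loading(depth, lm["c"], 80)
      hf <- matrix(stats::rnorm(n_w * cfg$n_channels), n_w)
      hf <- fft_bandpass(hf, cfg$fs_wideband, 400, 7000, 100)
      base <- base + sweep(hf, 2, mua_sd, `*`)
      probe_recording(base, cfg$fs_wideband, depth)
    })
  }

  truth <- structure(list(
    gamma_phase = if (isTRUE(cfg$keep_phases)) gam$theta else NULL,
    layer_of_channel = layer_of_channel,
    landmarks_um = lm,
    source_loadings = gam$loadings,
    source_center_freq = gam$center_freq,
    uniform_share = cfg$uniform_share,
    state_intervals = states,
    downup_intervals = downup,
    unit_table = unit_table,
    true_edges = edges), class = "ground_truth")

  structure(list(lfp = lfp, wideband = wideband, spikes = spikes,
                 events = events, truth = truth, cfg = cfg),
            class = "sim_session")
}

#' @export
print.sim_session <- function(x, ...) {
  cat(sprintf(
    "<sim_session> %.0f s, %d channels, %d units, %d planted edges\n",
    x$cfg$duration_s, x$cfg$n_channels, x$cfg$n_units,
    nrow(x$truth$true_edges)))
  invisible(x)
}

#' Write a simulated session to disk
#'
#' LFP to `<stem>.lfp` (+ descriptor), wideband to `<stem>.dat` if present,
#' spikes and events to TSV, ground truth to JSON.
#' @param sess a `sim_session`.
#' @param stem output path stem.
#' @export
write_session <- function(sess, stem) {
  write_recording(sess$lfp, paste0(stem, ".lfp"))
  if (!is.null(sess$wideband)) {
    write_recording(sess$wideband, paste0(stem, ".dat"))
  }
  write_spikes(sess$spikes, stem)
  write_events(sess$events, paste0(stem, "_events.tsv"))
  tr <- sess$truth
  jsonlite::write_json(
    list(layer_of_channel = tr$layer_of_channel,
         landmarks_um = as.list(tr$landmarks_um),
         source_loadings = tr$source_loadings,
         uniform_share = tr$uniform_share,
         state_intervals = tr$state_intervals,
         downup_intervals = tr$downup_intervals,
         unit_table = tr$unit_table, true_edges = tr$true_edges),
    paste0(stem, "_truth.json"), auto_unbox = TRUE, digits = NA)
  invisible(stem)
}

#' Simulate a monosynaptically coupled spike-train pair
#'
#' Two homogeneous Poisson trains; for `sign = "E"` each presynaptic spike
#' adds a postsynaptic spike with probability `p` at a lag uniform in
#' 1.5-4 ms (the postsynaptic base rate is reduced so the total rate stays
#' at `rate_post`); for `sign = "I"` postsynaptic spikes in the lag window
#' after a presynaptic spike are removed with probability `p`.
#'
#' @param duration_s recording length.
#' @param rate_pre,rate_post rates, Hz.
#' @param p transmission probability (or thinning fraction for "I").
#' @param sign "E", "I" or "none".
#' @param seed RNG seed.
#' @return list with sorted `pre` and `post` spike-time vectors.
#' @export
simulate_spike_pair <- function(duration_s, rate_pre, rate_post, p = 0,
                                sign = c("none", "E", "I"), seed = 1) {
  sign <- match.arg(sign)
  with_seed(seed, {
    pre <- sort(stats::runif(stats::rpois(1, rate_pre * duration_s),
                             0, duration_s))
    base_rate <- if (sign == "E") max(rate_post - p * rate_pre, 0.1)
                 else rate_post
    post <- sort(stats::runif(stats::rpois(1, base_rate * duration_s),
                              0, duration_s))
    if (sign == "E" && p > 0) {
      sel <- pre[stats::runif(length(pre)) < p]
      add <- sel + stats::runif(length(sel), 0.0015, 0.004)
      post <- sort(c(post, add[add < duration_s]))
    } else if (sign == "I" && p > 0) {
      drop <- logical(length(post))
      lo <- findInterval(pre + 0.0015, post)
      hi <- findInterval(pre + 0.004, post)
      for (i in which(hi > lo)) {
        cand <- (lo[i] + 1L):hi[i]
        drop[cand] <- drop[cand] | (stats::runif(length(cand)) < p)
      }
      post <- post[!drop]
    }
    list(pre = pre, post = post)
  })
}
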
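# Unit classification (waveform, optotagging, spike-IC coupling clusters)
# and per-unit physiological statistics.

# trough-to-peak latency of a negative-going mean waveform, ms
tp_latency_ms <- function(w, fs) {
  i_tr <- which.min(w)
  if (i_tr >= length(w)) return(NA_real_)
  i_pk <- i_tr + which.max(w[(i_tr + 1):length(w)])
  (i_pk - i_tr) / fs * 1000
}

# excess kurtosis of the second derivative of the normalized waveform
waveform_kurtosis <- function(w) {
  wn <- w / max(abs(w))
  d2 <- diff(wn, differences = 2)
  m <- mean(d2); s <- stats::sd(d2)
  if (s == 0) return(NA_real_)
  mean((d2 - m)^4) / s^4
}

#' Classify a single mean waveform
#'
#' POSITIVE if the extreme value is positive; otherwise E if the
#' trough-to-peak latency exceeds `tp_threshold_ms` (0.55 ms), I if not.
#' The FIBER class is population-relative; see [classify_units()].
#'
#' @param mean_waveform numeric waveform (>= 32 samples).
#' @param fs waveform sampling rate, Hz (>= 10 kHz).
#' @param tp_threshold_ms E/I boundary on trough-to-peak latency.
#' @return list: `waveform_class` ("E", "I" or "POSITIVE"),
#'   `tp_latency_ms`, `kurtosis` (of the second derivative, used by the
#'   population fiber rule).
#' @export
classify_waveform <- function(mean_waveform, fs, tp_threshold_ms = 0.55) {
  if (length(mean_waveform) < 32) stop("waveform too short (< 32 samples)")
  if (fs < 10000) stop("waveform sampling rate must be >= 10 kHz")
  if (stats::sd(mean_waveform) == 0) {
    stop("classification error: flat waveform")
  }
  if (abs(max(mean_waveform)) > abs(min(mean_waveform))) {
    return(list(waveform_class = "POSITIVE", tp_latency_ms = NA_real_,
                kurtosis = waveform_kurtosis(mean_waveform)))
  }
  tp <- tp_latency_ms(mean_waveform, fs)
  list(waveform_class = if (tp > tp_threshold_ms) "E" else "I",
       tp_latency_ms = tp, kurtosis = waveform_kurtosis(mean_waveform))
}

#' Waveform classification for a whole dataset
#'
#' Applies [classify_waveform()] per unit, then reclassifies negative-
#' waveform units as FIBER when the kurtosis of the second derivative of
#' the normalized waveform is an outlier beyond +/- `fiber_sd` of the
#' population (robust median/MAD z by default; `robust = FALSE` restores
#' the literal mean/SD rule).
#'
#' @param spikes a [spike_dataset()].
#' @param tp_threshold_ms E/I boundary, ms.
#' @param fiber_sd outlier threshold in SD (or MAD) units.
#' @param robust use median/MAD-scaled z for the fiber rule.
#' @return data.frame, one row per unit: `unit`, `waveform_class`,
#'   `tp_latency_ms`, `kurtosis`.
#' @export
classify_units <- function(spikes, tp_threshold_ms = 0.55, fiber_sd = 5,
                           robust = TRUE) {
  stopifnot(inherits(spikes, "spike_dataset"))
  res <- lapply(spikes$units, function(u)
    classify_waveform(u$mean_waveform, spikes$fs_waveform,
                      tp_threshold_ms))
  df <- data.frame(unit = names(spikes$units),
                   waveform_class = vapply(res, `[[`, "", "waveform_class"),
                   tp_latency_ms = vapply(res, `[[`, 0, "tp_latency_ms"),
                   kurtosis = vapply(res, `[[`, 0, "kurtosis"))
  neg <- df$waveform_class %in% c("E", "I")
  k <- df$kurtosis[neg]
  if (sum(neg) >= 5) {
    z <- if (robust) {
      s <- stats::mad(k)
      if (s == 0) rep(0, length(k)) else (k - stats::median(k)) / s
    } else {
      (k - mean(k)) / stats::sd(k)
    }
    df$waveform_class[neg][abs(z) > fiber_sd] <- "FIBER"
  }
  rownames(df) <- NULL
  df
}

#' Optogenetic tagging test
#'
#' A unit is tagged when the mean of the two largest 1 ms bins of the
#' light-triggered histogram within the 1-6 ms response window exceeds
#' the baseline mean by more than 8 baseline SD.
#'
#' @param spike_times unit spike times, s.
#' @param pulse_times light pulse onsets, s (>= 100 pulses).
#' @param bin_ms histogram bin, ms.
#' @param window_ms response window after light onset, ms.
#' @param baseline_ms baseline window relative to onset, ms.
#' @param sd_mult threshold in baseline SD units.
#' @return list: `tagged`, `peak_rate_hz`, `baseline_mean_hz`,
#'   `baseline_sd_hz`, `degenerate` (TRUE when the baseline was silent).
#' @export
optotag <- function(spike_times, pulse_times, bin_ms = 1,
                    window_ms = c(1, 6), baseline_ms = c(-100, 0),
                    sd_mult = 8) {
  if (length(pulse_times) < 100) stop("need at least 100 pulses")
  bw <- bin_ms / 1000
  resp_edges <- seq(window_ms[1], window_ms[2], by = bin_ms) / 1000
  base_edges <- seq(baseline_ms[1], baseline_ms[2], by = bin_ms) / 1000
  resp_counts <- numeric(length(resp_edges) - 1)
  base_counts <- numeric(length(base_edges) - 1)
  for (tt in pulse_times) {
    rel <- spike_times[spike_times >= tt + baseline_ms[1] / 1000 &
                         spike_times < tt + window_ms[2] / 1000] - tt
    if (!length(rel)) next
    resp_counts <- resp_counts +
      graphics::hist(rel[rel >= resp_edges[1] & rel < max(resp_edges)],
                     breaks = resp_edges, plot = FALSE)$counts
    base_counts <- base_counts +
      graphics::hist(rel[rel >= base_edges[1] & rel < max(base_edges)],
                     breaks = base_edges, plot = FALSE)$counts
  }
  n <- length(pulse_times)
  resp_rate <- resp_counts / (n * bw)
  base_rate <- base_counts / (n * bw)
  peak <- mean(sort(resp_rate, decreasing = TRUE)[1:2])
  mu <- mean(base_rate); s <- stats::sd(base_rate)
  if (s == 0) {
    return(list(tagged = peak > 0, peak_rate_hz = peak,
                baseline_mean_hz = mu, baseline_sd_hz = 0,
                degenerate = TRUE))
  }
  list(tagged = peak > mu + sd_mult * s, peak_rate_hz = peak,
       baseline_mean_hz = mu, baseline_sd_hz = s, degenerate = FALSE)
}

# autocorrelogram counts at 0.5 ms bins up to max_lag (zero-lag excluded;
# vectorized over spike-index offsets)
acg_counts <- function(spike_times, bin_s = 5e-4, max_lag_s = 0.3) {
  n <- length(spike_times)
  nb <- ceiling(max_lag_s / bin_s)
  counts <- numeric(nb)
  k <- 1L
  while (k < n) {
    d <- spike_times[(1L + k):n] - spike_times[1:(n - k)]
    d <- d[d < max_lag_s]
    if (!length(d)) break
    counts <- counts + tabulate(pmin(floor(d / bin_s) + 1L, nb), nb)
    k <- k + 1L
  }
  list(lag_s = (seq_len(nb) - 0.5) * bin_s, counts = counts)
}

#' Burst index from the spike autocorrelogram
#'
#' Mean autocorrelogram count in the burst window (1.5-13.5 ms) divided
#' by the mean count in the baseline window (200-300 ms); 0.5 ms bins,
#' zero-lag excluded. Near 1 for a Poisson train, near 0 for a refractory
#' train, large for bursty units.
#'
#' @param spike_times sorted spike times, s (>= 100 spikes).
#' @param burst_ms,baseline_ms numerator and denominator lag windows, ms.
#'   Defaults follow the operational definition; `burst_ms = c(3, 10)`
#'   with `baseline_ms = c(200, 300)` reproduces the coarser variant.
#' @return list: `index` (NA and `defined = FALSE` when the baseline
#'   window is empty), `defined`.
#' @export
burst_index <- function(spike_times, burst_ms = c(1.5, 13.5),
                        baseline_ms = c(200, 300)) {
  if (length(spike_times) < 100) stop("need at least 100 spikes")
  acg <- acg_counts(spike_times, bin_s = 5e-4,
                    max_lag_s = baseline_ms[2] / 1000)
  lag_ms <- acg$lag_s * 1000
  num <- mean(acg$counts[lag_ms > burst_ms[1] & lag_ms <= burst_ms[2]])
  den <- mean(acg$counts[lag_ms > baseline_ms[1] &
                           lag_ms <= baseline_ms[2]])
  if (!is.finite(den) || den == 0) {
    return(list(index = NA_real_, defined = FALSE))
  }
  list(index = num / den, defined = TRUE)
}

#' Firing dynamics around DOWN-UP transitions
#'
#' PETH at 10 ms bins after UP onsets. The transient/steady ratio is the
#' peak rate in 0-200 ms divided by the mean rate in 100-200 ms (the
#' windows overlap by construction of the definition). The DOWN-UP
#' latency is the median over transitions of the first spike time within
#' 0-500 ms (transitions with no spike excluded).
#'
#' @param spike_times sorted spike times, s.
#' @param downup a `downup_events` object (or data.frame of UP starts in
#'   column `start`).
#' @param min_onsets minimum number of UP onsets required.
#' @return list: `transient_steady_ratio` (`NA` + `defined = FALSE` when
#'   the steady rate is 0), `downup_latency_s`, `peth` (data.frame).
#' @export
up_state_dynamics <- function(spike_times, downup, min_onsets = 50) {
  onsets <- if (inherits(downup, "downup_events")) downup$up$start
            else downup$start
  if (length(onsets) < min_onsets) {
    stop("need at least ", min_onsets, " UP onsets")
  }
  edges <- seq(0, 0.5, by = 0.01)
  counts <- numeric(length(edges) - 1)
  first <- rep(NA_real_, length(onsets))
  for (i in seq_along(onsets)) {
    rel <- spike_times[spike_times >= onsets[i] &
                         spike_times < onsets[i] + 0.5] - onsets[i]
    if (length(rel)) {
      counts <- counts + graphics::hist(rel, breaks = edges,
                                        plot = FALSE)$counts
      first[i] <- rel[1]
    }
  }
  rate <- counts / (length(onsets) * 0.01)
  mids <- (edges[-1] + edges[-length(edges)]) / 2
  peak <- max(rate[mids < 0.2])
  steady <- mean(rate[mids >= 0.1 & mids < 0.2])
  ratio <- if (steady > 0) peak / steady else NA_real_
  list(transient_steady_ratio = ratio, defined = steady > 0,
       downup_latency_s = stats::median(first, na.rm = TRUE),
       peth = data.frame(time_s = mids, rate_hz = rate))
}

#' Detect DOWN-state-active units
#'
#' Compares per-event firing rates between DOWN and UP states with a
#' Wilcoxon rank-sum test. A unit is flagged when its median DOWN rate
#' exceeds its median UP rate and the one-sided test is significant.
#'
#' @param spike_times sorted spike times, s.
#' @param downup a `downup_events` object (>= `min_events` DOWN and UP).
#' @param alpha significance level.
#' @param min_events minimum events per state.
#' @return list: `flagged`, `rate_down_hz`, `rate_up_hz`, `p_value`.
#' @export
detect_down_active <- function(spike_times, downup, alpha = 0.05,
                               min_events = 50) {
  down <- as_intervals(downup$down[, c("start", "end")])
  up <- as_intervals(downup$up[, c("start", "end")])
  if (nrow(down) < min_events || nrow(up) < min_events) {
    stop("need at least ", min_events, " DOWN and UP events")
  }
  rate_in <- function(iv) {
    cnt <- findInterval(iv[, 2] - 1e-9, spike_times) -
      findInterval(iv[, 1] - 1e-9, spike_times)
    cnt / (iv[, 2] - iv[, 1])
  }
  rd <- rate_in(down); ru <- rate_in(up)
  if (!length(spike_times)) {
    return(list(flagged = FALSE, rate_down_hz = 0, rate_up_hz = 0,
                p_value = 1))
  }
  p <- suppressWarnings(
    stats::wilcox.test(rd, ru, alternative = "greater")$p.value)
  md <- stats::median(rd); mu <- stats::median(ru)
  list(flagged = md > mu && p < alpha,
       rate_down_hz = sum(rd * (down[, 2] - down[, 1])) / iv_total(down),
       rate_up_hz = sum(ru * (up[, 2] - up[, 1])) / iv_total(up),
       p_value = p)
}

# ---- cityblock k-means with silhouette model selection ---------------------

# Lloyd-type k-means under the L1 (cityblock) metric: centroids are
# coordinate-wise medians. Multiple starts, best objective kept.
kmeans_l1 <- function(X, k, n_start = 10, iter_max = 50) {
  n <- nrow(X)
  best <- NULL
  for (s in seq_len(n_start)) {
    ctr <- X[sample.int(n, k), , drop = FALSE]
    z <- integer(n)
    for (it in seq_len(iter_max)) {
      D <- vapply(seq_len(k), function(j)
        rowSums(abs(sweep(X, 2, ctr[j, ]))), numeric(n))
      z_new <- max.col(-D, ties.method = "first")
      # re-seed empty clusters at distinct worst-fit points
      empty <- setdiff(seq_len(k), unique(z_new))
      if (length(empty)) {
        worst <- order(D[cbind(seq_len(n), z_new)], decreasing = TRUE)
        z_new[worst[seq_along(empty)]] <- empty
      }
      if (identical(z_new, z)) break
      z <- z_new
      for (j in seq_len(k)) {
        if (any(z == j)) {
          ctr[j, ] <- apply(X[z == j, , drop = FALSE], 2, stats::median)
        }
      }
    }
    obj <- sum(D[cbind(seq_len(n), z)])
    if (is.null(best) || obj < best$obj) {
      best <- list(cluster = z, centers = ctr, obj = obj)
    }
  }
  best
}

#' Cluster units by their spike-IC coupling profiles
#'
#' k-means under the cityblock metric on the units x ICs coupling matrix
#' (mean resultant length at the unit's preferred gamma frequency per IC;
#' non-significant couplings entered as 0). The number of clusters is
#' chosen over `k_range` by the silhouette criterion (mean silhouette
#' width under the manhattan distance).
#'
#' @param coupling numeric matrix, units x ICs (>= 20 units with at least
#'   one nonzero row entry).
#' @param k_range candidate cluster counts.
#' @param seed RNG seed (clustering is deterministic given the seed).
#' @param n_start k-means restarts per K.
#' @return object of class `coupling_clusters`: `cluster`, `k`,
#'   `silhouette` (per-unit widths), `mean_silhouette` (per K),
#'   `degenerate` (TRUE when all profiles coincide).
#' @export
cluster_by_ic_coupling <- function(coupling, k_range = 2:12, seed = 1,
                                   n_start = 10) {
  X <- as.matrix(coupling)
  sig <- rowSums(X != 0) > 0
  if (sum(sig) < 20) {
    stop("need at least 20 units with a significant IC coupling")
  }
  if (all(apply(X, 2, stats::sd) == 0)) {
    return(structure(list(cluster = rep(1L, nrow(X)), k = 1L,
                          silhouette = rep(NA_real_, nrow(X)),
                          mean_silhouette = NULL, degenerate = TRUE),
                     class = "coupling_clusters"))
  }
  D <- stats::dist(X, method = "manhattan")
  k_range <- k_range[k_range < nrow(X)]
  fits <- with_seed(derive_seed(seed, "ic_kmeans"), {
    lapply(k_range, function(k) kmeans_l1(X, k, n_start = n_start))
  })
  msil <- vapply(seq_along(k_range), function(i) {
    sw <- cluster::silhouette(fits[[i]]$cluster, D)
    if (is.null(dim(sw))) return(NA_real_)
    mean(sw[, "sil_width"])
  }, 0)
  best <- which.max(msil)
  sw <- cluster::silhouette(fits[[best]]$cluster, D)
  structure(list(cluster = fits[[best]]$cluster, k = k_range[best],
                 silhouette = sw[, "sil_width"],
                 mean_silhouette = stats::setNames(msil, k_range),
                 degenerate = FALSE),
            class = "coupling_clusters")
}

#' @export
print.coupling_clusters <- function(x, ...) {
  cat(sprintf("<coupling_clusters> K = %d%s\n", x$k,
              if (x$degenerate) " (degenerate)" else ""))
  invisible(x)
}

#' Spike-IC coupling matrix for a unit population
#'
#' For each unit and each laminar IC time course, computes the
#' spike-phase coupling across gamma wavelet scales and enters the mean
#' resultant length at the unit's preferred frequency, or 0 when no
#' frequency is significantly modulated (Rayleigh p >= alpha).
#'
#' @param spikes a [spike_dataset()].
#' @param ica a [gamma_ica()] result.
#' @param band,n_scales passed to [spike_phase_coupling()].
#' @param intervals optional analysis intervals.
#' @param alpha Rayleigh significance level.
#' @return matrix units x laminar ICs.
#' @export
spike_ic_coupling_matrix <- function(spikes, ica, band = c(30, 100),
                                     n_scales = 20, intervals = NULL,
                                     alpha = 0.05) {
  ics <- ica$laminar
  M <- matrix(0, length(spikes$units), length(ics),
              dimnames = list(names(spikes$units), paste0("IC", ics)))
  for (j in seq_along(ics)) {
    # one wavelet transform per IC, shared across units
    W <- cwt_morlet(ica$time_series[, ics[j]], ica$fs, band[1], band[2],
                    n_freqs = n_scales)
    for (i in seq_along(spikes$units)) {
      pc <- spike_phase_coupling(spikes$units[[i]]$spike_times, W,
                                 ica$fs, band, n_scales, intervals, alpha)
      if (!pc$insufficient && !is.na(pc$R)) M[i, j] <- pc$R
    }
  }
  M
}

#' Per-state firing rates and state ratio
#'
#' @param spike_times sorted spike times, s.
#' @param states a `state_segmentation` or intervals data.frame with
#'   start/end/label.
#' @param min_state_s minimum per-state duration, seconds.
#' @return list: `rates_hz` (named by state), `wake_nrem_ratio`
#'   (`Inf` flagged via `ratio_defined = FALSE` when NREM is silent, `NA`
#'   when a state is absent).
#' @export
state_rate_table <- function(spike_times, states, min_state_s = 60) {
  labs <- c("WAKE", "NREM", "REM")
  rates <- stats::setNames(rep(NA_real_, 3), labs)
  for (l in labs) {
    iv <- state_intervals(states, l)
    tot <- iv_total(iv)
    if (tot >= min_state_s) {
      rates[l] <- length(iv_restrict(spike_times, iv)) / tot
    }
  }
  ratio <- NA_real_; defined <- FALSE
  if (!is.na(rates["WAKE"]) && !is.na(rates["NREM"])) {
    if (rates["NREM"] > 0) {
      ratio <- rates["WAKE"] / rates["NREM"]; defined <- TRUE
    } else {
      ratio <- Inf
    }
  }
  list(rates_hz = rates, wake_nrem_ratio = unname(ratio),
       ratio_defined = defined)
}
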
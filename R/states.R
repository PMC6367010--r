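# Brain-state scoring (WAKE / NREM / REM) and DOWN/UP slow-wave detection.

#' Scoring traces: broadband PC1, theta ratio, EMG proxy
#'
#' Builds a 1 s-step spectrogram (10 s centered windows, truncated at the
#' edges) of the scoring channel at log-spaced frequencies 1-100 Hz.
#' PC1 of the z-scored log spectrogram is oriented so that frames with
#' high low-frequency (< 20 Hz) power are positive (non-REM-like). The
#' theta ratio is 5-10 Hz power over 2-16 Hz power. The EMG proxy is the
#' mean zero-lag correlation, per frame, between 300-600 Hz filtered
#' signals across channels (filter shoulders 275-625 Hz).
#'
#' @param rec LFP [probe_recording()] (>= 60 s, >= 2 channels).
#' @param scoring_channel channel used for the spectrogram (default: the
#'   middle channel; pass the landmark-c channel when known).
#' @param emg_channels channels used for the EMG proxy (default: up to 8
#'   evenly spaced channels).
#' @param win_s,step_s spectrogram window and step, seconds.
#' @return object of class `scoring_traces`: data.frame `frames`
#'   (time_s, pc1, theta_ratio, emg), plus `freqs` and `spec` (frames x
#'   freqs, log power).
#' @export
compute_scoring_traces <- function(rec, scoring_channel = NULL,
                                   emg_channels = NULL, win_s = 10,
                                   step_s = 1) {
  stopifnot(inherits(rec, "probe_recording"))
  dur <- duration_s(rec)
  if (dur < 20) stop("session shorter than 20 s cannot be scored")
  if (dur < 60) warning("less than 60 s of data; scoring will be crude")
  nch <- ncol(rec$samples)
  if (nch < 2) stop("EMG proxy needs at least 2 channels")
  if (is.null(scoring_channel)) scoring_channel <- ceiling(nch / 2)
  if (is.null(emg_channels)) {
    emg_channels <- unique(round(seq(1, nch, length.out = min(8, nch))))
  }
  fs <- rec$fs
  centers <- seq(0.5, dur - 0.5, by = step_s)
  x <- rec$samples[, scoring_channel]
  freqs <- exp(seq(log(1), log(100), length.out = 80))
  spec <- matrix(NA_real_, length(centers), length(freqs))
  for (i in seq_along(centers)) {
    i0 <- max(1L, round((centers[i] - win_s / 2) * fs) + 1L)
    i1 <- min(length(x), round((centers[i] + win_s / 2) * fs))
    seg <- x[i0:i1]
    seg <- seg - mean(seg)
    nseg <- length(seg)
    P <- Mod(stats::fft(seg))^2 / nseg
    fgrid <- (seq_len(nseg) - 1) * fs / nseg
    half <- seq_len(floor(nseg / 2))
    pick <- findInterval(freqs, fgrid[half])
    # sum power between successive log-spaced bins for stability
    lo <- c(1L, pick[-length(pick)])
    spec[i, ] <- vapply(seq_along(pick), function(k) {
      sum(P[half][max(lo[k], 1L):max(pick[k], 1L)])
    }, 0)
  }
  lspec <- log10(spec + .Machine$double.xmin)
  z <- scale(lspec)
  z[!is.finite(z)] <- 0
  pc <- stats::prcomp(z, center = FALSE, scale. = FALSE)
  pc1 <- pc$x[, 1]
  lowf <- freqs < 20
  if (sum(pc$rotation[lowf, 1]) < 0) pc1 <- -pc1
  theta_ratio <- rowSums(spec[, freqs >= 5 & freqs <= 10, drop = FALSE]) /
    rowSums(spec[, freqs >= 2 & freqs <= 16, drop = FALSE])
  # EMG proxy: mean pairwise zero-lag correlation of 300-600 Hz signals
  hf <- fft_bandpass(rec$samples[, emg_channels, drop = FALSE], fs,
                     300, min(600, 0.98 * fs / 2), 25)
  hf <- as.matrix(hf)
  emg <- vapply(centers, function(tc) {
    i0 <- max(1L, round((tc - step_s / 2) * fs) + 1L)
    i1 <- min(nrow(hf), round((tc + step_s / 2) * fs))
    cc <- stats::cor(hf[i0:i1, , drop = FALSE])
    mean(cc[upper.tri(cc)])
  }, 0)
  structure(list(frames = data.frame(time_s = centers, pc1 = pc1,
                                     theta_ratio = theta_ratio,
                                     emg = emg),
                 freqs = freqs, spec = lspec,
                 scoring_channel = scoring_channel),
            class = "scoring_traces")
}

#' @export
print.scoring_traces <- function(x, ...) {
  cat(sprintf("<scoring_traces> %d frames (1 s), channel %d\n",
              nrow(x$frames), x$scoring_channel))
  invisible(x)
}

# frames -> merged interval data.frame for one label
frames_to_intervals <- function(time_s, keep, step_s = 1) {
  if (!any(keep)) {
    return(data.frame(start = numeric(), end = numeric()))
  }
  r <- rle(keep)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  sel <- which(r$values)
  data.frame(start = time_s[starts[sel]] - step_s / 2,
             end = time_s[ends[sel]] + step_s / 2)
}

#' Score brain states from the scoring traces
#'
#' Thresholds are set at the trough between the two largest modes of each
#' trace histogram (kernel density, Silverman bandwidth). Non-REM frames
#' are those above the PC1 dip; among the rest, REM requires EMG below
#' its dip and theta ratio above its dip; remaining frames are WAKE.
#' Waking bouts shorter than `min_wake_s` (default 420 s = 7 min) are
#' merged into the surrounding sleep (relabeled NREM) and flagged.
#'
#' A unimodal trace histogram carries no evidence of two states: unless
#' a fixed threshold is supplied for that trace, the corresponding
#' division then assigns nothing to the sleep side (with a warning).
#'
#' @param traces a [compute_scoring_traces()] result.
#' @param min_wake_s minimum duration of a reported WAKE bout, seconds.
#' @param fixed_thresholds optional named list (`pc1`, `emg`, `theta`)
#'   of absolute thresholds used when the trace histogram is unimodal.
#' @return object of class `state_segmentation`: `intervals`
#'   (start, end, label), `frame_labels`, `thresholds`, `merged_wake`
#'   (intervals relabeled by the minimum-duration rule).
#' @export
score_states <- function(traces, min_wake_s = 420,
                         fixed_thresholds = list()) {
  fr <- traces$frames
  if (nrow(fr) < 600) warning("fewer than 10 min of frames")
  thr <- list()
  get_thr <- function(x, name, key) {
    d <- bimodal_dip(x)
    if (!d$bimodal) {
      fixed <- fixed_thresholds[[key]]
      if (is.null(fixed)) {
        warning("unimodal ", name, " histogram and no fixed threshold; ",
                "no ", key, "-based sleep division made")
        return(NA_real_)
      }
      warning("unimodal ", name, " histogram; using the fixed threshold")
      d$threshold <- fixed
    }
    d$threshold
  }
  thr$pc1 <- get_thr(fr$pc1, "PC1", "pc1")
  lab <- if (is.na(thr$pc1)) rep("WAKE", nrow(fr))
         else ifelse(fr$pc1 > thr$pc1, "NREM", "WAKE")
  rest <- lab != "NREM"
  thr$emg <- get_thr(fr$emg[rest], "EMG", "emg")
  thr$theta <- get_thr(fr$theta_ratio[rest], "theta ratio", "theta")
  if (!is.na(thr$emg) && !is.na(thr$theta)) {
    lab[rest & fr$emg < thr$emg & fr$theta_ratio > thr$theta] <- "REM"
  }
  # enforce the minimum waking duration: short arousals merge into sleep
  step_s <- if (nrow(fr) > 1) fr$time_s[2] - fr$time_s[1] else 1
  merged <- data.frame(start = numeric(), end = numeric())
  r <- rle(lab)
  ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
  for (k in seq_along(r$values)) {
    if (r$values[k] == "WAKE" &&
        r$lengths[k] * step_s < min_wake_s &&
        (k > 1 || k < length(r$values))) {
      neighbor <- if (k > 1) r$values[k - 1] else r$values[k + 1]
      if (neighbor %in% c("NREM", "REM")) {
        lab[starts[k]:ends[k]] <- "NREM"
        merged <- rbind(merged,
                        data.frame(start = fr$time_s[starts[k]] - step_s / 2,
                                   end = fr$time_s[ends[k]] + step_s / 2))
      }
    }
  }
  ivs <- do.call(rbind, lapply(c("WAKE", "NREM", "REM"), function(l) {
    iv <- frames_to_intervals(fr$time_s, lab == l, step_s)
    if (nrow(iv)) cbind(iv, label = l) else NULL
  }))
  ivs <- ivs[order(ivs$start), , drop = FALSE]
  rownames(ivs) <- NULL
  structure(list(intervals = ivs, frame_labels = lab,
                 frame_time_s = fr$time_s, thresholds = thr,
                 merged_wake = merged),
            class = "state_segmentation")
}

#' @export
print.state_segmentation <- function(x, ...) {
  tot <- tapply(x$intervals$end - x$intervals$start, x$intervals$label, sum)
  cat("<state_segmentation> seconds per state:\n")
  print(round(tot))
  invisible(x)
}

#' Interval matrix for one state label
#' @param seg a `state_segmentation` (or any data.frame with
#'   start/end/label).
#' @param label state label.
#' @export
state_intervals <- function(seg, label) {
  df <- if (inherits(seg, "state_segmentation")) seg$intervals else seg
  as_intervals(df[df$label == label, c("start", "end")])
}

#' Detect DOWN/UP states of the non-REM slow oscillation
#'
#' Detects slow waves as the coincidence of a drop in high-frequency
#' (100-400 Hz) power and a peak in the delta-band (0.5-8 Hz) filtered
#' signal of the detection channel, inside non-REM intervals. Candidate
#' delta peaks above 0.25 SD are binned by magnitude; the adaptive peak
#' threshold is the smallest magnitude bin whose population spike rate at
#' the peak falls below `rate_criterion` times the mean rate. Event
#' boundaries are window-threshold crossings of the delta trace,
#' restricted to the overlap with a gamma-drop interval, and must last at
#' least `min_dur_s` (40 ms).
#'
#' @param rec LFP [probe_recording()].
#' @param spikes a [spike_dataset()] (population spiking calibrates the
#'   thresholds).
#' @param nrem_intervals interval matrix/data.frame of non-REM time (s).
#' @param channel detection channel (default: middle channel; use the
#'   landmark-c channel when known).
#' @param rate_criterion PETH rate criterion as a fraction of the mean
#'   population rate.
#' @param min_dur_s minimum DOWN duration, seconds.
#' @param n_mag_bins number of delta-peak magnitude bins.
#' @return object of class `downup_events`: data.frames `down` and `up`
#'   (start, end, plus per-DOWN `delta_peak_sd` and `gamma_min`),
#'   `thresholds`.
#' @export
detect_slow_waves <- function(rec, spikes, nrem_intervals,
                              channel = NULL, rate_criterion = 0.2,
                              min_dur_s = 0.04, n_mag_bins = 8) {
  stopifnot(inherits(rec, "probe_recording"))
  nrem_intervals <- as_intervals(nrem_intervals)
  if (iv_total(nrem_intervals) < 60) stop("need >= 60 s of non-REM")
  fs <- rec$fs
  if (is.null(channel)) channel <- ceiling(ncol(rec$samples) / 2)
  x <- rec$samples[, channel]
  tgrid <- (seq_along(x) - 0.5) / fs
  in_nrem <- iv_contains(nrem_intervals, tgrid)
  delta <- fft_bandpass(x, fs, 0.5, 8)
  gamma <- band_amplitude(x, fs, c(100, min(400, 0.95 * fs / 2)))
  k80 <- max(1L, round(0.08 * fs))
  gamma <- stats::filter(gamma, rep(1 / k80, k80), sides = 2)
  gamma[is.na(gamma)] <- mean(gamma, na.rm = TRUE)
  # local normalization against slow non-stationarities
  gmu <- mean(gamma[in_nrem]); gsd <- stats::sd(gamma[in_nrem])
  dsd <- stats::sd(delta[in_nrem])
  if (dsd == 0 || gsd == 0) return(empty_downup())   # flat signal
  gz <- (as.numeric(gamma) - gmu) / gsd
  dz <- (delta - mean(delta[in_nrem])) / dsd
  dz[!in_nrem] <- 0
  gz[!in_nrem] <- 0
  # candidate delta peaks > 0.25 SD
  iplus <- which(diff(sign(diff(dz))) == -2) + 1L
  iplus <- iplus[dz[iplus] > 0.25 & in_nrem[iplus]]
  if (!length(iplus)) {
    return(empty_downup())
  }
  # population spike PETH around candidate peaks, by magnitude bin
  all_sp <- sort(unlist(lapply(spikes$units, `[[`, "spike_times"),
                        use.names = FALSE))
  mags <- dz[iplus]
  qs <- stats::quantile(mags, seq(0, 1, length.out = n_mag_bins + 1))
  bin <- pmin(pmax(findInterval(mags, qs, rightmost.closed = TRUE,
                                all.inside = TRUE), 1L), n_mag_bins)
  peth_win <- 0.5; peth_bin <- 0.025
  edges <- seq(-peth_win, peth_win, by = peth_bin)
  peth0 <- vapply(seq_len(n_mag_bins), function(b) {
    pk <- iplus[bin == b]
    if (!length(pk)) return(NA_real_)
    counts <- numeric(length(edges) - 1)
    for (tt in tgrid[pk]) {
      rel <- all_sp[all_sp >= tt - peth_win & all_sp < tt + peth_win] - tt
      counts <- counts + graphics::hist(rel, breaks = edges,
                                        plot = FALSE)$counts
    }
    rate <- counts / (length(pk) * peth_bin)
    rate[which.min(abs((edges[-1] + edges[-length(edges)]) / 2))] /
      max(mean(rate), 1e-12)
  }, 0)
  ok <- which(!is.na(peth0) & peth0 < rate_criterion)
  if (!length(ok)) return(empty_downup())
  peak_thr <- qs[min(ok)]
  qual <- iplus[dz[iplus] > peak_thr]
  # window threshold: a fraction of the adaptive peak threshold, floored
  # at the 0.25 SD candidate level
  win_thr <- max(0.25, 0.25 * peak_thr)
  # delta events: window-threshold crossings around qualifying peaks
  above <- dz > win_thr
  d_iv <- runs_to_intervals(above, tgrid)
  keep <- vapply(seq_len(nrow(d_iv)), function(r) {
    any(tgrid[qual] >= d_iv[r, 1] & tgrid[qual] < d_iv[r, 2])
  }, TRUE)
  d_iv <- d_iv[keep, , drop = FALSE]
  # gamma-drop events, thresholded symmetrically (drop below -win_thr/2)
  g_iv <- runs_to_intervals(gz < -0.25, tgrid)
  rows <- list(); k <- 0L
  for (r in seq_len(nrow(d_iv))) {
    # gamma-drop coincidence gates the event; timing comes from the
    # delta window-threshold crossings
    ov <- iv_intersect(d_iv[r, , drop = FALSE], g_iv)
    if (nrow(ov) == 0) next
    if (d_iv[r, 2] - d_iv[r, 1] < min_dur_s) next
    i0 <- floor(d_iv[r, 1] * fs) + 1L
    i1 <- min(ceiling(d_iv[r, 2] * fs), length(dz))
    k <- k + 1L
    rows[[k]] <- data.frame(start = d_iv[r, 1], end = d_iv[r, 2],
                            delta_peak_sd = max(dz[i0:i1]),
                            gamma_min = min(gz[i0:i1]))
  }
  if (k == 0) return(empty_downup())
  down <- do.call(rbind, rows)
  down <- down[order(down$start), , drop = FALSE]
  # UP states: inter-DOWN intervals within non-REM
  up_rows <- list(); k <- 0L
  for (r in seq_len(nrow(nrem_intervals))) {
    dd <- down[down$start >= nrem_intervals[r, 1] &
                 down$end <= nrem_intervals[r, 2], , drop = FALSE]
    bounds <- c(nrem_intervals[r, 1], t(as.matrix(dd[, c("start", "end")])),
                nrem_intervals[r, 2])
    for (j in seq(1, length(bounds) - 1, by = 2)) {
      if (bounds[j + 1] - bounds[j] > 1e-9) {
        k <- k + 1L
        up_rows[[k]] <- data.frame(start = bounds[j], end = bounds[j + 1])
      }
    }
  }
  up <- if (k) do.call(rbind, up_rows) else
    data.frame(start = numeric(), end = numeric())
  structure(list(down = down, up = up,
                 thresholds = list(peak_sd = unname(peak_thr),
                                   window_sd = win_thr,
                                   rate_criterion = rate_criterion),
                 channel = channel),
            class = "downup_events")
}

empty_downup <- function() {
  structure(list(down = data.frame(start = numeric(), end = numeric(),
                                   delta_peak_sd = numeric(),
                                   gamma_min = numeric()),
                 up = data.frame(start = numeric(), end = numeric()),
                 thresholds = list(), channel = NA_integer_),
            class = "downup_events")
}

runs_to_intervals <- function(flag, tgrid) {
  flag[is.na(flag)] <- FALSE
  r <- rle(as.vector(flag))
  ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
  sel <- which(r$values)
  if (!length(sel)) return(matrix(numeric(0), ncol = 2))
  cbind(tgrid[starts[sel]], tgrid[ends[sel]])
}

#' @export
print.downup_events <- function(x, ...) {
  cat(sprintf("<downup_events> %d DOWN, %d UP\n",
              nrow(x$down), nrow(x$up)))
  invisible(x)
}
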
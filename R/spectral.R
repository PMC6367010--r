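# Spectral substrate: Morlet wavelet transforms, Welch band coherence,
# phase-amplitude coupling (modulation index) and spike-phase coupling.
#
# Phase convention throughout: phase 0 at the oscillation peak, +/- pi at
# the trough, increasing with time.

#' Complex Morlet wavelet transform
#'
#' Continuous wavelet transform with complex Morlet wavelets (omega0 = 6 by
#' default) on a logarithmically spaced frequency grid, computed by FFT
#' convolution.
#'
#' @param x numeric signal.
#' @param fs sampling rate, Hz.
#' @param f_lo,f_hi frequency band of interest (Hz); `f_hi` must be below
#'   Nyquist.
#' @param n_freqs number of log-spaced frequencies.
#' @param omega0 Morlet nondimensional frequency.
#' @return object of class `wavelet_spectrum` with `freqs` (Hz) and
#'   complex `coef` (time x frequency).
#' @export
cwt_morlet <- function(x, fs, f_lo = 1, f_hi = 100, n_freqs = 50,
                       omega0 = 6) {
  if (!(f_lo < f_hi)) stop("need f_lo < f_hi")
  if (f_hi >= fs / 2) stop("f_hi must be below the Nyquist frequency")
  n <- length(x)
  nfft <- next_fast_len(n)
  freqs <- exp(seq(log(f_lo), log(f_hi), length.out = n_freqs))
  # angular frequencies of the FFT grid
  w <- 2 * pi * c(seq(0, floor(nfft / 2)),
                  seq(-ceiling(nfft / 2) + 1, -1)) * fs / nfft
  X <- stats::fft(c(x, rep(0, nfft - n)))
  fourier_factor <- (omega0 + sqrt(2 + omega0^2)) / (4 * pi)
  coef <- matrix(0i, n, n_freqs)
  for (k in seq_len(n_freqs)) {
    s <- fourier_factor / freqs[k]
    psi <- sqrt(2 * pi * s * fs / nfft) * pi^(-0.25) *
      exp(-(s * w - omega0)^2 / 2) * (w > 0)
    y <- stats::fft(X * psi, inverse = TRUE) / nfft
    coef[, k] <- y[seq_len(n)]
  }
  structure(list(freqs = freqs, coef = coef, omega0 = omega0, fs = fs),
            class = "wavelet_spectrum")
}

#' @export
print.wavelet_spectrum <- function(x, ...) {
  cat(sprintf("<wavelet_spectrum> %d frames x %d freqs (%.3g-%.3g Hz)\n",
              nrow(x$coef), length(x$freqs), min(x$freqs), max(x$freqs)))
  invisible(x)
}

#' Pairwise band-averaged coherence matrix
#'
#' Magnitude-squared coherence between every channel pair, estimated from
#' Welch-averaged cross-spectra (Hann windows) restricted to the given
#' state intervals, then averaged across frequencies in `band`.
#'
#' @param rec a [probe_recording()].
#' @param band frequency band in Hz (default gamma, 30-100).
#' @param intervals optional interval matrix/data.frame (s); default whole
#'   recording. Windows never straddle interval boundaries.
#' @param win_s Welch window length (s), 50% overlap.
#' @return symmetric channel x channel matrix of class `coherence_matrix`,
#'   unit diagonal, entries in \[0, 1\].
#' @export
band_coherence_matrix <- function(rec, band = c(30, 100), intervals = NULL,
                                  win_s = 1) {
  stopifnot(inherits(rec, "probe_recording"))
  nch <- ncol(rec$samples)
  if (nch < 2) stop("need at least 2 channels")
  fs <- rec$fs
  if (is.null(intervals)) intervals <- cbind(0, duration_s(rec))
  intervals <- as_intervals(intervals)
  if (iv_total(intervals) < 10) stop("intervals must total at least 10 s")
  nwin <- round(win_s * fs)
  step <- floor(nwin / 2)
  taper <- 0.5 - 0.5 * cos(2 * pi * seq_len(nwin) / (nwin + 1))
  fgrid <- seq(0, fs / 2, by = 1 / win_s)[seq_len(floor(nwin / 2) + 1)]
  bidx <- which(fgrid >= band[1] & fgrid <= band[2])
  S <- array(0i, c(length(bidx), nch, nch))
  nseg <- 0L
  for (r in seq_len(nrow(intervals))) {
    i0 <- floor(intervals[r, 1] * fs) + 1
    i1 <- min(floor(intervals[r, 2] * fs), nrow(rec$samples))
    starts <- seq(i0, by = step, length.out =
                    max(0, floor((i1 - i0 + 1 - nwin) / step) + 1))
    for (s0 in starts) {
      seg <- rec$samples[s0:(s0 + nwin - 1), , drop = FALSE]
      seg <- sweep(seg, 2, colMeans(seg)) * taper
      F <- stats::mvfft(seg)[bidx, , drop = FALSE]
      for (k in seq_along(bidx)) {
        S[k, , ] <- S[k, , ] + outer(F[k, ], Conj(F[k, ]))
      }
      nseg <- nseg + 1L
    }
  }
  if (nseg == 0) stop("no complete windows inside intervals")
  C <- matrix(0, nch, nch)
  nvalid <- matrix(0, nch, nch)
  for (k in seq_along(bidx)) {
    Sk <- S[k, , ]
    p <- Re(diag(Sk))
    msc <- Mod(Sk)^2 / outer(p, p)
    ok <- is.finite(msc)        # zero-power bins are uninformative
    C[ok] <- C[ok] + msc[ok]
    nvalid <- nvalid + ok
  }
  if (all(nvalid == 0)) stop("no band power on any channel pair")
  C <- C / pmax(nvalid, 1)
  C[nvalid == 0] <- 0
  C <- (C + t(C)) / 2
  diag(C) <- 1
  structure(C, class = c("coherence_matrix", "matrix"),
            band = band, n_windows = nseg)
}

#' Phase-amplitude coupling modulation index
#'
#' Bins the instantaneous phase of `phase_signal` (filtered in
#' `phase_band`) and averages the amplitude envelope of `amp_signal`
#' (filtered in `amp_band`) per bin. The modulation index is the
#' Kullback-Leibler divergence of the normalized amplitude-per-bin
#' distribution from uniform, divided by `log(n_bins)`. Significance from
#' circular time-shift surrogates.
#'
#' @param phase_signal,amp_signal equal-length numeric signals.
#' @param fs sampling rate, Hz.
#' @param phase_band,amp_band filter bands, Hz.
#' @param n_bins phase bins (>= 8; default 20).
#' @param n_surrogates circular-shift surrogates for the p value.
#' @param seed RNG seed for surrogate shifts.
#' @return object of class `modulation_result`: `MI` in \[0,1\],
#'   `phase_bin_centers`, `mean_amp_per_bin` (normalized to sum 1),
#'   `surrogate_p`.
#' @export
modulation_index <- function(phase_signal, amp_signal, fs,
                             phase_band, amp_band, n_bins = 20,
                             n_surrogates = 1000, seed = 1) {
  if (length(phase_signal) != length(amp_signal)) {
    stop("signals must have equal length")
  }
  if (n_bins < 8) stop("need n_bins >= 8")
  ph <- band_phase(phase_signal, fs, phase_band)
  am <- band_amplitude(amp_signal, fs, amp_band)
  centers <- -pi + (seq_len(n_bins) - 0.5) * 2 * pi / n_bins
  bin <- pmin(floor((ph + pi) / (2 * pi / n_bins)) + 1L, n_bins)
  bin_n <- tabulate(bin, n_bins)
  mi_of <- function(amp) {
    s <- rowsum(amp, bin, reorder = TRUE)
    m <- numeric(n_bins)
    m[sort(unique(bin))] <- s / pmax(bin_n[sort(unique(bin))], 1L)
    m[!is.finite(m)] <- 0
    tot <- sum(m)
    if (tot <= 0) return(list(mi = 0, p_dist = rep(1 / n_bins, n_bins)))
    p <- m / tot
    nz <- p > 0
    mi <- sum(p[nz] * log(p[nz] * n_bins)) / log(n_bins)
    # KL divergence is >= 0; snap numerical noise to an exact zero
    if (mi < 1e-12) mi <- 0
    list(mi = mi, p_dist = p)
  }
  obs <- mi_of(am)
  if (all(am == 0)) warning("all-zero amplitude signal; MI = 0")
  surrogate_p <- NA_real_
  if (n_surrogates > 0) {
    n <- length(am)
    dur <- n / fs
    shifts <- with_seed(derive_seed(seed, "mi_surrogate"), {
      round(stats::runif(n_surrogates, 1, max(dur - 1, 2)) * fs)
    })
    mis <- vapply(shifts, function(s) {
      mi_of(am[(seq_len(n) + s - 1L) %% n + 1L])$mi
    }, 0)
    surrogate_p <- mean(mis >= obs$mi)
  }
  structure(list(MI = obs$mi, phase_bin_centers = centers,
                 mean_amp_per_bin = obs$p_dist, surrogate_p = surrogate_p),
            class = "modulation_result")
}

#' @export
print.modulation_result <- function(x, ...) {
  cat(sprintf("<modulation_result> MI = %.4g, surrogate p = %s\n", x$MI,
              format(x$surrogate_p)))
  invisible(x)
}

#' Spike-phase coupling across wavelet frequencies
#'
#' Extracts the Morlet wavelet phase of `lfp` at each spike time over
#' log-spaced frequencies in `band` and computes, per frequency, the mean
#' resultant length R, the circular mean (preferred phase) and a Rayleigh
#' test. The preferred frequency is the frequency with the largest R among
#' significantly modulated frequencies (Rayleigh p < `alpha`).
#'
#' @param spike_times spike times, seconds.
#' @param lfp numeric signal (an LFP channel or an IC time course), or a
#'   precomputed `wavelet_spectrum` to share across units.
#' @param fs sampling rate of `lfp`, Hz.
#' @param band analysis band, Hz.
#' @param n_scales number of log-spaced wavelet scales.
#' @param intervals optional intervals restricting the analysis.
#' @param alpha Rayleigh significance level.
#' @return object of class `phase_coupling`: data.frame `per_freq`
#'   (freq, R, preferred_phase, rayleigh_p), scalars `preferred_freq`, `R`,
#'   `preferred_phase`, `n_spikes`, flag `insufficient`.
#' @export
spike_phase_coupling <- function(spike_times, lfp, fs, band = c(30, 100),
                                 n_scales = 20, intervals = NULL,
                                 alpha = 0.05) {
  if (!is.null(intervals)) {
    spike_times <- iv_restrict(spike_times, as_intervals(intervals))
  }
  if (inherits(lfp, "wavelet_spectrum")) {
    W <- lfp
    n_scales <- length(W$freqs)
  } else {
    W <- cwt_morlet(lfp, fs, band[1], band[2], n_freqs = n_scales)
  }
  idx <- pmin(pmax(round(spike_times * fs) + 1L, 1L), nrow(W$coef))
  insufficient <- length(idx) < 10
  per <- data.frame(freq = W$freqs, R = NA_real_,
                    preferred_phase = NA_real_, rayleigh_p = NA_real_)
  if (length(idx) >= 1) {
    for (k in seq_len(n_scales)) {
      ph <- Arg(W$coef[idx, k])
      rt <- rayleigh_test(ph)
      per$R[k] <- rt$R
      per$preferred_phase[k] <- rt$mean
      per$rayleigh_p[k] <- rt$p
    }
  }
  sig <- which(per$rayleigh_p < alpha)
  best <- if (length(sig)) sig[which.max(per$R[sig])] else NA_integer_
  structure(list(
    per_freq = per,
    preferred_freq = if (is.na(best)) NA_real_ else per$freq[best],
    R = if (is.na(best)) NA_real_ else per$R[best],
    preferred_phase = if (is.na(best)) NA_real_
                      else per$preferred_phase[best],
    n_spikes = length(idx), insufficient = insufficient),
    class = "phase_coupling")
}

#' @export
print.phase_coupling <- function(x, ...) {
  cat(sprintf(
    "<phase_coupling> n = %d spikes; preferred %.3g Hz, R = %.3f\n",
    x$n_spikes, x$preferred_freq, x$R))
  invisible(x)
}

#' Mean-subtracted depth x frequency power map
#'
#' Welch power spectra per channel within `intervals`, with the cross-
#' channel mean spectrum subtracted at every frequency (so each frequency
#' sums to zero across channels). Power is log10 before subtraction.
#'
#' @param rec a [probe_recording()].
#' @param intervals state intervals (s); default the whole recording.
#' @param f_lo,f_hi,n_freqs log-spaced output frequency grid.
#' @param win_s Welch window (s).
#' @return list with `freqs`, `depth_um` and matrix `power`
#'   (channel x frequency, mean-subtracted log10 power).
#' @export
mean_subtracted_spectrum <- function(rec, intervals = NULL, f_lo = 0.5,
                                     f_hi = 100, n_freqs = 60,
                                     win_s = 2) {
  stopifnot(inherits(rec, "probe_recording"))
  if (ncol(rec$samples) < 2) stop("need at least 2 channels")
  fs <- rec$fs
  if (is.null(intervals)) intervals <- cbind(0, duration_s(rec))
  intervals <- as_intervals(intervals)
  nwin <- round(win_s * fs)
  step <- floor(nwin / 2)
  taper <- 0.5 - 0.5 * cos(2 * pi * seq_len(nwin) / (nwin + 1))
  fgrid <- seq(0, fs / 2, by = 1 / win_s)[seq_len(floor(nwin / 2) + 1)]
  P <- matrix(0, length(fgrid), ncol(rec$samples))
  nseg <- 0L
  for (r in seq_len(nrow(intervals))) {
    i0 <- floor(intervals[r, 1] * fs) + 1
    i1 <- min(floor(intervals[r, 2] * fs), nrow(rec$samples))
    starts <- seq(i0, by = step, length.out =
                    max(0, floor((i1 - i0 + 1 - nwin) / step) + 1))
    for (s0 in starts) {
      seg <- rec$samples[s0:(s0 + nwin - 1), , drop = FALSE]
      seg <- sweep(seg, 2, colMeans(seg)) * taper
      P <- P + Mod(stats::mvfft(seg)[seq_along(fgrid), , drop = FALSE])^2
      nseg <- nseg + 1L
    }
  }
  if (nseg == 0) stop("no complete windows inside intervals")
  P <- P / nseg
  fout <- exp(seq(log(max(f_lo, fgrid[2])), log(min(f_hi, max(fgrid))),
                  length.out = n_freqs))
  pick <- vapply(fout, function(f) which.min(abs(fgrid - f)), 0L)
  lp <- t(log10(P[pick, , drop = FALSE] + .Machine$double.xmin))
  lp <- sweep(lp, 2, colMeans(lp))
  list(freqs = fout, depth_um = rec$channel_depth_um, power = lp)
}
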
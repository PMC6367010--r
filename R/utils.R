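# Shared numerical utilities: zero-phase FFT filtering, analytic signal,
# circular statistics, histogram-dip thresholds, interval algebra, seeding.

# fast FFT length (products of 2,3,5)
next_fast_len <- function(n) stats::nextn(n, c(2L, 3L, 5L))

#' Zero-phase band-pass filter with raised-cosine shoulders
#'
#' Filters columns of `x` in the frequency domain with a flat passband
#' `[lo, hi]` and raised-cosine transition bands of width `shoulder` Hz on
#' each side. Zero-phase by construction (real frequency response).
#'
#' @param x numeric vector or matrix (time in rows).
#' @param fs sampling rate, Hz.
#' @param lo,hi passband edges in Hz; `NULL` for low-/high-pass.
#' @param shoulder transition width in Hz (default 10% of the nearer edge).
#' @return filtered signal, same shape as `x`.
#' @keywords internal
fft_bandpass <- function(x, fs, lo = NULL, hi = NULL, shoulder = NULL) {
  vec <- is.null(dim(x))
  x <- as.matrix(x)
  n <- nrow(x)
  nfft <- next_fast_len(n)
  freqs <- c(seq(0, floor(nfft / 2)), seq(-ceiling(nfft / 2) + 1, -1)) * fs / nfft
  af <- abs(freqs)
  if (is.null(shoulder)) {
    edge <- min(c(lo, hi))
    shoulder <- max(0.1 * edge, 1e-6)
  }
  H <- rep(1, nfft)
  if (!is.null(lo)) {
    H <- H * ifelse(af >= lo, 1,
      ifelse(af <= lo - shoulder, 0,
        0.5 * (1 + cos(pi * (lo - af) / shoulder))))
  }
  if (!is.null(hi)) {
    H <- H * ifelse(af <= hi, 1,
      ifelse(af >= hi + shoulder, 0,
        0.5 * (1 + cos(pi * (af - hi) / shoulder))))
  }
  # process columns in small batches: the complex FFT work arrays for a
  # long multichannel recording would otherwise dominate peak memory
  y <- matrix(0, n, ncol(x))
  for (j0 in seq(1, ncol(x), by = 8)) {
    cols <- j0:min(j0 + 7, ncol(x))
    xp <- rbind(x[, cols, drop = FALSE],
                matrix(0, nfft - n, length(cols)))
    X <- stats::mvfft(xp)
    yb <- Re(stats::mvfft(X * H, inverse = TRUE)) / nfft
    y[, cols] <- yb[seq_len(n), , drop = FALSE]
  }
  if (vec) drop(y) else y
}

# Analytic signal via FFT (Hilbert transform); x vector or matrix columns.
analytic_signal <- function(x) {
  vec <- is.null(dim(x))
  x <- as.matrix(x)
  n <- nrow(x)
  X <- stats::mvfft(x)
  h <- rep(0, n)
  if (n %% 2 == 0) {
    h[1] <- 1; h[n / 2 + 1] <- 1; h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1; h[2:((n + 1) / 2)] <- 2
  }
  z <- stats::mvfft(X * h, inverse = TRUE) / n
  if (vec) drop(z) else z
}

# instantaneous phase of band-filtered signal; 0 at oscillation peak
band_phase <- function(x, fs, band, shoulder = NULL) {
  Arg(analytic_signal(fft_bandpass(x, fs, band[1], band[2], shoulder)))
}

band_amplitude <- function(x, fs, band, shoulder = NULL) {
  Mod(analytic_signal(fft_bandpass(x, fs, band[1], band[2], shoulder)))
}

# ---- circular statistics ----------------------------------------------------

# mean resultant length and circular mean of phases (radians)
circ_resultant <- function(phases) {
  n <- length(phases)
  if (n == 0) return(list(R = NA_real_, mean = NA_real_, n = 0L))
  s <- sum(sin(phases)); c <- sum(cos(phases))
  list(R = sqrt(s^2 + c^2) / n, mean = atan2(s, c), n = n)
}

# Rayleigh test for circular non-uniformity
rayleigh_test <- function(phases) {
  r <- circ_resultant(phases)
  n <- r$n
  if (n == 0) return(list(R = NA_real_, mean = NA_real_, p = NA_real_, n = 0L))
  Z <- n * r$R^2
  p <- exp(-Z) * (1 + (2 * Z - Z^2) / (4 * n) -
    (24 * Z - 132 * Z^2 + 76 * Z^3 - 9 * Z^4) / (288 * n^2))
  list(R = r$R, mean = r$mean, p = min(max(p, 0), 1), n = n)
}

# wrap angle difference to (-pi, pi]
ang_diff <- function(a, b) {
  d <- (a - b) %% (2 * pi)
  ifelse(d > pi, d - 2 * pi, d)
}

# ---- histogram dip threshold ------------------------------------------------

# Threshold at the trough between the two highest modes of a kernel density
# estimate (Silverman bandwidth). Returns NA threshold when unimodal.
bimodal_dip <- function(x, adjust = 1) {
  x <- x[is.finite(x)]
  if (length(x) < 10 || stats::sd(x) == 0) {
    return(list(threshold = NA_real_, bimodal = FALSE))
  }
  d <- stats::density(x, bw = "nrd0", adjust = adjust, n = 512)
  y <- d$y
  ismax <- which(diff(sign(diff(y))) == -2) + 1L
  if (length(ismax) < 2) return(list(threshold = NA_real_, bimodal = FALSE))
  top2 <- sort(ismax[order(y[ismax], decreasing = TRUE)][1:2])
  seg <- seq(top2[1], top2[2])
  dip <- seg[which.min(y[seg])]
  # a KDE shoulder is not a mode: require the trough to drop well below
  # the smaller of the two peaks
  if (y[dip] > 0.5 * min(y[top2])) {
    return(list(threshold = NA_real_, bimodal = FALSE))
  }
  list(threshold = d$x[dip], bimodal = TRUE)
}

# ---- interval algebra -------------------------------------------------------
# Intervals are 2-column matrices [start, end) in seconds, rows ordered.

as_intervals <- function(x) {
  if (is.data.frame(x)) x <- as.matrix(x[, 1:2])
  x <- matrix(as.numeric(x), ncol = 2)
  x[order(x[, 1]), , drop = FALSE]
}

iv_total <- function(iv) if (nrow(iv) == 0) 0 else sum(iv[, 2] - iv[, 1])

# logical: which times fall inside any interval
iv_contains <- function(iv, t) {
  if (nrow(iv) == 0) return(rep(FALSE, length(t)))
  brk <- as.vector(t(iv))
  idx <- findInterval(t, brk)
  idx %% 2 == 1
}

# intersection of two ordered disjoint interval sets
iv_intersect <- function(a, b) {
  if (nrow(a) == 0 || nrow(b) == 0) return(matrix(numeric(0), ncol = 2))
  out <- list(); k <- 0L
  i <- 1L; j <- 1L
  while (i <= nrow(a) && j <= nrow(b)) {
    lo <- max(a[i, 1], b[j, 1]); hi <- min(a[i, 2], b[j, 2])
    if (hi > lo) { k <- k + 1L; out[[k]] <- c(lo, hi) }
    if (a[i, 2] < b[j, 2]) i <- i + 1L else j <- j + 1L
  }
  if (k == 0) matrix(numeric(0), ncol = 2) else do.call(rbind, out)
}

# restrict spike times to intervals
iv_restrict <- function(times, iv) times[iv_contains(iv, times)]

# ---- seeding ----------------------------------------------------------------

# Derive a stage seed from a master seed (splitmix-style mix, kept < 2^31).
derive_seed <- function(seed, stage) {
  x <- (as.double(seed) * 2654435761 + sum(utf8ToInt(stage)) * 40503) %%
    2147483647
  as.integer(x)
}

# evaluate expr with a local RNG state
with_seed <- function(seed, expr) {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    stats::runif(1)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  expr
}
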
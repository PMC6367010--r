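# Laminar mapping: MUA power landmark, event-triggered CSD, the five
# depth landmarks a-e, normalized-depth warping, interaction-energy
# coherence clustering, and gamma-band ICA decomposition.

#' Multi-unit activity power profile
#'
#' Per-channel power in a high-frequency band (default 500 Hz - 5 kHz) of
#' a wideband recording. The depth of the profile maximum is landmark c
#' (mid layer 5, where aggregate spike power peaks).
#'
#' @param rec wideband [probe_recording()] (fs >= 10 kHz).
#' @param band frequency band, Hz.
#' @return numeric vector of per-channel band power (uV^2), with
#'   attributes `depth_um` and `peak_depth_um` (NA when the profile is
#'   degenerate).
#' @export
mua_power_profile <- function(rec, band = c(500, 5000)) {
  stopifnot(inherits(rec, "probe_recording"))
  if (rec$fs < 10000) stop("wideband rate >= 10 kHz required for the band")
  filt <- fft_bandpass(rec$samples, rec$fs, band[1],
                       min(band[2], 0.98 * rec$fs / 2))
  p <- colMeans(as.matrix(filt)^2)
  peak <- if (max(p) <= 0 || stats::sd(p) == 0) {
    warning("degenerate (flat) MUA profile; no peak")
    NA_real_
  } else rec$channel_depth_um[which.max(p)]
  structure(p, depth_um = rec$channel_depth_um, peak_depth_um = peak)
}

#' Event-triggered current source density map
#'
#' Averages LFP around `event_times` and applies the second spatial
#' difference: CSD_i = -(V_{i-1} - 2 V_i + V_{i+1}) / dz^2 on interior
#' channels. Sign convention: sinks negative, sources positive.
#'
#' @param rec LFP [probe_recording()].
#' @param event_times trigger times, seconds.
#' @param window_s c(before, after) window around each event, seconds.
#' @param smooth_channels width (channels) of a moving-average spatial
#'   smoother applied to the averaged LFP; 0 disables.
#' @return object of class `csd_map`: `csd` (interior channels x time,
#'   uV/um^2), `lfp_avg`, `time_s`, `depth_um` (interior), `n_events`.
#' @export
event_triggered_csd <- function(rec, event_times, window_s = c(0.05, 0.2),
                                smooth_channels = 0) {
  stopifnot(inherits(rec, "probe_recording"))
  fs <- rec$fs
  dur <- duration_s(rec)
  event_times <- event_times[event_times - window_s[1] >= 0 &
                               event_times + window_s[2] <= dur]
  if (length(event_times) == 0) stop("no events inside the recording")
  if (length(event_times) < 10) {
    warning("fewer than 10 events; CSD computed anyway")
  }
  i_rel <- seq(-round(window_s[1] * fs), round(window_s[2] * fs))
  avg <- matrix(0, length(i_rel), ncol(rec$samples))
  for (tt in event_times) {
    avg <- avg + rec$samples[round(tt * fs) + 1L + i_rel, , drop = FALSE]
  }
  avg <- avg / length(event_times)
  if (smooth_channels > 1) {
    k <- rep(1 / smooth_channels, smooth_channels)
    avg <- t(apply(avg, 1, function(v)
      stats::filter(v, k, sides = 2, circular = FALSE)))
    # moving average leaves NA at the edges; keep original values there
    avg[is.na(avg)] <- 0
  }
  dz <- diff(rec$channel_depth_um)
  if (stats::sd(dz) > 1e-6 * mean(dz)) {
    warning("non-uniform channel pitch; using mean spacing")
  }
  dz <- mean(dz)
  nch <- ncol(avg)
  csd <- -(avg[, 1:(nch - 2), drop = FALSE] -
             2 * avg[, 2:(nch - 1), drop = FALSE] +
             avg[, 3:nch, drop = FALSE]) / dz^2
  structure(list(csd = t(csd), lfp_avg = t(avg), time_s = i_rel / fs,
                 depth_um = rec$channel_depth_um[2:(nch - 1)],
                 n_events = length(event_times)),
            class = "csd_map")
}

#' @export
print.csd_map <- function(x, ...) {
  cat(sprintf("<csd_map> %d interior channels x %d frames, %d events\n",
              nrow(x$csd), ncol(x$csd), x$n_events))
  invisible(x)
}

#' Find the five laminar landmarks a-e
#'
#' Landmark c is the depth of the MUA power maximum. Landmarks a, b, d, e
#' come from the DOWN-UP transition CSD: within a post-transition window,
#' a = most superficial prominent source (positive CSD), b = superficial
#' sink above c, d = deep sink below c, e = deepest source below d. Each
#' is located at the peak absolute amplitude of its depth range. Ordering
#' a < b < c < d < e is enforced.
#'
#' @param mua_profile output of [mua_power_profile()].
#' @param downup_csd a `csd_map` triggered on DOWN-UP transitions
#'   (computed from >= 10 transitions).
#' @param window_s time window (s, relative to the transition) searched
#'   for sinks/sources.
#' @return named numeric vector of landmark depths (um), class
#'   `laminar_landmarks`.
#' @export
find_landmarks <- function(mua_profile, downup_csd,
                           window_s = c(0, 0.15)) {
  c_um <- attr(mua_profile, "peak_depth_um")
  if (is.na(c_um)) stop("landmark error: degenerate MUA profile")
  tsel <- downup_csd$time_s >= window_s[1] & downup_csd$time_s <= window_s[2]
  M <- downup_csd$csd[, tsel, drop = FALSE]
  depth <- downup_csd$depth_um
  if (max(abs(M)) < 1e-12) stop("landmark error: flat CSD")
  # per-channel extreme CSD within the window
  mx <- apply(M, 1, max); mn <- apply(M, 1, min)
  pick <- function(mask, v, decreasing) {
    idx <- which(mask)
    if (!length(idx)) return(NA_real_)
    depth[idx[which.max(if (decreasing) v[idx] else -v[idx])]]
  }
  b_um <- pick(depth < c_um, -mn, TRUE)          # strongest sink above c
  a_um <- pick(depth < b_um & mx > 0, mx, TRUE)  # source above b
  d_um <- pick(depth > c_um, -mn, TRUE)          # strongest sink below c
  e_um <- pick(depth > d_um & mx > 0, mx, TRUE)  # source below d
  lmk <- c(a = a_um, b = b_um, c = c_um, d = d_um, e = e_um)
  if (anyNA(lmk) || is.unsorted(lmk, strictly = TRUE)) {
    stop("landmark error: ordering a < b < c < d < e violated (",
         paste(names(lmk), round(lmk), sep = "=", collapse = ", "), ")")
  }
  structure(lmk, class = "laminar_landmarks")
}

#' Piecewise-linear depth normalization warp
#'
#' Maps recorded depths onto canonical depths so that each landmark maps
#' exactly onto its canonical counterpart, linearly interpolating between
#' landmarks and extrapolating linearly beyond a and e. The estimated pia
#' surface is 80 um above landmark a.
#'
#' @param landmarks recorded landmark depths (named a-e, um), strictly
#'   increasing.
#' @param canonical canonical landmark depths (same order).
#' @return object of class `depth_warp`: function-like; use
#'   [warp_depth()] and [unwarp_depth()]. Field `pia_um` gives the
#'   canonical pia depth (canonical a - 80).
#' @export
normalize_depth <- function(landmarks, canonical) {
  landmarks <- as.numeric(landmarks); canonical <- as.numeric(canonical)
  if (length(landmarks) != length(canonical)) {
    stop("landmark sets must have equal length")
  }
  if (is.unsorted(landmarks, strictly = TRUE) ||
      is.unsorted(canonical, strictly = TRUE)) {
    stop("landmark sets must be strictly increasing")
  }
  structure(list(knots = landmarks, values = canonical,
                 pia_um = canonical[1] - 80),
            class = "depth_warp")
}

#' Apply / invert a depth warp
#' @param warp a `depth_warp`.
#' @param depth_um depths to map (um).
#' @export
warp_depth <- function(warp, depth_um) {
  piecewise_linear(warp$knots, warp$values, depth_um)
}

#' @rdname warp_depth
#' @export
unwarp_depth <- function(warp, depth_um) {
  piecewise_linear(warp$values, warp$knots, depth_um)
}

# piecewise-linear through the knots; unit slope beyond the outer knots
# (distances outside the landmark span are preserved, so a point 80 um
# above landmark a maps 80 um above its canonical position: the pia)
piecewise_linear <- function(x, y, xout) {
  n <- length(x)
  out <- stats::approx(x, y, xout = xout, rule = 1)$y
  lo <- xout < x[1]; hi <- xout > x[n]
  out[lo] <- y[1] + (xout[lo] - x[1])
  out[hi] <- y[n] + (xout[hi] - x[n])
  out
}

#' @export
print.depth_warp <- function(x, ...) {
  cat("<depth_warp>\n")
  print(data.frame(recorded_um = x$knots, canonical_um = x$values))
  invisible(x)
}

# ---- gradient-descent coherence clustering ---------------------------------

# total interaction energy of a partition: sum over clusters of
# -(1/N_A) * sum_{i,j in A, i != j} C_ij (ordered pairs, diagonal excluded)
partition_energy <- function(C, z) {
  e <- 0
  for (lab in unique(z)) {
    m <- which(z == lab)
    if (length(m) >= 2) {
      e <- e - (sum(C[m, m]) - sum(diag(C)[m])) / length(m)
    }
  }
  e
}

#' Cluster recording sites by coherence gradient descent
#'
#' Interaction-energy clustering of a channel coherence matrix. Starting
#' from a random assignment into `k0` labels, sites are visited in random
#' order; a site moves to the cluster with the largest normalized-
#' coherence energy gap provided the move strictly lowers the total
#' energy, until no improving move exists. The number of clusters emerges
#' (empty clusters are dropped). Restarts with fresh initializations are
#' combined into a modal assignment and a consistency score.
#'
#' @param C symmetric coherence matrix (entries in \[0, 1\]).
#' @param n_restarts number of random restarts.
#' @param seed RNG seed.
#' @param k0 number of initial random labels.
#' @param max_sweeps safety cap on full passes per restart.
#' @return object of class `coherence_clustering`: `assignment` (modal,
#'   relabeled in depth order), `n_clusters`, `energy` (of the modal
#'   assignment), `best_energy` (minimum across restarts), `consistency`
#'   (mean adjusted Rand index of restarts vs the modal assignment),
#'   `restart_assignments`.
#' @export
gradient_descent_cluster <- function(C, n_restarts = 50, seed = 1,
                                     k0 = 10, max_sweeps = 200) {
  C <- unclass(C)
  if (!isSymmetric(unname(C), tol = 1e-8)) {
    stop("coherence matrix must be symmetric")
  }
  if (n_restarts < 1) stop("need n_restarts >= 1")
  n <- nrow(C)
  Cn <- C; diag(Cn) <- 0
  one_run <- function() {
    z <- sample.int(min(k0, n), n, replace = TRUE)
    for (sweep in seq_len(max_sweeps)) {
      moved <- FALSE
      for (i in sample.int(n)) {
        labs <- unique(z)
        # own-cluster mean coherence term (N_A includes i, C_ii = 0)
        nA <- sum(z == z[i])
        own <- sum(Cn[i, z == z[i]]) / nA
        gaps <- vapply(labs, function(b) {
          if (b == z[i]) return(0)
          sum(Cn[i, z == b]) / sum(z == b) - own
        }, 0)
        b <- labs[which.max(gaps)]
        if (max(gaps) > 1e-12 && b != z[i]) {
          e0 <- partition_energy(Cn, z)
          z2 <- z; z2[i] <- b
          if (partition_energy(Cn, z2) < e0 - 1e-12) {
            z <- z2
            moved <- TRUE
          }
        }
      }
      if (!moved) {
        # site moves exhausted: try the best whole-cluster merge (single
        # site moves cannot cross uphill barriers between clusters)
        labs <- unique(z)
        if (length(labs) < 2) break
        e0 <- partition_energy(Cn, z)
        best <- NULL
        for (ai in seq_along(labs)[-length(labs)]) {
          for (bi in (ai + 1):length(labs)) {
            z2 <- z; z2[z2 == labs[bi]] <- labs[ai]
            e2 <- partition_energy(Cn, z2)
            if (e2 < e0 - 1e-12 && (is.null(best) || e2 < best$e)) {
              best <- list(z = z2, e = e2)
            }
          }
        }
        if (is.null(best)) break
        z <- best$z
      }
    }
    z
  }
  runs <- with_seed(derive_seed(seed, "gdc"), {
    lapply(seq_len(n_restarts), function(r) one_run())
  })
  # canonical label form: order of first appearance
  canon <- function(z) {
    u <- unique(z)
    match(z, u)
  }
  keys <- vapply(runs, function(z) paste(canon(z), collapse = ","), "")
  modal_key <- names(sort(table(keys), decreasing = TRUE))[1]
  modal <- canon(runs[[match(modal_key, keys)]])
  energies <- vapply(runs, function(z) partition_energy(Cn, z), 0)
  consistency <- mean(vapply(runs, function(z)
    mclust::adjustedRandIndex(z, modal), 0))
  structure(list(assignment = modal, n_clusters = length(unique(modal)),
                 energy = partition_energy(Cn, modal),
                 best_energy = min(energies),
                 consistency = consistency,
                 restart_assignments = runs, C = C),
            class = "coherence_clustering")
}

#' @export
print.coherence_clustering <- function(x, ...) {
  cat(sprintf(
    "<coherence_clustering> %d clusters, energy %.4f, consistency %.3f\n",
    x$n_clusters, x$energy, x$consistency))
  invisible(x)
}

# ---- ICA --------------------------------------------------------------------

# FastICA with logcosh contrast and symmetric decorrelation.
# X: time x d, assumed centered. Returns unmixing W (d x d) acting on
# whitened data and the whitening matrix K (d x d_white).
fast_ica_core <- function(X, n_comp, max_iter = 500, tol = 1e-4) {
  n <- nrow(X)
  cv <- crossprod(X) / n
  eg <- eigen(cv, symmetric = TRUE)
  # near-singular directions would be amplified by the whitening
  n_comp <- min(n_comp, sum(eg$values > 1e-10 * eg$values[1]))
  n_comp <- max(n_comp, 1L)
  keep <- seq_len(n_comp)
  K <- eg$vectors[, keep, drop = FALSE] %*%
    diag(1 / sqrt(eg$values[keep]), n_comp)
  Z <- X %*% K                     # whitened, time x n_comp
  W <- matrix(stats::rnorm(n_comp^2), n_comp)
  sym_decor <- function(W) {
    s <- svd(W)
    s$u %*% t(s$v)
  }
  W <- sym_decor(W)
  deltas <- rep(1, n_comp)
  for (it in seq_len(max_iter)) {
    WX <- Z %*% t(W)               # time x comp
    G <- tanh(WX)
    gp <- colMeans(1 - G^2)
    W1 <- crossprod(G, Z) / n - diag(gp, n_comp) %*% W
    W1 <- sym_decor(W1)
    deltas <- abs(abs(rowSums(W1 * W)) - 1)
    W <- W1
    if (max(deltas) < tol) break
  }
  converged <- max(deltas) < tol
  if (!converged) {
    # rotations inside the Gaussian residual subspace have no fixed
    # point and are unidentifiable; require stability only of the
    # non-Gaussian components (logcosh contrast away from its Gaussian
    # expectation)
    # residual Gaussian wobble leaks a little into the other rows
    # through the symmetric decorrelation, so allow them sqrt(tol)
    S <- Z %*% t(W)
    g0 <- mean(log(cosh(stats::rnorm(20000))))
    ng <- abs(colMeans(log(cosh(S))) - g0) > 0.01
    converged <- !any(ng) || all(deltas[ng] < sqrt(tol))
  }
  list(W = W, K = K, converged = converged, iterations = it)
}

#' Gamma-band ICA decomposition of a laminar LFP
#'
#' Band-passes the LFP, reduces it to `n_pcs` principal components and
#' runs FastICA (logcosh contrast, symmetric decorrelation). Components
#' are ranked by the share of band-limited variance they explain
#' (relative power). Loadings follow the convention that the
#' maximum-absolute element is positive. Components whose absolute
#' loading is near-flat across depth (coefficient of variation below
#' `flat_cv`) are flagged as volume-conducted and excluded from the
#' laminar set.
#'
#' @param rec LFP [probe_recording()].
#' @param band filter band, Hz (default gamma 30-100).
#' @param n_pcs principal components retained before ICA.
#' @param n_ics number of laminar ICs to report.
#' @param seed RNG seed (new seeds are drawn on non-convergence).
#' @param intervals optional state intervals restricting the data.
#' @param flat_cv flatness threshold for the volume-conducted flag.
#' @param max_retries ICA restarts before giving up.
#' @return object of class `gamma_ica`: `loadings` (channels x comp,
#'   ranked by relative power), `time_series` (full recording length and
#'   aligned to session time, even when the decomposition was fitted on
#'   intervals), `relative_power`, `is_flat`, `laminar` (indices of the
#'   `n_ics` laminar ICs), `depth_um`.
#' @export
gamma_ica <- function(rec, band = c(30, 100), n_pcs = 10, n_ics = 6,
                      seed = 1, intervals = NULL, flat_cv = 0.1,
                      max_retries = 3) {
  stopifnot(inherits(rec, "probe_recording"))
  if (ncol(rec$samples) < n_pcs) stop("need at least n_pcs channels")
  Xf <- as.matrix(fft_bandpass(rec$samples, rec$fs, band[1], band[2]))
  X <- Xf
  if (!is.null(intervals)) {
    keep <- iv_contains(as_intervals(intervals),
                        (seq_len(nrow(Xf)) - 0.5) / rec$fs)
    X <- Xf[keep, , drop = FALSE]
  }
  mu <- colMeans(X)
  X <- sweep(X, 2, mu)
  total_var <- sum(apply(X, 2, stats::var))
  res <- NULL
  for (try in seq_len(max_retries)) {
    res <- with_seed(derive_seed(seed + try - 1L, "ica"), {
      fast_ica_core(X, n_pcs)
    })
    if (res$converged) break
  }
  if (!res$converged) stop("ICA failed to converge after retries")
  unmix <- res$K %*% t(res$W)
  S <- X %*% unmix                       # fit-interval ICs, unit variance
  # mixing in channel space: X ~ S %*% t(loadings); the ICs are unit
  # variance and uncorrelated, so E[x s^T] recovers the mixing columns
  loadings <- crossprod(X, S) / nrow(X)  # channels x comp
  power <- colSums(loadings^2)           # variance explained per IC
  ord <- order(power, decreasing = TRUE)
  loadings <- loadings[, ord, drop = FALSE]
  unmix <- unmix[, ord, drop = FALSE]
  power <- power[ord]
  # sign convention
  for (k in seq_len(ncol(loadings))) {
    s <- sign(loadings[which.max(abs(loadings[, k])), k])
    loadings[, k] <- loadings[, k] * s
    unmix[, k] <- unmix[, k] * s
  }
  # IC time courses over the whole recording (aligned with session
  # time), projected with the unmixing fitted on the given intervals
  S <- sweep(Xf, 2, mu) %*% unmix
  al <- abs(loadings)
  cv <- apply(al, 2, function(v) stats::sd(v) / mean(v))
  is_flat <- cv < flat_cv
  laminar <- which(!is_flat)[seq_len(min(n_ics, sum(!is_flat)))]
  structure(list(loadings = loadings, time_series = S,
                 relative_power = power / total_var, loading_cv = cv,
                 is_flat = is_flat, laminar = laminar,
                 depth_um = rec$channel_depth_um, fs = rec$fs,
                 band = band),
            class = "gamma_ica")
}

#' @export
print.gamma_ica <- function(x, ...) {
  cat(sprintf(
    "<gamma_ica> %d ICs (%d laminar, %d flat); top relative power %.3f\n",
    ncol(x$loadings), length(x$laminar), sum(x$is_flat),
    max(x$relative_power)))
  invisible(x)
}

#' Assemble a laminar map
#'
#' Bundles landmarks, a depth warp, the coherence clustering and the ICA
#' decomposition into one laminar map object.
#'
#' @param landmarks [find_landmarks()] output.
#' @param warp [normalize_depth()] output.
#' @param clustering [gradient_descent_cluster()] output.
#' @param ica [gamma_ica()] output.
#' @return object of class `laminar_map`.
#' @export
laminar_map <- function(landmarks, warp = NULL, clustering = NULL,
                        ica = NULL) {
  structure(list(landmarks = landmarks, warp = warp,
                 clustering = clustering, ica = ica),
            class = "laminar_map")
}

#' @export
print.laminar_map <- function(x, ...) {
  cat("<laminar_map> landmarks (um):\n")
  print(round(unclass(x$landmarks), 1))
  if (!is.null(x$clustering)) {
    cat(sprintf("  %d coherence clusters\n", x$clustering$n_clusters))
  }
  if (!is.null(x$ica)) {
    cat(sprintf("  %d laminar ICs\n", length(x$ica$laminar)))
  }
  invisible(x)
}
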
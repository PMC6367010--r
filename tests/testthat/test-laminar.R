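test_that("MUA power profile finds the amplified channel", {
  fs <- 20000; n <- 2 * fs
  set.seed(10)
  X <- matrix(rnorm(n * 8), n)
  X[, 5] <- 3 * X[, 5]
  rec <- probe_recording(X, fs, (0:7) * 20)
  p <- mua_power_profile(rec)
  expect_equal(which.max(p), 5)
  expect_equal(attr(p, "peak_depth_um"), 80)
  # DC channels: degenerate profile flagged
  dc <- probe_recording(matrix(1, n, 4), fs, (0:3) * 20)
  expect_warning(pd <- mua_power_profile(dc), "degenerate")
  expect_true(is.na(attr(pd, "peak_depth_um")))
  expect_error(mua_power_profile(
    probe_recording(matrix(0, 100, 2), 1250, c(0, 20))), "10 kHz")
})

test_that("CSD of a linear depth profile vanishes on interior channels", {
  fs <- 1250; n <- 10 * fs
  depth <- (0:15) * 20
  ramp <- outer(sin(2 * pi * 3 * seq_len(n) / fs), depth / 100)
  rec <- probe_recording(ramp, fs, depth)
  csd <- suppressWarnings(
    event_triggered_csd(rec, c(2, 4, 6), window_s = c(0.1, 0.1)))
  expect_lt(max(abs(csd$csd)), 1e-9)
})

test_that("a planted dipole is recovered within one channel", {
  fs <- 1250; n <- 60 * fs
  depth <- (0:63) * 20
  set.seed(11)
  h <- numeric(n)
  ev <- seq(1, 59, by = 0.5)
  for (tt in ev) {
    idx <- round(tt * fs) + seq_len(round(0.1 * fs))
    h[idx] <- sin(pi * seq_along(idx) / length(idx))
  }
  prof <- -exp(-(depth - depth[40])^2 / (2 * 50^2)) +   # sink at ch 40
    exp(-(depth - depth[48])^2 / (2 * 50^2))            # source at ch 48
  X <- outer(h, prof) * 100 + matrix(rnorm(n * 64, sd = 5), n)
  rec <- probe_recording(X, fs, depth)
  csd <- event_triggered_csd(rec, ev + 0.02, window_s = c(0, 0.08))
  peak_frame <- which.max(colSums(abs(csd$csd)))
  prof_t <- csd$csd[, peak_frame]
  expect_lte(abs(which.min(prof_t) + 1 - 40), 1)
  expect_lte(abs(which.max(prof_t) + 1 - 48), 1)
  # n = 1 identity: a single event equals that event's window average
  one <- event_triggered_csd(rec, ev[5], window_s = c(0, 0.08))
  i0 <- round(ev[5] * fs) + 1
  seg <- X[i0:(i0 + round(0.08 * fs)), ]
  csd_direct <- -(seg[, 1:62] - 2 * seg[, 2:63] + seg[, 3:64]) / 20^2
  expect_equal(one$csd, t(csd_direct), tolerance = 1e-9)
})

test_that("landmarks are recovered from a synthetic session", {
  s <- session_64ch()
  mua <- mua_power_profile(s$wideband)
  truth <- s$truth$downup_intervals
  trans <- truth$end[truth$label == "DOWN"]
  csd <- event_triggered_csd(s$lfp, trans, window_s = c(0.05, 0.2))
  lmk <- find_landmarks(mua, csd)
  expect_true(all(abs(lmk - s$truth$landmarks_um) <= 20))
  expect_true(!is.unsorted(lmk, strictly = TRUE))
  # flat CSD is a landmark error
  flat <- csd
  flat$csd[] <- 0
  expect_error(find_landmarks(mua, flat), "landmark error")
})

test_that("inter-landmark distances are stable across simulated animals", {
  # jittered landmark sets across 10 simulated animals: the recovered
  # distances vary by less than 100 um (SD)
  dists <- t(vapply(1:10, function(a) {
    cfg <- sim_config(duration_s = 600, seed = 200 + a)
    jit <- cfg$landmarks_um + c(0, round(rnorm(4, 0, 30) / 20) * 20)
    jit <- sort(jit)
    diff(jit)
  }, numeric(4)))
  expect_true(all(apply(dists, 2, stats::sd) <= 100))
})

test_that("depth warp is exact at landmarks, monotone and invertible", {
  lmk <- c(120, 400, 700, 860, 1080)
  canon <- c(100, 390, 680, 830, 1100)
  w <- normalize_depth(lmk, canon)
  expect_equal(warp_depth(w, lmk), canon)
  # identity when landmark sets coincide
  wi <- normalize_depth(canon, canon)
  expect_equal(warp_depth(wi, seq(0, 1300, by = 50)),
               seq(0, 1300, by = 50))
  # uniform x1.1 stretch gives slope 1/1.1 between all pairs
  ws <- normalize_depth(canon * 1.1, canon)
  x <- seq(min(canon * 1.1), max(canon * 1.1), length.out = 30)
  slopes <- diff(warp_depth(ws, x)) / diff(x)
  expect_equal(slopes, rep(1 / 1.1, 29), tolerance = 1e-9)
  # pia: 80 um above landmark a maps to canonical a - 80
  expect_equal(warp_depth(w, lmk[1] - 80), canon[1] - 80)
  expect_equal(w$pia_um, canon[1] - 80)
  # warp composed with its inverse is the identity
  x <- seq(0, 1300, by = 13)
  expect_lt(max(abs(unwarp_depth(w, warp_depth(w, x)) - x)), 1e-9)
  # monotone
  expect_true(all(diff(warp_depth(w, x)) > 0))
  expect_error(normalize_depth(c(2, 1, 3), c(1, 2, 3)), "increasing")
})

test_that("gradient descent recovers perfect blocks and descends energy", {
  C <- matrix(0, 6, 6)
  C[1:3, 1:3] <- 1; C[4:6, 4:6] <- 1; diag(C) <- 1
  cl <- gradient_descent_cluster(C, n_restarts = 10, seed = 1)
  expect_equal(cl$n_clusters, 2)
  expect_equal(cl$consistency, 1)
  expect_true(all(vapply(cl$restart_assignments, function(z)
    mclust::adjustedRandIndex(z, rep(1:2, each = 3)) == 1, TRUE)))
  expect_error(gradient_descent_cluster(matrix(runif(9), 3)), "symmetric")
})

test_that("converged energy matches exhaustive enumeration on 6 sites", {
  parts <- all_partitions(6)
  expect_length(parts, 203)
  set.seed(12)
  bad <- 0
  for (r in 1:60) {
    C <- matrix(runif(36), 6); C <- (C + t(C)) / 2; diag(C) <- 1
    cl <- gradient_descent_cluster(C, n_restarts = 8, seed = r)
    emin <- min(vapply(parts, oracle_energy, 0, C = C))
    expect_gte(cl$energy, emin - 1e-9)   # never below the true optimum
    if (cl$energy > emin + 1e-9) bad <- bad + 1
  }
  expect_lt(bad / 60, 0.2)
})

test_that("ICA recovers planted mixtures and flags the flat component", {
  fs <- 1250; n <- 120 * fs
  set.seed(13)
  mk_src <- function(f) {
    e <- exp(0.6 * as.numeric(scale(lamprobe:::fft_bandpass(
      rnorm(n), fs, NULL, 2))))
    s <- e * cos(2 * pi * f * seq_len(n) / fs +
                   cumsum(rnorm(n, sd = 0.05)))
    s / stats::sd(s)
  }
  A <- cbind(c(1, 0.8, 0.3, 0, 0, 0, 0, 0),
             c(0, 0, 0.2, 0.9, 1, 0.4, 0.1, 0))
  X <- cbind(mk_src(45), mk_src(70)) %*% t(A) * 20 +
    matrix(rnorm(n * 8, sd = 2), n)
  rec <- probe_recording(X, fs, (0:7) * 20)
  ic <- gamma_ica(rec, n_pcs = 6, n_ics = 2, seed = 1)
  for (k in 1:2) {
    r <- max(abs(stats::cor(A[, k],
                            ic$loadings[, ic$laminar, drop = FALSE])))
    expect_gte(r, 0.95)
  }
  # one dominant source -> first IC explains most of the band variance
  X1 <- outer(rep(1, n), runif(8, 0.5, 1)) * mk_src(55) * 20 +
    matrix(rnorm(n * 8, sd = 0.5), n)
  ic1 <- gamma_ica(probe_recording(X1, fs, (0:7) * 20), n_pcs = 6,
                   n_ics = 1, seed = 1)
  expect_gte(max(ic1$relative_power), 0.95)
  # session with a volume-conducted source: one near-flat IC, excluded
  s <- session_64ch()
  wake <- state_intervals(s$truth$state_intervals, "WAKE")
  ics <- fixture("ica64", function()
    gamma_ica(s$lfp, n_pcs = 10, n_ics = 6, seed = 1, intervals = wake))
  expect_gte(sum(ics$is_flat), 1)
  expect_true(all(ics$loading_cv[ics$laminar] >= 0.1))
})
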
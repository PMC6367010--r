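make_wf <- function(class, tp_ms) lamprobe:::make_waveform(class, tp_ms,
                                                           20000)

test_that("waveform classes follow the trough-to-peak boundary", {
  e <- classify_waveform(make_wf("E", 0.60), 20000)
  expect_equal(e$waveform_class, "E")
  expect_equal(e$tp_latency_ms, 0.60, tolerance = 0.05)
  i <- classify_waveform(make_wf("I", 0.40), 20000)
  expect_equal(i$waveform_class, "I")
  p <- classify_waveform(make_wf("POSITIVE", 0.7), 20000)
  expect_equal(p$waveform_class, "POSITIVE")
  expect_error(classify_waveform(rep(0, 64), 20000), "flat")
  # scale invariance
  for (a in c(0.1, 3, 1000)) {
    expect_equal(classify_waveform(a * make_wf("E", 0.8),
                                   20000)$waveform_class, "E")
  }
})

test_that("population fiber rule isolates kurtosis outliers", {
  set.seed(14)
  units <- lapply(1:12, function(k) list(
    spike_times = sort(runif(200, 0, 100)), peak_channel = 1L,
    mean_waveform = make_wf("E", runif(1, 0.7, 0.9)) + rnorm(64, sd = 0.5)))
  units$fib <- list(spike_times = sort(runif(200, 0, 100)),
                    peak_channel = 1L,
                    mean_waveform = make_wf("FIBER", 0.3))
  names(units)[1:12] <- paste0("u", 1:12)
  spk <- spike_dataset(units, 20000, 100)
  cls <- classify_units(spk)
  expect_equal(cls$waveform_class[cls$unit == "fib"], "FIBER")
  expect_true(all(cls$waveform_class[cls$unit != "fib"] == "E"))
})

test_that("optotagging detects planted responses and not null spiking", {
  pulses <- seq(10, 509, by = 1)
  set.seed(15)
  resp <- pulses[runif(500) < 0.8] + 0.003 + rnorm(500, 0, 2e-4)[seq_len(
    sum(runif(500) < 0.8))]
  st <- sort(c(runif(1000, 0, 520), resp))
  r <- optotag(st, pulses)
  expect_true(r$tagged)
  # baseline-rate-matched jittered control: tag rate below 1 percent
  tags <- vapply(1:200, function(k) {
    set.seed(1000 + k)
    optotag(sort(runif(1040, 0, 520)), pulses)$tagged
  }, TRUE)
  expect_lt(mean(tags), 0.01)
  # degenerate silent baseline flagged
  only_resp <- sort(pulses + 0.003)
  rd <- optotag(only_resp, pulses)
  expect_true(rd$degenerate)
  expect_true(rd$tagged)
  expect_error(optotag(st, pulses[1:50]), "100 pulses")
})

test_that("burst index is calibrated on Poisson, refractory and bursty trains", {
  idx <- vapply(1:40, function(k)
    burst_index(poisson_train(10, 1000, seed = 2000 + k))$index, 0)
  # simulation confidence interval covers 1
  ci <- mean(idx) + c(-2, 2) * stats::sd(idx) / sqrt(length(idx))
  expect_gt(1, ci[1]); expect_lt(1, ci[2])
  expect_true(all(abs(idx - 1) < 0.1))
  # refractory train: empty burst window
  set.seed(16)
  refr <- cumsum(rexp(20000, 10) + 0.02)
  expect_equal(burst_index(refr)$index, 0)
  # planted doublets at 4 ms
  base <- cumsum(rexp(5000, 2))
  burster <- sort(c(base, base + 0.004))
  expect_gt(burst_index(burster)$index, 2)
  expect_error(burst_index(1:50), "100 spikes")
})

test_that("UP-state dynamics separate transient from steady firing", {
  set.seed(17)
  onsets <- sort(runif(300, 1, 999))
  # constant-rate unit: ratio near 1 (binomial noise only)
  flat <- poisson_train(20, 1000, seed = 18)
  r_flat <- up_state_dynamics(flat, data.frame(start = onsets))
  expect_lt(abs(r_flat$transient_steady_ratio - 1), 0.35)
  # onset burst decaying within 100 ms
  burst <- sort(c(flat, unlist(lapply(onsets, function(o)
    o + rexp(3, 30)))))
  r_burst <- up_state_dynamics(burst, data.frame(start = onsets))
  expect_gt(r_burst$transient_steady_ratio, 2)
  # planted 10 ms first-spike latency
  lat <- sort(c(unlist(lapply(onsets, function(o) o + 0.01)),
                poisson_train(0.5, 1000, seed = 19)))
  r_lat <- up_state_dynamics(lat, data.frame(start = onsets))
  expect_equal(r_lat$downup_latency_s, 0.010, tolerance = 0.003)
  expect_error(up_state_dynamics(flat, data.frame(start = onsets[1:10])),
               "50")
})

test_that("DOWN-active detection flags the planted unit and controls errors", {
  s <- session_states()
  nrem <- state_intervals(s$truth$state_intervals, "NREM")
  du <- fixture("du_states", function()
    detect_slow_waves(s$lfp, s$spikes, nrem, channel = 12))
  expect_gt(nrow(du$down), 50)
  ut <- s$truth$unit_table
  da <- which(ut$class == "DOWN_ACTIVE")
  r <- detect_down_active(s$spikes$units[[da]]$spike_times, du)
  expect_true(r$flagged)
  expect_gt(r$rate_down_hz, r$rate_up_hz)
  # ordinary UP-active units are not flagged
  for (u in which(ut$class == "E")[1:3]) {
    expect_false(detect_down_active(s$spikes$units[[u]]$spike_times,
                                    du)$flagged)
  }
  # null false-positive rate at most alpha (rate-matched, state-blind)
  dur <- max(du$up$end)
  fp <- vapply(1:300, function(k) {
    detect_down_active(poisson_train(3, dur, seed = 3000 + k), du,
                       alpha = 0.05)$flagged
  }, TRUE)
  expect_lte(mean(fp), 0.05)
})

test_that("cityblock k-means with silhouettes recovers planted profiles", {
  set.seed(20)
  proto <- matrix(runif(18, 0, 0.6), 3, 6)
  X <- proto[rep(1:3, each = 15), ] + matrix(rnorm(45 * 6, 0, 0.03), 45)
  X[X < 0] <- 0
  cl <- cluster_by_ic_coupling(X, seed = 1)
  expect_equal(cl$k, 3)
  expect_equal(mclust::adjustedRandIndex(cl$cluster, rep(1:3, each = 15)),
               1)
  # deterministic given the seed
  cl2 <- cluster_by_ic_coupling(X, seed = 1)
  expect_identical(cl$cluster, cl2$cluster)
  # identical profiles degenerate to a single flagged cluster
  cld <- cluster_by_ic_coupling(matrix(0.4, 25, 6), seed = 1)
  expect_true(cld$degenerate)
  expect_equal(cld$k, 1L)
  expect_error(cluster_by_ic_coupling(matrix(0, 25, 6)), "20 units")
  # modal K across seeds on a separated 5-cluster mixture
  proto5 <- diag(5)[, c(1:5, 1)] * 0.5
  X5 <- proto5[rep(1:5, each = 12), ] +
    matrix(rnorm(60 * 6, 0, 0.02), 60)
  ks <- vapply(1:10, function(sd) cluster_by_ic_coupling(X5,
                                                         seed = sd)$k, 0L)
  expect_equal(as.integer(names(which.max(table(ks)))), 5L)
})

test_that("state rate tables compute per-state rates and ratios", {
  states <- data.frame(start = c(0, 300), end = c(300, 600),
                       label = c("WAKE", "NREM"))
  st <- seq(0.05, 599.95, by = 0.1)      # 10 Hz throughout
  r <- state_rate_table(st, states)
  expect_equal(unname(r$rates_hz["WAKE"]), 10, tolerance = 0.01)
  expect_equal(r$wake_nrem_ratio, 1, tolerance = 0.01)
  # planted 2x elevation in wake
  st2 <- sort(c(seq(0.05, 299.95, by = 0.05), seq(300.1, 599.9, by = 0.1)))
  r2 <- state_rate_table(st2, states)
  expect_equal(r2$wake_nrem_ratio, 2, tolerance = 0.02)
  # silent NREM: infinite ratio flagged undefined
  st3 <- runif(100, 0, 299)
  r3 <- state_rate_table(sort(st3), states)
  expect_true(is.infinite(r3$wake_nrem_ratio))
  expect_false(r3$ratio_defined)
})

test_that("spike-IC coupling matrix reflects planted layer coupling", {
  s <- session_64ch()
  wake <- state_intervals(s$truth$state_intervals, "WAKE")
  ics <- fixture("ica64", function()
    gamma_ica(s$lfp, n_pcs = 10, n_ics = 6, seed = 1, intervals = wake))
  spk_sub <- spike_dataset(s$spikes$units[1:8], s$spikes$fs_waveform,
                           s$spikes$duration_s)
  M <- spike_ic_coupling_matrix(spk_sub, ics, intervals = wake)
  expect_equal(dim(M), c(8L, length(ics$laminar)))
  expect_true(all(M >= 0 & M <= 1))
  # each unit's strongest coupling is to an IC loading peaked in its layer
  ut <- s$truth$unit_table[1:8, ]
  hits <- vapply(1:8, function(u) {
    if (max(M[u, ]) == 0) return(NA)
    best_ic <- ics$laminar[which.max(M[u, ])]
    peak_depth <- ics$depth_um[which.max(abs(ics$loadings[, best_ic]))]
    lb <- c(s$cfg$layer_bounds_um, 1280)
    findInterval(peak_depth, s$cfg$layer_bounds_um) == ut$layer[u]
  }, NA)
  expect_gte(mean(hits, na.rm = TRUE), 0.7)
})
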
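# Shared fixtures: sessions are generated once per test run and cached.

.fixture_cache <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (!exists(name, envir = .fixture_cache)) {
    assign(name, build(), envir = .fixture_cache)
    gc(verbose = FALSE)
  }
  get(name, envir = .fixture_cache)
}

# drop a cached fixture once the last test that needs it has run
drop_fixture <- function(name) {
  if (exists(name, envir = .fixture_cache)) {
    rm(list = name, envir = .fixture_cache)
    gc(verbose = FALSE)
  }
  invisible(NULL)
}

# 64-channel session: 300 s NREM then 300 s WAKE, wideband head segment.
# Serves laminar-map recovery (coherence clustering, ICA, landmarks) and
# slow-wave boundary checks.
session_64ch <- function() {
  fixture("s64", function() {
    simulate_session(sim_config(
      duration_s = 600, seed = 101, n_channels = 64, n_units = 20,
      wideband_s = 10,
      state_schedule = data.frame(start = c(0, 300), end = c(300, 600),
                                  label = c("NREM", "WAKE"))))
  })
}

# 30-minute three-state session at 16 channels for state scoring and
# DOWN-active detection. 60 units so the single DOWN-active cell stays a
# small minority of the population (its DOWN-state firing would otherwise
# mask the population silence that calibrates the slow-wave threshold).
session_states <- function() {
  fixture("sstates", function() {
    simulate_session(sim_config(
      duration_s = 1800, seed = 102, n_channels = 16, n_units = 60,
      n_down_active = 1))
  })
}

# NREM/WAKE alternation with a 5-minute and a 7-minute waking bout, for
# the minimum-waking-duration rule (8 channels: scoring only).
session_arousal <- function() {
  fixture("s_arousal", function() {
    sched <- data.frame(start = c(0, 480, 780, 1320),
                        end = c(480, 780, 1320, 1800),
                        label = c("NREM", "WAKE", "NREM", "WAKE"))
    simulate_session(sim_config(duration_s = 1800, seed = 104,
                                n_channels = 8, n_units = 15,
                                state_schedule = sched))
  })
}

# all-NREM session with explicit 30 ms DOWN states (40 ms rule checks)
session_short_down <- function() {
  fixture("s_short_down", function() {
    st <- seq(0, 570, by = 0.5)
    duv <- data.frame(start = c(rbind(st, st + 0.47)),
                      end = c(rbind(st + 0.47, st + 0.5)),
                      label = c(rbind("UP", "DOWN")))
    duv <- duv[duv$end <= 600, ]
    simulate_session(sim_config(
      duration_s = 600, seed = 106, n_channels = 16, n_units = 15,
      state_schedule = data.frame(start = 0, end = 600, label = "NREM"),
      slow = list(downup_intervals = duv)))
  })
}

# 20-unit connectivity session with planted E edges at three strengths.
session_network <- function() {
  fixture("snet", function() {
    edges <- data.frame(pre = 1:5, post = 6:10, sign = "E",
                        p = c(0.05, 0.1, 0.1, 0.2, 0.2))
    simulate_session(sim_config(
      duration_s = 600, seed = 103, n_channels = 16, n_units = 20,
      edges = edges,
      units_par = list(rate_meanlog = log(5), rate_sdlog = 0.3)))
  })
}

# homogeneous Poisson spike train
poisson_train <- function(rate_hz, duration_s, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  sort(stats::runif(stats::rpois(1, rate_hz * duration_s), 0, duration_s))
}

# exhaustive enumeration of all set partitions of n items (oracle for the
# gradient-descent optimality checks; Bell(6) = 203)
all_partitions <- function(n) {
  res <- list()
  gen <- function(assign, i, k) {
    if (i > n) {
      res[[length(res) + 1L]] <<- assign
      return(invisible())
    }
    for (lab in seq_len(k + 1L)) gen(c(assign, lab), i + 1L, max(k, lab))
  }
  gen(integer(0), 1L, 0L)
  res
}

# total interaction energy of a labeled partition (independent of the
# package internals: direct double sum, diagonal excluded)
oracle_energy <- function(C, z) {
  e <- 0
  for (lab in unique(z)) {
    m <- which(z == lab)
    s <- 0
    for (i in m) for (j in m) if (i != j) s <- s + C[i, j]
    e <- e - s / length(m)
  }
  e
}

# per-boundary absolute errors (s) between detected and true DOWN events
boundary_errors <- function(detected, truth) {
  unlist(lapply(seq_len(nrow(detected)), function(i) {
    j <- which.min(abs(truth$start - detected$start[i]))
    c(abs(detected$start[i] - truth$start[j]),
      abs(detected$end[i] - truth$end[j]))
  }))
}

# majority per-frame state labels from a truth interval table
truth_frame_labels <- function(truth_states, frame_times) {
  lab <- rep(NA_character_, length(frame_times))
  for (r in seq_len(nrow(truth_states))) {
    sel <- frame_times >= truth_states$start[r] &
      frame_times < truth_states$end[r]
    lab[sel] <- truth_states$label[r]
  }
  lab
}
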
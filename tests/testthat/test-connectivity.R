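test_that("cross-correlograms count lags as specified", {
  pre <- c(1, 2, 3, 4)
  post <- pre + 0.0022
  cc <- compute_ccg(pre, post)
  expect_equal(sum(cc$counts), 4)
  expect_equal(cc$lag_ms[which(cc$counts == 4)], 2.25)  # bin [2.0, 2.5)
  # identical trains: self-pairs excluded, symmetric counts remain
  cc_self <- compute_ccg(pre, pre)
  expect_equal(sum(cc_self$counts), 0)    # spacing 1 s > 50 ms window
  # CCG(pre->post) at +t mirrors CCG(post->pre) at -t
  set.seed(21)
  a <- sort(runif(500, 0, 100)); b <- sort(runif(500, 0, 100))
  expect_equal(compute_ccg(a, b)$counts,
               rev(compute_ccg(b, a)$counts))
  # independent Poisson trains match the analytic expectation
  a <- poisson_train(5, 600, seed = 22); b <- poisson_train(5, 600,
                                                            seed = 23)
  cc2 <- compute_ccg(a, b)
  expect_equal(mean(cc2$counts), length(a) * 5 * 5e-4, tolerance = 0.05)
  expect_error(compute_ccg(numeric(0), b), "empty")
})

test_that("the Gaussian baseline predictor is unbiased and mass-preserving", {
  cc <- structure(list(lag_ms = (seq_len(200) - 100.5) * 0.5,
                       counts = rep(7, 200), n_pre = 100L, n_post = 100L,
                       bin_ms = 0.5), class = "ccg")
  pred <- baseline_predictor(cc)
  expect_equal(pred, rep(7, 200), tolerance = 1e-9)     # flat stays flat
  cc$counts <- c(rep(0, 99), 50, rep(0, 100))
  pred <- baseline_predictor(cc)
  expect_equal(which.max(pred), 100)                    # peak at the bin
  expect_equal(sum(pred), 50, tolerance = 1e-6)         # mass preserved
  expect_true(all(pred >= 0))
})

test_that("Poisson bounds match an independent oracle over a lambda grid", {
  grid <- c(0.01, 0.1, 1, 5, 10, 50)
  b <- poisson_bounds(grid)
  # oracle: exact distribution functions from stats
  k_hi_oracle <- qpois(0.999999, grid)
  k_lo_oracle <- vapply(grid, function(l) {
    ks <- 0:qpois(0.5, l)
    ok <- ks[ppois(ks, l) <= 1e-6]
    if (length(ok)) max(ok) else -1L
  }, 0)
  expect_identical(b$k_hi, as.integer(k_hi_oracle))
  expect_identical(b$k_lo, as.integer(k_lo_oracle))
  expect_identical(poisson_bounds(0)$k_hi, 0L)
  expect_identical(poisson_bounds(0)$k_lo, -1L)
  # monotone in lambda
  ks <- poisson_bounds(seq(0.1, 30, by = 0.1))$k_hi
  expect_true(all(diff(ks) >= 0))
  expect_error(poisson_bounds(-1), "non-negative")
})

test_that("edge detection requires two consecutive significant bins", {
  # flat CCG matching its predictor: no edge
  set.seed(24)
  a <- poisson_train(5, 600); b <- poisson_train(5, 600)
  cc <- compute_ccg(a, b)
  expect_null(detect_edges(cc))
  # single significant bin only: no edge under the two-bin rule
  cc1 <- cc
  idx <- lamprobe:::mono_window_idx(cc1)
  pred <- baseline_predictor(cc1)
  k_hi <- poisson_bounds(pred[idx[3]])$k_hi
  cc1$counts[idx[3]] <- k_hi + 30
  expect_null(detect_edges(cc1, baseline_predictor(cc)))
  # two consecutive raised bins: excitatory edge
  cc2 <- cc
  cc2$counts[idx[2:3]] <- cc2$counts[idx[2:3]] + 40
  ed <- detect_edges(cc2, baseline_predictor(cc))
  expect_equal(ed$sign, "E")
  expect_error(detect_edges(cc, predictor = 1:5), "aligned")
})

test_that("planted pairs are detected with accurate transmission", {
  pr <- simulate_spike_pair(600, 5, 5, p = 0.1, sign = "E", seed = 25)
  cc <- compute_ccg(pr$pre, pr$post)
  pred <- baseline_predictor(cc)
  ed <- detect_edges(cc, pred)
  expect_equal(ed$sign, "E")
  tp <- transmission_probability(cc, pred)
  expect_lt(abs(tp$transmission - 0.1), 0.025)
  expect_gt(tp$peak_to_baseline, 1.5)
  # counts equal to the predictor give zero transmission
  ccf <- structure(list(lag_ms = cc$lag_ms, counts = rep(5, 200),
                        n_pre = 1000L, n_post = 1000L, bin_ms = 0.5),
                   class = "ccg")
  expect_equal(transmission_probability(ccf,
                                        rep(5, 200))$transmission, 0)
  # inhibitory thinning yields negative transmission
  pri <- simulate_spike_pair(600, 15, 15, p = 0.3, sign = "I", seed = 26)
  cci <- compute_ccg(pri$pre, pri$post)
  expect_lt(transmission_probability(cci)$transmission, 0)
})

test_that("detection sensitivity grows with transmission and duration", {
  det_rate <- function(p, dur, n = 12) {
    mean(vapply(seq_len(n), function(k) {
      pr <- simulate_spike_pair(dur, 4, 4, p = p, sign = "E",
                                seed = 37 * k + round(1e4 * p) + dur)
      !is.null(detect_edges(compute_ccg(pr$pre, pr$post)))
    }, TRUE))
  }
  r_small <- det_rate(0.02, 300)
  r_mid <- det_rate(0.05, 300)
  r_big <- det_rate(0.15, 300)
  expect_lte(r_small, r_mid + 1e-9)
  expect_lte(r_mid, r_big + 1e-9)
  expect_gte(det_rate(0.05, 900), r_mid - 1e-9)   # longer helps
})

test_that("state-resolved transmission compares paired edges", {
  s <- session_network()
  det <- fixture("net_edges", function() detect_connections(s$spikes))
  expect_gte(sum(det$sign == "E"), 3)
  states <- s$truth$state_intervals
  res <- state_dependent_transmission(det, s$spikes, states,
                                      min_pre_spikes = 200)
  expect_equal(nrow(res$per_edge) + length(res$excluded), nrow(det))
  # single state present: refused
  one_state <- data.frame(start = 0, end = 600, label = "WAKE")
  expect_error(state_dependent_transmission(det, s$spikes, one_state),
               "both states")
})

test_that("CCG identity matches the planted presynaptic classes", {
  s <- session_network()
  det <- fixture("net_edges", function() detect_connections(s$spikes))
  ids <- ccg_identity(det)
  ut <- s$truth$unit_table
  classified <- ids[ids$ccg_class %in% c("E", "I"), ]
  truth_cls <- ut$class[match(classified$unit, ut$unit)]
  expect_gte(mean(classified$ccg_class == truth_cls), 0.95)
  # direct rules
  ed <- data.frame(pre = c("a", "b", "b"), post = c("x", "y", "z"),
                   sign = c("E", "E", "I"), ambiguous = FALSE)
  ids2 <- ccg_identity(ed, unit_ids = c("a", "b", "c"))
  expect_equal(ids2$ccg_class, c("E", "AMBIGUOUS", "NONE"))
})
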
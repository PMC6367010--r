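# Monosynaptic connectivity from cross-correlograms: Gaussian-convolved
# baseline predictor, exact Poisson significance bounds, edge detection
# in the +1.5 to +4 ms window, spike transmission probability and its
# brain-state dependence.

#' Spike-train cross-correlogram
#'
#' Counts of postsynaptic spikes at lag (post - pre) in 0.5 ms bins over
#' +/- `halfwidth_ms`, optionally restricted to intervals (both trains
#' are restricted; lags never span interval boundaries because spikes
#' outside the intervals are removed before counting).
#'
#' @param pre_times,post_times sorted spike times, s (non-empty within
#'   `intervals`). When the trains are identical, self-pairs (lag 0 of a
#'   spike with itself) are excluded.
#' @param bin_ms bin width, ms.
#' @param halfwidth_ms correlogram half width, ms.
#' @param intervals optional interval matrix/data.frame, s.
#' @return object of class `ccg`: `lag_ms` (bin centers), `counts`,
#'   `n_pre`, `n_post`, `bin_ms`.
#' @export
compute_ccg <- function(pre_times, post_times, bin_ms = 0.5,
                        halfwidth_ms = 50, intervals = NULL) {
  if (!is.null(intervals)) {
    iv <- as_intervals(intervals)
    pre_times <- iv_restrict(pre_times, iv)
    post_times <- iv_restrict(post_times, iv)
  }
  if (!length(pre_times) || !length(post_times)) {
    stop("empty spike train within the analysis intervals")
  }
  bw <- bin_ms / 1000
  hw <- halfwidth_ms / 1000
  # bin edges at multiples of the bin width: bins [k*bw, (k+1)*bw), so
  # the (+1.5, +4] ms window is exactly the bins centered 1.75-3.75 ms
  half <- round(hw / bw)
  n_bins <- 2L * half
  identical_trains <- length(pre_times) == length(post_times) &&
    all(pre_times == post_times)
  lo <- findInterval(pre_times - hw, post_times)
  hi <- findInterval(pre_times + hw, post_times)
  nper <- pmax(hi - lo, 0L)
  keep <- nper > 0L
  post_idx <- sequence(nper[keep]) + rep(lo[keep], nper[keep])
  d <- post_times[post_idx] - rep(pre_times[keep], nper[keep])
  if (identical_trains) d <- d[d != 0]
  b <- floor(d / bw) + half + 1L
  b <- b[b >= 1 & b <= n_bins]
  counts <- tabulate(b, n_bins)
  structure(list(lag_ms = (seq_len(n_bins) - half - 0.5) * bin_ms,
                 counts = counts, n_pre = length(pre_times),
                 n_post = length(post_times), bin_ms = bin_ms),
            class = "ccg")
}

#' @export
print.ccg <- function(x, ...) {
  cat(sprintf("<ccg> %d bins x %.2g ms, n_pre = %d, n_post = %d\n",
              length(x$counts), x$bin_ms, x$n_pre, x$n_post))
  invisible(x)
}

#' Gaussian-convolved baseline predictor
#'
#' Convolves the CCG counts with a unit-area Gaussian window (SD
#' `sigma_ms`, default 7 ms) with reflected-edge handling, yielding the
#' expected count per bin under a slowly varying baseline.
#'
#' @param ccg a [compute_ccg()] result.
#' @param sigma_ms Gaussian SD, ms.
#' @return numeric vector of expected counts (>= 0), same length as the
#'   CCG.
#' @export
baseline_predictor <- function(ccg, sigma_ms = 7) {
  counts <- ccg$counts
  n <- length(counts)
  half_k <- ceiling(3 * sigma_ms / ccg$bin_ms)
  kern <- stats::dnorm(seq(-half_k, half_k) * ccg$bin_ms, sd = sigma_ms)
  kern <- kern / sum(kern)
  padded <- c(rev(counts[seq_len(half_k)]), counts,
              rev(counts[(n - half_k + 1L):n]))
  out <- stats::filter(padded, kern, sides = 2)
  pmax(as.numeric(out[(half_k + 1L):(half_k + n)]), 0)
}

#' Exact Poisson outlier bounds
#'
#' `k_hi` is the smallest integer whose Poisson CDF at rate `lambda`
#' reaches `p_hi` (99.9999th percentile by default); `k_lo` is the
#' largest integer with CDF at most `1 - p_hi` (-1 when none). Computed
#' by exact pmf summation with the multiplicative recurrence, no normal
#' approximation.
#'
#' @param lambda expected count (>= 0); vectorized.
#' @param p_hi upper-tail percentile.
#' @return list of integer vectors `k_hi`, `k_lo`.
#' @export
poisson_bounds <- function(lambda, p_hi = 0.999999) {
  if (any(lambda < 0)) stop("lambda must be non-negative")
  one <- function(lam) {
    if (lam == 0) return(c(0L, -1L))
    p <- exp(-lam)        # pmf at k = 0
    cdf <- p
    k <- 0L
    k_lo <- if (cdf <= 1 - p_hi) 0L else -1L
    while (cdf < p_hi) {
      k <- k + 1L
      p <- p * lam / k
      cdf <- cdf + p
      if (cdf <= 1 - p_hi) k_lo <- k
      if (k > 10 * (lam + 100)) break   # numeric safety
    }
    c(k, k_lo)
  }
  res <- vapply(lambda, one, integer(2))
  list(k_hi = res[1, ], k_lo = res[2, ])
}

# index set of the monosynaptic window (+1.5, +4] ms at the CCG bins
# (bin centers 1.75, 2.25, ..., 3.75 ms at 0.5 ms bins)
mono_window_idx <- function(ccg, window_ms = c(1.5, 4)) {
  which(ccg$lag_ms > window_ms[1] + 1e-9 &
          ccg$lag_ms < window_ms[2] + 1e-9)
}

#' Detect a putative monosynaptic edge from a CCG
#'
#' An excitatory edge requires at least two consecutive bins within
#' (+1.5, +4\] ms whose counts strictly exceed the upper Poisson bound of
#' the baseline predictor; an inhibitory edge requires two consecutive
#' bins strictly below the lower bound (same per-bin tail level). Both
#' may coexist; the result is then flagged.
#'
#' @param ccg a [compute_ccg()] result.
#' @param predictor baseline expected counts per bin (defaults to
#'   [baseline_predictor()]).
#' @param window_ms detection window, ms (half-open, bin centers
#'   1.75-3.75 ms at 0.5 ms bins).
#' @param p_hi Poisson percentile (per-bin tail 1e-6).
#' @return `NULL` when no edge; otherwise object of class `edge`: `sign`
#'   ("E" or "I"), `sig_bins_ms` (lags of significant bins), `ambiguous`
#'   flag, plus the window and threshold vectors.
#' @export
detect_edges <- function(ccg, predictor = baseline_predictor(ccg),
                         window_ms = c(1.5, 4), p_hi = 0.999999) {
  if (length(predictor) != length(ccg$counts)) {
    stop("predictor not aligned with the CCG bins")
  }
  idx <- mono_window_idx(ccg, window_ms)
  b <- poisson_bounds(predictor[idx], p_hi)
  hi_sig <- ccg$counts[idx] > b$k_hi
  lo_sig <- ccg$counts[idx] < b$k_lo
  two_consec <- function(v) any(v[-1] & v[-length(v)])
  e_edge <- two_consec(hi_sig)
  i_edge <- two_consec(lo_sig)
  if (!e_edge && !i_edge) return(NULL)
  sign <- if (e_edge && !i_edge) "E" else if (i_edge && !e_edge) "I"
          else "E"
  structure(list(sign = sign,
                 ambiguous = e_edge && i_edge,
                 sig_bins_ms = ccg$lag_ms[idx][if (sign == "E") hi_sig
                                               else lo_sig],
                 window_ms = window_ms, k_hi = b$k_hi, k_lo = b$k_lo),
            class = "edge")
}

#' Spike transmission probability and peak-to-baseline ratio
#'
#' The basic excess-probability estimate: the sum of (count - predictor)
#' over the monosynaptic window divided by the number of presynaptic
#' spikes (negative for inhibitory connections). Also reports the
#' peak-to-baseline ratio (maximum window count over mean predictor in
#' the window).
#'
#' @param ccg a [compute_ccg()] result.
#' @param predictor baseline expected counts.
#' @param window_ms transmission window, ms.
#' @return list: `transmission`, `peak_to_baseline`.
#' @export
transmission_probability <- function(ccg,
                                     predictor = baseline_predictor(ccg),
                                     window_ms = c(1.5, 4)) {
  if (ccg$n_pre == 0) stop("undefined: no presynaptic spikes")
  idx <- mono_window_idx(ccg, window_ms)
  excess <- sum(ccg$counts[idx] - predictor[idx])
  list(transmission = excess / ccg$n_pre,
       peak_to_baseline = max(ccg$counts[idx]) /
         max(mean(predictor[idx]), .Machine$double.eps))
}

#' Scan all unit pairs for monosynaptic edges
#'
#' @param spikes a [spike_dataset()].
#' @param intervals optional analysis intervals.
#' @param min_spikes minimum spikes per train inside the intervals.
#' @param ... passed to [detect_edges()].
#' @return data.frame of class `connection_graph`: one row per detected
#'   edge with `pre`, `post`, `sign`, `transmission`,
#'   `peak_to_baseline`, `ambiguous`.
#' @export
detect_connections <- function(spikes, intervals = NULL, min_spikes = 100,
                               ...) {
  ids <- names(spikes$units)
  trains <- lapply(spikes$units, `[[`, "spike_times")
  if (!is.null(intervals)) {
    iv <- as_intervals(intervals)
    trains <- lapply(trains, iv_restrict, iv = iv)
  }
  rows <- list(); k <- 0L
  for (i in seq_along(ids)) {
    for (j in seq_along(ids)) {
      if (i == j) next
      if (length(trains[[i]]) < min_spikes ||
          length(trains[[j]]) < min_spikes) next
      cc <- compute_ccg(trains[[i]], trains[[j]])
      pred <- baseline_predictor(cc)
      ed <- detect_edges(cc, pred, ...)
      if (is.null(ed)) next
      tp <- transmission_probability(cc, pred)
      k <- k + 1L
      rows[[k]] <- data.frame(pre = ids[i], post = ids[j],
                              sign = ed$sign,
                              transmission = tp$transmission,
                              peak_to_baseline = tp$peak_to_baseline,
                              ambiguous = ed$ambiguous)
    }
  }
  out <- if (k) do.call(rbind, rows) else
    data.frame(pre = character(), post = character(), sign = character(),
               transmission = numeric(), peak_to_baseline = numeric(),
               ambiguous = logical())
  class(out) <- c("connection_graph", "data.frame")
  out
}

#' State-dependent spike transmission for an edge list
#'
#' Recomputes each edge's CCG, predictor and transmission probability
#' separately within two brain states and compares the paired per-edge
#' values with a Wilcoxon signed-rank test. Edges with fewer than
#' `min_pre_spikes` presynaptic spikes in either state are excluded and
#' listed in `excluded`.
#'
#' @param edges a `connection_graph` (or data.frame with pre/post).
#' @param spikes a [spike_dataset()].
#' @param states a `state_segmentation` (or intervals data.frame).
#' @param state_a,state_b labels to compare (default WAKE vs NREM).
#' @param min_pre_spikes per-state presynaptic spike minimum.
#' @return list: `per_edge` (data.frame with per-state transmission),
#'   `p_value` (signed-rank), `excluded`.
#' @export
state_dependent_transmission <- function(edges, spikes, states,
                                         state_a = "WAKE",
                                         state_b = "NREM",
                                         min_pre_spikes = 500) {
  iv_a <- state_intervals(states, state_a)
  iv_b <- state_intervals(states, state_b)
  if (nrow(iv_a) == 0 || nrow(iv_b) == 0) {
    stop("both states must be present for the comparison")
  }
  rows <- list(); k <- 0L; excluded <- character()
  for (r in seq_len(nrow(edges))) {
    pre <- spikes$units[[edges$pre[r]]]$spike_times
    post <- spikes$units[[edges$post[r]]]$spike_times
    pa <- iv_restrict(pre, iv_a); pb <- iv_restrict(pre, iv_b)
    if (length(pa) < min_pre_spikes || length(pb) < min_pre_spikes) {
      excluded <- c(excluded, paste0(edges$pre[r], "->", edges$post[r]))
      next
    }
    ta <- transmission_probability(compute_ccg(pre, post,
                                               intervals = iv_a))
    tb <- transmission_probability(compute_ccg(pre, post,
                                               intervals = iv_b))
    k <- k + 1L
    rows[[k]] <- data.frame(pre = edges$pre[r], post = edges$post[r],
                            sign = edges$sign[r],
                            transmission_a = ta$transmission,
                            transmission_b = tb$transmission)
  }
  per_edge <- if (k) do.call(rbind, rows) else
    data.frame(pre = character(), post = character(), sign = character(),
               transmission_a = numeric(), transmission_b = numeric())
  p <- if (k >= 5) {
    suppressWarnings(stats::wilcox.test(per_edge$transmission_a,
                                        per_edge$transmission_b,
                                        paired = TRUE)$p.value)
  } else NA_real_
  list(per_edge = per_edge, p_value = p, excluded = excluded,
       states = c(state_a, state_b))
}

#' CCG-based cell identity from outgoing edges
#'
#' A unit is CCG-E when it has at least one outgoing excitatory edge,
#' CCG-I with at least one outgoing inhibitory edge; units with both are
#' flagged AMBIGUOUS.
#'
#' @param edges a `connection_graph`.
#' @param unit_ids optional full unit list (units without outgoing edges
#'   get "NONE").
#' @return data.frame: `unit`, `ccg_class` in E/I/AMBIGUOUS/NONE.
#' @export
ccg_identity <- function(edges, unit_ids = NULL) {
  if (is.null(unit_ids)) unit_ids <- unique(c(edges$pre, edges$post))
  cls <- vapply(unit_ids, function(u) {
    s <- unique(edges$sign[edges$pre == u & !edges$ambiguous])
    if (all(c("E", "I") %in% s)) "AMBIGUOUS"
    else if ("E" %in% s) "E"
    else if ("I" %in% s) "I"
    else "NONE"
  }, "")
  data.frame(unit = unit_ids, ccg_class = unname(cls))
}
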
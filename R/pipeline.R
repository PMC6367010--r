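# End-to-end session analysis: states -> slow waves -> laminar map ->
# units -> (optional) spike-IC coupling -> connectivity -> report.

#' Run the full analysis pipeline on a session
#'
#' Stages mirror the analysis order: brain-state scoring, slow-wave
#' detection within non-REM, laminar mapping (MUA landmark when a
#' wideband segment is available, DOWN-UP CSD landmarks, gamma coherence
#' clustering, gamma ICA), unit classification and statistics,
#' optionally the spike-IC coupling matrix with k-means clusters, and
#' monosynaptic connectivity with the wake/non-REM transmission
#' comparison. Deterministic given `seed` (stage seeds are derived from
#' it).
#'
#' @param lfp LFP [probe_recording()].
#' @param spikes a [spike_dataset()].
#' @param wideband optional wideband [probe_recording()] for the MUA
#'   landmark.
#' @param events optional [event_table()].
#' @param seed master seed.
#' @param canonical_landmarks canonical depths for the warp (defaults to
#'   the recovered landmarks, i.e. an identity warp).
#' @param do_coupling compute the spike-IC coupling matrix and clusters
#'   (the most expensive stage).
#' @param n_restarts restarts for the coherence clustering.
#' @param verbose print stage progress.
#' @return object of class `session_report` (a named list of stage
#'   results plus a `summary` list).
#' @export
run_session <- function(lfp, spikes, wideband = NULL, events = NULL,
                        seed = 1, canonical_landmarks = NULL,
                        do_coupling = FALSE, n_restarts = 20,
                        verbose = TRUE) {
  say <- function(...) if (verbose) message("[lamprobe] ", ...)
  out <- list(seed = seed)

  say("scoring brain states")
  traces <- compute_scoring_traces(lfp)
  out$states <- score_states(traces)
  nrem <- state_intervals(out$states, "NREM")
  wake <- state_intervals(out$states, "WAKE")

  out$downup <- NULL
  if (iv_total(nrem) >= 60) {
    say("detecting DOWN/UP states")
    out$downup <- detect_slow_waves(lfp, spikes, nrem)
  }

  say("building laminar map")
  mua <- if (!is.null(wideband)) mua_power_profile(wideband) else NULL
  landmarks <- NULL
  if (!is.null(mua) && !is.null(out$downup) && nrow(out$downup$down) >= 10) {
    csd <- event_triggered_csd(lfp, out$downup$down$end,
                               window_s = c(0.05, 0.2))
    landmarks <- tryCatch(find_landmarks(mua, csd),
                          error = function(e) {
                            say("landmark search failed: ",
                                conditionMessage(e))
                            NULL
                          })
    out$csd <- csd
  }
  out$landmarks <- landmarks
  if (!is.null(landmarks)) {
    canon <- if (is.null(canonical_landmarks)) unclass(landmarks)
             else canonical_landmarks
    out$warp <- normalize_depth(landmarks, canon)
  }
  coh_iv <- if (iv_total(wake) >= 10) wake else cbind(0, duration_s(lfp))
  C <- band_coherence_matrix(lfp, band = c(30, 100), intervals = coh_iv)
  out$clustering <- gradient_descent_cluster(C, n_restarts = n_restarts,
                                             seed = derive_seed(seed,
                                                                "cluster"))
  out$ica <- gamma_ica(lfp, seed = derive_seed(seed, "ica"),
                       intervals = coh_iv)

  say("classifying units")
  out$unit_classes <- classify_units(spikes)
  out$unit_stats <- lapply(names(spikes$units), function(u) {
    st <- spikes$units[[u]]$spike_times
    bi <- if (length(st) >= 100) burst_index(st)
          else list(index = NA_real_, defined = FALSE)
    sr <- state_rate_table(st, out$states)
    list(unit = u, burst_index = bi$index,
         rates_hz = sr$rates_hz, wake_nrem_ratio = sr$wake_nrem_ratio)
  })

  if (do_coupling) {
    say("spike-IC coupling")
    out$coupling <- spike_ic_coupling_matrix(spikes, out$ica,
                                             intervals = coh_iv)
    out$coupling_clusters <- tryCatch(
      cluster_by_ic_coupling(out$coupling,
                             seed = derive_seed(seed, "coupling")),
      error = function(e) NULL)
  }

  say("detecting monosynaptic connections")
  out$edges <- detect_connections(spikes)
  out$state_transmission <- NULL
  if (nrow(out$edges) && iv_total(wake) > 0 && iv_total(nrem) > 0) {
    out$state_transmission <- state_dependent_transmission(
      out$edges, spikes, out$states)
  }

  out$summary <- list(
    n_channels = ncol(lfp$samples),
    duration_s = duration_s(lfp),
    seconds_per_state = {
      iv <- out$states$intervals
      as.list(tapply(iv$end - iv$start, iv$label, sum))
    },
    n_down_events = if (is.null(out$downup)) 0 else nrow(out$downup$down),
    landmarks_um = if (is.null(landmarks)) NULL else as.list(landmarks),
    n_coherence_clusters = out$clustering$n_clusters,
    clustering_consistency = out$clustering$consistency,
    n_laminar_ics = length(out$ica$laminar),
    unit_class_counts = as.list(table(out$unit_classes$waveform_class)),
    n_edges_E = sum(out$edges$sign == "E"),
    n_edges_I = sum(out$edges$sign == "I"),
    transmission_comparison_p =
      if (is.null(out$state_transmission)) NULL
      else out$state_transmission$p_value)
  structure(out, class = "session_report")
}

#' @export
print.session_report <- function(x, ...) {
  s <- x$summary
  cat("<session_report>\n")
  cat(sprintf("  %d channels, %.0f s\n", s$n_channels, s$duration_s))
  cat("  state seconds:",
      paste(names(s$seconds_per_state),
            round(unlist(s$seconds_per_state)), collapse = ", "), "\n")
  cat(sprintf("  %d DOWN events; %d coherence clusters; %d laminar ICs\n",
              s$n_down_events, s$n_coherence_clusters, s$n_laminar_ics))
  cat(sprintf("  edges: %d E, %d I\n", s$n_edges_E, s$n_edges_I))
  invisible(x)
}

#' Write the machine-readable session report
#'
#' @param report a `session_report`.
#' @param path output JSON path.
#' @export
write_report <- function(report, path) {
  jsonlite::write_json(report$summary, path, auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}
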
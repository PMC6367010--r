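# Recording, spike and event IO. Conventions owned here: times are seconds
# (recording start = 0, half-open intervals [start, end)), depths are um
# with 0 at the shallowest site increasing downward, frequencies are Hz.
# Continuous files are flat binary interleaved int16 ("Neuroscope-style"
# .dat/.lfp) with a JSON sidecar descriptor for geometry and scaling.

#' Multichannel probe recording
#'
#' Container for continuous extracellular voltage from a linear probe.
#'
#' @param samples numeric matrix, time x channels, in microvolts.
#' @param fs sampling rate in Hz.
#' @param channel_depth_um per-channel depth in micrometers, 0 at the
#'   shallowest site, strictly increasing downward.
#' @param uV_per_bit scale used when serializing to int16 (default 0.195).
#' @param meta optional named list of session metadata.
#' @return an object of class `probe_recording`.
#' @export
probe_recording <- function(samples, fs, channel_depth_um,
                            uV_per_bit = 0.195, meta = list()) {
  samples <- as.matrix(samples)
  if (ncol(samples) != length(channel_depth_um)) {
    stop("channel count of `samples` does not match `channel_depth_um`")
  }
  if (fs <= 0) stop("`fs` must be positive")
  if (is.unsorted(channel_depth_um, strictly = TRUE)) {
    stop("`channel_depth_um` must be strictly increasing (top to bottom)")
  }
  structure(
    list(samples = samples, fs = fs,
         channel_depth_um = as.numeric(channel_depth_um),
         uV_per_bit = uV_per_bit, meta = meta),
    class = "probe_recording")
}

#' @export
print.probe_recording <- function(x, ...) {
  cat(sprintf("<probe_recording> %d channels, %.6g s @ %g Hz (%.0f-%.0f um)\n",
              ncol(x$samples), nrow(x$samples) / x$fs, x$fs,
              min(x$channel_depth_um), max(x$channel_depth_um)))
  invisible(x)
}

#' @export
dim.probe_recording <- function(x) dim(x$samples)

#' Recording duration in seconds
#' @param rec a `probe_recording`.
#' @export
duration_s <- function(rec) nrow(rec$samples) / rec$fs

#' Write a recording as flat binary int16 plus descriptor
#'
#' Samples are quantized at `rec$uV_per_bit` and written channel-interleaved
#' (little-endian int16). The descriptor (`<path>.json`) records channel
#' count, sampling rate, depths and the voltage scale.
#'
#' @param rec a [probe_recording()].
#' @param path output file path (conventionally `.dat` or `.lfp`).
#' @return `path`, invisibly.
#' @export
write_recording <- function(rec, path) {
  stopifnot(inherits(rec, "probe_recording"))
  q <- round(t(rec$samples) / rec$uV_per_bit)
  q <- pmin(pmax(q, -32768), 32767)
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(as.integer(q), con, size = 2L, endian = "little")
  desc <- list(n_channels = ncol(rec$samples), fs = rec$fs,
               channel_depth_um = rec$channel_depth_um,
               uV_per_bit = rec$uV_per_bit, meta = rec$meta)
  jsonlite::write_json(desc, paste0(path, ".json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Load a flat binary int16 recording
#'
#' Any time window read yields identical values regardless of access
#' pattern: windows are addressed by sample offset in the file.
#'
#' @param path binary file path.
#' @param descriptor path to the JSON geometry descriptor, or a list with
#'   the descriptor fields. Defaults to `<path>.json`.
#' @param t_start,t_end optional window in seconds (half-open).
#' @return a [probe_recording()].
#' @export
load_recording <- function(path, descriptor = paste0(path, ".json"),
                           t_start = 0, t_end = Inf) {
  if (is.character(descriptor)) {
    if (!file.exists(descriptor)) {
      stop("missing geometry descriptor: ", descriptor)
    }
    descriptor <- jsonlite::read_json(descriptor, simplifyVector = TRUE)
  }
  nch <- descriptor$n_channels
  sz <- file.info(path)$size
  if (is.na(sz)) stop("recording file not found: ", path)
  if (sz %% (2 * nch) != 0) {
    stop("format error: file size ", sz,
         " not divisible by 2 bytes x ", nch, " channels")
  }
  n_total <- sz / (2 * nch)
  fs <- descriptor$fs
  i0 <- max(0, floor(t_start * fs))
  i1 <- min(n_total, if (is.finite(t_end)) floor(t_end * fs) else n_total)
  if (i1 <= i0) stop("empty time window requested")
  con <- file(path, "rb")
  on.exit(close(con))
  seek(con, where = i0 * 2 * nch)
  raw <- readBin(con, "integer", n = (i1 - i0) * nch, size = 2L,
                 signed = TRUE, endian = "little")
  samples <- t(matrix(raw, nrow = nch)) * descriptor$uV_per_bit
  probe_recording(samples, fs, descriptor$channel_depth_um,
                  uV_per_bit = descriptor$uV_per_bit,
                  meta = if (is.null(descriptor$meta)) list()
                         else descriptor$meta)
}

#' Down-sample a recording with anti-alias filtering
#'
#' Applies a zero-phase low-pass at 0.45 x `target_fs` before decimation.
#'
#' @param rec a [probe_recording()].
#' @param target_fs target rate in Hz; must divide `rec$fs`.
#' @return a [probe_recording()] at `target_fs`.
#' @export
downsample_lfp <- function(rec, target_fs) {
  stopifnot(inherits(rec, "probe_recording"))
  ratio <- rec$fs / target_fs
  if (abs(ratio - round(ratio)) > 1e-9) {
    stop("`target_fs` must divide the recording rate (ratio ", ratio, ")")
  }
  ratio <- round(ratio)
  if (ratio == 1L) return(rec)
  filt <- fft_bandpass(rec$samples, rec$fs, lo = NULL, hi = 0.4 * target_fs,
                       shoulder = 0.1 * target_fs)
  filt <- as.matrix(filt)
  idx <- seq(1, nrow(filt), by = ratio)
  probe_recording(filt[idx, , drop = FALSE], target_fs,
                  rec$channel_depth_um, rec$uV_per_bit, rec$meta)
}

#' Sorted-unit spike dataset
#'
#' @param units named list; each element a list with `spike_times` (sorted
#'   seconds), `peak_channel`, `mean_waveform` (wideband samples), and
#'   optional `quality`.
#' @param fs_waveform sampling rate of the mean waveforms, Hz.
#' @param duration_s session duration used to validate spike times.
#' @return an object of class `spike_dataset`.
#' @export
spike_dataset <- function(units, fs_waveform, duration_s = Inf) {
  for (u in names(units)) {
    st <- units[[u]]$spike_times
    if (is.unsorted(st)) stop("spike times of unit ", u, " are not sorted")
    if (length(st) && (st[1] < 0 || st[length(st)] > duration_s)) {
      stop("spike times of unit ", u, " outside [0, duration]")
    }
  }
  structure(list(units = units, fs_waveform = fs_waveform,
                 duration_s = duration_s),
            class = "spike_dataset")
}

#' @export
print.spike_dataset <- function(x, ...) {
  n <- vapply(x$units, function(u) length(u$spike_times), integer(1))
  cat(sprintf("<spike_dataset> %d units, %d spikes\n",
              length(x$units), sum(n)))
  invisible(x)
}

#' Write / read spike datasets as delimited text
#'
#' Spike times go to `<stem>_spikes.tsv` (unit, time_s); waveforms to
#' `<stem>_waveforms.tsv` (one row per unit).
#' @param spk a [spike_dataset()].
#' @param stem file path stem.
#' @export
write_spikes <- function(spk, stem) {
  rows <- do.call(rbind, lapply(names(spk$units), function(u) {
    data.frame(unit = u, time_s = spk$units[[u]]$spike_times)
  }))
  utils::write.table(rows, paste0(stem, "_spikes.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  wf <- t(vapply(spk$units, function(u) u$mean_waveform,
                 numeric(length(spk$units[[1]]$mean_waveform))))
  meta <- data.frame(unit = names(spk$units),
                     peak_channel = vapply(spk$units, function(u)
                       as.integer(u$peak_channel), integer(1)),
                     fs_waveform = spk$fs_waveform)
  utils::write.table(cbind(meta, wf), paste0(stem, "_waveforms.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(stem)
}

#' @rdname write_spikes
#' @param duration_s session duration for validation.
#' @export
read_spikes <- function(stem, duration_s = Inf) {
  sp <- utils::read.table(paste0(stem, "_spikes.tsv"), header = TRUE,
                          sep = "\t")
  wf <- utils::read.table(paste0(stem, "_waveforms.tsv"), header = TRUE,
                          sep = "\t", check.names = FALSE)
  units <- lapply(seq_len(nrow(wf)), function(i) {
    u <- wf$unit[i]
    list(spike_times = sort(sp$time_s[sp$unit == u]),
         peak_channel = wf$peak_channel[i],
         mean_waveform = as.numeric(wf[i, -(1:3)]))
  })
  names(units) <- wf$unit
  spike_dataset(units, fs_waveform = wf$fs_waveform[1],
                duration_s = duration_s)
}

#' Event table (light pulses and other timed events)
#'
#' @param time_s event times, seconds.
#' @param type character event type (e.g. `"LIGHT_VISUAL"`, `"LIGHT_OPTO"`).
#' @param duration_s per-event duration, seconds.
#' @param intensity optional tag.
#' @return a `data.frame` of class `event_table`, sorted by time.
#' @export
event_table <- function(time_s = numeric(), type = character(),
                        duration_s = numeric(), intensity = NA) {
  n <- length(time_s)
  df <- data.frame(time_s = time_s, type = rep_len(type, n),
                   duration_s = rep_len(duration_s, n),
                   intensity = rep_len(intensity, n))
  df <- df[order(df$time_s), , drop = FALSE]
  rownames(df) <- NULL
  class(df) <- c("event_table", "data.frame")
  df
}

#' @export
write_events <- function(ev, path) {
  utils::write.table(ev, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_events
#' @param ev an [event_table()]; `path` a TSV file path.
#' @export
read_events <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t")
  event_table(df$time_s, df$type, df$duration_s, df$intensity)
}
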
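#' Raw multi-channel recording
#'
#' Per-electrode extracellular voltage traces with their sampling metadata.
#' Traces are stored as a list of numeric vectors (microvolts), one per
#' electrode in row-major grid order. The platform's native sampling rates are
#' 7800 Hz (full-frame, 4096 electrodes) and 22000 Hz (region-of-interest
#' readout); other rates are accepted but flagged with a warning.
#'
#' @param geometry an [array_geometry()].
#' @param sampling_rate samples per second per electrode (Hz).
#' @param duration recording duration (s).
#' @param traces list of numeric vectors, one per electrode, each of length
#'   `round(sampling_rate * duration)`.
#' @param roi optional descriptor of a sub-grid region of interest.
#' @return an object of class `mea_recording`.
#' @export
mea_recording <- function(geometry, sampling_rate, duration, traces, roi = NULL) {
  stopifnot(inherits(geometry, "array_geometry"))
  if (!sampling_rate %in% c(7800, 22000))
    warning(sprintf("non-native sampling rate %g Hz (native: 7800 or 22000)",
                    sampling_rate))
  n_samp <- round(sampling_rate * duration)
  if (length(traces) != n_electrodes(geometry))
    stop("number of traces must equal the electrode count")
  len <- lengths(traces)
  if (any(len != n_samp))
    stop(sprintf("trace length mismatch: expected %d samples, electrodes %s differ",
                 n_samp, paste(utils::head(which(len != n_samp), 5L), collapse = ", ")))
  structure(
    list(geometry = geometry, sampling_rate = sampling_rate,
         duration = duration, traces = traces, roi = roi),
    class = "mea_recording"
  )
}

#' @export
print.mea_recording <- function(x, ...) {
  cat(sprintf("<mea_recording> %d electrodes, %g s at %g Hz\n",
              n_electrodes(x$geometry), x$duration, x$sampling_rate))
  invisible(x)
}

#' Electrode-indexed spike trains
#'
#' The central intermediate of the pipeline: sorted spike times per electrode,
#' with optional peak-centred waveform snippets and per-spike amplitudes
#' (peak-to-peak, microvolts). Times are seconds from the recording start.
#'
#' @param geometry an [array_geometry()].
#' @param duration recording duration (s).
#' @param trains list of strictly increasing numeric vectors of spike times,
#'   one per electrode.
#' @param waveforms optional list (per electrode) of snippet matrices, one row
#'   per spike (4 ms, peak-centred).
#' @param amplitudes optional list of per-spike amplitudes parallel to
#'   `trains`.
#' @param sampling_rate optional sampling rate the snippets were cut at (Hz).
#' @return an object of class `spike_train_set`.
#' @export
spike_train_set <- function(geometry, duration, trains, waveforms = NULL,
                            amplitudes = NULL, sampling_rate = NULL) {
  stopifnot(inherits(geometry, "array_geometry"))
  if (length(trains) != n_electrodes(geometry))
    stop("`trains` must have one element per electrode")
  for (i in seq_along(trains)) {
    t <- trains[[i]]
    if (length(t) == 0L) next
    if (is.unsorted(t, strictly = TRUE))
      stop(sprintf("spike times on electrode %d are not strictly increasing", i))
    if (t[1L] < 0 || t[length(t)] > duration)
      stop(sprintf("spike times on electrode %d fall outside [0, duration]", i))
  }
  if (!is.null(amplitudes) &&
      !identical(lengths(amplitudes), lengths(trains)))
    stop("`amplitudes` must be parallel to `trains`")
  structure(
    list(geometry = geometry, duration = duration, trains = trains,
         waveforms = waveforms, amplitudes = amplitudes,
         sampling_rate = sampling_rate),
    class = "spike_train_set"
  )
}

#' @export
print.spike_train_set <- function(x, ...) {
  n <- sum(lengths(x$trains))
  cat(sprintf("<spike_train_set> %d spikes on %d electrodes over %g s\n",
              n, n_electrodes(x$geometry), x$duration))
  invisible(x)
}

#' Total spike count of a spike-train set
#' @param trains a [spike_train_set()].
#' @return integer total number of spikes.
#' @export
n_spikes <- function(trains) sum(lengths(trains$trains))

#' Multi-site stimulation protocol
#'
#' Low-frequency trains of biphasic current pulses delivered sequentially from
#' the chip's stimulation sites: by default 0.2 Hz trains of 35 pulses per
#' site (300 us per phase, positive phase first, 300 uA peak-to-peak). Pulse
#' times per site are spaced by `1 / rate`.
#'
#' @param n_sites number of stimulation sites.
#' @param rate pulse rate per site (Hz).
#' @param n_pulses_per_site pulses delivered per site.
#' @param start time of the first pulse (s).
#' @param site_order order in which sites are stimulated; pulses of
#'   consecutive sites are interleaved block-wise (site 1's train completes,
#'   then site 2's, ...). Default `seq_len(n_sites)`.
#' @param phase_duration,amplitude,polarity pulse shape metadata (s, uA,
#'   `"positive-first"`); carried for reporting, not used numerically.
#' @return object of class `stim_protocol` with `pulse_times`: a list of
#'   per-site onset-time vectors (s).
#' @export
stim_protocol <- function(n_sites = 16L, rate = 0.2, n_pulses_per_site = 35L,
                          start = 5, site_order = seq_len(n_sites),
                          phase_duration = 300e-6, amplitude = 300,
                          polarity = "positive-first") {
  n_sites <- as.integer(n_sites)
  n_pulses_per_site <- as.integer(n_pulses_per_site)
  stopifnot(n_sites >= 1L, rate > 0, n_pulses_per_site >= 1L)
  if (!setequal(site_order, seq_len(n_sites)))
    stop("`site_order` must be a permutation of 1..n_sites")
  isi <- 1 / rate
  train_len <- n_pulses_per_site * isi
  pulse_times <- vector("list", n_sites)
  for (k in seq_len(n_sites)) {
    site <- site_order[k]
    t0 <- start + (k - 1L) * train_len
    pulse_times[[site]] <- t0 + (seq_len(n_pulses_per_site) - 1L) * isi
  }
  structure(
    list(site_order = as.integer(site_order), pulse_times = pulse_times,
         rate = rate, n_pulses_per_site = n_pulses_per_site,
         phase_duration = phase_duration, amplitude = amplitude,
         polarity = polarity),
    class = "stim_protocol"
  )
}

#' @export
print.stim_protocol <- function(x, ...) {
  cat(sprintf("<stim_protocol> %d sites, %d pulses/site at %g Hz\n",
              length(x$pulse_times), x$n_pulses_per_site, x$rate))
  invisible(x)
}

#' Total duration spanned by a stimulation protocol
#' @param protocol a [stim_protocol()].
#' @param tail extra time after the last pulse (s).
#' @return time (s) from 0 to the end of the last inter-pulse interval plus
#'   `tail`.
#' @export
protocol_duration <- function(protocol, tail = 1 / protocol$rate) {
  max(unlist(protocol$pulse_times)) + tail
}
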
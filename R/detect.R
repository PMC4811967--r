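#' Spike-detection parameters
#'
#' Parameters of the peak-to-peak differential threshold detector: an event is
#' emitted where the peak-to-peak excursion of the trace inside a short
#' peak-search window exceeds `threshold_multiplier` times the per-electrode
#' noise SD. The detector follows the precise-timing family of threshold
#' detectors used for high-density MEA recordings; timing is assigned to the
#' extremum of the dominant phase.
#'
#' @param threshold_multiplier detection threshold in noise-SD units
#'   (default 9).
#' @param noise_estimator `"robust-mad"` (default) or `"plain-sd"`; see
#'   [estimate_noise_sd()].
#' @param peak_window peak-search window (s) for the peak-to-peak excursion.
#' @param refractory minimum separation between events (s); closer events are
#'   merged keeping the larger excursion.
#' @param snippet_length snippet duration (s), peak-centred.
#' @return object of class `detection_params`.
#' @export
detection_params <- function(threshold_multiplier = 9,
                             noise_estimator = c("robust-mad", "plain-sd"),
                             peak_window = 0.001, refractory = 0.001,
                             snippet_length = 0.004) {
  noise_estimator <- match.arg(noise_estimator)
  stopifnot(threshold_multiplier > 0, peak_window > 0, refractory > 0,
            snippet_length > 0)
  structure(list(threshold_multiplier = threshold_multiplier,
                 noise_estimator = noise_estimator,
                 peak_window = peak_window, refractory = refractory,
                 snippet_length = snippet_length),
            class = "detection_params")
}

#' Estimate the noise SD of a trace
#'
#' Robust estimate `median(|x - median(x)|) / 0.6745` by default, which is
#' insensitive to embedded spikes; the plain sample SD is selectable (and is
#' inflated by spikes, which is why the robust estimator is the default).
#'
#' @param trace numeric voltage trace (uV), at least 100 samples.
#' @param method `"robust-mad"` or `"plain-sd"`.
#' @return noise SD (uV). A constant trace returns 0 with a warning.
#' @export
estimate_noise_sd <- function(trace, method = c("robust-mad", "plain-sd")) {
  method <- match.arg(method)
  if (length(trace) < 100L) stop("trace must have at least 100 samples")
  s <- if (method == "robust-mad") stats::mad(trace) else stats::sd(trace)
  if (s == 0) warning("constant trace: noise SD is 0")
  s
}

roll_max <- function(x, w) {
  # centred rolling max over w samples; edges use the partial window.
  # implemented as a pmax cascade over shifted copies: O(w) vectorized passes.
  h <- (w - 1L) %/% 2L
  n <- length(x)
  m <- x
  for (k in seq_len(h)) {
    fwd <- c(x[-seq_len(k)], rep(-Inf, k))
    bwd <- c(rep(-Inf, k), x[seq_len(n - k)])
    m <- pmax(m, fwd, bwd)
  }
  m
}

#' Detect spikes in a single trace
#'
#' Core detector: the noise SD is estimated over the full trace, and samples
#' where the peak-to-peak excursion within the centred peak-search window
#' exceeds `threshold_multiplier * sd` are grouped into events (gaps shorter
#' than the refractory period are bridged). Each event is timed at the
#' extremum of its dominant phase; events closer than the refractory period
#' keep the larger excursion. Snippets are `snippet_length` (4 ms),
#' peak-centred, zero-padded and flagged at trace edges.
#'
#' @param trace numeric voltage trace (uV).
#' @param sampling_rate sampling rate (Hz); must give at least 2 samples/ms.
#' @param params a [detection_params()].
#' @return list with `times` (s), `amplitudes` (peak-to-peak excursions, uV),
#'   `snippets` (matrix, one row per event), `padded` (logical), `noise_sd`.
#' @export
detect_spikes_trace <- function(trace, sampling_rate,
                                params = detection_params()) {
  if (sampling_rate < 2000)
    stop("sampling rate too low for 4 ms snippets (< 2 samples/ms)")
  n <- length(trace)
  L <- round(params$snippet_length * sampling_rate)
  pre <- floor((L - 1) / 2)
  post <- L - 1L - pre
  empty <- list(times = numeric(0), amplitudes = numeric(0),
                snippets = matrix(0, 0L, L), padded = logical(0))
  sd_hat <- estimate_noise_sd(trace, method = params$noise_estimator)
  if (sd_hat == 0) return(c(empty, noise_sd = 0))
  thr <- params$threshold_multiplier * sd_hat
  w <- max(3L, round(params$peak_window * sampling_rate))
  if (w %% 2L == 0L) w <- w + 1L
  ptp <- roll_max(trace, w) + roll_max(-trace, w)
  cand <- which(ptp > thr)
  if (length(cand) == 0L) return(c(empty, noise_sd = sd_hat))
  refr <- max(1L, round(params$refractory * sampling_rate))
  grp <- cumsum(c(1L, diff(cand) > refr))
  half <- (w - 1L) %/% 2L
  peaks <- integer(0); excs <- numeric(0)
  for (g in split(cand, grp)) {
    lo <- max(1L, g[1L] - half)
    hi <- min(n, g[length(g)] + half)
    seg <- trace[lo:hi]
    p <- lo + which.max(abs(seg)) - 1L
    peaks <- c(peaks, p)
    excs <- c(excs, max(seg) - min(seg))
  }
  # merge events closer than the refractory period, keeping larger excursion
  if (length(peaks) > 1L) {
    keep <- rep(TRUE, length(peaks))
    i <- 1L
    while (i < length(peaks)) {
      j <- i + 1L
      while (j <= length(peaks) && keep[j] == FALSE) j <- j + 1L
      if (j > length(peaks)) break
      if (peaks[j] - peaks[i] <= refr) {
        if (excs[j] >= excs[i]) keep[i] <- FALSE else keep[j] <- FALSE
        if (keep[j]) i <- j
      } else i <- j
    }
    peaks <- peaks[keep]; excs <- excs[keep]
  }
  snip <- matrix(0, length(peaks), L)
  padded <- logical(length(peaks))
  for (k in seq_along(peaks)) {
    lo <- peaks[k] - pre; hi <- peaks[k] + post
    s_lo <- max(1L, lo); s_hi <- min(n, hi)
    snip[k, (s_lo - lo + 1L):(s_hi - lo + 1L)] <- trace[s_lo:s_hi]
    padded[k] <- lo < 1L || hi > n
  }
  list(times = (peaks - 1L) / sampling_rate, amplitudes = excs,
       snippets = snip, padded = padded, noise_sd = sd_hat)
}

#' Detect spikes in a recording
#'
#' Runs [detect_spikes_trace()] on every electrode and assembles a
#' [spike_train_set()] with snippets and per-spike peak-to-peak amplitudes.
#'
#' @param recording an [mea_recording()].
#' @param params a [detection_params()].
#' @return a [spike_train_set()].
#' @export
detect_spikes <- function(recording, params = detection_params()) {
  stopifnot(inherits(recording, "mea_recording"))
  n <- n_electrodes(recording$geometry)
  trains <- vector("list", n)
  waveforms <- vector("list", n)
  amplitudes <- vector("list", n)
  for (e in seq_len(n)) {
    det <- detect_spikes_trace(recording$traces[[e]], recording$sampling_rate,
                               params)
    trains[[e]] <- det$times
    waveforms[[e]] <- det$snippets
    amplitudes[[e]] <- det$amplitudes
  }
  spike_train_set(recording$geometry, recording$duration, trains,
                  waveforms = waveforms, amplitudes = amplitudes,
                  sampling_rate = recording$sampling_rate)
}
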
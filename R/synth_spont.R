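#' Spontaneous-activity regime specification
#'
#' Describes the statistical structure of spontaneous network activity at one
#' developmental stage. Three regimes are emulated, mirroring the development
#' of cultured networks from sparse random spiking, through tonic network-wide
#' firing, to synchronized network bursting:
#' \itemize{
#'   \item `sparse`: independent low-rate Poisson trains (young cultures);
#'   \item `tonic`: independent Poisson trains at higher rates;
#'   \item `bursting`: network-synchronized burst epochs superposed on Poisson
#'     background spiking (mature cultures).
#' }
#' Per-electrode firing rates are drawn from a lognormal distribution with
#' log10-mean `rate_log_mean` and log10-SD `rate_log_sd`, the canonical shape
#' of population firing-rate distributions.
#'
#' @param regime `"sparse"`, `"tonic"` or `"bursting"`.
#' @param rate_log_mean,rate_log_sd lognormal parameters of the per-electrode
#'   background rate, in log10(events/s). Regime defaults: sparse (-1, 0.4),
#'   tonic (0, 0.45), bursting (-0.3, 0.45).
#' @param burst_rate network bursts per minute (bursting regime).
#' @param intra_burst_isi nominal intra-burst inter-spike interval (s).
#' @param isi_jitter relative jitter on intra-burst ISIs.
#' @param spikes_per_burst spikes emitted per electrode per burst.
#' @param synchrony_frac probability that an electrode participates in a
#'   network burst.
#' @param noise_sd raw-trace background noise SD (uV).
#' @param spike_amplitude_snr spike peak amplitude in units of the noise SD
#'   used when rendering raw traces.
#' @param class_mix waveform-class proportions over [waveform_classes].
#' @return object of class `regime_spec`.
#' @export
regime_spec <- function(regime = c("sparse", "tonic", "bursting"),
                        rate_log_mean = NULL, rate_log_sd = NULL,
                        burst_rate = 6, intra_burst_isi = 0.020,
                        isi_jitter = 0.1, spikes_per_burst = 8L,
                        synchrony_frac = 0.6, noise_sd = 10,
                        spike_amplitude_snr = 12,
                        class_mix = c(0.41, 0.15, 0.26, 0.18)) {
  regime <- match.arg(regime)
  defaults <- switch(regime,
    sparse   = c(-1, 0.4),
    tonic    = c(0, 0.45),
    bursting = c(-0.3, 0.45)
  )
  if (is.null(rate_log_mean)) rate_log_mean <- defaults[1L]
  if (is.null(rate_log_sd)) rate_log_sd <- defaults[2L]
  if (!all(is.finite(c(rate_log_mean, rate_log_sd, burst_rate, intra_burst_isi,
                       spikes_per_burst, synchrony_frac, noise_sd,
                       spike_amplitude_snr))))
    stop("regime parameters must be finite")
  if (rate_log_sd < 0) stop("`rate_log_sd` must be >= 0")
  if (noise_sd <= 0) stop("`noise_sd` must be > 0")
  if (abs(sum(class_mix) - 1) > 1e-8)
    stop("`class_mix` proportions must sum to 1")
  structure(
    list(regime = regime, rate_log_mean = rate_log_mean,
         rate_log_sd = rate_log_sd, burst_rate = burst_rate,
         intra_burst_isi = intra_burst_isi, isi_jitter = isi_jitter,
         spikes_per_burst = as.integer(spikes_per_burst),
         synchrony_frac = synchrony_frac, noise_sd = noise_sd,
         spike_amplitude_snr = spike_amplitude_snr, class_mix = class_mix),
    class = "regime_spec"
  )
}

poisson_train <- function(rate, duration) {
  n <- stats::rpois(1L, rate * duration)
  if (n == 0L) return(numeric(0))
  t <- sort(stats::runif(n, 0, duration))
  # runif's ~2^-32 resolution produces exact ties in long trains; drop them
  t[c(TRUE, diff(t) > 0)]
}

#' Generate spontaneous spike trains with ground truth
#'
#' Draws per-electrode firing rates from the regime's lognormal distribution
#' and emits homogeneous Poisson background trains; in the bursting regime,
#' network burst epochs (evenly scheduled at `burst_rate` per minute) are
#' superposed: each participating electrode fires `spikes_per_burst` spikes at
#' the intra-burst ISI (jittered), with a small per-electrode onset jitter
#' reproducing network synchrony. The ground truth records per-electrode true
#' rates, every burst epoch, and the waveform class of each electrode's unit.
#'
#' @param geometry an [array_geometry()].
#' @param regime a [regime_spec()].
#' @param duration recording duration (s).
#' @param seed random seed.
#' @return list with `trains` (a [spike_train_set()]) and `truth` (list:
#'   `rates`, `bursts` data frame, `classes`, `regime`).
#' @export
gen_spontaneous <- function(geometry, regime, duration, seed = 1L) {
  stopifnot(inherits(regime, "regime_spec"), duration > 0)
  set.seed(seed)
  n <- n_electrodes(geometry)
  rates <- 10^stats::rnorm(n, regime$rate_log_mean, regime$rate_log_sd)
  classes <- sample(waveform_classes, n, replace = TRUE,
                    prob = regime$class_mix)
  trains <- lapply(rates, poisson_train, duration = duration)
  bursts <- NULL
  if (regime$regime == "bursting" && regime$burst_rate > 0) {
    nb <- max(1L, round(regime$burst_rate * duration / 60))
    burst_len <- (regime$spikes_per_burst - 1L) * regime$intra_burst_isi
    onsets <- (seq_len(nb) - 0.5) * duration / nb
    rec <- vector("list", n)
    for (e in seq_len(n)) {
      take <- stats::runif(nb) < regime$synchrony_frac
      if (!any(take)) next
      b_start <- b_end <- numeric(0)
      spikes <- numeric(0)
      for (o in onsets[take]) {
        t0 <- o + stats::runif(1, 0, 0.005)
        isi <- regime$intra_burst_isi *
          (1 + stats::runif(regime$spikes_per_burst - 1L,
                            -regime$isi_jitter, regime$isi_jitter))
        ts <- t0 + c(0, cumsum(isi))
        ts <- ts[ts <= duration]
        if (length(ts) < 2L) next
        spikes <- c(spikes, ts)
        b_start <- c(b_start, ts[1L])
        b_end <- c(b_end, ts[length(ts)])
      }
      if (length(spikes)) {
        all_t <- sort(c(trains[[e]], spikes))
        trains[[e]] <- all_t[c(TRUE, diff(all_t) > 0)]
        rec[[e]] <- data.frame(electrode = e, start = b_start, end = b_end,
                               n_spikes = regime$spikes_per_burst)
      }
    }
    rec <- rec[!vapply(rec, is.null, TRUE)]
    bursts <- if (length(rec)) do.call(rbind, rec) else
      data.frame(electrode = integer(0), start = numeric(0),
                 end = numeric(0), n_spikes = integer(0))
    if (!is.null(bursts)) {
      expected_len <- burst_len * (1 + regime$isi_jitter)
      attr(bursts, "nominal_length") <- expected_len
    }
  }
  list(
    trains = spike_train_set(geometry, duration, trains),
    truth = list(rates = rates, bursts = bursts, classes = classes,
                 regime = regime$regime)
  )
}

#' Render one raw voltage trace from spike times
#'
#' Low-level single-electrode renderer: Gaussian background noise of SD
#' `noise_sd` with one spike template inserted (peak-centred) at each spike
#' time. Used by [gen_raw_traces()] and directly when streaming over many
#' electrodes without holding a full recording in memory.
#'
#' @param spike_times spike times (s).
#' @param duration trace duration (s).
#' @param sampling_rate sampling rate (Hz).
#' @param noise_sd noise SD (uV).
#' @param amplitude spike peak amplitude (uV).
#' @param class waveform class of the electrode's unit.
#' @param seed optional seed (set by the caller when absent).
#' @return numeric trace of `round(sampling_rate * duration)` samples.
#' @export
synth_trace <- function(spike_times, duration, sampling_rate, noise_sd,
                        amplitude, class = "neg_mono", seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (amplitude < noise_sd)
    warning("spike amplitude below one noise SD: detection untestable")
  n_samp <- round(sampling_rate * duration)
  x <- stats::rnorm(n_samp, 0, noise_sd)
  if (length(spike_times)) {
    tpl <- waveform_template(class, sampling_rate) * amplitude
    L <- length(tpl)
    centre <- floor((L - 1) / 2) + 1L
    for (t in spike_times) {
      p <- round(t * sampling_rate) + 1L
      lo <- p - centre + 1L
      hi <- lo + L - 1L
      s_lo <- max(1L, lo); s_hi <- min(n_samp, hi)
      if (s_lo > s_hi) next
      x[s_lo:s_hi] <- x[s_lo:s_hi] + tpl[(s_lo - lo + 1L):(s_hi - lo + 1L)]
    }
  }
  x
}

#' Render raw traces for a whole spike-train set
#'
#' Renders every electrode with [synth_trace()]: Gaussian background noise of
#' the regime's SD, spike amplitude `spike_amplitude_snr * noise_sd`, one
#' waveform class per electrode (ground-truth classes or drawn from the
#' regime's class mix).
#'
#' @param trains a [spike_train_set()].
#' @param regime a [regime_spec()] providing noise SD, amplitude and class mix.
#' @param sampling_rate sampling rate (Hz), >= 7000.
#' @param seed random seed.
#' @param classes optional per-electrode waveform classes.
#' @return an [mea_recording()].
#' @export
gen_raw_traces <- function(trains, regime, sampling_rate = 7800, seed = 1L,
                           classes = NULL) {
  stopifnot(inherits(trains, "spike_train_set"), inherits(regime, "regime_spec"))
  if (sampling_rate < 7000) stop("`sampling_rate` must be >= 7000 Hz")
  set.seed(seed)
  n <- n_electrodes(trains$geometry)
  if (is.null(classes))
    classes <- sample(waveform_classes, n, replace = TRUE,
                      prob = regime$class_mix)
  amplitude <- regime$spike_amplitude_snr * regime$noise_sd
  traces <- vector("list", n)
  for (e in seq_len(n)) {
    traces[[e]] <- synth_trace(trains$trains[[e]], trains$duration,
                               sampling_rate, regime$noise_sd, amplitude,
                               class = classes[e])
  }
  mea_recording(trains$geometry, sampling_rate, trains$duration, traces)
}
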
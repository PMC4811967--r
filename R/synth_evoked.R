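#' Generate an evoked-response stimulation experiment with ground truth
#'
#' Simulates the spike-level outcome of a multi-site low-frequency stimulation
#' session. Each site is assigned one of two response forms observed in
#' mature cultured networks: \emph{fast} responses whose evoked spiking is
#' confined to ~100 ms after the pulse with first-spike latencies around
#' 70 ms, and \emph{long-lasting} responses extending up to ~500 ms with
#' first-spike latencies around 120 ms.
#'
#' For every site a set of responding electrodes is drawn around the site
#' (inclusion probability decays with distance). Each responding electrode is
#' programmed to respond in an exact number of the 35 trials (a configurable
#' fraction of electrodes is programmed below the 10-of-35 reliability rule so
#' the rule's exclusions are testable). In a responding trial the electrode
#' emits a first spike at the class latency (Gaussian jitter) followed by
#' extra spikes inside the class envelope (uniform within 105 ms for fast
#' sites; front-loaded beta profile within 480 ms for long-lasting sites).
#' Saturating stimulation artifacts (events of `artifact_amp` uV) are placed
#' 0.5 ms after every pulse on electrodes within 20 um of the site, and
#' independent Poisson background spiking runs on all electrodes.
#'
#' @param geometry an [array_geometry()] with stimulation sites.
#' @param protocol a [stim_protocol()] with one pulse train per site.
#' @param response_classes character vector, one of `"fast"`/`"long"` per site.
#' @param seed random seed.
#' @param n_responding responding electrodes per site.
#' @param resp_radius maximum distance (pitch units) of responding electrodes.
#' @param decay distance-decay constant (pitch units) of inclusion weight.
#' @param rel_trials_high,rel_trials_low programmed responding-trial counts
#'   for reliable and unreliable electrodes (out of `n_pulses_per_site`).
#' @param low_frac fraction of responding electrodes programmed unreliable.
#' @param latency_fast,latency_long mean first-spike latencies (s).
#' @param jitter_fast,jitter_long latency jitter SDs (s).
#' @param background_rate Poisson background rate on every electrode (ev/s).
#' @param artifact_amp artifact event amplitude (uV).
#' @param spike_amp_mean,spike_amp_sd genuine-spike amplitude model (uV).
#' @return list with `trains` (a [spike_train_set()] carrying per-spike
#'   amplitudes) and `truth` (site classes, responding-electrode table,
#'   per-trial first-spike latencies, artifact events).
#' @export
gen_evoked_experiment <- function(geometry, protocol, response_classes,
                                  seed = 1L,
                                  n_responding = 40L, resp_radius = 22,
                                  decay = 12,
                                  rel_trials_high = 32L, rel_trials_low = 7L,
                                  low_frac = 0.2,
                                  latency_fast = 0.070, latency_long = 0.120,
                                  jitter_fast = 0.005, jitter_long = 0.015,
                                  background_rate = 0.05,
                                  artifact_amp = 2000,
                                  spike_amp_mean = 60, spike_amp_sd = 8) {
  stopifnot(inherits(geometry, "array_geometry"),
            inherits(protocol, "stim_protocol"))
  n_sites <- length(protocol$pulse_times)
  if (is.null(geometry$stim_sites) || nrow(geometry$stim_sites) < n_sites)
    stop("geometry must define at least as many stimulation sites as the protocol")
  response_classes <- match.arg(response_classes, c("fast", "long"),
                                several.ok = TRUE)
  if (length(response_classes) != n_sites)
    stop("`response_classes` must name one class per site")
  all_pulses <- sort(unlist(protocol$pulse_times))
  if (any(diff(all_pulses) < 0.5))
    stop("overlapping site schedules: pulses closer than 0.5 s")
  isi <- 1 / protocol$rate
  set.seed(seed)
  duration <- protocol_duration(protocol)
  n <- n_electrodes(geometry)
  n_trials <- protocol$n_pulses_per_site

  events <- lapply(seq_len(n), function(i) numeric(0))
  amps <- lapply(seq_len(n), function(i) numeric(0))
  add_events <- function(e, t, a) {
    events[[e]] <<- c(events[[e]], t)
    amps[[e]] <<- c(amps[[e]], a)
  }

  # background spiking
  for (e in seq_len(n)) {
    bg <- poisson_train(background_rate, duration)
    if (length(bg))
      add_events(e, bg, stats::rnorm(length(bg), spike_amp_mean, spike_amp_sd))
  }

  resp_tabs <- vector("list", n_sites)
  lat_tabs <- vector("list", n_sites)
  art_tabs <- vector("list", n_sites)
  for (s in seq_len(n_sites)) {
    cls <- response_classes[s]
    d <- electrode_distances(geometry, s)
    pool <- which(d <= resp_radius & d > 0)
    if (length(pool) < n_responding)
      stop("response radius too small for the requested responding count")
    resp <- sample(pool, n_responding, prob = exp(-d[pool] / decay))
    n_low <- round(low_frac * n_responding)
    low <- rep(FALSE, n_responding)
    if (n_low > 0) low[sample.int(n_responding, n_low)] <- TRUE
    rel_trials <- ifelse(low, rel_trials_low, rel_trials_high)
    lat_mean <- if (cls == "fast") latency_fast else latency_long
    lat_sd <- if (cls == "fast") jitter_fast else jitter_long
    pulses <- protocol$pulse_times[[s]]
    lat_rows <- vector("list", n_responding)
    for (k in seq_len(n_responding)) {
      e <- resp[k]
      trials <- sort(sample.int(n_trials, rel_trials[k]))
      lat <- stats::rnorm(length(trials), lat_mean, lat_sd)
      lat <- pmin(pmax(lat, 0.012), 0.30)
      for (j in seq_along(trials)) {
        t0 <- pulses[trials[j]]
        ts <- t0 + lat[j]
        if (cls == "fast") {
          n_extra <- stats::rpois(1L, 2)
          if (n_extra > 0 && lat[j] < 0.105)
            ts <- c(ts, t0 + stats::runif(n_extra, lat[j], 0.105))
        } else {
          n_extra <- stats::rpois(1L, 6)
          if (n_extra > 0 && lat[j] < 0.48)
            ts <- c(ts, t0 + lat[j] +
                      (0.48 - lat[j]) * stats::rbeta(n_extra, 1, 1.5))
        }
        ts <- ts[ts <= duration]
        if (length(ts))
          add_events(e, ts, stats::rnorm(length(ts), spike_amp_mean,
                                         spike_amp_sd))
      }
      lat_rows[[k]] <- data.frame(site = s, electrode = e, trial = trials,
                                  latency = lat)
    }
    resp_tabs[[s]] <- data.frame(site = s, electrode = resp,
                                 rel_trials = rel_trials, unreliable = low,
                                 distance = d[resp])
    lat_tabs[[s]] <- do.call(rbind, lat_rows)
    near <- which(d * geometry$pitch <= 20)
    if (length(near)) {
      art_t <- rep(pulses, each = length(near)) + 0.0005
      art_e <- rep(near, times = length(pulses))
      for (e in unique(art_e))
        add_events(e, art_t[art_e == e], rep(artifact_amp, sum(art_e == e)))
      art_tabs[[s]] <- data.frame(site = s, electrode = art_e, time = art_t)
    }
  }

  trains <- vector("list", n)
  amplitudes <- vector("list", n)
  for (e in seq_len(n)) {
    if (length(events[[e]]) == 0L) {
      trains[[e]] <- numeric(0); amplitudes[[e]] <- numeric(0); next
    }
    o <- order(events[[e]])
    t <- events[[e]][o]; a <- amps[[e]][o]
    keep <- c(TRUE, diff(t) > 0)
    trains[[e]] <- t[keep]; amplitudes[[e]] <- a[keep]
  }
  sts <- spike_train_set(geometry, duration, trains, amplitudes = amplitudes)
  list(
    trains = sts,
    protocol = protocol,
    truth = list(
      classes = response_classes,
      responding = do.call(rbind, resp_tabs),
      latencies = do.call(rbind, lat_tabs),
      artifacts = do.call(rbind, art_tabs),
      params = list(latency_fast = latency_fast, latency_long = latency_long,
                    rel_trials_high = rel_trials_high,
                    rel_trials_low = rel_trials_low)
    )
  )
}
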
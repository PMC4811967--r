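#' Remove stimulation artifacts from spike trains
#'
#' Removes every event whose amplitude exceeds the hard artifact threshold
#' (saturating deflections near the stimulation site) and every event inside
#' the post-stimulus discard window (first 10 ms after any pulse), the period
#' contaminated by the stimulus transient. Removal counts are recorded per
#' electrode in the `removed` attribute.
#'
#' @param trains a [spike_train_set()]; per-spike amplitudes are used when
#'   present.
#' @param protocol a [stim_protocol()], or `NULL` when no pulses were
#'   delivered (only the amplitude rule applies).
#' @param hard_threshold amplitude bound (uV) above which an event is an
#'   artifact.
#' @param detection_threshold optional detection-level amplitude (uV); an
#'   error is raised if `hard_threshold` does not exceed it (it would delete
#'   genuine spikes).
#' @param config an [analysis_config()] (discard window).
#' @return a cleaned [spike_train_set()] with attribute `removed` (integer
#'   per-electrode counts).
#' @export
remove_artifacts <- function(trains, protocol, hard_threshold = 500,
                             detection_threshold = NULL,
                             config = analysis_config()) {
  stopifnot(inherits(trains, "spike_train_set"),
            is.null(protocol) || inherits(protocol, "stim_protocol"))
  if (!is.null(detection_threshold) && hard_threshold <= detection_threshold)
    stop("hard artifact threshold must exceed the detection threshold")
  pulses <- if (is.null(protocol)) numeric(0) else
    sort(unlist(protocol$pulse_times))
  if (length(pulses) && max(pulses) > trains$duration)
    stop("protocol pulses fall outside the recording duration")
  discard <- config$psth_discard
  n <- length(trains$trains)
  removed <- integer(n)
  new_trains <- trains$trains
  new_amps <- trains$amplitudes
  for (e in seq_len(n)) {
    t <- trains$trains[[e]]
    if (!length(t)) next
    drop <- rep(FALSE, length(t))
    if (!is.null(trains$amplitudes))
      drop <- drop | trains$amplitudes[[e]] > hard_threshold
    if (length(pulses)) {
      # index of the latest pulse at or before each event
      idx <- findInterval(t, pulses)
      has <- idx >= 1L
      dt <- t[has] - pulses[pmax(idx[has], 1L)]
      in_win <- rep(FALSE, length(t))
      in_win[has] <- dt >= 0 & dt < discard
      drop <- drop | in_win
    }
    removed[e] <- sum(drop)
    new_trains[[e]] <- t[!drop]
    if (!is.null(new_amps)) new_amps[[e]] <- trains$amplitudes[[e]][!drop]
  }
  out <- spike_train_set(trains$geometry, trains$duration, new_trains,
                         waveforms = trains$waveforms, amplitudes = new_amps,
                         sampling_rate = trains$sampling_rate)
  attr(out, "removed") <- removed
  out
}

#' Post-stimulus time histogram for one stimulation site
#'
#' Aggregates spikes over all electrodes into trial-aligned 25 ms bins
#' starting after the 10 ms discard window, and computes the per-bin mean and
#' lower/upper percentile bands (default 5th/95th) across the trials. The
#' total of the binned counts equals the number of spikes inside the union of
#' trial windows (count conservation).
#'
#' @param trains an artifact-cleaned [spike_train_set()].
#' @param protocol a [stim_protocol()].
#' @param site site index.
#' @param window response window (s) from the pulse; must not exceed the
#'   inter-stimulus interval. The binned span is the largest whole number of
#'   bins fitting in `(discard, window]`.
#' @param percentiles lower/upper band probabilities.
#' @param config an [analysis_config()] (bin width, discard window).
#' @return object of class `psth`: list with `site`, `edges` (s,
#'   post-stimulus), `mean`, `lower`, `upper`, `n_trials`, `trial_counts`
#'   (bins x trials matrix), `total`.
#' @export
compute_psth <- function(trains, protocol, site, window = 0.510,
                         percentiles = c(0.05, 0.95),
                         config = analysis_config()) {
  stopifnot(inherits(trains, "spike_train_set"))
  pulses <- protocol$pulse_times[[site]]
  if (is.null(pulses) || !length(pulses)) stop("site has no pulses")
  if (window > 1 / protocol$rate)
    stop("window must not exceed the inter-stimulus interval")
  nb <- floor((window - config$psth_discard) / config$psth_bin)
  if (nb < 1L) stop("window too short for one bin")
  edges <- config$psth_discard + config$psth_bin * (0:nb)
  all_t <- sort(unlist(trains$trains))
  counts <- matrix(0L, nb, length(pulses))
  for (j in seq_along(pulses)) {
    rel <- all_t - pulses[j]
    rel <- rel[rel >= edges[1L] & rel < edges[nb + 1L]]
    if (length(rel))
      counts[, j] <- tabulate(findInterval(rel, edges), nbins = nb)
  }
  structure(list(
    site = site, edges = edges,
    mean = rowMeans(counts),
    lower = apply(counts, 1L, stats::quantile, probs = percentiles[1L]),
    upper = apply(counts, 1L, stats::quantile, probs = percentiles[2L]),
    n_trials = length(pulses), trial_counts = counts,
    total = sum(counts)
  ), class = "psth")
}

#' Baseline per-bin count for a stimulation site
#'
#' Mean spike count per PSTH bin expected from ongoing activity, estimated
#' from the 1 s window preceding each pulse (all electrodes aggregated).
#'
#' @param trains a [spike_train_set()].
#' @param protocol a [stim_protocol()].
#' @param site site index.
#' @param pre_window baseline window before each pulse (s).
#' @param config an [analysis_config()].
#' @return list with `per_bin` (mean count per 25 ms bin) and `se` (standard
#'   error of that mean across pulses).
#' @export
psth_baseline <- function(trains, protocol, site, pre_window = 1,
                          config = analysis_config()) {
  pulses <- protocol$pulse_times[[site]]
  all_t <- sort(unlist(trains$trains))
  counts <- vapply(pulses, function(p)
    sum(all_t >= p - pre_window & all_t < p), numeric(1))
  per_s <- counts / pre_window
  per_bin <- per_s * config$psth_bin
  list(per_bin = mean(per_bin),
       se = stats::sd(per_bin) / sqrt(length(per_bin)))
}

#' Classify an evoked response as fast or long-lasting
#'
#' Finds contiguous runs of supra-baseline PSTH bins; among runs starting
#' within 100 ms of the stimulus, the response duration is the end of the
#' last one (ms post-stimulus). The site is `fast` when the duration does not
#' exceed the configurable boundary (default 150 ms), `long-lasting` when it
#' does, and `non-responsive` when no supra-baseline run starts within
#' 100 ms. A bin is supra-baseline when its trial-mean count exceeds the
#' baseline by `z` standard errors of a Poisson count at the baseline rate
#' (a small margin that keeps ongoing-activity fluctuations from extending
#' response runs).
#'
#' @param psth a [compute_psth()] result.
#' @param baseline expected per-bin count from ongoing activity (a number or
#'   the result of [psth_baseline()]).
#' @param z baseline-exceedance margin in Poisson standard errors.
#' @param onset_max latest run start (s) counting as a response.
#' @param config an [analysis_config()] (fast/long boundary).
#' @return object of class `response_classification`: list with `site`,
#'   `class`, `duration` (s or `NA`), `onset` (s or `NA`), `baseline`.
#' @export
classify_response <- function(psth, baseline, z = 3, onset_max = 0.100,
                              config = analysis_config()) {
  stopifnot(inherits(psth, "psth"))
  if (missing(baseline) || is.null(baseline)) stop("baseline is required")
  b <- if (is.list(baseline)) baseline$per_bin else baseline
  margin <- z * sqrt(max(b, 1e-6) / psth$n_trials)
  supra <- psth$mean > b + margin
  r <- rle(supra)
  ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
  runs <- which(r$values)
  cls <- "non-responsive"; dur <- NA_real_; onset <- NA_real_
  if (length(runs)) {
    run_start_t <- psth$edges[starts[runs]]
    ok <- run_start_t <= onset_max
    if (any(ok)) {
      last <- max(which(ok))
      dur <- psth$edges[ends[runs[last]] + 1L]
      onset <- run_start_t[which.max(ok)]
      cls <- if (dur <= config$fast_long_boundary) "fast" else "long-lasting"
    }
  }
  structure(list(site = psth$site, class = cls, duration = dur,
                 onset = onset, baseline = b),
            class = "response_classification")
}

#' First-spike latencies for one stimulation site
#'
#' For every electrode and trial, the latency of the first spike in
#' `(discard, window]` after the pulse. Electrodes are kept ("reliable") when
#' they respond in at least `reliability_min` of the trials (10 of 35);
#' others are excluded with their counts reported.
#'
#' @param trains an artifact-cleaned [spike_train_set()].
#' @param protocol a [stim_protocol()].
#' @param site site index.
#' @param config an [analysis_config()] (discard, window, reliability rule).
#' @return list with `latencies` (data frame `electrode`, `trial`,
#'   `latency` in s; reliable electrodes only), `reliability` (data frame
#'   `electrode`, `n_responding`, `reliable`) and `n_excluded`.
#' @export
first_spike_latencies <- function(trains, protocol, site,
                                  config = analysis_config()) {
  pulses <- protocol$pulse_times[[site]]
  lo <- config$psth_discard; hi <- config$response_window
  rows <- vector("list", length(trains$trains))
  rel <- integer(length(trains$trains))
  for (e in seq_along(trains$trains)) {
    t <- trains$trains[[e]]
    if (!length(t)) next
    lat <- vapply(pulses, function(p) {
      i <- findInterval(p + lo, t) + 1L  # first spike strictly after p + lo
      if (i <= length(t) && t[i] <= p + hi) t[i] - p else NA_real_
    }, numeric(1))
    resp <- which(!is.na(lat))
    rel[e] <- length(resp)
    if (length(resp))
      rows[[e]] <- data.frame(electrode = e, trial = resp,
                              latency = lat[resp])
  }
  reliable <- rel >= config$reliability_min
  responded <- rel > 0L
  keep <- rows[reliable & responded]
  lat_df <- if (length(keep)) do.call(rbind, keep) else
    data.frame(electrode = integer(0), trial = integer(0),
               latency = numeric(0))
  list(
    latencies = lat_df,
    reliability = data.frame(electrode = which(responded),
                             n_responding = rel[responded],
                             reliable = reliable[responded]),
    n_excluded = sum(responded & !reliable)
  )
}

#' Mean first-spike latency versus distance in electrode rings
#'
#' Assigns every reliable electrode to a concentric ring around the
#' stimulation site (grid Euclidean distance in pitch units; innermost disc,
#' then annuli between consecutive radii) and reports the per-ring mean and
#' SEM of the first-spike latency. Rings containing no reliable electrode are
#' flagged empty.
#'
#' @param latencies `latencies` data frame from [first_spike_latencies()].
#' @param geometry an [array_geometry()].
#' @param site site index or `(row, col)` position.
#' @param rings a [ring_spec()].
#' @return data frame with `radius` (pitch units), `area` (pi r^2),
#'   `n_electrodes`, `mean_latency_ms`, `sem_ms`, `empty`.
#' @export
latency_vs_distance <- function(latencies, geometry, site,
                                rings = ring_spec()) {
  member <- ring_membership(geometry, site, rings)
  per_e <- tapply(latencies$latency, latencies$electrode, mean)
  e_id <- as.integer(names(per_e))
  ring_of <- member[e_id]
  out <- data.frame(radius = rings$radii, area = rings$area)
  out$n_electrodes <- vapply(seq_along(rings$radii), function(k)
    sum(ring_of == k, na.rm = TRUE), numeric(1))
  agg <- function(k, f) {
    v <- per_e[!is.na(ring_of) & ring_of == k]
    if (length(v)) f(v) * 1000 else NA_real_
  }
  out$mean_latency_ms <- vapply(seq_along(rings$radii), agg, numeric(1),
                                f = mean)
  out$sem_ms <- vapply(seq_along(rings$radii), agg, numeric(1),
                       f = function(v) if (length(v) > 1L)
                         stats::sd(v) / sqrt(length(v)) else NA_real_)
  out$empty <- out$n_electrodes == 0
  attr(out, "units") <- c(radius = "pitch", area = "pitch^2",
                          n_electrodes = "count", mean_latency_ms = "ms",
                          sem_ms = "ms", empty = "flag")
  out
}
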
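#' Classify active electrodes
#'
#' An electrode is "active" when its firing rate (spike count / duration) lies
#' within the configured bounds, 0.05-10 events/s inclusive on both ends. All
#' network-wide statistics are computed over active electrodes only.
#'
#' @param trains a [spike_train_set()].
#' @param config an [analysis_config()].
#' @return logical vector, one entry per electrode.
#' @export
classify_active_electrodes <- function(trains, config = analysis_config()) {
  stopifnot(inherits(trains, "spike_train_set"))
  if (trains$duration <= 0) stop("duration must be positive")
  r <- lengths(trains$trains) / trains$duration
  r >= config$active_rate_bounds[1L] & r <= config$active_rate_bounds[2L]
}

#' Per-electrode firing rates
#' @param trains a [spike_train_set()].
#' @return numeric vector of rates (events/s).
#' @export
electrode_rates <- function(trains) {
  lengths(trains$trains) / trains$duration
}

#' Detect bursts in one spike train
#'
#' A burst is a maximal run of at least `burst_min_spikes` (5) consecutive
#' spikes whose every inter-spike interval is strictly below `burst_max_isi`
#' (100 ms). Maximality means the run cannot be extended in either direction.
#'
#' @param times sorted spike times (s).
#' @param config an [analysis_config()].
#' @return data frame with `start`, `end` (s) and `n_spikes` per burst.
#' @export
detect_bursts <- function(times, config = analysis_config()) {
  if (is.unsorted(times)) stop("spike times must be sorted")
  empty <- data.frame(start = numeric(0), end = numeric(0),
                      n_spikes = integer(0))
  if (length(times) < config$burst_min_spikes) return(empty)
  short <- diff(times) < config$burst_max_isi
  r <- rle(short)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  ok <- r$values & r$lengths >= (config$burst_min_spikes - 1L)
  if (!any(ok)) return(empty)
  # run of k consecutive short ISIs spans spikes starts[i] .. ends[i]+1
  data.frame(start = times[starts[ok]],
             end = times[ends[ok] + 1L],
             n_spikes = r$lengths[ok] + 1L)
}

#' Detect bursts on every electrode
#'
#' @param trains a [spike_train_set()].
#' @param config an [analysis_config()].
#' @return data frame with `electrode`, `start`, `end`, `n_spikes`.
#' @export
detect_bursts_all <- function(trains, config = analysis_config()) {
  out <- lapply(seq_along(trains$trains), function(e) {
    b <- detect_bursts(trains$trains[[e]], config)
    if (nrow(b)) cbind(electrode = e, b) else NULL
  })
  out <- out[!vapply(out, is.null, TRUE)]
  if (!length(out))
    return(data.frame(electrode = integer(0), start = numeric(0),
                      end = numeric(0), n_spikes = integer(0)))
  do.call(rbind, out)
}

#' Network-wide activity summary
#'
#' Computes the per-recording summary statistics over active electrodes only:
#' number of active electrodes, total spikes, mean firing rate
#' (total spikes / (n_active * duration)) and burst count. Total spikes are
#' additionally reported per 10-minute recording phase; when the recording is
#' not 600 s long the scaled value is flagged (`scaled = TRUE`), never silent.
#'
#' @param trains a [spike_train_set()].
#' @param div_label optional developmental label (e.g. DIV age) carried into
#'   the summary.
#' @param config an [analysis_config()].
#' @return object of class `network_summary`: a list with `n_active`,
#'   `total_spikes`, `total_spikes_per_10min`, `scaled`, `mean_firing_rate`,
#'   `n_bursts`, `duration`, `div_label`.
#' @export
summarize_network <- function(trains, div_label = NA, config = analysis_config()) {
  active <- classify_active_electrodes(trains, config)
  n_active <- sum(active)
  if (n_active == 0L) {
    warning("no active electrodes; summary is all zeros")
    return(structure(list(n_active = 0L, total_spikes = 0L,
                          total_spikes_per_10min = 0,
                          scaled = trains$duration != 600,
                          mean_firing_rate = 0, n_bursts = 0L,
                          duration = trains$duration, div_label = div_label),
                     class = "network_summary"))
  }
  total <- sum(lengths(trains$trains)[active])
  bursts <- detect_bursts_all(trains, config)
  n_bursts <- sum(bursts$electrode %in% which(active))
  structure(list(
    n_active = n_active,
    total_spikes = total,
    total_spikes_per_10min = total * 600 / trains$duration,
    scaled = trains$duration != 600,
    mean_firing_rate = total / (n_active * trains$duration),
    n_bursts = n_bursts,
    duration = trains$duration,
    div_label = div_label
  ), class = "network_summary")
}

#' @export
print.network_summary <- function(x, ...) {
  cat(sprintf(
    "<network_summary%s> %d active electrodes, %d spikes (%.3g/10 min%s), MFR %.3g ev/s, %d bursts\n",
    if (is.na(x$div_label)) "" else paste0(" DIV ", x$div_label),
    x$n_active, x$total_spikes, x$total_spikes_per_10min,
    if (x$scaled) ", scaled" else "", x$mean_firing_rate, x$n_bursts))
  invisible(x)
}

summary_metrics <- function(s) {
  c(n_active = s$n_active,
    total_spikes_per_10min = s$total_spikes_per_10min,
    mean_firing_rate = s$mean_firing_rate,
    n_bursts = s$n_bursts)
}

#' Compare pre- and post-stimulation network summaries
#'
#' Builds the pre/post comparison table of network features (active
#' electrodes, total spikes per 10 min, mean firing rate, bursts): mean and
#' SEM across replicate cultures on each side, difference (post - pre) and
#' ratio (post / pre) of the means. With a single replicate the SEM is `NA`
#' and flagged. Mismatched durations are handled upstream: totals are already
#' normalized per 10-minute phase and rates are time-normalized.
#'
#' @param pre,post a `network_summary` or a list of them (replicates).
#' @return data frame with one row per metric: `pre_mean`, `pre_sem`,
#'   `post_mean`, `post_sem`, `delta`, `ratio`; attribute `sem_defined`.
#' @export
pre_post_comparison <- function(pre, post) {
  as_list <- function(x) if (inherits(x, "network_summary")) list(x) else x
  pre <- as_list(pre); post <- as_list(post)
  pre_m <- vapply(pre, summary_metrics, numeric(4))
  post_m <- vapply(post, summary_metrics, numeric(4))
  sem <- function(m) if (ncol(m) > 1L) apply(m, 1L, stats::sd) / sqrt(ncol(m))
    else rep(NA_real_, nrow(m))
  out <- data.frame(
    metric = rownames(pre_m),
    pre_mean = rowMeans(pre_m), pre_sem = sem(pre_m),
    post_mean = rowMeans(post_m), post_sem = sem(post_m)
  )
  out$delta <- out$post_mean - out$pre_mean
  out$ratio <- ifelse(out$pre_mean == 0, NA_real_,
                      out$post_mean / out$pre_mean)
  attr(out, "sem_defined") <- length(pre) > 1L && length(post) > 1L
  attr(out, "units") <- c(metric = "", pre_mean = "mixed", pre_sem = "mixed",
                          post_mean = "mixed", post_sem = "mixed",
                          delta = "mixed", ratio = "dimensionless")
  rownames(out) <- NULL
  out
}
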
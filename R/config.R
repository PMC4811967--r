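#' Analysis configuration
#'
#' Collects every numeric parameter of the pipeline in one validated object.
#' Defaults follow standard practice for high-density MEA recordings of
#' cultured networks:
#' \itemize{
#'   \item spike detection at 9 times the per-electrode noise SD;
#'   \item "active" electrodes fire between 0.05 and 10 events/s (inclusive);
#'   \item a burst is at least 5 consecutive spikes with every inter-spike
#'     interval below 100 ms;
#'   \item PSTHs use 25 ms bins starting after a 10 ms post-stimulus discard
#'     window, over a 500 ms response window;
#'   \item latency-vs-distance rings at radii 4, 6, ..., 30 pitch units;
#'   \item an electrode's evoked response is "reliable" if it responds in at
#'     least 10 of 35 stimulation trials;
#'   \item puncta are picked above a filtered-intensity offset of 0.07 and
#'     kept when their major axis lies within 0.3-1.3 um.
#' }
#'
#' @param threshold_multiplier detection threshold in noise-SD units.
#' @param active_rate_bounds inclusive firing-rate bounds (events/s) defining
#'   an active electrode.
#' @param burst_min_spikes minimum spikes per burst.
#' @param burst_max_isi maximum (strict) intra-burst inter-spike interval (s).
#' @param psth_bin PSTH bin width (s).
#' @param psth_discard post-stimulus discard window (s).
#' @param response_window evoked-response search window (s), from the pulse.
#' @param ring_radii ring radii in pitch units.
#' @param reliability_min,n_trials reliability rule: electrodes must respond
#'   in at least `reliability_min` of `n_trials` trials.
#' @param fast_long_boundary PSTH response-duration boundary (s) between fast
#'   and long-lasting classes.
#' @param puncta_offset filtered-intensity offset above which puncta count.
#' @param puncta_axis_bounds major-axis bounds in micrometres.
#' @param phase_presence_frac fraction of the dominant peak amplitude above
#'   which a waveform side phase counts as present.
#' @param seed global random seed propagated to stochastic stages.
#' @return a validated list of class `analysis_config`.
#' @export
analysis_config <- function(threshold_multiplier = 9,
                            active_rate_bounds = c(0.05, 10),
                            burst_min_spikes = 5L,
                            burst_max_isi = 0.100,
                            psth_bin = 0.025,
                            psth_discard = 0.010,
                            response_window = 0.500,
                            ring_radii = seq(4, 30, by = 2),
                            reliability_min = 10L,
                            n_trials = 35L,
                            fast_long_boundary = 0.150,
                            puncta_offset = 0.07,
                            puncta_axis_bounds = c(0.3, 1.3),
                            phase_presence_frac = 0.2,
                            seed = 1L) {
  cfg <- list(
    threshold_multiplier = threshold_multiplier,
    active_rate_bounds = as.numeric(active_rate_bounds),
    burst_min_spikes = as.integer(burst_min_spikes),
    burst_max_isi = burst_max_isi,
    psth_bin = psth_bin,
    psth_discard = psth_discard,
    response_window = response_window,
    ring_radii = as.numeric(ring_radii),
    reliability_min = as.integer(reliability_min),
    n_trials = as.integer(n_trials),
    fast_long_boundary = fast_long_boundary,
    puncta_offset = puncta_offset,
    puncta_axis_bounds = as.numeric(puncta_axis_bounds),
    phase_presence_frac = phase_presence_frac,
    seed = as.integer(seed)
  )
  validate_config(cfg)
  structure(cfg, class = "analysis_config")
}

validate_config <- function(cfg) {
  pos <- c("threshold_multiplier", "burst_max_isi", "psth_bin", "psth_discard",
           "response_window", "fast_long_boundary", "phase_presence_frac")
  for (f in pos)
    if (!is.finite(cfg[[f]]) || cfg[[f]] <= 0)
      stop(sprintf("config field `%s` must be positive", f))
  for (f in c("active_rate_bounds", "puncta_axis_bounds")) {
    b <- cfg[[f]]
    if (length(b) != 2L || !all(is.finite(b)) || b[1L] >= b[2L] || b[1L] < 0)
      stop(sprintf("config field `%s` must be increasing non-negative bounds", f))
  }
  if (cfg$burst_min_spikes < 2L) stop("`burst_min_spikes` must be >= 2")
  if (cfg$reliability_min < 1L || cfg$reliability_min > cfg$n_trials)
    stop("`reliability_min` must lie in [1, n_trials]")
  if (any(cfg$ring_radii <= 0) || any(diff(cfg$ring_radii) <= 0))
    stop("`ring_radii` must be positive and strictly increasing")
  if (cfg$puncta_offset < 0 || cfg$puncta_offset >= 1)
    stop("`puncta_offset` must lie in [0, 1)")
  invisible(cfg)
}

#' Write / read an analysis configuration as YAML
#'
#' @param config an [analysis_config()].
#' @param path file path.
#' @return `write_config` returns `path` invisibly; `read_config` returns the
#'   validated `analysis_config`.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  raw <- yaml::read_yaml(path)
  do.call(analysis_config, raw)
}
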
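#!/usr/bin/env Rscript
# Stage 1: simulate spontaneous activity over network development and compute
# the network-wide activity metrics.
#
# Three 10-minute recordings of a 64 x 64 array emulate the developmental
# regimes of a maturing culture: sparse random spiking (young network, 8 DIV),
# tonic network-wide firing (28 DIV), and synchronized network bursting
# (90 DIV). Each recording is summarized over its active electrodes
# (0.05-10 events/s) into total spikes per 10-minute phase, active-electrode
# count, mean firing rate, and burst count (>= 5 spikes, ISI < 100 ms).

suppressMessages(library(hdmea))
dir.create("results", showWarnings = FALSE)
seed <- 20260901L

geom <- array_geometry()
stages <- list(
  list(div = 8,  regime = regime_spec("sparse")),
  list(div = 28, regime = regime_spec("tonic")),
  list(div = 90, regime = regime_spec("bursting"))
)

rows <- list()
rates <- list()
for (st in stages) {
  sim <- gen_spontaneous(geom, st$regime, duration = 600,
                         seed = seed + st$div)
  s <- summarize_network(sim$trains, div_label = st$div)
  message(sprintf(
    "DIV %2d (%s): %d active electrodes, %d spikes/10 min, MFR %.2f ev/s, %d bursts",
    st$div, st$regime$regime, s$n_active, s$total_spikes,
    s$mean_firing_rate, s$n_bursts))
  rows[[length(rows) + 1L]] <- data.frame(
    div = st$div, regime = st$regime$regime, n_active = s$n_active,
    total_spikes_per_10min = s$total_spikes_per_10min,
    mean_firing_rate = s$mean_firing_rate, n_bursts = s$n_bursts)
  rates[[as.character(st$div)]] <- electrode_rates(sim$trains)
}

summary_tab <- do.call(rbind, rows)
attr(summary_tab, "units") <- c(div = "days", regime = "",
                                n_active = "count",
                                total_spikes_per_10min = "count",
                                mean_firing_rate = "events/s",
                                n_bursts = "count")
export_results(summary_tab, "results/network_summary.csv", "csv")
rate_tab <- do.call(rbind, lapply(names(rates), function(d)
  data.frame(div = as.integer(d), electrode = seq_along(rates[[d]]),
             rate = rates[[d]])))
attr(rate_tab, "units") <- c(div = "days", electrode = "index",
                             rate = "events/s")
export_results(rate_tab, "results/electrode_rates.csv", "csv")
message("wrote results/network_summary.csv and results/electrode_rates.csv")
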
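#!/usr/bin/env Rscript
# Stage 2: firing-frequency distributions and their Gaussian fits on the
# log10 axis.
#
# Reads the per-electrode rates written by stage 01 (or regenerates them when
# stage 01 has not run), builds the density-normalized log10 rate histogram
# of the active electrodes for each developmental stage, fits a Gaussian on
# the log axis, and quantifies the shift between stages as the fold change
# 10^(mu_early - mu_late). A mature network whose distribution moved toward
# low firing rates shows a fold change above 1.

suppressMessages(library(hdmea))
dir.create("results", showWarnings = FALSE)
seed <- 20260901L

rates_path <- "results/electrode_rates.csv"
if (file.exists(rates_path)) {
  rate_tab <- read_results(rates_path, "csv")
} else {
  message("stage 01 output not found; regenerating with the same seeds")
  geom <- array_geometry()
  regs <- list(`8` = regime_spec("sparse"), `28` = regime_spec("tonic"),
               `90` = regime_spec("bursting"))
  rate_tab <- do.call(rbind, lapply(names(regs), function(d) {
    sim <- gen_spontaneous(geom, regs[[d]], 600, seed = seed + as.integer(d))
    data.frame(div = as.integer(d), electrode = seq_along(sim$truth$rates),
               rate = electrode_rates(sim$trains))
  }))
}

fits <- list()
hist_rows <- list()
fit_rows <- list()
for (d in sort(unique(rate_tab$div))) {
  h <- rate_histogram(rate_tab$rate[rate_tab$div == d])
  fit <- fit_lognormal(h)
  fits[[as.character(d)]] <- fit
  message(sprintf(
    "DIV %2d: mu = %.3f, sigma = %.3f log10(ev/s), peak %.2f, R^2 = %.3f%s",
    d, fit$mu, fit$sigma, fit$amplitude, fit$gof,
    if (fit$poor_fit) " [poor fit]" else ""))
  hist_rows[[length(hist_rows) + 1L]] <- data.frame(
    div = d, log10_rate = h$mids, density = h$density, count = h$counts)
  fit_rows[[length(fit_rows) + 1L]] <- data.frame(
    div = d, mu = fit$mu, sigma = fit$sigma, amplitude = fit$amplitude,
    mu_se = fit$se[["mu"]], sigma_se = fit$se[["sigma"]],
    r_squared = fit$gof, poor_fit = fit$poor_fit)
}

divs <- names(fits)
shift_rows <- list()
for (k in seq_len(length(divs) - 1L)) {
  a <- divs[k]; b <- divs[length(divs)]
  cmp <- compare_fits(fits[[a]], fits[[b]])
  message(sprintf("DIV %s vs %s: %.2f-fold shift %s (peak ratio %.2f)",
                  a, b, cmp$fold_shift, cmp$direction, cmp$peak_ratio))
  shift_rows[[k]] <- data.frame(div_early = as.integer(a),
                                div_late = as.integer(b),
                                fold_shift = cmp$fold_shift,
                                peak_ratio = cmp$peak_ratio,
                                direction = cmp$direction)
}

export_results(do.call(rbind, hist_rows), "results/rate_histograms.csv", "csv")
export_results(do.call(rbind, fit_rows), "results/rate_fits.csv", "csv")
export_results(do.call(rbind, shift_rows), "results/rate_shifts.csv", "csv")
message("wrote results/rate_histograms.csv, rate_fits.csv, rate_shifts.csv")
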
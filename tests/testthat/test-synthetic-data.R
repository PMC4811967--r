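test_that("degenerate lognormal gives exact expected rates", {
  reg <- regime_spec("tonic", rate_log_mean = log10(1), rate_log_sd = 0)
  gs <- gen_spontaneous(array_geometry(8, 8), reg, 600, seed = 42)
  expect_equal(gs$truth$rates, rep(1, 64))
  # observed mean rate within 3 standard errors of 1 ev/s
  obs <- mean(electrode_rates(gs$trains))
  se <- sqrt(1 / 600 / 64)  # Poisson SE of the pooled mean rate
  expect_lt(abs(obs - 1), 3 * se)
})

test_that("programmed bursts are recovered by the burst detector", {
  reg <- regime_spec("bursting", rate_log_mean = -10, rate_log_sd = 0,
                     burst_rate = 1, intra_burst_isi = 0.020,
                     spikes_per_burst = 6, synchrony_frac = 1)
  gs <- gen_spontaneous(array_geometry(4, 4), reg, 600, seed = 3)
  bursts <- detect_bursts_all(gs$trains)
  per_e <- table(factor(bursts$electrode, levels = 1:16))
  expect_equal(as.integer(per_e), rep(10L, 16L))
  expect_equal(bursts$n_spikes, rep(6L, nrow(bursts)))
  # ground truth records the same epochs
  expect_equal(nrow(gs$truth$bursts), 160L)
})

test_that("generators are deterministic under a fixed seed", {
  reg <- regime_spec("bursting")
  g1 <- gen_spontaneous(array_geometry(4, 4), reg, 30, seed = 9)
  g2 <- gen_spontaneous(array_geometry(4, 4), reg, 30, seed = 9)
  expect_identical(g1$trains$trains, g2$trains$trains)
  r1 <- gen_raw_traces(g1$trains, reg, 7800, seed = 5)
  r2 <- gen_raw_traces(g2$trains, reg, 7800, seed = 5)
  expect_identical(r1$traces, r2$traces)
  b1 <- gen_waveform_bank(n = 50, seed = 4)
  b2 <- gen_waveform_bank(n = 50, seed = 4)
  expect_identical(b1$snippets, b2$snippets)
  p1 <- gen_puncta_image(n_puncta = 10, seed = 6)
  p2 <- gen_puncta_image(n_puncta = 10, seed = 6)
  expect_identical(p1$image$pixels, p2$image$pixels)
})

test_that("lognormal rate samples are Gaussian on the log scale", {
  reg <- regime_spec("tonic", rate_log_mean = 0, rate_log_sd = 0.45)
  gs <- gen_spontaneous(array_geometry(64, 64), reg, 1, seed = 12)
  expect_gt(stats::shapiro.test(log10(gs$truth$rates))$p.value, 0.01)
})

test_that("empirical rates converge to ground-truth rates", {
  reg <- regime_spec("tonic", rate_log_mean = 0, rate_log_sd = 0.3)
  gs <- gen_spontaneous(array_geometry(6, 6), reg, 900, seed = 21)
  obs <- electrode_rates(gs$trains)
  se <- sqrt(gs$truth$rates / 900)
  expect_gt(mean(abs(obs - gs$truth$rates) <= 3 * se), 0.95)
})

test_that("pure-noise traces have the specified noise SD", {
  tr <- synth_trace(numeric(0), 1, 7800, noise_sd = 10, amplitude = 120,
                    seed = 31)
  expect_lt(abs(sd(tr) - 10) / 10, 0.05)
  expect_warning(synth_trace(0.5, 1, 7800, noise_sd = 10, amplitude = 5,
                             seed = 1), "untestable")
})

test_that("a single 12-SD spike is detected within 1 ms", {
  tr <- synth_trace(0.5, 1, 7800, noise_sd = 10, amplitude = 120,
                    class = "neg_mono", seed = 17)
  det <- detect_spikes_trace(tr, 7800)
  expect_length(det$times, 1L)
  expect_lt(abs(det$times - 0.5), 0.001)
})

test_that("waveform bank respects the requested class mix", {
  bank <- gen_waveform_bank(c(1, 0, 0, 0), n = 100, seed = 2)
  expect_true(all(bank$labels == "neg_mono"))
  pred <- apply(bank$snippets, 1, categorize_waveform, sampling_rate = 7800)
  expect_true(all(pred == "neg_mono"))
  bank4 <- gen_waveform_bank(c(0.25, 0.25, 0.25, 0.25), n = 4, seed = 2)
  expect_equal(sort(as.character(bank4$labels)), sort(waveform_classes))
  expect_error(gen_waveform_bank(c(0.5, 0.5, 0.5, 0.5)), "proportions")
})

test_that("evoked generator honours latency, envelope and reliability", {
  geom <- array_geometry(stim_sites = default_stim_sites())
  prot <- stim_protocol(n_sites = 2)
  # zero latency jitter: every trial's first spike at exactly 70 ms
  ex <- gen_evoked_experiment(geom, prot, c("fast", "long"), seed = 2,
                              jitter_fast = 0, background_rate = 0,
                              low_frac = 0)
  fl <- first_spike_latencies(ex$trains, prot, 1)
  expect_true(all(abs(fl$latencies$latency - 0.070) < 1e-9))
  # long-lasting site: PSTH support extends beyond 300 ms
  psth <- compute_psth(ex$trains, prot, 2)
  late_bins <- which(psth$edges[-1] > 0.300)
  expect_gt(sum(psth$mean[late_bins]), 0)
  # reliability 7/35: excluded under the >= 10/35 rule
  ex2 <- gen_evoked_experiment(geom, prot, c("fast", "fast"), seed = 3,
                               background_rate = 0, low_frac = 0.25,
                               rel_trials_low = 7)
  fl2 <- first_spike_latencies(ex2$trains, prot, 1)
  truth2 <- ex2$truth$responding[ex2$truth$responding$site == 1, ]
  expect_setequal(
    fl2$reliability$electrode[!fl2$reliability$reliable],
    truth2$electrode[truth2$unreliable]
  )
  expect_equal(fl2$n_excluded, sum(truth2$unreliable))
})

test_that("puncta generator produces blank and dense images correctly", {
  g0 <- gen_puncta_image(n_puncta = 0, seed = 5)
  ps0 <- count_puncta(granulometric_filter(g0$image))
  expect_equal(ps0$n, 0L)
  expect_error(gen_puncta_image(n_puncta = 4000, size = 256, seed = 1),
               "density too high")
  expect_error(gen_puncta_image(axis_range = c(0.05, 0.1), scale = 0.077),
               "2 pixels")
})
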
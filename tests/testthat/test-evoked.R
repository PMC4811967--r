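make_evoked_fixture <- function(classes = c("fast", "long"), seed = 2, ...) {
  geom <- array_geometry(stim_sites = default_stim_sites())
  prot <- stim_protocol(n_sites = length(classes))
  ex <- gen_evoked_experiment(geom, prot, classes, seed = seed, ...)
  list(geom = geom, prot = prot, ex = ex)
}

test_that("artifact removal drops exactly the programmed artifacts", {
  fx <- make_evoked_fixture(background_rate = 0)
  clean <- remove_artifacts(fx$ex$trains, fx$prot, hard_threshold = 500)
  # all artifact events gone (they sit at +0.5 ms, inside the discard window,
  # and saturate the hard threshold)
  art <- fx$ex$truth$artifacts
  for (k in seq_len(nrow(art)))
    expect_false(art$time[k] %in% clean$trains[[art$electrode[k]]])
  # genuine evoked spikes all survive (latencies > 10 ms, amplitudes ~60 uV)
  expect_equal(n_spikes(clean), n_spikes(fx$ex$trains) - nrow(art))
})

test_that("events inside the 10 ms discard window are removed", {
  geom <- array_geometry(4, 4)
  prot <- stim_protocol(n_sites = 1, n_pulses_per_site = 3, start = 1)
  pulses <- prot$pulse_times[[1]]
  trains <- rep(list(numeric(0)), 16)
  trains[[1]] <- sort(pulses + 0.005)   # all inside [0, 10 ms)
  trains[[2]] <- sort(pulses + 0.050)   # all outside
  sts <- spike_train_set(geom, 20, trains)
  clean <- remove_artifacts(sts, prot, hard_threshold = 500)
  expect_length(clean$trains[[1]], 0L)
  expect_equal(clean$trains[[2]], trains[[2]])
  # no pulses: identity transform
  same <- remove_artifacts(sts, NULL, hard_threshold = 500)
  expect_identical(same$trains, sts$trains)
  expect_error(remove_artifacts(sts, prot, hard_threshold = 90,
                                detection_threshold = 90), "exceed")
})

test_that("PSTH bins a hand-countable construction correctly", {
  geom <- array_geometry(2, 2)
  prot <- stim_protocol(n_sites = 1, n_pulses_per_site = 5, start = 1)
  pulses <- prot$pulse_times[[1]]
  trains <- rep(list(numeric(0)), 4)
  trains[[1]] <- sort(pulses + 0.030)  # one spike at +30 ms per trial
  sts <- spike_train_set(geom, 30, trains)
  psth <- compute_psth(sts, prot, 1)
  expect_equal(psth$edges[1], 0.010)
  expect_equal(diff(psth$edges), rep(0.025, length(psth$edges) - 1))
  expect_equal(psth$mean[1], 1)
  expect_equal(sum(psth$mean[-1]), 0)
  expect_equal(psth$n_trials, 5L)
  # all-zero PSTH for a silent network
  psth0 <- compute_psth(spike_train_set(geom, 30, rep(list(numeric(0)), 4)),
                        prot, 1)
  expect_true(all(psth0$mean == 0))
  # mean lies between the percentile bands
  expect_true(all(psth$mean >= psth$lower - 1e-12))
  expect_true(all(psth$mean <= psth$upper + 1e-12))
})

test_that("PSTH counts are conserved against a direct window count", {
  fx <- make_evoked_fixture(seed = 6)
  clean <- remove_artifacts(fx$ex$trains, fx$prot, hard_threshold = 500)
  all_t <- sort(unlist(clean$trains))
  for (s in 1:2) {
    psth <- compute_psth(clean, fx$prot, s)
    span <- range(psth$edges)
    direct <- sum(vapply(fx$prot$pulse_times[[s]], function(p)
      sum(all_t >= p + span[1] & all_t < p + span[2]), numeric(1)))
    expect_equal(psth$total, direct)
    expect_equal(sum(psth$trial_counts), sum(psth$mean) * psth$n_trials)
  }
})

test_that("response classification separates fast and long-lasting PSTHs", {
  mk_psth <- function(mean_counts) {
    nb <- length(mean_counts)
    structure(list(site = 1L, edges = 0.010 + 0.025 * (0:nb),
                   mean = mean_counts, lower = rep(0, nb),
                   upper = mean_counts, n_trials = 35L,
                   trial_counts = matrix(rep(mean_counts, 35), nb),
                   total = sum(mean_counts) * 35), class = "psth")
  }
  # supra-baseline only in [10, 85) ms -> fast
  fast <- mk_psth(c(5, 5, 5, rep(0, 17)))
  cls_f <- classify_response(fast, baseline = 0.2)
  expect_equal(cls_f$class, "fast")
  expect_lte(cls_f$duration, 0.150)
  # supra-baseline through 460 ms -> long-lasting
  long <- mk_psth(c(rep(3, 18), 0, 0))
  cls_l <- classify_response(long, baseline = 0.2)
  expect_equal(cls_l$class, "long-lasting")
  expect_gt(cls_l$duration, 0.150)
  # nothing above baseline -> non-responsive
  flat <- mk_psth(rep(0.2, 20))
  expect_equal(classify_response(flat, baseline = 0.2)$class,
               "non-responsive")
  # a run starting after 100 ms does not count as a response onset
  late <- mk_psth(c(rep(0, 6), rep(5, 6), rep(0, 8)))
  expect_equal(classify_response(late, baseline = 0.2)$class,
               "non-responsive")
  expect_error(classify_response(fast, baseline = NULL), "baseline")
})

test_that("first-spike latencies apply the 10-of-35 reliability rule", {
  geom <- array_geometry(4, 4)
  prot <- stim_protocol(n_sites = 1, n_pulses_per_site = 35, start = 1)
  pulses <- prot$pulse_times[[1]]
  trains <- rep(list(numeric(0)), 16)
  trains[[1]] <- sort(pulses + 0.070)          # responds 35/35 at 70 ms
  trains[[2]] <- sort(pulses[1:9] + 0.080)     # responds 9/35 -> excluded
  trains[[3]] <- sort(pulses[1:10] + 0.090)    # responds 10/35 -> kept
  sts <- spike_train_set(geom, 200, trains)
  fl <- first_spike_latencies(sts, prot, 1)
  expect_setequal(unique(fl$latencies$electrode), c(1L, 3L))
  expect_true(all(abs(fl$latencies$latency[fl$latencies$electrode == 1] -
                        0.070) < 1e-9))
  expect_equal(fl$n_excluded, 1L)
  rel <- fl$reliability
  expect_equal(rel$n_responding[rel$electrode == 1], 35L)
  expect_false(rel$reliable[rel$electrode == 2])
})

test_that("ring latency table reproduces printed region sizes and flatness", {
  geom <- array_geometry(stim_sites = default_stim_sites())
  prot <- stim_protocol(n_sites = 1, n_pulses_per_site = 35, start = 1)
  pulses <- prot$pulse_times[[1]]
  # uniform programmed latency on electrodes at many distances
  d <- electrode_distances(geom, 1)
  chosen <- which(d > 0 & d <= 30)[seq(1, sum(d > 0 & d <= 30), by = 4)]
  trains <- rep(list(numeric(0)), n_electrodes(geom))
  for (e in chosen) trains[[e]] <- sort(pulses + 0.070)
  sts <- spike_train_set(geom, 200, trains)
  fl <- first_spike_latencies(sts, prot, 1)
  tab <- latency_vs_distance(fl$latencies, geom, 1)
  expect_equal(tab$area[tab$radius == 4], 50.27, tolerance = 1e-3)
  expect_equal(tab$area[tab$radius == 30], 2827.43, tolerance = 1e-3)
  # distance-independence: every occupied ring shows the programmed latency
  expect_true(all(abs(tab$mean_latency_ms[!tab$empty] - 70) < 1e-9))
})

test_that("well-separated response forms classify correctly across seeds", {
  geom <- array_geometry(stim_sites = default_stim_sites())
  prot <- stim_protocol(n_sites = 2)
  for (seed in 1:20) {
    ex <- gen_evoked_experiment(geom, prot, c("fast", "long"), seed = seed,
                                background_rate = 0)
    got <- vapply(1:2, function(s) {
      psth <- compute_psth(ex$trains, prot, s)
      classify_response(psth, psth_baseline(ex$trains, prot, s))$class
    }, character(1))
    expect_equal(got, c("fast", "long-lasting"))
  }
})

test_that("no plasticity: pre/post features unchanged without programmed change", {
  set.seed(91)
  mk <- function(seed) {
    reg <- regime_spec("tonic", rate_log_mean = -0.2, rate_log_sd = 0.3)
    gen_spontaneous(array_geometry(16, 16), reg, 600, seed = seed)$trains
  }
  pre <- summarize_network(mk(1))
  post <- summarize_network(mk(2))
  cmp <- pre_post_comparison(pre, post)
  mfr <- cmp[cmp$metric == "mean_firing_rate", ]
  expect_lt(abs(mfr$ratio - 1), 0.1)
})
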
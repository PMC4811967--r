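test_that("noise SD estimators behave as specified", {
  set.seed(101)
  x <- rnorm(1e5)
  expect_lt(abs(estimate_noise_sd(x, "robust-mad") - 1), 0.02)
  expect_lt(abs(estimate_noise_sd(x, "plain-sd") - 1), 0.02)
  expect_equal(estimate_noise_sd(rep(0, 200)), 0) |>
    expect_warning("constant")
  expect_error(estimate_noise_sd(rnorm(50)), "100 samples")
})

test_that("robust estimator resists spike contamination; plain SD inflates", {
  set.seed(102)
  x <- rnorm(1e5, sd = 10)
  idx <- sample.int(1e5, 1000)  # 1% contamination at 20x sd
  x[idx] <- x[idx] - 200
  robust <- estimate_noise_sd(x, "robust-mad")
  plain <- estimate_noise_sd(x, "plain-sd")
  expect_lt(abs(robust - 10) / 10, 0.05)
  expect_gt(plain, 1.5 * robust)
})

test_that("flat and pure-noise traces produce no events at 9 SD", {
  expect_warning(det0 <- detect_spikes_trace(rep(0, 7800), 7800))
  expect_length(det0$times, 0L)
  # 60 s of noise: false-positive rate below 0.1 ev/s
  tr <- synth_trace(numeric(0), 60, 7800, noise_sd = 10, amplitude = 120,
                    seed = 55)
  det <- detect_spikes_trace(tr, 7800)
  expect_lt(length(det$times) / 60, 0.1)
})

test_that("injected 12-SD templates are recovered with sample accuracy", {
  # sample-aligned truth: the renderer places templates on the sample grid
  true_t <- round(seq(0.25, 59.75, length.out = 100) * 7800) / 7800
  tr <- synth_trace(true_t, 60, 7800, noise_sd = 10, amplitude = 120,
                    class = "neg_bi", seed = 77)
  det <- detect_spikes_trace(tr, 7800)
  hits <- vapply(true_t, function(t) {
    err <- min(abs(det$times - t))
    err <= 1 / 7800 + 1e-9
  }, logical(1))
  expect_gte(sum(hits), 99L)
})

test_that("detection count is monotone non-increasing in the threshold", {
  true_t <- sort(runif(40, 0.5, 29.5))
  tr <- synth_trace(true_t, 30, 7800, noise_sd = 10, amplitude = 110,
                    class = "neg_tri", seed = 13)
  counts <- vapply(c(5, 7, 9, 11, 13, 20), function(k) {
    length(detect_spikes_trace(tr, 7800,
                               detection_params(threshold_multiplier = k))$times)
  }, numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("detector output satisfies the spike-train-set contract", {
  reg <- regime_spec("tonic", rate_log_mean = 0.3, rate_log_sd = 0.2)
  gs <- gen_spontaneous(array_geometry(3, 3), reg, 10, seed = 8)
  rec <- gen_raw_traces(gs$trains, reg, 7800, seed = 9)
  sts <- detect_spikes(rec)
  expect_s3_class(sts, "spike_train_set")
  L <- round(0.004 * 7800)
  for (e in 1:9) {
    expect_true(!is.unsorted(sts$trains[[e]], strictly = TRUE))
    expect_equal(ncol(sts$waveforms[[e]]), L)
    expect_equal(nrow(sts$waveforms[[e]]), length(sts$trains[[e]]))
  }
})

test_that("snippets are peak-centred and edge spikes are flagged padded", {
  tr <- synth_trace(c(0.001, 0.5), 1, 7800, noise_sd = 10, amplitude = 150,
                    class = "neg_mono", seed = 3)
  det <- detect_spikes_trace(tr, 7800)
  expect_equal(det$padded, c(TRUE, FALSE))
  L <- ncol(det$snippets)
  centre <- floor((L - 1) / 2) + 1L
  expect_equal(which.max(abs(det$snippets[2, ])), centre)
  expect_error(detect_spikes_trace(rnorm(1000), 1500), "too low")
})

test_that("detection is consistent across 7.8 and 22 kHz renderings", {
  reg <- regime_spec("tonic", rate_log_mean = 0.3, rate_log_sd = 0.15)
  gs <- gen_spontaneous(array_geometry(4, 4), reg, 20, seed = 30)
  classes <- gs$truth$classes
  counts <- list()
  props <- list()
  for (fs in c(7800, 22000)) {
    rec <- gen_raw_traces(gs$trains, reg, fs, seed = 31, classes = classes)
    det <- detect_spikes(rec)
    counts[[as.character(fs)]] <- lengths(det$trains)
    cls <- unlist(lapply(seq_along(det$waveforms), function(e) {
      sn <- det$waveforms[[e]]
      if (nrow(sn) == 0) return(character(0))
      apply(sn, 1, categorize_waveform, sampling_rate = fs)
    }))
    props[[as.character(fs)]] <-
      prop.table(table(factor(cls, levels = waveform_classes)))
  }
  n_true <- lengths(gs$trains$trains)
  # per-electrode counts agree within 5% of the true count at both rates
  expect_lt(max(abs(counts[["7800"]] - counts[["22000"]]) / pmax(n_true, 1)),
            0.05)
  # class proportions agree within 5 percentage points
  expect_lt(max(abs(props[["7800"]] - props[["22000"]])), 0.05)
})
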
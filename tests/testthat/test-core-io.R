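test_that("recording container round-trips bit-exactly", {
  geom <- array_geometry(2, 2, stim_sites = rbind(c(1, 1)))
  traces <- lapply(1:4, function(i) rnorm(7800, sd = i))
  rec <- mea_recording(geom, 7800, 1, traces)
  f <- withr::local_tempfile()
  write_recording(rec, f)
  r2 <- read_recording(f)
  expect_identical(r2$traces, rec$traces)
  expect_identical(r2$sampling_rate, rec$sampling_rate)
  expect_identical(r2$duration, rec$duration)
  expect_identical(r2$geometry$stim_sites, geom$stim_sites)
})

test_that("zero-duration recording round-trips", {
  rec <- mea_recording(array_geometry(2, 2), 7800, 0,
                       rep(list(numeric(0)), 4))
  f <- withr::local_tempfile()
  write_recording(rec, f)
  r2 <- read_recording(f)
  expect_equal(r2$duration, 0)
  expect_identical(lengths(r2$traces), rep(0L, 4L))
})

test_that("full-array synthetic recording round-trips elementwise", {
  reg <- regime_spec("sparse")
  gs <- gen_spontaneous(array_geometry(8, 8), reg, 2, seed = 7)
  rec <- gen_raw_traces(gs$trains, reg, 7800, seed = 8)
  f <- withr::local_tempfile()
  write_recording(rec, f)
  r2 <- read_recording(f)
  expect_identical(r2$traces, rec$traces)
})

test_that("schema validation rejects corrupted containers", {
  rec <- mea_recording(array_geometry(2, 2), 7800, 0.1,
                       lapply(1:4, function(i) rnorm(780)))
  f <- withr::local_tempfile()
  write_recording(rec, f)

  # truncated trace block
  raw <- readBin(f, "raw", file.size(f))
  f_trunc <- withr::local_tempfile()
  writeBin(raw[seq_len(length(raw) - 100L)], f_trunc)
  expect_error(read_recording(f_trunc), "truncated")

  # bad magic
  f_magic <- withr::local_tempfile()
  raw2 <- raw
  raw2[1:8] <- charToRaw("NOTMAGIC")
  writeBin(raw2, f_magic)
  expect_error(read_recording(f_magic), "magic")

  # header missing a required field (rewrite the container by hand)
  hlen <- readBin(raw[9:12], "integer", 1L, size = 4L, endian = "little")
  header <- jsonlite::fromJSON(rawToChar(raw[13:(12 + hlen)]))
  for (field in c("sampling_rate", "n_samples", "duration")) {
    h <- header
    h[[field]] <- NULL
    hj <- charToRaw(jsonlite::toJSON(h, auto_unbox = TRUE, null = "null"))
    f_bad <- withr::local_tempfile()
    con <- file(f_bad, "wb")
    writeBin(charToRaw("HDMEAREC"), con)
    writeBin(length(hj), con, size = 4L, endian = "little")
    writeBin(hj, con)
    writeBin(raw[(13L + hlen):length(raw)], con)
    close(con)
    expect_error(read_recording(f_bad), field)
  }
})

test_that("result export round-trips with units and full precision", {
  tab <- data.frame(bin = 1:3,
                    mean_count = c(1.23456789e-4, pi, 2 / 3),
                    label = c("a", "b", "c"))
  attr(tab, "units") <- c(bin = "index", mean_count = "count", label = "")
  f_csv <- withr::local_tempfile(fileext = ".csv")
  export_results(tab, f_csv, "csv")
  back <- read_results(f_csv, "csv")
  expect_equal(back$mean_count, tab$mean_count, tolerance = 1e-9)
  expect_identical(attr(back, "units"), attr(tab, "units"))

  f_json <- withr::local_tempfile(fileext = ".json")
  export_results(tab, f_json, "json")
  back_j <- read_results(f_json, "json")
  expect_equal(back_j$mean_count, tab$mean_count, tolerance = 1e-9)

  # empty table -> header only
  f_empty <- withr::local_tempfile(fileext = ".csv")
  empty <- tab[0, ]
  attr(empty, "units") <- NULL
  export_results(empty, f_empty, "csv")
  expect_equal(length(readLines(f_empty)), 1L)
  # 3-row table -> 3 data lines after the header
  f3 <- withr::local_tempfile(fileext = ".csv")
  export_results(empty[0, ], f3, "csv")
  export_results(tab, f3, "csv")
  expect_equal(length(readLines(f3)), 5L)  # units + header + 3 rows
  expect_error(export_results(tab, f_csv, "parquet"))
})

test_that("configuration validates bounds and round-trips through YAML", {
  cfg <- analysis_config()
  expect_equal(cfg$threshold_multiplier, 9)
  expect_equal(cfg$active_rate_bounds, c(0.05, 10))
  expect_equal(cfg$ring_radii, seq(4, 30, by = 2))
  expect_error(analysis_config(psth_bin = -1), "positive")
  expect_error(analysis_config(active_rate_bounds = c(10, 0.05)), "bounds")
  expect_error(analysis_config(reliability_min = 40), "reliability")
  f <- withr::local_tempfile(fileext = ".yaml")
  write_config(cfg, f)
  expect_equal(read_config(f), cfg)
})

test_that("container types enforce their invariants", {
  geom <- array_geometry(2, 2)
  expect_error(mea_recording(geom, 7800, 1, rep(list(rnorm(10)), 4)),
               "length mismatch")
  expect_error(mea_recording(geom, 7800, 1, rep(list(rnorm(7800)), 3)),
               "electrode count")
  expect_warning(mea_recording(geom, 5000, 0.01, rep(list(rnorm(50)), 4)),
                 "non-native")
  expect_error(spike_train_set(geom, 1, list(c(0.2, 0.1), 0.5, 0.7, 0.9)),
               "increasing")
  expect_error(spike_train_set(geom, 1, list(c(0.1, 1.5), 0.5, 0.7, 0.9)),
               "outside")
  expect_error(array_geometry(2, 2, stim_sites = rbind(c(3, 1))), "inside")
  expect_error(array_geometry(pitch = -1), "pitch")
})
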
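# Independent brute-force oracle for burst detection: walk the train spike by
# spike, growing a run while the next ISI is strictly below max_isi, and emit
# every maximal run of at least min_spikes spikes.
brute_force_bursts <- function(times, min_spikes = 5L, max_isi = 0.100) {
  out <- data.frame(start = numeric(0), end = numeric(0),
                    n_spikes = integer(0))
  n <- length(times)
  i <- 1L
  while (i <= n) {
    j <- i
    while (j < n && (times[j + 1L] - times[j]) < max_isi) j <- j + 1L
    if (j - i + 1L >= min_spikes)
      out <- rbind(out, data.frame(start = times[i], end = times[j],
                                   n_spikes = j - i + 1L))
    i <- j + 1L
  }
  out
}

# a tiny spike-train set over an r x c grid with the given trains
make_sts <- function(trains, duration, r = 1L, c = length(trains)) {
  spike_train_set(array_geometry(r, c), duration, trains)
}

# a regular spike train at a fixed rate
regular_train <- function(rate, duration) {
  if (rate <= 0) return(numeric(0))
  seq(0.5 / rate, duration, by = 1 / rate)
}
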
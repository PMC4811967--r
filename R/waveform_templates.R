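#' Extracellular waveform phase classes
#'
#' The four phase classes used to categorize extracellular spike shapes:
#' negative monophasic, negative biphasic (a dominant negative peak followed
#' by a positive rebound), negative triphasic (a small positive peak, a large
#' negative peak, then a second small positive peak) and positive biphasic
#' (a dominant positive peak followed by a negative one).
#'
#' @format character vector of class labels.
#' @export
waveform_classes <- c("neg_mono", "neg_bi", "neg_tri", "pos_bi")

#' Parametric spike waveform template
#'
#' Builds a 4 ms, peak-centred snippet for one of the four phase classes from
#' Gaussian-lobe phases. The dominant extremum sits at the centre sample and
#' has unit amplitude; side-phase amplitudes and lobe widths are either the
#' class defaults or randomized within class constraints (see
#' [gen_waveform_bank()]).
#'
#' @param class one of [waveform_classes].
#' @param sampling_rate sampling rate (Hz); the snippet has
#'   `round(0.004 * sampling_rate)` samples.
#' @param side_amp optional length-2 numeric: amplitudes of the (pre, post)
#'   side phases relative to the dominant peak. Defaults per class.
#' @param main_sd,side_sd lobe standard deviations (s).
#' @param side_offset side-lobe centre offset from the main peak (s).
#' @return numeric snippet with `max(abs(.)) == 1`.
#' @export
waveform_template <- function(class, sampling_rate = 7800,
                              side_amp = NULL,
                              main_sd = 0.0003, side_sd = 0.00035,
                              side_offset = 0.0007) {
  class <- match.arg(class, waveform_classes)
  L <- round(0.004 * sampling_rate)
  centre <- floor((L - 1) / 2) + 1L
  t <- (seq_len(L) - centre) / sampling_rate
  lobe <- function(amp, mu, sd) amp * exp(-0.5 * ((t - mu) / sd)^2)
  if (is.null(side_amp)) {
    side_amp <- switch(class,
      neg_mono = c(0, 0.06),
      neg_bi   = c(0, 0.45),
      neg_tri  = c(0.36, 0.32),
      pos_bi   = c(0, 0.5)
    )
  }
  main_sign <- if (class == "pos_bi") 1 else -1
  side_sign <- -main_sign
  w <- lobe(main_sign, 0, main_sd) +
    lobe(side_sign * side_amp[1L], -side_offset, side_sd) +
    lobe(side_sign * side_amp[2L], side_offset, side_sd)
  w / max(abs(w))
}

random_template <- function(class, sampling_rate) {
  side_amp <- switch(class,
    neg_mono = c(0, stats::runif(1, 0.02, 0.10)),
    neg_bi   = c(0, stats::runif(1, 0.38, 0.55)),
    neg_tri  = c(stats::runif(1, 0.32, 0.44), stats::runif(1, 0.30, 0.40)),
    pos_bi   = c(0, stats::runif(1, 0.40, 0.60))
  )
  waveform_template(class, sampling_rate,
                    side_amp = side_amp,
                    main_sd = stats::runif(1, 0.00025, 0.00035),
                    side_sd = stats::runif(1, 0.00030, 0.00042),
                    side_offset = stats::runif(1, 0.00065, 0.00080))
}

#' Generate a labelled bank of spike-waveform snippets
#'
#' Draws 4 ms snippets from the parametric phase templates with per-snippet
#' randomized phase amplitudes and widths (within class constraints) plus
#' additive Gaussian noise. Class counts follow `class_mix` deterministically
#' (largest-remainder rounding), so the returned label proportions equal the
#' mix up to rounding; labels are ground truth for classifier validation.
#'
#' @param class_mix proportions over [waveform_classes]; must sum to 1.
#' @param n number of snippets.
#' @param sampling_rate sampling rate (Hz).
#' @param noise_sd additive noise SD relative to the unit dominant amplitude.
#' @param seed random seed.
#' @return list with `snippets` (n x L matrix), `labels` (factor) and
#'   `sampling_rate`.
#' @export
gen_waveform_bank <- function(class_mix = c(0.41, 0.15, 0.26, 0.18), n = 2000,
                              sampling_rate = 7800, noise_sd = 0.03,
                              seed = 1L) {
  if (length(class_mix) != 4L || abs(sum(class_mix) - 1) > 1e-8)
    stop("`class_mix` must be 4 proportions summing to 1")
  if (n < 1L) stop("`n` must be positive")
  set.seed(seed)
  counts <- floor(class_mix * n)
  rem <- n - sum(counts)
  if (rem > 0) {
    frac <- class_mix * n - counts
    counts[order(frac, decreasing = TRUE)[seq_len(rem)]] <-
      counts[order(frac, decreasing = TRUE)[seq_len(rem)]] + 1L
  }
  labels <- sample(rep(waveform_classes, counts))
  L <- round(0.004 * sampling_rate)
  snippets <- matrix(0, nrow = n, ncol = L)
  for (i in seq_len(n)) {
    w <- random_template(labels[i], sampling_rate)
    snippets[i, ] <- w + stats::rnorm(L, 0, noise_sd)
  }
  list(snippets = snippets,
       labels = factor(labels, levels = waveform_classes),
       sampling_rate = sampling_rate)
}
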
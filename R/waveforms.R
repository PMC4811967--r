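#' Categorize a spike waveform into a phase class
#'
#' Classifies a peak-centred, baseline-subtracted mean waveform by the
#' amplitudes of its positive and negative peaks. The dominant polarity is the
#' sign of the larger absolute extremum; a side phase counts as present when
#' its absolute extremum reaches `phase_presence_frac` (default 0.2) of the
#' dominant amplitude. Negative-dominant waveforms with 1, 2 or 3 present
#' phases map to negative mono-/bi-/tri-phasic (the triphasic pattern is a
#' small positive peak, the large negative peak, then a second small positive
#' peak); positive-dominant waveforms are positive biphasic (a large positive
#' peak followed by a negative one). The rule is invariant to amplitude
#' scaling.
#'
#' @param w numeric snippet (peak-centred). Baseline is taken as the mean of
#'   the first 0.5 ms when `sampling_rate` is given.
#' @param sampling_rate optional sampling rate (Hz) for baseline subtraction.
#' @param config an [analysis_config()] (`phase_presence_frac`).
#' @return one of [waveform_classes].
#' @export
categorize_waveform <- function(w, sampling_rate = NULL,
                                config = analysis_config()) {
  w <- as.numeric(w)
  if (!is.null(sampling_rate)) {
    nb <- max(1L, round(0.0005 * sampling_rate))
    w <- w - mean(w[seq_len(min(nb, length(w)))])
  }
  if (all(w == 0)) stop("all-zero snippet cannot be classified")
  p <- which.max(abs(w))
  A <- abs(w[p])
  alpha <- config$phase_presence_frac
  if (w[p] > 0) return("pos_bi")
  pre <- if (p > 1L) max(w[seq_len(p - 1L)]) else 0
  post <- if (p < length(w)) max(w[(p + 1L):length(w)]) else 0
  n_side <- (pre >= alpha * A) + (post >= alpha * A)
  c("neg_mono", "neg_bi", "neg_tri")[n_side + 1L]
}

snippet_features <- function(snippets) {
  # shape-parameter features (dominant-peak amplitude, side-peak amplitudes,
  # energy). These are near-Gaussian under additive noise and invariant to
  # the residual sample-alignment jitter of sharp spikes at 7.8 kHz, which
  # dominates the principal components of the raw samples and would split
  # single units into alignment modes.
  L <- ncol(snippets)
  centre <- floor((L - 1) / 2) + 1L
  cbind(
    dominant = snippets[, centre],
    pre_peak = apply(snippets[, seq_len(centre - 1L), drop = FALSE], 1L, max),
    post_peak = apply(snippets[, (centre + 1L):L, drop = FALSE], 1L, max),
    energy = sqrt(rowSums(snippets^2))
  )
}

merge_overlapping <- function(cl, feats, min_sep = 3) {
  # merge cluster pairs whose mean separation (per-dimension, scaled by the
  # pooled within-cluster SD) is below min_sep: such pairs model skew of one
  # unit's amplitude distribution, not distinct units
  repeat {
    ids <- sort(unique(cl))
    if (length(ids) == 1L) break
    stats_of <- lapply(ids, function(k) {
      f <- feats[cl == k, , drop = FALSE]
      v <- if (nrow(f) > 1L) apply(f, 2L, stats::var) else numeric(ncol(f))
      list(mu = colMeans(f), v = v, n = nrow(f))
    })
    best <- NULL; best_sep <- Inf
    for (a in seq_along(ids)) for (b in seq_len(a - 1L)) {
      sa <- stats_of[[a]]; sb <- stats_of[[b]]
      pooled <- (sa$n * sa$v + sb$n * sb$v) / (sa$n + sb$n)
      sep <- sqrt(mean((sa$mu - sb$mu)^2 / pmax(pooled, 1e-12)))
      if (sep < best_sep) { best_sep <- sep; best <- c(ids[a], ids[b]) }
    }
    if (best_sep >= min_sep) break
    cl[cl == best[1L]] <- best[2L]
  }
  cl
}

#' Isolate units from one electrode's snippets
#'
#' Spike sorting surrogate for one electrode: snippets are mapped to
#' shift-invariant shape parameters (dominant-peak amplitude, pre- and
#' post-peak side amplitudes, energy) and clustered with a Gaussian mixture
#' whose component count is selected in 1-3 by BIC. Two safeguards follow the
#' practice of spike-sorting pipelines: clusters holding less than
#' `min_unit_frac` of the spikes (outliers such as overlapping spikes) are
#' dissolved into the nearest unit, and cluster pairs whose mean separation
#' is below `min_sep` pooled within-cluster SDs are merged (they model the
#' skew of one unit's amplitude distribution, not distinct units). Fewer than
#' 20 snippets yield a single unit with a warning (too few for model
#' selection).
#'
#' @param snippets matrix, one snippet per row.
#' @param max_units maximum number of units (default 3).
#' @param min_unit_frac clusters holding fewer than this fraction of the
#'   snippets (outliers such as overlapping spikes) are dissolved into the
#'   nearest remaining unit.
#' @param min_sep minimum between-cluster mean separation, in pooled
#'   within-cluster SDs, for clusters to count as distinct units.
#' @return object of class `unit_set`: list with `n_units`, `assignments`
#'   (one label per snippet), `means` (list of per-unit mean waveforms),
#'   `n_snippets`.
#' @importFrom mclust Mclust mclustBIC
#' @export
sort_units <- function(snippets, max_units = 3L, min_unit_frac = 0.1,
                       min_sep = 3) {
  snippets <- as.matrix(snippets)
  n <- nrow(snippets)
  if (n < 20L) {
    warning("fewer than 20 snippets: returning a single unit")
    return(structure(list(n_units = 1L, assignments = rep(1L, n),
                          means = list(colMeans(snippets)), n_snippets = n),
                     class = "unit_set"))
  }
  feats <- snippet_features(snippets)
  fit <- mclust::Mclust(feats, G = seq_len(max_units), verbose = FALSE)
  cl <- as.integer(fit$classification)
  cl <- merge_overlapping(cl, feats, min_sep)
  # dissolve outlier clusters into the nearest surviving unit
  repeat {
    sizes <- table(cl)
    small <- names(sizes)[sizes < max(3, min_unit_frac * n)]
    if (!length(small) || length(sizes) == 1L) break
    u <- as.integer(small[1L])
    keep_u <- setdiff(unique(cl), u)
    cents <- vapply(keep_u, function(k)
      colMeans(feats[cl == k, , drop = FALSE]), numeric(ncol(feats)))
    for (i in which(cl == u)) {
      d2 <- colSums((cents - feats[i, ])^2)
      cl[i] <- keep_u[which.min(d2)]
    }
  }
  cl <- match(cl, sort(unique(cl)))  # relabel 1..k
  means <- lapply(sort(unique(cl)), function(u)
    colMeans(snippets[cl == u, , drop = FALSE]))
  structure(list(n_units = length(unique(cl)), assignments = cl,
                 means = means, n_snippets = n),
            class = "unit_set")
}

#' @export
print.unit_set <- function(x, ...) {
  cat(sprintf("<unit_set> %d unit(s) from %d snippets\n",
              x$n_units, x$n_snippets))
  invisible(x)
}

#' Waveform-class repertoire table
#'
#' Tabulates phase-class proportions over a collection of classified units
#' (or snippets). Proportions sum to 1; the negative total (the sum of the
#' three negative classes) is attached as an attribute.
#'
#' @param classes character vector or factor of [waveform_classes] labels.
#' @return data frame with `class`, `n`, `proportion`; attribute
#'   `negative_total`.
#' @export
repertoire_table <- function(classes) {
  classes <- factor(as.character(classes), levels = waveform_classes)
  if (!length(classes) || all(is.na(classes)))
    stop("at least one classified unit is required")
  n <- table(classes)
  out <- data.frame(class = waveform_classes, n = as.integer(n),
                    proportion = as.numeric(n) / sum(n))
  attr(out, "negative_total") <-
    sum(out$proportion[out$class != "pos_bi"])
  attr(out, "units") <- c(class = "", n = "count",
                          proportion = "fraction")
  out
}

#' Sort and categorize every electrode of a spike-train set
#'
#' Runs [sort_units()] on each electrode with enough snippets and categorizes
#' every unit's mean waveform with [categorize_waveform()].
#'
#' @param trains a [spike_train_set()] with waveform snippets.
#' @param min_snippets electrodes with fewer snippets are skipped.
#' @param config an [analysis_config()].
#' @return data frame with `electrode`, `unit`, `n_spikes`, `class`.
#' @export
catalog_waveforms <- function(trains, min_snippets = 20L,
                              config = analysis_config()) {
  stopifnot(inherits(trains, "spike_train_set"))
  if (is.null(trains$waveforms)) stop("spike-train set has no snippets")
  rows <- list()
  for (e in seq_along(trains$waveforms)) {
    sn <- trains$waveforms[[e]]
    if (is.null(sn) || nrow(sn) < min_snippets) next
    us <- sort_units(sn)
    for (u in seq_len(us$n_units)) {
      cls <- categorize_waveform(us$means[[u]], trains$sampling_rate, config)
      rows[[length(rows) + 1L]] <-
        data.frame(electrode = e, unit = u,
                   n_spikes = sum(us$assignments == u), class = cls)
    }
  }
  if (!length(rows))
    return(data.frame(electrode = integer(0), unit = integer(0),
                      n_spikes = integer(0), class = character(0)))
  do.call(rbind, rows)
}
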
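---
title: "Analysing spontaneous and evoked activity on high-density MEAs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Analysing spontaneous and evoked activity on high-density MEAs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Scope

`hdmea` implements the analysis chain used to characterize in vitro neuronal
networks — here, cultures of human iPSC-derived neurons — recorded on
high-density CMOS multielectrode arrays (64 x 64 = 4096 electrodes, 42 um
pitch, 7.8 kHz/electrode full-frame or 22 kHz for a 1024-electrode region of
interest). The chain covers spike detection, spontaneous-activity metrics,
firing-rate distribution fitting, evoked-response analysis around multi-site
electrical stimulation, spike-waveform categorization with unit isolation,
and granulometric quantification of synaptic puncta in fluorescence
micrographs. Because raw recordings of this kind are rarely shared, the
package carries a synthetic-data module that generates recordings,
stimulation experiments and puncta images with known ground truth; every
analysis stage is validated against that ground truth. The numbered scripts
under `analysis/` run the stages as a narrative workflow and write their
tables under `results/`.

# Spike detection

Extracellular spikes are detected per electrode with a peak-to-peak
differential threshold: an event is emitted where the peak-to-peak excursion
of the trace within a 1 ms search window exceeds **9 times the electrode's
noise SD**, the event is timed at the extremum of its dominant phase, and
events closer than a 1 ms refractory period merge, keeping the larger
excursion. Snippets of 4 ms, centred on the peak, are cut for downstream
waveform analysis (zero-padded and flagged at trace edges).

Design notes:

* The threshold multiplier applies to a *peak-to-peak* excursion. Published
  descriptions of precise-timing detectors leave open whether the multiplier
  applies to raw amplitude or a differential quantity; the peak-to-peak
  reading is this package's documented choice, and the detector should be
  read as a surrogate for that family of algorithms.
* The noise SD is the robust estimate `median(|x - median(x)|)/0.6745`
  (`estimate_noise_sd`, default `"robust-mad"`). The plain SD is selectable
  but inflates under spike contamination — with 1% of samples replaced by
  20-SD spikes the plain SD overshoots by >50% while the robust estimate
  stays within 5% (this contamination experiment is a unit test).
* The SD is estimated once per electrode over the full recording, assuming
  noise stationarity at the 10-minute scale of a recording phase.

On synthetic traces with 12-SD spikes the detector recovers >= 95% of events
with timing error at most one sample at 7.8 kHz, with a false-positive rate
below 0.1 events/s on pure noise (the acceptance suite measures both on a
1024-electrode x 60 s scenario). Detection counts are monotone non-increasing
in the threshold, and detection of the same scenario rendered at 7.8 and
22 kHz agrees in counts and class proportions within 5%.

# Spontaneous-activity metrics

An electrode is **active** when its firing rate over the recording lies in
**[0.05, 10] events/s, inclusive on both ends** ("between ... and" is read
inclusively; the boundary behaviour is pinned by tests at exactly 30 and
6001 spikes per 600 s). All network-wide statistics — active-electrode count,
total spikes, mean firing rate `total / (n_active * duration)`, burst count —
are computed **over active electrodes only**; how inactive electrodes'
spikes should enter network totals is not specified anywhere authoritative,
and excluding them is this package's documented choice.

A **burst** is a maximal run of at least 5 consecutive spikes whose every
inter-spike interval is *strictly* below 100 ms. `detect_bursts` implements
the rule with a run-length scan and is verified against an independent
brute-force maximal-run oracle on 1000 random trains. Bursts are
per-electrode; the cross-electrode aggregation of network bursts is not part
of the core metric set.

Total spike counts are reported per 10-minute recording phase; recordings of
any other duration are rescaled and carry an explicit `scaled` flag, never
silently.

# Firing-rate distributions

Population firing rates of cultured networks are lognormal-like, so the
distribution is summarized by a Gaussian fit on the log10 axis. The package
bins active-electrode rates on a fixed grid (bin width 0.1 log10 units over
[-1.5, 1.1], covering the active range) and fits
`A * exp(-(x - mu)^2 / (2 sigma^2))` by least squares (`minpack.lm::nlsLM`),
reporting parameter standard errors from the fit covariance and the fit
R-squared (flagged poor below 0.8, e.g. for bimodal histograms). Least
squares on the density histogram — rather than maximum likelihood — matches
the "Gaussian fit to the distribution" framing this analysis style uses, and
the fixed grid keeps fits comparable across developmental time points. The
binning grid is this package's choice; the upstream procedure it emulates is
not published in enough detail to restate.

Developmental shifts are quantified by `compare_fits` as the fold change
`10^(mu_early - mu_late)`; a fold above 1 is a shift *toward low firing
rates*. Parameter recovery (|error| < 0.05 log10 units in the median over
100 seeds at n = 4096) and exact scale equivariance under grid-aligned
rescaling are tested.

In the bursting regime the empirical rate distribution mixes the lognormal
background with the near-constant burst-participation rate, which narrows
the fitted sigma relative to the programmed background sigma — a property of
the scenario, not a fitting artefact.

# Evoked-response analysis

Stimulation sessions deliver 0.2 Hz trains of 35 biphasic pulses per site
from up to 16 on-chip sites. The pipeline:

1. **Artifact removal** (`remove_artifacts`): events above a hard amplitude
   threshold (default 500 uV, far above the ~60 uV spike regime but far
   below saturating artifacts) and all events in the first **10 ms** after
   any pulse are discarded. The hard threshold must exceed the detection
   threshold or an error is raised.
2. **PSTH** (`compute_psth`): spikes of all electrodes are aligned to each
   pulse and binned in **25 ms bins starting at +10 ms**; the per-bin mean
   and 5th/95th percentile bands over the 35 trials are reported. The
   percentile probabilities are configurable ("lower and uppermost
   percentiles" is otherwise unspecified). Binned counts exactly equal the
   raw spike count in the union of trial windows (a conservation invariant
   tested on every scenario).
3. **Classification** (`classify_response`): a bin is supra-baseline when
   its trial-mean count exceeds the pre-pulse baseline (mean per-bin count
   in the 1 s before each pulse) by 3 Poisson standard errors — the margin
   keeps ongoing-activity fluctuations from extending response runs. Among
   contiguous supra-baseline runs starting within 100 ms of the pulse, the
   response duration is the end of the last one; sites are `fast` at
   duration <= 150 ms, `long-lasting` above, `non-responsive` without a
   qualifying run. The 150 ms boundary is configurable: observed response
   forms are either confined to ~100 ms or extend to ~500 ms, so a
   midpoint-low boundary separates them cleanly.
4. **First-spike latencies** (`first_spike_latencies`): per electrode and
   trial, the first spike in (10, 500] ms after the pulse; electrodes are
   kept only when they respond in at least **10 of 35** trials.
5. **Latency versus distance** (`latency_vs_distance`): electrodes are
   assigned to concentric rings around the site at radii 4, 6, ..., 30 in
   pitch units (innermost disc, then annuli); per-ring mean +/- SEM latency
   is reported, with empty rings flagged.

The circular region size at radius r is `pi * r^2` in squared pitch units:
50.27 at r = 4, 706.86 at r = 15, 2827.43 at r = 30. Descriptions of this
analysis sometimes attach "um" to these numbers although they equal
`pi * r^2` in electrode units and are not distances at any stated pitch; the
package implements the `pi * r^2` reading and treats the unit label as a
suspected erratum.

PSTHs aggregate all electrodes by default (whether they should be restricted
to reliable electrodes is unspecified; a restriction flag would be a natural
extension).

# Waveform catalogue

Per electrode, snippets are sorted into 1-3 units and each unit's mean
waveform is categorized into one of four phase classes: negative
mono-/bi-/tri-phasic and positive biphasic.

**Unit isolation** (`sort_units`) clusters shift-invariant shape parameters
(dominant-peak amplitude, pre- and post-peak side amplitudes, snippet
energy) with a Gaussian mixture whose component count is selected in 1-3 by
BIC. Two safeguards follow common sorting practice: clusters holding under
10% of the spikes (overlap outliers) are dissolved into the nearest unit,
and cluster pairs whose means are separated by fewer than 3 pooled
within-cluster SDs are merged. The shape-parameter features are deliberate:
at 7.8 kHz the sub-sample alignment jitter of sharp spikes dominates the
principal components of the raw samples and splits single units into
alignment modes, and spectral-magnitude features are Rice-skewed, which BIC
over-fits with additional components once snippet counts grow. With these
features, single-template scenarios yield one unit on essentially all
electrodes (mirroring the observation that the vast majority of electrodes
in such cultures record single units), while mixtures of two templates at
3-fold amplitude separation are recovered with >= 95% membership accuracy.
This sorter is a documented stand-in for proprietary t-distribution EM
sorters, of which only the 1-3 unit range is adopted.

**Categorization** (`categorize_waveform`): after baseline subtraction (mean
of the first 0.5 ms), the dominant polarity is the sign of the larger
absolute extremum; a side phase is present when it reaches **0.2 of the
dominant amplitude** (configurable; descriptions of the side phases say only
"small amplitude"). Negative-dominant snippets with 1/2/3 present phases map
to mono-/bi-/tri-phasic (the triphasic pattern is positive-negative-positive
by construction); positive-dominant snippets are positive biphasic. The rule
is invariant to amplitude scaling, and class proportions always sum to 1.
Categorization uses per-unit mean waveforms by default; the per-spike
variant is a one-line change in `catalog_waveforms`.

# Puncta quantification

Fluorescence micrographs (normalized to [0,1], with a um/pixel scale) are
processed in three steps:

1. **Granulometric filtering** (`granulometric_filter`): the smooth
   heterogeneous background is estimated by grayscale morphological opening
   with a disc slightly larger than the maximum punctum diameter (derived
   from the 1.3 um upper axis bound and the scale) and subtracted (white
   top-hat). The image is lightly Gaussian-smoothed (sigma 2 px) before the
   opening so pixel noise does not bias the background estimate low — the
   opening of raw noise sits about 2.5 SD below its mean, which would leave
   a positive pedestal in the filtered image. A disc *smaller* than the
   puncta, as a literal reading of some descriptions would suggest, would
   remove the puncta themselves from the top-hat; the implemented sizing is
   the standard reading.
2. **Binarization**: the filtered image is cut at `max(threshold, offset)`
   with the threshold defaulting to Otsu's method and the offset defaulting
   to **0.07** — the floor above which filtered intensity counts as a
   punctum. Along any cross-section the reported punctum locations are
   exactly the runs above the offset (`cross_section_runs`).
3. **Counting** (`count_puncta`): connected components are measured by their
   second-moment best-fit ellipse; components with major axis outside
   **[0.3, 1.3] um** are discarded; density is count per um^2 of the field.

Condition comparisons report the fold change of mean per-field densities
with first-order error propagation and a Wilcoxon rank-sum p-value (at least
3 fields per condition); the excitatory/inhibitory balance is the per-field
V-GLUT/V-GAT count ratio, mean +/- SEM over fields, excluding (with a
warning) fields with zero V-GAT counts.

# The synthetic-data module

The generators reproduce the statistical structure the analyses assume — not
the biophysics:

* **Spontaneous activity** (`gen_spontaneous`): per-electrode rates are
  lognormal (log10-mean/SD per regime: sparse -1/0.4, tonic 0/0.45,
  bursting -0.3/0.45 — chosen so sparse networks sit near 0.1 ev/s and
  mature ones near 1 ev/s, the realistic range for such cultures);
  out-of-burst spiking is homogeneous Poisson (the simplest model consistent
  with "random spiking"); network bursts are scheduled evenly at the burst
  rate (default 6/min) with per-electrode participation probability 0.6 and
  a small onset jitter — synchrony without a network model. Per-electrode
  intra-burst structure is 8 spikes at 20 ms ISI (10% jitter).
* **Raw traces** (`gen_raw_traces`/`synth_trace`): Gaussian noise (default
  10 uV SD) with parametric Gaussian-lobe waveform templates inserted at
  spike times, default amplitude 12x the noise SD. Templates are
  peak-centred with unit dominant amplitude; side-phase amplitudes randomize
  within class constraints chosen so that classes stay separated under the
  0.2 presence fraction (e.g. triphasic side lobes in 0.30-0.44, monophasic
  rebounds below 0.10).
* **Evoked experiments** (`gen_evoked_experiment`): responding electrodes
  are drawn around each site with distance-decaying weight; each electrode
  responds in an exact programmed number of trials (32 by default, with 20%
  of electrodes programmed at 7 of 35 so the reliability rule's exclusions
  are exactly testable); first-spike latencies are Gaussian around 70 ms
  (fast, SD 5 ms) or 120 ms (long-lasting, SD 15 ms); later spikes fill a
  uniform envelope to 105 ms (fast) or a front-loaded beta profile to 480 ms
  (long-lasting) — mass profiles that keep 95% of fast activity within
  100 ms and long-lasting activity within 500 ms. Artifacts are saturating
  2 mV events 0.5 ms after each pulse on electrodes within 20 um of the
  site (artifacts on these arrays are confined to that distance). No
  quantitative responding-fraction or reliability is published for such
  experiments; both are free scenario parameters with the defaults above.
* **Puncta images** (`gen_puncta_image`): Gaussian-profile ellipses
  (diffraction-limited puncta are approximately Gaussian) with major-axis SD
  `axis/2.9`, calibrated so the measured above-threshold major axis
  approximates the programmed value at typical filtered-intensity cutoffs;
  placement is rejection-sampled to forbid overlap; background is a plateau
  plus broad Gaussian blobs plus pixel noise (default peak/noise >= 25).

What the generators do **not** emulate — and hence what passing tests do not
show about real data: electrode-to-electrode noise correlation and line
artifacts, electrode impedance variation, bursts with rate modulation inside
the burst, spike-amplitude adaptation, overlapping puncta and out-of-focus
light. Results on real recordings depend on those factors; the tests
establish correctness of the computations, not field performance.

# Determinism and numeric choices

Every generator takes an explicit seed and is bit-reproducible; the analysis
stages are deterministic given their inputs. Degenerate inputs are handled
explicitly: constant traces estimate a zero noise SD (warning) and detect
nothing; empty spike-train sets summarize to zeros with a warning; fits with
fewer than 5 occupied bins and histograms from fewer than 10 active
electrodes are errors carrying advice; single-replicate SEMs are `NA` and
flagged rather than fabricated. The recording container is a single-file
binary format (8-byte magic, JSON header, little-endian float64 trace
block) with schema validation that names the failing field; it round-trips
bit-exactly. No HDF5 dependency is used; the documented header makes the
format readable from any language.

Problem sizes in the test and acceptance suites are chosen to exercise the
full pipeline at desk scale: detection sensitivity on 1024 electrodes x
60 s, distribution fits at the full 4096-electrode population over 100
seeds, a complete 16-site x 35-trial stimulation session, and 40 synthetic
image fields. The analysis scripts run the 4096-electrode, 10-minute
spontaneous scenarios in full.

# Known limitations

* The detector does not resolve superimposed spikes; coincident events
  within the refractory window merge.
* Unit isolation uses amplitude-shape parameters; units differing only in
  fine temporal structure at equal amplitudes will not separate at 7.8 kHz.
* The lognormal fit reports least-squares uncertainties, which understate
  the sampling variability of histogram heights at small electrode counts.
* Puncta measurement assumes a single focal plane and non-overlapping
  objects; densities beyond ~0.5/um^2 violate the placement model and the
  counting guarantee.
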
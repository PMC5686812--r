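---
title: "Quantifying dendritic and spine calcium transients with dendrocalc"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying dendritic and spine calcium transients with dendrocalc}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dendrocalc)
```

## The measurement problem

Two-photon imaging of GCaMP6-expressing cortical pyramidal neurons yields
time-lapse image stacks in which somata, dendritic shafts and individual
spines are visible as regions of interest (ROIs). The analysis task this
package addresses is the post-hoc quantification stage: turning raw per-ROI
fluorescence into calibrated event statistics — how often calcium transients
occur, how long they last, how large they are — and into the two derived
readouts that matter for studying dendritic plateau ("calcium spike")
pathology: spine-specific synaptic signals cleaned of back-propagating
action-potential (bAP) contamination, and spine-head size tracked across
imaging sessions. Prolonged dendritic transients (duration > 8 s) and very
large ones (peak ΔF/F~0~ > 400%) are the abnormality criteria of interest,
and the package follows events around them: does a spine's calcium response
shrink after a prolonged dendritic event, and does its head shrink
structurally over 1.5 h?

Because raw in vivo recordings for this kind of study are rarely deposited,
the package treats its synthetic-data generator as a first-class module:
every stage of the pipeline is exercised against simulated sessions with
exact ground truth.

## From raw fluorescence to events

**Background.** Raw traces are mean pixel intensities over each ROI
(`extract_traces()`). A vessel lumen carries no indicator, so its
fluorescence estimates the imaging background; the per-frame mean over all
`background_vessel` ROIs is subtracted from every trace
(`subtract_background()`). The background is per-frame by default; a
constant works identically since the subtraction is elementwise.

**Baseline.** For each ROI and each 60 s analysis window (one window per
trial, matching the acquisition block length), the baseline F~0~ is the mean
of the lowest 10% of raw F samples in the window, and
ΔF/F~0~ = (F − F~0~)/F~0~ (`compute_dff()`). A window with fewer than 10
samples cannot support a 10th-percentile statistic and is an error, as is
F~0~ ≤ 0, which indicates background over-subtraction.

**Threshold.** Detection uses a threshold of 3 × the baseline SD of ΔF/F~0~
per window. Two choices here were genuinely open and deserve their
rationale:

* *Which samples are "baseline"?* Using only the lowest-10% samples (the
  F~0~ set) systematically underestimates the noise SD. The default
  `two_pass` scheme instead takes samples below the window median for a
  provisional SD, detects provisional events at 3 × that value, and
  recomputes the SD over everything outside those events. The `f0_set` mode
  is retained for sensitivity analysis.
* *SD about what centre?* Because F~0~ is a low-percentile statistic, the
  baseline band of ΔF/F~0~ sits slightly **above** zero (about 1.7 noise
  SDs for 120-sample windows). The baseline SD is therefore computed as the
  root-mean-square deviation of baseline ΔF/F~0~ from zero — i.e. from the
  window's own F~0~ — so the 3 × SD level lands roughly 4.3 noise SDs above
  the baseline mean. An SD taken about the baseline-sample mean would place
  the threshold barely above the baseline band and fire continually on
  noise.

A zero-noise trace has baseline SD exactly 0; an absolute threshold floor
(ΔF/F~0~ = 0.05 by default) prevents detecting numerical dust in that
degenerate case.

**Events.** A transient is a maximal run of consecutive samples with
ΔF/F~0~ ≥ threshold (`detect_transients()`); runs are evaluated within
trials, so excursions split at trial boundaries. No gap-merging is applied
and a single sample is a valid event: the minimal definition keeps the
detector equivalent to a per-sample scan, which the test suite verifies
against an independently written oracle on a thousand random traces. Per
event the package reports duration (supra-threshold time), peak, and
integrated activity (sum of supra-threshold ΔF/F~0~ × Δt); per ROI and
behavioural state it reports frequency per minute and per-minute integrated
activity (`summarize_activity()`). The prolonged (> 8 s) and
large-amplitude (> 400%) flags use strict inequalities; both cutoffs are
arguments. Integrated activity sums the full ΔF/F~0~ of supra-threshold
samples rather than the threshold-subtracted excess — the plainer reading
of "accumulated activity above the threshold" — and the alternative is one
subtraction away for anyone who needs it.

Dendrite-level fractions (`dendrite_fraction_with()`) use as denominator
only dendrites that exhibited at least one detected transient, which is how
such percentages are normally reported; the correlation between event
duration and peak is Pearson by default with Spearman available
(`duration_amplitude_correlation()`).

## Spine-specific signals and the first-vs-third comparison

bAP-evoked calcium invades spines together with their parent dendrite. The
spine-specific trace removes the shared component by scaled subtraction,
ΔF/F~0~^specific^ = ΔF/F~0~^spine^ − 0.7 × ΔF/F~0~^dendrite^
(`spine_specific()`). The 0.7 coupling is the conventional empirical value;
it is a function argument, and the generator uses the same constant
(`bap_scale`) so that the subtraction is exactly invertible at zero noise —
a property the tests exploit. Thresholds for the specific trace are
recomputed with the same baseline rule, applied to the specific trace
itself.

Two active-spine rules coexist, because both appear in practice: a spine is
active at a dendritic event if (a) its spine-specific trace crosses its
3 × SD threshold inside the event window, or (b) the spine-head /
adjacent-shaft intensity ratio of the functional channel is at least 1.0 —
the midpoint between the published mean ratios of active (1.56) and
inactive (0.46) spines (`classify_active()`).

`first_third_comparison()` implements the depotentiation probe: in every
(dendrite, trial) with ≥ 3 detected dendritic transients, each child
spine's peak ΔF/F~0~ inside the 1st and the 3rd event window is paired,
stratified by whether the 2nd ("middle") transient exceeded 8 s. The spine
peak is measured on the spine-specific trace by default (`measure = "raw"`
is available), and the window is the detected [onset, offset] of the
dendritic event — the natural choice where no explicit window is specified.
When more than three transients occur, all sliding triplets are emitted but
flagged, and only the first is marked `primary`; inference should use
primary triplets, which are independent across trials.

## Spine-head morphometry

Spine-head size is scored on the structural (tdTomato-like) channel as
(Mean OD~spine~ − Mean OD~background~)/(Mean OD~dendrite~ − Mean
OD~background~), where Mean OD is mean pixel brightness over the oval
spine-head ROI, a shaft sample adjacent to the spine, and a nearby
background patch (`measure_spine_size()`). The conventional published form
of this formula multiplies every term by the spine area; the area cancels
algebraically, so the reduced form is computed, and the literal
area-carrying form (`spine_size_ratio_full()`) is kept and tested for exact
agreement. The ratio is invariant under per-image affine intensity changes,
which is what makes it comparable across sessions with different laser
power or detector gain.

Size change between sessions is the ratio of ratios
(`size_change()`), grouped by activity call and by the parent dendrite's
transient-duration class. Turnover (`turnover()`) classifies spines as
stable, eliminated or formed from presence calls; a spine is present when
its size ratio reaches 0.2 (an essentially invisible head scores near 0, a
shaft-bright one near 1; the cutoff is an argument since no published
criterion exists). All three rates are normalized to the session-0 count —
the convention matters only when turnover is nonzero.

## Statistical routing

`route_and_test()` mirrors the routing convention of the imaging
literature: screen each sample for normality with a Kolmogorov–Smirnov
test; if both pass (p > 0.05), a two-tailed Student's t test (paired or
unpaired), otherwise Mann-Whitney (unpaired) or Wilcoxon signed-rank
(paired), always reporting mean ± s.e.m. Since the plain KS test against a
normal with parameters estimated from the same data is anticonservative,
the default screen is the Lilliefors-corrected version
(`nortest::lillie.test`); `ks_mode = "plain"` reproduces SPSS-style
behaviour. No multiple-testing correction is applied by default, matching
common practice for these designs. The routed procedure's type-I error is
Monte-Carlo calibrated in the test suite (2,000 null replicates at
n = 30/group under normal and lognormal nulls, acceptance band
0.035–0.065). Zero-variance samples route nonparametric with a warning;
identical paired samples short-circuit to p = 1.

`figure_tables()` packages events, summaries, paired deltas and size
changes into fixed-schema tables with a manifest (package version, config
hash, seed) and `write_report()` writes them as CSVs plus JSON.

## What the generator emulates — and what it does not

`generate_trace_set()` renders raw fluorescence as
F(t) = background + F~rest~ (1 + A(t)) + noise at 2 Hz over 60 s trials
(five running, one resting by default). A(t) sums plateau waveforms: a step
to the event amplitude (the rise occupies the preceding inter-frame
interval), a flat top for the drawn duration, then an exponential decay.
Design choices worth knowing:

* **Durations** come from a two-component lognormal mixture: brief events
  (median 2 s) and plateau events (median 12 s) with mixture weight
  `p_long`. The heavy upper tail of the plateau component is what produces
  prolonged (> 8 s) events.
* **Amplitudes** are linearly coupled to duration
  (amplitude = a + b·duration + ε, clipped), reproducing the observed
  tendency of longer dendritic transients to be larger. Fractions, not
  per-event means, are the calibration targets (below), so the intercept
  absorbs most of the calibration.
* **Decay tau defaults to 0.2 s**, deliberately short relative to the
  0.5 s frame interval, so that an event's supra-threshold duration
  coincides with its plateau duration at the default frame rate (at most
  one extra decay sample). A slow indicator tail would smear every
  detected duration upward by several samples and make duration ground
  truth ambiguous. The decay is truncated below 0.1% of the amplitude, and
  event schedules enforce a clearance covering the rendered decay plus
  `min_gap_s`, so events never interact.
* **Spines** are composed in fractional space —
  A~spine~ = 0.7 × A~dendrite~ + A~synaptic~ — then mapped back to raw F on
  the spine's own baseline, making scaled subtraction exactly invertible at
  zero noise. Spine event amplitudes are a spine-level lognormal base times
  a mean-one event-level jitter, so paired first/third comparisons have
  realistic within-spine correlation and no drift under the null.
  `depot_attenuation` multiplies post-plateau spine amplitudes by
  1 − attenuation, injecting a depotentiation effect of known size.
* **Noise** is additive Gaussian on raw F (default SD 2% of F~rest~); a
  multiplicative shot-noise-like mode exists. Seeds are explicit
  everywhere and the generator restores the caller's RNG state.
* **Regime presets.** `regime_config("AD")` and `regime_config("WT")`
  calibrate `p_long` and the amplitude intercept analytically so that, over
  a 5-minute running observation, the expected percentage of event-bearing
  dendrites with ≥ 1 prolonged transient is 47% vs 18%, and with ≥ 1
  large-amplitude transient 37.2% vs 25.0% — the study conditions the
  pipeline is meant to resolve. With events Poisson (mean m over the
  observation) and each event qualifying independently with probability q,
  that fraction is (1 − e^−mq^)/(1 − e^−m^)
  (`expected_dendrite_fraction()`). The amplitude calibration additionally
  converts the 400% cutoff on *measured* peaks to its equivalent on true
  amplitudes, correcting for the known upward bias of peaks measured
  against a percentile baseline under noise.

The generator does **not** model indicator binding kinetics, optics or the
point-spread function, motion artifacts, bleaching, or neuropil
contamination beyond the single bAP coupling constant. Passing tests
therefore demonstrate that the *quantification* is correct and
well-calibrated on data with the assumed statistical structure — not that
the assumed structure captures every property of real recordings.

`generate_spine_image_pair()` renders the two-channel morphometry fixture:
a vertical shaft band and a circular spine head on a uniform background,
optional Gaussian blur (EBImage) and pixel noise, with ground-truth ratio
(S − B)/(D − B) and measurement masks eroded ~3 px inside their regions so
that blur around 1 px does not bleed neighbouring intensities into the
measurement.

## Problem sizes and numerical conventions

The validation suite runs entirely on synthetic data at desk scale: 1,000
traces for the detector-oracle equivalence, ~270 zero-noise events for
exact recovery (peaks to 1 × 10^−9^, durations to one sample), 500
dendrites for the prolonged-fraction recovery (agreement within 3 binomial
SEs of the analytic 0.47), 200 replicate sessions of 50 spines for the
injected depotentiation (20% attenuation) and shrink (15%) effects at
power ≥ 0.8, 2,000 Monte-Carlo replicates per null for routing
calibration, and 10,000 random inputs for the area-cancellation identity.
These sizes were chosen so the whole suite completes in minutes while
leaving each check statistically sharp.

Conventions: frames are 0-based and event intervals inclusive; times are
seconds, frequencies per minute; ΔF/F~0~ is dimensionless (1.0 = 100%);
pixel coordinates are 0-based with `x` = column, `y` = row, and a pixel
belongs to an ROI iff its centre does. Detected event tables are sorted by
ROI, trial and onset.

## Known limitations

* The 0.7 bAP coupling is assumed constant across spines; the pipeline
  exposes it but cannot estimate it from data.
* Events separated by less than one frame merge; at 2 Hz this limits
  resolvable event rates well below the generator's enforced gap.
* The per-event duration of a real slow indicator would include the decay
  tail; users simulating slower indicators should increase
  `tau_decay_s` knowingly and treat duration recovery as approximate.
* ROI geometry is taken as given (no segmentation, no motion correction),
  and saturated frames are flagged, not repaired.

## A worked example

```{r example, eval = FALSE}
cfg <- regime_config("AD", seed = 1)
g <- generate_trace_set(cfg, n_dendrites = 100, n_spines_per_dendrite = 4)
d <- compute_dff(subtract_background(g$traces))
events <- detect_transients(d)
running <- events[events$trial <= 5, ]
dendrite_fraction_with(running[grepl("^dend", running$roi_id) &
                               !grepl("_sp", running$roi_id), ], "prolonged")
summarize_activity(events, d)
```
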
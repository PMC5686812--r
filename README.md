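# dendrocalc

Quantification of somatic, dendritic and spine calcium transients from
two-photon fluorescence imaging of cortical pyramidal neurons — the post-hoc
analysis stage between "image stacks plus ROI outlines" and "statistics per
figure panel". The package targets studies of dendritic plateau events
(NMDAR-dependent calcium spikes): abnormally prolonged (> 8 s) or very large
(peak ΔF/F₀ > 400%) dendritic transients, their effect on spine calcium
(depotentiation) and on spine-head structure.

It is aimed at imaging labs and methods developers who need a tested,
scriptable reference implementation of this quantification, including a
synthetic-data generator with exact ground truth so that every stage can be
validated without microscope data.

## The quantification in brief

With F the mean pixel intensity over an ROI (vessel background subtracted):

* **Baseline:** F₀ = mean of the lowest 10% of F samples per 60 s window;
  ΔF/F₀ = (F − F₀)/F₀.
* **Detection:** a calcium transient is a maximal run of samples with
  ΔF/F₀ ≥ 3 × SD of baseline ΔF/F₀ (RMS about zero, two-pass baseline
  selection). Per event: duration, peak, integrated activity
  (Σ ΔF/F₀ · Δt); per ROI: frequency/min, totals, prolonged (> 8 s) and
  large-amplitude (> 400%) flags.
* **Spine isolation:** ΔF/F₀^specific = ΔF/F₀^spine − 0.7 × ΔF/F₀^dendrite
  removes back-propagating action-potential contamination; active spines
  cross 3 SD on the specific trace (or a head/shaft intensity ratio ≥ 1.0).
* **Depotentiation probe:** spine peaks paired between the 1st and 3rd
  dendritic transients of a trial, stratified by whether the 2nd exceeded
  8 s.
* **Morphometry:** spine size = (OD_spine − OD_bg)/(OD_dendrite − OD_bg) on
  the structural channel (the published area-carrying form cancels to this);
  size change = ratio of ratios across sessions; turnover from presence
  calls.
* **Statistics:** Kolmogorov–Smirnov normality screen (Lilliefors-corrected
  by default) routing to Student's t, Mann-Whitney or Wilcoxon signed-rank,
  mean ± s.e.m. always reported.

## A worked example

```r
library(dendrocalc)

cfg <- regime_config("AD", seed = 1)        # amyloid-model-like regime
g   <- generate_trace_set(cfg, n_dendrites = 500)
d   <- compute_dff(subtract_background(g$traces))
ev  <- detect_transients(d)
run <- ev[ev$trial <= 5, ]                  # the five running trials

100 * dendrite_fraction_with(run, "prolonged")
#> [1] 47.42268
100 * dendrite_fraction_with(run, "large_amplitude")
#> [1] 37.73196
duration_amplitude_correlation(run)$r
#> [1] 0.6045304
```

The first two numbers are the percentage of event-bearing dendrites with at
least one prolonged (> 8 s) and one large-amplitude (> 400%) transient over
the 5-minute running observation. The `"AD"` preset calibrates the
generator analytically so these percentages are expected at 47 and 37.2
(the `"WT"` preset: 18 and 25.0); the values above are what the full
detection pipeline recovers from one 500-dendrite simulation. The
correlation confirms the duration–amplitude coupling the generator injects.

The depotentiation readout:

```r
s   <- simulate_depotentiation_session(n_spines = 50, attenuation = 0.2,
                                       middle_duration_s = 10, seed = 1)
d   <- compute_dff(subtract_background(s$traces))
dev <- detect_transients(d); dev <- dev[dev$roi_id == s$dendrite_id, ]
ft  <- first_third_comparison(dev, d)
route_and_test(ft$peak_post, ft$peak_pre, paired = TRUE,
               metric = "spine peak")
#> spine peak: a vs b (n = 50, 50)
#>   a = 0.9181 +/- 0.0465, b = 1.146 +/- 0.0544
#>   normality p = 0.00582, 0.147 -> Wilcoxon signed-rank: statistic = 49, p = 1.378e-08 *
mean(ft$peak_post / ft$peak_pre)
#> [1] 0.8073221
```

Spine peaks after the prolonged middle transient are ~19% lower than
before it — recovering the 20% attenuation injected by the simulator.

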
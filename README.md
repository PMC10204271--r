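# dyntract

Alpha waves — the 8–12 Hz posterior dominant rhythm — augment with eye
closure and attenuate with eye opening; high-gamma activity (70–110 Hz)
indexes local cortical activation and reacts to the same movements.
`dyntract` is an R package for quantifying these eye-movement-related
amplitude dynamics in intracranial EEG and for turning sustained region-pair
co-modulations into time-resolved, streamline-gated functional-connectivity
edge tables ("dynamic tractography"). It is aimed at electrophysiologists
working with subdural recordings plus electro-oculography, and at anyone who
wants a fully testable, offline reimplementation of this analysis style.

## What it computes

1. **EOG event detection** — eye-closure/opening events as EOG deflections
   greater than 50 µV (after a 1.0 s time-constant high-pass), with the 2 s
   opposite-kind exclusion rule.
2. **Band amplitude by complex demodulation** — multiplication with a
   complex exponential followed by a Gaussian FIR low-pass (a Gabor
   transform). The alpha kernel's ±39.4 ms time-domain half-power width
   implies a ±2.8 Hz frequency half-power width through Gaussian duality
   (f_h = ln 2 / (2π t_h)).
3. **Percent-change maps** — amplitude per 25 ms (alpha) or 5 ms (high
   gamma) bin, averaged across events and normalised to the baseline
   200–600 ms before movement onset; 89 (alpha) or 441 (gamma) analysis
   bins span −200..+2000 ms around each mark.
4. **ROI statistics** — studentized-bootstrap means and 99.99% confidence
   bands across the clean electrode sites of each (hemisphere, ROI)
   (≥4 sites), with significance requiring ≥8 consecutive bins beyond zero,
   onset latencies, and distance-from-calcarine shell profiles on the
   flattened surface.
5. **Coupling** — Pearson r between alpha and high-gamma percent change
   over the 89-epoch grid.
6. **Dynamic connectivity** — co-modulation epochs (same polarity, both
   ROIs, ≥8 consecutive bins), the analytic chance probability
   (R/2)(R−1)(T−L+1) χ^L χ^L, legitimacy filtering of streamlines
   (QA ≥ 0.05, turning angle ≤ 70°, length 10–250 mm, anatomical masks),
   and strengthened/weakened edges for pairs with at least one legitimate
   streamline.

A synthetic-data module generates recordings, electrode tables and
streamline sets with known ground truth so the entire pipeline runs and is
validated without any clinical data.

## Worked example

```r
library(dyntract)

cfg <- pipelineConfig(
  sim = simConfig(nEventsPerKind = 16),
  bands = "alpha", marks = "closure_onset",
  level = 0.9999, nResamples = 2000, seed = 3,
  outDir = "atlas_out")
bundle <- runPipeline(cfg)

bundle$events
#> EyeEventSet: 16 closure, 16 opening events
#>   span 3.0-88.5 s; median closure duration 181 ms

subset(onsetTable(bundle$roiSeries[["alpha.closure_onset"]]),
       roi == "lateral_occipital")
#>                 roi hemisphere  band          mark onset_aug_ms onset_att_ms peak_pct
#> 3 lateral_occipital          L alpha closure_onset          125           NA 51.95088
#> 8 lateral_occipital          R alpha closure_onset          200           NA 50.93691

head(edgeTable(bundle$edges[["alpha.closure_onset"]]), 3)
#>                 roi_a               roi_b  band     polarity t_start_ms t_end_ms n_streamlines
#> 1 L lateral_occipital     L pericalcarine alpha strengthened        150      375             1
#> 2 L lateral_occipital R lateral_occipital alpha strengthened        200      375             1
#> 3     L pericalcarine R lateral_occipital alpha strengthened        200      425             1
```

The generator injects a +50% alpha augmentation in the lateral occipital
region starting 50 ms after closure onset, with a weaker +30% in the
pericalcarine region; the pipeline reports each ROI's significance onset
latency (the first bin of the first ≥8-bin run beyond the 99.99% band —
later than the injected onset at this small 4-site, 16-event scale), the
peak percent change (+52.0 and +50.9% versus +50 injected), and, because
legitimate streamlines connect the co-augmenting occipital regions,
strengthened alpha edges over the co-modulation epochs. `bundle$chance`
reports the observed significant-bin fraction χ per band/mark (here 11.6%
augmented) and the corresponding analytic Type I error (≈ 3.8 × 10⁻¹²).
With a fixed seed the run is bit-for-bit reproducible.

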
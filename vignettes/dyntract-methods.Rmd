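---
title: "Eye-movement-related iEEG amplitude dynamics and streamline-gated connectivity: methods"
author: "dyntract"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{dyntract methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Scope and model

`dyntract` analyses how the amplitudes of two intracranial-EEG bands react to
spontaneous eye closure and opening, and converts sustained region-pair
co-modulations into time-resolved connectivity edges gated by plausible
white-matter streamlines:

* **alpha** (8–12 Hz), the posterior dominant rhythm that augments with eye
  closure and attenuates with eye opening;
* **high gamma** (70–110 Hz), a summary measure of local cortical activation
  (augmentation) and deactivation (attenuation).

The pipeline operates on amplitude only (the square root of power). Phase,
coherence and travelling-wave measures are deliberately out of scope: the
method is designed so that signals sampled from different patients can be
pooled per anatomical region.

## Band amplitude by complex demodulation

Amplitude at a centre frequency $f_0$ is estimated by complex demodulation:
the signal is multiplied by $e^{-i 2\pi f_0 t}$ and low-passed with a
Gaussian FIR kernel, which makes the estimator equivalent to a Gabor
transform. The kernel is parameterised by its *time-domain half-power
half-width* $t_h$ (the time at which the squared kernel envelope falls to
one half): $\sigma = t_h/\sqrt{\ln 2}$, truncated at $\pm 4\sigma$ and
normalised to unit DC gain. Gaussian time–frequency duality then fixes the
frequency half-power half-width at

$$f_h = \frac{\ln 2}{2 \pi t_h},$$

so the alpha setting $t_h = 39.4$ ms gives $f_h = 2.8$ Hz. For the
high-gamma setting $t_h = 7.9$ ms the duality gives $f_h = 13.96$ Hz; the
conventional rounded figure of 14.2 Hz violates the duality product by
about 2%, so the time-domain value is treated as primary and the frequency
resolution is always *measured* from the designed kernel
(`measureFreqHalfPower()`), never assumed.

Amplitude is scaled so that a pure sinusoid of peak amplitude $A$ at $f_0$
returns $A$ in steady state. The percent-change normalisation makes this
convention immaterial downstream, but it is pinned by tests for
reproducibility. Band amplitude is the mean across the band's bin-centre
frequencies: 9 and 11 Hz for alpha (two 2-Hz bins spanning 8–12 Hz) and
75, 85, 95, 105 Hz for high gamma (10-Hz bins spanning 70–110 Hz); the bin
widths are standard, the centres are the natural symmetric choice.

## Event-locked percent change

Epochs span $-1000..+2000$ ms around four behavioural marks (closure
onset/offset, opening onset/offset) with bin centres every 25 ms (alpha) or
5 ms (high gamma); windows are inclusive of both endpoints so the analysis
window $-200..+2000$ ms contains exactly 89 and 441 bins. Each bin value is
the amplitude averaged over the bin, averaged across events
(*trial-average-then-normalise*; a per-trial variant would weight noisy
trials differently and is not what the ROI-level averages represent), then
expressed as

$$100 \cdot \frac{\bar a(t) - \bar a_{\mathrm{base}}}{\bar a_{\mathrm{base}}},$$

where the baseline is the window 200–600 ms *before the movement onset* —
also when epochs are aligned to an offset mark, so that pre-movement
activity anchors every map. For onset-aligned maps the baseline mean of the
map is exactly zero by construction. Epochs are cut from a signal
demodulated in full, so there are no per-epoch filter transients; the
samples within one kernel half-length of the recording edges are flagged
unreliable instead.

## EOG event detection

Clinically, eye-movement events are marked from video plus EOG. At desk
scale only the EOG rule is quantitative, so detection is automated: the
trace is high-passed with a first-order RC filter matching the amplifier
time constant (1.0 s), and an event is a deflection exceeding 50 µV, onset
at the first crossing. Two choices are ours because the marking rule does
not define them: the *offset* uses a half-threshold (25 µV) return level as
hysteresis against chatter, and the closure polarity is configurable
(positive by default) since montage polarity is not standardised. Closure
events with an opening onset within 2 s (and vice versa) are removed; the
minimum of 16 events per kind is a cohort-inclusion rule, so falling short
of it flags the result rather than aborting.

## ROI statistics

Sites flagged as seizure-onset zone, interictal-spike generating, lesional
or artefactual never enter statistics; a (hemisphere, ROI) needs at least 4
clean sites. Hemispheres are analysed separately throughout.

Per ROI and time bin, the mean percent change across sites gets a
*studentized bootstrap* (bootstrap-t) interval: sites are resampled with
replacement, the pivot $t^\* = (\bar x^\* - \bar x)/\widehat{se}^\*$ uses
the analytic standard error of each resample (a nested bootstrap would be
prohibitively slow and is not needed for a mean), and the interval is
$\bar x - q_{t^\*} \cdot \widehat{se}$. One resample set serves all bins of
a ROI so the bands are coherent across time. Resamples drawing a single
site give $se^\* = 0$ and are assigned $t^\* = 0$; an all-identical input
yields the degenerate interval lower = upper = mean by convention.

Significance uses the run-length rule: augmentation where the lower 99.99%
bound exceeds 0 for at least 8 consecutive bins (two oscillatory cycles),
attenuation symmetrically; shorter runs are discarded entirely. Because
percent change is baseline-anchored, "beyond the CI" reduces to the CI
excluding zero. The 99.99% level is equivalent to a Bonferroni correction
for 500 comparisons at a family-wise 0.05.

A caveat the test suite makes explicit: with very few sites the extreme
tail of the bootstrap-t pivot is dominated by near-degenerate resamples
(e.g. seven copies of one site), so 99.99% intervals computed from 8 or
fewer sites are erratic in width. The recovery checks therefore use 16-site
ROIs — comfortably inside the per-ROI site counts the method is meant for
(tens of sites per region) — and 20 000 resamples, enough to resolve the
5×10⁻⁵ tail. The package default of 10 000 resamples is a compromise for
interactive use; raise it for final analyses.

Distance-shell profiles express the same statistics as a function of
distance from the calcarine sulcus on a flattened cortical map: electrode
values are interpolated to mesh points within 10 mm, mesh points are
grouped into ventral/dorsal 10-mm shells (the calcarine line is
`flat_y_mm = 0`, ventral negative; distance is Euclidean in flat-map mm —
3-D geodesics are out of scope), and uncovered shells are reported missing
rather than zero.

## Coupling and connectivity

Alpha/high-gamma coupling is the Pearson correlation across the 89 25-ms
epochs of the analysis window, with the 5-ms high-gamma series aggregated
by averaging the bins whose centres fall within ±12.5 ms of each epoch
centre. p-values use the exact t transform on $n-2$ degrees of freedom,
matching how such correlations are conventionally reported at $n = 89$.

Co-modulation between two ROIs requires the *same* polarity of significance
in both, at every bin of a window of at least 8 bins (200 ms alpha, 40 ms
high gamma); overlapping windows merge into maximal epochs. The analytic
chance probability of seeing any such epoch anywhere, when each of $R$ ROIs
is significant in a fraction $\chi$ of $T$ bins independently, is

$$\frac{R}{2}(R-1)\,(T-L+1)\,\chi^L\,\chi^L,$$

i.e. pair count × window starts × the joint probability that both ROIs are
significant at all $L$ bins. The $\chi^L$ exponents reproduce the six
published reference values for this model to their printed precision,
whereas reading the factor as a plain $\chi^2$ yields probabilities above 1;
the exponent form is therefore pinned by the acceptance tests. Per-bin
independence is assumed exactly as in the source model — no autocorrelation
correction.

A streamline is *legitimate* when its minimum per-vertex quantitative
anisotropy is ≥ 0.05, every vertex-to-vertex turning angle is ≤ 70°, its
arc length is 10–250 mm, and it stays inside the parenchyma but outside the
brainstem/basal-ganglia/thalamus masks. Turning angles are measured between
successive polyline segments as given ("step size 0" refers to the original
tracking; streamlines are never resampled). Desk-scale masks are
axis-aligned boxes; volumetric masks reduce to the same vertex-in-region
test. Streamline endpoints are captured by the nearest ROI centroid within
3 mm (an electrode-scale radius; the original workflow seeds ROIs inside
the tracking software, which has no desk-scale equivalent). An edge is
emitted per co-modulation epoch whose pair has at least one legitimate
streamline: co-augmentation → strengthened, co-attenuation → weakened;
opposite-polarity overlap produces no edge.

# The synthetic-data generator

The generator emulates the study conditions so every stage runs offline:

* 1000 Hz sampling; alternating closure/opening events with
  offset-to-onset gaps drawn from 2.2–3.0 s, guaranteeing the 2-s
  opposite-kind separation rule;
* event durations log-normal with median 176 ms (closure) and 175 ms
  (opening), σ matched to the published inter-quartile ranges (143–217 and
  128–215 ms). The distribution family is a stand-in: the sources report
  only median and IQR, and a log-normal is the simplest strictly positive,
  right-skewed match;
* per channel: 1/f-amplitude background noise (10 µV SD) + a 10 Hz alpha
  component (40 µV baseline amplitude, one random phase per channel) + a
  70–110 Hz band-limited-noise high-gamma component (5 µV). A strong
  posterior rhythm over a weaker broadband background is what occipital
  subdural recordings in wakeful rest look like, and these ratios satisfy
  the generator's null contract (empty profiles leave every channel's mean
  percent change within ±3 points over the analysis window). Phase
  structure is irrelevant to an amplitude-only analysis, which is why the
  alpha component is a plain sinusoid and no per-event phase reset is
  modelled;
* modulations are raised-cosine envelope bumps: a profile starts at its
  nominal onset, rises over 100 ms (avoiding spectral splatter that sharp
  edges would leak into the band estimates), holds, and returns to zero at
  onset + duration. Ground truth records the injected percent-change curve,
  exactly zero over the baseline window;
* the EOG channel carries sub-threshold noise (5 µV SD) plus a monophasic
  100 µV deflection spanning each event, positive for closure; its 10-ms
  linear rise puts the 50 µV crossing 5 ms after the true onset, so
  detected onsets match ground truth to within 10 ms;
* streamline fixtures include one valid gently-curved polyline per ROI pair
  plus deliberate violators of each legitimacy criterion (too short, too
  long, an 80° bend, a low-QA vertex, a vertex inside the exclusion box),
  with labels in the ground truth.

What the generator does *not* emulate: epileptiform activity, sleep states,
volume conduction, inter-patient variability, realistic head geometry or
thalamic recordings. Passing the recovery tests therefore shows the
pipeline's statistics behave correctly under the stated signal model, not
that clinical recordings will be as clean.

# Numerical choices and test problem sizes

* One master seed fans out to per-stage derived seeds, so each stage is
  individually reproducible and a fixed seed gives bit-identical output.
* FFT convolution (zero-padded to a power of two) implements the Gaussian
  low-pass exactly; bin values use cumulative sums, so epoching is O(n).
* Quantiles use R's default type-7 interpolation; ties in `which.max` (peak
  location) resolve to the earliest bin.
* The recovery suite uses 20 seeded replicates of 2 ROIs × 16 sites with 30
  events per kind; the null-control suite 20 replicates at 20 events; the
  coupling suite 20 replicates of one 6-site ROI. These sizes keep the full
  suite to a few minutes while leaving each check adequately powered.
* Serialisation is plain text (TSV/CSV/JSON) with units in the headers;
  times are milliseconds relative to the event mark, voltages microvolts,
  distances millimetres.

# Known limitations

* Directionality of information flow is not estimated, by design.
* The chance model ignores temporal autocorrelation of significance masks,
  exactly as formulated.
* Bootstrap-t intervals at extreme levels require tens of sites and enough
  resamples to populate the tail; the package warns through documented
  guidance rather than refusing.
* Real-data ingestion expects plain-text electrode tables and
  vertex-table streamlines; binary clinical formats (EDF, HDF5, TRK/TCK)
  should be converted upstream.
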
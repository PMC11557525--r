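---
title: "Methods: feature extraction and analysis for HD-MEA cardiomyocyte recordings"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: feature extraction and analysis for HD-MEA cardiomyocyte recordings}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hdmea)
```

## Scope

High-density microelectrode arrays (HD-MEAs) record the electrical activity
of cardiomyocyte monolayers on thousands of closely spaced electrodes. Two
signal classes arise: extracellular *field potentials* (FPs), whose sharp
biphasic deflection is the R spike and whose late, small deflection is the
T wave; and *intracellular-like* signals, membrane-potential-shaped action
potential (AP) waveforms obtained through transiently porated membranes on
planar electrodes. This package extracts the standard feature set of both
classes — R-spike amplitude and width, field-potential duration (FPD),
conduction speed, time-domain heart-rate-variability (HRV) metrics,
AP amplitude, depolarization time, APD50 and APD90 — processes many
recordings in parallel into an append-only SQL feature store, and provides
the downstream analysis used to compare cell lines: feature triage,
cross-validated classification, a majority baseline, permutation importance,
and Mann–Whitney group comparison.

Everything is exercisable without real recordings through synthetic
generators with analytic ground truth; the generators are first-class,
tested code, not test scaffolding.

## Extracellular pipeline

### Spike detection

The R-spike detector thresholds the absolute deviation from the trace
median at `threshold_sd` (default 6) times a robust noise estimate,
`mad/0.6745`. Suprathreshold samples closer than the refractory spacing
(default 200 ms, far below any physiological beat rate on these
preparations) merge into one event; the event's maximum is the R positive
peak and the minimum within the following 50 ms is the trough. When the
robust noise estimate is zero — noiseless synthetic traces, or traces that
are baseline almost everywhere — the threshold falls back to 30% of the
maximum absolute deflection, so ideal fixtures detect cleanly while flat
traces yield an empty spike train rather than an error. A spike is flagged
`clipped` when five or more consecutive samples sit at the trace extreme:
saturation at the acquisition rails produces exactly such plateaus, and
clipped R amplitudes should be treated with suspicion downstream.

R amplitude is peak minus trough (µV); R width is trough time minus peak
time (ms). Both are averaged over spikes within an electrode, then over
electrodes — a recording contributes one row to the feature store, while the
per-electrode table is kept alongside for distribution-level displays.

### T wave and FPD

The textbook definition of FPD — time from the R spike to the T-wave
peak — leaves the R fiducial and the search rule open; here the fiducial is
the R positive peak and the T peak is searched in
`[t_R + 80 ms, t_R + min(700 ms, 0.9 · median RR)]`. The T wave on these
preparations may point either way and is small, so the candidate is the
extremum of largest absolute baseline deviation after a 5 ms moving
average, and the result is declared absent when no candidate strictly
exceeds a minimum amplitude (default three times the robust noise SD).
The blanking interval keeps the detector off the R-spike recovery; the RR
cap keeps it inside the beat.

### Beat grouping and synchrony

All R times are pooled and sorted; a gap larger than `sync_window`
(default 50 ms) starts a new cluster. Because propagation across even a
millimetre-scale array at physiological conduction speeds spans only a few
milliseconds, a window of tens of milliseconds cleanly separates beats at
normal rates. Clusters containing at least half of the active electrodes
are kept as array-wide beats; an electrode counts as synchronous when it
participates in at least 90% of kept beats, and
`active_area_in_percent = 100 · n_electrodes_sync / n_electrodes`. All
three fractions are configuration-exposed, since the underlying counts are
defined but the grouping rule is a design choice.

### Conduction speed

Beat latencies are fitted to a cone-shaped surface

$$T(x, y) = \sqrt{a\,(x - x')^2 + b\,(y - y')^2} + c,$$

where $(x', y')$ is the wave origin, $a$ and $b$ are squared slowness
coefficients, and $c$ absorbs the latency reference (so re-referencing
latencies by a constant provably does not change speeds). For a radial wave
at speed $v$, $a = b = 1/v^2$. The true-cone (square-root) form is used
because latency grows linearly with distance in a medium with constant
conduction speed; a paraboloid variant is available behind
`surface = "paraboloid"` for users who prefer a smooth surface at the
apex. Fitting is bounded Levenberg–Marquardt ($a, b \ge 0$) with two
starting points — the earliest-latency electrode and the centroid — and the
better fit by residual wins. With only four electrodes (the minimum) the
five-parameter anisotropic surface is underdetermined, so the fit falls
back to the isotropic form $a = b$. A latency spread below numerical noise
is reported as a degenerate flat fit ($a = b = 0$) rather than an error.

The gradient of the fitted surface is the slowness vector, so the local
speed at each electrode is $1/\lVert\nabla T\rVert$. The cone gradient is
singular at the apex; electrodes within one electrode pitch of the apex are
excluded. Local speeds are averaged within each beat, then across beats.
Units are µm/ms, numerically equal to mm/s.

On noiseless synthetic data the fit recovers origin and speed essentially
to solver tolerance (residual below 1e-9 ms). One caveat is quantization:
extraction-level latencies are R-peak times on the sample grid, so on very
small arrays (where the total latency span is a few samples) the
recording-level conduction speed carries a quantization bias even without
noise; the conduction module itself is unbiased, as the direct
latency-fitting tests show. Real HD-MEA workflows fit hundreds of
electrodes spanning many samples of latency, where this bias vanishes.

### HRV metrics

The 16 time-domain metrics follow their textual definitions exactly;
an independent brute-force evaluation (literal loops over the definitions)
agrees to 1e-9 relative on a thousand random series. Two conventions had to
be fixed:

* `median_nni` is implemented as stated — the median of the *absolute
  successive differences* — although the HRV literature usually means the
  median RR interval; `median_nni_mode = "median_of_intervals"` provides
  the conventional reading. The default follows the stated definition.
* `nni_50`/`nni_20` count successive differences *strictly* greater than
  50/20 ms, and `pnni_X` divides by the total number of RR intervals (not
  the number of differences), returning fractions in [0, 1]. `sdnn` and
  `std_hr` use the sample (n−1) denominator.

Heart rates are per-interval, `60000 / RR_i` beats/min.

## Intracellular-like pipeline

Three consecutively measured waveform windows are averaged pointwise into a
single waveform per electrode (fewer than three available: the single
best window is used and flagged). A waveform is admitted as
intracellular-like when its peak amplitude strictly exceeds 1 mV *and* its
full width at half amplitude strictly exceeds 50 ms; both thresholds are
arguments, and the strictness matters at the boundary — a 1 mV, 50 ms
waveform is rejected. Width at half amplitude was chosen over width at base
because the baseline on porated-membrane recordings is the less stable of
the two references.

The upstroke onset — the start of every timing feature — is not sharply
defined on planar-electrode APs, which show a gradual voltage rise before
the rapid upstroke. The convention here is the *last pre-peak upward
crossing of baseline + 10% amplitude*, which ignores that slow foot; the
fraction is an argument. On the piecewise-linear synthetic template
(upstroke of duration $d$, linear repolarization of duration $r$) this
convention gives closed forms used throughout the tests:

$$\mathrm{APD}_{50} = 0.9\,d + 0.5\,r, \qquad
  \mathrm{APD}_{90} = 0.9\,d + 0.9\,r, \qquad
  \mathrm{depol.~time} = 0.9\,d.$$

APD$_p$ ends at the first post-peak downward crossing of the level at which
$p\%$ of the amplitude has been lost, located with linear interpolation for
sub-sample precision; a waveform that never repolarizes to the level within
its window yields `NA` with a truncation flag. AP amplitude is max − min
over the window. Time features are invariant under voltage offset and
positive scaling by construction.

Under additive noise, a first-crossing rule meets the level early by
roughly $\sigma/\text{slope}$; with three-waveform averaging at 1% of
amplitude noise this is a ~2 ms effect on APD90 of the standard template
(noise SD 0.0115 mV against a repolarization slope of 0.0067 mV/ms), which
is what the noisy-recovery tests assert. Users needing tighter APDs at high
noise should average more waveforms or smooth before feature extraction.

## Synthetic generators

The generators emulate exactly what the extraction stages measure and
nothing else:

* **FP recordings** — radial propagation at constant speed from a known
  origin across a rectangular grid; a triangular biphasic R spike
  (peak +amp/2, trough −amp/2 a width later; equal flank slopes) and a
  Gaussian T bump peaking `fpd` after the R peak; optional Gaussian trace
  noise and per-spike latency jitter. Defaults are the package's standard
  study conditions: 8×8 grid at 17.5 µm pitch, 400 µm/ms, 10 beats at
  1000 ms, 1000 µV / 2 ms R spike, 300 ms FPD, 10 kHz sampling.
* **AP recordings** — the piecewise-linear template above (default 10 ms
  upstroke, 300 ms repolarization, 2 mV over a −70 mV baseline).
* **RR series** — i.i.d. normal intervals with nonpositive draws resampled,
  which preserves small-SD series exactly.
* **Feature tables** — two classes with informative features separated by a
  chosen number of SDs and class-independent noise features.

Ground truth is reported at two levels: nominal (programmed) values and
*sample-grid-realized* values read off the clean signal, so tests can
assert exact agreement where quantization is the only discrepancy. All
generators are pure functions of their specification, seed included.

What the generators deliberately do not model: ionic-channel dynamics,
T-wave morphology beyond a single bump, field decay with electrode-source
distance, movement artifacts, electrode drop-out, and arrhythmic dynamics.
Passing recovery tests therefore demonstrates correctness of the
*measurement* pipeline, not robustness to every pathology of real
recordings — thresholds were chosen to be robust (MAD-based noise,
strictly-positive checks), but real-data validation remains the user's
responsibility.

## Batch pipeline and feature store

Files are processed in batches equal to the worker count in forked,
shared-nothing processes; each worker returns its feature row by value, and
per-file failures become entries in a failure report while the run
continues. Results are sorted by file path, so the output is identical for
any worker count — a property the tests assert directly with planted
corrupt files.

The store is a single-file SQLite database with one table per signal class
(`extracellular_features`, `intracellular_features`). Rows are only ever
appended, each stamped with a UTC ISO-8601 `processed_at` at insertion;
reprocessing a file adds a row, and `latest_only` queries resolve to the
newest row per file (insertion order breaks timestamp ties). A schema
mismatch on insert names the offending columns instead of silently
widening the table.

## Feature analysis

* **Correlation triage** uses Spearman rank correlation
  (pairwise-complete, mid-ranked ties; entries with fewer than three
  complete pairs are absent). Pairs with $|\rho| > 0.8$ drop the *later*
  column — a deterministic stand-in for the interactive choice a human
  makes on a dashboard.
* **Multicollinearity** is the variance inflation factor,
  $\mathrm{VIF}_j = 1/(1 - R^2_j)$ from regressing feature $j$ on all
  others; features are dropped worst-first until all indices are ≤ 5, the
  conventional rule-of-thumb threshold. Perfect collinearity reports
  infinity with a flag rather than failing.
* **Similarity clustering** is average-linkage agglomeration on
  $1 - |\rho|$; the dendrogram is reported, and eliminating "similar"
  features is left to an explicit `manual_drops` argument — no automatic
  similarity threshold is imposed, because that judgement is genuinely
  visual.
* **Classification** evaluates a pluggable list of candidate models by
  stratified k-fold cross-validation (default 3-fold) on a stratified
  training split and refits the best on the full training set. The default
  grid covers logistic regression, a random forest, and an RBF-SVM with
  fixed modest hyperparameters; no ensembling is performed, model averaging
  being a known overfitting amplifier at these sample sizes. Automated
  model search engines can be plugged in through the same interface.
* **The majority baseline** predicts each evaluation fold with its training
  folds' most frequent label, aggregated over repeats × folds; it equals
  the majority class fraction up to fold-composition granularity and
  anchors any claimed classifier performance.
* **Permutation importance** shuffles one held-out feature column at a
  time and records the accuracy drop, `repeats` times per feature
  (default 30), against the held-out test accuracy. Samples are kept raw —
  means without the dot distribution hide exactly the outliers that signal
  correlated-feature effects.
* **Group comparison** is the two-sided Mann–Whitney U test: exact null
  distribution when $n_A n_B \le 400$ with no ties, normal approximation
  with tie and continuity correction otherwise, plus medians and IQRs as
  display statistics. The test suite checks the exact branch against a
  full enumeration oracle on all small layouts.

## Problem sizes and numerical choices

The test and acceptance fixtures use an 8×8 grid at 10 kHz for the standard
FP recording, 3×3 or 4×4 grids at 5 kHz for batch fixtures, 1000 random RR
series for the HRV equivalence sweep, 50 seeds for jittered conduction
recovery, and 200 rows for classification fixtures — sizes chosen so the
full suite exercises every numerical path in well under a minute per
module while keeping Monte-Carlo assertions stable. Level crossings use
linear interpolation; latency fits run to `ftol = ptol = 1e-15`; flat
surfaces and flat traces are explicit degenerate results, not errors; and
every stochastic component takes an explicit integer seed.

## Known limitations

The synthetic templates are idealized (see above); the beat grouper assumes
beat intervals well above the synchronization window and will merge beats
in sustained tachyarrhythmic regimes; FPD detection inherits the difficulty
that real T waves can sit below the noise floor, in which case the feature
is absent rather than guessed; conduction speeds from very small arrays are
quantization-limited; and vendor HDF5 dialects must be supplied as reader
plug-ins — the built-in layout is an open fixture format, not a
reconstruction of any proprietary one.
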
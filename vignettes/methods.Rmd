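---
title: "Models and methods behind spikedc"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind spikedc}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(spikedc)
```

This vignette documents the models, the tunable parameters, and the design
choices behind the package, in the spirit of a methods section: what each
stage assumes, why the defaults are what they are, and what the synthetic
benchmark does and does not establish about real recordings.

## What the synthetic generator emulates

The generator produces phase-tagged recording sets of one stimulus modality
(noxious thermal, noxious press, tactile, or proprioceptive), either as
trial-aligned spike tables (the fast path used throughout the tests) or as
rendered 30 kHz voltage with planted templates (`render_voltage()`).

**Evoked profiles.** Each unit fires an inhomogeneous-Poisson evoked response
per stimulus. The paradigm drives the shape: a thermal burst supported on
roughly 0.85–1.5 s after the laser trigger (a symmetric Beta(2, 2) hump around
the unit's burst centre, ~1.15 s), plus a weak uniform sustained tail over
1.5–4.5 s; a broad press burst (Gaussian, σ = 60 ms, centre ~140 ms) inside
0–500 ms; one or two tightly timed tactile spikes near the unit's latency
centre (within-trial jitter σ = 1 ms); and a bimodal proprioceptive burst with
modes 200 ms apart (rotation and counter-rotation of the joint) inside
0–400 ms. Expected evoked counts per stimulus default to 15 (thermal main
window), 4 (press), 1.5 (tactile), and 3 (proprioceptive), with a log-normal
unit-to-unit scale (σ = 0.3) so the population is heterogeneous. A single
Poisson process per unit is the simplest generative model that reproduces the
published peristimulus histogram shapes; a 1.5 ms dead time is enforced on
rendered trains so a clean unit can never trip the refractory contamination
rule on its own.

**Pain-model alterations.** Pain groups scale evoked counts by 1.3 (elevated
baseline responses) and recruit a late tactile latency mode: each tactile
unit's latency centre is drawn from a two-component mixture with modes at
8.31 ms and 16 ms. The mixture weight is solved from the reported group means
(weight = (mean − 8.31)/7.69, i.e. 0.33 for the neuropathic group's 10.85 ms
and 0.27 for the inflammatory group's 10.41 ms), which makes the unit-level
latency distribution unimodal in naïve sessions and dip-test-detectably
bimodal in pain sessions — the qualitative pattern the latency analysis is
meant to recover.

**DC conditioning.** During DC, every spike inside the analysed response
window is removed independently with probability `r`, so the expected
windowed count is exactly `(1 − r)` times its pre-DC value — the ground-truth
invariant the reduction estimator is benchmarked against. In-window
spontaneous spikes are indistinguishable from evoked ones there, so they are
thinned too; exempting them would break the `(1 − r)` relation by an amount
that grows with the spontaneous rate. Outside the window, spontaneous
activity is instead *elevated* by `dc_spontaneous_gain` (default 1.1,
matching the mild ~10% multi-unit increase the method reports). Polarity
carries no effect on evoked counts; it is metadata, as is sex. After DC
offset, the thinning probability decays as `r · 2^(−t/h)` with
modality-specific half-lives `h` (defaults: thermal 20 min, press 8 min,
tactile 2 min).

**Ground-truth reductions.** `dc_reduction_defaults()` carries one thinning
fraction per modality × group × amplitude × window cell, calibrated to the
lower bound of each reported percent-reduction range (e.g. 0.705 for thermal
units in pain models, 0.576 for tactile units in the neuropathic group,
0.305 for tactile units in the inflammatory group at 1000 µA only) and 0 in
cells where no significant change was reported. These are configuration, not
physiological truth: the benchmark asks whether the pipeline recovers
whatever value is planted.

**What passing tests do not show.** The generator is stationary within a
set, has Gaussian noise, no electrode drift, no overlapping-spike
decomposition problem beyond linear superposition, no DC-onset artifacts, and
its units are exactly refractory. Passing the recovery benchmarks therefore
demonstrates the *analysis logic* — windows, tests, models, bookkeeping — on
data satisfying its assumptions, not robustness to the full messiness of
in-vivo recordings.

## Preprocessing choices

The band-pass is a 4th-order Butterworth applied forward–backward
(zero-phase). `signal::filtfilt` starts from zero filter state, so the
implementation odd-reflects the signal by `3 · rate / low_hz` samples at both
ends before filtering and trims afterwards; without that padding a DC offset
rings through the start of the trace. The detector is the field-standard
negative threshold at 4.5 robust noise SDs per channel
(median(|v|)/0.6745), a 1 ms group lockout, and snippets from 0.6 ms before
to 1.0 ms after the aligned trough. Troughs are localised to sub-sample
precision by parabolic interpolation and the snippet is resampled at the
fractional offset: without this, ±1-sample alignment jitter masquerades as a
waveform difference and can dominate the clustering geometry. Channel groups
are chosen automatically by an evoked-energy score (post-trigger RMS minus
pre-trigger RMS summed over each triple of adjacent channels); the original
workflow did this by eye, so the score definition is ours and the selection
is flagged when no triple's score clears the noise floor.

## Sorting choices

Waveforms are concatenated across the three channels and projected on the
first 10 principal components (or fewer if 95% of variance is reached
earlier); k is chosen from 2–8 by maximum mean silhouette with 10 k-means
restarts under a fixed seed. A best silhouette below 0.3, or too few events
(under 10 per candidate cluster), falls back to a single cluster. The
refractory contamination rule is implemented exactly as stated and inclusive
on both sides: a cluster is flagged when the fraction of inter-spike
intervals ≤ 1 ms is ≥ 1% (with a 1e-9 relative slack so an interval of
exactly 1 ms stays inside the rule despite floating point). Flagged clusters
are isolated and split with k = 2 in the *template's* principal-component
space — re-fitting PCA on the isolated cluster is the other defensible
reading; reusing the basis is the minimal one and is configurable in
principle by re-running the fit. Each split increments the lineage's
reiteration count; a still-flagged cluster at count 4 is excluded. Transfer
to other recording sets assigns each event to the nearest non-excluded
centroid, with events beyond 3 × the template cluster's 95th-percentile
centroid distance left unassigned so that during-DC artifacts cannot silently
join a unit.

## Window derivation

Response windows come from pooled relative-frequency latency histograms
(bins tile the trial span with an edge at t = 0; 50 ms thermal, 10 ms press
and proprioceptive, 1 ms tactile). The baseline is the mean per-bin frequency
over the whole pre-stimulus span. The window runs from the first to the last
post-stimulus bin at ≥ 1.5 × baseline, and the edges are rounded *away from
the peak-frequency bin* to one significant figure. The rounding step is taken
from the magnitude of the raw window width (10^⌊log10(width)⌋): a tactile
crossing of 2–38 ms (width 36, step 10) rounds to 0–40 ms, and a thermal
crossing of 820–1480 ms (width 660, step 100) rounds to 800–1500 ms. Reading
the step from each edge's own magnitude instead cannot produce both of those
canonical results (2 would stay 2, and 1480 would jump to 2000), which is why
the width-based reading was adopted. Counting is half-open, `[start, end)`,
everywhere; the sustained thermal window multiplies its 1 s pre-window counts
by 3 to match its 3 s post window. The pipeline defaults to the fixed
canonical window table for comparability; derived mode recomputes the window
from the session's pooled pre-DC histogram, and needs several pre-DC sets for
the thermal paradigm (2 trials per set) before the baseline is stable enough
for the 1.5× rule.

## Evoked criterion and reduction estimation

The evoked test is a paired one-sided t-test on per-trial (post − pre)
differences at α = .05 — "significantly more" implies direction, and pairing
is the natural per-trial structure; an unpaired variant is available since
the original wording does not settle it. Zero-variance differences are
resolved by sign: constant positive → evoked (p = 0), otherwise not evoked.
Under a Poisson null the empirical false-positive rate sits at the nominal
5% (the t-test on count differences is well within its CLT regime at 50
trials).

Windowed counts are modelled on the raw count scale with a Gaussian LMM
(REML, Satterthwaite degrees of freedom; random intercepts for unit and,
when present, animal), not a GLMM — fidelity to the original analysis of
spike totals. Estimated marginal means average over non-focal factors;
pairwise contrasts use Tukey adjustment. The percent reduction is
`100 × (1 − EMM_during / EMM_pre)`, with a delta-method standard error, and
increases are reported as negative reductions rather than clamped. Singular
fits (common when the between-unit variance is genuinely near zero) are
flagged on the result, not hidden; they do not bias the EMM ratio.

## Recovery analysis

A unit counts as blocked when the evoked criterion fails in every during-DC
set; its recovery time is the `time_since_dc_end` of the first post-DC set
that passes, censored at a 45 min horizon. The default post-DC schedule
samples minutes 1–5 and then every 5 min to 45: under exponential block
decay, the tactile response (half-life 2 min, high-powered 50-trial test on a
tight 40 ms window) reappears within the first couple of minutes, so a
coarser grid could not separate it from the press response. The thermal
paradigm has only 2 stimuli per set, so its evoked test has a single degree
of freedom and low power — late apparent thermal recovery is partly a
property of the paradigm itself, which mirrors the real design. With the
default half-lives, median recovery orders tactile < press < thermal and the
tactile contrasts are significant at 30 units per modality under
Bonferroni-corrected rank tests.

## Hartigans' dip test

No installed package provides the dip statistic, so it is implemented from
scratch: the iterative greatest-convex-minorant / least-concave-majorant
algorithm over a shrinking modal interval, returning the maximum deviation of
the empirical CDF from the closest unimodal CDF. The implementation was
validated against analytic values (an equally spaced sample attains the
1/(2n) lower bound; two equal point masses attain 1/4; unequal masses give
min(p, q)/2) and against an independent brute-force oracle that minimises the
sup-distance by linear programming over all candidate mode placements
(including an atom at the mode); agreement is at machine precision on
hundreds of random samples, and a frozen set of those oracle values lives in
the test suite. The p value is calibrated by bootstrap against the uniform
distribution — Hartigan and Hartigan's asymptotically least favourable
unimodal null — as the fraction of `n_boot = 2000` uniform samples of the
same size whose dip meets or exceeds the observed one; `dip_null()` lets
repeated tests at one sample size share a null table.

## Numerical and degenerate-input conventions

Time is in seconds with 0-based samples; a trigger defines t = 0 of its
trial; trial-aligned times are in ms. Histogram and counting intervals are
half-open. Peak-latency ties break toward the earlier bin. Fewer than two
spikes define a contamination fraction of 0; fewer than two trials make the
evoked test an error rather than a guess; an empty spike pool cannot build a
histogram; a window that does not fit its trial segment is an error. Every
stochastic stage takes an explicit seed, and the pipeline derives per-stage
seeds deterministically from one global seed.

## Problem sizes used by the benchmarks

The test-suite benchmarks run at sizes chosen to make their statistical
assertions sharp but cheap to verify: 20 seeded sessions of 3–6 planted units
(30 s at 8 Hz, snr 8) for sorter recovery; 5000 simulated null units for the
type-I calibration; 40–60 units per condition for the reduction recovery
(thermal conditions use 10 repeated 2-trial sets per phase, the others two
50-trial sets); 30 units per modality for recovery ordering; and dip
calibration at n = 200 with 2000 bootstrap replicates. These sizes give
standard errors comfortably inside each assertion's tolerance (for example,
the reduction estimator's standard error is about 1 percentage point at the
benchmark sizes, against a ±3-point criterion).

## Known limitations

- The generator's evoked magnitudes, spontaneous rate (3 Hz), and pain-group
  gain (1.3) are plausible-scale choices, not fitted to recordings; only the
  reduction fractions and tactile latency structure are calibrated to
  reported values.
- The sustained thermal tail is kept weak (0.3 Hz above a 3 Hz background) so
  that the pooled histogram's 1.5×-baseline rule closes the main thermal
  window at 1.5 s; a strong tail would legitimately extend the derived
  window, which is a property of the published rule, not of this
  implementation.
- Silhouette-based k selection can over-split at high k ranges; the
  downstream analyses are robust to over-splitting (a split unit stays
  evoked) but merging two units can dilute a reduction estimate.
- The voltage path models noise as white and Gaussian; real recordings have
  correlated noise, drift, and stimulus artifacts that the detector's
  non-goals exclude.
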
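---
title: "From inertial signals to an aging biomarker: the LDA-value pipeline"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From inertial signals to an aging biomarker: the LDA-value pipeline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(motorage)
```

## The problem

Fine motor control of the hand declines with age, but no single signal
parameter tracks that decline linearly across decades: individual features can
separate a young from an elderly group, yet fail to order eight decade groups.
The pipeline in this package addresses that by *combining* features: it
projects each participant's normalized feature vector, written in
hyperspherical coordinates, onto a rotated one-dimensional axis whose rotation
angles are chosen by a genetic algorithm (GA) to maximize the pairwise
separability of the age groups. The projection — the LDA-value — is a single
scalar per participant that orders the groups and correlates linearly with
age.

## The model and its assumptions

**Cohort design.** Eight age groups covering the decades from the 20s to the
90s, with group sizes 13, 12, 13, 15, 11, 14, 13, 8 (99 participants) and
group age means/SDs of roughly 24.5±3.1 through 93.6±2.7 years. Recordings:
two inertial units (forearm and hand dorsum), each with a 3-axis
accelerometer, gyroscope and magnetometer, 50 Hz, three tasks (rest, pinch,
pronation/supination), three trials of at least 5 s.

**Preprocessing.** Each axis is band-pass filtered at 1–16 Hz with a
5th-order Butterworth filter and mean-removed, then the three axes collapse
into the resultant magnitude. Choices the method text leaves open, fixed
here:

* *Filter before resultant* — the stated processing order is honored
  literally: filtering and detrending act per axis, the resultant comes last.
* *Zero-phase filtering* (forward–backward) is the default because feature
  extraction cares about waveform shape, not latency; a causal single pass is
  available (`zero_phase = FALSE`). Odd end-extensions of 3× the filter
  order suppress edge transients; no samples are trimmed.
* *The resultant is not re-detrended* — its positive mean is a legitimate
  amplitude property; `detrend_resultant = TRUE` exists for sensitivity
  analyses.

**Features.** Eighteen parameters per resultant series, in four families:
amplitude (MAV, MAVFD, MAVSD, RMS, Peak), frequency (zero crossings, mean/
peak/median frequency, F80, band power 3.5–7.5 Hz), entropy (approximate and
fuzzy), statistics (VAR, RANGE, IQR, skewness, kurtosis). Conventions that
needed fixing:

* *VAR is the literal unnormalized sum of squared deviations* (the printed
  formula carries no 1/N). Downstream min-max normalization makes the scale
  irrelevant, and literal fidelity is testable; `sample_variance = TRUE`
  restores 1/(N−1).
* *Skewness and kurtosis use the population SD* (1/N); configurable.
* *ApEn*: window length m = 2, tolerance r = 0.2·SD — the field-standard
  defaults, since the method text names but does not fix them. The literal
  counting construction is used, self-matches included, so ApEn ≥ 0 with
  equality for constant series. The often-quoted "values between 0 and 2" is
  descriptive, not enforced.
* *FuzzyEn*: membership exp(−d²/r) on mean-centered windows, self-matches
  excluded, N−m windows at both scales. Note this membership is *not*
  scale-invariant (the exponent scales with signal amplitude even with
  r ∝ SD); approximate entropy with its hard threshold is. The test suite
  asserts scale-invariance for ApEn only.
* *Spectra*: Welch's method (periodic Hann window, 256-sample segments, 50%
  overlap) by default; a plain periodogram is available and is what the test
  oracles use. F50/F80 are resolved to the first grid frequency at which the
  cumulative power crosses 50%/80% — deterministic and grid-anchored, no
  interpolation.
* *The DC bin is excluded from spectral summaries.* The resultant has a large
  positive mean; with DC included, FMean/F50/F80/FPeak collapse to 0 Hz for
  every participant and carry no information. This is the one place the
  implementation deliberately departs from the printed "sum over all bins".
* *Quartiles* (for IQR and the outlier fences) use linear interpolation
  between order statistics (R type 7), documented and fixed.
* *Peak* considers positive samples only; a series with none yields 0 with a
  warning.

**Reduction.** Outlier fences `Q1 − 1.5·IQR, Q3 + 1.5·IQR` are computed *per
feature within each age group* — cohort-wide fences would flag genuine age
effects as anomalies. Flagged values are winsorized to the nearest fence by
default, keeping the matrix complete for the axis search (dropping with
exclusion from trial averaging is available). Winsorizing precedes trial
averaging and correlation pruning. Pruning removes the later of any feature
pair with |r| > 0.9 in a greedy scan over the canonical column order —
"higher than 0.9" is read as magnitude because anti-correlated features are
equally redundant, and keep-first tie-breaking makes the reduction
deterministic and auditable.

**The LDA-value.** Columns are normalized to [0, 1] and shifted by 0.1, so
every entry is positive, the radius p is positive and all n−1 angles are well
defined in (0, π/2). The GA searches the rotation angles:

* population of 50 axes, angles uniform on [0, 2π);
* fitness is E_z, the sum over all 28 group pairs of the absolute
  standardized mean difference of the projections, with population variances
  and a 1e−12 variance floor for degenerate pairs;
* roulette-wheel selection proportional to E_z (uniform fallback if all
  fitness is zero), consecutive-pair mating (an odd last individual passes
  through);
* with probability 0.8 a pair is replaced by the two fittest of its three
  arithmetic children 1.5p₁−0.5p₂, 0.5p₁+0.5p₂, −0.5p₁+1.5p₂, wrapped to
  [0, 2π);
* each gene mutates to a fresh uniform angle with probability 0.1 (per-gene;
  a per-individual mode is exposed since the original description is
  ambiguous);
* elitism: the best axis of each generation survives unmodified. The original
  description never states elitism, but without it the "axis with the highest
  E_z" over tens of thousands of epochs need not survive; the global best is
  tracked regardless, so elitism only accelerates convergence and makes the
  best-so-far trace monotone.

After the search, the relevance of each feature is the relative change of E_z
when that feature is frozen at its column mean — freezing removes its
variation without changing the dimensionality mid-axis, which a leave-one-out
re-projection would. Features below 1% relevance are dropped, the
hyperspherical representation is recomputed on the survivors, and the GA runs
again (with seed + 1, so both stages are reproducible in isolation); the
printed 46-strong relevant set with its own re-fitted offsets could only have
arisen from such a re-fit. If fewer than two features pass the threshold, the
two most relevant are kept (a one-feature space has no angle to rotate).

**Orientation.** E_z is invariant to a reflection of the axis (adding π to
one rotation angle flips the sign of every projection), so "increasing with
age" is a convention, not a property the fitness can fix. The final axis is
oriented so group-mean LDA-values increase with group index, matching the
published positive age trend. This uses only the group ordering that the
fitness already consumes.

**Statistics.** All tests are two-sided. The young/elderly split follows the
WHO convention at 60 years (groups 1–4 vs 5–8). The per-feature
Mann–Whitney screen is uncorrected for multiplicity by default, mirroring the
original per-feature tables (a corrected mode exists); the pairwise group
comparison on the LDA-value is Kruskal–Wallis followed by pairwise
Mann–Whitney with Bonferroni correction over the 28 pairs (Dunn's z-test is
the configurable alternative, since the original names only the correction,
not the pairwise statistic).

## The synthetic world

The study's recordings are not public, so the package carries a simulator
whose defaults *are* the stated cohort design. Two generators exist:

* `simulate_cohort_signals()` produces raw streams: a tremor-band oscillation
  at a participant-specific frequency (Normal(5, 0.5) Hz) plus Gaussian
  noise, with the oscillation amplitude and the noise-to-signal ratio
  drifting linearly with age. This model was chosen because its two knobs
  (amplitude, noise ratio) move all four parameter families. Magnetometers
  are simulated as low-amplitude slow drift with a quarter-strength age
  effect, reflecting their weak discriminative role in this setting. The
  pinch task carries the largest base amplitude, matching its reported
  prominence.
* `simulate_feature_matrix()` is the feature-level shortcut used for the
  reduction and axis-search stages: affected columns follow
  μⱼ + γⱼ·age + ε, redundant columns are noisy copies of existing ones
  (r ≈ 0.97; contamination hits both members of a pair coherently, as
  redundant readouts of the same signal would), and contamination replaces
  values with extremes 8–15 SD out. A registry records affected columns,
  duplicate pairs and outlier positions so recovery can be scored.

**Canonical effect model** (fixed a priori, not tuned): no per-group effect
sizes were ever reported, so these are the package's own stated world —
one third of features carry an age trend (mirroring the 46-of-143 relevant
fraction), a drift of 0.03 noise-SD units per year (a feature-age correlation
of ≈ 0.5: strong enough to separate pooled young from elderly, too weak for
any single feature to resolve adjacent decades — the regime the method was
designed for), 12 duplicate pairs on top of 143 base features (so pruning
returns the 143-column width that entered the original axis search), and 2%
contamination. What a green recovery test establishes is that the
implementation can extract a linear aging signal of plausible strength from a
cohort of this size and structure; it does not establish anything about real
sensors, real task biomechanics, cross-feature correlation structure beyond
the injected duplicates, or the specific published coefficients.

## Numerical notes and edge cases

* Filter design is validated against an independent reference implementation
  to 9 significant digits at the design stage; the tests assert band-energy
  properties instead, which is what matters downstream.
* Constant feature columns normalize to all-0.1 (warning) and are removed
  before pruning; constant series make skewness/kurtosis NaN in the
  standalone function and 0 in assembled vectors (the column dies in
  reduction anyway).
* An all-zero spectrum yields zero spectral features with a warning.
* Groups with fewer than four values still get fences, with a warning.
* The published axis prints 46 cosine terms for 46 relevant features, but 46
  features yield 45 angles under the hyperspherical construction — an
  off-by-one in the printed indexing. The evaluator takes the printed form at
  face value (46 offsets, 46 angles required); the CLI's `apply-published`
  pads the 45 data-derived angles with a zero 46th. The letter labels a–z,
  A–U skip R (the radius symbol), and the letter-to-sensor assignment is not
  recoverable from the printed table layout, so only (letter, task,
  parameter) ships.
* All GA randomness flows through R's RNG under the configured seed; the full
  pipeline fans one global seed out to per-stage seeds by fixed offsets.

## Limitations

* The simulator's feature-level world is linear-Gaussian with independent
  noise; real feature matrices have heavier tails and richer cross-feature
  structure.
* The GA at test-scale settings (2000 epochs) finds strong but not optimal
  axes in 140-dimensional angle spaces; production settings are 50,000
  epochs.
* The published 46 offsets cannot be validated beyond their printed form
  without the original cohort.
* The signal-level generator does not model orientation dynamics, gravity, or
  sensor calibration; magnetometer realism is limited to "weak and slow".
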
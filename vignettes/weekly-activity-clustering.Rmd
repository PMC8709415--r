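---
title: "Methods: clustering weekly activity profiles"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: clustering weekly activity profiles}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(actiweek)
```

# The problem and the model

A participant-week of wrist accelerometry arrives as a sequence of
fixed-length epoch summaries of acceleration magnitude (ENMO, in
milli-gravity units, mg): at the native 5 s resolution, 120,960 epochs
per week. The analysis goal is a categorical description of *how* a
person distributes activity over the week, not just how much: the week
is reduced to a 168-dimensional vector of hourly means and the cohort is
partitioned with k-medoids under plain Euclidean distance.

k-medoids is chosen over k-means for two reasons. First, cluster centres
are constrained to be actual observed profiles, so every centre is a
plausible human week and directly interpretable; the centre behaves like
a median rather than a mean. Second, the objective sums plain rather
than squared distances,

$$\mathrm{TD}(M) = \sum_i \min_{m \in M} \lVert x_i - m \rVert_2 ,$$

which limits the leverage of unusual profiles. Both choices matter
because hourly activity data remain noisy and right-skewed even after
averaging. The fitted medoids also travel: a saved medoid set labels any
new 168-hour profile by nearest distance (`assign_profiles()`), with
ties broken deterministically toward the lowest cluster index.

Euclidean distance treats the 168 hours as fixed coordinates, so two
profiles that do the same things shifted by an hour are "far". Dynamic
time warping is the standard alternative that forgives such shifts, but
it is far more expensive and precludes the n-by-k distance computations
that make k-medoids feasible at cohort scale. The package therefore
implements classical DTW (absolute-difference local cost, unit
match/insert/delete steps, no path normalisation, optional Sakoe–Chiba
band) *as a check*: `metric_agreement()` reports the Spearman rank
correlation between the two metrics' pairwise distances on a seeded
subsample (40 profiles by default usage). A high rank agreement is the
evidence that the cheap metric orders profile pairs the way the
shift-tolerant one does; the rank statistic formalises what is otherwise
a visual comparison of two distance heatmaps.

# Preprocessing

**Quality categories.** A weekly series is classified purely from slot
and blank counts, scaled by the epoch length (`epochs_per_hour()`):
complete-and-perfect and complete-and-imputed weeks carry a full week of
valid slots (distinguished by the upstream imputation flags); a
recoverable week has exactly one blank epoch (one hourly mean is then
taken over 719 rather than 720 readings); a spring DST week has one
extra hour of slots with at least one full clock hour blank (the hour
skipped when clocks go forward, with wear extending an hour later); an
autumn DST week is one hour of slots short. Everything else is unusable.
Classification never silently swallows malformed input — non-series
objects and inconsistent flag lengths are errors.

**DST repair.** The missing clock hour is filled epoch-wise with the
mean of the same clock hour on the other six days, flagged imputed; the
spring week's extra trailing hour is discarded. Repair always returns
exactly one week of slots, so downstream aggregation needs no special
cases.

**Exclusions.** Four filters follow, in a fixed order that makes the
funnel reconcile exactly: metadata-flagged withdrawals and age
ineligibility, unusable quality, weekly mean activity at or above
100 mg, and non-imputed wear under 72 h. Two wordings of the mean filter
circulate ("greater than 100 mg" vs "100 mg or more"); the package
adopts the inclusive boundary, mean ≥ 100 mg, the stricter reading and
the one attached to a reported count. Wear is accounted at the epoch
grain — valid epochs not flagged imputed, converted to hours — the
finest defensible unit; exactly 72.0 h is retained ("less than 72 h" is
strict). The mean and wear filters are evaluated jointly: a participant
failing both carries both reason codes, but is counted once (under the
mean filter) so that supplied = retained + all exclusion counts on every
input. Percentage reporting uses half-away-from-zero rounding
(`round_half_up()`) so printed values match hand arithmetic.

**Alignment.** Profiles are circularly rotated so index 1 is Monday
00:00, using the recorded start weekday. Weekday/weekend patterning only
makes sense on a calendar-aligned week; whether to align is exposed
(`preprocess_cohort(align = FALSE)`) for analyses that prefer
wear-start-relative weeks, since either convention is defensible.

# Choosing k

PAM is implemented from scratch: greedy BUILD (first medoid minimises
total distance; each addition maximises the reduction) followed by
steepest-descent SWAP in which the best single medoid/non-medoid
exchange is accepted only if it strictly decreases TD. A relative guard
of 1e-12 on the improvement prevents floating-point cycling; hitting
`max_iter` (default 100 accepted swaps) returns with a warning, never
silently. BUILD is deterministic; `n_restarts > 1` adds seeded random
initial medoid sets and keeps the best final solution. Restarts are the
designed escape from SWAP local optima — on tiny instances where the
exhaustive optimum is computable, single-start PAM occasionally lands in
the same local optima as independent PAM implementations, and a handful
of restarts removes them.

`scree_curve()` fits every k in a range with a shared seed policy so the
curve is comparable across k, and warm-starts each k from the previous
k's medoids plus the best additional point (keeping the better of the
warm start and BUILD after SWAP). Because adding a medoid can only
reduce the warm-start cost and SWAP only decreases it further, the
resulting curve is non-increasing by construction and the first
differences $\Delta(k) = \mathrm{TD}(k{-}1) - \mathrm{TD}(k)$ are
non-negative.

`select_k()` formalises the "last sizeable reduction" reading of a
first-difference plot: the suggested k is the largest k with
$\Delta(k) > (1+\tau)\,\mathrm{median}\{\Delta(k{+}1),\dots,\Delta(k_{\max})\}$.
Past the true number of clusters the reductions level off, so the tail
median estimates the noise-level reduction and τ (default 0.5) sets how
far above it a drop must stand. The largest examined k cannot qualify
(it has no tail to compare against), and a curve with no qualifying drop
returns the smallest k examined — a flat curve is evidence of no
recoverable structure, not of many clusters. The rule is deliberately
simple and monotone in τ; it is a formalisation of an elbow heuristic,
not an optimality criterion, and the suggested k should always be
sanity-checked against cluster sizes and the plausibility of the medoid
profiles.

# The synthetic cohort

The generator exists so that every stage — classification, repair,
exclusion, aggregation, alignment, distances, clustering, profiling —
can be exercised end-to-end with known ground truth. Nine archetypal
weekly patterns are parameterised as a non-negative base level plus
Gaussian bumps in clock time (per weekday group) and a weekend
multiplier: a commuter pattern with morning and late-afternoon weekday
peaks, a sustained-activity day, a morning-only burst, a morning burst
with a moderate plateau, a weekend-dominated week with a Sunday-morning
spike, a featureless moderate plateau, a lower-intensity commuter
pattern without weekend spikes, a low morning-weighted pattern, and a
near-flat inactive pattern. Template amplitudes are free parameters
chosen once to span the realistic hourly ENMO range (night floors of
3–5 mg, daytime means up to ~60 mg); tests therefore assert ordinal and
shape properties of templates (peak windows, mean orderings), never
absolute levels.

Epoch noise is independent Gaussian around the hourly template value,
truncated at 0 mg, with sd 15 mg at the default settings — the simplest
noise model under which hourly averaging is meaningful. The default
scenario mix reproduces the quality composition observed in large
wrist-accelerometer cohorts (21 % perfect, 44 % upstream-imputed, 21 %
recoverable, 1 % spring DST, 2 % autumn DST, 11 % unusable), and the
generator plants 3 high-mean outliers (constant 150 mg weeks), 5
low-wear participants (wear flagged down to 60 h), 2 withdrawals and 3
age-ineligible participants, so every funnel stage fires. Start
weekdays are uniform so week alignment is genuinely exercised. Everything
is a deterministic function of the configuration seed.

What the generator does *not* emulate — and what passing tests therefore
do not show about real data: within-hour autocorrelation and bout
structure, day-to-day habit correlation within a person, seasonal and
weather effects, device calibration error, non-wear that masquerades as
inactivity, and the raw-signal processing upstream of epoch summaries.
Recovery of planted archetypes is a necessary correctness check for the
pipeline, not evidence that nine clusters exist in any particular
cohort.

# Problem sizes and numerical conventions

The packaged tests and the acceptance script run the recovery analyses
on a cohort of 100 participants per archetype (about 900 series) at
300 s epochs — 12 epochs per hour, preserving every code path including
the 5 s bookkeeping, which is tested separately at native resolution —
with a scree over k = 1…16. These sizes were chosen as the smallest at
which the nine-archetype structure is comfortably overdetermined;
`select_k` recovers k = 9 and the k = 9 partition agrees with the
planted labels at adjusted Rand index above 0.98 across the seeds
exercised, with Euclidean-vs-DTW rank agreement above 0.9 on 40-profile
subsamples.

Table cells round half-up to one decimal (whole percentages where a
funnel stage is conventionally printed whole); outcome-difference cells
are computed on unrounded percentages and rounded last, so each row's
differences sum to ~0. Missing characteristic values are excluded from
both numerator and denominator of their cell, with per-cell denominators
reported alongside. Positivity rates over zero tests are `NA`, never 0.

# Limitations

Medoid solutions are local optima of a combinatorial objective;
different restart policies can yield different partitions of comparable
quality, and exact reproduction of any particular published partition is
out of scope without the underlying data. Euclidean distance on aligned
hours penalises time-shifted but otherwise identical behaviour — the DTW
agreement check bounds, but does not remove, this effect. The
first-difference rule inherits the arbitrariness of all elbow
heuristics through τ. Keeping all seven days separate weights weekdays
over the weekend in cluster formation; an averaged weekday + Saturday +
Sunday profile is a natural variant the package does not currently
implement. Composition and outcome tables are descriptive
cross-tabulations with no significance testing and support no causal
claims.
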
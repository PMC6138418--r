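---
title: "Methods and modelling choices in siestacline"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods and modelling choices in siestacline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, message = FALSE}
library(siestacline)
```

This vignette is the package's account of its own methods: the sleep and
rhythm definitions it implements, the statistical conventions it follows,
what the synthetic-data generators do and do not emulate, and the choices we
made where the underlying analysis tradition leaves room.

## Time conventions and monitor data

All series are per-minute beam-crossing counts; coarser input is rejected
rather than resampled, because the 5-minute sleep criterion presumes 1-minute
resolution. Intervals are half-open `[start, end)` in minutes. Zeitgeber time
anchors everything: ZT0 is lights-on, `zt = (clock − lights_on) mod 1440`,
and the cycle index increments at each ZT0. In an LD cycle the light phase is
ZT0–12 and the dark phase ZT12–24.

Recording gaps and rows with a non-OK monitor status become *explicit*
missing minutes, never silent drops. Any candidate sleep bout that touches a
missing minute is discarded from bout statistics — its true extent is
unknowable, and dropping it is conservative for totals and bout-length
distributions alike. How error-status rows were handled in the original
tradition is not documented; flagged-and-excluded is this package's choice.

## Sleep annotation and windowed metrics

A sleep bout is a maximal run of at least `threshold_min = 5` contiguous
zero-count minutes. Runs truncated by the start or end of the recording are
kept when their observed length reaches the threshold; always dropping them
would bias against long bouts at the span edges.

Windowed metrics (4-h fragmentation windows, 30-min profile bins, the
day/night split at ZT12) all use one clipping rule: a bout spanning a
boundary contributes to each window only the minutes inside it. Clipping
conserves total duration exactly, which the tests verify on random
bout/partition pairs. Two decisions sit on top of the rule:

* **Counts as well as durations use clipped segments** — a boundary-spanning
  bout is counted once in each window it overlaps. The tradition states the
  rule explicitly only for durations; applying it to counts keeps
  `bout_count`, `sleep_min` and MSBL mutually consistent within a window.
* **MSBL is the median of clipped segment durations**, our literal reading
  of the per-window rule. A window with no segment yields a missing MSBL and
  is excluded from group means rather than zero-filled: zero-filling would
  conflate "slept not at all" with "slept in very short bouts".

Group averages pool equal numbers of flies per line and keep sexes separate;
lines, not flies, are the replication unit in the between-region tests.

## Activity profiles

Per fly: 30-min bins averaged over the last three LD cycles, then the
startle correction, then peak normalization, then the group mean. The
correction replaces the bin right after each light transition with the mean
of its flanking bins (circularly on a daily profile). Correction must
precede normalization — otherwise the startle spike, not the evening peak,
frequently sets the maximum; the tradition does not state the order, so we
fixed it on that argument. Normalization divides by the fly's global daily
maximum. One strand of the tradition says "peak of evening activity", another
"peak value in daily activity"; these coincide in practice, and the per-fly
argmax bin is recorded (`peak_bin` attribute) so the choice is auditable.
All-zero flies cannot be normalized and are excluded from the group mean with
a warning.

## Chi-square periodogram

The free-running period is estimated from at least six DD days by the
Sokolove–Bushell statistic. The series is summed into 10-min bins (1-min Qp
is noisy); for each candidate period `P` (18–30 h, 0.1-h steps) the binned
points are folded modulo `P` into `round(P/bin)` phase classes and

$$Q_p = \frac{N \sum_h K_h (M_h - \bar M)^2}{\sum_i (x_i - \bar M)^2},$$

with `M_h` the class means, `K_h` the class sizes. Folding is how a 0.1-h
period grid can be honoured on 10-min bins at all: the classic
integer-cycle reshape only exists when `P` is a multiple of the bin width,
and the folded form reduces to it in that case. Under the null, `Qp` is
approximately chi-square with (classes − 1) degrees of freedom; the tests
confirm the per-period 0.95 line is exceeded ~5% of the time on pure Poisson
noise.

Because ~121 candidate periods are scanned, calling a fly rhythmic whenever
*any* period clears its own 0.95 line would misclassify the majority of
arrhythmic flies (we measure a ~99% scan-level false-positive rate on
noise). The rhythmicity call therefore uses a Bonferroni-adjusted line
(`alpha / n_periods`); the period estimate is the candidate maximizing
`Qp − line`, which also removes the bias toward long periods that raw-`Qp`
argmax has (its null mean grows with the class count). `adjust = FALSE`
restores the unadjusted per-period line. Arrhythmic flies are excluded from
group period means and reported as percent rhythmic.

## Haplotype classification

Six UTR sites are scored: SNP1–4 plus Af1 and Af3. The classification rule
is: SNP3 = G is dominant and defines the SNP3G class (all such lines share
one sequence); among SNP3 = A lines the SNP1/SNP2/Af1/Af3 string C/A/T/T is
the major tropical haplotype, T/T/C/A the major temperate one, and anything
else is reported verbatim as `other:<string>`. One sequence per isofemale
line is assumed; ambiguity codes at scored sites are an error, never a
guess, and a base outside a site's allele set is flagged as unknown rather
than coerced.

The nucleotide offsets of the scored sites are not public in machine-readable
form; they live in a sequence supplement. The bundled reference
(`utr_reference()`) is therefore **synthetic**: a fixed 497-bp backbone (the
span of the real UTR region) with arbitrary offsets that respect the known
topology — SNP2 and Af1 inside the dmpi8 intron, SNP1 upstream, Af3
downstream — and fixed weak 5'/3' splice-site substrings shared by every
record. Real-data use requires supplying true offsets in the same reference
structure. Offsets are 0-based internally; the 6872-based coordinates used in
the source material are carried alongside for cross-reference. Indel-bearing
sequences are rejected rather than aligned: the known small indel variants
are outside the scored sites, and silent coercion would be worse than a
refusal.

The deterministic cohort allocation (`australian_haplotypes()`) honours every
published margin — 42 lines, 12 SNP3G, C/A/T/T in 9 tropical + 2 temperate
lines, T/T/C/A in 3 + 6, six classes, 25 tropical / 17 temperate lines in
total — and fills the remaining ten SNP3A lines with three invented minor
haplotypes. The minor-class split is synthetic and is labelled as such.

## Splicing quantification

Efficiency is `spliced / (spliced + unspliced)`; the CBP20 loading control
cancels in the ratio and only normalizes the total transcript level. Daily
curves pool lines per timepoint. For the curve comparison the observational
unit is the line mean per timepoint, compared across groups by one-way
ANOVA; the original factor structure is not documented, so this choice is
ours and is stated, not asserted as the tradition's.

## Statistical conventions

* **Chi-square without continuity correction.** It is the variant whose
  p-value (0.0277 on the published table) matches the printed 0.027; the
  Yates-corrected p is ≈ 0.08.
* **Fisher one-sided by default**, the hypergeometric tail for enrichment of
  the first class in the first region. Again it is the variant reproducing
  the printed 0.039 (two-sided ≈ 0.065). Whether the original test was
  one-sided is an inference from the printed value, and both variants are
  available.
* **Pooled-variance Student's t** (the era's default), one-sided where the
  tradition is; Welch behind a flag. Two constant equal groups give the
  p = 0.5 convention.
* **No multiple-testing correction** anywhere, matching the source
  analyses; everything is a raw p-value.

The tests check these implementations against independent oracles: direct
hypergeometric enumeration with binomial coefficients, a 10⁴-shuffle
permutation test, the F = t² identity, and KS-uniformity of null p-values.

## The activity generator

`simulate_activity()` is a two-state semi-Markov process per fly on the
minute grid. While awake, the sleep-onset hazard is
`siesta_propensity · f_mid(φ) + night_hazard · f_night(φ)` with `f_mid` a
von-Mises-shaped bump peaking at ZT6 and `f_night` a smooth night indicator;
bout lengths are geometric (support ≥ 1 min) with separate day/night means;
awake minutes emit Poisson counts at `wake_rate` times a bimodal template
(morning and evening peaks over a positive floor, mean 1); the minute after
each LD light transition receives an extra Poisson spike of intensity
`startle_gain · wake_rate`. In DD the phase free-runs at
`free_run_period_h`; in LL the circadian modulation is removed and the
daily-mean hazard and rate apply flat, reflecting the loss of clock function
in constant light while regional sleep-propensity differences persist.

The semi-Markov form (rather than per-minute Bernoulli sleep) exists so that
bout-length distributions are directly controllable — the fragmentation
contrast needs shorter *and more frequent* bouts in temperate flies at
similar totals. Geometric bout lengths are an assumption of convenience; the
data tradition offers no distributional facts about bout lengths.

Default parameters (`sim_params()`) encode the study's qualitative structure
at 25 °C: tropical `siesta_propensity` 0.030 vs temperate 0.015, day bout
means 25 vs 15 min, night bout means 40 vs 25 min, with the temperate night
hazard raised (0.120 vs 0.075) so night totals stay comparable while night
sleep is more fragmented. The siesta propensity scales with temperature
(factors 0.6 / 1.0 / 1.3 at 18 / 25 / 29 °C) and the night hazard slightly
against it, matching the direction of the published temperature effects.
These constants were calibrated once so that the tropical > temperate
day-sleep ordering is recoverable at the study scale of 8 lines × 16 flies —
the regime the acceptance checks exercise — and are not otherwise tuned.
Line-level variability is multiplicative lognormal jitter (CV 0.1) on the
hazard and bout-length parameters.

What the generator does *not* emulate: arousal thresholds and sleep depth,
heat-induced nighttime sleep disruption as a mechanism (only its direction,
via the parameter maps), social or feeding effects, and any mechanistic
splicing→sleep coupling — the haplotype and splicing contrasts are injected
as parameter differences, not derived from sequence. Passing tests therefore
show that the *pipeline* recovers what the model puts in, not that the model
is a faithful fly.

With `min_wake_count = 1` every awake minute registers at least one count,
making sleep annotation on the output exactly invertible against the truth
log; with pure Poisson emission (the default) occasional zero-count wake
runs can masquerade as sleep, which is the realistic regime and is why
recovery tests distinguish "noise-free exact" from "noisy, unbiased within
2 SE".

## Degenerate inputs and numerical points

Duplicated or backward timestamps, negative counts, frequency vectors not
summing to 1, empty groups, zero-margin tables, and all-zero profiles are
hard errors with specific messages; none are silently repaired. The
efficiency ratio refuses `spliced + unspliced = 0` and `cbp20 = 0`. The
periodogram refuses series under six days and constant series. Ties in the
periodogram peak resolve to the shortest candidate period (`which.max`);
exact ties are a measure-zero event under the generators.

## Problem sizes

The test suite and acceptance checks run at the study's own scale where the
design calls for it — 8 lines × 16 flies per region, five LD days with the
last three analysed, seven DD days, 42-line sequence cohorts — and at
reduced scale (fewer replicates, shorter series) for property checks where
the property is size-independent, e.g. 10⁴ short random series for the
annotation oracle and 100 seeded cohort replicates for the cline-recovery
rate. The Monte-Carlo cline check is the single most expensive item
(~2.5 min on one CPU).

## Known limitations

* The bundled UTR reference is a synthetic stand-in; real sequence panels
  need true offsets and may require indel-aware alignment upstream.
* The rhythmicity call inherits the chi-square periodogram's approximations;
  estimators from the actogram literature (Lomb–Scargle, autocorrelation)
  are not implemented, though the interface isolates the estimator so one
  can be swapped in.
* `read_dam()` supports the bundled tab-delimited dialect with a
  configurable count-column offset; video-tracking and ethoscope formats are
  out of scope.
* The DAM dialect cannot represent per-channel missingness; a row with any
  missing count round-trips as a whole missing row.
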
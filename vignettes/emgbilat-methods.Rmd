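---
title: "Assessing bilateral motion symmetry from surface EMG: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Assessing bilateral motion symmetry from surface EMG: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(emgbilat)
```

## The problem

After a stroke, recovery of upper-limb motion is driven by at least two
distinguishable neural processes: re-learning *which* muscles to contract
together (coordination), and re-tuning *how strongly* each contraction is
driven (effective strength). A single clinical impairment score collapses
both. During bilateral symmetric motions — both arms performing the same
movement — the unaffected side provides a within-subject reference, so the
two processes can be measured separately by comparing sides.

`emgbilat` implements this comparison for an 18-channel surface-EMG montage:
nine muscles recorded on both sides of the body (brachioradialis, pronator
teres, biceps, triceps, anterior deltoid, posterior deltoid, pectoralis,
infraspinatus, erector spinae), sampled at 1000 Hz while the subject performs
repeated bilateral movements (elbow flexion, or steering-wheel half-cycles)
paced at 0.25 Hz in 20-s trials.

## The model

Per trial, the electrical power of muscle $i$ is quantized as the mean of
per-second RMS values of its rectified, low-pass-filtered EMG envelope,
$P_i \ge 0$. Side totals are $P_r = \sum_i P_i$ (right) and
$P_l = \sum_i P_i$ (left). Each side's power distribution over muscles is
normalized into coordination coefficients

$$a_i = P_i / P_r, \qquad b_i = P_i / P_l, \qquad \textstyle\sum_i a_i = \sum_i b_i = 1,$$

which describe the side's muscle-use *strategy* independent of overall
effort. Two indexes then separate the two recovery axes:

* **Effective Strength Balance.**
  $\mathrm{ESB} = (P_r - P_l)/(P_r + P_l) \in [-1, 1]$. Zero means both
  sides spend equal electrical power; $\pm 1$ means total dominance of the
  right/left side. ESB responds to overall drive and is blind to strategy.

* **Muscle Coordination Similarity.**
  $\mathrm{MCS}$ is the Pearson product-moment correlation of the paired
  coefficient vectors $(a_i, b_i)$ over the $n = 9$ muscles, evaluated in
  summation form. $1$ is perfect muscle mirroring, $0$ a loss of
  between-side correlation, negative values mean homologous muscles have
  switched roles. MCS responds to strategy and, because the coefficients
  are normalized, is invariant to any rescaling of a side's overall drive.

This *dissociation* is the design centre of the model: multiplying one
side's powers by $k > 0$ moves ESB monotonically but leaves MCS unchanged,
while permuting one side's powers changes MCS but not ESB. The test suite
asserts both numerically.

### Degenerate trials

A side with zero total power makes the coefficients of that side undefined:
the trial still yields $\mathrm{ESB} = \pm 1$, and MCS is reported as
`NA` rather than silently 0 or 1 — a constant coefficient vector likewise
gives `NA` (the correlation's denominator vanishes). Such trials are
excluded from MCS group panels with their exclusion count reported, but are
retained in ESB panels.

## Preprocessing chain

Each channel passes through, in order: fifth-order Butterworth high-pass at
20 Hz (motion artifacts), full-wave rectification, fifth-order Butterworth
low-pass at 32 Hz (contraction envelope). Amplitudes are then standardized
by the median envelope value of the experimental session pooled over **all**
channels and samples.

Design choices the chain's description leaves open, and how they were
resolved:

* **Phase handling.** Filters are applied forward and backward
  (`zero_phase = TRUE` default). The paper-style single-pass response is
  available (`zero_phase = FALSE`); the documented $-3$ dB cutoff applies to
  a single pass and becomes $-6$ dB for the two-pass default. Zero phase was
  chosen because envelope *timing* symmetry between sides matters when
  powers are integrated over a common window.
* **Pooled vs per-channel median.** The standardization divisor is one
  pooled session median. A per-channel divisor would flatten between-muscle
  power ratios and destroy the information the coefficients carry; it is
  available as `standardization_mode = "per_channel"` for sensitivity
  analysis only. Both indexes are mathematically invariant to the pooled
  scalar (it cancels in ESB's ratio and in the coefficient normalization),
  which the tests assert numerically — standardization matters for
  cross-session comparability of raw powers, not for the indexes.
* **Clipping.** The low-pass of a rectified signal can overshoot slightly
  below zero near sharp transients; envelopes are clipped at exactly 0 so
  powers stay nonnegative.
* **Edge transients.** The first and last second of each trial
  (`edge_trim_s = 1`) are excluded from power integration.
* **RMS stage.** Per-second RMS is computed on the end-of-chain envelope by
  default; `standardize_stage = "rectified"` switches the standardization
  reference to the rectified, pre-low-pass signal for sensitivity analysis.

Per-second windows are non-overlapping; a trailing partial second is
dropped; trial power $P_i$ is the **mean** of the per-second RMS values
(robust to trials of slightly different usable length — a sum would scale
both sides equally and leave both indexes unchanged).

## Synthetic data generator

No public recording of this protocol exists, so validation runs on a
generator that emulates only the statistical features the pipeline
consumes. Each channel of side $s$ is amplitude-modulated band-limited
Gaussian noise — the standard surrogate for interference-pattern surface
EMG:

$$x_i(t) = g_s\, w_i\, E(t)\, G_i(t) + \phi\, G_i'(t)$$

* $E(t)$: a raised-cosine burst per motion cycle (0.25 Hz, duty 0.5 by
  default), onsets jittered with SD 0.05 s. $E(t)$ is shared by every
  channel of a trial — it *is* the motion — so bilateral timing is
  intrinsically symmetric.
* $G_i, G_i'$: independent zero-mean unit-variance carriers, band-limited
  to 20–450 Hz by spectral synthesis (Fourier bins outside the band
  zeroed). At sampling rates too low for a 450 Hz edge the band is capped
  at 45 % of the sampling rate.
* $w_i$: the side's ground-truth coordination weight (sums to 1 per side);
  per-motion presets load elbow flexors for elbow flexion and the shoulder
  girdle for steering.
* $g_s$: the side's amplitude gain. Because RMS is linear in amplitude, a
  programmed gain ratio $g$ propagates through the pipeline to
  $\mathrm{ESB} \approx (g-1)/(g+1)$ — the basis of the parameter-recovery
  tests.
* $\phi$: the baseline-noise amplitude, `noise_floor` (default 0.05)
  relative to a unit-gain channel of average weight. The floor models the
  acquisition chain, so it deliberately does **not** scale with the
  subject's contraction strength; its additive contribution to weak-side
  power is what keeps recovered ESB a few percent below the programmed
  value at large gain ratios.

Cohorts are generated from impairment profiles with two orthogonal
severity axes, mirroring the model's two indexes: a per-trial additive
Gaussian perturbation of the affected side's coordination vector (floored
at 0, renormalized), and a subject-level affected/unaffected gain ratio
drawn from a lognormal — a strictly positive amplitude ratio whose spread
grows multiplicatively with severity (a truncated normal was rejected: its
pile-up at the truncation bound, combined with the index's $\pm1$ ceiling,
made dispersion non-monotone at the severe end, violating the intended
severity ordering). The unaffected (or dominant) side always receives a
small physiological perturbation (SD 0.01), and both gains get a per-trial
lognormal jitter (CV 0.03). The default ladder (SIAS-like levels 5 → 1)
spaces coordination-noise SD as 0.02/0.04/0.07/0.12/0.22 and the gain-ratio
draw as median 0.85/0.70/0.55/0.40/0.25 with log-SD
0.08/0.14/0.24/0.40/0.70; no quantitative per-level effect sizes exist to
calibrate against, so the ladder encodes only the qualitative ordering
(means and dispersions of both indexes worsen monotonically with severity)
and is documented as illustrative. Subject-level draws come from the master
seed's stream and each trial's noise from its own derived seed, so cohort
structure is reproducible independently of trial count.

What the generator does **not** emulate: motor-unit recruitment and firing
statistics, volume conduction and electrode crosstalk, electrode lift-off
artifacts, fatigue drift, or task biomechanics. Passing tests therefore
demonstrate that the pipeline recovers programmed coordination and strength
structure from realistic-bandwidth amplitude-modulated signals — not that
it is robust to every artifact of clinical recordings.

```{r example}
seg <- generate_trial(trial_spec(seed = 7, gain_right = 2))
trial_indexes(seg)[, c("esb", "mcs")]
```

## Cohort statistics

Group comparisons mirror the published analysis convention: per motion and
per index (MCS, and |ESB| so side balance is assessed independently of
which arm is paretic), all-vs-all pairwise two-sided Wilcoxon rank-sum
tests, Holm-corrected within each (index, motion) panel, with per-group
sample SDs ($n-1$ denominator) reported alongside. For combined sample
sizes up to 20 the rank-sum null distribution is enumerated exactly
(midranks for ties; the two-sided p-value is the null probability of a
rank sum at least as far from its mean as observed); larger samples use
the normal approximation with tie and continuity correction. The
comparison family is configurable (`family = "vs_healthy"`) because
published descriptions of such analyses vary between all-vs-all and
healthy-vs-rest; all-vs-all is the default.

Muscle *activity prints* summarize coefficient distributions per muscle and
side role (dominant/non-dominant for healthy subjects, non-paretic/paretic
for patients) as Tukey boxplot statistics: type-7 linearly interpolated
quartiles, whiskers clipped to the most extreme points within 1.5 IQR of
the quartiles, and points beyond the fences enumerated as outliers. The
quartile convention is recorded in the result's metadata.

## Numerical choices

* Coefficient sums are exact to 1e-12 by construction; the test suite
  asserts this on every processed trial.
* The MCS summation form is clamped to $[-1, 1]$ against floating-point
  overshoot of the Cauchy–Schwarz bound; an independent-correlation
  cross-check holds to 1e-12.
* MCS is bit-identical under power-of-two side scalings; other scalings
  agree to within ~1 ulp (asserted at 1e-12).
* Zero-variance detection in MCS uses a relative threshold
  (1e-14 of the vector's squared scale).
* The trial-annotation model requires non-overlapping windows; segments
  shorter than the nominal 20 s are accepted but flagged.

## Problem sizes used in the shipped tests

Validation suites were sized for a single-CPU desk run while keeping the
signal scale of the protocol (1000 Hz, 20-s trials): parameter-recovery
conditions use 50 seeded trials per gain ratio and per perturbation level;
the null-cohort type-I check uses 20 replicates of three identically
distributed groups (3 subjects × 3 trials each, one motion, 1-s inter-trial
rest, zero between-subject gain spread so that trials are exchangeable);
the severity-sweep check uses 48 subjects × 3 trials per SIAS-like level, a
size chosen by a surrogate power analysis so that the five-level SD chain
of both indexes is sampled reliably above its population-monotone ordering.
File-format and statistics unit tests use second-scale toy signals at
reduced sampling rates where only structure, not signal content, is under
test.

## Known limitations

* The indexes quantify *symmetry*, not absolute motor ability: a subject
  moving both arms equally badly scores like a healthy one. They are
  companions to, not replacements for, clinical scales.
* MCS is undefined for single-muscle or constant-coefficient activity;
  severe patients can produce such trials, which then carry only ESB.
* With nine muscle pairs, MCS is a correlation over nine points; its
  sampling variability is intrinsically large, which is visible in the
  dispersion of severe synthetic cohorts.
* The session-median standardization assumes the session contains a
  representative mix of activity and rest; a session consisting only of
  maximal effort would shift the scalar (though not the indexes).
* Generator profile defaults are illustrative severity ladders, not
  clinically calibrated effect sizes.
* The group-comparison panels follow the published convention of testing
  *trials*. Trials within a subject are correlated through subject-level
  deficits (especially the strength axis), so cohorts with few subjects and
  strong between-subject heterogeneity inflate the trial-level type-I error
  by pseudo-replication. Interpret panels accordingly, or aggregate to one
  value per subject before testing when subjects are few.
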
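---
title: "Detecting stretch and shortening responses and movement units in infant recordings"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting stretch and shortening responses and movement units in infant recordings}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(infantemg)
```

## The problem

In the first year of life, muscle tone — the background readiness of a
muscle to resist or comply with length changes — reorganizes rapidly.
Two complementary windows onto this process are (a) the muscle responses
evoked by slow passive flexion/extension of a joint, where a lengthened
muscle may fire a stretch response (StR) and a shortened one a shortening
reaction (ShR), and (b) spontaneous supine movements, where episodes of
prominent limb-endpoint motion (movement units, MUs) are accompanied by
antagonist muscle activity whose correlation and coactivation index the
maturity of coordination. Both analyses reduce to careful, threshold-driven
event detection on noisy surface-EMG envelopes and video-tracked endpoint
trajectories. This package implements that chain end to end, together with
a synthetic-data module that generates both session types with complete
ground truth, so every stage can be validated by recovery experiments even
though infant recordings of this kind are not publicly deposited.

## Signal model and processing chain

### Time conventions

All intervals are half-open `[t_start, t_end)` in seconds from the start of
the recording; sample `i` (1-based) covers `[(i-1)/rate, i/rate)`. EMG
(nominally 1926 Hz) and video (nominally 50 Hz) carry independent clocks
assumed synchronized at `t = 0`; no drift correction is attempted because
the recording systems used in this field synchronize at acquisition time.

### Envelope

Raw EMG is rectified and smoothed with a sliding 20-ms RMS window
(`rms_window_s = 0.020`), centered on each sample. Edge windows shrink
rather than zero-pad: padding with zeros would create an artificial dip at
the recording edges that the burst detector could misread as an offset.

### Baseline

Quiet fragments are intervals of at least `baseline_min_dur_s = 0.5` s
whose windowed mean stays within `baseline_factor = 1.2` times the minimum
level of the trial. Two operationalizations of "minimum level" are
possible; the single-sample minimum is noise-dominated (for a rectified
envelope it can be arbitrarily close to 0, making the 1.2x tolerance
vacuous), so the package uses the minimum over all sliding 0.5-s window
means. The baseline level is the mean envelope over the union of
qualifying windows. Because the minimizing window always satisfies the
tolerance, at least one quiet fragment always exists and no fallback path
is needed. A known small effect of the union-of-windows definition is that
up to `(factor - 1)/(burst/baseline - 1)` of a window's length adjacent to
a burst can leak into the quiet set, biasing the level upward by a few
percent; this is harmless for detection because the burst threshold is a
further factor of 2 above the level, and it is shared by any window-mean
reading of the rule.

### Bursts

Muscle responses are periods where the envelope strictly exceeds
`burst_factor = 2` times the baseline level for at least
`burst_min_dur_s = 0.030` s; responses separated by less than
`burst_merge_gap_s = 0.050` s are combined into one. The duration filter is
applied to raw supra-threshold runs *before* merging, following the order
in which the two rules are stated for this protocol; merging then iterates
to a fixed point (a single left-to-right pass suffices, but the
implementation guards the contract). Ties at the threshold fall below it:
"exceeding twice the baseline" is read as a strict amplitude ratio, since
the alternative reading ("exceeding at least twice" as two occurrences)
leaves the threshold undefined.

### Stretch/shortening classification

The stretch map records, per (joint, movement direction, muscle), whether
the muscle is lengthened, shortened or unaffected. The default map encodes
the biarticular thigh anatomy — rectus femoris (hip flexor, knee extensor)
shortens during hip flexion and knee extension; biceps femoris mirrors it —
plus tibialis anterior/gastrocnemius lateralis at the ankle (flexion =
dorsiflexion) and biceps/triceps brachii at the elbow. Gastrocnemius
lateralis is deliberately *unaffected* for knee movements: as a biarticular
muscle its length change during knee motion is ambiguous, so only tibialis
anterior is interpreted there.

A burst is assigned to exactly the phase containing its onset. If activity
persists past a direction change, its duration is truncated at the phase
end, and the >100-ms classification rule (`response_min_dur_s = 0.100`) is
applied to that truncated duration. The ordering question (truncate first
or classify first) is genuinely open; truncating first was chosen so that
classification and the reported duration use one and the same quantity, and
so that a burst beginning moments before a direction change is not credited
to the expiring phase. A strict comparison with a 1e-9 relative guard
excludes durations equal to the threshold up to floating-point noise.
Occurrence counts a movement as responsive if at least one response of the
kind occurred in it — multiple bursts in one phase count once — and pools
the left and right sides by summing counts.

### Rhythmic activity in distant joints

Muscles of joints not being moved sometimes respond consistently across
consecutive movement cycles. No quantitative criterion for "consistent"
exists in the protocol this package operationalizes, so one was defined
here and both knobs are exposed: with at least `min_cycles = 3` complete
flexion/extension cycles, a distant muscle is flagged rhythmic when it has
a burst onset in at least `lock_frac = 0.5` of the phases of one direction
(whichever direction locks more often). Trials with fewer cycles return
`NA` — "not evaluable" is deliberately distinct from "not rhythmic".

### Movement units

Endpoint velocity is computed by central differences (forward/backward at
the edges) and smoothed with a centered 0.3-s moving average
(`mu_speed_smooth_s`). Episodes are supra-threshold runs
(`mu_speed_threshold_mps = 0.2`, strict) lasting more than
`mu_min_dur_s = 0.2` s, merged across gaps under `mu_merge_gap_s = 0.5` s,
and retained when the per-coordinate excursion (max minus min within the
final episode) reaches `mu_excursion_frac = 0.15` of body height in x *or*
y. The operation order threshold → duration → merge → excursion follows the
order in which the criteria are stated; the consequence that sub-0.2-s
fragments cannot seed an MU is a real modelling choice, and a
`merge_first` flag is provided for sensitivity analysis. The alternative
criterion set (> 0.1 s, < 0.3 s merge, ≥ 10 %) is available via
`pipeline_config(mu_criteria = "alternative")`. Excursion is assessed after
merging (on the final episode), and the strictness of each comparison
matches its printed form: strict for speed and duration, non-strict for
excursion.

Invalid trajectory spans act as barriers. The pose-tracker reader marks
points under `likelihood_threshold = 0.6` invalid, linearly interpolates
interior gaps up to `max_gap_fill_s = 0.2` s, and leaves longer gaps
excluded: supra-threshold runs never cross them and episodes are not merged
across them. The tracking protocol this consumes used median-filtered
predictions but no published gap policy; interpolation bounded by 0.2 s
(one smoothing window) keeps the velocity estimate defensible while longer
dropouts are simply not analyzable.

An MU is *separated* when its temporal overlap with other limbs' movement
is below `separated_overlap_frac = 0.25` of its duration. "Overlap with any
MU of the other limbs" is read as the maximum intersection with a single
other-limb MU (the default); reading it as the union of other-limb MU time
is available via `overlap_mode = "union"`. MU frequency (per minute) and
mean duration are reported per limb and averaged over sides per limb class.

### Antagonist coordination

Within each MU window (at the full EMG rate — no downsampling, since the
correlation of smoothed envelopes is insensitive to it but decimation would
discard phase detail), the package computes the Pearson correlation `r` of
the two antagonist envelopes and the coactivation index

$$ CI = \frac{1}{N}\sum_{j=1}^{N} \frac{EMG_{Hj} + EMG_{Lj}}{2}\cdot
        \frac{EMG_{Lj}}{EMG_{Hj}}, $$

where at each sample `j`, `EMG_H` is the higher and `EMG_L` the lower of
the pair. The per-sample (rather than per-muscle) assignment of H and L is
what makes the index symmetric in the two muscles and is the standard
reading of "highest and lowest activity". A sample with `H = 0` contributes
0, the limit for `L -> 0`. The identities `CI(a, a) = mean(a)`,
`CI(a, 0) = 0` and the bounds `mean(L)/2 <= CI <= mean(L)` follow directly
and are asserted in the tests. An undefined correlation (zero variance in a
window) is recorded as missing and excluded from averages — mapping it to 0
would bias group means toward zero. Aggregation averages across MUs within
(subject, pair, side), then across sides, then across subjects.

## The synthetic-data module

The generators define the study conditions under which the pipeline is
validated; they emulate the statistical structure the analysis assumes, not
infant biomechanics.

**Passive sessions.** Alternating flexion/extension phases with durations
drawn from a normal distribution with mean 1.5 s and SD 0.2 s (a 3–4-s
movement cycle), a quiet margin at both ends, and per phase — with
probability 0.7 each by default — a step burst injected into the lengthened
(StR) and/or shortened (ShR) muscle of the moved joint's antagonist pair.
Onsets fall uniformly between 10 % and 50 % of the phase, the band where
such responses concentrate; with a 1.5-s phase this also reproduces the
observed several-hundred-millisecond absolute latencies. Burst durations
are N(0.4, 0.1) s clamped at 0.15 s, truncated at the phase end and
recorded as such. The baseline envelope is 5 µV and bursts 20 µV, matching
the printed µV scale of such recordings.

**Raw EMG synthesis.** Raw signal is zero-mean Gaussian noise amplitude-
modulated by the target envelope profile. This is the minimal model under
which the *real* rectify-and-smooth path recovers the profile in
expectation (up to a 0.6 % small-sample RMS bias), so the full
preprocessing chain is exercised rather than bypassed. The 20-ms RMS of
white noise leaves a dispersion of about 16 % of the local level, which is
what the envelope-level generator's rectified-Gaussian noise scale
(0.8 µV on a 5-µV baseline) mirrors.

**Spontaneous sessions.** Per limb, MU onsets follow a Poisson-like renewal
process (8 per minute by default) thinned to a minimum gap, with durations
N(1.2, 0.4) s — the observed ~6–9 per minute and ~1–1.5 s. Each MU is a
trapezoidal endpoint-speed pulse peaking at 0.5 m/s with 50-ms ramps,
integrated along a jittered axis-aligned direction; with the default
threshold and smoothing, this peak makes the *smoothed* speed cross
0.2 m/s almost exactly at the true onset and offset, so detection accuracy
reflects the detector rather than pulse-shape bias. Small tracking jitter
(0.05 cm SD) emulates residual pose noise. With probability 0.7 an MU is
co-scheduled on another limb (onset jittered ±0.2 s), reproducing the
observed preponderance of overlapped over separated MUs.

**Correlated antagonist envelopes.** During each MU the pair's envelopes
are `baseline + 11 µV * exp(0.8 * Z)` with `Z` a 100-ms-smoothed Gaussian
pair. For bivariate lognormals the Pearson correlation of the exponentials
is `(exp(rho_g s^2) - 1)/(exp(s^2) - 1)` for Gaussian correlation `rho_g`
and log-SD `s`, so the Gaussian correlation achieving a target `rho` is
available in closed form — `rho = 1` yields identical modulation and
exactly unit correlation on the clean profiles. Each output stream draws
from its own substream derived from the master seed, so adding channels or
limbs never perturbs existing ones.

**What the generators do not emulate** — and hence what passing recovery
tests do and do not show about real data: no crosstalk between channels, no
movement artifacts or crying-state noise, no pose-tracker likelihood noise
beyond simple dropout handling, straight-line (not curved or reversing)
movement pulses, and step-shaped rather than physiologically ramped EMG
bursts. Recovery results therefore certify the *rules* (thresholds,
merging, truncation, normalization, index formulas), not robustness to
every artifact of real recordings.

## Numerical choices

* Durations compare as `k/rate` for a run of `k` samples against the
  threshold with a 1e-9 guard in the strict direction, so that a 30-ms run
  at an exact sample count is kept ("at least") while an exactly-100-ms
  response is rejected ("longer than").
* Windowed statistics use cumulative sums; subtractive cancellation is
  negligible at the magnitudes involved (µV envelopes, minutes of data).
* The baseline tolerance `1.2 * floor` carries a 1e-12 relative slack so
  the minimizing window always qualifies regardless of summation order.
* Merging iterates to a fixed point in both detectors; gaps are compared
  in sample counts converted to seconds, never in floating sample indices.
* Result tables are written with 17 significant digits, so every
  reader/writer pair round-trips bit-identically and two runs of the
  pipeline with one seed are byte-identical.

## Validation design and problem sizes

The test suite validates each rule against an independently coded oracle
(direct per-sample summation for the RMS, an exhaustive window scan for the
baseline, an rle-plus-explicit-merge implementation for burst keep/merge, a
per-sample state machine for the MU chain, a literal per-sample evaluation
of the CI formula), and the full chain against generator ground truth. The
sizes were chosen to make the checks sharp while keeping a test run on one
CPU in minutes: all 2^20 supra-threshold patterns of 20 coarse samples for
the burst detector; 200 seeded envelopes for burst recovery (precision and
recall 1, onset error ≤ 10 ms); 100 sessions of 200 phases for occurrence
recovery (within ±0.1 of the injected 0.7 in at least 95); two 75-cycle
sessions for latency recovery (≥ 95 % of mass in the injected 10–50 % band,
mean within 20 ms); five 10-minute sessions for MU recovery (exact counts,
per-MU temporal Jaccard ≥ 0.9); and two 10-minute sessions per setting for
correlation recovery (`rho` of 0, 0.5, 1 within ±0.1).

## Known limitations

* The claim that the alternative MU criteria can only find *more* MUs than
  the main set is true when episodes are separated by more than the main
  merge gap (as in the validation sessions) but false in general: the
  merge gap shrinks from 0.5 to 0.3 s, and two fragments that pass the
  excursion bound only jointly can be lost when no longer merged. The
  package therefore tests the monotonicity property under separated-pulse
  conditions only.
* The union-of-qualifying-windows baseline can include a sliver (≤ ~2 %
  of a window) of burst edges, as discussed above.
* MUs are identified in the camera plane only; out-of-plane motion
  shortens excursions and can lose episodes, exactly as in 2D video
  protocols.
* No artifact rejection or crosstalk correction is attempted; inputs are
  assumed to be pre-screened recordings of awake, non-crying epochs.
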
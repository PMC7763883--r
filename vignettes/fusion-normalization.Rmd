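---
title: "Time-frequency fusion normalization of post-exercise ECG"
author: "ecgfuse"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Time-frequency fusion normalization of post-exercise ECG}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", fig.width = 7)
library(ecgfuse)
```

## The problem

Heartbeat morphology — the shapes of the P wave, QRS complex and T wave in a
single-lead ECG — is stable enough within a person, and variable enough
between people, to serve as a biometric. But the template enrolled at rest
stops matching as soon as the subject exercises: sympathetic activation
shortens the RR interval, and the P and T waves compress toward the R peak,
while the QRS complex is essentially rate-invariant. A probe beat recorded
right after exercise therefore looks like a stranger's beat to any matcher
that compares raw cycle samples.

`ecgfuse` implements a normalization pipeline that maps tachycardic
post-exercise cycles back onto resting morphology before matching:

1. **Time normalization** re-expands the compressed P and T sections by
   uniform neighbor-average sample insertion until they reach the enrollment
   section durations; the QRS section is copied through untouched.
2. **Frequency normalization** applies a zero-phase Butterworth bandpass
   (default 10–80 Hz) to both states, discarding the band where the two
   states disagree most.
3. **Fusion** composes the two: post-exercise cycles are time-normalized and
   then band-filtered; enrollment cycles go through the same (for them,
   nearly neutral) steps so that every cycle lands on one common sample grid.

Around this core sit a seeded synthetic-cohort generator, standard
preprocessing (wideband Butterworth, Pan–Tompkins R detection, QRS-sparing
median smoothing, piecewise-linear baseline removal), fiducial segmentation,
Euclidean similarity evaluation, and a closed-set 1:N identification harness.

## The time normalization scheme

For one wave section of actual duration $t_r$ seconds, target duration $t_n$
and sampling rate $r_s$, the sample counts and insertion count are

$$d_n = \operatorname{round}(r_s t_n), \qquad
  d_r = \operatorname{round}(r_s t_r), \qquad
  N_i = d_n - d_r .$$

The $N_i$ new samples are created at uniformly spaced positions of the
original section,

$$x_i = \operatorname{Int}\!\left(\frac{d_r}{N_i + 1}\right) i + 1,
  \qquad i = 1, \dots, N_i ,$$

and each inserted amplitude is the average of the samples immediately left
and right of the insertion point at application time. `Int` truncates (the
choice is not forced by the scheme; truncation is the conventional reading
and is what the package uses). Three properties follow directly and are
enforced by tests: the original samples survive in order as a subsequence of
the output; every inserted amplitude lies in the closed interval of its two
neighbors; and the QRS section is never touched.

Two completions are needed beyond the stated scheme. When a section is
*longer* than its target ($N_i < 0$) the mirrored positions are deleted
instead — the symmetric counterpart of insertion. When more samples are
requested than one pass can produce ($N_i \ge d_r$, so the step collapses
below 1), the pass is applied repeatedly, each pass inserting at most
$d_r - 1$ samples; this preserves the neighbor-average construction rather
than silently switching to generic resampling. Both paths are exercised by
`resize_wave()`.

## Section boundaries: why the margins are proportional

The section boundaries are: QRS onset `Rls` = R − 50 ms and offset `Rrs` =
R + 60 ms (never rate-scaled — the QRS is rate-invariant); `Pls` left of the
P peak and `Trs` right of the T peak. The margins placing `Pls` and `Trs`
are **fractions of the peak-to-QRS-boundary gap** (defaults 0.5 and 0.65,
about 40 ms and 110 ms at a resting RR of 0.75 s), not fixed offsets in
seconds.

The reason is geometric. Uniform insertion stretches a section linearly, so
it can only align the wave apex between states if the apex sits at the same
*relative* position inside the section before and after exercise. A fixed
absolute margin fails this: the wave-to-QRS gap compresses with heart rate
while the margin does not, so the apex drifts. With a margin proportional to
the gap, the apex position is $c/(1+c)$ of the wave-side span for any
compression — constant by construction. On synthetic cohorts this choice
reduced the post-normalization P-peak misalignment from ~14 ms to ~2 ms.

A residual limitation remains and is worth stating plainly: the *T section*
spans from the rate-invariant `Rrs` to the rate-scaled T offset, so its
overall stretch factor is the boundary-gap ratio, not the RR ratio. Uniform
insertion therefore over-widens the restored T wave by roughly
(gap ratio × RR ratio) — about 20–25% at a 0.75 s → 0.50 s transition. This
is inherent to normalizing a section anchored on the QRS edge; it is the
dominant residual of time-only normalization, and it is exactly the part
that the frequency step of the fusion mode subsequently removes.

## Targets, lengths, and the fusion contract

The target durations $t_n$ are not universal constants; the package derives
them as the mean P and T section durations over the enrollment
(pre-exercise) cycles of the cohort (`tn_scope = "global"`). A per-subject
variant exists, but it yields per-subject cycle lengths and is refused for
cross-subject feature matrices: matching requires every cycle — both states,
all subjects — to share one sample count, and the global target is what
guarantees that. For the same reason the pre-exercise cycles also pass
through the time step in time/fusion modes; since the target *is* their mean
duration, this moves each enrollment cycle by only a few samples.

Modes `"none"` and `"frequency"` operate on the fixed R-centered windows
(0.2 s left, 0.4 s right — equal length by construction); modes `"time"` and
`"fusion"` operate on the resegmented `Pls`–`Trs` cycles brought to the
target grid. The frequency step is applied per cycle in both states: the
mandated order for post-exercise cycles (time, then frequency) forces
per-cycle filtering anyway, and symmetry keeps the two states' filter edge
behavior identical. The band-search helper `select_optimal_band()`
exhaustively scores candidate bands by mean filtered pre/post distance
(ties to the widest band); its default grid is a coarse 4 × 9 lattice over
lows {5..20} and highs {40..120} Hz — a full-resolution grid can be passed
explicitly, the default merely keeps the exhaustive search cheap.

## The synthetic cohort generator

No public paired rest/exercise ECG corpus ships with the package, so all
tests run on a seeded generator that emulates the acquisition protocol of a
rest/stepper-exercise study: per subject and session, one resting record
(default 60 s) and one post-exercise record (default 180 s); tests and the
acceptance script use 30 s / 20 s at 500 Hz, which still yields the 30+
usable cycles per state that the similarity protocol needs while keeping
runtimes in seconds. 2000 Hz is available to mirror clinical hardware.

Each heartbeat is a sum of five Gaussian bumps (P, Q, R, S, T) with
subject-specific amplitudes, widths and centers drawn uniformly from
physiological lead-I ranges: resting RR in 0.70–0.80 s, exercise RR in
0.46–0.54 s, R amplitude 1.0–1.6 mV, P peak 120–150 ms before R, T peak
210–260 ms after R. Tachycardia is encoded literally as the stated
physiology: in the post state the P and T centers *and widths* scale by
RR_post / RR_rest while Q, R, S parameters are untouched, so the QRS is
bit-identical across states. The bumps are truncated to compact ±4 sd
support so that this identity holds to machine precision near the R peak.
Records add white Gaussian noise (default 20 dB SNR) and one sinusoidal
baseline-wander term (0.1 mV at 0.3 Hz, a breathing surrogate); true R-peak
positions are retained as ground truth.

What the generator does **not** emulate — and hence what passing tests do
not certify about real data: beat-to-beat morphological and RR variability,
asymmetric wave shapes with high-frequency content, muscle-artifact and
electrode noise, ectopy, and multi-lead structure. Two consequences are
worth knowing. First, Gaussian P/T waves carry almost no energy above 10 Hz,
so the 10–80 Hz frequency normalization removes nearly the entire
between-state mismatch on synthetic data — it is *more* effective here than
it can be on real ECGs, where the band retains substantial wave content and,
at high heart rates, the next beat's QRS intrudes into the fixed window.
Second, combined with the T-section stretch residual above, this makes
frequency-only normalization score *better* than time-only normalization on
synthetic cohorts, whereas on the real data the method was designed for the
relation is reversed. The fusion mode is the best performer in both worlds,
and the package's stochastic checks therefore pin down the robust relations
(fusion beats no normalization; the fusion similarity-change rate is
positive; fusion never hurts nearest-neighbor identification) rather than
the full four-mode ordering.

## Preprocessing choices

The initial denoising band is Butterworth order 4, 0.5–100 Hz, zero-phase —
wide enough not to pre-empt the 10–80 Hz normalization band. All filters in
the package are zero-phase (forward–backward) so fiducial latencies stay
comparable before and after filtering. The R detector is the classic
Pan–Tompkins chain (5–15 Hz bandpass, derivative, squaring, 150 ms
moving-window integration, adaptive dual thresholds with 0.125/0.25 update
coefficients, 200 ms refractory period, search-back at 1.66 × the running
RR), with detections snapped to the raw-signal maximum within ±50 ms.
Candidate peaks are restricted to integrated-signal maxima that dominate
their 200 ms neighborhood — without this, shoulder ripples on the energy
envelope fire the threshold early and the refractory period then masks the
true peak.

The running median (default 40 ms window) smooths everything *except* a
±60 ms exclusion zone around each R peak: the QRS carries the
subject-specific information and must not be degraded. Baseline drift is
removed by continuous piecewise first-order regression: per inter-beat
segment a line is fitted to isoelectric reference samples (the
T-offset-to-next-P window, [R + 400 ms, next R − 260 ms]; for tachycardic
gaps too short for that absolute window, a proportional late-diastole window
[R + 0.50 RR, R + 0.72 RR] that still clears both the T offset and the next
P onset), adjacent fits are averaged at shared boundaries, and the resulting
continuous piecewise-linear baseline is subtracted. Cycles whose P/T
fiducial detection is flagged low-confidence (flat search window, apex on a
window edge) are dropped, never imputed, and counted.

## Identification harness

Features are whole normalized cycles, concatenated into blocks of
consecutive cycles per subject/state/session. Enrollment is *all*
pre-exercise observations, recognition is all post-exercise observations —
no cross-validation, mirroring the enrollment/probe asymmetry of a biometric
deployment. Dimensionality reduction is a Fisher discriminant projection
fitted on enrollment only (at most C − 1 dimensions), with a shrinkage ridge
added when the within-class scatter is singular, and the discriminant
directions sphered to unit pooled within-class variance so distance-based
classifiers downstream are well scaled. Classifiers: 1-nearest-neighbor and
an RBF SVM (the literature-style `gamma = 100`, `cost = 10` defaults are
kept in `classifier_spec()`, but `gamma = NULL` defers to the SVM library's
own scaling heuristics, which behave far better on discriminant features); a
shallow single-hidden-layer autoencoder with 1-NN matching in code space
(a reduced stand-in for a stacked design — no deep-learning backend is
bundled); and an `lstm` kind that dispatches to a user-supplied backend
function. Metrics pool the one-vs-rest confusion counts (micro-averaging):
note that pooled "accuracy" over class-wise binary decisions is more
forgiving than the plain fraction correct for more than two classes, so the
report carries both (`accuracy` and `accuracy_simple`), and micro
precision/recall/F1 all coincide with the fraction correct.

## Numerical conventions

Sections are half-open `[start, end)` except the T section, closed at `Trs`;
CSV writers emit 0-based indices and document it. Cycle distance is the
plain Euclidean norm of the sample difference on amplitude-unscaled mV
cycles — no amplitude normalization anywhere, matching the method's scope
(time and frequency only). The similarity-change rate between an
unnormalized and a normalized report is the mean over the cycle-count grid
{5, 10, …, 30} of the pointwise relative distance drop, in percent; this
reconstruction of the usual summary row is labeled as such. Subject pairing
for similarity is i-th cycle against i-th cycle (an all-pairs mean is
available); grid points with zero unnormalized distance are excluded rather
than divided by. All randomness flows from explicit seeds; identical
configurations reproduce cohorts bit-exactly.

## A worked example

```{r example, eval = FALSE}
cfg <- cohort_config(n_subjects = 10, n_sessions = 1,
                     duration_pre = 30, duration_post = 20,
                     rs = 500, snr_db = 20, seed = 1)
prep <- prepare_cohort(synth_cohort(cfg))

sets <- lapply(c(none = "none", fusion = "fusion"), function(m)
  normalize_cycles(prep, normalization_spec(rs = 500, mode = m)))

state <- function(s, st) {
  keep <- s$meta$state == st
  cycle_set(s$cycles[keep, ], s$meta[keep, ], s$rs, s$mode)
}
for (m in names(sets))
  cat(m, "mean pre/post distance (30 cycles):",
      round(as.numeric(average_similarity(state(sets[[m]], "pre"),
                                          state(sets[[m]], "post"), 30)), 3), "\n")

identify_cohort(sets$fusion, classifier_spec("knn"), block_size = 2)
```

The distances shrink by roughly a factor of eight under fusion, and the
nearest-neighbor identification report shows the corresponding jump in the
fraction of post-exercise probes assigned to the right enrolled identity.
`scripts/acceptance.R` runs this experiment at full scale (10 seeded
20-subject cohorts) and writes every headline number it computes to JSON.

## Known limitations

- The T-section stretch residual discussed above: time-only normalization
  cannot fully restore the T-wave width when the section is anchored at the
  rate-invariant QRS offset.
- Deletion (for sections longer than target) and multi-pass expansion are
  principled completions of the insertion scheme, but repeated passes
  compound the local linearization error; extreme expansions (beyond ~2×)
  are increasingly smoothed.
- The recognition harness is closed-set only: every probe is assigned to
  some enrolled identity; there is no impostor rejection, FAR/FRR or EER.
- Synthetic validation bounds what can be claimed about real ECGs, as
  detailed in the generator section.
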
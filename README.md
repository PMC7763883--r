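# ecgfuse

Time–frequency fusion normalization of post-exercise ECG cycles for
heartbeat-based user identification.

## The problem

Single-lead ECG morphology — the P wave, QRS complex and T wave of one
heartbeat — works as a biometric: stable within a person, distinctive
between people. It stops working right after exercise. Tachycardia shortens
the RR interval and compresses the P and T waves toward the R peak while
leaving the QRS shape essentially unchanged, so post-exercise probe beats no
longer match the resting template enrolled for each user. `ecgfuse` is for
researchers in biometric and physiological signal processing who need that
mismatch corrected before matching — and who need a fully seeded synthetic
test bed to validate the pipeline without access to a paired rest/exercise
ECG corpus.

## The method

Each accepted heartbeat is resegmented from `Pls` (left of the P peak) to
`Trs` (right of the T peak) and split into P = [Pls, Rls), QRS = [Rls, Rrs),
T = [Rrs, Trs] sections. **Time normalization** expands a compressed section
of duration *t_r* to the enrollment target *t_n* by uniform linear data
interpolation: with sampling rate *r_s*,

    dn = round(rs * tn),   dr = round(rs * tr),   Ni = dn - dr
    x_i = Int(dr / (Ni + 1)) * i + 1,   i = 1..Ni
    v   = (left neighbor + right neighbor) / 2

inserting `Ni` neighbor-average samples at the uniformly spaced positions
`x_i`; the QRS section is copied through bit-exactly. **Frequency
normalization** is a zero-phase Butterworth bandpass (default 10–80 Hz, with
an exhaustive optimal-band search available). **Fusion** applies time
normalization and then the bandpass to post-exercise cycles, and the (for
them nearly neutral) same steps to enrollment cycles, so every cycle of
every subject and state shares one sample grid.

Around the core: a seeded sum-of-Gaussians generator of paired rest/exercise
cohorts with ground-truth R peaks; Butterworth denoising, Pan–Tompkins
R-peak detection, QRS-sparing median smoothing and piecewise-linear baseline
removal; Euclidean cycle-similarity evaluation (mean distance vs. number of
cycles, similarity-change rate); and a closed-set 1:N identification harness
(Fisher discriminant reduction with shrinkage, k-NN / SVM / shallow
autoencoder, precision–recall–F1–accuracy reports).

## Worked example

Ten synthetic subjects, one session, resting and post-exercise records;
compare matching with no normalization and with fusion normalization:

```r
library(ecgfuse)

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

Output:

```
none mean pre/post distance (30 cycles): 2.421
fusion mean pre/post distance (30 cycles): 0.304
Closed-set identification report
  counts: TP 160  TN 1696  FP 32  FN 32
  precision 0.8333  recall 0.8333  F1 0.8333  accuracy 0.9667
  fraction correct 0.8333
```

The mean Euclidean distance between paired pre/post cycles drops by a
factor of eight under fusion normalization, and 83% of post-exercise
2-cycle probes are assigned to the correct enrolled identity (k-NN, K = 1,
after discriminant reduction); on the same cohort without normalization the
fraction correct is around 10%.

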
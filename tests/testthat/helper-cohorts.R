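# Shared synthetic cohorts, built once per test run. The acceptance checks
# and several module tests work from the same study conditions: 20 subjects,
# resting RR centered on 0.75 s, exercise RR centered on 0.50 s, 20 dB SNR.
# Record durations are kept at 30 s (pre) / 20 s (post), enough for > 30
# usable cycles per state at 500 Hz while keeping the suite fast.

.cohort_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .cohort_cache))
    assign(key, expr, envir = .cohort_cache)
  get(key, envir = .cohort_cache)
}

study_config <- function(seed, n_subjects = 20, n_sessions = 1) {
  cohort_config(n_subjects = n_subjects, n_sessions = n_sessions,
                duration_pre = 30, duration_post = 20,
                rs = 500, snr_db = 20, seed = seed)
}

study_prep <- function(seed, n_subjects = 20) {
  cached(sprintf("prep_%d_%d", seed, n_subjects), {
    prepare_cohort(synth_cohort(study_config(seed, n_subjects)))
  })
}

study_set <- function(seed, mode, n_subjects = 20) {
  cached(sprintf("set_%d_%s_%d", seed, mode, n_subjects), {
    normalize_cycles(study_prep(seed, n_subjects),
                     normalization_spec(rs = 500, mode = mode))
  })
}

pre_of <- function(set) ecgfuse:::subset_cycles(set, set$meta$state == "pre")
post_of <- function(set) ecgfuse:::subset_cycles(set, set$meta$state == "post")
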
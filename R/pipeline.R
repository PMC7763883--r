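#' Extract per-beat cycles and wave splits from one record
#'
#' Runs the preprocessing chain, cuts fixed-window cycles around the detected
#' R peaks, locates the P/T fiducials and resegments each accepted cycle into
#' its P / QRS / T sections. Cycles whose fiducial detection is flagged
#' low-confidence are dropped (never imputed) and counted.
#'
#' @param rec an [ecg_record()].
#' @param ... passed to [preprocess_record()].
#' @return List with `segments` (fixed-window `cycle_segment`s of accepted
#'   cycles), `splits` (matching `wave_split`s), `fiducials`, `peaks`, and
#'   `n_dropped`.
#' @export
extract_cycles <- function(rec, ...) {
  pr <- preprocess_record(rec, ...)
  segs <- segment_cycles(pr$samples, pr$peaks, pr$rs)
  keep_segs <- list(); splits <- list(); fids <- list()
  dropped <- 0L
  for (seg in segs) {
    fid <- detect_p_t_peaks(seg)
    if (!isTRUE(fid$ok)) { dropped <- dropped + 1L; next }
    keep_segs[[length(keep_segs) + 1L]] <- seg
    splits[[length(splits) + 1L]] <- resegment_and_split(seg, fid)
    fids[[length(fids) + 1L]] <- fid
  }
  list(segments = keep_segs, splits = splits, fiducials = fids,
       peaks = pr$peaks, n_dropped = dropped + attr(segs, "n_skipped"))
}

#' Prepare a cohort for normalization and matching
#'
#' Applies [extract_cycles()] to every record and tags each accepted cycle
#' with its subject / state / session.
#'
#' @param cohort an `ecg_cohort` from [synth_cohort()], or any list of
#'   `ecg_record`s.
#' @param ... passed to [extract_cycles()].
#' @return A `cohort_cycles` object: list of per-record entries, each with
#'   `subject`, `state`, `session`, `segments`, `splits`.
#' @export
prepare_cohort <- function(cohort, ...) {
  records <- if (inherits(cohort, "ecg_cohort")) cohort$records else cohort
  rs <- records[[1]]$rs
  out <- lapply(records, function(rec) {
    ex <- extract_cycles(rec, ...)
    list(subject = rec$subject, state = rec$state, session = rec$session,
         segments = ex$segments, splits = ex$splits, n_dropped = ex$n_dropped)
  })
  structure(list(entries = out, rs = rs), class = "cohort_cycles")
}

#' A set of equal-length cycles with per-cycle metadata
#'
#' @param cycles numeric matrix, one cycle per row (mV).
#' @param meta data frame with columns `subject`, `state`, `session`, `cycle`.
#' @param rs sampling rate.
#' @param mode the normalization mode that produced the set.
#' @return Object of class `cycle_set`.
#' @export
cycle_set <- function(cycles, meta, rs, mode = "none") {
  cycles <- as.matrix(cycles)
  stopifnot(nrow(cycles) == nrow(meta))
  structure(list(cycles = cycles, meta = meta, rs = rs, mode = mode),
            class = "cycle_set")
}

#' @export
print.cycle_set <- function(x, ...) {
  cat(sprintf("Cycle set (%s): %d cycles x %d samples @ %g Hz, %d subjects\n",
              x$mode, nrow(x$cycles), ncol(x$cycles), x$rs,
              length(unique(x$meta$subject))))
  invisible(x)
}

## Resolve the target section durations from enrollment (pre-exercise) splits.
resolve_tn <- function(pre_splits, spec, scope = "global", subjects = NULL) {
  if (!is.null(spec$tn_p) && !is.null(spec$tn_t)) {
    return(list(tn_p = function(s) spec$tn_p, tn_t = function(s) spec$tn_t))
  }
  trp <- vapply(pre_splits, function(s) s$tr_p, numeric(1))
  trt <- vapply(pre_splits, function(s) s$tr_t, numeric(1))
  if (scope == "global") {
    mp <- mean(trp); mt <- mean(trt)
    list(tn_p = function(s) mp, tn_t = function(s) mt)
  } else {
    stopifnot(!is.null(subjects))
    mp <- tapply(trp, subjects, mean); mt <- tapply(trt, subjects, mean)
    list(tn_p = function(s) mp[[s]], tn_t = function(s) mt[[s]])
  }
}

#' Fusion / time / frequency normalization of paired cycle collections
#'
#' The fusion scheme matches post-exercise cycles to pre-exercise morphology:
#' the tachycardia-compressed P and T sections of each post cycle are expanded
#' to the enrollment target durations by linear data interpolation (time
#' step), and the result is bandpass-filtered to the normalization band
#' (frequency step). Pre-exercise cycles pass through the frequency step, and
#' — so that every cycle lands on one common sample grid — are also
#' interpolated to the same target durations (for cycles already at the
#' enrollment mean this is an adjustment of a few samples). Mode `"time"`
#' skips the bandpass; mode `"frequency"` skips the interpolation and instead
#' filters the fixed-window cycles.
#'
#' @param pre_splits,post_splits lists of `wave_split` objects (modes `time` /
#'   `fusion`), or matrices of equal-length fixed-window cycles (mode
#'   `frequency`).
#' @param spec a [normalization_spec()]. `tn_p`/`tn_t` of `NULL` are resolved
#'   as the mean pre-exercise section durations.
#' @return List with `pre` and `post` cycle matrices (one common column
#'   count) and the resolved `spec`.
#' @export
fusion_normalize <- function(pre_splits, post_splits, spec) {
  stopifnot(inherits(spec, "normalization_spec"))
  rs <- spec$rs
  if (spec$mode == "frequency") {
    pre <- as.matrix(pre_splits); post <- as.matrix(post_splits)
    pre <- t(apply(pre, 1, frequency_normalize, rs = rs, band = spec$band))
    post <- t(apply(post, 1, frequency_normalize, rs = rs, band = spec$band))
    return(list(pre = pre, post = post, spec = spec))
  }
  if (!spec$mode %in% c("time", "fusion"))
    stop("fusion_normalize handles modes frequency, time and fusion", call. = FALSE)
  tn <- resolve_tn(pre_splits, spec)
  spec$tn_p <- tn$tn_p(NULL); spec$tn_t <- tn$tn_t(NULL)
  norm1 <- function(split) {
    y <- time_normalize_cycle(split, spec)
    if (spec$mode == "fusion") frequency_normalize(as.numeric(y), rs, spec$band)
    else as.numeric(y)
  }
  pre <- do.call(rbind, lapply(pre_splits, norm1))
  post <- do.call(rbind, lapply(post_splits, norm1))
  list(pre = pre, post = post, spec = spec)
}

#' Normalize a prepared cohort under one mode
#'
#' Dispatches on the normalization mode and returns equal-length cycle
#' matrices with metadata. Modes `"none"` and `"frequency"` operate on the
#' fixed 0.6 s R-centered windows (equal length by construction); modes
#' `"time"` and `"fusion"` operate on the resegmented Pls-Trs cycles brought
#' to the enrollment target durations.
#'
#' @param prep a `cohort_cycles` from [prepare_cohort()].
#' @param spec a [normalization_spec()].
#' @param tn_scope `"global"` (one target across the cohort; default, which
#'   guarantees one common cycle length for matching) or `"subject"`.
#' @return A single [cycle_set()] containing both states.
#' @export
normalize_cycles <- function(prep, spec, tn_scope = c("global", "subject")) {
  stopifnot(inherits(prep, "cohort_cycles"), inherits(spec, "normalization_spec"))
  tn_scope <- match.arg(tn_scope)
  rs <- prep$rs
  meta_of <- function(e, n) if (n == 0) NULL else
    data.frame(subject = e$subject, state = e$state, session = e$session,
               cycle = seq_len(n), stringsAsFactors = FALSE)

  if (spec$mode %in% c("none", "frequency")) {
    rows <- list(); metas <- list()
    for (e in prep$entries) {
      if (!length(e$segments)) next
      m <- do.call(rbind, lapply(e$segments, function(s) s$samples))
      if (spec$mode == "frequency")
        m <- t(apply(m, 1, frequency_normalize, rs = rs, band = spec$band))
      rows[[length(rows) + 1L]] <- m
      metas[[length(metas) + 1L]] <- meta_of(e, nrow(m))
    }
    return(cycle_set(do.call(rbind, rows), do.call(rbind, metas), rs, spec$mode))
  }

  ## time / fusion: resolve tn from pre-state splits, then normalize everything
  all_splits <- list(); meta <- list()
  for (e in prep$entries) {
    for (s in e$splits) all_splits[[length(all_splits) + 1L]] <- s
    meta[[length(meta) + 1L]] <- meta_of(e, length(e$splits))
  }
  meta <- do.call(rbind, meta)
  pre_idx <- meta$state == "pre"
  tn <- resolve_tn(all_splits[pre_idx], spec, tn_scope, meta$subject[pre_idx])
  rows <- vector("list", length(all_splits))
  for (i in seq_along(all_splits)) {
    sp <- spec
    sp$tn_p <- tn$tn_p(meta$subject[i]); sp$tn_t <- tn$tn_t(meta$subject[i])
    y <- as.numeric(time_normalize_cycle(all_splits[[i]], sp))
    if (spec$mode == "fusion") y <- frequency_normalize(y, rs, spec$band)
    rows[[i]] <- y
  }
  if (tn_scope == "global")
    rows <- do.call(rbind, rows)
  else {
    # per-subject targets give per-subject lengths; pad is refused — callers
    # comparing across subjects must use the global scope
    len <- vapply(rows, length, integer(1))
    if (length(unique(len)) > 1L)
      return(structure(list(rows = rows, meta = meta, rs = rs, mode = spec$mode),
                       class = "cycle_list"))
    rows <- do.call(rbind, rows)
  }
  cycle_set(rows, meta, rs, spec$mode)
}

## Convenience: subset a cycle_set by metadata predicate.
subset_cycles <- function(set, keep) {
  cycle_set(set$cycles[keep, , drop = FALSE], set$meta[keep, , drop = FALSE],
            set$rs, set$mode)
}
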
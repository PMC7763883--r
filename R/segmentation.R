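#' Cut fixed-window cycles around R peaks
#'
#' One cycle per R peak, spanning `round(0.2 * rs)` samples to the left of the
#' R peak (the P-wave side) and `round(0.4 * rs)` samples to the right (the
#' T-wave side). Peaks too close to the record edges are skipped; the skipped
#' count is reported in the `n_skipped` attribute.
#'
#' @param x numeric signal.
#' @param peaks an [r_peak_annotation()].
#' @param rs sampling rate.
#' @return A list of `cycle_segment` objects: numeric samples with fields
#'   `r_index` (1-based index of R within the segment) and `rs`.
#' @export
segment_cycles <- function(x, peaks, rs) {
  stopifnot(inherits(peaks, "r_peak_annotation"))
  left <- round(0.2 * rs)
  right <- round(0.4 * rs)
  # record-level heart rate, carried on each segment so downstream boundary
  # placement can scale with the tachycardic compression
  rr <- if (length(peaks$indices) >= 2)
    stats::median(diff(peaks$indices)) / rs else NA_real_
  segs <- list()
  skipped <- 0L
  for (r in peaks$indices) {
    if (r - left < 1L || r + right - 1L > length(x)) { skipped <- skipped + 1L; next }
    seg <- structure(list(samples = x[(r - left):(r + right - 1L)],
                          r_index = left + 1L, rs = rs, r_source = r, rr = rr),
                     class = "cycle_segment")
    segs[[length(segs) + 1L]] <- seg
  }
  attr(segs, "n_skipped") <- skipped
  segs
}

#' Locate P and T peaks and section boundaries within a cycle
#'
#' The P peak is the maximum of the sub-window left of the nominal QRS onset
#' (`Rls = R - 50 ms`); the T peak is the maximum right of the nominal QRS
#' offset (`Rrs = R + 60 ms`). Section boundaries are anchored
#' proportionally to the wave's own geometry: `Pls` sits `p_frac` times the
#' P-peak-to-Rls gap left of the P peak, and `Trs` sits `t_frac` times the
#' Rrs-to-T-peak gap right of the T peak (both clamped to the segment).
#' Because tachycardia compresses the wave and its onset/offset span
#' together, a proportional margin keeps the wave apex at a constant
#' relative position inside its section across heart rates — which is what
#' lets the uniform insertion of the time normalization align the waves. A
#' fixed absolute margin (in seconds) would shift the apex between states.
#' The QRS boundaries never scale: the QRS complex is rate-invariant. A flat
#' search window, or a maximum sitting on a window edge, marks the cycle
#' low-confidence.
#'
#' @param seg a `cycle_segment` from [segment_cycles()].
#' @param qrs_onset,qrs_offset QRS half-widths in seconds defining Rls/Rrs
#'   (never rate-scaled).
#' @param p_frac,t_frac Pls/Trs margins as fractions of the peak-to-QRS-
#'   boundary gap. The defaults correspond to roughly 40 ms before the P
#'   peak and 110 ms after the T peak at a resting RR of 0.75 s.
#' @return A `fiducial_set`: list with 1-based indices `pls, p_peak, rls,
#'   r_peak, rrs, t_peak, trs` and a logical `ok`.
#' @export
detect_p_t_peaks <- function(seg, qrs_onset = 0.05, qrs_offset = 0.06,
                             p_frac = 0.5, t_frac = 0.65) {
  stopifnot(inherits(seg, "cycle_segment"))
  x <- seg$samples; rs <- seg$rs; r <- seg$r_index
  n <- length(x)
  rls <- r - round(qrs_onset * rs)
  rrs <- r + round(qrs_offset * rs)
  ok <- TRUE
  flat <- function(w) diff(range(w)) < 1e-9
  p_win <- 1:(rls - 1L)
  t_win <- (rrs + 1L):n
  if (rls <= 2L || rrs >= n - 1L || flat(x[p_win]) || flat(x[t_win])) {
    return(structure(list(ok = FALSE), class = "fiducial_set"))
  }
  p_peak <- p_win[which.max(x[p_win])]
  t_peak <- t_win[which.max(x[t_win])]
  # an argmax on the inner window edge means the wave's apex is not resolved
  if (p_peak == rls - 1L || t_peak == rrs + 1L) ok <- FALSE
  pls <- max(1L, p_peak - round(p_frac * (rls - p_peak)))
  trs <- min(n, t_peak + round(t_frac * (t_peak - rrs)))
  fid <- list(pls = pls, p_peak = p_peak, rls = rls, r_peak = r,
              rrs = rrs, t_peak = t_peak, trs = trs, ok = ok)
  if (ok && !(pls < p_peak && p_peak < rls && rls < r && r < rrs &&
              rrs < t_peak && t_peak < trs))
    fid$ok <- FALSE
  structure(fid, class = "fiducial_set")
}

#' Resegment one cycle from Pls to Trs and split it into P / QRS / T sections
#'
#' Sections are contiguous half-open runs of the resegmented cycle:
#' P = `[Pls, Rls)`, QRS = `[Rls, Rrs)`, T = `[Rrs, Trs]` — so their
#' concatenation reproduces the resegmented cycle exactly.
#'
#' @param seg a `cycle_segment`.
#' @param fid a `fiducial_set` from [detect_p_t_peaks()] with `ok = TRUE`.
#' @return A `wave_split`: list with numeric sections `p`, `qrs`, `t`, their
#'   durations `tr_p` and `tr_t` in seconds, and `rs`.
#' @export
resegment_and_split <- function(seg, fid) {
  stopifnot(inherits(seg, "cycle_segment"), inherits(fid, "fiducial_set"))
  if (!isTRUE(fid$ok))
    stop("fiducial set flagged low-confidence; cycle excluded", call. = FALSE)
  ord <- c(pls = fid$pls, p_peak = fid$p_peak, rls = fid$rls, r_peak = fid$r_peak,
           rrs = fid$rrs, t_peak = fid$t_peak, trs = fid$trs)
  if (is.unsorted(ord, strictly = TRUE)) {
    bad <- which(diff(ord) <= 0)[1]
    stop(sprintf("fiducial ordering violated between %s and %s",
                 names(ord)[bad], names(ord)[bad + 1]), call. = FALSE)
  }
  x <- seg$samples
  p <- x[fid$pls:(fid$rls - 1L)]
  qrs <- x[fid$rls:(fid$rrs - 1L)]
  t <- x[fid$rrs:fid$trs]
  structure(list(p = p, qrs = qrs, t = t,
                 tr_p = length(p) / seg$rs, tr_t = length(t) / seg$rs,
                 rs = seg$rs),
            class = "wave_split")
}

#' @export
print.wave_split <- function(x, ...) {
  cat(sprintf("Wave split @ %g Hz: P %d samples (%.0f ms), QRS %d, T %d (%.0f ms)\n",
              x$rs, length(x$p), 1000 * x$tr_p, length(x$qrs),
              length(x$t), 1000 * x$tr_t))
  invisible(x)
}

## Reassemble a split into the full resegmented cycle.
split_to_cycle <- function(split) c(split$p, split$qrs, split$t)
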
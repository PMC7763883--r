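#' Bandpass filter specification
#'
#' @param low,high cutoff frequencies in Hz, `0 < low < high`.
#' @param order Butterworth order (>= 1).
#' @param zero_phase apply forward-backward (no group delay)? Default TRUE:
#'   all filtering in this package is zero-phase so fiducial latencies stay
#'   comparable before and after filtering.
#' @return An object of class `filter_spec`.
#' @export
filter_spec <- function(low, high, order = 4L, zero_phase = TRUE) {
  stop_if_not_scalar_pos(low, "low")
  stop_if_not_scalar_pos(high, "high")
  if (low >= high) stop("low cutoff must be below high cutoff", call. = FALSE)
  if (order < 1) stop("order must be >= 1", call. = FALSE)
  structure(list(low = low, high = high, order = as.integer(order),
                 zero_phase = isTRUE(zero_phase)),
            class = "filter_spec")
}

#' Butterworth bandpass filtering
#'
#' @param x numeric signal.
#' @param rs sampling rate (samples/s).
#' @param spec a [filter_spec()]; default is the wide 0.5-100 Hz denoising
#'   band used ahead of R-peak detection.
#' @return Filtered signal, same length as `x`.
#' @export
bandpass <- function(x, rs, spec = filter_spec(0.5, 100)) {
  stop_if_not_scalar_pos(rs, "rs")
  stopifnot(inherits(spec, "filter_spec"))
  if (spec$high >= rs / 2)
    stop(sprintf("high cutoff %g Hz must be below the Nyquist frequency %g Hz",
                 spec$high, rs / 2), call. = FALSE)
  if (length(x) <= 3 * spec$order)
    stop("signal too short for the requested filter order", call. = FALSE)
  bt <- signal::butter(spec$order, c(spec$low, spec$high) / (rs / 2), type = "pass")
  if (spec$zero_phase) signal::filtfilt(bt, x) else
    as.numeric(signal::filter(bt, x))
}

#' R-peak annotation
#'
#' @param indices strictly increasing 1-based sample indices of R peaks.
#' @param rs sampling rate.
#' @return Object of class `r_peak_annotation`.
#' @export
r_peak_annotation <- function(indices, rs) {
  stop_if_not_scalar_pos(rs, "rs")
  indices <- as.integer(indices)
  if (is.unsorted(indices, strictly = TRUE))
    stop("R-peak indices must be strictly increasing", call. = FALSE)
  if (length(indices) >= 2 && min(diff(indices)) < 0.2 * rs)
    stop("R-peak spacing violates the 200 ms refractory period", call. = FALSE)
  structure(list(indices = indices, rs = rs), class = "r_peak_annotation")
}

#' @export
print.r_peak_annotation <- function(x, ...) {
  cat(sprintf("%d R peaks @ %g Hz", length(x$indices), x$rs))
  if (length(x$indices) >= 2)
    cat(sprintf(" (mean RR %.0f ms)", mean(diff(x$indices)) / x$rs * 1000))
  cat("\n")
  invisible(x)
}

#' Pan-Tompkins R-peak detection
#'
#' The classic 1985 chain: 5-15 Hz bandpass, derivative, squaring, 150 ms
#' moving-window integration, then adaptive signal/noise thresholds with
#' 0.125/0.25 update coefficients, a 200 ms refractory period, and search-back
#' at 1.66 x the running RR estimate. Each accepted detection is finally
#' snapped to the raw-signal local maximum within +/-50 ms.
#'
#' @param x numeric signal (ideally already wideband-filtered).
#' @param rs sampling rate; must resolve the 5-15 Hz band and >= 2 s of signal
#'   are required.
#' @return An [r_peak_annotation()]; empty when nothing crosses threshold.
#' @export
detect_r_peaks <- function(x, rs) {
  stop_if_not_scalar_pos(rs, "rs")
  if (length(x) < 2 * rs)
    stop("need at least 2 s of signal", call. = FALSE)
  if (rs < 40)
    stop("sampling rate too low for the derivative kernel", call. = FALSE)

  f <- bandpass(x, rs, filter_spec(5, 15, order = 2))
  d <- c(0, diff(f)) * rs
  sq <- d^2
  w <- max(3L, round(0.150 * rs))
  mwi <- stats::filter(sq, rep(1 / w, w), sides = 2)
  mwi[is.na(mwi)] <- 0
  mwi <- as.numeric(mwi)

  # candidate peaks of the integrated signal: local maxima that dominate
  # their 200 ms neighborhood (one candidate per QRS energy burst)
  n <- length(mwi)
  refr <- as.integer(round(0.2 * rs))
  cand_all <- which(diff(sign(diff(mwi))) < 0) + 1L
  if (!length(cand_all)) return(r_peak_annotation(integer(0), rs))
  ord <- cand_all[order(mwi[cand_all], decreasing = TRUE)]
  taken <- logical(n)
  sel <- integer(0)
  for (i in ord) {
    lo <- max(1L, i - refr + 1L); hi <- min(n, i + refr - 1L)
    if (!any(taken[lo:hi])) { sel <- c(sel, i); taken[i] <- TRUE }
  }
  cand <- sort(sel)
  spki <- 0.25 * max(mwi[seq_len(min(n, 2 * rs))])
  npki <- 0.5 * mean(mwi[seq_len(min(n, 2 * rs))])
  thr1 <- function() npki + 0.25 * (spki - npki)

  beats <- integer(0)
  rr_hist <- numeric(0)
  missed <- function(i) {
    # search-back: strongest candidate above the lower threshold in the gap
    lo <- if (length(beats)) beats[length(beats)] + refr else 1L
    gap <- cand[cand > lo & cand < i]
    if (!length(gap)) return(NA_integer_)
    g <- gap[mwi[gap] > 0.5 * thr1()]
    if (!length(g)) return(NA_integer_)
    g[which.max(mwi[g])]
  }
  for (i in cand) {
    pk <- mwi[i]
    if (length(beats) && (i - beats[length(beats)]) < refr) next
    if (pk > thr1()) {
      # search-back first if we overshot 1.66x the running RR
      if (length(rr_hist) >= 2 && length(beats)) {
        rr_avg <- mean(utils::tail(rr_hist, 8))
        if ((i - beats[length(beats)]) > 1.66 * rr_avg) {
          sb <- missed(i)
          if (!is.na(sb) && (i - sb) >= refr && (sb - beats[length(beats)]) >= refr) {
            beats <- c(beats, sb)
            rr_hist <- c(rr_hist, diff(utils::tail(beats, 2)))
            spki <- 0.25 * mwi[sb] + 0.75 * spki
          }
        }
      }
      if (length(beats)) rr_hist <- c(rr_hist, i - beats[length(beats)])
      beats <- c(beats, i)
      spki <- 0.125 * pk + 0.875 * spki
    } else {
      npki <- 0.125 * pk + 0.875 * npki
    }
  }
  if (!length(beats)) return(r_peak_annotation(integer(0), rs))

  # snap to the raw-signal local maximum within +/-50 ms
  half <- as.integer(round(0.05 * rs))
  snapped <- vapply(beats, function(b) {
    lo <- max(1L, as.integer(b) - half); hi <- min(length(x), as.integer(b) + half)
    lo + which.max(x[lo:hi]) - 1L
  }, integer(1))
  snapped <- sort(unique(snapped))
  # enforce refractory on the snapped indices (keep the larger raw peak)
  if (length(snapped) >= 2) {
    keep <- rep(TRUE, length(snapped))
    last <- 1L
    for (k in seq_along(snapped)[-1]) {
      if (snapped[k] - snapped[last] < refr) {
        if (x[snapped[k]] > x[snapped[last]]) { keep[last] <- FALSE; last <- k }
        else keep[k] <- FALSE
      } else last <- k
    }
    snapped <- snapped[keep]
  }
  r_peak_annotation(snapped, rs)
}

#' Running-median smoothing that spares the QRS complexes
#'
#' Applies a running median everywhere except within an exclusion zone around
#' each R peak (default R +/- 60 ms), whose samples are copied through
#' unmodified — the QRS carries the subject-specific information and must not
#' be smoothed.
#'
#' @param x numeric signal.
#' @param peaks an [r_peak_annotation()].
#' @param rs sampling rate.
#' @param window median window in seconds; windows shorter than 3 samples
#'   leave the signal unchanged.
#' @param exclude_halfwidth half-width of the QRS exclusion zone in seconds.
#' @return Smoothed signal, same length.
#' @export
median_smooth_excluding_qrs <- function(x, peaks, rs, window = 0.06,
                                        exclude_halfwidth = 0.06) {
  stopifnot(inherits(peaks, "r_peak_annotation"))
  k <- round(window * rs)
  if (k < 3) return(x)
  if (k %% 2 == 0) k <- k + 1L
  if (k > length(x)) return(x)
  sm <- as.numeric(stats::runmed(x, k, endrule = "median"))
  half <- round(exclude_halfwidth * rs)
  for (r in peaks$indices) {
    lo <- max(1L, r - half); hi <- min(length(x), r + half)
    sm[lo:hi] <- x[lo:hi]
  }
  sm
}

#' Baseline-drift removal by continuous piecewise first-order regression
#'
#' For each inter-beat segment a straight line is fitted to the segment's
#' isoelectric reference samples (the late-diastole window between the end of
#' the T wave and the onset of the next P wave). Adjacent fits are evaluated
#' at their shared boundary and averaged, and the baseline is the continuous
#' piecewise-linear curve through those boundary values, extended with the
#' first/last fit's slope beyond the outermost beats. The baseline is
#' subtracted from the signal.
#'
#' @param x numeric signal.
#' @param peaks an [r_peak_annotation()] with at least 2 peaks.
#' @param rs sampling rate.
#' @param iso_start offset after each R peak where the isoelectric window
#'   opens (s).
#' @param iso_end margin before the next R peak where the window closes (s).
#' @return Detrended signal, same length.
#' @export
remove_baseline_drift <- function(x, peaks, rs, iso_start = 0.40,
                                  iso_end = 0.26) {
  stopifnot(inherits(peaks, "r_peak_annotation"))
  p <- peaks$indices
  if (length(p) < 2) stop("need at least 2 R peaks", call. = FALSE)
  n <- length(x)

  nseg <- length(p) - 1L
  fits <- vector("list", nseg)
  for (k in seq_len(nseg)) {
    lo <- p[k] + round(iso_start * rs)
    hi <- p[k + 1] - round(iso_end * rs)
    if (hi - lo < 4L) {
      # tachycardic gap too short for the absolute window: fall back to a
      # proportional late-diastole window that clears both the T offset and
      # the next beat's P onset
      rrk <- p[k + 1] - p[k]
      lo <- p[k] + round(0.50 * rrk)
      hi <- p[k] + round(0.72 * rrk)
    }
    lo <- max(1L, lo); hi <- min(n, hi)
    idx <- lo:hi
    cf <- stats::lm.fit(cbind(1, idx), x[idx])$coefficients
    fits[[k]] <- cf
  }
  eval_fit <- function(k, at) fits[[k]][1] + fits[[k]][2] * at

  # baseline value at each beat boundary: average of the two adjacent fits
  knots_x <- p
  knots_y <- numeric(length(p))
  knots_y[1] <- eval_fit(1, p[1])
  knots_y[length(p)] <- eval_fit(nseg, p[length(p)])
  if (length(p) > 2)
    for (k in 2:(length(p) - 1))
      knots_y[k] <- (eval_fit(k - 1, p[k]) + eval_fit(k, p[k])) / 2

  base <- stats::approx(knots_x, knots_y, xout = seq_len(n), rule = 2)$y
  # extend the outer segments with their fitted slope instead of a constant
  if (p[1] > 1) {
    idx <- 1:(p[1] - 1)
    base[idx] <- knots_y[1] + fits[[1]][2] * (idx - p[1])
  }
  if (p[length(p)] < n) {
    idx <- (p[length(p)] + 1):n
    base[idx] <- knots_y[length(p)] + fits[[nseg]][2] * (idx - p[length(p)])
  }
  x - base
}

#' Full preprocessing chain for one record
#'
#' Wideband Butterworth filtering, Pan-Tompkins R detection, QRS-sparing
#' median smoothing, and baseline removal — in that order.
#'
#' @param rec an [ecg_record()].
#' @param spec initial denoising band, a [filter_spec()].
#' @param median_window running-median window (s); `0` disables smoothing.
#' @return The record with `samples` replaced by the cleaned signal and an
#'   added `peaks` field ([r_peak_annotation()]).
#' @export
preprocess_record <- function(rec, spec = filter_spec(0.5, 100),
                              median_window = 0.04) {
  stopifnot(inherits(rec, "ecg_record"))
  y <- bandpass(rec$samples, rec$rs, spec)
  peaks <- detect_r_peaks(y, rec$rs)
  if (median_window > 0 && length(peaks$indices))
    y <- median_smooth_excluding_qrs(y, peaks, rec$rs, window = median_window)
  if (length(peaks$indices) >= 2)
    y <- remove_baseline_drift(y, peaks, rec$rs)
  rec$samples <- y
  rec$peaks <- peaks
  rec
}
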
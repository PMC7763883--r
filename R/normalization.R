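#' Normalization settings
#'
#' @param tn_p,tn_t target P and T section durations in seconds. `NULL` means
#'   "derive from the enrollment (pre-exercise) cycles" — see
#'   [normalize_cycles()].
#' @param rs sampling rate (samples/s).
#' @param band frequency-normalization band `c(low, high)` in Hz; the default
#'   10-80 Hz band keeps the QRS energy and discards the slow-wave band where
#'   the two states disagree.
#' @param mode one of `"none"`, `"frequency"`, `"time"`, `"fusion"`.
#' @return An object of class `normalization_spec`.
#' @export
normalization_spec <- function(tn_p = NULL, tn_t = NULL, rs = 500,
                               band = c(10, 80),
                               mode = c("fusion", "time", "frequency", "none")) {
  mode <- match.arg(mode)
  stop_if_not_scalar_pos(rs, "rs")
  if (!is.null(tn_p)) stop_if_not_scalar_pos(tn_p, "tn_p")
  if (!is.null(tn_t)) stop_if_not_scalar_pos(tn_t, "tn_t")
  if (length(band) != 2 || band[1] <= 0 || band[1] >= band[2] || band[2] >= rs / 2)
    stop("band must satisfy 0 < low < high < rs/2", call. = FALSE)
  structure(list(tn_p = tn_p, tn_t = tn_t, rs = rs, band = band, mode = mode),
            class = "normalization_spec")
}

#' Interpolation count for one wave section
#'
#' The number of samples to insert so that a section of actual duration `tr`
#' reaches the target duration `tn` at sampling rate `rs`:
#' `dn = round(rs * tn)`, `dr = round(rs * tr)`, `Ni = dn - dr`. `Ni` may be
#' negative (section longer than target) or zero.
#'
#' @param rs sampling rate (samples/s).
#' @param tn target section duration (s).
#' @param tr actual section duration (s).
#' @return Named list `dn`, `dr`, `ni` (integers).
#' @export
interpolation_count <- function(rs, tn, tr) {
  stop_if_not_scalar_pos(rs, "rs")
  stop_if_not_scalar_pos(tn, "tn")
  stop_if_not_scalar_pos(tr, "tr")
  dn <- as.integer(round(rs * tn))
  dr <- as.integer(round(rs * tr))
  list(dn = dn, dr = dr, ni = dn - dr)
}

#' Interpolation positions for one expansion pass
#'
#' Positions in the ORIGINAL section at which new samples are created:
#' `x_i = Int(dr / (Ni + 1)) * i + 1` for `i = 1..Ni`, where `Int` truncates.
#' The `+1` shift places each new sample between original neighbors
#' `x_i - 1` and `x_i`. When the step `Int(dr / (Ni + 1))` collapses below 1
#' the request cannot be met in a single pass and a condition of class
#' `ecgfuse_step_underflow` is signalled ([resize_wave()] then applies the
#' scheme repeatedly).
#'
#' @param dr actual sample count of the section (>= 2).
#' @param ni number of samples to insert (>= 0).
#' @return Integer vector of `ni` positions (empty when `ni = 0`), strictly
#'   increasing, each in `[2, dr]`.
#' @export
interpolation_positions <- function(dr, ni) {
  dr <- as.integer(dr); ni <- as.integer(ni)
  if (dr < 2) stop("dr must be >= 2", call. = FALSE)
  if (ni < 0) stop("ni must be >= 0", call. = FALSE)
  if (ni == 0) return(integer(0))
  step <- dr %/% (ni + 1L)
  if (step < 1L)
    stop(structure(class = c("ecgfuse_step_underflow", "error", "condition"),
                   list(message = sprintf(
                     "cannot insert %d samples into %d in one pass", ni, dr),
                     call = sys.call())))
  step * seq_len(ni) + 1L
}

#' Insert neighbor-average samples at planned positions
#'
#' Applies the insertion positions in increasing order with a running offset;
#' each inserted amplitude is the average of the samples immediately left and
#' right of the insertion point *at application time*, so consecutive
#' insertions at unit step chain off the previously inserted value.
#'
#' @param wave numeric section of length `dr`.
#' @param positions positions from [interpolation_positions()] computed for
#'   this `dr`.
#' @return Numeric vector of length `dr + length(positions)`; the original
#'   samples survive in order as a subsequence.
#' @export
interpolate_wave <- function(wave, positions) {
  dr <- length(wave)
  positions <- as.integer(positions)
  if (length(positions)) {
    if (is.unsorted(positions, strictly = TRUE) ||
        min(positions) < 2L || max(positions) > dr)
      stop("positions must be strictly increasing within [2, dr]", call. = FALSE)
  }
  cur <- wave
  for (k in seq_along(positions)) {
    at <- positions[k] + (k - 1L)   # running offset from prior insertions
    v <- (cur[at - 1L] + cur[at]) / 2
    cur <- append(cur, v, after = at - 1L)
  }
  cur
}

## Uniform deletion at mirrored positions (the symmetric completion of the
## insertion scheme, used when a section is longer than its target).
delete_positions <- function(dr, nd) {
  dr <- as.integer(dr); nd <- as.integer(nd)
  if (nd == 0) return(integer(0))
  step <- dr %/% (nd + 1L)
  if (step < 1L)
    stop(structure(class = c("ecgfuse_step_underflow", "error", "condition"),
                   list(message = "cannot delete that many samples in one pass",
                        call = sys.call())))
  step * seq_len(nd) + 1L
}

#' Resize a wave section to a target sample count
#'
#' Expansion uses the neighbor-average insertion scheme of
#' [interpolation_positions()] / [interpolate_wave()]. When more samples are
#' requested than one pass can supply (`Ni >= dr`), the pass is applied
#' repeatedly — each pass inserts at most `dr - 1` samples — until the target
#' is reached, preserving the neighbor-average construction instead of
#' switching to generic resampling. Contraction (`Ni < 0`) deletes samples at
#' the mirrored uniform positions, likewise in passes.
#'
#' @param wave numeric section (length >= 2).
#' @param dn target sample count (>= 2).
#' @return Numeric vector of length `dn`, with attribute `passes` (number of
#'   insertion/deletion passes applied).
#' @export
resize_wave <- function(wave, dn) {
  dn <- as.integer(dn)
  if (length(wave) < 2 || dn < 2)
    stop("wave and target must have at least 2 samples", call. = FALSE)
  passes <- 0L
  while (length(wave) != dn) {
    dr <- length(wave)
    ni <- dn - dr
    if (ni > 0) {
      ni_pass <- min(ni, dr - 1L)
      wave <- interpolate_wave(wave, interpolation_positions(dr, ni_pass))
    } else {
      nd_pass <- min(-ni, dr %/% 2L)   # keep the per-pass step >= 1
      wave <- wave[-delete_positions(dr, nd_pass)]
    }
    passes <- passes + 1L
  }
  structure(wave, passes = passes)
}

#' Time-normalize one split cycle
#'
#' Expands (or contracts) the P and T sections independently to the target
#' durations of `spec` via the linear-interpolation scheme, and copies the
#' QRS section through bit-exactly — the QRS is never altered.
#'
#' @param split a `wave_split` from [resegment_and_split()].
#' @param spec a [normalization_spec()] with concrete `tn_p`, `tn_t` and
#'   mode `"time"` or `"fusion"`.
#' @return Numeric cycle of length `dn_p + length(qrs) + dn_t`, with
#'   attributes `ni_p` and `ni_t` (net samples inserted per section).
#' @export
time_normalize_cycle <- function(split, spec) {
  stopifnot(inherits(split, "wave_split"), inherits(spec, "normalization_spec"))
  if (!spec$mode %in% c("time", "fusion"))
    stop("time normalization requires mode 'time' or 'fusion'", call. = FALSE)
  if (is.null(spec$tn_p) || is.null(spec$tn_t))
    stop("spec must carry concrete target durations tn_p and tn_t", call. = FALSE)
  cp <- interpolation_count(spec$rs, spec$tn_p, split$tr_p)
  ct <- interpolation_count(spec$rs, spec$tn_t, split$tr_t)
  p2 <- resize_wave(split$p, cp$dn)
  t2 <- resize_wave(split$t, ct$dn)
  structure(c(as.numeric(p2), split$qrs, as.numeric(t2)),
            ni_p = cp$ni, ni_t = ct$ni)
}

#' Frequency normalization: zero-phase Butterworth bandpass
#'
#' @param x numeric cycle or record.
#' @param rs sampling rate.
#' @param band `c(low, high)` in Hz; default 10-80 Hz.
#' @param order Butterworth order.
#' @return Filtered array, same length.
#' @export
frequency_normalize <- function(x, rs, band = c(10, 80), order = 4L) {
  bandpass(x, rs, filter_spec(band[1], band[2], order = order, zero_phase = TRUE))
}

#' Search the optimal frequency-normalization band
#'
#' Exhaustively filters paired pre- and post-exercise cycles with every
#' candidate band and returns the band minimizing the mean Euclidean distance
#' between the filtered pairs. Ties are broken toward the widest band.
#'
#' @param pre_cycles,post_cycles matrices with one equal-length cycle per row;
#'   rows are paired (row i of one against row i of the other, recycled to
#'   the shorter count).
#' @param rs sampling rate.
#' @param lows,highs candidate cutoffs in Hz; the grid is their cross product
#'   restricted to `low < high < rs/2`.
#' @return Named numeric `c(low, high)`, with attribute `distance` (the
#'   winning mean distance).
#' @export
select_optimal_band <- function(pre_cycles, post_cycles, rs,
                                lows = seq(5, 20, by = 5),
                                highs = seq(40, 120, by = 10)) {
  pre_cycles <- as.matrix(pre_cycles); post_cycles <- as.matrix(post_cycles)
  if (!nrow(pre_cycles) || !nrow(post_cycles))
    stop("need at least one cycle per state", call. = FALSE)
  if (ncol(pre_cycles) != ncol(post_cycles))
    stop("pre and post cycles must share one length", call. = FALSE)
  grid <- expand.grid(low = lows, high = highs)
  grid <- grid[grid$low < grid$high & grid$high < rs / 2, , drop = FALSE]
  if (!nrow(grid)) stop("candidate band grid is empty", call. = FALSE)
  m <- min(nrow(pre_cycles), nrow(post_cycles))
  best <- NULL; best_d <- Inf; best_w <- -Inf
  for (g in seq_len(nrow(grid))) {
    band <- c(grid$low[g], grid$high[g])
    dsum <- 0
    for (i in seq_len(m)) {
      a <- frequency_normalize(pre_cycles[i, ], rs, band)
      b <- frequency_normalize(post_cycles[i, ], rs, band)
      dsum <- dsum + euclidean_distance(a, b)
    }
    d <- dsum / m
    w <- band[2] - band[1]
    if (d < best_d - 1e-12 || (abs(d - best_d) <= 1e-12 && w > best_w)) {
      best <- band; best_d <- d; best_w <- w
    }
  }
  structure(c(low = best[1], high = best[2]), distance = best_d)
}
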
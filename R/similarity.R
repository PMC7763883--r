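#' Euclidean distance between two cycles
#'
#' `sqrt(sum((q - p)^2))` over equal-length sample vectors. A length mismatch
#' is an error: it signals a normalization failure upstream, since matching
#' operates only on length-normalized cycles.
#'
#' @param p,q numeric vectors of equal length.
#' @return Non-negative scalar distance.
#' @export
euclidean_distance <- function(p, q) {
  if (length(p) != length(q))
    stop(sprintf("cycle lengths differ (%d vs %d): normalization failed upstream",
                 length(p), length(q)), call. = FALSE)
  sqrt(sum((q - p)^2))
}

#' Mean cycle distance between two collections
#'
#' Pairs the i-th cycle of each subject in `set_a` with the i-th cycle of the
#' same subject in `set_b` (an all-pairs mean is available via `pairing`),
#' averages the first `n_cycles` pairwise distances per subject, then averages
#' over subjects. Subjects with fewer than `n_cycles` cycles in either set are
#' skipped and reported in the `n_skipped` attribute.
#'
#' @param set_a,set_b [cycle_set()]s with equal cycle lengths.
#' @param n_cycles number of leading cycles per subject to compare.
#' @param pairing `"indexed"` (i-th against i-th) or `"all"` (mean over the
#'   full cross product).
#' @return Mean distance (scalar) with attribute `n_skipped`.
#' @export
average_similarity <- function(set_a, set_b, n_cycles,
                               pairing = c("indexed", "all")) {
  pairing <- match.arg(pairing)
  stopifnot(inherits(set_a, "cycle_set"), inherits(set_b, "cycle_set"))
  if (ncol(set_a$cycles) != ncol(set_b$cycles))
    stop("cycle lengths differ between the two sets", call. = FALSE)
  subjects <- intersect(unique(set_a$meta$subject), unique(set_b$meta$subject))
  vals <- numeric(0); skipped <- 0L
  for (s in subjects) {
    a <- set_a$cycles[set_a$meta$subject == s, , drop = FALSE]
    b <- set_b$cycles[set_b$meta$subject == s, , drop = FALSE]
    if (nrow(a) < n_cycles || nrow(b) < n_cycles) { skipped <- skipped + 1L; next }
    if (pairing == "indexed") {
      d <- mean(vapply(seq_len(n_cycles),
                       function(i) euclidean_distance(a[i, ], b[i, ]),
                       numeric(1)))
    } else {
      dd <- outer(seq_len(n_cycles), seq_len(n_cycles),
                  Vectorize(function(i, j) euclidean_distance(a[i, ], b[j, ])))
      d <- mean(dd)
    }
    vals <- c(vals, d)
  }
  structure(mean(vals), n_skipped = skipped)
}

#' Similarity report over a grid of cycle counts
#'
#' @param set_a,set_b [cycle_set()]s to compare (e.g. pre vs post state).
#' @param n_grid cycle counts to evaluate; default `c(5, 10, 15, 20, 25, 30)`.
#' @param ... passed to [average_similarity()].
#' @return Data frame with columns `n_cycles`, `mean_distance` and attribute
#'   `mode` taken from `set_b`.
#' @export
similarity_report <- function(set_a, set_b, n_grid = seq(5, 30, by = 5), ...) {
  d <- vapply(n_grid, function(n) as.numeric(average_similarity(set_a, set_b, n, ...)),
              numeric(1))
  structure(data.frame(n_cycles = n_grid, mean_distance = d),
            mode = set_b$mode)
}

#' Average rate of similarity change
#'
#' Mean over the shared cycle-count grid of the pointwise relative distance
#' drop `(d_non - d_norm) / d_non * 100`; positive values mean the
#' normalization brought pre- and post-exercise cycles closer. Grid points
#' with a zero unnormalized distance are excluded (counted in the
#' `n_excluded` attribute). This pointwise reconstruction is the package's
#' reading of the "average rate of similarity change" summary; report it as
#' such.
#'
#' @param report_non,report_norm data frames from [similarity_report()] over
#'   the same `n_cycles` grid.
#' @return Percent change (scalar) with attribute `n_excluded`.
#' @export
similarity_change_rate <- function(report_non, report_norm) {
  if (!identical(report_non$n_cycles, report_norm$n_cycles))
    stop("reports must share one cycle-count grid", call. = FALSE)
  d0 <- report_non$mean_distance
  d1 <- report_norm$mean_distance
  ok <- d0 != 0
  structure(mean((d0[ok] - d1[ok]) / d0[ok] * 100),
            n_excluded = sum(!ok))
}
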
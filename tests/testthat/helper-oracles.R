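# Independent brute-force oracles for the interpolation scheme and the
# distance metric. These deliberately use the most naive construction
# available (element-by-element list surgery, explicit loops) so they share
# no code path with the package implementation.

# Interpolation positions by literal evaluation of the position formula.
oracle_positions <- function(dr, ni) {
  if (ni == 0) return(integer(0))
  step <- floor(dr / (ni + 1))
  out <- integer(0)
  for (i in seq_len(ni)) out <- c(out, step * i + 1)
  out
}

# One expansion pass: walk the positions left to right, rebuilding the
# vector from scratch at every insertion; the neighbors are whatever sits
# immediately left/right of the insertion point at that moment.
oracle_insert_pass <- function(wave, positions) {
  inserted <- 0
  for (x in positions) {
    at <- x + inserted            # index the new sample will occupy
    left <- wave[at - 1]
    right <- wave[at]
    wave <- c(wave[seq_len(at - 1)], (left + right) / 2,
              wave[at:length(wave)])
    inserted <- inserted + 1
  }
  wave
}

oracle_euclidean <- function(p, q) {
  s <- 0
  for (i in seq_along(p)) s <- s + (q[i] - p[i])^2
  sqrt(s)
}

# Tiny morphology with known parameters for fiducial ground-truth tests.
fixed_morphology <- function(rr_rest = 0.75, rr_post = 0.50) {
  subject_morphology(
    amp    = c(P = 0.15, Q = -0.10, R = 1.30, S = -0.20, T = 0.35),
    width  = c(P = 0.024, Q = 0.010, R = 0.011, S = 0.010, T = 0.045),
    center = c(P = -0.145, Q = -0.030, R = 0, S = 0.030, T = 0.235),
    rr_rest = rr_rest, rr_post = rr_post)
}
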
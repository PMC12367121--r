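# Independent oracles used across the suite.

# Direct eigenvalue-based stability classification of a 2x2 Jacobian,
# bypassing the trace/determinant sign rules under test.
oracle_classify <- function(A, B, C, D) {
  ev <- eigen(matrix(c(A, C, B, D), 2, 2), only.values = TRUE)$values
  re <- Re(ev)
  im <- Im(ev)
  if (is.complex(ev) && any(abs(im) > 1e-12)) {
    if (max(abs(re)) < 1e-12) return("center/degenerate")
    if (all(re < 0)) return("stable spiral") else return("unstable spiral")
  }
  re <- sort(re)
  if (re[1] < 0 && re[2] > 0) return("saddle")
  if (any(abs(re) < 1e-12)) return("center/degenerate")
  if (all(re < 0)) return("stable node")
  "unstable node"
}

# Reference metric formulas, written independently of compare_traces().
oracle_metrics <- function(ref, test) {
  d <- test - ref
  list(
    mae = sum(abs(d)) / length(d),
    rmse = sqrt(sum(d^2) / length(d)),
    nrmse = sqrt(sum(d^2) / length(d)) / (max(ref) - min(ref))
  )
}

# Exhaustive subset-sum check that y is representable as a signed sum of
# the powers 2^-i over the window (used on small windows only).
oracle_recodable <- function(y, i_min, i_max) {
  pows <- 2^(-(i_min:i_max))
  combos <- expand.grid(rep(list(c(-1, 0, 1)), length(pows)))
  sums <- as.matrix(combos) %*% pows
  any(abs(sums - y) < 1e-12)
}

default_sched <- function(backend = "real") cordic_schedule(backend = backend)
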
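# Shared generators for property-style tests. All randomness is seeded by
# the calling test.

# random smooth closed equal-segment curve (low-order Fourier modes)
random_skeleton <- function(s, l = 1) {
  plasmidmc:::random_closed_curve(s, l = l)
}

# rigid rotation of a vertex matrix about a random axis through the origin
rotate_rigid <- function(v, axis = NULL, angle = NULL) {
  if (is.null(axis)) {
    axis <- rnorm(3)
    axis <- axis / sqrt(sum(axis^2))
  }
  if (is.null(angle)) angle <- runif(1, 0, 2 * pi)
  t(apply(v, 1L, function(p) plasmidmc:::rodrigues(p, axis, angle)))
}

# brute-force re-measurement of all segment lengths (independent of the
# package's own helpers)
brute_lengths <- function(v) {
  s <- nrow(v)
  vapply(seq_len(s), function(i) {
    j <- if (i == s) 1L else i + 1L
    sqrt(sum((v[j, ] - v[i, ])^2))
  }, numeric(1))
}

# standard conditions of the reference experiments
puc19_bp <- 2686L
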
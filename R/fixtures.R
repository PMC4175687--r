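#' Generate closed equal-segment test polygons
#'
#' Fixture skeletons for topology and invariant testing: a planar circle,
#' trefoil and figure-eight knots (equal-arc resampled from their standard
#' parametric curves and then length-equalized by iterative relaxation),
#' and a perturbed circle (seeded Gaussian vertex noise, re-equalized).
#'
#' @param kind One of `"circle"`, `"trefoil"`, `"figure-eight"`,
#'   `"perturbed-circle"`.
#' @param s Number of segments (at least 5; knotted fixtures need enough
#'   segments to realize their crossings, 24+ recommended).
#' @param l Segment length.
#' @param seed RNG seed (perturbed circle).
#' @param noise Noise standard deviation as a fraction of `l`.
#' @return A `dna_skeleton`.
#' @examples
#' tf <- make_fixture("trefoil", s = 30)
#' is_unknotted(tf)$is_unknotted
#' @export
make_fixture <- function(kind = c("circle", "trefoil", "figure-eight",
                                  "perturbed-circle"),
                         s = 30L, l = 1, seed = NULL, noise = 0.1) {
  kind <- match.arg(kind)
  s <- as.integer(s)
  if (s < 5L) stop("s must be at least 5")
  if (!is.null(seed)) set.seed(as.integer(seed))
  v <- switch(kind,
    "circle" = return(build_circular_skeleton(s, l)),
    "trefoil" = {
      t <- seq(0, 2 * pi, length.out = 4096L)[-1L]
      cbind((2 + cos(3 * t)) * cos(2 * t), (2 + cos(3 * t)) * sin(2 * t),
            sin(3 * t))
    },
    "figure-eight" = {
      t <- seq(0, 2 * pi, length.out = 4096L)[-1L]
      cbind((2 + cos(2 * t)) * cos(3 * t), (2 + cos(2 * t)) * sin(3 * t),
            sin(4 * t))
    },
    "perturbed-circle" = {
      ck <- build_circular_skeleton(s, l)
      ck$vertices + matrix(rnorm(3L * s, sd = noise * l), s, 3L)
    })
  if (kind %in% c("trefoil", "figure-eight")) {
    v <- resample_equal_arc(v, s)
  }
  v <- equalize_segments(v)
  lens <- segment_lengths(v)
  v <- v * (l / mean(lens))
  skeleton(v, l = l)
}

# Resample a densely sampled closed curve at s equal-arc-length positions.
resample_equal_arc <- function(v, s) {
  closed <- rbind(v, v[1L, ])
  seg <- sqrt(rowSums(diff(closed)^2))
  arc <- c(0, cumsum(seg))
  total <- arc[length(arc)]
  targets <- total * (seq_len(s) - 1L) / s
  idx <- findInterval(targets, arc, all.inside = TRUE)
  frac <- (targets - arc[idx]) / seg[idx]
  closed[idx, ] + frac * (closed[idx + 1L, ] - closed[idx, ])
}

# Iterative relaxation to equal segment lengths: gradient steps on
# sum (L_i - l)^2 until the worst relative deviation is below tol.
equalize_segments <- function(v, tol = 1e-12, max_iter = 50000L) {
  s <- nrow(v)
  for (it in seq_len(max_iter)) {
    nxt <- rbind(v[-1L, ], v[1L, ])
    d <- nxt - v
    lens <- sqrt(rowSums(d^2))
    l <- mean(lens)
    if (max(abs(lens - l)) / l < tol) return(v)
    u <- d / lens
    excess <- lens - l
    gprev <- rbind(u[s, ] * excess[s], u[-s, ] * excess[-s])
    grad <- gprev - u * excess
    v <- v - 0.45 * grad
  }
  stop("segment equalization failed to converge")
}

# Random smooth closed curve (low-order Fourier modes), equalized; used as
# a generator of valid non-planar skeletons in property tests.
random_closed_curve <- function(s, l = 1, modes = 3L, amp = 0.35) {
  t <- 2 * pi * (seq_len(max(8L * s, 256L)) - 1L) / max(8L * s, 256L)
  v <- cbind(cos(t), sin(t), rep(0, length(t)))
  for (k in seq_len(modes)) {
    for (dim in 1:3) {
      v[, dim] <- v[, dim] + amp / k * (runif(1, -1, 1) * cos(k * t) +
                                          runif(1, -1, 1) * sin(k * t))
    }
  }
  v <- resample_equal_arc(v, s)
  v <- equalize_segments(v)
  v <- v * (l / mean(segment_lengths(v)))
  skeleton(v, l = l)
}
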
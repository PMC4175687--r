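#' Choose the number of skeleton segments for a plasmid
#'
#' Finds the segment count `s` such that each segment of the closed skeleton
#' represents about 30 base pairs. For every admissible bp-per-segment value
#' `i` in `[min_bp, max_bp]` the candidate `s_i = round(n_bp / i)` is scored
#' by `|n_bp - s_i * i|`; the best-scoring candidate wins. Ties are broken
#' toward `i` closest to 30, then toward the smaller `i`.
#'
#' @param n_bp Plasmid size in base pairs (pUC19 is 2686).
#' @param min_bp,max_bp Integer bounds on base pairs per segment; must
#'   bracket 30.
#' @return A list with `s` (segment count), `bp_per_segment` (the winning
#'   `i`) and `residual_bp` (`|n_bp - s * i|`).
#' @examples
#' choose_segment_count(2686) # 79 segments of 34 bp
#' @export
choose_segment_count <- function(n_bp, min_bp = 25L, max_bp = 35L) {
  n_bp <- as.integer(n_bp)
  min_bp <- as.integer(min_bp)
  max_bp <- as.integer(max_bp)
  if (!(min_bp < 30L && 30L < max_bp)) {
    stop("min_bp and max_bp must satisfy min_bp < 30 < max_bp")
  }
  if (min_bp > max_bp) stop("empty candidate range")
  if (n_bp < 5L * min_bp) {
    stop("n_bp too small: fewer than 5 segments for every admissible i")
  }
  i <- seq.int(min_bp, max_bp)
  # round half away from zero using exact integer arithmetic
  s_i <- (2L * n_bp + i) %/% (2L * i)
  resid <- abs(n_bp - s_i * i)
  best <- resid == min(resid)
  cand <- i[best]
  cand <- cand[order(abs(cand - 30L), cand)]
  i_win <- cand[1L]
  s <- s_i[i == i_win]
  if (s < 5L) stop("n_bp too small: chosen segment count below 5")
  list(s = as.integer(s), bp_per_segment = as.integer(i_win),
       residual_bp = as.integer(abs(n_bp - s * i_win)))
}

#' Construct a skeleton conformation object
#'
#' A skeleton is the closed polyline standing in for the DNA axis: `s`
#' vertices (rows of a numeric matrix, coordinates in Angstrom) joined by
#' `s` equal-length segments, vertex `i` to vertex `i + 1` modulo `s`.
#'
#' @param vertices Numeric `s x 3` matrix of vertex coordinates (Angstrom).
#' @param l Segment length in Angstrom; measured from the vertices when
#'   omitted.
#' @param validate Check the closure/equal-length invariants on creation.
#' @return An object of class `dna_skeleton`.
#' @export
skeleton <- function(vertices, l = NULL, validate = TRUE) {
  vertices <- as.matrix(vertices)
  storage.mode(vertices) <- "double"
  if (ncol(vertices) != 3L) stop("vertices must be an s x 3 matrix")
  s <- nrow(vertices)
  if (s < 5L) stop("a skeleton needs at least 5 vertices")
  if (is.null(l)) {
    l <- mean(segment_lengths(vertices))
  }
  obj <- structure(list(vertices = vertices, l = as.numeric(l), s = s),
                   class = "dna_skeleton")
  if (validate) {
    rep <- validate_skeleton(obj)
    if (!rep$pass) {
      stop("invalid skeleton: ", rep$message)
    }
  }
  obj
}

segment_lengths <- function(vertices) {
  nxt <- rbind(vertices[-1L, , drop = FALSE], vertices[1L, , drop = FALSE])
  sqrt(rowSums((nxt - vertices)^2))
}

#' Build the relaxed circular skeleton
#'
#' The initial relaxed conformation is a planar regular polygon with `s`
#' sides in the z = 0 plane, first vertex at `(R, 0, 0)`, successive
#' vertices rotated by `2 * pi / s`. The circumradius `R = l / (2 sin(pi/s))`
#' makes every chord exactly `l`.
#'
#' @param s Number of segments (at least 5).
#' @param l Segment length in Angstrom.
#' @return A `dna_skeleton`.
#' @examples
#' build_circular_skeleton(79, 34 * 3.3)
#' @export
build_circular_skeleton <- function(s, l) {
  s <- as.integer(s)
  if (s < 5L) stop("s must be at least 5")
  if (l <= 0) stop("l must be positive")
  R <- l / (2 * sin(pi / s))
  ang <- 2 * pi * (seq_len(s) - 1L) / s
  v <- cbind(R * cos(ang), R * sin(ang), rep(0, s))
  skeleton(v, l = l, validate = FALSE)
}

#' Validate skeleton invariants
#'
#' Report-only check of closure (s segments joining consecutive vertices
#' cyclically), equal segment lengths within a relative tolerance, and the
#' minimum vertex count.
#'
#' @param x A `dna_skeleton` (or bare vertex matrix).
#' @param tol Relative tolerance on segment-length deviation.
#' @return List with `pass`, `worst_rel_dev`, `worst_segment` (1-based index
#'   of the most deviant segment) and `message`.
#' @export
validate_skeleton <- function(x, tol = 1e-9) {
  v <- if (inherits(x, "dna_skeleton")) x$vertices else as.matrix(x)
  l <- if (inherits(x, "dna_skeleton")) x$l else mean(segment_lengths(v))
  s <- nrow(v)
  if (s < 5L) {
    return(list(pass = FALSE, worst_rel_dev = NA_real_, worst_segment = NA_integer_,
                message = "fewer than 5 vertices"))
  }
  lens <- segment_lengths(v)
  rel <- abs(lens - l) / l
  worst <- which.max(rel)
  pass <- rel[worst] <= tol
  list(pass = pass, worst_rel_dev = rel[worst], worst_segment = worst,
       message = if (pass) "ok" else
         sprintf("segment %d deviates by %.3g relative (tol %.3g)",
                 worst, rel[worst], tol))
}

#' Build a skeleton directly from a base-pair count
#'
#' Convenience wrapper: chooses the segment count, sets the segment length
#' to `bp_per_segment * rise` so the polygon perimeter tracks the molecule
#' contour length, and builds the relaxed circle.
#'
#' @inheritParams choose_segment_count
#' @param rise Helical rise per base pair in Angstrom (default 3.3).
#' @return A `dna_skeleton` with attributes `n_bp` and `bp_per_segment`.
#' @export
skeleton_from_bp <- function(n_bp, min_bp = 25L, max_bp = 35L, rise = 3.3) {
  cs <- choose_segment_count(n_bp, min_bp, max_bp)
  sk <- build_circular_skeleton(cs$s, cs$bp_per_segment * rise)
  attr(sk, "n_bp") <- as.integer(n_bp)
  attr(sk, "bp_per_segment") <- cs$bp_per_segment
  sk
}

#' @export
print.dna_skeleton <- function(x, ...) {
  cat(sprintf("dna_skeleton: %d vertices, segment length %.4f A, perimeter %.1f A\n",
              x$s, x$l, x$s * x$l))
  invisible(x)
}
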
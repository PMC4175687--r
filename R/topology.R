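#' Intersection of two projected segments
#'
#' Open-segment intersection test in the plane (the z = 0 projection used
#' throughout the topology code), solving the 2 x 2 linear system of the
#' parametric forms. Collinear overlapping projections are flagged as
#' degenerate: the caller is expected to resample the projection by a small
#' rigid rotation.
#'
#' @param a1,a2,b1,b2 Numeric length-2 vectors: endpoints of the two
#'   segments.
#' @return `NULL` when the open segments do not intersect, otherwise a list
#'   with the intersection `point` and parameters `t1`, `t2` along each
#'   segment.
#' @export
segments_cross <- function(a1, a2, b1, b2) {
  d1 <- a2 - a1
  d2 <- b2 - b1
  if (all(d1 == 0) || all(d2 == 0)) stop("degenerate zero-length segment")
  r <- b1 - a1
  den <- d1[1] * d2[2] - d1[2] * d2[1]
  scale <- sqrt(sum(d1^2) * sum(d2^2))
  if (abs(den) < 1e-12 * scale) {
    off <- r[1] * d1[2] - r[2] * d1[1]
    if (abs(off) < 1e-12 * scale) {
      t0 <- sum(r * d1) / sum(d1^2)
      t1 <- t0 + sum(d2 * d1) / sum(d1^2)
      if (max(min(t0, t1), 0) <= min(max(t0, t1), 1)) {
        stop("degenerate collinear overlapping projections: resample")
      }
    }
    return(NULL)
  }
  t1 <- (r[1] * d2[2] - r[2] * d2[1]) / den
  t2 <- (r[1] * d1[2] - r[2] * d1[1]) / den
  if (t1 <= 0 || t1 >= 1 || t2 <= 0 || t2 >= 1) return(NULL)
  list(point = a1 + t1 * d1, t1 = t1, t2 = t2)
}

as_vertex_matrix <- function(c) {
  if (inherits(c, "dna_skeleton")) c$vertices else as.matrix(c)
}

# Retry a projection-dependent computation under small random rigid
# rotations when the z = 0 projection is degenerate.
with_generic_projection <- function(v, fun, max_attempts = 6L) {
  for (attempt in seq_len(max_attempts)) {
    out <- fun(v)
    if (isTRUE(out$ok)) {
      out$rotated <- attempt > 1L
      return(out)
    }
    axis <- rnorm(3)
    axis <- axis / sqrt(sum(axis^2))
    ang <- 1e-3 * (1 + runif(1))
    cen <- colMeans(v)
    v <- t(apply(v, 1L, function(p) cen + rodrigues(p - cen, axis, ang)))
  }
  stop("projection still degenerate after ", max_attempts, " resampling attempts")
}

rodrigues <- function(p, k, ang) {
  p * cos(ang) + crossprod3(k, p) * sin(ang) + k * sum(k * p) * (1 - cos(ang))
}

crossprod3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2], a[3] * b[1] - a[1] * b[3], a[1] * b[2] - a[2] * b[1])
}

#' Projected crossings of a skeleton
#'
#' All crossings of the z = 0 projection over non-adjacent segment pairs,
#' with the right-handed sign (which strand is higher in z at the crossing)
#' and the identity of the over strand. Degenerate projections are
#' resampled by a small random rigid rotation.
#'
#' @param c A `dna_skeleton` or vertex matrix.
#' @return Data frame with columns `i`, `j` (0-based segment indices), `x`,
#'   `y`, `sign`, `over`.
#' @export
crossings <- function(c) {
  v <- as_vertex_matrix(c)
  out <- with_generic_projection(v, function(vv) cpp_crossings(vv))
  data.frame(i = out$i, j = out$j, x = out$x, y = out$y,
             sign = out$sign, over = out$over)
}

#' Directional writhe of the z = 0 projection
#'
#' Sum of signed crossings of the projection over all non-adjacent segment
#' pairs. For the vertical auxiliary ribbon this integer equals the linking
#' number of the skeleton with its z-offset copy.
#'
#' @inheritParams crossings
#' @return Integer-valued numeric.
#' @export
directional_writhe <- function(c) {
  v <- as_vertex_matrix(c)
  out <- with_generic_projection(v, function(vv) cpp_crossings(vv))
  out$dz
}

#' Auxiliary chain for the writhe computation
#'
#' The auxiliary chain runs parallel to the skeleton at a small offset
#' along the +z direction (the unit vector `u` of the twist formula), with
#' one vertex per skeleton vertex.
#'
#' @inheritParams crossings
#' @param eps Offset as a fraction of the segment length.
#' @return A vertex matrix of the same dimension.
#' @export
auxiliary_chain <- function(c, eps = 0.01) {
  v <- as_vertex_matrix(c)
  l <- if (inherits(c, "dna_skeleton")) c$l else mean(segment_lengths(v))
  v + matrix(c(0, 0, eps * l), nrow(v), 3L, byrow = TRUE)
}

#' Twist of a discrete ribbon
#'
#' Twist of the ribbon defined by the skeleton and an auxiliary chain with
#' the same number of vertices: the total rotation of the ribbon vector
#' about the local tangent, accumulated per segment and across each vertex
#' by parallel transport, divided by 2 pi.
#'
#' @inheritParams crossings
#' @param aux Auxiliary chain (vertex matrix or skeleton), same vertex
#'   count; defaults to the vertical offset chain of [auxiliary_chain()].
#' @return Dimensionless twist.
#' @export
ribbon_twist <- function(c, aux = auxiliary_chain(c)) {
  v <- as_vertex_matrix(c)
  a <- as_vertex_matrix(aux)
  s <- nrow(v)
  if (nrow(a) != s) stop("auxiliary chain must have the same vertex count")
  u <- a - v
  un <- sqrt(rowSums(u^2))
  if (any(un < 1e-12)) stop("auxiliary chain touches the skeleton")
  u <- u / un
  tang <- rbind(v[-1L, ], v[1L, ]) - v
  tang <- tang / sqrt(rowSums(tang^2))
  total <- 0
  for (i in seq_len(s)) {
    ip <- if (i == s) 1L else i + 1L
    ti <- tang[i, ]
    # in-segment rotation of the ribbon vector about the tangent
    aperp <- u[i, ] - sum(u[i, ] * ti) * ti
    bperp <- u[ip, ] - sum(u[ip, ] * ti) * ti
    na <- sqrt(sum(aperp^2)); nb <- sqrt(sum(bperp^2))
    if (na < 1e-12 || nb < 1e-12) {
      stop("ribbon vector parallel to a segment at vertex ", i)
    }
    aperp <- aperp / na; bperp <- bperp / nb
    total <- total + atan2(sum(crossprod3(aperp, bperp) * ti), sum(aperp * bperp))
    # transport across the vertex to the next tangent frame
    tn <- tang[ip, ]
    ax <- crossprod3(ti, tn)
    sa <- sqrt(sum(ax^2)); ca <- sum(ti * tn)
    if (sa > 1e-15) {
      bpt <- rodrigues(bperp, ax / sa, atan2(sa, ca))
    } else if (ca < 0) {
      stop("antiparallel consecutive segments at vertex ", ip)
    } else {
      bpt <- bperp
    }
    cperp <- u[ip, ] - sum(u[ip, ] * tn) * tn
    nc <- sqrt(sum(cperp^2))
    if (nc < 1e-12) stop("ribbon vector parallel to a segment at vertex ", ip)
    cperp <- cperp / nc
    total <- total + atan2(sum(crossprod3(bpt, cperp) * tn), sum(bpt * cperp))
  }
  total / (2 * pi)
}

#' Writhe by the auxiliary-chain (Lk - Tw) method
#'
#' Production writhe: the linking number of the skeleton with its vertical
#' auxiliary chain equals the directional writhe of the z = 0 projection
#' (an integer), the twist of that ribbon is accumulated by parallel
#' transport, and `Wr = Lk - Tw`. Degenerate projections are resampled by
#' small random rigid rotations (the writhe itself is
#' projection-invariant).
#'
#' @inheritParams crossings
#' @return A list (topology report) with `Wr`, `Tw`, `Lk` and
#'   `directional_writhe`.
#' @export
writhe_2b <- function(c) {
  v <- as_vertex_matrix(c)
  out <- with_generic_projection(v, function(vv) {
    res <- cpp_topo_eval(vv, FALSE, FALSE)
    res
  })
  list(Wr = out$wr, Tw = out$tw, Lk = as.numeric(out$lk),
       directional_writhe = as.numeric(out$lk))
}

#' Writhe by the discretized Gauss double integral
#'
#' Independent oracle: exact closed-form Gauss-integral contribution
#' (signed solid angle) summed over all non-adjacent segment pairs. Slower
#' than [writhe_2b()] but free of any projection.
#'
#' @inheritParams crossings
#' @return Dimensionless writhe.
#' @export
writhe_gauss <- function(c) {
  v <- as_vertex_matrix(c)
  s <- nrow(v)
  nxt <- rbind(v[-1L, ], v[1L, ])
  total <- 0
  for (i in seq_len(s - 1L)) {
    p1 <- v[i, ]; p2 <- nxt[i, ]
    for (j in seq.int(i + 1L, s)) {
      if (j == i + 1L || (i == 1L && j == s)) next
      p3 <- v[j, ]; p4 <- nxt[j, ]
      r13 <- p3 - p1; r14 <- p4 - p1; r23 <- p3 - p2; r24 <- p4 - p2
      n1 <- crossprod3(r13, r14); n2 <- crossprod3(r14, r24)
      n3 <- crossprod3(r24, r23); n4 <- crossprod3(r23, r13)
      nn <- c(sqrt(sum(n1^2)), sqrt(sum(n2^2)), sqrt(sum(n3^2)), sqrt(sum(n4^2)))
      if (any(nn < 1e-14)) next  # coplanar pair contributes nothing
      n1 <- n1 / nn[1]; n2 <- n2 / nn[2]; n3 <- n3 / nn[3]; n4 <- n4 / nn[4]
      clamp <- function(x) min(1, max(-1, x))
      omega <- asin(clamp(sum(n1 * n2))) + asin(clamp(sum(n2 * n3))) +
        asin(clamp(sum(n3 * n4))) + asin(clamp(sum(n4 * n1)))
      sgn <- sign(sum(crossprod3(p4 - p3, p2 - p1) * r13))
      total <- total + omega * sgn
    }
  }
  total / (2 * pi)
}

#' Alexander-polynomial knot test
#'
#' Builds the knot diagram from the projected crossings, assembles the
#' Alexander matrix from the Wirtinger presentation, and evaluates the
#' determinant. The unknot evaluates to 1 (up to sign at `t = -1`; up to a
#' power of 2 at `t = -2`); any other value flags a knotted conformation.
#' The verdict itself is computed at `t = -1` in exact modular integer
#' arithmetic (two 31-bit primes), so it does not depend on floating-point
#' determinant accuracy even for dense diagrams.
#'
#' @inheritParams crossings
#' @param t Evaluation points for the reported determinant values.
#' @return A knot report: list with `alexander_values`, `n_crossings` and
#'   `is_unknotted`.
#' @export
is_unknotted <- function(c, t = c(-1, -2)) {
  v <- as_vertex_matrix(c)
  out <- with_generic_projection(v, function(vv) cpp_alexander(vv, t))
  vals <- out$dets
  names(vals) <- paste0("t=", t)
  list(alexander_values = vals, n_crossings = out$ncross,
       is_unknotted = isTRUE(out$unknot_exact))
}
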
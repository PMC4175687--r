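#' Propose a local three-vertex move
#'
#' Picks a mobile vertex `v_m` (uniformly unless given), resamples its
#' position in spherical displacement coordinates relative to the fixed
#' vertex `v_{m-2}` -- radial displacement `dd` uniform on `[-r, r]`,
#' angular displacements uniform -- rejecting until the candidate lies in
#' the intersection of the neighborhood sphere `N_m` (radius `r` about the
#' old `v_m`) and the reach spheres `S_{m-2}`, `S_{m+2}` (radius `2l` about
#' the fixed vertices). The semi-mobile flanks `v_{m-1}`, `v_{m+1}` are
#' then placed on the exact circles `{|x - v_{m+-2}| = l, |x - v_m'| = l}`
#' at the projection of their old positions, rotated by independent random
#' crankshaft angles `psi` uniform on `[-pi, pi)`. Exactly three vertices
#' move; closure and segment lengths are preserved by construction.
#'
#' @param c A `dna_skeleton`.
#' @param m Mobile vertex (1-based); random when `NULL`.
#' @param r Sampling radius in Angstrom (default `2 * 3.3`, twice the rise
#'   per base pair).
#' @param max_attempts Rejection-sampling cap before a new `m` is drawn by
#'   the caller.
#' @return A `move_proposal` (list with `kind`, `moved`, `old_pos`,
#'   `new_pos`, `params`, `attempts`) or `NULL` if sampling failed.
#' @export
propose_local_move <- function(c, m = NULL, r = 6.6, max_attempts = 100L) {
  v <- c$vertices
  picks <- if (is.null(m)) 50L else 1L
  for (pick in seq_len(picks)) {
    m0 <- if (is.null(m)) -1L else as.integer(m) - 1L
    out <- cpp_propose_local(v, m0, r, c$l, as.integer(max_attempts))
    if (isTRUE(out$ok)) break
  }
  if (!isTRUE(out$ok)) return(NULL)
  moved <- out$moved + 1L
  structure(list(kind = "local", m = out$m + 1L, moved = moved,
                 old_pos = v[moved, , drop = FALSE], new_pos = out$new_pos,
                 params = out$params, attempts = out$attempts),
            class = "move_proposal")
}

#' Apply a move proposal to a skeleton
#'
#' @param c The source `dna_skeleton` (must be the conformation the
#'   proposal was generated from).
#' @param p A `move_proposal`.
#' @return The new `dna_skeleton`.
#' @export
apply_proposal <- function(c, p) {
  v <- c$vertices
  v[p$moved, ] <- p$new_pos
  skeleton(v, l = c$l, validate = FALSE)
}

#' Deterministic local move core
#'
#' Places the mobile vertex at `vm_new` and the flanks on their two-sphere
#' intersection circles at the given crankshaft angles. Used to replay
#' recorded proposals and to verify geometric reversibility.
#'
#' @inheritParams propose_local_move
#' @param vm_new New mobile-vertex position (length-3).
#' @param psi_left,psi_right Crankshaft angles (radians) for `v_{m-1}` and
#'   `v_{m+1}`.
#' @return A `move_proposal`.
#' @export
apply_local_move <- function(c, m, vm_new, psi_left = 0, psi_right = 0) {
  out <- cpp_apply_local(c$vertices, as.integer(m) - 1L, as.numeric(vm_new),
                         psi_left, psi_right, c$l)
  if (!isTRUE(out$ok)) stop("mobile vertex out of reach of a fixed vertex")
  moved <- out$moved + 1L
  structure(list(kind = "local", m = as.integer(m), moved = moved,
                 old_pos = c$vertices[moved, , drop = FALSE],
                 new_pos = out$new_pos,
                 params = c(psi_left = psi_left, psi_right = psi_right),
                 attempts = 1L),
            class = "move_proposal")
}

#' Reverse of a local move
#'
#' Constructs the local-move parameters that return `c_new` (the result of
#' applying `p`) to the original conformation: the mobile vertex targets
#' its old position and the flank angles are measured on the reverse
#' two-sphere circles. Used to verify microscopic reversibility.
#'
#' @param p A local `move_proposal`.
#' @param c_new The skeleton after applying `p`.
#' @return A `move_proposal` whose application to `c_new` restores the
#'   original conformation.
#' @export
reverse_local_move <- function(p, c_new) {
  if (p$kind != "local") stop("reverse_local_move applies to local proposals")
  s <- c_new$s
  m <- p$m
  vm_old <- p$old_pos[2L, ]
  anchors <- c((m - 3L) %% s + 1L, (m + 1L) %% s + 1L)   # v_{m-2}, v_{m+2}
  flanks <- c((m - 2L) %% s + 1L, m %% s + 1L)           # v_{m-1}, v_{m+1}
  psi <- numeric(2L)
  for (k in 1:2) {
    anchor <- c_new$vertices[anchors[k], ]
    axis <- vm_old - anchor
    axis <- axis / sqrt(sum(axis^2))
    center <- anchor + axis * sum((vm_old - anchor) * axis) / 2
    ref <- c_new$vertices[flanks[k], ] - center
    ref <- ref - sum(ref * axis) * axis
    tgt <- p$old_pos[c(1L, 3L)[k], ] - center
    tgt <- tgt - sum(tgt * axis) * axis
    psi[k] <- atan2(sum(crossprod3(ref, tgt) * axis), sum(ref * tgt))
  }
  apply_local_move(c_new, m, vm_old, psi_left = psi[1L], psi_right = psi[2L])
}

#' Standard crankshaft move
#'
#' Chooses two distinct non-adjacent vertices `v_m`, `v_n` and rotates all
#' vertices of the shorter arc between them by a random angle `theta`
#' uniform on `[-pi, pi)` about the axis through `v_m` and `v_n` (ties on
#' arc length rotate the arc following `m`). A rigid rotation, so all
#' segment lengths are preserved exactly.
#'
#' @param c A `dna_skeleton`.
#' @param m,n Endpoint vertices (1-based); random when `NULL`.
#' @param theta Rotation angle; random when `NULL`.
#' @param theta_max Half-range for the random angle.
#' @return A `move_proposal`.
#' @export
standard_crankshaft <- function(c, m = NULL, n = NULL, theta = NULL,
                                theta_max = pi) {
  out <- cpp_crankshaft(c$vertices,
                        if (is.null(m)) -1L else as.integer(m) - 1L,
                        if (is.null(n)) -1L else as.integer(n) - 1L,
                        if (is.null(theta)) NA_real_ else theta,
                        theta_max)
  if (!isTRUE(out$ok)) return(NULL)
  moved <- out$moved + 1L
  structure(list(kind = "crankshaft", m = out$m + 1L, n = out$n + 1L,
                 theta = out$theta, moved = moved,
                 old_pos = c$vertices[moved, , drop = FALSE],
                 new_pos = out$new_pos, attempts = 1L),
            class = "move_proposal")
}

#' Adaptive angle-range state for the biased crankshaft
#'
#' @param theta_max Initial half-range of the rotation angle, radians (the
#'   constant-temperature experiment tunes this to 2.043, the annealing
#'   experiment to 1.854).
#' @return An `angle_range_state`.
#' @export
angle_range_state <- function(theta_max) {
  stopifnot(theta_max > 0, theta_max <= pi)
  structure(list(theta_max = theta_max), class = "angle_range_state")
}

#' Biased (adaptive-angle) crankshaft move
#'
#' As [standard_crankshaft()] but with `theta` uniform on
#' `[-theta_max, theta_max]`, where `theta_max` is adapted during the
#' simulation toward a 50% acceptance rate (see [adapt_angle_range()]).
#'
#' @inheritParams standard_crankshaft
#' @param state An [angle_range_state()].
#' @return A `move_proposal`.
#' @export
biased_crankshaft <- function(c, state, m = NULL, n = NULL) {
  standard_crankshaft(c, m = m, n = n, theta = NULL,
                      theta_max = state$theta_max)
}

#' Adapt the biased-crankshaft angle range
#'
#' Multiplicative controller keeping roughly half the trials accepted:
#' `theta_max` grows by a factor `1 + gamma` when the last slice accepted
#' more than half its trials, shrinks by `1 - gamma` when it accepted
#' less, clipped to `(1e-4, pi]`.
#'
#' @param state An [angle_range_state()].
#' @param slice_acceptance Fraction of accepted trials in the last slice.
#' @param gamma Adaptation rate per slice.
#' @return The updated `angle_range_state`.
#' @export
adapt_angle_range <- function(state, slice_acceptance, gamma = 0.05) {
  stopifnot(slice_acceptance >= 0, slice_acceptance <= 1)
  th <- state$theta_max
  if (slice_acceptance > 0.5) th <- min(pi, th * (1 + gamma))
  if (slice_acceptance < 0.5) th <- max(1e-4, th * (1 - gamma))
  state$theta_max <- th
  state
}

#' Reptation move
#'
#' Slides the sub-chain between `v_i` and `v_j` one segment along the chain
#' contour: the segment vector following `v_j` is removed from its slot and
#' reinserted after `v_i`, which rigidly translates the sub-chain by that
#' vector (with labels shifted by one) and fills the gap. A permutation of
#' the segment vectors, so closure and all segment lengths are preserved
#' exactly.
#'
#' @param c A `dna_skeleton`.
#' @param i,j Sub-chain endpoints (1-based); random when `NULL`. The moved
#'   arc `v_{i+1}..v_j` must contain between 1 and `s - 2` vertices.
#' @return A `move_proposal`.
#' @export
reptation <- function(c, i = NULL, j = NULL) {
  out <- cpp_reptation(c$vertices,
                       if (is.null(i)) -1L else as.integer(i) - 1L,
                       if (is.null(j)) -1L else as.integer(j) - 1L)
  if (!isTRUE(out$ok)) return(NULL)
  moved <- out$moved + 1L
  structure(list(kind = "reptation", i = out$i + 1L, j = out$j + 1L,
                 moved = moved, old_pos = c$vertices[moved, , drop = FALSE],
                 new_pos = out$new_pos, attempts = 1L),
            class = "move_proposal")
}
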
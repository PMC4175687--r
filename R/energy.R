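#' Physical constants and model parameters
#'
#' Bundle of the elastic-energy model parameters. Defaults follow the
#' constant-temperature pUC19 experiment: `k_B = 1.38e-23` J/K,
#' bending constant `alpha = 2.403`, torsional rigidity `C = 3e-28` J m,
#' superhelix density `sigma = -0.04` (physiological values lie in
#' `[-0.07, -0.05]`; the reference experiments use -0.04), helical repeat
#' 10.5 bp/turn and rise 3.3 Angstrom/bp.
#'
#' @param T Temperature in kelvin.
#' @param k_B Boltzmann constant, J/K.
#' @param alpha Dimensionless bending constant.
#' @param C Torsional rigidity, J m.
#' @param sigma Superhelix density (<= 0 for underwound plasmids).
#' @param helical_repeat Base pairs per double-helical turn.
#' @param rise Rise per base pair, Angstrom.
#' @return An object of class `mc_constants`.
#' @export
physical_constants <- function(T = 293, k_B = 1.38e-23, alpha = 2.403,
                               C = 3e-28, sigma = -0.04,
                               helical_repeat = 10.5, rise = 3.3) {
  stopifnot(T >= 0, alpha > 0, C > 0, sigma <= 0, helical_repeat > 0, rise > 0)
  structure(list(T = T, k_B = k_B, alpha = alpha, C = C, sigma = sigma,
                 helical_repeat = helical_repeat, rise = rise),
            class = "mc_constants")
}

bend_angles <- function(v) {
  s <- nrow(v)
  nxt <- rbind(v[-1L, ], v[1L, ])
  seg <- nxt - v
  seg2 <- rbind(seg[-1L, ], seg[1L, ])
  cr2 <- cbind(seg[, 2] * seg2[, 3] - seg[, 3] * seg2[, 2],
               seg[, 3] * seg2[, 1] - seg[, 1] * seg2[, 3],
               seg[, 1] * seg2[, 2] - seg[, 2] * seg2[, 1])
  atan2(sqrt(rowSums(cr2^2)), rowSums(seg * seg2))
}

#' Bending energy of a skeleton
#'
#' `E_b = (k_B T alpha / 2) * sum_i Theta_i^2`, where `Theta_i` is the
#' angle between the directions of consecutive segments, summed over all
#' `s` joints of the closed chain. Angles are computed with the
#' two-argument arctangent for stability near 0 and pi.
#'
#' @param c A `dna_skeleton` or vertex matrix.
#' @param k An [physical_constants()] object.
#' @return Energy in joules.
#' @export
bending_energy <- function(c, k = physical_constants()) {
  v <- as_vertex_matrix(c)
  lens <- segment_lengths(v)
  if (any(lens == 0)) stop("zero-length segment")
  0.5 * k$k_B * k$T * k$alpha * sum(bend_angles(v)^2)
}

#' Linking-number deficit of a supercoiled plasmid
#'
#' The relaxed linking number is `Lk0 = n_bp / helical_repeat`; the deficit
#' imposed by the superhelix density is `dLk = sigma * Lk0`.
#'
#' @param n_bp Plasmid size in base pairs.
#' @param k An [physical_constants()] object.
#' @return List with `Lk0` and `dLk`.
#' @export
delta_linking_number <- function(n_bp, k = physical_constants()) {
  stopifnot(n_bp > 0)
  Lk0 <- n_bp / k$helical_repeat
  list(Lk0 = Lk0, dLk = k$sigma * Lk0)
}

#' Torsional energy
#'
#' `E_t = 2 pi^2 C (dLk - Wr)^2 / L`, quadratic in the part of the
#' linking-number deficit not absorbed by writhe. `L` is the chain contour
#' length in meters.
#'
#' @inheritParams bending_energy
#' @param dLk Linking-number deficit (from [delta_linking_number()]).
#' @param Wr Writhe of the conformation.
#' @return Energy in joules.
#' @export
torsional_energy <- function(c, k = physical_constants(), dLk, Wr) {
  v <- as_vertex_matrix(c)
  L <- sum(segment_lengths(v)) * 1e-10  # Angstrom -> m
  if (L == 0) stop("zero contour length")
  2 * pi^2 * k$C * (dLk - Wr)^2 / L
}

#' Total elastic energy breakdown
#'
#' `E = E_b + E_t` with the writhe taken from [writhe_2b()]. Returns the
#' full breakdown used by the simulation metrics.
#'
#' @inheritParams bending_energy
#' @param n_bp Plasmid size in base pairs (sets the linking-number
#'   deficit).
#' @param Wr Optional precomputed writhe (skips the topology pass).
#' @return An `energy_breakdown` list: `E`, `E_b`, `E_t`, `Wr`, `dLk`,
#'   `Lk0`, `L` (meters).
#' @export
total_energy <- function(c, k = physical_constants(), n_bp, Wr = NULL) {
  v <- as_vertex_matrix(c)
  if (is.null(Wr)) Wr <- writhe_2b(v)$Wr
  lk <- delta_linking_number(n_bp, k)
  E_b <- bending_energy(v, k)
  E_t <- torsional_energy(v, k, lk$dLk, Wr)
  structure(list(E = E_b + E_t, E_b = E_b, E_t = E_t, Wr = Wr,
                 dLk = lk$dLk, Lk0 = lk$Lk0,
                 L = sum(segment_lengths(v)) * 1e-10),
            class = "energy_breakdown")
}

#' Incremental energy update after a local change
#'
#' Recomputes the breakdown after a move that changed only the vertices in
#' `moved`, touching only the bend angles and crossing/twist terms affected
#' by the changed segments. The bending sum is updated joint-by-joint; the
#' directional writhe is updated over segment pairs involving a changed
#' segment; the ribbon twist (linear in `s`) is recomputed. The result
#' equals [total_energy()] on the new conformation to within 1e-9 relative.
#'
#' @param prev Breakdown of the previous conformation (from
#'   [total_energy()] or a previous update).
#' @param c_old,c_new Old and new conformations.
#' @param moved Integer vector of 1-based indices of the changed vertices.
#' @param k An [physical_constants()] object.
#' @param n_bp Plasmid size in base pairs.
#' @return An `energy_breakdown` list.
#' @export
incremental_energy_update <- function(prev, c_old, c_new, moved,
                                      k = physical_constants(), n_bp) {
  vo <- as_vertex_matrix(c_old)
  vn <- as_vertex_matrix(c_new)
  s <- nrow(vo)
  if (length(moved) == 0L) return(prev)
  changed <- which(rowSums(vo != vn) > 0L)
  if (!all(changed %in% moved)) {
    stop("moved set inconsistent with the actual vertex differences")
  }
  # joints whose angle involves a moved vertex: moved-2 .. moved (0-based
  # joint i spans vertices i, i+1, i+2 in 1-based terms)
  ang_old <- bend_angles(vo)
  ang_new <- bend_angles(vn)
  joints <- sort(unique(unlist(lapply(moved, function(m) {
    ((m - 3L):(m - 1L)) %% s + 1L
  }))))
  prev_sum2 <- prev$E_b / (0.5 * k$k_B * k$T * k$alpha)
  new_sum2 <- prev_sum2 - sum(ang_old[joints]^2) + sum(ang_new[joints]^2)
  E_b <- 0.5 * k$k_B * k$T * k$alpha * new_sum2

  # directional writhe: pairs involving a changed segment; both partial
  # scans must use the same (unrotated) projection, so a degenerate
  # projection falls back to a full recomputation
  segs <- sort(unique(unlist(lapply(moved, function(m) {
    c((m - 2L) %% s, (m - 1L) %% s)  # 0-based segments ending/starting at m
  }))))
  po <- cpp_partial_dz(vo, as.integer(segs))
  pn <- cpp_partial_dz(vn, as.integer(segs))
  two <- cpp_twist_z(vo)
  twn <- cpp_twist_z(vn)
  if (!isTRUE(po$ok) || !isTRUE(pn$ok) || !isTRUE(two$ok) || !isTRUE(twn$ok)) {
    return(total_energy(vn, k, n_bp))
  }
  lk_old <- round(prev$Wr + two$tw)
  lk_new <- lk_old + (pn$dz - po$dz)
  Wr <- lk_new - twn$tw

  lk <- delta_linking_number(n_bp, k)
  E_t <- torsional_energy(vn, k, lk$dLk, Wr)
  structure(list(E = E_b + E_t, E_b = E_b, E_t = E_t, Wr = Wr,
                 dLk = lk$dLk, Lk0 = lk$Lk0,
                 L = sum(segment_lengths(vn)) * 1e-10),
            class = "energy_breakdown")
}
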
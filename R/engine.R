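#' Metropolis acceptance test
#'
#' Accepts any energy decrease; an increase `dE` is accepted with
#' probability `exp(-dE / (k_B * T_M))` against a uniform deviate. The
#' `T_M = 0` limit rejects every increase.
#'
#' @param E_prev,E_new Energies (J) of the current and trial conformations.
#' @param T_M Temperature of the experiment, K.
#' @param k_B Boltzmann constant, J/K.
#' @return Logical: accept the trial.
#' @export
metropolis_accept <- function(E_prev, E_new, T_M, k_B = 1.38e-23) {
  if (E_new < E_prev) return(TRUE)
  if (T_M <= 0) return(FALSE)
  runif(1) < exp(-(E_new - E_prev) / (k_B * T_M))
}

#' Annealing temperature rule
#'
#' Cools by the given factor whenever the mean elastic energy of the last
#' slice failed to drop below `factor` times the previous slice's mean
#' (i.e. cooling proceeds unless the energy fell by at least 10% with the
#' default factor), clamped at the floor temperature.
#'
#' @param T_M Current temperature, K.
#' @param slice_mean_E,prev_slice_mean_E Mean energies (J) of the last two
#'   slices.
#' @param factor Cooling/comparison factor.
#' @param T_floor Temperature floor, K.
#' @return The updated temperature.
#' @export
anneal_temperature <- function(T_M, slice_mean_E, prev_slice_mean_E,
                               factor = 0.9, T_floor = 10) {
  if (slice_mean_E > factor * prev_slice_mean_E) {
    T_M <- max(T_M * factor, T_floor)
  }
  T_M
}

#' Run a Monte Carlo supercoiling simulation
#'
#' Full Metropolis driver: each step proposes a trial conformation with the
#' chosen move, rejects it immediately if the Alexander-polynomial gate
#' detects a knot (before any energy computation), otherwise evaluates the
#' elastic energy `E = E_b + E_t` of the trial and applies the Metropolis
#' criterion. Constant-temperature and annealing modes share the driver;
#' annealing applies the 0.9-factor cooling rule on 1,000-step slices and
#' the biased crankshaft adapts its angle range on the same slices.
#'
#' @param n_bp Plasmid size in base pairs (or pass a prebuilt `skeleton`).
#' @param move One of `"local"`, `"crankshaft"`, `"biased-crankshaft"`,
#'   `"reptation"`.
#' @param steps Number of Monte Carlo steps.
#' @param temperature Constant temperature (K); ignored in annealing mode.
#' @param anneal `NULL` for constant temperature, or `c(T_start, T_floor)`
#'   (the reference annealing runs use `c(350, 10)`).
#' @param constants A [physical_constants()] bundle.
#' @param skeleton Optional starting `dna_skeleton` (defaults to the
#'   relaxed circle from `n_bp`).
#' @param seed RNG seed for a reproducible run.
#' @param r Local-move sampling radius, Angstrom.
#' @param theta_max Initial biased-crankshaft half-range, radians.
#' @param gamma Biased-crankshaft adaptation rate per slice.
#' @param anneal_slice Slice length (steps) for cooling decisions and angle
#'   adaptation.
#' @param knot_interval Run the Alexander gate every `knot_interval` trials
#'   (1 = every trial; larger values skip only the determinant, never the
#'   crossing scan, and change rejection statistics only if knots occur).
#' @param max_attempts Local-move rejection-sampling cap per mobile vertex.
#' @param traj_stride Record a trajectory frame every so many steps (0 =
#'   none).
#' @return An `mc_simulation` object: `metrics` (per-step data frame),
#'   `final` skeleton, `config`, counters and, in biased mode, the
#'   `theta_trace`.
#' @export
run_simulation <- function(n_bp = 2686, move = c("local", "crankshaft",
                                                 "biased-crankshaft",
                                                 "reptation"),
                           steps = 10000L, temperature = 293,
                           anneal = NULL, constants = physical_constants(),
                           skeleton = NULL, seed = NULL, r = NULL,
                           theta_max = NULL, gamma = 0.05,
                           anneal_slice = 1000L, knot_interval = 1L,
                           max_attempts = 100L, traj_stride = 0L) {
  move <- match.arg(move)
  steps <- as.integer(steps)
  if (steps < 0L) stop("steps must be non-negative")
  if (!is.null(seed)) set.seed(as.integer(seed))
  if (is.null(skeleton)) {
    skeleton <- skeleton_from_bp(n_bp, rise = constants$rise)
  }
  if (is.null(r)) r <- 2 * constants$rise
  annealing <- !is.null(anneal)
  T0 <- if (annealing) anneal[1L] else temperature
  T_floor <- if (annealing) anneal[2L] else 0
  if (is.null(theta_max)) {
    theta_max <- if (annealing) 1.854 else 2.043
  }
  lkd <- delta_linking_number(n_bp, constants)
  cfg <- list(move = match(move, c("local", "crankshaft", "biased-crankshaft",
                                   "reptation")) - 1L,
              steps = steps, k_B = constants$k_B, T0 = T0,
              anneal = annealing, T_floor = T_floor, cool_factor = 0.9,
              anneal_slice = as.integer(anneal_slice),
              alpha = constants$alpha, C = constants$C,
              L_m = skeleton$s * skeleton$l * 1e-10, dLk = lkd$dLk,
              r = r, l = skeleton$l, theta_max0 = theta_max, gamma = gamma,
              adapt_slice = as.integer(anneal_slice),
              knot_interval = as.integer(knot_interval),
              max_attempts = as.integer(max_attempts),
              traj_stride = as.integer(traj_stride))
  if (steps == 0L) {
    metrics <- data.frame(step = integer(0), E = numeric(0), E_b = numeric(0),
                          E_t = numeric(0), Wr = numeric(0), T = numeric(0),
                          accepted = integer(0), knot_rejected = integer(0),
                          avg_disp = numeric(0))
    return(structure(list(metrics = metrics, final = skeleton,
                          config = c(cfg, list(move_name = move, n_bp = n_bp,
                                               seed = seed)),
                          knot_rejections = 0, theta_trace = NULL,
                          frames = list()),
                     class = "mc_simulation"))
  }
  out <- cpp_run_mc(skeleton$vertices, cfg)
  m <- out$metrics
  metrics <- data.frame(step = seq_len(steps), E = m[, "E"], E_b = m[, "E_b"],
                        E_t = m[, "E_t"], Wr = m[, "Wr"], T = m[, "T"],
                        accepted = as.integer(m[, "accepted"]),
                        knot_rejected = as.integer(m[, "knot_rejected"]),
                        avg_disp = m[, "avg_disp"])
  theta_trace <- NULL
  if (move == "biased-crankshaft" && nrow(out$theta_trace) > 0) {
    theta_trace <- data.frame(step = out$theta_trace[, 1],
                              theta_max = out$theta_trace[, 2])
  }
  frames <- list()
  if (traj_stride > 0L && length(out$frames) > 0) {
    frames <- Map(function(f, st) list(step = st,
                                       skeleton = skeleton(f, l = skeleton$l,
                                                           validate = FALSE)),
                  out$frames, out$frame_steps)
  }
  structure(list(metrics = metrics,
                 final = skeleton(out$final, l = skeleton$l, validate = FALSE),
                 config = c(cfg, list(move_name = move, n_bp = n_bp,
                                      seed = seed)),
                 T_final = out$T_final, Wr_final = out$Wr_final,
                 knot_rejections = out$knot_rejections,
                 knot_checks = out$knot_checks,
                 local_first_attempt_rate =
                   if (out$local_proposals > 0)
                     out$local_first_attempt / out$local_proposals else NA_real_,
                 theta_trace = theta_trace, theta_max_final = out$theta_max_final,
                 frames = frames),
            class = "mc_simulation")
}

#' @export
print.mc_simulation <- function(x, ...) {
  n <- nrow(x$metrics)
  cat(sprintf("mc_simulation: %s move, %d steps\n", x$config$move_name, n))
  if (n > 0) {
    cat(sprintf("  acceptance %.1f%%, knot rejections %d, final E %.4g J, final Wr %.3f\n",
                100 * mean(x$metrics$accepted), as.integer(x$knot_rejections),
                x$metrics$E[n], x$metrics$Wr[n]))
  }
  invisible(x)
}

#' Average displacement of a move proposal
#'
#' Mean Euclidean distance between the new and previous positions of the
#' displaced vertices, `(d_i + ... + d_{i+n}) / (n + 1)`.
#'
#' @param p A `move_proposal`.
#' @return List with `avg` (Angstrom) and the per-vertex `distances`.
#' @export
displacement_metrics <- function(p) {
  if (is.null(p) || length(p$moved) == 0L) stop("proposal moved no vertex")
  d <- sqrt(rowSums((p$new_pos - p$old_pos)^2))
  list(avg = mean(d), distances = d)
}

#' Per-slice summary of a simulation
#'
#' Aggregates the per-step metrics into slices: acceptance counts and
#' ratios, mean energy and temperature, and the accumulated displacement
#' (sum of the average displacements of the accepted trials of the slice).
#'
#' @param sim An `mc_simulation` (or its `metrics` data frame).
#' @param slice_size Steps per slice (the acceptance-ratio figures use
#'   10,000).
#' @return Data frame, one row per slice; a trailing partial slice is
#'   flagged in the `partial` column.
#' @export
slice_report <- function(sim, slice_size = 10000L) {
  m <- if (inherits(sim, "mc_simulation")) sim$metrics else sim
  if (nrow(m) == 0L) {
    return(data.frame(slice_start = integer(0), n = integer(0),
                      accepted = integer(0), ratio = numeric(0),
                      mean_E = numeric(0), mean_T = numeric(0),
                      accum_disp = numeric(0), knot_rejected = integer(0),
                      partial = logical(0)))
  }
  idx <- (m$step - 1L) %/% slice_size
  agg <- function(f) tapply(seq_len(nrow(m)), idx, f)
  starts <- as.integer(tapply(m$step, idx, min))
  n <- as.integer(tapply(m$step, idx, length))
  acc <- as.integer(agg(function(i) sum(m$accepted[i])))
  accum <- as.numeric(agg(function(i) sum(m$avg_disp[i][m$accepted[i] == 1L])))
  data.frame(slice_start = starts, n = n, accepted = acc, ratio = acc / n,
             mean_E = as.numeric(agg(function(i) mean(m$E[i]))),
             mean_T = as.numeric(agg(function(i) mean(m$T[i]))),
             accum_disp = accum,
             knot_rejected = as.integer(agg(function(i) sum(m$knot_rejected[i]))),
             partial = n < slice_size)
}

#' Step at which a run reaches its energy-equilibrium plateau
#'
#' The plateau level is the mean energy over the final window; equilibrium
#' is declared at the first step whose trailing-window mean energy is
#' within `tol` (relative) of that plateau.
#'
#' @param sim An `mc_simulation` (or its `metrics`).
#' @param trailing Trailing-mean window, steps.
#' @param final_window Window defining the plateau level, steps.
#' @param tol Relative tolerance.
#' @return The detected step (integer), or `NA` if never reached.
#' @export
equilibrium_step <- function(sim, trailing = 10000L, final_window = 50000L,
                             tol = 0.10) {
  m <- if (inherits(sim, "mc_simulation")) sim$metrics else sim
  n <- nrow(m)
  if (n < trailing || n < final_window) {
    stop("run shorter than the detection windows")
  }
  plateau <- mean(m$E[(n - final_window + 1L):n])
  cm <- cumsum(m$E)
  trail <- (cm[trailing:n] - c(0, cm)[(trailing:n) - trailing + 1L]) / trailing
  hit <- which(abs(trail - plateau) <= tol * abs(plateau))
  if (length(hit) == 0L) return(NA_integer_)
  as.integer(hit[1L] + trailing - 1L)
}
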
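// Metropolis Monte Carlo driver: propose -> Alexander knot gate ->
// elastic-energy Metropolis test, with optional simulated annealing and
// adaptive biased-crankshaft angle range. One projected-crossing scan per
// trial serves both the knot gate and the writhe entering the torsional
// energy.

#include "pmc.h"

using namespace Rcpp;

static double sum_bend_sq(const Chain& P) {
  int s = (int)P.size();
  double tot = 0.0;
  for (int i = 0; i < s; ++i) {
    V3 u = P[modi(i + 1, s)] - P[i];
    V3 w = P[modi(i + 2, s)] - P[modi(i + 1, s)];
    double th = std::atan2(norm3(cross(u, w)), dot(u, w));
    tot += th * th;
  }
  return tot;
}

// [[Rcpp::export]]
List cpp_run_mc(NumericMatrix V0, List cfg) {
  Chain V = mat_to_chain(V0);
  int s = (int)V.size();

  int move = as<int>(cfg["move"]);  // 0 local, 1 crankshaft, 2 biased, 3 reptation
  int steps = as<int>(cfg["steps"]);
  double kB = as<double>(cfg["k_B"]);
  double T = as<double>(cfg["T0"]);
  bool anneal = as<bool>(cfg["anneal"]);
  double T_floor = as<double>(cfg["T_floor"]);
  double cool = as<double>(cfg["cool_factor"]);
  int anneal_slice = as<int>(cfg["anneal_slice"]);
  double alpha = as<double>(cfg["alpha"]);
  double Cc = as<double>(cfg["C"]);
  double Lm = as<double>(cfg["L_m"]);
  double dLk = as<double>(cfg["dLk"]);
  double r = as<double>(cfg["r"]);
  double l = as<double>(cfg["l"]);
  double theta_max = as<double>(cfg["theta_max0"]);
  double gamma = as<double>(cfg["gamma"]);
  int adapt_slice = as<int>(cfg["adapt_slice"]);
  int knot_interval = as<int>(cfg["knot_interval"]);
  int max_attempts = as<int>(cfg["max_attempts"]);
  int traj_stride = as<int>(cfg["traj_stride"]);

  double c_tor = 2.0 * M_PI * M_PI * Cc / Lm;  // torsional prefactor, J

  // initial state topology
  double det2 = NA_REAL;
  TopoEval te0 = topo_eval(V, true, false, &det2);
  if (!te0.ok) stop("degenerate initial conformation projection");
  if (!te0.unknotted) stop("initial conformation is knotted");
  double Wr = te0.wr;
  double S2 = sum_bend_sq(V);

  NumericMatrix metrics(steps, 8);
  colnames(metrics) = CharacterVector::create("E", "E_b", "E_t", "Wr", "T",
                                              "accepted", "knot_rejected",
                                              "avg_disp");
  int n_theta = (move == 2 && adapt_slice > 0) ? steps / adapt_slice : 0;
  NumericMatrix theta_trace(n_theta, 2);
  int theta_row = 0;

  int n_frames = traj_stride > 0 ? steps / traj_stride : 0;
  List frames(n_frames);
  IntegerVector frame_steps(n_frames);
  int frame_row = 0;

  List knot_frames(10);   // first few knot-rejected trials, for diagnostics
  int knot_frames_n = 0;
  long knot_checks = 0, knot_rej_total = 0;
  long local_props = 0, local_first = 0;
  long att_total = 0;

  double slice_E_sum = 0.0;
  int slice_n = 0, slice_acc = 0;
  double prev_slice_mean = NA_REAL;
  int adapt_acc = 0, adapt_n = 0;

  std::vector<int> moved;
  std::vector<V3> newpos, oldpos;
  moved.reserve(s);
  newpos.reserve(s);
  oldpos.reserve(s);

  for (int step = 0; step < steps; ++step) {
    moved.clear();
    newpos.clear();
    bool proposed = false;

    if (move == 0) {
      for (int pick = 0; pick < 50 && !proposed; ++pick) {
        int m = (int)std::floor(R::unif_rand() * s);
        if (m >= s) m = s - 1;
        LocalProposal pr = local_propose(V, m, r, l, max_attempts);
        ++local_props;
        att_total += pr.attempts;
        if (pr.ok) {
          if (pr.attempts == 1) ++local_first;
          moved.push_back(modi(m - 1, s));
          moved.push_back(m);
          moved.push_back(modi(m + 1, s));
          newpos.push_back(pr.vl_new);
          newpos.push_back(pr.vm_new);
          newpos.push_back(pr.vr_new);
          proposed = true;
        }
      }
    } else if (move == 1 || move == 2) {
      double tmax = (move == 1) ? M_PI : theta_max;
      ArcMove mv = crankshaft_move(V, -1, -1, NA_REAL, tmax);
      if (mv.ok) {
        for (int k = 0; k < mv.len; ++k) {
          moved.push_back(modi(mv.from + k + 1, s));
          newpos.push_back(mv.new_pos[k]);
        }
        proposed = true;
      }
    } else {
      ArcMove mv = reptation_move(V, -1, -1);
      if (mv.ok) {
        for (int k = 0; k < mv.len; ++k) {
          moved.push_back(modi(mv.from + k + 1, s));
          newpos.push_back(mv.new_pos[k]);
        }
        proposed = true;
      }
    }

    double E_prev = 0.5 * kB * T * alpha * S2 + c_tor * (dLk - Wr) * (dLk - Wr);
    bool accepted = false;
    bool knot_rej = false;
    double avg_disp = 0.0;

    if (proposed) {
      oldpos.clear();
      for (size_t k = 0; k < moved.size(); ++k) {
        oldpos.push_back(V[moved[k]]);
        V[moved[k]] = newpos[k];
        avg_disp += norm3(newpos[k] - oldpos[k]);
      }
      avg_disp /= (double)moved.size();

      bool need_knot = (knot_interval <= 1) || (step % knot_interval == 0);
      TopoEval te = topo_eval(V, need_knot, false, NULL);
      if (need_knot) ++knot_checks;

      if (!te.ok || (need_knot && !te.unknotted)) {
        knot_rej = need_knot && te.ok && !te.unknotted;
        if (knot_rej) {
          ++knot_rej_total;
          if (knot_frames_n < 10) knot_frames[knot_frames_n++] = chain_to_mat(V);
        }
        for (size_t k = 0; k < moved.size(); ++k) V[moved[k]] = oldpos[k];
      } else {
        double S2n = sum_bend_sq(V);
        double E_new =
            0.5 * kB * T * alpha * S2n + c_tor * (dLk - te.wr) * (dLk - te.wr);
        double dE = E_new - E_prev;
        if (dE < 0.0) {
          accepted = true;
        } else if (T > 0.0) {
          accepted = (R::unif_rand() < std::exp(-dE / (kB * T)));
        }
        if (accepted) {
          Wr = te.wr;
          S2 = S2n;
          E_prev = E_new;
        } else {
          for (size_t k = 0; k < moved.size(); ++k) V[moved[k]] = oldpos[k];
        }
      }
    }

    metrics(step, 0) = E_prev;
    metrics(step, 1) = 0.5 * kB * T * alpha * S2;
    metrics(step, 2) = c_tor * (dLk - Wr) * (dLk - Wr);
    metrics(step, 3) = Wr;
    metrics(step, 4) = T;
    metrics(step, 5) = accepted ? 1.0 : 0.0;
    metrics(step, 6) = knot_rej ? 1.0 : 0.0;
    metrics(step, 7) = avg_disp;

    slice_E_sum += E_prev;
    ++slice_n;
    if (accepted) ++slice_acc;
    if (accepted) ++adapt_acc;
    ++adapt_n;

    if (traj_stride > 0 && (step + 1) % traj_stride == 0 && frame_row < n_frames) {
      frames[frame_row] = chain_to_mat(V);
      frame_steps[frame_row] = step + 1;
      ++frame_row;
    }

    // biased-crankshaft angle adaptation per adapt_slice
    if (move == 2 && adapt_slice > 0 && (step + 1) % adapt_slice == 0) {
      double frac = (double)adapt_acc / (double)adapt_n;
      if (frac > 0.5)
        theta_max = std::min(M_PI, theta_max * (1.0 + gamma));
      else if (frac < 0.5)
        theta_max = std::max(1e-4, theta_max * (1.0 - gamma));
      if (theta_row < n_theta) {
        theta_trace(theta_row, 0) = step + 1;
        theta_trace(theta_row, 1) = theta_max;
        ++theta_row;
      }
      adapt_acc = 0;
      adapt_n = 0;
    }

    // annealing: cool when the slice mean failed to drop below 0.9x the
    // previous slice mean
    if (anneal && anneal_slice > 0 && (step + 1) % anneal_slice == 0) {
      double mean_E = slice_E_sum / slice_n;
      if (!ISNA(prev_slice_mean) && mean_E > cool * prev_slice_mean) {
        T = std::max(T * cool, T_floor);
      }
      prev_slice_mean = mean_E;
      slice_E_sum = 0.0;
      slice_n = 0;
      slice_acc = 0;
    }

    if ((step & 1023) == 0) Rcpp::checkUserInterrupt();
  }

  return List::create(
      _["metrics"] = metrics, _["final"] = chain_to_mat(V),
      _["T_final"] = T, _["Wr_final"] = Wr,
      _["theta_trace"] = theta_trace, _["theta_max_final"] = theta_max,
      _["frames"] = frames, _["frame_steps"] = frame_steps,
      _["knot_frames"] = knot_frames,
      _["knot_checks"] = (double)knot_checks,
      _["knot_rejections"] = (double)knot_rej_total,
      _["local_proposals"] = (double)local_props,
      _["local_first_attempt"] = (double)local_first,
      _["local_attempts_total"] = (double)att_total);
}
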
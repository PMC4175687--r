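// Trial-conformation generators: the three-vertex local move (mobile vertex
// resampled inside N_m * S_{m-2} * S_{m+2}, flanking vertices constrained to
// the exact two-sphere intersection circles), plus standard/biased crankshaft
// and reptation baselines. All randomness flows through R's RNG.

#include "pmc.h"

using namespace Rcpp;

// Place a flanking vertex on the circle {|x-anchor| = l, |x-vm| = l}:
// reference point is the projection of fref onto the circle, then rotated
// by psi about the anchor->vm axis.
bool flank_on_circle(V3 anchor, V3 vm, V3 fref, double l, double psi, V3& out) {
  V3 ax = vm - anchor;
  double D = norm3(ax);
  if (D < 1e-12 || D > 2.0 * l) return false;
  V3 axh = (1.0 / D) * ax;
  V3 center = anchor + (0.5 * D) * axh;
  double rad2 = l * l - 0.25 * D * D;
  double rad = rad2 > 0 ? std::sqrt(rad2) : 0.0;
  V3 w = fref - center;
  V3 wp = w - dot(w, axh) * axh;
  double nwp = norm3(wp);
  V3 e1;
  if (nwp > 1e-9) {
    e1 = (1.0 / nwp) * wp;
  } else {
    // reference sits on the axis: pick a deterministic perpendicular
    V3 h = std::fabs(axh.x) < 0.9 ? v3(1, 0, 0) : v3(0, 1, 0);
    e1 = unit3(cross(axh, h));
  }
  out = center + rad * rotate_axis(e1, axh, psi);
  return true;
}

// Sample the new mobile-vertex position uniformly (in spherical displacement
// coordinates relative to v_{m-2}) over N_m * S_{m-2} * S_{m+2} by rejection.
// The angular proposal box is restricted to the sub-box of [-pi,pi]^2 that
// can reach the ball N_m, which leaves the sampled distribution unchanged
// while keeping the first-attempt success rate high.
LocalProposal local_propose(const Chain& P, int m, double r, double l,
                            int max_attempts) {
  int s = (int)P.size();
  LocalProposal pr;
  pr.ok = false;
  pr.m = m;
  pr.attempts = 0;
  V3 a = P[modi(m - 2, s)];
  V3 b = P[modi(m + 2, s)];
  V3 vm = P[m];
  V3 rel = vm - a;
  double d = norm3(rel);
  double theta = std::acos(std::min(1.0, std::max(-1.0, rel.z / d)));
  double phi = std::atan2(rel.y, rel.x);
  double twol = 2.0 * l;

  for (int att = 1; att <= max_attempts; ++att) {
    pr.attempts = att;
    double dd = R::runif(-r, r);
    double d2 = d + dd;
    if (d2 <= 1e-9 || d2 > twol) continue;
    double dmin = std::min(d, d2);
    double cosg = (d * d + d2 * d2 - r * r) / (2.0 * d * d2);
    double gmax = (cosg <= -1.0) ? M_PI : std::acos(std::min(1.0, cosg));
    gmax = std::min(M_PI, 1.02 * gmax + 1e-9);
    double dth = R::runif(-gmax, gmax);
    double thlo = theta - gmax, thhi = theta + gmax;
    double dphmax;
    if (thlo <= 0.0 || thhi >= M_PI) {
      dphmax = M_PI;  // polar cap: azimuth unconstrained
    } else {
      double smin = std::min(std::sin(thlo), std::sin(thhi));
      dphmax = std::min(M_PI, 1.02 * gmax / smin + 1e-9);
    }
    double dph = R::runif(-dphmax, dphmax);
    double th2 = theta + dth, ph2 = phi + dph;
    V3 cand = a + v3(d2 * std::sin(th2) * std::cos(ph2),
                     d2 * std::sin(th2) * std::sin(ph2), d2 * std::cos(th2));
    if (norm3(cand - vm) > r) continue;
    if (norm3(cand - b) > twol) continue;
    pr.vm_new = cand;
    pr.dd = dd;
    pr.dth = dth;
    pr.dph = dph;
    pr.psiL = R::runif(-M_PI, M_PI);
    pr.psiR = R::runif(-M_PI, M_PI);
    V3 vl, vr;
    if (!flank_on_circle(a, cand, P[modi(m - 1, s)], l, pr.psiL, vl)) continue;
    if (!flank_on_circle(b, cand, P[modi(m + 1, s)], l, pr.psiR, vr)) continue;
    pr.vl_new = vl;
    pr.vr_new = vr;
    pr.ok = true;
    (void)dmin;
    return pr;
  }
  return pr;
}

// [[Rcpp::export]]
List cpp_propose_local(NumericMatrix V, int m, double r, double l,
                       int max_attempts) {
  Chain P = mat_to_chain(V);
  int s = (int)P.size();
  if (m < 0) m = (int)std::floor(R::unif_rand() * s);
  if (m >= s) m = s - 1;
  LocalProposal pr = local_propose(P, m, r, l, max_attempts);
  if (!pr.ok) {
    return List::create(_["ok"] = false, _["m"] = pr.m, _["attempts"] = pr.attempts);
  }
  NumericMatrix np(3, 3);
  np(0, 0) = pr.vl_new.x; np(0, 1) = pr.vl_new.y; np(0, 2) = pr.vl_new.z;
  np(1, 0) = pr.vm_new.x; np(1, 1) = pr.vm_new.y; np(1, 2) = pr.vm_new.z;
  np(2, 0) = pr.vr_new.x; np(2, 1) = pr.vr_new.y; np(2, 2) = pr.vr_new.z;
  IntegerVector moved = IntegerVector::create(modi(pr.m - 1, s), pr.m,
                                              modi(pr.m + 1, s));
  return List::create(
      _["ok"] = true, _["m"] = pr.m, _["moved"] = moved, _["new_pos"] = np,
      _["attempts"] = pr.attempts,
      _["params"] = NumericVector::create(
          _["dd"] = pr.dd, _["dtheta"] = pr.dth, _["dphi"] = pr.dph,
          _["psi_left"] = pr.psiL, _["psi_right"] = pr.psiR));
}

// Deterministic core of the local move: given the new mobile-vertex
// position, place the flanks at the psi-rotated projection of their old
// positions onto the two-sphere circles.
// [[Rcpp::export]]
List cpp_apply_local(NumericMatrix V, int m, NumericVector vm_new,
                     double psi_left, double psi_right, double l) {
  Chain P = mat_to_chain(V);
  int s = (int)P.size();
  V3 cand = v3(vm_new[0], vm_new[1], vm_new[2]);
  V3 vl, vr;
  bool okl = flank_on_circle(P[modi(m - 2, s)], cand, P[modi(m - 1, s)], l,
                             psi_left, vl);
  bool okr = flank_on_circle(P[modi(m + 2, s)], cand, P[modi(m + 1, s)], l,
                             psi_right, vr);
  if (!okl || !okr) return List::create(_["ok"] = false);
  NumericMatrix np(3, 3);
  np(0, 0) = vl.x; np(0, 1) = vl.y; np(0, 2) = vl.z;
  np(1, 0) = cand.x; np(1, 1) = cand.y; np(1, 2) = cand.z;
  np(2, 0) = vr.x; np(2, 1) = vr.y; np(2, 2) = vr.z;
  IntegerVector moved = IntegerVector::create(modi(m - 1, s), m, modi(m + 1, s));
  return List::create(_["ok"] = true, _["m"] = m, _["moved"] = moved,
                      _["new_pos"] = np);
}

// Standard/biased crankshaft: rotate the shorter arc between two random
// vertices about their connecting axis by theta ~ U[-theta_max, theta_max].
ArcMove crankshaft_move(const Chain& P, int m, int n, double theta,
                        double theta_max) {
  int s = (int)P.size();
  ArcMove mv;
  mv.ok = false;
  for (int tries = 0; tries < 100; ++tries) {
    int mm = m, nn = n;
    if (mm < 0) {
      mm = (int)std::floor(R::unif_rand() * s);
      do {
        nn = (int)std::floor(R::unif_rand() * s);
      } while (nn == mm || nn == modi(mm + 1, s) || nn == modi(mm - 1, s));
    }
    int lenF = modi(nn - mm, s);          // segments m -> n forward
    int lenB = s - lenF;
    int from, len;
    V3 vfrom, vto;
    if (lenF <= lenB) {                   // ties rotate the arc following m
      from = mm; len = lenF - 1; vfrom = P[mm]; vto = P[nn];
    } else {
      from = nn; len = lenB - 1; vfrom = P[nn]; vto = P[mm];
    }
    V3 ax = vto - vfrom;
    double D = norm3(ax);
    if (D < 1e-12) { if (m >= 0) return mv; continue; }  // degenerate axis
    V3 axh = (1.0 / D) * ax;
    double th = ISNA(theta) ? R::runif(-theta_max, theta_max) : theta;
    mv.ok = true;
    mv.from = from;
    mv.len = len;
    mv.theta = th;
    mv.m = mm;
    mv.n = nn;
    mv.new_pos.resize(len);
    for (int k = 1; k <= len; ++k) {
      int idx = modi(from + k, s);
      mv.new_pos[k - 1] = vfrom + rotate_axis(P[idx] - vfrom, axh, th);
    }
    return mv;
  }
  return mv;
}

// [[Rcpp::export]]
List cpp_crankshaft(NumericMatrix V, int m, int n, double theta,
                    double theta_max) {
  Chain P = mat_to_chain(V);
  int s = (int)P.size();
  ArcMove mv = crankshaft_move(P, m, n, theta, theta_max);
  if (!mv.ok) return List::create(_["ok"] = false);
  int len = mv.len;
  IntegerVector moved(len);
  NumericMatrix np(len, 3);
  for (int k = 0; k < len; ++k) {
    moved[k] = modi(mv.from + k + 1, s);
    np(k, 0) = mv.new_pos[k].x;
    np(k, 1) = mv.new_pos[k].y;
    np(k, 2) = mv.new_pos[k].z;
  }
  return List::create(_["ok"] = true, _["m"] = mv.m, _["n"] = mv.n,
                      _["theta"] = mv.theta, _["moved"] = moved,
                      _["new_pos"] = np);
}

// Reptation as a segment-vector permutation: the segment vector following
// v_j is removed and reinserted after v_i, rigidly translating the
// sub-chain v_{i+1}..v_j by that vector (labels shift by one). Closure and
// all segment lengths are preserved exactly.
ArcMove reptation_move(const Chain& P, int i, int j) {
  int s = (int)P.size();
  ArcMove mv;
  mv.ok = false;
  if (i < 0) {
    i = (int)std::floor(R::unif_rand() * s);
    int len;
    do {
      j = (int)std::floor(R::unif_rand() * s);
      len = modi(j - i, s);
    } while (len < 1 || len > s - 2);
  } else {
    int len = modi(j - i, s);
    if (len < 1 || len > s - 2) return mv;
  }
  V3 w = P[modi(j + 1, s)] - P[j];
  int len = modi(j - i, s);
  mv.ok = true;
  mv.from = i;
  mv.len = len;
  mv.m = i;
  mv.n = j;
  mv.theta = NA_REAL;
  mv.new_pos.resize(len);
  for (int k = 1; k <= len; ++k) {
    int idx = modi(i + k, s);
    mv.new_pos[k - 1] = P[modi(idx - 1, s)] + w;
  }
  return mv;
}

// [[Rcpp::export]]
List cpp_reptation(NumericMatrix V, int i, int j) {
  Chain P = mat_to_chain(V);
  int s = (int)P.size();
  ArcMove mv = reptation_move(P, i, j);
  if (!mv.ok) return List::create(_["ok"] = false);
  IntegerVector moved(mv.len);
  NumericMatrix np(mv.len, 3);
  for (int k = 0; k < mv.len; ++k) {
    moved[k] = modi(mv.from + k + 1, s);
    np(k, 0) = mv.new_pos[k].x;
    np(k, 1) = mv.new_pos[k].y;
    np(k, 2) = mv.new_pos[k].z;
  }
  return List::create(_["ok"] = true, _["i"] = mv.m, _["j"] = mv.n,
                      _["moved"] = moved, _["new_pos"] = np);
}
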
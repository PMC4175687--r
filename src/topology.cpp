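// Projected-crossing topology of closed equal-segment polylines:
// directional writhe, twist of the vertical auxiliary ribbon, and the
// Alexander-polynomial knot test built from the same crossing scan.

#include "pmc.h"
#include <algorithm>

using namespace Rcpp;

static const double PAR_EPS = 1e-12;   // relative parallel-projection tolerance
static const double END_EPS = 1e-9;    // crossing-parameter distance from segment ends

// Scan all non-adjacent segment pairs of the closed chain for projected
// (z = 0) crossings. ok = false flags a degenerate projection (crossing at
// or numerically too close to a segment end, or collinear overlap).
TopoScan crossing_scan(const Chain& P) {
  int s = (int)P.size();
  TopoScan res;
  res.ok = true;
  res.dz = 0;

  // bounding boxes for early rejection
  std::vector<double> xlo(s), xhi(s), ylo(s), yhi(s);
  for (int i = 0; i < s; ++i) {
    int i1 = modi(i + 1, s);
    xlo[i] = std::min(P[i].x, P[i1].x);
    xhi[i] = std::max(P[i].x, P[i1].x);
    ylo[i] = std::min(P[i].y, P[i1].y);
    yhi[i] = std::max(P[i].y, P[i1].y);
  }

  for (int i = 0; i < s - 1; ++i) {
    int i1 = modi(i + 1, s);
    for (int j = i + 2; j < s; ++j) {
      if (i == 0 && j == s - 1) continue;  // adjacent around the seam
      if (xlo[i] > xhi[j] || xlo[j] > xhi[i]) continue;
      if (ylo[i] > yhi[j] || ylo[j] > yhi[i]) continue;
      int j1 = modi(j + 1, s);
      double d1x = P[i1].x - P[i].x, d1y = P[i1].y - P[i].y;
      double d2x = P[j1].x - P[j].x, d2y = P[j1].y - P[j].y;
      double rx = P[j].x - P[i].x, ry = P[j].y - P[i].y;
      double den = d1x * d2y - d1y * d2x;
      double scale = std::sqrt((d1x * d1x + d1y * d1y) * (d2x * d2x + d2y * d2y));
      if (std::fabs(den) < PAR_EPS * scale) {
        // parallel projections: degenerate only if collinear and overlapping
        double off = rx * d1y - ry * d1x;
        if (std::fabs(off) < PAR_EPS * scale) {
          double l1sq = d1x * d1x + d1y * d1y;
          if (l1sq > 0) {
            double t0 = (rx * d1x + ry * d1y) / l1sq;
            double t1 = t0 + (d2x * d1x + d2y * d1y) / l1sq;
            if (std::max(std::min(t0, t1), 0.0) <= std::min(std::max(t0, t1), 1.0)) {
              res.ok = false;
              return res;
            }
          }
        }
        continue;
      }
      double ti = (rx * d2y - ry * d2x) / den;
      double tj = (rx * d1y - ry * d1x) / den;
      if (ti <= -END_EPS || ti >= 1.0 + END_EPS || tj <= -END_EPS || tj >= 1.0 + END_EPS)
        continue;
      if (ti < END_EPS || ti > 1.0 - END_EPS || tj < END_EPS || tj > 1.0 - END_EPS) {
        res.ok = false;  // crossing too close to a vertex: resample projection
        return res;
      }
      Crossing c;
      c.i = i;
      c.j = j;
      c.ti = ti;
      c.tj = tj;
      c.x = P[i].x + ti * d1x;
      c.y = P[i].y + ti * d1y;
      double zi = P[i].z + ti * (P[i1].z - P[i].z);
      double zj = P[j].z + tj * (P[j1].z - P[j].z);
      if (std::fabs(zi - zj) < END_EPS * (1.0 + std::fabs(zi))) {
        res.ok = false;  // strands touch in 3-D projection sense
        return res;
      }
      c.over = (zi > zj) ? i : j;
      // right-handed sign: +1 when (over tangent, under tangent) is a
      // positively oriented 2-D frame
      double co = (c.over == i) ? (d1x * d2y - d1y * d2x) : (d2x * d1y - d2y * d1x);
      c.sign = (co > 0) ? 1 : -1;
      res.dz += c.sign;
      res.cr.push_back(c);
    }
  }
  return res;
}

// Twist of the ribbon formed by the chain and its infinitesimal vertical
// (z) offset: per-vertex parallel-transport angles of the projected z
// direction. ok = false when a segment is (anti)parallel to z or two
// consecutive segments are antiparallel.
double twist_z(const Chain& P, bool& ok) {
  int s = (int)P.size();
  ok = true;
  double total = 0.0;
  const V3 uz = v3(0, 0, 1);
  for (int i = 0; i < s; ++i) {
    V3 tp = unit3(P[i] - P[modi(i - 1, s)]);
    V3 tc = unit3(P[modi(i + 1, s)] - P[i]);
    V3 ap = uz - dot(uz, tp) * tp;
    V3 ac = uz - dot(uz, tc) * tc;
    double nap = norm3(ap), nac = norm3(ac);
    if (nap < 1e-9 || nac < 1e-9) {  // segment parallel to z
      ok = false;
      return NA_REAL;
    }
    ap = (1.0 / nap) * ap;
    ac = (1.0 / nac) * ac;
    V3 ax = cross(tp, tc);
    double sa = norm3(ax), ca = dot(tp, tc);
    V3 apt = ap;
    if (sa > 1e-15) {
      apt = rotate_axis(ap, (1.0 / sa) * ax, std::atan2(sa, ca));
    } else if (ca < 0) {  // antiparallel consecutive segments
      ok = false;
      return NA_REAL;
    }
    total += std::atan2(dot(cross(apt, ac), tc), dot(apt, ac));
  }
  return total / (2.0 * M_PI);
}

// Alexander determinant |Delta(t)| of the knot diagram formed by the
// projected crossings (Harris-Harvey style matrix from the Wirtinger
// presentation). Value 1 (up to units) identifies the unknot diagram.
double alexander_det(const std::vector<Crossing>& cr, int s, double t) {
  int n = (int)cr.size();
  if (n <= 1) return 1.0;

  // underpasses in chain order
  struct Under {
    double g;      // position along the chain (segment index + parameter)
    int idx;       // crossing index
  };
  std::vector<Under> ups(n);
  std::vector<double> gover(n);
  for (int k = 0; k < n; ++k) {
    const Crossing& c = cr[k];
    int underseg = (c.over == c.i) ? c.j : c.i;
    double ut = (underseg == c.i) ? c.ti : c.tj;
    ups[k].g = underseg + ut;
    ups[k].idx = k;
    int overseg = c.over;
    double ot = (overseg == c.i) ? c.ti : c.tj;
    gover[k] = overseg + ot;
  }
  std::sort(ups.begin(), ups.end(),
            [](const Under& a, const Under& b) { return a.g < b.g; });
  std::vector<double> gu(n);
  for (int k = 0; k < n; ++k) gu[k] = ups[k].g;

  arma::mat A(n, n, arma::fill::zeros);
  for (int k = 0; k < n; ++k) {
    const Crossing& c = cr[ups[k].idx];
    // overpass generator: arc a runs from underpass a to underpass a+1
    double go = gover[ups[k].idx];
    int a = (int)(std::upper_bound(gu.begin(), gu.end(), go) - gu.begin()) - 1;
    if (a < 0) a = n - 1;  // before the first underpass: wrap to last arc
    // arc a starts at underpass a; the strand entering underpass k is arc
    // k-1 and the strand leaving is arc k
    int km = (k - 1 + n) % n;
    if (c.sign > 0) {
      A(k, km) += t;
      A(k, k) += -1.0;
      A(k, a) += 1.0 - t;
    } else {
      A(k, km) += 1.0;
      A(k, k) += -t;
      A(k, a) += t - 1.0;
    }
  }
  arma::mat M = A.submat(0, 0, n - 2, n - 2);
  return std::fabs(arma::det(M));
}

// Exact Alexander-determinant unknot test at integer t via modular
// arithmetic (Gaussian elimination mod a large prime): immune to the
// floating-point growth that can corrupt dense diagrams.
static long long mod_pow(long long b, long long e, long long p) {
  long long r = 1;
  b %= p;
  while (e > 0) {
    if (e & 1) r = (__int128)r * b % p;
    b = (__int128)b * b % p;
    e >>= 1;
  }
  return r;
}

static long long alexander_det_modp(const std::vector<Crossing>& cr, int s,
                                    long long t, long long p) {
  int n = (int)cr.size();
  if (n <= 1) return 1;
  struct Under {
    double g;
    int idx;
  };
  std::vector<Under> ups(n);
  std::vector<double> gover(n);
  for (int k = 0; k < n; ++k) {
    const Crossing& c = cr[k];
    int underseg = (c.over == c.i) ? c.j : c.i;
    double ut = (underseg == c.i) ? c.ti : c.tj;
    ups[k].g = underseg + ut;
    ups[k].idx = k;
    int overseg = c.over;
    double ot = (overseg == c.i) ? c.ti : c.tj;
    gover[k] = overseg + ot;
  }
  std::sort(ups.begin(), ups.end(),
            [](const Under& a, const Under& b) { return a.g < b.g; });
  std::vector<double> gu(n);
  for (int k = 0; k < n; ++k) gu[k] = ups[k].g;

  int m = n - 1;
  std::vector<long long> A((size_t)m * m, 0);
  long long tm = ((t % p) + p) % p;
  long long one_mt = ((1 - t) % p + p) % p;  // 1 - t mod p
  long long mt = (p - tm) % p;               // -t
  long long t_m1 = ((t - 1) % p + p) % p;    // t - 1
  auto add = [&](int r, int c, long long val) {
    if (r >= m || c >= m) return;  // deleted last row/column
    A[(size_t)r * m + c] = ((A[(size_t)r * m + c] + val) % p + p) % p;
  };
  for (int k = 0; k < n; ++k) {
    const Crossing& c = cr[ups[k].idx];
    double go = gover[ups[k].idx];
    int a = (int)(std::upper_bound(gu.begin(), gu.end(), go) - gu.begin()) - 1;
    if (a < 0) a = n - 1;
    int km = (k - 1 + n) % n;
    if (c.sign > 0) {
      add(k, km, tm);
      add(k, k, p - 1);
      add(k, a, one_mt);
    } else {
      add(k, km, 1);
      add(k, k, mt);
      add(k, a, t_m1);
    }
  }
  // Gaussian elimination mod p
  long long det = 1;
  for (int col = 0; col < m; ++col) {
    int piv = -1;
    for (int r = col; r < m; ++r) {
      if (A[(size_t)r * m + col] != 0) { piv = r; break; }
    }
    if (piv < 0) return 0;
    if (piv != col) {
      for (int c2 = col; c2 < m; ++c2)
        std::swap(A[(size_t)piv * m + c2], A[(size_t)col * m + c2]);
      det = (p - det) % p;
    }
    long long pv = A[(size_t)col * m + col];
    det = (__int128)det * pv % p;
    long long inv = mod_pow(pv, p - 2, p);
    for (int r = col + 1; r < m; ++r) {
      long long f = (__int128)A[(size_t)r * m + col] * inv % p;
      if (f == 0) continue;
      for (int c2 = col; c2 < m; ++c2) {
        A[(size_t)r * m + c2] =
            ((A[(size_t)r * m + c2] -
              (__int128)f * A[(size_t)col * m + c2]) % p + p) % p;
      }
    }
  }
  return det;
}

// Unknot iff |Delta(-1)| = 1: det == +-1 modulo two independent primes.
static bool alexander_unknot_exact(const std::vector<Crossing>& cr, int s) {
  const long long p1 = 2147483647LL, p2 = 2147483629LL;
  long long d1 = alexander_det_modp(cr, s, -1, p1);
  if (d1 != 1 && d1 != p1 - 1) return false;
  long long d2 = alexander_det_modp(cr, s, -1, p2);
  return d2 == 1 || d2 == p2 - 1;
}

// Full topology evaluation with degeneracy handling: on a degenerate
// projection the conformation is rigidly rotated by a small random angle
// (R RNG) and re-scanned, up to 5 retries. Wr is projection-invariant.
TopoEval topo_eval(const Chain& P, bool need_knot, bool need_det2, double* det2out) {
  TopoEval out;
  out.ok = false;
  Chain Q = P;
  for (int attempt = 0; attempt < 6; ++attempt) {
    if (attempt > 0) {
      // small random rigid rotation about a random axis through the centroid
      V3 axis = unit3(v3(R::norm_rand(), R::norm_rand(), R::norm_rand()));
      double ang = 1e-3 * (1.0 + R::unif_rand());
      V3 cen = v3(0, 0, 0);
      for (size_t i = 0; i < P.size(); ++i) cen = cen + P[i];
      cen = (1.0 / P.size()) * cen;
      for (size_t i = 0; i < P.size(); ++i)
        Q[i] = cen + rotate_axis(P[i] - cen, axis, ang);
    }
    TopoScan sc = crossing_scan(Q);
    if (!sc.ok) continue;
    bool twok = true;
    double tw = twist_z(Q, twok);
    if (!twok) continue;
    out.ok = true;
    out.dz = sc.dz;
    out.tw = tw;
    out.wr = (double)sc.dz - tw;
    out.ncross = (int)sc.cr.size();
    if (need_knot) {
      out.unknotted = alexander_unknot_exact(sc.cr, (int)Q.size());
      out.det1 = alexander_det(sc.cr, (int)Q.size(), -1.0);
      if (need_det2 && det2out) *det2out = alexander_det(sc.cr, (int)Q.size(), -2.0);
    } else {
      out.det1 = NA_REAL;
      out.unknotted = true;
    }
    return out;
  }
  return out;
}

// [[Rcpp::export]]
List cpp_crossings(NumericMatrix V) {
  Chain P = mat_to_chain(V);
  TopoScan sc = crossing_scan(P);
  int n = (int)sc.cr.size();
  IntegerVector ii(n), jj(n), sg(n), ov(n);
  NumericVector ti(n), tj(n), xx(n), yy(n);
  for (int k = 0; k < n; ++k) {
    ii[k] = sc.cr[k].i;
    jj[k] = sc.cr[k].j;
    sg[k] = sc.cr[k].sign;
    ov[k] = sc.cr[k].over;
    ti[k] = sc.cr[k].ti;
    tj[k] = sc.cr[k].tj;
    xx[k] = sc.cr[k].x;
    yy[k] = sc.cr[k].y;
  }
  return List::create(_["ok"] = sc.ok, _["dz"] = sc.dz, _["i"] = ii, _["j"] = jj,
                      _["ti"] = ti, _["tj"] = tj, _["x"] = xx, _["y"] = yy,
                      _["sign"] = sg, _["over"] = ov);
}

// Signed projected-crossing sum restricted to non-adjacent pairs touching
// the given 0-based segment set (each pair counted once). Used by the
// incremental energy update; shares the scan geometry above.
// [[Rcpp::export]]
List cpp_partial_dz(NumericMatrix V, IntegerVector segs) {
  Chain P = mat_to_chain(V);
  TopoScan sc = crossing_scan(P);
  if (!sc.ok) return List::create(_["ok"] = false, _["dz"] = NA_INTEGER);
  std::vector<bool> in_set(P.size(), false);
  for (int k = 0; k < segs.size(); ++k) in_set[modi(segs[k], (int)P.size())] = true;
  int dz = 0;
  for (size_t k = 0; k < sc.cr.size(); ++k) {
    if (in_set[sc.cr[k].i] || in_set[sc.cr[k].j]) dz += sc.cr[k].sign;
  }
  return List::create(_["ok"] = true, _["dz"] = dz);
}

// [[Rcpp::export]]
List cpp_twist_z(NumericMatrix V) {
  Chain P = mat_to_chain(V);
  bool ok = true;
  double tw = twist_z(P, ok);
  return List::create(_["ok"] = ok, _["tw"] = tw);
}

// [[Rcpp::export]]
List cpp_alexander(NumericMatrix V, NumericVector tvals) {
  Chain P = mat_to_chain(V);
  TopoScan sc = crossing_scan(P);
  NumericVector dets(tvals.size(), NA_REAL);
  bool unk = true;
  if (sc.ok) {
    for (int k = 0; k < tvals.size(); ++k)
      dets[k] = alexander_det(sc.cr, (int)P.size(), tvals[k]);
    unk = alexander_unknot_exact(sc.cr, (int)P.size());
  }
  return List::create(_["ok"] = sc.ok, _["ncross"] = (int)sc.cr.size(),
                      _["dets"] = dets, _["unknot_exact"] = unk);
}

// [[Rcpp::export]]
List cpp_topo_eval(NumericMatrix V, bool need_knot, bool need_det2) {
  Chain P = mat_to_chain(V);
  double det2 = NA_REAL;
  TopoEval te = topo_eval(P, need_knot, need_det2, &det2);
  return List::create(_["ok"] = te.ok, _["wr"] = te.wr, _["tw"] = te.tw,
                      _["lk"] = te.dz, _["ncross"] = te.ncross,
                      _["unknotted"] = te.unknotted, _["det1"] = te.det1,
                      _["det2"] = det2);
}
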
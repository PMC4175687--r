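#ifndef PLASMIDMC_PMC_H
#define PLASMIDMC_PMC_H

#include <RcppArmadillo.h>
#include <cmath>
#include <vector>

struct V3 {
  double x, y, z;
};

inline V3 v3(double x, double y, double z) { return V3{x, y, z}; }
inline V3 operator+(V3 a, V3 b) { return V3{a.x + b.x, a.y + b.y, a.z + b.z}; }
inline V3 operator-(V3 a, V3 b) { return V3{a.x - b.x, a.y - b.y, a.z - b.z}; }
inline V3 operator*(double s, V3 a) { return V3{s * a.x, s * a.y, s * a.z}; }
inline double dot(V3 a, V3 b) { return a.x * b.x + a.y * b.y + a.z * b.z; }
inline V3 cross(V3 a, V3 b) {
  return V3{a.y * b.z - a.z * b.y, a.z * b.x - a.x * b.z, a.x * b.y - a.y * b.x};
}
inline double norm3(V3 a) { return std::sqrt(dot(a, a)); }
inline V3 unit3(V3 a) {
  double n = norm3(a);
  return V3{a.x / n, a.y / n, a.z / n};
}

// Rodrigues rotation of v about unit axis k by angle.
inline V3 rotate_axis(V3 v, V3 k, double angle) {
  double c = std::cos(angle), s = std::sin(angle);
  V3 kxv = cross(k, v);
  double kv = dot(k, v);
  return V3{v.x * c + kxv.x * s + k.x * kv * (1.0 - c),
            v.y * c + kxv.y * s + k.y * kv * (1.0 - c),
            v.z * c + kxv.z * s + k.z * kv * (1.0 - c)};
}

typedef std::vector<V3> Chain;

inline Chain mat_to_chain(const Rcpp::NumericMatrix& V) {
  Chain c(V.nrow());
  for (int i = 0; i < V.nrow(); ++i) c[i] = V3{V(i, 0), V(i, 1), V(i, 2)};
  return c;
}

inline Rcpp::NumericMatrix chain_to_mat(const Chain& c) {
  Rcpp::NumericMatrix V(c.size(), 3);
  for (size_t i = 0; i < c.size(); ++i) {
    V(i, 0) = c[i].x;
    V(i, 1) = c[i].y;
    V(i, 2) = c[i].z;
  }
  return V;
}

inline int modi(int i, int s) {
  int r = i % s;
  return r < 0 ? r + s : r;
}

// One projected crossing of non-adjacent segments i < j.
struct Crossing {
  int i, j;        // segment indices (segment k runs vertex k -> k+1)
  double ti, tj;   // intersection parameters along each segment
  double x, y;     // projected intersection point
  int sign;        // right-handed crossing sign
  int over;        // which segment passes over (i or j)
};

// Result of one full topology pass over a conformation.
struct TopoScan {
  bool ok;                        // false if the projection was degenerate
  std::vector<Crossing> cr;
  int dz;                         // directional writhe = sum of crossing signs
};

TopoScan crossing_scan(const Chain& P);
double twist_z(const Chain& P, bool& ok);
double alexander_det(const std::vector<Crossing>& cr, int s, double t);

// Full per-trial topology evaluation with degeneracy resampling (random
// rigid rotations drawn from R's RNG). Returns Wr and knot verdict.
struct TopoEval {
  bool ok;
  double wr, tw;
  int dz;
  int ncross;
  bool unknotted;
  double det1;  // |Alexander determinant| at t = -1 (1 for the unknot)
};

TopoEval topo_eval(const Chain& P, bool need_knot, bool need_det2, double* det2out);

// Move machinery (moves.cpp)
struct LocalProposal {
  bool ok;
  int m, attempts;
  V3 vm_new, vl_new, vr_new;
  double dd, dth, dph, psiL, psiR;
};
LocalProposal local_propose(const Chain& P, int m, double r, double l,
                            int max_attempts);
bool flank_on_circle(V3 anchor, V3 vm, V3 fref, double l, double psi, V3& out);

struct ArcMove {
  bool ok;
  int from, len;              // moves vertices from+1 .. from+len (cyclic)
  std::vector<V3> new_pos;
  double theta;
  int m, n;
};
ArcMove crankshaft_move(const Chain& P, int m, int n, double theta,
                        double theta_max);
ArcMove reptation_move(const Chain& P, int i, int j);

#endif
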
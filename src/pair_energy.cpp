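#include <Rcpp.h>
#include <algorithm>
#include <vector>
using namespace Rcpp;

// Pairwise nonbonded terms of the surrogate all-atom energy.
//
// Lennard-Jones-like packing split into attractive (r >= rmin) and repulsive
// (r < rmin) parts with a linear extrapolation below 0.6*rmin so steric
// clashes from grid sampling score poorly but finitely.  Hydrogen bonds are
// scored between polar hydrogens and acceptors on the donor/acceptor
// heavy-atom distance with a hard zero at hb_dmax and a squared-cosine
// angular modulation at the hydrogen; backbone-backbone pairs fall in the
// hb_bb channel, everything else in hb_sc.
//
// hclass: 0 = ordinary atom, 1 = polar hydrogen, 2 = acceptor.
// hparent: 0-based index of a polar hydrogen's donor heavy atom (-1 else).
// excl_a/excl_b: 0-based atom pairs closer than 4 bonds (skipped entirely).
// mov: when use_mov, only pairs touching a movable atom are accumulated.
// incl: virtual atoms carry incl = false and never score.
// [[Rcpp::export(name = ".cpp_pair_terms")]]
NumericVector cpp_pair_terms(NumericMatrix xyz,
                             NumericVector radius,
                             IntegerVector hclass,
                             IntegerVector hparent,
                             LogicalVector bb,
                             LogicalVector incl,
                             LogicalVector mov,
                             bool use_mov,
                             IntegerVector excl_a,
                             IntegerVector excl_b,
                             double cutoff,
                             double eps,
                             double hb_dmax,
                             double hb_dflat) {
  const int n = xyz.nrow();
  std::vector<long long> excl;
  excl.reserve(excl_a.size());
  for (int k = 0; k < excl_a.size(); ++k) {
    long long i = excl_a[k], j = excl_b[k];
    if (i > j) std::swap(i, j);
    excl.push_back(i * (long long)n + j);
  }
  std::sort(excl.begin(), excl.end());
  auto excluded = [&](int i, int j) {
    long long a = i, b = j;
    if (a > b) std::swap(a, b);
    return std::binary_search(excl.begin(), excl.end(), a * (long long)n + b);
  };
  const double cut2 = cutoff * cutoff;
  const double sw_lo = cutoff - 0.5;  // switching region for attraction
  double atr = 0.0, rep = 0.0, hb_bb = 0.0, hb_sc = 0.0;

  for (int i = 0; i < n - 1; ++i) {
    if (!incl[i]) continue;
    const double xi = xyz(i, 0), yi = xyz(i, 1), zi = xyz(i, 2);
    for (int j = i + 1; j < n; ++j) {
      if (!incl[j]) continue;
      if (use_mov && !mov[i] && !mov[j]) continue;
      double dx = xi - xyz(j, 0), dy = yi - xyz(j, 1), dz = zi - xyz(j, 2);
      double r2 = dx * dx + dy * dy + dz * dz;
      if (r2 >= cut2) continue;
      if (excluded(i, j)) continue;
      double r = std::sqrt(r2);

      // packing term
      double rmin = radius[i] + radius[j];
      double lj;
      double r0 = 0.6 * rmin;
      if (r >= r0) {
        double q = rmin / r;
        double q3 = q * q * q, q6 = q3 * q3;
        lj = eps * (q6 * q6 - 2.0 * q6);
      } else {
        // linear continuation of the LJ curve below 0.6*rmin (finite at 0)
        double q = rmin / r0;
        double q3 = q * q * q, q6 = q3 * q3;
        double v0 = eps * (q6 * q6 - 2.0 * q6);
        double s0 = eps * (-12.0 * q6 * q6 + 12.0 * q6) / r0;
        lj = v0 + s0 * (r - r0);
      }
      if (r < rmin) {
        rep += lj + eps;
        atr += -eps;  // attractive channel flat inside rmin
      } else {
        double v = lj;
        if (r > sw_lo) {  // cubic switch to exactly zero at the cutoff
          double t = (cutoff - r) / (cutoff - sw_lo);
          v *= t * t * (3.0 - 2.0 * t);
        }
        atr += v;
      }

      // hydrogen bond (polar H vs acceptor)
      int hi = -1, ai = -1;
      if (hclass[i] == 1 && hclass[j] == 2) { hi = i; ai = j; }
      else if (hclass[j] == 1 && hclass[i] == 2) { hi = j; ai = i; }
      if (hi >= 0) {
        int di = hparent[hi];
        if (di >= 0 && !excluded(di, ai)) {
          double ddx = xyz(di, 0) - xyz(ai, 0);
          double ddy = xyz(di, 1) - xyz(ai, 1);
          double ddz = xyz(di, 2) - xyz(ai, 2);
          double dDA = std::sqrt(ddx * ddx + ddy * ddy + ddz * ddz);
          if (dDA < hb_dmax) {
            double f;
            if (dDA <= hb_dflat) {
              f = -1.0;
            } else {
              double t = (hb_dmax - dDA) / (hb_dmax - hb_dflat);
              f = -(t * t * (3.0 - 2.0 * t));
            }
            // angular factor: cos^2 of the D-H...A deviation from linear
            double ux = xyz(di, 0) - xyz(hi, 0);
            double uy = xyz(di, 1) - xyz(hi, 1);
            double uz = xyz(di, 2) - xyz(hi, 2);
            double vx = xyz(ai, 0) - xyz(hi, 0);
            double vy = xyz(ai, 1) - xyz(hi, 1);
            double vz = xyz(ai, 2) - xyz(hi, 2);
            double nu = std::sqrt(ux * ux + uy * uy + uz * uz);
            double nv = std::sqrt(vx * vx + vy * vy + vz * vz);
            if (nu > 1e-9 && nv > 1e-9) {
              double c = -(ux * vx + uy * vy + uz * vz) / (nu * nv);
              if (c > 0) {
                double e = f * c * c;
                if (bb[hi] && bb[ai]) hb_bb += e; else hb_sc += e;
              }
            }
          }
        }
      }
    }
  }
  return NumericVector::create(_["fa_atr"] = atr, _["fa_rep"] = rep,
                               _["hbond_bb"] = hb_bb, _["hbond_sc"] = hb_sc);
}

// Minimum heavy-atom pair distance between two atom index sets (1-based),
// used for clash checks in the fixture generator.
// [[Rcpp::export(name = ".cpp_min_dist")]]
double cpp_min_dist(NumericMatrix xyz, IntegerVector set1, IntegerVector set2) {
  double best = R_PosInf;
  for (int a = 0; a < set1.size(); ++a) {
    int i = set1[a] - 1;
    for (int b = 0; b < set2.size(); ++b) {
      int j = set2[b] - 1;
      if (i == j) continue;
      double dx = xyz(i, 0) - xyz(j, 0);
      double dy = xyz(i, 1) - xyz(j, 1);
      double dz = xyz(i, 2) - xyz(j, 2);
      double d = std::sqrt(dx * dx + dy * dy + dz * dz);
      if (d < best) best = d;
    }
  }
  return best;
}

// Apply a sequence of torsion moves to a coordinate matrix: for each move,
// rotate the listed atoms about the B->C axis so the dihedral
// (A, B, C, D) + off reaches the target value (degrees).  Sense matches
// the R-side move descriptors (+1 when the D side moves).
// [[Rcpp::export(name = ".cpp_apply_moves")]]
NumericMatrix cpp_apply_moves(NumericMatrix xyz_in,
                              IntegerVector A, IntegerVector B,
                              IntegerVector C, IntegerVector D,
                              NumericVector off, IntegerVector sense,
                              List moving, NumericVector target) {
  NumericMatrix xyz = clone(xyz_in);
  const double d2r = M_PI / 180.0;
  for (int m = 0; m < A.size(); ++m) {
    int a = A[m] - 1, b = B[m] - 1, c = C[m] - 1, d = D[m] - 1;
    double b1[3], b2[3], b3[3];
    for (int k = 0; k < 3; ++k) {
      b1[k] = xyz(b, k) - xyz(a, k);
      b2[k] = xyz(c, k) - xyz(b, k);
      b3[k] = xyz(d, k) - xyz(c, k);
    }
    double n1[3] = {b1[1]*b2[2]-b1[2]*b2[1], b1[2]*b2[0]-b1[0]*b2[2],
                    b1[0]*b2[1]-b1[1]*b2[0]};
    double n2[3] = {b2[1]*b3[2]-b2[2]*b3[1], b2[2]*b3[0]-b2[0]*b3[2],
                    b2[0]*b3[1]-b2[1]*b3[0]};
    double nb2 = std::sqrt(b2[0]*b2[0]+b2[1]*b2[1]+b2[2]*b2[2]);
    double m1[3] = {n1[1]*b2[2]-n1[2]*b2[1], n1[2]*b2[0]-n1[0]*b2[2],
                    n1[0]*b2[1]-n1[1]*b2[0]};
    double x = n1[0]*n2[0]+n1[1]*n2[1]+n1[2]*n2[2];
    double y = (m1[0]*n2[0]+m1[1]*n2[1]+m1[2]*n2[2]) / nb2;
    double cur = std::atan2(y, x) / d2r + off[m];
    // wrap to [-180, 180)
    double delta = target[m] - cur;
    delta -= 360.0 * std::floor((delta + 180.0) / 360.0);
    if (std::fabs(delta) < 1e-12) continue;
    double ang = -sense[m] * delta * d2r;
    double u[3] = {b2[0]/nb2, b2[1]/nb2, b2[2]/nb2};
    double ca = std::cos(ang), sa = std::sin(ang);
    IntegerVector mv = moving[m];
    for (int q = 0; q < mv.size(); ++q) {
      int i = mv[q] - 1;
      double p[3] = {xyz(i,0)-xyz(c,0), xyz(i,1)-xyz(c,1), xyz(i,2)-xyz(c,2)};
      double dotpu = p[0]*u[0]+p[1]*u[1]+p[2]*u[2];
      double cr[3] = {u[1]*p[2]-u[2]*p[1], u[2]*p[0]-u[0]*p[2],
                      u[0]*p[1]-u[1]*p[0]};
      for (int k = 0; k < 3; ++k)
        xyz(i, k) = xyz(c, k) + p[k]*ca + cr[k]*sa + u[k]*dotpu*(1.0-ca);
    }
  }
  return xyz;
}
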
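// Core numerics for non-sequential pocket alignment:
//  - O(n^3) Hungarian solver for the linear assignment subproblem
//  - Kabsch least-squares superposition
//  - the alternating assign/superpose loop over deterministic rotation seeds
// Compiled because calibration runs the full alignment on tens of thousands
// of pocket pairs.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

// Shortest-augmenting-path Hungarian algorithm; square min-cost assignment.
// Returns col_of_row (0-based), deterministic for a given cost matrix.
static arma::ivec lap_min(const arma::mat& a) {
  const int n = a.n_rows;
  const double INF = std::numeric_limits<double>::infinity();
  std::vector<double> u(n + 1, 0.0), v(n + 1, 0.0);
  std::vector<int> p(n + 1, 0), way(n + 1, 0);
  for (int i = 1; i <= n; ++i) {
    p[0] = i;
    int j0 = 0;
    std::vector<double> minv(n + 1, INF);
    std::vector<char> used(n + 1, 0);
    do {
      used[j0] = 1;
      int i0 = p[j0], j1 = -1;
      double delta = INF;
      for (int j = 1; j <= n; ++j) {
        if (used[j]) continue;
        double cur = a(i0 - 1, j - 1) - u[i0] - v[j];
        if (cur < minv[j]) { minv[j] = cur; way[j] = j0; }
        if (minv[j] < delta) { delta = minv[j]; j1 = j; }
      }
      for (int j = 0; j <= n; ++j) {
        if (used[j]) { u[p[j]] += delta; v[j] -= delta; }
        else minv[j] -= delta;
      }
      j0 = j1;
    } while (p[j0] != 0);
    do { int j1 = way[j0]; p[j0] = p[j1]; j0 = j1; } while (j0);
  }
  arma::ivec col_of_row(n);
  for (int j = 1; j <= n; ++j) col_of_row(p[j] - 1) = j - 1;
  return col_of_row;
}

// One-to-one correspondence between point sets A (n1 x 3) and Bt (n2 x 3,
// already transformed), gated at d2max on squared distance. Maximal size
// first, then minimal total squared distance: forbidden/dummy cells cost BIG,
// with BIG exceeding the sum of all admissible costs.
static arma::imat assign_gated(const arma::mat& A, const arma::mat& Bt,
                               double d2max) {
  const int n1 = A.n_rows, n2 = Bt.n_rows, n = std::max(n1, n2);
  arma::mat d2(n1, n2);
  double allowed_sum = 0.0;
  for (int i = 0; i < n1; ++i)
    for (int j = 0; j < n2; ++j) {
      double dd = arma::accu(arma::square(A.row(i) - Bt.row(j)));
      d2(i, j) = dd;
      if (dd <= d2max) allowed_sum += dd;
    }
  const double BIG = allowed_sum + 1.0;
  arma::mat cost(n, n, arma::fill::value(BIG));
  for (int i = 0; i < n1; ++i)
    for (int j = 0; j < n2; ++j)
      if (d2(i, j) <= d2max) cost(i, j) = d2(i, j);
  arma::ivec col = lap_min(cost);
  int k = 0;
  for (int i = 0; i < n1; ++i)
    if (col(i) < n2 && cost(i, col(i)) < BIG) ++k;
  arma::imat map(k, 2);
  k = 0;
  for (int i = 0; i < n1; ++i)
    if (col(i) < n2 && cost(i, col(i)) < BIG) {
      map(k, 0) = i; map(k, 1) = col(i); ++k;
    }
  return map;
}

struct Sup { arma::mat33 R; arma::vec3 t; double rmsd; };

// Least-squares proper rotation + translation mapping B onto A.
static Sup kabsch(const arma::mat& A, const arma::mat& B) {
  arma::rowvec ca = arma::mean(A, 0), cb = arma::mean(B, 0);
  arma::mat Ac = A.each_row() - ca, Bc = B.each_row() - cb;
  arma::mat H = Bc.t() * Ac;
  arma::mat U, V;
  arma::vec s;
  arma::svd(U, s, V, H);
  double d = arma::det(V * U.t());
  arma::mat D = arma::eye(3, 3);
  D(2, 2) = d;
  Sup out;
  out.R = V * D * U.t();
  out.t = ca.t() - out.R * cb.t();
  arma::mat Bt = B * out.R.t();
  Bt.each_row() += out.t.t();
  out.rmsd = std::sqrt(arma::accu(arma::square(A - Bt)) / A.n_rows);
  return out;
}

// Halton low-discrepancy sequence (deterministic rotation seeds).
static double halton(int idx, int base) {
  double f = 1.0, r = 0.0;
  while (idx > 0) {
    f /= base;
    r += f * (idx % base);
    idx /= base;
  }
  return r;
}

// Shoemake map: three uniforms -> uniform unit quaternion -> rotation matrix.
static arma::mat33 quat_rot(double u1, double u2, double u3) {
  const double two_pi = 2.0 * M_PI;
  double q1 = std::sqrt(1.0 - u1) * std::sin(two_pi * u2);
  double q2 = std::sqrt(1.0 - u1) * std::cos(two_pi * u2);
  double q3 = std::sqrt(u1) * std::sin(two_pi * u3);
  double q4 = std::sqrt(u1) * std::cos(two_pi * u3);
  arma::mat33 R;
  R(0,0) = 1 - 2*(q3*q3 + q4*q4); R(0,1) = 2*(q2*q3 - q1*q4); R(0,2) = 2*(q2*q4 + q1*q3);
  R(1,0) = 2*(q2*q3 + q1*q4); R(1,1) = 1 - 2*(q2*q2 + q4*q4); R(1,2) = 2*(q3*q4 - q1*q2);
  R(2,0) = 2*(q2*q4 - q1*q3); R(2,1) = 2*(q3*q4 + q1*q2); R(2,2) = 1 - 2*(q2*q2 + q3*q3);
  return R;
}

// Canonical principal-axis frame of a centered point cloud. The frame must
// be covariant under rigid motion so that rotation seeds composed in it make
// the whole alignment rigid-motion invariant: eigenvector signs are fixed by
// the (rotation-invariant) third moment of the projections, and the last
// axis is the cross product of the first two, so the frame is proper.
static arma::mat33 pa_frame(const arma::mat& C) {
  arma::mat33 cov = (C.t() * C) / C.n_rows;
  arma::vec eval;
  arma::mat evec;
  arma::eig_sym(eval, evec, cov);
  for (int d = 0; d < 2; ++d) {
    arma::vec proj = C * evec.col(d);
    double skew = arma::accu(arma::pow(proj, 3));
    if (skew < 0) evec.col(d) *= -1.0;
  }
  evec.col(2) = arma::cross(evec.col(0), evec.col(1));
  return evec;
}

// [[Rcpp::export(name = ".cpp_assign")]]
IntegerMatrix cpp_assign(const arma::mat& A, const arma::mat& Bt, double dmax) {
  arma::imat m = assign_gated(A, Bt, dmax * dmax);
  IntegerMatrix out(m.n_rows, 2);
  for (arma::uword i = 0; i < m.n_rows; ++i) {
    out(i, 0) = m(i, 0) + 1;  // 1-based for R
    out(i, 1) = m(i, 1) + 1;
  }
  return out;
}

// [[Rcpp::export(name = ".cpp_kabsch")]]
List cpp_kabsch(const arma::mat& A, const arma::mat& B) {
  Sup s = kabsch(A, B);
  return List::create(_["rotation"] = wrap(arma::mat(s.R)), _["translation"] = wrap(s.t),
                      _["rmsd"] = s.rmsd);
}

// Full alternating alignment. Seeds: centroid superposition under the four
// proper principal-axis frames, plus n_seeds Halton/Shoemake rotations
// (skipped when pa_only). Returns the converged result of maximal Q.
// [[Rcpp::export(name = ".cpp_align")]]
List cpp_align(const arma::mat& A, const arma::mat& B, double r0, double dmax,
               int n_seeds, int max_iter, double tol, bool pa_only) {
  const int n1 = A.n_rows, n2 = B.n_rows;
  arma::rowvec ca = arma::mean(A, 0), cb = arma::mean(B, 0);
  arma::mat Ac = A.each_row() - ca, Bc = B.each_row() - cb;

  std::vector<arma::mat33> seeds;
  arma::mat33 EA = pa_frame(Ac), EB = pa_frame(Bc);
  const double sgn[4][3] = {{1,1,1}, {1,-1,-1}, {-1,1,-1}, {-1,-1,1}};
  for (int s = 0; s < 4; ++s) {
    arma::mat33 S = arma::zeros(3, 3);
    for (int d = 0; d < 3; ++d) S(d, d) = sgn[s][d];
    seeds.push_back(EA * S * EB.t());
  }
  // quasi-uniform seeds are composed in the canonical frames (EA * R * EB')
  // so the seed set, like the principal-axis seeds, is rigid-motion
  // covariant
  if (!pa_only)
    for (int s = 1; s <= n_seeds; ++s)
      seeds.push_back(EA * quat_rot(halton(s, 2), halton(s, 3),
                                    halton(s, 5)) * EB.t());

  double best_q = -1.0, best_rmsd = NA_REAL;
  arma::imat best_map;
  Sup best_sup;
  bool have = false;

  for (size_t s = 0; s < seeds.size(); ++s) {
    Sup cur;
    cur.R = seeds[s];
    cur.t = ca.t() - cur.R * cb.t();
    double prev_rmsd = -1.0, rmsd = NA_REAL;
    arma::imat map;
    bool ok = false;
    for (int it = 0; it < max_iter; ++it) {
      arma::mat Bt = B * cur.R.t();
      Bt.each_row() += cur.t.t();
      map = assign_gated(A, Bt, dmax * dmax);
      if (map.n_rows < 3) { ok = false; break; }
      arma::mat Am(map.n_rows, 3), Bm(map.n_rows, 3);
      for (arma::uword i = 0; i < map.n_rows; ++i) {
        Am.row(i) = A.row(map(i, 0));
        Bm.row(i) = B.row(map(i, 1));
      }
      Sup fit = kabsch(Am, Bm);
      cur.R = fit.R; cur.t = fit.t;
      rmsd = fit.rmsd;
      ok = true;
      if (prev_rmsd >= 0 && std::abs(prev_rmsd - rmsd) < tol) break;
      prev_rmsd = rmsd;
    }
    if (!ok) continue;
    int na = map.n_rows;
    double q = (double)na * na /
               ((1.0 + (rmsd / r0) * (rmsd / r0)) * n1 * n2);
    if (q > best_q + 1e-15) {
      best_q = q; best_rmsd = rmsd; best_map = map; best_sup = cur;
      have = true;
    }
  }

  if (!have) {
    return List::create(_["n_align"] = 0, _["rmsd"] = NA_REAL, _["q"] = 0.0,
                        _["mapping"] = IntegerMatrix(0, 2),
                        _["rotation"] = wrap(arma::eye(3, 3)),
                        _["translation"] = wrap(arma::zeros(3)));
  }
  IntegerMatrix mout(best_map.n_rows, 2);
  for (arma::uword i = 0; i < best_map.n_rows; ++i) {
    mout(i, 0) = best_map(i, 0) + 1;
    mout(i, 1) = best_map(i, 1) + 1;
  }
  return List::create(_["n_align"] = (int)best_map.n_rows,
                      _["rmsd"] = best_rmsd, _["q"] = best_q,
                      _["mapping"] = mout,
                      _["rotation"] = wrap(arma::mat(best_sup.R)),
                      _["translation"] = wrap(best_sup.t));
}

// Maximum-weight one-to-one matching on a non-negative rectangular matrix.
// Zero-weight pairs never enter the matching. Ties among maximal-weight
// matchings are broken deterministically toward low (row, col) indices via an
// epsilon bonus (total < 0.5, exact for integer weights).
// [[Rcpp::export(name = ".cpp_mwm")]]
IntegerMatrix cpp_mwm(const arma::mat& W) {
  const int nr = W.n_rows, nc = W.n_cols, n = std::max(nr, nc);
  const double eta = 0.49 / ((double)nr * nc * ((double)nr * nc + 1.0));
  arma::mat gain(n, n, arma::fill::zeros);
  double gmax = 0.0;
  for (int i = 0; i < nr; ++i)
    for (int j = 0; j < nc; ++j) {
      double g = W(i, j);
      if (g > 0) g += ((double)(nr - i) * nc + (nc - j)) * eta;
      gain(i, j) = g;
      if (g > gmax) gmax = g;
    }
  arma::mat cost = gmax - gain;
  arma::ivec col = lap_min(cost);
  int k = 0;
  for (int i = 0; i < nr; ++i)
    if (col(i) < nc && W(i, col(i)) > 0) ++k;
  IntegerMatrix out(k, 2);
  k = 0;
  for (int i = 0; i < nr; ++i)
    if (col(i) < nc && W(i, col(i)) > 0) {
      out(k, 0) = i + 1;
      out(k, 1) = col(i) + 1;
      ++k;
    }
  return out;
}
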
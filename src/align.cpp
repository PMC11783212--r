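// Structural alignment core: Kabsch superposition, TM-score, and a
// TM-align-style iterative dynamic-programming aligner.
//
// Row-vector convention throughout: coordinates are n x 3 matrices and a
// rigid transform acts as  x' = x * R + t  with det(R) = +1.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static void kabsch_core(const arma::mat& A, const arma::mat& B,
                        arma::mat& R, arma::rowvec& t) {
  arma::rowvec ca = arma::mean(A, 0), cb = arma::mean(B, 0);
  arma::mat Ac = A.each_row() - ca;
  arma::mat Bc = B.each_row() - cb;
  arma::mat H = Ac.t() * Bc;            // 3x3
  arma::mat U, V;
  arma::vec s;
  arma::svd(U, s, V, H);
  arma::mat D = arma::eye(3, 3);
  if (arma::det(U * V.t()) < 0) D(2, 2) = -1.0;
  R = U * D * V.t();                    // minimizes ||Ac*R - Bc||
  t = cb - ca * R;
}

// [[Rcpp::export]]
List cpp_kabsch(const arma::mat& A, const arma::mat& B) {
  if (A.n_rows != B.n_rows) stop("coordinate sets differ in length");
  if (A.n_rows < 3) stop("need at least 3 points");
  arma::mat R;
  arma::rowvec t;
  kabsch_core(A, B, R, t);
  arma::mat Am = A * R;
  Am.each_row() += t;
  double rmsd = std::sqrt(arma::accu(arma::square(Am - B)) / A.n_rows);
  return List::create(_["rotation"] = R, _["translation"] = t, _["rmsd"] = rmsd);
}

static double d0_func(double L) {
  double v = 1.24 * std::cbrt(L - 15.0) - 1.8;
  return v < 0.5 ? 0.5 : v;
}

// [[Rcpp::export]]
double cpp_d0(double L) { return d0_func(L); }

// TM-score sum over mapped pairs for transformed A coordinates.
static double tm_sum(const arma::mat& At, const arma::mat& B,
                     const arma::uvec& mi, const arma::uvec& mj, double d0) {
  double s = 0.0, d02 = d0 * d0;
  for (arma::uword k = 0; k < mi.n_elem; ++k) {
    double dx = At(mi[k], 0) - B(mj[k], 0);
    double dy = At(mi[k], 1) - B(mj[k], 1);
    double dz = At(mi[k], 2) - B(mj[k], 2);
    s += 1.0 / (1.0 + (dx * dx + dy * dy + dz * dz) / d02);
  }
  return s;
}

// Needleman-Wunsch with affine gaps (open penalty, zero extension) and free
// terminal gaps. Maximizes sum of S over matched pairs minus gap openings.
// Traceback prefers the diagonal. Returns 0-based match pairs, strictly
// increasing in both indices.
static void dp_align(const arma::mat& S, double gap_open,
                     std::vector<int>& out_i, std::vector<int>& out_j) {
  const int n = S.n_rows, m = S.n_cols;
  const double NEG = -1e30;
  arma::mat M(n + 1, m + 1), Ix(n + 1, m + 1), Iy(n + 1, m + 1);
  M.fill(NEG); Ix.fill(NEG); Iy.fill(NEG);
  M(0, 0) = 0.0;
  for (int i = 1; i <= n; ++i) Ix(i, 0) = 0.0;   // free leading gaps
  for (int j = 1; j <= m; ++j) Iy(0, j) = 0.0;
  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= m; ++j) {
      double prev = std::max(M(i - 1, j - 1),
                             std::max(Ix(i - 1, j - 1), Iy(i - 1, j - 1)));
      M(i, j) = S(i - 1, j - 1) + prev;
      Ix(i, j) = std::max(M(i - 1, j) - gap_open, Ix(i - 1, j));
      Iy(i, j) = std::max(M(i, j - 1) - gap_open, Iy(i, j - 1));
    }
  }
  // free trailing gaps: best M cell on the last row or column
  int bi = n, bj = m;
  double best = NEG;
  for (int i = 1; i <= n; ++i)
    if (M(i, m) > best) { best = M(i, m); bi = i; bj = m; }
  for (int j = 1; j <= m; ++j)
    if (M(n, j) > best) { best = M(n, j); bi = n; bj = j; }
  if (best <= NEG / 2) return;

  // traceback
  std::vector<int> ri, rj;
  int i = bi, j = bj;
  int state = 0;  // 0 = M, 1 = Ix, 2 = Iy
  while (i > 0 && j > 0) {
    if (state == 0) {
      ri.push_back(i - 1);
      rj.push_back(j - 1);
      double prev = M(i, j) - S(i - 1, j - 1);
      // prefer diagonal
      if (std::abs(M(i - 1, j - 1) - prev) < 1e-12) state = 0;
      else if (std::abs(Ix(i - 1, j - 1) - prev) < 1e-12) state = 1;
      else state = 2;
      --i; --j;
    } else if (state == 1) {
      if (std::abs(M(i - 1, j) - gap_open - Ix(i, j)) < 1e-12) state = 0;
      --i;
    } else {
      if (std::abs(M(i, j - 1) - gap_open - Iy(i, j)) < 1e-12) state = 0;
      --j;
    }
  }
  for (int k = (int)ri.size() - 1; k >= 0; --k) {
    out_i.push_back(ri[k]);
    out_j.push_back(rj[k]);
  }
}

// [[Rcpp::export]]
IntegerMatrix cpp_dp(const arma::mat& S, double gap_open) {
  std::vector<int> oi, oj;
  dp_align(S, gap_open, oi, oj);
  IntegerMatrix out(oi.size(), 2);
  for (size_t k = 0; k < oi.size(); ++k) {
    out(k, 0) = oi[k] + 1;  // 1-based for R
    out(k, 1) = oj[k] + 1;
  }
  return out;
}

struct AlnState {
  arma::uvec mi, mj;
  arma::mat R;
  arma::rowvec t;
  double tm;  // under the search normalization
};

// Superpose on the current mapping and evaluate TM under the search d0/norm.
static bool eval_mapping(const arma::mat& A, const arma::mat& B,
                         const arma::uvec& mi, const arma::uvec& mj,
                         double d0s, double lnorm, AlnState& st) {
  if (mi.n_elem < 3) return false;
  arma::mat Am(mi.n_elem, 3), Bm(mi.n_elem, 3);
  for (arma::uword k = 0; k < mi.n_elem; ++k) {
    Am.row(k) = A.row(mi[k]);
    Bm.row(k) = B.row(mj[k]);
  }
  arma::mat R;
  arma::rowvec t;
  kabsch_core(Am, Bm, R, t);
  arma::mat At = A * R;
  At.each_row() += t;
  st.mi = mi; st.mj = mj; st.R = R; st.t = t;
  st.tm = tm_sum(At, B, mi, mj, d0s) / lnorm;
  return true;
}

// One full iterative refinement from a seed mapping; returns the best state
// (by search TM) encountered.
static AlnState refine(const arma::mat& A, const arma::mat& B,
                       arma::uvec mi, arma::uvec mj,
                       double d0s, double lnorm, double gap_open, int max_iter,
                       double d0_dp) {
  AlnState best; best.tm = -1.0;
  AlnState cur;
  std::vector<std::pair<std::vector<int>, std::vector<int>>> seen;
  double prev_tm = -2.0;
  for (int it = 0; it < max_iter; ++it) {
    if (!eval_mapping(A, B, mi, mj, d0s, lnorm, cur)) break;
    if (cur.tm > best.tm) best = cur;
    if (std::abs(cur.tm - prev_tm) < 1e-7) break;       // converged
    if (cur.tm < best.tm - 0.05) break;                 // diverging
    prev_tm = cur.tm;
    // score matrix under current transform
    arma::mat At = A * cur.R;
    At.each_row() += cur.t;
    arma::mat S(A.n_rows, B.n_rows);
    double d02 = d0_dp * d0_dp;
    for (arma::uword i = 0; i < A.n_rows; ++i) {
      for (arma::uword j = 0; j < B.n_rows; ++j) {
        double dx = At(i, 0) - B(j, 0);
        double dy = At(i, 1) - B(j, 1);
        double dz = At(i, 2) - B(j, 2);
        S(i, j) = 1.0 / (1.0 + (dx * dx + dy * dy + dz * dz) / d02);
      }
    }
    std::vector<int> oi, oj;
    dp_align(S, gap_open, oi, oj);
    if (oi.size() < 3) break;
    // convergence: mapping already visited
    bool repeat = false;
    for (auto& pr : seen) {
      if (pr.first == oi && pr.second == oj) { repeat = true; break; }
    }
    if (repeat) break;
    seen.emplace_back(oi, oj);
    mi = arma::conv_to<arma::uvec>::from(oi);
    mj = arma::conv_to<arma::uvec>::from(oj);
  }
  return best;
}

// Full heuristic alignment. seeds: list of integer matrices (1-based, k x 2).
// Search normalization: d0(min(na, nb)), lnorm = min(na, nb); the R wrapper
// recomputes reported TM under both normalizations from the returned mapping
// and transform.
// [[Rcpp::export]]
List cpp_align(const arma::mat& A, const arma::mat& B, List seeds,
               double gap_open, int max_iter, int top_seeds) {
  const double lmin = std::min(A.n_rows, B.n_rows);
  const double d0s = d0_func(lmin);
  const int ns = seeds.size();
  if (ns == 0) stop("no seed mappings");

  // rank seeds by single-superposition TM
  std::vector<std::pair<double, int>> ranked;
  std::vector<arma::uvec> smi(ns), smj(ns);
  for (int s = 0; s < ns; ++s) {
    IntegerMatrix sm = seeds[s];
    arma::uvec mi(sm.nrow()), mj(sm.nrow());
    for (int k = 0; k < sm.nrow(); ++k) {
      mi[k] = sm(k, 0) - 1;
      mj[k] = sm(k, 1) - 1;
    }
    smi[s] = mi; smj[s] = mj;
    AlnState st;
    if (eval_mapping(A, B, mi, mj, d0s, lmin, st))
      ranked.emplace_back(-st.tm, s);  // negative for ascending sort
  }
  if (ranked.empty()) stop("all seed mappings too short");
  std::stable_sort(ranked.begin(), ranked.end());

  AlnState best; best.tm = -1.0;
  int nrun = std::min<int>(top_seeds, ranked.size());
  for (int r = 0; r < nrun; ++r) {
    // prune seeds whose single-superposition TM is far below the best
    // refined TM so far (TM-align-style shortcut)
    if (r > 0 && -ranked[r].first < 0.7 * best.tm) break;
    int s = ranked[r].second;
    AlnState st = refine(A, B, smi[s], smj[s], d0s, lmin, gap_open, max_iter, d0s);
    if (st.tm > best.tm) best = st;
  }
  if (best.tm < 0) stop("alignment failed");

  IntegerMatrix mp(best.mi.n_elem, 2);
  for (arma::uword k = 0; k < best.mi.n_elem; ++k) {
    mp(k, 0) = best.mi[k] + 1;
    mp(k, 1) = best.mj[k] + 1;
  }
  return List::create(_["mapping"] = mp, _["rotation"] = best.R,
                      _["translation"] = best.t, _["tm_search"] = best.tm);
}

// Distinct atoms of set 1 having any atom of set 2 within cutoff, via a
// uniform spatial hash with cell size = cutoff (checks the 27 neighbor cells).
// [[Rcpp::export]]
IntegerVector cpp_clash_atoms(const arma::mat& X1, const arma::mat& X2,
                              double cutoff) {
  if (cutoff <= 0) stop("cutoff must be positive");
  const double inv = 1.0 / cutoff, c2 = cutoff * cutoff;
  // hash X2 into cells
  std::unordered_map<long long, std::vector<int>> grid;
  auto key = [](long long i, long long j, long long k) {
    return ((i + 100000LL) << 42) ^ ((j + 100000LL) << 21) ^ (k + 100000LL);
  };
  for (arma::uword a = 0; a < X2.n_rows; ++a) {
    long long i = (long long)std::floor(X2(a, 0) * inv);
    long long j = (long long)std::floor(X2(a, 1) * inv);
    long long k = (long long)std::floor(X2(a, 2) * inv);
    grid[key(i, j, k)].push_back(a);
  }
  std::vector<int> hits;
  for (arma::uword a = 0; a < X1.n_rows; ++a) {
    long long ci = (long long)std::floor(X1(a, 0) * inv);
    long long cj = (long long)std::floor(X1(a, 1) * inv);
    long long ck = (long long)std::floor(X1(a, 2) * inv);
    bool clash = false;
    for (long long di = -1; di <= 1 && !clash; ++di)
      for (long long dj = -1; dj <= 1 && !clash; ++dj)
        for (long long dk = -1; dk <= 1 && !clash; ++dk) {
          auto it = grid.find(key(ci + di, cj + dj, ck + dk));
          if (it == grid.end()) continue;
          for (int b : it->second) {
            double dx = X1(a, 0) - X2(b, 0);
            double dy = X1(a, 1) - X2(b, 1);
            double dz = X1(a, 2) - X2(b, 2);
            if (dx * dx + dy * dy + dz * dz < c2) { clash = true; break; }
          }
        }
    if (clash) hits.push_back(a + 1);  // 1-based
  }
  return wrap(hits);
}
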
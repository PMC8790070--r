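// Voxel-pair affinity graph for nucleus splitting, the Lanczos spectrum of
// its random-walk Laplacian, and a mean-silhouette helper for selecting the
// number of spectral clusters.

#include <RcppArmadillo.h>
#include <vector>
#include <cmath>

using namespace Rcpp;

// Pairwise similarity rho_ij = p_rd * p_ta * p_td for all voxel pairs of one
// structure. X: voxel positions (um), E: unit orientations, vtm: transmural
// vector of the structure. Pairs with rho below `cutoff` are dropped (their
// contribution to the degrees is negligible by construction). Returns the
// upper triangle as 1-based triplets plus the full degree vector.
// [[Rcpp::export]]
List affinity_pairs_cpp(NumericMatrix X, NumericMatrix E, NumericVector vtm,
                        double sigma_r, double sigma_td, double cutoff) {
  const int n = X.nrow();
  double vn = std::sqrt(vtm[0]*vtm[0] + vtm[1]*vtm[1] + vtm[2]*vtm[2]);
  if (vn <= 0) stop("transmural vector has zero length");
  const double v0 = vtm[0]/vn, v1 = vtm[1]/vn, v2 = vtm[2]/vn;
  const double* X0 = X.begin(); const double* X1 = X0 + n; const double* X2 = X1 + n;
  const double* E0 = E.begin(); const double* E1 = E0 + n; const double* E2 = E1 + n;

  // separable per-voxel terms: transmural coordinate and in-plane factor
  std::vector<double> tcoord(n), aplane(n), la(n);
  for (int i = 0; i < n; ++i) {
    tcoord[i] = X0[i]*v0 + X1[i]*v1 + X2[i]*v2;
    double a = 1.0 - std::fabs(E0[i]*v0 + E1[i]*v1 + E2[i]*v2);
    aplane[i] = a > 0 ? a : 0.0;
    la[i] = a > 0 ? std::log(a) : -INFINITY;
  }
  const double inv2sr = 1.0 / (2.0 * sigma_r * sigma_r);
  const double inv2st = 1.0 / (2.0 * sigma_td * sigma_td);
  const double lcut = std::log(cutoff);

  std::vector<int> ii, jj;
  std::vector<double> xx;
  const size_t cap = (size_t)n * (n - 1) / 2;
  ii.reserve(cap < 20000000 ? cap : 20000000);
  jj.reserve(cap < 20000000 ? cap : 20000000);
  xx.reserve(cap < 20000000 ? cap : 20000000);
  std::vector<double> deg(n, 0.0);

  for (int i = 0; i < n; ++i) {
    const double xi0 = X0[i], xi1 = X1[i], xi2 = X2[i];
    const double ei0 = E0[i], ei1 = E1[i], ei2 = E2[i];
    const double ti = tcoord[i], lai = la[i];
    if (!R_FINITE(lai)) continue;
    double degi = 0.0;
    for (int j = i + 1; j < n; ++j) {
      const double laj = la[j];
      double dt = ti - tcoord[j];
      // log rho = la_i + la_j - dt^2/(2 std^2) - (r_ij^2 + r_ji^2)/(2 sr^2)
      double arg = lai + laj - dt * dt * inv2st;
      if (arg < lcut) continue;
      double d0 = xi0 - X0[j], d1 = xi1 - X1[j], d2 = xi2 - X2[j];
      double dd = d0*d0 + d1*d1 + d2*d2;
      double pj = d0*E0[j] + d1*E1[j] + d2*E2[j];  // proj on E_j
      double pi = d0*ei0 + d1*ei1 + d2*ei2;        // proj on E_i
      double rij2 = dd - pj*pj; if (rij2 < 0) rij2 = 0;
      double rji2 = dd - pi*pi; if (rji2 < 0) rji2 = 0;
      arg -= (rij2 + rji2) * inv2sr;
      if (arg < lcut) continue;
      double rho = std::exp(arg);
      ii.push_back(i + 1); jj.push_back(j + 1); xx.push_back(rho);
      degi += rho; deg[j] += rho;
    }
    deg[i] += degi;
  }
  return List::create(_["i"] = wrap(ii), _["j"] = wrap(jj), _["x"] = wrap(xx),
                      _["degree"] = wrap(deg));
}

// k smallest-absolute eigenvalues (and eigenvectors) of the random-walk
// Laplacian L_rw = I - D^-1 R of the graph given by upper-triangle triplets.
// Eigenvalues of L_rw coincide with those of the symmetric normalized
// Laplacian, so we run a Lanczos (Krylov) iteration on the shifted operator
// M = I + D^-1/2 R D^-1/2 (largest-algebraic mode, no factorization needed)
// and map back: lambda_L = 2 - lambda_M; eigenvectors of L_rw are
// D^-1/2 times those of the symmetric form. Returns NULL if the iteration
// fails to converge (caller falls back to a dense solve).
// [[Rcpp::export]]
SEXP lrw_spectrum_cpp(IntegerVector ti, IntegerVector tj, NumericVector tx,
                      int n, int k, double tol) {
  const R_xlen_t m = ti.size();
  arma::vec deg(n, arma::fill::zeros);
  for (R_xlen_t t = 0; t < m; ++t) {
    deg[ti[t] - 1] += tx[t];
    deg[tj[t] - 1] += tx[t];
  }
  if (deg.min() <= 0) stop("graph has an isolated vertex; exclude it first");
  arma::vec dis = 1.0 / arma::sqrt(deg);

  // CSC assembly in O(nnz): symmetric entries plus unit diagonal. Column
  // counts -> prefix sums -> scatter; within each column, rows end up sorted
  // because entries are scattered in ascending row order (upper triangle has
  // ti < tj, so pass 1 in ti order fills lower rows first, and the diagonal
  // and transposed entries are interleaved by a row-ordered merge below).
  const arma::uword nnz = 2 * (arma::uword)m + n;
  arma::uvec colptr(n + 1, arma::fill::zeros);
  for (R_xlen_t t = 0; t < m; ++t) {
    colptr[tj[t]]++;          // entry (ti-1, tj-1): column tj-1 -> slot tj
    colptr[ti[t]]++;          // entry (tj-1, ti-1): column ti-1 -> slot ti
  }
  for (int c = 0; c < n; ++c) colptr[c + 1]++;   // diagonal
  for (int c = 0; c < n; ++c) colptr[c + 1] += colptr[c];
  arma::uvec rowind(nnz);
  arma::vec val(nnz);
  // scatter in three row-ordered sweeps per column (upper rows < c, then the
  // diagonal, then transposed rows > c); the triplets arrive with ascending
  // (i, j), so each sweep appends rows in increasing order and the CSC ends
  // up row-sorted within every column
  arma::uvec pos(n);
  for (int c = 0; c < n; ++c) pos[c] = colptr[c];
  for (R_xlen_t t = 0; t < m; ++t) {       // upper triangle: row ti-1 < col tj-1
    int a = ti[t] - 1, b = tj[t] - 1;
    double w = tx[t] * dis[a] * dis[b];
    arma::uword p = pos[b]++;
    rowind[p] = a; val[p] = w;
  }
  for (int c = 0; c < n; ++c) {            // diagonal
    arma::uword p = pos[c]++;
    rowind[p] = c; val[p] = 1.0;
  }
  for (R_xlen_t t = 0; t < m; ++t) {       // transposed: row tj-1 > col ti-1
    int a = ti[t] - 1, b = tj[t] - 1;
    double w = tx[t] * dis[a] * dis[b];
    arma::uword p = pos[a]++;
    rowind[p] = b; val[p] = w;
  }
  arma::sp_mat M(rowind, colptr, val, n, n);

  if (k >= n) k = n - 1;
  if (k < 1) return R_NilValue;
  arma::vec eval;
  arma::mat evec;
  bool ok = arma::eigs_sym(eval, evec, M, k, "la", tol);
  if (!ok || (int)eval.n_elem < k) return R_NilValue;

  // arma returns ascending eigenvalues of M; reverse so lambda_L ascends
  arma::uvec ord = arma::sort_index(2.0 - eval, "ascend");
  NumericVector values(k);
  NumericMatrix vectors(n, k);
  for (int c = 0; c < k; ++c) {
    arma::uword oc = ord[c];
    values[c] = 2.0 - eval[oc];
    arma::vec v = evec.col(oc) % dis;
    v /= arma::norm(v);
    for (int r = 0; r < n; ++r) vectors(r, c) = v[r];
  }
  return List::create(_["values"] = values, _["vectors"] = vectors);
}

// Mean silhouette of a labeled embedding (Euclidean distances, computed
// pairwise without materializing the distance matrix).
// [[Rcpp::export]]
double mean_silhouette_cpp(NumericMatrix emb, IntegerVector labels, int k) {
  const int n = emb.nrow(), d = emb.ncol();
  std::vector<int> cnt(k, 0);
  for (int i = 0; i < n; ++i) {
    if (labels[i] < 1 || labels[i] > k) stop("labels must lie in 1..k");
    cnt[labels[i] - 1]++;
  }
  // sums(i, g): total distance from point i to all points of cluster g
  std::vector<double> sums((size_t)n * k, 0.0);
  for (int i = 0; i < n; ++i) {
    const int gi = labels[i] - 1;
    for (int j = i + 1; j < n; ++j) {
      double acc = 0.0;
      for (int c = 0; c < d; ++c) {
        double df = emb(i, c) - emb(j, c);
        acc += df * df;
      }
      double dist = std::sqrt(acc);
      sums[(size_t)i * k + (labels[j] - 1)] += dist;
      sums[(size_t)j * k + gi] += dist;
    }
  }
  double stot = 0.0;
  for (int i = 0; i < n; ++i) {
    int gi = labels[i] - 1;
    double a = cnt[gi] > 1 ? sums[(size_t)i * k + gi] / (cnt[gi] - 1) : 0.0;
    double b = R_PosInf;
    for (int g = 0; g < k; ++g) {
      if (g == gi || cnt[g] == 0) continue;
      double mb = sums[(size_t)i * k + g] / cnt[g];
      if (mb < b) b = mb;
    }
    double s;
    if (cnt[gi] <= 1) s = 0.0;                  // singleton convention
    else if (!R_FINITE(b)) s = 0.0;             // single non-empty cluster
    else {
      double mx = a > b ? a : b;
      s = mx > 0 ? (b - a) / mx : 0.0;
    }
    stot += s;
  }
  return stot / n;
}
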
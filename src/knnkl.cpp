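#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

// Squared Euclidean cross-distance matrix (n x m), clamped at 0 to absorb
// cancellation error in the |a|^2 + |b|^2 - 2ab expansion.
static arma::mat cross_dist2(const arma::mat& A, const arma::mat& B) {
  arma::vec an = arma::sum(arma::square(A), 1);
  arma::vec bn = arma::sum(arma::square(B), 1);
  arma::mat D = -2.0 * (A * B.t());
  D.each_col() += an;
  D.each_row() += bn.t();
  D.transform([](double x) { return x < 0.0 ? 0.0 : x; });
  return D;
}

// k-th smallest squared distance from each row of A to the other rows of A.
static arma::vec within_kth2(const arma::mat& A, int k) {
  const int n = A.n_rows;
  arma::mat D = cross_dist2(A, A);
  arma::vec out(n);
  std::vector<double> row(n - 1);
  for (int i = 0; i < n; ++i) {
    int idx = 0;
    for (int j = 0; j < n; ++j)
      if (j != i) row[idx++] = D(i, j);
    std::nth_element(row.begin(), row.begin() + (k - 1), row.end());
    out[i] = std::max(row[k - 1], 1e-300);
  }
  return out;
}

// k-th smallest entry of each row of a distance matrix.
static arma::vec rows_kth2(const arma::mat& D, int k) {
  const int n = D.n_rows, m = D.n_cols;
  arma::vec out(n);
  std::vector<double> row(m);
  for (int i = 0; i < n; ++i) {
    for (int j = 0; j < m; ++j) row[j] = D(i, j);
    std::nth_element(row.begin(), row.begin() + (k - 1), row.end());
    out[i] = std::max(row[k - 1], 1e-300);
  }
  return out;
}

// Directed k-NN divergence estimate D(P||Q): rho2/nu2 hold squared k-th
// neighbour distances within the P sample and from P into the Q sample.
// The 1/2 factor converts the squared-distance log ratio.
static double kl_directed(const arma::vec& rho2, const arma::vec& nu2,
                          int d, int m) {
  const int n = rho2.n_elem;
  double s = 0.0;
  for (int i = 0; i < n; ++i) s += std::log(nu2[i] / rho2[i]);
  return 0.5 * static_cast<double>(d) / n * s +
         std::log(static_cast<double>(m) / (n - 1.0));
}

// [[Rcpp::export]]
double knn_sym_kl_cpp(const arma::mat& A, const arma::mat& B, int k) {
  const int d = A.n_cols;
  arma::vec rhoA = within_kth2(A, k);
  arma::vec rhoB = within_kth2(B, k);
  arma::mat D = cross_dist2(A, B);
  arma::vec nuA = rows_kth2(D, k);
  arma::mat Dt = D.t();
  arma::vec nuB = rows_kth2(Dt, k);
  double kl = kl_directed(rhoA, nuA, d, B.n_rows) +
              kl_directed(rhoB, nuB, d, A.n_rows);
  return kl < 0.0 ? 0.0 : kl;
}

// Full region-by-region MIND matrix for one subject. feats is a list of
// vertex-by-feature matrices, one per region. Within-region k-th neighbour
// distances are computed once per region; all cross-pair work runs on
// reused buffers with hand-rolled loops (the matrices are far too small
// for BLAS dispatch to pay off).
// [[Rcpp::export]]
arma::mat mind_matrix_cpp(const List& feats, int k) {
  const int R = feats.size();
  std::vector<arma::mat> X(R);
  std::vector<arma::vec> rho2(R), logrho(R);
  int nmax = 0;
  for (int r = 0; r < R; ++r) {
    X[r] = as<arma::mat>(feats[r]);   // column-major: vertex index fastest
    rho2[r] = within_kth2(X[r], k);
    logrho[r] = arma::log(rho2[r]);
    nmax = std::max(nmax, static_cast<int>(X[r].n_rows));
  }
  const int d = X[0].n_cols;
  std::vector<double> D(static_cast<size_t>(nmax) * nmax);
  std::vector<double> scratch(nmax);
  arma::mat S(R, R, arma::fill::ones);

  for (int a = 0; a < R; ++a) {
    Rcpp::checkUserInterrupt();
    const int na = X[a].n_rows;
    for (int b = a + 1; b < R; ++b) {
      const int nb = X[b].n_rows;
      // D[i + na*j] = squared distance between X[a] row i and X[b] row j
      std::fill(D.begin(), D.begin() + static_cast<size_t>(na) * nb, 0.0);
      for (int f = 0; f < d; ++f) {
        const double* xa = X[a].colptr(f);
        const double* xb = X[b].colptr(f);
        for (int j = 0; j < nb; ++j) {
          double* col = D.data() + static_cast<size_t>(na) * j;
          const double bj = xb[j];
          for (int i = 0; i < na; ++i) {
            const double diff = xa[i] - bj;
            col[i] += diff * diff;
          }
        }
      }
      double sum_a = 0.0, sum_b = 0.0;
      for (int j = 0; j < nb; ++j) {       // nu for X[b] points: columns
        const double* col = D.data() + static_cast<size_t>(na) * j;
        std::copy(col, col + na, scratch.begin());
        std::nth_element(scratch.begin(), scratch.begin() + (k - 1),
                         scratch.begin() + na);
        sum_b += std::log(std::max(scratch[k - 1], 1e-300)) - logrho[b][j];
      }
      for (int i = 0; i < na; ++i) {       // nu for X[a] points: rows
        for (int j = 0; j < nb; ++j)
          scratch[j] = D[static_cast<size_t>(na) * j + i];
        std::nth_element(scratch.begin(), scratch.begin() + (k - 1),
                         scratch.begin() + nb);
        sum_a += std::log(std::max(scratch[k - 1], 1e-300)) - logrho[a][i];
      }
      double kl = 0.5 * static_cast<double>(d) / na * sum_a +
                  std::log(static_cast<double>(nb) / (na - 1.0)) +
                  0.5 * static_cast<double>(d) / nb * sum_b +
                  std::log(static_cast<double>(na) / (nb - 1.0));
      if (kl < 0.0) kl = 0.0;
      const double s = 1.0 / (1.0 + kl);
      S(a, b) = s;
      S(b, a) = s;
    }
  }
  return S;
}
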
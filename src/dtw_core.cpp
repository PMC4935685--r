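#include <Rcpp.h>
using namespace Rcpp;

// Dynamic-time-warping core. A and B are frame matrices whose columns are
// already on a common scale (acoustic features divided by their pooled SDs,
// the time column premultiplied by q / L_max), so the local distance is the
// plain Euclidean distance between rows. Steps {(1,0),(0,1),(1,1)} with unit
// weights; the optimal path minimizes the accumulated local distance from
// (0,0) to (n-1,m-1), and the returned dissimilarity is that path's sum
// divided by its length in cells. Ties are broken deterministically
// (diagonal, then vertical, then horizontal).
// [[Rcpp::export]]
double dtw_core(NumericMatrix A, NumericMatrix B) {
  const int n = A.nrow(), m = B.nrow(), d = A.ncol();
  if (n == 0 || m == 0) stop("empty unit in dtw_core");
  if (B.ncol() != d) stop("feature dimension mismatch in dtw_core");

  std::vector<double> cost(n * m);
  std::vector<int> len(n * m);

  for (int i = 0; i < n; ++i) {
    for (int j = 0; j < m; ++j) {
      double s = 0.0;
      for (int k = 0; k < d; ++k) {
        const double diff = A(i, k) - B(j, k);
        s += diff * diff;
      }
      const double local = std::sqrt(s);
      const int idx = i * m + j;
      if (i == 0 && j == 0) {
        cost[idx] = local;
        len[idx] = 1;
      } else {
        double best = R_PosInf;
        int blen = 0;
        if (i > 0 && j > 0) {                 // diagonal
          best = cost[(i - 1) * m + (j - 1)];
          blen = len[(i - 1) * m + (j - 1)];
        }
        if (i > 0 && cost[(i - 1) * m + j] < best) {   // vertical
          best = cost[(i - 1) * m + j];
          blen = len[(i - 1) * m + j];
        }
        if (j > 0 && cost[i * m + (j - 1)] < best) {   // horizontal
          best = cost[i * m + (j - 1)];
          blen = len[i * m + (j - 1)];
        }
        cost[idx] = best + local;
        len[idx] = blen + 1;
      }
    }
  }
  return cost[n * m - 1] / len[n * m - 1];
}

// Full pairwise DTW matrix. Each element of `mats` is a frame matrix whose
// first columns are the SD-scaled acoustic features and whose LAST column is
// the raw frame time in ms; `durs` holds unit durations. For each pair the
// time column is scaled by q / max(dur_i, dur_j) before the shared DP.
// [[Rcpp::export]]
NumericMatrix dtw_pairwise(List mats, NumericVector durs, double q) {
  const int n = mats.size();
  std::vector<NumericMatrix> M(n);
  for (int i = 0; i < n; ++i) M[i] = as<NumericMatrix>(mats[i]);
  NumericMatrix D(n, n);
  for (int i = 0; i < n - 1; ++i) {
    const NumericMatrix &A = M[i];
    const int na = A.nrow(), d = A.ncol();
    for (int j = i + 1; j < n; ++j) {
      const NumericMatrix &B = M[j];
      const int nb = B.nrow();
      const double tscale = q / std::max(durs[i], durs[j]);
      std::vector<double> cost(na * nb);
      std::vector<int> len(na * nb);
      for (int a = 0; a < na; ++a) {
        for (int b = 0; b < nb; ++b) {
          double s = 0.0;
          for (int k = 0; k < d - 1; ++k) {
            const double diff = A(a, k) - B(b, k);
            s += diff * diff;
          }
          const double tdiff = tscale * (A(a, d - 1) - B(b, d - 1));
          s += tdiff * tdiff;
          const double local = std::sqrt(s);
          const int idx = a * nb + b;
          if (a == 0 && b == 0) {
            cost[idx] = local;
            len[idx] = 1;
          } else {
            double best = R_PosInf;
            int blen = 0;
            if (a > 0 && b > 0) {
              best = cost[(a - 1) * nb + (b - 1)];
              blen = len[(a - 1) * nb + (b - 1)];
            }
            if (a > 0 && cost[(a - 1) * nb + b] < best) {
              best = cost[(a - 1) * nb + b];
              blen = len[(a - 1) * nb + b];
            }
            if (b > 0 && cost[a * nb + (b - 1)] < best) {
              best = cost[a * nb + (b - 1)];
              blen = len[a * nb + (b - 1)];
            }
            cost[idx] = best + local;
            len[idx] = blen + 1;
          }
        }
      }
      D(i, j) = D(j, i) = cost[na * nb - 1] / len[na * nb - 1];
    }
  }
  return D;
}
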
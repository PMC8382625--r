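#include <Rcpp.h>
using namespace Rcpp;

// Shared Lloyd iteration: runs to assignment convergence (or max_iter) from
// the centers currently in `centers`.  Squared Euclidean; distance ties break
// toward the lowest cluster index; a cluster that empties is reseeded to the
// point farthest from its current centroid and iteration continues.
// `xr` is the data in row-major layout (point i at xr + i*p) for cache-local
// access in the assignment step.
static double lloyd_run(const std::vector<double>& xr, int n, int p,
                        std::vector<double>& centers, std::vector<int>& assign,
                        int k, int max_iter, int& iter_out) {
  std::vector<int> assign_old(n, -1), count(k);
  std::vector<double> dmin(n), csq(k);
  int iter = 0;
  while (iter < max_iter) {
    ++iter;
    // assignment step: minimize ||x||^2 - 2 x.c + ||c||^2; the first term is
    // constant across centers, so compare h(c) = ||c||^2/2 - x.c instead
    for (int j = 0; j < k; ++j) {
      double s = 0.0;
      const double* c = centers.data() + j * p;
      for (int v = 0; v < p; ++v) s += c[v] * c[v];
      csq[j] = 0.5 * s;
    }
    std::fill(count.begin(), count.end(), 0);
    for (int i = 0; i < n; ++i) {
      const double* x = xr.data() + i * p;
      double hbest = R_PosInf;
      int jbest = 0;
      for (int j = 0; j < k; ++j) {
        const double* c = centers.data() + j * p;
        double dot = 0.0;
        for (int v = 0; v < p; ++v) dot += x[v] * c[v];
        double h = csq[j] - dot;
        if (h < hbest) { hbest = h; jbest = j; }
      }
      assign[i] = jbest;
      dmin[i] = hbest;          // squared distance up to the ||x||^2 shift
      ++count[jbest];
    }
    // reseed empty clusters to the farthest point, then re-assign; dmin is
    // only compared within one point so the per-point shift is irrelevant
    // for identifying the farthest point only up to ||x||^2 -- recover the
    // true squared distance before comparing across points
    bool any_empty = false;
    for (int j = 0; j < k; ++j) any_empty = any_empty || (count[j] == 0);
    if (any_empty) {
      for (int i = 0; i < n; ++i) {
        const double* x = xr.data() + i * p;
        double s = 0.0;
        for (int v = 0; v < p; ++v) s += x[v] * x[v];
        dmin[i] = s + 2.0 * dmin[i];   // = ||x - c||^2
      }
      for (int j = 0; j < k; ++j) {
        if (count[j] == 0) {
          int far = 0;
          double dfar = -1.0;
          for (int i = 0; i < n; ++i)
            if (dmin[i] > dfar) { dfar = dmin[i]; far = i; }
          std::copy(xr.data() + far * p, xr.data() + (far + 1) * p,
                    centers.data() + j * p);
          dmin[far] = -1.0;
        }
      }
      continue;
    }
    if (std::equal(assign.begin(), assign.end(), assign_old.begin())) break;
    assign_old = assign;
    std::fill(centers.begin(), centers.end(), 0.0);
    for (int i = 0; i < n; ++i) {
      double* c = centers.data() + assign[i] * p;
      const double* x = xr.data() + i * p;
      for (int v = 0; v < p; ++v) c[v] += x[v];
    }
    for (int j = 0; j < k; ++j)
      for (int v = 0; v < p; ++v) centers[j * p + v] /= count[j];
  }
  iter_out = iter;
  double W = 0.0;
  for (int i = 0; i < n; ++i) {
    const double* x = xr.data() + i * p;
    const double* c = centers.data() + assign[i] * p;
    for (int v = 0; v < p; ++v) {
      double diff = x[v] - c[v];
      W += diff * diff;
    }
  }
  return W;
}

static std::vector<double> to_row_major(const NumericMatrix& X) {
  const int n = X.nrow(), p = X.ncol();
  std::vector<double> xr(static_cast<size_t>(n) * p);
  for (int v = 0; v < p; ++v)
    for (int i = 0; i < n; ++i) xr[static_cast<size_t>(i) * p + v] = X(i, v);
  return xr;
}

static List pack_solution(const std::vector<double>& centers,
                          const std::vector<int>& assign,
                          double W, int iter, int restart, int k, int n, int p) {
  NumericMatrix cen(k, p);
  for (int j = 0; j < k; ++j)
    for (int v = 0; v < p; ++v) cen(j, v) = centers[j * p + v];
  IntegerVector cl(n);
  for (int i = 0; i < n; ++i) cl[i] = assign[i] + 1;
  return List::create(_["cluster"] = cl, _["centers"] = cen,
                      _["tot_withinss"] = W, _["iter"] = iter,
                      _["restart"] = restart);
}

// Best-of-restarts Lloyd k-means.  init_idx is an nstart x k matrix of
// 1-based row indices giving each restart's initial centroids (drawn in R so
// the whole procedure is reproducible from one seed).
// [[Rcpp::export]]
List lloyd_kmeans(NumericMatrix X, IntegerMatrix init_idx, int max_iter) {
  const int n = X.nrow(), p = X.ncol();
  const int nstart = init_idx.nrow(), k = init_idx.ncol();
  std::vector<double> xr = to_row_major(X);
  std::vector<double> best_centers, centers(k * p);
  std::vector<int> best_assign, assign(n);
  double best_W = R_PosInf;
  int best_iter = 0, best_restart = 0;
  for (int r = 0; r < nstart; ++r) {
    for (int j = 0; j < k; ++j) {
      int row = init_idx(r, j) - 1;
      std::copy(xr.data() + static_cast<size_t>(row) * p,
                xr.data() + static_cast<size_t>(row + 1) * p,
                centers.data() + j * p);
    }
    int iter = 0;
    double W = lloyd_run(xr, n, p, centers, assign, k, max_iter, iter);
    if (W < best_W) {
      best_W = W; best_assign = assign; best_centers = centers;
      best_iter = iter; best_restart = r + 1;
    }
  }
  return pack_solution(best_centers, best_assign, best_W, best_iter,
                       best_restart, k, n, p);
}

// Single Lloyd run from an explicit k x p matrix of starting centers (used
// for warm starts when chaining fits across increasing k).
// [[Rcpp::export]]
List lloyd_from_centers(NumericMatrix X, NumericMatrix start, int max_iter) {
  const int n = X.nrow(), p = X.ncol(), k = start.nrow();
  std::vector<double> xr = to_row_major(X);
  std::vector<double> centers(k * p);
  for (int j = 0; j < k; ++j)
    for (int v = 0; v < p; ++v) centers[j * p + v] = start(j, v);
  std::vector<int> assign(n);
  int iter = 0;
  double W = lloyd_run(xr, n, p, centers, assign, k, max_iter, iter);
  return pack_solution(centers, assign, W, iter, 0, k, n, p);
}
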
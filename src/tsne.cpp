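// Exact (O(n^2)) t-SNE gradient descent with packed upper-triangular
// pair storage (sequential memory access).  Deterministic given the R
// RNG state: the 2-D initialisation draws from R's RNG, so callers fix
// the layout with set.seed().

#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Conditional P row for point i via binary search on precision beta so
// the perplexity of the row matches the target.
static void perplexity_row(const std::vector<double>& d2row, int i, int n,
                           double log_perp, std::vector<double>& p) {
  double beta = 1.0, betamin = -1e300, betamax = 1e300;
  for (int it = 0; it < 50; ++it) {
    double sum = 0.0, dsum = 0.0;
    for (int j = 0; j < n; ++j) {
      if (j == i) { p[j] = 0.0; continue; }
      double v = std::exp(-beta * d2row[j]);
      p[j] = v; sum += v;
      dsum += d2row[j] * v;
    }
    if (sum <= 0) sum = 1e-300;
    double H = std::log(sum) + beta * dsum / sum;
    double diff = H - log_perp;
    if (std::fabs(diff) < 1e-5) break;
    if (diff > 0) { betamin = beta; beta = (betamax > 1e299) ? beta * 2 : (beta + betamax) / 2; }
    else          { betamax = beta; beta = (betamin < -1e299) ? beta / 2 : (beta + betamin) / 2; }
  }
  double sum = 0.0;
  for (int j = 0; j < n; ++j) sum += p[j];
  if (sum <= 0) sum = 1e-300;
  for (int j = 0; j < n; ++j) p[j] /= sum;
}

// [[Rcpp::export(name = ".tsne_cpp")]]
NumericMatrix tsne_cpp(NumericMatrix X, double perplexity, int n_iter,
                       double learning_rate, double exaggeration,
                       int exaggerate_iter) {
  const int n = X.nrow(), d = X.ncol();
  const size_t npair = (size_t)n * (n - 1) / 2;
  // symmetrised joint P, packed over pairs i < j
  std::vector<double> P(npair, 0.0);
  {
    // conditional probabilities, full matrix (transient)
    std::vector<double> cond((size_t)n * n, 0.0);
    std::vector<double> d2row(n), prow(n);
    double log_perp = std::log(perplexity);
    for (int i = 0; i < n; ++i) {
      for (int j = 0; j < n; ++j) {
        double s = 0.0;
        for (int k = 0; k < d; ++k) {
          double diff = X(i, k) - X(j, k);
          s += diff * diff;
        }
        d2row[j] = s;
      }
      perplexity_row(d2row, i, n, log_perp, prow);
      for (int j = 0; j < n; ++j) cond[(size_t)i * n + j] = prow[j];
    }
    double psum = 0.0;
    size_t k = 0;
    for (int i = 0; i < n; ++i)
      for (int j = i + 1; j < n; ++j, ++k) {
        double v = (cond[(size_t)i * n + j] + cond[(size_t)j * n + i]) / 2.0;
        P[k] = v;
        psum += 2.0 * v;
      }
    for (size_t q = 0; q < npair; ++q)
      P[q] = std::max(P[q] / psum, 1e-12);
  }
  // init layout from R's RNG
  NumericMatrix Yout(n, 2);
  std::vector<double> Y((size_t)n * 2);
  {
    NumericVector r = rnorm(2 * n, 0.0, 1e-4);
    for (int i = 0; i < 2 * n; ++i) Y[i] = r[i];
  }
  std::vector<double> dY((size_t)n * 2), iY((size_t)n * 2, 0.0),
      gains((size_t)n * 2, 1.0), num(npair);
  for (int iter = 0; iter < n_iter; ++iter) {
    double ex = (iter < exaggerate_iter) ? exaggeration : 1.0;
    double Z = 0.0;
    size_t k = 0;
    for (int i = 0; i < n; ++i) {
      const double yi0 = Y[(size_t)i * 2], yi1 = Y[(size_t)i * 2 + 1];
      for (int j = i + 1; j < n; ++j, ++k) {
        double dx = yi0 - Y[(size_t)j * 2], dy = yi1 - Y[(size_t)j * 2 + 1];
        double v = 1.0 / (1.0 + dx * dx + dy * dy);
        num[k] = v;
        Z += v;
      }
    }
    Z *= 2.0;
    if (Z < 1e-300) Z = 1e-300;
    std::fill(dY.begin(), dY.end(), 0.0);
    k = 0;
    const double invZ = 1.0 / Z;
    for (int i = 0; i < n; ++i) {
      const double yi0 = Y[(size_t)i * 2], yi1 = Y[(size_t)i * 2 + 1];
      double gx = 0.0, gy = 0.0;
      for (int j = i + 1; j < n; ++j, ++k) {
        double v = num[k];
        double mult = (ex * P[k] - v * invZ) * v;
        double cx = mult * (yi0 - Y[(size_t)j * 2]);
        double cy = mult * (yi1 - Y[(size_t)j * 2 + 1]);
        gx += cx; gy += cy;
        dY[(size_t)j * 2] -= 4.0 * cx;
        dY[(size_t)j * 2 + 1] -= 4.0 * cy;
      }
      dY[(size_t)i * 2] += 4.0 * gx;
      dY[(size_t)i * 2 + 1] += 4.0 * gy;
    }
    double momentum = (iter < 250) ? 0.5 : 0.8;
    for (size_t id = 0; id < (size_t)n * 2; ++id) {
      gains[id] = ((dY[id] > 0) != (iY[id] > 0)) ? gains[id] + 0.2
                                                 : gains[id] * 0.8;
      if (gains[id] < 0.01) gains[id] = 0.01;
      iY[id] = momentum * iY[id] - learning_rate * gains[id] * dY[id];
      Y[id] += iY[id];
    }
    double mx = 0.0, my = 0.0;
    for (int i = 0; i < n; ++i) { mx += Y[(size_t)i * 2]; my += Y[(size_t)i * 2 + 1]; }
    mx /= n; my /= n;
    for (int i = 0; i < n; ++i) { Y[(size_t)i * 2] -= mx; Y[(size_t)i * 2 + 1] -= my; }
    if (iter % 50 == 0) Rcpp::checkUserInterrupt();
  }
  for (int i = 0; i < n; ++i) {
    Yout(i, 0) = Y[(size_t)i * 2];
    Yout(i, 1) = Y[(size_t)i * 2 + 1];
  }
  return Yout;
}

// [[Rcpp::export(name = ".mean_shift_cpp")]]
List mean_shift_cpp(NumericMatrix pts, double bandwidth, int max_iter,
                    double tol) {
  const int n = pts.nrow();
  NumericMatrix modes(n, 2);
  const double bw2 = bandwidth * bandwidth;
  for (int i = 0; i < n; ++i) {
    double x = pts(i, 0), y = pts(i, 1);
    for (int it = 0; it < max_iter; ++it) {
      double sx = 0.0, sy = 0.0; int cnt = 0;
      for (int j = 0; j < n; ++j) {
        double dx = pts(j, 0) - x, dy = pts(j, 1) - y;
        if (dx * dx + dy * dy <= bw2) { sx += pts(j, 0); sy += pts(j, 1); ++cnt; }
      }
      if (cnt == 0) break;
      double nx = sx / cnt, ny = sy / cnt;
      double shift = (nx - x) * (nx - x) + (ny - y) * (ny - y);
      x = nx; y = ny;
      if (shift < tol * tol) break;
    }
    modes(i, 0) = x; modes(i, 1) = y;
  }
  // deduplicate converged modes within bandwidth / 2
  std::vector<double> cx, cy;
  IntegerVector labels(n);
  const double dedup2 = (bandwidth / 2.0) * (bandwidth / 2.0);
  for (int i = 0; i < n; ++i) {
    int hit = -1;
    double bestd = 1e300;
    for (size_t c = 0; c < cx.size(); ++c) {
      double dx = modes(i, 0) - cx[c], dy = modes(i, 1) - cy[c];
      double dd = dx * dx + dy * dy;
      if (dd <= dedup2 && dd < bestd) { bestd = dd; hit = (int)c; }
    }
    if (hit < 0) {
      cx.push_back(modes(i, 0)); cy.push_back(modes(i, 1));
      hit = (int)cx.size() - 1;
    }
    labels[i] = hit + 1;  // 1-based
  }
  NumericMatrix centroids(cx.size(), 2);
  for (size_t c = 0; c < cx.size(); ++c) {
    centroids(c, 0) = cx[c]; centroids(c, 1) = cy[c];
  }
  return List::create(_["centroids"] = centroids, _["labels"] = labels);
}

// Index (1-based) of the nearest row of `ref` for every row of `x`,
// Euclidean metric in arbitrary dimension.
// [[Rcpp::export(name = ".nearest_ref_cpp")]]
IntegerVector nearest_ref_cpp(NumericMatrix x, NumericMatrix ref) {
  const int n = x.nrow(), m = ref.nrow(), d = x.ncol();
  IntegerVector out(n);
  for (int i = 0; i < n; ++i) {
    double best = 1e300; int bj = 0;
    for (int j = 0; j < m; ++j) {
      double s = 0.0;
      for (int k = 0; k < d; ++k) {
        double diff = x(i, k) - ref(j, k);
        s += diff * diff;
        if (s >= best) break;
      }
      if (s < best) { best = s; bj = j; }
    }
    out[i] = bj + 1;
  }
  return out;
}
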
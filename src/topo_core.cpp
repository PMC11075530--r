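// Core geometry and path-optimization kernels.
//
// These are the numerical primitives behind the trajectory features:
//  * cpp_mvee            -- minimum-volume enclosing ellipsoid, Khachiyan-style
//                           multiplicative weight ascent with Wolfe-Atwood away
//                           (drop) steps on the lifted (d+1)-dimensional design.
//  * cpp_held_karp       -- exact shortest Hamiltonian path with both endpoints
//                           fixed, bitmask dynamic programming over interior
//                           points, lexicographically smallest optimal order.
//  * cpp_min_path_heuristic -- best of identity / nearest-neighbour / random
//                           restarts, each polished by 2-opt.
//
// All randomness is a seeded std::mt19937 with a hand-rolled Fisher-Yates so
// results are identical across platforms and standard-library versions.

#include <RcppArmadillo.h>
#include <random>
#include <vector>
#include <algorithm>
#include <limits>

// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static arma::mat pairwise_dist(const arma::mat& X) {
  const arma::uword T = X.n_rows;
  arma::mat D(T, T, arma::fill::zeros);
  for (arma::uword i = 0; i < T; ++i) {
    for (arma::uword j = i + 1; j < T; ++j) {
      double d = arma::norm(X.row(i) - X.row(j), 2);
      D(i, j) = d;
      D(j, i) = d;
    }
  }
  return D;
}

static double order_length(const arma::mat& D, const std::vector<int>& o) {
  double s = 0.0;
  for (size_t i = 1; i < o.size(); ++i) s += D(o[i - 1], o[i]);
  return s;
}

// [[Rcpp::export]]
List cpp_mvee(const arma::mat& X, double tol, int max_iter) {
  const arma::uword T = X.n_rows;
  const arma::uword d = X.n_cols;
  const double n = static_cast<double>(d) + 1.0;

  // Lifted design: q_i = (x_i, 1).
  arma::mat Q(d + 1, T);
  Q.rows(0, d - 1) = X.t();
  Q.row(d).ones();

  arma::vec u(T);
  u.fill(1.0 / static_cast<double>(T));

  arma::mat M = Q * arma::diagmat(u) * Q.t();
  arma::mat Minv;
  if (!arma::inv_sympd(Minv, M)) Minv = arma::pinv(M);

  arma::vec m(T);
  {
    arma::mat MQ = Minv * Q;
    for (arma::uword i = 0; i < T; ++i) m(i) = arma::dot(Q.col(i), MQ.col(i));
  }

  bool converged = false;
  int it = 0;
  for (; it < max_iter; ++it) {
    arma::uword imax = m.index_max();
    double eps_plus = m(imax) / n - 1.0;
    if (eps_plus <= tol) {
      converged = true;
      break;
    }
    // Away-step candidate: support point with smallest Mahalanobis value.
    double mmin = std::numeric_limits<double>::infinity();
    arma::uword imin = imax;
    for (arma::uword i = 0; i < T; ++i) {
      if (u(i) > 1e-10 && m(i) < mmin) { mmin = m(i); imin = i; }
    }
    double eps_minus = 1.0 - mmin / n;

    arma::uword j;
    double alpha;
    if (eps_plus >= eps_minus) {
      j = imax;
      alpha = (m(j) - n) / (n * (m(j) - 1.0));
    } else {
      j = imin;
      alpha = (m(j) - n) / (n * (m(j) - 1.0)); // negative
      double amin = -u(j) / (1.0 - u(j));
      if (!std::isfinite(alpha) || alpha < amin) alpha = amin;
    }

    // Rank-one update M <- (1-a) M + a q_j q_j', Sherman-Morrison on Minv,
    // and the induced update of every m_i.
    double oma = 1.0 - alpha;
    double denom = oma + alpha * m(j);
    if (denom <= 0.0 || oma <= 0.0 || !std::isfinite(denom)) {
      // Numerically hostile step: refresh from scratch and continue.
      M = Q * arma::diagmat(u) * Q.t();
      if (!arma::inv_sympd(Minv, M)) Minv = arma::pinv(M);
      arma::mat MQ = Minv * Q;
      for (arma::uword i = 0; i < T; ++i) m(i) = arma::dot(Q.col(i), MQ.col(i));
      continue;
    }
    arma::vec Mq = Minv * Q.col(j);
    arma::vec g = Q.t() * Mq; // g_i = q_i' Minv q_j
    m = (m - (alpha / denom) * arma::square(g)) / oma;
    Minv = (Minv - (alpha / denom) * (Mq * Mq.t())) / oma;
    u *= oma;
    u(j) += alpha;
    if (u(j) < 0.0) u(j) = 0.0;

    if ((it + 1) % 200 == 0) { // periodic refresh against drift
      M = Q * arma::diagmat(u) * Q.t();
      if (!arma::inv_sympd(Minv, M)) Minv = arma::pinv(M);
      arma::mat MQ = Minv * Q;
      for (arma::uword i = 0; i < T; ++i) m(i) = arma::dot(Q.col(i), MQ.col(i));
    }
  }

  // Center and scatter of the converged weights; the shape matrix is scaled by
  // the measured max Mahalanobis value so containment holds exactly.
  arma::vec c = X.t() * u;
  arma::mat S = X.t() * arma::diagmat(u) * X - c * c.t();
  S = arma::symmatu(S);
  arma::mat Sinv;
  if (!arma::inv_sympd(Sinv, S)) Sinv = arma::pinv(S);

  arma::vec maha(T);
  double kappa = 0.0;
  for (arma::uword i = 0; i < T; ++i) {
    arma::vec xc = X.row(i).t() - c;
    maha(i) = arma::dot(xc, Sinv * xc);
    if (maha(i) > kappa) kappa = maha(i);
  }
  arma::mat A = Sinv / kappa;

  double ld, sign;
  arma::log_det(ld, sign, S);
  // log of sqrt(det(kappa * S)); volume = unit_ball_volume(d) * exp(this).
  double log_sqrt_det = 0.5 * (static_cast<double>(d) * std::log(kappa) + ld);

  return List::create(
    _["center"] = c, _["shape"] = A, _["log_sqrt_det"] = log_sqrt_det,
    _["kappa"] = kappa, _["u"] = u, _["maha"] = maha,
    _["iterations"] = it, _["converged"] = converged);
}

// [[Rcpp::export]]
List cpp_held_karp(const arma::mat& X) {
  const int T = static_cast<int>(X.n_rows);
  arma::mat D = pairwise_dist(X);
  std::vector<int> ord;
  ord.reserve(T);
  ord.push_back(0);
  const int m = T - 2;
  double total;

  if (m <= 0) {
    total = D(0, T - 1);
  } else {
    // g[S*m + j] = shortest length from interior j through interior set S
    // (j not in S) and then to the fixed end point.
    const size_t full = (size_t(1) << m) - 1;
    std::vector<double> g((full + 1) * static_cast<size_t>(m));
    for (int j = 0; j < m; ++j) g[j] = D(j + 1, T - 1);
    for (size_t S = 1; S <= full; ++S) {
      for (int j = 0; j < m; ++j) {
        if (S & (size_t(1) << j)) continue;
        double best = std::numeric_limits<double>::infinity();
        for (int k = 0; k < m; ++k) {
          if (!(S & (size_t(1) << k))) continue;
          double v = D(j + 1, k + 1) + g[(S ^ (size_t(1) << k)) * m + k];
          if (v < best) best = v;
        }
        g[S * static_cast<size_t>(m) + j] = best;
      }
    }
    total = std::numeric_limits<double>::infinity();
    for (int k = 0; k < m; ++k) {
      double v = D(0, k + 1) + g[(full ^ (size_t(1) << k)) * m + k];
      if (v < total) total = v;
    }

    // Reconstruct the lexicographically smallest optimal order: at each step
    // take the smallest interior index still achieving the optimum.
    size_t S = full;
    int cur = 0;
    double remaining = total;
    const double eps = 1e-9 * (1.0 + total);
    while (S) {
      int chosen = -1;
      double fallback = std::numeric_limits<double>::infinity();
      int fallback_k = -1;
      for (int k = 0; k < m; ++k) {
        if (!(S & (size_t(1) << k))) continue;
        size_t S2 = S ^ (size_t(1) << k);
        double v = D(cur, k + 1) + g[S2 * static_cast<size_t>(m) + k];
        if (v < fallback) { fallback = v; fallback_k = k; }
        if (chosen < 0 && v <= remaining + eps) chosen = k;
      }
      if (chosen < 0) chosen = fallback_k; // numerical safety net
      ord.push_back(chosen + 1);
      remaining -= D(cur, chosen + 1);
      cur = chosen + 1;
      S ^= (size_t(1) << chosen);
    }
  }
  ord.push_back(T - 1);
  double len = order_length(D, ord);

  IntegerVector out(ord.size());
  for (size_t i = 0; i < ord.size(); ++i) out[i] = ord[i] + 1;
  return List::create(_["order"] = out, _["total_length"] = len);
}

// 2-opt on an open path with fixed endpoints: reverse interior segments while
// an improving move exists. First-improvement sweeps, deterministic.
static void two_opt(const arma::mat& D, std::vector<int>& o) {
  const int T = static_cast<int>(o.size());
  if (T < 4) return;
  bool improved = true;
  while (improved) {
    improved = false;
    for (int i = 1; i <= T - 3; ++i) {
      for (int j = i + 1; j <= T - 2; ++j) {
        double removed = D(o[i - 1], o[i]) + D(o[j], o[j + 1]);
        double added = D(o[i - 1], o[j]) + D(o[i], o[j + 1]);
        if (added < removed - 1e-12 * (1.0 + removed)) {
          std::reverse(o.begin() + i, o.begin() + j + 1);
          improved = true;
        }
      }
    }
  }
}

// [[Rcpp::export]]
List cpp_two_opt(const arma::mat& X, IntegerVector order1) {
  arma::mat D = pairwise_dist(X);
  std::vector<int> o(order1.size());
  for (int i = 0; i < order1.size(); ++i) o[i] = order1[i] - 1;
  two_opt(D, o);
  IntegerVector out(o.size());
  for (size_t i = 0; i < o.size(); ++i) out[i] = o[i] + 1;
  return List::create(_["order"] = out, _["total_length"] = order_length(D, o));
}

// [[Rcpp::export]]
List cpp_min_path_heuristic(const arma::mat& X, int restarts, int seed) {
  const int T = static_cast<int>(X.n_rows);
  arma::mat D = pairwise_dist(X);

  std::vector<int> ident(T);
  for (int i = 0; i < T; ++i) ident[i] = i;

  std::vector<int> best = ident;
  {
    std::vector<int> o = ident;
    two_opt(D, o);
    best = o;
  }
  double best_len = order_length(D, best);

  if (T >= 4) {
    // Nearest-neighbour construction from the fixed start.
    std::vector<int> o;
    o.push_back(0);
    std::vector<bool> used(T, false);
    used[0] = true;
    used[T - 1] = true;
    int cur = 0;
    for (int step = 0; step < T - 2; ++step) {
      int nxt = -1;
      double bd = std::numeric_limits<double>::infinity();
      for (int k = 1; k <= T - 2; ++k) {
        if (!used[k] && D(cur, k) < bd) { bd = D(cur, k); nxt = k; }
      }
      o.push_back(nxt);
      used[nxt] = true;
      cur = nxt;
    }
    o.push_back(T - 1);
    two_opt(D, o);
    double len = order_length(D, o);
    if (len < best_len - 1e-12 * (1.0 + best_len)) { best = o; best_len = len; }

    // Seeded random restarts; hand-rolled Fisher-Yates for portability.
    std::mt19937 gen(static_cast<unsigned int>(seed));
    for (int r = 0; r < restarts; ++r) {
      std::vector<int> p = ident;
      for (int i = T - 2; i > 1; --i) {
        int j = 1 + static_cast<int>(gen() % static_cast<unsigned int>(i));
        std::swap(p[i], p[j]);
      }
      two_opt(D, p);
      len = order_length(D, p);
      if (len < best_len - 1e-12 * (1.0 + best_len)) { best = p; best_len = len; }
    }
  }

  IntegerVector out(best.size());
  for (size_t i = 0; i < best.size(); ++i) out[i] = best[i] + 1;
  return List::create(_["order"] = out, _["total_length"] = best_len);
}

// Grouped chunk means without materializing the per-token vector copy.
// idx is 1-based into the store rows, 0 for out-of-vocabulary tokens.
// [[Rcpp::export]]
List cpp_chunk_means(const arma::mat& V, IntegerVector idx,
                     IntegerVector chunk_id, int n_chunks) {
  const int D = V.n_cols;
  arma::mat sums(n_chunks, D, arma::fill::zeros);
  arma::ivec counts(n_chunks, arma::fill::zeros);
  const int n = idx.size();
  for (int t = 0; t < n; ++t) {
    int r = idx[t];
    if (r > 0) {
      sums.row(chunk_id[t] - 1) += V.row(r - 1);
      counts(chunk_id[t] - 1) += 1;
    }
  }
  return List::create(_["sums"] = sums, _["counts"] = counts);
}
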
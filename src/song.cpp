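#include <Rcpp.h>
#include <vector>
#include <map>
#include <queue>
#include <utility>
#include <algorithm>
#include <cmath>

using namespace Rcpp;

// Self-organizing embedding core: online vector quantization with codebook
// growth, Hebbian topology-graph reinforcement, and a stochastic-gradient
// cross-entropy layout of the 2D node positions (1/(1+d^2) kernel, negative
// sampling). All randomness is drawn from R's RNG so a single set.seed()
// upstream makes sessions exactly reproducible.

static inline double sqdist_rows(const std::vector<double>& A, int i,
                                 const double* x, int D) {
  const double* a = &A[(size_t)i * D];
  double s = 0.0;
  for (int d = 0; d < D; ++d) {
    const double diff = a[d] - x[d];
    s += diff * diff;
  }
  return s;
}

static inline int rand_below(int n) {
  int k = (int)std::floor(R::unif_rand() * n);
  if (k >= n) k = n - 1;
  return k;
}

static inline double clamp4(double v, double cap) {
  if (v > cap) return cap;
  if (v < -cap) return -cap;
  return v;
}

// Find nearest and second-nearest node of x; ties broken by lowest index.
static void two_nearest(const std::vector<double>& C, int K, const double* x,
                        int D, int& best, int& second,
                        double& dbest, double& dsecond) {
  best = -1; second = -1;
  dbest = R_PosInf; dsecond = R_PosInf;
  for (int j = 0; j < K; ++j) {
    const double d2 = sqdist_rows(C, j, x, D);
    if (d2 < dbest) {
      second = best; dsecond = dbest;
      best = j; dbest = d2;
    } else if (d2 < dsecond) {
      second = j; dsecond = d2;
    }
  }
}

// One training session: organize the codebook/graph on X, then lay out Y.
// [[Rcpp::export(name = ".song_session_cpp")]]
List song_session_cpp(NumericMatrix C0, NumericMatrix E0, NumericMatrix Y0,
                      NumericMatrix X,
                      double theta, int org_epochs,
                      double lr_start, double lr_final,
                      double neighbor_lr_frac, double edge_decay,
                      double prune_rel, int max_nodes,
                      int layout_epochs, double layout_lr, int neg_samples,
                      double repulsion_eps, double grad_clip,
                      double spawn_jitter, double edge_ratio) {
  const int D = X.ncol();
  const int N = X.nrow();
  int K = C0.nrow();
  if (K > 0 && C0.ncol() != D)
    stop("dimension mismatch between codebook and data");

  // row-major copies that can grow
  std::vector<double> C((size_t)max_nodes * D);
  std::vector<double> Y((size_t)max_nodes * 2);
  for (int j = 0; j < K; ++j) {
    for (int d = 0; d < D; ++d) C[(size_t)j * D + d] = C0(j, d);
    Y[(size_t)j * 2 + 0] = Y0(j, 0);
    Y[(size_t)j * 2 + 1] = Y0(j, 1);
  }
  std::vector< std::map<int, double> > adj(max_nodes);
  for (int j = 0; j < E0.nrow(); ++j)
    for (int k = j + 1; k < E0.ncol(); ++k)
      if (E0(j, k) > 0) { adj[j][k] = E0(j, k); adj[k][j] = E0(j, k); }

  const double theta2 = theta * theta;
  std::vector<int> order(N);
  for (int i = 0; i < N; ++i) order[i] = i;
  std::vector<double> xbuf(D);

  // ---- (1) + (2): vector quantization with growth, Hebbian self-organization
  const int total_steps = org_epochs * std::max(N, 1);
  int step = 0;
  for (int ep = 0; ep < org_epochs; ++ep) {
    // Fisher-Yates shuffle via R RNG
    for (int i = N - 1; i > 0; --i) {
      const int k = rand_below(i + 1);
      std::swap(order[i], order[k]);
    }
    for (int ii = 0; ii < N; ++ii, ++step) {
      const int i = order[ii];
      for (int d = 0; d < D; ++d) xbuf[d] = X(i, d);
      const double lr = lr_start +
        (lr_final - lr_start) * ((double)step / (double)total_steps);

      int b, s; double db2, ds2;
      two_nearest(C, K, xbuf.data(), D, b, s, db2, ds2);

      if ((K == 0 || db2 > theta2) && K < max_nodes) {
        // spawn a new coding vector at the input; its 2D position starts
        // near the winner's so the layout stays locally continuous
        const int nw = K++;
        for (int d = 0; d < D; ++d) C[(size_t)nw * D + d] = xbuf[d];
        if (b >= 0) {
          Y[(size_t)nw * 2 + 0] = Y[(size_t)b * 2 + 0] + spawn_jitter * R::norm_rand();
          Y[(size_t)nw * 2 + 1] = Y[(size_t)b * 2 + 1] + spawn_jitter * R::norm_rand();
          adj[nw][b] = 1.0; adj[b][nw] = 1.0;
        } else {
          Y[(size_t)nw * 2 + 0] = spawn_jitter * R::norm_rand();
          Y[(size_t)nw * 2 + 1] = spawn_jitter * R::norm_rand();
        }
        continue;
      }
      if (b < 0) continue;

      // winner-take-most update
      double* cb = &C[(size_t)b * D];
      for (int d = 0; d < D; ++d) cb[d] += lr * (xbuf[d] - cb[d]);
      for (std::map<int, double>::iterator it = adj[b].begin();
           it != adj[b].end(); ++it) {
        double* cj = &C[(size_t)it->first * D];
        const double lrn = lr * neighbor_lr_frac;
        for (int d = 0; d < D; ++d) cj[d] += lrn * (xbuf[d] - cj[d]);
      }
      // Hebbian reinforcement of the winner/second edge, decay of the rest.
      // Reinforce only when the input genuinely lies between the two nodes'
      // neighborhoods (runner-up not much farther than the winner); this
      // keeps far-apart clusters from being welded together.
      const bool between = s >= 0 &&
        (std::sqrt(ds2) <= edge_ratio * std::sqrt(db2) + 1e-300 ||
         ds2 <= theta2);
      if (between) {
        for (std::map<int, double>::iterator it = adj[b].begin();
             it != adj[b].end(); ++it) {
          it->second *= edge_decay;
          adj[it->first][b] = it->second;
        }
        adj[b][s] += 1.0;
        adj[s][b] = adj[b][s];
      }
    }
  }

  // prune near-zero edges
  double wmax = 0.0;
  for (int j = 0; j < K; ++j)
    for (std::map<int, double>::iterator it = adj[j].begin();
         it != adj[j].end(); ++it)
      if (it->second > wmax) wmax = it->second;
  if (wmax > 0) {
    const double cut = prune_rel * wmax;
    for (int j = 0; j < K; ++j) {
      std::map<int, double>::iterator it = adj[j].begin();
      while (it != adj[j].end()) {
        if (it->second < cut) adj[j].erase(it++); else ++it;
      }
    }
  }

  // Edge list with weights compressed to [0, 1]: Hebbian counts span orders
  // of magnitude, so a log transform keeps all genuine topology edges
  // attractive in the layout instead of only the most-traversed one.
  const double lwmax = std::log1p(wmax);
  std::vector<int> ei, ej;
  std::vector<double> ew;
  for (int j = 0; j < K; ++j)
    for (std::map<int, double>::iterator it = adj[j].begin();
         it != adj[j].end(); ++it)
      if (it->first > j) {
        ei.push_back(j); ej.push_back(it->first);
        ew.push_back(lwmax > 0 ? std::log1p(it->second) / lwmax : 0.0);
      }
  const int nE = (int)ei.size();

  // ---- (3): stochastic-gradient cross-entropy layout with negative sampling
  NumericVector ce(layout_epochs);
  for (int ep = 0; ep < layout_epochs; ++ep) {
    const double alpha = layout_lr *
      (1.0 - (double)ep / (double)std::max(layout_epochs, 1));
    for (int e = 0; e < nE; ++e) {
      const int j = ei[e], k = ej[e];
      double* yj = &Y[(size_t)j * 2];
      double* yk = &Y[(size_t)k * 2];
      double dx = yj[0] - yk[0], dy = yj[1] - yk[1];
      double d2 = dx * dx + dy * dy;
      // attractive force along the edge, scaled by its weight
      double g = -2.0 * ew[e] / (1.0 + d2);
      double gx = clamp4(g * dx, grad_clip), gy = clamp4(g * dy, grad_clip);
      yj[0] += alpha * gx; yj[1] += alpha * gy;
      yk[0] -= alpha * gx; yk[1] -= alpha * gy;
      // repulsion of each endpoint from random negative samples
      for (int endp = 0; endp < 2; ++endp) {
        double* y = endp == 0 ? yj : yk;
        const int self = endp == 0 ? j : k;
        for (int t = 0; t < neg_samples; ++t) {
          const int r = rand_below(K);
          if (r == self) continue;
          const double* yr = &Y[(size_t)r * 2];
          dx = y[0] - yr[0]; dy = y[1] - yr[1];
          d2 = dx * dx + dy * dy;
          g = 2.0 / ((repulsion_eps + d2) * (1.0 + d2));
          y[0] += alpha * clamp4(g * dx, grad_clip);
          y[1] += alpha * clamp4(g * dy, grad_clip);
        }
      }
    }
    // full cross-entropy between graph weights and layout kernel
    double obj = 0.0;
    for (int j = 0; j < K; ++j)
      for (int k = j + 1; k < K; ++k) {
        const double dx2 = Y[(size_t)j * 2] - Y[(size_t)k * 2];
        const double dy2 = Y[(size_t)j * 2 + 1] - Y[(size_t)k * 2 + 1];
        const double q = 1.0 / (1.0 + dx2 * dx2 + dy2 * dy2);
        double w = 0.0;
        std::map<int, double>::const_iterator it = adj[j].find(k);
        if (it != adj[j].end() && lwmax > 0) w = std::log1p(it->second) / lwmax;
        obj += -w * std::log(q + 1e-12) - (1.0 - w) * std::log(1.0 - q + 1e-12);
      }
    ce[ep] = obj;
  }

  NumericMatrix Cout(K, D), Eout(K, K), Yout(K, 2);
  for (int j = 0; j < K; ++j) {
    for (int d = 0; d < D; ++d) Cout(j, d) = C[(size_t)j * D + d];
    Yout(j, 0) = Y[(size_t)j * 2];
    Yout(j, 1) = Y[(size_t)j * 2 + 1];
    for (std::map<int, double>::iterator it = adj[j].begin();
         it != adj[j].end(); ++it)
      Eout(j, it->first) = it->second;
  }
  return List::create(_["C"] = Cout, _["E"] = Eout, _["Y"] = Yout,
                      _["objective"] = ce);
}

// Map inputs to 2D as an inverse-squared-distance weighted combination of the
// layouts of the `knn` nearest coding vectors. An input equal to a coding
// vector maps exactly to that vector's layout position.
// [[Rcpp::export(name = ".song_transform_cpp")]]
NumericMatrix song_transform_cpp(NumericMatrix C, NumericMatrix Y,
                                 NumericMatrix X, int knn) {
  const int K = C.nrow(), D = C.ncol(), N = X.nrow();
  if (X.ncol() != D) stop("dimension mismatch between model and data");
  if (K < 1) stop("model has no coding vectors");
  if (knn > K) knn = K;
  NumericMatrix out(N, 2);
  std::vector<double> d2(K);
  std::vector<int> idx(K);
  for (int i = 0; i < N; ++i) {
    for (int j = 0; j < K; ++j) {
      double s = 0.0;
      for (int d = 0; d < D; ++d) {
        const double diff = C(j, d) - X(i, d);
        s += diff * diff;
      }
      d2[j] = s;
      idx[j] = j;
    }
    std::partial_sort(idx.begin(), idx.begin() + knn, idx.end(),
                      [&](int a, int b) {
                        return d2[a] < d2[b] || (d2[a] == d2[b] && a < b);
                      });
    if (d2[idx[0]] < 1e-24) {
      out(i, 0) = Y(idx[0], 0);
      out(i, 1) = Y(idx[0], 1);
      continue;
    }
    double wsum = 0.0, yx = 0.0, yy = 0.0;
    for (int q = 0; q < knn; ++q) {
      const int j = idx[q];
      const double w = 1.0 / d2[j];
      wsum += w;
      yx += w * Y(j, 0);
      yy += w * Y(j, 1);
    }
    out(i, 0) = yx / wsum;
    out(i, 1) = yy / wsum;
  }
  return out;
}

// Geodesic (shortest-path) distances over the topology graph augmented with
// each coding vector's `knn` nearest Euclidean neighbors. Edge lengths are
// input-space distances. The Hebbian graph alone is chain-like and sparse:
// without the k-NN shortcuts, geodesics between nearby but weakly connected
// structures detour through whatever bridge edge exists and grossly
// overestimate their truthful separation, which would distort the layout
// placement this matrix seeds. Unreachable pairs get the largest finite
// geodesic times 1.5 so disconnected components stay apart.
// [[Rcpp::export(name = ".song_geodesics_cpp")]]
NumericMatrix song_geodesics_cpp(NumericMatrix C, NumericMatrix E, int knn) {
  const int K = C.nrow(), D = C.ncol();
  NumericMatrix G(K, K);
  std::vector< std::map<int, double> > nbrmap(K);
  std::vector< std::vector<double> > dmat(K, std::vector<double>(K, 0.0));
  for (int j = 0; j < K; ++j)
    for (int k = j + 1; k < K; ++k) {
      double s = 0.0;
      for (int d = 0; d < D; ++d) {
        const double diff = C(j, d) - C(k, d);
        s += diff * diff;
      }
      dmat[j][k] = dmat[k][j] = std::sqrt(s);
    }
  for (int j = 0; j < K; ++j)
    for (int k = j + 1; k < K; ++k)
      if (E(j, k) > 0) {
        nbrmap[j][k] = dmat[j][k];
        nbrmap[k][j] = dmat[j][k];
      }
  if (knn > 0 && K > 1) {
    std::vector<int> idx(K);
    for (int j = 0; j < K; ++j) {
      for (int k = 0; k < K; ++k) idx[k] = k;
      const int take = std::min(knn + 1, K);
      std::partial_sort(idx.begin(), idx.begin() + take, idx.end(),
                        [&](int a, int b) {
                          return dmat[j][a] < dmat[j][b] ||
                                 (dmat[j][a] == dmat[j][b] && a < b);
                        });
      for (int q = 0; q < take; ++q) {
        const int k = idx[q];
        if (k == j) continue;
        nbrmap[j][k] = dmat[j][k];
        nbrmap[k][j] = dmat[j][k];
      }
    }
  }
  std::vector< std::vector< std::pair<int, double> > > nbr(K);
  for (int j = 0; j < K; ++j)
    for (std::map<int, double>::iterator it = nbrmap[j].begin();
         it != nbrmap[j].end(); ++it)
      nbr[j].push_back(std::make_pair(it->first, it->second));
  double gmax = 0.0;
  for (int src = 0; src < K; ++src) {
    std::vector<double> dist(K, R_PosInf);
    dist[src] = 0.0;
    // Dijkstra on a small graph; simple priority queue
    std::priority_queue< std::pair<double, int>,
                         std::vector< std::pair<double, int> >,
                         std::greater< std::pair<double, int> > > pq;
    pq.push(std::make_pair(0.0, src));
    while (!pq.empty()) {
      const double d0 = pq.top().first;
      const int u = pq.top().second;
      pq.pop();
      if (d0 > dist[u]) continue;
      for (size_t q = 0; q < nbr[u].size(); ++q) {
        const int v = nbr[u][q].first;
        const double nd = d0 + nbr[u][q].second;
        if (nd < dist[v]) {
          dist[v] = nd;
          pq.push(std::make_pair(nd, v));
        }
      }
    }
    for (int k = 0; k < K; ++k) {
      G(src, k) = dist[k];
      if (R_finite(dist[k]) && dist[k] > gmax) gmax = dist[k];
    }
  }
  for (int j = 0; j < K; ++j)
    for (int k = 0; k < K; ++k)
      if (!R_finite(G(j, k))) G(j, k) = 1.5 * gmax;
  return G;
}

// Mean distance from each input to its nearest coding vector.
// [[Rcpp::export(name = ".song_quant_error_cpp")]]
double song_quant_error_cpp(NumericMatrix C, NumericMatrix X) {
  const int K = C.nrow(), D = C.ncol(), N = X.nrow();
  if (K < 1 || N < 1) return NA_REAL;
  double acc = 0.0;
  for (int i = 0; i < N; ++i) {
    double best = R_PosInf;
    for (int j = 0; j < K; ++j) {
      double s = 0.0;
      for (int d = 0; d < D; ++d) {
        const double diff = C(j, d) - X(i, d);
        s += diff * diff;
      }
      if (s < best) best = s;
    }
    acc += std::sqrt(best);
  }
  return acc / N;
}
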
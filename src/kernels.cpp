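#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

static inline double wrap_2pi(double x) {
  const double TWOPI = 2.0 * M_PI;
  double w = x - std::floor(x / TWOPI) * TWOPI;
  if (w >= TWOPI) w -= TWOPI;
  return w;
}

// Delay-coupled Kuramoto integration (deterministic / stochastic Heun).
//
// dtheta_i/dt = omega + k * sum_j C[i,j] * sin(theta_j(t - tau_ij) - theta_i(t))
//
// Phase history is kept in a circular buffer wide enough for the largest
// delay. History is filled by running the uncoupled system (k = 0) forward
// for the maximal-delay duration from the supplied initial phases, with the
// same noise process as the coupled run. All randomness comes from the R RNG
// so set.seed() on the R side fixes the trajectory bitwise.
//
// Noise: one increment sigma*sqrt(dt)*xi per node per step, added to both
// the predictor and the corrector stage (stochastic Heun).
// [[Rcpp::export]]
NumericMatrix cpp_kuramoto(const NumericMatrix& weights,
                           const IntegerMatrix& delay_steps,
                           double omega, double k, double dt,
                           int n_steps, int n_transient,
                           double sigma, NumericVector init_phases,
                           int record_every) {
  const int N = weights.nrow();
  const double TWOPI = 2.0 * M_PI;

  // edge list of ordered nonzero pairs (receiver i, sender j)
  std::vector<int> ei, ej, ed;
  std::vector<double> ew;
  int max_d = 1;
  for (int i = 0; i < N; ++i)
    for (int j = 0; j < N; ++j)
      if (weights(i, j) != 0.0 && i != j) {
        ei.push_back(i); ej.push_back(j);
        ew.push_back(weights(i, j));
        int d = delay_steps(i, j);
        if (d < 1) d = 1;
        ed.push_back(d);
        if (d > max_d) max_d = d;
      }
  const int n_edges = (int) ei.size();
  const int B = max_d + 1;              // circular buffer width
  NumericMatrix buf(N, B);
  // sin/cos of buffered phases, so the edge loop needs no trig:
  // sin(theta_d_j - theta_i) = sin(theta_d_j)*cos(theta_i) -
  //                            cos(theta_d_j)*sin(theta_i)
  std::vector<double> sbuf((size_t) N * B), cbuf((size_t) N * B);
  const double sq = sigma * std::sqrt(dt);

  // uncoupled history: the drawn initial phases are theta(0) (column B-1);
  // earlier columns hold the k = 0 dynamics run for the maximal-delay
  // duration leading up to t = 0, so theta(-m*dt) = theta(0) - m*dt*omega
  // (plus noise when sigma > 0)
  {
    NumericVector th = clone(init_phases);
    for (int n = 0; n < N; ++n) buf(n, B - 1) = th[n];
    for (int c = B - 2; c >= 0; --c) {
      if (sigma > 0.0) {
        NumericVector xi = rnorm(N);
        for (int n = 0; n < N; ++n)
          th[n] = wrap_2pi(th[n] - dt * omega + sq * xi[n]);
      } else {
        for (int n = 0; n < N; ++n)
          th[n] = wrap_2pi(th[n] - dt * omega);
      }
      for (int n = 0; n < N; ++n) buf(n, c) = th[n];
    }
  }
  for (int c = 0; c < B; ++c)
    for (int n = 0; n < N; ++n) {
      sbuf[(size_t) c * N + n] = std::sin(buf(n, c));
      cbuf[(size_t) c * N + n] = std::cos(buf(n, c));
    }

  const int n_keep = n_steps - n_transient;
  const int n_rec = (n_keep + record_every - 1) / record_every;
  NumericMatrix out(N, n_rec);

  std::vector<double> th(N), f1(N), f2(N), tilde(N), noise(N, 0.0);
  std::vector<double> SA(N), CA(N), st(N), ct(N);
  int cur = B - 1;                       // buffer column holding theta(t)
  for (int n = 0; n < N; ++n) th[n] = buf(n, cur);

  for (int step = 0; step < n_steps; ++step) {
    // stage 1: derivative at time t
    std::fill(SA.begin(), SA.end(), 0.0);
    std::fill(CA.begin(), CA.end(), 0.0);
    for (int e = 0; e < n_edges; ++e) {
      int c = cur - ed[e]; if (c < 0) c += B;
      SA[ei[e]] += ew[e] * sbuf[(size_t) c * N + ej[e]];
      CA[ei[e]] += ew[e] * cbuf[(size_t) c * N + ej[e]];
    }
    const double* scur = &sbuf[(size_t) cur * N];
    const double* ccur = &cbuf[(size_t) cur * N];
    for (int n = 0; n < N; ++n)
      f1[n] = omega + k * (SA[n] * ccur[n] - CA[n] * scur[n]);
    if (sigma > 0.0) {
      NumericVector xi = rnorm(N);
      for (int n = 0; n < N; ++n) noise[n] = sq * xi[n];
    }
    for (int n = 0; n < N; ++n) {
      tilde[n] = th[n] + dt * f1[n] + noise[n];
      st[n] = std::sin(tilde[n]);
      ct[n] = std::cos(tilde[n]);
    }

    // stage 2: derivative at t + dt using predictor state; delayed phases
    // at t + dt - tau live at buffer column (cur + 1 - tau)
    int nxt = cur + 1; if (nxt == B) nxt = 0;
    std::fill(SA.begin(), SA.end(), 0.0);
    std::fill(CA.begin(), CA.end(), 0.0);
    for (int e = 0; e < n_edges; ++e) {
      int c = nxt - ed[e]; if (c < 0) c += B;
      SA[ei[e]] += ew[e] * sbuf[(size_t) c * N + ej[e]];
      CA[ei[e]] += ew[e] * cbuf[(size_t) c * N + ej[e]];
    }
    for (int n = 0; n < N; ++n)
      f2[n] = omega + k * (SA[n] * ct[n] - CA[n] * st[n]);
    for (int n = 0; n < N; ++n) {
      double v = wrap_2pi(th[n] + 0.5 * dt * (f1[n] + f2[n]) + noise[n]);
      if (!std::isfinite(v))
        stop("non-finite phase at integration step %d (node %d)", step + 1, n + 1);
      th[n] = v;
      buf(n, nxt) = v;
      sbuf[(size_t) nxt * N + n] = std::sin(v);
      cbuf[(size_t) nxt * N + n] = std::cos(v);
    }
    cur = nxt;

    int kept = step + 1 - n_transient;   // steps completed past transient
    if (kept > 0 && (kept - 1) % record_every == 0) {
      int col = (kept - 1) / record_every;
      for (int n = 0; n < N; ++n) out(n, col) = th[n];
    }
  }
  return out;
}

// Balloon/Windkessel hemodynamic model, Heun integration, one ODE state
// set (s, f, v, q) per node driven by z = activity, started at rest
// (0, 1, 1, 1). Output y = V0*(k1*(1-q) + k2*(1-q/v) + k3*(1-v)).
static inline void balloon_deriv(double z, double s, double f, double v,
                                 double q, double kappa, double gamma,
                                 double tau0, double ialpha, double E0,
                                 double* ds, double* df, double* dv, double* dq) {
  double fv = std::pow(v, ialpha);
  *ds = z - kappa * s - gamma * (f - 1.0);
  *df = s;
  *dv = (f - fv) / tau0;
  *dq = (f * (1.0 - std::pow(1.0 - E0, 1.0 / f)) / E0 - fv * q / v) / tau0;
}

// [[Rcpp::export]]
NumericMatrix cpp_balloon(const NumericMatrix& activity, double dt,
                          double kappa, double gamma, double tau0,
                          double alpha, double E0, double V0,
                          double k1, double k2, double k3) {
  const int N = activity.nrow(), T = activity.ncol();
  const double ialpha = 1.0 / alpha;
  NumericMatrix out(N, T);
  for (int n = 0; n < N; ++n) {
    double s = 0.0, f = 1.0, v = 1.0, q = 1.0;
    for (int t = 0; t < T; ++t) {
      out(n, t) = V0 * (k1 * (1.0 - q) + k2 * (1.0 - q / v) + k3 * (1.0 - v));
      double z0 = activity(n, t);
      double z1 = (t + 1 < T) ? activity(n, t + 1) : z0;
      double ds1, df1, dv1, dq1, ds2, df2, dv2, dq2;
      balloon_deriv(z0, s, f, v, q, kappa, gamma, tau0, ialpha, E0,
                    &ds1, &df1, &dv1, &dq1);
      double sp = s + dt * ds1, fp = f + dt * df1,
             vp = v + dt * dv1, qp = q + dt * dq1;
      if (vp <= 0.0 || qp <= 0.0 || fp <= 0.0)
        stop("hemodynamic state left physical bounds at step %d (node %d)",
             t + 1, n + 1);
      balloon_deriv(z1, sp, fp, vp, qp, kappa, gamma, tau0, ialpha, E0,
                    &ds2, &df2, &dv2, &dq2);
      s += 0.5 * dt * (ds1 + ds2);
      f += 0.5 * dt * (df1 + df2);
      v += 0.5 * dt * (dv1 + dv2);
      q += 0.5 * dt * (dq1 + dq2);
      if (v <= 0.0 || q <= 0.0 || f <= 0.0)
        stop("hemodynamic state left physical bounds at step %d (node %d)",
             t + 1, n + 1);
    }
  }
  return out;
}

// One Louvain run on a (signed) modularity matrix Bm: local node moves in
// random sweep order followed by community aggregation, repeated until no
// quality gain above tol. Returns 1-based contiguous membership and
// Q = sum of Bm over all within-module ordered pairs (diagonal included).
// Randomness (sweep order) uses the R RNG.
// [[Rcpp::export]]
List cpp_louvain(const NumericMatrix& Bm, double tol) {
  int N0 = Bm.nrow();
  std::vector<int> flat(N0);                  // node -> final community
  for (int i = 0; i < N0; ++i) flat[i] = i;

  NumericMatrix Bc = clone(Bm);
  bool improved_any_level = true;

  while (improved_any_level) {
    int N = Bc.nrow();
    std::vector<int> comm(N);
    for (int i = 0; i < N; ++i) comm[i] = i;

    bool moved_any = false, moved = true;
    while (moved) {
      moved = false;
      IntegerVector ord = sample(N, N, false);   // 1-based random order
      for (int oi = 0; oi < N; ++oi) {
        int i = ord[oi] - 1;
        int ci = comm[i];
        // strength of i towards every community (excluding self-loop)
        std::vector<double> S(N, 0.0);
        for (int j = 0; j < N; ++j)
          if (j != i) S[comm[j]] += Bc(i, j);
        double best_gain = tol; int best_c = ci;
        for (int c = 0; c < N; ++c) {
          if (c == ci) continue;
          double gain = 2.0 * (S[c] - S[ci]);
          if (gain > best_gain) { best_gain = gain; best_c = c; }
        }
        if (best_c != ci) { comm[i] = best_c; moved = true; moved_any = true; }
      }
    }
    if (!moved_any) break;

    // relabel communities contiguously
    std::vector<int> map(N, -1);
    int nc = 0;
    for (int i = 0; i < N; ++i)
      if (map[comm[i]] < 0) map[comm[i]] = nc++;
    for (int i = 0; i < N; ++i) comm[i] = map[comm[i]];

    // update flat membership
    for (int i = 0; i < N0; ++i) flat[i] = comm[flat[i]];

    // aggregate
    NumericMatrix Bn(nc, nc);
    for (int i = 0; i < N; ++i)
      for (int j = 0; j < N; ++j)
        Bn(comm[i], comm[j]) += Bc(i, j);
    Bc = Bn;
    improved_any_level = (nc < N);
  }

  int nfinal = Bc.nrow();
  double Q = 0.0;
  for (int a = 0; a < nfinal; ++a) Q += Bc(a, a);

  IntegerVector memb(N0);
  for (int i = 0; i < N0; ++i) memb[i] = flat[i] + 1;
  return List::create(_["membership"] = memb, _["Q"] = Q);
}

// Degree-preserving double-edge swaps on an undirected edge list.
// edges: m x 2 (1-based node ids). Returns the rewired edge list.
// Randomness from the R RNG.
// [[Rcpp::export]]
IntegerMatrix cpp_edge_swap(const IntegerMatrix& edges, int n_nodes,
                            int n_swaps) {
  const int m = edges.nrow();
  std::vector<int> ei(m), ej(m);
  std::vector<bool> adj((size_t) n_nodes * n_nodes, false);
  for (int e = 0; e < m; ++e) {
    ei[e] = edges(e, 0) - 1;
    ej[e] = edges(e, 1) - 1;
    adj[(size_t) ei[e] * n_nodes + ej[e]] = true;
    adj[(size_t) ej[e] * n_nodes + ei[e]] = true;
  }
  for (int it = 0; it < n_swaps; ++it) {
    int e1 = (int) (unif_rand() * m), e2 = (int) (unif_rand() * m);
    if (e1 == e2) continue;
    int a = ei[e1], b = ej[e1], d = ei[e2], c = ej[e2];
    if (unif_rand() < 0.5) { int t = c; c = d; d = t; }
    // propose replacing (a,b), (d,c) with (a,c) and (d,b)
    if (a == c || d == b || a == d || b == c) continue;
    if (adj[(size_t) a * n_nodes + c] || adj[(size_t) d * n_nodes + b])
      continue;
    adj[(size_t) a * n_nodes + b] = adj[(size_t) b * n_nodes + a] = false;
    adj[(size_t) d * n_nodes + c] = adj[(size_t) c * n_nodes + d] = false;
    adj[(size_t) a * n_nodes + c] = adj[(size_t) c * n_nodes + a] = true;
    adj[(size_t) d * n_nodes + b] = adj[(size_t) b * n_nodes + d] = true;
    ei[e1] = a; ej[e1] = c;
    ei[e2] = d; ej[e2] = b;
  }
  IntegerMatrix out(m, 2);
  for (int e = 0; e < m; ++e) { out(e, 0) = ei[e] + 1; out(e, 1) = ej[e] + 1; }
  return out;
}

// Strength-aware assignment of a weight multiset onto a fixed edge list
// (the positive-weight branch of the standard signed null model): rank the
// unassigned edges by the product of their endpoints' residual strengths,
// draw a random rank position, give that edge the rank-matched remaining
// weight, and subtract it from both endpoints' residual strengths.
// weights_desc must be sorted descending; returns, per edge, the 1-based
// index into weights_desc that was assigned to it. Randomness from the R
// RNG.
// [[Rcpp::export]]
IntegerVector cpp_rerank_weights(const IntegerMatrix& edges,
                                 NumericVector strengths,
                                 NumericVector weights_desc) {
  const int m = edges.nrow();
  std::vector<double> S(strengths.begin(), strengths.end());
  std::vector<int> irem(m);                  // remaining weight ranks
  for (int e = 0; e < m; ++e) irem[e] = e;
  std::vector<int> un(m);
  for (int e = 0; e < m; ++e) un[e] = e;
  IntegerVector out(m);
  std::vector<std::pair<double,int> > score;
  while (!un.empty()) {
    const int r = (int) un.size();
    score.clear();
    score.reserve(r);
    for (int u = 0; u < r; ++u) {
      int e = un[u];
      score.push_back(std::make_pair(
        -S[edges(e, 0) - 1] * S[edges(e, 1) - 1], u));
    }
    std::sort(score.begin(), score.end());
    int pick = (int) (unif_rand() * r);
    if (pick >= r) pick = r - 1;
    int u = score[pick].second;
    int e = un[u];
    double w = weights_desc[irem[pick]];    // rank-matched remaining weight
    out[e] = irem[pick] + 1;
    irem.erase(irem.begin() + pick);
    un.erase(un.begin() + u);
    S[edges(e, 0) - 1] -= w;
    S[edges(e, 1) - 1] -= w;
  }
  return out;
}

// Greedy refinement of a weight permutation on a fixed edge list: random
// pairs of edges propose swapping their (weight, length) assignments and
// the swap is kept when it lowers the squared deviation of node strengths
// from their targets. Returns the refined permutation (1-based indices
// into the weight vector). Randomness from the R RNG.
// [[Rcpp::export]]
IntegerVector cpp_strength_refine(const IntegerMatrix& edges,
                                  IntegerVector perm,
                                  NumericVector weights_desc,
                                  NumericVector target_strengths,
                                  int n_iter) {
  const int m = edges.nrow();
  const int n = target_strengths.size();
  std::vector<int> p(perm.begin(), perm.end());   // 1-based
  std::vector<double> S(n, 0.0);
  for (int e = 0; e < m; ++e) {
    double w = weights_desc[p[e] - 1];
    S[edges(e, 0) - 1] += w;
    S[edges(e, 1) - 1] += w;
  }
  std::vector<double> T(target_strengths.begin(), target_strengths.end());
  for (int it = 0; it < n_iter; ++it) {
    int e1 = (int) (unif_rand() * m), e2 = (int) (unif_rand() * m);
    if (e1 == e2) continue;
    double w1 = weights_desc[p[e1] - 1], w2 = weights_desc[p[e2] - 1];
    if (w1 == w2) continue;
    int nodes[4] = { edges(e1, 0) - 1, edges(e1, 1) - 1,
                     edges(e2, 0) - 1, edges(e2, 1) - 1 };
    double dw = w2 - w1;
    double before = 0.0, after = 0.0;
    double delta[4] = { dw, dw, -dw, -dw };
    // accumulate per distinct node (shared endpoints sum their deltas)
    for (int a = 0; a < 4; ++a) {
      bool first = true;
      double d = 0.0;
      for (int b = 0; b < 4; ++b) {
        if (nodes[b] == nodes[a]) {
          if (b < a) { first = false; break; }
          d += delta[b];
        }
      }
      if (!first) continue;
      double s0 = S[nodes[a]] - T[nodes[a]];
      before += s0 * s0;
      after += (s0 + d) * (s0 + d);
    }
    if (after < before) {
      int tmp = p[e1]; p[e1] = p[e2]; p[e2] = tmp;
      S[nodes[0]] += dw; S[nodes[1]] += dw;
      S[nodes[2]] -= dw; S[nodes[3]] -= dw;
    }
  }
  return IntegerVector(p.begin(), p.end());
}
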
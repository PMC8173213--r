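#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <cstring>

using namespace Rcpp;

// Piecewise-linear expected z-score grid for one sequence.
// pos[l * B + b] is the 1-based position of event (b, level l + 1);
// E is (N + 1) x B, row-major by stage.
static void build_expected(const std::vector<int>& pos, int B, int N,
                           std::vector<double>& E) {
  for (int b = 0; b < B; ++b) {
    double p1 = pos[b], p2 = pos[B + b], p3 = pos[2 * B + b];
    for (int k = 0; k <= N; ++k) {
      double v;
      if (k <= p1)      v = k / p1;
      else if (k <= p2) v = 1.0 + (k - p1) / (p2 - p1);
      else if (k <= p3) v = 2.0 + (k - p2) / (p3 - p2);
      else              v = 3.0;
      E[(size_t)k * B + b] = v;
    }
  }
}

// expected z-scores of a single biomarker over all stages
static void expected_column(const std::vector<int>& pos, int b, int B, int N,
                            double* col) {
  double p1 = pos[b], p2 = pos[B + b], p3 = pos[2 * B + b];
  for (int k = 0; k <= N; ++k) {
    double v;
    if (k <= p1)      v = k / p1;
    else if (k <= p2) v = 1.0 + (k - p1) / (p2 - p1);
    else if (k <= p3) v = 2.0 + (k - p2) / (p3 - p2);
    else              v = 3.0;
    col[k] = v;
  }
}

static void positions_of(const std::vector<int>& seq, int B,
                         std::vector<int>& pos) {
  for (size_t i = 0; i < seq.size(); ++i) {
    int id = seq[i] - 1;          // 0-based event id
    int b = id / 3, l = id % 3;   // biomarker, level-1
    pos[l * B + b] = (int)i + 1;
  }
}

struct Problem {
  int n, B, N;
  std::vector<double> Zt, inv_var;
  double logconst;
  Problem(const NumericMatrix& Z, const NumericVector& sigma)
      : n(Z.nrow()), B(Z.ncol()), N(3 * Z.ncol()),
        Zt((size_t)Z.nrow() * Z.ncol()), inv_var(Z.ncol()),
        logconst(-0.5 * Z.ncol() * std::log(2.0 * M_PI)) {
    for (int b = 0; b < B; ++b) {
      inv_var[b] = 1.0 / (sigma[b] * sigma[b]);
      logconst -= std::log(sigma[b]);
    }
    for (int i = 0; i < n; ++i)
      for (int b = 0; b < B; ++b) Zt[(size_t)i * B + b] = Z(i, b);
  }
};

// S[i][k] = sum_b ((z_ib - E_kb)/sigma_b)^2, subject-major
static void build_quadratic(const Problem& P, const std::vector<double>& E,
                            std::vector<double>& S) {
  const int n = P.n, B = P.B, N = P.N;
  for (int i = 0; i < n; ++i) {
    const double* zi = &P.Zt[(size_t)i * B];
    double* Si = &S[(size_t)i * (N + 1)];
    for (int k = 0; k <= N; ++k) {
      const double* Ek = &E[(size_t)k * B];
      double s = 0.0;
      for (int b = 0; b < B; ++b) {
        double d = zi[b] - Ek[b];
        s += d * d * P.inv_var[b];
      }
      Si[k] = s;
    }
  }
}

// Weighted total log marginal likelihood from the quadratic forms. Terms
// more than 37 log-units below the row maximum are dropped from the
// logsumexp: they are below double precision relative to the leading term.
static double score_from_quadratic(const Problem& P,
                                   const std::vector<double>& S,
                                   const double* w) {
  const int n = P.n, N = P.N;
  const double logN1 = std::log((double)(N + 1));
  double total = 0.0;
  for (int i = 0; i < n; ++i) {
    if (w[i] == 0) continue;
    const double* Si = &S[(size_t)i * (N + 1)];
    double mn = Si[0];
    for (int k = 1; k <= N; ++k)
      if (Si[k] < mn) mn = Si[k];
    double acc = 0.0;
    const double ceil = mn + 74.0; // 2 x 37 log-units in quadratic scale
    for (int k = 0; k <= N; ++k) {
      if (Si[k] < ceil) acc += std::exp(-0.5 * (Si[k] - mn));
    }
    total += w[i] * (-0.5 * mn + std::log(acc) - logN1 + P.logconst);
  }
  return total;
}

static double score_sequence(const Problem& P, const std::vector<int>& seq,
                             const double* w, std::vector<int>& pos,
                             std::vector<double>& E, std::vector<double>& S) {
  positions_of(seq, P.B, pos);
  build_expected(pos, P.B, P.N, E);
  build_quadratic(P, E, S);
  return score_from_quadratic(P, S, w);
}

// [[Rcpp::export]]
double cpp_seq_score(NumericMatrix Z, IntegerVector seq, NumericVector sigma,
                     NumericVector weights) {
  Problem P(Z, sigma);
  std::vector<int> s(seq.begin(), seq.end()), pos(3 * P.B);
  std::vector<double> E((size_t)(P.N + 1) * P.B);
  std::vector<double> S((size_t)P.n * (P.N + 1));
  return score_sequence(P, s, weights.begin(), pos, E, S);
}

// Replace biomarker b's expected-z column and fold the contribution change
// into the per-subject quadratic forms.
static void swap_column(const Problem& P, int b, const double* newcol,
                        std::vector<double>& E, std::vector<double>& S) {
  const int n = P.n, B = P.B, N = P.N;
  const double iv = P.inv_var[b];
  for (int i = 0; i < n; ++i) {
    const double z = P.Zt[(size_t)i * B + b];
    double* Si = &S[(size_t)i * (N + 1)];
    for (int k = 0; k <= N; ++k) {
      double dn = z - newcol[k];
      double dl = z - E[(size_t)k * B + b];
      Si[k] += (dn * dn - dl * dl) * iv;
    }
  }
  for (int k = 0; k <= N; ++k) E[(size_t)k * B + b] = newcol[k];
}

// Best-improvement relocation hill climbing over valid single-event moves.
// A move of event (b, l) from position i to j is valid exactly when j lies
// strictly between the positions of the biomarker's neighbouring levels.
// Each event's relocation window is swept by adjacent swaps so only the two
// biomarkers involved in a swap have their expected-z columns and quadratic
// contributions recomputed. Ties among improving moves break toward the
// first found; the climb stops when no move improves the weighted
// log-likelihood.
// [[Rcpp::export]]
List cpp_greedy_improve(NumericMatrix Z, IntegerVector seq, NumericVector sigma,
                        NumericVector weights, int max_passes) {
  Problem P(Z, sigma);
  const int B = P.B, N = P.N;
  const double* w = weights.begin();
  std::vector<int> cur(seq.begin(), seq.end());
  std::vector<int> pos_base(3 * B), pos_chain(3 * B);
  std::vector<int> seq_chain(N), best_seq(N);
  std::vector<double> E_base((size_t)(N + 1) * B), E_chain((size_t)(N + 1) * B);
  std::vector<double> S_base((size_t)P.n * (N + 1)), S_chain((size_t)P.n * (N + 1));
  std::vector<double> col(N + 1);

  double cur_score = score_sequence(P, cur, w, pos_base, E_base, S_base);
  int passes = 0;
  const double eps = 1e-9;

  positions_of(cur, B, pos_base);
  build_expected(pos_base, B, N, E_base);
  build_quadratic(P, E_base, S_base);
  cur_score = score_from_quadratic(P, S_base, w);

  while (passes < max_passes) {
    ++passes;
    bool moved_any = false;

    for (int i0 = 0; i0 < N; ++i0) { // 0-based position of the moved event
      int id = cur[i0] - 1;
      int be = id / 3, le = id % 3;
      int q1 = (le > 0) ? pos_base[(le - 1) * B + be] : 0;       // 1-based
      int q2 = (le < 2) ? pos_base[(le + 1) * B + be] : N + 1;
      double best_score = cur_score;
      bool found = false;

      for (int dir = 0; dir < 2; ++dir) {
        if (dir == 0 && i0 < q1 + 1) continue;         // nothing to the left
        if (dir == 1 && i0 + 2 > q2 - 1) continue;     // nothing to the right
        seq_chain = cur;
        pos_chain = pos_base;
        E_chain = E_base;
        S_chain = S_base;
        int e_at = i0; // 0-based location of the moved event in seq_chain
        int steps = (dir == 0) ? (i0 - q1) : (q2 - 2 - i0);
        for (int t = 0; t < steps; ++t) {
          int nb_at = (dir == 0) ? e_at - 1 : e_at + 1; // neighbour to swap
          int xid = seq_chain[nb_at] - 1;
          int bx = xid / 3, lx = xid % 3;
          std::swap(seq_chain[e_at], seq_chain[nb_at]);
          pos_chain[le * B + be] = nb_at + 1;
          pos_chain[lx * B + bx] = e_at + 1;
          e_at = nb_at;
          // two biomarkers changed position: refresh their columns
          expected_column(pos_chain, be, B, N, col.data());
          swap_column(P, be, col.data(), E_chain, S_chain);
          expected_column(pos_chain, bx, B, N, col.data());
          swap_column(P, bx, col.data(), E_chain, S_chain);
          double sc = score_from_quadratic(P, S_chain, w);
          if (sc > best_score + eps) {
            best_score = sc;
            best_seq = seq_chain;
            found = true;
          }
        }
      }
      if (found) { // apply this event's best relocation immediately
        cur = best_seq;
        positions_of(cur, B, pos_base);
        build_expected(pos_base, B, N, E_base);
        build_quadratic(P, E_base, S_base);
        cur_score = score_from_quadratic(P, S_base, w);
        moved_any = true;
      }
    }
    if (!moved_any) break;
  }

  // report the exact score of the final sequence (no accumulated drift)
  cur_score = score_sequence(P, cur, w, pos_base, E_base, S_base);

  return List::create(_["seq"] = IntegerVector(cur.begin(), cur.end()),
                      _["loglik"] = cur_score,
                      _["passes"] = passes);
}
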
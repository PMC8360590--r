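#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Reaction channel codes (1-based on the R side):
//   1 transcription   mn_i += 1
//   2 export          mn_i -= 1, mc_i += 1
//   3 mrna_decay      mc_i -= 1
//   4 translation     pc_i += 1, then redistribution of the shared pool
//   5 import          pc_i -= 1, pn_i += 1, then redistribution
//   6 protein_decay   pn_i -= 1

static inline double hill_factor(double pn, double K, int r, double Vn) {
  if (r == 0) return 1.0;
  double h = K / (K + pn / Vn);
  double f = 1.0;
  for (int j = 0; j < r; ++j) f *= h;
  return f;
}

// Reallocate the cytoplasmic protein pool across compartments.
// method 0: randomized largest-remainder on weights w (reduces to the
//           floor(p_tot/N) + random distinct extras rule when uniform);
// method 1: multinomial on weights w (sensitivity alternative).
// Draws consume the caller's R RNG stream in event order.
static void redistribute_counts(std::vector<int>& pc,
                                const std::vector<double>& w,
                                bool uniform, int method,
                                std::vector<int>& scratch) {
  const int N = (int) pc.size();
  long ptot = 0;
  for (int i = 0; i < N; ++i) ptot += pc[i];

  if (method == 1) { // multinomial via sequential binomials
    double wrem = 0.0;
    for (int i = 0; i < N; ++i) wrem += w[i];
    long left = ptot;
    for (int i = 0; i < N - 1; ++i) {
      double p = (wrem > 0.0) ? w[i] / wrem : 0.0;
      if (p > 1.0) p = 1.0;
      int x = (left > 0) ? (int) R::rbinom((double) left, p) : 0;
      pc[i] = x;
      left -= x;
      wrem -= w[i];
    }
    pc[N - 1] = (int) left;
    return;
  }

  if (uniform) {
    const int base = (int) (ptot / N);
    int rem = (int) (ptot % N);
    for (int i = 0; i < N; ++i) pc[i] = base;
    // rem distinct compartments chosen uniformly without replacement
    for (int i = 0; i < N; ++i) scratch[i] = i;
    for (int k = 0; k < rem; ++k) {
      int j = k + (int) (unif_rand() * (N - k));
      if (j > N - 1) j = N - 1;
      std::swap(scratch[k], scratch[j]);
      pc[scratch[k]] += 1;
    }
    return;
  }

  // randomized largest remainder: floor the real-valued targets, then hand
  // the leftover units one-each to distinct compartments drawn with
  // probability proportional to their fractional remainders
  std::vector<double> frac(N);
  long alloc = 0;
  for (int i = 0; i < N; ++i) {
    double target = w[i] * (double) ptot;
    int base = (int) std::floor(target);
    pc[i] = base;
    alloc += base;
    frac[i] = target - base;
  }
  int rem = (int) (ptot - alloc);
  std::vector<bool> used(N, false);
  for (int k = 0; k < rem; ++k) {
    double tot = 0.0;
    for (int i = 0; i < N; ++i) if (!used[i]) tot += frac[i];
    int pick = -1;
    if (tot > 1e-12) {
      double u = unif_rand() * tot, c = 0.0;
      for (int i = 0; i < N; ++i) {
        if (used[i]) continue;
        c += frac[i];
        if (u <= c) { pick = i; break; }
      }
    }
    if (pick < 0) { // all remainders ~0 (rounding): uniform over unused
      int nfree = 0;
      for (int i = 0; i < N; ++i) if (!used[i]) ++nfree;
      if (nfree == 0) break;
      int j = (int) (unif_rand() * nfree);
      if (j >= nfree) j = nfree - 1;
      for (int i = 0; i < N; ++i) {
        if (!used[i] && j-- == 0) { pick = i; break; }
      }
    }
    used[pick] = true;
    pc[pick] += 1;
  }
}

// [[Rcpp::export]]
IntegerVector redistribute_cpp(IntegerVector pc, NumericVector weights,
                               bool uniform, int method) {
  std::vector<int> p(pc.begin(), pc.end());
  std::vector<double> w(weights.begin(), weights.end());
  std::vector<int> scratch(p.size());
  redistribute_counts(p, w, uniform, method, scratch);
  return IntegerVector(p.begin(), p.end());
}

// Exact SSA for the N-compartment oscillator. Samples counts on a uniform
// grid (right-continuous: value at grid time t is the state after the last
// event at or before t) and optionally logs events.
// log_mode: 0 none, 1 transcription events only, 2 all events.
// [[Rcpp::export]]
List ssa_run_cpp(double alpha, double beta, double gamma_m, double gamma_p,
                 double delta_m, double delta_p, double K, int r, double Vn,
                 NumericVector weights, bool uniform, bool share,
                 int redist_method,
                 IntegerVector mn0, IntegerVector mc0,
                 IntegerVector pc0, IntegerVector pn0,
                 double t_end, double dt_sample, int log_mode) {
  const int N = weights.size();
  std::vector<int> mn(mn0.begin(), mn0.end()), mc(mc0.begin(), mc0.end());
  std::vector<int> pc(pc0.begin(), pc0.end()), pn(pn0.begin(), pn0.end());
  std::vector<double> w(weights.begin(), weights.end());
  std::vector<int> scratch(N);
  std::vector<double> a(6 * N);

  const int n_grid = (int) std::floor(t_end / dt_sample + 1e-9) + 1;
  IntegerMatrix mn_s(n_grid, N), mc_s(n_grid, N), pc_s(n_grid, N),
      pn_s(n_grid, N);
  std::vector<double> ev_t;
  std::vector<int> ev_ch, ev_ci;

  double t = 0.0;
  int gi = 0; // next grid row to fill
  unsigned long long n_events = 0;

  for (;;) {
    double atot = 0.0;
    for (int i = 0; i < N; ++i) {
      double* ai = &a[6 * i];
      ai[0] = alpha * hill_factor((double) pn[i], K, r, Vn);
      ai[1] = gamma_m * mn[i];
      ai[2] = delta_m * mc[i];
      ai[3] = beta * mc[i];
      ai[4] = gamma_p * pc[i];
      ai[5] = delta_p * pn[i];
      atot += ai[0] + ai[1] + ai[2] + ai[3] + ai[4] + ai[5];
    }
    if (atot <= 0.0) break; // frozen state: nothing can fire

    double tnew = t + exp_rand() / atot;
    if (tnew > t_end) break;

    double u = unif_rand() * atot, c = 0.0;
    int ch = -1, ci = -1;
    for (int i = 0; i < N && ch < 0; ++i) {
      for (int k = 0; k < 6; ++k) {
        c += a[6 * i + k];
        if (u <= c) { ch = k; ci = i; break; }
      }
    }
    if (ch < 0) { // float round-off: take the last positive channel
      for (int i = 6 * N - 1; i >= 0; --i) {
        if (a[i] > 0.0) { ch = i % 6; ci = i / 6; break; }
      }
      if (ch < 0) break;
    }

    // sample grid points the process passed while waiting
    while (gi < n_grid && gi * dt_sample < tnew) {
      for (int i = 0; i < N; ++i) {
        mn_s(gi, i) = mn[i]; mc_s(gi, i) = mc[i];
        pc_s(gi, i) = pc[i]; pn_s(gi, i) = pn[i];
      }
      ++gi;
    }

    switch (ch) {
      case 0: mn[ci] += 1; break;
      case 1: mn[ci] -= 1; mc[ci] += 1; break;
      case 2: mc[ci] -= 1; break;
      case 3:
        pc[ci] += 1;
        if (share && N > 1)
          redistribute_counts(pc, w, uniform, redist_method, scratch);
        break;
      case 4:
        pc[ci] -= 1; pn[ci] += 1;
        if (share && N > 1)
          redistribute_counts(pc, w, uniform, redist_method, scratch);
        break;
      case 5: pn[ci] -= 1; break;
    }
    t = tnew;
    ++n_events;
    if (log_mode == 2 || (log_mode == 1 && ch == 0)) {
      ev_t.push_back(t);
      ev_ch.push_back(ch + 1);
      ev_ci.push_back(ci + 1);
    }
    if ((n_events & 0xFFFFF) == 0) Rcpp::checkUserInterrupt();
  }

  while (gi < n_grid) { // tail after the last event (or frozen state)
    for (int i = 0; i < N; ++i) {
      mn_s(gi, i) = mn[i]; mc_s(gi, i) = mc[i];
      pc_s(gi, i) = pc[i]; pn_s(gi, i) = pn[i];
    }
    ++gi;
  }

  return List::create(
      _["mn"] = mn_s, _["mc"] = mc_s, _["pc"] = pc_s, _["pn"] = pn_s,
      _["ev_time"] = NumericVector(ev_t.begin(), ev_t.end()),
      _["ev_channel"] = IntegerVector(ev_ch.begin(), ev_ch.end()),
      _["ev_compartment"] = IntegerVector(ev_ci.begin(), ev_ci.end()),
      _["n_events"] = (double) n_events);
}
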
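// Conditional-likelihood engines under GTR+I+Gamma.
//
// Two modes share the same arithmetic (identical operation order, so their
// results agree bitwise):
//
//   mode 0 (fused): one pass per internal node -- terminal transition
//   matrices are transformed to prelike lookups inline, the conditional
//   likelihoods (clp) are computed, and per-site rescaling is merged into
//   the same pass; scaler flag switches are queued and committed after the
//   pass (deferred) or per node. The root combination is merged into the
//   root's pass.
//
//   mode 1 (multipass): the five-stage reference pipeline with materialized
//   intermediates -- stage 1 writes prelike to the simulated global store
//   and stage 2 re-reads it; stages 3 (old-scaler subtraction) and 4 (new
//   scaler) are separate passes re-reading clp; stage 5 re-reads the root
//   clp for the likelihood combination.
//
// Both modes carry a ledger of simulated global-store traffic per parameter
// class: clp counted in residue units (one residue = ncat*4 values), tip in
// whole transition-block units, ls (lnScaler) in per-site float units.

#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

namespace {

struct Ledger {
  // rows: clp_w, clp_r, tip_w, tip_r, ls_w, ls_r; cols: down, root
  double m[6][2];
  Ledger() { for (int i = 0; i < 6; ++i) m[i][0] = m[i][1] = 0.0; }
  void add(int row, int col, double v) { if (col >= 0) m[row][col] += v; }
};

inline double dot4(const double* p, const double* c) {
  return p[0] * c[0] + p[1] * c[1] + p[2] * c[2] + p[3] * c[3];
}

// P[m*4+j] = sum_k C1(m,k) exp(ev[k] * rt) C2(k,j), clamped at 0
void trans_mat(const double* ev, const double* C1, const double* C2,
               double rt, double* P) {
  double e[4];
  for (int k = 0; k < 4; ++k) e[k] = std::exp(ev[k] * rt);
  for (int m = 0; m < 4; ++m)
    for (int j = 0; j < 4; ++j) {
      double s = 0.0;
      for (int k = 0; k < 4; ++k) s += C1[m + 4 * k] * e[k] * C2[k + 4 * j];
      P[m * 4 + j] = s < 0.0 ? 0.0 : s;
    }
}

// prelike[mask][m] for one category: sum of P[m][j] over states j in mask
void prelike_cat(const double* P, double* pre) {
  for (int mask = 1; mask < 16; ++mask)
    for (int m = 0; m < 4; ++m) {
      double s = 0.0;
      for (int j = 0; j < 4; ++j)
        if (mask & (1 << j)) s += P[m * 4 + j];
      pre[mask * 4 + m] = s;
    }
}

inline double logsumexp2(double a, double b) {
  if (a == R_NegInf) return b;
  if (b == R_NegInf) return a;
  double hi = a > b ? a : b, lo = a > b ? b : a;
  return hi + std::log1p(std::exp(lo - hi));
}

}  // namespace

// [[Rcpp::export(name = ".eval_tree_cpp")]]
List eval_tree_cpp(IntegerMatrix tipstates,      // ntip x L, masks 1..15
                   IntegerVector weights,        // L
                   IntegerVector post,           // internal ids, postorder
                   IntegerVector child1,         // per node id (1-based)
                   IntegerVector child2,
                   NumericVector elen,           // branch length above node
                   NumericVector evals,          // 4 eigenvalues of Q
                   NumericMatrix C1, NumericMatrix C2,
                   NumericVector rates,          // ncat category rates
                   NumericVector freqs,          // 4
                   double pinvar,
                   LogicalVector scaler_node,    // per node id
                   LogicalVector scalers_set,    // per node id (updated)
                   NumericMatrix stored_scaler,  // L x n_internal (updated)
                   NumericVector ln_scaler,      // L (updated)
                   int mode, int layout, bool defer_switches,
                   bool want_sites, IntegerVector count_mask,
                   double perturb) {
  const int ntip = tipstates.nrow();
  const int L = tipstates.ncol();
  const int ncat = rates.size();
  const int nint = post.size();
  const int res = ncat * 4;  // values per residue
  if (nint != ntip - 1) stop("internal error: expected a rooted binary tree");

  // scratch persists across calls (R is single-threaded); avoids paying a
  // multi-megabyte allocation per likelihood evaluation inside MCMC
  static std::vector<double> clp;
  if (clp.size() < (size_t)nint * L * res) clp.resize((size_t)nint * L * res);
  std::vector<double> P1(ncat * 16), P2(ncat * 16);
  std::vector<double> pre1(ncat * 64), pre2(ncat * 64);
  Ledger led;
  IntegerVector variants(nint), stages(nint);
  NumericVector site_lnl(want_sites ? L : 0);
  std::vector<int> switch_on, switch_off;
  double lnL = 0.0;

  for (int vi = 0; vi < nint; ++vi) {
    const int v = post[vi];
    const int col = v - ntip - 1;           // stored_scaler column
    const int c1 = child1[v - 1], c2 = child2[v - 1];
    const bool tip1 = c1 <= ntip, tip2 = c2 <= ntip;
    const bool is_root = (vi == nint - 1);
    const int lcol = count_mask[v - 1] - 1; // -1 skip, 0 down, 1 root

    for (int r = 0; r < ncat; ++r) {
      trans_mat(REAL(evals), REAL(C1), REAL(C2), rates[r] * elen[c1 - 1],
                &P1[r * 16]);
      trans_mat(REAL(evals), REAL(C1), REAL(C2), rates[r] * elen[c2 - 1],
                &P2[r * 16]);
    }
    if (perturb != 0.0 && mode == 0 && vi == 0) {
      if (tip1) P1[0] += perturb; else if (tip2) P2[0] += perturb;
    }

    // stage 1 (kernel1): prelike for terminal children. Fused computes the
    // same tables into on-chip storage (one tip read, nothing written back);
    // multipass writes them to the global store and re-reads them in stage 2.
    if (tip1) {
      for (int r = 0; r < ncat; ++r) prelike_cat(&P1[r * 16], &pre1[r * 64]);
      if (mode == 1) { led.add(3, lcol, 1); led.add(2, lcol, 1); led.add(3, lcol, 1); }
      else led.add(3, lcol, 1);
    }
    if (tip2) {
      for (int r = 0; r < ncat; ++r) prelike_cat(&P2[r * 16], &pre2[r * 64]);
      if (mode == 1) { led.add(3, lcol, 1); led.add(2, lcol, 1); led.add(3, lcol, 1); }
      else led.add(3, lcol, 1);
    }

    // stage 2 (kernel2): conditional likelihoods of this node
    double* out = &clp[(size_t)vi * L * res];
    const double* in1 = tip1 ? nullptr : &clp[(size_t)0];
    const double* in2 = tip2 ? nullptr : &clp[(size_t)0];
    int i1 = 0, i2 = 0;
    if (!tip1) { for (int k = 0; k < nint; ++k) if (post[k] == c1) i1 = k;
                 in1 = &clp[(size_t)i1 * L * res]; led.add(1, lcol, L); }
    if (!tip2) { for (int k = 0; k < nint; ++k) if (post[k] == c2) i2 = k;
                 in2 = &clp[(size_t)i2 * L * res]; led.add(1, lcol, L); }
    led.add(0, lcol, L);  // clp write

    // tipstates is ntip x L, column-major: state of taxon i at site l is
    // tipstates[i + l*ntip]
    const int* ts = INTEGER(tipstates);
    const int o1 = c1 - 1, o2 = c2 - 1;
    // one residue-category quartet of the node's clp block; identical
    // arithmetic in both layouts, so state-major and site-major agree
    // bitwise
    auto quad = [&](int l, int r) {
      const size_t off = (size_t)(l * ncat + r) * 4;
      double lv[4], rv[4];
      if (tip1) {
        const double* p = &pre1[r * 64 + ts[o1 + l * ntip] * 4];
        lv[0] = p[0]; lv[1] = p[1]; lv[2] = p[2]; lv[3] = p[3];
      } else {
        const double* cv = &in1[off];
        const double* P = &P1[r * 16];
        for (int m = 0; m < 4; ++m) lv[m] = dot4(&P[m * 4], cv);
      }
      if (tip2) {
        const double* p = &pre2[r * 64 + ts[o2 + l * ntip] * 4];
        rv[0] = p[0]; rv[1] = p[1]; rv[2] = p[2]; rv[3] = p[3];
      } else {
        const double* cv = &in2[off];
        const double* P = &P2[r * 16];
        for (int m = 0; m < 4; ++m) rv[m] = dot4(&P[m * 4], cv);
      }
      double* o = &out[off];
      for (int m = 0; m < 4; ++m) o[m] = lv[m] * rv[m];
    };
    if (layout == 0) {  // state-major: all 16 slots of a site together
      for (int l = 0; l < L; ++l)
        for (int r = 0; r < ncat; ++r) quad(l, r);
    } else {            // site-major: one worker per site, sites innermost
      for (int r = 0; r < ncat; ++r)
        for (int l = 0; l < L; ++l) quad(l, r);
    }

    // scaler shortcut T = 2S + N selects the variant together with the
    // node shape x = (left terminal) + 2 * (right terminal)
    const int S = scalers_set[v - 1] ? 1 : 0;
    const int N = scaler_node[v - 1] ? 1 : 0;
    const int T = 2 * S + N;
    variants[vi] = (tip1 ? 1 : 0) * 1 + (tip2 ? 1 : 0) * 2;  // x
    variants[vi] = variants[vi] * 4 + T;

    // stages 3+4: rescaling. Multipass runs them as separate passes with
    // their own global traffic; fused merges them into the node's pass.
    if (mode == 1) {
      if (S) {  // kernel3: remove old scaler
        for (int l = 0; l < L; ++l) ln_scaler[l] -= stored_scaler(l, col);
        led.add(5, lcol, L); led.add(4, lcol, L);
      }
      if (N) {  // kernel4: new scaler = max clp within each residue
        led.add(1, lcol, L);  // re-read clp
        for (int l = 0; l < L; ++l) {
          double mx = 0.0;
          double* cl = &out[(size_t)l * res];
          for (int k = 0; k < res; ++k) if (cl[k] > mx) mx = cl[k];
          if (mx <= 0.0)
            stop("impossible-data error: all conditional likelihoods zero at a site");
          double lmx = std::log(mx);
          for (int k = 0; k < res; ++k) cl[k] /= mx;
          stored_scaler(l, col) = lmx;
          ln_scaler[l] += lmx;
        }
        led.add(0, lcol, L);  // scaled clp re-write
        led.add(5, lcol, L); led.add(4, lcol, L);
      }
    } else {
      if (S || N) { led.add(5, lcol, L); led.add(4, lcol, L); }
      for (int l = 0; l < L; ++l) {
        if (S) ln_scaler[l] -= stored_scaler(l, col);
        if (N) {
          double mx = 0.0;
          double* cl = &out[(size_t)l * res];
          for (int k = 0; k < res; ++k) if (cl[k] > mx) mx = cl[k];
          if (mx <= 0.0)
            stop("impossible-data error: all conditional likelihoods zero at a site");
          double lmx = std::log(mx);
          for (int k = 0; k < res; ++k) cl[k] /= mx;
          stored_scaler(l, col) = lmx;
          ln_scaler[l] += lmx;
        }
      }
    }

    // queued bit switches: S-removal clears scalersSet unless a new scaler
    // was just installed
    if (N) switch_on.push_back(v);
    else if (S) switch_off.push_back(v);
    if (!defer_switches) {
      for (int id : switch_on) scalers_set[id - 1] = true;
      for (int id : switch_off) scalers_set[id - 1] = false;
      switch_on.clear(); switch_off.clear();
    }

    stages[vi] = ((tip1 || tip2) ? 1 : 0) + 1 + S + N + (is_root ? 1 : 0);

    // stage 5 (kernel5): root likelihood combination. Fused reads the root
    // clp from on-chip storage; multipass re-reads it from the global store.
    if (is_root) {
      if (mode == 1) led.add(1, lcol, L);
      for (int l = 0; l < L; ++l) {
        double mix = 0.0;
        const double* cl = &out[(size_t)l * res];
        for (int r = 0; r < ncat; ++r)
          for (int m = 0; m < 4; ++m) mix += freqs[m] * cl[r * 4 + m];
        mix /= (double)ncat;
        double lnl;
        if (pinvar > 0.0) {
          // states compatible with every taxon at this pattern
          int am = 15;
          for (int i = 0; i < ntip; ++i) am &= tipstates[i + l * ntip];
          double inv = 0.0;
          for (int m = 0; m < 4; ++m) if (am & (1 << m)) inv += freqs[m];
          // lnScaler + log((1-P) mix + P inv exp(-lnScaler)), evaluated
          // in log space so the invariable term survives deep rescaling
          double a = mix > 0.0
            ? ln_scaler[l] + std::log((1.0 - pinvar) * mix) : R_NegInf;
          double b = inv > 0.0 ? std::log(pinvar * inv) : R_NegInf;
          lnl = logsumexp2(a, b);
        } else {
          lnl = mix > 0.0 ? ln_scaler[l] + std::log(mix) : R_NegInf;
        }
        if (want_sites) site_lnl[l] = lnl;
        lnL += (double)weights[l] * lnl;
      }
    }
  }

  if (defer_switches) {
    for (int id : switch_on) scalers_set[id - 1] = true;
    for (int id : switch_off) scalers_set[id - 1] = false;
  }

  NumericMatrix ledger(6, 2);
  for (int i = 0; i < 6; ++i) { ledger(i, 0) = led.m[i][0]; ledger(i, 1) = led.m[i][1]; }
  return List::create(_["loglik"] = lnL,
                      _["sites"] = site_lnl,
                      _["ledger"] = ledger,
                      _["variants"] = variants,
                      _["stages"] = stages);
}
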
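// Explicit-duration HMM core for CRM discovery.
//
// State space (silent bookkeeping states compiled away):
//   b_g  inter-CRM background, geometric run length via per-base
//        self-transition (1 - p_r)
//   m_i  motif states i = 0..M-1 (fixed duration len[i]); the second half
//        of the states are reverse complements of the first half
//   b_c  intra-CRM spacer, destined for a known next motif, geometric
//        length (1 - p_h)^(d-1) p_h with d >= 1
//
// Sequence-end convention: a CRM still open at the end pays its q0
// termination factor; trailing background pays (1 - p_r) per base and no
// terminal factor.  All arithmetic in natural-log space.
//
// Emissions are precomputed in R and passed per position:
//   e0[t], e1[t]  background / spacer log emission of position t (0-based)
//   memit(i, t)   log emission of a full site of motif i ENDING at t
//                 (-Inf where t + 1 < len[i])

#include <Rcpp.h>
#include <vector>
#include <limits>
#include <cmath>

using namespace Rcpp;

static const double NEG_INF = -std::numeric_limits<double>::infinity();

static inline double logadd(double a, double b) {
  if (a == NEG_INF) return b;
  if (b == NEG_INF) return a;
  if (a < b) std::swap(a, b);
  return a + std::log1p(std::exp(b - a));
}

struct FwdTables {
  int L, M;
  std::vector<double> D;              // (L+1)
  std::vector<double> Fm;             // M x (L+1): motif i ends at t
  std::vector<double> S;              // M x (L+1): in spacer -> j at t
  double loglik;
  double &fm(int i, int t) { return Fm[(size_t)i * (L + 1) + t]; }
  double &s(int j, int t) { return S[(size_t)j * (L + 1) + t]; }
};

static void run_forward(const NumericVector &e0, const NumericVector &e1,
                        const NumericMatrix &memit, const IntegerVector &len,
                        double lpr, double l1pr, double lq0, double l1q0,
                        const NumericVector &lq, const NumericMatrix &lQ,
                        double lph, double l1ph, FwdTables &F) {
  const int L = e0.size(), M = len.size();
  F.L = L; F.M = M;
  F.D.assign(L + 1, NEG_INF);
  F.Fm.assign((size_t)M * (L + 1), NEG_INF);
  F.S.assign((size_t)M * (L + 1), NEG_INF);
  F.D[0] = 0.0;
  std::vector<double> m2s(M);         // enter-spacer scores at u = t - 1
  for (int t = 1; t <= L; ++t) {
    // motif i ending at t
    for (int i = 0; i < M; ++i) {
      int u = t - len[i];
      if (u < 0 || memit(i, t - 1) == NEG_INF) continue;
      double from_d = (F.D[u] == NEG_INF) ? NEG_INF : F.D[u] + lpr + lq[i];
      double from_s = (u >= 1 && F.s(i, u) != NEG_INF)
                          ? F.s(i, u) + lph : NEG_INF;
      double v = logadd(from_d, from_s);
      if (v != NEG_INF) F.fm(i, t) = v + memit(i, t - 1);
    }
    // spacer base at t destined for j (uses Fm at t - 1)
    int u = t - 1;
    bool any_m = false;
    for (int i = 0; i < M; ++i)
      if (u >= 1 && F.fm(i, u) != NEG_INF) { any_m = true; break; }
    for (int j = 0; j < M; ++j) {
      double enter = NEG_INF;
      if (any_m)
        for (int i = 0; i < M; ++i)
          if (F.fm(i, u) != NEG_INF)
            enter = logadd(enter, F.fm(i, u) + l1q0 + lQ(i, j));
      double cont = (u >= 1 && F.s(j, u) != NEG_INF)
                        ? F.s(j, u) + l1ph : NEG_INF;
      double v = logadd(enter, cont);
      if (v != NEG_INF) F.s(j, t) = v + e1[t - 1];
    }
    // decision point after t bases
    double v = (F.D[t - 1] == NEG_INF) ? NEG_INF
                                       : F.D[t - 1] + l1pr + e0[t - 1];
    for (int i = 0; i < M; ++i)
      if (F.fm(i, t) != NEG_INF) v = logadd(v, F.fm(i, t) + lq0);
    F.D[t] = v;
  }
  F.loglik = F.D[L];
}

struct BwdTables {
  int L, M;
  std::vector<double> Bd;             // (L+1)
  std::vector<double> Bm;             // M x (L+1): after motif i ended at t
  std::vector<double> Bs;             // M x (L+1): in spacer -> j, emitted t
  double &bm(int i, int t) { return Bm[(size_t)i * (L + 1) + t]; }
  double &bs(int j, int t) { return Bs[(size_t)j * (L + 1) + t]; }
};

static void run_backward(const NumericVector &e0, const NumericVector &e1,
                         const NumericMatrix &memit, const IntegerVector &len,
                         double lpr, double l1pr, double lq0, double l1q0,
                         const NumericVector &lq, const NumericMatrix &lQ,
                         double lph, double l1ph, BwdTables &B) {
  const int L = e0.size(), M = len.size();
  B.L = L; B.M = M;
  B.Bd.assign(L + 1, NEG_INF);
  B.Bm.assign((size_t)M * (L + 1), NEG_INF);
  B.Bs.assign((size_t)M * (L + 1), NEG_INF);
  B.Bd[L] = 0.0;
  // Mstart(j, t): motif j occupies t+1 .. t+len[j]
  auto mstart = [&](int j, int t) -> double {
    int e = t + len[j];
    if (e > L || memit(j, e - 1) == NEG_INF || B.bm(j, e) == NEG_INF)
      return NEG_INF;
    return memit(j, e - 1) + B.bm(j, e);
  };
  for (int t = L; t >= 0; --t) {
    if (t < L) {
      double v = (B.Bd[t + 1] == NEG_INF)
                     ? NEG_INF : B.Bd[t + 1] + l1pr + e0[t];
      for (int i = 0; i < M; ++i) {
        double ms = mstart(i, t);
        if (ms != NEG_INF) v = logadd(v, lpr + lq[i] + ms);
      }
      B.Bd[t] = v;
    }
    if (t >= 1) {
      for (int j = 0; j < M; ++j) {
        double exit = mstart(j, t);
        double v = (exit == NEG_INF) ? NEG_INF : lph + exit;
        if (t < L && B.bs(j, t + 1) != NEG_INF)
          v = logadd(v, l1ph + e1[t] + B.bs(j, t + 1));
        B.bs(j, t) = v;
      }
      for (int i = 0; i < M; ++i) {
        double v = (B.Bd[t] == NEG_INF) ? NEG_INF : lq0 + B.Bd[t];
        if (t < L) {
          // continue the CRM: first spacer base is position t + 1
          double cont = NEG_INF;
          for (int j = 0; j < M; ++j)
            if (B.bs(j, t + 1) != NEG_INF)
              cont = logadd(cont, lQ(i, j) + e1[t] + B.bs(j, t + 1));
          if (cont != NEG_INF) v = logadd(v, l1q0 + cont);
        }
        B.bm(i, t) = v;
      }
    }
  }
}

// [[Rcpp::export]]
List crm_forward_backward_cpp(NumericVector e0, NumericVector e1,
                              NumericMatrix memit, IntegerVector len,
                              double p_r, double q0, NumericVector q,
                              NumericMatrix Q, double p_h,
                              bool posteriors = true) {
  const int L = e0.size(), M = len.size();
  const double lpr = std::log(p_r), l1pr = std::log1p(-p_r);
  const double lq0 = std::log(q0), l1q0 = std::log1p(-q0);
  const double lph = std::log(p_h),
               l1ph = (p_h < 1.0) ? std::log1p(-p_h) : NEG_INF;
  NumericVector lq(M);
  for (int i = 0; i < M; ++i) lq[i] = std::log(q[i]);
  NumericMatrix lQ(M, M);
  for (int i = 0; i < M; ++i)
    for (int j = 0; j < M; ++j)
      lQ(i, j) = (Q(i, j) > 0) ? std::log(Q(i, j)) : NEG_INF;

  FwdTables F;
  run_forward(e0, e1, memit, len, lpr, l1pr, lq0, l1q0, lq, lQ, lph, l1ph, F);
  BwdTables B;
  run_backward(e0, e1, memit, len, lpr, l1pr, lq0, l1q0, lq, lQ, lph, l1ph, B);

  List out = List::create(_["loglik"] = F.loglik,
                          _["loglik_backward"] = B.Bd[0]);
  if (!posteriors || F.loglik == NEG_INF) {
    out["posteriors_available"] = posteriors && F.loglik != NEG_INF;
    return out;
  }
  const double LL = F.loglik;

  NumericMatrix T(M, M), gamma_site(M, L);
  NumericVector C1(M);
  NumericMatrix occ(3, L);            // rows: bg, motif, spacer
  double total_spacer = 0.0;

  for (int t = 1; t <= L; ++t) {
    // background occupancy of position t
    if (F.D[t - 1] != NEG_INF && B.Bd[t] != NEG_INF)
      occ(0, t - 1) = std::exp(F.D[t - 1] + l1pr + e0[t - 1] + B.Bd[t] - LL);
    for (int i = 0; i < M; ++i) {
      if (F.fm(i, t) != NEG_INF && B.bm(i, t) != NEG_INF) {
        double g = std::exp(F.fm(i, t) + B.bm(i, t) - LL);
        gamma_site(i, t - 1) = g;
        for (int p = t - len[i]; p < t; ++p) occ(1, p) += g;
      }
      if (F.s(i, t) != NEG_INF && B.bs(i, t) != NEG_INF) {
        double g = std::exp(F.s(i, t) + B.bs(i, t) - LL);
        occ(2, t - 1) += g;
        total_spacer += g;
      }
    }
  }
  // expected first-motif usage
  for (int i = 0; i < M; ++i)
    for (int u = 0; u + len[i] <= L; ++u) {
      int e = u + len[i];
      if (F.D[u] != NEG_INF && memit(i, e - 1) != NEG_INF &&
          B.bm(i, e) != NEG_INF)
        C1[i] += std::exp(F.D[u] + lpr + lq[i] + memit(i, e - 1) +
                          B.bm(i, e) - LL);
    }
  // expected adjacent-pair transition counts (motif i -> spacer -> motif j)
  for (int u = 1; u < L; ++u)
    for (int i = 0; i < M; ++i) {
      if (F.fm(i, u) == NEG_INF) continue;
      for (int j = 0; j < M; ++j) {
        if (lQ(i, j) == NEG_INF || B.bs(j, u + 1) == NEG_INF) continue;
        T(i, j) += std::exp(F.fm(i, u) + l1q0 + lQ(i, j) + e1[u] +
                            B.bs(j, u + 1) - LL);
      }
    }

  out["posteriors_available"] = true;
  out["T"] = T;
  out["first_motif"] = C1;
  out["gamma_site"] = gamma_site;
  out["occupancy"] = occ;
  out["expected_spacer_bases"] = total_spacer;
  return out;
}

// Posterior mean and second moment of the count of (i0 -> spacer -> j0)
// adjacencies, via exact moment propagation along the forward recursion.
// [[Rcpp::export]]
List crm_pair_moments_cpp(NumericVector e0, NumericVector e1,
                          NumericMatrix memit, IntegerVector len,
                          double p_r, double q0, NumericVector q,
                          NumericMatrix Q, double p_h, int i0, int j0) {
  const int L = e0.size(), M = len.size();
  const double lpr = std::log(p_r), l1pr = std::log1p(-p_r);
  const double lq0 = std::log(q0), l1q0 = std::log1p(-q0);
  const double lph = std::log(p_h),
               l1ph = (p_h < 1.0) ? std::log1p(-p_h) : NEG_INF;
  --i0; --j0;                          // to 0-based
  std::vector<double> lq(M);
  for (int i = 0; i < M; ++i) lq[i] = std::log(q[i]);
  std::vector<double> lQ((size_t)M * M);
  for (int i = 0; i < M; ++i)
    for (int j = 0; j < M; ++j)
      lQ[(size_t)i * M + j] = (Q(i, j) > 0) ? std::log(Q(i, j)) : NEG_INF;

  struct Acc { double la, m1, m2; };
  auto zero = []() { return Acc{NEG_INF, 0.0, 0.0}; };
  // combine incoming branch (la_b + w, with count increment c) into `out`
  auto add = [](Acc &out, const Acc &in, double w, double c) {
    if (in.la == NEG_INF || w == NEG_INF) return;
    double la_b = in.la + w;
    double m1_b = in.m1 + c, m2_b = in.m2 + 2.0 * c * in.m1 + c * c;
    if (out.la == NEG_INF) {
      out.la = la_b; out.m1 = m1_b; out.m2 = m2_b;
    } else {
      double la_n = logadd(out.la, la_b);
      double wo = std::exp(out.la - la_n), wb = std::exp(la_b - la_n);
      out.m1 = wo * out.m1 + wb * m1_b;
      out.m2 = wo * out.m2 + wb * m2_b;
      out.la = la_n;
    }
  };

  std::vector<Acc> D(L + 1, zero()), Fm((size_t)M * (L + 1), zero()),
      S((size_t)M * (L + 1), zero());
  D[0].la = 0.0;
  for (int t = 1; t <= L; ++t) {
    for (int i = 0; i < M; ++i) {
      int u = t - len[i];
      if (u < 0 || memit(i, t - 1) == NEG_INF) continue;
      Acc &o = Fm[(size_t)i * (L + 1) + t];
      add(o, D[u], lpr + lq[i], 0.0);
      if (u >= 1) add(o, S[(size_t)i * (L + 1) + u], lph, 0.0);
      if (o.la != NEG_INF) o.la += memit(i, t - 1);
    }
    int u = t - 1;
    for (int j = 0; j < M; ++j) {
      Acc &o = S[(size_t)j * (L + 1) + t];
      if (u >= 1)
        for (int i = 0; i < M; ++i)
          add(o, Fm[(size_t)i * (L + 1) + u],
              l1q0 + lQ[(size_t)i * M + j],
              (i == i0 && j == j0) ? 1.0 : 0.0);
      if (u >= 1) add(o, S[(size_t)j * (L + 1) + u], l1ph, 0.0);
      if (o.la != NEG_INF) o.la += e1[t - 1];
    }
    Acc &o = D[t];
    add(o, D[t - 1], l1pr + e0[t - 1], 0.0);
    for (int i = 0; i < M; ++i)
      add(o, Fm[(size_t)i * (L + 1) + t], lq0, 0.0);
  }
  return List::create(_["loglik"] = D[L].la, _["mean"] = D[L].m1,
                      _["second_moment"] = D[L].m2,
                      _["variance"] = D[L].m2 - D[L].m1 * D[L].m1);
}

// Duration Viterbi with deterministic tie-breaking (prefer background,
// then lower motif index, then shorter spacer).
// [[Rcpp::export]]
List crm_viterbi_cpp(NumericVector e0, NumericVector e1,
                     NumericMatrix memit, IntegerVector len,
                     double p_r, double q0, NumericVector q,
                     NumericMatrix Q, double p_h) {
  const int L = e0.size(), M = len.size();
  const double lpr = std::log(p_r), l1pr = std::log1p(-p_r);
  const double lq0 = std::log(q0), l1q0 = std::log1p(-q0);
  const double lph = std::log(p_h),
               l1ph = (p_h < 1.0) ? std::log1p(-p_h) : NEG_INF;
  std::vector<double> lq(M);
  for (int i = 0; i < M; ++i) lq[i] = std::log(q[i]);
  std::vector<double> lQ((size_t)M * M);
  for (int i = 0; i < M; ++i)
    for (int j = 0; j < M; ++j)
      lQ[(size_t)i * M + j] = (Q(i, j) > 0) ? std::log(Q(i, j)) : NEG_INF;

  std::vector<double> D(L + 1, NEG_INF), Fm((size_t)M * (L + 1), NEG_INF),
      S((size_t)M * (L + 1), NEG_INF);
  // backpointers: D -> 0 = bg, i+1 = CRM ended with motif i
  //               Fm -> 0 = from decision point (CRM start), 1 = from spacer
  //               S  -> -1 = spacer continued, i = entered after motif i
  std::vector<int> bpD(L + 1, 0), bpM((size_t)M * (L + 1), 0),
      bpS((size_t)M * (L + 1), -1);
  D[0] = 0.0;
  for (int t = 1; t <= L; ++t) {
    for (int i = 0; i < M; ++i) {
      int u = t - len[i];
      if (u < 0 || memit(i, t - 1) == NEG_INF) continue;
      double best = NEG_INF; int bp = 0;
      if (D[u] != NEG_INF) { best = D[u] + lpr + lq[i]; bp = 0; }
      if (u >= 1 && S[(size_t)i * (L + 1) + u] != NEG_INF) {
        double v = S[(size_t)i * (L + 1) + u] + lph;
        if (v > best) { best = v; bp = 1; }
      }
      if (best != NEG_INF) {
        Fm[(size_t)i * (L + 1) + t] = best + memit(i, t - 1);
        bpM[(size_t)i * (L + 1) + t] = bp;
      }
    }
    int u = t - 1;
    for (int j = 0; j < M; ++j) {
      double best = NEG_INF; int bp = -1;
      if (u >= 1)
        for (int i = 0; i < M; ++i) {          // shorter spacer preferred:
          double fm = Fm[(size_t)i * (L + 1) + u];  // entries first
          if (fm == NEG_INF || lQ[(size_t)i * M + j] == NEG_INF) continue;
          double v = fm + l1q0 + lQ[(size_t)i * M + j];
          if (v > best) { best = v; bp = i; }
        }
      if (u >= 1 && S[(size_t)j * (L + 1) + u] != NEG_INF) {
        double v = S[(size_t)j * (L + 1) + u] + l1ph;
        if (v > best) { best = v; bp = -1; }
      }
      if (best != NEG_INF) {
        S[(size_t)j * (L + 1) + t] = best + e1[t - 1];
        bpS[(size_t)j * (L + 1) + t] = bp;
      }
    }
    double best = NEG_INF; int bp = 0;       // background preferred on ties
    if (D[t - 1] != NEG_INF) { best = D[t - 1] + l1pr + e0[t - 1]; bp = 0; }
    for (int i = 0; i < M; ++i) {
      double fm = Fm[(size_t)i * (L + 1) + t];
      if (fm != NEG_INF && fm + lq0 > best) { best = fm + lq0; bp = i + 1; }
    }
    D[t] = best; bpD[t] = bp;
  }

  // traceback
  std::vector<int> seg_state, seg_start, seg_end, seg_motif, seg_crmstart;
  int t = L, mode = 0, cur = -1;             // mode: 0 = D, 1 = motif, 2 = S
  int spacer_end = -1;
  while (t > 0 || mode != 0) {
    if (mode == 0) {
      if (t == 0) break;
      int bp = bpD[t];
      if (bp == 0) {
        seg_state.push_back(0); seg_start.push_back(t - 1);
        seg_end.push_back(t); seg_motif.push_back(NA_INTEGER);
        seg_crmstart.push_back(0);
        --t;
      } else {
        mode = 1; cur = bp - 1;
      }
    } else if (mode == 1) {                  // motif `cur` ends at t
      int st = t - len[cur];
      int bp = bpM[(size_t)cur * (L + 1) + t];
      seg_state.push_back(1); seg_start.push_back(st); seg_end.push_back(t);
      seg_motif.push_back(cur + 1); seg_crmstart.push_back(bp == 0 ? 1 : 0);
      t = st;
      if (bp == 0) mode = 0;
      else { mode = 2; spacer_end = t; }
    } else {                                 // in spacer destined `cur`, base t
      int bp = bpS[(size_t)cur * (L + 1) + t];
      if (bp == -1) { --t; }
      else {
        seg_state.push_back(2); seg_start.push_back(t - 1);
        seg_end.push_back(spacer_end); seg_motif.push_back(NA_INTEGER);
        seg_crmstart.push_back(0);
        --t; mode = 1; cur = bp;
      }
    }
  }
  // merge consecutive single-base bg segments and reverse order
  int n = seg_state.size();
  std::vector<int> st2, a2, b2, m2, cs2;
  for (int k = n - 1; k >= 0; --k) {
    if (seg_state[k] == 0 && !st2.empty() && st2.back() == 0 &&
        b2.back() == seg_start[k]) {
      b2.back() = seg_end[k];
    } else {
      st2.push_back(seg_state[k]); a2.push_back(seg_start[k]);
      b2.push_back(seg_end[k]); m2.push_back(seg_motif[k]);
      cs2.push_back(seg_crmstart[k]);
    }
  }
  return List::create(_["score"] = D[L], _["state"] = wrap(st2),
                      _["start"] = wrap(a2), _["end"] = wrap(b2),
                      _["motif"] = wrap(m2), _["crm_start"] = wrap(cs2));
}
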
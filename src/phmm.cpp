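// Forward and Viterbi dynamic programming for a minimal Krogh-style profile
// HMM with global alignment to the profile. States: begin (M0), match
// M1..Mn, insert I0..In, delete D1..Dn, end. Allowed transitions:
// M->{M,I,D}, I->{M,I}, D->{M,D}. All computation in natural-log space.
//
// Sequence encoding: residues as 0..19 indices into the emission columns;
// -1 marks a non-standard residue that emits the background probability in
// every emitting state (score-neutral).

#include <Rcpp.h>
#include <cmath>
#include <limits>
using namespace Rcpp;

static const double NEG_INF = -std::numeric_limits<double>::infinity();

static inline double lse2(double a, double b) {
  if (a == NEG_INF) return b;
  if (b == NEG_INF) return a;
  double m = a > b ? a : b;
  return m + std::log(std::exp(a - m) + std::exp(b - m));
}

static inline double lse3(double a, double b, double c) {
  return lse2(lse2(a, b), c);
}

static inline double emit(const NumericMatrix& logem, int row, int res,
                          const NumericVector& logbg) {
  if (res < 0) return logbg[0];  // uniform background: score-neutral residue
  return logem(row, res);
}

// [[Rcpp::export(name = ".phmm_forward")]]
double phmm_forward(IntegerVector x, int n_match,
                    NumericMatrix log_me,   // n_match x 20
                    NumericMatrix log_ie,   // (n_match+1) x 20, row j = I_j
                    NumericVector log_bg,   // 20
                    NumericVector t_mm, NumericVector t_mi, NumericVector t_md,
                    NumericVector t_im, NumericVector t_ii,
                    NumericVector t_dm, NumericVector t_dd) {
  const int T = x.size();
  const int n = n_match;
  std::vector<double> pm(n + 1, NEG_INF), pi(n + 1, NEG_INF), pd(n + 1, NEG_INF);
  std::vector<double> vm(n + 1), vi(n + 1), vd(n + 1);

  // i = 0: begin occupied; delete chain reachable without emission
  pm[0] = 0.0;
  if (n >= 1) {
    pd[1] = pm[0] + t_md[0];
    for (int j = 2; j <= n; ++j) pd[j] = pd[j - 1] + t_dd[j - 1];
  }

  for (int i = 1; i <= T; ++i) {
    const int res = x[i - 1];
    std::fill(vm.begin(), vm.end(), NEG_INF);
    std::fill(vi.begin(), vi.end(), NEG_INF);
    std::fill(vd.begin(), vd.end(), NEG_INF);

    vi[0] = emit(log_ie, 0, res, log_bg) +
            lse2(pm[0] + t_mi[0], pi[0] + t_ii[0]);
    for (int j = 1; j <= n; ++j) {
      double from_m = pm[j - 1] + t_mm[j - 1];
      double from_i = pi[j - 1] + t_im[j - 1];
      double from_d = (j >= 2) ? pd[j - 1] + t_dm[j - 1] : NEG_INF;
      vm[j] = emit(log_me, j - 1, res, log_bg) + lse3(from_m, from_i, from_d);
      vi[j] = emit(log_ie, j, res, log_bg) +
              lse2(pm[j] + t_mi[j], pi[j] + t_ii[j]);
    }
    for (int j = 1; j <= n; ++j) {  // deletes: same i, increasing j
      double from_m = vm[j - 1] + t_md[j - 1];  // vm[0] = -inf once i >= 1
      double from_d = (j >= 2) ? vd[j - 1] + t_dd[j - 1] : NEG_INF;
      vd[j] = lse2(from_m, from_d);
    }
    pm.swap(vm); pi.swap(vi); pd.swap(vd);
  }

  return lse3(pm[n] + t_mm[n], pi[n] + t_im[n],
              (n >= 1) ? pd[n] + t_dm[n] : NEG_INF);
}

// [[Rcpp::export(name = ".phmm_viterbi")]]
List phmm_viterbi(IntegerVector x, int n_match,
                  NumericMatrix log_me, NumericMatrix log_ie,
                  NumericVector log_bg,
                  NumericVector t_mm, NumericVector t_mi, NumericVector t_md,
                  NumericVector t_im, NumericVector t_ii,
                  NumericVector t_dm, NumericVector t_dd) {
  const int T = x.size();
  const int n = n_match;
  // value[(i * 3 + state) * (n+1) + j]; state 0=M, 1=I, 2=D
  auto idx = [n](int i, int s, int j) { return (i * 3 + s) * (n + 1) + j; };
  std::vector<double> val((T + 1) * 3 * (n + 1), NEG_INF);
  std::vector<signed char> bp((T + 1) * 3 * (n + 1), -1);
  // backpointer: the predecessor's state code (M_0 at i=0 is the begin state)

  val[idx(0, 0, 0)] = 0.0;
  if (n >= 1) {
    val[idx(0, 2, 1)] = t_md[0];
    bp[idx(0, 2, 1)] = 0;
    for (int j = 2; j <= n; ++j) {
      val[idx(0, 2, j)] = val[idx(0, 2, j - 1)] + t_dd[j - 1];
      bp[idx(0, 2, j)] = 2;
    }
  }

  for (int i = 1; i <= T; ++i) {
    const int res = x[i - 1];
    {  // insert state I_0
      double a = val[idx(i - 1, 0, 0)] + t_mi[0];
      double b = val[idx(i - 1, 1, 0)] + t_ii[0];
      double e = emit(log_ie, 0, res, log_bg);
      if (a >= b && a > NEG_INF) { val[idx(i, 1, 0)] = e + a; bp[idx(i, 1, 0)] = 0; }
      else if (b > NEG_INF)      { val[idx(i, 1, 0)] = e + b; bp[idx(i, 1, 0)] = 1; }
    }
    for (int j = 1; j <= n; ++j) {
      double cand[3] = {
        val[idx(i - 1, 0, j - 1)] + t_mm[j - 1],
        val[idx(i - 1, 1, j - 1)] + t_im[j - 1],
        (j >= 2) ? val[idx(i - 1, 2, j - 1)] + t_dm[j - 1] : NEG_INF
      };
      int best = 0;
      for (int s = 1; s < 3; ++s) if (cand[s] > cand[best]) best = s;
      if (cand[best] > NEG_INF) {
        val[idx(i, 0, j)] = emit(log_me, j - 1, res, log_bg) + cand[best];
        bp[idx(i, 0, j)] = (signed char)best;
      }
      double a = val[idx(i - 1, 0, j)] + t_mi[j];
      double b = val[idx(i - 1, 1, j)] + t_ii[j];
      double e = emit(log_ie, j, res, log_bg);
      if (a >= b && a > NEG_INF) { val[idx(i, 1, j)] = e + a; bp[idx(i, 1, j)] = 0; }
      else if (b > NEG_INF)      { val[idx(i, 1, j)] = e + b; bp[idx(i, 1, j)] = 1; }
    }
    for (int j = 1; j <= n; ++j) {  // deletes at same i
      double a = val[idx(i, 0, j - 1)] + t_md[j - 1];
      double b = (j >= 2) ? val[idx(i, 2, j - 1)] + t_dd[j - 1] : NEG_INF;
      if (a >= b && a > NEG_INF) { val[idx(i, 2, j)] = a; bp[idx(i, 2, j)] = 0; }
      else if (b > NEG_INF)      { val[idx(i, 2, j)] = b; bp[idx(i, 2, j)] = 2; }
    }
  }

  double endc[3] = {
    val[idx(T, 0, n)] + t_mm[n],
    val[idx(T, 1, n)] + t_im[n],
    (n >= 1) ? val[idx(T, 2, n)] + t_dm[n] : NEG_INF
  };
  int bstate = 0;
  for (int s = 1; s < 3; ++s) if (endc[s] > endc[bstate]) bstate = s;
  double logp = endc[bstate];

  std::vector<std::string> path;
  if (logp > NEG_INF) {
    int i = T, s = bstate, j = n;
    while (!(i == 0 && s == 0 && j == 0)) {
      char lab = s == 0 ? 'M' : (s == 1 ? 'I' : 'D');
      path.push_back(std::string(1, lab) + std::to_string(j));
      signed char b = bp[idx(i, s, j)];
      if (b < 0) stop("viterbi traceback failed");
      if (s == 0)      { i -= 1; j -= 1; }  // match consumed a residue
      else if (s == 1) { i -= 1; }          // insert consumed a residue
      else             { j -= 1; }          // delete consumed none
      s = b;
      if (i < 0 || j < 0) stop("viterbi traceback failed");
    }
    std::reverse(path.begin(), path.end());
  }

  return List::create(_["logp"] = logp, _["path"] = wrap(path));
}
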
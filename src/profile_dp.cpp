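#include <Rcpp.h>
#include <cmath>
#include <limits>
using namespace Rcpp;

// Local profile/sequence alignment with fixed transitions.
//
// States: match columns 1..M (emitting, position-specific log-odds), insert
// states after each column (emitting at background, log-odds 0), silent
// delete states. Entry is free into any match column at any target position;
// exit is free from any match column. The Viterbi score is the best single
// path; the Forward score is the log-sum over all local paths. Both are
// returned in nats and converted to bits by the caller.
//
// em:  M x 20 matrix of per-column emission log-odds (natural log)
// seq: integer-encoded target, 0..19, or -1 for unknown (scores 0)
// trans: c(mm, mi, md, ii, im, dd, dm) log-probabilities

static inline double lse2(double a, double b) {
  if (a == R_NegInf) return b;
  if (b == R_NegInf) return a;
  double m = a > b ? a : b;
  return m + std::log(std::exp(a - m) + std::exp(b - m));
}

// [[Rcpp::export(name = ".dp_local_score")]]
List dp_local_score(NumericMatrix em, IntegerVector seq, NumericVector trans) {
  const int M = em.nrow();
  const int L = seq.size();
  const double tMM = trans[0], tMI = trans[1], tMD = trans[2];
  const double tII = trans[3], tIM = trans[4], tDD = trans[5], tDM = trans[6];
  const double NEG = R_NegInf;

  // Matrices indexed [c][i], c = 0..M (0 is a sentinel), i = 0..L.
  NumericMatrix VM(M + 1, L + 1), VI(M + 1, L + 1), VD(M + 1, L + 1);
  NumericMatrix FM(M + 1, L + 1), FI(M + 1, L + 1), FD(M + 1, L + 1);
  IntegerMatrix SM(M + 1, L + 1), SI(M + 1, L + 1), SD(M + 1, L + 1);
  std::fill(VM.begin(), VM.end(), NEG);
  std::fill(VI.begin(), VI.end(), NEG);
  std::fill(VD.begin(), VD.end(), NEG);
  std::fill(FM.begin(), FM.end(), NEG);
  std::fill(FI.begin(), FI.end(), NEG);
  std::fill(FD.begin(), FD.end(), NEG);

  double best = NEG;
  int best_c = 0, best_i = 0;
  double ftotal = NEG;

  for (int i = 1; i <= L; ++i) {
    const int a = seq[i - 1];
    for (int c = 1; c <= M; ++c) {
      const double e = (a >= 0) ? em(c - 1, a) : 0.0;

      // match: free entry, or continue from M/I/D at column c-1, position i-1
      double v = 0.0;          // entry
      int src = 0;             // 0 entry, 1 M, 2 I, 3 D
      if (VM(c - 1, i - 1) + tMM > v) { v = VM(c - 1, i - 1) + tMM; src = 1; }
      if (VI(c - 1, i - 1) + tIM > v) { v = VI(c - 1, i - 1) + tIM; src = 2; }
      if (VD(c - 1, i - 1) + tDM > v) { v = VD(c - 1, i - 1) + tDM; src = 3; }
      VM(c, i) = e + v;
      SM(c, i) = (src == 0) ? i
               : (src == 1) ? SM(c - 1, i - 1)
               : (src == 2) ? SI(c - 1, i - 1)
                            : SD(c - 1, i - 1);

      double f = 0.0;          // entry mass
      f = lse2(f, FM(c - 1, i - 1) + tMM);
      f = lse2(f, FI(c - 1, i - 1) + tIM);
      f = lse2(f, FD(c - 1, i - 1) + tDM);
      FM(c, i) = e + f;

      // insert after column c (emits at background, log-odds 0)
      double vi1 = VM(c, i - 1) + tMI, vi2 = VI(c, i - 1) + tII;
      if (vi1 >= vi2) { VI(c, i) = vi1; SI(c, i) = SM(c, i - 1); }
      else            { VI(c, i) = vi2; SI(c, i) = SI(c, i - 1); }
      FI(c, i) = lse2(FM(c, i - 1) + tMI, FI(c, i - 1) + tII);

      // delete at column c (silent)
      double vd1 = VM(c - 1, i) + tMD, vd2 = VD(c - 1, i) + tDD;
      if (vd1 >= vd2) { VD(c, i) = vd1; SD(c, i) = SM(c - 1, i); }
      else            { VD(c, i) = vd2; SD(c, i) = SD(c - 1, i); }
      FD(c, i) = lse2(FM(c - 1, i) + tMD, FD(c - 1, i) + tDD);

      // free exit from any match
      if (VM(c, i) > best) { best = VM(c, i); best_c = c; best_i = i; }
      ftotal = lse2(ftotal, FM(c, i));
    }
  }

  const double ln2 = std::log(2.0);
  int env_start = (best_c > 0) ? SM(best_c, best_i) : NA_INTEGER;
  int env_end = (best_c > 0) ? best_i : NA_INTEGER;
  return List::create(
    _["viterbi_bits"] = best / ln2,
    _["forward_bits"] = ftotal / ln2,
    _["env_start"] = env_start,
    _["env_end"] = env_end);
}
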
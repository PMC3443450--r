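// Four-state transmission HMM for integrated single-dose linkage maps.
//
// Hidden state at each locus: the pair (a, b) of homologs transmitted by
// parent 1 and parent 2, in the fixed order (0,0), (0,1), (1,0), (1,1).
// Transitions between adjacent loci factorize over parents with one shared
// recombination fraction per interval; emissions are deterministic band
// indicators per state (precomputed in R), with missing scores emitting 1.

#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

static const int A[4] = {0, 0, 1, 1};
static const int B[4] = {0, 1, 0, 1};
static const double TINY = 1e-300;

static void transition(double r, double T[4][4]) {
  for (int s = 0; s < 4; ++s) {
    for (int t = 0; t < 4; ++t) {
      double ta = (A[s] == A[t]) ? 1.0 - r : r;
      double tb = (B[s] == B[t]) ? 1.0 - r : r;
      T[s][t] = ta * tb;
    }
  }
}

// emission vector for locus j, individual i
static inline void emit(const IntegerMatrix& geno, const NumericMatrix& bs,
                        int j, int i, double e[4]) {
  int y = geno(j, i);
  for (int s = 0; s < 4; ++s) {
    if (y == NA_INTEGER) e[s] = 1.0;
    else if (y == 1) e[s] = bs(j, s);
    else e[s] = 1.0 - bs(j, s);
  }
}

// [[Rcpp::export]]
double hmm_forward_cpp(IntegerMatrix geno, NumericMatrix bs,
                       NumericVector rfs) {
  int m = geno.nrow(), N = geno.ncol();
  std::vector<std::array<double, 16>> Ts(m > 1 ? m - 1 : 0);
  for (int j = 0; j + 1 < m; ++j) {
    double T[4][4];
    transition(rfs[j], T);
    for (int s = 0; s < 4; ++s)
      for (int t = 0; t < 4; ++t) Ts[j][4 * s + t] = T[s][t];
  }
  double ll = 0.0;
  double e[4], f[4], fn[4];
  for (int i = 0; i < N; ++i) {
    emit(geno, bs, 0, i, e);
    double c = 0.0;
    for (int s = 0; s < 4; ++s) { f[s] = 0.25 * e[s]; c += f[s]; }
    if (c < TINY) c = TINY;
    ll += std::log(c);
    for (int s = 0; s < 4; ++s) f[s] /= c;
    for (int j = 0; j + 1 < m; ++j) {
      emit(geno, bs, j + 1, i, e);
      c = 0.0;
      for (int t = 0; t < 4; ++t) {
        double acc = 0.0;
        for (int s = 0; s < 4; ++s) acc += f[s] * Ts[j][4 * s + t];
        fn[t] = acc * e[t];
        c += fn[t];
      }
      if (c < TINY) c = TINY;
      ll += std::log(c);
      for (int t = 0; t < 4; ++t) f[t] = fn[t] / c;
    }
  }
  return ll;
}

// Baum-Welch: E-step accumulates expected recombination events per interval
// and per parent; M-step pools both parents over 2N meioses.
// [[Rcpp::export]]
List hmm_em_cpp(IntegerMatrix geno, NumericMatrix bs, NumericVector r_init,
                double tol, int maxit) {
  int m = geno.nrow(), N = geno.ncol();
  int K = m - 1;
  if (K <= 0)
    return List::create(_["rfs"] = NumericVector(0),
                        _["loglik"] = hmm_forward_cpp(geno, bs, NumericVector(0)),
                        _["converged"] = true, _["n_iter"] = 0);
  std::vector<double> r(K);
  for (int j = 0; j < K; ++j)
    r[j] = std::min(std::max(r_init[j], 1e-4), 0.49);
  std::vector<double> alpha(4 * m), csc(m);
  std::vector<std::array<double, 16>> Ts(K);
  double ll = R_NegInf, ll_old = R_NegInf;
  bool converged = false;
  int it = 0;
  double e[4], beta[4], bn[4], G[4];
  std::vector<double> era(K), erb(K);
  while (true) {
    ++it;
    for (int j = 0; j < K; ++j) {
      double T[4][4];
      transition(r[j], T);
      for (int s = 0; s < 4; ++s)
        for (int t = 0; t < 4; ++t) Ts[j][4 * s + t] = T[s][t];
    }
    std::fill(era.begin(), era.end(), 0.0);
    std::fill(erb.begin(), erb.end(), 0.0);
    ll = 0.0;
    for (int i = 0; i < N; ++i) {
      // forward, scaled
      emit(geno, bs, 0, i, e);
      double c = 0.0;
      for (int s = 0; s < 4; ++s) { alpha[s] = 0.25 * e[s]; c += alpha[s]; }
      if (c < TINY) c = TINY;
      csc[0] = c;
      ll += std::log(c);
      for (int s = 0; s < 4; ++s) alpha[s] /= c;
      for (int j = 0; j < K; ++j) {
        emit(geno, bs, j + 1, i, e);
        c = 0.0;
        for (int t = 0; t < 4; ++t) {
          double acc = 0.0;
          for (int s = 0; s < 4; ++s) acc += alpha[4 * j + s] * Ts[j][4 * s + t];
          alpha[4 * (j + 1) + t] = acc * e[t];
          c += alpha[4 * (j + 1) + t];
        }
        if (c < TINY) c = TINY;
        csc[j + 1] = c;
        ll += std::log(c);
        for (int t = 0; t < 4; ++t) alpha[4 * (j + 1) + t] /= c;
      }
      // backward with the forward scaling; xi accumulation per interval
      for (int s = 0; s < 4; ++s) beta[s] = 1.0;
      for (int j = K - 1; j >= 0; --j) {
        emit(geno, bs, j + 1, i, e);
        for (int t = 0; t < 4; ++t) G[t] = e[t] * beta[t] / csc[j + 1];
        for (int s = 0; s < 4; ++s) {
          for (int t = 0; t < 4; ++t) {
            double xi = alpha[4 * j + s] * Ts[j][4 * s + t] * G[t];
            if (A[s] != A[t]) era[j] += xi;
            if (B[s] != B[t]) erb[j] += xi;
          }
        }
        for (int s = 0; s < 4; ++s) {
          double acc = 0.0;
          for (int t = 0; t < 4; ++t) acc += Ts[j][4 * s + t] * G[t];
          bn[s] = acc;
        }
        for (int s = 0; s < 4; ++s) beta[s] = bn[s];
      }
    }
    if (R_finite(ll) && it > 1 && ll - ll_old < tol) { converged = true; break; }
    if (it > maxit) break;
    ll_old = ll;
    for (int j = 0; j < K; ++j) {
      double rn = (era[j] + erb[j]) / (2.0 * N);
      r[j] = std::min(std::max(rn, 1e-6), 0.5 - 1e-6);
    }
  }
  return List::create(_["rfs"] = NumericVector(r.begin(), r.end()),
                      _["loglik"] = ll, _["converged"] = converged,
                      _["n_iter"] = it);
}
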
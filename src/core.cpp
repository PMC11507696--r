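// Numerical cores: inside/outside partition function over pseudoknot-free
// structures, pair-HMM forward/backward posteriors, maximum-expected-accuracy
// structure DP, and a posterior-sum Needleman-Wunsch used by the progressive
// aligner. All indices at the R interface are 1-based; internal arrays 0-based.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// Inside/outside over the unambiguous grammar
//   Q(i,j)  = Q(i,j-1) + sum_k Q(i,k-1) * Qb(k,j)
//   Qb(i,j) = w(i,j) * [ Q(i+1,j-1) + (sigma-1) * Qb(i+1,j-1) ]
// where w holds the Boltzmann weight of each admissible pair (0 if the pair is
// non-canonical or violates the hairpin minimum) and sigma is the extra
// multiplicative weight earned when the enclosed pair stacks directly inside.
// [[Rcpp::export]]
List c_partition(const arma::mat& w, double sigma, int min_hairpin) {
  const int L = w.n_rows;
  arma::mat Q(L + 2, L + 2, arma::fill::zeros);
  arma::mat Qb(L + 2, L + 2, arma::fill::zeros);
  auto Qget = [&](int i, int j) -> double { return (j < i) ? 1.0 : Q(i, j); };

  for (int s = 1; s <= L; ++s) {
    for (int i = 1; i + s - 1 <= L; ++i) {
      const int j = i + s - 1;
      if (s >= min_hairpin + 2 && w(i - 1, j - 1) > 0) {
        double inner = Qget(i + 1, j - 1);
        if (j - 1 >= i + 1) inner += (sigma - 1.0) * Qb(i + 1, j - 1);
        Qb(i, j) = w(i - 1, j - 1) * inner;
      }
      double acc = Qget(i, j - 1);
      for (int k = i; k <= j - min_hairpin - 1; ++k) {
        if (Qb(k, j) > 0) acc += Qget(i, k - 1) * Qb(k, j);
      }
      Q(i, j) = acc;
    }
  }
  const double Ztot = Qget(1, L);
  if (!std::isfinite(Ztot) || Ztot <= 0)
    stop("partition function overflow or underflow (Z not finite)");

  arma::mat OQ(L + 2, L + 2, arma::fill::zeros);
  arma::mat OQb(L + 2, L + 2, arma::fill::zeros);
  arma::mat P(L, L, arma::fill::zeros);
  if (L >= 1) OQ(1, L) = 1.0;

  for (int s = L; s >= 1; --s) {
    for (int i = 1; i + s - 1 <= L; ++i) {
      const int j = i + s - 1;
      const double oq = OQ(i, j);
      if (oq != 0.0) {
        if (j - 1 >= i) OQ(i, j - 1) += oq;
        for (int k = i; k <= j - min_hairpin - 1; ++k) {
          if (Qb(k, j) > 0) {
            if (k - 1 >= i) OQ(i, k - 1) += oq * Qb(k, j);
            OQb(k, j) += oq * Qget(i, k - 1);
          }
        }
      }
      if (Qb(i, j) > 0) {
        const double ob = OQb(i, j);
        if (ob != 0.0) {
          const double ww = w(i - 1, j - 1);
          if (j - 1 >= i + 1) {
            OQ(i + 1, j - 1) += ob * ww;
            OQb(i + 1, j - 1) += ob * ww * (sigma - 1.0);
          }
          double p = Qb(i, j) * ob / Ztot;
          if (p < 0) p = 0;            // guard tiny negative round-off
          if (p > 1) p = 1;
          P(i - 1, j - 1) = p;
          P(j - 1, i - 1) = p;
        }
      }
    }
  }
  return List::create(_["P"] = P, _["logQ"] = std::log(Ztot));
}

static inline double lse2(double a, double b) {
  if (a == R_NegInf) return b;
  if (b == R_NegInf) return a;
  double m = std::max(a, b);
  return m + std::log(std::exp(a - m) + std::exp(b - m));
}
static inline double lse3(double a, double b, double c) {
  return lse2(lse2(a, b), c);
}

// Pair-HMM posterior alignment probabilities (states M, X = insert in first
// sequence, Y = insert in second). logEmit holds the match-state emission
// log-odds per cell; gap states emit at log-odds 0. No X<->Y transitions.
// Returns the L1 x L2 posterior matrix of the match state.
// [[Rcpp::export]]
NumericMatrix c_hmm_posterior(const NumericMatrix& logEmit,
                              double delta, double eps) {
  const int L1 = logEmit.nrow(), L2 = logEmit.ncol();
  const double lMM = std::log(1.0 - 2.0 * delta);
  const double lMG = std::log(delta);
  const double lGG = std::log(eps);
  const double lGM = std::log(1.0 - eps);
  const double NI = R_NegInf;

  arma::mat FM(L1 + 1, L2 + 1), FX(L1 + 1, L2 + 1), FY(L1 + 1, L2 + 1);
  FM.fill(NI); FX.fill(NI); FY.fill(NI);
  FM(0, 0) = 0.0;  // virtual begin behaves like a match state
  for (int i = 0; i <= L1; ++i) {
    for (int k = 0; k <= L2; ++k) {
      if (i > 0 && k > 0) {
        double t = lse3(FM(i - 1, k - 1) + lMM,
                        FX(i - 1, k - 1) + lGM,
                        FY(i - 1, k - 1) + lGM);
        FM(i, k) = t + logEmit(i - 1, k - 1);
      }
      if (i > 0) {
        FX(i, k) = lse2(FM(i - 1, k) + lMG, FX(i - 1, k) + lGG);
      }
      if (k > 0) {
        FY(i, k) = lse2(FM(i, k - 1) + lMG, FY(i, k - 1) + lGG);
      }
    }
  }
  const double logZ = lse3(FM(L1, L2), FX(L1, L2), FY(L1, L2));
  if (!std::isfinite(logZ)) stop("alignment likelihood is zero");

  arma::mat BM(L1 + 1, L2 + 1), BX(L1 + 1, L2 + 1), BY(L1 + 1, L2 + 1);
  BM.fill(NI); BX.fill(NI); BY.fill(NI);
  BM(L1, L2) = 0.0; BX(L1, L2) = 0.0; BY(L1, L2) = 0.0;
  for (int i = L1; i >= 0; --i) {
    for (int k = L2; k >= 0; --k) {
      if (i == L1 && k == L2) continue;
      double em = (i < L1 && k < L2) ? logEmit(i, k) + BM(i + 1, k + 1) : NI;
      double bx = (i < L1) ? BX(i + 1, k) : NI;
      double by = (k < L2) ? BY(i, k + 1) : NI;
      BM(i, k) = lse3((em == NI ? NI : em + lMM),
                      (bx == NI ? NI : bx + lMG),
                      (by == NI ? NI : by + lMG));
      BX(i, k) = lse2((em == NI ? NI : em + lGM),
                      (bx == NI ? NI : bx + lGG));
      BY(i, k) = lse2((em == NI ? NI : em + lGM),
                      (by == NI ? NI : by + lGG));
    }
  }

  NumericMatrix post(L1, L2);
  for (int i = 1; i <= L1; ++i)
    for (int k = 1; k <= L2; ++k) {
      double lp = FM(i, k) + BM(i, k) - logZ;
      double p = (lp == NI) ? 0.0 : std::exp(lp);
      if (p > 1.0) p = 1.0;
      post(i - 1, k - 1) = p;
    }
  return post;
}

// Maximum expected accuracy structure: maximize
//   sum_{pairs} 2*gamma*P(i,j) + sum_{unpaired} q(i)
// over pseudoknot-free structures respecting the hairpin minimum. Ties prefer
// leaving positions unpaired, then the smallest 5' index, then smallest 3'.
// [[Rcpp::export]]
IntegerMatrix c_mea(const arma::mat& P, const arma::vec& q, double gamma,
                    int min_hairpin) {
  const int L = P.n_rows;
  arma::mat M(L + 2, L + 2, arma::fill::zeros);
  auto Mget = [&](int i, int j) -> double { return (j < i) ? 0.0 : M(i, j); };
  const double tol = 1e-12;

  for (int s = 1; s <= L; ++s) {
    for (int i = 1; i + s - 1 <= L; ++i) {
      const int j = i + s - 1;
      double best = Mget(i, j - 1) + q(j - 1);
      for (int k = i; k <= j - min_hairpin - 1; ++k) {
        if (P(k - 1, j - 1) <= 0) continue;
        double v = Mget(i, k - 1) + 2.0 * gamma * P(k - 1, j - 1) +
                   Mget(k + 1, j - 1);
        if (v > best + tol) best = v;
      }
      M(i, j) = best;
    }
  }

  std::vector<std::pair<int, int>> stack_, pairs;
  if (L >= 1) stack_.push_back({1, L});
  while (!stack_.empty()) {
    int i = stack_.back().first, j = stack_.back().second;
    stack_.pop_back();
    if (j < i) continue;
    const double target = M(i, j);
    // prefer the unpaired decomposition on ties
    if (std::fabs(Mget(i, j - 1) + q(j - 1) - target) <= tol) {
      stack_.push_back({i, j - 1});
      continue;
    }
    int hit = -1;
    for (int k = i; k <= j - min_hairpin - 1; ++k) {
      if (P(k - 1, j - 1) <= 0) continue;
      double v = Mget(i, k - 1) + 2.0 * gamma * P(k - 1, j - 1) +
                 Mget(k + 1, j - 1);
      if (std::fabs(v - target) <= tol) { hit = k; break; }
    }
    if (hit < 0) stop("MEA traceback failed");  // should be unreachable
    pairs.push_back({hit, j});
    stack_.push_back({i, hit - 1});
    stack_.push_back({hit + 1, j - 1});
  }
  std::sort(pairs.begin(), pairs.end());
  IntegerMatrix out(pairs.size(), 2);
  for (size_t r = 0; r < pairs.size(); ++r) {
    out(r, 0) = pairs[r].first;
    out(r, 1) = pairs[r].second;
  }
  return out;
}

// Global alignment of two profiles given a column-vs-column score matrix;
// gaps score 0 (posterior-sum objective). Returns per-alignment-column source
// columns (0 = gap) for each profile. Tie order: diagonal, up, left.
// [[Rcpp::export]]
List c_nw(const arma::mat& S) {
  const int A = S.n_rows, B = S.n_cols;
  arma::mat M(A + 1, B + 1, arma::fill::zeros);
  for (int a = 1; a <= A; ++a)
    for (int b = 1; b <= B; ++b) {
      double d = M(a - 1, b - 1) + S(a - 1, b - 1);
      double u = M(a - 1, b);
      double l = M(a, b - 1);
      M(a, b) = std::max(d, std::max(u, l));
    }
  std::vector<int> ca, cb;
  int a = A, b = B;
  const double tol = 1e-12;
  while (a > 0 || b > 0) {
    if (a > 0 && b > 0 &&
        std::fabs(M(a, b) - (M(a - 1, b - 1) + S(a - 1, b - 1))) <= tol) {
      ca.push_back(a); cb.push_back(b); --a; --b;
    } else if (a > 0 && std::fabs(M(a, b) - M(a - 1, b)) <= tol) {
      ca.push_back(a); cb.push_back(0); --a;
    } else {
      ca.push_back(0); cb.push_back(b); --b;
    }
  }
  std::reverse(ca.begin(), ca.end());
  std::reverse(cb.begin(), cb.end());
  return List::create(_["a"] = wrap(ca), _["b"] = wrap(cb));
}
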
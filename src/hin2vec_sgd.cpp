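#include <Rcpp.h>
#include <random>
#include <algorithm>
#include <cmath>
using namespace Rcpp;

// Stochastic gradient descent on the meta-path embedding objective.
//
// Per tuple (a, b, z, R):
//   s = sum_j WA(a,j) * WA(b,j) * f01(WZ(z,j))
//   P = sigmoid(s)
//   loss = -(R log P + (1-R) log(1-P)),  dloss/ds = P - R
// with f01 either the logistic map (smooth) or a hard clip into
// [1e-6, 1-1e-6] (subgradient 1 inside the band, 0 outside).
//
// The matrices arrive transposed (d x N / d x |Z|) so each vector is a
// contiguous column; they are modified in place (the caller allocates
// fresh copies). Tuples are shuffled each epoch with a dedicated Mersenne
// Twister so the trajectory is reproducible independently of R's RNG.
// [[Rcpp::export]]
List hin2vec_sgd(NumericMatrix WAt, NumericMatrix WZt,
                 IntegerVector a, IntegerVector b, IntegerVector z,
                 IntegerVector label, int epochs, double lr,
                 int seed, int f01_clip) {
  const int n = a.size();
  const int d = WAt.nrow();
  if (b.size() != n || z.size() != n || label.size() != n)
    stop("tuple columns have inconsistent lengths");
  if (WZt.nrow() != d) stop("dimension mismatch between WA and WZ");

  double *A = WAt.begin();
  double *Z = WZt.begin();
  std::vector<int> order(n);
  for (int i = 0; i < n; ++i) order[i] = i;
  std::mt19937 rng(static_cast<unsigned int>(seed));

  NumericVector epochLoss(epochs);
  std::vector<double> ca(d), cb(d), fz(d), dfz(d);

  for (int e = 0; e < epochs; ++e) {
    std::shuffle(order.begin(), order.end(), rng);
    double total = 0.0;
    for (int t = 0; t < n; ++t) {
      const int i = order[t];
      double *pa = A + static_cast<size_t>(a[i]) * d;
      double *pb = A + static_cast<size_t>(b[i]) * d;
      double *pz = Z + static_cast<size_t>(z[i]) * d;
      const int R = label[i];
      double s = 0.0;
      for (int j = 0; j < d; ++j) {
        ca[j] = pa[j];
        cb[j] = pb[j];
        const double zz = pz[j];
        if (f01_clip) {
          if (zz < 1e-6)            { fz[j] = 1e-6;       dfz[j] = 0.0; }
          else if (zz > 1.0 - 1e-6) { fz[j] = 1.0 - 1e-6; dfz[j] = 0.0; }
          else                      { fz[j] = zz;         dfz[j] = 1.0; }
        } else {
          const double f = 1.0 / (1.0 + std::exp(-zz));
          fz[j] = f;
          dfz[j] = f * (1.0 - f);
        }
        s += ca[j] * cb[j] * fz[j];
      }
      const double P = 1.0 / (1.0 + std::exp(-s));
      const double Pc = std::min(std::max(P, 1e-12), 1.0 - 1e-12);
      total += R ? -std::log(Pc) : -std::log(1.0 - Pc);
      const double g = lr * (P - static_cast<double>(R));
      for (int j = 0; j < d; ++j) {
        pa[j] -= g * cb[j] * fz[j];
        pb[j] -= g * ca[j] * fz[j];
        pz[j] -= g * ca[j] * cb[j] * dfz[j];
      }
    }
    if (!std::isfinite(total))
      stop("non-finite training loss at epoch %d", e + 1);
    epochLoss[e] = total / n;
  }
  return List::create(_["nodes"] = WAt, _["relations"] = WZt,
                      _["loss"] = epochLoss);
}
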
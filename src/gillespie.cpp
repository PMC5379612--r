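#include <Rcpp.h>
using namespace Rcpp;

// Exact event-driven simulation of the linear birth-death-immigration chain
// (up-rate kappa + n*lambda, down-rate n*mu) along one branch of length t,
// for a vector of independent start states. Uses R's RNG so results are
// reproducible under set.seed().
// [[Rcpp::export]]
IntegerVector simulateBdiEdgeCpp(IntegerVector start, double t, double kappa,
                                 double lambda, double mu) {
  int R = start.size();
  IntegerVector out(R);
  for (int r = 0; r < R; ++r) {
    double time = 0.0;
    long n = start[r];
    for (;;) {
      double up = kappa + n * lambda;
      double down = n * mu;
      double tot = up + down;
      if (tot <= 0.0) break;  // absorbing (kappa = 0, n = 0)
      time += R::exp_rand() / tot;
      if (time > t) break;
      if (R::unif_rand() * tot < up) ++n; else --n;
    }
    out[r] = (int)n;
  }
  return out;
}
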